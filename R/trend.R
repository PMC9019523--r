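## Trend analysis: log-linear regression of per-species mean PD
## contributions on time or discovery count, per-order accumulation
## summaries, decade-by-order fraction matrices, most-distinctive
## discoveries per decade, and the recent per-discovery PD increment.

#' Fit the log-linear decline in per-species PD contributions
#'
#' Ordinary least squares of `log(mean contribution)` on either the
#' description year or the discovery count (one point per species).
#' The per-unit percent decline is `100 * (1 - exp(slope))` — the
#' multiplicative reading "percent lower than the previous unit's value"
#' — with its standard error by the delta method,
#' `100 * exp(slope) * SE(slope)`.
#'
#' For `x = "count"` the explanatory variable is the discovery rank;
#' species sharing a year get their average rank, which equals the
#' expected rank under uniform within-year randomization.
#'
#' @param contribs A `contribution_table` (or any data frame with
#'   columns `year` and `mean_pd`).
#' @param x `"year"` or `"count"`.
#' @param from_x Optional lower cutoff: only species with `x >= from_x`
#'   enter the fit (e.g. `from_x = 1780` to exclude the initial burst of
#'   Linnaean-era descriptions).
#' @return A `trend_fit` list: `slope`, `slope_se`, `intercept`,
#'   `percent_decline`, `percent_decline_se`, `x_variable`, `from_x`,
#'   `n_points`, `r_squared`.
#' @export
fit_decline <- function(contribs, x = c("year", "count"), from_x = NULL) {
  x <- match.arg(x)
  stopifnot(all(c("year", "mean_pd") %in% names(contribs)))
  xv <- if (x == "year") as.numeric(contribs$year)
        else rank(contribs$year, ties.method = "average")
  keep <- contribs$mean_pd > 0
  if (!is.null(from_x)) keep <- keep & xv >= from_x
  xv <- xv[keep]
  yv <- log(contribs$mean_pd[keep])
  if (length(xv) < 3L)
    stop("need at least 3 species at or after from_x to fit a trend",
         call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  co <- summary(fit)$coefficients
  slope <- co["xv", "Estimate"]
  se <- co["xv", "Std. Error"]
  structure(list(slope = slope, slope_se = se,
                 intercept = co["(Intercept)", "Estimate"],
                 percent_decline = 100 * (1 - exp(slope)),
                 percent_decline_se = 100 * exp(slope) * se,
                 x_variable = x, from_x = from_x,
                 n_points = length(xv),
                 r_squared = summary(fit)$r.squared),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Log-linear decline of PD contributions on %s%s:\n", x$x_variable,
    if (is.null(x$from_x)) "" else sprintf(" (from %s onwards)", x$from_x)))
  cat(sprintf("  slope %.6g (SE %.3g), n = %d, R^2 = %.3f\n",
              x$slope, x$slope_se, x$n_points, x$r_squared))
  cat(sprintf("  decline per unit: %.4g%% (SE %.3g%%)\n",
              x$percent_decline, x$percent_decline_se))
  invisible(x)
}

#' Per-order accumulation curves
#'
#' Groups species' mean contributions by taxonomic order and builds, for
#' each order, the cumulative known-PD and species-richness curves over
#' its own discovery years, both raw and normalized by the order's final
#' totals.
#'
#' @param contribs A `contribution_table` (columns `order`, `year`,
#'   `mean_pd`).
#' @return A data frame with columns `order`, `year`, `pd_cum`,
#'   `pd_frac`, `rich_cum`, `rich_frac` (one row per order x discovery
#'   year).
#' @export
per_order_curves <- function(contribs) {
  stopifnot(all(c("order", "year", "mean_pd") %in% names(contribs)))
  if (anyNA(contribs$order))
    stop("every species needs an order label", call. = FALSE)
  pieces <- lapply(split(contribs, contribs$order), function(d) {
    yrs <- sort(unique(d$year))
    g <- match(d$year, yrs)
    pd <- cumsum(rowsum(d$mean_pd, g)[, 1])
    rich <- cumsum(tabulate(g, nbins = length(yrs)))
    data.frame(order = d$order[1], year = yrs,
               pd_cum = pd, pd_frac = pd / pd[length(pd)],
               rich_cum = rich, rich_frac = rich / rich[length(rich)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.decade_of <- function(year, decade_start = 1750, width = 10) {
  decade_start + width * floor((year - decade_start) / width)
}

#' Decade-by-order fractions of new and cumulative known PD
#'
#' Entry (d, o) of the `new_fraction` matrix is the summed mean
#' contribution of species of order o described in decade d, divided by
#' the decade's total across orders; `cumulative_fraction` divides the
#' running per-order cumulative totals by the running grand total.
#' Decades are calendar decades starting at `decade_start` (default
#' 1750); a final partial decade is kept as-is.
#'
#' @param contribs A `contribution_table`.
#' @param decade_start First decade boundary.
#' @return A list of matrices (rows = decades with at least one
#'   discovery for `new_fraction`; all decades for the others):
#'   `new_fraction`, `cumulative_fraction`, `new_pd`.
#' @export
decade_fractions <- function(contribs, decade_start = 1750) {
  stopifnot(all(c("order", "year", "mean_pd") %in% names(contribs)))
  dec <- .decade_of(contribs$year, decade_start)
  decades <- seq(min(dec), max(dec), by = 10)
  orders <- sort(unique(contribs$order))
  new_pd <- matrix(0, length(decades), length(orders),
                   dimnames = list(decades, orders))
  agg <- stats::aggregate(contribs$mean_pd,
                          by = list(dec = dec, ord = contribs$order), sum)
  new_pd[cbind(match(agg$dec, decades), match(agg$ord, orders))] <- agg$x
  rs <- rowSums(new_pd)
  new_fraction <- sweep(new_pd[rs > 0, , drop = FALSE], 1, rs[rs > 0], "/")
  cum_pd <- apply(new_pd, 2, cumsum)
  cum_pd <- matrix(cum_pd, nrow = length(decades),
                   dimnames = dimnames(new_pd))
  cumulative_fraction <- sweep(cum_pd, 1, rowSums(cum_pd), "/")
  list(new_fraction = new_fraction,
       cumulative_fraction = cumulative_fraction,
       new_pd = new_pd)
}

#' Most distinctive species discovery in each decade
#'
#' The species with the highest mean PD contribution among those
#' described in each decade; ties are broken by earlier description
#' year, then lexicographic species name.
#'
#' @param contribs A `contribution_table`.
#' @param decade_start First decade boundary.
#' @return A data frame with columns `decade`, `species`, `year`,
#'   `contribution`.
#' @export
distinctive_per_decade <- function(contribs, decade_start = 1750) {
  dec <- .decade_of(contribs$year, decade_start)
  pieces <- lapply(split(seq_len(nrow(contribs)), dec), function(i) {
    d <- contribs[i, , drop = FALSE]
    d <- d[order(-d$mean_pd, d$year, d$species), , drop = FALSE]
    data.frame(decade = .decade_of(d$year[1], decade_start),
               species = d$species[1], year = d$year[1],
               contribution = d$mean_pd[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$decade), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recent per-discovery PD increment
#'
#' Mean of the per-species mean contributions over the trailing window
#' of description years — an estimate of the asymptotic PD added per new
#' discovery (the minimum divergence a newly recognized species tends to
#' carry).
#'
#' @param contribs A `contribution_table`.
#' @param window_years Width of the trailing window (years), counted
#'   back from the latest description year.
#' @return Mean contribution (Myr) over the window.
#' @export
recent_increment <- function(contribs, window_years = 50) {
  stopifnot(window_years >= 1)
  if (!nrow(contribs))
    stop("no species described within the trailing window", call. = FALSE)
  cutoff <- max(contribs$year) - window_years + 1
  sel <- contribs$year >= cutoff
  if (!any(sel))
    stop("no species described within the trailing window", call. = FALSE)
  mean(contribs$mean_pd[sel])
}
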