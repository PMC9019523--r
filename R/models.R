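## Counterfactual discovery orders: a null model that uniformly permutes
## which species carries which description year (preserving the
## historical tempo of descriptions), order reversal, and pointwise
## observed-minus-reference difference curves.

#' Null model: fully randomized discovery order
#'
#' Reruns the accumulation analysis after randomizing the sequence of
#' species discovery: in each randomization the observed multiset of
#' description years is reassigned to species uniformly at random (year
#' labels permuted, remaining ties broken at random), so each
#' randomization is a uniform permutation of all species while the time
#' axis stays comparable to the observed record.
#'
#' @param trees A `phylo` or list of `phylo` trees.
#' @param table Species table (`species`, `order`, `family`, `year`).
#' @param n_rand Number of randomizations per tree.
#' @param seed Master seed.
#' @return A `null_ensemble`: list with `curve_year` and `curve_count`
#'   (`pd_curve` objects summarizing mean and 95% quantile envelope
#'   across randomizations) and `n_rand`.
#' @export
null_model <- function(trees, table, n_rand = 100, seed = NULL) {
  stopifnot(n_rand >= 1)
  .validate_species_table(table)
  if (inherits(trees, "phylo")) trees <- list(trees)
  n <- nrow(table)
  seeds <- .replicate_seeds(seed, length(trees) * n_rand)
  grid_year <- sort(unique(table$year))
  Cy <- matrix(NA_real_, length(grid_year), length(trees) * n_rand)
  Cc <- matrix(NA_real_, n, length(trees) * n_rand)
  tot <- numeric(length(trees) * n_rand)
  k <- 0L
  for (tr in trees) {
    .match_tips(tr, table$species)
    for (j in seq_len(n_rand)) {
      k <- k + 1L
      set.seed(seeds[k])
      yr <- sample(table$year)  # permute year labels across species
      o <- order(yr, stats::runif(n))
      contrib <- contribution_sequence(tr, table$species[o])
      Cc[, k] <- cumsum(contrib)
      g <- match(sort(yr), grid_year)  # years of the ordered discoveries
      Cy[, k] <- cumsum(rowsum(contrib, g)[, 1])[
        match(grid_year, sort(unique(yr)))]
      tot[k] <- sum(contrib)
    }
  }
  mk_curve <- function(C, grid, richness) {
    Frac <- sweep(C, 2, tot, "/")
    s <- .curve_summary(C)
    f <- .curve_summary(Frac)
    out <- data.frame(x = grid, pd = s$mean, pd_lo = s$lo, pd_hi = s$hi,
                      frac = f$mean, frac_lo = f$lo, frac_hi = f$hi,
                      richness = richness, richness_frac = richness / n)
    attr(out, "replicates") <- C
    attr(out, "total_pd") <- mean(tot)
    class(out) <- c("pd_curve", "data.frame")
    out
  }
  rich_year <- cumsum(tabulate(match(table$year, grid_year),
                               nbins = length(grid_year)))
  cy <- mk_curve(Cy, grid_year, rich_year)
  attr(cy, "axis") <- "year"
  cc <- mk_curve(Cc, seq_len(n), seq_len(n))
  attr(cc, "axis") <- "count"
  structure(list(curve_year = cy, curve_count = cc, n_rand = n_rand),
            class = "null_ensemble")
}

#' Accumulation curve under reversed discovery order
#'
#' Treats the most recently described species as the first discovery and
#' so on backwards; within-year ties are still randomized. The curve is
#' indexed by discovery count.
#'
#' @param trees A `phylo` or list of `phylo` trees.
#' @param table Species table.
#' @param n_perm Number of within-year randomizations per tree.
#' @param seed Master seed.
#' @return A count-axis `pd_curve`.
#' @export
reversed_order <- function(trees, table, n_perm = 100, seed = NULL) {
  .validate_species_table(table)
  rep <- .contribution_replicates(trees, table, n_perm, seed,
                                  key = -table$year)
  M <- rep$contrib; R <- rep$rank
  n <- nrow(M)
  C <- vapply(seq_len(ncol(M)), function(r)
    cumsum(M[order(R[, r]), r]), numeric(n))
  C <- matrix(C, nrow = n)
  tot <- colSums(M)
  Frac <- sweep(C, 2, tot, "/")
  s <- .curve_summary(C)
  f <- .curve_summary(Frac)
  out <- data.frame(x = seq_len(n), pd = s$mean, pd_lo = s$lo, pd_hi = s$hi,
                    frac = f$mean, frac_lo = f$lo, frac_hi = f$hi,
                    richness = seq_len(n), richness_frac = seq_len(n) / n)
  attr(out, "axis") <- "count"
  attr(out, "replicates") <- C
  attr(out, "total_pd") <- mean(tot)
  class(out) <- c("pd_curve", "data.frame")
  out
}

#' Pointwise difference between two accumulation curves
#'
#' Computes observed minus reference, pointwise on the observed grid
#' (the reference is carried onto that grid by stepwise-constant
#' interpolation, cumulative curves being step functions). When both
#' curves carry replicate matrices on an identical grid, the 95%
#' envelope is taken over replicate-level differences (replicates paired
#' cyclically); otherwise the envelope is `NA`.
#'
#' @param observed,reference `pd_curve` objects sharing the same axis.
#' @return A data frame with columns `x`, `diff`, `diff_lo`, `diff_hi`,
#'   `frac_diff` (difference of cumulative fractions), of class
#'   `pd_difference`.
#' @export
difference_curve <- function(observed, reference) {
  stopifnot(inherits(observed, "pd_curve"), inherits(reference, "pd_curve"))
  if (!identical(attr(observed, "axis"), attr(reference, "axis")))
    stop("curves must share the same axis (year or count)", call. = FALSE)
  step_interp <- function(x, y, xout)
    stats::approx(x, y, xout = xout, method = "constant", f = 0,
                  yleft = 0, yright = y[length(y)])$y
  ref_pd <- step_interp(reference$x, reference$pd, observed$x)
  ref_frac <- step_interp(reference$x, reference$frac, observed$x)
  d <- observed$pd - ref_pd
  lo <- hi <- rep(NA_real_, length(d))
  Mo <- attr(observed, "replicates")
  Mr <- attr(reference, "replicates")
  if (!is.null(Mo) && !is.null(Mr) &&
      isTRUE(all.equal(observed$x, reference$x))) {
    np <- max(ncol(Mo), ncol(Mr))
    D <- vapply(seq_len(np), function(i)
      Mo[, ((i - 1L) %% ncol(Mo)) + 1L] - Mr[, ((i - 1L) %% ncol(Mr)) + 1L],
      numeric(nrow(Mo)))
    D <- matrix(D, nrow = nrow(Mo))
    lo <- apply(D, 1, stats::quantile, 0.025, names = FALSE)
    hi <- apply(D, 1, stats::quantile, 0.975, names = FALSE)
  }
  out <- data.frame(x = observed$x, diff = d, diff_lo = lo, diff_hi = hi,
                    frac_diff = observed$frac - ref_frac)
  attr(out, "axis") <- attr(observed, "axis")
  class(out) <- c("pd_difference", "data.frame")
  out
}
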