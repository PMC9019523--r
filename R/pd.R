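## Known-PD accumulation: total PD, marginal per-species contributions
## under a given discovery order, averaging over randomized within-year
## orders, accumulation curves and milestone years.
##
## The marginal contribution of a species is the reduction in total PD
## when it is removed from the tree containing only it and
## earlier-discovered species; equivalently (forward view) the path from
## its tip to its attachment point on the subtree spanned by previously
## discovered species plus the root.  The forward view gives an O(n)
## edge-marking algorithm per discovery order: walk from each newly
## discovered tip toward the root, crediting every not-yet-seen edge to
## that species and stopping at the first seen node.  Contributions then
## sum to total PD exactly, because every edge is credited exactly once.

#' Total phylogenetic diversity of a tree
#'
#' Faith's PD in the strict sense: the sum of all branch lengths. The
#' root, having no edge, contributes nothing.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Total PD in the tree's branch-length units (Myr here).
#' @export
total_pd <- function(tree) {
  .check_phylo(tree)
  sum(tree$edge.length)
}

#' Marginal PD contributions along one discovery order
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param order Character vector: a permutation of the tip labels in
#'   discovery order (earliest first).
#' @return Named numeric vector of contributions (Myr), in discovery
#'   order; the first species is credited its full root-to-tip path, and
#'   the contributions sum exactly to [total_pd()].
#' @export
contribution_sequence <- function(tree, order) {
  .check_phylo(tree)
  n <- ape::Ntip(tree)
  idx <- match(order, tree$tip.label)
  if (anyNA(idx) || length(idx) != n || anyDuplicated(idx))
    stop("'order' must be a permutation of the tree's tip labels",
         call. = FALSE)
  nnode <- n + tree$Nnode
  parent <- integer(nnode)
  elen <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  seen <- logical(nnode)
  seen[n + 1L] <- TRUE  # root
  contrib <- numeric(n)
  for (k in seq_len(n)) {
    v <- idx[k]
    s <- 0
    while (!seen[v]) {
      s <- s + elen[v]
      seen[v] <- TRUE
      v <- parent[v]
    }
    contrib[k] <- s
  }
  names(contrib) <- order
  contrib
}

## Shared replicate engine.  `key` orders discoveries (ties broken
## uniformly at random per replicate); rows of the returned matrices are
## aligned with `table`, columns are (tree x permutation) replicates.
.contribution_replicates <- function(trees, table, n_perm, seed,
                                     key = table$year) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n <- nrow(table)
  n_rep <- length(trees) * n_perm
  seeds <- .replicate_seeds(seed, n_rep)
  M <- matrix(NA_real_, n, n_rep)
  R <- matrix(NA_integer_, n, n_rep)
  k <- 0L
  for (tr in trees) {
    tip_idx <- .match_tips(tr, table$species)
    if (length(tip_idx) != n)
      stop("tree has ", ape::Ntip(tr), " tips but the species table has ",
           n, " rows", call. = FALSE)
    tip_of_row <- character(n)
    tip_of_row[tip_idx] <- tr$tip.label  # table row -> this tree's label
    for (j in seq_len(n_perm)) {
      k <- k + 1L
      set.seed(seeds[k])
      o <- order(key, stats::runif(n))
      contrib <- contribution_sequence(tr, tip_of_row[o])
      M[o, k] <- contrib
      R[o, k] <- seq_len(n)
    }
  }
  list(contrib = M, rank = R,
       total = vapply(trees, total_pd, 0))
}

#' Mean marginal PD contributions over randomized within-year orders
#'
#' Species are removed latest-described first; species sharing a
#' description year are removed in uniformly random order, independently
#' in each of `n_perm` permutations per tree. Each species's mean
#' contribution and empirical 95% interval are taken across all
#' (tree x permutation) replicates.
#'
#' @param trees A `phylo` or list of `phylo` trees sharing the same tip
#'   set (e.g. donor samples from [run_merge()]).
#' @param table Species table: data frame with columns `species`,
#'   `order`, `family`, `year` covering every tip.
#' @param n_perm Number of within-year randomizations per tree.
#' @param seed Master seed; per-replicate streams are derived from it so
#'   results are reproducible.
#' @return A `contribution_table`: data frame with columns `species`,
#'   `order`, `family`, `year`, `mean_pd`, `lo95`, `hi95`,
#'   `n_replicates`, carrying the replicate contribution and rank
#'   matrices as attributes for downstream curve construction.
#' @export
mean_contributions <- function(trees, table, n_perm = 100, seed = NULL) {
  stopifnot(n_perm >= 1)
  .validate_species_table(table)
  if (anyNA(table$year))
    stop("every species must have a discovery year", call. = FALSE)
  rep <- .contribution_replicates(trees, table, n_perm, seed)
  M <- rep$contrib
  out <- data.frame(species = table$species, order = table$order,
                    family = table$family, year = table$year,
                    mean_pd = rowMeans(M),
                    lo95 = apply(M, 1, stats::quantile, 0.025, names = FALSE),
                    hi95 = apply(M, 1, stats::quantile, 0.975, names = FALSE),
                    n_replicates = ncol(M),
                    stringsAsFactors = FALSE)
  attr(out, "replicates") <- M
  attr(out, "ranks") <- rep$rank
  attr(out, "total_pd") <- rep$total
  class(out) <- c("contribution_table", "data.frame")
  out
}

## Summaries (mean, 2.5%, 97.5%) across the columns of a replicate
## cumulative matrix.
.curve_summary <- function(C) {
  list(mean = rowMeans(C),
       lo = apply(C, 1, stats::quantile, 0.025, names = FALSE),
       hi = apply(C, 1, stats::quantile, 0.975, names = FALSE))
}

#' Accumulation curve of known PD
#'
#' Builds the cumulative known-PD curve, either over calendar years
#' (cumulative contribution of all species described up to each year) or
#' over successive discoveries (cumulative contribution by discovery
#' rank), with an empirical 95% envelope across replicates and the
#' matching species-richness series.
#'
#' @param contribs A `contribution_table` from [mean_contributions()].
#' @param axis `"year"` or `"count"`.
#' @return A `pd_curve`: data frame with columns `x`, `pd`, `pd_lo`,
#'   `pd_hi`, `frac`, `frac_lo`, `frac_hi`, `richness`, `richness_frac`;
#'   the per-replicate cumulative matrix is kept as an attribute.
#' @export
accumulation_curve <- function(contribs, axis = c("year", "count")) {
  axis <- match.arg(axis)
  M <- attr(contribs, "replicates")
  R <- attr(contribs, "ranks")
  if (is.null(M))
    stop("'contribs' lacks replicate data; use mean_contributions()",
         call. = FALSE)
  n <- nrow(M)
  tot <- colSums(M)  # per-replicate total PD (exact by conservation)
  if (axis == "year") {
    grid <- sort(unique(contribs$year))
    g <- match(contribs$year, grid)
    C <- apply(M, 2, function(col) cumsum(rowsum(col, g)[, 1]))
    C <- matrix(C, nrow = length(grid))
    richness <- cumsum(tabulate(g, nbins = length(grid)))
  } else {
    grid <- seq_len(n)
    C <- vapply(seq_len(ncol(M)), function(r)
      cumsum(M[order(R[, r]), r]), numeric(n))
    C <- matrix(C, nrow = n)
    richness <- grid
  }
  Frac <- sweep(C, 2, tot, "/")
  s <- .curve_summary(C)
  f <- .curve_summary(Frac)
  out <- data.frame(x = grid, pd = s$mean, pd_lo = s$lo, pd_hi = s$hi,
                    frac = f$mean, frac_lo = f$lo, frac_hi = f$hi,
                    richness = richness, richness_frac = richness / n)
  attr(out, "axis") <- axis
  attr(out, "replicates") <- C
  attr(out, "total_pd") <- mean(tot)
  class(out) <- c("pd_curve", "data.frame")
  out
}

#' Year (or rank) at which a fraction of present-day diversity was known
#'
#' @param curve A `pd_curve` from [accumulation_curve()].
#' @param fraction Target fraction in (0, 1), e.g. 0.5 for the halfway
#'   milestone.
#' @param measure `"pd"` (cumulative mean fraction of known PD) or
#'   `"richness"`.
#' @return The earliest grid value (year or discovery count) whose
#'   cumulative mean fraction reaches `fraction`.
#' @export
milestone_year <- function(curve, fraction = 0.5,
                           measure = c("pd", "richness")) {
  measure <- match.arg(measure)
  stopifnot(inherits(curve, "pd_curve"), fraction > 0, fraction < 1)
  f <- if (measure == "pd") curve$frac else curve$richness_frac
  i <- which(f >= fraction)
  if (!length(i))
    stop("curve never reaches fraction ", fraction, call. = FALSE)
  curve$x[min(i)]
}
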