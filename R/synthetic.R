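## Synthetic-data generator: birth-death time trees with a nested
## order/family taxonomy, discovery-year assignment (optionally biased
## toward evolutionarily distinct species), fixture sets for the supertree
## merge, and a direct log-linear contribution generator for trend tests.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator: a constant-rate
#' birth-death time tree conditioned on a fixed number of extant species,
#' a nested order/family taxonomy cut from the tree's oldest nodes, and a
#' discovery process spanning the era of formal taxonomy with a large
#' initial burst of descriptions and an optional bias toward
#' evolutionarily distinct species.
#'
#' @param n_species Number of extant species (tree tips).
#' @param birth_rate Speciation rate per lineage per Myr (> 0).
#' @param death_rate Extinction rate per lineage per Myr (>= 0).
#' @param n_orders Number of monophyletic orders to cut from the tree
#'   (<= `n_species`).
#' @param families_per_order Target number of families within each order
#'   (orders with fewer species get fewer families).
#' @param year_range Integer vector of length 2: first and last description
#'   year. Defaults to 1758-2013, the span of formal taxonomy covered by
#'   the avian discovery record this generator emulates.
#' @param initial_burst_fraction Proportion of species described in the
#'   first year (the Linnaean start), in `[0, 1)`.
#' @param distinctness_bias Strength of the preference for describing
#'   evolutionarily distinct species first; 0 gives a uniformly random
#'   discovery order. Sampling weights are `exp(bias * z)` where `z` is the
#'   standardized fair-proportion evolutionary distinctness.
#' @param decline_rate Per-year proportional decline used by
#'   [simulate_contributions()], the direct log-linear generator.
#' @param noise_sd Standard deviation of log-scale noise in
#'   [simulate_contributions()].
#' @param tree_age Root-to-tip depth of the simulated tree, Myr.
#' @param seed Optional integer seed; fixed seed gives byte-identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_tree()], [assign_discovery_years()],
#'   [simulate_source_trees()], [simulate_contributions()]
#' @export
sim_config <- function(n_species = 200, birth_rate = 0.1, death_rate = 0.03,
                       n_orders = 8, families_per_order = 3,
                       year_range = c(1758L, 2013L),
                       initial_burst_fraction = 0.1,
                       distinctness_bias = 0, decline_rate = 0.008,
                       noise_sd = 0.5, tree_age = 100, seed = NULL) {
  stopifnot(length(n_species) == 1L, n_species >= 1,
            n_species == as.integer(n_species))
  if (!is.finite(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be finite and > 0", call. = FALSE)
  if (!is.finite(death_rate) || death_rate < 0)
    stop("death_rate must be finite and >= 0", call. = FALSE)
  stopifnot(n_orders >= 1, n_orders <= n_species,
            families_per_order >= 1)
  if (length(year_range) != 2L || year_range[1] >= year_range[2])
    stop("year_range must be two integers with start < end", call. = FALSE)
  if (initial_burst_fraction < 0 || initial_burst_fraction >= 1)
    stop("initial_burst_fraction must be in [0, 1)", call. = FALSE)
  if (!is.finite(distinctness_bias) || distinctness_bias < 0)
    stop("distinctness_bias must be finite and >= 0", call. = FALSE)
  stopifnot(is.finite(decline_rate), is.finite(noise_sd), noise_sd >= 0,
            tree_age > 0)
  structure(list(n_species = as.integer(n_species), birth_rate = birth_rate,
                 death_rate = death_rate, n_orders = as.integer(n_orders),
                 families_per_order = as.integer(families_per_order),
                 year_range = as.integer(year_range),
                 initial_burst_fraction = initial_burst_fraction,
                 distinctness_bias = distinctness_bias,
                 decline_rate = decline_rate, noise_sd = noise_sd,
                 tree_age = tree_age, seed = seed),
            class = "sim_config")
}

## Split a clade into k monophyletic groups by repeatedly opening the
## oldest remaining internal node.  Returns a list of tip-index vectors.
.partition_clades <- function(phy, k) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  if (k <= 1L || n == 1L) return(list(seq_len(n)))
  k <- min(k, n)
  nd <- .node_depths(phy)
  groups <- root
  while (length(groups) < k) {
    ints <- groups[groups > n]
    if (!length(ints)) break
    v <- ints[which.min(nd[ints])]
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    groups <- c(groups[groups != v], ch)
  }
  lapply(groups, function(g) .clade_tips(phy, g))
}

#' Simulate a time-calibrated tree with a nested taxonomy
#'
#' Simulates a constant-rate birth-death tree conditioned on
#' `config$n_species` extant tips, rescales it so the root-to-tip depth is
#' `config$tree_age` Myr, and cuts it into monophyletic orders (at the
#' `n_orders - 1` oldest internal nodes) and families within orders.
#' The resulting tree is ultrametric with strictly positive branch
#' lengths; the taxonomy is attached as `attr(tree, "taxonomy")`, a data
#' frame with columns `species`, `order`, `family`.
#'
#' @param config A [sim_config()].
#' @return A rooted ultrametric `phylo` with `n_species` tips.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_species
  if (n == 1L) {
    phy <- .one_tip_phylo("sp0001", config$tree_age)
  } else {
    phy <- NULL
    for (try in seq_len(25L)) {
      phy <- tryCatch(
        ape::rphylo(n, birth = config$birth_rate, death = config$death_rate),
        error = function(e) NULL)
      if (!is.null(phy) && ape::Ntip(phy) == n &&
          all(phy$edge.length > 0)) break
      phy <- NULL
    }
    if (is.null(phy))
      stop("birth-death simulation failed to produce a valid ", n,
           "-tip tree after bounded retries (is birth_rate <= death_rate?)",
           call. = FALSE)
    phy$edge.length <- phy$edge.length *
      (config$tree_age / max(.node_depths(phy)[seq_len(n)]))
  }
  phy$tip.label <- sprintf("sp%04d", seq_len(n))
  ord_groups <- .partition_clades(phy, config$n_orders)
  ## stable order naming: by smallest tip index in each clade
  ord_groups <- ord_groups[order(vapply(ord_groups, min, 1L))]
  taxonomy <- data.frame(species = phy$tip.label,
                         order = NA_character_, family = NA_character_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(ord_groups)) {
    tips <- ord_groups[[i]]
    oname <- sprintf("Ord%02d", i)
    taxonomy$order[tips] <- oname
    if (length(tips) == 1L) {
      taxonomy$family[tips] <- sprintf("%s_f1", oname)
      next
    }
    sub <- ape::keep.tip(phy, tips)
    fam_groups <- .partition_clades(sub, config$families_per_order)
    for (j in seq_along(fam_groups)) {
      sp <- sub$tip.label[fam_groups[[j]]]
      taxonomy$family[match(sp, taxonomy$species)] <- sprintf("%s_f%d", oname, j)
    }
  }
  attr(phy, "taxonomy") <- taxonomy
  phy
}

#' Fair-proportion evolutionary distinctness
#'
#' Each branch's length is divided equally among the tips descending from
#' it; a tip's distinctness is the sum of its shares along its root-to-tip
#' path. Higher values mark species on long, sparsely shared branches.
#'
#' @param phy A rooted `phylo` with branch lengths.
#' @return Named numeric vector of fair-proportion scores, one per tip.
#' @export
fair_proportion <- function(phy) {
  .check_phylo(phy)
  n <- ape::Ntip(phy)
  nnode <- n + phy$Nnode
  ndesc <- integer(nnode)
  ndesc[seq_len(n)] <- 1L
  ## postorder accumulation of descendant-tip counts
  eo <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(eo$edge)))
    ndesc[eo$edge[i, 1]] <- ndesc[eo$edge[i, 1]] + ndesc[eo$edge[i, 2]]
  share <- numeric(nnode)  # cumulative share from root down to each node
  pre <- rev(seq_len(nrow(eo$edge)))
  for (i in pre) {
    p <- eo$edge[i, 1]; v <- eo$edge[i, 2]
    share[v] <- share[p] + eo$edge.length[i] / ndesc[v]
  }
  ed <- share[seq_len(n)]
  names(ed) <- phy$tip.label
  ed
}

#' Assign discovery years to the tips of a tree
#'
#' Emulates the historical structure of the species-description record:
#' a fraction of species is described in the first year (the initial
#' burst), and the rest receive years across the remaining range in an
#' order drawn by successive weighted sampling, with weight
#' `exp(distinctness_bias * z)` for standardized fair-proportion
#' distinctness `z`. With `distinctness_bias = 0` the discovery order is
#' an exchangeable uniform permutation; large bias makes distinct species
#' tend to be described early.
#'
#' @param tree A `phylo`, typically from [simulate_tree()].
#' @param config A [sim_config()].
#' @param taxonomy Optional data frame with columns `species`, `order`,
#'   `family`; defaults to `attr(tree, "taxonomy")`.
#' @return A species table: data frame with columns `species`, `order`,
#'   `family`, `year`.
#' @export
assign_discovery_years <- function(tree, config,
                                   taxonomy = attr(tree, "taxonomy")) {
  .check_phylo(tree)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- ape::Ntip(tree)
  if (is.null(taxonomy))
    taxonomy <- data.frame(species = tree$tip.label, order = "Ord01",
                           family = "Ord01_f1", stringsAsFactors = FALSE)
  ed <- fair_proportion(tree)
  z <- if (length(ed) > 1L && stats::sd(ed) > 0) {
    (ed - mean(ed)) / stats::sd(ed)
  } else {
    rep(0, n)
  }
  w <- exp(config$distinctness_bias * z)
  ord <- sample.int(n, n, prob = w)  # successive weighted draws, no replacement
  burst_n <- round(config$initial_burst_fraction * n)
  years <- integer(n)
  y0 <- config$year_range[1]; y1 <- config$year_range[2]
  if (burst_n > 0) years[ord[seq_len(burst_n)]] <- y0
  n_rest <- n - burst_n
  if (n_rest > 0) {
    pool <- sort(sample(seq(y0 + 1L, y1), n_rest, replace = TRUE))
    years[ord[seq(burst_n + 1L, n)]] <- pool
  }
  out <- taxonomy[match(tree$tip.label, taxonomy$species), , drop = FALSE]
  out$year <- years
  rownames(out) <- NULL
  out
}

#' Simulate a source-tree set for the supertree merge
#'
#' Builds a known "truth" tree plus the derived inputs the merge pipeline
#' consumes, so that running [run_merge()] on them should recover the
#' truth topology: an order-level backbone with one order deliberately
#' omitted (exercising missing-order placement), an order-level reference
#' tree on a different time scale (the ratio donor for the missing
#' order's stem), and one or more species-level donor trees whose branch
#' lengths are uniformly inflated (exercising rescaling), each containing
#' one species deliberately moved into the wrong order (exercising
#' non-monophyly repair) and one unrecognized tip (exercising taxonomy
#' reconciliation).
#'
#' @param config A [sim_config()] with `n_orders >= 3`.
#' @param n_donor_samples Number of species-level donor samples to emit.
#' @return A list with elements `truth`, `taxonomy`, `backbone`,
#'   `reference_orders`, `donors` (list of `phylo`), `misplaced`
#'   (data frame `species`, `true_family`), `omitted_order`,
#'   `sister_order`, and `plan` (a [merge_plan()] ready for
#'   [run_merge()]).
#' @export
simulate_source_trees <- function(config, n_donor_samples = 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_orders < 3L)
    stop("simulate_source_trees needs n_orders >= 3", call. = FALSE)
  truth <- simulate_tree(config)
  taxonomy <- attr(truth, "taxonomy")
  if (!is.null(config$seed)) set.seed(config$seed + 2L)

  orders <- sort(unique(taxonomy$order))
  ## order-level tree: one exemplar tip per order, relabeled to order names
  exemplar <- vapply(orders, function(o)
    taxonomy$species[taxonomy$order == o][1L], "")
  order_tree <- ape::keep.tip(truth, exemplar)
  order_tree$tip.label <-
    orders[match(order_tree$tip.label, exemplar)]

  ## crown age of each order in the truth tree (0 for single-species orders)
  tree_age <- max(.tip_depths(truth))
  crown_age <- vapply(orders, function(o) {
    sp <- taxonomy$species[taxonomy$order == o]
    if (length(sp) < 2L) return(0)
    tree_age - .node_depths(truth)[ape::getMRCA(truth, sp)]
  }, 0)

  ## order-level reference with STEM pendants (each order collapsed to a
  ## tip sitting at its crown), on a deliberately different time scale:
  ## only stem-length ratios carry over to the backbone
  reference_orders <- order_tree
  tip_edges <- match(seq_len(ape::Ntip(order_tree)),
                     reference_orders$edge[, 2])
  reference_orders$edge.length[tip_edges] <-
    reference_orders$edge.length[tip_edges] -
    crown_age[reference_orders$tip.label]
  reference_orders$edge.length <- reference_orders$edge.length * 0.7

  ## pick a cherry whose stem ratio (omitted / sister) is strictly < 1,
  ## so the omitted order can be re-inserted on the sister's stem edge
  stem_ref <- reference_orders$edge.length[tip_edges]
  names(stem_ref) <- reference_orders$tip.label
  cherry <- NULL
  n_ot <- ape::Ntip(order_tree)
  for (v in seq_len(n_ot)) {
    p <- order_tree$edge[order_tree$edge[, 2] == v, 1]
    sibs <- setdiff(order_tree$edge[order_tree$edge[, 1] == p, 2], v)
    if (length(sibs) == 1L && sibs <= n_ot) {
      a <- order_tree$tip.label[v]; b <- order_tree$tip.label[sibs]
      for (pair in list(c(a, b), c(b, a)))
        if (stem_ref[pair[1]] < 0.999 * stem_ref[pair[2]] &&
            is.null(cherry)) cherry <- pair
    }
    if (!is.null(cherry)) break
  }
  if (is.null(cherry))
    stop("no order-level cherry with an informative stem ratio; ",
         "try another seed", call. = FALSE)
  omitted <- cherry[1L]; sister <- cherry[2L]

  backbone <- ape::drop.tip(order_tree, omitted)

  ## misplaced species: from a family with >= 3 members, in an order that
  ## still keeps >= 2 species, moved into a different order's crown
  fam_sizes <- table(taxonomy$family)
  ord_sizes <- table(taxonomy$order)
  cand <- taxonomy[fam_sizes[taxonomy$family] >= 3 &
                     ord_sizes[taxonomy$order] >= 3, , drop = FALSE]
  if (!nrow(cand))
    stop("no family large enough to plant a misplaced species; ",
         "increase n_species", call. = FALSE)
  mis_sp <- cand$species[1L]
  mis_fam <- cand$family[1L]
  mis_ord <- cand$order[1L]
  host_ord <- setdiff(orders, c(mis_ord, omitted))[1L]
  host_sp <- taxonomy$species[taxonomy$order == host_ord]

  make_donor <- function(scale) {
    donor <- truth
    donor$edge.length <- donor$edge.length * scale
    ## move the misplaced tip into the host order's crown
    donor <- ape::drop.tip(donor, mis_sp)
    if (length(host_sp) >= 2L) {
      crown <- ape::getMRCA(donor, host_sp)
      age <- max(.tip_depths(donor)) - .node_depths(donor)[crown]
      donor <- ape::bind.tree(donor, .one_tip_phylo(mis_sp, age),
                              where = crown, position = 0)
    } else {
      host_tip <- which(donor$tip.label == host_sp[1L])
      len <- donor$edge.length[donor$edge[, 2] == host_tip]
      donor <- ape::bind.tree(donor, .one_tip_phylo(mis_sp, len / 2),
                              where = host_tip, position = len / 2)
    }
    ## one unrecognized tip (e.g. a subspecies) inside the host order
    crown2 <- ape::getMRCA(donor, c(host_sp, mis_sp))
    age2 <- max(.tip_depths(donor)) - .node_depths(donor)[crown2]
    donor <- ape::bind.tree(donor, .one_tip_phylo("sp_unrecognized", age2),
                            where = crown2, position = 0)
    donor
  }
  scales <- 1.3 + 0.2 * seq_len(n_donor_samples)
  donors <- lapply(scales, make_donor)

  misplaced <- data.frame(species = mis_sp, true_family = mis_fam,
                          stringsAsFactors = FALSE)
  plan <- merge_plan(
    backbone = "backbone",
    grafts = lapply(orders, function(o)
      list(donor = "species", group = o, level = "order")),
    missing = omitted,
    reference_a = "reference_orders",
    reference_b = "reference_orders")
  list(truth = truth, taxonomy = taxonomy, backbone = backbone,
       reference_orders = reference_orders, donors = donors,
       misplaced = misplaced, omitted_order = omitted,
       sister_order = sister, plan = plan)
}

#' Direct log-linear contribution generator
#'
#' Draws per-species PD contributions from the log-linear model
#' `log c = log c0 - r (t - t0) + eps`, `eps ~ Normal(0, noise_sd)`, with
#' description years uniform over `year_range`. This is the generating
#' process matched by [fit_decline()], used for parameter-recovery tests
#' of the trend regression without going through a tree.
#'
#' @param config A [sim_config()]; uses `n_species`, `year_range`,
#'   `decline_rate`, `noise_sd`, `seed`.
#' @param c0 Contribution (Myr) at the first year, before noise.
#' @return A data frame with columns `species`, `order`, `family`,
#'   `year`, `mean_pd`, usable by the trend-analysis functions.
#' @export
simulate_contributions <- function(config, c0 = 100) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_species
  years <- sort(sample(seq(config$year_range[1], config$year_range[2]),
                       n, replace = TRUE))
  eps <- stats::rnorm(n, 0, config$noise_sd)
  contrib <- c0 * exp(-config$decline_rate * (years - config$year_range[1]) + eps)
  data.frame(species = sprintf("sp%04d", seq_len(n)),
             order = "Ord01", family = "Ord01_f1",
             year = years, mean_pd = contrib,
             stringsAsFactors = FALSE)
}
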