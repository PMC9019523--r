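## Supertree assembly: clade extraction with its stem, branch-length
## rescaling, grafting into a backbone, placement of groups missing from
## the backbone, basal-polytomy repair of non-monophyletic families, and
## taxonomy reconciliation.  Clades travel with their stem edge stored in
## the phylo root.edge component.

#' Extract a clade together with its stem edge
#'
#' Returns the subtree spanning `taxa`, including the stem edge from the
#' group's most recent common ancestor to its parent (stored as
#' `root.edge`). The input tree is not modified. If `taxa` is not
#' monophyletic the intruding tips are named in the error.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param taxa Character vector of tip labels forming the clade.
#' @return A `phylo` whose `root.edge` carries the stem length (0 when
#'   `taxa` spans the whole tree).
#' @export
extract_clade <- function(tree, taxa) {
  .check_phylo(tree)
  taxa <- unique(taxa)
  if (!length(taxa)) stop("'taxa' is empty", call. = FALSE)
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss))
    stop("taxa not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  n <- ape::Ntip(tree)
  if (length(taxa) == n) {
    out <- tree
    out$root.edge <- 0
    return(out)
  }
  if (length(taxa) == 1L) {
    i <- which(tree$tip.label == taxa)
    out <- .one_tip_phylo(taxa, 0)
    out$root.edge <- tree$edge.length[tree$edge[, 2] == i]
    return(out)
  }
  mrca <- ape::getMRCA(tree, taxa)
  below <- tree$tip.label[.clade_tips(tree, mrca)]
  intruders <- setdiff(below, taxa)
  if (length(intruders))
    stop("taxa are not monophyletic; intruding tips: ",
         paste(intruders, collapse = ", "), call. = FALSE)
  out <- ape::extract.clade(tree, mrca)
  out$root.edge <- tree$edge.length[tree$edge[, 2] == mrca]
  out
}

#' Rescale a clade to a target stem-to-tip depth
#'
#' Multiplies every edge (and the stem) by
#' `target_depth / current stem-to-tip depth`, preserving all edge-length
#' ratios exactly. Depth is measured from the top of the stem edge to the
#' deepest tip.
#'
#' @param clade A `phylo` carrying its stem in `root.edge`.
#' @param target_depth Positive target depth in Myr.
#' @return The rescaled clade.
#' @export
rescale_clade <- function(clade, target_depth) {
  .check_phylo(clade, "clade")
  stopifnot(target_depth > 0)
  depth <- .clade_depth(clade)
  if (depth <= 0) stop("degenerate clade of zero depth", call. = FALSE)
  f <- target_depth / depth
  clade$edge.length <- clade$edge.length * f
  clade$root.edge <- (clade$root.edge %||% 0) * f
  clade
}

#' Graft a clade into a backbone, replacing a represented group
#'
#' Removes the backbone subtree identified by `at` (a placeholder tip or
#' the tip set of the group being replaced) and attaches `clade` in its
#' place, connected by the clade's stem (`root.edge`). If the clade was
#' rescaled to the depth of the replaced representative, the grafted tips
#' sit at the same depth it had and all other backbone distances are
#' unchanged.
#'
#' @param backbone A rooted `phylo`.
#' @param at Tip label(s) identifying the replaced group.
#' @param clade A `phylo` with its stem in `root.edge`.
#' @return The merged `phylo`.
#' @export
graft_clade <- function(backbone, at, clade) {
  .check_phylo(backbone, "backbone")
  .check_phylo(clade, "clade")
  if (anyNA(match(at, backbone$tip.label)))
    stop("attachment tips not found in backbone: ",
         paste(setdiff(at, backbone$tip.label), collapse = ", "),
         call. = FALSE)
  if (length(at) > 1L) {
    mrca <- ape::getMRCA(backbone, at)
    below <- backbone$tip.label[.clade_tips(backbone, mrca)]
    if (length(setdiff(below, at)))
      stop("'at' does not subtend a complete backbone subtree; extra tips: ",
           paste(setdiff(below, at), collapse = ", "), call. = FALSE)
    backbone <- ape::drop.tip(backbone, at[-1L])
    at <- at[1L]
  }
  i <- which(backbone$tip.label == at)
  e <- which(backbone$edge[, 2] == i)
  stem <- clade$root.edge %||% 0
  if (ape::Ntip(clade) == 1L) {
    ## degenerate graft: rename the placeholder and set its pendant
    backbone$tip.label[i] <- clade$tip.label
    backbone$edge.length[e] <- stem + sum(clade$edge.length)
    return(backbone)
  }
  backbone$edge.length[e] <- 0
  clade$root.edge <- stem
  ape::bind.tree(backbone, clade, where = i)
}

#' Insert groups missing from the backbone next to their sisters
#'
#' For each missing group, its sister is read from `reference_a` and its
#' stem length is set so that the ratio (missing stem)/(sister stem in
#' the backbone, before insertion) equals the ratio of the two groups'
#' stem lengths measured in `reference_b`. The group is inserted on the
#' sister's stem edge at that age, so tips remain at the present.
#'
#' @param backbone Order-level `phylo` lacking the missing groups.
#' @param reference_a `phylo` containing the missing groups and their
#'   sisters (topology donor).
#' @param reference_b `phylo` donating the stem-length ratios (may be the
#'   same tree as `reference_a`).
#' @param missing Character vector of group (tip) labels to insert; may
#'   be empty.
#' @return The backbone with all missing groups inserted.
#' @export
place_missing_groups <- function(backbone, reference_a, reference_b, missing) {
  .check_phylo(backbone, "backbone")
  if (!length(missing)) return(backbone)
  .check_phylo(reference_a, "reference_a")
  .check_phylo(reference_b, "reference_b")
  for (g in missing) {
    if (!(g %in% reference_a$tip.label) || !(g %in% reference_b$tip.label))
      stop("missing group '", g, "' absent from the reference trees",
           call. = FALSE)
    v <- which(reference_a$tip.label == g)
    p <- reference_a$edge[reference_a$edge[, 2] == v, 1]
    sibs <- setdiff(reference_a$edge[reference_a$edge[, 1] == p, 2], v)
    sis_tips <- reference_a$tip.label[unlist(lapply(sibs, function(s)
      .clade_tips(reference_a, s)))]
    sister <- intersect(sis_tips, backbone$tip.label)
    if (length(sister) != 1L)
      stop("cannot resolve a single sister for missing group '", g,
           "' present in both backbone and reference", call. = FALSE)
    stem_of <- function(phy, lab) {
      i <- which(phy$tip.label == lab)
      phy$edge.length[phy$edge[, 2] == i]
    }
    ratio <- stem_of(reference_b, g) / stem_of(reference_b, sister)
    s_stem <- stem_of(backbone, sister)
    m_stem <- ratio * s_stem
    if (m_stem >= s_stem)
      stop("placement of '", g, "' not resolvable: inferred stem (",
           signif(m_stem, 6), ") is not shorter than the sister's stem (",
           signif(s_stem, 6), ")", call. = FALSE)
    backbone <- ape::bind.tree(backbone, .one_tip_phylo(g, m_stem),
                               where = which(backbone$tip.label == sister),
                               position = m_stem)
  }
  backbone
}

#' Reattach misplaced species as basal polytomies of their families
#'
#' Each listed species is detached (if present) and reattached at the
#' crown node of its target family as an additional child, with pendant
#' length equal to the family's crown age — the maximum value that keeps
#' the species inside the family crown while its tip stays at the
#' present. Afterwards every family with listed members is monophyletic.
#'
#' @param tree A rooted `phylo`.
#' @param taxonomy Data frame with columns `species`, `family` (and
#'   optionally `order`).
#' @param misplaced Data frame with columns `species`, `true_family`; may
#'   have zero rows.
#' @return The repaired `phylo`.
#' @export
repair_nonmonophyly <- function(tree, taxonomy, misplaced) {
  .check_phylo(tree)
  if (is.null(misplaced) || !nrow(misplaced)) return(tree)
  for (k in seq_len(nrow(misplaced))) {
    sp <- misplaced$species[k]
    fam <- misplaced$true_family[k]
    if (sp %in% tree$tip.label) tree <- ape::drop.tip(tree, sp)
    fam_sp <- setdiff(taxonomy$species[taxonomy$family == fam],
                      misplaced$species)
    fam_tips <- intersect(fam_sp, tree$tip.label)
    if (!length(fam_tips))
      stop("cannot repair '", sp, "': target family '", fam,
           "' absent from the tree", call. = FALSE)
    if (length(fam_tips) == 1L) {
      ## no crown exists for a single-tip family: attach at the midpoint
      ## of its pendant edge so the family stays monophyletic
      i <- which(tree$tip.label == fam_tips)
      len <- tree$edge.length[tree$edge[, 2] == i]
      tree <- ape::bind.tree(tree, .one_tip_phylo(sp, len / 2),
                             where = i, position = len / 2)
    } else {
      crown <- ape::getMRCA(tree, fam_tips)
      age <- max(.tip_depths(tree)[fam_tips]) - .node_depths(tree)[crown]
      tree <- ape::bind.tree(tree, .one_tip_phylo(sp, age),
                             where = crown, position = 0)
    }
  }
  tree
}

#' Drop tips not recognized by the reference taxonomy
#'
#' Prunes tips absent from the recognized-species set (pendant edges
#' removed, resulting degree-2 nodes suppressed with their edge lengths
#' summed, so all pairwise path lengths among retained tips are
#' preserved) and reports both the dropped tips and recognized species
#' missing from the tree.
#'
#' @param tree A rooted `phylo`.
#' @param taxonomy Data frame with a `species` column listing recognized
#'   species.
#' @return A list with `tree` (pruned `phylo`) and `report` (list with
#'   `dropped` and `missing` character vectors).
#' @export
reconcile_taxonomy <- function(tree, taxonomy) {
  .check_phylo(tree)
  recognized <- taxonomy$species
  dropped <- setdiff(tree$tip.label, recognized)
  missing <- setdiff(recognized, tree$tip.label)
  if (length(dropped) == ape::Ntip(tree))
    stop("all tips would be dropped: no tree tip is a recognized species",
         call. = FALSE)
  out <- if (length(dropped)) ape::drop.tip(tree, dropped) else tree
  list(tree = out, report = list(dropped = dropped, missing = missing))
}

#' Build a merge plan
#'
#' @param backbone Name of the backbone tree in the tree set.
#' @param grafts List of graft instructions, each a list with elements
#'   `donor` (name of the donor tree), `group` (order or family name) and
#'   `level` (`"order"` or `"family"`).
#' @param missing Character vector of groups absent from the backbone,
#'   to be inserted by [place_missing_groups()] before grafting.
#' @param reference_a,reference_b Names of the reference trees used for
#'   missing-group placement (topology and stem-ratio donors).
#' @return An object of class `merge_plan`.
#' @export
merge_plan <- function(backbone, grafts = list(), missing = character(),
                       reference_a = NULL, reference_b = NULL) {
  stopifnot(is.character(backbone), length(backbone) == 1L)
  for (g in grafts)
    stopifnot(all(c("donor", "group", "level") %in% names(g)),
              g$level %in% c("order", "family"))
  if (length(missing) && (is.null(reference_a) || is.null(reference_b)))
    stop("missing groups require reference_a and reference_b", call. = FALSE)
  structure(list(backbone = backbone, grafts = grafts, missing = missing,
                 reference_a = reference_a, reference_b = reference_b),
            class = "merge_plan")
}

#' Run the full supertree merge
#'
#' For each species-level donor sample: inserts groups missing from the
#' backbone, then for every graft instruction extracts the group's clade
#' from its donor (ignoring misplaced and unrecognized species), rescales
#' it to the depth of the group's backbone representative, and grafts it
#' in place; finally reattaches misplaced species as basal polytomies of
#' their families and prunes unrecognized tips. All merged trees share
#' the backbone-determined inter-group structure and differ only within
#' groups.
#'
#' @param plan A [merge_plan()].
#' @param trees Named list of `phylo` objects; donor entries may be a
#'   list of `phylo` samples (one merged tree is produced per sample).
#' @param taxonomy Data frame with columns `species`, `order`, `family`.
#' @param misplaced Optional data frame with columns `species`,
#'   `true_family`.
#' @return A list of merged `phylo` trees, one per donor sample, with a
#'   `reports` attribute carrying per-sample reconciliation reports.
#' @export
run_merge <- function(plan, trees, taxonomy, misplaced = NULL) {
  stopifnot(inherits(plan, "merge_plan"))
  if (!plan$backbone %in% names(trees))
    stop("backbone tree '", plan$backbone, "' not supplied", call. = FALSE)
  group_taxa <- function(group, level) {
    col <- if (level == "order") taxonomy$order else taxonomy$family
    sp <- taxonomy$species[col == group]
    if (!is.null(misplaced)) sp <- setdiff(sp, misplaced$species)
    sp
  }
  donor_names <- unique(vapply(plan$grafts, `[[`, "", "donor"))
  n_samples <- max(1L, vapply(donor_names, function(d) {
    x <- trees[[d]]
    if (inherits(x, "phylo")) 1L else length(x)
  }, 1L))
  get_donor <- function(name, s) {
    x <- trees[[name]]
    if (inherits(x, "phylo")) x else x[[min(s, length(x))]]
  }
  merged <- vector("list", n_samples)
  reports <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    bb <- trees[[plan$backbone]]
    if (length(plan$missing))
      bb <- place_missing_groups(bb, trees[[plan$reference_a]],
                                 trees[[plan$reference_b]], plan$missing)
    ## clean each donor once: drop misplaced and unrecognized tips
    donors <- lapply(donor_names, function(d) {
      tr <- get_donor(d, s)
      drop <- union(setdiff(tr$tip.label, taxonomy$species),
                    if (is.null(misplaced)) character() else
                      intersect(misplaced$species, tr$tip.label))
      if (length(drop)) tr <- ape::drop.tip(tr, drop)
      tr
    })
    names(donors) <- donor_names
    for (g in plan$grafts) {
      taxa <- intersect(group_taxa(g$group, g$level),
                        donors[[g$donor]]$tip.label)
      if (!length(taxa))
        stop("graft step for group '", g$group,
             "': no taxa available in donor '", g$donor, "'", call. = FALSE)
      step <- function(expr) tryCatch(expr, error = function(e)
        stop("graft step for group '", g$group, "' failed: ",
             conditionMessage(e), call. = FALSE))
      clade <- step(extract_clade(donors[[g$donor]], taxa))
      if (!g$group %in% bb$tip.label)
        stop("graft step for group '", g$group,
             "': no backbone representative", call. = FALSE)
      i <- which(bb$tip.label == g$group)
      target <- bb$edge.length[bb$edge[, 2] == i]
      clade <- step(rescale_clade(clade, target))
      bb <- step(graft_clade(bb, g$group, clade))
    }
    if (!is.null(misplaced) && nrow(misplaced))
      bb <- repair_nonmonophyly(bb, taxonomy, misplaced)
    rec <- reconcile_taxonomy(bb, taxonomy)
    merged[[s]] <- rec$tree
    reports[[s]] <- rec$report
  }
  attr(merged, "reports") <- reports
  merged
}
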