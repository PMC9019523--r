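## Independent oracles and shared fixtures.
##
## The subset-PD oracle uses phangorn's descendant sets (a code path
## disjoint from the package's root-ward edge-marking algorithm): the PD
## of a species set, root included, is the summed length of every edge
## with at least one descendant in the set.

oracle_subset_pd <- function(phy, tips, desc = NULL) {
  if (is.null(desc)) desc <- phangorn::Descendants(phy, phy$edge[, 2], "tips")
  keep <- vapply(desc, function(d) any(phy$tip.label[d] %in% tips),
                 logical(1))
  sum(phy$edge.length[keep])
}

## Brute-force remove-and-recompute: contribution of the k-th discovered
## species is PD(first k) - PD(first k-1).
oracle_contributions <- function(phy, ord) {
  desc <- phangorn::Descendants(phy, phy$edge[, 2], "tips")
  pd <- vapply(seq_along(ord), function(k)
    oracle_subset_pd(phy, ord[seq_len(k)], desc), numeric(1))
  out <- diff(c(0, pd))
  names(out) <- ord
  out
}

## All permutations of a small vector.
all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(all_perms(x[-i]), function(p) c(x[i], p)))
  out
}

## Brute-force monophyly check for every named group with >= 2 members.
families_monophyletic <- function(phy, taxonomy) {
  for (f in unique(taxonomy$family)) {
    sp <- intersect(taxonomy$species[taxonomy$family == f], phy$tip.label)
    if (length(sp) < 2L) next
    mrca <- ape::getMRCA(phy, sp)
    below <- phy$tip.label[unlist(phangorn::Descendants(phy, mrca, "tips"))]
    if (!setequal(below, sp)) return(FALSE)
  }
  TRUE
}

ultrametric_spread <- function(phy) {
  d <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  (max(d) - min(d)) / max(d)
}

## The worked 3-tip example used throughout.
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):2,C:3);")

worked_table <- function() {
  data.frame(species = c("A", "B", "C"),
             order = c("O1", "O1", "O2"),
             family = c("F1", "F1", "F2"),
             year = c(1760L, 1800L, 1850L),
             stringsAsFactors = FALSE)
}

random_bd_tree <- function(n, birth = 0.15, death = 0.05) {
  phy <- ape::rphylo(n, birth, death)
  phy$tip.label <- sprintf("t%03d", seq_len(n))
  phy
}
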