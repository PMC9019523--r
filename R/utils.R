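## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_phylo <- function(phy, arg = "tree") {
  if (!inherits(phy, "phylo"))
    stop(sprintf("'%s' must be a 'phylo' object", arg), call. = FALSE)
  if (is.null(phy$edge.length))
    stop(sprintf("'%s' has no branch lengths", arg), call. = FALSE)
  if (anyNA(phy$edge.length))
    stop(sprintf("'%s' has missing branch lengths", arg), call. = FALSE)
  if (any(phy$edge.length < 0))
    stop(sprintf("'%s' has negative branch lengths", arg), call. = FALSE)
  invisible(phy)
}

## Distance from the root for every node (tips 1..n first), root.edge excluded.
.node_depths <- function(phy) {
  ape::node.depth.edgelength(phy)
}

.tip_depths <- function(phy) {
  d <- .node_depths(phy)[seq_len(ape::Ntip(phy))]
  names(d) <- phy$tip.label
  d
}

## Relative spread of tip depths; 0 for a perfectly ultrametric tree.
.ultrametric_spread <- function(phy) {
  d <- .tip_depths(phy)
  if (length(d) < 2L) return(0)
  (max(d) - min(d)) / max(d)
}

## Tip indices descending from `node` (which may itself be a tip).
.clade_tips <- function(phy, node) {
  n <- ape::Ntip(phy)
  if (node <= n) return(node)
  kids <- phy$edge[, 2][order(phy$edge[, 1])]  # unused ordering; traverse below
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  sort(out)
}

## Stem-to-tip depth of a clade carrying a root.edge stem.
.clade_depth <- function(clade) {
  (clade$root.edge %||% 0) + max(.tip_depths(clade))
}

## Single-tip phylo used for binding pendant tips into a tree.
.one_tip_phylo <- function(label, length) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 edge.length = length,
                 tip.label = label,
                 Nnode = 1L),
            class = "phylo")
}

## Canonical species-name form: trimmed, single underscores, lower case.
.normalize_name <- function(x) {
  x <- gsub("[ _]+", "_", trimws(x))
  tolower(x)
}

## Map tree tip labels onto table species names (exact after normalization).
## Returns integer index into `species` for each tip; errors on any mismatch.
.match_tips <- function(phy, species, context = "tree") {
  key <- .normalize_name(species)
  if (anyDuplicated(key))
    stop("species table has names that collide after normalization: ",
         paste(species[duplicated(key)], collapse = ", "), call. = FALSE)
  idx <- match(.normalize_name(phy$tip.label), key)
  if (anyNA(idx))
    stop(sprintf("%s tips absent from the species table: %s", context,
                 paste(phy$tip.label[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  idx
}

## Deterministic per-replicate seed streams from one master seed.
.replicate_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
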