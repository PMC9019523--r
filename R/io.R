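## File I/O (Newick trees, species and misplaced-species CSVs) and the
## end-to-end pipeline with its machine-readable run manifest.

#' Read trees from a Newick file
#'
#' One tree per line; empty lines are skipped. Every non-root edge must
#' carry a branch length; quoted labels are accepted, labels are written
#' unquoted with underscores.
#'
#' @param path Path to a Newick file.
#' @return A list of `phylo` objects (class `multiPhylo`).
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  trees <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    tr <- tryCatch(ape::read.tree(text = lines[ln]),
                   error = function(e) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
      stop("malformed Newick on line ", ln, " of ", path, call. = FALSE)
    if (is.null(tr$edge.length))
      stop("tree on line ", ln, " has no branch lengths", call. = FALSE)
    if (anyNA(tr$edge.length)) {
      bad <- tr$edge[is.na(tr$edge.length), 2]
      lab <- ifelse(bad <= ape::Ntip(tr), tr$tip.label[bad],
                    paste0("node ", bad))
      stop("tree on line ", ln, " is missing branch lengths above: ",
           paste(lab, collapse = ", "), call. = FALSE)
    }
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Write trees to a Newick file, one per line
#'
#' @param trees A `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(tr)
    ape::write.tree(tr, digits = 12), "")
  writeLines(txt, path)
  invisible(path)
}

.validate_species_table <- function(table) {
  req <- c("species", "order", "family", "year")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("species table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dup <- table$species[duplicated(table$species)]
  if (length(dup))
    stop("duplicate species in table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  invisible(table)
}

#' Read and validate a species table CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `species,order,family,year`. Duplicate species and non-integer years
#' are rejected, naming the offending rows.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  .validate_species_table(tab)
  yr <- suppressWarnings(as.numeric(tab$year))
  bad <- which(is.na(yr) | yr != floor(yr))
  if (length(bad))
    stop("non-integer year(s) in species table, row(s): ",
         paste(bad, collapse = ", "), " (",
         paste(tab$year[bad], collapse = ", "), ")", call. = FALSE)
  tab$year <- as.integer(yr)
  tab
}

#' Read a misplaced-species CSV (`species,true_family`)
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `species` and `true_family`.
#' @export
read_misplaced_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "true_family"), names(tab))
  if (length(miss))
    stop("misplaced-species table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab
}

#' Pipeline configuration
#'
#' @param trees Path to a Newick file of (merged) trees, or an in-memory
#'   `phylo`/list of `phylo`.
#' @param species Path to the species CSV, or an in-memory data frame.
#' @param misplaced Optional misplaced-species CSV path or data frame.
#' @param out_dir Output directory (created if absent).
#' @param n_perm Within-year randomizations per tree.
#' @param n_rand Null-model randomizations per tree (0 disables the null
#'   model).
#' @param seed Master seed for all randomized stages.
#' @param from_year Lower cutoff for the second set of trend fits.
#' @param window_years Trailing window for [recent_increment()].
#' @param reversed Whether to compute the reversed-order curve.
#' @param per_order Whether to write per-order summaries.
#' @param decade_start First decade boundary.
#' @return An object of class `run_config`.
#' @export
run_config <- function(trees, species, misplaced = NULL,
                       out_dir = "pdaccum_out", n_perm = 100, n_rand = 100,
                       seed = 1L, from_year = 1780, window_years = 50,
                       reversed = TRUE, per_order = TRUE,
                       decade_start = 1750) {
  stopifnot(n_perm >= 1, n_rand >= 0, window_years >= 1)
  structure(list(trees = trees, species = species, misplaced = misplaced,
                 out_dir = out_dir, n_perm = n_perm, n_rand = n_rand,
                 seed = as.integer(seed), from_year = from_year,
                 window_years = window_years, reversed = reversed,
                 per_order = per_order, decade_start = decade_start),
            class = "run_config")
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the end-to-end accumulation pipeline
#'
#' Reads and validates the inputs (every tree tip must match exactly one
#' species-table row; mismatches abort before any computation), computes
#' mean contributions, accumulation curves on both axes, the null-model
#' and reversed-order counterfactuals with their difference curves,
#' trend fits (both axes, with and without the `from_year` cutoff),
#' per-order summaries, decade fractions and most-distinctive species,
#' then writes CSV/JSON outputs and a manifest (seed, versions, input
#' and output checksums) to `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  trees <- config$trees
  input_files <- character()
  if (is.character(trees)) {
    input_files <- c(input_files, trees)
    trees <- read_trees(trees)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  table <- config$species
  if (is.character(table)) {
    input_files <- c(input_files, table)
    table <- read_species_table(table)
  }
  .validate_species_table(table)
  for (tr in trees) .match_tips(tr, table$species)  # fail fast
  if (any(!.normalize_name(table$species) %in%
            .normalize_name(trees[[1]]$tip.label)))
    stop("species table rows without a matching tree tip: ",
         paste(table$species[!.normalize_name(table$species) %in%
                               .normalize_name(trees[[1]]$tip.label)],
               collapse = ", "), call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  contribs <- mean_contributions(trees, table, n_perm = config$n_perm,
                                 seed = config$seed)
  paths["contributions"] <- .write_csv(
    as.data.frame(contribs), file.path(config$out_dir, "contributions.csv"))
  curve_year <- accumulation_curve(contribs, "year")
  curve_count <- accumulation_curve(contribs, "count")
  paths["curve_year"] <- .write_csv(
    as.data.frame(curve_year), file.path(config$out_dir, "curve_year.csv"))
  paths["curve_count"] <- .write_csv(
    as.data.frame(curve_count), file.path(config$out_dir, "curve_count.csv"))

  null_ens <- NULL
  if (config$n_rand > 0) {
    null_ens <- null_model(trees, table, n_rand = config$n_rand,
                           seed = config$seed + 1L)
    paths["null_curves"] <- .write_csv(
      as.data.frame(null_ens$curve_year),
      file.path(config$out_dir, "null_curves.csv"))
    paths["difference_count"] <- .write_csv(
      as.data.frame(difference_curve(curve_count, null_ens$curve_count)),
      file.path(config$out_dir, "difference_count.csv"))
    paths["difference_year"] <- .write_csv(
      as.data.frame(difference_curve(curve_year, null_ens$curve_year)),
      file.path(config$out_dir, "difference_year.csv"))
  }
  rev_curve <- NULL
  if (isTRUE(config$reversed)) {
    rev_curve <- reversed_order(trees, table, n_perm = config$n_perm,
                                seed = config$seed + 2L)
    paths["reversed_curve"] <- .write_csv(
      as.data.frame(rev_curve),
      file.path(config$out_dir, "reversed_curve.csv"))
  }

  fits <- list(
    year_all = fit_decline(contribs, "year"),
    year_from = fit_decline(contribs, "year", from_x = config$from_year),
    count_all = fit_decline(contribs, "count"))
  fits$count_from <- tryCatch(
    fit_decline(contribs[contribs$year >= config$from_year, , drop = FALSE],
                "count"),
    error = function(e) NULL)
  trend_path <- file.path(config$out_dir, "trend.json")
  jsonlite::write_json(lapply(fits, unclass), trend_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths["trend"] <- trend_path

  if (isTRUE(config$per_order)) {
    paths["order_curves"] <- .write_csv(
      per_order_curves(contribs),
      file.path(config$out_dir, "order_curves.csv"))
    df <- decade_fractions(contribs, config$decade_start)
    nf <- data.frame(decade = rownames(df$new_fraction),
                     df$new_fraction, check.names = FALSE)
    paths["decade_fractions"] <- .write_csv(
      nf, file.path(config$out_dir, "decade_fractions.csv"))
    paths["distinctive"] <- .write_csv(
      distinctive_per_decade(contribs, config$decade_start),
      file.path(config$out_dir, "distinctive.csv"))
  }

  milestones <- list(
    half_pd_year = milestone_year(curve_year, 0.5, "pd"),
    half_richness_year = milestone_year(curve_year, 0.5, "richness"))
  increment <- recent_increment(contribs, config$window_years)

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pdaccum")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_trees = length(trees), n_species = nrow(table),
    n_perm = config$n_perm, n_rand = config$n_rand,
    total_pd = mean(attr(contribs, "total_pd")),
    milestones = milestones,
    recent_increment = increment,
    inputs = stats::setNames(as.list(unname(tools::md5sum(input_files))),
                             basename(input_files)),
    outputs = stats::setNames(as.list(unname(tools::md5sum(unname(paths)))),
                              basename(unname(paths))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  paths["manifest"] <- manifest_path

  invisible(list(contributions = contribs, curve_year = curve_year,
                 curve_count = curve_count, null = null_ens,
                 reversed = rev_curve, fits = fits,
                 milestones = milestones, recent_increment = increment,
                 manifest = manifest, paths = paths))
}
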