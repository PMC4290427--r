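## Tree ensembles: replicate phylogenies (e.g. a posterior sample) over one
## identical tip set; species-level scores are aggregated by the per-species
## median across member trees.

#' Build a tree ensemble
#'
#' @param trees a list of rooted `phylo` objects (or a `multiPhylo`), all
#'   sharing exactly the same tip-label set.
#' @param id optional ensemble identifier.
#' @return an object of class `tree_ensemble` (a list of `phylo` trees).
#' @export
tree_ensemble <- function(trees, id = "ensemble") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  attr(trees, "TipLabel") <- NULL
  if (length(trees) < 1L)
    stop("ensemble must contain at least one tree", call. = FALSE)
  lapply(trees, .validate_tree, min_tips = 2L)
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tips <- sort(trees[[i]]$tip.label)
    if (!identical(tips, ref)) {
      extra <- setdiff(tips, ref)
      missing <- setdiff(ref, tips)
      stop(sprintf(
        "tree %d does not share the ensemble tip set (only in tree %d: %s; only in tree 1: %s)",
        i, i,
        paste(utils::head(extra, 10L), collapse = ", "),
        paste(utils::head(missing, 10L), collapse = ", ")), call. = FALSE)
    }
  }
  structure(trees, class = "tree_ensemble", id = id)
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("Tree ensemble '%s': %d tree(s), %d tips\n",
              attr(x, "id"), length(x), ape::Ntip(x[[1L]])))
  invisible(x)
}

#' Read a tree ensemble from file
#'
#' Newick files are read one tree per line (blank lines skipped); NEXUS
#' files via their TREES block.  All trees must share one tip-label set.
#'
#' @param path path to the tree file.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return a [tree_ensemble()].
#' @export
read_trees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("tree file not found: ", path, call. = FALSE)
  if (format == "newick") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (length(keep) == 0L)
      stop("no trees found in ", path, call. = FALSE)
    trees <- vector("list", length(keep))
    for (k in seq_along(keep)) {
      tr <- tryCatch(suppressWarnings(ape::read.tree(text = lines[keep[k]])),
                     error = function(e) NULL)
      if (is.null(tr) || !inherits(tr, "phylo"))
        stop(sprintf("failed to parse Newick on line %d of %s",
                     keep[k], path), call. = FALSE)
      trees[[k]] <- tr
    }
  } else {
    trees <- tryCatch(ape::read.nexus(path), error = function(e)
      stop("failed to parse NEXUS file ", path, ": ", conditionMessage(e),
           call. = FALSE))
    if (inherits(trees, "phylo")) trees <- list(trees)
  }
  tree_ensemble(trees, id = basename(path))
}

#' Write an ensemble as a multi-line Newick file
#'
#' @param ensemble a [tree_ensemble()] (or single `phylo`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(ensemble, path) {
  if (inherits(ensemble, "phylo")) ensemble <- tree_ensemble(ensemble)
  txt <- vapply(unclass(ensemble), ape::write.tree, character(1))
  writeLines(txt, path)
  invisible(path)
}

#' Median species scores across a tree ensemble
#'
#' Per-species median of ED, PE and APD over the member trees; even-sized
#' ensembles use the midpoint of the two central values.
#'
#' @param ensemble a [tree_ensemble()] (a single `phylo` is promoted to an
#'   ensemble of one).
#' @param metrics which metrics to aggregate (default all three).
#' @param scope scope tag on the result (default `"GLOBAL"`).
#' @return data.frame with `species` plus one column per metric, species in
#'   the first tree's tip order; `"scope"` attribute set.
#' @export
median_scores <- function(ensemble, metrics = c("ED", "PE", "APD"),
                          scope = "GLOBAL") {
  if (inherits(ensemble, "phylo")) ensemble <- tree_ensemble(ensemble)
  metrics <- match.arg(metrics, c("ED", "PE", "APD"), several.ok = TRUE)
  species <- ensemble[[1L]]$tip.label
  fns <- list(ED = fair_proportion_ed, PE = pendant_edge_pe,
              APD = average_pairwise_apd)
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  for (m in metrics) {
    vals <- vapply(unclass(ensemble),
                   function(tr) fns[[m]](tr)[species], numeric(length(species)))
    vals <- matrix(vals, nrow = length(species))
    out[[m]] <- apply(vals, 1L, stats::median)
  }
  attr(out, "scope") <- scope
  out
}

#' Write a score table to CSV
#'
#' Columns `species, scope, ED, PE, APD` (whichever metric columns exist).
#'
#' @param scores a score data.frame from [tree_scores()] or
#'   [median_scores()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  scope <- attr(scores, "scope")
  if (is.null(scope)) scope <- "GLOBAL"
  cols <- intersect(c("ED", "PE", "APD", "TU", "TAPD"), names(scores))
  out <- cbind(data.frame(species = scores$species, scope = scope,
                          stringsAsFactors = FALSE),
               scores[cols])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
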