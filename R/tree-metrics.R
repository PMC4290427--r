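## Trees are plain ape "phylo" objects (rooted, with branch lengths).  A
## pruned community subtree keeps the path from the community's MRCA up to
## the pool root as `root.edge`, so that its total length equals rooted
## Faith PD of the community on the pool tree.

.validate_tree <- function(tree, min_tips = 2L) {
  if (!inherits(tree, "phylo"))
    stop("expected an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and non-missing", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("tip labels must be unique", call. = FALSE)
  if (ape::Ntip(tree) < min_tips)
    stop(sprintf("tree must have at least %d tips", min_tips), call. = FALSE)
  invisible(tree)
}

.root_edge <- function(tree) {
  if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Total branch length of a tree
#'
#' Sum of all edge lengths, including the root edge if one is present.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return a single non-negative number.
#' @export
tree_length <- function(tree) {
  .validate_tree(tree, min_tips = 1L)
  sum(tree$edge.length) + .root_edge(tree)
}

## number of tip descendants of every node (tips count themselves)
.tips_below <- function(tree) {
  n <- ape::Ntip(tree)
  po <- stats::reorder(tree, "postorder")
  ndesc <- c(rep(1L, n), integer(tree$Nnode))
  for (e in seq_len(nrow(po$edge)))
    ndesc[po$edge[e, 1L]] <- ndesc[po$edge[e, 1L]] + ndesc[po$edge[e, 2L]]
  ndesc
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Apportions every edge's length equally among the tips descending from it
#' and sums each tip's shares along its root-to-tip path.  A root edge, if
#' present (as on a pruned community subtree), is shared equally by all tips,
#' so that the scores always sum to the total tree length.
#'
#' @param tree a rooted `phylo` with branch lengths and at least two tips.
#'   Polytomies and zero-length edges are handled without special casing.
#' @return named numeric vector of ED scores, one per tip.
#' @seealso [pendant_edge_pe()], [average_pairwise_apd()]
#' @export
fair_proportion_ed <- function(tree) {
  .validate_tree(tree, min_tips = 2L)
  n <- ape::Ntip(tree)
  po <- stats::reorder(tree, "postorder")
  ne <- nrow(po$edge)
  ndesc <- c(rep(1L, n), integer(tree$Nnode))
  for (e in seq_len(ne))
    ndesc[po$edge[e, 1L]] <- ndesc[po$edge[e, 1L]] + ndesc[po$edge[e, 2L]]
  share <- po$edge.length / ndesc[po$edge[, 2L]]
  ## postorder reversed is a valid preorder: parents before children
  acc <- numeric(n + tree$Nnode)
  for (e in rev(seq_len(ne)))
    acc[po$edge[e, 2L]] <- acc[po$edge[e, 1L]] + share[e]
  ed <- acc[seq_len(n)] + .root_edge(tree) / n
  names(ed) <- tree$tip.label
  ed
}

#' Pendant-edge length (unique PD contribution)
#'
#' The length of each species' terminal branch: the phylogenetic diversity
#' lost if that single species is dropped from the tips' spanning tree.
#'
#' @inheritParams fair_proportion_ed
#' @return named numeric vector of pendant edge lengths.
#' @export
pendant_edge_pe <- function(tree) {
  .validate_tree(tree, min_tips = 1L)
  n <- ape::Ntip(tree)
  pe <- numeric(n)
  tip_edge <- match(seq_len(n), tree$edge[, 2L])
  pe <- tree$edge.length[tip_edge]
  names(pe) <- tree$tip.label
  pe
}

#' Patristic (cophenetic) distance matrix
#'
#' Pairwise path-length distances between tips: the sum of branch lengths
#' along the tree path connecting each pair.
#'
#' @inheritParams fair_proportion_ed
#' @return symmetric numeric matrix with zero diagonal, rows and columns in
#'   `tree$tip.label` order.
#' @export
patristic_matrix <- function(tree) {
  .validate_tree(tree, min_tips = 2L)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Average pairwise patristic distance (APD)
#'
#' Mean patristic distance from each species to all other species in the
#' tree; the self-distance is excluded, i.e. the divisor is `n - 1`.
#'
#' @inheritParams fair_proportion_ed
#' @param d optional precomputed patristic matrix (saves recomputation).
#' @return named numeric vector of APD scores.
#' @export
average_pairwise_apd <- function(tree, d = NULL) {
  .validate_tree(tree, min_tips = 2L)
  if (is.null(d)) d <- patristic_matrix(tree)
  n <- nrow(d)
  apd <- rowSums(d) / (n - 1)
  names(apd) <- rownames(d)
  apd
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of edge lengths on the union of root-to-tip paths over the set.  By
#' default the path from the set's most recent common ancestor up to the
#' tree root is included (rooted convention): single-lineage sets then have
#' positive PD and `sum(fair_proportion_ed(tree))` equals PD of the full tip
#' set exactly.  Set `include_root = FALSE` for the MRCA-rooted variant.
#'
#' @inheritParams fair_proportion_ed
#' @param species character vector of tip labels (non-empty, all present).
#' @param include_root logical; include the MRCA-to-root path (default TRUE).
#' @return a single non-negative number.
#' @export
faith_pd <- function(tree, species, include_root = TRUE) {
  .validate_tree(tree, min_tips = 1L)
  species <- unique(as.character(species))
  if (length(species) == 0L)
    stop("species set must be non-empty", call. = FALSE)
  idx <- match(species, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip label(s): ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  n <- ape::Ntip(tree)
  po <- stats::reorder(tree, "postorder")
  cnt <- integer(n + tree$Nnode)
  cnt[idx] <- 1L
  for (e in seq_len(nrow(po$edge)))
    cnt[po$edge[e, 1L]] <- cnt[po$edge[e, 1L]] + cnt[po$edge[e, 2L]]
  child_cnt <- cnt[po$edge[, 2L]]
  incl <- child_cnt > 0L
  pd <- sum(po$edge.length[incl]) + .root_edge(tree)
  if (!include_root)
    pd <- pd - sum(po$edge.length[incl & child_cnt == length(idx)]) -
      .root_edge(tree)
  pd
}

#' Prune a tree to a community's species
#'
#' Returns the subtree linking the given species.  Degree-2 internal nodes
#' are suppressed (their edge lengths summed) and, under the default rooted
#' convention, the path from the community MRCA up to the original root is
#' retained as the subtree's root edge, so the pruned tree's total length
#' ([tree_length()]) equals [faith_pd()] of the set.
#'
#' @inheritParams faith_pd
#' @param keep_root_path keep the MRCA-to-root path as a root edge (default
#'   TRUE, matching the rooted PD convention).
#' @return a `phylo` object with exactly the requested tips.
#' @export
prune_to_community <- function(tree, species, keep_root_path = TRUE) {
  .validate_tree(tree, min_tips = 2L)
  species <- unique(as.character(species))
  species <- species[species %in% tree$tip.label]
  if (length(species) < 2L)
    stop("need at least 2 matching tips to prune to", call. = FALSE)
  sub <- ape::keep.tip(tree, species)
  sub$root.edge <- NULL
  if (keep_root_path) {
    stem <- faith_pd(tree, species, include_root = TRUE) - sum(sub$edge.length)
    if (stem > .Machine$double.eps^0.5 * max(1, sum(sub$edge.length)))
      sub$root.edge <- stem
  }
  sub
}

#' All three isolation metrics for one tree
#'
#' @inheritParams fair_proportion_ed
#' @param scope scope tag recorded on the result (`"GLOBAL"` or a community
#'   id).
#' @return data.frame with columns `species`, `ED`, `PE`, `APD` and a
#'   `"scope"` attribute.
#' @export
tree_scores <- function(tree, scope = "GLOBAL") {
  ed <- fair_proportion_ed(tree)
  pe <- pendant_edge_pe(tree)
  apd <- average_pairwise_apd(tree)
  out <- data.frame(species = tree$tip.label,
                    ED = unname(ed[tree$tip.label]),
                    PE = unname(pe[tree$tip.label]),
                    APD = unname(apd[tree$tip.label]),
                    stringsAsFactors = FALSE)
  attr(out, "scope") <- scope
  out
}
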