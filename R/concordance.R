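## Per-community concordance between global (species-pool) scores and local
## (community-subtree / community-submatrix) scores, summarized across
## communities as in a multi-site survey analysis.

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks (average ranks) are used for ties; the two-sided p-value comes
#' from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom, with `|rho| = 1` mapped to `p = 0`.
#'
#' @param x,y numeric vectors of equal length (>= 3), each with at least two
#'   distinct values.
#' @return list with elements `rho`, `p` and `n`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant vector: correlation undefined", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) == 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Median local isolation scores for one community
#'
#' Prunes each ensemble tree to the community, computes ED, PE and APD on
#' the subtree (root path retained per the rooted convention), and takes
#' per-species medians across trees.
#'
#' @param ensemble a [tree_ensemble()] or single `phylo`.
#' @param species community species (>= 2 present on the trees).
#' @param scope scope tag (community id).
#' @return data.frame `species`, `ED`, `PE`, `APD`.
#' @export
local_phylo_scores <- function(ensemble, species, scope = "LOCAL") {
  if (inherits(ensemble, "phylo")) ensemble <- tree_ensemble(ensemble)
  species <- intersect(unique(as.character(species)),
                       ensemble[[1L]]$tip.label)
  if (length(species) < 2L)
    stop("need at least 2 community species present on the tree",
         call. = FALSE)
  subtrees <- lapply(unclass(ensemble), prune_to_community, species = species)
  median_scores(tree_ensemble(subtrees, id = scope), scope = scope)
}

.default_pairs <- function(with_traits = TRUE) {
  loc <- c("ED", "PE", "APD", if (with_traits) c("TU", "TAPD"))
  expand.grid(global = c("ED", "PE", "APD"), local = loc,
              stringsAsFactors = FALSE)
}

.undef_record <- function(community, variant, global, local, n) {
  data.frame(community = community, variant = variant,
             pair = paste0(global, "_x_", local),
             global = global, local = local, n = n,
             rho = NA_real_, p = NA_real_, defined = FALSE,
             stringsAsFactors = FALSE)
}

#' Concordance records for one community
#'
#' One Spearman record per requested (global metric, local metric) pair,
#' vectors aligned by species label over the community.  Records with fewer
#' than 3 shared species, or with a constant score vector, are marked
#' undefined and excluded from summaries.
#'
#' @param global_scores data.frame with `species` plus global metric
#'   columns (`ED`, `PE`, `APD`, and optionally `TU`, `TAPD`).
#' @param local_scores data.frame with `species` plus local phylogenetic
#'   metric columns for this community.
#' @param local_traits optional data.frame `species`, `TU`, `TAPD` of local
#'   trait scores; species missing a trait row are excluded from
#'   trait-based records only.
#' @param community character vector of the community's species.
#' @param pairs data.frame with columns `global`, `local` (defaults to all
#'   global x local combinations available).
#' @param community_id id recorded on the records.
#' @param variant dataset variant tag.
#' @return data.frame of concordance records.
#' @export
community_concordance <- function(global_scores, local_scores,
                                  local_traits = NULL, community,
                                  pairs = NULL,
                                  community_id = "community",
                                  variant = "FULL") {
  if (is.null(pairs)) pairs <- .default_pairs(!is.null(local_traits))
  community <- unique(as.character(community))
  recs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$global[i]; l <- pairs$local[i]
    loc_tab <- if (l %in% c("TU", "TAPD")) local_traits else local_scores
    if (is.null(loc_tab) || !l %in% names(loc_tab)) {
      recs[[i]] <- .undef_record(community_id, variant, g, l, 0L)
      next
    }
    shared <- intersect(intersect(community, global_scores$species),
                        loc_tab$species)
    n <- length(shared)
    if (n < 3L) {
      recs[[i]] <- .undef_record(community_id, variant, g, l, n)
      next
    }
    gv <- global_scores[[g]][match(shared, global_scores$species)]
    lv <- loc_tab[[l]][match(shared, loc_tab$species)]
    res <- tryCatch(spearman_rho(gv, lv), error = function(e) NULL)
    recs[[i]] <- if (is.null(res))
      .undef_record(community_id, variant, g, l, n)
    else
      data.frame(community = community_id, variant = variant,
                 pair = paste0(g, "_x_", l), global = g, local = l,
                 n = n, rho = res$rho, p = res$p, defined = TRUE,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' Summarize concordance records across communities
#'
#' Per metric pair: arithmetic mean and sample standard deviation of rho
#' over defined records, and the proportion of communities significant at
#' `alpha` (two-sided).
#'
#' @param records data.frame from [community_concordance()] (rows from many
#'   communities may be concatenated).
#' @param alpha significance level (default 0.05).
#' @return data.frame `pair, global, local, n_communities, mean_rho,
#'   sd_rho, prop_significant`.
#' @export
summarize_concordance <- function(records, alpha = 0.05) {
  def <- records[records$defined, , drop = FALSE]
  pairs <- unique(records[c("pair", "global", "local")])
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- def[def$pair == pairs$pair[i], , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no defined records for pair ", pairs$pair[i], call. = FALSE)
    sd_rho <- if (nrow(sub) > 1L) stats::sd(sub$rho) else {
      warning("single defined record for pair ", pairs$pair[i],
              "; s.d. set to 0", call. = FALSE)
      0
    }
    data.frame(pair = pairs$pair[i], global = pairs$global[i],
               local = pairs$local[i], n_communities = nrow(sub),
               mean_rho = mean(sub$rho), sd_rho = sd_rho,
               prop_significant = mean(sub$p < alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Global-versus-local concordance across all communities
#'
#' Driver for the concordance stage: computes global median scores over the
#' ensemble (plus global TU/TAPD when a trait matrix is given), local
#' scores per community (pruned-subtree medians; trait submatrix TU/TAPD),
#' and Spearman records with their summary.
#'
#' @param ensemble a [tree_ensemble()].
#' @param communities a `community_table`.
#' @param traits optional complete `trait_dist` over the pool.
#' @param pairs metric pairs (default: all available combinations).
#' @param alpha significance level for the summary.
#' @param variant variant tag; defaults to the community table's.
#' @return object of class `concordance_result`: list with `records`,
#'   `summary`, `global_scores`.
#' @export
concordance_analysis <- function(ensemble, communities, traits = NULL,
                                 pairs = NULL, alpha = 0.05,
                                 variant = NULL) {
  if (inherits(ensemble, "phylo")) ensemble <- tree_ensemble(ensemble)
  if (is.null(variant)) variant <- communities$variant
  global_scores <- median_scores(ensemble)
  if (!is.null(traits)) {
    gt <- trait_scores(traits)
    global_scores <- merge(global_scores, gt, by = "species",
                           all.x = TRUE, sort = FALSE)
  }
  if (is.null(pairs)) pairs <- .default_pairs(!is.null(traits))
  tips <- ensemble[[1L]]$tip.label
  recs <- lapply(names(communities$communities), function(s) {
    sp <- names(communities$communities[[s]])
    sp_tree <- intersect(sp, tips)
    if (length(sp_tree) < 3L)
      return(do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
        .undef_record(s, variant, pairs$global[i], pairs$local[i],
                      length(sp_tree)))))
    loc <- local_phylo_scores(ensemble, sp_tree, scope = s)
    loc_tr <- NULL
    if (!is.null(traits)) {
      sp_tr <- intersect(sp, rownames(traits$d))
      if (length(sp_tr) >= 2L)
        loc_tr <- trait_scores(restrict_to_community(traits, sp_tr,
                                                     scope = s))
    }
    community_concordance(global_scores, loc, loc_tr, sp, pairs,
                          community_id = s, variant = variant)
  })
  records <- do.call(rbind, recs)
  structure(list(records = records,
                 summary = summarize_concordance(records, alpha = alpha),
                 global_scores = global_scores),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Global vs local concordance over",
      length(unique(x$records$community)), "communities\n")
  print(x$summary, digits = 3)
  invisible(x)
}
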