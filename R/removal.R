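## Top-K species-removal experiment: remove the globally top-ranked species
## from every community, measure the loss of rooted Faith PD and the change
## in mean pairwise trait distance, and compare against a random-removal
## null (uniform m-subsets, R replicates) with add-one empirical p-values
## and Benjamini-Hochberg FDR control across communities.

#' Precompute an edge-incidence context for fast repeated PD
#'
#' Builds the edge x tip incidence matrix of a rooted tree so that PD of
#' many tip subsets can be computed by counting, which the removal null
#' exploits.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return an opaque list used by the removal functions.
#' @export
pd_context <- function(tree) {
  .validate_tree(tree, min_tips = 2L)
  n <- ape::Ntip(tree)
  ne <- nrow(tree$edge)
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  eidx <- integer(nmax)
  eidx[tree$edge[, 2L]] <- seq_len(ne)
  root <- n + 1L
  M <- matrix(0, ne, n)
  for (i in seq_len(n)) {
    v <- i
    while (v != root) {
      M[eidx[v], i] <- 1
      v <- parent[v]
    }
  }
  list(M = M, len = tree$edge.length, labels = tree$tip.label,
       root_edge = .root_edge(tree))
}

.ctx_pd <- function(ctx, idx) {
  if (length(idx) == 0L) return(0)
  cnt <- rowSums(ctx$M[, idx, drop = FALSE])
  sum(ctx$len[cnt > 0]) + ctx$root_edge
}

#' Top-K species by a global metric
#'
#' The K species with the largest metric values; ties at the cutoff are
#' broken deterministically by label order (and reported via a message).
#'
#' @param scores score data.frame with columns `species` and the metric.
#' @param metric one of the metric columns (e.g. `"ED"`, `"PE"`, `"APD"`).
#' @param k number of species to select.
#' @return character vector of K labels, in decreasing score order.
#' @export
top_k_species <- function(scores, metric, k) {
  if (!metric %in% names(scores))
    stop("metric '", metric, "' not in score table", call. = FALSE)
  v <- scores[[metric]]
  if (k < 1L || k > length(v))
    stop("k must be between 1 and the number of scored species (",
         length(v), ")", call. = FALSE)
  ord <- order(-v, scores$species)
  if (k < length(v) && v[ord[k]] == v[ord[k + 1L]])
    message("tie at the top-", k, " cutoff broken by label order")
  scores$species[ord[seq_len(k)]]
}

#' Observed effect of removing the top-ranked set from a community
#'
#' PD loss is the rooted Faith PD of the community minus that of the
#' community without the top-set members; the trait change is mean pairwise
#' Gower distance before minus after (positive values mean the depleted
#' community is more similar in traits).
#'
#' @param community community species: a character vector or named count
#'   vector.
#' @param tree pool phylogeny (`phylo`).
#' @param traits complete `trait_dist` over the pool, or NULL to skip the
#'   trait measure.
#' @param topset character vector of globally top-ranked species.
#' @param context optional [pd_context()] of `tree` (computed if missing).
#' @return list with `pd_loss`, `tapd_change` (`NA` when undefined) and
#'   `m`, the number of top-set species present in the community.
#' @export
observed_removal <- function(community, tree, traits = NULL, topset,
                             context = NULL) {
  sp <- if (!is.null(names(community))) names(community)
        else as.character(community)
  sp <- intersect(unique(sp), tree$tip.label)
  if (length(sp) < 2L)
    stop("community must have at least 2 species on the tree",
         call. = FALSE)
  if (is.null(context)) context <- pd_context(tree)
  idx <- match(sp, context$labels)
  removed <- intersect(sp, topset)
  kept <- setdiff(sp, removed)
  m <- length(removed)
  pd_full <- .ctx_pd(context, idx)
  pd_loss <- pd_full - .ctx_pd(context, match(kept, context$labels))
  tapd_change <- NA_real_
  if (!is.null(traits)) {
    sp_tr <- intersect(sp, rownames(traits$d))
    kept_tr <- intersect(kept, rownames(traits$d))
    if (length(sp_tr) >= 2L && length(kept_tr) >= 2L)
      tapd_change <- mean_pairwise_trait_distance(traits, sp_tr) -
        mean_pairwise_trait_distance(traits, kept_tr)
  }
  list(pd_loss = pd_loss, tapd_change = tapd_change, m = m)
}

#' Random-removal null distribution for one community
#'
#' Removes `m` species uniformly at random (without replacement) from the
#' community, `R` times, returning the PD-loss and trait-change vectors.
#'
#' @inheritParams observed_removal
#' @param m number of species to remove per replicate.
#' @param R number of replicates (default 500).
#' @param seed optional seed set before sampling (for standalone use; the
#'   experiment driver seeds once globally).
#' @return list with numeric vectors `pd_loss` and `tapd_change` of length
#'   `R` (`tapd_change` is all-`NA` when `traits` is NULL or the community
#'   has < 2 trait species).
#' @export
random_removal_null <- function(community, tree, traits = NULL, m,
                                R = 500L, seed = NULL, context = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- if (!is.null(names(community))) names(community)
        else as.character(community)
  sp <- intersect(unique(sp), tree$tip.label)
  k <- length(sp)
  if (m < 0L || m > k)
    stop("m must be between 0 and the community size", call. = FALSE)
  if (is.null(context)) context <- pd_context(tree)
  R <- as.integer(R)
  if (m == 0L)
    return(list(pd_loss = numeric(R),
                tapd_change = if (is.null(traits)) rep(NA_real_, R)
                              else numeric(R)))
  idx <- match(sp, context$labels)
  A <- context$M[, idx, drop = FALSE]
  cntS <- rowSums(A)
  pdS <- sum(context$len[cntS > 0]) + context$root_edge
  Z <- matrix(0, k, R)
  for (r in seq_len(R)) Z[sample.int(k, m), r] <- 1
  cnt_rem <- A %*% Z
  incl <- (cntS - cnt_rem) > 0
  pd_after <- colSums(context$len * incl) +
    ifelse(colSums(incl) > 0, context$root_edge, 0)
  pd_loss <- pdS - pd_after
  tapd_change <- rep(NA_real_, R)
  if (!is.null(traits)) {
    tr_rows <- sp %in% rownames(traits$d)
    sp_tr <- sp[tr_rows]
    if (length(sp_tr) >= 2L) {
      D <- .complete_dist(traits)[sp_tr, sp_tr, drop = FALSE]
      k_tr <- length(sp_tr)
      S_tot <- sum(D)
      rvec <- rowSums(D)
      mean_before <- S_tot / (k_tr * (k_tr - 1))
      ZT <- Z[tr_rows, , drop = FALSE]
      rem_tr <- colSums(ZT)
      term1 <- as.numeric(crossprod(rvec, ZT))
      term2 <- colSums(ZT * (D %*% ZT))
      sum_after <- S_tot - 2 * term1 + term2
      k_after <- k_tr - rem_tr
      mean_after <- ifelse(k_after >= 2,
                           sum_after / (k_after * (k_after - 1)), NA_real_)
      tapd_change <- mean_before - mean_after
    }
  }
  list(pd_loss = pd_loss, tapd_change = tapd_change)
}

#' Add-one empirical p-value (one-sided, greater)
#'
#' `p = (1 + #\{null >= observed\}) / (R + 1)`; never exactly zero, testing
#' whether the observed loss exceeds random expectation.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null replicates (non-empty; `NA`s dropped).
#' @return a p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  null <- null[!is.na(null)]
  if (length(null) == 0L) stop("null distribution is empty", call. = FALSE)
  (1 + sum(null >= observed)) / (length(null) + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1.
#'
#' @param pvals numeric vector of p-values in `(0, 1]` (`NA`s passed
#'   through).
#' @return vector of q-values.
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Top-K removal experiment across communities
#'
#' For each requested global metric: rank the pool by the metric, take the
#' top K species, remove them from every community, and compare the
#' observed PD loss and mean-pairwise-trait-distance change against a
#' uniform random-removal null of the same size (R replicates per
#' community).  Empirical p-values use the add-one estimator; q-values are
#' BH-adjusted across communities within each metric.
#'
#' @param tree the pool phylogeny used to measure PD (a single `phylo`;
#'   with an ensemble, scores are aggregated upstream and a representative
#'   tree is used here).
#' @param communities a `community_table`.
#' @param traits complete `trait_dist` over the pool, or NULL.
#' @param global_scores score data.frame (e.g. from [median_scores()]).
#' @param metrics which global metrics to rank by (default all three).
#' @param k top-rank cutoff (default 500).
#' @param R null replicates per community (default 500).
#' @param seed RNG seed for the null draws.
#' @param alpha FDR significance level used in the summary (default 0.05).
#' @return object of class `removal_result`: list with per-community
#'   `results` and the per-metric `summary` table.
#' @export
removal_experiment <- function(tree, communities, traits = NULL,
                               global_scores, metrics = c("ED", "PE", "APD"),
                               k = 500L, R = 500L, seed = NULL,
                               alpha = 0.05) {
  if (inherits(tree, "tree_ensemble")) tree <- tree[[1L]]
  .validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  ctx <- pd_context(tree)
  metrics <- match.arg(metrics, c("ED", "PE", "APD"), several.ok = TRUE)
  rows <- list()
  for (metric in metrics) {
    topset <- top_k_species(global_scores, metric, k)
    for (s in names(communities$communities)) {
      cm <- communities$communities[[s]]
      sp <- intersect(names(cm), tree$tip.label)
      if (length(sp) < 2L) next
      obs <- observed_removal(sp, tree, traits, topset, context = ctx)
      nul <- random_removal_null(sp, tree, traits, obs$m, R = R,
                                 context = ctx)
      p_pd <- empirical_pvalue(obs$pd_loss, nul$pd_loss)
      p_tapd <- if (is.na(obs$tapd_change) || all(is.na(nul$tapd_change)))
        NA_real_ else empirical_pvalue(obs$tapd_change, nul$tapd_change)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = communities$variant, metric = metric, community = s,
        n_species = length(sp), m = obs$m,
        pd_loss = obs$pd_loss,
        null_pd_mean = mean(nul$pd_loss),
        null_pd_sd = stats::sd(nul$pd_loss),
        tapd_change = obs$tapd_change,
        null_tapd_mean = mean(nul$tapd_change, na.rm = TRUE),
        null_tapd_sd = stats::sd(nul$tapd_change, na.rm = TRUE),
        p_pd = p_pd, p_tapd = p_tapd,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  results$q_pd <- NA_real_
  results$q_tapd <- NA_real_
  for (metric in metrics) {
    i <- results$metric == metric
    results$q_pd[i] <- fdr_adjust(results$p_pd[i])
    results$q_tapd[i] <- fdr_adjust(results$p_tapd[i])
  }
  structure(list(results = results,
                 summary = summarize_removal(results, alpha = alpha),
                 k = k, R = R),
            class = "removal_result")
}

#' Summarize a removal experiment per metric
#'
#' The machine analogue of a "loss under targeted vs random removal"
#' table: mean observed and mean null PD loss, mean observed and mean null
#' trait-distance change, mean q-values and the share of communities
#' significant after FDR control.
#'
#' @param results per-community results data.frame from
#'   [removal_experiment()] (or a `removal_result`).
#' @param alpha FDR significance level (default 0.05).
#' @return one-row-per-metric data.frame.
#' @export
summarize_removal <- function(results, alpha = 0.05) {
  if (inherits(results, "removal_result")) results <- results$results
  if (is.null(results$q_pd)) {
    results$q_pd <- NA_real_
    results$q_tapd <- NA_real_
    for (metric in unique(results$metric)) {
      i <- results$metric == metric
      results$q_pd[i] <- fdr_adjust(results$p_pd[i])
      results$q_tapd[i] <- fdr_adjust(results$p_tapd[i])
    }
  }
  out <- lapply(unique(results$metric), function(metric) {
    sub <- results[results$metric == metric, , drop = FALSE]
    data.frame(metric = metric,
               n_communities = nrow(sub),
               mean_pd_loss = mean(sub$pd_loss),
               mean_null_pd_loss = mean(sub$null_pd_mean),
               mean_tapd_change = mean(sub$tapd_change, na.rm = TRUE),
               mean_null_tapd_change = mean(sub$null_tapd_mean, na.rm = TRUE),
               mean_q_pd = mean(sub$q_pd, na.rm = TRUE),
               prop_sig_pd = mean(sub$q_pd < alpha, na.rm = TRUE),
               mean_q_tapd = mean(sub$q_tapd, na.rm = TRUE),
               prop_sig_tapd = mean(sub$q_tapd < alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.removal_result <- function(x, ...) {
  cat(sprintf("Top-%d removal experiment (%d null replicates)\n", x$k, x$R))
  print(x$summary, digits = 4)
  invisible(x)
}
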