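# Brute-force oracles, deliberately independent of the package internals:
# edge sets are enumerated by recursion over the ape edge table, distances
# by root-to-tip edge-set algebra, Gower by an explicit per-pair/per-column
# loop, Spearman by hand-computed mid-ranks and the Pearson formula.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

xyz_traits <- function() {
  tab <- data.frame(mass = c(1, 3, 3),
                    habitat = c("forest", "forest", "grass"),
                    row.names = c("X", "Y", "Z"))
  spec <- trait_type_spec(c(mass = "quantitative", habitat = "nominal"),
                          standardize = FALSE)
  list(tab = tab, spec = spec)
}

random_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0, 2)
  tr
}

# named list: for each edge (child-node id), the set of tip labels below it
oracle_edge_tipsets <- function(tree) {
  n <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], below), use.names = FALSE)
  }
  lapply(seq_len(nrow(tree$edge)),
         function(e) below(tree$edge[e, 2L]))
}

oracle_ed <- function(tree) {
  tipsets <- oracle_edge_tipsets(tree)
  ed <- stats::setNames(numeric(ape::Ntip(tree)), tree$tip.label)
  for (e in seq_along(tipsets))
    ed[tipsets[[e]]] <- ed[tipsets[[e]]] +
      tree$edge.length[e] / length(tipsets[[e]])
  re <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  ed + re / ape::Ntip(tree)
}

oracle_pe <- function(tree) {
  tipsets <- oracle_edge_tipsets(tree)
  pe <- stats::setNames(numeric(ape::Ntip(tree)), tree$tip.label)
  for (e in seq_along(tipsets))
    if (length(tipsets[[e]]) == 1L)
      pe[tipsets[[e]]] <- tree$edge.length[e]
  pe
}

# root-to-tip edge index sets; distance = total length of the symmetric
# difference of the two paths
oracle_root_paths <- function(tree) {
  tipsets <- oracle_edge_tipsets(tree)
  lapply(tree$tip.label, function(sp)
    which(vapply(tipsets, function(s) sp %in% s, logical(1))))
}

oracle_patristic <- function(tree) {
  paths <- oracle_root_paths(tree)
  n <- ape::Ntip(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sym <- c(setdiff(paths[[i]], paths[[j]]),
             setdiff(paths[[j]], paths[[i]]))
    d[i, j] <- sum(tree$edge.length[sym])
  }
  d
}

oracle_apd <- function(tree) {
  d <- oracle_patristic(tree)
  rowSums(d) / (ncol(d) - 1)
}

oracle_pd <- function(tree, species, include_root = TRUE) {
  paths <- oracle_root_paths(tree)
  names(paths) <- tree$tip.label
  edges <- unique(unlist(paths[species], use.names = FALSE))
  re <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  pd <- sum(tree$edge.length[edges]) + re
  if (!include_root) {
    shared <- Reduce(intersect, paths[species])
    pd <- pd - sum(tree$edge.length[shared]) - re
  }
  pd
}

oracle_gower <- function(tab, spec) {
  n <- nrow(tab)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(tab), rownames(tab)))
  ranges <- list()
  for (cn in names(tab)) {
    ty <- spec$type[spec$trait == cn]
    x <- tab[[cn]]
    if (ty == "ordinal") x <- match(x, sort(unique(stats::na.omit(x))))
    if (ty != "nominal")
      ranges[[cn]] <- diff(range(x, na.rm = TRUE))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- 0; cnt <- 0L
    for (cn in names(tab)) {
      ty <- spec$type[spec$trait == cn]
      x <- tab[[cn]]
      if (ty == "ordinal") x <- match(x, sort(unique(stats::na.omit(x))))
      xi <- x[i]; xj <- x[j]
      if (is.na(xi) || is.na(xj)) next
      cnt <- cnt + 1L
      tot <- tot + if (ty == "nominal") as.numeric(xi != xj)
        else if (ranges[[cn]] == 0) 0
        else abs(xi - xj) / ranges[[cn]]
    }
    d[i, j] <- if (cnt == 0L) NA_real_ else tot / cnt
  }
  diag(d) <- 0
  d
}

oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

.read_synonyms_for_test <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$to, df$from)
}

# small community table built directly from named count vectors
make_communities <- function(..., variant = "FULL") {
  cms <- list(...)
  tab <- collapse_years(do.call(rbind, lapply(names(cms), function(s)
    data.frame(site = s, species = names(cms[[s]]),
               count = as.numeric(cms[[s]]), stringsAsFactors = FALSE))))
  tab$variant <- variant
  tab
}
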