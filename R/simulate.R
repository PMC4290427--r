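## Seeded synthetic data with the statistical structure the analysis
## assumes: a pure-birth pool phylogeny, an ensemble of branch-length
## jittered replicates of it, traits evolved on the tree (Brownian motion
## for quantitative, Mk for nominal) so trait distance tracks patristic
## distance, and communities drawn as abundance-weighted, optionally
## phylogenetically clustered subsets of the pool.

#' Simulation configuration
#'
#' @param n_species pool size (default 300).
#' @param n_trees ensemble size (default 10).
#' @param birth Yule speciation rate (default 1; time units are arbitrary).
#' @param jitter_sd s.d. of multiplicative log-normal branch-length jitter
#'   across ensemble trees (default 0.1).
#' @param n_communities number of communities (default 200).
#' @param richness community richness range `c(lo, hi)` (default
#'   `c(26, 150)`; the lower bound mirrors the post-filter survey floor).
#' @param alpha phylogenetic clustering strength: community members are
#'   drawn with weight `exp(-alpha * d(i, seed_species))`; 0 = uniform
#'   subsets (default 0).
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters
#'   (defaults `log(20)` and 1.5, giving a realistic tail of locally rare
#'   species below the 1-percent rarity threshold).
#' @param n_quant_traits number of Brownian quantitative traits (default
#'   16, the size of a typical avian ecological trait set once diet
#'   composition is split into its component columns).
#' @param bm_sigma Brownian s.d. per unit branch length (default 0.5);
#'   quantitative traits are exponentiated (body-mass-like, positive).
#' @param n_nominal_traits number of Mk nominal traits (default 6: e.g.
#'   habitat, guild, social structure, nest type, nest substrate, activity
#'   pattern).
#' @param mk_rate Mk transition rate (default 0.3).
#' @param n_states states per nominal trait (default 8).
#' @param missingness probability a trait cell is masked missing
#'   (default 0.05).
#' @param n_aliens number of pool species labelled alien (default 10).
#' @param seed RNG seed (or NULL).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 300L, n_trees = 10L, birth = 1,
                       jitter_sd = 0.1, n_communities = 200L,
                       richness = c(26L, 150L), alpha = 0,
                       abundance_meanlog = log(20), abundance_sdlog = 1.5,
                       n_quant_traits = 16L, bm_sigma = 0.5,
                       n_nominal_traits = 6L, mk_rate = 0.3,
                       n_states = 8L, missingness = 0.05,
                       n_aliens = 10L, seed = NULL) {
  stopifnot(n_species >= 2L, n_trees >= 1L, birth > 0, jitter_sd >= 0,
            length(richness) == 2L, richness[1L] >= 2L,
            richness[1L] <= richness[2L], alpha >= 0,
            missingness >= 0, missingness < 1, mk_rate >= 0,
            n_states >= 2L, bm_sigma >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth (Yule) pool phylogeny
#'
#' Exponential waiting times between speciation events, stopped at
#' `n_species` extant tips; tips relabelled `sp0001, sp0002, ...`.  Yule
#' trees are ultrametric.
#'
#' @param cfg a [sim_config()].
#' @param seed seed set before simulation (default `cfg$seed`).
#' @return a rooted ultrametric `phylo`.
#' @export
simulate_yule_tree <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(cfg$n_species, birth = cfg$birth, death = 0)
  tr$tip.label <- sprintf("sp%04d", seq_len(cfg$n_species))
  tr
}

#' Simulate a tree ensemble by branch-length jitter
#'
#' A base Yule tree plus `n_trees - 1` copies whose branch lengths are
#' multiplied by i.i.d. log-normal noise (mean 1), emulating replicate
#' trees from a posterior sample while keeping one tip set and topology.
#'
#' @inheritParams simulate_yule_tree
#' @return a [tree_ensemble()].
#' @export
simulate_tree_ensemble <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  base <- simulate_yule_tree(cfg, seed = NULL)
  trees <- vector("list", cfg$n_trees)
  trees[[1L]] <- base
  ne <- nrow(base$edge)
  if (cfg$n_trees > 1L) {
    for (i in 2L:cfg$n_trees) {
      tr <- base
      if (cfg$jitter_sd > 0)
        tr$edge.length <- tr$edge.length *
          stats::rlnorm(ne, meanlog = -cfg$jitter_sd^2 / 2,
                        sdlog = cfg$jitter_sd)
      trees[[i]] <- tr
    }
  }
  tree_ensemble(trees, id = "simulated")
}

#' Trait type spec matching the synthetic trait table
#'
#' @param cfg a [sim_config()].
#' @return a [trait_type_spec()] covering the simulated columns.
#' @export
sim_trait_types <- function(cfg = sim_config()) {
  types <- c(
    stats::setNames(rep("quantitative", cfg$n_quant_traits),
                    sprintf("qt%02d", seq_len(cfg$n_quant_traits))),
    stats::setNames(rep("nominal", cfg$n_nominal_traits),
                    sprintf("nom%02d", seq_len(cfg$n_nominal_traits))))
  trait_type_spec(types, standardize = TRUE)
}

#' Simulate traits on a tree
#'
#' Quantitative traits evolve by Brownian motion along branches (variance
#' `bm_sigma^2 * branch length`) and are exponentiated so they are positive
#' and body-mass-like; nominal traits evolve under an equal-rates Mk
#' process.  Cells are masked missing independently at the configured rate.
#'
#' @param tree the pool phylogeny.
#' @inheritParams simulate_yule_tree
#' @return trait data.frame (rownames = tip labels) whose columns match
#'   [sim_trait_types()].
#' @export
simulate_traits <- function(tree, cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  .validate_tree(tree)
  n <- ape::Ntip(tree)
  tab <- data.frame(row.names = tree$tip.label)
  for (j in seq_len(cfg$n_quant_traits)) {
    x <- ape::rTraitCont(tree, model = "BM", sigma = cfg$bm_sigma,
                         root.value = 0)
    tab[[sprintf("qt%02d", j)]] <- exp(x[tree$tip.label])
  }
  for (j in seq_len(cfg$n_nominal_traits)) {
    x <- ape::rTraitDisc(tree, model = "ER", k = cfg$n_states,
                         rate = cfg$mk_rate,
                         states = LETTERS[seq_len(cfg$n_states)])
    tab[[sprintf("nom%02d", j)]] <- as.character(x[tree$tip.label])
  }
  if (cfg$missingness > 0) {
    mask <- matrix(stats::runif(n * ncol(tab)) < cfg$missingness,
                   n, ncol(tab))
    for (j in seq_len(ncol(tab))) tab[[j]][mask[, j]] <- NA
  }
  tab
}

#' Simulate communities from the pool
#'
#' Each community draws its richness uniformly from the configured range,
#' picks a seed species uniformly, then samples the remaining members
#' without replacement with weight `exp(-alpha * d(i, seed))` on the
#' patristic distance (`alpha = 0` gives uniform subsets; large `alpha`
#' concentrates communities within clades).  Abundance counts are
#' integerized log-normal draws (minimum 1).
#'
#' @param tree the pool phylogeny.
#' @inheritParams simulate_yule_tree
#' @return a `community_table` (variant `"FULL"`) with random site
#'   coordinates.
#' @export
simulate_communities <- function(tree, cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  .validate_tree(tree)
  n <- ape::Ntip(tree)
  if (cfg$richness[2L] > n)
    stop("richness range exceeds pool size", call. = FALSE)
  D <- patristic_matrix(tree)
  communities <- vector("list", cfg$n_communities)
  ids <- sprintf("site%04d", seq_len(cfg$n_communities))
  for (c_i in seq_len(cfg$n_communities)) {
    k <- if (cfg$richness[1L] == cfg$richness[2L]) cfg$richness[1L]
         else sample(seq.int(cfg$richness[1L], cfg$richness[2L]), 1L)
    seed_sp <- sample.int(n, 1L)
    members <- seed_sp
    if (k > 1L) {
      w <- exp(-cfg$alpha * D[, seed_sp])
      w[seed_sp] <- 0
      members <- c(seed_sp,
                   sample(seq_len(n)[-seed_sp], k - 1L,
                          prob = w[-seed_sp]))
    }
    counts <- pmax(1, round(stats::rlnorm(k, cfg$abundance_meanlog,
                                          cfg$abundance_sdlog)))
    sp <- sort(tree$tip.label[members])
    communities[[c_i]] <- stats::setNames(
      counts[order(tree$tip.label[members])], sp)
  }
  coords <- data.frame(site = ids,
                       lat = stats::runif(cfg$n_communities, 25, 50),
                       lon = stats::runif(cfg$n_communities, -125, -70),
                       stringsAsFactors = FALSE)
  .new_community_table(stats::setNames(communities, ids), coords,
                       variant = "FULL")
}

#' Explode a community table into multi-year survey records
#'
#' Splits each species' count across one or two survey years so the
#' year-collapsing step is exercised by round-trips through the survey CSV.
#'
#' @param communities a `community_table`.
#' @param years candidate survey years.
#' @param seed optional seed.
#' @return data.frame of survey records (`site, species, count, year, lat,
#'   lon`).
#' @export
simulate_surveys <- function(communities, years = 2000:2002, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (s in names(communities$communities)) {
    cm <- communities$communities[[s]]
    co <- communities$coords[communities$coords$site == s, , drop = FALSE]
    for (sp in names(cm)) {
      cnt <- cm[[sp]]
      yr <- sample(years, 1L)
      if (cnt > 1L && stats::runif(1) < 0.5) {
        c1 <- sample.int(cnt - 1L, 1L)
        yr2 <- sample(setdiff(years, yr), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          site = s, species = sp, count = c(c1, cnt - c1),
          year = c(yr, yr2), lat = co$lat, lon = co$lon,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          site = s, species = sp, count = cnt, year = yr,
          lat = co$lat, lon = co$lon, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes the exact file formats the pipeline consumes: a multi-line Newick
#' ensemble, a survey CSV (with years split so collapsing is exercised), a
#' trait CSV with its JSON type spec, an alien-species list and a synonym
#' map (a few survey records are relabelled as `<species>_sub` sub-species
#' so the reconciliation step has work to do).
#'
#' @param out_dir output directory (created if needed).
#' @param cfg a [sim_config()]; `cfg$seed` seeds the whole bundle.
#' @return invisibly, a named list of the file paths plus the in-memory
#'   objects (`ensemble`, `traits`, `communities`).
#' @export
simulate_dataset <- function(out_dir, cfg = sim_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ens <- simulate_tree_ensemble(cfg, seed = NULL)
  tree <- ens[[1L]]
  traits <- simulate_traits(tree, cfg, seed = NULL)
  communities <- simulate_communities(tree, cfg, seed = NULL)
  surveys <- simulate_surveys(communities, seed = NULL)
  ## relabel a few records as sub-species; the synonym map restores them
  pool <- tree$tip.label
  syn_parents <- sample(pool, min(5L, length(pool)))
  synonyms <- stats::setNames(syn_parents, paste0(syn_parents, "_sub"))
  hit <- which(surveys$species %in% syn_parents)
  hit <- hit[seq_len(min(20L, length(hit)))]
  surveys$species[hit] <- paste0(surveys$species[hit], "_sub")
  aliens <- sample(pool, min(cfg$n_aliens, length(pool)))

  paths <- list(
    trees = file.path(out_dir, "trees.nwk"),
    surveys = file.path(out_dir, "surveys.csv"),
    traits = file.path(out_dir, "traits.csv"),
    trait_types = file.path(out_dir, "trait_types.json"),
    aliens = file.path(out_dir, "aliens.txt"),
    synonyms = file.path(out_dir, "synonyms.csv"))
  write_trees(ens, paths$trees)
  utils::write.csv(surveys, paths$surveys, row.names = FALSE)
  utils::write.csv(cbind(species = rownames(traits), traits),
                   paths$traits, row.names = FALSE)
  write_trait_types(sim_trait_types(cfg), paths$trait_types)
  writeLines(aliens, paths$aliens)
  utils::write.csv(data.frame(from = names(synonyms),
                              to = unname(synonyms)),
                   paths$synonyms, row.names = FALSE)
  invisible(c(paths, list(ensemble = ens, traits = traits,
                          communities = communities)))
}
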