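test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_species = 20, n_trees = 3, n_communities = 5,
                    richness = c(5, 10), seed = 123)
  t1 <- simulate_yule_tree(cfg)
  t2 <- simulate_yule_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  e1 <- simulate_tree_ensemble(cfg)
  e2 <- simulate_tree_ensemble(cfg)
  expect_identical(lapply(unclass(e1), ape::write.tree),
                   lapply(unclass(e2), ape::write.tree))
  c1 <- simulate_communities(t1, cfg)
  c2 <- simulate_communities(t1, cfg)
  expect_identical(c1$communities, c2$communities)
  tr1 <- simulate_traits(t1, cfg)
  tr2 <- simulate_traits(t1, cfg)
  expect_identical(tr1, tr2)
})

test_that("Yule trees are ultrametric with the requested tip count", {
  cfg <- sim_config(n_species = 2, seed = 5)
  cherry <- simulate_yule_tree(cfg)
  expect_equal(ape::Ntip(cherry), 2)
  depths <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(depths[1], depths[2])     # both tips at the same depth
  big <- simulate_yule_tree(sim_config(n_species = 50, seed = 6))
  expect_equal(ape::Ntip(big), 50)
  expect_true(ape::is.ultrametric(big, tol = 1e-8))
  expect_equal(sort(big$tip.label)[1], "sp0001")
})

test_that("ensembles share one tip set; zero jitter gives identical trees", {
  cfg0 <- sim_config(n_species = 15, n_trees = 4, jitter_sd = 0, seed = 9)
  ens0 <- simulate_tree_ensemble(cfg0)
  expect_length(ens0, 4)
  for (i in 2:4)
    expect_equal(ens0[[i]]$edge.length, ens0[[1]]$edge.length)
  ms <- median_scores(ens0)
  one <- tree_scores(ens0[[1]])
  expect_equal(ms$ED, one$ED)
  cfg1 <- sim_config(n_species = 15, n_trees = 4, jitter_sd = 0.3,
                     seed = 9)
  ens1 <- simulate_tree_ensemble(cfg1)
  expect_false(identical(ens1[[2]]$edge.length, ens1[[1]]$edge.length))
  for (i in 2:4)
    expect_setequal(ens1[[i]]$tip.label, ens1[[1]]$tip.label)
})

test_that("trait generation respects sigma and missingness settings", {
  tr <- simulate_yule_tree(sim_config(n_species = 30, seed = 12))
  cfg0 <- sim_config(n_species = 30, bm_sigma = 0, missingness = 0,
                     n_nominal_traits = 1, seed = 13)
  tab <- simulate_traits(tr, cfg0)
  expect_equal(length(unique(tab$qt01)), 1L)  # sigma 0: constant trait
  expect_false(anyNA(tab))                    # missingness 0: complete
  cfg1 <- sim_config(n_species = 30, missingness = 0.3, seed = 14)
  tab1 <- simulate_traits(tr, cfg1)
  frac <- mean(is.na(as.matrix(tab1)))
  expect_gt(frac, 0.15); expect_lt(frac, 0.45)
})

test_that("Brownian traits make trait distance track patristic distance", {
  hits <- 0L
  for (rep in 1:20) {
    set.seed(500 + rep)
    cfg <- sim_config(n_species = 40, bm_sigma = 1, missingness = 0,
                      n_quant_traits = 3, n_nominal_traits = 0,
                      seed = NULL)
    tr <- simulate_yule_tree(cfg, seed = NULL)
    tab <- simulate_traits(tr, cfg, seed = NULL)
    D <- patristic_matrix(tr)
    sq <- as.matrix(dist(log(as.matrix(tab))))^2
    ut <- upper.tri(D)
    if (cor(D[ut], sq[ut], method = "spearman") > 0) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("communities respect richness bounds and clustering direction", {
  cfg <- sim_config(n_species = 50, n_communities = 30,
                    richness = c(5, 12), seed = 31)
  tr <- simulate_yule_tree(cfg)
  comm <- simulate_communities(tr, cfg)
  rich <- community_richness(comm)
  expect_true(all(rich >= 5 & rich <= 12))
  expect_true(all(unlist(comm$communities) >= 1))
  # richness = pool size with alpha 0: every community is the pool
  cfgP <- sim_config(n_species = 20, n_communities = 3,
                     richness = c(20, 20), alpha = 0, seed = 32)
  trP <- simulate_yule_tree(cfgP)
  commP <- simulate_communities(trP, cfgP)
  for (cm in commP$communities)
    expect_setequal(names(cm), trP$tip.label)
  # strong clustering concentrates communities: lower local PD
  pdfrac <- function(alpha, seed) {
    cfgA <- sim_config(n_species = 80, n_communities = 15,
                       richness = c(10, 10), alpha = alpha, seed = seed)
    trA <- simulate_yule_tree(cfgA)
    cmA <- simulate_communities(trA, cfgA)
    mean(vapply(cmA$communities, function(cm)
      faith_pd(trA, names(cm)), numeric(1))) / sum(trA$edge.length)
  }
  expect_lt(pdfrac(5, 33), pdfrac(0, 33))
})

test_that("the on-disk bundle is consumable by the readers", {
  tdir <- withr::local_tempdir()
  cfg <- sim_config(n_species = 25, n_trees = 2, n_communities = 4,
                    richness = c(5, 10), seed = 44)
  bundle <- simulate_dataset(tdir, cfg)
  expect_true(all(file.exists(unlist(bundle[1:6]))))
  ens <- read_trees(bundle$trees)
  expect_length(ens, 2)
  spec <- read_trait_types(bundle$trait_types)
  tab <- read_trait_table(bundle$traits, spec)
  expect_equal(sort(rownames(tab)), sort(ens[[1]]$tip.label))
  rec <- read_survey_records(bundle$surveys)
  collapsed <- collapse_years(rec)
  # survey year-splitting plus synonym records still conserve counts
  cfg_syn <- filter_config(synonyms = .read_synonyms_for_test(bundle$synonyms))
  rec_tab <- reconcile_names(collapsed, ens[[1]]$tip.label, cfg_syn)
  expect_equal(sum(unlist(rec_tab$communities)),
               sum(unlist(bundle$communities$communities)))
  expect_identical(rec_tab$communities, bundle$communities$communities)
})
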