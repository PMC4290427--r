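test_that("top-k selection ranks by metric with deterministic tie-breaking", {
  scores <- data.frame(species = c("A", "B", "C"), ED = c(3, 2, 1))
  expect_equal(top_k_species(scores, "ED", 2), c("A", "B"))
  expect_equal(top_k_species(scores, "ED", 3), c("A", "B", "C"))
  tied <- data.frame(species = c("B", "A", "C"), ED = c(2, 2, 1))
  expect_message(top <- top_k_species(tied, "ED", 1), "tie")
  expect_equal(top, "A")      # label order at the cutoff
  expect_error(top_k_species(scores, "ED", 4), "between 1")
  expect_error(top_k_species(scores, "APD", 1), "APD")
})

test_that("observed removal measures PD loss and trait-distance change", {
  tr <- toy_tree()
  obs <- observed_removal(c("A", "B", "C"), tr, NULL, topset = "C")
  expect_equal(obs$pd_loss, 2)    # 5 - 3
  expect_equal(obs$m, 1)
  # disjoint top set: nothing changes
  obs0 <- observed_removal(c("A", "B", "C"), tr, NULL, topset = "Z")
  expect_equal(obs0$pd_loss, 0)
  expect_equal(obs0$m, 0)
  # trait change on the X/Y/Z fixture, removing the outlier Z
  xyz <- xyz_traits()
  td <- gower_matrix(xyz$tab, xyz$spec)
  tr3 <- ape::read.tree(text = "((X:1,Y:1):1,Z:2);")
  obs2 <- observed_removal(c("X", "Y", "Z"), tr3, td, topset = "Z")
  expect_equal(obs2$tapd_change, (0.5 + 0.5 + 1) / 3 - 0.5)  # +1/6
  expect_gt(obs2$tapd_change, 0)  # outlier removal leaves similar species
})

test_that("random null has correct degenerate and exhaustive behaviour", {
  tr <- toy_tree()
  # m = 0: all-zero null
  nul0 <- random_removal_null(c("A", "B", "C"), tr, NULL, m = 0, R = 10)
  expect_equal(nul0$pd_loss, rep(0, 10))
  # m = community size: every replicate loses the full PD
  nulF <- random_removal_null(c("A", "B", "C"), tr, NULL, m = 3, R = 10,
                              seed = 1)
  expect_equal(nulF$pd_loss, rep(5, 10))
  # m = 1 on the toy tree: exhaustive mean is (1 + 1 + 2) / 3
  nul1 <- random_removal_null(c("A", "B", "C"), tr, NULL, m = 1, R = 600,
                              seed = 2)
  se <- sd(nul1$pd_loss) / sqrt(length(nul1$pd_loss))
  expect_lt(abs(mean(nul1$pd_loss) - 4 / 3), 3 * se)
  # determinism under a fixed seed
  a <- random_removal_null(c("A", "B", "C"), tr, NULL, m = 2, R = 50,
                           seed = 7)
  b <- random_removal_null(c("A", "B", "C"), tr, NULL, m = 2, R = 50,
                           seed = 7)
  expect_identical(a, b)
})

test_that("null PD losses agree with picante-based enumeration", {
  set.seed(91)
  tr <- random_tree(7)
  sp <- sample(tr$tip.label, 5)
  cm <- matrix(1, 1, length(sp), dimnames = list("s", sp))
  ref_full <- picante::pd(cm, tr, include.root = TRUE)$PD
  expect_equal(faith_pd(tr, sp), ref_full, tolerance = 1e-10)
  # exhaustive m = 2 enumeration with oracle PD
  pairs <- combn(sp, 2)
  exp_loss <- mean(apply(pairs, 2, function(rm)
    oracle_pd(tr, sp) - oracle_pd(tr, setdiff(sp, rm))))
  nul <- random_removal_null(sp, tr, NULL, m = 2, R = 800, seed = 5)
  se <- sd(nul$pd_loss) / sqrt(800)
  expect_lt(abs(mean(nul$pd_loss) - exp_loss), 3 * se)
})

test_that("empirical p uses the add-one estimator", {
  expect_equal(empirical_pvalue(10, rep(1, 500)), 1 / 501)
  expect_equal(empirical_pvalue(1, rep(1, 500)), 1)
  nul <- 1:99
  expect_equal(empirical_pvalue(50, nul), (1 + 50) / 100)
  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("BH adjustment reproduces the hand-computed example", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.1, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("removal experiment is seed-deterministic and summarizes per metric", {
  set.seed(95)
  cfg <- sim_config(n_species = 40, n_trees = 2, n_communities = 8,
                    richness = c(5, 15), seed = NULL)
  ens <- simulate_tree_ensemble(cfg, seed = NULL)
  comm <- simulate_communities(ens[[1]], cfg, seed = NULL)
  traits <- trait_distance(simulate_traits(ens[[1]], cfg, seed = NULL),
                           sim_trait_types(cfg))
  scores <- median_scores(ens)
  r1 <- removal_experiment(ens[[1]], comm, traits, scores, k = 8, R = 60,
                           seed = 42)
  r2 <- removal_experiment(ens[[1]], comm, traits, scores, k = 8, R = 60,
                           seed = 42)
  expect_identical(r1$results, r2$results)
  expect_setequal(r1$summary$metric, c("ED", "PE", "APD"))
  expect_true(all(r1$results$pd_loss >= 0))
  expect_true(all(r1$results$p_pd > 0 & r1$results$p_pd <= 1))
  expect_true(all(r1$results$q_pd > 0 & r1$results$q_pd <= 1))
  expect_true(all(r1$results$m <= 8))
  # topset = whole pool loses the full community PD everywhere
  all_sp <- median_scores(ens)$species
  rall <- removal_experiment(ens[[1]], comm, NULL, scores, k = 40, R = 5,
                             seed = 1)
  pool_pd <- vapply(names(comm$communities), function(s)
    faith_pd(ens[[1]], names(comm$communities[[s]])), numeric(1))
  for (m in c("ED", "PE", "APD")) {
    sub <- rall$results[rall$results$metric == m, ]
    expect_equal(sub$pd_loss, unname(pool_pd[sub$community]))
  }
})

test_that("mean summary matches simple aggregation", {
  res <- data.frame(variant = "FULL", metric = "ED",
                    community = c("a", "b"), n_species = 10, m = 2,
                    pd_loss = c(2, 4), null_pd_mean = c(1, 1),
                    null_pd_sd = 0.1, tapd_change = c(0.1, 0.3),
                    null_tapd_mean = 0, null_tapd_sd = 0.01,
                    p_pd = c(0.01, 0.2), p_tapd = c(0.5, 0.6))
  s <- summarize_removal(res)
  expect_equal(s$mean_pd_loss, 3)
  expect_equal(s$mean_tapd_change, 0.2)
  expect_equal(s$mean_null_pd_loss, 1)
})
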