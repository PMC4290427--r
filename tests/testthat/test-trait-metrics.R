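test_that("mean standardization divides by the column mean", {
  tab <- data.frame(mass = c(2, 4, NA), row.names = c("a", "b", "c"))
  spec <- trait_type_spec(c(mass = "quantitative"))
  out <- standardize_quantitative(tab, spec)
  expect_equal(out$mass, c(2 / 3, 4 / 3, NA))
  tab2 <- data.frame(mass = c(5, 5), row.names = c("a", "b"))
  expect_equal(standardize_quantitative(tab2, spec)$mass, c(1, 1))
  tab3 <- data.frame(mass = c(0, 0), row.names = c("a", "b"))
  expect_error(standardize_quantitative(tab3, spec), "mass")
  # centering variant
  expect_equal(standardize_quantitative(tab, spec, center = TRUE)$mass,
               c(-1, 1, NA))
})

test_that("Gower distances reproduce the hand-computed mixed-type example", {
  xyz <- xyz_traits()
  td <- gower_matrix(xyz$tab, xyz$spec)
  expect_equal(td$d["X", "Y"], 0.5)
  expect_equal(td$d["Y", "Z"], 0.5)
  expect_equal(td$d["X", "Z"], 1.0)
  expect_equal(diag(td$d), c(X = 0, Y = 0, Z = 0))
  expect_equal(trait_uniqueness(td), c(X = 0.5, Y = 0.5, Z = 0.5))
  expect_equal(trait_apd(td), c(X = 0.75, Y = 0.5, Z = 0.75))
})

test_that("identical rows give distance zero and all-different nominals one", {
  tab <- data.frame(a = c(1, 1), b = c("x", "x"), row.names = c("s1", "s2"))
  spec <- trait_type_spec(c(a = "quantitative", b = "nominal"),
                          standardize = FALSE)
  expect_warning(td <- gower_matrix(tab, spec), "zero range")
  expect_equal(td$d["s1", "s2"], 0)
  tab2 <- data.frame(a = c("p", "q"), b = c("x", "y"),
                     row.names = c("s1", "s2"))
  spec2 <- trait_type_spec(c(a = "nominal", b = "nominal"))
  expect_equal(gower_matrix(tab2, spec2)$d["s1", "s2"], 1)
})

test_that("Gower matches a brute-force per-pair loop on random mixed tables", {
  set.seed(55)
  for (rep in 1:8) {
    n <- sample(4:12, 1); p <- sample(3:10, 1)
    types <- sample(c("quantitative", "ordinal", "nominal"), p,
                    replace = TRUE)
    tab <- data.frame(row.names = sprintf("s%02d", 1:n))
    for (j in 1:p) {
      col <- switch(types[j],
                    quantitative = round(runif(n, 0, 10), 2),
                    ordinal = sample(1:4, n, replace = TRUE),
                    nominal = sample(letters[1:3], n, replace = TRUE))
      col[runif(n) < 0.25] <- NA   # >= 20% missingness on average
      tab[[sprintf("t%02d", j)]] <- col
    }
    spec <- trait_type_spec(stats::setNames(types, names(tab)),
                            standardize = FALSE)
    td <- suppressWarnings(gower_matrix(tab, spec))
    expect_equal(td$d, oracle_gower(tab, spec), tolerance = 1e-12)
    # range, symmetry, zero diagonal
    vals <- td$d[!is.na(td$d)]
    expect_true(all(vals >= 0 & vals <= 1))
    expect_identical(td$d, t(td$d))
  }
})

test_that("incomparable pairs are awarded the median computable distance", {
  tab <- data.frame(a = c(1, 3, NA, NA), b = c("x", "x", NA, NA),
                    row.names = c("s1", "s2", "s3", "s4"))
  spec <- trait_type_spec(c(a = "quantitative", b = "nominal"),
                          standardize = FALSE)
  td <- gower_matrix(tab, spec)
  expect_true(is.na(td$d["s3", "s4"]))
  imp <- impute_incomparable_pairs(td)
  med <- median(td$d[upper.tri(td$d)], na.rm = TRUE)
  expect_equal(imp$d["s3", "s4"], med)
  expect_true(imp$imputed["s3", "s4"])
  expect_false(imp$imputed["s1", "s2"])
  # no incomparable pairs: identity
  xyz <- xyz_traits()
  td2 <- gower_matrix(xyz$tab, xyz$spec)
  expect_identical(impute_incomparable_pairs(td2), td2)
  # single computable pair: median of one
  tab3 <- data.frame(a = c(1, 2, NA), row.names = c("s1", "s2", "s3"))
  spec3 <- trait_type_spec(c(a = "quantitative"), standardize = FALSE)
  imp3 <- impute_incomparable_pairs(gower_matrix(tab3, spec3))
  expect_equal(imp3$d["s1", "s3"], 1)   # the only computable d(s1,s2) = 1
})

test_that("imputation fails when nothing is computable", {
  tab <- data.frame(a = c(NA_real_, NA_real_), row.names = c("s1", "s2"))
  spec <- trait_type_spec(c(a = "quantitative"), standardize = FALSE)
  expect_error(impute_incomparable_pairs(gower_matrix(tab, spec)),
               "no computable")
})

test_that("duplicated species rows give TU = 0; two species share their TU", {
  tab <- data.frame(a = c(1, 1, 5), row.names = c("s1", "s2", "s3"))
  spec <- trait_type_spec(c(a = "quantitative"), standardize = FALSE)
  td <- gower_matrix(tab, spec)
  tu <- trait_uniqueness(td)
  expect_equal(tu[["s1"]], 0)
  expect_equal(tu[["s2"]], 0)
  tab2 <- data.frame(a = c(0, 0.7), b = c(0, 0.7),
                     row.names = c("s1", "s2"))
  spec2 <- trait_type_spec(c(a = "quantitative", b = "quantitative"),
                           standardize = FALSE)
  td2 <- gower_matrix(tab2, spec2)
  expect_equal(unname(trait_uniqueness(td2)), c(1, 1))
  expect_equal(unname(trait_apd(td2)), c(1, 1))
})

test_that("community restriction reuses global distances and flips local TU", {
  xyz <- xyz_traits()
  td <- gower_matrix(xyz$tab, xyz$spec)
  sub <- restrict_to_community(td, c("X", "Z"), scope = "siteA")
  expect_equal(dim(sub$d), c(2L, 2L))
  expect_equal(sub$d["X", "Z"], 1.0)
  expect_equal(sub$scope, "siteA")
  expect_equal(unname(trait_uniqueness(sub)), c(1, 1))  # global TU was 0.5
  # full-set restriction is the identity on the matrix
  expect_equal(restrict_to_community(td, c("X", "Y", "Z"))$d, td$d)
  expect_error(restrict_to_community(td, c("X", "Q")), "Q")
  expect_error(restrict_to_community(td, "X"), "at least 2")
  # local TU equals the min over the same global distances
  expect_equal(trait_uniqueness(sub)[["X"]],
               min(td$d["X", setdiff(c("X", "Z"), "X")]))
})

test_that("a fully-missing column never changes any distance", {
  xyz <- xyz_traits()
  d0 <- gower_matrix(xyz$tab, xyz$spec)$d
  tab2 <- xyz$tab
  tab2$extra <- NA_real_
  spec2 <- trait_type_spec(c(mass = "quantitative", habitat = "nominal",
                             extra = "quantitative"), standardize = FALSE)
  expect_equal(gower_matrix(tab2, spec2)$d, d0)
})

test_that("Gower agrees with cluster::daisy on complete mixed tables", {
  set.seed(66)
  n <- 10
  tab <- data.frame(q1 = runif(n, 0, 5), q2 = runif(n, -2, 2),
                    o1 = sample(1:4, n, replace = TRUE),
                    n1 = sample(letters[1:3], n, replace = TRUE),
                    row.names = sprintf("s%02d", 1:n))
  spec <- trait_type_spec(c(q1 = "quantitative", q2 = "quantitative",
                            o1 = "ordinal", n1 = "nominal"),
                          standardize = FALSE)
  mine <- gower_matrix(tab, spec)$d
  dtab <- tab
  dtab$o1 <- factor(dtab$o1, ordered = TRUE)
  dtab$n1 <- factor(dtab$n1)
  ref <- as.matrix(cluster::daisy(dtab, metric = "gower"))
  expect_equal(mine, ref[rownames(mine), colnames(mine)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("trait tables and type specs round-trip through CSV and JSON", {
  tdir <- withr::local_tempdir()
  spec <- trait_type_spec(c(mass = "quantitative", habitat = "nominal",
                            layer = "ordinal"),
                          standardize = c(mass = TRUE))
  fspec <- file.path(tdir, "types.json")
  write_trait_types(spec, fspec)
  spec2 <- read_trait_types(fspec)
  expect_equal(spec2$type, spec$type)
  expect_equal(spec2$standardize, spec$standardize)
  ftab <- file.path(tdir, "traits.csv")
  write.csv(data.frame(species = c("X", "Y"), mass = c(1, NA),
                       habitat = c("f", ""), layer = c(1, 2)),
            ftab, row.names = FALSE)
  tab <- read_trait_table(ftab, spec)
  expect_equal(rownames(tab), c("X", "Y"))
  expect_true(is.na(tab$mass[2]))
  expect_true(is.na(tab$habitat[2]))   # empty cell is missing
})
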