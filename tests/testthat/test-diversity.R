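inc_from_sets <- function(sets) {
  taxa <- sort(unique(unlist(sets)))
  mat <- vapply(sets, function(s) as.integer(taxa %in% s),
                integer(length(taxa)))
  rownames(mat) <- taxa
  structure(mat, class = c("incidence_matrix", "matrix", "array"),
            sample_unit = "formation")
}

test_that("dissimilarity indices match their closed forms", {
  inc <- inc_from_sets(list(A = c("x", "y", "z"), B = c("y", "z", "w")))
  expect_equal(unclass(pairwise_dissimilarity(inc, "jaccard"))["A", "B"], 0.5)
  expect_equal(unclass(pairwise_dissimilarity(inc, "kulczynski2"))["A", "B"],
               1 / 3)
  same <- inc_from_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(unclass(pairwise_dissimilarity(same, "jaccard"))["A", "B"], 0)
  expect_equal(unclass(pairwise_dissimilarity(same, "kulczynski2"))["A", "B"],
               0)
})

test_that("dissimilarities agree with direct shared/unique taxon counts", {
  for (s in 1:4) {
    mat <- withr::with_seed(s, matrix(rbinom(60, 1, 0.4), nrow = 10,
                                      dimnames = list(paste0("t", 1:10),
                                                      paste0("f", 1:6))))
    mat[1, ] <- 1  # avoid empty samples
    inc <- structure(mat, class = c("incidence_matrix", "matrix", "array"),
                     sample_unit = "formation")
    dj <- unclass(pairwise_dissimilarity(inc, "jaccard"))
    dk <- unclass(pairwise_dissimilarity(inc, "kulczynski2"))
    for (i in 1:5) for (j in (i + 1):6) {
      a <- sum(mat[, i] & mat[, j])
      b <- sum(mat[, i] & !mat[, j])
      cc <- sum(!mat[, i] & mat[, j])
      expect_equal(dj[i, j], 1 - a / (a + b + cc), tolerance = 1e-12)
      expect_equal(dk[i, j], 1 - (a / (a + b) + a / (a + cc)) / 2,
                   tolerance = 1e-12)
      expect_equal(dj[i, j], dj[j, i])
      expect_true(dj[i, j] >= 0 && dj[i, j] <= 1)
    }
  }
})

test_that("UPGMA reproduces hand-computed merges and is ultrametric", {
  dm <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D <- structure(dm, class = c("dissimilarity_matrix", "matrix", "array"),
                 index = "jaccard")
  hc <- upgma(D)
  expect_equal(sort(hc$height), c(1, 4))
  coph <- as.matrix(stats::cophenetic(hc))
  expect_equal(coph["a", "b"], 1)
  expect_equal(coph["a", "c"], 4)

  # ultrametric input is a fixed point
  expect_equal(cophenetic_correlation(structure(
    coph, class = class(D), index = "jaccard"), hc), 1)

  # ultrametric inequality on clustered random data
  for (s in 1:3) {
    mat <- withr::with_seed(s, matrix(rbinom(80, 1, 0.5), nrow = 10,
                                      dimnames = list(paste0("t", 1:10),
                                                      paste0("f", 1:8))))
    mat[1, ] <- 1
    inc <- structure(mat, class = c("incidence_matrix", "matrix", "array"),
                     sample_unit = "formation")
    hc2 <- upgma(pairwise_dissimilarity(inc, "jaccard"))
    cm <- as.matrix(stats::cophenetic(hc2))
    labs <- rownames(cm)
    for (x in labs) for (y in labs) for (z in labs) {
      expect_lte(cm[x, z], max(cm[x, y], cm[y, z]) + 1e-12)
    }
  }
})

test_that("cophenetic correlation matches a direct Pearson computation", {
  mat <- withr::with_seed(5, matrix(rbinom(70, 1, 0.5), nrow = 10,
                                    dimnames = list(paste0("t", 1:10),
                                                    paste0("f", 1:7))))
  mat[1, ] <- 1
  inc <- structure(mat, class = c("incidence_matrix", "matrix", "array"),
                   sample_unit = "formation")
  D <- pairwise_dissimilarity(inc, "kulczynski2")
  hc <- upgma(D)
  labs <- hc$labels
  dm <- unclass(D)[labs, labs]
  cm <- as.matrix(stats::cophenetic(hc))[labs, labs]
  lower <- lower.tri(dm)
  expect_equal(cophenetic_correlation(D, hc),
               stats::cor(dm[lower], cm[lower]), tolerance = 1e-12)
  expect_error(cophenetic_correlation(structure(
    dm[1:2, 1:2], class = class(D), index = "kulczynski2")), "undefined")
})

test_that("bootstrap support separates clean clusters from noise", {
  sets <- list(A = paste0("x", 1:8), B = paste0("x", 1:8),
               C = paste0("y", 1:8), D = paste0("y", 1:8))
  sets$A <- c(sets$A, "ax"); sets$C <- c(sets$C, "cx")
  bs <- bootstrap_support(inc_from_sets(sets), reps = 60, seed = 2)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  ab <- which(vapply(bs$clades, function(cl)
    setequal(cl, c("A", "B")), logical(1)))
  expect_gte(bs$support[ab], 0.95)
})

test_that("rarefaction matches the closed form and exhaustive enumeration", {
  # N = 3, Y = (3, 1): S(1) = 4/3
  inc <- incidence_from_counts(c(3, 1), 3)
  expect_equal(rarefy_incidence(inc, 1)$S, 4 / 3, tolerance = 1e-12)
  expect_equal(rarefy_incidence(inc, 3)$S, 2, tolerance = 1e-12)

  for (s in 1:3) {
    Y <- withr::with_seed(s, sample(1:6, 9, replace = TRUE))
    inc <- incidence_from_counts(pmin(Y, 6), 6, seed = s)
    mat <- unclass(inc)
    for (n in 1:6) {
      expect_equal(rarefy_incidence(inc, n)$S, enumerate_rarefaction(mat, n),
                   tolerance = 1e-9)
    }
    st <- incidence_stats(inc)
    expect_equal(rarefy_incidence(inc, st$N)$S, st$S_obs, tolerance = 1e-12)
  }
  expect_error(rarefy_incidence(inc, 9), "out of range")
})

test_that("analytical rarefaction mean matches Monte-Carlo subsampling", {
  gen <- generate_occurrences(synthetic_config(
    n_biozones = 2L, formations_per_biozone = 4L, taxon_pool_size = 25L,
    collections_per_formation = c(4L, 8L), seed = 3))
  inc <- build_incidence(gen$table, "collection_point")
  mat <- unclass(inc)
  n <- ncol(mat) %/% 2
  reps <- 1000
  draws <- withr::with_seed(9, replicate(reps, {
    sum(rowSums(mat[, sample.int(ncol(mat), n), drop = FALSE]) > 0)
  }))
  se <- stats::sd(draws) / sqrt(reps)
  expect_lt(abs(rarefy_incidence(inc, n)$S - mean(draws)), 3 * se)
})

test_that("unconditional confidence intervals stay open at full sampling", {
  inc <- incidence_from_counts(c(1, 1, 2, 3, 5, 5), 5)
  r <- rarefy_incidence(inc, 5)
  expect_gt(r$variance, 0)
  expect_true(r$lower < r$S && r$upper > r$S)
})

test_that("extrapolation is flat without singletons and tends to the Chao2 asymptote", {
  flat <- incidence_from_counts(c(3, 3, 2), 3)
  ext <- extrapolate_incidence(flat, 1:5, ci_reps = 0)
  expect_true(all(ext$S == 3))

  inc <- incidence_from_counts(c(1, 1, 1, 2, 2, 4, 5, 5), 5)
  st <- incidence_stats(inc)
  chao <- richness_estimators(inc)
  asym <- chao$estimate[chao$estimator == "chao2"]
  far <- extrapolate_incidence(inc, 5000, ci_reps = 0)$S
  expect_equal(far, asym, tolerance = 1e-6)
  near <- extrapolate_incidence(inc, 1, ci_reps = 0)$S
  expect_gte(near, st$S_obs)
  expect_lte(near, far)
})

test_that("richness estimators match their closed forms", {
  # S_obs = 10, Q1 = 4, Q2 = 2, N = 10 -> chao2 = 13.6
  inc <- incidence_from_counts(c(1, 1, 1, 1, 2, 2, 5, 5, 6, 7), 10)
  est <- richness_estimators(inc)
  expect_equal(est$estimate[est$estimator == "chao2"], 13.6,
               tolerance = 1e-9)

  # S_obs = 10, Q1 = 5, N = 20 -> jackknife1 = 14.75
  inc2 <- incidence_from_counts(c(1, 1, 1, 1, 1, 3, 4, 6, 8, 9), 20)
  est2 <- richness_estimators(inc2)
  expect_equal(est2$estimate[est2$estimator == "jackknife1"], 14.75,
               tolerance = 1e-9)

  # a single ubiquitous taxon: bootstrap adds nothing
  ubi <- incidence_from_counts(4, 4)
  est3 <- richness_estimators(ubi)
  expect_equal(est3$estimate[est3$estimator == "bootstrap"], 1,
               tolerance = 1e-12)

  # no rare taxa at all: every estimator returns S_obs
  sat <- incidence_from_counts(c(4, 4, 4), 4)
  est4 <- richness_estimators(sat)
  expect_true(all(abs(est4$estimate - 3) < 1e-9))
})

test_that("estimators never fall below observed richness and match vegan", {
  for (s in 1:4) {
    Y <- withr::with_seed(s + 5, sample(1:8, 12, replace = TRUE))
    inc <- incidence_from_counts(Y, 8, seed = s)
    est <- richness_estimators(inc)
    st <- incidence_stats(inc)
    # (jackknife2 can legitimately dip below S_obs when doubletons dominate)
    for (e in c("chao2", "jackknife1")) {
      expect_gte(est$estimate[est$estimator == e], st$S_obs)
    }
    # independent cross-check: vegan implements the same jackknife/bootstrap
    sp <- vegan::specpool(t(unclass(inc)))
    expect_equal(est$estimate[est$estimator == "jackknife1"], sp$jack1,
                 tolerance = 1e-9)
    expect_equal(est$estimate[est$estimator == "jackknife2"], sp$jack2,
                 tolerance = 1e-9)
    expect_equal(est$estimate[est$estimator == "bootstrap"], sp$boot,
                 tolerance = 1e-9)
  }
})

test_that("estimator curves converge with conditional CIs collapsing at N", {
  inc <- incidence_from_counts(c(1, 1, 2, 3, 3, 4, 6, 6), 6)
  cur <- estimator_curves(inc, reps = 30, seed = 4)
  full <- cur[cur$n == 6, ]
  est <- richness_estimators(inc)
  for (e in full$estimator) {
    expect_equal(full$mean[full$estimator == e],
                 est$estimate[est$estimator == e], tolerance = 1e-9)
    expect_equal(full$cond_lower[full$estimator == e],
                 full$cond_upper[full$estimator == e])
  }
  # deterministic under a fixed seed
  cur2 <- estimator_curves(inc, reps = 30, seed = 4)
  expect_identical(cur, cur2)
})

test_that("biozone comparison distinguishes planted 3x richness but not identity", {
  rich <- incidence_from_counts(
    withr::with_seed(1, sample(1:10, 90, replace = TRUE,
                               prob = 1 / (1:10))), 40, seed = 2)
  poor <- incidence_from_counts(
    withr::with_seed(2, sample(1:10, 30, replace = TRUE,
                               prob = 1 / (1:10))), 40, seed = 3)
  ca <- rarefaction_curve(rich)
  cb <- rarefaction_curve(poor)
  cmp <- compare_biozones(ca, cb)
  expect_equal(cmp$verdict, "significantly_different")
  expect_gt(cmp$richness_ratio, 2)

  same <- compare_biozones(ca, ca)
  expect_equal(same$verdict, "not_distinguishable")
  expect_equal(same$richness_ratio, 1)
})

test_that("dendrograms export to Newick with matching topology", {
  sets <- list(A = paste0("x", 1:5), B = c(paste0("x", 1:4), "b1"),
               C = paste0("y", 1:5), D = c(paste0("y", 1:4), "d1"))
  hc <- upgma(pairwise_dissimilarity(inc_from_sets(sets), "jaccard"))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
})
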