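# Distance / similarity matrices ----------------------------------------------

test_that("squared-Euclidean distances match direct arithmetic", {
  D <- nn_distance_matrix(c(1, 2, 4))$values
  expect_equal(unname(D), rbind(c(0, 1, 9), c(1, 0, 4), c(9, 4, 0)),
               tolerance = 1e-12)
  expect_true(all(nn_distance_matrix(rep(3, 4))$values == 0))
})

test_that("time-course distance obeys D = 2T(1 - r) on z-scored data", {
  coh <- simulate_shared_response(shared_response_spec(
    6, 250, shared_weights = 1, noise_sd = 1, seed = 14))
  Z <- t(vapply(coh$data, function(m) {
    x <- m[1, ] - mean(m[1, ])
    x / sqrt(mean(x^2))
  }, numeric(250)))
  D <- nn_distance_matrix(Z)$values
  R <- cor(t(Z))
  expect_lt(max(abs(D - 2 * 250 * (1 - R))), 1e-8)
})

test_that("AnnaK similarities follow the mean-rank formula with tie handling", {
  S <- annak_similarity_matrix(c(10, 20, 30))$values
  expect_equal(S[1, 3], 4 / 6, tolerance = 1e-12)
  expect_equal(S[2, 3], 5 / 6, tolerance = 1e-12)
  St <- annak_similarity_matrix(c(5, 5, 7))$values
  expect_equal(St[1, 2], 1.5 / 3, tolerance = 1e-12)  # average ranks
  # rank invariance under strictly increasing transforms
  sc <- c(3, 17, 42, 55, 80)
  expect_equal(annak_similarity_matrix(exp(sc / 20))$values,
               annak_similarity_matrix(sc)$values, tolerance = 1e-12)
})

# IS-RSA correlation -----------------------------------------------------------

test_that("a similarity structure correlates perfectly with itself", {
  b <- annak_similarity_matrix(c(4, 8, 15, 16, 23, 42))
  expect_equal(isrsa_correlation(b, b), 1, tolerance = 1e-12)
  # exact monotone transform of the behaviour similarities: Spearman r = 1
  m <- similarity_matrix(tanh(b$values), "annak_similarity")
  expect_equal(isrsa_correlation(m, b, method = "spearman"), 1,
               tolerance = 1e-12)
})

test_that("upper-triangle rank correlation matches a brute-force oracle", {
  nv <- rbind(c(1, .3, .1, .6), c(.3, 1, .2, .5),
              c(.1, .2, 1, .4), c(.6, .5, .4, 1))
  bv <- rbind(c(1, .9, .2, .3), c(.9, 1, .8, .1),
              c(.2, .8, 1, .7), c(.3, .1, .7, 1))
  n1 <- similarity_matrix(nv, "pearson_r")
  b1 <- similarity_matrix(bv, "pearson_r")
  u1 <- nv[upper.tri(nv)]; u2 <- bv[upper.tri(bv)]
  # Spearman via explicit rank formula over the 6 pairs (no ties)
  r1 <- rank(u1); r2 <- rank(u2)
  brute <- 1 - 6 * sum((r1 - r2)^2) / (6 * (6^2 - 1))
  expect_equal(isrsa_correlation(n1, b1), brute, tolerance = 1e-12)
})

test_that("distances are negated before correlating so orientations agree", {
  sc <- c(10, 30, 50, 70, 90)
  d <- nn_distance_matrix(sc)
  # negated distance is a perfect monotone similarity in score proximity:
  # correlating it with itself as distance must give +1, not -1
  expect_equal(isrsa_correlation(d, d), 1, tolerance = 1e-12)
})

test_that("too-few subjects and mismatched sizes are rejected", {
  b3 <- annak_similarity_matrix(c(1, 2, 3))
  b4 <- annak_similarity_matrix(c(1, 2, 3, 4))
  expect_error(isrsa_correlation(b4, b3), "size")
  b2 <- annak_similarity_matrix(c(1, 2))
  expect_error(isrsa_correlation(b2, b2), ">= 3")
})

# Permutation inference --------------------------------------------------------

test_that("IS-RSA permutation test is calibrated on uncoupled cohorts", {
  rej <- vapply(1:200, function(r) {
    scores <- neurosync:::.with_seed(r, runif(20, 0, 100))
    base <- shared_response_spec(20, 300, shared_weights = 0.8, noise_sd = 1,
                                 seed = 900 + r)
    cc <- simulate_coupled_cohort(behavior_coupling_spec(scores, "none", 0,
                                                         base))
    swp_isrsa_test(pairwise_isc(cc$cohort), annak_similarity_matrix(scores),
                   n_perm = 199, seed = r)$p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("strong AnnaK coupling is detected in nearly every cohort", {
  hits <- vapply(1:100, function(r) {
    scores <- neurosync:::.with_seed(r + 300, runif(30, 0, 100))
    base <- shared_response_spec(30, 200, shared_weights = 0, noise_sd = 1,
                                 seed = 4000 + r)
    cc <- simulate_coupled_cohort(behavior_coupling_spec(scores, "annak", 2.5,
                                                         base))
    swp_isrsa_test(pairwise_isc(cc$cohort), annak_similarity_matrix(scores),
                   n_perm = 499, seed = r)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("IS-RSA results reproduce bit-for-bit from the seed", {
  scores <- c(10, 40, 20, 80, 60, 30, 90, 55)
  coh <- simulate_shared_response(shared_response_spec(8, 200, seed = 5))
  r1 <- swp_isrsa_test(pairwise_isc(coh), annak_similarity_matrix(scores),
                       n_perm = 300, seed = 12)
  r2 <- swp_isrsa_test(pairwise_isc(coh), annak_similarity_matrix(scores),
                       n_perm = 300, seed = 12)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 301)
})

# Mantel test ------------------------------------------------------------------

test_that("Mantel of a matrix with itself and with affine copies gives r = 1", {
  m <- neurosync:::.with_seed(6, {a <- matrix(rnorm(64), 8); a + t(a)})
  res <- mantel_test(m, m, n_perm = 499, seed = 3)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 500, tolerance = 1e-12)
  res2 <- mantel_test(m, 2.5 * m + 1, n_perm = 199, seed = 3)
  expect_equal(res2$r, 1, tolerance = 1e-12)
})

test_that("Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  m1 <- as.matrix(dist(matrix(neurosync:::.with_seed(8, rnorm(30)), 10)))
  m2 <- as.matrix(dist(matrix(neurosync:::.with_seed(9, rnorm(30)), 10)))
  ours <- mantel_test(m1, m2, n_perm = 199, seed = 1)
  ref <- vegan::mantel(m1, m2, permutations = 199)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("Mantel p-values are roughly uniform under independence", {
  ps <- vapply(1:150, function(r) {
    m1 <- neurosync:::.with_seed(r, {a <- matrix(rnorm(400), 20); a + t(a)})
    m2 <- neurosync:::.with_seed(r + 7000, {a <- matrix(rnorm(400), 20); a + t(a)})
    mantel_test(m1, m2, n_perm = 199, seed = r)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

# Model comparison -------------------------------------------------------------

test_that("identical fit vectors give t = 0, p = 1", {
  cmp <- compare_similarity_models(c(.2, .3, .4), c(.2, .3, .4))
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p, 1)
  expect_false(cmp$consistent_difference)
})

test_that("a constant non-zero difference is flagged, not given a fake p", {
  cmp <- compare_similarity_models(c(.3, .4, .5), c(.1, .2, .3))
  expect_true(cmp$consistent_difference)
  expect_identical(cmp$t_statistic, Inf)
  expect_true(is.na(cmp$p))
  expect_equal(cmp$per_channel$difference, rep(0.2, 3), tolerance = 1e-12)
})

test_that("joint subject reordering leaves IS-RSA unchanged", {
  scores <- c(12, 87, 45, 33, 70, 58, 21, 95)
  coh <- simulate_shared_response(shared_response_spec(
    8, 300, shared_weights = 1, noise_sd = 1, seed = 61))
  r0 <- isrsa_correlation(pairwise_isc(coh), annak_similarity_matrix(scores))
  perm <- neurosync:::.with_seed(2, sample.int(8))
  coh2 <- cohort(coh$data[perm], sampling_rate = coh$sampling_rate)
  r1 <- isrsa_correlation(pairwise_isc(coh2),
                          annak_similarity_matrix(scores[perm]))
  expect_equal(r1, r0, tolerance = 1e-12)
})
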