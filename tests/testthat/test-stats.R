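test_that("signed-rank test is exact in the small-n regime", {
  pre <- c(10, 12, 9, 14, 11, 13)
  post <- pre - runif(6, 1, 3)
  w <- wilcoxon_signed_rank(pre, post)
  expect_equal(w$p_value, 0.03125)
  expect_equal(w$method, "exact")
  same <- wilcoxon_signed_rank(pre, pre)
  expect_equal(same$p_value, 1)
  expect_equal(same$flag, "all-zero")
})

test_that("signed-rank p matches the exhaustive enumeration oracle", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n)
    w <- wilcoxon_signed_rank(pre, post)
    expect_equal(w$p_value, exhaustive_signed_rank_p(post - pre),
                 tolerance = 1e-12)
  }
})

test_that("KS comparison returns D, p and DKW bands", {
  x <- c(1, 2, 3, 4, 5)
  r <- ks_two_sample_with_ci(x, x)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
  eps <- sqrt(log(2 / 0.05) / (2 * 5))
  expect_equal(r$band_x$upper, pmin(r$band_x$cdf + eps, 1))
  expect_equal(r$band_x$lower, pmax(r$band_x$cdf - eps, 0))
  expect_error(ks_two_sample_with_ci(numeric(), x), "non-empty")
})

test_that("KS test is calibrated under the null and powerful under shift", {
  set.seed(12)
  rej <- 0
  for (i in 1:400) {
    p <- ks_two_sample_with_ci(rnorm(100), rnorm(100))$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 400, 0.02)
  expect_lt(rej / 400, 0.09)
  small <- vapply(1:50, function(i)
    ks_two_sample_with_ci(rnorm(100), rnorm(100) + 3)$p_value, 0)
  expect_gte(mean(small < 0.001), 0.98)
})

test_that("Kruskal-Wallis contract separates shifted groups", {
  set.seed(13)
  v <- c(rnorm(8), rnorm(8) + 3, rnorm(8) + 3)
  g <- rep(c("a", "b", "c"), each = 8)
  r <- kruskal_wallis(v, g)
  expect_lt(r$p_value, 0.01)
  ab <- r$pairwise$p_value[r$pairwise$a == "a" & r$pairwise$b == "b"]
  ac <- r$pairwise$p_value[r$pairwise$a == "a" & r$pairwise$b == "c"]
  expect_lt(ab, 0.01)
  expect_lt(ac, 0.01)
  expect_equal(nrow(r$pairwise), 3L)
})

test_that("identical conditions produce no significant frequencies", {
  set.seed(14)
  A <- matrix(rexp(6 * 40), 6)
  r <- permutation_spectrum_test(A, A, freq_hz = 1:40)
  expect_false(any(r$significant_mask))
  expect_equal(nrow(r$significant_ranges_hz), 0L)
})

test_that("max-statistic threshold dominates per-frequency thresholds", {
  set.seed(15)
  A <- matrix(rnorm(6 * 40), 6)
  B <- A + matrix(rnorm(6 * 40, sd = 0.5), 6)
  r <- permutation_spectrum_test(A, B, freq_hz = 1:40)
  D <- B - A
  S <- wavegate:::sign_matrix(6)
  null_stat <- abs(S %*% D) / 6
  per_freq <- apply(null_stat, 2, function(v) sort(v)[ceiling(0.95 * 64)])
  expect_true(all(r$corrected_threshold >= per_freq - 1e-12))
})

test_that("exhaustive and Monte-Carlo permutation nulls agree for n = 6", {
  set.seed(16)
  A <- matrix(rnorm(6 * 30), 6)
  B <- A + 0.8 + matrix(rnorm(6 * 30, sd = 0.3), 6)
  ex <- permutation_spectrum_test(A, B, freq_hz = 1:30)
  expect_true(ex$exhaustive)
  expect_equal(ex$n_permutations, 64L)
  # Monte-Carlo reconstruction of the same max-statistic null
  D <- B - A
  set.seed(99)
  S <- matrix(sample(c(1, -1), 20000 * 6, replace = TRUE), ncol = 6)
  null_max <- apply(abs(S %*% D) / 6, 1, max)
  thr_mc <- sort(null_max)[ceiling(0.95 * 20000)]
  expect_lt(abs(thr_mc - ex$corrected_threshold) / ex$corrected_threshold,
            0.1)
  # a large-n design takes the Monte-Carlo route
  A2 <- matrix(rnorm(13 * 30), 13)
  B2 <- A2 + 0.8 + matrix(rnorm(13 * 30, sd = 0.3), 13)
  mc <- permutation_spectrum_test(A2, B2, freq_hz = 1:30, n_perm = 4000,
                                  seed = 7)
  expect_false(mc$exhaustive)
  expect_equal(mc$n_permutations, 4000L)
  expect_gt(mean(mc$significant_mask), 0.9)
})

test_that("results are invariant to frequency-bin reordering", {
  set.seed(17)
  A <- matrix(rnorm(6 * 30), 6)
  B <- A + matrix(rnorm(6 * 30, sd = 1), 6)
  r1 <- permutation_spectrum_test(A, B, freq_hz = 1:30)
  perm <- sample(30)
  r2 <- permutation_spectrum_test(A[, perm], B[, perm], freq_hz = (1:30)[perm])
  expect_equal(r2$significant_mask[order(perm)], r1$significant_mask)
  expect_equal(r2$corrected_threshold, r1$corrected_threshold)
})

test_that("cluster-mass correction flags contiguous effects", {
  set.seed(18)
  A <- matrix(rnorm(6 * 40, mean = 5), 6)
  B <- A
  B[, 15:22] <- B[, 15:22] - 2.5
  r <- permutation_spectrum_test(A, B, freq_hz = 1:40,
                                 correction = "cluster")
  expect_true(any(r$significant_mask[15:22]))
  expect_false(any(r$significant_mask[c(1:10, 30:40)]))
})

test_that("permutation test rejects malformed designs", {
  A <- matrix(rnorm(12), 6)
  expect_error(permutation_spectrum_test(A, A[, 1, drop = FALSE],
                                         freq_hz = 1:2), "identical dim")
  expect_error(permutation_spectrum_test(A, A), "freq_hz")
  s1 <- wavegate:::new_spectrum(1:5, runif(5))
  s2 <- wavegate:::new_spectrum(2:6, runif(5))
  expect_error(permutation_spectrum_test(list(s1, s2), list(s1, s2)),
               "common")
  expect_warning(permutation_spectrum_test(rbind(A, A, A)[1:13, ],
                                           rbind(A, A, A)[1:13, ] + 1,
                                           freq_hz = 1:2, n_perm = 50),
                 "coarse")
})
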