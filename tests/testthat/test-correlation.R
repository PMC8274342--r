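# Within-/inter-subject correlations, t-to-r conversion, window selection.

test_that("within-subject correlation behaves like Pearson r", {
  a <- rnorm(50)
  expect_equal(within_subject_corr(a, 2 * a + 1), 1)
  expect_equal(within_subject_corr(a, -a), -1)
  # 5-vertex hand oracle
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(within_subject_corr(x, y), num / den)
  flagged <- within_subject_corr(rep(1, 10), rnorm(10))
  expect_true(is.na(flagged))
  expect_identical(attr(flagged, "reason"), "zero variance")
  expect_error(within_subject_corr(1:2, 1:2), "at least 3")
  # invariance under common affine rescaling
  expect_equal(within_subject_corr(10 * x - 3, y), within_subject_corr(x, y))
})

test_that("t-to-r conversion has the right limits and the simple-regression identity", {
  expect_equal(t_to_r(0, 10, 2), 0)
  expect_gt(abs(t_to_r(1e6, 10, 2)), 0.999)
  expect_lt(t_to_r(-1e6, 10, 2), -0.999)
  expect_error(t_to_r(1, 2, 2), "n > rank_m")
  set.seed(9)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    fit <- summary(lm(y ~ x))
    t <- fit$coefficients["x", "t value"]
    expect_equal(t_to_r(t, n, 2), cor(x, y), tolerance = 1e-12)
  }
})

test_that("inter-subject correlation recovers identity and flags constants", {
  set.seed(4)
  A <- matrix(rnorm(30 * 12), 30, 12)
  out <- inter_subject_corr(A, A)
  expect_equal(out$r, rep(1, 30), tolerance = 1e-9)
  B <- A; A[3, ] <- 5  # constant regressor at vertex 3
  out2 <- inter_subject_corr(A, B)
  expect_true(is.na(out2$r[3]))
  expect_true(3 %in% out2$constant_vertices)
  expect_error(inter_subject_corr(A[, 1:3], B[, 1:3]), "at least 4")
})

test_that("pairing-permutation p-values are calibrated under the null", {
  set.seed(21)
  V <- 200; n <- 20
  A <- matrix(rnorm(V * n), V, n)
  B <- matrix(rnorm(V * n), V, n)
  out <- inter_subject_corr(A, B, n_perm = 200, seed = 77)
  frac <- mean(out$p < 0.05)
  ci <- qbinom(c(0.005, 0.995), V, 0.05) / V  # wide CI; vertices correlated
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2] + 0.02)
})

test_that("window selection handles trivial, dominated and tied inputs", {
  w1 <- frame_window(0, 4); w2 <- frame_window(1, 5)
  V <- 40; area <- rep(1, V)
  # single candidate
  s1 <- select_optimal_window(list(w1), matrix(0.5, V, 1), matrix(0.1, V, 1),
                              area)
  expect_identical(s1$selected_name, "0-4")
  expect_equal(unname(s1$fdg_area_fraction), 1)
  # candidate 1 dominates everywhere on both criteria
  r_fdg <- cbind(rep(0.9, V), rep(0.5, V))
  r_lav <- cbind(rep(-0.2, V), rep(0.3, V))
  s2 <- select_optimal_window(list(w1, w2), r_fdg, r_lav, area)
  expect_identical(s2$selected_name, "0-4")
  expect_equal(unname(s2$fdg_area_fraction), c(1, 0))
  # area fractions (with tie splitting) always sum to one
  set.seed(2)
  r_f <- matrix(rnorm(V * 3), V, 3); r_l <- matrix(rnorm(V * 3), V, 3)
  r_f[1:5, ] <- 0.4  # exact ties split equally
  s3 <- select_optimal_window(list(w1, w2, frame_window(2, 6)), r_f, r_l, area)
  expect_equal(sum(s3$fdg_area_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(s3$late_area_fraction), 1, tolerance = 1e-12)
  # fully degenerate input reports a tie and picks the earliest candidate
  expect_warning(
    s4 <- select_optimal_window(list(w1, w2), matrix(0.3, V, 2),
                                matrix(0.3, V, 2), area),
    "tied")
  expect_identical(s4$selected_name, "0-4")
})
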