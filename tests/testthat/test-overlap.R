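# TFCE, permutation GLM with FWE, pattern overlap, threshold sweep.

test_that("TFCE of a zero or negative map is zero", {
  m <- fixture_mesh(2)
  expect_equal(tfce_transform(numeric(n_vertices(m)), m),
               numeric(n_vertices(m)))
  expect_equal(tfce_transform(rep(-2, n_vertices(m)), m),
               numeric(n_vertices(m)))
})

test_that("single-vertex spike matches the closed-form geometric sum", {
  m <- flat_mesh(15, 15, spacing = 1)
  centre <- 113
  h0 <- 2.3
  x <- numeric(n_vertices(m)); x[centre] <- h0
  params <- tfce_params(extent_exp = 1, height_exp = 2)
  tf <- tfce_transform(x, m, params)
  expected <- m$area[centre] * h0^3 / 3   # exact integral of a * h^2
  expect_lt(abs(tf[centre] - expected) / expected, 0.01)
  expect_true(all(tf[-centre] == 0))
})

test_that("TFCE is stable under step refinement and monotone in the statistic", {
  m <- fixture_mesh(3)
  x <- pmax(0, m$unit[, 3])          # analytic cap: smooth cluster growth
  mx <- max(x)
  t1 <- tfce_transform(x, m, tfce_params(dh = mx / 100))
  t2 <- tfce_transform(x, m, tfce_params(dh = mx / 200))
  expect_lt(max(abs(t1 - t2)) / max(t2), 0.01)
  y <- x + 0.3 * abs(rnorm(n_vertices(m)))  # pointwise >= x
  ty <- tfce_transform(y, m, tfce_params(dh = mx / 100))
  expect_true(all(ty >= t1 - 1e-9))
})

test_that("pattern overlap gets the confusion arithmetic right", {
  # identical patterns
  p <- runif(100, 0, 1)
  expect_equal(pattern_overlap(p, p, 0.5)$bacc, 1)
  # complement (both classes nonempty)
  pt <- c(rep(0.01, 40), rep(0.9, 60))
  pc <- c(rep(0.9, 40), rep(0.01, 60))
  expect_equal(pattern_overlap(pt, pc, 0.05)$bacc, 0)
  # arithmetic: TP=30 FN=10 TN=50 FP=10
  p_true <- c(rep(0.01, 40), rep(0.5, 60))
  p_pred <- c(rep(0.01, 30), rep(0.5, 10), rep(0.5, 50), rep(0.01, 10))
  ov <- pattern_overlap(p_true, p_pred, 0.05)
  expect_equal(ov$sensitivity, 0.75)
  expect_equal(ov$specificity, 5 / 6)
  expect_equal(ov$bacc, (0.75 + 5 / 6) / 2)
  # label symmetry: swapping the positive/negative coding preserves BACC
  ov_sw <- pattern_overlap(1 - p_true + 0.04, 1 - p_pred + 0.04, 1 - 0.05 + 0.04)
  expect_equal(ov_sw$bacc, ov$bacc)
  # empty true pattern reports missing
  ov_empty <- pattern_overlap(rep(0.9, 50), p_pred[1:50], 0.05)
  expect_true(is.na(ov_empty$bacc))
  expect_identical(ov_empty$reason, "empty true pattern")
})

test_that("the threshold sweep has exact endpoints and is strictly decreasing", {
  th <- threshold_sweep()
  expect_length(th, 91)
  expect_equal(th[1], 0.05)
  expect_equal(th[91], 0.001)
  expect_true(all(diff(th) < 0))
})

test_that("permutation GLM flags degenerate designs and bounded p-values", {
  m <- fixture_mesh(2)
  n <- 14
  set.seed(3)
  Y <- matrix(rnorm(n * n_vertices(m)), n, n_vertices(m))
  x <- rep(0:1, each = n / 2)
  out <- permutation_glm_tfce(Y, x, NULL, m, n_perm = 50, seed = 1)
  pv <- out$p_fwe[m$cortex]
  expect_true(all(pv >= 1 / 51 - 1e-12 & pv <= 1, na.rm = TRUE))
  # collinear design errors with the offending column named
  bad_nuis <- cbind(age = x)
  expect_error(permutation_glm_tfce(Y, x, bad_nuis, m, n_perm = 10),
               "collinear")
  # constant response at a vertex: flagged missing, never significant
  Y2 <- Y; Y2[, which(m$cortex)[1]] <- 3
  out2 <- permutation_glm_tfce(Y2, x, NULL, m, n_perm = 50, seed = 1)
  expect_true(is.na(out2$p_fwe[which(m$cortex)[1]]))
})

test_that("a strong localized effect is detected inside the vulnerable patch", {
  m <- fixture_mesh(2)
  n <- 16
  set.seed(6)
  Y <- matrix(rnorm(n * n_vertices(m), sd = 0.05), n, n_vertices(m))
  x <- rep(c(1, 0), each = n / 2)
  core <- m$patches$vulnerable[m$vulnerable_weight[m$patches$vulnerable] > 0.6]
  Y[x == 0, core] <- Y[x == 0, core] - 1   # patients depressed, eHC > AD
  out <- permutation_glm_tfce(Y, x, NULL, m, n_perm = 200, seed = 2)
  sig <- which(out$p_fwe < 0.05)
  expect_true(all(core %in% sig))
  outside <- setdiff(which(m$cortex), m$patches$vulnerable)
  expect_lt(length(intersect(sig, outside)) / length(outside), 0.02)
})

test_that("sweep_and_rank orders dominating and tied regions correctly", {
  m <- fixture_mesh(2)
  V <- n_vertices(m)
  set.seed(10)
  base_true <- runif(V, 0.001, 0.2)
  good_pred <- base_true                      # perfect agreement
  bad_pred <- sample(base_true)               # shuffled
  p_true <- list(good = base_true, bad = base_true)
  p_pred <- list(good = good_pred, bad = bad_pred)
  sw <- suppressWarnings(
    sweep_and_rank(p_true, p_pred, threshold_sweep(), include = m$cortex))
  expect_equal(unname(sw$ranking$mean_ranks["good"]), 2)
  expect_identical(sw$ranking$groups[[1]], "good")
  # identical regions tie completely
  p_pred2 <- list(good = good_pred, bad = good_pred)
  sw2 <- suppressWarnings(
    sweep_and_rank(p_true, p_pred2, threshold_sweep(), include = m$cortex))
  expect_length(sw2$ranking$groups, 1)
  expect_equal(unname(diff(sw2$ranking$mean_ranks)), 0)
})
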