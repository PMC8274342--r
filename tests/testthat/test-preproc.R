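# Window enumeration/averaging, reference scaling, amyloid calling.

test_that("window enumeration matches the brute-force count and order", {
  w <- enumerate_windows()
  expect_length(w, 34)
  # independent oracle: exhaustive double loop
  cnt <- 0
  for (t1 in 0:3) for (t2 in 1:10) if (t2 > t1) cnt <- cnt + 1
  expect_equal(length(w), cnt)
  expect_equal(format(w[[1]]), "0-1")
  expect_equal(format(w[[34]]), "3-10")
  expect_length(enumerate_windows(t1_values = 0, t2_values = 1), 1)
  expect_error(frame_window(4, 5))
  expect_error(frame_window(2, 2))
})

test_that("window means are plain frame averages", {
  V <- 20
  frames <- matrix(rep(0:9, each = V), V, 10)  # frame k valued k everywhere
  expect_equal(window_mean(frames, frame_window(0, 4)), rep(1.5, V))
  expect_equal(window_mean(frames, frame_window(0, 1)), frames[, 1])
  const <- matrix(7, V, 10)
  expect_equal(window_mean(const, frame_window(2, 9)), rep(7, V))
  # linearity: mean over [0,6] = weighted average of [0,2] and [2,6]
  x <- matrix(rnorm(V * 10), V, 10)
  lhs <- window_mean(x, frame_window(0, 6))
  rhs <- (2 * window_mean(x, frame_window(0, 2)) +
          4 * window_mean(x, frame_window(2, 6))) / 6
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(window_mean(x[, 1:5], frame_window(0, 10)), "outside")
})

test_that("surface reference scaling self-normalizes and is scale invariant", {
  m <- fixture_mesh(2)
  x <- rep(5, n_vertices(m))
  sp <- ref_region_spec("pons")
  y <- scale_image(x, sp, mesh = m)
  expect_equal(as.numeric(y), rep(1, n_vertices(m)))
  expect_equal(attr(y, "reference_mean"), 5)
  z <- abs(rnorm(n_vertices(m))) + 0.5
  for (spec in reference_regions()) {
    a <- as.numeric(scale_image(z, spec, mesh = m))
    b <- as.numeric(scale_image(3.7 * z, spec, mesh = m))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("volumetric scaling matches hand arithmetic on a toy grid", {
  dm <- c(6, 6, 6)
  img <- array(0, dm)
  mask <- array(FALSE, dm)
  mask[1:10] <- TRUE
  img[1:10] <- 1:10
  img[11] <- 11
  sp <- ref_region_spec("pons", mask = mask, erosion_mm = 0)
  out <- scale_image(img, sp, voxel_mm = 2)
  expect_equal(attr(out, "reference_mean"), 5.5)
  expect_equal(out[11], 2.0)
  # global: output brain mean is exactly 6.5
  brain <- array(TRUE, dm)
  img2 <- array(abs(rnorm(prod(dm))) + 1, dm)
  g <- scale_image(img2, ref_region_spec("global"), brain_mask = brain)
  expect_equal(mean(g[brain]), 6.5, tolerance = 1e-12)
})

test_that("volumetric erosion is monotone and can empty a reference", {
  dm <- c(12, 12, 12)
  centre <- c(6.5, 6.5, 6.5)
  co <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  r <- sqrt((co$x - centre[1])^2 + (co$y - centre[2])^2 + (co$z - centre[3])^2)
  mask <- array(r <= 4, dm)
  e2 <- erode_mask_volume(mask, 2, 1)
  e3 <- erode_mask_volume(mask, 3, 1)
  expect_true(all(e2[!mask] == FALSE))
  expect_true(all(which(e3) %in% which(e2)))
  expect_lt(sum(e3), sum(e2))
  img <- array(1, dm)
  sp <- ref_region_spec("pons", mask = mask, erosion_mm = 10)
  expect_error(scale_image(img, sp, voxel_mm = 1), "vanished")
})

test_that("amyloid status uses a strict cutoff on the neocortical mean", {
  m <- fixture_mesh(2)
  V <- n_vertices(m)
  expect_identical(as.character(call_amyloid_status(rep(1.22, V), m)), "low")
  expect_identical(as.character(call_amyloid_status(rep(2, V), m)), "high")
  expect_error(call_amyloid_status(rep(1, 4),
                                   structure(list(neocortex = logical(0),
                                                  area = numeric(0)))),
               "empty")
  # synthetic AD-d subject at default effect sizes is called high
  co <- fixture_cohort()
  cgm <- ref_region_spec("cerebellar_GM")
  ad_high <- which(co$subjects$group == "AD-d" &
                     co$subjects$amyloid_status == "high")[1]
  suvr <- scale_image(co$late[, ad_high], cgm, mesh = co$mesh)
  expect_identical(as.character(call_amyloid_status(suvr, co$mesh)), "high")
})
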