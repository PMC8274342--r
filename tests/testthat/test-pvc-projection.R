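# Mueller-Gaertner correction, surface projection, smoothing, ROI means.

test_that("MG correction reduces to identity for a near-delta PSF on pure GM", {
  dm <- c(16, 16, 16)
  set.seed(1)
  pet <- array(abs(rnorm(prod(dm))) + 2, dm)
  gm <- array(1, dm); wm <- array(0, dm); csf <- array(0, dm)
  gm[1:3, 1:3, 1:3] <- 0; wm[1:3, 1:3, 1:3] <- 1  # a WM corner for A_WM
  out <- muller_gartner(pet, list(GM = gm, WM = wm, CSF = csf),
                        pvc_params(psf_fwhm_mm = 0.2, wm_erosion_mm = 0),
                        voxel_mm = 2)
  interior <- gm > 0.5
  interior[1:6, , ] <- FALSE   # away from the WM corner
  expect_equal(out[interior], pet[interior], tolerance = 1e-6)
})

test_that("MG recovers the true GM activity on the phantom", {
  ph <- generate_phantom(shape = c(48, 48, 48), voxel_mm = 2, psf_fwhm_mm = 6,
                         activities = c(GM = 4, WM = 1, CSF = 0))
  out <- muller_gartner(ph$observed, ph$prob, pvc_params(psf_fwhm_mm = 6),
                        voxel_mm = 2)
  core <- phantom_gm_core(ph, margin_mm = 3)
  err <- abs(out[core] - 4) / 4
  expect_lt(median(err), 0.05)
  # homogeneity of degree one
  out2 <- muller_gartner(2 * ph$observed, ph$prob, pvc_params(psf_fwhm_mm = 6),
                         voxel_mm = 2)
  expect_equal(out2[core], 2 * out[core], tolerance = 1e-10)
})

test_that("projection normalizes weights, handles flat limit, gradients and clamping", {
  ph <- generate_phantom(shape = c(40, 40, 40), voxel_mm = 2, psf_fwhm_mm = 0,
                         activities = c(GM = 3, WM = 3, CSF = 3))
  # constant volume projects to the constant
  v <- project_to_surface(ph$observed, ph$mesh, voxel_mm = 2)
  expect_equal(as.numeric(v), rep(3, n_vertices(ph$mesh)), tolerance = 1e-9)
  expect_length(attr(v, "qc_clamped"), 0)
  # sigma -> Inf equals the unweighted mean of the depth samples
  dm <- c(40, 40, 40)
  vol <- array(rnorm(prod(dm)), dm)
  flat <- project_to_surface(vol, ph$mesh, projection_params(sigma = 1e6),
                             voxel_mm = 2)
  byhand <- Reduce(`+`, lapply(seq(0.35, 0.65, by = 0.05), function(d) {
    pts <- ph$mesh$vertices + ph$mesh$normals * (d - 0.5) * ph$mesh$thickness
    idx <- pts / 2 + 0.5
    earlypet:::trilinear_interp(vol, idx)
  })) / 7
  expect_equal(as.numeric(flat), as.numeric(byhand), tolerance = 1e-9)
  # linear gradient along the normal: symmetric weights cancel the odd term
  m <- flat_mesh(15, 15, spacing = 2)
  m$vertices[, 3] <- 15           # mid-grid plane, normals along +z
  grad <- array(0, c(20, 20, 20))
  for (k in 1:20) grad[, , k] <- (k - 0.5) * 2   # value = z coordinate
  g <- project_to_surface(grad, m, voxel_mm = 2)
  expect_equal(as.numeric(g), rep(15, n_vertices(m)), tolerance = 1e-9)
  # out-of-grid samples are clamped and flagged
  m$vertices[1, 3] <- 200
  g2 <- project_to_surface(grad, m, voxel_mm = 2)
  expect_true(1 %in% attr(g2, "qc_clamped"))
})

test_that("smoothing is conservative, positive, and a fixed point on constants", {
  m <- fixture_mesh(2)
  inc <- rep(TRUE, n_vertices(m))
  x <- abs(rnorm(n_vertices(m)))
  expect_identical(smooth_surface(x, m, 0, include = inc), x)
  cst <- rep(2.5, n_vertices(m))
  expect_equal(smooth_surface(cst, m, 12, include = inc), cst,
               tolerance = 1e-12)
  y <- smooth_surface(x, m, 12, include = inc)
  expect_true(all(y >= 0))
  m0 <- sum(m$area * x) / sum(m$area)
  m1 <- sum(m$area * y) / sum(m$area)
  expect_lt(abs(m1 - m0) / abs(m0), 1e-6)
  # medial wall excluded: values outside the mask pass through untouched
  z <- smooth_surface(x, m, 12)
  expect_identical(z[!m$cortex], x[!m$cortex])
})

test_that("impulse response has the requested FWHM on a flat lattice", {
  m <- flat_mesh(41, 41, spacing = 1)
  centre <- which.min(rowSums(sweep(m$vertices[, 1:2], 2,
                                    colMeans(m$vertices[, 1:2]))^2))
  x <- numeric(n_vertices(m)); x[centre] <- 1
  y <- smooth_surface(x, m, 8)
  d <- sqrt(rowSums(sweep(m$vertices, 2, m$vertices[centre, ])^2))
  r_half <- max(d[y >= max(y) / 2])
  expect_gte(r_half, 3)   # FWHM/2 minus one edge length
  expect_lte(r_half, 5)   # FWHM/2 plus one edge length
})

test_that("ROI means are area-weighted and flag empty parcels", {
  m <- fixture_mesh(2)
  cst <- rep(3.25, n_vertices(m))
  rm1 <- extract_roi_means(cst, m)
  expect_true(all(abs(rm1 - 3.25) < 1e-12))
  # indicator of one parcel
  p1 <- names(rm1)[1]
  ind <- as.numeric(!is.na(m$parcel) & m$parcel == p1)
  rm2 <- extract_roi_means(ind, m)
  expect_equal(unname(rm2[p1]), 1)
  expect_true(all(rm2[names(rm2) != p1] == 0))
  # random map matches the direct area-weighted sum
  x <- rnorm(n_vertices(m))
  rm3 <- extract_roi_means(x, m)
  for (p in sample(names(rm3), 5)) {
    v <- which(!is.na(m$parcel) & m$parcel == p & m$cortex)
    expect_equal(unname(rm3[p]), sum(x[v] * m$area[v]) / sum(m$area[v]))
  }
  # matrix input: subjects in columns become rows
  xx <- cbind(x, 2 * x)
  rmm <- extract_roi_means(xx, m)
  expect_equal(dim(rmm), c(2L, length(rm3)))
  expect_equal(unname(rmm[2, ]), unname(2 * rm3))
})
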