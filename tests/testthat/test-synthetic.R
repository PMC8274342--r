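# Cohort generator and volumetric phantom.

test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_yhc = 0, n_ehc = 0, n_amci = 0, n_add = 0),
               "at least one subject")
  expect_error(cohort_config(coupling = 1.5), "coupling")
  expect_error(cohort_config(frame_noise_sd = -1), "noise")
})

test_that("identical config and seed give bit-identical cohorts", {
  m <- fixture_mesh(2)
  cfg <- cohort_config(n_yhc = 1, n_ehc = 4, n_amci = 2, n_add = 2, seed = 7)
  a <- generate_cohort(cfg, m)
  b <- generate_cohort(cfg, m)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$series, b$series)
  expect_identical(a$fdg, b$fdg)
  expect_identical(a$late, b$late)
})

test_that("vertex-pooled perfusion-metabolism correlation recovers the coupling", {
  m <- fixture_mesh(2)
  cfg <- cohort_config(n_yhc = 10, n_ehc = 10, n_amci = 10, n_add = 10,
                       coupling = 0.85, seed = 11)
  co <- generate_cohort(cfg, m)
  r <- cor(as.vector(co$truth$perfusion[m$cortex, ]),
           as.vector(co$truth$metabolism[m$cortex, ]))
  expect_lt(abs(r - 0.85), 0.05)
})

test_that("noiseless, binding-free, fully coupled cohort makes every window mean proportional to FDG", {
  m <- fixture_mesh(2)
  cfg <- cohort_config(n_yhc = 0, n_ehc = 2, n_amci = 0, n_add = 2,
                       coupling = 1, binding_slope = 0,
                       frame_noise_sd = 0, fdg_noise_sd = 0,
                       ref_wm_sd = 0, ref_cerebellum_sd = 0, seed = 3)
  co <- generate_cohort(cfg, m)
  for (w in list(frame_window(0, 4), frame_window(1, 6), frame_window(3, 10))) {
    for (s in 1:4) {
      em <- window_mean(co$series[[s]], w)
      ratio <- em / co$fdg[, s]
      expect_lt(diff(range(ratio)), 1e-9 * abs(mean(ratio)))
    }
  }
})

test_that("patients show depressed vulnerable-patch metabolism in expectation", {
  co <- fixture_cohort()
  m <- co$mesh
  vu <- m$patches$vulnerable
  g <- co$subjects$group
  truth <- colMeans(co$truth$metabolism[vu, ])
  expect_gt(mean(truth[g == "eHC"]), mean(truth[g == "AD-d"]))
  expect_gt(mean(truth[g == "eHC"]), mean(truth[g == "aMCI"]))
})

test_that("correlation structure: FDG correlation falls past binding onset, late-phase correlation rises", {
  m <- fixture_mesh(2)
  cfg <- cohort_config(n_yhc = 2, n_ehc = 8, n_amci = 5, n_add = 5, seed = 5)
  co <- generate_cohort(cfg, m)
  spec <- ref_region_spec("pons"); cgm <- ref_region_spec("cerebellar_GM")
  fdg <- smooth_surface(apply(co$fdg, 2, scale1, spec = spec, mesh = m), m, 8)
  late <- smooth_surface(apply(co$late, 2, scale1, spec = cgm, mesh = m), m, 8)
  n <- ncol(fdg)
  mean_r <- function(t2, target) {
    em <- smooth_surface(vapply(co$series, function(fr)
      scale1(window_mean(fr, frame_window(0, t2)), spec, m),
      numeric(n_vertices(m))), m, 8)
    mean(vapply(seq_len(n), function(s)
      within_subject_corr(em[, s], target[, s], m$cortex), numeric(1)))
  }
  r_fdg <- vapply(c(5, 10), mean_r, numeric(1), target = fdg)
  expect_gt(r_fdg[1], r_fdg[2])   # decline past the onset
  r_late <- vapply(c(2, 5, 8, 10), mean_r, numeric(1), target = late)
  expect_true(all(diff(r_late) > 0))  # monotone rise with end time
})

test_that("phantom obeys its construction invariants", {
  ph0 <- generate_phantom(shape = c(36, 36, 36), voxel_mm = 2, psf_fwhm_mm = 0,
                          activities = c(GM = 4, WM = 1, CSF = 0))
  expect_identical(ph0$observed, ph0$truth)     # delta PSF
  ph <- generate_phantom(shape = c(48, 48, 48), voxel_mm = 2, psf_fwhm_mm = 6,
                         activities = c(GM = 4, WM = 1, CSF = 0))
  probs <- ph$prob$GM + ph$prob$WM + ph$prob$CSF
  expect_true(all(probs <= 1 + 1e-12))
  core <- phantom_gm_core(ph, margin_mm = 2)
  expect_true(all(ph$observed[core] > 1 & ph$observed[core] < 4))
  # Gaussian convolution conserves mass away from the grid edges
  expect_lt(abs(sum(ph$observed) - sum(ph$truth)) / sum(ph$truth), 1e-3)
  expect_error(generate_phantom(shape = c(10, 10, 10), voxel_mm = 2),
               "too small")
})
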