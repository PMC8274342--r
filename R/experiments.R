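# End-to-end parameter-recovery experiments on synthetic cohorts.  These
# wire the full pipeline together the way the analysis is meant to be run,
# and are what the acceptance suite replicates under multiple seeds.

#' Recover the optimal early time-frame window from a synthetic cohort
#'
#' Generates a cohort, scales every candidate window mean and the FDG and
#' late-phase maps (pons scaling for the perfusion-weighted comparisons,
#' cerebellar GM for the late phase), smooths, computes within-subject
#' correlations of every window with FDG, takes the top Friedman CD group
#' as candidates, computes vertex-wise inter-subject correlations of the
#' candidates with FDG and with the late phase, and applies the joint
#' selection rule.  Under the default generator (delivery peaking at 2.5
#' min, binding onset 4 min) the expected winner is the 0-4 min window:
#' the longest binding-free window.
#'
#' @param seed cohort seed
#' @param mesh a `pet_mesh` (default: subdivision-3 cortical mesh)
#' @param config cohort configuration; default: 40 subjects (5 yHC, 15
#'   eHC, 10 aMCI, 10 AD-d) at default effect sizes
#' @param fwhm smoothing FWHM (mm)
#' @return the `window_selection`, with the within-subject ranking attached
#'   as attribute `ranking`
#' @export
recover_optimal_window <- function(seed, mesh = cortical_mesh(3),
                                   config = NULL, fwhm = 8) {
  if (is.null(config))
    config <- cohort_config(n_yhc = 5, n_ehc = 15, n_amci = 10, n_add = 10,
                            seed = seed)
  co <- generate_cohort(config, mesh)
  pons <- ref_region_spec("pons")
  cgm <- ref_region_spec("cerebellar_GM")
  sc <- function(x, sp) as.numeric(scale_image(x, sp, mesh = mesh))
  windows <- enumerate_windows()
  early <- lapply(windows, function(w)
    smooth_surface(vapply(co$series, function(fr)
      sc(window_mean(fr, w), pons), numeric(n_vertices(mesh))), mesh, fwhm))
  names(early) <- vapply(windows, format, character(1))
  fdg <- smooth_surface(apply(co$fdg, 2, sc, sp = pons), mesh, fwhm)
  late <- smooth_surface(apply(co$late, 2, sc, sp = cgm), mesh, fwhm)
  n <- ncol(fdg)
  within <- sapply(seq_along(windows), function(wi)
    vapply(seq_len(n), function(s)
      within_subject_corr(early[[wi]][, s], fdg[, s], mesh$cortex),
      numeric(1)))
  colnames(within) <- names(early)
  ranking <- friedman_rank(within, direction = "higher")
  top <- ranking$groups[[1]]
  cand <- windows[match(top, names(early))]
  r_fdg <- sapply(top, function(w)
    inter_subject_corr(early[[w]], fdg, mesh$cortex)$r)
  r_late <- sapply(top, function(w)
    inter_subject_corr(early[[w]], late, mesh$cortex)$r)
  sel <- select_optimal_window(cand, r_fdg, r_late, mesh$area, mesh$cortex)
  attr(sel, "ranking") <- ranking
  sel
}

#' Recover the reference-region ranking from a synthetic two-group cohort
#'
#' Generates an elderly-control vs AD-dementia cohort, keeps low-amyloid
#' controls and high-amyloid patients, and for each elementary reference
#' region (pons, cerebellum, cerebellar GM, cerebral WM, global) computes
#' the FDG and early-window group-difference patterns by permutation GLM
#' with TFCE and max-statistic FWE correction (sex, age and education as
#' nuisance covariates), sweeps the balanced accuracy of the early-phase
#' pattern against the FDG pattern over the 91-threshold grid, and ranks
#' the regions with a Friedman/Nemenyi test (thresholds as blocks).  The
#' two composite regions are excluded here: they are near-duplicates of
#' pons and would only split ranks in the comparison.
#'
#' @param seed cohort seed
#' @param mesh a `pet_mesh`
#' @param n_ehc,n_add group sizes (control-heavy by design, like the
#'   cohorts this analysis is meant for)
#' @param n_perm permutations for the FWE correction
#' @param window early window to evaluate (default the optimal 0-4 min)
#' @param fwhm smoothing FWHM (mm)
#' @return list: `ranking` (a `ranking_result`), `bacc` (threshold x
#'   region), `top_group` (condition names), `n` (subjects used)
#' @export
recover_reference_ranking <- function(seed, mesh = cortical_mesh(3),
                                      n_ehc = 30, n_add = 24, n_perm = 600,
                                      window = frame_window(0, 4), fwhm = 8) {
  config <- cohort_config(n_yhc = 0, n_ehc = n_ehc, n_amci = 0,
                          n_add = n_add, seed = seed)
  co <- generate_cohort(config, mesh)
  sub <- co$subjects
  keep <- (sub$group == "eHC" & sub$amyloid_status == "low") |
    (sub$group == "AD-d" & sub$amyloid_status == "high")
  idx <- which(keep)
  x <- as.numeric(sub$group[idx] == "eHC")   # one-sided eHC > AD-d
  nuis <- cbind(sex = as.numeric(sub$sex[idx] == "F"),
                age = sub$age[idx], edu = sub$education[idx])
  em_raw <- vapply(co$series[idx], function(fr) window_mean(fr, window),
                   numeric(n_vertices(mesh)))
  fdg_raw <- co$fdg[, idx, drop = FALSE]
  regions <- c("pons", "cerebellum", "cerebellar_GM", "cerebral_WM", "global")
  p_true <- list(); p_pred <- list()
  for (rn in regions) {
    sp <- ref_region_spec(rn)
    sc <- function(v) as.numeric(scale_image(v, sp, mesh = mesh))
    fdg <- t(smooth_surface(apply(fdg_raw, 2, sc), mesh, fwhm))
    eav <- t(smooth_surface(apply(em_raw, 2, sc), mesh, fwhm))
    p_true[[rn]] <- permutation_glm_tfce(fdg, x, nuis, mesh, n_perm = n_perm,
                                         seed = seed + 1000)$p_fwe
    p_pred[[rn]] <- permutation_glm_tfce(eav, x, nuis, mesh, n_perm = n_perm,
                                         seed = seed + 2000)$p_fwe
  }
  sw <- suppressWarnings(
    sweep_and_rank(p_true, p_pred, threshold_sweep(), include = mesh$cortex))
  list(ranking = sw$ranking, bacc = sw$bacc,
       top_group = sw$ranking$groups[[1]], n = length(idx))
}
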