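# Synthetic dynamic-PET cohort generator.
#
# Signal model, per subject s and vertex v (frame k covers minute [k, k+1),
# evaluated at the frame midpoint tau = k + 0.5):
#
#   frame_k(v) = g_s * [ P_s(v) * D(tau) + A_s(v) * B(tau) + eps ]
#
# where D is a perfusion-weighted delivery curve (gamma variate peaking
# before 4 min plus a retained fraction), B is an amyloid-binding
# contamination weight that is zero before its onset and grows linearly
# afterwards, P_s is the subject's ground-truth perfusion map, A_s its
# amyloid map (late-phase units), g_s a global injected-dose factor and
# eps i.i.d. frame measurement noise.  Metabolism is coupled to perfusion
# with correlation r and carries an additional, perfusion-independent
# hypometabolism component in the vulnerable patch.

delivery_curve <- function(tau, time_to_peak, shape, retention) {
  (tau / time_to_peak)^shape * exp(shape * (1 - tau / time_to_peak)) + retention
}

binding_curve <- function(tau, onset, slope) {
  pmax(0, tau - onset) * slope
}

#' Cohort configuration
#'
#' Defaults encode the study population the analysis assumes: group sizes
#' of the combined cohorts (16 young controls, 145 elderly controls, 15
#' amnestic MCI, 15 AD dementia), a delivery curve peaking at 2.5 min (so
#' the peak falls within the first 4 minutes by construction), amyloid
#' binding that contaminates frames only after 4 min, and a
#' perfusion--metabolism coupling of 0.85.
#'
#' @param n_yhc,n_ehc,n_amci,n_add group sizes (>= 0, total > 0)
#' @param delivery_time_to_peak,delivery_shape,delivery_retention gamma
#'   variate delivery-curve parameters: time to peak (min), shape, and the
#'   retained (non-washing-out) fraction added to the curve
#' @param binding_onset,binding_slope amyloid contamination: onset (min)
#'   and slope as fraction of the late-phase signal per minute
#' @param coupling perfusion--metabolism correlation r in \[-1, 1\]
#' @param hypoperfusion,hypometabolism_extra named per-group relative
#'   deficits in the vulnerable patch; the extra metabolism deficit enters
#'   through the perfusion-independent channel (so coupling = 1 forces
#'   metabolism = perfusion exactly)
#' @param diffuse_hypoperfusion,diffuse_hypometabolism named per-group
#'   diffuse cortex-wide deficits (with strong between-patient variability),
#'   the component that makes the global mean disease-affected while
#'   leaving the reference patches untouched
#' @param amyloid_prob per-group probability of high amyloid status
#' @param amyloid_severity per-group mean cortical amyloid elevation
#'   (late-phase SUVR units) of high-amyloid subjects
#' @param frame_noise_sd i.i.d. measurement noise SD per 1-minute frame
#'   (units of baseline cortical signal; 1-minute PET frames are noisy)
#' @param fdg_noise_sd,late_noise_sd measurement noise SD of the FDG and
#'   late-phase static maps
#' @param subject_field_sd SD of the smooth subject-specific perfusion field
#' @param cognition_noise_sd SD of the noise added to MMSE and Total Recall
#' @param ref_cerebellum_affected relative reduction of cerebellar signal in
#'   patients (mild disease involvement, cross-cerebellar diaschisis); the
#'   pons patch is always stable
#' @param ref_wm_affected relative reduction of cerebral white matter signal
#'   in patients (pathology influencing WM signal)
#' @param ref_cerebellum_sd between-subject instability of the cerebellar
#'   patch (early-phase side; the metabolism side gets half of it)
#' @param ref_wm_sd extra between-subject SD of the cerebral white matter
#'   patch (an unstable reference)
#' @param seed random seed (integer)
#' @return a validated `cohort_config` list
#' @export
cohort_config <- function(n_yhc = 16, n_ehc = 145, n_amci = 15, n_add = 15,
                          delivery_time_to_peak = 2.5, delivery_shape = 0.4,
                          delivery_retention = 0.45,
                          binding_onset = 4, binding_slope = 0.15,
                          coupling = 0.85,
                          hypoperfusion = c(yHC = 0, eHC = 0, aMCI = 0.095, `AD-d` = 0.20),
                          hypometabolism_extra = c(yHC = 0, eHC = 0, aMCI = 0.06, `AD-d` = 0.12),
                          diffuse_hypoperfusion = c(yHC = 0, eHC = 0, aMCI = 0, `AD-d` = 0),
                          diffuse_hypometabolism = c(yHC = 0, eHC = 0, aMCI = 0, `AD-d` = 0),
                          amyloid_prob = c(yHC = 0.125, eHC = 0.51, aMCI = 0.867, `AD-d` = 0.933),
                          amyloid_severity = c(yHC = 0.28, eHC = 0.28, aMCI = 0.36, `AD-d` = 0.40),
                          frame_noise_sd = 0.07, fdg_noise_sd = 0.03,
                          late_noise_sd = 0.05, subject_field_sd = 0.08,
                          cognition_noise_sd = 1.5,
                          ref_cerebellum_affected = 0.035, ref_wm_affected = 0.015, ref_wm_sd = 0.05,
                          ref_cerebellum_sd = 0.012,
                          seed = 1) {
  sizes <- c(yHC = n_yhc, eHC = n_ehc, aMCI = n_amci, `AD-d` = n_add)
  if (any(sizes < 0)) stop("group sizes must be >= 0")
  if (sum(sizes) == 0) stop("cohort must contain at least one subject")
  if (!is.finite(coupling) || coupling < -1 || coupling > 1)
    stop("coupling must lie in [-1, 1]")
  sds <- c(frame_noise_sd, fdg_noise_sd, late_noise_sd, subject_field_sd,
           cognition_noise_sd)
  if (any(sds < 0)) stop("noise SDs must be >= 0")
  structure(list(
    sizes = sizes,
    delivery_time_to_peak = delivery_time_to_peak,
    delivery_shape = delivery_shape,
    delivery_retention = delivery_retention,
    binding_onset = binding_onset, binding_slope = binding_slope,
    coupling = coupling,
    hypoperfusion = hypoperfusion,
    hypometabolism_extra = hypometabolism_extra,
    diffuse_hypoperfusion = diffuse_hypoperfusion,
    diffuse_hypometabolism = diffuse_hypometabolism,
    amyloid_prob = amyloid_prob, amyloid_severity = amyloid_severity,
    frame_noise_sd = frame_noise_sd, fdg_noise_sd = fdg_noise_sd,
    late_noise_sd = late_noise_sd, subject_field_sd = subject_field_sd,
    cognition_noise_sd = cognition_noise_sd,
    ref_cerebellum_affected = ref_cerebellum_affected,
    ref_wm_affected = ref_wm_affected, ref_wm_sd = ref_wm_sd,
    ref_cerebellum_sd = ref_cerebellum_sd,
    seed = as.integer(seed)), class = "cohort_config")
}

# Deterministic baseline maps (no randomness).
cohort_baselines <- function(mesh) {
  V <- n_vertices(mesh)
  u <- mesh$unit
  if (is.null(u)) u <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  phi <- atan2(u[, 2], u[, 1])
  sinth <- sqrt(pmax(0, 1 - u[, 3]^2))
  # perfusion/metabolism landscape: spatial SD ~0.14 of the mean, the
  # dynamic range surface PET maps show across the cortex
  base_p <- 1 + 0.18 * u[, 3] + 0.10 * u[, 2] +
    0.08 * sin(3 * phi) * sinth + 0.10 * cos(phi) * sinth
  # amyloid deposition pattern: deliberately near-orthogonal to the
  # perfusion landscape, spatial SD ~0.5 (so high-amyloid subjects show
  # binding topography clearly distinct from perfusion)
  patt_a <- 1 + 1.05 * cos(2 * phi) * sinth - 0.80 * u[, 3] +
    0.65 * sin(phi) * sinth
  # metabolism-specific baseline topography (FDG and perfusion landscapes
  # differ systematically); standardized over the cortex below
  dev_m <- 0.9 * sin(2 * phi) * sinth + 0.8 * (u[, 3]^2 - 1 / 3) -
    0.5 * cos(3 * phi) * sinth
  p <- mesh$patches
  set_patch <- function(x, idx, value) { x[idx] <- value; x }
  base_p <- set_patch(base_p, p$medial_wall, 0.90)
  base_p <- set_patch(base_p, p$cerebral_WM, 0.65)
  base_p <- set_patch(base_p, p$cerebellum, 1.00)
  base_p <- set_patch(base_p, p$pons, 0.85)
  patt_a <- set_patch(patt_a, p$medial_wall, 0)
  patt_a <- set_patch(patt_a, p$cerebral_WM, 0)
  patt_a <- set_patch(patt_a, p$cerebellum, 0)
  patt_a <- set_patch(patt_a, p$pons, 0)
  amy_base <- rep(1.05, V)
  amy_base <- set_patch(amy_base, p$medial_wall, 1.10)
  amy_base <- set_patch(amy_base, p$cerebral_WM, 1.60)
  amy_base <- set_patch(amy_base, p$cerebellum, 1.00)
  amy_base <- set_patch(amy_base, p$pons, 1.00)
  if (!is.null(mesh$cortex)) {
    dev_m[!mesh$cortex] <- 0
    ok <- mesh$cortex
    dev_m[ok] <- (dev_m[ok] - mean(dev_m[ok])) / sd(dev_m[ok])
  }
  list(perfusion = base_p, amyloid_base = amy_base, amyloid_pattern = patt_a,
       metab_dev = dev_m)
}

# n smooth standardized random fields (V x n), one diffusion operator.
gen_smooth_fields <- function(mesh, n, fwhm = 15) {
  V <- n_vertices(mesh)
  x <- matrix(rnorm(V * n), V, n)
  op <- smooth_operator(mesh, fwhm, rep(TRUE, V))
  y <- x
  for (s in seq_len(op$steps)) y <- as.matrix(op$S %*% y)
  scale(y)  # zero mean, unit SD per column
}

#' Generate a synthetic dynamic-PET cohort on a mesh
#'
#' Draws a cohort under [cohort_config()] on the supplied mesh and returns
#' per-subject dynamic early-phase frames, static late-phase and FDG maps,
#' a subject table with demographics and cognition, and full ground truth.
#' Patients' perfusion and metabolism maps are depressed in the mesh's
#' vulnerable patch (metabolism more strongly than perfusion), amyloid maps
#' are elevated cortex-wide in high-amyloid subjects, cognition scores
#' decrease with the vulnerable-patch metabolism deficit, and the pons
#' patch is a stable reference while cerebellum/white matter/global signal
#' are disease-affected or unstable.  Identical config (including seed)
#' gives bit-identical output.
#'
#' @param config a [cohort_config()]
#' @param mesh a `pet_mesh` from [cortical_mesh()] (needs `vulnerable` and
#'   reference patches)
#' @return a `pet_cohort` list: `subjects` (data frame), `series` (list of
#'   V x 10 frame matrices), `fdg`, `late` (V x n matrices), `truth`
#'   (ground-truth perfusion/metabolism/amyloid maps and deficit burden),
#'   `mesh`, `config`
#' @export
generate_cohort <- function(config, mesh) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(mesh$patches$vulnerable) || is.null(mesh$patches$pons))
    stop("mesh must provide 'vulnerable' and reference patches")
  set.seed(config$seed)
  V <- n_vertices(mesh)
  groups <- rep(names(config$sizes), times = config$sizes)
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  bl <- cohort_baselines(mesh)
  # graded disease topography: severity-tapered vulnerable cap carrying
  # both hypoperfusion and (stronger) hypometabolism, plus a mild
  # "decoupled" cap where perfusion is at least as affected as metabolism
  wv <- mesh$vulnerable_weight %||% as.numeric(seq_len(V) %in% mesh$patches$vulnerable)
  wd <- mesh$decoupled_weight %||% rep(0, V)
  ctx <- as.numeric(mesh$cortex)
  cereb <- rep(0, V); cereb[mesh$patches$cerebellum] <- 1
  wm <- rep(0, V); wm[mesh$patches$cerebral_WM] <- 1
  r <- config$coupling

  # subject-level draws
  amyloid_high <- rbinom(n, 1, config$amyloid_prob[groups]) == 1
  sev <- ifelse(amyloid_high,
                pmax(0.12, rnorm(n, config$amyloid_severity[groups], 0.08)),
                pmax(0, rnorm(n, 0.02, 0.02)))
  dp <- pmax(0, rnorm(n, config$hypoperfusion[groups],
                      0.2 * config$hypoperfusion[groups]))
  dm <- pmax(0, rnorm(n, config$hypometabolism_extra[groups],
                      0.2 * config$hypometabolism_extra[groups]))
  # diffuse disease: highly variable across patients, so the cortical mean
  # used by global scaling carries patient-specific bias
  ddp <- pmax(0, rnorm(n, config$diffuse_hypoperfusion[groups],
                       0.3 * config$diffuse_hypoperfusion[groups]))
  ddm <- pmax(0, rnorm(n, config$diffuse_hypometabolism[groups],
                       0.3 * config$diffuse_hypometabolism[groups]))
  g_early <- exp(rnorm(n, 0, 0.10))
  g_fdg <- exp(rnorm(n, 0, 0.10))
  g_late <- exp(rnorm(n, 0, 0.10))
  # modality-independent reference-patch instability: early-phase uptake
  # and glucose metabolism fluctuate separately in WM and cerebellum
  wm_shift_p <- rnorm(n, 0, config$ref_wm_sd)
  wm_shift_m <- rnorm(n, 0, 0.3 * config$ref_wm_sd)
  cb_shift_p <- rnorm(n, 0, config$ref_cerebellum_sd)
  cb_shift_m <- rnorm(n, 0, 0.5 * config$ref_cerebellum_sd)
  patient <- groups %in% c("aMCI", "AD-d")

  fields_F <- gen_smooth_fields(mesh, n)
  fields_G <- gen_smooth_fields(mesh, n)
  fields_A <- gen_smooth_fields(mesh, n)
  # reference-region stability: the pons is nearly free of between-subject
  # variability (the property that makes it a good reference); cerebellum
  # and white matter are intermediate, and white matter additionally
  # carries its own between-subject instability (wm_shift below)
  damp <- rep(1, V)
  damp[mesh$patches$medial_wall] <- 0.5
  damp[mesh$patches$cerebellum] <- 0.3
  damp[mesh$patches$cerebral_WM] <- 0.3
  damp[mesh$patches$pons] <- 0.05
  fields_F <- fields_F * damp
  fields_G <- fields_G * damp
  fields_A <- fields_A * damp

  # ground-truth perfusion (V x n)
  P <- matrix(0, V, n)
  for (s in seq_len(n)) {
    p <- bl$perfusion * (1 - dp[s] * (wv + wd) - ddp[s] * ctx) +
      config$subject_field_sd * fields_F[, s]
    p <- p * (1 - config$ref_cerebellum_affected * patient[s] * cereb) *
      (1 - config$ref_wm_affected * patient[s] * wm)
    p <- p + wm_shift_p[s] * wm + cb_shift_p[s] * cereb
    P[, s] <- p
  }
  sdP <- sd(as.vector(P[mesh$cortex, , drop = FALSE]))

  # metabolism coupled to perfusion; extra deficit in the independent channel
  M <- matrix(0, V, n)
  for (s in seq_len(n)) {
    # the perfusion-independent channel is mostly a fixed FDG-specific
    # topography (shared across subjects), plus a small subject field, so
    # metabolism keeps low between-subject noise while the vertex-pooled
    # correlation with perfusion stays at the configured coupling
    # metabolism is preserved in the decoupled cap (pure neurovascular
    # decoupling): the compensation term cancels the perfusion deficit
    # that would otherwise propagate through the coupling; it is gated by
    # sqrt(1-r^2) so that coupling = 1 still forces metabolism = perfusion
    comp <- if (abs(r) < 1) (r / sqrt(1 - r^2)) * dp[s] * wd * bl$perfusion
            else 0
    M[, s] <- r * P[, s] + sqrt(1 - r^2) *
      (sdP * (0.97 * bl$metab_dev + 0.24 * fields_G[, s]) -
         (dm[s] * wv + ddm[s] * ctx) * bl$perfusion + comp)
    # reference-patch fluctuations must not leak from perfusion into
    # metabolism through the coupling: remove the inherited component so
    # each modality's reference error is its own
    M[, s] <- M[, s] +
      (wm_shift_m[s] - r * wm_shift_p[s]) * wm +
      (cb_shift_m[s] - r * cb_shift_p[s]) * cereb
  }

  # amyloid maps (late-phase SUVR-like units)
  A <- matrix(0, V, n)
  for (s in seq_len(n)) {
    A[, s] <- bl$amyloid_base + sev[s] * bl$amyloid_pattern +
      0.03 * fields_A[, s]
  }

  tau <- (0:9) + 0.5
  Dcur <- delivery_curve(tau, config$delivery_time_to_peak,
                         config$delivery_shape, config$delivery_retention)
  Bcur <- binding_curve(tau, config$binding_onset, config$binding_slope)

  series <- vector("list", n)
  names(series) <- ids
  fdg <- matrix(0, V, n, dimnames = list(NULL, ids))
  late <- matrix(0, V, n, dimnames = list(NULL, ids))
  for (s in seq_len(n)) {
    noise <- if (config$frame_noise_sd > 0)
      matrix(rnorm(V * 10, 0, config$frame_noise_sd), V, 10) else 0
    fr <- outer(P[, s], Dcur) + outer(A[, s], Bcur) + noise
    series[[s]] <- g_early[s] * fr
    fdg[, s] <- g_fdg[s] * (M[, s] + rnorm(V, 0, config$fdg_noise_sd))
    late[, s] <- g_late[s] * (A[, s] + rnorm(V, 0, config$late_noise_sd))
  }

  # cognition: decreasing in the effective vulnerable-patch metabolism deficit
  burden <- r * dp + sqrt(1 - r^2) * dm
  mmse <- round(pmin(30, pmax(0, 29 - 47 * burden +
                                rnorm(n, 0, config$cognition_noise_sd))))
  recall <- round(pmin(16, pmax(0, 15 - 53 * burden +
                                  rnorm(n, 0, config$cognition_noise_sd))))
  age_mu <- c(yHC = 40.2, eHC = 70.4, aMCI = 75.6, `AD-d` = 69.4)
  age_sd <- c(yHC = 12.7, eHC = 4.6, aMCI = 7.2, `AD-d` = 8.2)
  female_p <- c(yHC = 0.44, eHC = 0.61, aMCI = 0.13, `AD-d` = 0.40)
  subjects <- data.frame(
    id = ids, group = groups,
    amyloid_status = ifelse(amyloid_high, "high", "low"),
    sex = ifelse(rbinom(n, 1, female_p[groups]) == 1, "F", "M"),
    age = round(rnorm(n, age_mu[groups], age_sd[groups]), 1),
    education = round(pmax(5, rnorm(n, 12.5, 3))),
    mmse = mmse, total_recall = recall,
    stringsAsFactors = FALSE)

  structure(list(subjects = subjects, series = series, fdg = fdg, late = late,
                 truth = list(perfusion = P, metabolism = M, amyloid = A,
                              burden = burden,
                              global_factors = cbind(early = g_early,
                                                     fdg = g_fdg, late = g_late)),
                 mesh = mesh, config = config),
            class = "pet_cohort")
}

#' @exportS3Method base::print
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort> %d subjects on %d-vertex mesh\n",
              nrow(x$subjects), n_vertices(x$mesh)))
  print(table(x$subjects$group, x$subjects$amyloid_status))
  invisible(x)
}
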