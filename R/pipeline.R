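# Pipeline orchestration: synthetic cohort -> scaling -> smoothing ->
# within-subject correlations -> Friedman ranking -> inter-subject
# correlations -> optimal-window selection, with per-stage JSON manifests
# and hash-based stage skipping.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()]
#' @param mesh_subdivisions,mesh_radius mesh geometry
#' @param reference scaling region for the early/FDG maps (one of the seven
#'   reference names)
#' @param smoothing_fwhm smoothing kernel FWHM (mm)
#' @param n_perm_inter permutations for inter-subject correlation p-values
#'   (0 disables)
#' @param stages character vector of stages to run, in order; a subset of
#'   `c("synth", "preproc", "correlate", "rank", "select")`
#' @param seed top-level seed; stage seeds are derived from it
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            mesh_subdivisions = 3, mesh_radius = 70,
                            reference = "pons", smoothing_fwhm = 8,
                            n_perm_inter = 0,
                            stages = c("synth", "preproc", "correlate",
                                       "rank", "select"),
                            seed = 1) {
  known <- c("synth", "preproc", "correlate", "rank", "select")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stop("unknown stage(s) in pipeline_config$stages: ",
         paste(bad, collapse = ", "))
  structure(list(cohort = cohort, mesh_subdivisions = mesh_subdivisions,
                 mesh_radius = mesh_radius, reference = reference,
                 smoothing_fwhm = smoothing_fwhm,
                 n_perm_inter = n_perm_inter, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash of a canonical JSON rendering; stable across
# sessions (doubles hold the intermediate products exactly below 2^53).
params_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(dir, stage, params, outputs) {
  man <- list(stage = stage, hash = params_hash(params), outputs = outputs,
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  man
}

stage_current <- function(dir, stage, params) {
  mf <- file.path(dir, paste0("manifest_", stage, ".json"))
  if (!file.exists(mf)) return(FALSE)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(man$hash, params_hash(params))) return(FALSE)
  all(file.exists(file.path(dir, man$outputs)))
}

#' Run the surface pipeline end to end
#'
#' Executes the configured stages in dependency order.  Every stage writes
#' its outputs plus a JSON manifest (stage name, parameter hash, output
#' list); a stage is skipped when its manifest matches the current
#' parameters, its outputs exist on disk, and nothing upstream was
#' recomputed.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @return invisibly, a list with the in-memory results and a `recomputed`
#'   logical vector (by stage)
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  recomputed <- logical(0)
  upstream_changed <- FALSE
  run_stage <- function(stage, params, outputs, compute_fn, write_fn) {
    fresh <- upstream_changed || !stage_current(out_dir, stage, params)
    value <- compute_fn()
    if (fresh) {
      write_fn(value)
      write_manifest(out_dir, stage, params, outputs)
      upstream_changed <<- TRUE
    }
    recomputed[stage] <<- fresh
    value
  }

  mesh <- cortical_mesh(config$mesh_subdivisions, config$mesh_radius)

  if ("synth" %in% config$stages) {
    res$cohort <- run_stage(
      "synth",
      list(cohort = unclass(config$cohort), sub = config$mesh_subdivisions,
           radius = config$mesh_radius),
      c("subjects.csv"),
      function() generate_cohort(config$cohort, mesh),
      function(v) write_subject_table(v$subjects,
                                      file.path(out_dir, "subjects.csv")))
  }

  if ("preproc" %in% config$stages) {
    stopifnot(!is.null(res$cohort))
    spec <- ref_region_spec(config$reference)
    cgm <- ref_region_spec("cerebellar_GM")
    res$preproc <- run_stage(
      "preproc",
      list(reference = config$reference, fwhm = config$smoothing_fwhm),
      c("amyloid_status.csv"),
      function() {
        co <- res$cohort
        windows <- enumerate_windows()
        n <- nrow(co$subjects)
        scale1 <- function(x, sp) as.numeric(scale_image(x, sp, mesh = mesh))
        early <- lapply(windows, function(w) {
          m <- vapply(co$series, function(fr)
            scale1(window_mean(fr, w), spec), numeric(n_vertices(mesh)))
          smooth_surface(m, mesh, config$smoothing_fwhm)
        })
        fdg <- smooth_surface(apply(co$fdg, 2, scale1, sp = spec), mesh,
                              config$smoothing_fwhm)
        late_suvr <- apply(co$late, 2, scale1, sp = cgm)
        late <- smooth_surface(late_suvr, mesh, config$smoothing_fwhm)
        status <- vapply(seq_len(n), function(s)
          as.character(call_amyloid_status(late_suvr[, s], mesh)),
          character(1))
        list(windows = windows, early = early, fdg = fdg, late = late,
             amyloid_status = status)
      },
      function(v) write.csv(data.frame(id = res$cohort$subjects$id,
                                       amyloid_status = v$amyloid_status),
                            file.path(out_dir, "amyloid_status.csv"),
                            row.names = FALSE))
  }

  if ("correlate" %in% config$stages) {
    stopifnot(!is.null(res$preproc))
    res$within <- run_stage(
      "correlate", list(fwhm = config$smoothing_fwhm),
      c("within_subject_corr.csv"),
      function() {
        pp <- res$preproc
        n <- ncol(pp$fdg)
        wc <- sapply(seq_along(pp$windows), function(wi)
          vapply(seq_len(n), function(s)
            within_subject_corr(pp$early[[wi]][, s], pp$fdg[, s],
                                mesh$cortex), numeric(1)))
        colnames(wc) <- vapply(pp$windows, format, character(1))
        wc
      },
      function(v) write.csv(v, file.path(out_dir, "within_subject_corr.csv"),
                            row.names = FALSE))
  }

  if ("rank" %in% config$stages) {
    stopifnot(!is.null(res$within))
    res$ranking <- run_stage(
      "rank", list(direction = "higher"), c("window_ranking.json"),
      function() friedman_rank(res$within, direction = "higher"),
      function(v) jsonlite::write_json(
        unclass(v), file.path(out_dir, "window_ranking.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA))
  }

  if ("select" %in% config$stages) {
    stopifnot(!is.null(res$ranking), !is.null(res$preproc))
    res$selection <- run_stage(
      "select", list(n_perm = config$n_perm_inter), c("window_selection.json"),
      function() {
        pp <- res$preproc
        top <- res$ranking$groups[[1]]
        names(pp$early) <- vapply(pp$windows, format, character(1))
        cand <- pp$windows[match(top, names(pp$early))]
        r_fdg <- sapply(top, function(w)
          inter_subject_corr(pp$early[[w]], pp$fdg, mesh$cortex)$r)
        r_late <- sapply(top, function(w)
          inter_subject_corr(pp$early[[w]], pp$late, mesh$cortex)$r)
        select_optimal_window(cand, r_fdg, r_late, mesh$area, mesh$cortex)
      },
      function(v) jsonlite::write_json(
        list(selected = v$selected_name,
             fdg_area_fraction = as.list(v$fdg_area_fraction),
             late_area_fraction = as.list(v$late_area_fraction)),
        file.path(out_dir, "window_selection.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA))
  }

  res$recomputed <- recomputed
  invisible(res)
}
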