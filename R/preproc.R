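# Early-window enumeration and averaging, reference-region intensity
# scaling, and amyloid-status calling.

#' Construct an early time-frame window
#'
#' Frame k covers minute \[k, k+1); the window \[T1, T2\] averages frames
#' T1 .. T2-1.
#'
#' @param t1 start minute (0, 1, 2 or 3)
#' @param t2 end minute (1..10), strictly greater than `t1`
#' @return a `frame_window`
#' @export
frame_window <- function(t1, t2) {
  stopifnot(t1 %in% 0:3, t2 %in% 1:10, t2 > t1)
  structure(list(t1 = as.integer(t1), t2 = as.integer(t2)),
            class = "frame_window")
}

#' @exportS3Method base::format
format.frame_window <- function(x, ...) sprintf("%d-%d", x$t1, x$t2)

#' @exportS3Method base::print
print.frame_window <- function(x, ...) {
  cat("<frame_window>", format(x), "min\n"); invisible(x)
}

#' Enumerate all candidate early time-frame windows
#'
#' All (T1, T2) with T1 in \{0,1,2,3\}, T2 in \{1..10\} and T2 > T1, in
#' lexicographic order: 34 windows.
#'
#' @param t1_values,t2_values admissible start/end minutes (restrict for
#'   reduced variants)
#' @return list of [frame_window()] objects
#' @examples
#' length(enumerate_windows())  # 34
#' @export
enumerate_windows <- function(t1_values = 0:3, t2_values = 1:10) {
  out <- list()
  for (t1 in sort(t1_values)) for (t2 in sort(t2_values))
    if (t2 > t1) out[[length(out) + 1L]] <- frame_window(t1, t2)
  out
}

#' Mean image over an early time-frame window
#'
#' @param series V x 10 matrix of frame maps (columns = frames 0..9) or a
#'   list of 10 equally-shaped arrays
#' @param window a [frame_window()]
#' @return arithmetic mean of frames T1 .. T2-1, same grid as the input
#' @export
window_mean <- function(series, window) {
  stopifnot(inherits(window, "frame_window"))
  idx <- (window$t1 + 1):window$t2
  if (is.list(series)) {
    if (max(idx) > length(series)) stop("window outside the acquired frames")
    return(Reduce(`+`, series[idx]) / length(idx))
  }
  if (max(idx) > ncol(series)) stop("window outside the acquired frames")
  rowMeans(series[, idx, drop = FALSE])
}

# ---- reference regions ---------------------------------------------------

#' Reference-region specification for intensity scaling
#'
#' The seven regions considered for scaling are cerebellum, cerebellar grey
#' matter, global (proportional scaling to 6.5 mg/100 mL/min), pons,
#' pons+cerebellum, pons+cerebellar GM, and cerebral white matter.  Region
#' masks are eroded by a 4-mm margin and, for volumetric masks, intersected
#' with the matching thresholded tissue probability map (threshold 0.5)
#' before the reference mean is computed.
#'
#' @param name one of `"cerebellum"`, `"cerebellar_GM"`, `"global"`,
#'   `"pons"`, `"pons+cerebellum"`, `"pons+cerebellar_GM"`, `"cerebral_WM"`
#' @param mask optional logical 3D array (volumetric mask); if `NULL` the
#'   region is resolved from mesh patches of the same name
#' @param tissue tissue class(es) used for volumetric masking: `"GM"`,
#'   `"WM"` or `"GM+WM"`; defaults depend on the region
#' @param threshold tissue-probability threshold, in (0, 1)
#' @param erosion_mm erosion radius in mm (>= 0)
#' @param global_value physiological reference value used only by
#'   `name = "global"`
#' @return a `ref_region_spec`
#' @export
ref_region_spec <- function(name, mask = NULL, tissue = NULL, threshold = 0.5,
                            erosion_mm = 4, global_value = 6.5) {
  regions <- c("cerebellum", "cerebellar_GM", "global", "pons",
               "pons+cerebellum", "pons+cerebellar_GM", "cerebral_WM")
  name <- match.arg(name, regions)
  stopifnot(threshold > 0, threshold < 1, erosion_mm >= 0)
  if (is.null(tissue)) {
    tissue <- switch(name,
                     cerebellar_GM = "GM",
                     `pons+cerebellar_GM` = "GM",
                     cerebral_WM = "WM",
                     "GM+WM")
  }
  structure(list(name = name, mask = mask, tissue = tissue,
                 threshold = threshold, erosion_mm = erosion_mm,
                 global_value = global_value),
            class = "ref_region_spec")
}

#' The seven standard reference-region specifications
#' @param ... passed to [ref_region_spec()] (e.g. `erosion_mm`)
#' @return named list of `ref_region_spec`s
#' @export
reference_regions <- function(...) {
  nm <- c("cerebellum", "cerebellar_GM", "global", "pons",
          "pons+cerebellum", "pons+cerebellar_GM", "cerebral_WM")
  stats::setNames(lapply(nm, ref_region_spec, ...), nm)
}

# Erode a logical 3D mask by a discrete ball: a voxel survives iff every
# voxel whose centre lies within radius_mm of it is inside the mask
# (outside the grid counts as background).
erode_mask_volume <- function(mask, radius_mm, voxel_mm) {
  stopifnot(radius_mm >= 0, voxel_mm > 0)
  if (radius_mm == 0) return(mask)
  r <- floor(radius_mm / voxel_mm)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= (radius_mm / voxel_mm)^2, ]
  dm <- dim(mask)
  out <- array(TRUE, dm)
  for (k in seq_len(nrow(off))) {
    sh <- array(FALSE, dm)
    xs <- max(1, 1 + off$dx[k]):min(dm[1], dm[1] + off$dx[k])
    ys <- max(1, 1 + off$dy[k]):min(dm[2], dm[2] + off$dy[k])
    zs <- max(1, 1 + off$dz[k]):min(dm[3], dm[3] + off$dz[k])
    sh[xs - off$dx[k], ys - off$dy[k], zs - off$dz[k]] <-
      mask[xs, ys, zs]
    out <- out & sh
  }
  out & mask
}

# Eroded reference masks are cached: scaling is called once per map and
# the erosion depends only on the mesh geometry and the spec.
.ref_cache <- new.env(parent = emptyenv())

resolve_surface_reference <- function(spec, mesh) {
  key <- paste(spec$name, spec$erosion_mm, n_vertices(mesh),
               nrow(mesh$edges), signif(sum(mesh$area), 12), sep = "|")
  hit <- .ref_cache[[key]]
  if (!is.null(hit)) return(hit)
  parts <- strsplit(spec$name, "+", fixed = TRUE)[[1]]
  idx <- integer(0)
  for (p in parts) {
    patch <- mesh$patches[[p]]
    if (is.null(patch)) stop("mesh has no patch named '", p, "'")
    idx <- union(idx, erode_patch(mesh, patch, spec$erosion_mm))
  }
  .ref_cache[[key]] <- idx
  idx
}

#' Scale an image by a reference-region mean
#'
#' For a named reference region, divides the image by the mean value over
#' the eroded (and, for volumes, tissue-masked) reference region, so the
#' scaled image has reference mean exactly 1.  For `name = "global"`,
#' applies proportional scaling `x * global_value / mean(x over the brain
#' mask)` so the brain mean equals `global_value` (6.5 mg/100 mL/min by
#' default).  Scaling is invariant to any positive rescaling of the input.
#'
#' @param x numeric vector (surface map; requires `mesh`) or 3D array
#'   (volume; requires `spec$mask`, `tissue_probs`, `voxel_mm`)
#' @param spec a [ref_region_spec()]
#' @param mesh `pet_mesh` for surface maps
#' @param tissue_probs named list of probability arrays (`GM`, `WM`, `CSF`)
#'   for volumetric masking
#' @param voxel_mm voxel size for volumetric erosion
#' @param brain_mask logical mask used by global scaling (volumes); surface
#'   maps use the mesh cortex mask
#' @return the scaled image, with attribute `reference_mean` (the mean that
#'   was divided out, on the input scale)
#' @export
scale_image <- function(x, spec, mesh = NULL, tissue_probs = NULL,
                        voxel_mm = NULL, brain_mask = NULL) {
  stopifnot(inherits(spec, "ref_region_spec"))
  is_vol <- is.array(x) && length(dim(x)) == 3
  if (spec$name == "global") {
    if (is_vol) {
      if (is.null(brain_mask)) stop("global scaling of a volume needs brain_mask")
      ref <- mean(x[brain_mask])
    } else {
      if (is.null(mesh)) stop("surface scaling needs a mesh")
      ref <- mean(x[mesh$cortex])
    }
    if (!is.finite(ref) || ref <= 0) stop("non-positive global mean")
    out <- x * spec$global_value / ref
    attr(out, "reference_mean") <- ref
    return(out)
  }
  if (is_vol) {
    if (is.null(spec$mask)) stop("volumetric scaling needs spec$mask")
    if (is.null(voxel_mm)) stop("volumetric scaling needs voxel_mm")
    m <- erode_mask_volume(spec$mask, spec$erosion_mm, voxel_mm)
    if (!is.null(tissue_probs)) {
      cls <- strsplit(spec$tissue, "+", fixed = TRUE)[[1]]
      p <- Reduce(`+`, tissue_probs[cls])
      m <- m & (p > spec$threshold)
    }
    if (!any(m)) stop("reference region vanished after erosion/masking")
    ref <- mean(x[m])
  } else {
    if (is.null(mesh)) stop("surface scaling needs a mesh")
    idx <- resolve_surface_reference(spec, mesh)
    if (length(idx) == 0) stop("reference region vanished after erosion")
    ref <- mean(x[idx])
  }
  if (!is.finite(ref) || ref <= 0) stop("non-positive reference mean")
  out <- x / ref
  attr(out, "reference_mean") <- ref
  out
}

# ---- amyloid status ------------------------------------------------------

#' Amyloid positivity cutoff
#'
#' @param threshold SUVR threshold (default 1.22, derived in the source
#'   cohort from the 95th percentile of young controls and taken here as a
#'   given constant); must be > 0
#' @return an `amyloid_cutoff`
#' @export
amyloid_cutoff <- function(threshold = 1.22) {
  stopifnot(threshold > 0)
  structure(list(threshold = threshold), class = "amyloid_cutoff")
}

#' Call amyloid status from a scaled late-phase map
#'
#' The late map must already be scaled by cerebellar grey matter (the
#' late-phase SUVR convention).  Status is `"high"` iff the area-weighted
#' mean over the neocortical mask is strictly greater than the threshold
#' (a value exactly at the cutoff is called `"low"`).
#'
#' @param late_map scaled late-phase surface map
#' @param mesh `pet_mesh` with a `neocortex` mask
#' @param cutoff an [amyloid_cutoff()]
#' @return `"high"` or `"low"`, with attribute `neocortical_mean`
#' @export
call_amyloid_status <- function(late_map, mesh, cutoff = amyloid_cutoff()) {
  stopifnot(inherits(cutoff, "amyloid_cutoff"))
  mask <- which(mesh$neocortex)
  if (length(mask) == 0) stop("empty neocortical mask")
  m <- sum(late_map[mask] * mesh$area[mask]) / sum(mesh$area[mask])
  structure(if (m > cutoff$threshold) "high" else "low",
            neocortical_mean = m)
}
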