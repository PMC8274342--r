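# Volumetric phantom: nested spherical compartments blurred by an isotropic
# Gaussian PSF, with an embedded central-surface mesh.  Substrate for the
# partial-volume correction and surface projection operations.

# Separable 3D Gaussian convolution with zero padding outside the grid
# (kernel rows are shift-invariant and sum to one in the interior, so mass
# is conserved away from the edges).  The same routine is used by the
# phantom generator and by the Mueller-Gaertner correction, which is what
# makes the correction exact on phantom data.
gaussian_blur_3d <- function(arr, fwhm_mm, voxel_mm) {
  stopifnot(fwhm_mm >= 0, voxel_mm > 0)
  if (fwhm_mm == 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    n <- dim(a)[axis]
    K <- matrix(0, n, n)
    for (off in seq(-half, half)) {
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[off + half + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- K %*% matrix(ap, nrow = d[1])
    aperm(array(m, d), order(perm))
  }
  for (axis in 1:3) arr <- conv_axis(arr, axis)
  arr
}

#' Generate a spherical-shell volumetric phantom
#'
#' Builds a 3D grid with three nested compartments -- a white-matter core,
#' a grey-matter shell and surrounding CSF -- each with piecewise-constant
#' true activity, and an observed grid equal to the truth convolved with an
#' isotropic Gaussian point-spread function.  A central-surface icosphere
#' mesh is embedded mid-shell, with the shell width as its thickness field,
#' for testing surface projection.
#'
#' @param shape grid dimensions (3 integers); must be large enough to hold
#'   the shells plus a PSF margin
#' @param voxel_mm isotropic voxel size (mm, > 0)
#' @param psf_fwhm_mm PSF full width at half maximum (mm, >= 0)
#' @param activities named numeric: true activity per compartment,
#'   `c(GM =, WM =, CSF =)`, all >= 0
#' @param wm_radius_mm,gm_outer_mm radii of the WM core and the outer GM
#'   boundary (the GM shell spans `wm_radius_mm` to `gm_outer_mm`)
#' @param mesh_subdivisions icosphere subdivision level of the embedded mesh
#' @return a `volume_phantom` list: `observed`, `truth`, `prob` (list of
#'   GM/WM/CSF indicator grids), `activities`, `voxel_mm`, `psf_fwhm_mm`,
#'   `origin`, and `mesh` (a `pet_mesh` in the grid's physical space)
#' @examples
#' ph <- generate_phantom(shape = c(30, 30, 30), voxel_mm = 2, psf_fwhm_mm = 0,
#'                        activities = c(GM = 4, WM = 1, CSF = 0))
#' all.equal(ph$observed, ph$truth)
#' @export
generate_phantom <- function(shape = c(48, 48, 48), voxel_mm = 2,
                             psf_fwhm_mm = 6,
                             activities = c(GM = 4, WM = 1, CSF = 0),
                             wm_radius_mm = 22, gm_outer_mm = 30,
                             mesh_subdivisions = 2) {
  stopifnot(length(shape) == 3, voxel_mm > 0, psf_fwhm_mm >= 0,
            all(activities >= 0), gm_outer_mm > wm_radius_mm)
  if (min(shape) * voxel_mm < 2 * gm_outer_mm + 2 * psf_fwhm_mm)
    stop("grid too small to contain the shells (plus PSF margin)")
  centre <- shape * voxel_mm / 2
  co <- lapply(1:3, function(d) (seq_len(shape[d]) - 0.5) * voxel_mm - centre[d])
  r2 <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  r <- sqrt(r2)
  wm <- array(as.numeric(r <= wm_radius_mm), shape)
  gm <- array(as.numeric(r > wm_radius_mm & r <= gm_outer_mm), shape)
  csf <- array(as.numeric(r > gm_outer_mm), shape)
  truth <- activities[["GM"]] * gm + activities[["WM"]] * wm +
    activities[["CSF"]] * csf
  observed <- gaussian_blur_3d(truth, psf_fwhm_mm, voxel_mm)

  ico <- icosphere(mesh_subdivisions)
  mid_r <- (wm_radius_mm + gm_outer_mm) / 2
  verts <- ico$vertices * mid_r + matrix(centre, nrow(ico$vertices), 3, byrow = TRUE)
  mesh <- new_pet_mesh(verts, ico$triangles,
                       rep(gm_outer_mm - wm_radius_mm, nrow(verts)),
                       rep("L", nrow(verts)))
  mesh$cortex <- rep(TRUE, nrow(verts))
  mesh$parcel <- rep("p01", nrow(verts))
  mesh$patches <- list()

  structure(list(observed = observed, truth = truth,
                 prob = list(GM = gm, WM = wm, CSF = csf),
                 activities = activities, voxel_mm = voxel_mm,
                 psf_fwhm_mm = psf_fwhm_mm, origin = c(0, 0, 0),
                 mesh = mesh, gm_core_radius = c(wm_radius_mm, gm_outer_mm)),
            class = "volume_phantom")
}

# Logical mask of GM-core voxels: inner part of the shell, at least
# `margin_mm` from both shell boundaries.
phantom_gm_core <- function(phantom, margin_mm = 4) {
  shape <- dim(phantom$truth)
  centre <- shape * phantom$voxel_mm / 2
  co <- lapply(1:3, function(d)
    (seq_len(shape[d]) - 0.5) * phantom$voxel_mm - centre[d])
  r <- sqrt(outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+"))
  r > phantom$gm_core_radius[1] + margin_mm &
    r < phantom$gm_core_radius[2] - margin_mm
}
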