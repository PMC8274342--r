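# Mueller-Gaertner three-compartment voxel-wise partial-volume correction.

#' Partial-volume correction parameters
#'
#' @param psf_fwhm_mm scanner point-spread FWHM (mm, > 0)
#' @param gm_threshold GM-probability threshold defining the output domain,
#'   in (0, 1); division by the blurred GM fraction is only performed where
#'   it is safely away from zero (default 0.3)
#' @param wm_prob_threshold WM probability above which voxels enter the
#'   eroded mask used to estimate the white-matter compartment activity
#' @param wm_erosion_mm erosion of that WM mask (defaults to half the PSF
#'   FWHM, keeping the estimate away from spill-over at tissue boundaries)
#' @param csf_activity assumed CSF compartment activity (standard practice
#'   is 0); set to `NULL` to estimate it as the mean observed value in
#'   high-probability CSF
#' @return a `pvc_params` list
#' @export
pvc_params <- function(psf_fwhm_mm = 6, gm_threshold = 0.3,
                       wm_prob_threshold = 0.9, wm_erosion_mm = NULL,
                       csf_activity = 0) {
  stopifnot(psf_fwhm_mm > 0, gm_threshold > 0, gm_threshold < 1)
  if (is.null(wm_erosion_mm)) wm_erosion_mm <- psf_fwhm_mm / 2
  structure(list(psf_fwhm_mm = psf_fwhm_mm, gm_threshold = gm_threshold,
                 wm_prob_threshold = wm_prob_threshold,
                 wm_erosion_mm = wm_erosion_mm, csf_activity = csf_activity),
            class = "pvc_params")
}

#' Mueller-Gaertner partial-volume correction
#'
#' Removes PSF-blurred white-matter and CSF spill-in from a PET volume and
#' divides by the blurred grey-matter fraction:
#'
#'   corrected = (PET - A_WM * (p_WM (x) G) - A_CSF * (p_CSF (x) G)) / (p_GM (x) G)
#'
#' on voxels with `p_GM > gm_threshold`, where G is an isotropic Gaussian
#' PSF.  The WM compartment activity A_WM is the mean observed PET value in
#' an eroded high-probability WM mask; A_CSF defaults to 0.  Voxels outside
#' the domain are `NA`.
#'
#' @param pet 3D PET array
#' @param tissue_probs named list of probability arrays `GM`, `WM`, `CSF`
#'   aligned with `pet`
#' @param params a [pvc_params()]
#' @param voxel_mm isotropic voxel size (mm)
#' @return corrected GM volume (array, `NA` outside the GM domain) with
#'   attributes `wm_activity` and `csf_activity`
#' @export
muller_gartner <- function(pet, tissue_probs, params = pvc_params(),
                           voxel_mm = 1) {
  stopifnot(inherits(params, "pvc_params"),
            all(c("GM", "WM", "CSF") %in% names(tissue_probs)),
            all(dim(pet) == dim(tissue_probs$GM)))
  fw <- params$psf_fwhm_mm
  wm_mask <- erode_mask_volume(tissue_probs$WM > params$wm_prob_threshold,
                               params$wm_erosion_mm, voxel_mm)
  if (!any(wm_mask)) stop("no white-matter voxels left to estimate A_WM")
  a_wm <- mean(pet[wm_mask])
  a_csf <- params$csf_activity
  if (is.null(a_csf)) {
    csf_mask <- tissue_probs$CSF > params$wm_prob_threshold
    a_csf <- if (any(csf_mask)) mean(pet[csf_mask]) else 0
  }
  g_gm <- gaussian_blur_3d(tissue_probs$GM, fw, voxel_mm)
  g_wm <- gaussian_blur_3d(tissue_probs$WM, fw, voxel_mm)
  g_csf <- gaussian_blur_3d(tissue_probs$CSF, fw, voxel_mm)
  domain <- tissue_probs$GM > params$gm_threshold & g_gm > 1e-6
  if (!any(domain)) stop("empty GM domain: no voxel with p_GM above threshold")
  out <- array(NA_real_, dim(pet))
  out[domain] <- (pet[domain] - a_wm * g_wm[domain] - a_csf * g_csf[domain]) /
    g_gm[domain]
  attr(out, "wm_activity") <- a_wm
  attr(out, "csf_activity") <- a_csf
  out
}
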