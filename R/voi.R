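#' Perfused liver mask by SPECT thresholding
#'
#' The perfused liver (PL) is the set of liver voxels whose reconstructed
#' counts are at least `fraction` (default 5%, inclusive) of the maximum
#' counts within the liver, intersected with the liver mask.
#'
#' @param recon a [vol3d()] reconstruction.
#' @param liver logical array, liver mask (including tumors).
#' @param fraction threshold fraction of the in-liver maximum (default 0.05).
#' @return logical array, the PL mask.
#' @export
perfused_liver <- function(recon, liver, fraction = 0.05) {
  if (!any(liver)) stop("perfused_liver: empty liver mask")
  mx <- max(recon$data[liver])
  (recon$data >= fraction * mx) & liver
}

#' Derive the seven planning volumes of interest
#'
#' Applies the planning set algebra: voxels shared by liver and lungs are
#' first reassigned (to the liver by default), then
#' healthy liver `HL = liver - tumors`,
#' healthy perfused liver `HPL = PL - tumors`, and
#' hepatic reserve `HR = liver - PL - tumors`. The PL mask is forced inside
#' the (post-resolution) liver. Tumor voxels outside the liver are kept in
#' the tumor masks with a warning.
#'
#' @param liver,lungs logical arrays (liver includes tumor voxels).
#' @param tumors list of logical arrays, one per lesion (may be empty).
#' @param pl logical array from [perfused_liver()].
#' @param spacing voxel spacing mm (for volume summaries).
#' @param overlap_to `"liver"` (default) or `"lungs"`: which organ receives
#'   shared voxels.
#' @return object of class `voi_set`: named masks `liver`, `lungs`,
#'   `tumors` (per-lesion list), `tumor_any`, `PL`, `HL`, `HPL`, `HR`,
#'   plus `spacing`.
#' @export
derive_vois <- function(liver, lungs, tumors, pl, spacing = c(1, 1, 1),
                        overlap_to = c("liver", "lungs")) {
  overlap_to <- match.arg(overlap_to)
  overlap <- liver & lungs
  if (overlap_to == "liver") lungs <- lungs & !overlap else liver <- liver & !overlap
  tumor_any <- Reduce(`|`, tumors, array(FALSE, dim(liver)))
  if (any(tumor_any & !liver))
    warning("derive_vois: tumor voxels outside the liver; kept in tumor mask")
  pl <- pl & liver
  structure(list(
    liver = liver, lungs = lungs, tumors = tumors, tumor_any = tumor_any,
    PL = pl,
    HL = liver & !tumor_any,
    HPL = pl & !tumor_any,
    HR = liver & !pl & !tumor_any,
    overlap = overlap, overlap_to = overlap_to,
    spacing = as.numeric(spacing)), class = "voi_set")
}

#' @rdname derive_vois
#' @param vois a `voi_set`.
#' @export
voi_summary <- function(vois) {
  nm <- c("liver", "lungs", "tumor_any", "PL", "HL", "HPL", "HR")
  vox <- vapply(vois[nm], sum, 0)
  data.frame(voi = nm, n_voxels = vox,
             volume_ml = vox * prod(vois$spacing) / 1000, row.names = NULL)
}
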