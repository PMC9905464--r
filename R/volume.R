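#' 3D volumetric image container
#'
#' A minimal S3 container for a 3D scalar image on a regular grid: a numeric
#' array plus voxel spacing (mm) and physical origin (mm, position of the
#' center of voxel `[1,1,1]`). Axis convention throughout the package:
#' x = left-right, y = antero-posterior, z = cranio-caudal (CC).
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (must be > 0).
#' @param origin numeric length-3, mm. Defaults to half a voxel so that the
#'   grid covers `[0, dim * spacing]`.
#' @return an object of class `vol3d`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = spacing / 2) {
  if (length(dim(data)) != 3L) stop("vol3d: `data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("vol3d: spacing must be positive and finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("vol3d: %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' @rdname vol3d
#' @param x a `vol3d`.
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

# physical coordinates (mm) of voxel centers along each axis
vol_axis_mm <- function(x, axis) {
  (seq_len(dim(x$data)[axis]) - 1) * x$spacing[axis] + x$origin[axis]
}

# voxel-center coordinates (mm) for a logical mask, as an n x 3 matrix
mask_coords_mm <- function(mask, spacing, origin = spacing / 2) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) stop(sprintf("geometry mismatch between %s", what))
  invisible(TRUE)
}

#' Read and write MetaImage volumes
#'
#' Plain MetaImage (.mha, local binary data) I/O for exchanging reconstructed
#' images and masks with other tools. Data are stored as little-endian
#' `MET_DOUBLE`.
#'
#' @param vol a [vol3d()].
#' @param path file path ending in `.mha`.
#' @return `read_mha` returns a [vol3d()]; `write_mha` returns `path`
#'   invisibly.
#' @export
write_mha <- function(vol, path) {
  stopifnot(inherits(vol, "vol3d"))
  d <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2], vol$origin[3]),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_mha
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_mha: no ElementDataFile line found")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementType"]], "MET_DOUBLE"))
    stop("read_mha: only MET_DOUBLE supported")
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("read_mha: only LOCAL data supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  off <- as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  vals <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  vol3d(array(vals, dim = d), spacing = sp, origin = off)
}

#' CSV exchange helpers
#'
#' Flat-file exports for the pipeline's intermediate objects: list-mode
#' events (`time, projection, iu, iv, window, phase_true`), the respiratory
#' signal (`time, amplitude, phase`), and the per-phase/per-angle affine
#' transforms (`phase, angle_index, m11, m12, m21, m22, tu, tv`).
#'
#' @param lm a [acquire_listmode()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_listmode_csv <- function(lm, path) {
  utils::write.csv(lm$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_listmode_csv
#' @param signal a [laplacian_eigenmap_signal()] result.
#' @param phases optional [assign_phases()] result supplying per-bin labels.
#' @export
write_signal_csv <- function(signal, path, phases = NULL) {
  df <- data.frame(time = signal$time, amplitude = signal$amplitude)
  if (!is.null(phases)) df$phase <- phases$time_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_listmode_csv
#' @param transforms a [register_phases_2d_affine()] result.
#' @export
write_transforms_csv <- function(transforms, path) {
  n_ph <- dim(transforms)[1]; n_an <- dim(transforms)[2]
  df <- do.call(rbind, lapply(seq_len(n_ph), function(p)
    data.frame(phase = p - 1L, angle_index = seq_len(n_an) - 1L,
               m11 = transforms[p, , 1], m12 = transforms[p, , 2],
               m21 = transforms[p, , 3], m22 = transforms[p, , 4],
               tu = transforms[p, , 5], tv = transforms[p, , 6])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
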