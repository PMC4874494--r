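#' Create an ImageVolume
#'
#' @param voxels 3-D numeric array.
#' @param spacing numeric(3), voxel size in mm.
#' @param origin numeric(3), world position (mm) of the center of voxel
#'   (0,0,0).
#' @param orientation 3x3 direction-cosine matrix (columns = world
#'   directions of the voxel axes).
#' @param modality `"PET"` or `"CT"`.
#' @return An [ImageVolume-class].
#' @export
ImageVolume <- function(voxels, spacing, origin = c(0, 0, 0),
                        orientation = diag(3), modality = "CT") {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation,
      modality = modality)
}

#' Read a DICOM series into a geometry-aware volume
#'
#' Reads a single-modality DICOM series (one single-frame file per slice),
#' sorts the slices into ascending axial position using the projection of
#' Image Position (Patient) onto the slice normal, and populates spacing,
#' origin and orientation from the header tags.  Vendor rescale
#' slope/intercept is applied to the stored pixel values.
#'
#' @param path a directory containing `.dcm` files, or a character vector of
#'   file paths.
#' @return An [ImageVolume-class].
#' @section Errors: missing geometry tags signal a `nemaiq_malformedSeries`
#'   error; inter-slice spacing inconsistent beyond 1% signals
#'   `nemaiq_irregularSeries`.
#' @export
readDicomSeries <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.dcm$", full.names = TRUE) else path
  if (length(files) == 0L)
    stop(.nemaiq_error("malformedSeries", "no DICOM files found"))
  slices <- lapply(files, .dcm_read_file)

  ref <- slices[[1L]]
  same <- function(f, tol = 1e-6) all(vapply(slices, function(s)
    isTRUE(all(abs(s[[f]] - ref[[f]]) <= tol)), logical(1)))
  if (!all(vapply(slices, function(s) identical(s$modality, ref$modality),
                  logical(1))) ||
      !same("iop") || !same("pixelSpacing") ||
      !all(vapply(slices, function(s)
        s$rows == ref$rows && s$cols == ref$cols, logical(1))))
    stop(.nemaiq_error("malformedSeries",
                       "series mixes geometry, size or modality"))

  rowdir <- ref$iop[1:3]; coldir <- ref$iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  proj <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(proj)
  slices <- slices[ord]; proj <- proj[ord]

  n <- length(slices)
  if (n >= 2L) {
    dzs <- diff(proj)
    dz <- stats::median(dzs)
    if (dz <= 0 || any(abs(dzs - dz) > 0.01 * dz))
      stop(.nemaiq_error("irregularSeries",
                         "inconsistent inter-slice spacing (> 1%)"))
  } else {
    dz <- if (!is.null(ref$sliceThickness)) ref$sliceThickness else 1
  }

  nx <- ref$cols; ny <- ref$rows
  vox <- array(0, c(nx, ny, n))
  for (k in seq_len(n)) vox[, , k] <- slices[[k]]$values
  modality <- switch(ref$modality, CT = "CT", PT = "PET",
                     stop(.nemaiq_error("malformedSeries",
                                        paste("unsupported modality:",
                                              ref$modality))))
  ImageVolume(vox,
              spacing = c(ref$pixelSpacing[2], ref$pixelSpacing[1], dz),
              origin = slices[[1L]]$ipp,
              orientation = cbind(rowdir, coldir, normal, deparse.level = 0),
              modality = modality)
}

#' Write a volume as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame file per slice, with
#' the geometry tags [readDicomSeries()] consumes.  Integer-valued volumes
#' round-trip exactly (rescale slope 1); other volumes are quantized to 16
#' bits with a rescale slope/intercept.
#'
#' @param volume an [ImageVolume-class].
#' @param dir output directory (created if needed).
#' @param seriesNumber integer used to build deterministic UIDs.
#' @return Invisibly, the written file paths.
#' @export
writeDicomSeries <- function(volume, dir, seriesNumber = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume@voxels)
  sp <- volume@spacing
  modalityCode <- if (volume@modality == "PET") "PT" else "CT"

  v <- volume@voxels
  vmin <- min(v); vmax <- max(v)
  # CT is conventionally signed (HU); PET stores unsigned counts unless
  # post-reconstruction noise leaves negative values
  signed <- volume@modality == "CT" || vmin < 0
  isInt <- max(abs(v - round(v))) < 1e-9
  lim <- if (signed) c(-32768, 32767) else c(0, 65535)
  if (isInt && vmin >= lim[1] && vmax <= lim[2]) {
    slope <- 1; icpt <- 0
  } else {
    # quantize to 16 bits; stored = round((v - intercept) / slope)
    icpt <- vmin
    slope <- if (vmax > vmin) (vmax - vmin) / 65000 else 1
    v <- round((v - icpt) / slope)
    if (signed) {
      v <- v - 32000
      icpt <- icpt + 32000 * slope
    }
  }
  stored <- v

  studyUid <- paste0(.uid_root, ".2.", seriesNumber)
  seriesUid <- paste0(.uid_root, ".3.", seriesNumber)
  forUid <- paste0(.uid_root, ".4.1")
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- volume@origin + volume@orientation[, 3] * (k - 1L) * sp[3]
    files[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    .dcm_write_slice(files[k],
                     pixels = as.vector(stored[, , k]),
                     rows = d[2], cols = d[1], modalityCode = modalityCode,
                     ipp = ipp,
                     iop = c(volume@orientation[, 1], volume@orientation[, 2]),
                     pixelSpacingRowCol = c(sp[2], sp[1]),
                     sliceThickness = sp[3], instanceNumber = k,
                     seriesUid = seriesUid, studyUid = studyUid,
                     forUid = forUid, signedPixels = signed,
                     rescaleIntercept = icpt, rescaleSlope = slope)
  }
  invisible(files)
}

#' Check slice orthogonality
#'
#' Verifies that every entry of the first two orientation columns (the
#' Image Orientation Patient direction cosines) is one of -1, 0 or +1
#' within 1e-6.  Volumes failing the check cannot be analysed and the
#' pipeline terminates.
#'
#' @param volume an [ImageVolume-class].
#' @return `TRUE` invisibly on pass.
#' @section Errors: a `nemaiq_nonOrthogonalSlices` error carrying the
#'   offending values.
#' @export
checkOrthogonal <- function(volume) {
  vals <- as.vector(volume@orientation[, 1:2])
  bad <- abs(vals - round(vals)) > 1e-6 | abs(round(vals)) > 1
  if (any(bad))
    stop(.nemaiq_error("nonOrthogonalSlices",
                       paste("non-orthogonal slices; offending direction",
                             "cosines:",
                             paste(signif(vals[bad], 4), collapse = ", ")),
                       data = vals[bad]))
  invisible(TRUE)
}

#' Convert voxel indices to world coordinates and back
#'
#' Voxel indices are 0-based, fractional, and refer to voxel centers:
#' `world = origin + orientation %*% (index * spacing)`.  `worldToVoxel()`
#' is the exact inverse.
#'
#' @param volume an [ImageVolume-class].
#' @param index n x 3 matrix (or 3-vector) of fractional 0-based indices.
#' @param point n x 3 matrix (or 3-vector) of mm world coordinates.
#' @return An n x 3 matrix.
#' @export
voxelToWorld <- function(volume, index) {
  idx <- rbind3(index)
  out <- sweep(idx, 2L, volume@spacing, "*") %*% t(volume@orientation)
  sweep(out, 2L, volume@origin, "+")
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(volume, point) {
  p <- sweep(rbind3(point), 2L, volume@origin, "-")
  sweep(p %*% volume@orientation, 2L, volume@spacing, "/")
}

#' Header-derived CT-to-PET isometry
#'
#' Both series carry patient-frame world coordinates, so the header
#' isometry is the identity on world coordinates; any header misalignment
#' manifests through each series' own origin and orientation.  Composing
#' `worldToVoxel(pet)`, this transform and `voxelToWorld(ct)` maps CT voxel
#' indices into PET voxel indices.
#'
#' @param ct,pet [ImageVolume-class] objects sharing a frame of reference.
#' @return A [RigidTransform-class] labelled `"DICOM"`.
#' @export
dicomIsometry <- function(ct, pet) {
  stopifnot(is(ct, "ImageVolume"), is(pet, "ImageVolume"))
  RigidTransform(diag(3), c(0, 0, 0), label = "DICOM")
}
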