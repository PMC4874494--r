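# Step 10: spherical ROIs at the accurate PET centers, per-sphere and
# six-sphere-union statistics, and the repeatability statistics used to
# characterize the pipeline.

#' Spherical ROI masks at the accurate PET centers
#'
#' Binary-Center-Inclusion filled spheres at the sub-voxel accurate centers
#' with the physical inner diameters, as the NEMA NU-2 protocol requires
#' ("as close as possible to the physical inner diameters").
#'
#' @param pet an [ImageVolume-class] (PET).
#' @param centersVox 6x3 matrix of fractional 0-based PET voxel centers, or
#'   a [SphereCenterSet-class] in the `PET_VOXEL` frame.
#' @param diametersMm the six inner diameters, ascending with sphere index.
#' @return list of six logical arrays over the PET grid.
#' @export
sphereRois <- function(pet, centersVox,
                       diametersMm = c(10, 13, 17, 22, 28, 37)) {
  if (is(centersVox, "SphereCenterSet")) {
    stopifnot(centersVox@frame == "PET_VOXEL")
    centersVox <- centersVox@centers
  }
  d <- dim(pet@voxels); sp <- pet@spacing
  masks <- vector("list", 6L)
  for (i in 1:6) {
    a <- centersVox[i, ]
    r <- diametersMm[i] / 2
    if (any(a - r / sp < 0) || any(a + r / sp > d - 1))
      .nemaiq_warn("clippedRoi",
                   sprintf("ROI for sphere %d clipped by the volume boundary", i))
    j0 <- pmax(ceiling(a - r / sp), 0)
    j1 <- pmin(floor(a + r / sp), d - 1)
    mask <- array(FALSE, d)
    if (all(j0 <= j1)) {
      xs <- j0[1]:j1[1]; ys <- j0[2]:j1[2]; zs <- j0[3]:j1[3]
      d2 <- outer(outer(((xs - a[1]) * sp[1])^2,
                        ((ys - a[2]) * sp[2])^2, "+"),
                  ((zs - a[3]) * sp[3])^2, "+")
      mask[xs + 1, ys + 1, zs + 1] <- d2 <= r^2
    }
    masks[[i]] <- mask
  }
  names(masks) <- paste0("sphere", 1:6)
  masks
}

#' ROI statistics
#'
#' Mean, maximum and voxel count per sphere ROI, plus the statistics over
#' the six-sphere union (the union of the six masks; overlapping voxels,
#' which do not occur for a correctly assembled phantom, would be counted
#' once).
#'
#' @param pet an [ImageVolume-class] (PET).
#' @param masks list of six logical arrays from [sphereRois()].
#' @return list with `perSphere` (data.frame: sphere, mean, max, nvox) and
#'   `union` (mean, max, nvox).
#' @export
roiStats <- function(pet, masks) {
  v <- pet@voxels
  per <- lapply(seq_along(masks), function(i) {
    vals <- v[masks[[i]]]
    if (length(vals) == 0L)
      stop(.nemaiq_error("emptyRoi", sprintf("ROI %d is empty", i)))
    data.frame(sphere = i, mean = mean(vals), max = max(vals),
               nvox = length(vals))
  })
  union <- Reduce(`|`, masks)
  uv <- v[union]
  list(perSphere = do.call(rbind, per),
       union = list(mean = mean(uv), max = max(uv), nvox = length(uv)))
}

#' Pairwise-distance discrepancies between two center sets
#'
#' For two labelled sets of the six sphere centers, the absolute difference
#' of each of the 15 pairwise inter-sphere distances.  Exactly zero
#' whenever one set is a rigid transform of the other, so non-zero values
#' diagnose broken sphere-to-sphere geometry (e.g. uncompensated bubbles).
#'
#' @param centersA,centersB 6x3 matrices (mm).
#' @return named numeric(15) of absolute discrepancies (mm).
#' @export
distanceDiscrepancy <- function(centersA, centersB) {
  abs(pairwiseDistances(centersA) - pairwiseDistances(centersB))
}

#' Repeatability statistics over repeated localizations
#'
#' For a list of repeated center sets: per-sphere, per-axis standard
#' deviations (mm) and the mean centers with their 15 pairwise distances.
#' For a numeric series of repeated ROI statistics: mean, SD and
#' coefficient of variation.  The sample SD (n-1 denominator) is the
#' default, as is standard for repeatability series.
#'
#' @param centerSets list of 6x3 center matrices (mm), one per realization.
#' @param statSeries numeric vector of a repeated ROI statistic.
#' @param sample logical; `FALSE` uses the population SD.
#' @return list of class `ReproStats` with the available components:
#'   `sd` (6x3), `meanCenters`, `pairwise` for center sets; `mean`, `sdStat`
#'   and `cov` for stat series.
#' @export
reproStats <- function(centerSets = NULL, statSeries = NULL, sample = TRUE) {
  sdfun <- if (sample) stats::sd else function(x) sqrt(mean((x - mean(x))^2))
  out <- list()
  if (!is.null(centerSets)) {
    stopifnot(length(centerSets) >= 2L)
    arr <- simplify2array(centerSets)  # 6 x 3 x n
    out$sd <- apply(arr, c(1, 2), sdfun)
    out$meanCenters <- apply(arr, c(1, 2), mean)
    dimnames(out$sd) <- dimnames(out$meanCenters) <-
      list(paste0("sphere", seq_len(dim(arr)[1])), c("x", "y", "z"))
    out$pairwise <- pairwiseDistances(out$meanCenters)
  }
  if (!is.null(statSeries)) {
    stopifnot(length(statSeries) >= 2L)
    out$mean <- mean(statSeries)
    out$sdStat <- sdfun(statSeries)
    out$cov <- out$sdStat / out$mean
  }
  structure(out, class = "ReproStats")
}
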