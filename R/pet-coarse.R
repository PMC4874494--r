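#' Coarse PET detection of the three largest spheres
#'
#' Iterated matched filtering with zero-out suppression: for each of the
#' three largest sphere diameters (largest first), a filled binary template
#' at the PET voxel spacing is scanned over the whole volume with the sum
#' statistic; the argmax voxel is recorded as that sphere's estimated
#' center, the covered voxels are set to zero (so the same sphere cannot be
#' re-detected), and the scan repeats.  The input volume is not mutated.
#'
#' @param pet an [ImageVolume-class] (PET).
#' @param diametersMm the six sphere inner diameters in mm, ascending with
#'   sphere index (sphere 6 = largest).
#' @return A [SphereCenterSet-class] in the `PET_VOXEL` frame with integer
#'   estimates for spheres 6, 5, 4.
#' @export
estimateThreeLargest <- function(pet,
                                 diametersMm = c(10, 13, 17, 22, 28, 37)) {
  stopifnot(is(pet, "ImageVolume"), length(diametersMm) == 6L)
  work <- pet@voxels
  cen <- matrix(NA_real_, 6L, 3L,
                dimnames = list(paste0("sphere", 1:6), c("x", "y", "z")))
  warnings <- character()
  for (i in c(6L, 5L, 4L)) {
    tpl <- buildTemplate("FILLED", diametersMm[i], spacing = pet@spacing)
    mvs <- withCallingHandlers(
      matchedScan(work, tpl, "sum"),
      nemaiq_multipleMaxima = function(w) invokeRestart("muffleWarning"))
    if (mvs$nmaxima > 1L)
      warnings <- c(warnings, sprintf("sphere %d: multiple coarse maxima", i))
    cen[i, ] <- mvs$argmax
    cov <- sweep(templateOffsets(tpl), 2L, mvs$argmax, "+") + 1L
    work[cov] <- 0
  }
  new("SphereCenterSet", centers = cen, frame = "PET_VOXEL",
      quality = c("NA", "NA", "NA", "ESTIMATE", "ESTIMATE", "ESTIMATE"),
      warnings = warnings)
}
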