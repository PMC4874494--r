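# Accurate CT localization: subvolume extraction, air-bubble detection,
# shell matched filtering, plastic-wall learning, hexagonal extrapolation,
# integer up-sampling and sub-voxel quadratic refinement.

#' Extract a bounding box around a center estimate
#'
#' The per-axis extent is the minimum voxel count whose physical span is at
#' least `kDiameters` sphere diameters, centered on the rounded center
#' estimate; boxes clipped by the volume edge shrink on the clipped side
#' only and carry a warning.
#'
#' @param ct an [ImageVolume-class].
#' @param centerEstimate fractional 0-based voxel index.
#' @param diameterMm sphere inner diameter in mm.
#' @param kDiameters 2 (large spheres) or 3 (small spheres).
#' @return list with `lo` (inclusive) and `hi` (exclusive) 0-based corners
#'   and a `clipped` flag.
#' @export
extractBox <- function(ct, centerEstimate, diameterMm, kDiameters) {
  d <- dim(ct@voxels)
  extent <- ceiling(kDiameters * diameterMm / ct@spacing)
  ctr <- round(centerEstimate)
  lo <- ctr - extent %/% 2
  hi <- lo + extent
  clipped <- any(lo < 0) || any(hi > d)
  lo <- pmax(lo, 0)
  hi <- pmin(hi, d)
  if (clipped)
    .nemaiq_warn("clippedBox",
                 "bounding box clipped at the volume edge; extents shrink on the clipped side")
  list(lo = as.integer(lo), hi = as.integer(hi), clipped = clipped)
}

cropBox <- function(arr, box) {
  arr[(box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2],
      (box$lo[3] + 1):box$hi[3], drop = FALSE]
}

#' Detect air voxels in a CT subvolume
#'
#' The subvolume values are histogrammed into 10 equal-width bins from the
#' minimum to the maximum value.  If the mode of the histogram lies in the
#' upper half (bins 6-10, 1-based), air is present: the water peak can only
#' land that high when very low (air) values stretch the histogram range
#' downward.  In that case every voxel at or below `mean - 2*sd` (population
#' SD over all subvolume voxels) is labelled air.
#'
#' Values exactly at a bin edge go to the higher bin, except the maximum,
#' which stays in bin 10.
#'
#' @param sub 3-D numeric array of CT values (HU).
#' @return list with `detected`, `airMask` (logical array; all-FALSE when
#'   not detected), `mean`, `sd` and `modeBin`.
#' @export
detectAir <- function(sub) {
  v <- as.vector(sub)
  rng <- range(v)
  if (rng[1] == rng[2])
    return(list(detected = FALSE, airMask = array(FALSE, dim(sub)),
                mean = rng[1], sd = 0, modeBin = NA_integer_))
  w <- (rng[2] - rng[1]) / 10
  bins <- pmin(floor((v - rng[1]) / w) + 1L, 10L)
  counts <- tabulate(bins, nbins = 10L)
  modeBin <- which.max(counts)
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  detected <- modeBin >= 6L
  mask <- if (detected) array(v <= mu - 2 * sdv, dim(sub))
          else array(FALSE, dim(sub))
  list(detected = detected, airMask = mask, mean = mu, sd = sdv,
       modeBin = modeBin)
}

# shared shell-scan + concave-box + quadratic-vertex refinement; values are
# scanned in the given (sub)volume and the sub-voxel peak returned in its
# 0-based fractional index coordinates
.shellRefine <- function(values, template, airMask, airDetected) {
  warnings <- character()
  mvs <- withCallingHandlers(
    if (airDetected) matchedScan(values, template, "mean", exclude = airMask)
    else matchedScan(values, template, "sum"),
    nemaiq_multipleMaxima = function(w) invokeRestart("muffleWarning"))
  if (mvs$nmaxima > 1L)
    warnings <- c(warnings, "MultipleMaxima: first matched-value maximum used")
  box <- tryCatch(concaveSubset(mvs), nemaiq_noConcaveNeighborhood = function(e) {
    warnings <<- c(warnings, "NoConcaveNeighborhood: 3x3x3 box used")
    list(lo = pmax(mvs$argmax - 1L, mvs$lo), hi = pmin(mvs$argmax + 1L, mvs$hi))
  })
  vals <- mvs$values[(box$lo[1] + 1):(box$hi[1] + 1),
                     (box$lo[2] + 1):(box$hi[2] + 1),
                     (box$lo[3] + 1):(box$hi[3] + 1), drop = FALSE]
  fit <- withCallingHandlers(
    fitQuadraticVertex(vals, coords = lapply(1:3, function(a)
      box$lo[a]:box$hi[a])),
    nemaiq_nonConcaveFit = function(w) invokeRestart("muffleWarning"))
  if (fit$usedArgmax)
    warnings <- c(warnings, "NonConcaveFit: grid argmax used")
  list(center = fit$vertex, mvs = mvs, warnings = warnings)
}

#' Accurately localize a large sphere in CT
#'
#' A hollow-shell template (NEMA inner diameter, 1 mm wall) is matched over
#' the subvolume: with air detected, by the mean over non-air voxels; with
#' no air, by the sum.  The shell voxels at the argmax, minus air, are
#' labelled plastic sphere wall and their HU values returned for pooling
#' into the wall model.  The sub-voxel center comes from the concave-down
#' neighborhood and a 3-D quadratic vertex.
#'
#' @param ct an [ImageVolume-class] (CT).
#' @param box a box from [extractBox()] (built with `kDiameters = 2`).
#' @param innerDiameterMm sphere inner diameter in mm.
#' @param wallMm shell thickness in mm.
#' @param airDetection logical; `FALSE` disables the bubble compensation
#'   (comparison arm).
#' @return list with `center` (0-based fractional index in the parent CT
#'   grid), `wallValues` (HU of wall-labelled voxels), `air` and `warnings`.
#' @export
localizeLarge <- function(ct, box, innerDiameterMm, wallMm = 1,
                          airDetection = TRUE) {
  sub <- cropBox(ct@voxels, box)
  air <- if (airDetection) detectAir(sub)
         else list(detected = FALSE, airMask = array(FALSE, dim(sub)))
  tpl <- buildTemplate("SHELL", innerDiameterMm, spacing = ct@spacing,
                       wallMm = wallMm)
  ref <- .shellRefine(sub, tpl, air$airMask, air$detected)
  cov <- sweep(templateOffsets(tpl), 2L, ref$mvs$argmax, "+") + 1L
  isAir <- air$airMask[cov]
  wallValues <- sub[cov][!isAir]
  list(center = box$lo + ref$center, wallValues = wallValues, air = air,
       warnings = ref$warnings)
}

#' Pool the plastic-wall model
#'
#' The wall model is the mean CT value over the union of all voxels
#' labelled plastic sphere wall on the three largest spheres.
#'
#' @param wallValueList list of HU vectors from [localizeLarge()].
#' @return list with `muPSW` and `nWallVoxels`.
#' @export
learnWall <- function(wallValueList) {
  v <- unlist(wallValueList, use.names = FALSE)
  if (length(v) == 0L)
    stop(.nemaiq_error("wallModelFailure", "no plastic-wall voxels labelled"))
  list(muPSW = mean(v), nWallVoxels = length(v))
}

#' Extrapolate the small-sphere centers through the hexagon center
#'
#' The six spheres sit on a hexagon in descending-diameter order, so each
#' small sphere faces its large partner across the center.  From three
#' consecutive vertices the center is `cH = c4 + c6 - c5`, and the
#' small-sphere estimates are the point reflections `2*cH - c(i+3)`.
#'
#' @param c4,c5,c6 centers of spheres 4, 5, 6 (any affine frame; 3-vectors).
#' @return 3x3 matrix with rows = estimated centers of spheres 1, 2, 3.
#' @section Errors: collinear inputs signal
#'   `nemaiq_degenerateSphereArrangement`.
#' @export
hexagonExtrapolate <- function(c4, c5, c6) {
  u <- c5 - c4; w <- c6 - c4
  cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  if (sqrt(sum(cr^2)) <= 1e-6 * sqrt(sum(u^2)) * sqrt(sum(w^2)))
    stop(.nemaiq_error("degenerateSphereArrangement",
                       "the three large-sphere centers are collinear"))
  cH <- c4 + c6 - c5
  out <- rbind(2 * cH - c4, 2 * cH - c5, 2 * cH - c6)
  rownames(out) <- paste0("sphere", 1:3)
  out
}

#' Integer up-sampling of a CT subvolume
#'
#' Per axis, voxels are replicated by the smallest integer factor that
#' makes the new voxel size strictly less than 1 mm (factor 1 if already
#' below 1 mm).  No interpolation: the value multiset is preserved up to
#' multiplicity.  Needed because the sphere walls are about 1 mm thick.
#'
#' @param sub 3-D numeric array.
#' @param spacing numeric(3), parent voxel size in mm.
#' @return list with `values` (up-sampled array), `factor` (integer(3)) and
#'   `spacing` (new voxel size).
#' @export
upsampleInteger <- function(sub, spacing) {
  f <- ifelse(spacing < 1, 1L, floor(spacing) + 1L)
  vals <- sub[rep(seq_len(dim(sub)[1]), each = f[1]),
              rep(seq_len(dim(sub)[2]), each = f[2]),
              rep(seq_len(dim(sub)[3]), each = f[3]), drop = FALSE]
  list(values = vals, factor = as.integer(f), spacing = spacing / f)
}

#' Rescale CT values against the learned wall model
#'
#' `Vnew = -|Vold - muPSW|`: the maximum attainable value is 0, reached
#' exactly at the plastic-wall mean, so the shell matched filter rewards
#' wall-like values instead of bright values; air is maximally penalized.
#'
#' @param values numeric array or vector.
#' @param muPSW plastic-wall mean HU from [learnWall()].
#' @return Rescaled values, same shape.
#' @export
rescaleToWall <- function(values, muPSW) {
  stopifnot(is.finite(muPSW))
  -abs(values - muPSW)
}

#' Accurately localize a small sphere in CT
#'
#' Pipeline: crop the k=3 box, integer up-sample, detect air on the
#' up-sampled values, rescale against the wall model, shell matched filter
#' with the mean over non-air voxels (sum when no air), concave-down
#' neighborhood, quadratic vertex; the up-sampled peak index u maps back to
#' the parent grid as `(u + 0.5)/f - 0.5` per axis (center-aligned
#' replication).
#'
#' @param ct an [ImageVolume-class] (CT).
#' @param box a box from [extractBox()] (built with `kDiameters = 3`).
#' @param innerDiameterMm sphere inner diameter in mm.
#' @param muPSW plastic-wall mean HU from [learnWall()].
#' @param wallMm shell thickness in mm.
#' @param airDetection logical; `FALSE` disables bubble compensation.
#' @param upsample logical; `FALSE` skips the up-sampling step (used to
#'   cross-check the small- and large-sphere code paths).
#' @return list with `center` (0-based fractional parent index), `air`,
#'   `factor` and `warnings`.
#' @export
localizeSmall <- function(ct, box, innerDiameterMm, muPSW, wallMm = 1,
                          airDetection = TRUE, upsample = TRUE) {
  sub <- cropBox(ct@voxels, box)
  up <- if (upsample) upsampleInteger(sub, ct@spacing)
        else list(values = sub, factor = c(1L, 1L, 1L), spacing = ct@spacing)
  air <- if (airDetection) detectAir(up$values)
         else list(detected = FALSE, airMask = array(FALSE, dim(up$values)))
  resc <- rescaleToWall(up$values, muPSW)
  tpl <- buildTemplate("SHELL", innerDiameterMm, spacing = up$spacing,
                       wallMm = wallMm)
  ref <- .shellRefine(resc, tpl, air$airMask, air$detected)
  center <- box$lo + (ref$center + 0.5) / up$factor - 0.5
  list(center = center, air = air, factor = up$factor,
       warnings = ref$warnings)
}

#' Localize all six spheres in CT
#'
#' Orchestrates the accurate CT stage: k=2 boxes and shell filters for the
#' three largest spheres, pooling of the plastic-wall model, hexagonal
#' extrapolation to the three smallest spheres, and the up-sampled
#' wall-rescaled localization for each of them.
#'
#' @param ct an [ImageVolume-class] (CT).
#' @param estimates 3x3 matrix of initial 0-based voxel estimates, rows =
#'   spheres 6, 5, 4 (e.g. mapped coarse PET estimates or user seeds).
#' @param diametersMm the six inner diameters, ascending with sphere index.
#' @param wallMm shell thickness in mm.
#' @param airDetection logical; `FALSE` reproduces the no-bubble-detection
#'   comparison arm.
#' @return list with `centers` (a [SphereCenterSet-class], `CT_VOXEL`
#'   frame, all six accurate), `muPSW`, `nWallVoxels` and `warnings`.
#' @export
localizeSpheresCT <- function(ct, estimates,
                              diametersMm = c(10, 13, 17, 22, 28, 37),
                              wallMm = 1, airDetection = TRUE) {
  stopifnot(is(ct, "ImageVolume"), nrow(estimates) == 3L)
  cen <- matrix(NA_real_, 6L, 3L,
                dimnames = list(paste0("sphere", 1:6), c("x", "y", "z")))
  warnings <- character()
  wallVals <- list()
  for (k in 1:3) {
    i <- c(6L, 5L, 4L)[k]
    box <- extractBox(ct, estimates[k, ], diametersMm[i], 2)
    if (box$clipped) warnings <- c(warnings, sprintf("sphere %d: ClippedBox", i))
    loc <- localizeLarge(ct, box, diametersMm[i], wallMm, airDetection)
    cen[i, ] <- loc$center
    wallVals[[k]] <- loc$wallValues
    if (length(loc$warnings))
      warnings <- c(warnings, paste0("sphere ", i, ": ", loc$warnings))
  }
  wall <- learnWall(wallVals)
  est123 <- hexagonExtrapolate(cen[4L, ], cen[5L, ], cen[6L, ])
  for (i in 1:3) {
    box <- extractBox(ct, est123[i, ], diametersMm[i], 3)
    if (box$clipped) warnings <- c(warnings, sprintf("sphere %d: ClippedBox", i))
    loc <- localizeSmall(ct, box, diametersMm[i], wall$muPSW, wallMm,
                         airDetection)
    cen[i, ] <- loc$center
    if (length(loc$warnings))
      warnings <- c(warnings, paste0("sphere ", i, ": ", loc$warnings))
  }
  list(centers = new("SphereCenterSet", centers = cen, frame = "CT_VOXEL",
                     quality = rep("ACCURATE", 6L), warnings = warnings),
       muPSW = wall$muPSW, nWallVoxels = wall$nWallVoxels,
       warnings = warnings)
}
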