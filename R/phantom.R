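# Synthetic NEMA NU-2-like phantom: paired CT and PET volumes with exact
# ground truth, so every pipeline stage is testable without scanner data.

#' Synthetic phantom configuration
#'
#' Defines the phantom geometry and imaging conditions: six hollow plastic
#' spheres (inner diameters 10-37 mm, 1 mm walls) in a descending-diameter
#' hexagonal ring inside a water-equivalent elliptical body; CT values for
#' water/plastic/air; PET activity in all six spheres above background
#' (4:1 by default); per-modality blur and Gaussian noise; optional air
#' bubbles inside spheres; optional rigid PET-vs-CT misalignment.
#'
#' Voxel spacings default to a clinical phantom protocol: CT
#' 1.37 x 1.37 x 2.5 mm, PET 2.73 x 2.73 x 3.27 mm.  The hexagon radius
#' (sphere-center circle) defaults to 57.2 mm; the pipeline never relies on
#' the absolute value, only on the descending-diameter hexagonal pattern.
#'
#' @param diametersMm six inner diameters (mm), ascending with sphere index.
#' @param wallMm plastic wall thickness (mm).
#' @param hexRadiusMm radius of the sphere-center circle (mm).
#' @param planeZMm axial position of the sphere plane (mm).  The default
#'   1 mm puts the plane at an arbitrary sub-voxel phase of both grids, as
#'   for a physically positioned phantom; 0 would sit exactly halfway
#'   between PET slices, an artificial degeneracy.
#' @param winding `"standard"` or `"mirrored"` hexagon winding.
#' @param phaseDeg in-plane rotation of the hexagon (degrees).
#' @param bodySemiAxesMm in-plane semi-axes of the elliptical body (mm).
#' @param bodyLengthMm axial body extent (mm).
#' @param ctDim,petDim grid sizes.
#' @param ctSpacing,petSpacing voxel sizes (mm).
#' @param huWater,huPlastic,huAir CT values (HU).
#' @param petBackground background activity (arbitrary integer units).
#' @param sphereRatio sphere-to-background activity ratio.
#' @param ctBlurFwhmMm,petBlurFwhmMm isotropic Gaussian blur FWHM (mm).
#' @param ctNoiseSd,petNoiseSd Gaussian noise SD (HU / activity units).
#' @param noiseWhen `"after"` (default) or `"before"` the blur.
#' @param bubbles list of `list(sphere=, diameterMm=, offsetMm=)`; each
#'   bubble is carved at `offsetMm` toward the sphere top (the -y world
#'   direction, where bubbles collect in a supine phantom).
#' @param misalignment optional [RigidTransform-class]: the physical PET
#'   placement differs from the header geometry by this transform.
#' @param supersample integer sub-voxel sampling factor for rasterization.
#' @param seed integer; fully determines the generated volumes.
#' @param keepNoiseless keep the noiseless (post-blur) arrays in the truth.
#' @return A validated config list of class `PhantomConfig`.
#' @export
phantomConfig <- function(diametersMm = c(10, 13, 17, 22, 28, 37),
                          wallMm = 1,
                          hexRadiusMm = 57.2,
                          planeZMm = 1,
                          winding = c("standard", "mirrored"),
                          phaseDeg = 0,
                          bodySemiAxesMm = c(147, 110),
                          bodyLengthMm = 100,
                          ctDim = c(228L, 174L, 48L),
                          ctSpacing = c(1.37, 1.37, 2.5),
                          petDim = c(114L, 86L, 36L),
                          petSpacing = c(2.73, 2.73, 3.27),
                          huWater = 0, huPlastic = 120, huAir = -1000,
                          petBackground = 1000, sphereRatio = 4,
                          ctBlurFwhmMm = 0.8, petBlurFwhmMm = 6,
                          ctNoiseSd = 15, petNoiseSd = 100,
                          noiseWhen = c("after", "before"),
                          bubbles = list(),
                          misalignment = NULL,
                          supersample = 4L,
                          seed = 1L,
                          keepNoiseless = TRUE) {
  winding <- match.arg(winding)
  noiseWhen <- match.arg(noiseWhen)
  stopifnot(length(diametersMm) == 6L, all(diff(diametersMm) > 0),
            wallMm > 0, hexRadiusMm > 0)
  s <- if (winding == "standard") 1 else -1
  ang <- (phaseDeg + s * (0:5) * 60) * pi / 180
  centers <- cbind(hexRadiusMm * cos(ang), hexRadiusMm * sin(ang), planeZMm)
  dimnames(centers) <- list(paste0("sphere", 1:6), c("x", "y", "z"))
  router <- diametersMm / 2 + wallMm
  dd <- as.matrix(dist(centers))
  lim <- outer(router, router, "+")
  diag(dd) <- Inf
  if (any(dd <= lim))
    stop(.nemaiq_error("invalidGeometry",
                       "spheres overlap at the configured hexagon radius"))
  for (b in bubbles) {
    stopifnot(b$sphere %in% 1:6, b$diameterMm > 0)
    # the bubble region is clipped to the sphere interior (air collects as
    # a cap against the top wall), so only the center must stay inside
    if (b$offsetMm > diametersMm[b$sphere] / 2)
      stop(.nemaiq_error("invalidGeometry",
                         sprintf("bubble center outside sphere %d", b$sphere)))
  }
  if (!is.null(misalignment)) stopifnot(is(misalignment, "RigidTransform"))
  structure(list(diametersMm = diametersMm, wallMm = wallMm,
                 hexRadiusMm = hexRadiusMm, planeZMm = planeZMm,
                 winding = winding,
                 phaseDeg = phaseDeg, centers = centers,
                 bodySemiAxesMm = bodySemiAxesMm,
                 bodyLengthMm = bodyLengthMm,
                 ctDim = as.integer(ctDim), ctSpacing = ctSpacing,
                 petDim = as.integer(petDim), petSpacing = petSpacing,
                 huWater = huWater, huPlastic = huPlastic, huAir = huAir,
                 petBackground = petBackground, sphereRatio = sphereRatio,
                 ctBlurFwhmMm = ctBlurFwhmMm, petBlurFwhmMm = petBlurFwhmMm,
                 ctNoiseSd = ctNoiseSd, petNoiseSd = petNoiseSd,
                 noiseWhen = noiseWhen, bubbles = bubbles,
                 misalignment = misalignment,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed), keepNoiseless = keepNoiseless),
            class = "PhantomConfig")
}

# world coordinates of voxel-center grids for a centered, axis-aligned volume
.gridCoords <- function(dimv, spacingv) {
  orig <- -(dimv - 1) / 2 * spacingv
  lapply(1:3, function(a) orig[a] + (seq_len(dimv[a]) - 1) * spacingv[a])
}

# accumulate, over an s^3 sub-voxel offset sweep, the fractions of each
# voxel in a box that fall in the sphere interior (minus bubbles), the
# wall, and any bubble; centers/radii in the same world frame as coords
.sphereFractions <- function(xs, ys, zs, center, rin, rout, bubbles, s) {
  nb <- length(bubbles)
  dims <- c(length(xs), length(ys), length(zs))
  fint <- array(0, dims); fwall <- array(0, dims); fbub <- array(0, dims)
  offs <- ((seq_len(s) - 0.5) / s - 0.5)
  for (oz in offs) {
    dz2 <- (zs + oz * attr(zs, "sp") - center[3])^2
    for (oy in offs) {
      dy2 <- (ys + oy * attr(ys, "sp") - center[2])^2
      for (ox in offs) {
        dx2 <- (xs + ox * attr(xs, "sp") - center[1])^2
        d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
        inside <- d2 <= rin^2
        wall <- d2 > rin^2 & d2 <= rout^2
        inBub <- array(FALSE, dims)
        for (b in bubbles) {
          bx2 <- (xs + ox * attr(xs, "sp") - b$center[1])^2
          by2 <- (ys + oy * attr(ys, "sp") - b$center[2])^2
          bz2 <- (zs + oz * attr(zs, "sp") - b$center[3])^2
          inBub <- inBub | (outer(outer(bx2, by2, "+"), bz2, "+") <=
                              (b$diameterMm / 2)^2)
        }
        fint <- fint + (inside & !inBub)
        fwall <- fwall + wall
        fbub <- fbub + (inside & inBub)
      }
    }
  }
  n <- length(offs)^3
  list(interior = fint / n, wall = fwall / n, bubble = fbub / n)
}

.renderModality <- function(cfg, which) {
  ct <- which == "CT"
  dimv <- if (ct) cfg$ctDim else cfg$petDim
  sp <- if (ct) cfg$ctSpacing else cfg$petSpacing
  orig <- -(dimv - 1) / 2 * sp
  co <- .gridCoords(dimv, sp)
  mis <- if (!ct && !is.null(cfg$misalignment)) cfg$misalignment
         else RigidTransform()
  centers <- transformPoints(mis, cfg$centers)
  bubbleCenters <- lapply(cfg$bubbles, function(b) {
    bc <- cfg$centers[b$sphere, ] + c(0, -b$offsetMm, 0)
    c(transformPoints(mis, bc))
  })

  a <- cfg$bodySemiAxesMm[1]; b2 <- cfg$bodySemiAxesMm[2]
  halfL <- cfg$bodyLengthMm / 2

  if (ct) {
    # body by voxel-center classification (edges far from any sphere)
    vox <- array(cfg$huAir, dimv)
    inPlane <- outer((co[[1]] / a)^2, (co[[2]] / b2)^2, "+") <= 1
    inZ <- abs(co[[3]]) <= halfL
    for (k in which(inZ)) vox[, , k][inPlane] <- cfg$huWater
  } else {
    # body fraction by a 3^3 sub-voxel sweep so total activity is accurate;
    # classify in the phantom frame (inverse of any misalignment)
    Rt <- t(mis@rotation); tv <- mis@translation
    frac <- array(0, dimv)
    offs <- ((1:3) - 0.5) / 3 - 0.5
    for (oz in offs) for (oy in offs) for (ox in offs) {
      px <- co[[1]] + ox * sp[1]; py <- co[[2]] + oy * sp[2]
      pz <- co[[3]] + oz * sp[3]
      # q = R^T (p - t), vectorized over the full grid
      qx <- outer(outer(Rt[1, 1] * px, Rt[1, 2] * py, "+"),
                  Rt[1, 3] * pz, "+") - sum(Rt[1, ] * tv)
      qy <- outer(outer(Rt[2, 1] * px, Rt[2, 2] * py, "+"),
                  Rt[2, 3] * pz, "+") - sum(Rt[2, ] * tv)
      qz <- outer(outer(Rt[3, 1] * px, Rt[3, 2] * py, "+"),
                  Rt[3, 3] * pz, "+") - sum(Rt[3, ] * tv)
      frac <- frac + ((qx / a)^2 + (qy / b2)^2 <= 1 & abs(qz) <= halfL)
    }
    vox <- cfg$petBackground * frac / 27
  }

  hot <- cfg$petBackground * cfg$sphereRatio
  for (i in 1:6) {
    rin <- cfg$diametersMm[i] / 2
    rout <- rin + cfg$wallMm
    cen <- centers[i, ]
    j0 <- pmax(ceiling((cen - rout - orig) / sp - 1), 0)
    j1 <- pmin(floor((cen + rout - orig) / sp + 1), dimv - 1)
    xs <- co[[1]][(j0[1] + 1):(j1[1] + 1)]; attr(xs, "sp") <- sp[1]
    ys <- co[[2]][(j0[2] + 1):(j1[2] + 1)]; attr(ys, "sp") <- sp[2]
    zs <- co[[3]][(j0[3] + 1):(j1[3] + 1)]; attr(zs, "sp") <- sp[3]
    bubs <- list()
    for (k in seq_along(cfg$bubbles))
      if (cfg$bubbles[[k]]$sphere == i)
        bubs <- c(bubs, list(list(center = bubbleCenters[[k]],
                                  diameterMm = cfg$bubbles[[k]]$diameterMm)))
    fr <- .sphereFractions(xs, ys, zs, cen, rin, rout, bubs,
                           cfg$supersample)
    ix <- (j0[1] + 1):(j1[1] + 1); iy <- (j0[2] + 1):(j1[2] + 1)
    iz <- (j0[3] + 1):(j1[3] + 1)
    base <- vox[ix, iy, iz]
    covered <- fr$interior + fr$wall + fr$bubble
    vox[ix, iy, iz] <- if (ct)
      base * (1 - covered) + fr$wall * cfg$huPlastic +
        fr$bubble * cfg$huAir + fr$interior * cfg$huWater
    else
      base * (1 - covered) + fr$interior * hot
  }

  fwhm <- if (ct) cfg$ctBlurFwhmMm else cfg$petBlurFwhmMm
  sigmaVox <- (fwhm / 2.354820045) / sp
  noiseSd <- if (ct) cfg$ctNoiseSd else cfg$petNoiseSd

  if (cfg$noiseWhen == "before" && noiseSd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, noiseSd)
  vox <- gaussianBlur3d(vox, sigmaVox)
  noiseless <- if (cfg$noiseWhen == "before") NULL else round(vox)
  if (cfg$noiseWhen == "after" && noiseSd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, noiseSd)
  vox <- round(vox)

  list(volume = ImageVolume(vox, spacing = sp, origin = orig,
                            orientation = diag(3), modality = which),
       noiseless = noiseless, centers = centers,
       bubbleCenters = bubbleCenters)
}

#' Generate a synthetic phantom CT/PET pair with ground truth
#'
#' Rasterizes the phantom with sub-voxel supersampling (so the ~1 mm walls
#' are representable as partial-volume fractions), applies per-modality
#' Gaussian blur and seeded Gaussian noise, and quantizes to integer values
#' (matching the integer DICOM pixel representation).  Any configured
#' misalignment moves the physical PET content while the PET header keeps
#' the nominal geometry, so the header isometry and the true physical
#' relationship disagree by exactly the configured transform.
#'
#' @param config a [phantomConfig()].
#' @param modalities subset of `c("CT", "PET")` to render.
#' @return list with `ct`, `pet` ([ImageVolume-class] or `NULL`) and
#'   `truth` (a [PhantomTruth-class]).
#' @export
generatePhantom <- function(config, modalities = c("CT", "PET")) {
  stopifnot(inherits(config, "PhantomConfig"))
  withSeed(config$seed, {
    ctR <- if ("CT" %in% modalities) .renderModality(config, "CT") else NULL
    petR <- if ("PET" %in% modalities) .renderModality(config, "PET") else NULL
  })
  bubdf <- if (length(config$bubbles)) {
    do.call(rbind, lapply(config$bubbles, function(b) {
      bc <- config$centers[b$sphere, ] + c(0, -b$offsetMm, 0)
      data.frame(sphere = b$sphere, diameterMm = b$diameterMm,
                 offsetMm = b$offsetMm, x = bc[1], y = bc[2], z = bc[3])
    }))
  } else data.frame(sphere = integer(), diameterMm = numeric(),
                    offsetMm = numeric(), x = numeric(), y = numeric(),
                    z = numeric())
  mis <- if (is.null(config$misalignment)) RigidTransform()
         else config$misalignment
  centersPET <- transformPoints(mis, config$centers)
  dimnames(centersPET) <- dimnames(config$centers)
  keep <- isTRUE(config$keepNoiseless)
  truth <- new("PhantomTruth", centersCT = config$centers,
               centersPET = centersPET, misalignment = mis,
               bubbles = bubdf,
               noiselessCT = if (keep && !is.null(ctR)) ctR$noiseless,
               noiselessPET = if (keep && !is.null(petR)) petR$noiseless,
               config = unclass(config))
  list(ct = if (!is.null(ctR)) ctR$volume,
       pet = if (!is.null(petR)) petR$volume,
       truth = truth)
}

#' Write a phantom pair as DICOM series with a truth sidecar
#'
#' Writes `ct/` and `pet/` DICOM series under `dir` plus a `truth.json`
#' sidecar holding the true centers, the applied misalignment and the
#' bubble definitions, so file-based round trips can be verified against
#' the generating truth.
#'
#' @param phantom result of [generatePhantom()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writePhantomSeries <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(phantom$ct))
    writeDicomSeries(phantom$ct, file.path(dir, "ct"), seriesNumber = 1L)
  if (!is.null(phantom$pet))
    writeDicomSeries(phantom$pet, file.path(dir, "pet"), seriesNumber = 2L)
  tr <- phantom$truth
  sidecar <- list(centersCT = tr@centersCT, centersPET = tr@centersPET,
                  misalignment = list(rotation = tr@misalignment@rotation,
                                      translation = tr@misalignment@translation),
                  bubbles = tr@bubbles)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a truth sidecar
#'
#' @param path a directory written by [writePhantomSeries()] or the
#'   `truth.json` path itself.
#' @return list with `centersCT`, `centersPET`, `misalignment` (a
#'   [RigidTransform-class]) and `bubbles`.
#' @export
readPhantomTruth <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "truth.json") else path
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  list(centersCT = as.matrix(j$centersCT),
       centersPET = as.matrix(j$centersPET),
       misalignment = RigidTransform(as.matrix(j$misalignment$rotation),
                                     j$misalignment$translation),
       bubbles = as.data.frame(j$bubbles))
}
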