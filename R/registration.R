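# CT-to-PET registration: three-point initial isometry, 6-DOF perturbation
# search with a six-sphere template, 6-D quadratic refinement, and
# misalignment diagnostics against the DICOM-header isometry.

.unit <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Initial three-point CT-to-PET isometry
#'
#' Constructs the proper isometry that (1) maps the CT sphere-6 center
#' exactly onto the PET sphere-6 estimate, (2) maps the 6-5 line onto the
#' 6-5 line, and (3) maps the 6-5-4 plane onto the 6-5-4 plane.  Conditions
#' 2 and 3 each admit two symmetric solutions; all four candidate proper
#' isometries are evaluated and the one minimizing the total Euclidean
#' distance between mapped CT centers and the PET estimates is chosen.
#'
#' @param ctPoints 3x3 matrix, rows = CT centers of spheres 6, 5, 4 (mm).
#' @param petPoints 3x3 matrix, rows = PET centers of spheres 6, 5, 4 (mm).
#' @return A [RigidTransform-class] labelled `"ESTIMATE"`.
#' @section Errors: collinear triples signal
#'   `nemaiq_degenerateSphereArrangement` (the pipeline terminates).
#' @export
initialIsometry <- function(ctPoints, petPoints) {
  ctPoints <- rbind3(ctPoints); petPoints <- rbind3(petPoints)
  frame <- function(p, s1 = 1, s2 = 1) {
    u <- p[2, ] - p[1, ]
    w <- .cross(u, p[3, ] - p[1, ])
    nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
    if (nu <= 0 || nw <= 1e-6 * nu * sqrt(sum((p[3, ] - p[1, ])^2)))
      stop(.nemaiq_error("degenerateSphereArrangement",
                         "the three sphere centers are collinear"))
    u <- s1 * u / nu
    w <- s2 * w / nw
    cbind(u, .cross(w, u), w, deparse.level = 0)
  }
  Fc <- frame(ctPoints)
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    Fp <- frame(petPoints, s1, s2)
    R <- Fp %*% t(Fc)
    tr <- petPoints[1, ] - as.numeric(R %*% ctPoints[1, ])
    d <- sum(sqrt(rowSums((ctPoints %*% t(R) +
                           matrix(tr, 3, 3, byrow = TRUE) - petPoints)^2)))
    if (is.null(best) || d < best$d) best <- list(R = R, t = tr, d = d)
  }
  RigidTransform(best$R, best$t, label = "ESTIMATE")
}

#' Six-sphere binary template on the PET grid
#'
#' Union of six Binary-Center-Inclusion filled spheres at sub-voxel anchors
#' (the mapped CT centers); overlapping voxels are counted once.
#'
#' @param pet an [ImageVolume-class] (PET), or its dim/spacing via a list.
#' @param centersVox 6x3 matrix of fractional 0-based PET voxel anchors.
#' @param diametersMm the six inner diameters, ascending with sphere index.
#' @return logical array over the PET grid.
#' @section Errors: a sphere with no voxel center inside the volume signals
#'   `nemaiq_mappingOutOfBounds`; anchors outside the grid raise a
#'   `BoundaryWarning`.
#' @export
buildSixSphereTemplate <- function(pet, centersVox,
                                   diametersMm = c(10, 13, 17, 22, 28, 37)) {
  d <- dim(pet@voxels); sp <- pet@spacing
  mask <- array(FALSE, d)
  for (i in 1:6) {
    a <- centersVox[i, ]
    if (any(a < 0 | a > d - 1))
      .nemaiq_warn("boundaryWarning",
                   sprintf("sphere %d anchor outside the PET grid", i))
    r <- diametersMm[i] / 2
    j0 <- pmax(ceiling(a - r / sp), 0)
    j1 <- pmin(floor(a + r / sp), d - 1)
    if (any(j0 > j1))
      stop(.nemaiq_error("mappingOutOfBounds",
                         sprintf("sphere %d maps entirely outside the PET volume", i)))
    xs <- j0[1]:j1[1]; ys <- j0[2]:j1[2]; zs <- j0[3]:j1[3]
    d2 <- outer(outer(((xs - a[1]) * sp[1])^2, ((ys - a[2]) * sp[2])^2, "+"),
                ((zs - a[3]) * sp[3])^2, "+")
    mask[xs + 1, ys + 1, zs + 1] <- mask[xs + 1, ys + 1, zs + 1] |
      (d2 <= r^2)
  }
  mask
}

#' Six-degree-of-freedom perturbation search
#'
#' Perturbs the initial isometry over a 7-node grid per axis: rotations
#' about the centroid of the mapped sphere centers and translations, both
#' in 1 mm increments to +-3 mm.  One rotation increment moves the
#' most-displaced mapped sphere center by exactly 1 mm of arc (per axis,
#' the angular increment is 1 mm divided by the maximum distance of any
#' mapped center from the rotation axis through the centroid).  At each of
#' the 7^6 nodes the six CT centers are mapped, the six-sphere filled
#' template rasterized at sub-voxel anchors, and the sum of covered PET
#' voxels recorded.  Nodes where any sphere leaves the volume are invalid
#' and excluded from the subsequent fit.
#'
#' @param phiE the initial [RigidTransform-class].
#' @param ctCentersMm 6x3 matrix of accurate CT centers (mm, CT world).
#' @param pet an [ImageVolume-class] (PET).
#' @param diametersMm the six inner diameters, ascending with sphere index.
#' @param rangeMm search half-range in mm (3).
#' @param stepMm increment in mm (1).
#' @return list of class `PerturbationGrid`: `values` (7^6 array, NA at
#'   invalid nodes), `nodes` (axis coordinates in increments), `dTheta`
#'   (radians per increment), `stepMm`, `centroid`, `phiE`, `warnings`.
#' @export
perturbationSearch <- function(phiE, ctCentersMm, pet,
                               diametersMm = c(10, 13, 17, 22, 28, 37),
                               rangeMm = 3, stepMm = 1) {
  mapped0 <- transformPoints(phiE, ctCentersMm)
  centroid <- colMeans(mapped0)
  rel <- sweep(mapped0, 2L, centroid)
  rperp <- c(max(sqrt(rel[, 2]^2 + rel[, 3]^2)),
             max(sqrt(rel[, 1]^2 + rel[, 3]^2)),
             max(sqrt(rel[, 1]^2 + rel[, 2]^2)))
  dTheta <- stepMm / rperp
  ks <- seq.int(-rangeMm / stepMm, rangeMm / stepMm)
  n1 <- length(ks)
  nr <- n1^3

  # rotation nodes enumerated with theta_x fastest, matching the
  # column-major layout of the 6-D value array
  rotCenters <- matrix(0, nr * 6L, 3L)
  for (iz in seq_len(n1)) for (iy in seq_len(n1)) for (ix in seq_len(n1)) {
    R <- rotationMatrix(ks[ix] * dTheta[1], ks[iy] * dTheta[2],
                        ks[iz] * dTheta[3])
    rot <- sweep(rel %*% t(R), 2L, centroid, "+")
    idx <- (ix - 1L) + n1 * (iy - 1L) + n1^2 * (iz - 1L)
    rotCenters[idx * 6L + 1:6, ] <- worldToVoxel(pet, rot)
  }

  tgrid <- as.matrix(expand.grid(x = ks, y = ks, z = ks)) * stepMm
  transVox <- tgrid %*% pet@orientation
  transVox <- sweep(transVox, 2L, pet@spacing, "/")

  vals <- cpp_perturb_search(as.numeric(pet@voxels), dim(pet@voxels),
                             pet@spacing, rotCenters, transVox,
                             diametersMm / 2)
  vals <- array(vals, rep(n1, 6L))
  warnings <- character()
  if (anyNA(vals))
    warnings <- .nemaiq_warn("mappingOutOfBounds",
                             sprintf("%d perturbation nodes map spheres outside the PET volume; excluded from the fit",
                                     sum(is.na(vals))))
  structure(list(values = vals, nodes = ks, dTheta = dTheta,
                 stepMm = stepMm, centroid = centroid, phiE = phiE,
                 warnings = warnings),
            class = "PerturbationGrid")
}

#' Optimal isometry from the perturbation grid
#'
#' Fits the six-dimensional quadratic to the matched values in a
#' neighborhood of the grid maximum (a `(2*fitHalfWidth+1)^6` sub-box
#' centered on the argmax, shifted inward where the argmax touches the
#' search boundary) and composes the analytic vertex with the initial
#' isometry.  Restricting the fit to the peak neighborhood parallels the
#' concave-down subset used for the 3-D fits: the matched-value surface is
#' only near-quadratic close to its peak, and a fit over the whole +-3
#' range drags the vertex toward the surface's flat tails.  A
#' `BoundaryMax` warning is raised when the grid argmax lies on a face of
#' the search range; a `VertexFarFromMax` warning when the vertex is more
#' than two grid increments from the argmax in any dimension.  If the 6-D
#' fit is degenerate or not concave, the argmax node is used instead.
#'
#' @param grid a `PerturbationGrid` from [perturbationSearch()].
#' @param fitHalfWidth half-width (in grid increments) of the fit
#'   neighborhood; 2 gives a 5^6 sub-box, balancing quadratic-model bias
#'   against the rasterization noise of the discrete templates.  `Inf`
#'   fits the whole grid.
#' @return list with `transform` (a [RigidTransform-class] labelled
#'   `"OPTIMAL"`), `vertex` (fractional node coordinates), `argmaxNode` and
#'   `warnings`.
#' @export
optimalIsometry <- function(grid, fitHalfWidth = 2) {
  v <- grid$values
  ks <- grid$nodes
  n1 <- length(ks)
  warnings <- character()
  if (!any(is.finite(v)))
    stop(.nemaiq_error("mappingOutOfBounds",
                       "every perturbation node maps spheres outside the PET volume"))
  am <- which(v == max(v, na.rm = TRUE))[1L]
  amIdx <- arrayInd(am, dim(v))
  amNode <- ks[amIdx[1, ]]
  if (any(abs(amNode) == max(ks)))
    warnings <- c(warnings,
                  .nemaiq_warn("boundaryMax",
                               "matched-value maximum lies on the boundary of the search range"))
  if (is.finite(fitHalfWidth) && 2 * fitHalfWidth + 1 < n1) {
    sel <- lapply(1:6, function(a) {
      s <- (amIdx[1, a] - fitHalfWidth):(amIdx[1, a] + fitHalfWidth)
      s - min(0, s[1] - 1L) - max(0, s[length(s)] - n1)
    })
    vFit <- do.call(`[`, c(list(v), sel, list(drop = FALSE)))
    coords <- lapply(sel, function(s) ks[s])
  } else {
    vFit <- v
    coords <- rep(list(ks), 6L)
  }
  fit <- tryCatch(
    withCallingHandlers(
      fitQuadraticVertex(vFit, coords = coords),
      nemaiq_nonConcaveFit = function(w) invokeRestart("muffleWarning")),
    nemaiq_degenerateFit = function(e) list(vertex = amNode, usedArgmax = TRUE))
  vertex <- fit$vertex
  if (fit$usedArgmax)
    warnings <- c(warnings, "NonConcaveFit: argmax node used for the optimal isometry")
  if (any(abs(vertex - amNode) > 2))
    warnings <- c(warnings,
                  .nemaiq_warn("vertexFarFromMax",
                               "quadratic vertex more than two increments from the grid maximum"))
  # keep the composed transform sane when the fit extrapolates: the vertex
  # may leave the sampled cube by at most half an increment
  vertex <- pmin(pmax(vertex, min(ks) - 0.5), max(ks) + 0.5)
  Rp <- rotationMatrix(vertex[1] * grid$dTheta[1], vertex[2] * grid$dTheta[2],
                       vertex[3] * grid$dTheta[3])
  tmm <- vertex[4:6] * grid$stepMm
  phiE <- grid$phiE
  rotation <- Rp %*% phiE@rotation
  translation <- as.numeric(Rp %*% (phiE@translation - grid$centroid)) +
    grid$centroid + tmm
  list(transform = RigidTransform(rotation, translation, label = "OPTIMAL"),
       vertex = vertex, argmaxNode = amNode, warnings = warnings)
}

#' Final accurate PET sphere centers
#'
#' Maps the six accurate CT centers through the optimal isometry; returns
#' both world-frame (mm) and voxel-frame centers.  Deterministic: the same
#' inputs give bit-identical outputs.
#'
#' @param phiO the optimal [RigidTransform-class].
#' @param ctCentersMm 6x3 matrix of accurate CT centers (mm, CT world).
#' @param pet an [ImageVolume-class] (PET), for the voxel frame.
#' @return list with `world` and `voxel` [SphereCenterSet-class] objects.
#' @export
finalPetCenters <- function(phiO, ctCentersMm, pet) {
  w <- transformPoints(phiO, ctCentersMm)
  dimnames(w) <- list(paste0("sphere", 1:6), c("x", "y", "z"))
  v <- worldToVoxel(pet, w)
  dimnames(v) <- dimnames(w)
  list(world = new("SphereCenterSet", centers = w, frame = "PET_WORLD",
                   quality = rep("ACCURATE", 6L), warnings = character()),
       voxel = new("SphereCenterSet", centers = v, frame = "PET_VOXEL",
                   quality = rep("ACCURATE", 6L), warnings = character()))
}

#' PET/CT misalignment diagnostics
#'
#' Per sphere, the displacement between the optimal and the header
#' isometry, `Di = phiO(ci) - phiDicom(ci)` in mm, its norm, and the
#' maximum pairwise angle between the six displacement vectors.  Large
#' norms with a small angle indicate a coherent rigid misalignment; the
#' report carries raw values only and no pass/fail verdict.
#'
#' @param phiO,phiDicom [RigidTransform-class] objects.
#' @param ctCentersMm 6x3 matrix of accurate CT centers (mm, CT world).
#' @return list of class `MisalignmentReport`: `Di` (6x3 mm), `norms`,
#'   `thetaD` (degrees) and `note`.
#' @export
misalignmentReport <- function(phiO, phiDicom, ctCentersMm) {
  Di <- transformPoints(phiO, ctCentersMm) -
    transformPoints(phiDicom, ctCentersMm)
  dimnames(Di) <- list(paste0("sphere", 1:6), c("x", "y", "z"))
  norms <- sqrt(rowSums(Di^2))
  nz <- which(norms > 1e-12)
  note <- character()
  if (length(nz) < nrow(Di))
    note <- sprintf("%d zero displacement vector(s) excluded from the angle",
                    nrow(Di) - length(nz))
  thetaD <- 0
  if (length(nz) >= 2L) {
    U <- Di[nz, , drop = FALSE] / norms[nz]
    cosines <- tcrossprod(U)
    thetaD <- max(acos(pmin(pmax(cosines[upper.tri(cosines)], -1), 1))) *
      180 / pi
  } else if (length(nz) == 0L) {
    note <- c(note, "all displacement vectors are zero; thetaD reported as 0")
  }
  structure(list(Di = Di, norms = norms, thetaD = thetaD, note = note),
            class = "MisalignmentReport")
}

#' @export
print.MisalignmentReport <- function(x, ...) {
  cat("PET/CT misalignment (optimal vs. header isometry)\n")
  tab <- cbind(x$Di, norm = x$norms)
  print(round(tab, 2))
  cat(sprintf("thetaD (max pairwise angle): %.1f deg\n", x$thetaD))
  if (length(x$note)) cat("note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}
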