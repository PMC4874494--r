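#' Build a binary matched-filter template
#'
#' Rasterizes a filled sphere or a hollow spherical shell with the Binary
#' Center Inclusion Method: a voxel belongs to the template iff its center
#' lies within or on the analytic boundary (distances in mm; ties at the
#' boundary are included, with no floating tolerance).  For shells a voxel
#' is included iff its center distance d satisfies
#' `innerRadius < d <= innerRadius + wallMm`, so the shell is disjoint from
#' the filled sphere of the same diameter.
#'
#' `centerOffset = c(0,0,0)` places the sphere center at the exact center of
#' a voxel; non-zero sub-voxel offsets support templates anchored between
#' voxel centers (as the six-sphere PET template requires).
#'
#' @param kind `"FILLED"` or `"SHELL"`.
#' @param innerDiameterMm sphere inner diameter in mm.
#' @param spacing numeric(3), voxel size in mm.
#' @param wallMm shell thickness in mm (shells only).
#' @param centerOffset numeric(3), sub-voxel offset of the sphere center in
#'   voxel units.
#' @return A [BinaryTemplate-class].
#' @export
buildTemplate <- function(kind = c("FILLED", "SHELL"), innerDiameterMm,
                          spacing, wallMm = 1, centerOffset = c(0, 0, 0)) {
  kind <- match.arg(toupper(kind[1]), c("FILLED", "SHELL"))
  stopifnot(innerDiameterMm > 0, all(spacing > 0))
  if (kind == "SHELL") stopifnot(wallMm > 0)
  r <- innerDiameterMm / 2
  router <- if (kind == "SHELL") r + wallMm else r
  half <- ceiling(router / spacing + abs(centerOffset))
  anchor <- half + centerOffset
  nd <- 2L * half + 1L
  dx2 <- ((seq_len(nd[1]) - 1 - anchor[1]) * spacing[1])^2
  dy2 <- ((seq_len(nd[2]) - 1 - anchor[2]) * spacing[2])^2
  dz2 <- ((seq_len(nd[3]) - 1 - anchor[3]) * spacing[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  mask <- if (kind == "FILLED") d2 <= r^2 else (d2 > r^2 & d2 <= router^2)
  mask <- array(mask, nd)
  if (!any(mask))
    stop(.nemaiq_error("degenerateTemplate",
                       "template empty after rasterization"))
  # trim all-empty slabs at the grid faces
  rng <- lapply(1:3, function(a) range(which(apply(mask, a, any))))
  mask <- mask[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
               rng[[3]][1]:rng[[3]][2], drop = FALSE]
  anchor <- anchor - c(rng[[1]][1], rng[[2]][1], rng[[3]][1]) + 1
  new("BinaryTemplate", mask = mask, anchor = anchor, kind = kind,
      innerDiameterMm = innerDiameterMm,
      wallMm = if (kind == "SHELL") wallMm else 0,
      spacing = as.numeric(spacing))
}

# 0-based voxel offsets of the template's set voxels relative to its anchor
# voxel (the voxel whose center is nearest the anchor point)
templateOffsets <- function(template) {
  idx <- which(template@mask, arr.ind = TRUE) - 1L
  sweep(idx, 2L, as.integer(round(template@anchor)), "-")
}

#' Evaluate a matched filter over a volume
#'
#' Slides the binary template across the volume and records, at each anchor
#' position, the sum of covered voxels (`statistic = "sum"`) or the mean of
#' the covered voxels not flagged in `exclude` (`statistic = "mean"`, used
#' for air compensation).  Positions where the template extends beyond the
#' volume, or where every covered voxel is excluded, are not populated.
#' When several positions attain the maximum, the first in lexicographic
#' (z, y, x) scan order is kept and a `MultipleMaxima` warning is raised.
#'
#' @param volume a 3-D numeric array or an [ImageVolume-class].
#' @param template a [BinaryTemplate-class].
#' @param statistic `"sum"` or `"mean"`.
#' @param exclude optional logical array (same dims as the volume) of voxels
#'   to leave out of the mean.
#' @return A list of class `MatchedValueSpace`: `values` (array, `NA` where
#'   not populated), `argmax` (0-based voxel index of the maximum), `max`,
#'   `nmaxima`, `lo`/`hi` (0-based valid anchor range) and `warnings`.
#' @export
matchedScan <- function(volume, template, statistic = c("sum", "mean"),
                        exclude = NULL) {
  statistic <- match.arg(statistic)
  arr <- if (is(volume, "ImageVolume")) volume@voxels else volume
  off <- templateOffsets(template)
  res <- tryCatch(
    cpp_matched_scan(as.numeric(arr), dim(arr), off,
                     if (statistic == "sum") 0L else 1L,
                     if (is.null(exclude)) NULL else as.logical(exclude)),
    error = function(e)
      stop(.nemaiq_error("templateLargerThanVolume", conditionMessage(e))))
  warnings <- character()
  if (res$nmaxima > 1L)
    warnings <- .nemaiq_warn("multipleMaxima",
                             sprintf("%d positions attain the maximum matched value; first in (z,y,x) order used",
                                     res$nmaxima))
  structure(list(values = array(res$values, dim(arr)),
                 argmax = as.integer(res$argmax), max = res$max,
                 nmaxima = res$nmaxima, nvalid = res$nvalid,
                 lo = as.integer(res$lo), hi = as.integer(res$hi),
                 warnings = warnings),
            class = "MatchedValueSpace")
}

#' Concave-down neighborhood of the matched-value maximum
#'
#' Finds the largest axis-aligned box around the argmax such that, along
#' each of the three axis profiles through the argmax, every interior point
#' of the box has strictly negative discrete second difference (the
#' discrete analogue of concave-down profiles).  The box half-width is at
#' least 1 per axis.
#'
#' @param space a `MatchedValueSpace` from [matchedScan()].
#' @return list with `lo` and `hi`, inclusive 0-based box corners.
#' @section Errors: if a profile is not strictly concave at the argmax
#'   itself (e.g. a flat plateau), a `nemaiq_noConcaveNeighborhood` error is
#'   signalled; callers fall back to the 3x3x3 box around the argmax with a
#'   warning.
#' @export
concaveSubset <- function(space) {
  v <- space$values
  m <- space$argmax + 1L  # 1-based
  d <- dim(v)
  lo <- integer(3); hi <- integer(3)
  for (a in 1:3) {
    prof <- switch(a, v[, m[2], m[3]], v[m[1], , m[3]], v[m[1], m[2], ])
    c0 <- m[a]
    d2 <- function(q) prof[q - 1L] - 2 * prof[q] + prof[q + 1L]
    ok <- function(q) q > 1L && q < length(prof) && !is.na(prof[q - 1L]) &&
      !is.na(prof[q]) && !is.na(prof[q + 1L]) && d2(q) < 0
    if (!ok(c0))
      stop(.nemaiq_error("noConcaveNeighborhood",
                         sprintf("profile along axis %d is not strictly concave at the maximum", a)))
    l <- c0 - 1L; h <- c0 + 1L
    while (ok(h)) h <- h + 1L
    while (ok(l)) l <- l - 1L
    lo[a] <- l; hi[a] <- h
  }
  list(lo = lo - 1L, hi = hi - 1L)
}

#' Fit an N-dimensional quadratic and locate its vertex
#'
#' Ordinary least-squares fit of the full N-variate quadratic (constant,
#' linear, and all pure and cross second-order terms) to sampled values; the
#' sub-grid peak is the analytic vertex where the gradient vanishes.  If the
#' fitted Hessian is not negative definite the grid argmax is returned
#' instead, flagged with a `NonConcaveFit` warning.
#'
#' @param values an N-dimensional array of sampled values (`NA` entries are
#'   excluded from the fit).
#' @param coords optional list of N axis-coordinate vectors; defaults to
#'   0-based grid indices.
#' @return list with `vertex` (in the supplied coordinates),
#'   `hessian`, `gradientCoef`, `negDefinite`, `usedArgmax` and `warnings`.
#' @section Errors: singular normal equations signal `nemaiq_degenerateFit`.
#' @export
fitQuadraticVertex <- function(values, coords = NULL) {
  d <- dim(values)
  if (is.null(d)) d <- length(values)
  N <- length(d)
  if (is.null(coords)) coords <- lapply(d, function(n) seq_len(n) - 1)
  X <- as.matrix(do.call(expand.grid, coords))
  y <- as.vector(values)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  ncoef <- 1L + N + N * (N + 1L) / 2L
  if (length(y) < ncoef)
    stop(.nemaiq_error("degenerateFit",
                       sprintf("%d samples for %d quadratic coefficients",
                               length(y), ncoef)))
  pairs <- which(upper.tri(diag(N), diag = TRUE), arr.ind = TRUE)
  D <- cbind(1, X, X[, pairs[, 1], drop = FALSE] *
                  X[, pairs[, 2], drop = FALSE])
  qrD <- qr(D)
  if (qrD$rank < ncoef)
    stop(.nemaiq_error("degenerateFit", "singular normal equations"))
  beta <- qr.coef(qrD, y)
  b <- beta[2:(N + 1L)]
  A <- matrix(0, N, N)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    cf <- beta[1L + N + k]
    if (i == j) A[i, i] <- cf else A[i, j] <- A[j, i] <- cf / 2
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  negDef <- all(ev < 0)
  warnings <- character()
  if (negDef) {
    vertex <- as.numeric(solve(-2 * A, b))
    usedArgmax <- FALSE
  } else {
    am <- X[which.max(y), ]
    vertex <- as.numeric(am)
    usedArgmax <- TRUE
    warnings <- .nemaiq_warn("nonConcaveFit",
                             "fitted quadratic is not concave; grid argmax used")
  }
  list(vertex = vertex, hessian = A, gradientCoef = b, negDefinite = negDef,
       usedArgmax = usedArgmax, warnings = warnings)
}
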