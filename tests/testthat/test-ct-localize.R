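test_that("bounding-box extents are the minimal voxel counts spanning k diameters", {
  ct <- ImageVolume(array(0, c(300, 300, 100)), spacing = c(1.37, 1.37, 2.5),
                    modality = "CT")
  b <- extractBox(ct, c(150, 150, 50), 37, 2)
  expect_equal(b$hi[1] - b$lo[1], ceiling(74 / 1.37))  # 55
  expect_equal(b$hi[1] - b$lo[1], 55L)
  b2 <- extractBox(ct, c(150, 150, 50), 10, 3)
  expect_equal(b2$hi[3] - b2$lo[3], 12L)               # 12 * 2.5 >= 30
  expect_false(b$clipped)
})

test_that("boxes at the volume corner are clipped with a warning", {
  ct <- ImageVolume(array(0, c(40, 40, 20)), spacing = c(1.37, 1.37, 2.5),
                    modality = "CT")
  expect_warning(b <- extractBox(ct, c(1, 1, 1), 37, 2),
                 class = "nemaiq_clippedBox")
  expect_true(b$clipped)
  expect_equal(b$lo, c(0L, 0L, 0L))
})

test_that("air detection follows the 10-bin histogram mode rule", {
  # 90% water, 6% plastic, 4% air: the air stretches the histogram range
  # so the water mode lands in the upper half
  v <- c(rep(0, 900), rep(120, 60), rep(-1000, 40))
  sub <- array(v, c(10, 10, 10))
  air <- detectAir(sub)
  # independent recomputation of the bin layout and the 2 SD rule
  w <- (max(v) - min(v)) / 10
  waterBin <- floor((0 - min(v)) / w) + 1
  expect_gte(waterBin, 6)
  expect_true(air$detected)
  expect_equal(air$modeBin, waterBin)
  mu <- mean(v); sdv <- sqrt(mean((v - mu)^2))
  expect_equal(air$airMask, array(v <= mu - 2 * sdv, c(10, 10, 10)))
  expect_identical(sort(unique(sub[air$airMask])), -1000)

  # no air: water sits in the bottom bin, nothing is flagged
  v2 <- c(rep(0, 940), rep(120, 60))
  air2 <- detectAir(array(v2, c(10, 10, 10)))
  expect_false(air2$detected)
  expect_equal(sum(air2$airMask), 0L)

  # constant subvolume
  air3 <- detectAir(array(5, c(3, 3, 3)))
  expect_false(air3$detected)
})

test_that("the wall model pools voxels across the three large spheres", {
  wm <- learnWall(list(rep(100, 10), rep(120, 20), rep(140, 10)))
  expect_equal(wm$muPSW, 120)
  expect_equal(wm$nWallVoxels, 40L)
  expect_equal(learnWall(list(rep(120, 5)))$muPSW, 120)
  expect_error(learnWall(list(numeric(0))), class = "nemaiq_wallModelFailure")
})

test_that("hexagon extrapolation is exact on a perfect hexagon", {
  ctr <- c(12.5, -7, 33)
  ang <- (0:5) * 60 * pi / 180 + 0.3
  hexv <- sweep(cbind(57.2 * cos(ang), 57.2 * sin(ang), 0), 2, ctr, "+")
  est <- hexagonExtrapolate(hexv[4, ], hexv[5, ], hexv[6, ])
  expect_lt(max(abs(est - hexv[1:3, ])), 1e-9)
  # the reconstructed center matches the configured one exactly
  cH <- (hexv[4, ] + hexv[6, ] - hexv[5, ])
  expect_lt(max(abs(cH - ctr)), 1e-9)
})

test_that("hexagon extrapolation is equivariant under rigid motion", {
  set.seed(5)
  ang <- (3:5) * 60 * pi / 180
  v <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)
  R <- rotationMatrix(0.3, -0.2, 0.9); tr <- c(4, -8, 12)
  f <- function(m) hexagonExtrapolate(m[1, ], m[2, ], m[3, ])
  lhs <- f(sweep(v %*% t(R), 2, tr, "+"))
  rhs <- sweep(f(v) %*% t(R), 2, tr, "+")
  expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("extrapolation error propagates linearly from vertex jitter", {
  # est_i = 2(c4 + c6 - c5) - c_{i+3}, so the prediction error is an exact
  # linear image of the three jitters; verify against that closed form,
  # then check that jitter at the demonstrated CT localization accuracy
  # keeps every prediction well inside the k=3 search box
  ang <- (3:5) * 60 * pi / 180
  v <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)  # rows: spheres 4, 5, 6
  truthSmall <- -v
  A <- list(c(1, -2, 2), c(2, -3, 2), c(2, -2, 1))  # weights on (e4,e5,e6)
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    e <- matrix(runif(9, -2, 2), 3, 3)
    est <- hexagonExtrapolate(v[1, ] + e[1, ], v[2, ] + e[2, ],
                              v[3, ] + e[3, ])
    for (i in 1:3) {
      predicted <- truthSmall[i, ] + as.numeric(A[[i]] %*% e)
      expect_lt(max(abs(est[i, ] - predicted)), 1e-9)
    }
    # realistic jitter: scale to the ~0.3 mm large-sphere accuracy
    estR <- hexagonExtrapolate(v[1, ] + 0.15 * e[1, ], v[2, ] + 0.15 * e[2, ],
                               v[3, ] + 0.15 * e[3, ])
    worst <- max(worst, sqrt(max(rowSums((estR - truthSmall)^2))))
  }
  expect_lt(worst, 6)
})

test_that("collinear sphere centers abort the extrapolation", {
  expect_error(hexagonExtrapolate(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "nemaiq_degenerateSphereArrangement")
})

test_that("integer up-sampling uses the smallest factor below 1 mm", {
  sub <- array(1:8, c(2, 2, 2))
  expect_equal(upsampleInteger(sub, c(2.5, 2.0, 0.7))$factor, c(3L, 3L, 1L))
  expect_equal(upsampleInteger(sub, c(1.37, 1.0, 2.5))$factor, c(2L, 2L, 3L))
  up <- upsampleInteger(sub, c(2.5, 2.5, 2.5))
  expect_equal(dim(up$values), c(6L, 6L, 6L))
  # replication preserves the value multiset up to multiplicity
  expect_equal(sort(unique(as.vector(up$values))), 1:8)
  expect_equal(as.vector(table(up$values)), rep(27L, 8))
  # already sub-millimeter: unchanged
  expect_identical(upsampleInteger(sub, c(0.7, 0.7, 0.7))$values, sub)
})

test_that("wall rescaling is the negative absolute difference from the wall mean", {
  expect_equal(rescaleToWall(120, 120), 0)
  expect_equal(rescaleToWall(c(120 - 7, 120 + 7), 120), c(-7, -7))
  expect_equal(rescaleToWall(c(0, -1000), 120), c(-120, -1120))
})

test_that("large and small spheres localize to sub-voxel accuracy (noiseless)", {
  ph <- noiselessPhantom()
  ct <- ph$ct
  truth <- worldToVoxel(ct, ph$truth@centersCT)
  est <- truth[c(6, 5, 4), ] + matrix(c(0.9, -0.6, 0.4), 3, 3, byrow = TRUE)
  loc <- suppressWarnings(localizeSpheresCT(ct, est))
  errMm <- sqrt(rowSums(sweep(centers(loc$centers) - truth, 2,
                              spacing(ct), "*")^2))
  expect_lt(errMm[6], 0.5 * min(spacing(ct)))
  expect_true(all(errMm < 0.5))
  expect_gt(loc$muPSW, 20)   # learned wall value is well above water
})

test_that("localization is invariant to a mis-centered search box", {
  ph <- noiselessPhantom()
  ct <- ph$ct
  truth <- worldToVoxel(ct, ph$truth@centersCT)
  b0 <- extractBox(ct, truth[6, ], 37, 2)
  l0 <- suppressWarnings(localizeLarge(ct, b0, 37))
  # displace the box by ~5 mm; the argmax slides within the box
  b1 <- extractBox(ct, truth[6, ] + c(3.6, -2.2, 1.2), 37, 2)
  l1 <- suppressWarnings(localizeLarge(ct, b1, 37))
  expect_lt(max(abs(l0$center - l1$center)), 0.05)
})

test_that("a small sphere displaced up to the hexagon error bound is recovered", {
  ph <- noiselessPhantom()
  ct <- ph$ct
  truth <- worldToVoxel(ct, ph$truth@centersCT)
  b <- extractBox(ct, truth[3, ] + c(5, 3, -1.5), 17, 3)  # ~8 mm off
  l <- suppressWarnings(localizeSmall(ct, b, 17, muPSW = 44))
  errMm <- sqrt(sum(((l$center - truth[3, ]) * spacing(ct))^2))
  expect_lt(errMm, 0.5)
})

test_that("small- and large-sphere code paths agree on a mid-size sphere", {
  ph <- noiselessPhantom()
  ct <- ph$ct
  truth <- worldToVoxel(ct, ph$truth@centersCT)
  est <- truth[c(6, 5, 4), ] + matrix(c(0.9, -0.6, 0.4), 3, 3, byrow = TRUE)
  bL <- extractBox(ct, est[3, ], 22, 2)
  lL <- suppressWarnings(localizeLarge(ct, bL, 22))
  muTrue <- mean(lL$wallValues)
  bS <- extractBox(ct, est[3, ], 22, 3)
  lS <- suppressWarnings(localizeSmall(ct, bS, 22, muPSW = muTrue,
                                       upsample = FALSE))
  errMm <- sqrt(sum(((lL$center - lS$center) * spacing(ct))^2))
  expect_lt(errMm, 0.3)
})

test_that("bubble compensation removes the air-induced localization bias", {
  bub <- function(s, d, rin) list(sphere = s, diameterMm = d,
                                  offsetMm = rin - d / 2)
  bubbles <- list(bub(2, 4, 6.5), bub(3, 5, 8.5), bub(4, 6, 11),
                  bub(5, 8, 14))
  cfg <- phantomConfig(ctNoiseSd = 0, petNoiseSd = 0, seed = 5,
                       bubbles = bubbles)
  ph <- generatePhantom(cfg, modalities = "CT")
  ct <- ph$ct
  truth <- worldToVoxel(ct, ph$truth@centersCT)
  est <- truth[c(6, 5, 4), ] + matrix(c(0.9, -0.6, 0.4), 3, 3, byrow = TRUE)
  on <- suppressWarnings(localizeSpheresCT(ct, est, airDetection = TRUE))
  off <- suppressWarnings(localizeSpheresCT(ct, est, airDetection = FALSE))
  sp <- spacing(ct)
  errOn <- sqrt(rowSums(sweep(centers(on$centers) - truth, 2, sp, "*")^2))
  errOff <- sqrt(rowSums(sweep(centers(off$centers) - truth, 2, sp, "*")^2))
  for (i in 2:5) {
    expect_gt(errOff[i], errOn[i])         # uncompensated bias
    expect_lt(errOn[i], 2 * max(errOn[c(1, 6)]) + 0.3)
  }
  # the bubble-free largest sphere is bit-identical between the arms
  expect_identical(centers(on$centers)[6, ], centers(off$centers)[6, ])
})

test_that("pairwise sphere distances survive a phantom repositioning", {
  phA <- noiselessPhantom()
  cfgB <- phantomConfig(ctNoiseSd = 0, petNoiseSd = 0, seed = 43,
                        phaseDeg = 150)
  phB <- generatePhantom(cfgB, modalities = "CT")
  run <- function(ph) {
    ct <- ph$ct
    truth <- worldToVoxel(ct, ph$truth@centersCT)
    est <- truth[c(6, 5, 4), ] + matrix(c(0.9, -0.6, 0.4), 3, 3, byrow = TRUE)
    loc <- suppressWarnings(localizeSpheresCT(ct, est))
    voxelToWorld(ct, centers(loc$centers))
  }
  delta <- distanceDiscrepancy(run(phA), run(phB))
  expect_lt(max(delta), 0.6)
  expect_lt(mean(delta), 0.15)
})
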