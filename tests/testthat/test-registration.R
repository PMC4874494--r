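test_that("the three-point isometry reproduces exact rigid correspondences", {
  set.seed(21)
  ang <- (3:5) * 60 * pi / 180
  ctPts <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)[3:1, ]  # rows 6,5,4
  expect_equal(rotation(initialIsometry(ctPts, ctPts)), diag(3),
               tolerance = 1e-12)
  for (k in 1:100) {
    R <- rotationMatrix(runif(1, -pi, pi), runif(1, -1, 1), runif(1, -2, 2))
    tr <- runif(3, -50, 50)
    petPts <- sweep(ctPts %*% t(R), 2, tr, "+")
    phi <- initialIsometry(ctPts, petPts)
    expect_lt(max(abs(rotation(phi) - R)), 1e-9)
    expect_lt(max(abs(translation(phi) - tr)), 1e-9)
  }
})

test_that("the chosen symmetric branch minimizes the total distance", {
  set.seed(22)
  ang <- (3:5) * 60 * pi / 180
  ctPts <- cbind(57.2 * cos(ang), 57.2 * sin(ang), 0)[3:1, ]
  for (k in 1:20) {
    noise <- matrix(runif(9, -1.6, 1.6), 3, 3)   # ~voxel rounding
    petPts <- ctPts + noise
    phi <- initialIsometry(ctPts, petPts)
    # condition 1 is exact, the rest within ~2 voxels
    expect_lt(max(abs(transformPoints(phi, ctPts[1, ]) - petPts[1, ])), 1e-9)
    d <- sqrt(rowSums((transformPoints(phi, ctPts) - petPts)^2))
    expect_lt(max(d), 2 * 3.27)
    expect_equal(det(rotation(phi)), 1, tolerance = 1e-9)
  }
})

test_that("collinear triples terminate the isometry construction", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  expect_error(initialIsometry(pts, pts + 1),
               class = "nemaiq_degenerateSphereArrangement")
})

test_that("the six-sphere template is the union of per-sphere rasterizations", {
  ph <- noiselessPhantom()
  pet <- ph$pet
  cen <- worldToVoxel(pet, ph$truth@centersPET)
  mask <- buildSixSphereTemplate(pet, cen)
  counts <- vapply(1:6, function(i) {
    tpl <- buildTemplate("FILLED", c(10, 13, 17, 22, 28, 37)[i],
                         spacing = spacing(pet),
                         centerOffset = cen[i, ] - round(cen[i, ]))
    sum(tpl@mask)
  }, numeric(1))
  expect_equal(sum(mask), sum(counts))  # well-separated: no double counting

  # on-lattice shift moves the mask voxel-for-voxel
  m1 <- buildSixSphereTemplate(pet, sweep(cen, 2, c(1, 0, 0), "+"))
  expect_identical(m1[-1, , ], mask[-dim(mask)[1], , ])
  # a half-voxel shift changes the voxel set (sub-voxel sensitivity)
  mh <- buildSixSphereTemplate(pet, sweep(cen, 2, c(0.5, 0, 0), "+"))
  expect_false(identical(mh, mask))
})

test_that("spheres mapped outside the PET volume are an error", {
  ph <- noiselessPhantom()
  cen <- worldToVoxel(ph$pet, ph$truth@centersPET)
  cen[1, ] <- c(-300, -300, -300)
  expect_error(suppressWarnings(buildSixSphereTemplate(ph$pet, cen)),
               class = "nemaiq_mappingOutOfBounds")
})

test_that("the perturbation search peaks at the self-match node", {
  ph <- noiselessPhantom()
  pet <- ph$pet
  phiTrue <- RigidTransform(label = "ESTIMATE")  # no misalignment applied
  grid <- perturbationSearch(phiTrue, ph$truth@centersCT, pet)
  am <- arrayInd(which.max(grid$values), dim(grid$values))
  # discrete template rasterization can favor an immediate neighbor of the
  # exact alignment; the peak must sit in the central +-1 node region
  expect_true(all(abs(grid$nodes[am[1, ]]) <= 1))
  expect_equal(grid$values[matrix(am, 1)] / max(grid$values, na.rm = TRUE),
               1, tolerance = 1e-12)
  expect_equal(dim(grid$values), rep(7L, 6L))
})

test_that("grid values match an independent template-sum recomputation", {
  ph <- noiselessPhantom()
  pet <- ph$pet
  phiE <- RigidTransform(label = "ESTIMATE")
  grid <- perturbationSearch(phiE, ph$truth@centersCT, pet)
  diameters <- c(10, 13, 17, 22, 28, 37)
  mapped0 <- transformPoints(phiE, ph$truth@centersCT)
  centroid <- colMeans(mapped0)
  set.seed(33)
  nodes <- matrix(sample(-3:3, 6 * 30, replace = TRUE), ncol = 6)
  for (r in seq_len(nrow(nodes))) {
    nd <- nodes[r, ]
    R <- rotationMatrix(nd[1] * grid$dTheta[1], nd[2] * grid$dTheta[2],
                        nd[3] * grid$dTheta[3])
    pts <- sweep(sweep(mapped0, 2, centroid) %*% t(R), 2,
                 centroid + nd[4:6], "+")
    mask <- buildSixSphereTemplate(pet, worldToVoxel(pet, pts), diameters)
    expected <- sum(voxels(pet)[mask])
    got <- grid$values[matrix(nd + 4L, 1)]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("a constructed translation offset moves the argmax to its node", {
  mis <- RigidTransform(diag(3), c(2, 0, 0))
  cfg <- phantomConfig(ctNoiseSd = 0, petNoiseSd = 0, seed = 8,
                       misalignment = mis)
  ph <- generatePhantom(cfg, modalities = "PET")
  phiE <- RigidTransform(label = "ESTIMATE")
  grid <- perturbationSearch(phiE, ph$truth@centersCT, ph$pet)
  am <- grid$nodes[arrayInd(which.max(grid$values), dim(grid$values))[1, ]]
  expect_equal(am, c(0, 0, 0, 2, 0, 0))
})

test_that("a sub-grid translation offset is recovered by the 6-D fit", {
  mis <- RigidTransform(diag(3), c(0, 1.4, 0))
  cfg <- phantomConfig(ctNoiseSd = 0, petNoiseSd = 0, seed = 9,
                       misalignment = mis)
  ph <- generatePhantom(cfg, modalities = "PET")
  phiE <- RigidTransform(label = "ESTIMATE")
  grid <- perturbationSearch(phiE, ph$truth@centersCT, ph$pet)
  opt <- optimalIsometry(grid)
  rec <- transformPoints(opt$transform, ph$truth@centersCT)
  err <- sqrt(rowSums((rec - ph$truth@centersPET)^2))
  expect_lt(max(err), 0.5)
})

test_that("an offset beyond the search range raises BoundaryMax", {
  mis <- RigidTransform(diag(3), c(5, 0, 0))
  cfg <- phantomConfig(ctNoiseSd = 0, petNoiseSd = 0, seed = 10,
                       misalignment = mis)
  ph <- generatePhantom(cfg, modalities = "PET")
  phiE <- RigidTransform(label = "ESTIMATE")
  grid <- perturbationSearch(phiE, ph$truth@centersCT, ph$pet)
  warns <- character()
  opt <- withCallingHandlers(optimalIsometry(grid), warning = function(w) {
    warns <<- c(warns, class(w)[1])
    invokeRestart("muffleWarning")
  })
  expect_true("nemaiq_boundaryMax" %in% warns)
  expect_true(any(abs(opt$argmaxNode) == 3))
})

test_that("the optimal isometry is a proper isometry", {
  mis <- RigidTransform(rotationMatrix(0.01, 0, -0.01), c(1, -1, 0.5))
  cfg <- phantomConfig(ctNoiseSd = 0, petNoiseSd = 0, seed = 12,
                       misalignment = mis)
  ph <- generatePhantom(cfg, modalities = "PET")
  grid <- perturbationSearch(RigidTransform(label = "ESTIMATE"),
                             ph$truth@centersCT, ph$pet)
  opt <- optimalIsometry(grid)
  phiO <- opt$transform
  expect_equal(det(rotation(phiO)), 1, tolerance = 1e-9)
  set.seed(4)
  p <- matrix(rnorm(30, sd = 50), ncol = 3)
  q <- matrix(rnorm(30, sd = 50), ncol = 3)
  dp <- sqrt(rowSums((p - q)^2))
  dt <- sqrt(rowSums((transformPoints(phiO, p) - transformPoints(phiO, q))^2))
  expect_lt(max(abs(dp - dt)), 1e-9)
})

test_that("final PET centers are deterministic and frame-consistent", {
  ph <- noiselessPhantom()
  phiO <- RigidTransform(rotationMatrix(0.002, 0, 0.001), c(0.5, -0.2, 0.1),
                         label = "OPTIMAL")
  a <- finalPetCenters(phiO, ph$truth@centersCT, ph$pet)
  b <- finalPetCenters(phiO, ph$truth@centersCT, ph$pet)
  expect_identical(centers(a$world), centers(b$world))
  expect_equal(voxelToWorld(ph$pet, centers(a$voxel)), centers(a$world),
               ignore_attr = TRUE)
  # identity transform re-expresses the CT centers in the PET frame
  id <- finalPetCenters(RigidTransform(label = "OPTIMAL"),
                        ph$truth@centersCT, ph$pet)
  expect_equal(centers(id$world), ph$truth@centersCT, ignore_attr = TRUE)
})

test_that("misalignment diagnostics match their geometric definition", {
  ph <- noiselessPhantom()
  ctMm <- ph$truth@centersCT
  phiD <- RigidTransform(label = "DICOM")

  same <- misalignmentReport(phiD, phiD, ctMm)
  expect_true(all(same$norms == 0))
  expect_equal(same$thetaD, 0)
  expect_true(length(same$note) > 0)

  # pure translation: all Di equal, thetaD zero; the displacement pattern
  # of a coherently misaligned scanner
  tr <- c(8.6, 4.8, 4.8)
  phiO <- composeTransform(RigidTransform(diag(3), tr, "OPTIMAL"), phiD,
                           label = "OPTIMAL")
  rep2 <- misalignmentReport(phiO, phiD, ctMm)
  expect_equal(unname(rep2$Di), matrix(tr, 6, 3, byrow = TRUE))
  expect_equal(unname(rep2$norms), rep(sqrt(sum(tr^2)), 6))
  expect_equal(round(rep2$norms[[1]], 1), 11.0)
  expect_equal(rep2$thetaD, 0, tolerance = 1e-5)

  # a small rotation spreads the Di directions
  phiR <- composeTransform(RigidTransform(rotationMatrix(0, 0, 0.02),
                                          c(5, 0, 0), "OPTIMAL"), phiD,
                           label = "OPTIMAL")
  rep3 <- misalignmentReport(phiR, phiD, ctMm)
  expect_gt(rep3$thetaD, 1)
  expect_lte(rep3$thetaD, 180)
})
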