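test_that("Binary Center Inclusion counts match brute-force enumeration", {
  diameters <- c(10, 13, 17, 22, 28, 37)
  spacings <- list(c(2.73, 2.73, 3.27), c(1.37, 1.37, 2.5))
  for (sp in spacings) for (d in diameters) {
    tpl <- buildTemplate("FILLED", d, spacing = sp)
    expect_equal(sum(tpl@mask), oracleSphereCount(d / 2, sp),
                 info = sprintf("filled d=%g sp=%s", d, paste(sp, collapse = "x")))
    sh <- buildTemplate("SHELL", d, spacing = sp, wallMm = 1)
    expect_equal(sum(sh@mask), oracleSphereCount(d / 2, sp, shellWallMm = 1),
                 info = sprintf("shell d=%g", d))
  }
})

test_that("a sub-voxel-diameter sphere rasterizes to a single voxel", {
  tpl <- buildTemplate("FILLED", 1.9, spacing = c(2, 2, 2))
  expect_equal(sum(tpl@mask), 1L)
  expect_equal(dim(tpl@mask), c(1L, 1L, 1L))
})

test_that("shell and filled masks obey the set algebra of their radii", {
  sp <- c(0.5, 0.5, 0.5)
  f10 <- buildTemplate("FILLED", 10, spacing = sp)
  sh <- buildTemplate("SHELL", 10, spacing = sp, wallMm = 1)
  f12 <- buildTemplate("FILLED", 12, spacing = sp)
  # compare on a common grid via center distances
  dset <- function(tpl) {
    idx <- which(tpl@mask, arr.ind = TRUE) - 1L
    sort(round(sqrt(rowSums(sweep(sweep(idx, 2, tpl@anchor), 2, sp, "*")^2)), 9))
  }
  expect_true(max(dset(f10)) <= 5)
  expect_true(all(dset(sh) > 5) && max(dset(sh)) <= 6)
  # inner radius 5 + 1 mm wall reaches exactly the 12 mm filled boundary
  expect_equal(c(dset(f10), dset(sh))[order(c(dset(f10), dset(sh)))], dset(f12))
})

test_that("rasterized volume converges to the analytic sphere volume", {
  sp <- c(0.25, 0.25, 0.25)
  tpl <- buildTemplate("FILLED", 37, spacing = sp)
  vol <- sum(tpl@mask) * prod(sp)
  expect_lt(abs(vol - 4 / 3 * pi * 18.5^3) / (4 / 3 * pi * 18.5^3), 0.02)
})

test_that("centered templates are symmetric under axis reflection", {
  tpl <- buildTemplate("SHELL", 17, spacing = c(1.37, 1.37, 2.5))
  m <- tpl@mask
  expect_identical(m, m[rev(seq_len(dim(m)[1])), , ])
  expect_identical(m, m[, rev(seq_len(dim(m)[2])), ])
  expect_identical(m, m[, , rev(seq_len(dim(m)[3]))])
})

test_that("degenerate templates are rejected", {
  expect_error(buildTemplate("SHELL", 0.2, spacing = c(5, 5, 5), wallMm = 0.1),
               class = "nemaiq_degenerateTemplate")
})

test_that("a template larger than the volume cannot be scanned", {
  tpl <- buildTemplate("FILLED", 20, spacing = c(1, 1, 1))
  expect_error(matchedScan(array(0, c(5, 5, 5)), tpl, "sum"),
               class = "nemaiq_templateLargerThanVolume")
})

test_that("matched scan equals the direct sliding-window oracle", {
  set.seed(11)
  vol <- array(rnorm(20^3), c(20, 20, 20))
  tpl <- buildTemplate("FILLED", 4.5, spacing = c(1, 1, 1))
  off <- which(tpl@mask, arr.ind = TRUE) - 1L
  off <- sweep(off, 2, as.integer(round(tpl@anchor)))

  mvs <- matchedScan(vol, tpl, "sum")
  expect_equal(mvs$values, oracleMatchedScan(vol, off, "sum"),
               tolerance = 1e-6)

  excl <- array(runif(20^3) < 0.1, c(20, 20, 20))
  mvsM <- matchedScan(vol, tpl, "mean", exclude = excl)
  expect_equal(mvsM$values, oracleMatchedScan(vol, off, "mean", excl),
               tolerance = 1e-6)
})

test_that("matched scan honors its simple invariants", {
  ones <- array(1, c(12, 12, 12))
  tpl <- buildTemplate("FILLED", 5, spacing = c(1, 1, 1))
  n <- sum(tpl@mask)
  s <- suppressWarnings(matchedScan(ones, tpl, "sum"))  # all positions tie
  m <- suppressWarnings(matchedScan(ones, tpl, "mean"))
  expect_true(all(s$values[!is.na(s$values)] == n))
  expect_true(all(m$values[!is.na(m$values)] == 1))
  # sum = mean * count with no exclusions, on arbitrary data
  set.seed(2)
  v <- array(rexp(12^3), c(12, 12, 12))
  expect_equal(matchedScan(v, tpl, "sum")$values,
               matchedScan(v, tpl, "mean")$values * n, tolerance = 1e-9)
  # impulse volume with a single-voxel template peaks at the impulse
  imp <- array(0, c(9, 9, 9)); imp[4, 6, 2] <- 1
  one <- buildTemplate("FILLED", 0.5, spacing = c(1, 1, 1))
  expect_equal(matchedScan(imp, one, "sum")$argmax, c(3L, 5L, 1L))
})

test_that("ties at the maximum use (z,y,x) scan order and warn", {
  v <- array(0, c(5, 5, 5))
  v[2, 2, 2] <- 7; v[4, 4, 4] <- 7
  one <- buildTemplate("FILLED", 0.5, spacing = c(1, 1, 1))
  expect_warning(mvs <- matchedScan(v, one, "sum"),
                 class = "nemaiq_multipleMaxima")
  expect_equal(mvs$argmax, c(1L, 1L, 1L))
  expect_equal(mvs$nmaxima, 2L)
})

test_that("the concave-down neighborhood follows the profile curvature", {
  grid <- seq(-5, 5)
  f <- function(x, y, z) -(x^2 + y^2 + z^2)
  v <- outer(outer(grid^2, grid^2, "+"), grid^2, "+") * -1
  space <- list(values = v, argmax = c(5L, 5L, 5L),
                lo = c(0L, 0L, 0L), hi = c(10L, 10L, 10L))
  box <- concaveSubset(space)
  expect_equal(box$lo, c(0L, 0L, 0L))
  expect_equal(box$hi, c(10L, 10L, 10L))

  # a secondary bump along x clips the box before the bump
  v2 <- v
  v2[9, 6, 6] <- v2[9, 6, 6] + 8   # bump two voxels beyond the peak
  space2 <- list(values = v2, argmax = c(5L, 5L, 5L))
  box2 <- concaveSubset(space2)
  d2 <- v2[7, 6, 6] - 2 * v2[8, 6, 6] + v2[9, 6, 6]
  expect_gte(d2, 0)                # curvature flips before the bump
  expect_equal(box2$hi[1], 7L)
  expect_equal(box2$hi[2:3], c(10L, 10L))

  # flat plateau at the peak: no concave neighborhood
  v3 <- array(0, c(5, 5, 5))
  expect_error(concaveSubset(list(values = v3, argmax = c(2L, 2L, 2L))),
               class = "nemaiq_noConcaveNeighborhood")
})

test_that("quadratic vertex recovery is exact on exact quadratics", {
  grid <- 0:4
  v <- outer(outer(-(grid - 1.3)^2, -2 * (grid + 0.4)^2, "+"),
             -0.5 * grid^2, "+") + 7
  fit <- fitQuadraticVertex(v)
  expect_lt(max(abs(fit$vertex - c(1.3, -0.4, 0))), 1e-9)
  expect_true(fit$negDefinite)

  # 6-D exact quadratic on the 7^6 grid
  ks <- -3:3
  X <- as.matrix(expand.grid(ks, ks, ks, ks, ks, ks))
  truth <- c(0.5, -1.2, 0.3, 1.9, -0.7, 0)
  y <- -colSums((t(X) - truth)^2 * c(1, 2, 0.5, 1, 3, 0.25))
  v6 <- array(y, rep(7, 6))
  fit6 <- fitQuadraticVertex(v6, coords = rep(list(ks), 6))
  expect_lt(max(abs(fit6$vertex - truth)), 1e-8)
})

test_that("quadratic vertex tolerates small noise", {
  grid <- -2:2
  mk <- function() outer(outer(-(grid - 0.7)^2, -1.5 * (grid + 0.2)^2, "+"),
                         -0.8 * (grid - 0.1)^2, "+")
  worst <- 0
  for (s in 1:50) {
    set.seed(s)
    v <- mk() + array(rnorm(125, 0, 1e-3), c(5, 5, 5))
    fit <- fitQuadraticVertex(v, coords = rep(list(grid), 3))
    worst <- max(worst, max(abs(fit$vertex - c(0.7, -0.2, 0.1))))
  }
  expect_lt(worst, 0.02)
})

test_that("quadratic fit is equivariant under translation and axis permutation", {
  set.seed(9)
  grid <- 0:4
  v <- outer(outer(-(grid - 2.1)^2, -(grid - 1.7)^2, "+"), -(grid - 2.6)^2, "+")
  f0 <- fitQuadraticVertex(v)
  fShift <- fitQuadraticVertex(v, coords = list(grid + 10, grid - 3, grid))
  expect_equal(fShift$vertex, f0$vertex + c(10, -3, 0), tolerance = 1e-9)
  fPerm <- fitQuadraticVertex(aperm(v, c(2, 3, 1)))
  expect_equal(fPerm$vertex, f0$vertex[c(2, 3, 1)], tolerance = 1e-9)
})

test_that("a non-concave surface falls back to the argmax with a warning", {
  grid <- 0:4
  v <- outer(outer(grid^2, grid^2, "+"), grid^2, "+")  # convex bowl
  expect_warning(fit <- fitQuadraticVertex(v), class = "nemaiq_nonConcaveFit")
  expect_true(fit$usedArgmax)
  expect_equal(fit$vertex, c(4, 4, 4))
})
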