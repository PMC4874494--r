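# Independent brute-force oracles, kept deliberately naive (triple loops)
# so they share no code path with the package's vectorized/C++ routines.

# count voxels whose centers fall within (or on) radius r of the center,
# scanning an index cube one voxel at a time
oracleSphereCount <- function(radiusMm, spacing, shellWallMm = NULL) {
  half <- ceiling((radiusMm + max(0, shellWallMm %||% 0)) / spacing) + 1L
  n <- 0L
  for (i in -half[1]:half[1]) for (j in -half[2]:half[2])
    for (k in -half[3]:half[3]) {
      d <- sqrt((i * spacing[1])^2 + (j * spacing[2])^2 + (k * spacing[3])^2)
      inc <- if (is.null(shellWallMm)) d <= radiusMm
             else d > radiusMm && d <= radiusMm + shellWallMm
      if (inc) n <- n + 1L
    }
  n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct sliding-window matched filter
oracleMatchedScan <- function(vol, maskOffsets, statistic = "sum",
                              exclude = NULL) {
  d <- dim(vol)
  out <- array(NA_real_, d)
  lo <- -apply(maskOffsets, 2, min)
  hi <- d - 1L - apply(maskOffsets, 2, max)
  for (z in lo[3]:hi[3]) for (y in lo[2]:hi[2]) for (x in lo[1]:hi[1]) {
    s <- 0; n <- 0L
    for (m in seq_len(nrow(maskOffsets))) {
      xi <- x + maskOffsets[m, 1] + 1L
      yi <- y + maskOffsets[m, 2] + 1L
      zi <- z + maskOffsets[m, 3] + 1L
      if (!is.null(exclude) && exclude[xi, yi, zi]) next
      s <- s + vol[xi, yi, zi]
      n <- n + 1L
    }
    out[x + 1L, y + 1L, z + 1L] <-
      if (statistic == "sum") s else if (n > 0L) s / n else NA_real_
  }
  out
}

# a small, fast phantom for I/O and structural tests (not NEMA-scaled)
tinyConfig <- function(...) {
  args <- list(ctDim = c(60L, 50L, 8L), petDim = c(40L, 30L, 6L),
               bodySemiAxesMm = c(30, 25), bodyLengthMm = 12,
               hexRadiusMm = 20, diametersMm = c(4, 5, 6, 7, 8, 9),
               planeZMm = 0.5, ctBlurFwhmMm = 0, petBlurFwhmMm = 2,
               ctNoiseSd = 0, petNoiseSd = 0, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantomConfig, args)
}

# default-geometry noiseless phantom, rendered once per test session
noiselessPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePhantom(phantomConfig(ctNoiseSd = 0, petNoiseSd = 0,
                                              seed = 42))
    cache
  }
})
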