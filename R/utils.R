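# classed conditions so callers can distinguish the pipeline's hard failures
.nemaiq_error <- function(class, message, data = NULL) {
  structure(class = c(paste0("nemaiq_", class), "nemaiqError", "error",
                      "condition"),
            list(message = message, call = sys.call(-1), data = data))
}

.nemaiq_warn <- function(class, message, data = NULL) {
  warning(structure(class = c(paste0("nemaiq_", class), "nemaiqWarning",
                              "warning", "condition"),
                    list(message = message, call = sys.call(-1),
                         data = data)))
  message
}

# run code with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  force(code)
}

#' Add seeded Gaussian noise to a volume
#'
#' Returns a copy of the volume with i.i.d. Gaussian noise added to every
#' voxel.  Used to produce repeated noisy realizations of one noiseless
#' synthetic render; the seed fully determines the output and the caller's
#' RNG state is left untouched.
#'
#' @param volume an [ImageVolume-class] or a numeric array.
#' @param sd noise standard deviation (HU for CT, activity units for PET).
#' @param seed integer seed.
#' @param quantize round the result to integers (matching the integer pixel
#'   representation the DICOM writer uses).
#' @return Same type as `volume`.
#' @export
addGaussianNoise <- function(volume, sd, seed, quantize = TRUE) {
  arr <- if (is(volume, "ImageVolume")) volume@voxels else volume
  noisy <- withSeed(seed, arr + stats::rnorm(length(arr), 0, sd))
  if (quantize) noisy <- round(noisy)
  noisy <- array(noisy, dim(arr))
  if (is(volume, "ImageVolume")) {
    volume@voxels <- noisy
    volume
  } else noisy
}

# separable Gaussian blur by FFT with zero padding (kernels normalized to
# unit sum; tails beyond ~4 sigma are truncated)
gaussianBlur3d <- function(arr, sigmaVox) {
  if (all(sigmaVox <= 0)) return(arr)
  d <- dim(arr)
  pad <- ifelse(sigmaVox > 0, ceiling(4 * sigmaVox), 0L)
  dp <- d + 2L * pad
  big <- array(0, dp)
  big[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
      pad[3] + seq_len(d[3])] <- arr
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1L)))
    x <- c(0:(n %/% 2L), -rev(seq_len(n - n %/% 2L - 1L)))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  k <- outer(outer(kern1(dp[1], sigmaVox[1]), kern1(dp[2], sigmaVox[2])),
             kern1(dp[3], sigmaVox[3]))
  k <- array(k, dp)
  sm <- Re(fft(fft(big) * fft(k), inverse = TRUE)) / prod(dp)
  sm[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])]
}

# pairwise Euclidean distances between the rows of a k x 3 matrix,
# returned as a named vector over the k*(k-1)/2 pairs ("i-j")
pairwiseDistances <- function(points) {
  p <- rbind3(points)
  k <- nrow(p)
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  d <- sqrt(rowSums((p[idx[, 1], , drop = FALSE] -
                     p[idx[, 2], , drop = FALSE])^2))
  names(d) <- paste0(idx[, 1], "-", idx[, 2])
  d
}
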