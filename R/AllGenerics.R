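#' @rdname ImageVolume-class
#' @param object an object.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname ImageVolume-class
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname ImageVolume-class
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))
#' @rdname ImageVolume-class
#' @export
setGeneric("orientation", function(object) standardGeneric("orientation"))
#' @rdname ImageVolume-class
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname SphereCenterSet-class
#' @param object an object.
#' @export
setGeneric("centers", function(object) standardGeneric("centers"))
#' @rdname SphereCenterSet-class
#' @export
setGeneric("centerFrame", function(object) standardGeneric("centerFrame"))

#' @rdname RigidTransform-class
#' @param object an object.
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))
#' @rdname RigidTransform-class
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))

#' @rdname ImageVolume-class
setMethod("voxels", "ImageVolume", function(object) object@voxels)
#' @rdname ImageVolume-class
setMethod("spacing", "ImageVolume", function(object) object@spacing)
#' @rdname ImageVolume-class
setMethod("origin", "ImageVolume", function(object) object@origin)
#' @rdname ImageVolume-class
setMethod("orientation", "ImageVolume", function(object) object@orientation)
#' @rdname ImageVolume-class
setMethod("modality", "ImageVolume", function(object) object@modality)

#' @rdname SphereCenterSet-class
setMethod("centers", "SphereCenterSet", function(object) object@centers)
#' @rdname SphereCenterSet-class
setMethod("centerFrame", "SphereCenterSet", function(object) object@frame)

#' @rdname RigidTransform-class
setMethod("rotation", "RigidTransform", function(object) object@rotation)
#' @rdname RigidTransform-class
setMethod("translation", "RigidTransform", function(object) object@translation)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume [%s] %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (mm): %.3f %.3f %.3f\n",
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform <%s>\n", object@label))
  cat("  rotation:\n")
  print(round(object@rotation, 6))
  cat(sprintf("  translation (mm): %.4f %.4f %.4f\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "BinaryTemplate", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryTemplate [%s] inner %.4g mm%s, %d/%d voxels set, grid %d x %d x %d\n",
              object@kind, object@innerDiameterMm,
              if (object@kind == "SHELL") sprintf(" + %.4g mm wall", object@wallMm) else "",
              sum(object@mask), prod(d), d[1], d[2], d[3]))
})

setMethod("show", "SphereCenterSet", function(object) {
  cat(sprintf("SphereCenterSet in %s\n", object@frame))
  m <- cbind(object@centers, quality = NA)
  tab <- data.frame(sphere = 1:6, x = object@centers[, 1],
                    y = object@centers[, 2], z = object@centers[, 3],
                    quality = object@quality)
  print(tab, row.names = FALSE, digits = 6)
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth: six sphere centers (CT world mm)\n")
  print(round(object@centersCT, 3))
  if (nrow(object@bubbles))
    cat(sprintf("  %d bubble(s) in sphere(s) %s\n", nrow(object@bubbles),
                paste(object@bubbles$sphere, collapse = ", ")))
  if (max(abs(object@misalignment@rotation - diag(3))) > 0 ||
      any(object@misalignment@translation != 0))
    cat("  PET-vs-CT misalignment applied\n")
})
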