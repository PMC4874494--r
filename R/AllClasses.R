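#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Geometry-aware image volume
#'
#' A single-modality 3-D image volume with its acquisition geometry: voxel
#' values (Hounsfield units for CT, activity-proportional units for PET),
#' per-axis voxel spacing in mm, the world position of the center of voxel
#' index (0,0,0), and a 3x3 direction-cosine matrix whose columns are the
#' world directions of the three voxel axes.  Voxel indices are 0-based and
#' refer to voxel centers; fractional indices are meaningful throughout.
#'
#' @slot voxels 3-D numeric array of voxel values.
#' @slot spacing numeric(3), voxel size in mm, all > 0.
#' @slot origin numeric(3), world coordinates (mm) of the center of voxel
#'   (0,0,0).
#' @slot orientation 3x3 orthonormal direction-cosine matrix.
#' @slot modality character, `"PET"` or `"CT"`.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 orientation = "matrix", modality = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L || any(dim(object@voxels) < 1L))
      msg <- c(msg, "voxels must be a non-empty 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be a finite 3-vector (mm)")
    O <- object@orientation
    if (!all(dim(O) == c(3L, 3L)) ||
        max(abs(crossprod(O) - diag(3))) > 1e-6)
      msg <- c(msg, "orientation must be a 3x3 orthonormal matrix")
    if (!object@modality %in% c("PET", "CT"))
      msg <- c(msg, "modality must be 'PET' or 'CT'")
    if (length(msg)) msg else TRUE
  })

#' Rigid isometry between world frames
#'
#' A proper rigid-body transform x -> R x + t in mm, used for the CT-to-PET
#' mappings: the DICOM-header isometry, the initial three-point estimate, and
#' the optimal isometry from the perturbation search.
#'
#' @slot rotation 3x3 rotation matrix (orthogonal, determinant +1).
#' @slot translation numeric(3) in mm.
#' @slot label character, one of `"DICOM"`, `"ESTIMATE"`, `"OPTIMAL"`.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 label = "character"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), label = "DICOM"),
  validity = function(object) {
    msg <- character()
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
      msg <- c(msg, "rotation must be 3x3")
    else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        msg <- c(msg, "rotation must be orthogonal to 1e-9")
      if (abs(det(R) - 1) > 1e-9)
        msg <- c(msg, "rotation must have determinant +1 (no reflection)")
    }
    if (length(object@translation) != 3L || any(!is.finite(object@translation)))
      msg <- c(msg, "translation must be a finite 3-vector (mm)")
    if (!object@label %in% c("DICOM", "ESTIMATE", "OPTIMAL"))
      msg <- c(msg, "label must be DICOM, ESTIMATE or OPTIMAL")
    if (length(msg)) msg else TRUE
  })

#' Binary matched-filter template
#'
#' A binary mask of the expected object (a filled sphere or a hollow
#' spherical shell) built with the Binary Center Inclusion Method: a voxel
#' belongs to the template iff its center lies within or on the analytic
#' boundary.  The anchor is the fractional 0-based index of the geometric
#' sphere center within the mask grid.
#'
#' @slot mask 3-D logical array.
#' @slot anchor numeric(3), fractional 0-based index of the sphere center.
#' @slot kind character, `"FILLED"` or `"SHELL"`.
#' @slot innerDiameterMm numeric(1).
#' @slot wallMm numeric(1); 0 for filled templates.
#' @slot spacing numeric(3), mm.
#' @exportClass BinaryTemplate
setClass("BinaryTemplate",
  representation(mask = "array", anchor = "numeric", kind = "character",
                 innerDiameterMm = "numeric", wallMm = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3-D logical array")
    else if (!any(object@mask))
      msg <- c(msg, "mask must contain at least one voxel")
    if (!object@kind %in% c("FILLED", "SHELL"))
      msg <- c(msg, "kind must be FILLED or SHELL")
    if (length(object@anchor) != 3L ||
        any(object@anchor < -0.5 | object@anchor > dim(object@mask) - 0.5))
      msg <- c(msg, "anchor must lie within the mask grid")
    if (length(msg)) msg else TRUE
  })

#' Per-sphere center estimates
#'
#' The six sphere centers (or a subset) in a named coordinate frame.  Voxel
#' frames hold fractional 0-based indices, world frames hold mm.  Sphere 6
#' is the largest (37 mm), sphere 1 the smallest (10 mm).
#'
#' @slot centers 6x3 numeric matrix (rows sphere 1..6; NA for spheres not
#'   yet located).
#' @slot frame character: `"PET_VOXEL"`, `"CT_VOXEL"`, `"PET_WORLD"` or
#'   `"CT_WORLD"`.
#' @slot quality character(6): `"ESTIMATE"` or `"ACCURATE"` per sphere.
#' @slot warnings character vector of accumulated warnings.
#' @exportClass SphereCenterSet
setClass("SphereCenterSet",
  representation(centers = "matrix", frame = "character",
                 quality = "character", warnings = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@centers) == c(6L, 3L)))
      msg <- c(msg, "centers must be a 6x3 matrix")
    if (any(is.infinite(object@centers)))
      msg <- c(msg, "centers must be finite or NA")
    if (!object@frame %in% c("PET_VOXEL", "CT_VOXEL", "PET_WORLD", "CT_WORLD"))
      msg <- c(msg, "unknown frame")
    if (length(object@quality) != 6L ||
        !all(object@quality %in% c("ESTIMATE", "ACCURATE", "NA")))
      msg <- c(msg, "quality must be six ESTIMATE/ACCURATE tags")
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a synthetic phantom
#'
#' Emitted alongside every generated CT/PET pair: the true sphere centers in
#' both world frames, the configured PET-vs-CT misalignment, the bubble
#' definitions, and the noiseless volumes (before noise, after blur).
#'
#' @slot centersCT 6x3 matrix, true centers in CT world mm.
#' @slot centersPET 6x3 matrix, true physical centers in PET world mm (these
#'   differ from `centersCT` exactly by the applied misalignment).
#' @slot misalignment [RigidTransform-class] applied between the CT truth
#'   and the physical PET placement.
#' @slot bubbles data.frame with one row per bubble (sphere, diameterMm,
#'   offsetMm and the bubble center in CT world mm).
#' @slot noiselessCT,noiselessPET noiseless voxel arrays (or NULL).
#' @slot config the generating [phantomConfig()] list.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(centersCT = "matrix", centersPET = "matrix",
                 misalignment = "RigidTransform", bubbles = "data.frame",
                 noiselessCT = "arrayOrNULL", noiselessPET = "arrayOrNULL",
                 config = "list"))
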