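# Accessors and show methods.

#' @describeIn CTVolume dimensions of the grid.
#' @param x,object a `CTVolume`.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@values))

#' Grid values of a CTVolume
#'
#' @param x a [CTVolume-class].
#' @return The 3-D numeric array of grid values (HU or occupancy).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "CTVolume", function(x) x@values)

#' Voxel spacing in mm
#'
#' @param x a [CTVolume-class].
#' @return numeric(3) spacing (mm).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' Volume of one voxel in mm^3
#'
#' @param x a [CTVolume-class].
#' @return scalar voxel volume (mm^3).
#' @export
voxelVolumeMm3 <- function(x) prod(voxelSpacing(x))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g], origin (%.3g, %.3g, %.3g) mm\n",
              min(object@values), max(object@values),
              object@origin[1], object@origin[2], object@origin[3]))
})

#' @describeIn beadPack number of spheres in the pack.
#' @param x a `BeadPack`.
#' @export
setMethod("length", "BeadPack", function(x) length(x@radii))

#' Sphere centres and radii of a BeadPack
#'
#' @param x a [BeadPack-class].
#' @return `beadCenters`: n x 3 matrix (mm); `beadRadii`: numeric(n) (mm).
#' @export
beadCenters <- function(x) x@centers

#' @rdname beadCenters
#' @export
beadRadii <- function(x) x@radii

setMethod("show", "BeadPack", function(object) {
  cat(sprintf("BeadPack: %d spheres, radii %.2f-%.2f mm, analytic volume %.2f cm^3\n",
              length(object@radii), min(object@radii), max(object@radii),
              analyticVolume(object)))
})

#' Material density accessors
#'
#' @param x a [MaterialPair-class].
#' @return scalar density (HU) or SD (HU, possibly `NA`).
#' @export
huObject <- function(x) x@huObject

#' @rdname huObject
#' @export
huBackground <- function(x) x@huBackground

#' @rdname huObject
#' @export
sdObject <- function(x) x@sdObject

#' @rdname huObject
#' @export
sdBackground <- function(x) x@sdBackground

setMethod("show", "MaterialPair", function(object) {
  fmt <- function(m, s) if (is.na(s)) sprintf("%.1f HU", m)
         else sprintf("%.1f +/- %.1f HU", m, s)
  cat("MaterialPair: object", fmt(object@huObject, object@sdObject),
      "| background", fmt(object@huBackground, object@sdBackground), "\n")
})

setMethod("show", "SliceROI", function(object) {
  cat(sprintf("SliceROI (%s): slice %d, %d pixels\n", object@kind,
              object@sliceIndex, sum(object@mask)))
})

#' VolumetryResult accessors
#'
#' @param x a [VolumetryResult-class].
#' @return `volumeCm3`: total volume (cm^3); `sliceFractions` /
#'   `sliceVolumes`: per-slice vectors; `measurements`: the input per-slice
#'   table; `outOfRangeSlices`: count of slices whose fraction fell outside
#'   [0, 1] (a noise diagnostic).
#' @export
volumeCm3 <- function(x) x@totalVolumeCm3

#' @rdname volumeCm3
#' @export
sliceFractions <- function(x) x@fractions

#' @rdname volumeCm3
#' @export
sliceVolumes <- function(x) x@sliceVolumesCm3

#' @rdname volumeCm3
#' @export
measurements <- function(x) x@measurements

#' @rdname volumeCm3
#' @export
outOfRangeSlices <- function(x) x@nOutOfRange

setMethod("show", "VolumetryResult", function(object) {
  cat(sprintf("VolumetryResult: %.1f cm^3 over %d slices (T = %.4g mm)\n",
              object@totalVolumeCm3, nrow(object@measurements),
              object@sliceThicknessMm))
  if (object@nOutOfRange > 0L)
    cat(sprintf("  %d slice fraction(s) outside [0, 1] (noise diagnostic)\n",
                object@nOutOfRange))
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(
    "AcquisitionConfig: %.1f / %.1f HU, pixel %.4g mm, thin slice %.4g mm,\n",
    object@huObject, object@huBackground, object@pixelMm, object@thinSliceMm))
  cat(sprintf("  noise SD %.1f HU, kernel %s, supersampling %d\n",
              object@noiseSdHu, object@kernel, object@supersampling))
})
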