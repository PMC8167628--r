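# S4 containers shared by the phantom, ROI, volumetry and sensitivity layers.

#' CTVolume: a 3-D scalar density grid
#'
#' Holds a 3-D array of scalar values (Hounsfield units for simulated or
#' measured scans, occupancy fractions for ground-truth grids) together with
#' the voxel spacing in mm and the position of the grid's lower corner.
#' Axis 3 is always the stacking (slice) axis; axes 1 and 2 are in-plane.
#' The centre of voxel (i, j, k) (1-based) sits at
#' \code{origin + (c(i, j, k) - 0.5) * spacing}.
#'
#' @slot values 3-D numeric array.
#' @slot spacing numeric(3), voxel spacing in mm, strictly positive.
#' @slot origin numeric(3), mm position of the grid's lower corner.
#' @exportClass CTVolume
setClass("CTVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-D array")
  if (any(d < 1L)) return("grid dimensions must all be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers (mm)")
  TRUE
})

#' Construct a CTVolume
#'
#' @param values 3-D numeric array (HU or occupancy).
#' @param spacing numeric(3) voxel spacing in mm (in-plane x, in-plane y,
#'   slice spacing).
#' @param origin numeric(3) mm position of the grid's lower corner.
#' @return A [CTVolume-class] object.
#' @examples
#' v <- CTVolume(array(-149.7, c(4, 4, 2)), spacing = c(0.5, 0.5, 0.625))
#' voxelSpacing(v)
#' @export
CTVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' MaterialPair: reference densities of the two compartments
#'
#' The mean (and optionally SD) Hounsfield densities of the contained object
#' material and the surrounding background material. The two means must
#' differ, otherwise the mixture inversion is degenerate.
#'
#' @slot huObject mean density of the contained material (HU).
#' @slot huBackground mean density of the surrounding material (HU).
#' @slot sdObject,sdBackground density SDs (HU); `NA` when unknown.
#' @exportClass MaterialPair
setClass("MaterialPair",
  representation(huObject = "numeric", huBackground = "numeric",
                 sdObject = "numeric", sdBackground = "numeric"),
  prototype(sdObject = NA_real_, sdBackground = NA_real_))

setValidity("MaterialPair", function(object) {
  if (length(object@huObject) != 1L || length(object@huBackground) != 1L ||
      !is.finite(object@huObject) || !is.finite(object@huBackground))
    return("huObject and huBackground must be single finite numbers")
  if (object@huObject == object@huBackground)
    return("object and background densities must differ (mixture inversion is degenerate)")
  for (s in c(object@sdObject, object@sdBackground))
    if (!is.na(s) && s < 0) return("SDs must be >= 0 when present")
  TRUE
})

#' Construct a MaterialPair
#'
#' @param huObject,huBackground mean densities (HU) of the contained and the
#'   surrounding material; must differ.
#' @param sdObject,sdBackground optional density SDs (HU).
#' @return A [MaterialPair-class] object.
#' @examples
#' materialPair(119.9, -149.7, sdObject = 3.7, sdBackground = 5.3)
#' @export
materialPair <- function(huObject, huBackground,
                         sdObject = NA_real_, sdBackground = NA_real_) {
  new("MaterialPair", huObject = as.numeric(huObject),
      huBackground = as.numeric(huBackground),
      sdObject = as.numeric(sdObject), sdBackground = as.numeric(sdBackground))
}

#' BeadPack: a set of non-overlapping spheres in a box
#'
#' Ground truth of the digital phantom: sphere centres and radii (mm) inside
#' an axis-aligned box container. The analytic total sphere volume is the
#' reference against which every simulated measurement is scored.
#'
#' @slot centers n x 3 numeric matrix of sphere centres (mm).
#' @slot radii numeric(n) radii (mm).
#' @slot container 2 x 3 matrix, rows = lower/upper corner of the box (mm).
#' @slot seed integer seed that produced the pack.
#' @exportClass BeadPack
setClass("BeadPack",
  representation(centers = "matrix", radii = "numeric",
                 container = "matrix", seed = "integer"))

setValidity("BeadPack", function(object) {
  n <- nrow(object@centers)
  if (ncol(object@centers) != 3L) return("centers must be an n x 3 matrix")
  if (length(object@radii) != n) return("radii length must match centers rows")
  if (n == 0L) return("pack must contain at least one sphere")
  if (any(object@radii <= 0)) return("radii must be positive")
  if (!all(dim(object@container) == c(2L, 3L)))
    return("container must be a 2 x 3 (lo/hi) matrix")
  lo <- object@container[1, ]; hi <- object@container[2, ]
  if (any(hi <= lo)) return("container upper corner must exceed lower corner")
  for (a in 1:3) {
    if (any(object@centers[, a] - object@radii < lo[a] - 1e-9) ||
        any(object@centers[, a] + object@radii > hi[a] + 1e-9))
      return("every sphere must lie fully inside the container")
  }
  TRUE
})

#' Construct a BeadPack
#'
#' Most users obtain packs from [packBeads]; this constructor is for
#' hand-built fixtures. Sphere overlap is not re-checked here (it is an O(n^2)
#' operation); [packBeads] guarantees it and tests verify it.
#'
#' @param centers n x 3 matrix of centres (mm).
#' @param radii numeric(n) radii (mm).
#' @param container either a 2 x 3 lo/hi matrix or a numeric(3) of box side
#'   lengths (box then spans \code{[0, side]} on each axis).
#' @param seed integer provenance seed.
#' @return A [BeadPack-class] object.
#' @export
beadPack <- function(centers, radii, container, seed = NA_integer_) {
  if (is.null(dim(container))) {
    container <- rbind(c(0, 0, 0), as.numeric(container))
  }
  storage.mode(container) <- "double"
  new("BeadPack", centers = rbind(centers), radii = as.numeric(radii),
      container = container, seed = as.integer(seed))
}

#' AcquisitionConfig: scanner emulation parameters
#'
#' Bundles the parameters of the emulated acquisition: the two material
#' densities, native in-plane pixel size and thin-slice spacing, noise SD,
#' reconstruction kernel and the per-axis sub-voxel supersampling used by the
#' partial-volume voxelizer. Defaults mirror a 14 cm reconstruction FOV on a
#' 512 matrix (0.2734375 mm pixels), 0.625 mm native slices, PMMA at
#' 119.9 HU in petroleum jelly at -149.7 HU, and a low-noise SD of 4.6 HU.
#'
#' @slot huObject,huBackground material densities (HU).
#' @slot pixelMm native in-plane pixel size (mm).
#' @slot thinSliceMm native slice spacing (mm).
#' @slot noiseSdHu additive Gaussian noise SD (HU).
#' @slot kernel `"standard"` or `"edge_enhanced"`.
#' @slot kernelStrength,kernelRadiusMm unsharp-mask parameters used when
#'   `kernel == "edge_enhanced"`.
#' @slot supersampling integer per-axis sub-voxel subdivision (>= 1).
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(huObject = "numeric", huBackground = "numeric",
                 pixelMm = "numeric", thinSliceMm = "numeric",
                 noiseSdHu = "numeric", kernel = "character",
                 kernelStrength = "numeric", kernelRadiusMm = "numeric",
                 supersampling = "integer"))

setValidity("AcquisitionConfig", function(object) {
  if (object@pixelMm <= 0 || object@thinSliceMm <= 0)
    return("pixel and slice sizes must be positive")
  if (object@noiseSdHu < 0) return("noiseSdHu must be >= 0")
  if (object@supersampling < 1L) return("supersampling must be >= 1")
  if (!object@kernel %in% c("standard", "edge_enhanced"))
    return("kernel must be 'standard' or 'edge_enhanced'")
  if (object@huObject == object@huBackground)
    return("material densities must differ")
  TRUE
})

#' Construct an AcquisitionConfig
#'
#' @param huObject,huBackground material densities (HU).
#' @param pixelMm native in-plane pixel size (mm); default 14 cm FOV / 512.
#' @param thinSliceMm native slice spacing (mm).
#' @param noiseSdHu Gaussian noise SD (HU); 4.6 emulates a low-noise scan.
#' @param kernel `"standard"` (no filtering) or `"edge_enhanced"`.
#' @param kernelStrength,kernelRadiusMm unsharp-mask strength and Gaussian
#'   radius (mm) for the edge-enhancing kernel emulation.
#' @param supersampling per-axis sub-voxel subdivision for voxelization.
#' @return An [AcquisitionConfig-class] object.
#' @examples
#' acquisitionConfig()
#' @export
acquisitionConfig <- function(huObject = 119.9, huBackground = -149.7,
                              pixelMm = 140 / 512, thinSliceMm = 0.625,
                              noiseSdHu = 4.6, kernel = "standard",
                              kernelStrength = 1.5, kernelRadiusMm = 0.8,
                              supersampling = 4L) {
  new("AcquisitionConfig", huObject = as.numeric(huObject),
      huBackground = as.numeric(huBackground), pixelMm = as.numeric(pixelMm),
      thinSliceMm = as.numeric(thinSliceMm), noiseSdHu = as.numeric(noiseSdHu),
      kernel = kernel, kernelStrength = as.numeric(kernelStrength),
      kernelRadiusMm = as.numeric(kernelRadiusMm),
      supersampling = as.integer(supersampling))
}

#' SliceROI: a per-slice region of interest
#'
#' A binary in-plane raster tied to one slice of a [CTVolume-class]. ROIs are
#' built from ground truth ([autoMixtureROI]), from polygons
#' ([rasterizePolygon] / [polygonROI]) or by enlargement ([scaleROI]).
#'
#' @slot sliceIndex 1-based index along the stacking axis.
#' @slot mask logical matrix matching the in-plane grid dimensions.
#' @slot kind `"mixture"`, `"background_cal"` or `"object_cal"`.
#' @slot achievedFactor area enlargement factor actually reached by
#'   [scaleROI] (`NA` for unscaled ROIs).
#' @exportClass SliceROI
setClass("SliceROI",
  representation(sliceIndex = "integer", mask = "matrix", kind = "character",
                 achievedFactor = "numeric"),
  prototype(kind = "mixture", achievedFactor = NA_real_))

setValidity("SliceROI", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (!any(object@mask)) return("mask must be nonempty")
  if (length(object@sliceIndex) != 1L || object@sliceIndex < 1L)
    return("sliceIndex must be a single index >= 1")
  if (!object@kind %in% c("mixture", "background_cal", "object_cal"))
    return("kind must be mixture, background_cal or object_cal")
  TRUE
})

#' Construct a SliceROI from a raster mask
#'
#' @param sliceIndex 1-based slice index.
#' @param mask logical in-plane matrix.
#' @param kind ROI role: `"mixture"`, `"background_cal"` or `"object_cal"`.
#' @return A [SliceROI-class] object.
#' @export
sliceROI <- function(sliceIndex, mask, kind = "mixture") {
  new("SliceROI", sliceIndex = as.integer(sliceIndex), mask = mask, kind = kind)
}

#' VolumetryResult: per-slice fractions and total volume
#'
#' Output of [totalVolume]: the per-slice object fractions, per-slice partial
#' volumes, their total in cm^3, and provenance (measurements, material
#' densities, slice thickness). Fractions are deliberately not clamped to
#' [0, 1]; the count of out-of-range slices is kept as a diagnostic.
#'
#' @slot measurements data.frame with columns slice_index, area_mm2, mean_hu,
#'   sd_hu.
#' @slot fractions numeric per-slice object fractions.
#' @slot sliceVolumesCm3 numeric per-slice partial volumes (cm^3).
#' @slot totalVolumeCm3 total volume (cm^3).
#' @slot sliceThicknessMm slice thickness T (mm).
#' @slot materials the [MaterialPair-class] used for the inversion.
#' @slot nOutOfRange number of slices with fraction outside [0, 1].
#' @exportClass VolumetryResult
setClass("VolumetryResult",
  representation(measurements = "data.frame", fractions = "numeric",
                 sliceVolumesCm3 = "numeric", totalVolumeCm3 = "numeric",
                 sliceThicknessMm = "numeric", materials = "MaterialPair",
                 nOutOfRange = "integer"))

setValidity("VolumetryResult", function(object) {
  n <- nrow(object@measurements)
  if (length(object@fractions) != n || length(object@sliceVolumesCm3) != n)
    return("per-slice vectors must match the number of measurements")
  if (abs(object@totalVolumeCm3 - sum(object@sliceVolumesCm3)) >
      1e-9 * max(1, abs(object@totalVolumeCm3)))
    return("total volume must equal the sum of per-slice volumes")
  if (object@sliceThicknessMm <= 0) return("slice thickness must be positive")
  TRUE
})
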