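# Two-material partial-volume volumetry: mixture inversion, per-slice
# integration, ROI statistics and material-density calibration.

#' Object fraction from the mean ROI density
#'
#' Inverts the two-material mixture relation: a region containing only the
#' object and the background material has mean density
#' \eqn{\bar{HU} = f \cdot HU_{obj} + (1 - f) \cdot HU_{bkg}}, so
#' \deqn{f = (\bar{HU} - HU_{bkg}) / (HU_{obj} - HU_{bkg}).}
#' The result is deliberately not clamped to [0, 1]: under noise per-slice
#' fractions legitimately stray slightly outside, and clamping would bias the
#' integrated volume upward. Out-of-range fractions are counted by
#' [totalVolume] as a diagnostic.
#'
#' @param meanHu mean ROI density (HU); vectorized.
#' @param materials a [MaterialPair-class] with distinct densities.
#' @return Numeric vector of object fractions (dimensionless).
#' @examples
#' m <- materialPair(119.9, -149.7)
#' objectFraction(-14.9, m)  # exact midpoint: 0.5
#' @export
objectFraction <- function(meanHu, materials) {
  stopifnot(is(materials, "MaterialPair"))
  validObject(materials)
  (meanHu - materials@huBackground) /
    (materials@huObject - materials@huBackground)
}

#' Validate a per-slice measurement table
#'
#' Checks (and returns) a data.frame of per-slice ROI measurements with
#' columns `slice_index`, `area_mm2`, `mean_hu`, `sd_hu` — the triple a PACS
#' workstation reports per slice. `sd_hu` may be `NA` (it is a diagnostic and
#' does not enter the volume).
#'
#' @param df data.frame of per-slice measurements.
#' @return The validated data.frame (row order preserved).
#' @export
sliceMeasurements <- function(df) {
  needed <- c("slice_index", "area_mm2", "mean_hu")
  if (!is.data.frame(df) || !all(needed %in% names(df)))
    stop("measurements need columns slice_index, area_mm2, mean_hu (and optionally sd_hu)")
  if (nrow(df) == 0L) stop("measurement set is empty")
  if (!"sd_hu" %in% names(df)) df$sd_hu <- NA_real_
  if (anyDuplicated(df$slice_index))
    stop("slice_index must be unique within one measurement set")
  if (any(!is.finite(df$area_mm2)) || any(df$area_mm2 <= 0))
    stop("all ROI areas must be positive")
  if (any(!is.finite(df$mean_hu))) stop("all mean HU values must be finite")
  df[, c("slice_index", "area_mm2", "mean_hu", "sd_hu")]
}

#' Total object volume from per-slice ROI measurements
#'
#' Integrates the per-slice object fractions into a volume:
#' \deqn{V = \frac{T}{1000} \sum_{i=1}^{N} A_i f_i \quad [cm^3]}
#' with \eqn{T} the slice thickness (mm), \eqn{A_i} the ROI area (mm^2) of
#' slice \eqn{i} and \eqn{f_i} from [objectFraction].
#'
#' @param meas per-slice measurement data.frame (see [sliceMeasurements]).
#' @param materials a [MaterialPair-class].
#' @param sliceThicknessMm slice thickness T in mm (> 0).
#' @return A [VolumetryResult-class] with per-slice fractions and volumes.
#' @examples
#' m <- materialPair(119.9, -149.7)
#' meas <- data.frame(slice_index = 1, area_mm2 = 1000, mean_hu = -14.9,
#'                    sd_hu = 0)
#' volumeCm3(totalVolume(meas, m, 5))  # 2.5 cm^3
#' @export
totalVolume <- function(meas, materials, sliceThicknessMm) {
  meas <- sliceMeasurements(meas)
  stopifnot(is(materials, "MaterialPair"))
  if (!is.finite(sliceThicknessMm) || sliceThicknessMm <= 0)
    stop("slice thickness must be a positive number of mm")
  f <- objectFraction(meas$mean_hu, materials)
  v <- sliceThicknessMm * meas$area_mm2 * f / 1000
  new("VolumetryResult", measurements = meas, fractions = f,
      sliceVolumesCm3 = v, totalVolumeCm3 = sum(v),
      sliceThicknessMm = sliceThicknessMm, materials = materials,
      nOutOfRange = sum(f < 0 | f > 1))
}

#' Signed relative error of a calculated volume
#'
#' \eqn{100 (V - V_{ref}) / V_{ref}} in percent, signed (negative =
#' underestimation).
#'
#' @param calculatedCm3 calculated volume (cm^3); vectorized.
#' @param actualCm3 reference volume (cm^3, > 0).
#' @return Signed percent error.
#' @examples
#' relativeError(34.6, 35.5)  # about -2.5
#' @export
relativeError <- function(calculatedCm3, actualCm3) {
  if (length(actualCm3) != 1L || !is.finite(actualCm3) || actualCm3 <= 0)
    stop("reference volume must be a single positive number")
  100 * (calculatedCm3 - actualCm3) / actualCm3
}

#' Contrast-to-noise ratio
#'
#' Material contrast divided by the image noise SD:
#' \eqn{(HU_{obj} - HU_{bkg}) / \sigma}. The noise SD is passed explicitly;
#' callers may use the background-material SD or a dedicated noise indicator.
#'
#' @param materials a [MaterialPair-class].
#' @param noiseSdHu noise SD (HU, > 0).
#' @return Dimensionless ratio.
#' @examples
#' cnr(materialPair(119.9, -149.7), 22.3)  # about 12.1
#' @export
cnr <- function(materials, noiseSdHu) {
  stopifnot(is(materials, "MaterialPair"))
  if (!is.finite(noiseSdHu) || noiseSdHu <= 0)
    stop("noiseSdHu must be a positive number")
  (materials@huObject - materials@huBackground) / noiseSdHu
}

#' Per-slice ROI statistics
#'
#' Mean density, population SD and area of a region of interest on one slice,
#' exactly the per-slice triple the volumetry needs. Area is the number of
#' masked pixels times the in-plane pixel area, matching what a workstation
#' reports for a rasterized ROI.
#'
#' @param volume a [CTVolume-class].
#' @param roi a [SliceROI-class], or a logical in-plane mask (then
#'   `sliceIndex` is required).
#' @param sliceIndex 1-based slice index when `roi` is a bare mask.
#' @return One-row data.frame with `slice_index`, `area_mm2`, `mean_hu`,
#'   `sd_hu` (population SD: divide-by-n).
#' @export
measureROI <- function(volume, roi, sliceIndex = NULL) {
  stopifnot(is(volume, "CTVolume"))
  if (is(roi, "SliceROI")) {
    sliceIndex <- roi@sliceIndex
    mask <- roi@mask
  } else {
    if (is.null(sliceIndex)) stop("sliceIndex is required with a bare mask")
    mask <- roi
  }
  d <- dim(volume@values)
  if (sliceIndex < 1L || sliceIndex > d[3])
    stop("slice index ", sliceIndex, " outside the stack (1..", d[3], ")")
  if (!is.logical(mask) || !all(dim(mask) == d[1:2]))
    stop("mask dimensions must match the in-plane grid (",
         d[1], " x ", d[2], ")")
  if (!any(mask)) stop("ROI mask is empty")
  px <- volume@values[, , sliceIndex][mask]
  n <- length(px)
  mu <- mean(px)
  data.frame(slice_index = as.integer(sliceIndex),
             area_mm2 = n * volume@spacing[1] * volume@spacing[2],
             mean_hu = mu,
             sd_hu = sqrt(sum((px - mu)^2) / n))
}

#' Calibrate the two material densities from reference ROIs
#'
#' Emulates the workstation calibration step: the background density is the
#' mean over one large background-only ROI (about 10 cm^2), and the object
#' density is the unweighted mean of per-ROI means over several small ROIs
#' drawn fully inside individual objects on the thin-slice volume. SDs are
#' recorded likewise (background: population SD of the ROI pixels; object:
#' mean of per-ROI population SDs).
#'
#' @param volume a [CTVolume-class], normally the thin-slice stack.
#' @param backgroundROI a [SliceROI-class] over pure background.
#' @param objectROIs list of [SliceROI-class], each interior to one object.
#' @param occupancy optional ground-truth occupancy [CTVolume-class]; when
#'   given, object ROIs touching any pixel with occupancy < 1 trigger a
#'   warning (partial-volume contamination of the calibration).
#' @return A [MaterialPair-class].
#' @export
calibrateMaterials <- function(volume, backgroundROI, objectROIs,
                               occupancy = NULL) {
  if (length(objectROIs) == 0L) stop("at least one object ROI is required")
  if (is(objectROIs, "SliceROI")) objectROIs <- list(objectROIs)
  bg <- measureROI(volume, backgroundROI)
  if (!is.null(occupancy)) {
    for (r in objectROIs) {
      occ <- occupancy@values[, , r@sliceIndex][r@mask]
      if (any(occ < 1))
        warning("object calibration ROI on slice ", r@sliceIndex,
                " overlaps background (min occupancy ",
                signif(min(occ), 3), ")")
    }
  }
  per <- do.call(rbind, lapply(objectROIs, function(r) measureROI(volume, r)))
  materialPair(huObject = mean(per$mean_hu), huBackground = bg$mean_hu,
               sdObject = mean(per$sd_hu), sdBackground = bg$sd_hu)
}

#' Map stored integer values to Hounsfield units
#'
#' Applies the affine rescale used by DICOM-style storage:
#' `HU = slope * stored + intercept`.
#'
#' @param stored numeric stored values.
#' @param slope,intercept rescale slope and intercept.
#' @return Values in HU.
#' @examples
#' rescaleToHU(874, 1, -1024)  # -150
#' @export
rescaleToHU <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}
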