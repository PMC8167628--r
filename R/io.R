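# File formats: NIfTI volumes, per-slice measurement CSV, result/materials
# JSON, bead-pack JSON sidecars, ROI JSON, YAML configs.

#' Read / write a CTVolume as NIfTI
#'
#' Round-trips the grid values bit-exactly and the voxel spacing to header
#' precision through RNifti.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume a [CTVolume-class].
#' @return `readVolume`: a [CTVolume-class]; `writeVolume`: `path`,
#'   invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3-D NIfTI volume: ", path)
  CTVolume(array(as.numeric(arr), dim(arr)), spacing = sp[1:3])
}

#' @rdname readVolume
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  img <- RNifti::asNifti(structure(volume@values, pixdim = volume@spacing))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write per-slice measurements as CSV
#'
#' Plain CSV with header `slice_index,area_mm2,mean_hu,sd_hu` — the per-slice
#' record the workstation procedure produces.
#'
#' @param meas measurement data.frame (see [sliceMeasurements]).
#' @param path CSV file path.
#' @return `readMeasurements`: validated data.frame; `writeMeasurements`:
#'   `path`, invisibly.
#' @export
readMeasurements <- function(path) {
  sliceMeasurements(read.csv(path))
}

#' @rdname readMeasurements
#' @export
writeMeasurements <- function(meas, path) {
  write.csv(sliceMeasurements(meas), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a VolumetryResult to JSON
#'
#' Per-slice arrays plus totals and provenance (material densities, slice
#' thickness, out-of-range diagnostic).
#'
#' @param result a [VolumetryResult-class].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
writeVolumetryJSON <- function(result, path) {
  stopifnot(is(result, "VolumetryResult"))
  m <- result@materials
  obj <- list(
    total_volume_cm3 = result@totalVolumeCm3,
    slice_thickness_mm = result@sliceThicknessMm,
    n_slices = nrow(result@measurements),
    n_out_of_range = result@nOutOfRange,
    materials = list(hu_object = m@huObject, hu_background = m@huBackground,
                     sd_object = m@sdObject, sd_background = m@sdBackground),
    per_slice = list(slice_index = result@measurements$slice_index,
                     area_mm2 = result@measurements$area_mm2,
                     mean_hu = result@measurements$mean_hu,
                     sd_hu = result@measurements$sd_hu,
                     fraction = result@fractions,
                     volume_cm3 = result@sliceVolumesCm3))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read / write a MaterialPair as JSON
#'
#' @param materials a [MaterialPair-class].
#' @param path JSON file path.
#' @return `readMaterials`: a [MaterialPair-class]; `writeMaterials`:
#'   `path`, invisibly.
#' @export
writeMaterials <- function(materials, path) {
  stopifnot(is(materials, "MaterialPair"))
  jsonlite::write_json(
    list(hu_object = materials@huObject,
         hu_background = materials@huBackground,
         sd_object = materials@sdObject,
         sd_background = materials@sdBackground),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeMaterials
#' @export
readMaterials <- function(path) {
  x <- jsonlite::read_json(path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  materialPair(num(x$hu_object), num(x$hu_background),
               num(x$sd_object), num(x$sd_background))
}

#' Write / read a BeadPack JSON sidecar
#'
#' Centres, radii, container, seed and analytic volume — the ground truth
#' accompanying a simulated volume on disk.
#'
#' @param pack a [BeadPack-class].
#' @param path JSON file path.
#' @return `readBeadPack`: a [BeadPack-class]; `writeBeadPack`: `path`,
#'   invisibly.
#' @export
writeBeadPack <- function(pack, path) {
  stopifnot(is(pack, "BeadPack"))
  jsonlite::write_json(
    list(centers_mm = unname(pack@centers),
         radii_mm = pack@radii,
         container_mm = list(lo = pack@container[1, ],
                             hi = pack@container[2, ]),
         seed = pack@seed,
         analytic_volume_cm3 = analyticVolume(pack)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBeadPack
#' @export
readBeadPack <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- matrix(as.numeric(x$centers_mm), ncol = 3)
  beadPack(centers, x$radii_mm,
           rbind(as.numeric(x$container_mm$lo), as.numeric(x$container_mm$hi)),
           seed = x$seed)
}

#' Read polygon ROIs from JSON
#'
#' JSON array of objects `{slice_index, kind, polygon: [[x_mm, y_mm], ...]}`
#' with closed-ring polygons in mm coordinates.
#'
#' @param path JSON file path.
#' @param volume target [CTVolume-class] used to rasterize.
#' @return list of [SliceROI-class].
#' @export
readROIPolygons <- function(path, volume) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    polygonROI(poly, as.integer(r$slice_index), volume,
               kind = if (is.null(r$kind)) "mixture" else r$kind)
  })
}

#' Read an AcquisitionConfig from YAML
#'
#' Recognized keys mirror [acquisitionConfig] arguments in snake_case
#' (`hu_object`, `hu_background`, `pixel_mm`, `thin_slice_mm`, `noise_sd_hu`,
#' `kernel`, `kernel_strength`, `kernel_radius_mm`, `supersampling`);
#' omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return An [AcquisitionConfig-class].
#' @export
readAcquisitionConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  acquisitionConfig(
    huObject = pick("hu_object", 119.9),
    huBackground = pick("hu_background", -149.7),
    pixelMm = pick("pixel_mm", 140 / 512),
    thinSliceMm = pick("thin_slice_mm", 0.625),
    noiseSdHu = pick("noise_sd_hu", 4.6),
    kernel = pick("kernel", "standard"),
    kernelStrength = pick("kernel_strength", 1.5),
    kernelRadiusMm = pick("kernel_radius_mm", 0.8),
    supersampling = pick("supersampling", 4L))
}

#' Write experiment grid results
#'
#' CSV of the aggregated table plus a JSON companion with per-replicate
#' detail and provenance (seeds, bead counts, analytic volumes).
#'
#' @param results output of [runExperimentGrid].
#' @param csvPath,jsonPath output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
writeGridResults <- function(results, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) write.csv(results, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(summary = results,
           replicates = attr(results, "replicates"),
           provenance = attr(results, "provenance")),
      jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(c(csvPath, jsonPath))
}
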