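# End-to-end simulation pipeline: phantom -> acquisition variant ->
# calibration -> ROIs -> volumetry -> error vs analytic ground truth, and the
# robustness experiment grid.

#' Mixture ROIs for every slice containing object
#'
#' Builds an [autoMixtureROI] on every slice whose ground-truth occupancy is
#' positive (the "slices that included any portion of the beads" rule),
#' optionally enlarged by [scaleROI].
#'
#' @param occupancy ground-truth occupancy [CTVolume-class], on the same
#'   grid as the measured volume.
#' @param marginMm background rim width (mm).
#' @param areaFactor ROI area enlargement factor (1 = none).
#' @return list of [SliceROI-class].
#' @export
mixtureROIs <- function(occupancy, marginMm = 2, areaFactor = 1) {
  withObject <- which(apply(occupancy@values > 0, 3, any))
  if (length(withObject) == 0L) stop("no slice contains any object")
  lapply(withObject, function(k) {
    roi <- autoMixtureROI(occupancy, k, marginMm)
    if (areaFactor > 1) roi <- scaleROI(roi, areaFactor, occupancy)
    roi
  })
}

#' Volumetry of a simulated phantom volume
#'
#' Runs the measurement side of the pipeline on one reconstructed volume:
#' per-slice mixture ROIs from ground truth, ROI statistics, mixture
#' inversion, slice integration.
#'
#' @param hu measured/simulated [CTVolume-class].
#' @param occupancy ground-truth occupancy [CTVolume-class] on the same grid.
#' @param materials [MaterialPair-class] (measured or true densities).
#' @param marginMm mixture-ROI background rim (mm).
#' @param areaFactor ROI enlargement factor.
#' @return A [VolumetryResult-class].
#' @export
phantomVolumetry <- function(hu, occupancy, materials, marginMm = 2,
                             areaFactor = 1) {
  stopifnot(all(dim(hu) == dim(occupancy)))
  rois <- mixtureROIs(occupancy, marginMm, areaFactor)
  meas <- do.call(rbind, lapply(rois, function(r) measureROI(hu, r)))
  totalVolume(meas, materials, voxelSpacing(hu)[3])
}

#' Calibrate material densities on a simulated phantom
#'
#' Convenience wrapper: builds [autoCalibrationROIs] from the ground truth
#' and runs [calibrateMaterials] on the given (normally thin-slice, noisy)
#' volume.
#'
#' @param hu [CTVolume-class] to measure densities on.
#' @param occupancy ground-truth occupancy on the same grid.
#' @param pack the generating [BeadPack-class].
#' @param nBeads number of bead ROIs.
#' @param seed seed for bead selection.
#' @return A [MaterialPair-class].
#' @export
calibratePhantom <- function(hu, occupancy, pack, nBeads = 10, seed = 1L) {
  rois <- autoCalibrationROIs(occupancy, pack, nBeads = nBeads, seed = seed)
  calibrateMaterials(hu, rois$background, rois$objects, occupancy = occupancy)
}

#' Named acquisition variations of the robustness grid
#'
#' The full variation set of the robustness study: standard axial 5 mm
#' reconstruction, thinner slices, quadrupled noise, edge-enhancing kernel,
#' coronal/sagittal reformats, pixel coarsening emulating 30 and 50 cm
#' reconstruction FOVs (x30/14 and x50/14 the native pixel), and a doubled
#' mixture ROI.
#'
#' @return Named list of variation descriptors (fields `thicknessMm`,
#'   `noiseSdHu`, `plane`, `kernel`, `pixelFactor`, `roiFactor`).
#' @export
defaultVariations <- function() {
  v <- function(thicknessMm = 5, noiseSdHu = 4.6, plane = "axial",
                kernel = "standard", pixelFactor = 1, roiFactor = 1)
    list(thicknessMm = thicknessMm, noiseSdHu = noiseSdHu, plane = plane,
         kernel = kernel, pixelFactor = pixelFactor, roiFactor = roiFactor)
  list(standard = v(),
       thin_0.625mm = v(thicknessMm = 0.625),
       mid_2.5mm = v(thicknessMm = 2.5),
       high_noise = v(noiseSdHu = 22.3),
       edge_kernel = v(kernel = "edge_enhanced"),
       coronal = v(plane = "coronal"),
       sagittal = v(plane = "sagittal"),
       fov_30cm = v(pixelFactor = 30 / 14),
       fov_50cm = v(pixelFactor = 50 / 14),
       roi_doubled = v(roiFactor = 2))
}

#' Experiment grid definition
#'
#' Bundles everything one robustness run needs: acquisition config, phantom
#' scale, replicate seeds and the variation set. `quick = TRUE` uses a
#' reduced phantom (120 beads in a 42 x 42 x 30 mm box) that keeps the full
#' grid within a few CPU-minutes; `quick = FALSE` uses the full 750-bead
#' pack in a 70 x 70 x 45 mm box.
#'
#' @param config an [AcquisitionConfig-class].
#' @param seeds integer replicate seeds (one phantom + noise realization
#'   each).
#' @param variations named list as [defaultVariations].
#' @param quick logical: reduced phantom scale.
#' @param countTarget,container override the phantom scale directly.
#' @param marginMm mixture-ROI margin (mm).
#' @param padMm background (jelly) rim simulated around the bead container
#'   (mm). The default leaves enough surrounding material for the
#'   doubled-ROI variation to grow into.
#' @return list of class `"experimentGrid"`.
#' @export
experimentGrid <- function(config = acquisitionConfig(), seeds = 1:3,
                           variations = defaultVariations(), quick = TRUE,
                           countTarget = NULL, container = NULL,
                           marginMm = 2, padMm = 14) {
  if (is.null(countTarget)) countTarget <- if (quick) 120L else 750L
  if (is.null(container))
    container <- if (quick) c(42, 42, 30) else c(70, 70, 45)
  if (length(seeds) < 1L) stop("at least one replicate seed is required")
  if (is.null(names(variations)) || any(names(variations) == ""))
    stop("variations must be a named list")
  structure(list(config = config, seeds = as.integer(seeds),
                 variations = variations, countTarget = countTarget,
                 container = container, marginMm = marginMm, padMm = padMm),
            class = "experimentGrid")
}

# Derive a sub-seed for one (replicate, stage) pair; stays within 32-bit int.
.subSeed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483647)
}

#' Apply one acquisition variation to a native simulated volume
#'
#' Transforms the noise-free native thin-slice volume (and its occupancy
#' ground truth) into the reconstructed variant: optional edge-enhancing
#' kernel, pixel coarsening, reformat plane, reslicing to the target
#' thickness (nearest achievable integer multiple of the native spacing
#' along the stacking axis), then additive noise.
#'
#' @param hu noise-free native [CTVolume-class].
#' @param occupancy matching occupancy [CTVolume-class].
#' @param variation one descriptor from [defaultVariations].
#' @param config the [AcquisitionConfig-class] (kernel parameters, pixel
#'   size).
#' @param noiseSeed seed for the noise stage.
#' @return list `hu`, `occupancy` (transformed) and `thicknessMm` achieved.
#' @export
applyVariation <- function(hu, occupancy, variation,
                           config = acquisitionConfig(), noiseSeed = 1L) {
  if (identical(variation$kernel, "edge_enhanced"))
    hu <- edgeEnhance(hu, config@kernelStrength, config@kernelRadiusMm)
  if (variation$pixelFactor > 1) {
    target <- variation$pixelFactor * config@pixelMm
    hu <- resamplePixels(hu, target)
    occupancy <- resamplePixels(occupancy, target)
  }
  if (variation$plane != "axial") {
    hu <- reformat(hu, variation$plane)
    occupancy <- reformat(occupancy, variation$plane)
  }
  dz <- voxelSpacing(hu)[3]
  th <- max(1, round(variation$thicknessMm / dz)) * dz
  hu <- reslice(hu, th)
  occupancy <- reslice(occupancy, th)
  hu <- addNoise(hu, variation$noiseSdHu, noiseSeed)
  list(hu = hu, occupancy = occupancy, thicknessMm = th)
}

#' Run the robustness experiment grid
#'
#' For every replicate seed: pack beads, voxelize the native thin-slice
#' volume, calibrate material densities on the (noisy) thin slices, then for
#' every variation apply the acquisition transform, build mixture ROIs,
#' measure, invert and integrate, and score against the pack's analytic
#' volume. Calibration for the edge-enhanced kernel variant is redone on the
#' kernel-filtered thin slices, mirroring how densities would be re-measured
#' on such a reconstruction. Fully deterministic given the seeds.
#'
#' @param grid an [experimentGrid].
#' @return data.frame with one row per variation: mean volume, mean signed
#'   relative error, its SD over replicates, achieved thickness and replicate
#'   count. Per-replicate detail is attached as `attr(, "replicates")` and
#'   provenance (seeds, bead counts, analytic volumes) as
#'   `attr(, "provenance")`.
#' @export
runExperimentGrid <- function(grid) {
  stopifnot(inherits(grid, "experimentGrid"))
  cfg <- grid$config
  detail <- list()
  prov <- list(seeds = grid$seeds, countTarget = grid$countTarget,
               container = grid$container, beads = integer(0),
               analytic_cm3 = numeric(0))
  for (s in grid$seeds) {
    pack <- packBeads(grid$countTarget, grid$container, seed = s)
    vox <- voxelize(pack, cfg,
                    grid = gridSpec(pack, pixelMm = cfg@pixelMm,
                                    thinSliceMm = cfg@thinSliceMm,
                                    padMm = grid$padMm))
    truth <- analyticVolume(pack)
    prov$beads <- c(prov$beads, length(pack))
    prov$analytic_cm3 <- c(prov$analytic_cm3, truth)
    # density calibration on noisy thin slices (per replicate)
    calStd <- calibratePhantom(addNoise(vox$hu, cfg@noiseSdHu,
                                        .subSeed(s, 1L)),
                               vox$occupancy, pack, seed = s)
    calEdge <- NULL
    for (vi in seq_along(grid$variations)) {
      vname <- names(grid$variations)[vi]
      vr <- grid$variations[[vi]]
      materials <- calStd
      if (identical(vr$kernel, "edge_enhanced")) {
        if (is.null(calEdge)) {
          enhanced <- edgeEnhance(vox$hu, cfg@kernelStrength,
                                  cfg@kernelRadiusMm)
          calEdge <- calibratePhantom(addNoise(enhanced, cfg@noiseSdHu,
                                               .subSeed(s, 2L)),
                                      vox$occupancy, pack, seed = s)
        }
        materials <- calEdge
      }
      acq <- applyVariation(vox$hu, vox$occupancy, vr, cfg,
                            noiseSeed = .subSeed(s, 10L + vi))
      res <- phantomVolumetry(acq$hu, acq$occupancy, materials,
                              marginMm = grid$marginMm,
                              areaFactor = vr$roiFactor)
      detail[[length(detail) + 1L]] <- data.frame(
        variation = vname, seed = s, volume_cm3 = volumeCm3(res),
        analytic_cm3 = truth,
        relative_error_pct = relativeError(volumeCm3(res), truth),
        thickness_mm = acq$thicknessMm,
        out_of_range_slices = outOfRangeSlices(res))
    }
  }
  detail <- do.call(rbind, detail)
  agg <- do.call(rbind, lapply(split(detail, detail$variation), function(d) {
    data.frame(variation = d$variation[1],
               mean_volume_cm3 = mean(d$volume_cm3),
               mean_relative_error_pct = mean(d$relative_error_pct),
               sd_relative_error_pct = if (nrow(d) > 1) sd(d$relative_error_pct) else NA_real_,
               thickness_mm = d$thickness_mm[1],
               n_replicates = nrow(d))
  }))
  agg <- agg[match(names(grid$variations), agg$variation), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- detail
  attr(agg, "provenance") <- prov
  agg
}
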