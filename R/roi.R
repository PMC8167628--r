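# Region-of-interest construction: freehand-like mixture ROIs from ground
# truth, area scaling, polygon rasterization and calibration ROIs.

# Binary dilation by a metric radius: the structuring element is the set of
# pixel offsets whose physical displacement is within marginMm, so the
# dilation is correct for anisotropic in-plane spacing (e.g. reformatted
# planes). Implemented as shift-OR over the offset set.
.dilateMm <- function(mask, marginMm, dx, dy) {
  if (marginMm <= 0) return(mask)
  hi <- floor(marginMm / dx)
  hj <- floor(marginMm / dy)
  out <- mask
  n <- nrow(mask); m <- ncol(mask)
  for (di in -hi:hi) {
    if (abs(di) >= n) next
    for (dj in -hj:hj) {
      if (abs(dj) >= m) next
      if ((di == 0 && dj == 0) || (di * dx)^2 + (dj * dy)^2 > marginMm^2) next
      ti <- max(1L, 1L + di):min(n, n + di)
      tj <- max(1L, 1L + dj):min(m, m + dj)
      out[ti, tj] <- out[ti, tj] | mask[ti - di, tj - dj]
    }
  }
  out
}

.touchesEdge <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

#' Automatic mixture ROI for one slice
#'
#' Emulates the freehand mixture ROI: the slice's object support (ground
#' truth occupancy > 0) dilated by a metric margin, so the ROI contains every
#' object pixel of the slice plus a rim of pure background — the construction
#' the mixture inversion requires. An ROI reaching the grid edge would leak
#' outside the phantom and is an error.
#'
#' @param occupancy ground-truth occupancy [CTVolume-class].
#' @param sliceIndex 1-based slice index.
#' @param marginMm background rim width (mm); 0 gives the exact object
#'   support.
#' @return A [SliceROI-class] of kind `"mixture"`.
#' @export
autoMixtureROI <- function(occupancy, sliceIndex, marginMm = 2) {
  stopifnot(is(occupancy, "CTVolume"))
  d <- dim(occupancy@values)
  if (sliceIndex < 1L || sliceIndex > d[3]) stop("slice index out of range")
  support <- occupancy@values[, , sliceIndex] > 0
  if (!any(support))
    stop("slice ", sliceIndex, " contains no object; cannot build a mixture ROI")
  mask <- .dilateMm(support, marginMm, occupancy@spacing[1],
                    occupancy@spacing[2])
  if (.touchesEdge(mask))
    stop("mixture ROI touches the grid edge on slice ", sliceIndex,
         "; it would include pixels outside the phantom")
  sliceROI(sliceIndex, mask, "mixture")
}

#' Enlarge an ROI into background-only area
#'
#' Grows the ROI by repeated one-pixel dilation steps, accepting only pixels
#' that are pure background in the ground truth and not on the grid edge,
#' until the raster area reaches `areaFactor` times the original. Emulates
#' drawing a deliberately oversized mixture ROI. The factor actually achieved
#' (the dilation step granularity overshoots slightly) is stored in the
#' result's `achievedFactor` slot.
#'
#' @param roi a [SliceROI-class].
#' @param areaFactor target area ratio (>= 1; 1 returns `roi` unchanged).
#' @param occupancy ground-truth occupancy [CTVolume-class].
#' @return A [SliceROI-class] with the enlarged mask.
#' @export
scaleROI <- function(roi, areaFactor, occupancy) {
  stopifnot(is(roi, "SliceROI"), is(occupancy, "CTVolume"))
  if (!is.finite(areaFactor) || areaFactor < 1)
    stop("areaFactor must be >= 1")
  if (areaFactor == 1) return(roi)
  occSlice <- occupancy@values[, , roi@sliceIndex]
  if (!all(dim(occSlice) == dim(roi@mask)))
    stop("occupancy grid does not match the ROI raster")
  mask <- roi@mask
  a0 <- sum(mask)
  n <- nrow(mask); m <- ncol(mask)
  while (sum(mask) < areaFactor * a0) {
    grown <- .dilateMm(mask, 1, 1, 1)  # one-pixel euclidean step
    grown <- mask | (grown & !mask & occSlice == 0)
    grown[c(1, n), ] <- mask[c(1, n), ]
    grown[, c(1, m)] <- mask[, c(1, m)]
    if (sum(grown) == sum(mask))
      stop("cannot reach area factor ", areaFactor,
           " without leaving the phantom")
    mask <- grown
  }
  out <- sliceROI(roi@sliceIndex, mask, roi@kind)
  out@achievedFactor <- sum(mask) / a0
  out
}

#' Rasterize a polygon to a pixel mask
#'
#' Even-odd (crossing-number) rule on pixel centres: a pixel belongs to the
#' ROI iff its centre lies inside the closed polygon. Deterministic; vertices
#' are in mm, in the in-plane coordinate frame of the target grid.
#'
#' @param polygon n x 2 matrix of vertices (mm), closed ring (a repeated
#'   final vertex is tolerated and dropped).
#' @param dim integer(2) in-plane grid dimensions.
#' @param spacing numeric(2) in-plane pixel size (mm).
#' @param origin numeric(2) mm position of the grid's lower corner.
#' @return Logical `dim[1]` x `dim[2]` matrix.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' sum(rasterizePolygon(sq, c(12, 12), c(1, 1)))  # 100 pixels
#' @export
rasterizePolygon <- function(polygon, dim, spacing = c(1, 1),
                             origin = c(0, 0)) {
  polygon <- rbind(polygon)
  if (nrow(polygon) >= 2 && all(polygon[1, ] == polygon[nrow(polygon), ]))
    polygon <- polygon[-nrow(polygon), , drop = FALSE]
  if (nrow(polygon) < 3) stop("polygon needs at least 3 distinct vertices")
  xc <- origin[1] + (seq_len(dim[1]) - 0.5) * spacing[1]
  yc <- origin[2] + (seq_len(dim[2]) - 0.5) * spacing[2]
  X <- matrix(xc, dim[1], dim[2])
  Y <- matrix(yc, dim[1], dim[2], byrow = TRUE)
  crossings <- matrix(0L, dim[1], dim[2])
  nv <- nrow(polygon)
  for (e in seq_len(nv)) {
    p1 <- polygon[e, ]; p2 <- polygon[if (e == nv) 1L else e + 1L, ]
    straddles <- (p1[2] > Y) != (p2[2] > Y)
    if (!any(straddles)) next
    xint <- p1[1] + (Y - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2])
    crossings <- crossings + (straddles & X < xint)
  }
  crossings %% 2L == 1L
}

#' ROI from a polygon
#'
#' Convenience wrapper rasterizing an in-plane polygon onto a volume's grid.
#'
#' @param polygon n x 2 vertex matrix (mm).
#' @param sliceIndex 1-based slice index.
#' @param volume the target [CTVolume-class] (supplies grid and origin).
#' @param kind ROI role.
#' @return A [SliceROI-class].
#' @export
polygonROI <- function(polygon, sliceIndex, volume, kind = "mixture") {
  d <- dim(volume@values)
  mask <- rasterizePolygon(polygon, d[1:2], volume@spacing[1:2],
                           volume@origin[1:2])
  sliceROI(sliceIndex, mask, kind)
}

#' Per-slice ROIs from a binary mask volume
#'
#' Converts a label/mask volume (nonzero = inside) on the same grid as the
#' image into one [SliceROI-class] per slice that contains any masked voxel
#' — the raster counterpart of polygon ROI input.
#'
#' @param maskVolume a [CTVolume-class] whose nonzero voxels mark the ROIs.
#' @param kind ROI role assigned to every slice.
#' @return list of [SliceROI-class].
#' @export
maskROIs <- function(maskVolume, kind = "mixture") {
  stopifnot(is(maskVolume, "CTVolume"))
  m <- maskVolume@values != 0
  withMask <- which(apply(m, 3, any))
  if (length(withMask) == 0L) stop("mask volume is empty")
  lapply(withMask, function(k) sliceROI(k, m[, , k], kind))
}

#' Automatic calibration ROIs from ground truth
#'
#' Builds the density-calibration ROIs the workstation procedure uses: one
#' large square ROI (about `bgAreaMm2`) on a background-only slice, and small
#' discs fully interior to `nBeads` randomly chosen beads, each on the slice
#' where that bead's cross-section is largest. Disc radii are capped at 0.58
#' of the bead radius (roughly 1/3 of the cross-section area) and shrunk so
#' that every covered voxel, over its full footprint including slice
#' thickness, lies inside the bead — on a noise-free volume these ROIs read
#' the pure material densities exactly.
#'
#' @param occupancy ground-truth occupancy [CTVolume-class] (thin-slice
#'   grid).
#' @param pack the [BeadPack-class] that generated the volume.
#' @param nBeads number of bead ROIs (default 10).
#' @param bgAreaMm2 background ROI area (mm^2).
#' @param seed seed for the random bead selection.
#' @return list with elements `background` ([SliceROI-class]) and `objects`
#'   (list of [SliceROI-class]).
#' @export
autoCalibrationROIs <- function(occupancy, pack, nBeads = 10,
                                bgAreaMm2 = 1000, seed = 1L) {
  stopifnot(is(occupancy, "CTVolume"), is(pack, "BeadPack"))
  d <- dim(occupancy@values)
  sp <- occupancy@spacing
  org <- occupancy@origin
  dz <- sp[3]
  rdiag <- sqrt(sp[1]^2 + sp[2]^2) / 2

  # beads large enough for an interior disc of a few pixels
  eligible <- which(pack@radii >= 1.5)
  if (length(eligible) < nBeads)
    stop("not enough sufficiently large beads for calibration")
  pick <- withr::with_seed(as.integer(seed),
                           sample(eligible, nBeads))
  xc <- org[1] + (seq_len(d[1]) - 0.5) * sp[1]
  yc <- org[2] + (seq_len(d[2]) - 0.5) * sp[2]
  objects <- lapply(pick, function(b) {
    ctr <- pack@centers[b, ]
    r <- pack@radii[b]
    k <- max(1L, min(d[3], round((ctr[3] - org[3]) / dz + 0.5)))
    zext <- abs(ctr[3] - (org[3] + (k - 0.5) * dz)) + dz / 2
    rin <- sqrt(max(r^2 - zext^2, 0)) - rdiag
    roiR <- min(0.58 * r, rin)
    if (roiR <= max(sp[1:2]))
      stop("bead ", b, " too small for an interior calibration ROI")
    mask <- outer((xc - ctr[1])^2, (yc - ctr[2])^2, `+`) <= roiR^2
    sliceROI(k, mask, "object_cal")
  })

  # background square on the first fully object-free slice from the top
  side <- sqrt(bgAreaMm2)
  hx <- ceiling(side / sp[1] / 2); hy <- ceiling(side / sp[2] / 2)
  ci <- round(d[1] / 2); cj <- round(d[2] / 2)
  bg <- NULL
  for (k in rev(seq_len(d[3]))) {
    if (any(occupancy@values[, , k] > 0)) next
    mask <- matrix(FALSE, d[1], d[2])
    mask[(ci - hx):(ci + hx), (cj - hy):(cj + hy)] <- TRUE
    bg <- sliceROI(k, mask, "background_cal")
    break
  }
  if (is.null(bg))
    stop("no background-only slice available for the calibration ROI")
  list(background = bg, objects = objects)
}
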