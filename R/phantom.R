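# Digital bead-in-jelly phantom: sphere packing, partial-volume voxelization
# and the acquisition emulation (reslicing, noise, kernel, reformats, pixel
# coarsening).

#' Default bead diameter mixture
#'
#' Discrete diameter distribution of the simulated PMMA beads. Diameters span
#' 3.2-6.4 mm; the weights are skewed toward the small end so that a
#' 750-bead pack has an analytic volume close to 35.5 cm^3 (a uniform
#' diameter distribution over the same range would give about 48 cm^3).
#' Ground truth is always the analytic sphere-volume sum of the realized
#' pack, never the nominal 35.5.
#'
#' @return data.frame with columns `diameter_mm` and `weight`.
#' @export
defaultBeadMix <- function() {
  data.frame(diameter_mm = c(3.2, 4.0, 4.8, 5.6, 6.4),
             weight = c(0.32, 0.30, 0.20, 0.11, 0.07))
}

#' Pack non-overlapping spheres into a box
#'
#' Random sequential addition with a gravity-like settling bias: candidate
#' centres are drawn biased toward the lower centre of the container
#' (emulating beads resting in a concave scoop of jelly), and a candidate is
#' accepted when it overlaps no previously placed sphere (tangency within
#' 1e-6 mm is allowed). Larger beads are placed first. Deterministic given
#' the seed.
#'
#' @param countTarget number of spheres to attempt (>= 1).
#' @param container numeric(3) box side lengths (mm) or a 2 x 3 lo/hi matrix.
#' @param seed integer seed.
#' @param mix diameter distribution, as [defaultBeadMix].
#' @param diameterRange allowed diameter range (mm); the mix must lie inside
#'   it and inside the container.
#' @param attemptsPerBead placement attempts per sphere before it is skipped.
#' @return A [BeadPack-class] with at most `countTarget` spheres.
#'   Fewer than 50% placed is an error (container too small).
#' @examples
#' p <- packBeads(20, container = c(30, 30, 20), seed = 1)
#' length(p)
#' @export
packBeads <- function(countTarget = 750, container = c(70, 70, 45), seed = 1L,
                      mix = defaultBeadMix(), diameterRange = c(3.2, 6.4),
                      attemptsPerBead = 400L) {
  if (countTarget < 1L) stop("countTarget must be >= 1")
  if (is.null(dim(container))) container <- rbind(c(0, 0, 0), as.numeric(container))
  lo <- container[1, ]; hi <- container[2, ]; size <- hi - lo
  if (any(mix$diameter_mm < diameterRange[1] - 1e-9) ||
      any(mix$diameter_mm > diameterRange[2] + 1e-9))
    stop("diameter mix outside diameterRange")
  if (max(mix$diameter_mm) >= min(size))
    stop("largest diameter does not fit in the container")

  res <- withr::with_seed(as.integer(seed), {
    d <- sample(mix$diameter_mm, countTarget, replace = TRUE,
                prob = mix$weight)
    d <- sort(d, decreasing = TRUE)  # large first packs better
    centers <- matrix(NA_real_, countTarget, 3)
    radii <- numeric(countTarget)
    nPlaced <- 0L
    mid <- (lo + hi) / 2
    for (b in seq_len(countTarget)) {
      r <- d[b] / 2
      for (a in seq_len(attemptsPerBead)) {
        # radially centre-biased in-plane, settling bias along z
        x <- mid[1] + (size[1] / 2 - r) * (2 * runif(1) - 1) * sqrt(runif(1))
        y <- mid[2] + (size[2] / 2 - r) * (2 * runif(1) - 1) * sqrt(runif(1))
        z <- lo[3] + r + (size[3] - 2 * r) * runif(1)^1.5
        if (nPlaced > 0L) {
          dd2 <- (centers[seq_len(nPlaced), 1] - x)^2 +
                 (centers[seq_len(nPlaced), 2] - y)^2 +
                 (centers[seq_len(nPlaced), 3] - z)^2
          if (any(dd2 < (radii[seq_len(nPlaced)] + r - 1e-6)^2)) next
        }
        nPlaced <- nPlaced + 1L
        centers[nPlaced, ] <- c(x, y, z)
        radii[nPlaced] <- r
        break
      }
    }
    list(centers = centers[seq_len(nPlaced), , drop = FALSE],
         radii = radii[seq_len(nPlaced)])
  })
  if (nrow(res$centers) < countTarget / 2)
    stop("packing failed: placed ", nrow(res$centers), " of ", countTarget,
         " spheres; use a larger container")
  beadPack(res$centers, res$radii, container, seed = seed)
}

#' Analytic total sphere volume of a pack
#'
#' \eqn{\sum_i \frac{4}{3}\pi r_i^3 / 1000} in cm^3 — the simulation ground
#' truth standing in for the physical pack's water-displacement volume.
#'
#' @param pack a [BeadPack-class].
#' @return Volume in cm^3.
#' @examples
#' analyticVolume(beadPack(matrix(c(5, 5, 5), 1), 5, c(10, 10, 10)))
#' @export
analyticVolume <- function(pack) {
  stopifnot(is(pack, "BeadPack"))
  sum(4 / 3 * pi * pack@radii^3) / 1000
}

#' Grid specification covering a bead pack
#'
#' Builds the voxel grid used by [voxelize]: the container plus a padding rim
#' of background, centred, with plane dimensions rounded up to a multiple of
#' `roundXY` and slices to a multiple of `roundZ` so that downstream block
#' averaging (reslicing to 2.5 / 5 mm, reformat reslicing) divides evenly.
#'
#' @param pack a [BeadPack-class].
#' @param pixelMm in-plane pixel size (mm).
#' @param thinSliceMm native slice spacing (mm).
#' @param padMm background padding around the container (mm).
#' @param roundXY,roundZ round grid dimensions up to these multiples.
#' @return list with `dim`, `spacing`, `origin`.
#' @export
gridSpec <- function(pack, pixelMm = 140 / 512, thinSliceMm = 0.625,
                     padMm = 2, roundXY = 18L, roundZ = 8L) {
  lo <- pack@container[1, ] - padMm
  hi <- pack@container[2, ] + padMm
  ctr <- (lo + hi) / 2
  sp <- c(pixelMm, pixelMm, thinSliceMm)
  rnd <- c(roundXY, roundXY, roundZ)
  n <- pmax(rnd, rnd * ceiling(ceiling((hi - lo) / sp) / rnd))
  list(dim = as.integer(n), spacing = sp, origin = ctr - n * sp / 2)
}

#' Voxelize a bead pack into HU and occupancy grids
#'
#' Computes per-voxel occupancy (fraction of the voxel inside any sphere) by
#' regular sub-voxel sampling at `supersampling`^3 points, then maps it to
#' density by the two-material weighted average
#' \eqn{HU = o \cdot HU_{obj} + (1 - o) \cdot HU_{bkg}}. Noise-free; the
#' background material fills the whole grid outside the spheres.
#'
#' @param pack a [BeadPack-class].
#' @param config an [AcquisitionConfig-class].
#' @param grid grid specification from [gridSpec]; defaults to one derived
#'   from the pack's container and the config's pixel/slice sizes.
#' @return list with elements `hu` and `occupancy`, both [CTVolume-class].
#' @export
voxelize <- function(pack, config = acquisitionConfig(), grid = NULL) {
  stopifnot(is(pack, "BeadPack"), is(config, "AcquisitionConfig"))
  if (is.null(grid))
    grid <- gridSpec(pack, pixelMm = config@pixelMm,
                     thinSliceMm = config@thinSliceMm)
  gLo <- grid$origin
  gHi <- grid$origin + grid$dim * grid$spacing
  for (a in 1:3)
    if (any(pack@centers[, a] - pack@radii < gLo[a] - 1e-9) ||
        any(pack@centers[, a] + pack@radii > gHi[a] + 1e-9))
      stop("spheres extend outside the voxel grid; enlarge the grid")
  occ <- cpp_sphere_occupancy(grid$dim, grid$spacing, grid$origin,
                              pack@centers, pack@radii,
                              as.integer(config@supersampling))
  occ <- pmin(occ, 1)
  dim(occ) <- grid$dim
  hu <- config@huObject * occ + config@huBackground * (1 - occ)
  list(hu = CTVolume(hu, grid$spacing, grid$origin),
       occupancy = CTVolume(occ, grid$spacing, grid$origin))
}

#' Reslice a volume to a thicker slice spacing
#'
#' Non-overlapping mean over consecutive native slices along the stacking
#' axis. The target thickness must be an integer multiple of the native
#' spacing and the slice count must divide evenly (no slice-sensitivity
#' profile is modelled); the volume-wide mean is preserved exactly.
#'
#' @param volume a [CTVolume-class].
#' @param newThicknessMm target slice thickness (mm).
#' @return A [CTVolume-class] with updated spacing.
#' @export
reslice <- function(volume, newThicknessMm) {
  stopifnot(is(volume, "CTVolume"))
  dz <- volume@spacing[3]
  k <- round(newThicknessMm / dz)
  if (k < 1 || abs(k * dz - newThicknessMm) > 1e-6 * newThicknessMm)
    stop("new thickness must be an integer multiple of the native slice spacing (",
         signif(dz, 6), " mm)")
  if (k == 1) return(volume)
  d <- dim(volume@values)
  if (d[3] %% k != 0L)
    stop("slice count (", d[3], ") is not divisible by the averaging factor (",
         k, ")")
  nzo <- d[3] %/% k
  m <- volume@values
  dim(m) <- c(d[1] * d[2], d[3])
  out <- matrix(0, d[1] * d[2], nzo)
  for (j in seq_len(nzo))
    out[, j] <- rowMeans(m[, ((j - 1) * k + 1):(j * k), drop = FALSE])
  CTVolume(array(out, c(d[1], d[2], nzo)),
           spacing = c(volume@spacing[1:2], dz * k), origin = volume@origin)
}

#' Add Gaussian white noise
#'
#' Adds zero-mean i.i.d. Gaussian noise per voxel, deterministic given the
#' seed. Real CT noise is spatially correlated and kernel-shaped; white noise
#' is a documented simplification. `sdHu = 0` returns the input unchanged.
#'
#' @param volume a [CTVolume-class].
#' @param sdHu noise SD (HU, >= 0).
#' @param seed integer seed.
#' @return A [CTVolume-class].
#' @export
addNoise <- function(volume, sdHu, seed = 1L) {
  stopifnot(is(volume, "CTVolume"))
  if (!is.finite(sdHu) || sdHu < 0) stop("sdHu must be >= 0")
  if (sdHu == 0) return(volume)
  n <- length(volume@values)
  noise <- withr::with_seed(as.integer(seed), rnorm(n, 0, sdHu))
  CTVolume(volume@values + array(noise, dim(volume@values)),
           spacing = volume@spacing, origin = volume@origin)
}

# Row-renormalized truncated Gaussian smoothing matrix: rows sum to exactly 1
# (after renormalization) so a constant field is reproduced, including at the
# edges.
.gaussBand <- function(n, sigmaPx) {
  h <- max(1L, ceiling(3 * sigmaPx))
  w <- dnorm(seq(-h, h), sd = sigmaPx)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    kk <- w[j - i + h + 1L]
    K[i, j] <- kk / sum(kk)
  }
  K
}

#' Emulate an edge-enhancing reconstruction kernel
#'
#' In-plane unsharp mask: `out = in + strength * (in - blur(in))` with a
#' separable Gaussian blur of the given radius. Flat regions are preserved
#' exactly; overshoot/undershoot at material boundaries is the intended
#' emulation of how sharp ("Lung"-type) kernels alter CT numbers near edges.
#'
#' @param volume a [CTVolume-class].
#' @param strength unsharp-mask gain (>= 0; 0 = identity).
#' @param radiusMm Gaussian blur sigma in mm (applied per in-plane axis, so
#'   anisotropic pixels are handled in metric units).
#' @return A [CTVolume-class].
#' @export
edgeEnhance <- function(volume, strength = 1.5, radiusMm = 0.8) {
  stopifnot(is(volume, "CTVolume"))
  if (!is.finite(strength) || strength < 0) stop("strength must be >= 0")
  if (strength == 0) return(volume)
  d <- dim(volume@values)
  Kx <- .gaussBand(d[1], radiusMm / volume@spacing[1])
  KyT <- t(.gaussBand(d[2], radiusMm / volume@spacing[2]))
  out <- volume@values
  for (k in seq_len(d[3])) {
    s <- volume@values[, , k]
    out[, , k] <- s + strength * (s - Kx %*% s %*% KyT)
  }
  CTVolume(out, spacing = volume@spacing, origin = volume@origin)
}

#' Multiplanar reformat
#'
#' Transposes the volume so that the chosen anatomical plane becomes the
#' slicing plane (axis 3), optionally followed by [reslice] to the output
#' thickness. Pure axis permutation: values are untouched, so the global mean
#' is preserved exactly. Applying `coronal` twice returns the original
#' volume; `sagittal` is a cyclic permutation (three applications return the
#' original).
#'
#' @param volume a [CTVolume-class] (normally the thin-slice stack).
#' @param plane `"coronal"` or `"sagittal"`.
#' @param outThicknessMm optional output slice thickness (mm) along the new
#'   stacking axis; must be an integer multiple of the new native spacing.
#' @return A [CTVolume-class].
#' @export
reformat <- function(volume, plane = c("coronal", "sagittal"),
                     outThicknessMm = NULL) {
  stopifnot(is(volume, "CTVolume"))
  plane <- match.arg(plane)
  perm <- if (plane == "coronal") c(1, 3, 2) else c(2, 3, 1)
  out <- CTVolume(aperm(volume@values, perm),
                  spacing = volume@spacing[perm], origin = volume@origin[perm])
  if (!is.null(outThicknessMm)) out <- reslice(out, outThicknessMm)
  out
}

# 1-D area-overlap weights mapping nOld cells of width dOld onto nNew equal
# cells spanning the same extent; rows sum to 1, columns to dOld/dNew.
.overlapWeights <- function(nOld, dOld, nNew) {
  dNew <- nOld * dOld / nNew
  W <- matrix(0, nNew, nOld)
  for (i in seq_len(nNew)) {
    a <- (i - 1) * dNew; b <- i * dNew
    j0 <- max(1L, floor(a / dOld + 1e-12) + 1L)
    j1 <- min(nOld, ceiling(b / dOld - 1e-12))
    for (j in j0:j1)
      W[i, j] <- max(0, min(b, j * dOld) - max(a, (j - 1) * dOld)) / dNew
  }
  W
}

#' Coarsen the in-plane pixel size
#'
#' Area-weighted in-plane averaging onto a coarser pixel grid spanning the
#' same extent, emulating reconstruction at a larger field of view. The new
#' pixel count is `round(extent / newPixelMm)` per axis, so the achieved
#' pixel size may differ slightly from the request; the global mean is
#' preserved. Only coarsening is supported.
#'
#' @param volume a [CTVolume-class].
#' @param newPixelMm requested pixel size (mm, >= native).
#' @return A [CTVolume-class].
#' @export
resamplePixels <- function(volume, newPixelMm) {
  stopifnot(is(volume, "CTVolume"))
  sp <- volume@spacing
  if (newPixelMm < max(sp[1], sp[2]) - 1e-9)
    stop("only coarsening is emulated: new pixel must be >= native (",
         signif(max(sp[1:2]), 6), " mm)")
  d <- dim(volume@values)
  nNewX <- max(1L, round(d[1] * sp[1] / newPixelMm))
  nNewY <- max(1L, round(d[2] * sp[2] / newPixelMm))
  if (nNewX == d[1] && nNewY == d[2]) return(volume)
  Wx <- .overlapWeights(d[1], sp[1], nNewX)
  WyT <- t(.overlapWeights(d[2], sp[2], nNewY))
  out <- array(0, c(nNewX, nNewY, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- Wx %*% volume@values[, , k] %*% WyT
  CTVolume(out, spacing = c(d[1] * sp[1] / nNewX, d[2] * sp[2] / nNewY, sp[3]),
           origin = volume@origin)
}
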