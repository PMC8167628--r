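# Shared in-code fixtures; cached per test file so expensive simulations are
# built once.

.fixtures <- new.env(parent = emptyenv())

trueMaterials <- function() materialPair(119.9, -149.7)

# a small multi-bead phantom on the native thin-slice grid
smallPhantom <- function() {
  if (is.null(.fixtures$small)) {
    pack <- packBeads(40, container = c(30, 30, 20), seed = 7)
    vox <- voxelize(pack, acquisitionConfig(),
                    grid = gridSpec(pack, padMm = 4))
    .fixtures$small <- list(pack = pack, hu = vox$hu, occ = vox$occupancy)
  }
  .fixtures$small
}

# a single r = 5 mm sphere voxelized on a fine isotropic-ish grid
singleSphere <- function(pixelMm = 0.27, thinMm = 0.27, supersampling = 4L) {
  pack <- beadPack(matrix(c(0, 0, 0), 1), 5,
                   rbind(c(-6, -6, -6), c(6, 6, 6)))
  cfg <- acquisitionConfig(supersampling = supersampling)
  grid <- gridSpec(pack, pixelMm = pixelMm, thinSliceMm = thinMm,
                   padMm = 3, roundXY = 1L, roundZ = 1L)
  c(list(pack = pack), voxelize(pack, cfg, grid = grid))
}

# robustness-grid run shared by the axial / reformat accuracy checks:
# standard-scale quick phantom, 3 replicate seeds
accuracyGrid <- function() {
  if (is.null(.fixtures$accuracy)) {
    g <- experimentGrid(seeds = 1:3, quick = TRUE,
                        variations = defaultVariations()[c("standard",
                                                           "coronal",
                                                           "sagittal")])
    .fixtures$accuracy <- runExperimentGrid(g)
  }
  .fixtures$accuracy
}

# uniform background volume
flatVolume <- function(dim = c(20, 20, 4), value = -149.7,
                       spacing = c(0.5, 0.5, 0.625)) {
  CTVolume(array(value, dim), spacing = spacing)
}
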