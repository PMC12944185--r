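# 3D shape descriptors (14 features), computed once per patient image from
# the resampled mask only. Volume is voxel-count based and surface area is
# the exposed-voxel-face area (no surface meshing); axis lengths, Elongation
# and Flatness follow the principal-component definition (4 * sqrt of the
# eigenvalues of the voxel-coordinate covariance).

shapeFeatureNames <- function() c(
  "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "Maximum2DDiameterSlice",
  "Maximum3DDiameter", "MeshVolume", "MinorAxisLength", "Sphericity",
  "SurfaceArea", "SurfaceVolumeRatio", "VoxelVolume"
)

.surfaceVoxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  exposed <- array(0L, dim = d)
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[2:(d[1] + 1) + off[1], 2:(d[2] + 1) + off[2],
              2:(d[3] + 1) + off[3]]
    exposed <- exposed + (core & !nb)
  }
  exposed  # per-voxel count of exposed faces (0 for interior/background)
}

.maxPairDist <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  max(stats::dist(coords))
}

shapeFeatures <- function(mask, spacing) {
  n <- sum(mask)
  stopifnot(n >= 1L)
  vv <- prod(spacing)
  volume <- n * vv

  exposed <- .surfaceVoxels(mask)
  faceAreas <- c(spacing[2] * spacing[3], spacing[2] * spacing[3],
                 spacing[1] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2], spacing[1] * spacing[2])
  # recompute per-direction for anisotropic spacing
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  surfArea <- 0
  for (k in seq_along(offs)) {
    off <- offs[[k]]
    nb <- pad[2:(d[1] + 1) + off[1], 2:(d[2] + 1) + off[2],
              2:(d[3] + 1) + off[3]]
    surfArea <- surfArea + sum(mask & !nb) * faceAreas[k]
  }

  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, `*`)
  # principal axes from the population covariance of voxel centers
  if (n > 1L) {
    cv <- stats::cov(coords) * (n - 1) / n
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])

  surf <- which(exposed > 0, arr.ind = TRUE)
  sc <- sweep(surf - 1, 2, spacing, `*`)
  max3d <- .maxPairDist(sc)
  maxIn <- function(groupCol, keepCols) {
    m <- 0
    for (gval in unique(surf[, groupCol])) {
      sel <- surf[, groupCol] == gval
      m <- max(m, .maxPairDist(sc[sel, keepCols, drop = FALSE]))
    }
    m
  }
  max2dSlice <- maxIn(3L, 1:2)   # axial plane (x, y)
  max2dColumn <- maxIn(2L, c(1, 3))  # coronal plane (x, z)
  max2dRow <- maxIn(1L, 2:3)     # sagittal plane (y, z)

  sphericity <- if (surfArea > 0) (36 * pi * volume^2)^(1 / 3) / surfArea else 0

  c(
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    LeastAxisLength = least,
    MajorAxisLength = major,
    Maximum2DDiameterColumn = max2dColumn,
    Maximum2DDiameterRow = max2dRow,
    Maximum2DDiameterSlice = max2dSlice,
    Maximum3DDiameter = max3d,
    MeshVolume = volume,
    MinorAxisLength = minor,
    Sphericity = sphericity,
    SurfaceArea = surfArea,
    SurfaceVolumeRatio = if (volume > 0) surfArea / volume else 0,
    VoxelVolume = volume
  )
}
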