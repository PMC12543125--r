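# Shape features from the binary VOI mask. The surface is the level-0.5
# isosurface of the padded binary mask under a marching-tetrahedra
# decomposition (each grid cell split into six tetrahedra around its main
# diagonal). Because vertex values are binary, the cut in every tetrahedron
# is the plane {sum of inside barycentric coordinates = 1/2}, giving exact
# closed forms: the inside volume fraction is 1/8, 1/2 or 7/8 by the number
# of inside corners, and the cut area is a fixed multiple of the tetrahedron
# face/diagonal-quad areas, precomputable per spacing.

# 6-tetra decomposition of the unit cell (corner ids 1..8 in x-fastest order:
# 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0) 5=(0,0,1) 6=(1,0,1) 7=(0,1,1)
# 8=(1,1,1)); all tets share the main diagonal 1-8.
TET_CORNERS <- rbind(
  c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8)
)

CELL_CORNER_XYZ <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))

tri_area <- function(a, b, c) {
  u <- b - a
  v <- c - a
  0.5 * sqrt(sum(crossprod_vec(u, v)^2))
}

crossprod_vec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Cut-area lookup: 6 tets x 16 corner configurations (config index
# 1 + b1 + 2 b2 + 4 b3 + 8 b4 over the tet's 4 corners, in TET_CORNERS order).
tet_area_lut <- function(spacing) {
  lut <- matrix(0, 6, 16)
  for (t in 1:6) {
    V <- CELL_CORNER_XYZ[TET_CORNERS[t, ], ] * rep(spacing, each = 4)
    for (cfg in 0:15) {
      b <- as.integer(intToBits(cfg))[1:4]
      s <- sum(b)
      area <- 0
      if (s == 1 || s == 3) {
        apex <- if (s == 1) which(b == 1) else which(b == 0)
        others <- setdiff(1:4, apex)
        # cut triangle = opposite face scaled by 1/2 about the apex
        area <- tri_area(V[others[1], ], V[others[2], ], V[others[3], ]) / 4
      } else if (s == 2) {
        ins <- which(b == 1)
        outs <- which(b == 0)
        p1 <- (V[ins[1], ] + V[outs[1], ]) / 2
        p2 <- (V[ins[1], ] + V[outs[2], ]) / 2
        p3 <- (V[ins[2], ] + V[outs[2], ]) / 2
        p4 <- (V[ins[2], ] + V[outs[1], ]) / 2
        # planar quad: half the cross product of its diagonals
        area <- 0.5 * sqrt(sum(crossprod_vec(p3 - p1, p4 - p2)^2))
      }
      lut[t, cfg + 1] <- area
    }
  }
  lut
}

# Inside-volume fraction of a tetrahedron by number of inside corners.
TET_VOL_FRAC <- c(0, 1 / 8, 1 / 2, 7 / 8, 1)

# Mesh volume and surface area of a binary mask.
mask_mesh <- function(mask, spacing) {
  d <- dim(mask)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  dp <- dim(pad)
  nc <- dp - 1L
  # corner values of every cell, cells indexed over (nc1, nc2, nc3)
  corner <- matrix(0L, prod(nc), 8)
  for (k in 1:8) {
    o <- CELL_CORNER_XYZ[k, ]
    corner[, k] <- as.vector(pad[(1:nc[1]) + o[1], (1:nc[2]) + o[2],
                                 (1:nc[3]) + o[3]])
  }
  ncorners <- rowSums(corner)
  mixed <- which(ncorners > 0 & ncorners < 8)
  vol_cell <- prod(spacing)
  volume <- sum(ncorners == 8) * vol_cell
  area <- 0
  if (length(mixed)) {
    lut <- tet_area_lut(spacing)
    cm <- corner[mixed, , drop = FALSE]
    for (t in 1:6) {
      cfg <- cm[, TET_CORNERS[t, 1]] + 2L * cm[, TET_CORNERS[t, 2]] +
        4L * cm[, TET_CORNERS[t, 3]] + 8L * cm[, TET_CORNERS[t, 4]]
      area <- area + sum(lut[t, cfg + 1])
      volume <- volume + sum(TET_VOL_FRAC[rowSums(cm[, TET_CORNERS[t, ],
                                                     drop = FALSE]) + 1]) *
        vol_cell / 6
    }
  }
  list(volume = volume, area = area)
}

# Largest pairwise distance among border voxel centres, optionally
# restricted to pairs sharing one index (for the per-plane diameters).
max_pairwise <- function(pts, plane_index = NULL) {
  if (nrow(pts) < 2) return(0)
  if (is.null(plane_index)) {
    return(sqrt(max(as.vector(stats::dist(pts))^2, 0)))
  }
  best <- 0
  for (v in unique(plane_index)) {
    sub <- pts[plane_index == v, , drop = FALSE]
    if (nrow(sub) >= 2) best <- max(best, max(stats::dist(sub)))
  }
  best
}

shape_features <- function(mask, spacing) {
  n <- sum(mask)
  if (n == 0) rr_abort("empty mask")
  mesh <- mask_mesh(mask, spacing)
  coords <- arrayInd(which(mask == 1L), dim(mask))
  phys <- sweep(coords, 2, spacing, "*")
  # principal axes from the voxel-centre covariance (physical mm)
  ev <- if (n > 1) {
    sort(pmax(eigen(stats::cov(phys) * (n - 1) / n, symmetric = TRUE,
                    only.values = TRUE)$values, 0), decreasing = TRUE)
  } else {
    c(0, 0, 0)
  }
  # border voxels: any missing 6-neighbour
  lin <- which(mask == 1L)
  border <- rep(FALSE, length(lin))
  d <- dim(mask)
  for (ax in 1:3) {
    for (o in c(-1L, 1L)) {
      nb <- coords
      nb[, ax] <- nb[, ax] + o
      out <- nb[, ax] < 1 | nb[, ax] > d[ax]
      nb[out, ax] <- coords[out, ax]
      nb_lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      border <- border | out | mask[nb_lin] == 0L
    }
  }
  bp <- phys[border, , drop = FALSE]
  if (nrow(bp) == 0) bp <- phys
  vol <- mesh$volume
  sa <- mesh$area
  c(
    MeshVolume = vol,
    VoxelVolume = n * prod(spacing),
    SurfaceArea = sa,
    SurfaceVolumeRatio = if (vol > 0) sa / vol else NA_real_,
    Sphericity = if (sa > 0 && vol > 0) (36 * pi * vol^2)^(1 / 3) / sa else NA_real_,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_,
    Maximum3DDiameter = max_pairwise(bp),
    Maximum2DDiameterSlice = max_pairwise(bp[, 1:2, drop = FALSE],
                                          plane_index = coords[border, 3]),
    Maximum2DDiameterColumn = max_pairwise(bp[, c(1, 3), drop = FALSE],
                                           plane_index = coords[border, 2]),
    Maximum2DDiameterRow = max_pairwise(bp[, 2:3, drop = FALSE],
                                        plane_index = coords[border, 1])
  )
}
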