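# Digital NEMA-IQ-style phantom: six fillable spheres (37..10 mm inner
# diameter) on a 114.4 mm circle, a central low-activity cylindrical "lung"
# insert, and a uniform warm background at a sphere-to-background activity
# ratio of 4:1.

REGION_LABELS <- c("sphere1", "sphere2", "sphere3", "sphere4", "sphere5",
                   "sphere6", "Bckgrnd1R", "Bckgrnd2L", "LungInsert")

#' Phantom geometry and activity specification
#'
#' Defaults describe the standard image-quality phantom: sphere inner
#' diameters 37, 28, 22, 17, 13 and 10 mm with 20 kBq/mL activity, a 5
#' kBq/mL background (4:1 ratio) and a cold central lung insert. Sphere
#' centres sit on a 114.4 mm-diameter circle in the central transaxial
#' plane. Background sample VOIs (37 mm diameter) sit right and left of the
#' insert circle; the lung VOI is a 24 mm sphere at the phantom centre.
#'
#' @param sphere_diameters Sphere inner diameters in mm, strictly decreasing.
#' @param sphere_activity Activity concentration in the spheres, kBq/mL.
#' @param background_activity Background activity, kBq/mL.
#' @param lung_activity Lung-insert activity, kBq/mL.
#' @param field_of_view Transaxial field of view, mm.
#' @param axial_extent Axial coverage, mm.
#' @param lung_diameter Lung-insert cylinder diameter, mm.
#' @param ring_diameter Diameter of the circle the sphere centres lie on, mm.
#' @return A `phantom_spec` list.
#' @examples
#' spec <- phantom_spec()
#' spec$sphere_activity / spec$background_activity  # 4
#' @export
phantom_spec <- function(sphere_diameters = c(37, 28, 22, 17, 13, 10),
                         sphere_activity = 20,
                         background_activity = 5,
                         lung_activity = 0,
                         field_of_view = 600,
                         axial_extent = 180,
                         lung_diameter = 50,
                         ring_diameter = 114.4) {
  if (length(sphere_diameters) > 0) {
    if (any(sphere_diameters <= 0) || is.unsorted(rev(sphere_diameters), strictly = TRUE)) {
      rr_abort("sphere_diameters must be positive and strictly decreasing",
               class = "radiorobust_validation_error")
    }
  }
  n <- length(sphere_diameters)
  ang <- if (n > 0) 2 * pi * (seq_len(n) - 1) / max(n, 1) else numeric()
  r <- ring_diameter / 2
  centres <- cbind(x = r * cos(ang), y = r * sin(ang), z = rep(0, n))
  spec <- list(
    sphere_diameters = sphere_diameters,
    sphere_activity = sphere_activity,
    background_activity = background_activity,
    lung_activity = lung_activity,
    field_of_view = field_of_view,
    axial_extent = axial_extent,
    lung_diameter = lung_diameter,
    sphere_centres = centres,
    background_sample_centres = cbind(x = c(160, -160), y = c(0, 0), z = c(0, 0)),
    background_sample_diameter = 37,
    lung_sample_centre = c(x = 0, y = 0, z = 0),
    lung_sample_diameter = 24
  )
  class(spec) <- "phantom_spec"
  spec
}

# Voxel-centre coordinate vectors for a grid centred on the phantom origin.
grid_coords <- function(field_of_view, axial_extent, matrix_size,
                        slice_thickness) {
  vx <- field_of_view / matrix_size
  nz <- max(1L, round(axial_extent / slice_thickness))
  list(
    x = (seq_len(matrix_size) - (matrix_size + 1) / 2) * vx,
    y = (seq_len(matrix_size) - (matrix_size + 1) / 2) * vx,
    z = (seq_len(nz) - (nz + 1) / 2) * slice_thickness,
    spacing = c(vx, vx, slice_thickness)
  )
}

# Partial-volume fraction of each voxel inside a sphere, computed on the
# sphere's bounding box only. Interior/exterior voxels are classified by the
# voxel circumscribed radius; boundary voxels are supersampled ss^3.
sphere_fractions <- function(gc, centre, radius, ss = 4L) {
  hd <- sqrt(sum((gc$spacing / 2)^2))
  ix <- which(abs(gc$x - centre[1]) <= radius + hd)
  iy <- which(abs(gc$y - centre[2]) <= radius + hd)
  iz <- which(abs(gc$z - centre[3]) <= radius + hd)
  if (!length(ix) || !length(iy) || !length(iz)) {
    return(NULL)
  }
  d2 <- outer(outer((gc$x[ix] - centre[1])^2, (gc$y[iy] - centre[2])^2, "+"),
              (gc$z[iz] - centre[3])^2, "+")
  d <- sqrt(d2)
  frac <- array(0, dim(d))
  frac[d <= radius - hd] <- 1
  bnd <- which(d > radius - hd & d < radius + hd)
  if (length(bnd)) {
    sub <- ((seq_len(ss) - 0.5) / ss - 0.5)
    offs <- as.matrix(expand.grid(sub * gc$spacing[1], sub * gc$spacing[2],
                                  sub * gc$spacing[3]))
    idx <- arrayInd(bnd, dim(d))
    cx <- gc$x[ix][idx[, 1]] - centre[1]
    cy <- gc$y[iy][idx[, 2]] - centre[2]
    cz <- gc$z[iz][idx[, 3]] - centre[3]
    r2 <- radius^2
    cnt <- numeric(length(bnd))
    for (k in seq_len(nrow(offs))) {
      cnt <- cnt + ((cx + offs[k, 1])^2 + (cy + offs[k, 2])^2 +
                      (cz + offs[k, 3])^2 <= r2)
    }
    frac[bnd] <- cnt / nrow(offs)
  }
  list(ix = ix, iy = iy, iz = iz, frac = frac)
}

check_inside_grid <- function(gc, centre, radius, what) {
  half_x <- abs(gc$x[1]) + gc$spacing[1] / 2
  half_z <- abs(gc$z[1]) + gc$spacing[3] / 2
  if (abs(centre[1]) + radius > half_x || abs(centre[2]) + radius > half_x ||
      abs(centre[3]) + radius > half_z) {
    rr_abort(sprintf("%s (radius %.1f mm) extends outside the image grid", what, radius),
             class = "radiorobust_geometry_error")
  }
}

#' Rasterize the noise-free phantom activity map
#'
#' Builds the ideal activity-concentration volume for a phantom on the
#' requested grid: background activity everywhere, sphere activity inside
#' each sphere insert, lung activity inside the central cylinder. Sphere and
#' cylinder boundaries are anti-aliased by subvoxel supersampling so VOI mean
#' activities converge to the analytic values.
#'
#' @param spec A [phantom_spec()].
#' @param matrix_size Transaxial matrix dimension (128, 192, 256 or 384).
#' @param slice_thickness Slice thickness in mm (default 2.78).
#' @param supersample Subvoxel sampling factor per axis at boundaries.
#' @return An [as_volume()] image volume in kBq/mL.
#' @examples
#' vol <- build_activity_map(phantom_spec(), 128)
#' range(vol$data)
#' @export
build_activity_map <- function(spec, matrix_size, slice_thickness = 2.78,
                               supersample = 4L) {
  if (!matrix_size %in% MATRIX_SIZES) {
    rr_abort(sprintf("matrix_size %s not in {%s}", matrix_size,
                     paste(MATRIX_SIZES, collapse = ", ")),
             class = "radiorobust_validation_error")
  }
  rasterize_activity(spec, matrix_size, slice_thickness, supersample)
}

# Grid-size-agnostic rasterizer (the exported builder restricts to the
# documented matrix sizes; the pipeline's reduced-scale mode calls this).
rasterize_activity <- function(spec, matrix_size, slice_thickness = 2.78,
                               supersample = 4L) {
  gc <- grid_coords(spec$field_of_view, spec$axial_extent, matrix_size,
                    slice_thickness)
  vol <- array(spec$background_activity,
               dim = c(matrix_size, matrix_size, length(gc$z)))
  # lung cylinder: 2D fractions replicated along z
  if (spec$lung_diameter > 0) {
    lr <- spec$lung_diameter / 2
    hd2 <- sqrt(sum((gc$spacing[1:2] / 2)^2))
    d2 <- sqrt(outer(gc$x^2, gc$y^2, "+"))
    f2 <- matrix(0, matrix_size, matrix_size)
    f2[d2 <= lr - hd2] <- 1
    bnd <- which(d2 > lr - hd2 & d2 < lr + hd2)
    if (length(bnd)) {
      ss <- supersample
      sub <- ((seq_len(ss) - 0.5) / ss - 0.5)
      offs <- as.matrix(expand.grid(sub * gc$spacing[1], sub * gc$spacing[2]))
      idx <- arrayInd(bnd, dim(d2))
      cx <- gc$x[idx[, 1]]
      cy <- gc$y[idx[, 2]]
      cnt <- numeric(length(bnd))
      for (k in seq_len(nrow(offs))) {
        cnt <- cnt + ((cx + offs[k, 1])^2 + (cy + offs[k, 2])^2 <= lr^2)
      }
      f2[bnd] <- cnt / nrow(offs)
    }
    delta <- spec$lung_activity - spec$background_activity
    vol <- vol + outer(f2, rep(1, length(gc$z))) * delta
  }
  for (i in seq_along(spec$sphere_diameters)) {
    radius <- spec$sphere_diameters[i] / 2
    centre <- spec$sphere_centres[i, ]
    check_inside_grid(gc, centre, radius, sprintf("sphere%d", i))
    sf <- sphere_fractions(gc, centre, radius, ss = supersample)
    delta <- spec$sphere_activity - spec$background_activity
    vol[sf$ix, sf$iy, sf$iz] <- vol[sf$ix, sf$iy, sf$iz] + sf$frac * delta
  }
  as_volume(vol, gc$spacing)
}

#' Logical mask of voxels fully interior to a phantom sphere
#'
#' Voxels whose centre lies more than half a voxel diagonal inside the
#' sphere surface, i.e. voxels unaffected by boundary partial volume; used
#' to check activity-ratio recovery free of rasterization dilution.
#'
#' @param spec A [phantom_spec()].
#' @param vol A volume on the phantom grid (for dimensions/spacing).
#' @param sphere Sphere index (1 = largest).
#' @return Logical array matching `vol$data`.
#' @export
sphere_interior_mask <- function(spec, vol, sphere = 1) {
  d <- dim(vol$data)
  gc <- list(
    x = (seq_len(d[1]) - (d[1] + 1) / 2) * vol$spacing[1],
    y = (seq_len(d[2]) - (d[2] + 1) / 2) * vol$spacing[2],
    z = (seq_len(d[3]) - (d[3] + 1) / 2) * vol$spacing[3]
  )
  ctr <- spec$sphere_centres[sphere, ]
  r <- spec$sphere_diameters[sphere] / 2
  hd <- sqrt(sum((vol$spacing / 2)^2))
  d2 <- outer(outer((gc$x - ctr[1])^2, (gc$y - ctr[2])^2, "+"),
              (gc$z - ctr[3])^2, "+")
  d2 <= max(r - hd, 0)^2
}

#' Rasterize the nine analysis VOIs as a label map
#'
#' Produces an integer label volume with one label per analysis region: the
#' six sphere inserts (labels 1-6, largest to smallest), two background
#' samples (7, 8) and the lung-insert sample (9). A voxel belongs to a VOI
#' when its centre falls inside the VOI sphere; labels never overlap for the
#' default geometry. VOIs with very few voxels on coarse grids are reported
#' in the `low_count` attribute so downstream validity filtering can act.
#'
#' @inheritParams build_activity_map
#' @return An `rr_volume` whose data are integer labels 0-9, with attributes
#'   `region_labels` (label number -> region name) and `low_count`.
#' @examples
#' m <- make_voi_masks(phantom_spec(), 128)
#' table(m$data[m$data > 0])
#' @export
make_voi_masks <- function(spec, matrix_size, slice_thickness = 2.78) {
  if (length(spec$sphere_diameters) == 0) {
    rr_abort("phantom has no sphere inserts: no VOIs to rasterize",
             class = "radiorobust_geometry_error")
  }
  gc <- grid_coords(spec$field_of_view, spec$axial_extent, matrix_size,
                    slice_thickness)
  lab <- array(0L, dim = c(matrix_size, matrix_size, length(gc$z)))
  centres <- rbind(spec$sphere_centres,
                   spec$background_sample_centres,
                   matrix(spec$lung_sample_centre, nrow = 1))
  radii <- c(spec$sphere_diameters / 2,
             rep(spec$background_sample_diameter / 2, nrow(spec$background_sample_centres)),
             spec$lung_sample_diameter / 2)
  low <- character()
  for (i in seq_along(radii)) {
    check_inside_grid(gc, centres[i, ], radii[i], REGION_LABELS[i])
    ix <- which(abs(gc$x - centres[i, 1]) <= radii[i])
    iy <- which(abs(gc$y - centres[i, 2]) <= radii[i])
    iz <- which(abs(gc$z - centres[i, 3]) <= radii[i])
    n_vox <- 0L
    if (length(ix) && length(iy) && length(iz)) {
      d2 <- outer(outer((gc$x[ix] - centres[i, 1])^2,
                        (gc$y[iy] - centres[i, 2])^2, "+"),
                  (gc$z[iz] - centres[i, 3])^2, "+")
      inside <- d2 <= radii[i]^2
      if (any(lab[ix, iy, iz][inside] != 0L)) {
        rr_abort(sprintf("VOI %s overlaps an earlier VOI", REGION_LABELS[i]),
                 class = "radiorobust_geometry_error")
      }
      sub <- lab[ix, iy, iz]
      sub[inside] <- i
      lab[ix, iy, iz] <- sub
      n_vox <- sum(inside)
    }
    if (n_vox < 16L) {
      low <- c(low, REGION_LABELS[i])
      warning(sprintf("VOI %s has only %d voxel(s) on this grid",
                      REGION_LABELS[i], n_vox))
    }
  }
  out <- as_volume(lab, gc$spacing)
  attr(out, "region_labels") <- stats::setNames(seq_along(radii),
                                                REGION_LABELS[seq_along(radii)])
  attr(out, "low_count") <- low
  out
}
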