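# Transport geometries: contiguous z-stacked regions (vacuum, homogeneous
# slab, voxel grid), beam travelling toward decreasing z; plus voxel phantom
# construction from HU arrays via a Schneider-style conversion table.

#' Build a transport geometry from a region list
#'
#' Regions must be contiguous and ordered from upstream (largest z) to
#' downstream. Usually assembled with the helper constructors
#' [region_slab()], [region_vacuum()], [region_voxel()] or the high-level
#' [geom_water_phantom()], [make_slab_phantom()], [beam_geometry()].
#'
#' @param regions List of region lists.
#' @return A `pbs_geometry`.
#' @export
geometry <- function(regions) {
  if (!length(regions)) stop("empty geometry")
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (r$z_top <= r$z_bottom) stop("region ", i, ": z_top must exceed z_bottom")
    if (i > 1 && abs(regions[[i - 1]]$z_bottom - r$z_top) > 1e-6)
      stop("regions must be contiguous (gap before region ", i, ")")
  }
  structure(list(regions = regions,
                 z_top = regions[[1]]$z_top,
                 z_exit = regions[[length(regions)]]$z_bottom),
            class = "pbs_geometry")
}

#' @rdname geometry
#' @param material A [material()].
#' @param z_top,z_bottom Region extent, mm (z_top > z_bottom).
#' @param density Override density, g/cm^3 (defaults to the material's).
#' @export
region_slab <- function(material, z_top, z_bottom, density = material$density) {
  list(type = 1L, z_top = z_top, z_bottom = z_bottom,
       material = material, density = density)
}

#' @rdname geometry
#' @export
region_vacuum <- function(z_top, z_bottom) {
  list(type = 0L, z_top = z_top, z_bottom = z_bottom)
}

#' @rdname geometry
#' @param voxels A `pbs_voxels` object (see [hu_to_voxels()] /
#'   [make_slab_phantom()]).
#' @param z_top Position of the upstream voxel face, mm.
#' @export
region_voxel <- function(voxels, z_top) {
  ext_z <- voxels$dims[3] * voxels$spacing[3]
  list(type = 2L, z_top = z_top, z_bottom = z_top - ext_z, voxels = voxels)
}

#' Homogeneous water phantom geometry
#'
#' @param thickness_mm Phantom thickness along the beam, mm.
#' @param surface_z Position of the entrance surface, mm (0 = isocenter).
#' @export
geom_water_phantom <- function(thickness_mm = 400, surface_z = 0) {
  geometry(list(region_slab(builtin_material("water"),
                            surface_z, surface_z - thickness_mm)))
}

# ---- voxel grids -------------------------------------------------------------

#' Voxel grid of material ids and densities
#'
#' Voxels use 0-based indices with half-open intervals; the world position of
#' voxel center (i, j, k) is `origin + (index + 0.5) * spacing`. The origin is
#' the lower corner in all three coordinates; the beam enters through the
#' high-z face.
#'
#' @param matid Integer 3D array indexing into `materials`.
#' @param density Numeric 3D array, g/cm^3.
#' @param materials List of [material()] objects.
#' @param spacing Voxel size, mm (length 3 or scalar).
#' @param origin Lower-corner world position, mm (length 3).
#' @return A `pbs_voxels`.
#' @export
voxel_grid <- function(matid, density, materials, spacing, origin = c(0, 0, 0)) {
  spacing <- rep(spacing, length.out = 3)
  if (any(spacing <= 0)) stop("voxel size must be > 0")
  dims <- dim(matid)
  if (!identical(dim(density), dims)) stop("matid and density dims differ")
  if (any(density < 0)) stop("densities must be non-negative")
  if (any(matid < 1L | matid > length(materials)))
    stop("matid out of range of the material list")
  structure(list(matid = matid, density = density, materials = materials,
                 spacing = spacing, origin = origin, dims = dims),
            class = "pbs_voxels")
}

#' Analytic slab phantom as a voxel geometry
#'
#' Stacks homogeneous slabs along the beam axis into a voxel grid, e.g. a
#' water / lung / water sandwich.
#'
#' @param slabs List of `list(material, thickness_mm)` pairs ordered from the
#'   entrance surface downstream.
#' @param lateral_mm Lateral extent (square), mm.
#' @param voxel_mm Isotropic voxel size, mm.
#' @param surface_z Entrance surface position, mm.
#' @return A `pbs_geometry` containing one voxel region.
#' @export
make_slab_phantom <- function(slabs, lateral_mm = 300, voxel_mm = 1,
                              surface_z = 0) {
  mats <- lapply(slabs, `[[`, 1)
  th <- vapply(slabs, `[[`, numeric(1), 2)
  nz_per <- round(th / voxel_mm)
  if (any(abs(nz_per * voxel_mm - th) > 1e-6))
    stop("slab thicknesses must be multiples of the voxel size")
  nl <- round(lateral_mm / voxel_mm)
  nz <- sum(nz_per)
  # slab index per z voxel, ordered from the downstream (low-z) end because
  # array index k runs from the origin (lower corner) upward in z
  slab_of_k <- rev(rep(seq_along(slabs), nz_per))
  matid <- array(rep(as.integer(slab_of_k), each = nl * nl), c(nl, nl, nz))
  dens <- array(rep(vapply(mats, `[[`, numeric(1), "density")[slab_of_k],
                    each = nl * nl), c(nl, nl, nz))
  vox <- voxel_grid(matid, dens, mats, voxel_mm,
                    origin = c(-lateral_mm / 2, -lateral_mm / 2,
                               surface_z - nz * voxel_mm))
  geometry(list(region_voxel(vox, surface_z)))
}

#' Assemble the delivery geometry for a field
#'
#' Places the machine's range shifter (when the field requests it) at the
#' source plane, a vacuum gap (the in-air divergence is already folded into
#' the fitted optics), and the phantom below `surface_z`. The air gap between
#' the downstream range-shifter face and the phantom surface follows from the
#' machine's source-plane position and `surface_z`.
#'
#' @param machine A [machine_model()].
#' @param phantom A `pbs_geometry` (phantom only), or `NULL` for an in-air
#'   geometry ending at `plane_z`.
#' @param use_range_shifter Logical.
#' @param plane_z For `phantom = NULL`: downstream end of the (vacuum)
#'   geometry, mm.
#' @return A `pbs_geometry` starting at the source plane.
#' @export
beam_geometry <- function(machine, phantom = NULL, use_range_shifter = FALSE,
                          plane_z = -10) {
  zs <- machine$source_plane_z
  regs <- list()
  z_cur <- zs
  if (use_range_shifter) {
    rs <- machine$range_shifter
    if (is.null(rs)) stop("machine has no range shifter configured")
    regs <- c(regs, list(region_slab(rs$material, zs, zs - rs$thickness_mm)))
    z_cur <- zs - rs$thickness_mm
  }
  if (is.null(phantom)) {
    if (z_cur > plane_z)
      regs <- c(regs, list(region_vacuum(z_cur, plane_z)))
  } else {
    z_surf <- phantom$z_top
    if (z_cur < z_surf - 1e-9)
      stop("phantom surface (z = ", z_surf, ") is upstream of z = ", z_cur)
    if (z_cur > z_surf) regs <- c(regs, list(region_vacuum(z_cur, z_surf)))
    regs <- c(regs, phantom$regions)
  }
  geometry(regs)
}

# ---- HU conversion (Schneider-style, toy scale) ------------------------------

#' Default HU conversion table
#'
#' A compact Schneider-style segmentation of the HU axis into tissue classes
#' (air, lung, adipose, soft tissue, connective tissue, bone ramp), each with
#' a representative elemental composition and a base density that is linear
#' in HU within the bin. A per-bin density correction factor (default 1) is
#' solved by [solve_density_correction()] so that the converted voxels
#' reproduce a target HU-to-RSP calibration curve.
#'
#' @return A `pbs_hu_table`: data frame of bins plus a material list.
#' @export
hu_conversion_table <- function() {
  mk <- function(name, syms, fr, density, I)
    material(name, data.frame(symbol = syms, fraction = fr), density, I)
  mats <- list(
    air  = builtin_material("air"),
    lung = mk("lung_tissue", c("H", "C", "N", "O"),
              c(0.103, 0.105, 0.031, 0.761), 1.05, 75.3),
    adipose = mk("adipose", c("H", "C", "N", "O"),
                 c(0.114, 0.598, 0.007, 0.281), 0.95, 63.2),
    soft = mk("soft_tissue", c("H", "C", "N", "O"),
              c(0.102, 0.143, 0.034, 0.721), 1.06, 74.7),
    connective = mk("connective", c("H", "C", "N", "O"),
                    c(0.094, 0.207, 0.062, 0.637), 1.12, 74.5),
    bone = mk("bone", c("H", "C", "N", "O", "P", "Ca"),
              c(0.056, 0.235, 0.050, 0.434, 0.072, 0.153), 1.60, 106.4)
  )
  bins <- data.frame(
    hu_lo = c(-1000, -950, -120, -20, 100, 300),
    hu_hi = c(-950, -120, -20, 100, 300, 3000),
    mat = c("air", "lung", "adipose", "soft", "connective", "bone"),
    # density linear in HU inside the bin: rho = d0 + d1 * HU
    d0 = c(0.00121, 1.000, 1.000, 1.000, 1.000, 1.100),
    d1 = c(0, 1.0e-3, 1.0e-3, 1.0e-3, 0.9e-3, 1.0e-3),
    correction = 1.0,
    stringsAsFactors = FALSE
  )
  structure(list(bins = bins, materials = mats), class = "pbs_hu_table")
}

.hu_bin <- function(table, hu) {
  findInterval(hu, c(table$bins$hu_lo, table$bins$hu_hi[nrow(table$bins)]),
               all.inside = TRUE)
}

#' Convert an HU array to a voxel grid
#'
#' Per-voxel lookup in the HU conversion table; density is the bin's linear
#' HU-density model times the bin's correction factor. HU outside the table
#' span are clamped with a warning.
#'
#' @param hu_array 3D numeric array of Hounsfield units.
#' @param table A [hu_conversion_table()].
#' @param spacing,origin Voxel geometry, mm.
#' @return A `pbs_voxels`.
#' @export
hu_to_voxels <- function(hu_array, table = hu_conversion_table(),
                         spacing = 1, origin = c(0, 0, 0)) {
  rng <- range(table$bins$hu_lo, table$bins$hu_hi)
  if (any(hu_array < rng[1] | hu_array > rng[2])) {
    warning("HU values outside [", rng[1], ", ", rng[2], "] clamped")
    hu_array[] <- pmin(pmax(hu_array, rng[1]), rng[2])
  }
  bin <- .hu_bin(table, hu_array)
  b <- table$bins
  dens <- (b$d0[bin] + b$d1[bin] * as.numeric(hu_array)) * b$correction[bin]
  dens <- pmax(dens, 0)
  mat_index <- match(b$mat, names(table$materials))
  matid <- array(as.integer(mat_index[bin]), dim = dim(hu_array))
  voxel_grid(matid, array(dens, dim = dim(hu_array)),
             unname(table$materials), spacing, origin)
}

#' Relative stopping power of a material at a density
#' @param material A [material()].
#' @param energy Proton energy, MeV.
#' @param density Override density, g/cm^3.
#' @export
rsp <- function(material, energy = 160, density = material$density) {
  water <- builtin_material("water")
  .mass_stopping_power(material, energy) * density /
    (.mass_stopping_power(water, energy) * water$density)
}

#' Solve per-bin density correction factors
#'
#' For each HU bin center, sets the correction factor to
#' `target RSP / RSP(tissue at base density)` so that converted voxels
#' reproduce the target HU-to-RSP calibration curve (RSP is linear in
#' density, so the solve is exact at bin centers).
#'
#' @param table A [hu_conversion_table()].
#' @param target_curve Function mapping HU to target RSP, or data frame with
#'   columns `hu`, `rsp` (interpolated linearly).
#' @param reference_energy Energy at which RSP is evaluated, MeV.
#' @return The table with updated `correction` column.
#' @export
solve_density_correction <- function(table, target_curve,
                                     reference_energy = 160) {
  f <- if (is.function(target_curve)) target_curve
       else approxfun(target_curve$hu, target_curve$rsp, rule = 2)
  b <- table$bins
  for (i in seq_len(nrow(b))) {
    hu_c <- (b$hu_lo[i] + b$hu_hi[i]) / 2
    rho_base <- b$d0[i] + b$d1[i] * hu_c
    m <- table$materials[[b$mat[i]]]
    r0 <- rsp(m, reference_energy, rho_base)
    if (r0 > 0) b$correction[i] <- f(hu_c) / r0
  }
  table$bins <- b
  table
}
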