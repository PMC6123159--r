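# Virtual machine fixture: ground-truth parameter tables emulating a
# dedicated PBS nozzle, and pseudo-measurement generation, so the whole
# commissioning and validation chain runs end-to-end without external data.

.fixture_energies <- c(100, 115, 150, 180, 210, 225)
.fixture_planes <- c(455, 330, 200, 100, 0, -100)

#' Ground-truth virtual machine
#'
#' A machine model with parameter tables at the six commissioned energies
#' {100, 115, 150, 180, 210, 225} MeV, emulating a dedicated PBS nozzle:
#' spot sigma decreasing with energy (more elliptical at low energy, with a
#' slight increase from 210 to 225 MeV), divergence falling from ~6 mrad at
#' 100 MeV to ~3 mrad at 210 MeV, energy spread from 0.67% at 100 MeV to
#' 0.28% at 225 MeV, protons per MU exactly proportional to the inverse
#' electronic stopping power of air and anchored at 9e7 at 100 MeV, scanning
#' focal distances fx = 1859.1 mm / fy = 2234.8 mm, and a 65 mm Lexan range
#' shifter at the source plane.
#'
#' @param seed Unused by the (deterministic) tables; kept so fixture
#'   generation has a uniform signature.
#' @return A [machine_model()].
#' @export
make_virtual_machine <- function(seed = 1L) {
  e <- .fixture_energies
  air <- builtin_material("air")
  s_air <- stopping_power(air, e)
  tab <- data.frame(
    nominal = e,
    mean_energy = e,
    spread_pct = c(0.67, 0.62, 0.50, 0.40, 0.31, 0.28),
    protons_per_mu = 9e7 * stopping_power(air, 100) / s_air,
    x_sigma0 = c(6.0, 5.4, 4.4, 3.8, 3.2, 3.4),
    x_sigma_theta = c(6.0, 5.6, 4.7, 3.9, 3.2, 3.1),
    x_rho0 = c(0.20, 0.18, 0.15, 0.12, 0.10, 0.10),
    y_sigma0 = c(4.9, 4.6, 4.0, 3.5, 3.1, 3.3),
    y_sigma_theta = c(5.8, 5.4, 4.6, 3.8, 3.1, 3.0),
    y_rho0 = c(0.50, 0.48, 0.44, 0.40, 0.36, 0.36)
  )
  machine_model(tab, fx = 1859.1, fy = 2234.8, source_plane_z = 460,
                range_shifter = list(material = builtin_material("lexan"),
                                     thickness_mm = 65))
}

#' Generate a pseudo-measurement set from a ground-truth machine
#'
#' Emulates the commissioning measurement campaign: spot sigmas at the six
#' in-air planes (455, 330, 200, 100, 0, -100 mm) from the drift law plus
#' relative Gaussian noise; integral depth-dose curves from the transport
#' engine; beam positions at two planes for several scanned deflections (for
#' the effective-SAD fit); and absolute reference doses computed from the
#' ground-truth protons per MU (emulating the air-filled monitor chamber)
#' with relative noise.
#'
#' @param machine Ground-truth [machine_model()].
#' @param noise List: `sigma_rel` (spot sigma, default 1%), `dose_rel`
#'   (absolute dose, default 0.5%), `pos_mm` (deflection positions, mm).
#' @param n_idd Protons per measured depth-dose curve.
#' @param n_ref Protons for the reference-dose simulation.
#' @param energies Subset of commissioned energies (default: all).
#' @param seed RNG seed (stored in the set).
#' @return A `pbs_measurement_set`.
#' @export
generate_measurement_set <- function(machine,
                                     noise = list(sigma_rel = 0.01,
                                                  dose_rel = 0.005,
                                                  pos_mm = 0.05),
                                     n_idd = 2e5, n_ref = 1e5,
                                     energies = machine$energy_table$nominal,
                                     seed = 1L) {
  set.seed(seed)
  per <- list()
  for (en in energies) {
    p <- interpolate_machine(machine, en)
    sig <- do.call(rbind, lapply(c("x", "y"), function(ax) {
      opt <- if (ax == "x") p$optics_x else p$optics_y
      s <- sigma_at(opt, .fixture_planes)
      data.frame(axis = ax, z = .fixture_planes,
                 sigma = s * (1 + rnorm(length(s), 0, noise$sigma_rel)))
    }))
    idd <- simulate_idd(p$mean_energy, p$spread_pct, n = n_idd,
                        seed = seed + 1000L + as.integer(en))
    dpp <- simulate_reference_dose(machine, en, n = n_ref,
                                   seed = seed + 2000L + as.integer(en))
    ref_dose <- p$protons_per_mu * dpp * (1 + rnorm(1, 0, noise$dose_rel))
    per[[as.character(en)]] <- list(spot_sigma = sig, idd = idd,
                                    ref_dose_gy = ref_dose)
  }
  # deflection positions at two planes for +/- 100 mm requested offsets
  defl <- do.call(rbind, lapply(c("x", "y"), function(ax) {
    f <- if (ax == "x") machine$fx else machine$fy
    do.call(rbind, lapply(c(-100, 100), function(off) {
      z <- c(455, 0)
      data.frame(axis = ax, offset = off, z = z,
                 x = off * (f - z) / f + rnorm(2, 0, noise$pos_mm))
    }))
  }))
  structure(list(energies = energies, per_energy = per, deflections = defl,
                 source_plane_z = machine$source_plane_z,
                 range_shifter = machine$range_shifter,
                 meta = list(seed = seed, noise = noise, n_idd = n_idd)),
            class = "pbs_measurement_set")
}

#' Write / read a measurement set as a CSV + JSON bundle
#'
#' The bundle is a directory holding `measurements.json` (index, reference
#' doses, geometry, noise metadata and seed) plus per-energy CSV files for
#' spot sigmas and depth-dose curves and one CSV of deflection positions.
#'
#' @param ms A `pbs_measurement_set`.
#' @param dir Bundle directory (created if missing).
#' @export
write_measurement_set <- function(ms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- list(format = "pbsmc-measurements", version = 1,
              energies = ms$energies,
              source_plane_z = ms$source_plane_z,
              ref_dose_gy = lapply(ms$per_energy, `[[`, "ref_dose_gy"),
              range_shifter = if (is.null(ms$range_shifter)) NULL else list(
                thickness_mm = ms$range_shifter$thickness_mm,
                material = ms$range_shifter$material$name),
              meta = ms$meta)
  jsonlite::write_json(idx, file.path(dir, "measurements.json"),
                       auto_unbox = TRUE, digits = NA)
  for (en in ms$energies) {
    m <- ms$per_energy[[as.character(en)]]
    utils::write.csv(m$spot_sigma,
                     file.path(dir, sprintf("spots_%g.csv", en)),
                     row.names = FALSE)
    utils::write.csv(m$idd, file.path(dir, sprintf("idd_%g.csv", en)),
                     row.names = FALSE)
  }
  utils::write.csv(ms$deflections, file.path(dir, "deflections.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_measurement_set
#' @export
read_measurement_set <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "measurements.json"),
                             simplifyVector = TRUE)
  if (is.null(idx$format) || idx$format != "pbsmc-measurements")
    stop("not a pbsmc measurement bundle: ", dir)
  per <- list()
  for (en in idx$energies) {
    per[[as.character(en)]] <- list(
      spot_sigma = utils::read.csv(file.path(dir, sprintf("spots_%g.csv", en))),
      idd = utils::read.csv(file.path(dir, sprintf("idd_%g.csv", en))),
      ref_dose_gy = idx$ref_dose_gy[[as.character(en)]])
  }
  rs <- NULL
  if (!is.null(idx$range_shifter))
    rs <- list(material = builtin_material(idx$range_shifter$material),
               thickness_mm = idx$range_shifter$thickness_mm)
  structure(list(energies = idx$energies, per_energy = per,
                 deflections = utils::read.csv(file.path(dir, "deflections.csv")),
                 source_plane_z = idx$source_plane_z,
                 range_shifter = rs, meta = idx$meta),
            class = "pbs_measurement_set")
}

#' Toy heterogeneous lung phantom
#'
#' A soft-tissue box with a low-density lung insert (relative stopping power
#' ~0.31) and an embedded soft-tissue target, returned as an HU array plus a
#' target mask — a desk-scale analog of an anthropomorphic thorax phantom
#' for heterogeneity studies.
#'
#' @param voxel_mm Isotropic voxel size, mm.
#' @param size_mm Box edge length, mm.
#' @return List: `hu` (3D array), `target_mask` (logical array), `spacing`,
#'   `lung_hu`.
#' @export
make_toy_lung_phantom <- function(voxel_mm = 2, size_mm = 120) {
  n <- round(size_mm / voxel_mm)
  hu <- array(0, c(n, n, n))            # soft tissue (water-like)
  cx <- (seq_len(n) - 0.5) * voxel_mm - size_mm / 2
  # lung slab occupying the middle third of the depth (z) extent
  lung_hu <- -690                        # converts to density ~0.31
  iz_lung <- which(cx > -size_mm / 6 & cx < size_mm / 6)
  hu[, , iz_lung] <- lung_hu
  # spherical soft-tissue target centered in the lung slab
  r_target <- size_mm / 8
  dist <- sqrt(outer(cx^2, outer(cx^2, cx^2, `+`), `+`))
  dim(dist) <- c(n, n, n)
  mask <- dist <= r_target
  hu[mask] <- 0
  list(hu = hu, target_mask = mask, spacing = voxel_mm, lung_hu = lung_hu)
}
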