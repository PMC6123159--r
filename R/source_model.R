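# Parameterized phase-space source model: Courant-Snyder spot optics at the
# source plane, scanning geometry via effective focal distances, per-energy
# machine lookup tables.
#
# Coordinates: IEC61217 gantry system; the origin is at isocenter, the source
# plane sits on the positive z axis (upstream face of the range shifter) and
# the beam travels toward decreasing z. All positions in mm.
#
# Sign convention: the slope theta is dx per unit path toward isocenter, so a
# particle at plane z reaches x(0) = x(z) + z * theta. The correlation rho is
# positive for a defocusing beam and negative for a focusing beam.

#' Spot optics parameters for one transverse axis
#'
#' Courant-Snyder description of the transverse phase space of a scanned spot
#' at isocenter: spatial sigma, angular sigma and their correlation. The spot
#' sigma at any plane z follows
#' `sigma^2(z) = sigma0^2 - 2 rho0 sigma0 sigtheta z + sigtheta^2 z^2`.
#'
#' @param sigma0 Spot sigma at isocenter, mm.
#' @param sigma_theta Angular sigma, mrad.
#' @param rho0 Correlation coefficient at isocenter, in `[-1, 1]`.
#' @return An object of class `pbs_optics`.
#' @export
optics_params <- function(sigma0, sigma_theta, rho0) {
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (sigma_theta <= 0) stop("sigma_theta must be > 0")
  if (abs(rho0) > 1) stop("|rho0| must be <= 1")
  structure(list(sigma0 = sigma0, sigma_theta = sigma_theta, rho0 = rho0),
            class = "pbs_optics")
}

#' Spot sigma and correlation at a plane
#'
#' Closed-form drift propagation of the beam sigma-matrix from isocenter to
#' plane `z` (positive z is upstream, toward the source).
#'
#' @param params A [optics_params()].
#' @param z Plane position, mm (vectorized).
#' @return `sigma_at`: spot sigma in mm. `rho_at`: correlation in `[-1, 1]`.
#' @export
sigma_at <- function(params, z) {
  st <- params$sigma_theta * 1e-3  # mrad -> rad; z in mm gives mm
  sqrt(params$sigma0^2 - 2 * params$rho0 * params$sigma0 * st * z + st^2 * z^2)
}

#' @rdname sigma_at
#' @export
rho_at <- function(params, z) {
  st <- params$sigma_theta * 1e-3
  (params$rho0 * params$sigma0 - st * z) / sigma_at(params, z)
}

# 2x2 sigma-matrix propagated by the drift matrix [[1, -z], [0, 1]];
# used as the matrix-product cross-check of the closed forms above
propagate_sigma_matrix <- function(params, z) {
  st <- params$sigma_theta * 1e-3
  s0 <- matrix(c(params$sigma0^2, params$rho0 * params$sigma0 * st,
                 params$rho0 * params$sigma0 * st, st^2), 2, 2)
  m <- matrix(c(1, 0, -z, 1), 2, 2)
  m %*% s0 %*% t(m)
}

#' Fit spot optics from in-air spot-size measurements
#'
#' Least-squares fit of measured spot sigmas at several planes to the
#' quadratic drift law for `sigma^2(z)`, recovering the isocenter parameters.
#'
#' @param measurements Data frame with columns `z` (plane position, mm) and
#'   `sigma` (measured spot sigma, mm); at least 3 distinct planes.
#' @return A list with `params` ([optics_params()]), `rms_residual` (mm, on
#'   sigma), and `physical` (FALSE when the unconstrained fit gives
#'   |rho0| > 1, in which case rho0 is clamped and the result flagged).
#' @export
fit_optics <- function(measurements) {
  stopifnot(is.data.frame(measurements), all(c("z", "sigma") %in% names(measurements)))
  z <- measurements$z; s <- measurements$sigma
  if (length(unique(z)) < 3)
    stop("at least 3 distinct planes are required to fit the optics")
  fit <- lm(I(s^2) ~ z + I(z^2))
  cf <- coef(fit)
  a <- cf[[1]]; b <- cf[[2]]; c2 <- cf[[3]]
  if (a <= 0 || c2 <= 0)
    stop("non-physical fit: sigma^2 or sigma_theta^2 not positive")
  sigma0 <- sqrt(a)
  sig_theta <- sqrt(c2)           # rad
  rho0 <- -b / (2 * sigma0 * sig_theta)
  physical <- abs(rho0) <= 1
  rho0_cl <- max(-1, min(1, rho0))
  params <- optics_params(sigma0, sig_theta * 1e3, rho0_cl)
  pred <- sigma_at(params, z)
  list(params = params,
       rms_residual = sqrt(mean((pred - s)^2)),
       physical = physical, rho0_unclamped = rho0)
}

#' Fit the effective source-axis distance
#'
#' The scanned spot offset at plane z follows `x(z) = x_iso * (f - z) / f`
#' for an effective focal distance f; f is recovered from beam positions at
#' two or more planes by a straight-line fit (`f = -intercept / slope`).
#'
#' @param deflections Data frame with columns `z` (mm) and `x` (measured
#'   lateral position, mm), optionally `offset` identifying the requested
#'   deflection when several are measured; at least 2 distinct planes.
#' @return Effective focal distance in mm (`Inf`, with a warning, for a
#'   parallel beam).
#' @export
fit_effective_sad <- function(deflections) {
  stopifnot(is.data.frame(deflections), all(c("z", "x") %in% names(deflections)))
  groups <- if ("offset" %in% names(deflections))
    split(deflections, deflections$offset) else list(deflections)
  fs <- vapply(groups, function(d) {
    if (length(unique(d$z)) < 2) stop("at least 2 distinct planes required")
    fit <- lm(x ~ z, data = d)
    slope <- coef(fit)[[2]]; inter <- coef(fit)[[1]]
    if (abs(slope) < 1e-12 * max(abs(inter), 1)) {
      warning("parallel beam: effective SAD is infinite")
      return(Inf)
    }
    -inter / slope
  }, numeric(1))
  mean(fs)
}

#' Assemble a machine model
#'
#' The machine model is the per-energy lookup table produced by
#' commissioning: spot optics per axis, energy-spectrum model and protons per
#' MU at each commissioned nominal energy, plus the scanning geometry and the
#' range-shifter specification.
#'
#' @param energy_table Data frame with one row per commissioned nominal
#'   energy and columns `nominal`, `mean_energy`, `spread_pct` (energy-spread
#'   sigma as % of the mean), `protons_per_mu`, and the six optics columns
#'   `x_sigma0`, `x_sigma_theta`, `x_rho0`, `y_sigma0`, `y_sigma_theta`,
#'   `y_rho0` (mm / mrad / dimensionless).
#' @param fx,fy Effective source-axis distances, mm.
#' @param source_plane_z Source plane position (upstream range-shifter face),
#'   mm, > 0.
#' @param range_shifter `NULL`, or a list with `material` ([material()]) and
#'   `thickness_mm`.
#' @return An object of class `pbs_machine`.
#' @export
machine_model <- function(energy_table, fx, fy, source_plane_z,
                          range_shifter = NULL) {
  need <- c("nominal", "mean_energy", "spread_pct", "protons_per_mu",
            "x_sigma0", "x_sigma_theta", "x_rho0",
            "y_sigma0", "y_sigma_theta", "y_rho0")
  if (!all(need %in% names(energy_table)))
    stop("energy_table is missing columns: ",
         paste(setdiff(need, names(energy_table)), collapse = ", "))
  if (fx <= 0 || fy <= 0) stop("fx and fy must be > 0")
  if (source_plane_z <= 0) stop("source_plane_z must be > 0")
  if (is.unsorted(energy_table$nominal, strictly = TRUE))
    energy_table <- energy_table[order(energy_table$nominal), ]
  if (any(abs(energy_table$mean_energy - energy_table$nominal) >
          0.05 * energy_table$nominal))
    stop("mean energy deviates more than 5% from nominal")
  if (any(energy_table$spread_pct < 0)) stop("energy spread must be >= 0")
  structure(list(energy_table = energy_table, fx = fx, fy = fy,
                 source_plane_z = source_plane_z,
                 range_shifter = range_shifter),
            class = "pbs_machine")
}

#' @export
print.pbs_machine <- function(x, ...) {
  cat(sprintf("<pbs_machine> %d commissioned energies (%.0f-%.0f MeV), fx = %.1f mm, fy = %.1f mm\n",
              nrow(x$energy_table), min(x$energy_table$nominal),
              max(x$energy_table$nominal), x$fx, x$fy))
  if (!is.null(x$range_shifter))
    cat(sprintf("  range shifter: %.0f mm %s (WET %.1f mm at 160 MeV)\n",
                x$range_shifter$thickness_mm, x$range_shifter$material$name,
                wet(x$range_shifter$material, x$range_shifter$thickness_mm, 160)))
  print(x$energy_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Interpolate machine parameters at an intermediate energy
#'
#' Componentwise linear interpolation between the bracketing commissioned
#' energies; exact at the commissioned nodes, error outside the band.
#'
#' @param machine A [machine_model()].
#' @param energy Nominal energy, MeV.
#' @return A list with `optics_x`, `optics_y` ([optics_params()]),
#'   `mean_energy`, `spread_pct`, `protons_per_mu`.
#' @export
interpolate_machine <- function(machine, energy) {
  tab <- machine$energy_table
  if (energy < min(tab$nominal) || energy > max(tab$nominal))
    stop("energy ", energy, " MeV outside the commissioned band [",
         min(tab$nominal), ", ", max(tab$nominal), "]")
  cols <- setdiff(names(tab), "nominal")
  vals <- vapply(cols, function(cl)
    approx(tab$nominal, tab[[cl]], xout = energy)$y, numeric(1))
  v <- as.list(vals)
  list(optics_x = optics_params(v$x_sigma0, v$x_sigma_theta, v$x_rho0),
       optics_y = optics_params(v$y_sigma0, v$y_sigma_theta, v$y_rho0),
       mean_energy = v$mean_energy, spread_pct = v$spread_pct,
       protons_per_mu = v$protons_per_mu)
}

#' Sample the phase space of a scanned spot at the source plane
#'
#' Draws correlated (position, slope) pairs per axis from the sigma-matrix
#' propagated from isocenter to the source plane, adds the scanning
#' deflection (mean trajectory aimed from the effective focal point through
#' the spot's isocenter position), and Gaussian kinetic energies. The region
#' between source plane and phantom is vacuum, so a free drift of the sample
#' back to isocenter reproduces the isocenter optics.
#'
#' @param machine A [machine_model()].
#' @param energy Nominal energy, MeV (inside the commissioned band).
#' @param spot_position Spot (x, y) at isocenter, mm.
#' @param n Number of protons.
#' @return A `pbs_batch`: list of numeric vectors `x, y, z, dx, dy, dz`
#'   (unit direction), `energy` (MeV), `weight`, and integer `species`
#'   (0 = primary).
#' @export
sample_spot_phase_space <- function(machine, energy, spot_position = c(0, 0), n) {
  p <- interpolate_machine(machine, energy)
  zs <- machine$source_plane_z
  draw_axis <- function(opt) {
    st <- opt$sigma_theta * 1e-3
    var_x <- sigma_at(opt, zs)^2
    cov_xt <- st * (opt$rho0 * opt$sigma0 - st * zs)
    var_t <- st^2
    # Cholesky of the 2x2 covariance
    l11 <- sqrt(var_x)
    l21 <- cov_xt / l11
    l22 <- sqrt(max(var_t - l21^2, 0))
    u1 <- rnorm(n); u2 <- rnorm(n)
    list(x = l11 * u1, theta = l21 * u1 + l22 * u2)
  }
  ax <- draw_axis(p$optics_x)
  ay <- draw_axis(p$optics_y)
  x <- ax$x + spot_position[1] * (machine$fx - zs) / machine$fx
  y <- ay$x + spot_position[2] * (machine$fy - zs) / machine$fy
  tx <- ax$theta + spot_position[1] / machine$fx
  ty <- ay$theta + spot_position[2] / machine$fy
  # slope (dx per unit path toward isocenter) -> unit direction with dz < 0
  nrm <- sqrt(tx^2 + ty^2 + 1)
  en <- rnorm(n, p$mean_energy, p$spread_pct / 100 * p$mean_energy)
  structure(list(x = x, y = y, z = rep(zs, n),
                 dx = tx / nrm, dy = ty / nrm, dz = -1 / nrm,
                 energy = en, weight = rep(1, n),
                 species = rep(0L, n)),
            class = "pbs_batch")
}

#' Drift a particle batch in vacuum to a plane
#'
#' Straight-line propagation to plane `z`; energies unchanged.
#' @param batch A `pbs_batch`.
#' @param z Target plane, mm.
#' @return The drifted batch.
#' @export
drift_to_plane <- function(batch, z) {
  t <- (z - batch$z) / batch$dz
  if (any(t < -1e-9)) stop("plane is upstream of the batch")
  batch$x <- batch$x + t * batch$dx
  batch$y <- batch$y + t * batch$dy
  batch$z <- rep(z, length(batch$x))
  batch
}

# ---- machine model JSON I/O --------------------------------------------------

#' Write / read a machine model as versioned JSON
#'
#' @param machine A [machine_model()].
#' @param path Output path.
#' @export
write_machine <- function(machine, path) {
  rs <- machine$range_shifter
  obj <- list(
    format = "pbsmc-machine", version = 1,
    fx = machine$fx, fy = machine$fy,
    source_plane_z = machine$source_plane_z,
    range_shifter = if (is.null(rs)) NULL else list(
      thickness_mm = rs$thickness_mm,
      material = list(name = rs$material$name, density = rs$material$density,
                      I = rs$material$I,
                      composition = as.list(stats::setNames(
                        rs$material$composition$fraction,
                        rs$material$composition$symbol)))),
    energy_table = machine$energy_table
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_machine
#' @export
read_machine <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "pbsmc-machine")
    stop("not a pbsmc machine file: ", path)
  rs <- NULL
  if (!is.null(obj$range_shifter)) {
    m <- obj$range_shifter$material
    comp <- data.frame(symbol = names(m$composition),
                       fraction = unlist(m$composition, use.names = FALSE))
    rs <- list(material = material(m$name, comp, m$density, m$I),
               thickness_mm = obj$range_shifter$thickness_mm)
  }
  machine_model(as.data.frame(obj$energy_table), obj$fx, obj$fy,
                obj$source_plane_z, rs)
}
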