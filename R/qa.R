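# Dosimetric QA: field-size factors, lateral profile metrics, gamma index,
# DVH statistics, radial halo integrals.

#' Field-size factors
#'
#' FSF(S) is the central-axis dose of a square field of side S relative to
#' the reference size, at fixed depth and MU per spot. The halo makes FSF
#' grow with field size; the relative difference between two sizes,
#' `(FSF(S2) - FSF(S1)) / FSF(S2)`, is the standard halo metric.
#'
#' @param central_doses Named numeric vector of central-axis doses, names =
#'   field side in mm.
#' @param reference Reference side, mm (must be among the names).
#' @return Data frame `size`, `dose`, `fsf`.
#' @export
field_size_factor <- function(central_doses, reference) {
  sizes <- as.numeric(names(central_doses))
  iref <- match(reference, sizes)
  if (is.na(iref)) stop("reference size not among the supplied doses")
  data.frame(size = sizes, dose = as.numeric(central_doses),
             fsf = as.numeric(central_doses) / central_doses[[iref]])
}

#' Field-size-factor study by kernel superposition
#'
#' Simulates one single-spot kernel and superposes it on square spot grids of
#' several sizes, evaluating the central-axis dose (mean over a centered
#' 10 x 10 mm^2 aperture) at each depth.
#'
#' @param machine A [machine_model()].
#' @param energy Nominal energy, MeV.
#' @param sizes Field sides, mm.
#' @param depths Depths, mm.
#' @param reference Reference size, mm (default: largest).
#' @param n Kernel protons.
#' @param use_range_shifter Logical.
#' @param kernel Optional precomputed [simulate_kernel()] result (overrides
#'   `n`).
#' @param seed Optional RNG seed.
#' @return List: `fsf` (data frame depth x size of FSF values), `doses`
#'   (central doses), `kernel`.
#' @export
fsf_study <- function(machine, energy, sizes = c(40, 100, 200),
                      depths, reference = max(sizes), n = 1e6,
                      use_range_shifter = FALSE, kernel = NULL, seed = NULL,
                      nuclear = nuclear_table()) {
  if (is.null(kernel))
    kernel <- simulate_kernel(machine, energy, n = n,
                              use_range_shifter = use_range_shifter,
                              r_max_mm = max(sizes) * 1.5, seed = seed,
                              nuclear = nuclear)
  doses <- sapply(sizes, function(s) {
    f <- make_square_field(energy, s, spacing = 4)
    field_central_dose(kernel, f, depths, aperture_mm = 10)$dose
  })
  doses <- matrix(doses, nrow = length(depths),
                  dimnames = list(NULL, sizes))
  iref <- match(reference, sizes)
  fsf <- doses / doses[, iref]
  list(fsf = data.frame(depth = depths, fsf, check.names = FALSE),
       doses = data.frame(depth = depths, doses, check.names = FALSE),
       kernel = kernel)
}

#' Lateral dose-profile metrics
#'
#' The 20-80% penumbra (averaged over both shoulders) and the half-widths at
#' the 95% and 5% of maximum levels, all by linear interpolation of the
#' crossing positions.
#'
#' @param profile Data frame `x` (mm, increasing), `dose`.
#' @return List `penumbra_20_80`, `halfwidth_95`, `halfwidth_5` (mm).
#' @export
lateral_profile_metrics <- function(profile) {
  x <- profile$x; d <- profile$dose / max(profile$dose)
  cross <- function(level) {
    # left and right crossings of a plateau profile
    ipk <- which.max(d)
    left <- right <- NA_real_
    for (i in seq(2, ipk)) if (d[i - 1] < level && d[i] >= level) {
      left <- x[i - 1] + (level - d[i - 1]) * (x[i] - x[i - 1]) / (d[i] - d[i - 1])
      break
    }
    for (i in seq(length(d), ipk + 1)) if (d[i - 1] >= level && d[i] < level) {
      right <- x[i - 1] + (level - d[i - 1]) * (x[i] - x[i - 1]) / (d[i] - d[i - 1])
      break
    }
    c(left, right)
  }
  c20 <- cross(0.2); c80 <- cross(0.8)
  c95 <- cross(0.95); c05 <- cross(0.05)
  pen <- mean(c(abs(c80[1] - c20[1]), abs(c20[2] - c80[2])), na.rm = TRUE)
  if (!is.finite(pen)) pen <- 0
  list(penumbra_20_80 = pen,
       halfwidth_95 = if (all(is.finite(c95))) diff(c95) / 2 else NA_real_,
       halfwidth_5 = if (all(is.finite(c05))) diff(c05) / 2 else NA_real_)
}

# ---- gamma index -------------------------------------------------------------

#' Gamma-index comparison of two dose distributions
#'
#' Global gamma analysis: for every reference point above the low-dose
#' threshold, gamma is the minimum over evaluated positions of
#' `sqrt((dose difference / dose criterion)^2 + (distance / DTA)^2)`; a point
#' passes when gamma <= 1. The dose criterion is a percentage of the
#' reference maximum. The search covers a neighborhood of 2 x DTA with
#' subvoxel interpolation of the evaluated grid. Note that gamma is
#' asymmetric in (reference, evaluated).
#'
#' @param ref,eval Numeric arrays (1D-3D) on the same grid.
#' @param dose_crit Dose-difference criterion, % of the reference maximum.
#' @param dta Distance-to-agreement criterion, mm.
#' @param spacing Grid spacing, mm (scalar or per dimension).
#' @param threshold Low-dose exclusion threshold, % of reference max.
#' @param subdivide Subvoxel interpolation factor for the search.
#' @return List: `pass_rate` (%), `gamma` (array, NA below threshold),
#'   `n_evaluated`.
#' @export
gamma_index <- function(ref, eval, dose_crit = 3, dta = 3, spacing = 1,
                        threshold = 10, subdivide = 3L) {
  ref <- as.array(ref); eva <- as.array(eval)
  if (!identical(dim(ref), dim(eva))) stop("grids must be co-registered")
  nd <- length(dim(ref))
  spacing <- rep(spacing, length.out = nd)
  dmax <- max(ref)
  dcrit <- dose_crit / 100 * dmax
  fine <- .upsample(eva, subdivide)
  fsp <- spacing / subdivide
  offs <- .neighborhood_offsets(nd, fsp, 2 * dta)
  g2 <- array(Inf, dim(ref))
  for (k in seq_len(nrow(offs$idx))) {
    shifted <- .shift_array(fine, offs$idx[k, ], subdivide, dim(ref))
    cand <- ((ref - shifted) / dcrit)^2 + (offs$dist2[k] / dta^2)
    g2 <- pmin(g2, cand, na.rm = TRUE)
  }
  gamma <- sqrt(g2)
  gamma[ref < threshold / 100 * dmax] <- NA
  n_eval <- sum(!is.na(gamma))
  list(pass_rate = 100 * sum(gamma <= 1, na.rm = TRUE) / n_eval,
       gamma = gamma, n_evaluated = n_eval)
}

# multilinear upsampling of an array by an integer factor per dimension
.upsample <- function(a, s) {
  if (s == 1L) return(a)
  nd <- length(dim(a))
  for (ax in seq_len(nd)) {
    d <- dim(a)
    n <- d[ax]
    if (n == 1) next
    xo <- seq(1, n, length.out = (n - 1) * s + 1)
    others <- setdiff(seq_len(nd), ax)
    m <- apply(a, others, function(v) approx(seq_len(n), v, xout = xo)$y)
    dim(m) <- c(length(xo), d[others])
    # current order is (ax, others); permute back to 1..nd
    a <- aperm(m, match(seq_len(nd), c(ax, others)))
  }
  a
}

.neighborhood_offsets <- function(nd, fsp, radius) {
  rng <- lapply(seq_len(nd), function(ax) {
    m <- floor(radius / fsp[ax])
    (-m):m
  })
  idx <- as.matrix(expand.grid(rng))
  dist2 <- rowSums(sweep(idx, 2, fsp, `*`)^2)
  keep <- dist2 <= radius^2
  list(idx = idx[keep, , drop = FALSE], dist2 = dist2[keep])
}

# value of the fine grid at ref nodes displaced by fine-grid offset `off`;
# out-of-bounds entries become NA
.shift_array <- function(fine, off, s, ref_dim) {
  nd <- length(ref_dim)
  pos <- lapply(seq_len(nd), function(ax) {
    p <- (seq_len(ref_dim[ax]) - 1) * s + 1 + off[ax]
    ifelse(p >= 1 & p <= dim(fine)[ax], p, NA_integer_)
  })
  grid <- as.matrix(expand.grid(pos))
  out <- array(NA_real_, ref_dim)
  ok <- !apply(is.na(grid), 1, any)
  out[ok] <- fine[grid[ok, , drop = FALSE]]
  out
}

#' Brute-force gamma index (reference implementation)
#'
#' Direct double loop over all reference and evaluated points; exact up to
#' grid resolution, used as the oracle for [gamma_index()] on small grids.
#'
#' @inheritParams gamma_index
#' @export
gamma_index_brute <- function(ref, eval, dose_crit = 3, dta = 3, spacing = 1,
                              threshold = 10) {
  ref <- as.array(ref); eva <- as.array(eval)
  nd <- length(dim(ref))
  spacing <- rep(spacing, length.out = nd)
  dmax <- max(ref)
  dcrit <- dose_crit / 100 * dmax
  coords <- as.matrix(expand.grid(lapply(seq_len(nd), function(ax)
    (seq_len(dim(ref)[ax]) - 1) * spacing[ax])))
  rv <- as.numeric(ref); ev <- as.numeric(eva)
  sel <- rv >= threshold / 100 * dmax
  gam <- rep(NA_real_, length(rv))
  for (i in which(sel)) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ], `-`)^2)
    gam[i] <- sqrt(min(((rv[i] - ev) / dcrit)^2 + d2 / dta^2))
  }
  n_eval <- sum(sel)
  list(pass_rate = 100 * sum(gam <= 1, na.rm = TRUE) / n_eval,
       gamma = array(gam, dim(ref)), n_evaluated = n_eval)
}

# ---- DVH ---------------------------------------------------------------------

#' Cumulative dose-volume histogram
#'
#' @param dose Numeric array or `pbs_dose_grid`.
#' @param mask Logical array selecting the structure (default: all voxels).
#' @param n_bins Number of dose bins.
#' @return Data frame `dose`, `volume_fraction` (fraction of the masked
#'   volume receiving at least that dose).
#' @export
dvh <- function(dose, mask = NULL, n_bins = 200) {
  d <- .dose_values(dose, mask)
  lev <- seq(0, max(d), length.out = n_bins)
  vol <- vapply(lev, function(l) mean(d >= l), numeric(1))
  data.frame(dose = lev, volume_fraction = vol)
}

#' @rdname dvh
#' @param q Coverage percentage: `dvh_stat(d, m, 95)` is D95, the maximum
#'   dose covering 95% of the masked volume; `q = 0` gives the maximum and
#'   `q = 100` the minimum dose.
#' @export
dvh_stat <- function(dose, mask = NULL, q = 95) {
  d <- sort(.dose_values(dose, mask), decreasing = TRUE)
  n <- length(d)
  if (q <= 0) return(d[1])
  d[min(n, max(1L, ceiling(q / 100 * n)))]
}

.dose_values <- function(dose, mask) {
  if (inherits(dose, "pbs_dose_grid")) dose <- dose$dose
  d <- as.numeric(dose)
  if (!is.null(mask)) d <- d[as.logical(mask)]
  if (!length(d)) stop("empty mask")
  d
}

# ---- radial halo -------------------------------------------------------------

#' Fractional integrated dose versus radius
#'
#' Integrates a planar dose distribution over disks of increasing radius
#' around the beam axis and normalizes to the integral within 200 mm. The
#' halo metric `1 - fraction(40 mm)` captures the dose carried by large-angle
#' scattering and nuclear secondaries beyond the primary spot.
#'
#' @param plane List with `x`, `y` (bin centers, mm) and `dose` matrix, as
#'   from [field_plane_dose()], or a matrix with `spacing` given.
#' @param radii Radii at which the fraction is evaluated, mm.
#' @param spacing Pixel size when `plane` is a bare matrix.
#' @param norm_radius Normalization radius, mm (default 200).
#' @return Data frame `radius`, `fraction`; attribute `halo_metric`.
#' @export
radial_halo_fraction <- function(plane, radii = c(10, 20, 40, 100, 200),
                                 spacing = NULL, norm_radius = 200) {
  if (is.matrix(plane)) {
    if (is.null(spacing)) stop("spacing required for a bare matrix")
    nx <- nrow(plane); ny <- ncol(plane)
    x <- (seq_len(nx) - (nx + 1) / 2) * spacing
    y <- (seq_len(ny) - (ny + 1) / 2) * spacing
    plane <- list(x = x, y = y, dose = plane)
  }
  rr <- sqrt(outer(plane$x^2, plane$y^2, `+`))
  tot <- sum(plane$dose[rr <= norm_radius])
  frac <- vapply(radii, function(r) sum(plane$dose[rr <= r]) / tot, numeric(1))
  out <- data.frame(radius = radii, fraction = frac)
  i40 <- match(40, radii)
  attr(out, "halo_metric") <- if (!is.na(i40)) 1 - frac[i40] else NA_real_
  out
}

#' Halo fraction from an exit phase space drifted in air
#'
#' Bins the (weighted) particle fluence-dose at a plane downstream of the
#' range shifter and evaluates [radial_halo_fraction()]. Used for the
#' air-gap halo studies.
#'
#' @param exit_matrix Exit phase-space matrix from [transport()] with
#'   `collect_exit = TRUE`.
#' @param gap_mm Drift distance from the exit plane, mm.
#' @param step_mm Pixel size of the intermediate planar map.
#' @inheritParams radial_halo_fraction
#' @export
halo_from_exit <- function(exit_matrix, gap_mm, radii = c(40, 200),
                           step_mm = 2, norm_radius = 200) {
  t <- gap_mm / (-exit_matrix[, "dz"])
  x <- exit_matrix[, "x"] + t * exit_matrix[, "dx"]
  y <- exit_matrix[, "y"] + t * exit_matrix[, "dy"]
  # energy-weighted fluence as a planar dose surrogate
  w <- exit_matrix[, "weight"] * exit_matrix[, "energy"]
  half <- norm_radius + 10
  brk <- seq(-half, half, by = step_mm)
  keep <- abs(x) < half & abs(y) < half
  ix <- findInterval(x[keep], brk, all.inside = TRUE)
  iy <- findInterval(y[keep], brk, all.inside = TRUE)
  n <- length(brk) - 1
  m <- matrix(0, n, n)
  for (i in seq_along(ix)) m[ix[i], iy[i]] <- m[ix[i], iy[i]] + w[keep][i]
  ctr <- (brk[-1] + brk[-length(brk)]) / 2
  radial_halo_fraction(list(x = ctr, y = ctr, dose = m), radii,
                       norm_radius = norm_radius)
}
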