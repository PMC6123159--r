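# Delivery data model: spot lists, square/reference fields, SOBP builder,
# versioned JSON plan I/O.

#' Construct a PBS field
#'
#' @param spots Data frame with columns `energy` (MeV), `x`, `y` (isocenter
#'   position, mm), `mu` (monitor units, > 0).
#' @param range_shifter Logical: deliver through the machine's range shifter.
#' @param gantry,couch Angles in degrees (carried as metadata; transport
#'   supports normal incidence).
#' @param air_gap Air gap between range shifter and surface, mm (metadata).
#' @return A `pbs_field`.
#' @export
pbs_field <- function(spots, range_shifter = FALSE, gantry = 0, couch = 0,
                      air_gap = NULL) {
  need <- c("energy", "x", "y", "mu")
  if (!all(need %in% names(spots)))
    stop("spots must have columns ", paste(need, collapse = ", "))
  bad <- which(!(spots$mu > 0))
  if (length(bad))
    stop("spot ", bad[1], ": mu must be > 0")
  structure(list(spots = spots, range_shifter = isTRUE(range_shifter),
                 gantry = gantry, couch = couch, air_gap = air_gap),
            class = "pbs_field")
}

#' @export
print.pbs_field <- function(x, ...) {
  cat(sprintf("<pbs_field> %d spots, %d energy layer(s), %s range shifter, %.0f MU total\n",
              nrow(x$spots), length(unique(x$spots$energy)),
              if (x$range_shifter) "with" else "no", sum(x$spots$mu)))
  invisible(x)
}

#' Square scanned field of monoenergetic spots
#'
#' @param energy Nominal energy, MeV.
#' @param side_mm Field side, mm.
#' @param spacing Spot spacing, mm (default 4).
#' @param mu_per_spot MU per spot (default 1).
#' @param edge `"inclusive"`: spots at both edges, `(side/spacing + 1)^2`
#'   spots; `"exclusive"`: `(side/spacing)^2` spots centered on the axis (the
#'   625-spot reference field over 100 x 100 mm^2 uses this mode).
#' @param range_shifter Logical.
#' @return A `pbs_field`.
#' @export
make_square_field <- function(energy, side_mm, spacing = 4, mu_per_spot = 1,
                              edge = c("inclusive", "exclusive"),
                              range_shifter = FALSE) {
  edge <- match.arg(edge)
  k <- if (edge == "inclusive") floor(side_mm / spacing) + 1
       else max(round(side_mm / spacing), 1)
  if (side_mm < spacing) k <- 1
  pos <- (seq_len(k) - (k + 1) / 2) * spacing
  g <- expand.grid(x = pos, y = pos)
  pbs_field(data.frame(energy = energy, x = g$x, y = g$y, mu = mu_per_spot),
            range_shifter = range_shifter)
}

#' Build a spread-out Bragg peak field
#'
#' Selects energy layers so the distal layer's r80 equals `range_mm` and the
#' proximal layer reaches `range_mm - modulation_mm`, with layer spacing of
#' about 80% of the pristine-peak FWHM, then solves non-negative
#' least-squares layer weights on simulated central-axis depth-dose curves
#' for a flat dose across the modulation region.
#'
#' @param range_mm Nominal range (distal r80), mm.
#' @param modulation_mm Nominal modulation width, mm (0 gives a single layer).
#' @param machine A [machine_model()]; must cover the required energies
#'   (with the range shifter for shallow ranges).
#' @param field_mm Lateral field size (square, inclusive edges), mm.
#' @param n_per_layer Protons per layer depth-dose simulation.
#' @param use_range_shifter Logical; subtracts the range-shifter WET from the
#'   required water ranges.
#' @param seed RNG seed for the layer simulations.
#' @return A `pbs_sobp`: the `pbs_field` plus `layers` (energy, weight),
#'   per-layer depth-dose curves and the composite central-axis curve.
#' @export
make_sobp <- function(range_mm, modulation_mm, machine, field_mm = 96,
                      n_per_layer = 5e4, use_range_shifter = FALSE,
                      seed = 1L) {
  water <- builtin_material("water")
  rs_wet <- if (use_range_shifter)
    wet(machine$range_shifter$material, machine$range_shifter$thickness_mm)
  else 0
  energy_for_range <- function(r_mm)
    energy_from_range(water, (r_mm + rs_wet) / 10 * water$density)
  e_band <- range(machine$energy_table$nominal)
  e_distal <- energy_for_range(range_mm)
  if (e_distal > e_band[2] || energy_for_range(max(range_mm - modulation_mm,
                                                   10)) < e_band[1])
    stop("requested range/modulation infeasible for the commissioned band")
  # layer spacing ~ 80% of the pristine peak FWHM (straggling + spectrum)
  sig_r <- 0.012 * range_mm
  p <- interpolate_machine(machine, min(max(e_distal, e_band[1]), e_band[2]))
  sig_e_mm <- p$spread_pct / 100 * p$mean_energy *
    10 / (.mass_stopping_power(water, p$mean_energy) * water$density)
  step <- 0.8 * 2.355 * sqrt(sig_r^2 + sig_e_mm^2)
  r_targets <- if (modulation_mm <= 0) range_mm
               else rev(seq(range_mm - modulation_mm, range_mm, by = step))
  if (r_targets[1] < range_mm - 1e-9) r_targets <- c(range_mm, r_targets)
  energies <- vapply(r_targets, energy_for_range, numeric(1))
  energies <- pmin(pmax(energies, e_band[1]), e_band[2])
  curves <- lapply(seq_along(energies), function(i) {
    pi <- interpolate_machine(machine, energies[i])
    mean_e <- if (use_range_shifter)
      csda_exit_energy(machine$range_shifter$material,
                       machine$range_shifter$thickness_mm, pi$mean_energy)
    else pi$mean_energy
    simulate_idd(mean_e, pi$spread_pct, n = n_per_layer, seed = seed + i)
  })
  if (modulation_mm <= 0) {
    w <- 1
  } else {
    grid <- seq(range_mm - modulation_mm + 2, range_mm - 2, by = 1)
    A <- vapply(curves, function(cv)
      approx(cv$depth, cv$dose, xout = grid, rule = 2)$y, numeric(length(grid)))
    w <- pracma::lsqnonneg(A, rep(1, length(grid)))$x
    w <- w / max(w)
  }
  spots <- do.call(rbind, lapply(seq_along(energies), function(i) {
    if (w[i] <= 1e-8) return(NULL)
    f <- make_square_field(energies[i], field_mm, mu_per_spot = w[i])
    f$spots
  }))
  depth_grid <- seq(0.25, range_mm + 15, by = 0.5)
  comp <- Reduce(`+`, lapply(seq_along(curves), function(i)
    w[i] * approx(curves[[i]]$depth, curves[[i]]$dose, xout = depth_grid,
                  rule = 2)$y))
  out <- pbs_field(spots, range_shifter = use_range_shifter)
  out$layers <- data.frame(energy = energies, r80_target = r_targets,
                           weight = w)
  out$layer_curves <- curves
  out$central_axis <- data.frame(depth = depth_grid, dose = comp)
  class(out) <- c("pbs_sobp", class(out))
  out
}

#' SOBP flatness over the modulation region
#'
#' Maximum relative deviation of the composite central-axis dose from its
#' mean across `[range - modulation + margin, range - margin]`.
#'
#' @param sobp A [make_sobp()] result.
#' @param margin_mm Margins excluded at both ends of the modulation region.
#' @return Fractional deviation (e.g. 0.02 = 2%).
#' @export
sobp_flatness <- function(sobp, margin_mm = 2) {
  rng <- max(sobp$layers$r80_target); mod <- rng - min(sobp$layers$r80_target)
  sel <- sobp$central_axis$depth >= rng - mod + margin_mm &
         sobp$central_axis$depth <= rng - margin_mm
  d <- sobp$central_axis$dose[sel]
  max(abs(d - mean(d))) / mean(d)
}

# ---- JSON plan I/O -----------------------------------------------------------

#' Write / read treatment plans (versioned JSON)
#'
#' The dialect stores a list of fields, each with its range-shifter flag,
#' gantry/couch angles, air gap and spot list (energy, x, y, mu). Reading
#' validates the schema and reports the index of any offending spot.
#'
#' @param plan A `pbs_field` or list of them.
#' @param path File path.
#' @export
write_plan <- function(plan, path) {
  if (inherits(plan, "pbs_field")) plan <- list(plan)
  obj <- list(format = "pbsmc-plan", version = 1,
              fields = lapply(plan, function(f)
                list(range_shifter = f$range_shifter, gantry = f$gantry,
                     couch = f$couch, air_gap = f$air_gap,
                     spots = f$spots[, c("energy", "x", "y", "mu")])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_plan
#' @return `read_plan()` returns a list of `pbs_field` objects.
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "pbsmc-plan")
    stop("not a pbsmc plan file: ", path)
  lapply(seq_along(obj$fields), function(i) {
    f <- obj$fields[[i]]
    rows <- lapply(seq_along(f$spots), function(j) {
      s <- f$spots[[j]]
      for (col in c("energy", "x", "y", "mu"))
        if (is.null(s[[col]]) || !is.numeric(s[[col]]))
          stop("field ", i, ", spot ", j, ": missing or invalid '", col, "'")
      data.frame(energy = s$energy, x = s$x, y = s$y, mu = s$mu)
    })
    pbs_field(do.call(rbind, rows), range_shifter = isTRUE(f$range_shifter),
              gantry = f$gantry %||% 0, couch = f$couch %||% 0,
              air_gap = f$air_gap)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
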