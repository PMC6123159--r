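# Condensed-history transport: determinism, conservation, range-shifter
# traversal, depth-dose and lateral-spread physics.

test_that("vacuum regions give straight-line transport with unchanged energy", {
  g <- geometry(list(region_vacuum(100, -50)))
  b <- pbsmc:::pencil_batch(150, 10, z0 = 100)
  b$dx <- rep(0.1, 10); b$dz <- rep(-sqrt(1 - 0.01), 10)
  out <- transport(b, g, collect_exit = TRUE, seed = 1)
  expect_equal(unname(out$exit[, "energy"]), rep(150, 10))
  expect_equal(unname(out$exit[, "x"]), rep(0.1 * 150 / sqrt(0.99), 10),
               tolerance = 1e-9)
  expect_equal(out$e_deposited, 0)
})

test_that("identical seeds give bit-identical results", {
  g <- geom_water_phantom(60, 0)
  run <- function() {
    set.seed(77)
    b <- pbsmc:::pencil_batch(100, 5000, z0 = 0)
    transport(b, g, scorers = list(idd = scorer_idd(0, 60)))
  }
  a <- run(); b <- run()
  expect_identical(a$idd, b$idd)
  expect_identical(a$e_deposited, b$e_deposited)
})

test_that("energy bookkeeping closes to 0.1%", {
  lex <- builtin_material("lexan")
  g <- geometry(list(region_slab(lex, 460, 395)))
  set.seed(5)
  b <- pbsmc:::pencil_batch(115, 2e4, z0 = 460)
  out <- transport(b, g, collect_exit = TRUE)
  closure <- out$e_deposited + out$e_neutral + out$e_exit + out$e_lateral
  expect_equal(closure / out$e_initial, 1, tolerance = 1e-3)
})

test_that("range-shifter traversal matches the primary budget scale", {
  lex <- builtin_material("lexan")
  g <- geometry(list(region_slab(lex, 460, 395)))
  set.seed(8)
  b <- pbsmc:::pencil_batch(115, 1e5, z0 = 460)
  out <- transport(b, g, collect_exit = TRUE)
  surv <- 100 * out$n_exit_primary / 1e5
  expect_equal(surv, 91.04, tolerance = 0.02)   # paper-scale survival
  expect_equal(out$e_exit_primary / out$n_exit_primary, 54.6,
               tolerance = 3 / 54.6)            # mean exit energy
  # deterministic CSDA cross-check
  expect_equal(csda_exit_energy(lex, 65, 115), 54.6, tolerance = 3 / 54.6)
  expect_equal(csda_exit_energy(lex, 65, 225), 193.5, tolerance = 2 / 193.5)
})

test_that("simulated Bragg peak lands at the CSDA range", {
  w <- builtin_material("water")
  idd <- simulate_idd(100, 0, n = 4e4, seed = 12)
  expect_equal(r80(idd), csda_range(w, 100) * 10, tolerance = 1 / 77)
})

test_that("normalized depth-dose is invariant under particle count", {
  a <- simulate_idd(100, 0.5, n = 2e4, seed = 21)
  b <- simulate_idd(100, 0.5, n = 4e4, seed = 22)
  sel <- a$depth < 70
  expect_lt(mean(abs(a$dose[sel] - b$dose[sel])) / mean(a$dose[sel]), 0.05)
})

test_that("peak-to-plateau ratio falls and FWHM grows with energy spread", {
  lo <- simulate_idd(100, 0.3, n = 4e4, seed = 31)
  hi <- simulate_idd(100, 1.0, n = 4e4, seed = 32)
  expect_gt(peak_to_plateau(lo), peak_to_plateau(hi))
  expect_lt(fwhm(lo), fwhm(hi))
})

test_that("survival versus depth follows the nonelastic quadrature", {
  w <- builtin_material("water")
  nt <- nuclear_table()
  for (d in c(30, 60)) {
    g <- geom_water_phantom(d, 0)
    set.seed(40 + d)
    b <- pbsmc:::pencil_batch(115, 5e4, z0 = 0)
    out <- transport(b, g, nuclear = nt, collect_exit = FALSE)
    surv_mc <- out$n_exit_primary / 5e4
    surv_q <- 1 - nonelastic_probability(w, d, 115, nt)
    expect_equal(surv_mc, surv_q, tolerance = 0.003 / surv_q)
  }
})

test_that("in-water spot sigma matches Fermi-Eyges quadrature within 3%", {
  vm <- test_machine()
  w <- builtin_material("water")
  p <- interpolate_machine(vm, 115)
  r_mm <- csda_range(w, p$mean_energy) * 10
  fe_sigma <- function(d) {
    zs <- seq(0.5, d, by = 1)
    acc <- 0
    for (z in zs) {
      e <- energy_from_range(w, (r_mm - z) / 10)
      if (e < 3) break
      acc <- acc + mcs_sigma(w, 1, e, cumulative_mm = max(z, 1))^2 * (d - z)^2
    }
    sqrt(sigma_at(p$optics_x, -d)^2 + acc)
  }
  geom <- beam_geometry(vm, geom_water_phantom(300, 0))
  depths <- c(30, 60, 90)
  ss <- spot_sigma_at_planes(vm, 115, -depths, geom, n = 6e4, seed = 51)
  for (i in seq_along(depths))
    expect_equal(ss$sigma_x[i], fe_sigma(depths[i]), tolerance = 0.03)
  # monotone growth with depth until near end of range
  expect_true(all(diff(ss$sigma) > 0))
})

test_that("spot after the range shifter widens with air gap", {
  vm <- test_machine()
  g <- beam_geometry(vm, phantom = NULL, use_range_shifter = TRUE,
                     plane_z = 230)
  set.seed(61)
  b <- sample_spot_phase_space(vm, 115, c(0, 0), 3e4)
  out <- transport(b, g, collect_exit = TRUE)
  ex <- out$exit
  prim <- ex[ex[, "species"] == 0, ]
  drift_sd <- function(gap) {
    t <- gap / (-prim[, "dz"])
    sd(prim[, "x"] + t * prim[, "dx"])
  }
  expect_gt(drift_sd(150), drift_sd(5))
})

test_that("split fields superpose linearly", {
  vm <- test_machine()
  k <- cached("kernel115_small",
              simulate_kernel(vm, 115, n = 1e5, depth_mm = 90, seed = 71))
  f_full <- make_square_field(115, 40)
  left <- f_full$spots[f_full$spots$x < 0, ]
  right <- f_full$spots[f_full$spots$x >= 0, ]
  d_full <- field_central_dose(k, f_full, depths = c(20, 50))$dose
  d_l <- field_central_dose(k, pbs_field(left), depths = c(20, 50))$dose
  d_r <- field_central_dose(k, pbs_field(right), depths = c(20, 50))$dose
  expect_equal(d_l + d_r, d_full, tolerance = 1e-12)
})

test_that("3D field simulation produces a uniform central region and DVH", {
  vm <- test_machine()
  f <- make_square_field(115, 40, spacing = 4)
  phantom <- geom_water_phantom(60, 0)
  grid <- scorer_grid(origin = c(-40, -40, -60), spacing = 2,
                      dims = c(40, 40, 30))
  dg <- cached("grid115", simulate_field(vm, f, phantom, grid,
                                         n_per_spot = 800, n_batches = 2,
                                         seed = 81))
  expect_s3_class(dg, "pbs_dose_grid")
  expect_true(all(dg$dose >= 0))
  # central 10x10 mm^2 at 30 mm depth uniform within a few percent
  ix <- 16:25; iz <- 16  # voxel centers at -9..9 mm, depth 29-31 mm
  sl <- dg$dose[ix, ix, iz]
  expect_lt(sd(sl) / mean(sl), 0.1)
  expect_false(is.null(dg$uncertainty))
})

test_that("transport rejects non-normal incidence and bad batches", {
  vm <- test_machine()
  f <- make_square_field(115, 20)
  f$gantry <- 90
  expect_error(simulate_field(vm, f, geom_water_phantom(50),
                              scorer_grid(c(-20, -20, -50), 2, c(20, 20, 25)),
                              n_per_spot = 10),
               "incidence")
  b <- pbsmc:::pencil_batch(100, 5, z0 = 0)
  b$energy[2] <- NaN
  expect_error(transport(b, geom_water_phantom(50)), "non-finite")
})
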