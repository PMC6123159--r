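# Commissioning chain: depth-dose metrics, mean-energy and spread tuning,
# protons-per-MU calibration, end-to-end recovery.

test_that("r80 finds the constructed distal crossing and is scale invariant", {
  depth <- seq(0, 120, by = 0.5)
  # peak 100 at 100 mm, distal edge crossing 80 at 103.5 mm by construction
  dose <- ifelse(depth <= 100, 30 + 0.7 * depth,
                 100 - 20 * (depth - 100) / 3.5)
  curve <- data.frame(depth = depth, dose = pmax(dose, 0))
  expect_equal(r80(curve), 103.5, tolerance = 1e-6)
  curve2 <- transform(curve, dose = dose * 7.3)
  expect_equal(r80(curve2), r80(curve))
  expect_error(r80(data.frame(depth = 1:10, dose = 1:10)), "maximum")
})

test_that("mean-energy tuning inverts the range table and closes the loop", {
  w <- builtin_material("water")
  idd <- test_idd100()
  te <- tune_mean_energy(r80(idd), spread_pct = 0.67, n = 5e4, seed = 56)
  # initial estimate from table inversion is already close to 100 MeV
  expect_equal(te$initial_estimate, 100, tolerance = 0.01)
  expect_equal(te$mean_energy, 100, tolerance = 0.005)
  expect_lte(abs(tail(te$iterations$delta, 1)), 0.1)
  expect_true(te$converged)
  expect_error(tune_mean_energy(1e5), "span")
})

test_that("self-comparison gives a zero spread-tuning objective", {
  meas <- simulate_idd(100, 0.5, n = 2e4, seed = 99)
  ts <- tune_energy_spread(meas, 100, grid_resolution = 0.25,
                           max_sigma_mev = 1.0, n = 2e4, seed = 99)
  # the 0.5 MeV candidate was simulated with the measured curve's seed
  obj <- ts$trace$objective
  expect_equal(ts$sigma_mev, 0.5)
  expect_lt(obj[ts$trace$sigma_mev == 0.5], 1e-12)
})

test_that("spread tuning recovers the fixture value on a coarse grid", {
  idd <- test_idd100()
  ts <- tune_energy_spread(idd, 100, grid_resolution = 0.1,
                           max_sigma_mev = 1.2, n = 5e4, seed = 57)
  expect_equal(ts$sigma_mev, 0.67, tolerance = 0.16)  # within ~one 0.1 step
  # objective trace: peak-to-plateau monotone in the candidate sweep
  p2p <- sapply(c(0.3, 0.7, 1.1), function(sg)
    peak_to_plateau(simulate_idd(100, sg, n = 5e4, seed = 58)))
  expect_true(all(diff(p2p) < 0))
})

test_that("protons-per-MU calibration is Eq.-4 arithmetic and linear", {
  expect_equal(calibrate_protons_per_mu(2, 1, 1), 2)
  expect_equal(calibrate_protons_per_mu(1.5, 3e-9, 1e5), 1.5 / (3e-9 / 1e5))
  # doubling the measured dose doubles N_MU exactly
  expect_equal(calibrate_protons_per_mu(2.4, 5e-9, 1e5),
               2 * calibrate_protons_per_mu(1.2, 5e-9, 1e5))
  expect_error(calibrate_protons_per_mu(-1, 1, 1), "positive")
})

test_that("protons-per-MU recovery and air-stopping-power proportionality", {
  vm <- test_machine()
  air <- builtin_material("air")
  ens <- c(100, 225)
  nmu <- sapply(seq_along(ens), function(i) {
    p <- interpolate_machine(vm, ens[i])
    d_meas <- p$protons_per_mu *
      simulate_reference_dose(vm, ens[i], n = 5e4, seed = 800 + i)
    calibrate_protons_per_mu(d_meas,
                             simulate_reference_dose(vm, ens[i], n = 5e4,
                                                     seed = 900 + i), 1)
  })
  truth <- sapply(ens, function(e) interpolate_machine(vm, e)$protons_per_mu)
  expect_equal(nmu, truth, tolerance = 0.01)   # recovery within MC noise
  prod <- nmu * stopping_power(air, ens)
  expect_lt(abs(diff(prod)) / mean(prod), 0.015)
})

test_that("commission recovers a two-energy fixture and flags failures", {
  vm <- test_machine()
  ms <- cached("ms2", generate_measurement_set(
    vm, energies = c(100, 150), n_idd = 5e4, n_ref = 5e4, seed = 5))
  res <- cached("comm2", {
    # coarse spread grid keeps the unit test fast; the acceptance suite runs
    # the 0.05 MeV grid
    commission(ms, n_idd = 5e4, n_ref = 5e4, spread_grid_mev = 0.15, seed = 6)
  })
  tab <- res$machine$energy_table
  truth <- vm$energy_table[vm$energy_table$nominal %in% c(100, 150), ]
  expect_equal(tab$mean_energy, truth$mean_energy, tolerance = 0.005)
  expect_equal(tab$x_sigma0, truth$x_sigma0, tolerance = 0.03)
  expect_equal(tab$y_sigma_theta, truth$y_sigma_theta, tolerance = 0.06)
  expect_equal(tab$protons_per_mu, truth$protons_per_mu, tolerance = 0.02)
  expect_equal(tab$spread_pct, truth$spread_pct, tolerance = 0.3)
  expect_equal(res$machine$fx, 1859.1, tolerance = 0.002)
  expect_true(all(abs(res$report$delta_r80) <= 0.1))

  # a missing depth-dose curve fails that energy, not the whole run
  ms_bad <- ms
  ms_bad$per_energy[["150"]]$idd <- NULL
  ms_bad$energies <- c(100, 150)
  expect_error(commission(ms_bad, n_idd = 2e4, n_ref = 2e4,
                          spread_grid_mev = 0.3, seed = 6),
               "all but")
  ms3 <- cached("ms3", {
    m <- generate_measurement_set(vm, energies = c(100, 150, 210),
                                  n_idd = 2e4, n_ref = 2e4, seed = 7)
    m$per_energy[["150"]]$idd <- NULL
    m
  })
  res3 <- commission(ms3, n_idd = 2e4, n_ref = 2e4, spread_grid_mev = 0.4,
                     seed = 8)
  expect_named(res3$failures, "150")
  expect_setequal(res3$machine$energy_table$nominal, c(100, 210))
})

test_that("measurement sets round-trip through the CSV+JSON bundle", {
  vm <- test_machine()
  ms <- cached("ms2", generate_measurement_set(
    vm, energies = c(100, 150), n_idd = 5e4, n_ref = 5e4, seed = 5))
  dir <- tempfile("bundle")
  write_measurement_set(ms, dir)
  back <- read_measurement_set(dir)
  expect_equal(back$energies, ms$energies)
  expect_equal(back$per_energy[["100"]]$idd, ms$per_energy[["100"]]$idd,
               tolerance = 1e-12)
  expect_equal(back$per_energy[["150"]]$ref_dose_gy,
               ms$per_energy[["150"]]$ref_dose_gy, tolerance = 1e-12)
  expect_equal(back$source_plane_z, ms$source_plane_z)
})
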