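# Courant-Snyder spot optics, scanning geometry and phase-space sampling.

test_that("sigma_at follows the drift quadratic", {
  p <- optics_params(5, 5, 0)
  expect_equal(sigma_at(p, 0), 5)
  # sigma0 = 5 mm, sigma_theta = 5 mrad, z = 200 mm -> sqrt(25 + 1)
  expect_equal(sigma_at(p, 200), sqrt(26), tolerance = 1e-12)
  # sigma^2 is an upward parabola with vertex at z = rho0 sigma0 / sigma_theta
  p2 <- optics_params(4, 6, 0.3)
  z_min <- p2$rho0 * p2$sigma0 / (p2$sigma_theta * 1e-3)
  expect_lt(sigma_at(p2, z_min), sigma_at(p2, z_min + 50))
  expect_lt(sigma_at(p2, z_min), sigma_at(p2, z_min - 50))
  eps <- 1
  expect_lt(sigma_at(p2, z_min), sigma_at(p2, z_min + eps))
})

test_that("rho_at has the drift closed form and sign convention", {
  p <- optics_params(5, 5, 0.2)
  expect_equal(rho_at(p, 0), 0.2)
  # a beam with rho0 = 0 at isocenter is focusing upstream of it
  p0 <- optics_params(5, 5, 0)
  expect_lt(rho_at(p0, 100), 0)
  expect_true(all(abs(rho_at(p, seq(-300, 500, by = 50))) <= 1))
})

test_that("matrix propagation and closed forms agree to 1e-10", {
  set.seed(4)
  for (i in 1:25) {
    p <- optics_params(runif(1, 2, 8), runif(1, 2, 8), runif(1, -0.9, 0.9))
    z <- runif(1, -200, 500)
    m <- pbsmc:::propagate_sigma_matrix(p, z)
    expect_equal(sqrt(m[1, 1]), sigma_at(p, z), tolerance = 1e-10)
    expect_equal(m[1, 2] / (sqrt(m[1, 1]) * sqrt(m[2, 2])), rho_at(p, z),
                 tolerance = 1e-10)
  }
})

test_that("fit_optics recovers parameters from in-air spot sizes", {
  planes <- c(455, 330, 200, 100, 0, -100)
  truth <- optics_params(5.4, 5.6, 0.18)
  clean <- data.frame(z = planes, sigma = sigma_at(truth, planes))
  f <- fit_optics(clean)
  expect_equal(f$params$sigma0, 5.4, tolerance = 1e-6)
  expect_equal(f$params$sigma_theta, 5.6, tolerance = 1e-6)
  expect_equal(f$params$rho0, 0.18, tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-9)
  expect_true(f$physical)

  # 1% sigma noise: median recovery over seeds within 2% / 5%
  set.seed(9)
  rec <- replicate(40, {
    noisy <- data.frame(z = planes,
                        sigma = sigma_at(truth, planes) * (1 + rnorm(6, 0, 0.01)))
    ff <- fit_optics(noisy)
    c(ff$params$sigma0, ff$params$sigma_theta)
  })
  expect_lt(abs(median(rec[1, ]) / 5.4 - 1), 0.02)
  expect_lt(abs(median(rec[2, ]) / 5.6 - 1), 0.05)

  expect_error(fit_optics(data.frame(z = c(0, 0, 0), sigma = c(5, 5, 5))),
               "distinct planes")
})

test_that("effective SAD fit matches the two-plane arithmetic", {
  # 100 * (f - 100) / f = 94.62  =>  f = 1858.736 (rounds to the printed fx)
  f <- fit_effective_sad(data.frame(z = c(0, 100), x = c(100, 94.62)))
  expect_equal(f, 1858.736, tolerance = 1e-3)
  # noise-free three-plane input gives the same line
  f3 <- fit_effective_sad(data.frame(z = c(0, 100, 200),
                                     x = 100 * (1859.1 - c(0, 100, 200)) / 1859.1))
  expect_equal(f3, 1859.1, tolerance = 1e-6)
  expect_warning(f_inf <- fit_effective_sad(data.frame(z = c(0, 100),
                                                       x = c(50, 50))),
                 "parallel")
  expect_equal(f_inf, Inf)
})

test_that("sampled phase space reproduces the isocenter optics after drift", {
  vm <- test_machine()
  set.seed(31)
  b <- sample_spot_phase_space(vm, 115, c(0, 0), 6e4)
  b0 <- drift_to_plane(b, 0)
  p <- interpolate_machine(vm, 115)
  expect_equal(sd(b0$x), p$optics_x$sigma0, tolerance = 0.02)
  expect_equal(sd(b0$y), p$optics_y$sigma0, tolerance = 0.02)
  tx <- b0$dx / (-b0$dz)
  expect_equal(sd(tx) * 1e3, p$optics_x$sigma_theta, tolerance = 0.02)
  expect_equal(cor(b0$x, tx), p$optics_x$rho0, tolerance = 0.05)
  # empirical sigma at the six planes follows the drift law
  for (z in c(455, 200, 0, -100)) {
    bz <- drift_to_plane(sample_spot_phase_space(vm, 115, c(0, 0), 3e4), z)
    expect_equal(sd(bz$x), sigma_at(p$optics_x, z), tolerance = 0.03)
  }
  # vacuum drift preserves the angular spread exactly
  expect_identical(sd(b$dx), sd(b0$dx))
})

test_that("scanned spots aim from the effective focal points", {
  vm <- test_machine()
  set.seed(32)
  b <- sample_spot_phase_space(vm, 150, c(100, -60), 2e4)
  expect_equal(mean(b$dx / (-b$dz)), 100 / vm$fx, tolerance = 0.02)
  expect_equal(mean(b$dy / (-b$dz)), -60 / vm$fy, tolerance = 0.02)
  b0 <- drift_to_plane(b, 0)
  expect_equal(mean(b0$x), 100, tolerance = 0.01)
  expect_equal(mean(b0$y), -60, tolerance = 0.01)
})

test_that("machine interpolation is linear, exact at nodes, banded", {
  vm <- test_machine()
  tab <- vm$energy_table
  at_node <- interpolate_machine(vm, 150)
  expect_equal(at_node$spread_pct, tab$spread_pct[tab$nominal == 150])
  expect_equal(at_node$optics_x$sigma0, tab$x_sigma0[tab$nominal == 150])
  mid <- interpolate_machine(vm, (100 + 115) / 2)
  expect_equal(mid$spread_pct,
               mean(tab$spread_pct[tab$nominal %in% c(100, 115)]))
  expect_equal(mid$protons_per_mu,
               mean(tab$protons_per_mu[tab$nominal %in% c(100, 115)]))
  expect_error(interpolate_machine(vm, 99), "band")
  expect_error(interpolate_machine(vm, 226), "band")
})

test_that("machine model JSON round-trips", {
  vm <- test_machine()
  path <- tempfile(fileext = ".json")
  write_machine(vm, path)
  back <- read_machine(path)
  expect_equal(back$energy_table, vm$energy_table, tolerance = 1e-12)
  expect_equal(back$fx, vm$fx)
  expect_equal(back$range_shifter$thickness_mm, 65)
  expect_equal(back$range_shifter$material$I, 73.1)
})
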