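# Material definitions and single-proton physics quantities.

test_that("material constructor enforces its invariants", {
  expect_error(material("m", data.frame(symbol = "H", fraction = 0.9), 1, 75),
               "sum to 1")
  expect_error(material("m", data.frame(symbol = "H", fraction = 1), -1, 75),
               "density")
  expect_error(material("m", data.frame(symbol = "H", fraction = 1), 1, 0),
               "excitation")
  expect_error(material("m", data.frame(symbol = "Xx", fraction = 1), 1, 75),
               "unknown element")
  lex <- builtin_material("lexan")
  expect_equal(sum(lex$composition$fraction), 1, tolerance = 1e-4)
  expect_equal(lex$density, 1.20)
  expect_equal(lex$I, 73.1)
})

test_that("Bethe stopping power matches PSTAR water values within 1%", {
  w <- builtin_material("water")
  s <- stopping_power(w, pstar_water$energy)
  expect_equal(s, pstar_water$stopping, tolerance = 0.01)
  # decreasing in energy across the clinical band
  e <- seq(10, 250, by = 5)
  expect_true(all(diff(stopping_power(w, e)) < 0))
  expect_true(all(diff(stopping_power(builtin_material("lexan"), e)) < 0))
  expect_error(stopping_power(w, 1), "cutoff")
})

test_that("CSDA ranges match PSTAR and invert exactly", {
  w <- builtin_material("water")
  r <- csda_range(w, pstar_water$energy)
  expect_equal(r, pstar_water$range, tolerance = 0.005)
  # inverse-function contract
  e <- c(5, 30, 70, 120, 180, 240)
  expect_equal(energy_from_range(w, csda_range(w, e)), e, tolerance = 1e-4)
  expect_true(csda_range(w, 150) > csda_range(w, 100))
  expect_error(csda_range(w, 400), "domain")
})

test_that("stopping power and range are mutually consistent (dR/dE = 1/S)", {
  lex <- builtin_material("lexan")
  for (e in c(20, 80, 160, 240)) {
    de <- 0.05
    drde <- (csda_range(lex, e + de) - csda_range(lex, e - de)) / (2 * de)
    expect_equal(drde, 1 / (stopping_power(lex, e) / lex$density),
                 tolerance = 1e-3)
  }
})

test_that("water-equivalent thickness reproduces the Lexan range shifter", {
  lex <- builtin_material("lexan")
  expect_equal(wet(lex, 65, 160), 74.1, tolerance = 0.5 / 74.1)
  # WET of water is the identity
  w <- builtin_material("water")
  expect_equal(wet(w, 50, 100), 50, tolerance = 1e-3)
  expect_equal(wet(w, 50, 225), 50, tolerance = 1e-3)
  # lung surrogate: RSP 0.31, so 10 mm has WET 3.1 mm
  expect_equal(wet(builtin_material("lung"), 10, 160), 3.1, tolerance = 0.02)
  # additivity over stacked slabs within 0.1 mm
  e_mid <- csda_exit_energy(lex, 30, 160)
  expect_equal(wet(lex, 30, 160) + wet(lex, 35, e_mid), wet(lex, 65, 160),
               tolerance = 0.1 / 74)
  expect_error(wet(lex, 500, 100), "stops inside")
  expect_equal(wet(lex, 0, 160), 0)
})

test_that("Bohr straggling has the closed form and variance additivity", {
  w <- builtin_material("water")
  # independent evaluation of the Bohr formula at 115 MeV over 74.1 mm
  e <- 115
  b2 <- 1 - (938.27209 / (e + 938.27209))^2
  expected <- sqrt(0.1569 * 0.555087 * 7.41 * (1 - b2 / 2) / (1 - b2))
  expect_equal(straggling_sigma(w, 74.1, 115), expected, tolerance = 1e-3)
  expect_equal(straggling_sigma(w, 0, 100), 0)
  # doubling a thin path doubles the variance
  s1 <- straggling_sigma(w, 5, 150)
  s2 <- straggling_sigma(w, 10, 150)
  expect_equal(s2^2 / s1^2, 2, tolerance = 0.05)
  expect_error(straggling_sigma(w, 1e4, 20), "residual range")
})

test_that("Highland MCS sigma has the closed form and energy ordering", {
  w <- builtin_material("water")
  expect_equal(mcs_sigma(w, 0, 150), 0)
  expect_gt(mcs_sigma(w, 10, 115), mcs_sigma(w, 10, 225))
  # direct formula evaluation as the oracle: 10 mm water at 150 MeV
  pv <- 150 * (150 + 2 * 938.27209) / (150 + 938.27209)
  t_x0 <- 1 / w$X0
  expected <- 14.1 / pv * sqrt(t_x0) * (1 + log10(t_x0) / 9)
  expect_equal(mcs_sigma(w, 10, 150), expected, tolerance = 1e-6)
})

test_that("nonelastic probability follows the exponential law", {
  lex <- builtin_material("lexan")
  w <- builtin_material("water")
  nt <- nuclear_table()
  expect_equal(nonelastic_probability(w, 0, 115), 0)
  # paper-scale primary loss through the range shifter
  expect_equal(nonelastic_probability(lex, 65, 115, nt), 0.0896,
               tolerance = 0.15)
  # survival over a split path factorizes
  s_tot <- 1 - nonelastic_probability(w, 60, 115, nt, n_steps = 1200)
  e_mid <- csda_exit_energy(w, 25, 115)
  s_a <- 1 - nonelastic_probability(w, 25, 115, nt, n_steps = 500)
  s_b <- 1 - nonelastic_probability(w, 35, e_mid, nt, n_steps = 700)
  expect_equal(s_tot, s_a * s_b, tolerance = 2e-6)
  # constant-Sigma limit: thin high-energy slab where Sigma is ~flat
  sig <- pbsmc:::.sigma_water_at(nt, 220)
  p <- nonelastic_probability(w, 10, 220, nt)
  expect_equal(p, 1 - exp(-sig * 1), tolerance = 0.01)
})

test_that("material config round-trips through JSON", {
  mats <- list(list(name = "lexan", density = 1.20, I = 73.1,
                    composition = list(C = 0.75575, O = 0.18876, H = 0.05549)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(mats, path, auto_unbox = TRUE, digits = NA)
  got <- read_materials(path)
  expect_named(got, "lexan")
  expect_equal(got$lexan$density, 1.20)
  expect_equal(wet(got$lexan, 65, 160), wet(builtin_material("lexan"), 65, 160))
  # the shipped example config parses to the built-in definitions
  shipped <- read_materials(system.file("extdata", "materials_example.json",
                                        package = "pbsmc"))
  expect_setequal(names(shipped), c("lexan", "solid_water"))
  expect_equal(shipped$solid_water$density, 1.044)
})
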