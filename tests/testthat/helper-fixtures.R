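# Shared fixtures for the test suite. Heavy Monte Carlo artifacts are built
# lazily and cached for the session so several test files can reuse them.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

test_machine <- function() cached("vm", make_virtual_machine())

# 100 MeV "measured" depth-dose at ground-truth spread 0.67%
test_idd100 <- function(n = 1e5)
  cached("idd100", simulate_idd(100, 0.67, n = n, seed = 101))

# PSTAR water reference values (NIST): energy MeV, mass stopping power
# MeV cm^2/g, CSDA range g/cm^2
pstar_water <- data.frame(
  energy = c(10, 50, 100, 150, 200, 250),
  stopping = c(45.67, 12.45, 7.289, 5.445, 4.492, 3.911),
  range = c(0.1230, 2.227, 7.718, 15.77, 25.96, 37.94)
)

# error-function lateral edge profile with Gaussian penumbra sigma
erf_edge_profile <- function(sigma, half_width = 50, dx = 0.1) {
  x <- seq(-half_width - 30, half_width + 30, by = dx)
  d <- (pnorm((half_width - x) / sigma) - pnorm((-half_width - x) / sigma))
  data.frame(x = x, dose = d / max(d))
}
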