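#' @useDynLib pbsmc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx splinefun lm coef rnorm runif quantile approxfun sd uniroot
#' @importFrom utils head tail modifyList
"_PACKAGE"

# element lookup used to derive <Z/A> and radiation lengths from mass fractions
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "Ar", "K", "Ca", "Fe"),
  Z = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20, 26),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06, 35.45,
        39.948, 39.098, 40.078, 55.845),
  stringsAsFactors = FALSE
)

#' Define a material for proton transport
#'
#' A material is defined by its elemental mass fractions, mass density and
#' mean excitation energy (I-value). These three quantities fix the Bethe
#' electronic stopping power, the radiation length used by the Highland
#' multiple-scattering formula, and hence the range-energy tables of the
#' transport engine.
#'
#' @param name Character label.
#' @param composition Data frame with columns `symbol` (element symbol) and
#'   `fraction` (mass fraction); fractions must sum to 1 within 1e-4.
#' @param density Mass density in g/cm^3.
#' @param I Mean excitation energy in eV.
#' @return An object of class `pbs_material`.
#' @examples
#' lex <- material("lexan",
#'   data.frame(symbol = c("C", "O", "H"),
#'              fraction = c(0.75575, 0.18876, 0.05549)),
#'   density = 1.20, I = 73.1)
#' @export
material <- function(name, composition, density, I) {
  stopifnot(is.character(name), is.data.frame(composition),
            all(c("symbol", "fraction") %in% names(composition)))
  if (density <= 0) stop("density must be positive")
  if (I <= 0) stop("mean excitation energy must be positive")
  if (abs(sum(composition$fraction) - 1) > 1e-4)
    stop("mass fractions must sum to 1 within 1e-4 (got ",
         format(sum(composition$fraction)), ")")
  idx <- match(composition$symbol, .elements$symbol)
  if (anyNA(idx))
    stop("unknown element symbol(s): ",
         paste(composition$symbol[is.na(idx)], collapse = ", "))
  comp <- data.frame(symbol = composition$symbol,
                     fraction = composition$fraction,
                     Z = .elements$Z[idx], A = .elements$A[idx],
                     stringsAsFactors = FALSE)
  # Tsai-approximation radiation length per element, combined by mass fraction
  x0_el <- 716.408 * comp$A / (comp$Z * (comp$Z + 1) * log(287 / sqrt(comp$Z)))
  obj <- structure(list(
    name = name,
    composition = comp,
    density = density,
    I = I,
    z_over_a = sum(comp$fraction * comp$Z / comp$A),
    X0 = 1 / sum(comp$fraction / x0_el)   # g/cm^2
  ), class = "pbs_material")
  obj
}

#' @export
print.pbs_material <- function(x, ...) {
  cat(sprintf("<pbs_material> %s  (rho = %.5g g/cm^3, I = %.4g eV, <Z/A> = %.4f, X0 = %.2f g/cm^2)\n",
              x$name, x$density, x$I, x$z_over_a, x$X0))
  print(x$composition[, c("symbol", "fraction")], row.names = FALSE)
  invisible(x)
}

#' Built-in materials
#'
#' Returns one of the materials used throughout the package: `water`
#' (I = 75.0 eV), `air`, `lexan` (the range-shifter polycarbonate:
#' C 75.575%, O 18.876%, H 5.549%, density 1.20 g/cm^3, I = 73.1 eV),
#' `solid_water` (vendor epoxy formulation) and `lung` (a low-density
#' water-like surrogate with relative stopping power 0.31).
#'
#' @param name One of `"water"`, `"air"`, `"lexan"`, `"solid_water"`, `"lung"`.
#' @return A `pbs_material`.
#' @export
builtin_material <- function(name = c("water", "air", "lexan", "solid_water", "lung")) {
  name <- match.arg(name)
  switch(name,
    water = material("water",
      data.frame(symbol = c("H", "O"), fraction = c(0.111894, 0.888106)),
      density = 1.0, I = 75.0),
    air = material("air",
      data.frame(symbol = c("C", "N", "O", "Ar"),
                 fraction = c(0.000124, 0.755268, 0.231781, 0.012827)),
      density = 1.20479e-3, I = 85.7),
    lexan = material("lexan",
      data.frame(symbol = c("C", "O", "H"),
                 fraction = c(0.75575, 0.18876, 0.05549)),
      density = 1.20, I = 73.1),
    solid_water = material("solid_water",
      data.frame(symbol = c("C", "O", "H", "N", "Ca", "Cl"),
                 fraction = c(0.6717, 0.1988, 0.0809, 0.0241, 0.0231, 0.0014)),
      density = 1.044, I = 67.0),
    lung = material("lung",
      data.frame(symbol = c("H", "O"), fraction = c(0.111894, 0.888106)),
      density = 0.31, I = 75.0)
  )
}

#' Read material definitions from a JSON or YAML config
#'
#' The config is a list of objects with fields `name`, `density`, `I` and
#' `composition` (map of element symbol to mass fraction).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Named list of `pbs_material` objects.
#' @export
read_materials <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML material configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  mats <- lapply(raw, function(m) {
    comp <- data.frame(symbol = names(m$composition),
                       fraction = unlist(m$composition, use.names = FALSE))
    material(m$name, comp, m$density, m$I)
  })
  names(mats) <- vapply(mats, function(m) m$name, character(1))
  mats
}
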