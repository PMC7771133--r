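#' Recipe for a synthetic reflectance spectrum
#'
#' Parametric shapes covering the qualitative taxonomy of natural reflectance
#' curves: `sigmoid` (logistic step — UV-absorbing white, yellow, red,
#' depending on the inflection wavelength), `bell` (Gaussian bump — green),
#' `flat` (gray series), and `step` (hard threshold, useful for boundary
#' tests). Optional additive Gaussian noise (clipped at 0) makes fixtures
#' resemble spectrometer output; noise-free recipes are bitwise reproducible
#' and seeded noise is deterministic.
#'
#' @param shape one of `"sigmoid"`, `"bell"`, `"flat"`, `"step"`
#' @param center inflection (sigmoid/step) or peak (bell) wavelength in nm;
#'   ignored for `flat`
#' @param width steepness scale (sigmoid: logistic scale; bell: Gaussian sd),
#'   in nm
#' @param floor,ceiling reflectance limits in \[0, 1\], `floor <= ceiling`;
#'   a `flat` spectrum sits at `ceiling`
#' @param noise_sd sd of additive Gaussian noise (0 = none)
#' @param seed integer seed for the noise
#' @return object of class `spectrum_recipe`
#' @export
spectrum_recipe <- function(shape = c("sigmoid", "bell", "flat", "step"),
                            center = 500, width = 20, floor = 0, ceiling = 1,
                            noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  if (floor > ceiling) stop("floor must be <= ceiling", call. = FALSE)
  if (floor < 0 || ceiling > 1) {
    stop("floor and ceiling must lie in [0, 1]", call. = FALSE)
  }
  if (width <= 0 && shape %in% c("sigmoid", "bell")) {
    stop("width must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(shape = shape, center = center, width = width, floor = floor,
                 ceiling = ceiling, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spectrum_recipe")
}

#' Generate a reflectance spectrum from a recipe
#'
#' Deterministic for a fixed seed. The sigmoid is a logistic in wavelength
#' with its inflection (fastest increase, value halfway between floor and
#' ceiling) at `center`; the bell is a Gaussian bump peaking at `center`.
#' For non-flat shapes `center` must lie within the grid.
#'
#' @param recipe [spectrum_recipe()]
#' @param grid [wavelength_grid()] (default 300-700 nm at 1 nm)
#' @return reflectance [spectrum()]
#' @examples
#' r <- generate_spectrum(spectrum_recipe("sigmoid", center = 400),
#'                        wavelength_grid(300, 700, 1))
#' r$values[r$wl == 400] # 0.5
#' @export
generate_spectrum <- function(recipe, grid = wavelength_grid(300, 700, 1)) {
  stopifnot(inherits(recipe, "spectrum_recipe"), inherits(grid, "wavelength_grid"))
  wl <- grid$wl
  if (recipe$shape != "flat" &&
      (recipe$center < grid$lambda_min || recipe$center > grid$lambda_max)) {
    stop("recipe center lies outside the wavelength grid", call. = FALSE)
  }
  lo <- recipe$floor; hi <- recipe$ceiling
  v <- switch(recipe$shape,
    sigmoid = lo + (hi - lo) / (1 + exp(-(wl - recipe$center) / recipe$width)),
    bell    = lo + (hi - lo) * exp(-(wl - recipe$center)^2 / (2 * recipe$width^2)),
    flat    = rep(hi, length(wl)),
    step    = ifelse(wl < recipe$center, lo, hi)
  )
  if (recipe$noise_sd > 0) {
    v <- v + withr_seed(recipe$seed, stats::rnorm(length(v), 0, recipe$noise_sd))
    v[v < 0] <- 0
  }
  suppressWarnings(spectrum(wl, v, "reflectance"))
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Built-in fixture suite of synthetic spectra
#'
#' A named set of noise-free reflectance spectra spanning the shape taxonomy:
#' `uv_white` (sigmoid, inflection 400 nm — reflective except in the UV),
#' `yellow` (sigmoid, 500 nm), `red` (sigmoid, 600 nm), `green` (bell,
#' 550 nm), a gray series `gray_05` ... `gray_95` (flat at 0.05-0.95),
#' `black` (flat at 0.001 — not exactly 0, which would make chromatic
#' coordinates undefined), and `white_standard` (flat at 1).
#'
#' @param grid [wavelength_grid()] (default 300-700 nm at 1 nm)
#' @return named list of reflectance [spectrum()] objects
#' @export
fixture_suite <- function(grid = wavelength_grid(300, 700, 1)) {
  recipes <- list(
    uv_white       = spectrum_recipe("sigmoid", center = 400, width = 15,
                                     floor = 0.02, ceiling = 0.9),
    yellow         = spectrum_recipe("sigmoid", center = 500, width = 15,
                                     floor = 0.02, ceiling = 0.8),
    red            = spectrum_recipe("sigmoid", center = 600, width = 12,
                                     floor = 0.02, ceiling = 0.7),
    green          = spectrum_recipe("bell", center = 550, width = 40,
                                     floor = 0.03, ceiling = 0.45),
    gray_05        = spectrum_recipe("flat", ceiling = 0.05),
    gray_25        = spectrum_recipe("flat", ceiling = 0.25),
    gray_50        = spectrum_recipe("flat", ceiling = 0.50),
    gray_75        = spectrum_recipe("flat", ceiling = 0.75),
    gray_95        = spectrum_recipe("flat", ceiling = 0.95),
    black          = spectrum_recipe("flat", ceiling = 0.001),
    white_standard = spectrum_recipe("flat", ceiling = 1)
  )
  out <- lapply(recipes, generate_spectrum, grid = grid)
  for (nm in names(out)) out[[nm]]$name <- nm
  out
}

#' Write the fixture suite as a spectra CSV
#'
#' @param dir output directory (created if needed)
#' @param grid [wavelength_grid()]
#' @return path of the written CSV, invisibly
#' @export
write_fixtures <- function(dir, grid = wavelength_grid(300, 700, 1)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "synthetic_spectra.csv")
  write_spectra(fixture_suite(grid), path)
  invisible(path)
}
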