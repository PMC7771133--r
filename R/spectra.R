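#' Uniform wavelength grid
#'
#' A uniform sampling grid in wavelength, the common domain for all spectra in
#' the package. Sample points are `lambda_min, lambda_min + step, ...,
#' lambda_max`; the range must be an integer multiple of the step.
#'
#' @param lambda_min,lambda_max range endpoints in nm (`lambda_min <
#'   lambda_max`)
#' @param step bin width in nm (> 0)
#' @return an object of class `wavelength_grid` with fields `lambda_min`,
#'   `lambda_max`, `step`, and the vector of sample points `wl`
#' @examples
#' g <- wavelength_grid(300, 700, 1)
#' length(g$wl) # 401
#' @export
wavelength_grid <- function(lambda_min, lambda_max, step) {
  stopifnot(is.numeric(lambda_min), is.numeric(lambda_max), is.numeric(step))
  if (!(lambda_min < lambda_max)) {
    stop("lambda_min must be smaller than lambda_max", call. = FALSE)
  }
  if (step <= 0) stop("step must be positive", call. = FALSE)
  k <- (lambda_max - lambda_min) / step
  if (abs(k - round(k)) > 1e-8) {
    stop("(lambda_max - lambda_min) must be an integer multiple of step",
         call. = FALSE)
  }
  wl <- lambda_min + step * seq(0L, round(k))
  structure(
    list(lambda_min = lambda_min, lambda_max = lambda_max, step = step,
         wl = wl),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$lambda_min, x$lambda_max, x$step, length(x$wl)))
  invisible(x)
}

grid_of <- function(wl) {
  # reconstruct a wavelength_grid from a vector of sample points
  d <- diff(wl)
  wavelength_grid(wl[1L], wl[length(wl)], d[1L])
}

spectrum_kinds <- c("reflectance", "illuminant", "radiance")

#' Wavelength-sampled spectrum
#'
#' The package's basic container: a non-negative function of wavelength
#' sampled on a uniform grid. Three kinds are distinguished: `reflectance`
#' R(lambda) (proportion of photons reflected), `illuminant` D(lambda)
#' (relative photon flux of incident light), and `radiance` L(lambda) (photon
#' flux reaching the eye). Reflectance values above 1 are physically suspect
#' but occur in real spectrometer output; they trigger a warning, not an
#' error. Negative values are always an error.
#'
#' @param wl wavelengths in nm, strictly increasing and uniformly spaced
#' @param values non-negative spectral values, one per wavelength
#' @param kind one of `"reflectance"`, `"illuminant"`, `"radiance"`
#' @param name optional label carried through I/O and CLI output
#' @return an object of class `spectrum` with fields `wl`, `values`, `kind`,
#'   `name`
#' @export
spectrum <- function(wl, values, kind, name = NULL) {
  kind <- match.arg(kind, spectrum_kinds)
  wl <- as.numeric(wl)
  values <- as.numeric(values)
  if (length(wl) < 2L) stop("a spectrum needs at least 2 samples", call. = FALSE)
  if (length(wl) != length(values)) {
    stop("wl and values must have equal length", call. = FALSE)
  }
  d <- diff(wl)
  if (any(d <= 0)) stop("non-monotone wavelengths", call. = FALSE)
  if (max(d) - min(d) > 1e-6 * mean(d)) {
    stop("non-uniform wavelength spacing; resample onto a uniform grid first",
         call. = FALSE)
  }
  if (anyNA(values)) stop("spectrum contains NA values", call. = FALSE)
  if (any(values < 0)) stop("negative spectral values", call. = FALSE)
  if (kind == "reflectance" && any(values > 1)) {
    warning("reflectance values > 1 (keeping them; check calibration)",
            call. = FALSE)
  }
  structure(list(wl = wl, values = values, kind = kind, name = name),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum:%s>%s %g-%g nm, step %g nm, values in [%.4g, %.4g]\n",
              x$kind, if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$wl[1L], x$wl[length(x$wl)], x$wl[2L] - x$wl[1L],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read spectra from a CSV table
#'
#' Expects a header row `wavelength,<name1>,<name2>,...` with wavelength in nm
#' and one spectrum per value column. Wavelengths must be strictly increasing
#' and uniformly spaced (mixed spacing is an error rather than silently
#' regridded, because segment brightness is a plain sum over grid samples and
#' therefore bin-width dependent).
#'
#' @param path CSV file path
#' @param kind spectrum kind applied to every column (see [spectrum()])
#' @return named list of [spectrum()] objects, one per value column
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(wavelength = 300:700, white = 1), tf, row.names = FALSE)
#' sp <- read_spectra(tf, "reflectance")
#' names(sp)
#' @export
read_spectra <- function(path, kind = c("reflectance", "illuminant", "radiance")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("need a wavelength column and at least one value column",
                          call. = FALSE)
  wl_col <- grep("^wavelength$|^wl$|^nm$", names(df), ignore.case = TRUE)
  if (length(wl_col) == 0L) wl_col <- 1L else wl_col <- wl_col[1L]
  wl <- as.numeric(df[[wl_col]])
  if (anyNA(wl)) stop("non-numeric wavelength column", call. = FALSE)
  if (any(diff(wl) <= 0)) stop("non-monotone wavelengths", call. = FALSE)
  value_cols <- setdiff(seq_along(df), wl_col)
  out <- lapply(value_cols, function(j) {
    spectrum(wl, as.numeric(df[[j]]), kind, name = names(df)[j])
  })
  names(out) <- names(df)[value_cols]
  out
}

#' Write spectra to a CSV table
#'
#' Inverse of [read_spectra()]: all spectra must share one grid; columns are
#' named after each spectrum. Values are written in full precision so a
#' read/write/read round trip is value-exact.
#'
#' @param spectra a [spectrum()] or list of spectra on a common grid
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1L]]$wl
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wl, wl))) {
      stop("all spectra must share one wavelength grid", call. = FALSE)
    }
  }
  nm <- names(spectra)
  if (is.null(nm)) nm <- rep("", length(spectra))
  nm <- ifelse(nm == "",
               vapply(seq_along(spectra), function(i) {
                 if (!is.null(spectra[[i]]$name)) spectra[[i]]$name
                 else paste0("spec", i)
               }, character(1L)),
               nm)
  df <- data.frame(wavelength = wl, check.names = FALSE)
  for (i in seq_along(spectra)) df[[nm[i]]] <- spectra[[i]]$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation at the target sample points. The target range must lie
#' within the source range: extrapolation is refused, never silent.
#'
#' @param s a [spectrum()]
#' @param target a [wavelength_grid()]
#' @return a [spectrum()] on `target`, same kind
#' @export
resample <- function(s, target) {
  stopifnot(inherits(s, "spectrum"), inherits(target, "wavelength_grid"))
  if (target$lambda_min < s$wl[1L] || target$lambda_max > s$wl[length(s$wl)]) {
    stop(sprintf(
      "target grid %g-%g nm extends beyond source range %g-%g nm (no extrapolation)",
      target$lambda_min, target$lambda_max, s$wl[1L], s$wl[length(s$wl)]),
      call. = FALSE)
  }
  v <- stats::approx(s$wl, s$values, xout = target$wl, method = "linear")$y
  # clip tiny negative interpolation artifacts (cannot occur for linear interp
  # of non-negative data, but guard against floating noise)
  v[v < 0 & v > -1e-12] <- 0
  suppressWarnings(spectrum(target$wl, v, s$kind, name = s$name))
}

#' Radiance from reflectance and illuminant
#'
#' For pigment colors the light reaching the eye is the pointwise product
#' L(lambda) = R(lambda) * D(lambda). Structural colors violate this
#' (interference makes the reflected spectrum angle-dependent); for those,
#' construct a `radiance` spectrum from direct measurements instead.
#'
#' @param r reflectance [spectrum()]
#' @param d illuminant [spectrum()] on the identical grid (resample first)
#' @return radiance [spectrum()]
#' @export
radiance <- function(r, d) {
  stopifnot(inherits(r, "spectrum"), inherits(d, "spectrum"))
  if (r$kind != "reflectance") stop("r must be a reflectance spectrum", call. = FALSE)
  if (d$kind != "illuminant") stop("d must be an illuminant spectrum", call. = FALSE)
  if (length(r$wl) != length(d$wl) || !isTRUE(all.equal(r$wl, d$wl))) {
    stop("mismatched grids: resample reflectance and illuminant onto one grid first",
         call. = FALSE)
  }
  spectrum(r$wl, r$values * d$values, "radiance", name = r$name)
}

#' Standard D65 daylight illuminant
#'
#' The CIE D65 relative spectral power distribution (normalized to 100 at
#' 560 nm), embedded at 5 nm spacing over 300-780 nm and linearly interpolated
#' to finer grids on request. Brightness in this package is a photon-flux sum,
#' so by default the energy table is converted to relative photon flux by
#' multiplying by wavelength (photons per unit energy scale with lambda);
#' `units = "energy"` returns the table as published.
#'
#' @param grid target [wavelength_grid()]; default 300-700 nm at 1 nm
#' @param units `"photon"` (default) or `"energy"`
#' @return illuminant [spectrum()] on `grid`
#' @examples
#' d <- d65(wavelength_grid(300, 700, 5))
#' @export
d65 <- function(grid = wavelength_grid(300, 700, 1),
                units = c("photon", "energy")) {
  units <- match.arg(units)
  path <- system.file("extdata", "d65_energy_5nm.csv", package = "nscolor",
                      mustWork = TRUE)
  tab <- utils::read.csv(path)
  vals <- tab$d65
  if (units == "photon") {
    vals <- vals * tab$wavelength / 560  # relative photon flux, still 100 at 560
  }
  s <- spectrum(tab$wavelength, vals, "illuminant", name = "d65")
  resample(s, grid)
}

#' Flat (equal-quanta) illuminant
#'
#' A constant illuminant, useful as a neutral reference: under it, the
#' chromatic coordinates of a flat reflectance vanish exactly.
#'
#' @param grid target [wavelength_grid()]
#' @param level constant value (default 1)
#' @return illuminant [spectrum()]
#' @export
flat_illuminant <- function(grid = wavelength_grid(300, 700, 1), level = 1) {
  spectrum(grid$wl, rep(level, length(grid$wl)), "illuminant", name = "flat")
}
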