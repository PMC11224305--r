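#' Wavelength grid for hyperspectral emission spectra
#'
#' The canonical acquisition sweeps a liquid crystal tunable filter across the
#' visible range and records one image per band. Internally all spectra live on
#' a fixed grid of band-center wavelengths; the default is 310 bands at 1 nm
#' spacing from 420 to 729 nm, matching a 310-row basis matrix. Coarser
#' instrument grids are mapped onto it with [resample_to_grid()].
#'
#' @param start_nm First band center in nanometres.
#' @param stop_nm Last band center in nanometres.
#' @param n_bands Number of bands; band centers are equally spaced.
#' @param values Optional explicit vector of band centers (overrides the other
#'   arguments). Must be strictly increasing.
#'
#' @return A `wavelength_grid` object: a strictly increasing numeric vector of
#'   band centers with `start_nm`/`stop_nm` attributes.
#' @examples
#' g <- wavelength_grid()
#' length(g)          # 310
#' range(as.numeric(g))
#' @export
wavelength_grid <- function(start_nm = 420, stop_nm = 729, n_bands = 310,
                            values = NULL) {
  if (is.null(values)) {
    values <- seq(start_nm, stop_nm, length.out = n_bands)
  }
  values <- as.numeric(values)
  if (length(values) < 2 || any(diff(values) <= 0)) {
    stop_hsi("wavelength grid must be strictly increasing with >= 2 bands",
             "hsifluor_grid_error")
  }
  structure(values,
            start_nm = values[1], stop_nm = values[length(values)],
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d bands, %.1f-%.1f nm\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && max(abs(as.numeric(a) - as.numeric(b))) <= tol
}

#' Construct a spectrum on a wavelength grid
#'
#' @param values Numeric vector of intensities (arbitrary camera counts), one
#'   per band of `grid`.
#' @param grid A [wavelength_grid()].
#' @return A `spectrum` object (numeric vector with a `grid` attribute).
#' @export
spectrum <- function(values, grid = wavelength_grid()) {
  values <- as.numeric(values)
  if (length(values) != length(grid)) {
    stop_hsi(sprintf("spectrum length %d does not match grid length %d",
                     length(values), length(grid)), "hsifluor_shape_error")
  }
  structure(values, grid = grid, class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<spectrum> %d bands (%.0f-%.0f nm), max %.4g at %.0f nm\n",
              length(x), g[1], g[length(g)], max(x), g[which.max(x)]))
  invisible(x)
}

# classed error helper; all package errors inherit "hsifluor_error"
stop_hsi <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hsifluor_error")))
}

#' Resample a spectrum onto a different wavelength grid
#'
#' Linear interpolation between source band centers; the target grid must lie
#' within the source range. Interpolated values are clipped at zero so
#' non-negativity of fluorescence intensities is preserved.
#'
#' @param spec A [spectrum()].
#' @param target_grid A [wavelength_grid()] covered by the source grid.
#' @return A [spectrum()] on `target_grid`.
#' @export
resample_to_grid <- function(spec, target_grid) {
  src <- attr(spec, "grid")
  if (target_grid[1] < src[1] - 1e-9 ||
      target_grid[length(target_grid)] > src[length(src)] + 1e-9) {
    stop_hsi("target grid extends beyond the source grid range",
             "hsifluor_grid_error")
  }
  v <- stats::approx(as.numeric(src), as.numeric(spec),
                     xout = as.numeric(target_grid), method = "linear",
                     rule = 2)$y
  spectrum(pmax(v, 0), target_grid)
}
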