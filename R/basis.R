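#' @importFrom stats dnorm pnorm
NULL

FLUOROPHORES <- c("PpIX634", "PpIX620", "NADH", "lipofuscin", "flavins")

#' Default emission-peak parameters for the five-fluorophore basis
#'
#' Peak centers and full widths at half maximum (nm) for the two PpIX
#' photo-states and the three autofluorophores. The PpIX peak positions (634
#' and 620 nm) are the established photo-state emission maxima; the NADH,
#' flavin, and lipofuscin centers/widths are literature-typical values for
#' tissue autofluorescence, not measured endmembers — substitute measured
#' spectra via [read_basis_csv()] when available. `skew` > 0 gives each peak a
#' red (long-wavelength) emission tail.
#'
#' @return A data.frame with columns `fluorophore`, `center_nm`, `fwhm_nm`,
#'   `skew`.
#' @export
default_peak_params <- function() {
  data.frame(
    fluorophore = FLUOROPHORES,
    center_nm = c(634, 620, 460, 570, 525),
    fwhm_nm   = c(20,  25, 100, 120,  80),
    skew      = c(2, 2, 2, 2, 2)
  )
}

# skew-normal-shaped peak whose *mode* is at `center` and whose nominal width
# is fwhm/2.355 (exact FWHM->omega mapping for skew 0); the mode offset is
# found numerically so the argmax lands on the requested center.
skew_peak <- function(lambda, center, fwhm, skew = 0) {
  omega <- fwhm / (2 * sqrt(2 * log(2)))
  f <- function(x) dnorm(x / omega) * pnorm(skew * x / omega)
  xs <- seq(-4 * omega, 4 * omega, length.out = 4001)
  mode_x <- xs[which.max(f(xs))]
  f(lambda - center + mode_x)
}

#' Build a parameterized synthetic fluorophore basis
#'
#' Constructs the endmember matrix B (one column per fluorophore) from
#' skew-normal emission peaks. This is a self-contained stand-in for measured
#' endmember spectra; the column order is fixed as
#' `PpIX634, PpIX620, NADH, lipofuscin, flavins`.
#'
#' @param grid A [wavelength_grid()]; default 310 bands, 420-729 nm.
#' @param peak_params data.frame as returned by [default_peak_params()]; rows
#'   are matched to the canonical fluorophore order by name. All centers must
#'   lie inside the grid range and all widths must be positive.
#' @param normalization `"peak"` (each column max = 1, default) or `"area"`
#'   (each column sums to 1/bin-width, i.e. unit integrated emission).
#' @return A `fluorophore_basis`: list with `grid`, `matrix` (bands x 5,
#'   non-negative), `names`, `normalization`.
#' @examples
#' B <- synthetic_basis()
#' colnames(B$matrix)
#' # PpIX634 column peaks at the band nearest 634 nm:
#' B$grid[which.max(B$matrix[, "PpIX634"])]
#' @export
synthetic_basis <- function(grid = wavelength_grid(),
                            peak_params = default_peak_params(),
                            normalization = c("peak", "area")) {
  normalization <- match.arg(normalization)
  need <- c("fluorophore", "center_nm", "fwhm_nm")
  if (!all(need %in% names(peak_params))) {
    stop_hsi("peak_params needs columns fluorophore, center_nm, fwhm_nm",
             "hsifluor_parameter_error")
  }
  if (!all(FLUOROPHORES %in% peak_params$fluorophore)) {
    stop_hsi("peak_params must contain all five canonical fluorophores",
             "hsifluor_parameter_error")
  }
  pp <- peak_params[match(FLUOROPHORES, peak_params$fluorophore), ]
  if (is.null(pp$skew)) pp$skew <- 0
  lam <- as.numeric(grid)
  if (any(pp$center_nm < lam[1]) || any(pp$center_nm > lam[length(lam)])) {
    stop_hsi("peak center outside the wavelength grid",
             "hsifluor_parameter_error")
  }
  if (any(pp$fwhm_nm <= 0)) {
    stop_hsi("peak widths must be positive", "hsifluor_parameter_error")
  }
  B <- vapply(seq_len(nrow(pp)), function(i) {
    skew_peak(lam, pp$center_nm[i], pp$fwhm_nm[i], pp$skew[i])
  }, numeric(length(lam)))
  colnames(B) <- FLUOROPHORES
  new_basis(B, grid, normalization)
}

new_basis <- function(B, grid, normalization) {
  B <- normalize_basis(B, grid, normalization)
  if (any(B < 0) || any(colSums(B) == 0)) {
    stop_hsi("basis columns must be non-negative and non-zero",
             "hsifluor_parameter_error")
  }
  structure(list(grid = grid, matrix = B, names = colnames(B),
                 normalization = normalization),
            class = "fluorophore_basis")
}

normalize_basis <- function(B, grid, normalization) {
  if (normalization == "peak") {
    sweep(B, 2, apply(B, 2, max), "/")
  } else {
    dl <- mean(diff(as.numeric(grid)))
    sweep(B, 2, colSums(B) * dl, "/")
  }
}

#' @export
print.fluorophore_basis <- function(x, ...) {
  cat(sprintf("<fluorophore_basis> %d bands x %d fluorophores (%s-normalized)\n",
              nrow(x$matrix), ncol(x$matrix), x$normalization))
  peaks <- x$grid[apply(x$matrix, 2, which.max)]
  cat("  peak positions:",
      paste(sprintf("%s=%.0fnm", x$names, peaks), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a fluorophore basis as CSV
#'
#' Format: header `wavelength_nm,PpIX634,PpIX620,NADH,lipofuscin,flavins`,
#' one row per band, strictly increasing wavelengths. This is the drop-in
#' point for measured endmember spectra.
#'
#' @param path CSV path.
#' @param normalization Normalization applied after reading (`"peak"` or
#'   `"area"`); pass `"none"` to keep values as stored.
#' @return A `fluorophore_basis`.
#' @export
read_basis_csv <- function(path, normalization = c("peak", "area", "none")) {
  normalization <- match.arg(normalization)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", FLUOROPHORES)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_hsi(paste("basis CSV missing columns:",
                   paste(missing, collapse = ", ")), "hsifluor_format_error")
  }
  if (any(diff(df$wavelength_nm) <= 0)) {
    stop_hsi("basis CSV wavelengths must be strictly increasing",
             "hsifluor_format_error")
  }
  grid <- wavelength_grid(values = df$wavelength_nm)
  B <- as.matrix(df[, FLUOROPHORES])
  if (any(B < 0)) {
    stop_hsi("basis CSV contains negative intensities", "hsifluor_format_error")
  }
  if (normalization == "none") {
    structure(list(grid = grid, matrix = B, names = FLUOROPHORES,
                   normalization = "none"),
              class = "fluorophore_basis")
  } else {
    new_basis(B, grid, normalization)
  }
}

#' @rdname read_basis_csv
#' @param basis A `fluorophore_basis` to write.
#' @export
write_basis_csv <- function(basis, path) {
  df <- data.frame(wavelength_nm = as.numeric(basis$grid), basis$matrix,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a basis onto a different wavelength grid
#'
#' Each endmember column is linearly interpolated onto `target_grid` (see
#' [resample_to_grid()]) and the configured normalization is re-applied.
#' @param basis A `fluorophore_basis`.
#' @param target_grid A [wavelength_grid()] within the basis grid range.
#' @export
resample_basis <- function(basis, target_grid) {
  B <- apply(basis$matrix, 2, function(col) {
    as.numeric(resample_to_grid(spectrum(col, basis$grid), target_grid))
  })
  colnames(B) <- basis$names
  norm <- if (basis$normalization == "none") "peak" else basis$normalization
  new_basis(B, target_grid, norm)
}
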