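#' Write / read a cube triplet as multi-band TIFF + JSON sidecar
#'
#' Each illumination phase is written as one multi-page 32-bit float TIFF
#' (one page per band). Because float TIFF storage is defined on `[0, 1]`,
#' counts are divided by a per-cube scale factor recorded in the sidecar and
#' restored on read. The sidecar also carries the wavelength grid, phases,
#' exposure, pixel pitch, seed, and labels.
#'
#' @param triplet List with `blue`, `dark`, `white`
#'   ([hyperspectral_cube()]s), as from [simulate_biopsy_cube()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"cube"`).
#' @param seed,labels Optional provenance stored in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_cube_triplet <- function(triplet, dir, prefix = "cube", seed = NULL,
                               labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phases <- c("blue", "dark", "white")
  scales <- numeric(0)
  for (ph in phases) {
    cube <- triplet[[ph]]
    sc <- max(cube$data, 1e-12)
    scales[ph] <- sc
    pages <- lapply(seq_len(dim(cube$data)[3]),
                    function(k) cube$data[, , k] / sc)
    tiff::writeTIFF(pages, file.path(dir, sprintf("%s_%s.tif", prefix, ph)),
                    bits.per.sample = 32L)
  }
  g <- triplet$blue$grid
  meta <- list(
    format_version = "1.0",
    grid = list(start_nm = g[1], stop_nm = g[length(g)], n_bands = length(g)),
    phases = as.list(stats::setNames(
      sprintf("%s_%s.tif", prefix, phases), phases)),
    scale = as.list(scales),
    exposure_ms = triplet$blue$exposure_ms,
    px_per_mm = triplet$blue$px_per_mm,
    seed = seed, labels = as.list(labels))
  side <- file.path(dir, sprintf("%s.json", prefix))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(side)
}

#' @rdname write_cube_triplet
#' @param sidecar_path Path to the JSON sidecar written by
#'   [write_cube_triplet()].
#' @export
read_cube_triplet <- function(sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  grid <- wavelength_grid(meta$grid$start_nm, meta$grid$stop_nm,
                          meta$grid$n_bands)
  dir <- dirname(sidecar_path)
  out <- list()
  for (ph in c("blue", "dark", "white")) {
    pages <- tiff::readTIFF(file.path(dir, meta$phases[[ph]]), all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$scale[[ph]]
    out[[ph]] <- hyperspectral_cube(arr, grid, ph,
                                    exposure_ms = meta$exposure_ms,
                                    px_per_mm = meta$px_per_mm)
  }
  out$meta <- meta
  out
}

#' Write block spectra to the wide spectra CSV format
#'
#' Header: `sample_id,biopsy_id,row0,col0` followed by one column per band
#' (`nm<wavelength>`).
#'
#' @param block_spectra A `block_spectra` object (see
#'   [extract_block_spectra()]).
#' @param path Output CSV path.
#' @param biopsy_id Identifier written to every row.
#' @export
write_spectra_csv <- function(block_spectra, path, biopsy_id = "biopsy-1") {
  S <- block_spectra$spectra
  g <- as.numeric(block_spectra$grid)
  df <- data.frame(sample_id = seq_len(nrow(S)), biopsy_id = biopsy_id,
                   row0 = block_spectra$block_origin$row0,
                   col0 = block_spectra$block_origin$col0)
  sp <- as.data.frame(S)
  names(sp) <- sprintf("nm%g", g)
  utils::write.csv(cbind(df, sp), path, row.names = FALSE)
  invisible(path)
}
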