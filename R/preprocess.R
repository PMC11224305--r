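#' Dark-correct a blue-phase cube
#'
#' Subtracts the no-light (dark) cube from the fluorescence cube band by
#' band, removing the sensor offset and dark noise; negative results are
#' clipped at zero.
#'
#' @param blue,dark [hyperspectral_cube()]s of matching shape and grid, with
#'   phases `"blue"` (or `"white"`) and `"dark"`.
#' @return A corrected cube with the phase of the first argument.
#' @export
dark_correct <- function(blue, dark) {
  if (!identical(dim(blue$data), dim(dark$data)) ||
      !grids_equal(blue$grid, dark$grid)) {
    stop_hsi("blue and dark cubes must share shape and grid",
             "hsifluor_validation_error")
  }
  if (dark$phase != "dark" || blue$phase == "dark") {
    stop_hsi("expected a signal-phase cube and a dark-phase cube",
             "hsifluor_validation_error")
  }
  out <- blue
  out$data <- pmax(blue$data - dark$data, 0)
  out
}

#' Dual-band white-light normalization of a spectrum
#'
#' Divides a fluorescence spectrum by the geometric mean of the white-light
#' reflectance in two spectral bands:
#' `y / sqrt(mean(white[band_a]) * mean(white[band_b]))`. The result is
#' invariant under a uniform illumination scaling applied to both the
#' fluorescence and the white reference. Default bands 460-480 nm and
#' 620-640 nm bracket the autofluorescence and PpIX regions.
#'
#' @param y Fluorescence [spectrum()].
#' @param white White-light reference [spectrum()] on the same grid.
#' @param band_a,band_b Wavelength windows `c(lo, hi)` in nm.
#' @return Normalized [spectrum()] with attribute `norm_factor` (the
#'   divisor).
#' @export
dual_band_normalize <- function(y, white, band_a = c(460, 480),
                                band_b = c(620, 640)) {
  g <- as.numeric(attr(y, "grid"))
  in_a <- g >= band_a[1] & g <= band_a[2]
  in_b <- g >= band_b[1] & g <= band_b[2]
  if (!any(in_a) || !any(in_b)) {
    stop_hsi("normalization bands must lie within the wavelength grid",
             "hsifluor_validation_error")
  }
  ra <- mean(as.numeric(white)[in_a])
  rb <- mean(as.numeric(white)[in_b])
  if (ra <= 0 || rb <= 0) {
    stop_hsi("white reference has non-positive mean reflectance in a band",
             "hsifluor_degenerate_reference_error")
  }
  f <- sqrt(ra * rb)
  out <- spectrum(as.numeric(y) / f, attr(y, "grid"))
  attr(out, "norm_factor") <- f
  out
}

#' Segment the tumor from the 634 nm fluorescence image
#'
#' Thresholding stand-in for interactive segmentation: Otsu's threshold on
#' the band nearest 634 nm, morphological opening (disc brush), connected
#' components, and selection of the largest component. With
#' `exclude_artifacts = TRUE` (default) all components other than the largest
#' are dropped even if above threshold, which removes bright fluid blobs
#' adjacent to the tissue.
#'
#' @param blue A blue-phase (ideally dark-corrected) [hyperspectral_cube()]
#'   whose grid covers 634 nm.
#' @param exclude_artifacts Keep only the largest connected component.
#' @param brush_size Odd disc diameter for the morphological opening.
#' @return A `tumor_mask`: list with `mask` (H x W logical), `method`,
#'   `checked` (manual-review flag, always `FALSE` here).
#' @export
segment_tumor <- function(blue, exclude_artifacts = TRUE, brush_size = 5) {
  g <- as.numeric(blue$grid)
  if (634 < g[1] || 634 > g[length(g)]) {
    stop_hsi("wavelength grid does not cover 634 nm",
             "hsifluor_validation_error")
  }
  band <- which.min(abs(g - 634))
  img <- blue$data[, , band]
  method <- "otsu+opening+largest-component"
  if (max(img) <= 0) {
    warning("634 nm band is all zero; returning an empty mask")
    return(structure(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                          method = method, checked = FALSE),
                     class = "tumor_mask"))
  }
  norm <- img / max(img)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  bin <- norm > thr
  opened <- EBImage::opening(bin, EBImage::makeBrush(brush_size, "disc"))
  lab <- EBImage::bwlabel(opened)
  sizes <- tabulate(lab[lab > 0])
  mask <- if (!length(sizes)) {
    matrix(FALSE, nrow(img), ncol(img))
  } else if (exclude_artifacts) {
    lab == which.max(sizes)
  } else {
    lab > 0
  }
  structure(list(mask = matrix(as.logical(mask), nrow(img), ncol(img)),
                 method = method, checked = FALSE),
            class = "tumor_mask")
}

#' Extract non-overlapping block spectra from a masked cube
#'
#' Tiles the mask bounding box with grid-aligned `block_size` x `block_size`
#' tiles (anchored at the bounding-box origin), keeps tiles fully inside the
#' mask, and averages the cube over each tile to one spectrum per block.
#' Blocks are pairwise disjoint, so each spectrum is an independent data
#' point; tiles partially outside the mask are discarded.
#'
#' @param cube A [hyperspectral_cube()].
#' @param mask A `tumor_mask` or H x W logical matrix.
#' @param block_size Tile edge in pixels (default 10).
#' @return A `block_spectra`: list with `spectra` (n x bands matrix),
#'   `block_origin` (data.frame of 0-based `row0`, `col0`), `block_size`,
#'   `grid`. May contain zero rows.
#' @export
extract_block_spectra <- function(cube, mask, block_size = 10) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  if (!identical(dim(m), dim(cube$data)[1:2])) {
    stop_hsi("mask and cube spatial shapes differ", "hsifluor_shape_error")
  }
  tiles <- tiles_in_mask(m, block_size)
  nb <- dim(cube$data)[3]
  S <- matrix(0, nrow(tiles), nb)
  for (i in seq_len(nrow(tiles))) {
    r0 <- tiles$row0[i] + 1L
    c0 <- tiles$col0[i] + 1L
    sub <- cube$data[r0:(r0 + block_size - 1), c0:(c0 + block_size - 1), ,
                     drop = FALSE]
    S[i, ] <- colMeans(matrix(sub, block_size^2, nb))
  }
  structure(list(spectra = S, block_origin = tiles, block_size = block_size,
                 grid = cube$grid),
            class = "block_spectra")
}

#' @export
print.block_spectra <- function(x, ...) {
  cat(sprintf("<block_spectra> %d blocks of %dx%d px, %d bands\n",
              nrow(x$spectra), x$block_size, x$block_size, ncol(x$spectra)))
  invisible(x)
}

#' Full preprocessing of an illumination triplet
#'
#' The standard chain: dark-correct the blue and white cubes, segment the
#' tumor from the corrected blue cube, extract non-overlapping block spectra
#' from both, and dual-band normalize each block spectrum by its own white
#' reference block.
#'
#' @param triplet List with `blue`, `dark`, `white` cubes.
#' @param band_a,band_b Normalization bands (see [dual_band_normalize()]).
#' @param block_size Tile edge (default 10).
#' @param exclude_artifacts Passed to [segment_tumor()].
#' @param normalize Set `FALSE` to skip dual-band normalization.
#' @return A `block_spectra` with extra fields `norm_factor` (per-block
#'   divisor, 1 when `normalize = FALSE`) and `mask` (the `tumor_mask`).
#' @export
preprocess_triplet <- function(triplet, band_a = c(460, 480),
                               band_b = c(620, 640), block_size = 10,
                               exclude_artifacts = TRUE, normalize = TRUE) {
  blue <- dark_correct(triplet$blue, triplet$dark)
  white <- dark_correct(triplet$white, triplet$dark)
  mask <- segment_tumor(blue, exclude_artifacts = exclude_artifacts)
  bs <- extract_block_spectra(blue, mask, block_size)
  ws <- extract_block_spectra(white, mask, block_size)
  factors <- rep(1, nrow(bs$spectra))
  if (normalize && nrow(bs$spectra)) {
    for (i in seq_len(nrow(bs$spectra))) {
      y <- dual_band_normalize(spectrum(bs$spectra[i, ], bs$grid),
                               spectrum(ws$spectra[i, ], bs$grid),
                               band_a, band_b)
      bs$spectra[i, ] <- as.numeric(y)
      factors[i] <- attr(y, "norm_factor")
    }
  }
  bs$norm_factor <- factors
  bs$mask <- mask
  bs
}

#' Write a tumor mask as a single-page TIFF
#' @param mask A `tumor_mask`.
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
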