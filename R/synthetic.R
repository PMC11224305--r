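#' sCMOS acquisition noise model
#'
#' Additive Gaussian read noise, a constant dark offset, and a Gaussian
#' approximation of Poisson shot noise whose variance is
#' `shot_noise_gain * signal` (counts). All parameters in camera counts.
#'
#' @param read_noise_sd Read noise standard deviation.
#' @param shot_noise_gain Shot-noise variance per unit signal (1 ~ photon
#'   counting).
#' @param dark_offset Constant sensor offset present in every phase.
#' @return An `acquisition_noise_model` object.
#' @export
acquisition_noise_model <- function(read_noise_sd = 2, shot_noise_gain = 1,
                                    dark_offset = 100) {
  if (read_noise_sd < 0 || shot_noise_gain < 0 || dark_offset < 0) {
    stop_hsi("noise parameters must be >= 0", "hsifluor_parameter_error")
  }
  structure(list(read_noise_sd = read_noise_sd,
                 shot_noise_gain = shot_noise_gain,
                 dark_offset = dark_offset),
            class = "acquisition_noise_model")
}

#' Zero-noise model (deterministic acquisition, no offset)
#' @rdname acquisition_noise_model
#' @export
noiseless <- function() acquisition_noise_model(0, 0, 0)

#' Sample class-conditional fluorophore abundances
#'
#' Draws `n` block-level abundance vectors for one biopsy of the given class:
#' log-abundances are the profile mean plus one shared biopsy-level
#' brightness draw `N(0, biopsy_effect_sd)` plus independent
#' `N(0, sd_log_abundance)` per block and fluorophore.
#'
#' @param profile A [class_profile()].
#' @param n Number of blocks (rows) to draw.
#' @param seed Optional integer seed; same seed reproduces the table exactly.
#' @return An `n` x 5 matrix of strictly positive abundances, columns named by
#'   fluorophore.
#' @export
sample_abundances <- function(profile, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    u <- rnorm(1, 0, profile$biopsy_effect_sd)
    logc <- matrix(rnorm(n * 5,
                         mean = rep(profile$mean_log_abundance, each = n),
                         sd = rep(profile$sd_log_abundance, each = n)),
                   nrow = n, ncol = 5,
                   dimnames = list(NULL, FLUOROPHORES))
    exp(logc + u)
  })
}

# Pixel-center disk mask over the full field; pixel (r, c) (1-based) has
# center (r - 0.5, c - 0.5).
disk_mask <- function(field_size, center, radius) {
  r <- seq_len(field_size) - 0.5
  outer((r - center[1])^2, (r - center[2])^2, "+") <= radius^2
}

# Disk mask restricted to its bounding box (memory-friendly for large
# fields). Returns list(mask, r1, c1): `mask[1, 1]` sits at full-field pixel
# (r1, c1), 1-based.
disk_mask_bbox <- function(field_size, center, radius) {
  lo_r <- max(1L, floor(center[1] - radius)); hi_r <- min(field_size, ceiling(center[1] + radius) + 1L)
  lo_c <- max(1L, floor(center[2] - radius)); hi_c <- min(field_size, ceiling(center[2] + radius) + 1L)
  rr <- seq(lo_r, hi_r) - 0.5
  cc <- seq(lo_c, hi_c) - 0.5
  m <- outer((rr - center[1])^2, (cc - center[2])^2, "+") <= radius^2
  keep_r <- which(rowSums(m) > 0)
  keep_c <- which(colSums(m) > 0)
  list(mask = m[keep_r, keep_c, drop = FALSE],
       r1 = lo_r + keep_r[1] - 1L, c1 = lo_c + keep_c[1] - 1L)
}

# Expand a bbox mask back to the full field.
full_mask <- function(bbox, field_size) {
  m <- matrix(FALSE, field_size, field_size)
  m[bbox$r1 + seq_len(nrow(bbox$mask)) - 1L,
    bbox$c1 + seq_len(ncol(bbox$mask)) - 1L] <- bbox$mask
  m
}

# Grid-aligned block_size x block_size tiles fully inside `mask`, anchored at
# the mask bounding-box origin. Returns 0-based origins (row0, col0).
tiles_in_mask <- function(mask, block_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(row0 = integer(0), col0 = integer(0)))
  }
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  if (max(idx[, 1]) - r0 + 1 < block_size ||
      max(idx[, 2]) - c0 + 1 < block_size) {
    return(data.frame(row0 = integer(0), col0 = integer(0)))
  }
  rows <- seq(r0, max(idx[, 1]) - block_size + 1, by = block_size)
  cols <- seq(c0, max(idx[, 2]) - block_size + 1, by = block_size)
  full <- expand.grid(row = rows, col = cols)
  keep <- vapply(seq_len(nrow(full)), function(i) {
    rr <- full$row[i]; cc <- full$col[i]
    all(mask[rr:(rr + block_size - 1), cc:(cc + block_size - 1)])
  }, logical(1))
  data.frame(row0 = full$row[keep] - 1L, col0 = full$col[keep] - 1L)
}

#' Synthetic biopsy phantom
#'
#' A circular tissue phantom on a glass background: a disk of the given
#' diameter whose fluorophore abundances are piecewise constant over the
#' grid-aligned blocks that tile it, drawn from the class profile via
#' [sample_abundances()]. At the instrument scale of 47.62 px/mm the default
#' diameter range 190-476 px corresponds to 4-10 mm biopsies in a 2048 px
#' field.
#'
#' @param profile A [class_profile()] giving the class-conditional abundance
#'   distribution.
#' @param biopsy_id Identifier string.
#' @param labels Named character vector mapping task names to class labels;
#'   defaults to the profile's own task/label.
#' @param diameter_px Disk diameter in pixels; `NULL` draws uniformly from
#'   `diameter_range`.
#' @param diameter_range Default `c(190, 476)` px (4-10 mm).
#' @param field_size Square field edge (default 2048 px).
#' @param px_per_mm Spatial sampling (default 47.62).
#' @param block_size Tile edge for the abundance field (default 10 px).
#' @param has_fluid_artifact If `TRUE`, a bright fluid blob is placed adjacent
#'   to the tissue disk when a cube is rendered.
#' @param seed Optional integer seed.
#' @return A `biopsy_phantom`: list with the geometry, the 0-based block
#'   origins (`blocks`), and the per-block abundance matrix (`abundances`).
#' @export
biopsy_phantom <- function(profile, biopsy_id = "biopsy-1", labels = NULL,
                           diameter_px = NULL, diameter_range = c(190, 476),
                           field_size = 2048, px_per_mm = 47.62,
                           block_size = 10, has_fluid_artifact = FALSE,
                           seed = NULL) {
  with_seed(seed, {
    if (is.null(diameter_px)) {
      diameter_px <- stats::runif(1, diameter_range[1], diameter_range[2])
    }
    if (diameter_px > field_size - 2 * block_size) {
      stop_hsi("phantom does not fit in the field of view",
               "hsifluor_geometry_error")
    }
    if (is.null(labels)) labels <- stats::setNames(profile$label, profile$task)
    center <- rep(field_size / 2, 2)
    bbox <- disk_mask_bbox(field_size, center, diameter_px / 2)
    blocks <- tiles_in_mask(bbox$mask, block_size)
    blocks$row0 <- blocks$row0 + bbox$r1 - 1L   # to full-field coordinates
    blocks$col0 <- blocks$col0 + bbox$c1 - 1L
    if (!nrow(blocks)) {
      stop_hsi("phantom too small to contain one full block",
               "hsifluor_geometry_error")
    }
    abund <- sample_abundances(profile, nrow(blocks))
    artifact <- NULL
    if (has_fluid_artifact) {
      ad <- 0.4 * diameter_px
      acenter <- center + c(0, diameter_px / 2 + ad / 2 + 5)
      if (acenter[2] + ad / 2 > field_size) {
        stop_hsi("fluid artifact does not fit in the field of view",
                 "hsifluor_geometry_error")
      }
      artifact <- list(center = acenter, diameter_px = ad)
    }
    structure(list(biopsy_id = biopsy_id, labels = labels,
                   profile_label = profile$label, task = profile$task,
                   diameter_px = diameter_px, field_size = field_size,
                   px_per_mm = px_per_mm, block_size = block_size,
                   center = center, blocks = blocks,
                   abundances = abund,
                   has_fluid_artifact = has_fluid_artifact,
                   artifact = artifact),
              class = "biopsy_phantom")
  })
}

#' @export
print.biopsy_phantom <- function(x, ...) {
  cat(sprintf(
    "<biopsy_phantom> %s (%s=%s): diameter %.0f px (%.1f mm), %d blocks%s\n",
    x$biopsy_id, x$task, x$profile_label, x$diameter_px,
    x$diameter_px / x$px_per_mm, nrow(x$blocks),
    if (x$has_fluid_artifact) ", fluid artifact" else ""))
  invisible(x)
}

#' Full-field tissue mask of a phantom
#' @param phantom A [biopsy_phantom()].
#' @return H x W logical matrix (TRUE = tissue).
#' @export
phantom_mask <- function(phantom) {
  bbox <- disk_mask_bbox(phantom$field_size, phantom$center,
                         phantom$diameter_px / 2)
  full_mask(bbox, phantom$field_size)
}

phantom_n_pixels <- function(phantom) {
  bbox <- disk_mask_bbox(phantom$field_size, phantom$center,
                         phantom$diameter_px / 2)
  sum(bbox$mask)
}

# Per-pixel 5-channel abundance field: block value inside complete tiles,
# nearest-block value on the rim of the disk, zero on glass.
phantom_abundance_field <- function(phantom) {
  fs <- phantom$field_size
  field <- array(0, dim = c(fs, fs, 5))
  bs <- phantom$block_size
  block_id <- matrix(0L, fs, fs)
  for (i in seq_len(nrow(phantom$blocks))) {
    r0 <- phantom$blocks$row0[i] + 1L
    c0 <- phantom$blocks$col0[i] + 1L
    block_id[r0:(r0 + bs - 1), c0:(c0 + bs - 1)] <- i
  }
  rim <- which(phantom_mask(phantom) & block_id == 0L, arr.ind = TRUE)
  if (nrow(rim)) {
    bc_r <- phantom$blocks$row0 + bs / 2
    bc_c <- phantom$blocks$col0 + bs / 2
    nearest <- vapply(seq_len(nrow(rim)), function(k) {
      which.min((bc_r - rim[k, 1])^2 + (bc_c - rim[k, 2])^2)
    }, integer(1))
    block_id[rim] <- nearest
  }
  inside <- block_id > 0L
  for (ch in 1:5) {
    plane <- matrix(0, fs, fs)
    plane[inside] <- phantom$abundances[block_id[inside], ch]
    field[, , ch] <- plane
  }
  field
}

#' Hyperspectral cube container
#'
#' @param data H x W x bands numeric array of camera counts.
#' @param grid A [wavelength_grid()] (length = number of bands).
#' @param phase Illumination phase: `"blue"`, `"dark"`, or `"white"`.
#' @param exposure_ms Per-band exposure (default 500 ms).
#' @param px_per_mm Spatial sampling.
#' @return A `hyperspectral_cube` object.
#' @export
hyperspectral_cube <- function(data, grid, phase = c("blue", "dark", "white"),
                               exposure_ms = 500, px_per_mm = 47.62) {
  phase <- match.arg(phase)
  if (length(dim(data)) != 3 || dim(data)[3] != length(grid)) {
    stop_hsi("cube must be H x W x bands with bands matching the grid",
             "hsifluor_shape_error")
  }
  structure(list(data = data, grid = grid, phase = phase,
                 exposure_ms = exposure_ms, px_per_mm = px_per_mm),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyperspectral_cube> %s phase, %d x %d x %d bands\n",
              x$phase, d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate the blue/dark/white illumination triplet for a phantom
#'
#' Renders the three acquisition phases: under blue excitation every tissue
#' pixel emits `B c(pixel)` plus sensor offset and noise; the dark phase
#' records offset and read noise only; under white light a spectrally flat
#' reflectance field is recorded (glass brighter than tissue). The optional
#' fluid artifact appears as a bright broadband blob next to the tissue in
#' the blue phase.
#'
#' @param phantom A [biopsy_phantom()].
#' @param basis A `fluorophore_basis`.
#' @param noise An [acquisition_noise_model()]; use [noiseless()] for exact
#'   arithmetic.
#' @param seed Optional integer seed for the noise draws.
#' @param white_level White-light illumination level (counts).
#' @param tissue_reflectance,glass_reflectance Flat reflectance factors.
#' @return List with elements `blue`, `dark`, `white`
#'   ([hyperspectral_cube()]s) and `phantom`.
#' @export
simulate_biopsy_cube <- function(phantom, basis = synthetic_basis(),
                                 noise = acquisition_noise_model(),
                                 seed = NULL, white_level = 1000,
                                 tissue_reflectance = 0.6,
                                 glass_reflectance = 0.9) {
  with_seed(seed, {
    fs <- phantom$field_size
    nb <- length(basis$grid)
    field <- phantom_abundance_field(phantom)
    A <- matrix(field, nrow = fs * fs, ncol = 5)
    signal <- A %*% t(basis$matrix)          # (H*W) x bands

    if (phantom$has_fluid_artifact) {
      amask <- disk_mask(fs, phantom$artifact$center,
                         phantom$artifact$diameter_px / 2)
      peak <- max(signal)
      signal[as.vector(amask), ] <- 2 * max(peak, white_level)
    }

    add_noise <- function(sig) {
      if (noise$read_noise_sd == 0 && noise$shot_noise_gain == 0) {
        return(sig + noise$dark_offset)
      }
      sd_tot <- sqrt(noise$read_noise_sd^2 + noise$shot_noise_gain * sig)
      pmax(sig + noise$dark_offset + rnorm(length(sig), 0, sd_tot), 0)
    }

    blue <- array(add_noise(signal), dim = c(fs, fs, nb))
    dark <- array(add_noise(matrix(0, fs * fs, nb)), dim = c(fs, fs, nb))
    refl <- matrix(glass_reflectance, fs, fs)
    refl[phantom_mask(phantom)] <- tissue_reflectance
    wsig <- matrix(white_level * as.vector(refl), fs * fs, nb)
    white <- array(add_noise(wsig), dim = c(fs, fs, nb))

    list(blue = hyperspectral_cube(blue, basis$grid, "blue",
                                   px_per_mm = phantom$px_per_mm),
         dark = hyperspectral_cube(dark, basis$grid, "dark",
                                   px_per_mm = phantom$px_per_mm),
         white = hyperspectral_cube(white, basis$grid, "white",
                                    px_per_mm = phantom$px_per_mm),
         phantom = phantom)
  })
}

#' Simulate a labeled multi-biopsy dataset
#'
#' Generates block-level abundances (one [biopsy_phantom()] per biopsy, block
#' geometry included) for all classes of a task. Cubes are not rendered here
#' — use [simulate_biopsy_cube()] on individual phantoms when the full
#' imaging chain is needed. Regenerating with the same configuration and seed
#' reproduces the dataset exactly.
#'
#' @param task `"tissue_type"`, `"margin"`, `"who_grade"`, or `"idh"`.
#' @param class_profiles List of [class_profile()]s; default is the task
#'   preset at separation `delta`.
#' @param n_biopsies_per_class Single count or named vector per class;
#'   `NULL` uses the preset roster (the source cohort sizes).
#' @param delta Separability knob for the default preset.
#' @param seed Integer seed (required for reproducibility).
#' @param field_size,diameter_range,block_size Geometry passed to
#'   [biopsy_phantom()].
#' @param artifact_prob Probability that a biopsy carries a fluid artifact.
#' @return A `simulated_dataset`: list with `biopsies` (phantom list),
#'   `blocks` (data.frame: `biopsy_id`, `label`, `row0`, `col0`, task label
#'   columns), `abundances` (matrix), `task`, `seed`, `provenance`.
#' @export
simulate_dataset <- function(task, class_profiles = NULL,
                             n_biopsies_per_class = NULL, delta = 1,
                             seed = 1, field_size = 2048,
                             diameter_range = c(190, 476), block_size = 10,
                             artifact_prob = 0) {
  if (is.null(class_profiles)) class_profiles <- task_preset(task, delta)
  if (length(class_profiles) < 2) {
    stop_hsi("need at least two classes", "hsifluor_config_error")
  }
  labels <- vapply(class_profiles, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop_hsi("class labels must be unique", "hsifluor_config_error")
  }
  roster <- attr(class_profiles, "roster")
  if (is.null(n_biopsies_per_class)) {
    n_per <- if (!is.null(roster)) roster[labels] else rep(10, length(labels))
  } else if (length(n_biopsies_per_class) == 1) {
    n_per <- stats::setNames(rep(n_biopsies_per_class, length(labels)), labels)
  } else {
    n_per <- n_biopsies_per_class[labels]
  }
  if (anyNA(n_per)) {
    stop_hsi("n_biopsies_per_class must cover every class",
             "hsifluor_config_error")
  }

  biopsies <- list()
  rows <- list()
  abund <- list()
  bi <- 0L
  for (k in seq_along(class_profiles)) {
    pr <- class_profiles[[k]]
    for (j in seq_len(n_per[k])) {
      bi <- bi + 1L
      bseed <- derive_seed(seed, bi)
      id <- sprintf("B%04d", bi)
      lab <- biopsy_labels(pr, task, bseed)
      ph <- biopsy_phantom(pr, biopsy_id = id, labels = lab,
                           field_size = field_size,
                           diameter_range = diameter_range,
                           block_size = block_size,
                           has_fluid_artifact =
                             with_seed(derive_seed(bseed, "artifact"),
                                       stats::runif(1) < artifact_prob),
                           seed = bseed)
      biopsies[[bi]] <- ph
      nb <- nrow(ph$blocks)
      df <- data.frame(biopsy_id = rep(id, nb), label = rep(pr$label, nb),
                       row0 = ph$blocks$row0, col0 = ph$blocks$col0,
                       stringsAsFactors = FALSE)
      for (nm in names(lab)) df[[nm]] <- lab[[nm]]
      rows[[bi]] <- df
      abund[[bi]] <- ph$abundances
    }
  }
  blocks <- do.call(rbind, rows)
  structure(list(biopsies = biopsies, blocks = blocks,
                 abundances = do.call(rbind, abund), task = task,
                 seed = seed,
                 provenance = list(task = task, delta = delta,
                                   n_biopsies_per_class = as.list(n_per),
                                   field_size = field_size,
                                   diameter_range = diameter_range,
                                   block_size = block_size,
                                   artifact_prob = artifact_prob)),
            class = "simulated_dataset")
}

# Task label mapping for one biopsy. The tissue preset also assigns an IDH
# status (per-type wildtype fractions) and a WHO grade so downstream label
# surgery (WHO-2021 relabeling) has the fields it needs.
biopsy_labels <- function(profile, task, seed) {
  lab <- stats::setNames(profile$label, profile$task)
  if (task == "tissue_type") {
    wt <- TISSUE_WILDTYPE_FRAC[profile$label]
    idh <- with_seed(derive_seed(seed, "idh"),
                     if (stats::runif(1) < wt) "wildtype" else "mutant")
    lab <- c(lab, idh = idh, who_grade = unname(TISSUE_GRADE[profile$label]))
  }
  lab
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> task=%s: %d biopsies, %d blocks, seed=%d\n",
              x$task, length(x$biopsies), nrow(x$blocks), x$seed))
  print(table(vapply(x$biopsies, `[[`, "", "profile_label")))
  invisible(x)
}

#' Export a simulated dataset to CSV
#'
#' Writes the manifest
#' (`biopsy_id,task,label,n_pixels,has_fluid_artifact,seed`) and the
#' block-level abundance table
#' (`sample_id,biopsy_id,label,row0,col0,<fluorophores>`).
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
export_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    biopsy_id = vapply(dataset$biopsies, `[[`, "", "biopsy_id"),
    task = dataset$task,
    label = vapply(dataset$biopsies, `[[`, "", "profile_label"),
    n_pixels = vapply(dataset$biopsies, phantom_n_pixels, numeric(1)),
    has_fluid_artifact = vapply(dataset$biopsies, `[[`, NA,
                                "has_fluid_artifact"),
    seed = dataset$seed)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  ab <- data.frame(sample_id = seq_len(nrow(dataset$blocks)),
                   dataset$blocks[, c("biopsy_id", "label", "row0", "col0")],
                   dataset$abundances)
  apath <- file.path(dir, "abundances.csv")
  utils::write.csv(ab, apath, row.names = FALSE)
  invisible(c(manifest = mpath, abundances = apath))
}
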