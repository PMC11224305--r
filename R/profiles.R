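#' @importFrom stats rnorm setNames
NULL

# Base log-abundance level (counts) around which class presets are offset.
# Order: PpIX634, PpIX620, NADH, lipofuscin, flavins.
BASE_LOG_ABUNDANCE <- log(c(800, 300, 200, 150, 180))

#' Class-conditional abundance profile
#'
#' Describes one class of one classification task as a log-normal distribution
#' over the five fluorophore abundances: block-level log-abundances are
#' `mean_log_abundance` plus a biopsy-level brightness effect
#' `N(0, biopsy_effect_sd)` (shared by all blocks of a biopsy, applied to all
#' five fluorophores) plus independent per-block noise
#' `N(0, sd_log_abundance)`.
#'
#' @param label Class name (unique within a task).
#' @param task One of `"tissue_type"`, `"margin"`, `"who_grade"`, `"idh"`.
#' @param mean_log_abundance Numeric 5-vector, log counts.
#' @param sd_log_abundance Numeric 5-vector (>= 0), log-scale spread.
#' @param biopsy_effect_sd Scalar >= 0, biopsy-level brightness spread.
#' @return A `class_profile` object.
#' @export
class_profile <- function(label, task, mean_log_abundance,
                          sd_log_abundance = rep(0.3, 5),
                          biopsy_effect_sd = 0.15) {
  sd_log_abundance <- rep_len(as.numeric(sd_log_abundance), 5)
  if (any(sd_log_abundance < 0) || biopsy_effect_sd < 0) {
    stop_hsi("standard deviations must be >= 0", "hsifluor_parameter_error")
  }
  task <- match.arg(task, c("tissue_type", "margin", "who_grade", "idh"))
  structure(list(label = label, task = task,
                 mean_log_abundance = setNames(as.numeric(mean_log_abundance),
                                               FLUOROPHORES),
                 sd_log_abundance = sd_log_abundance,
                 biopsy_effect_sd = biopsy_effect_sd),
            class = "class_profile")
}

make_profiles <- function(task, offsets, delta, sd_log, biopsy_effect_sd) {
  lapply(rownames(offsets), function(lb) {
    class_profile(lb, task, BASE_LOG_ABUNDANCE + delta * offsets[lb, ],
                  sd_log, biopsy_effect_sd)
  })
}

# Log-scale offset directions for the margin classes: solid tumor is
# PpIX-rich, reactively altered brain is PpIX-poor and autofluorescence-rich,
# the infiltrating zone sits between them. The ST-IZ pair deliberately shares
# the lipofuscin component, so at most 4 of 5 fluorophores separate that pair.
MARGIN_OFFSETS <- matrix(c(
   0.8,  0.4, -0.2, 0.0, -0.2,   # ST
   0.0,  0.0,  0.0, 0.0,  0.0,   # IZ
  -0.8, -0.4,  0.3, 0.1,  0.3),  # RABT
  nrow = 3, byrow = TRUE,
  dimnames = list(c("ST", "IZ", "RABT"), FLUOROPHORES))

GRADE_OFFSETS <- matrix(c(
  -0.7, -0.40,  0.30,  0.15,  0.30,  # II
   0.0,  0.00,  0.00,  0.00,  0.00,  # III
   0.8,  0.45, -0.30, -0.15, -0.30), # IV
  nrow = 3, byrow = TRUE,
  dimnames = list(c("II", "III", "IV"), FLUOROPHORES))

IDH_OFFSETS <- matrix(c(
  -0.5, -0.25,  0.20,  0.10,  0.20,  # mutant
   0.5,  0.25, -0.20, -0.10, -0.20), # wildtype
  nrow = 2, byrow = TRUE,
  dimnames = list(c("mutant", "wildtype"), FLUOROPHORES))

# Twelve tissue types, 2016 WHO nomenclature. Offsets are hand-laid so that
# every pair differs in most fluorophores; strongly fluorescing high-grade
# entities (GB, AA, AE) carry positive PpIX offsets.
TISSUE_OFFSETS <- matrix(c(
  -0.9, -0.5,  0.5,  0.3,  0.4,   # PA
  -0.4, -0.3,  0.3, -0.2,  0.2,   # DA
   0.5,  0.3, -0.2,  0.2, -0.3,   # AA
   0.9,  0.5, -0.4, -0.3, -0.4,   # GB
  -0.2,  0.4,  0.2,  0.4, -0.2,   # OD
  -0.7,  0.2, -0.3,  0.5,  0.3,   # GG
   0.2, -0.6,  0.4, -0.4, -0.5,   # MB
   0.7, -0.2, -0.5,  0.4,  0.5,   # AE
  -0.1,  0.1,  0.6,  0.1, -0.6,   # AO
  -0.6,  0.6, -0.6, -0.1,  0.1,   # MN
   0.4, -0.4,  0.1,  0.6,  0.2,   # MT
  -1.1, -0.7,  0.7, -0.5, -0.1),  # RN
  nrow = 12, byrow = TRUE,
  dimnames = list(c("PA", "DA", "AA", "GB", "OD", "GG", "MB", "AE", "AO",
                    "MN", "MT", "RN"), FLUOROPHORES))

# Biopsy counts per class as used in the source cohorts.
TISSUE_ROSTER <- c(PA = 5, DA = 57, AA = 51, GB = 410, OD = 24, GG = 4,
                   MB = 6, AE = 8, AO = 4, MN = 37, MT = 6, RN = 20)
MARGIN_ROSTER <- c(ST = 131, IZ = 57, RABT = 100)
GRADE_ROSTER  <- c(II = 84, III = 57, IV = 421)
IDH_ROSTER    <- c(mutant = 126, wildtype = 285)

# Fraction of IDH-wildtype biopsies per tissue type (used by the tissue
# preset so records carry a plausible IDH status for WHO-2021 relabeling).
TISSUE_WILDTYPE_FRAC <- c(PA = 0.9, DA = 0.2, AA = 0.5, GB = 0.9, OD = 0.05,
                          GG = 0.8, MB = 1, AE = 1, AO = 0.05, MN = 1,
                          MT = 1, RN = 1)
TISSUE_GRADE <- c(PA = "I", DA = "II", AA = "III", GB = "IV", OD = "II",
                  GG = "I", MB = "IV", AE = "III", AO = "III", MN = "I",
                  MT = NA, RN = NA)

#' Class-profile presets for the four classification tasks
#'
#' Each preset returns the list of [class_profile()]s for one task, with a
#' separability knob `delta` scaling the between-class log-mean offsets:
#' `delta = 0` collapses all classes onto one distribution (the null preset),
#' `delta = 1` is the default working separation, larger values increase it.
#'
#' @param delta Separability multiplier (>= 0).
#' @param sd_log_abundance Per-block log-scale spread (recycled to length 5).
#' @param biopsy_effect_sd Biopsy-level brightness spread.
#' @return List of `class_profile` objects with a `roster` attribute giving
#'   the default number of biopsies per class.
#' @export
margin_preset <- function(delta = 1, sd_log_abundance = 0.3,
                          biopsy_effect_sd = 0.15) {
  structure(make_profiles("margin", MARGIN_OFFSETS, delta,
                          sd_log_abundance, biopsy_effect_sd),
            roster = MARGIN_ROSTER)
}

#' @rdname margin_preset
#' @export
who_grade_preset <- function(delta = 1, sd_log_abundance = 0.3,
                             biopsy_effect_sd = 0.15) {
  structure(make_profiles("who_grade", GRADE_OFFSETS, delta,
                          sd_log_abundance, biopsy_effect_sd),
            roster = GRADE_ROSTER)
}

#' @rdname margin_preset
#' @export
idh_preset <- function(delta = 1, sd_log_abundance = 0.3,
                       biopsy_effect_sd = 0.15) {
  structure(make_profiles("idh", IDH_OFFSETS, delta,
                          sd_log_abundance, biopsy_effect_sd),
            roster = IDH_ROSTER)
}

#' @rdname margin_preset
#' @export
tissue_type_preset <- function(delta = 1, sd_log_abundance = 0.3,
                               biopsy_effect_sd = 0.15) {
  structure(make_profiles("tissue_type", TISSUE_OFFSETS, delta,
                          sd_log_abundance, biopsy_effect_sd),
            roster = TISSUE_ROSTER)
}

task_preset <- function(task, delta = 1, ...) {
  switch(task,
         tissue_type = tissue_type_preset(delta, ...),
         margin = margin_preset(delta, ...),
         who_grade = who_grade_preset(delta, ...),
         idh = idh_preset(delta, ...),
         stop_hsi(paste("unknown task:", task), "hsifluor_config_error"))
}
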