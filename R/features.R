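#' Relabel per the 2021 WHO classification
#'
#' Under the 2021 WHO CNS tumor classification, IDH-wildtype anaplastic
#' astrocytomas are considered glioblastoma: records with tissue type `"AA"`
#' and IDH status `"wildtype"` are relabeled `"GB"`; all other records
#' (including IDH-mutant AA and records with unknown IDH status) are
#' unchanged.
#'
#' @param records data.frame carrying tissue type and IDH status columns.
#' @param tissue_col,idh_col Column names (defaults `"tissue_type"`,
#'   `"idh"`).
#' @return The records with relabeled tissue types and attribute
#'   `n_relabeled` (count of changed records).
#' @export
relabel_who2021 <- function(records, tissue_col = "tissue_type",
                            idh_col = "idh") {
  if (!all(c(tissue_col, idh_col) %in% names(records))) {
    stop_hsi("records must carry tissue-type and IDH columns",
             "hsifluor_validation_error")
  }
  hit <- records[[tissue_col]] == "AA" &
    !is.na(records[[idh_col]]) & records[[idh_col]] == "wildtype"
  hit[is.na(hit)] <- FALSE
  records[[tissue_col]][hit] <- "GB"
  if ("label" %in% names(records) && tissue_col != "label") {
    records$label[hit] <- "GB"
  }
  attr(records, "n_relabeled") <- sum(hit)
  records
}

#' Build a balanced feature table from block abundances
#'
#' Implements the sample-construction protocol: each sample is the
#' concatenated abundance vectors of `pixels_per_sample` spatially adjacent
#' blocks from one biopsy (the seed block plus its nearest disjoint blocks by
#' Euclidean tile distance, ties broken in row-major order), giving
#' `5 * pixels_per_sample` features. Classes with fewer candidate samples
#' than `samples_per_class` are excluded; from each surviving class exactly
#' `samples_per_class` samples are drawn without replacement (seeded), so
#' every included class is balanced.
#'
#' @param dataset A [simulate_dataset()] result, or a list with `blocks`
#'   (data.frame: `biopsy_id`, `label`, `row0`, `col0`, optional per-task
#'   label columns) and `abundances` (matrix).
#' @param task Label column to classify on; defaults to the dataset's own
#'   task (the `label` column).
#' @param pixels_per_sample 1, 2, or 3 blocks per sample.
#' @param samples_per_class Rows to draw per class; `NULL` uses the size of
#'   the smallest surviving class ("all available", balanced).
#' @param seed Integer seed for the sampling.
#' @param exclude Class labels to drop before balancing (e.g. `"AE"`).
#' @return A `feature_table`: list with `features`
#'   (m x 5*pixels_per_sample), `labels` (factor), `biopsy_ids`,
#'   `pixels_per_sample`, `samples_per_class`, `included_classes`,
#'   `excluded_classes`, `seed`.
#' @export
build_feature_table <- function(dataset, task = NULL, pixels_per_sample = 1,
                                samples_per_class = NULL, seed = 1,
                                exclude = character()) {
  if (!pixels_per_sample %in% 1:3) {
    stop_hsi("pixels_per_sample must be 1, 2, or 3",
             "hsifluor_parameter_error")
  }
  blocks <- dataset$blocks
  A <- as.matrix(dataset$abundances)
  lab_col <- if (!is.null(task) && task %in% names(blocks)) task else "label"
  labels <- as.character(blocks[[lab_col]])
  keep <- !labels %in% exclude & !is.na(labels)
  blocks <- blocks[keep, , drop = FALSE]
  A <- A[keep, , drop = FALSE]
  labels <- labels[keep]

  counts <- table(labels)
  if (is.null(samples_per_class)) {
    spc <- min(counts)
    included <- names(counts)
  } else {
    spc <- samples_per_class
    included <- names(counts)[counts >= spc]
  }
  excluded <- union(exclude, setdiff(names(counts), included))
  if (length(included) < 2) {
    stop_hsi("fewer than two classes survive the samples-per-class threshold",
             "hsifluor_task_infeasible_error")
  }

  with_seed(seed, {
    picked <- unlist(lapply(included, function(cl) {
      idx <- which(labels == cl)
      idx[sample.int(length(idx), spc)]
    }))
    feats <- matrix(0, length(picked), 5 * pixels_per_sample)
    if (pixels_per_sample == 1) {
      feats[] <- A[picked, , drop = FALSE]
    } else {
      # per-biopsy block lookup for neighbor search
      by_biopsy <- split(seq_len(nrow(blocks)), blocks$biopsy_id)
      for (i in seq_along(picked)) {
        b <- picked[i]
        sib <- by_biopsy[[blocks$biopsy_id[b]]]
        d2 <- (blocks$row0[sib] - blocks$row0[b])^2 +
              (blocks$col0[sib] - blocks$col0[b])^2
        ord <- sib[order(d2, blocks$row0[sib], blocks$col0[sib])]
        grp <- ord[seq_len(min(pixels_per_sample, length(ord)))]
        if (length(grp) < pixels_per_sample) {
          grp <- c(grp, rep(grp[length(grp)],
                            pixels_per_sample - length(grp)))
        }
        feats[i, ] <- as.vector(t(A[grp, , drop = FALSE]))
      }
    }
    colnames(feats) <- paste0("f", seq_len(ncol(feats)))
    structure(list(features = feats,
                   labels = factor(rep(included, each = spc)),
                   biopsy_ids = blocks$biopsy_id[picked],
                   pixels_per_sample = pixels_per_sample,
                   samples_per_class = spc,
                   included_classes = included,
                   excluded_classes = excluded,
                   seed = seed),
              class = "feature_table")
  })
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features (%d px/sample, %d per class)\n",
    nrow(x$features), ncol(x$features), x$pixels_per_sample,
    x$samples_per_class))
  cat("  classes:", paste(x$included_classes, collapse = ", "),
      if (length(x$excluded_classes)) {
        paste0("(excluded: ", paste(x$excluded_classes, collapse = ", "), ")")
      } else "", "\n")
  invisible(x)
}

subset_table <- function(table, idx) {
  out <- table
  out$features <- table$features[idx, , drop = FALSE]
  out$labels <- droplevels(table$labels[idx])
  out$biopsy_ids <- table$biopsy_ids[idx]
  out
}

#' Stratified 80/20 train/test split
#'
#' Splits a [build_feature_table()] result into disjoint training and test
#' sets, stratified by class. With `group_by_biopsy = TRUE` whole biopsies
#' are assigned to one side, so blocks of one biopsy never span the split
#' boundary (at the cost of approximate proportions); the default treats
#' every sample as independent.
#'
#' @param table A `feature_table`.
#' @param test_fraction Test share (default 0.2).
#' @param seed Integer seed.
#' @param group_by_biopsy Keep biopsies intact across the boundary.
#' @return List with `train` and `test` feature tables.
#' @export
split_train_test <- function(table, test_fraction = 0.2, seed = 1,
                             group_by_biopsy = FALSE) {
  if (!nrow(table$features)) {
    stop_hsi("empty feature table", "hsifluor_validation_error")
  }
  with_seed(seed, {
    test_idx <- integer(0)
    for (cl in levels(table$labels)) {
      idx <- which(table$labels == cl)
      n_test <- round(test_fraction * length(idx))
      if (group_by_biopsy) {
        bids <- sample(unique(table$biopsy_ids[idx]))
        take <- integer(0)
        for (b in bids) {
          if (length(take) >= n_test) break
          take <- c(take, idx[table$biopsy_ids[idx] == b])
        }
        test_idx <- c(test_idx, take)
      } else {
        test_idx <- c(test_idx, sample(idx, n_test))
      }
    }
    list(train = subset_table(table, setdiff(seq_len(nrow(table$features)),
                                             test_idx)),
         test = subset_table(table, test_idx))
  })
}

#' Export a feature table to CSV
#'
#' Columns: `sample_id,biopsy_id,label,f1..fN`.
#' @param table A `feature_table`.
#' @param path Output CSV.
#' @export
write_feature_csv <- function(table, path) {
  df <- data.frame(sample_id = seq_len(nrow(table$features)),
                   biopsy_id = table$biopsy_ids,
                   label = as.character(table$labels),
                   table$features)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
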