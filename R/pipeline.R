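#' Pipeline run configuration
#'
#' Plain-list configuration for [run_pipeline()], serializable to YAML. One
#' global seed drives every stage through [derive_seed()]'s counter scheme,
#' so an archived config reproduces a run exactly.
#'
#' @param task Classification task (default `"margin"`).
#' @param stages Ordered subset of
#'   `c("simulate", "preprocess", "unmix", "stats", "train", "evaluate")`.
#' @param delta Class-separability knob for the task preset.
#' @param n_biopsies_per_class Biopsies per class (`NULL` = preset roster).
#' @param pixels_per_sample,samples_per_class Feature-table protocol
#'   parameters.
#' @param grid `"default"` (small per-family grid) or `"table1"` (the full
#'   published grid).
#' @param group_by_biopsy Split mode for [split_train_test()].
#' @param field_size,diameter_range Phantom geometry for the example cube.
#' @param n_bands Spectral bands for the example cube (default the canonical
#'   310; smaller values speed up demo runs).
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(task = "margin", stages = c("simulate", "preprocess",
                                                   "unmix", "stats", "train",
                                                   "evaluate"),
                       delta = 1, n_biopsies_per_class = 10,
                       pixels_per_sample = 1, samples_per_class = 300,
                       grid = "default", group_by_biopsy = FALSE,
                       field_size = 512, diameter_range = c(190, 300),
                       n_bands = 310, seed = 1,
                       out_dir = tempfile("hsifluor_run_")) {
  cfg <- list(task = task, stages = stages, delta = delta,
              n_biopsies_per_class = n_biopsies_per_class,
              pixels_per_sample = pixels_per_sample,
              samples_per_class = samples_per_class, grid = grid,
              group_by_biopsy = group_by_biopsy, field_size = field_size,
              diameter_range = diameter_range, n_bands = n_bands,
              seed = seed, out_dir = out_dir, format_version = "1.0")
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  known <- c("simulate", "preprocess", "unmix", "stats", "train", "evaluate")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) {
    stop_hsi(paste("unknown stage(s):", paste(bad, collapse = ", ")),
             "hsifluor_config_error")
  }
  if (!cfg$task %in% c("tissue_type", "margin", "who_grade", "idh")) {
    stop_hsi(paste("unknown task:", cfg$task), "hsifluor_config_error")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[setdiff(names(cfg), "format_version")])
}

stage_log <- function(manifest, stage, t0, artifacts) {
  manifest$stages[[stage]] <- list(
    seed = derive_seed(manifest$seed, stage),
    seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
    artifacts = artifacts)
  message(sprintf("[%s] done in %.1fs (%d artifact(s))", stage,
                  manifest$stages[[stage]]$seconds, length(artifacts)))
  manifest
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop_hsi(sprintf(
      "stage '%s' requires an artifact from stage '%s' (missing: %s)",
      needed_by, stage, path), "hsifluor_dependency_error")
  }
  path
}

#' Run the staged analysis pipeline
#'
#' Executes the configured stages in order — simulate, preprocess, unmix,
#' stats, train, evaluate — writing every stage's artifacts (CSV/TIFF/JSON)
#' under the configured output directory, and returns a manifest listing
#' artifact paths, md5 checksums, per-stage seeds, and timings. Stages that
#' need an upstream artifact raise a dependency error naming the missing
#' stage.
#'
#' @param config A [run_config()].
#' @return A `run_manifest`: list with `config`, `seed`, `stages`,
#'   `artifacts` (named paths), `checksums`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   stages = list(), artifacts = character(0))
  basis <- synthetic_basis(wavelength_grid(n_bands = config$n_bands %||% 310))
  od <- config$out_dir

  if ("simulate" %in% config$stages) {
    t0 <- Sys.time()
    ds <- simulate_dataset(config$task, task_preset(config$task, config$delta),
                           n_biopsies_per_class = config$n_biopsies_per_class,
                           delta = config$delta,
                           seed = derive_seed(config$seed, "simulate"),
                           field_size = config$field_size,
                           diameter_range = config$diameter_range)
    paths <- export_dataset_csv(ds, od)
    # one example biopsy rendered as a full cube triplet for the imaging
    # stages
    trip <- simulate_biopsy_cube(ds$biopsies[[1]], basis,
                                 seed = derive_seed(config$seed, "cube"))
    side <- write_cube_triplet(trip, od, prefix = "example_cube",
                               seed = config$seed,
                               labels = ds$biopsies[[1]]$labels)
    saveRDS(ds, file.path(od, "dataset.rds"))
    manifest$artifacts <- c(manifest$artifacts, paths,
                            example_cube = side,
                            dataset = file.path(od, "dataset.rds"))
    manifest <- stage_log(manifest, "simulate", t0,
                          c(paths, side, file.path(od, "dataset.rds")))
  }

  if ("preprocess" %in% config$stages) {
    t0 <- Sys.time()
    side <- require_artifact(file.path(od, "example_cube.json"), "simulate",
                             "preprocess")
    trip <- read_cube_triplet(side)
    bs <- preprocess_triplet(trip)
    sp <- file.path(od, "block_spectra.csv")
    write_spectra_csv(bs, sp)
    mp <- write_mask_tiff(bs$mask, file.path(od, "tumor_mask.tif"))
    saveRDS(bs, file.path(od, "block_spectra.rds"))
    manifest$artifacts <- c(manifest$artifacts, block_spectra = sp, mask = mp)
    manifest <- stage_log(manifest, "preprocess", t0, c(sp, mp))
  }

  if ("unmix" %in% config$stages) {
    t0 <- Sys.time()
    bsp <- require_artifact(file.path(od, "block_spectra.rds"), "preprocess",
                            "unmix")
    bs <- readRDS(bsp)
    ab <- unmix_matrix(bs$spectra, basis)
    ap <- file.path(od, "example_abundances.csv")
    utils::write.csv(data.frame(sample_id = seq_len(nrow(ab)),
                                bs$block_origin, ab), ap, row.names = FALSE)
    manifest$artifacts <- c(manifest$artifacts, example_abundances = ap)
    manifest <- stage_log(manifest, "unmix", t0, ap)
  }

  if ("stats" %in% config$stages) {
    t0 <- Sys.time()
    dsp <- require_artifact(file.path(od, "dataset.rds"), "simulate", "stats")
    ds <- readRDS(dsp)
    pca <- data.frame(n = 2:5, variance_explained = vapply(2:5, function(n) {
      pca_variance_explained(ds$abundances, n)$variance_explained
    }, numeric(1)))
    pp <- file.path(od, "pca_variance_explained.csv")
    utils::write.csv(pca, pp, row.names = FALSE)
    ks <- ks_battery(ds$abundances, ds$blocks$label)
    kp <- write_ks_csv(ks, file.path(od, "ks_battery.csv"),
                       task = config$task)
    manifest$artifacts <- c(manifest$artifacts, pca = pp, ks = kp)
    manifest <- stage_log(manifest, "stats", t0, c(pp, kp))
  }

  if ("train" %in% config$stages) {
    t0 <- Sys.time()
    dsp <- require_artifact(file.path(od, "dataset.rds"), "simulate", "train")
    ds <- readRDS(dsp)
    ft <- build_feature_table(ds, pixels_per_sample = config$pixels_per_sample,
                              samples_per_class = config$samples_per_class,
                              seed = derive_seed(config$seed, "features"))
    fp <- write_feature_csv(ft, file.path(od, "feature_table.csv"))
    split <- split_train_test(ft, seed = derive_seed(config$seed, "split"),
                              group_by_biopsy = config$group_by_biopsy)
    grids <- if (config$grid == "table1") model_grid_table1()
             else model_grid_default()
    ranking <- cross_validate_grid(split$train, grids,
                                   seed = derive_seed(config$seed, "cv"))
    rp <- file.path(od, "cv_ranking.csv")
    utils::write.csv(as.data.frame(ranking), rp, row.names = FALSE)
    saveRDS(list(split = split, ranking = ranking),
            file.path(od, "train_state.rds"))
    manifest$artifacts <- c(manifest$artifacts, feature_table = fp,
                            cv_ranking = rp)
    manifest <- stage_log(manifest, "train", t0, c(fp, rp))
  }

  if ("evaluate" %in% config$stages) {
    t0 <- Sys.time()
    tsp <- require_artifact(file.path(od, "train_state.rds"), "train",
                            "evaluate")
    st <- readRDS(tsp)
    fit <- fit_model(best_model(st$ranking), st$split$train$features,
                     st$split$train$labels,
                     seed = derive_seed(config$seed, "fit"))
    report <- evaluate(fit, st$split$test)
    ep <- file.path(od, "evaluation_report.json")
    jsonlite::write_json(list(
      model = format(report$model),
      accuracy = report$accuracy,
      macro_auc = report$macro_auc,
      auc_per_class = as.list(report$auc_per_class),
      confusion = report$confusion,
      n_test = report$n_test), ep, auto_unbox = TRUE, digits = NA)
    for (cl in names(report$roc)) {
      utils::write.csv(report$roc[[cl]],
                       file.path(od, sprintf("roc_%s.csv", cl)),
                       row.names = FALSE)
    }
    saveRDS(report, file.path(od, "evaluation_report.rds"))
    manifest$artifacts <- c(manifest$artifacts, evaluation = ep)
    manifest <- stage_log(manifest, "evaluate", t0, ep)
  }

  files <- manifest$artifacts[file.exists(manifest$artifacts)]
  manifest$checksums <- as.list(tools::md5sum(files))
  mp <- file.path(od, "manifest.json")
  jsonlite::write_json(manifest[c("config", "seed", "stages", "artifacts",
                                  "checksums")],
                       mp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest$path <- mp
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d stage(s), %d artifact(s), seed=%d\n",
              length(x$stages), length(x$artifacts), x$seed))
  invisible(x)
}

#' Render a static report bundle from a pipeline run
#'
#' Writes PNG figures (confusion-matrix heatmap, one-vs-rest ROC curves,
#' 2-component PCA scatter of the abundances, PpIX634 abundance overlay of
#' the example biopsy) and a Markdown summary including the KS exception
#' table, into `<out_dir>/report/`.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param overlay_channel Fluorophore channel for the abundance overlay
#'   (default `"PpIX634"`).
#' @return Invisibly, the report directory path.
#' @export
make_report <- function(manifest, overlay_channel = "PpIX634") {
  od <- manifest$config$out_dir
  rd <- file.path(od, "report")
  dir.create(rd, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# Pipeline report", "",
             sprintf("Task: %s; seed: %d", manifest$config$task,
                     manifest$seed), "")

  ep <- file.path(od, "evaluation_report.rds")
  if (file.exists(ep)) {
    report <- readRDS(ep)
    cm <- as.data.frame(as.table(report$confusion))
    gg <- ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted,
                                           y = .data$truth,
                                           fill = .data$Freq)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
      ggplot2::labs(title = "Confusion matrix", x = "Predicted",
                    y = "True")
    ggplot2::ggsave(file.path(rd, "confusion_matrix.png"), gg,
                    width = 5, height = 4, dpi = 120)
    rocdf <- do.call(rbind, lapply(names(report$roc), function(cl) {
      cbind(class = cl, report$roc[[cl]])
    }))
    gg <- ggplot2::ggplot(rocdf, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                              color = .data$class)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(linetype = 2, color = "grey") +
      ggplot2::labs(title = "One-vs-rest ROC",
                    x = "False positive rate", y = "True positive rate")
    ggplot2::ggsave(file.path(rd, "roc.png"), gg, width = 5, height = 4,
                    dpi = 120)
    lines <- c(lines,
               sprintf("Best model: %s", format(report$model)),
               sprintf("Test accuracy: %.3f; macro AUC: %.3f",
                       report$accuracy, report$macro_auc), "",
               "![confusion](confusion_matrix.png)", "![roc](roc.png)", "")
  }

  dsp <- file.path(od, "dataset.rds")
  if (file.exists(dsp)) {
    ds <- readRDS(dsp)
    pca <- pca_variance_explained(ds$abundances, 2)
    sc <- data.frame(PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                     class = ds$blocks$label)
    gg <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                           color = .data$class)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.7) +
      ggplot2::labs(title = sprintf(
        "2-component PCA (%.0f%% variance explained)",
        100 * pca$variance_explained))
    ggplot2::ggsave(file.path(rd, "pca_scatter.png"), gg, width = 5,
                    height = 4, dpi = 120)
    lines <- c(lines, "![pca](pca_scatter.png)", "")
  }

  abp <- file.path(od, "example_abundances.csv")
  if (file.exists(abp)) {
    ab <- utils::read.csv(abp)
    bs <- manifest$config$field_size
    ab$mm_x <- ab$col0 / 47.62
    ab$mm_y <- ab$row0 / 47.62
    gg <- ggplot2::ggplot(ab, ggplot2::aes(x = .data$mm_x, y = .data$mm_y,
                                           fill = .data[[overlay_channel]])) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::coord_fixed() +
      ggplot2::labs(title = sprintf("%s abundance overlay", overlay_channel),
                    x = "mm", y = "mm")
    ggplot2::ggsave(file.path(rd, "abundance_overlay.png"), gg, width = 5,
                    height = 4, dpi = 120)
    lines <- c(lines, "![overlay](abundance_overlay.png)", "")
  }

  kp <- file.path(od, "ks_battery.csv")
  if (file.exists(kp)) {
    ks <- utils::read.csv(kp)
    exc <- ks[!ks$significant, , drop = FALSE]
    lines <- c(lines, "## Kolmogorov-Smirnov battery", "")
    if (nrow(exc)) {
      lines <- c(lines, "Pairs NOT significant at alpha:",
                 utils::capture.output(print(exc[, c("fluorophore", "class_a",
                                                     "class_b", "p_value")],
                                             row.names = FALSE)))
    } else {
      lines <- c(lines,
                 "All class pairs significantly different in all fluorophores.")
    }
  }
  writeLines(lines, file.path(rd, "report.md"))
  invisible(rd)
}
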