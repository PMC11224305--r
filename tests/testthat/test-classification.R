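test_that("WHO-2021 relabeling moves only IDH-wildtype AA to GB", {
  rec <- data.frame(tissue_type = c("AA", "AA", "GB", "DA", "AA"),
                    idh = c("wildtype", "mutant", "wildtype", "wildtype", NA))
  out <- relabel_who2021(rec)
  expect_equal(out$tissue_type, c("GB", "AA", "GB", "DA", "AA"))
  expect_equal(attr(out, "n_relabeled"), 1)
  expect_error(relabel_who2021(data.frame(a = 1)),
               class = "hsifluor_validation_error")
})

test_that("classes below the samples-per-class threshold are excluded", {
  ds <- roster_dataset(list(A = 600, B = 450, C = 600))
  ft <- build_feature_table(ds, samples_per_class = 500, seed = 1)
  expect_setequal(ft$included_classes, c("A", "C"))
  expect_true("B" %in% ft$excluded_classes)
  expect_equal(unname(table(ft$labels)["A"]), 500)
  expect_equal(unname(table(ft$labels)["C"]), 500)
  expect_equal(nrow(ft$features), 1000)

  # fewer than two survivors is infeasible
  expect_error(build_feature_table(ds, samples_per_class = 550, seed = 1,
                                   exclude = "C"),
               class = "hsifluor_task_infeasible_error")
})

test_that("explicit class exclusion removes the class from the table", {
  ds <- roster_dataset(list(A = 300, AE = 300, C = 300))
  ft <- build_feature_table(ds, samples_per_class = 200, exclude = "AE")
  expect_false("AE" %in% ft$included_classes)
  expect_false(any(ft$labels == "AE"))
})

test_that("pixels_per_sample widens features to 5 per block", {
  ds <- small_margin_dataset(n_biopsies = 2)
  for (pps in 1:3) {
    ft <- build_feature_table(ds, pixels_per_sample = pps,
                              samples_per_class = 50, seed = 2)
    expect_equal(ncol(ft$features), 5 * pps)
  }
  expect_error(build_feature_table(ds, pixels_per_sample = 4,
                                   samples_per_class = 50),
               class = "hsifluor_parameter_error")
})

test_that("multi-block samples concatenate the nearest same-biopsy blocks", {
  # one biopsy, four blocks in a row; neighbor of each block is its adjacent
  # tile, ties broken row-major
  blocks <- data.frame(biopsy_id = "b1", label = rep(c("A", "B"), each = 2),
                       row0 = 0, col0 = c(0, 10, 20, 30))
  A <- matrix(seq_len(4 * 5), 4, 5)
  ds <- list(blocks = blocks, abundances = A)
  ft <- build_feature_table(ds, pixels_per_sample = 2, samples_per_class = 2,
                            seed = 3)
  for (i in seq_len(nrow(ft$features))) {
    self <- ft$features[i, 1:5]
    nb <- ft$features[i, 6:10]
    self_idx <- which(apply(A, 1, function(r) all(r == self)))
    nb_idx <- which(apply(A, 1, function(r) all(r == nb)))
    d <- abs(blocks$col0 - blocks$col0[self_idx])
    d[self_idx] <- Inf
    # nearest other tile (10 px away; ties go to the lower column)
    expect_equal(blocks$col0[nb_idx], blocks$col0[self_idx] +
                   if (self_idx == 1) 10 else -10)
  }
})

test_that("stratified 80/20 split has exact per-class counts", {
  ds <- roster_dataset(list(A = 700, B = 700, C = 700))
  ft <- build_feature_table(ds, samples_per_class = 500, seed = 4)
  sp <- split_train_test(ft, test_fraction = 0.2, seed = 5)
  expect_equal(as.integer(table(sp$test$labels)), rep(100L, 3))
  expect_equal(as.integer(table(sp$train$labels)), rep(400L, 3))
  expect_equal(nrow(sp$train$features) + nrow(sp$test$features), 1500)

  sp2 <- split_train_test(ft, test_fraction = 0.2, seed = 5)
  expect_identical(sp$test$features, sp2$test$features)
})

test_that("biopsy-grouped splitting never splits a biopsy", {
  ds <- small_margin_dataset(n_biopsies = 6, seed = 11)
  ft <- build_feature_table(ds, samples_per_class = 200, seed = 6)
  sp <- split_train_test(ft, seed = 7, group_by_biopsy = TRUE)
  expect_length(intersect(unique(sp$train$biopsy_ids),
                          unique(sp$test$biopsy_ids)), 0)
})

test_that("cross-validation returns a single-model grid unchanged and ranks a separable problem at 1.0", {
  set.seed(8)
  X <- rbind(matrix(rnorm(100 * 5, 0), 100, 5),
             matrix(rnorm(100 * 5, 8), 100, 5))
  tab <- structure(list(features = X,
                        labels = factor(rep(c("lo", "hi"), each = 100)),
                        biopsy_ids = rep(c("b1", "b2"), 100)),
                   class = "feature_table")
  one <- cross_validate_grid(tab, list(model_spec("knn", k = 3)), seed = 9)
  expect_equal(nrow(one), 1)
  expect_equal(best_model(one)$algorithm, "knn")
  expect_equal(one$cv_accuracy[1], 1.0)
})

test_that("every engine fits, predicts probabilities, and beats chance on separated data", {
  set.seed(10)
  X <- rbind(matrix(rnorm(90 * 5, 0), 90, 5),
             matrix(rnorm(90 * 5, 4), 90, 5))
  y <- factor(rep(c("a", "b"), each = 90))
  for (spec in model_grid_default()) {
    fit <- fit_model(spec, X, y, seed = 11)
    pred <- predict_model(fit, X)
    expect_equal(dim(pred$prob), c(180, 2))
    expect_equal(unname(rowSums(pred$prob)), rep(1, 180), tolerance = 1e-6)
    expect_gt(mean(pred$class == y), 0.9)
  }
})

test_that("evaluation of a perfect classifier gives unit metrics", {
  set.seed(12)
  X <- rbind(matrix(rnorm(60 * 5, 0), 60, 5),
             matrix(rnorm(60 * 5, 10), 60, 5))
  tab <- structure(list(features = X,
                        labels = factor(rep(c("a", "b"), each = 60)),
                        biopsy_ids = rep("b", 120)),
                   class = "feature_table")
  sp <- split_train_test(tab, seed = 13)
  fit <- fit_model(model_spec("knn", k = 3), sp$train$features,
                   sp$train$labels)
  rep_ <- evaluate(fit, sp$test)
  expect_equal(rep_$accuracy, 1)
  expect_equal(sum(rep_$confusion) - sum(diag(rep_$confusion)), 0)
  expect_equal(unname(rep_$auc_per_class), c(1, 1))
  expect_equal(rep_$macro_auc, 1)
  # confusion rows sum to per-class test counts
  expect_equal(as.integer(rowSums(rep_$confusion)),
               as.integer(table(sp$test$labels)))
})

test_that("reported AUC equals the pairwise rank-comparison oracle", {
  # the textbook 4-point case: scores .9,.8,.3,.2 with labels +,-,+,-
  expect_equal(rank_auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  set.seed(14)
  X <- rbind(matrix(rnorm(80 * 5, 0), 80, 5),
             matrix(rnorm(80 * 5, 1.2), 80, 5))
  tab <- structure(list(features = X,
                        labels = factor(rep(c("a", "b"), each = 80)),
                        biopsy_ids = rep("b", 160)),
                   class = "feature_table")
  sp <- split_train_test(tab, seed = 15)
  fit <- fit_model(model_spec("random_forest", ntree = 50), sp$train$features,
                   sp$train$labels, seed = 16)
  rep_ <- evaluate(fit, sp$test)
  pred <- predict_model(fit, sp$test$features)
  for (cl in c("a", "b")) {
    expect_equal(unname(rep_$auc_per_class[cl]),
                 rank_auc(pred$prob[, cl], sp$test$labels == cl),
                 tolerance = 1e-10)
  }
})

test_that("chance-level data yields chance-level accuracy", {
  set.seed(17)
  K <- 3
  X <- matrix(rnorm(450 * 5), 450, 5)  # labels independent of features
  tab <- structure(list(features = X,
                        labels = factor(rep(c("a", "b", "c"), each = 150)),
                        biopsy_ids = rep("b", 450)),
                   class = "feature_table")
  sp <- split_train_test(tab, seed = 18)
  fit <- fit_model(model_spec("random_forest", ntree = 50), sp$train$features,
                   sp$train$labels, seed = 19)
  acc <- evaluate(fit, sp$test)$accuracy
  n <- nrow(sp$test$features)
  band <- 4 * sqrt((1 / K) * (1 - 1 / K) / n)
  expect_lt(abs(acc - 1 / K), band)
})

test_that("more samples per class does not hurt cross-validated accuracy", {
  ds <- small_margin_dataset(delta = 0.6, n_biopsies = 6, seed = 20)
  grid <- list(model_spec("random_forest", ntree = 50))
  accs <- vapply(c(60, 200), function(spc) {
    ft <- build_feature_table(ds, samples_per_class = spc, seed = 21)
    cross_validate_grid(ft, grid, seed = 22)$cv_accuracy[1]
  }, numeric(1))
  expect_gte(accs[2], accs[1] - 0.05)
})

test_that("the published search grid enumerates all five model families", {
  grid <- model_grid_table1()
  algos <- table(vapply(grid, `[[`, "", "algorithm"))
  expect_equal(unname(algos["random_forest"]), 45)  # 5 x 3 x 3
  expect_equal(unname(algos["knn"]), 16)            # 4 x 2 x 2
  expect_equal(unname(algos["svm"]), 4)
  expect_equal(unname(algos["mlp"]), 24)            # 3 x 4 x 2
  expect_equal(unname(algos["adaboost"]), 1)
})
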