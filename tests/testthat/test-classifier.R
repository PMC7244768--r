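# Shared small simulated cohort for the classifier tests (built once).
clf_cohort <- sim_gene_cohort(n_per_class = 12, seed = 21)

test_that("stratified split hits the per-class training counts", {
  # cohort of 429 samples with realistic class sizes, split two-thirds
  sizes <- c(ABC = 125, GCB = 127, PMBL = 43, FL = 47, MCL = 31, SLL = 17,
             MZL = 39)
  labels <- rep(names(sizes), sizes)
  expr <- expression_matrix(
    matrix(rnorm(429 * 4), 429, 4,
           dimnames = list(sprintf("S%03d", 1:429), paste0("G", 1:4))))
  cohort <- labeled_cohort(expr, labels)
  split <- split_cohort(cohort, fraction = 2 / 3, seed = 11)
  n_train <- sum(split$cohort == "TRAIN")
  expect_equal(n_train, sum(round(2 / 3 * sizes)))
  expect_true(abs(n_train - 286) <= 4)  # 2/3 of 429 up to rounding
  per_class <- table(split$labels[split$cohort == "TRAIN"])
  expect_equal(as.numeric(per_class[names(sizes)]),
               unname(round(2 / 3 * sizes)))
  # deterministic under seed; fraction 1 puts everything in TRAIN
  split2 <- split_cohort(cohort, fraction = 2 / 3, seed = 11)
  expect_equal(split$cohort, split2$cohort)
  all_train <- split_cohort(cohort, fraction = 1, seed = 11)
  expect_true(all(all_train$cohort == "TRAIN"))
})

test_that("split refuses labels with fewer than 2 samples", {
  expr <- expression_matrix(
    matrix(rnorm(12), 3, 4, dimnames = list(paste0("S", 1:3),
                                            paste0("G", 1:4))))
  cohort <- labeled_cohort(expr, c("ABC", "ABC", "GCB"))
  expect_error(split_cohort(cohort, fraction = 2 / 3), "fewer than 2")
})

test_that("MALT and LPL labels merge into the MZL class", {
  expr <- expression_matrix(
    matrix(rnorm(16), 4, 4, dimnames = list(paste0("S", 1:4),
                                            paste0("G", 1:4))))
  cohort <- labeled_cohort(expr, c("MZL", "MALT", "LPL", "ABC"))
  expect_equal(as.character(cohort$labels), c("MZL", "MZL", "MZL", "ABC"))
  expect_error(labeled_cohort(expr, c("MZL", "MALT", "LPL", "XXX")),
               "unknown subtype")
})

test_that("training validates its inputs", {
  cohort <- clf_cohort
  single <- labeled_cohort(expr_subset(cohort$expr, cohort$labels == "ABC"),
                           cohort$labels[cohort$labels == "ABC"])
  expect_error(train_subtype_model(single, forest_config(n_trees = 10)),
               "at least 2")
  broken <- cohort
  broken$expr$values[2, 3] <- NA
  expect_error(train_subtype_model(broken, forest_config(n_trees = 10)),
               paste0(rownames(cohort$expr$values)[2], ".*",
                      colnames(cohort$expr$values)[3]))
})

test_that("training and prediction are deterministic under a fixed seed", {
  cohort <- clf_cohort
  cfg <- forest_config(n_trees = 80, seed = 5)
  m1 <- train_subtype_model(cohort, cfg)
  m2 <- train_subtype_model(cohort, cfg)
  p1 <- predict_subtypes(m1, cohort$expr)
  p2 <- predict_subtypes(m2, cohort$expr)
  expect_equal(p1, p2)
})

test_that("prediction probabilities are vote fractions with argmax calls", {
  cohort <- clf_cohort
  model <- train_subtype_model(cohort, forest_config(n_trees = 80, seed = 5))
  pred <- predict_subtypes(model, cohort$expr)
  probs <- as.matrix(pred[, SUBTYPE_LEVELS])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
               tolerance = 1e-12)
  expect_equal(pred$call,
               SUBTYPE_LEVELS[max.col(probs, ties.method = "first")])
  # vote fractions are multiples of 1/n_trees
  expect_equal(probs * 80, round(probs * 80), tolerance = 1e-9)
})

test_that("prediction is invariant to expression column order and handles degenerate rows", {
  cohort <- clf_cohort
  model <- train_subtype_model(cohort, forest_config(n_trees = 60, seed = 5))
  perm <- expression_matrix(
    cohort$expr$values[, sample(ncol(cohort$expr$values))],
    level = "gene")
  expect_equal(predict_subtypes(model, perm),
               predict_subtypes(model, cohort$expr))
  zero <- expression_matrix(
    matrix(0, 1, ncol(cohort$expr$values),
           dimnames = list("Z1", colnames(cohort$expr$values))),
    level = "gene")
  pz <- predict_subtypes(model, zero)
  expect_equal(sum(pz[1, SUBTYPE_LEVELS]), 1, tolerance = 1e-9)
  expect_true(pz$call %in% SUBTYPE_LEVELS)
})

test_that("models survive a save/load round trip bit-compatibly", {
  cohort <- clf_cohort
  model <- train_subtype_model(cohort, forest_config(n_trees = 40, seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict_subtypes(back, cohort$expr),
               predict_subtypes(model, cohort$expr))
})

test_that("evaluate reports accuracy, per-class rates and confusion", {
  labels <- rep(SUBTYPE_LEVELS, each = 3)
  report <- evaluate_predictions(labels, labels)
  expect_equal(report$accuracy, 1)
  expect_equal(unname(diag(report$confusion)), rep(3L, 7))
  expect_equal(sum(report$confusion) - sum(diag(report$confusion)), 0L)
})

test_that("relabeling classes permutes the confusion matrix consistently", {
  set.seed(8)
  labels <- sample(SUBTYPE_LEVELS, 60, replace = TRUE)
  calls <- sample(SUBTYPE_LEVELS, 60, replace = TRUE)
  report <- evaluate_predictions(calls, labels)
  perm <- stats::setNames(SUBTYPE_LEVELS[c(2:7, 1)], SUBTYPE_LEVELS)
  report2 <- evaluate_predictions(unname(perm[calls]), unname(perm[labels]))
  idx <- match(SUBTYPE_LEVELS, perm)  # old-level index feeding each new level
  reordered <- report$confusion[idx, idx]
  expect_equal(unname(as.matrix(report2$confusion)),
               unname(as.matrix(reordered)))
  expect_equal(report2$accuracy, report$accuracy)
})

test_that("labels CSV loads with MALT/LPL remapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,subtype", "S1,GCB", "S2,MALT", "S3,LPL"), path)
  df <- read_labels(path)
  expect_equal(df$subtype, c("GCB", "MZL", "MZL"))
})
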