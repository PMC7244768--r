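# Seven-class random-forest B-NHL subtype predictor.

#' Canonical subtype label order
#'
#' The seven B-NHL classes the predictor distinguishes: activated B-cell-like
#' DLBCL, germinal-center B-cell-like DLBCL, primary mediastinal B-cell
#' lymphoma, follicular, mantle-cell and small lymphocytic lymphoma, and a
#' merged marginal-zone class (nodal/splenic MZL, MALT and LPL). Argmax ties
#' are broken by this order.
#'
#' @export
SUBTYPE_LEVELS <- c("ABC", "GCB", "PMBL", "FL", "MCL", "SLL", "MZL")

MZL_MERGED <- c("MZL", "MALT", "LPL")

#' Random-forest hyperparameters
#'
#' Defaults follow the assay's published training setup: 5000 trees, Gini
#' impurity, maximum depth 20 and a minimum of 4 samples to split a node,
#' with the usual classification defaults otherwise (sqrt(p) candidate
#' features per split, bootstrap resampling).
#'
#' @param n_trees number of trees (default 5000).
#' @param max_depth maximum tree depth (default 20).
#' @param min_node_size minimum node size eligible for splitting (default 4).
#' @param mtry candidate features per split; \code{NULL} = floor(sqrt(p)).
#' @param seed RNG seed baked into the model for reproducible training.
#' @return a \code{ForestConfig}.
#' @export
forest_config <- function(n_trees = 5000L, max_depth = 20L,
                          min_node_size = 4L, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_node_size >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 criterion = "gini",
                 max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 seed = as.integer(seed)),
            class = "ForestConfig")
}

normalize_subtype_labels <- function(labels) {
  labels <- as.character(labels)
  labels[labels %in% MZL_MERGED] <- "MZL"
  bad <- setdiff(unique(labels), SUBTYPE_LEVELS)
  if (length(bad)) stop("unknown subtype label: ", bad[1])
  factor(labels, levels = SUBTYPE_LEVELS)
}

#' Join an expression matrix with subtype labels and cohort assignment
#'
#' MALT and LPL labels are remapped to the merged MZL class on construction.
#'
#' @param expr an \code{ExpressionMatrix} (gene-level recommended).
#' @param labels per-sample subtype labels (named or in sample order).
#' @param cohort optional per-sample assignment, \code{"TRAIN"} or
#'   \code{"VALIDATION"}; \code{NA} = unassigned.
#' @return a \code{LabeledCohort}.
#' @export
labeled_cohort <- function(expr, labels, cohort = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!is.null(names(labels))) {
    missing <- setdiff(expr$samples, names(labels))
    if (length(missing)) stop("no label for sample ", missing[1])
    labels <- labels[expr$samples]
  }
  if (length(labels) != length(expr$samples))
    stop("labels length != number of samples")
  if (is.null(cohort)) cohort <- rep(NA_character_, length(expr$samples))
  if (!is.null(names(cohort))) cohort <- cohort[expr$samples]
  cohort <- factor(as.character(cohort), levels = c("TRAIN", "VALIDATION"))
  labels <- normalize_subtype_labels(labels)
  names(labels) <- expr$samples
  names(cohort) <- expr$samples
  structure(list(expr = expr, labels = labels, cohort = cohort),
            class = "LabeledCohort")
}

#' Stratified train/validation split
#'
#' Randomly assigns the given fraction of each subtype to the training
#' cohort (rounded per class), the rest to validation; reproducible under
#' \code{seed}.
#'
#' @param cohort a \code{LabeledCohort} with unassigned cohort tags.
#' @param fraction training fraction (default 2/3, the published split).
#' @param seed RNG seed.
#' @return the cohort with \code{cohort} tags filled in.
#' @export
split_cohort <- function(cohort, fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(cohort, "LabeledCohort"), fraction > 0, fraction <= 1)
  tab <- table(cohort$labels)
  tab <- tab[tab > 0]
  if (fraction < 1 && any(tab < 2))
    stop("cannot stratify: label ", names(tab)[tab < 2][1],
         " has fewer than 2 samples")
  assign <- rep("VALIDATION", length(cohort$labels))
  set.seed(seed)
  for (lab in names(tab)) {
    idx <- which(cohort$labels == lab)
    n_train <- round(fraction * length(idx))
    n_train <- max(1L, min(length(idx), n_train))
    if (fraction == 1) n_train <- length(idx)
    assign[sample(idx, n_train)] <- "TRAIN"
  }
  cohort$cohort <- factor(assign, levels = c("TRAIN", "VALIDATION"))
  cohort
}

#' Train the subtype random forest
#'
#' Fits a classification forest (Gini splits) on the TRAIN rows of the
#' cohort. Per-class probabilities at prediction time are vote fractions
#' over the trees. The fitted model records its feature order, label order,
#' configuration and training-data checksum, and is fully reproducible under
#' \code{config$seed}.
#'
#' @param cohort a \code{LabeledCohort}; rows tagged TRAIN are used (all
#'   rows if no tags are set).
#' @param config a \code{ForestConfig}.
#' @return a \code{SubtypeModel}.
#' @importFrom ranger ranger
#' @export
train_subtype_model <- function(cohort, config = forest_config()) {
  stopifnot(inherits(cohort, "LabeledCohort"),
            inherits(config, "ForestConfig"))
  use <- if (all(is.na(cohort$cohort))) rep(TRUE, length(cohort$labels))
         else !is.na(cohort$cohort) & cohort$cohort == "TRAIN"
  x <- cohort$expr$values[use, , drop = FALSE]
  y <- droplevels(cohort$labels[use])
  if (nlevels(y) < 2) stop("training requires at least 2 subtype labels")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing expression value for sample ", rownames(x)[bad[1]],
         ", marker ", colnames(x)[bad[2]])
  }
  df <- data.frame(x, check.names = FALSE)
  df$.subtype <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".subtype", data = df,
    num.trees = config$n_trees, splitrule = "gini",
    max.depth = config$max_depth, min.node.size = config$min_node_size,
    mtry = config$mtry, seed = config$seed, num.threads = 1,
    verbose = FALSE)
  structure(list(forest = fit,
                 config = config,
                 features = colnames(x),
                 class_levels = SUBTYPE_LEVELS,
                 trained_levels = levels(y)),
            class = "SubtypeModel")
}

#' Predict subtype probabilities
#'
#' Applies the forest to each sample; the probability of a class is the
#' fraction of trees voting for it, and the call is the argmax (ties broken
#' by the canonical label order).
#'
#' @param model a \code{SubtypeModel}.
#' @param expr an \code{ExpressionMatrix} whose markers cover the model's
#'   features (extra markers and arbitrary column order are fine).
#' @return data.frame: \code{sample}, one probability column per class in
#'   canonical order, \code{call}.
#' @export
predict_subtypes <- function(model, expr) {
  stopifnot(inherits(model, "SubtypeModel"),
            inherits(expr, "ExpressionMatrix"))
  missing <- setdiff(model$features, expr$markers)
  if (length(missing)) stop("expression matrix lacks model feature: ",
                            missing[1])
  x <- expr$values[, model$features, drop = FALSE]
  df <- data.frame(x, check.names = FALSE)
  pr <- stats::predict(model$forest, data = df, predict.all = TRUE,
                       num.threads = 1)
  votes <- pr$predictions  # samples x trees, level indices
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(df))
  lev <- model$forest$forest$levels
  probs <- matrix(0, nrow(df), length(SUBTYPE_LEVELS),
                  dimnames = list(rownames(x), SUBTYPE_LEVELS))
  for (k in seq_along(lev))
    probs[, lev[k]] <- rowMeans(votes == k)
  call <- SUBTYPE_LEVELS[max.col(probs, ties.method = "first")]
  out <- data.frame(sample = rownames(x), probs, call = call,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out
}

#' Save / load a fitted subtype model
#'
#' The file embeds the forest, its configuration, feature list and label
#' order; reloading reproduces predictions exactly.
#'
#' @param model a \code{SubtypeModel}.
#' @param path model file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "SubtypeModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "SubtypeModel")) stop("not a SubtypeModel file: ", path)
  model
}

#' Concordance report for subtype predictions
#'
#' @param calls predicted labels (character or factor), or the data.frame
#'   returned by \code{\link{predict_subtypes}}.
#' @param labels reference labels.
#' @return a \code{ConcordanceReport}: overall accuracy (proportion and
#'   percent to one decimal), per-class accuracy, and the 7x7 confusion
#'   matrix (reference in rows, prediction in columns).
#' @export
evaluate_predictions <- function(calls, labels) {
  if (is.data.frame(calls)) calls <- calls$call
  calls <- normalize_subtype_labels(calls)
  labels <- normalize_subtype_labels(labels)
  if (length(calls) != length(labels))
    stop("calls and labels differ in length")
  confusion <- table(reference = labels, prediction = calls)
  n_correct <- sum(diag(confusion))
  n_total <- length(labels)
  per_class <- data.frame(
    class = SUBTYPE_LEVELS,
    n = as.integer(rowSums(confusion)),
    n_correct = as.integer(diag(confusion)),
    stringsAsFactors = FALSE)
  per_class$accuracy <- ifelse(per_class$n > 0,
                               per_class$n_correct / per_class$n, NA_real_)
  per_class$accuracy_pct <- round(100 * per_class$accuracy, 1)
  structure(list(n_total = n_total, n_correct = n_correct,
                 accuracy = n_correct / n_total,
                 accuracy_pct = round(100 * n_correct / n_total, 1),
                 per_class = per_class,
                 confusion = confusion),
            class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat("ConcordanceReport: ", x$n_correct, "/", x$n_total, " correct (",
      x$accuracy_pct, "%)\n", sep = "")
  print(x$per_class[x$per_class$n > 0, ])
  invisible(x)
}

#' Read a labels CSV (sample_id, subtype[, cohort])
#'
#' MALT and LPL are remapped to MZL on load.
#'
#' @param path CSV path.
#' @return data.frame with \code{sample_id}, \code{subtype} and, when
#'   present, \code{cohort}.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subtype") %in% names(df)))
    stop("labels CSV needs columns sample_id, subtype")
  df$subtype <- as.character(normalize_subtype_labels(df$subtype))
  df
}
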