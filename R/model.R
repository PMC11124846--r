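# Stratified splitting, ensemble-tree classification, and confusion-matrix
# performance metrics.

#' Stratified train/test split
#'
#' Splits a feature table into disjoint, exhaustive train and test sets.
#' Within each stratum (default: animal x behavior) the train share is within
#' one row of `train_fraction`. Strata with fewer than 2 rows are pooled and
#' split globally, with a warning.
#'
#' @param table Feature tibble with the stratification columns.
#' @param train_fraction Fraction of rows assigned to training (default 0.7).
#' @param stratify_by Character vector of stratification columns; use
#'   `NULL` for a plain random split.
#' @param seed Integer seed; the partition is a pure function of it.
#' @return A list with `train` and `test` tibbles.
#' @export
split_train_test <- function(table, train_fraction = 0.7,
                             stratify_by = c("animal_id", "behavior"),
                             seed = 1L) {
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  withr::with_seed(seed, {
    if (is.null(stratify_by)) {
      idx <- seq_len(nrow(table))
      n_tr <- round_half_up(train_fraction * length(idx))
      tr <- sample(idx, n_tr)
      return(list(train = table[sort(tr), , drop = FALSE],
                  test = table[sort(setdiff(idx, tr)), , drop = FALSE]))
    }
    strata <- interaction(table[stratify_by], drop = TRUE)
    small <- names(which(table(strata) < 2L))
    train_rows <- logical(nrow(table))
    for (s in setdiff(levels(strata), small)) {
      idx <- which(strata == s)
      n_tr <- round_half_up(train_fraction * length(idx))
      train_rows[sample(idx, n_tr)] <- TRUE
    }
    if (length(small) > 0) {
      warning("stratum(s) with < 2 rows pooled into a global split: ",
              paste(small, collapse = ", "))
      idx <- which(strata %in% small)
      n_tr <- round_half_up(train_fraction * length(idx))
      if (n_tr > 0) train_rows[sample(idx, n_tr)] <- TRUE
    }
    list(train = table[train_rows, , drop = FALSE],
         test = table[!train_rows, , drop = FALSE])
  })
}

#' Train an ensemble-of-trees behavior classifier
#'
#' Fits a random forest (via `ranger`) on the feature columns of a labeled
#' feature table. Defaults follow random-forest convention: 500 trees,
#' `floor(sqrt(p))` candidate features per split, unlimited depth. Key and
#' label columns are excluded from the predictors automatically; the ordered
#' feature schema is stored with the model and enforced at prediction time.
#'
#' @param train Labeled feature tibble.
#' @param label_col Name of the label column (default `"behavior"`).
#' @param num_trees Number of trees (default 500).
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @param seed Integer seed; training is deterministic given it.
#' @param exclude_cols Extra non-feature columns to drop.
#' @return A `behavior_classifier` object.
#' @export
train_classifier <- function(train, label_col = "behavior", num_trees = 500,
                             mtry = NULL, seed = 1L, exclude_cols = NULL) {
  stopifnot(label_col %in% names(train))
  drop <- unique(c(feature_key_cols(), label_col, exclude_cols))
  feat_cols <- setdiff(names(train), drop)
  feat_cols <- feat_cols[vapply(train[feat_cols], is.numeric, TRUE)]
  if (length(feat_cols) == 0) stop("no feature columns found", call. = FALSE)
  X <- as.data.frame(train[feat_cols])
  bad <- feat_cols[vapply(X, function(v) any(!is.finite(v)), TRUE)]
  if (length(bad) > 0) {
    stop("Non-finite feature values in column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- factor(train[[label_col]])
  if (nlevels(y) < 2) stop("training labels contain a single class", call. = FALSE)
  fit <- ranger::ranger(x = X, y = y,
                        num.trees = num_trees,
                        mtry = mtry %||% max(1L, floor(sqrt(length(feat_cols)))),
                        seed = seed, num.threads = 1L)
  structure(list(fit = fit, schema = feat_cols, classes = levels(y),
                 label_col = label_col, num_trees = num_trees, seed = seed),
            class = "behavior_classifier")
}

#' Predict behaviors from a trained classifier
#'
#' The feature columns of `newdata` must match the training schema exactly,
#' in name and order; any discrepancy is an error listing the differing
#' columns.
#'
#' @param object A `behavior_classifier`.
#' @param newdata Feature tibble.
#' @param ... Unused.
#' @return Factor of predicted labels (training vocabulary).
#' @export
predict.behavior_classifier <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(factor(character(), levels = object$classes))
  got <- names(newdata)[names(newdata) %in% object$schema]
  if (!identical(got, object$schema)) {
    missing <- setdiff(object$schema, names(newdata))
    msg <- if (length(missing) > 0) {
      paste0("missing feature column(s): ", paste(missing, collapse = ", "))
    } else {
      "feature columns out of training order"
    }
    stop("Feature schema mismatch: ", msg, call. = FALSE)
  }
  pr <- stats::predict(object$fit, data = as.data.frame(newdata[object$schema]),
                       num.threads = 1L)
  factor(as.character(pr$predictions), levels = object$classes)
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat("<behavior_classifier> ", x$num_trees, " trees, ",
      length(x$schema), " features, classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Confusion matrix and classification performance metrics
#'
#' Builds the K x K confusion matrix (rows = observed, columns = predicted)
#' and computes overall accuracy plus per-class sensitivity (`TP/(TP+FN)`),
#' specificity (`TN/(TN+FP)`) and precision (`TP/(TP+FP)`). A metric whose
#' denominator is zero (class absent from the data or never predicted) is
#' `NA`, never coerced to 0.
#'
#' @param truth Observed labels.
#' @param predicted Predicted labels; same length as `truth`.
#' @param levels Class levels; defaults to the union of both vectors.
#' @return A `metrics_report`: list with `confusion`, `accuracy`, `n`, and a
#'   `per_class` tibble.
#' @export
confusion_and_metrics <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(truth) == 0) stop("empty inputs", call. = FALSE)
  lv <- levels %||% sort(union(as.character(truth), as.character(predicted)))
  tr <- factor(as.character(truth), levels = lv)
  pr <- factor(as.character(predicted), levels = lv)
  cm <- table(truth = tr, predicted = pr)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  per <- purrr::map_dfr(seq_along(lv), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
    tibble::tibble(class = lv[i], support = sum(cm[i, ]),
                   sensitivity = safe_div(tp, tp + fn),
                   specificity = safe_div(tn, tn + fp),
                   precision = safe_div(tp, tp + fp))
  })
  if (anyNA(per[c("sensitivity", "specificity", "precision")])) {
    warning("some per-class metrics are undefined (zero denominator); reported as NA")
  }
  structure(list(confusion = unclass(cm), accuracy = acc, n = n, per_class = per),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, " accuracy =", format(round(x$accuracy, 4)), "\n")
  print(x$confusion)
  print(as.data.frame(x$per_class), digits = 4)
  invisible(x)
}

#' Evaluate a classifier on a labeled table
#'
#' @param model A `behavior_classifier`.
#' @param table Labeled feature tibble.
#' @return A `metrics_report`.
#' @export
evaluate_classifier <- function(model, table) {
  pred <- predict(model, table)
  confusion_and_metrics(table[[model$label_col]], pred, levels = model$classes)
}

#' Serialize a metrics report to JSON
#'
#' Confusion matrix keyed by class names; metrics at four decimals.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write metrics JSON", call. = FALSE)
  }
  cm <- report$confusion
  conf <- stats::setNames(
    lapply(seq_len(nrow(cm)), function(i) as.list(stats::setNames(cm[i, ], colnames(cm)))),
    rownames(cm))
  out <- list(n = report$n, accuracy = round(report$accuracy, 4), confusion = conf,
              per_class = lapply(seq_len(nrow(report$per_class)), function(i) {
                r <- report$per_class[i, ]
                list(class = r$class, support = r$support,
                     sensitivity = round(r$sensitivity, 4),
                     specificity = round(r$specificity, 4),
                     precision = round(r$precision, 4))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Save / load a behavior classifier
#'
#' Persists the fitted model, including its ordered feature schema, to a
#' single artifact via R serialization.
#'
#' @param model A `behavior_classifier`.
#' @param path File path.
#' @return `path` (save) or the restored `behavior_classifier` (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "behavior_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "behavior_classifier")) stop("not a behavior_classifier artifact", call. = FALSE)
  model
}
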