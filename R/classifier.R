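# Random-forest neutral/high-impact classifier, cross-validation and metrics.
#
# Positive class = high_impact throughout. Hyperparameter defaults: 1000
# trees, minimum node size 42 (minimum samples at a leaf), maximum depth 60,
# mtry = sqrt(number of features), bootstrap sampling.

#' Random-forest configuration
#'
#' @param n_trees number of trees (default 1000)
#' @param min_samples_leaf minimum samples at a leaf node (default 42)
#' @param max_depth maximum tree depth (default 60)
#' @param max_features mtry; default `sqrt` = floor(sqrt(p))
#' @param bootstrap sample with replacement (default TRUE)
#' @param seed integer seed
#' @return list of class `vs_rf_config`
#' @export
rf_config <- function(n_trees = 1000, min_samples_leaf = 42, max_depth = 60,
                      max_features = "sqrt", bootstrap = TRUE, seed = 1) {
  structure(list(n_trees = n_trees, min_samples_leaf = min_samples_leaf,
                 max_depth = max_depth, max_features = max_features,
                 bootstrap = bootstrap, seed = seed),
            class = "vs_rf_config")
}

#' Remove outlier records on computed ddG and ddSvib
#'
#' Drops records whose robust z-score — (x - median) / (1.4826 * MAD) —
#' exceeds `z_cutoff` in absolute value on either the `ddg` or the `ddsvib`
#' feature. With fewer than 10 records filtering is skipped with a warning.
#'
#' @param records data.frame with `ddg` and `ddsvib` columns
#' @param z_cutoff robust z threshold (default 3)
#' @return filtered data.frame with attribute `n_dropped`
#' @export
filter_outliers <- function(records, z_cutoff = 3) {
  if (nrow(records) < 10) {
    warning("fewer than 10 records; outlier filtering skipped")
    attr(records, "n_dropped") <- 0L
    return(records)
  }
  rz <- function(x) {
    s <- stats::mad(x)
    if (s == 0) return(rep(0, length(x)))
    abs(x - stats::median(x)) / s
  }
  keep <- rz(records$ddg) <= z_cutoff & rz(records$ddsvib) <= z_cutoff
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Stratified train/test split
#'
#' @param records data.frame with a `label` column
#' @param train_fraction fraction assigned to training (default 0.75)
#' @param seed integer seed (same seed reproduces the partition)
#' @return list with `train` and `test` data.frames (disjoint, stratified by
#'   label)
#' @export
split_train_test <- function(records, train_fraction = 0.75, seed = 1) {
  if (nrow(records) < 4) stop("at least 4 records required")
  if (length(unique(records$label)) < 2)
    stop("stratification error: both classes must be present")
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_len(nrow(records)), records$label), function(ix) {
    sample(ix, round(train_fraction * length(ix)))
  }))
  list(train = records[sort(train_idx), , drop = FALSE],
       test = records[setdiff(seq_len(nrow(records)), train_idx), , drop = FALSE])
}

#' Train the random-forest classifier
#'
#' @param records data.frame with a `label` column and the feature columns of
#'   `features`
#' @param config a [rf_config()]
#' @param features feature columns to use (default [feature_names()])
#' @return object of class `vs_rf_model` with the fitted forest, config,
#'   feature schema and its checksum
#' @export
vs_train <- function(records, config = rf_config(), features = feature_names()) {
  if (length(unique(records$label)) < 2)
    stop("at least 2 classes required to train")
  miss <- setdiff(features, names(records))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ","))
  df <- records[, features, drop = FALSE]
  df$.label <- factor(records$label, levels = c("neutral", "high_impact"))
  mtry <- if (identical(config$max_features, "sqrt"))
    max(1, floor(sqrt(length(features)))) else as.integer(config$max_features)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = config$n_trees, mtry = mtry,
    min.node.size = config$min_samples_leaf, max.depth = config$max_depth,
    replace = config$bootstrap, probability = TRUE,
    seed = config$seed, num.threads = 1)
  structure(list(fit = fit, config = config, features = features,
                 checksum = feature_schema_checksum(features),
                 classes = c("neutral", "high_impact")),
            class = "vs_rf_model")
}

#' @export
print.vs_rf_model <- function(x, ...) {
  cat(sprintf("<vs_rf_model> %d trees, %d features (schema %s), OOB error %.3f\n",
              x$config$n_trees, length(x$features), x$checksum,
              x$fit$prediction.error))
  invisible(x)
}

#' Predict class and class probability for new variants
#'
#' @param object a `vs_rf_model`
#' @param newdata data.frame carrying the model's feature columns
#' @param ... unused
#' @return data.frame with `class` ("neutral"/"high_impact"), `p_high_impact`
#'   and `p_neutral` (summing to 1 per row)
#' @export
predict.vs_rf_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("feature schema mismatch: newdata lacks ", paste(miss, collapse = ","))
  if (!identical(feature_schema_checksum(object$features), object$checksum))
    stop("feature schema checksum mismatch; model artifact is corrupt")
  pr <- stats::predict(object$fit,
                       data = newdata[, object$features, drop = FALSE],
                       num.threads = 1)$predictions
  p_high <- pr[, "high_impact"]
  data.frame(class = ifelse(p_high >= 0.5, "high_impact", "neutral"),
             p_high_impact = p_high, p_neutral = pr[, "neutral"],
             stringsAsFactors = FALSE)
}

#' Confusion-count performance metrics
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN), TPR = TP/(TP+FN), TNR = TN/(TN+FP),
#' precision = TP/(TP+FP); undefined ratios (zero denominator) are returned
#' as NA with a warning. Positive class is high_impact.
#'
#' @param tp,tn,fp,fn nonnegative integer counts, sum > 0
#' @return list of class `vs_metrics`: counts plus `accuracy`, `tpr`, `tnr`,
#'   `precision`, `sensitivity_high_impact` (= tpr), `sensitivity_neutral`
#'   (= tnr)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("at least one count must be positive")
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else num / den
  }
  tpr <- ratio(tp, tp + fn, "TPR")
  tnr <- ratio(tn, tn + fp, "TNR")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / sum(counts),
                 tpr = tpr, tnr = tnr,
                 precision = ratio(tp, tp + fp, "precision"),
                 sensitivity_high_impact = tpr,
                 sensitivity_neutral = tnr),
            class = "vs_metrics")
}

#' @export
print.vs_metrics <- function(x, ...) {
  cat(sprintf("<vs_metrics> acc %.3f, TPR %.3f, TNR %.3f, precision %.3f (tp %d tn %d fp %d fn %d)\n",
              x$accuracy, x$tpr, x$tnr, x$precision, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

# Confusion counts of predicted vs true labels (positive = high_impact).
.confusion <- function(truth, predicted) {
  compute_metrics(tp = sum(truth == "high_impact" & predicted == "high_impact"),
                  tn = sum(truth == "neutral" & predicted == "neutral"),
                  fp = sum(truth == "neutral" & predicted == "high_impact"),
                  fn = sum(truth == "high_impact" & predicted == "neutral"))
}

#' ROC curve and AUC from class-probability scores
#'
#' Threshold sweep over the unique scores (equal scores grouped), positive
#' class high_impact, AUC by the trapezoid rule — equal to the Mann-Whitney
#' U statistic divided by (n+ * n-).
#'
#' @param scores numeric scores (higher = more likely high_impact)
#' @param labels "neutral"/"high_impact" per score
#' @return list of class `vs_roc`: `fpr`, `tpr` (curve points from (0,0) to
#'   (1,1)), `auc`
#' @export
roc_curve <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == "high_impact"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group ties: cumulative counts at each distinct descending threshold
  last_of_group <- c(diff(s) != 0, TRUE)
  ctp <- cumsum(p)[last_of_group]
  cfp <- cumsum(!p)[last_of_group]
  tpr <- c(0, ctp / sum(pos))
  fpr <- c(0, cfp / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "vs_roc")
}

#' @export
print.vs_roc <- function(x, ...) {
  cat(sprintf("<vs_roc> %d points, AUC %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' @param records data.frame with `label` and feature columns
#' @param k number of folds (default 10); every class must have >= k members
#' @param config a [rf_config()] (its seed also fixes fold assignment)
#' @param features feature columns (default [feature_names()])
#' @return list of class `vs_cv`: `folds` (list of `vs_metrics`), `aggregate`
#'   (mean accuracy/tpr/tnr/precision over folds), `assignments` (fold id per
#'   record)
#' @export
cross_validate <- function(records, k = 10, config = rf_config(),
                           features = feature_names()) {
  tab <- table(records$label)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
         " members, fewer than k = ", k, "; use a smaller k")
  set.seed(config$seed)
  fold <- integer(nrow(records))
  for (ix in split(seq_len(nrow(records)), records$label)) {
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  folds <- lapply(seq_len(k), function(f) {
    tr <- records[fold != f, , drop = FALSE]
    te <- records[fold == f, , drop = FALSE]
    model <- vs_train(tr, config, features)
    pred <- predict(model, te)
    suppressWarnings(.confusion(te$label, pred$class))
  })
  agg <- sapply(c("accuracy", "tpr", "tnr", "precision"), function(m) {
    mean(vapply(folds, function(f) f[[m]], numeric(1)), na.rm = TRUE)
  })
  structure(list(folds = folds, aggregate = agg, assignments = fold),
            class = "vs_cv")
}

#' @export
print.vs_cv <- function(x, ...) {
  cat(sprintf("<vs_cv> %d folds: mean accuracy %.3f, TPR %.3f, TNR %.3f\n",
              length(x$folds), x$aggregate["accuracy"], x$aggregate["tpr"],
              x$aggregate["tnr"]))
  invisible(x)
}
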