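# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

roc_points <- function(scores, labels, positive) {
  # standard ROC construction: sweep the score threshold over unique values
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord] == positive
  tp <- cumsum(y)
  fp <- cumsum(!y)
  np <- sum(y); nn <- sum(!y)
  keep <- c(diff(scores[ord]) != 0, TRUE)  # last point per distinct score
  data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Random-forest diagnostic classification with repeated stratified CV
#'
#' Trains a 500-tree random forest on subject-level network features under
#' repeated stratified k-fold cross-validation. Class imbalance is handled
#' by random undersampling of the majority class within each training fold.
#' Out-of-fold class probabilities are pooled into one ROC curve; accuracy,
#' F1, PPV and NPV are computed per fold at the 0.5 probability cut and
#' summarized as mean and sd, as is the per-fold AUROC. Feature importance
#' (mean decrease in Gini impurity) is averaged over all forests and
#' ranked.
#'
#' @param features Numeric matrix or data frame, subjects x features.
#' @param labels Two-level class label per subject.
#' @param folds Number of CV folds (default 6).
#' @param repeats Number of CV repetitions (default 10).
#' @param seed Integer seed (fixes folds, undersampling and forests).
#' @param positive Positive-class label (default: first factor level).
#' @param ntree Trees per forest (default 500).
#' @param undersample Balance training folds by undersampling (default TRUE).
#' @return A `wnet_classif`: list with `metrics` (mean/sd of accuracy, f1,
#'   ppv, npv, auroc), `roc` (pooled points), `auroc_pooled`,
#'   `optimal_point`, `importance` (ranked), `folds`, `repeats`.
#' @export
rf_crossval <- function(features, labels, folds = 6, repeats = 10, seed = 1,
                        positive = NULL, ntree = 500, undersample = TRUE) {
  x <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop_invalid("need exactly 2 classes")
  if (min(table(labels)) < folds) {
    stop_invalid("need at least `folds` subjects per class")
  }
  if (is.null(positive)) positive <- levels(labels)[1]

  per_fold <- list()
  pooled_scores <- numeric(0)
  pooled_labels <- character(0)
  imp_acc <- NULL
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      fold_id <- stratified_folds(labels, folds)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        xtr <- x[tr, , drop = FALSE]; ytr <- labels[tr]
        if (undersample) {
          tab <- table(ytr)
          n_min <- min(tab)
          keep <- unlist(lapply(levels(ytr), function(cl) {
            sample(which(ytr == cl), n_min)
          }))
          xtr <- xtr[keep, , drop = FALSE]; ytr <- ytr[keep]
        }
        fit <- randomForest::randomForest(xtr, ytr, ntree = ntree)
        imp <- randomForest::importance(fit)[, 1]
        imp_acc <- if (is.null(imp_acc)) imp else imp_acc + imp
        pr <- predict(fit, x[!tr, , drop = FALSE], type = "prob")[, positive]
        yte <- labels[!tr]
        pooled_scores <- c(pooled_scores, pr)
        pooled_labels <- c(pooled_labels, as.character(yte))
        pred_pos <- pr >= 0.5
        is_pos <- yte == positive
        tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
        tn <- sum(!pred_pos & !is_pos); fn <- sum(!pred_pos & is_pos)
        fold_roc <- roc_points(pr, yte, positive)
        per_fold[[length(per_fold) + 1]] <- c(
          accuracy = (tp + tn) / length(yte),
          f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA,
          ppv = if (tp + fp > 0) tp / (tp + fp) else NA,
          npv = if (tn + fn > 0) tn / (tn + fn) else NA,
          auroc = auc_trapezoid(fold_roc))
      }
    }
  })

  fold_mat <- do.call(rbind, per_fold)
  metrics <- data.frame(
    metric = colnames(fold_mat),
    mean = colMeans(fold_mat, na.rm = TRUE),
    sd = apply(fold_mat, 2, sd, na.rm = TRUE),
    row.names = NULL)
  roc <- roc_points(pooled_scores, factor(pooled_labels, levels(labels)), positive)
  imp <- sort(imp_acc / (folds * repeats), decreasing = TRUE)
  structure(list(
    metrics = metrics, roc = roc, auroc_pooled = auc_trapezoid(roc),
    optimal_point = optimal_roc_point(roc),
    importance = data.frame(feature = names(imp), importance = unname(imp)),
    folds = folds, repeats = repeats, positive = positive
  ), class = "wnet_classif")
}

#' @export
print.wnet_classif <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<wnet_classif> %d-fold x %d: acc %.2f±%.2f, AUROC %.2f±%.2f (pooled %.2f)\n",
              x$folds, x$repeats,
              m$mean[m$metric == "accuracy"], m$sd[m$metric == "accuracy"],
              m$mean[m$metric == "auroc"], m$sd[m$metric == "auroc"],
              x$auroc_pooled))
  cat(sprintf("  optimal point: sensitivity %.2f, specificity %.2f\n",
              x$optimal_point["sensitivity"], x$optimal_point["specificity"]))
  cat("  top features:", paste(head(x$importance$feature, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Youden-optimal point of an ROC curve
#'
#' Returns the ROC point maximizing `TPR - FPR` (Youden's J); ties are
#' broken toward higher specificity (lower false-positive rate).
#'
#' @param roc Data frame with columns `fpr` and `tpr`.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
optimal_roc_point <- function(roc) {
  if (nrow(roc) < 2) stop_invalid("need at least 2 ROC points")
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  best <- best[which.min(roc$fpr[best])]
  c(sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best])
}
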