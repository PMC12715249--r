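# Multi-metric evaluation framework for imbalanced three-class problems.
# Percentages are reported as integers rounded half away from zero; the
# ordinal label coding is CN = 0, MCI = 1, AD = 2.

#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted, both in (CN, MCI, AD) order.
#'
#' @param truth,predicted Equal-length label vectors over the three classes.
#' @return 3 x 3 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted)) stop("length mismatch", call. = FALSE)
  truth <- as_diagnosis(truth, "truth")
  predicted <- as_diagnosis(predicted, "predicted")
  cm <- table(truth, predicted)
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(true = diagnosis_levels(),
                              predicted = diagnosis_levels()))
  structure(m, class = c("confusion_matrix", "matrix"))
}

# One-vs-rest tallies for class k.
ovr_counts <- function(cm, k) {
  tp <- cm[k, k]
  fp <- sum(cm[-k, k])
  fn <- sum(cm[k, -k])
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Per-class classification metrics
#'
#' One-vs-rest precision, sensitivity (recall), specificity, F1 and support
#' for each class; 0/0 ratios are reported as 0 (the convention that matches
#' never-predicted classes).
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame with one row per class.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rows <- lapply(1:3, function(k) {
    n <- ovr_counts(cm, k)
    prec <- safe_div(n["tp"], n["tp"] + n["fp"])
    sens <- safe_div(n["tp"], n["tp"] + n["fn"])
    spec <- safe_div(n["tn"], n["tn"] + n["fp"])
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    data.frame(class = diagnosis_levels()[k], precision = unname(prec),
               sensitivity = unname(sens), specificity = unname(spec),
               f1 = unname(f1), support = unname(sum(cm[k, ])))
  })
  do.call(rbind, rows)
}

#' Accuracy and macro / weighted averages
#'
#' Accuracy is the trace over the total; macro averages are unweighted class
#' means; weighted averages weight each class by its support. Weighted recall
#' is identically the accuracy.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `accuracy`, `macro` and `weighted` (each with precision,
#'   sensitivity, specificity, f1), and `n`.
#' @export
aggregate_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pc <- per_class_metrics(cm)
  n <- sum(cm)
  w <- pc$support / n
  list(accuracy = sum(diag(cm)) / n,
       macro = list(precision = mean(pc$precision),
                    sensitivity = mean(pc$sensitivity),
                    specificity = mean(pc$specificity),
                    f1 = mean(pc$f1)),
       weighted = list(precision = sum(w * pc$precision),
                       sensitivity = sum(w * pc$sensitivity),
                       specificity = sum(w * pc$specificity),
                       f1 = sum(w * pc$f1)),
       n = n)
}

#' Balanced accuracy
#'
#' The mean of the macro-averaged sensitivity and the macro-averaged
#' specificity — the convention under which a single-class predictor on any
#' three-class problem scores exactly 50\%.
#'
#' @param cm A [confusion_matrix()].
#' @return Value in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  ag <- aggregate_metrics(cm)
  (ag$macro$sensitivity + ag$macro$specificity) / 2
}

#' Ordinal mean squared error
#'
#' Mean squared difference of ordinally coded labels (CN = 0, MCI = 1,
#' AD = 2), reported x100 as a percent-scaled value. Penalises CN/AD
#' confusions four times as heavily as adjacent-stage confusions.
#'
#' @param truth,predicted Label vectors.
#' @param coding Named coding map; default the canonical ordinal coding.
#' @return Nonnegative value (percent scale).
#' @export
ordinal_mse <- function(truth, predicted,
                        coding = c(CN = 0, MCI = 1, AD = 2)) {
  truth <- as_diagnosis(truth, "truth")
  predicted <- as_diagnosis(predicted, "predicted")
  stopifnot(length(coding) == 3, !is.null(names(coding)))
  ct <- coding[as.character(truth)]
  cp <- coding[as.character(predicted)]
  mean((ct - cp)^2) * 100
}

# AUC of a binary response/score pair with ties counted 1/2; degenerate
# single-class responses return 0.5 with a warning.
binary_auc <- function(response, score) {
  if (length(unique(response)) < 2) {
    warning("single-class truth: AUC undefined, reporting 0.5")
    return(0.5)
  }
  if (length(unique(score)) < 2) return(0.5)   # constant scores: all ties
  as.numeric(pROC::auc(pROC::roc(response, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

# Trapezoidal area under the precision-recall curve for a binary problem.
binary_auc_pr <- function(response, score) {
  if (sum(response) == 0) return(0)
  o <- order(score, decreasing = TRUE)
  y <- response[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # merge tied score groups so ties are handled as a block
  s <- score[o]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  prec <- c(1, prec)
  rec <- c(0, rec)
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

# Generalised (multiclass) Matthews correlation coefficient from a confusion
# matrix.
mcc_from_cm <- function(cm) {
  cm <- matrix(as.numeric(cm), nrow(cm))
  n <- sum(cm)
  t_k <- rowSums(cm)   # truth totals
  p_k <- colSums(cm)   # prediction totals
  num <- sum(diag(cm)) * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' Score-based and correlation metrics
#'
#' Macro ROC AUC (mean of one-vs-rest AUCs, ties counted 1/2), micro ROC AUC
#' (on the flattened one-vs-rest label/score pairs), macro AUC-PR (trapezoidal
#' precision-recall integration) and the generalised multiclass Matthews
#' correlation coefficient of the argmax predictions.
#'
#' @param scores n x 3 matrix of class scores (probabilities or capsule
#'   lengths), columns in (CN, MCI, AD) order.
#' @param truth True labels.
#' @return List with `roc_auc_micro`, `roc_auc_macro`, `auc_pr_macro`, `mcc`.
#' @export
auc_metrics <- function(scores, truth) {
  stopifnot(is.matrix(scores), ncol(scores) == 3, all(is.finite(scores)))
  truth <- as_diagnosis(truth, "truth")
  stopifnot(length(truth) == nrow(scores))
  onehot <- matrix(0, nrow(scores), 3)
  onehot[cbind(seq_len(nrow(scores)), as.integer(truth))] <- 1
  per_class_roc <- vapply(1:3, function(k) binary_auc(onehot[, k], scores[, k]),
                          numeric(1))
  per_class_pr <- vapply(1:3, function(k) binary_auc_pr(onehot[, k], scores[, k]),
                         numeric(1))
  pred <- diagnosis_levels()[max.col(scores, ties.method = "first")]
  cm <- confusion_matrix(truth, pred)
  list(roc_auc_micro = binary_auc(as.vector(onehot), as.vector(scores)),
       roc_auc_macro = mean(per_class_roc),
       auc_pr_macro = mean(per_class_pr),
       mcc = mcc_from_cm(cm))
}

#' Prediction-bias index
#'
#' Measures how far the predicted class distribution departs from the true
#' one, normalised so that every single-class (collapsed) predictor scores
#' exactly 1 and a distribution-matched predictor scores 0:
#' \deqn{B = \frac{\sum_c \max(0, \hat p_c - p_c)}{\sum_c \hat p_c (1 - p_c)}}
#' The numerator is the total-variation distance; the denominator is its
#' attainable ceiling under the predicted class mix (pointwise
#' `max(0, phat - p) <= phat (1 - p)` guarantees `B` in \[0, 1\]).
#'
#' @param predicted_dist,true_dist Distributions over the three classes
#'   (counts or proportions; normalised internally).
#' @param normalize If `FALSE`, return the raw total-variation distance
#'   instead.
#' @return Value in \[0, 1\].
#' @export
bias_index <- function(predicted_dist, true_dist, normalize = TRUE) {
  stopifnot(length(predicted_dist) == 3, length(true_dist) == 3,
            all(predicted_dist >= 0), all(true_dist >= 0))
  phat <- predicted_dist / sum(predicted_dist)
  p <- true_dist / sum(true_dist)
  tv <- sum(pmax(0, phat - p))
  if (!normalize) return(tv)
  den <- sum(phat * (1 - p))
  if (den == 0) 0 else tv / den
}

#' Degenerate single-class predictor fixture
#'
#' Builds the truth/prediction/score vectors of a classifier that outputs one
#' fixed class for every sample of a given test distribution — the exactly
#' reproducible fixture used to pin down the metric suite.
#'
#' @param counts Named true class counts, e.g.
#'   `c(CN = 447, MCI = 677, AD = 859)`.
#' @param target The class every sample is predicted as.
#' @return List with `truth`, `predicted` (factors) and `scores` (one-hot
#'   matrix).
#' @export
degenerate_predictions <- function(counts, target) {
  counts <- as_class_counts(counts)
  target <- match.arg(target, diagnosis_levels())
  truth <- factor(rep(diagnosis_levels(), counts), levels = diagnosis_levels())
  predicted <- factor(rep(target, sum(counts)), levels = diagnosis_levels())
  scores <- matrix(0, sum(counts), 3,
                   dimnames = list(NULL, diagnosis_levels()))
  scores[, target] <- 1
  list(truth = truth, predicted = predicted, scores = scores)
}

#' Full metric report
#'
#' Computes the complete evaluation state for a set of predictions: per-class
#' precision/sensitivity/specificity/F1/support, accuracy, macro and weighted
#' averages, balanced accuracy, ordinal MSE, bias index and (when scores are
#' supplied) ROC/PR AUCs and MCC.
#'
#' @param truth,predicted Label vectors.
#' @param scores Optional n x 3 score matrix.
#' @return Object of class `metric_report`.
#' @export
metric_report <- function(truth, predicted, scores = NULL) {
  cm <- confusion_matrix(truth, predicted)
  pc <- per_class_metrics(cm)
  ag <- aggregate_metrics(cm)
  rep <- list(confusion = cm, per_class = pc, accuracy = ag$accuracy,
              macro = ag$macro, weighted = ag$weighted,
              balanced_accuracy = balanced_accuracy(cm),
              ordinal_mse_percent = ordinal_mse(truth, predicted),
              bias_index = bias_index(table(as_diagnosis(predicted, "predicted")),
                                      table(as_diagnosis(truth, "truth"))),
              n = ag$n)
  if (!is.null(scores)) rep <- c(rep, auc_metrics(scores, truth))
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n = %d\n", x$n))
  df <- x$per_class
  for (col in c("precision", "sensitivity", "specificity", "f1")) {
    df[[col]] <- sprintf("%d%%", as_percent(df[[col]]))
  }
  print(df, row.names = FALSE)
  cat(sprintf("accuracy %d%% | balanced accuracy %d%% | macro F1 %d%% | MSE %d%% | bias %.2f\n",
              as_percent(x$accuracy), as_percent(x$balanced_accuracy),
              as_percent(x$macro$f1), round_half_up(x$ordinal_mse_percent),
              x$bias_index))
  if (!is.null(x$roc_auc_macro)) {
    cat(sprintf("ROC AUC micro %d%% / macro %d%% | AUC-PR macro %.2f | MCC %.2f\n",
                as_percent(x$roc_auc_micro), as_percent(x$roc_auc_macro),
                x$auc_pr_macro, x$mcc))
  }
  invisible(x)
}

#' Table-style summary of a metric report
#'
#' One-row data frame with the integer-percent columns in the conventional
#' order (accuracy, precision, sensitivity, specificity, F1, balanced
#' accuracy, MSE, ROC AUCs), matching the reporting style used for model
#' comparison tables.
#'
#' @param report A [metric_report()].
#' @return One-row data frame.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "metric_report"))
  out <- data.frame(
    accuracy = as_percent(report$accuracy),
    precision = as_percent(report$macro$precision),
    sensitivity = as_percent(report$macro$sensitivity),
    specificity = as_percent(report$macro$specificity),
    f1 = as_percent(report$macro$f1),
    balanced_accuracy = as_percent(report$balanced_accuracy),
    mse = round_half_up(report$ordinal_mse_percent))
  if (!is.null(report$roc_auc_micro)) {
    out$roc_auc_micro <- as_percent(report$roc_auc_micro)
    out$roc_auc_macro <- as_percent(report$roc_auc_macro)
  }
  out
}

#' Rank candidate models on a metadata table
#'
#' Min-max normalises every numeric criterion to \[0, 1\] (constant columns
#' map to 0 by convention), then sorts by performance score descending with
#' ties broken by top-5 accuracy descending and then parameter count
#' ascending.
#'
#' @param metadata Data frame with numeric columns `top1`, `top5`,
#'   `param_count`, `performance_score`.
#' @return The input with normalised columns (`norm_*`) and a `rank` column,
#'   sorted by rank.
#' @export
rank_models <- function(metadata) {
  if (!is.data.frame(metadata) || nrow(metadata) == 0) {
    stop("metadata table must be a nonempty data frame", call. = FALSE)
  }
  need <- c("top1", "top5", "param_count", "performance_score")
  stopifnot(all(need %in% names(metadata)))
  norm <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }
  for (col in need) metadata[[paste0("norm_", col)]] <- norm(metadata[[col]])
  o <- order(-metadata$performance_score, -metadata$top5, metadata$param_count)
  out <- metadata[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
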