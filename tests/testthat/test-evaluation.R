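# Multi-metric evaluation framework: exact degenerate-predictor rows,
# brute-force oracle equivalence, AUC behaviour, bias index, model ranking.

test_dist <- c(CN = 447, MCI = 677, AD = 859)

test_that("confusion matrices count by (true, predicted) pair", {
  truth <- c("CN", "CN", "MCI", "AD")
  expect_identical(unclass(confusion_matrix(truth, truth)),
                   matrix(c(2L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3,
                          dimnames = list(true = diagnosis_levels(),
                                          predicted = diagnosis_levels())))
  d <- degenerate_predictions(test_dist, "AD")
  cm <- confusion_matrix(d$truth, d$predicted)
  expect_identical(unname(cm[, 3]), c(447L, 677L, 859L))
  expect_identical(sum(cm[, 1:2]), 0L)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix(c("CN", "XX"), c("CN", "CN")), "unknown label")
})

test_that("the all-AD predictor reproduces the printed per-class row", {
  d <- degenerate_predictions(test_dist, "AD")
  pc <- per_class_metrics(confusion_matrix(d$truth, d$predicted))
  # CN and MCI rows are all zero under the 0/0 -> 0 convention
  expect_identical(demgrid:::as_percent(pc$precision), c(0, 0, 43))
  expect_identical(demgrid:::as_percent(pc$sensitivity), c(0, 0, 100))
  expect_identical(demgrid:::as_percent(pc$f1), c(0, 0, 60))
  expect_identical(pc$support, c(447L, 677L, 859L))
  # diagonal confusion matrix scores 100% everywhere
  perfect <- per_class_metrics(confusion_matrix(d$truth, d$truth))
  expect_true(all(perfect$precision == 1 & perfect$sensitivity == 1 &
                    perfect$specificity == 1 & perfect$f1 == 1))
})

test_that("aggregates reproduce the printed capsule-network table entries", {
  d <- degenerate_predictions(test_dist, "AD")
  cm <- confusion_matrix(d$truth, d$predicted)
  ag <- aggregate_metrics(cm)
  expect_identical(demgrid:::as_percent(ag$accuracy), 43)
  expect_identical(demgrid:::as_percent(ag$macro$precision), 14)
  # macro recall of the all-AD row is arithmetically 33% (mean of 0, 0, 100)
  expect_identical(demgrid:::as_percent(ag$macro$sensitivity), 33)
  expect_identical(demgrid:::as_percent(ag$macro$specificity), 67)
  expect_identical(demgrid:::as_percent(ag$macro$f1), 20)
  expect_identical(demgrid:::as_percent(balanced_accuracy(cm)), 50)
  bal <- confusion_matrix(rep(diagnosis_levels(), 5), rep(diagnosis_levels(), 5))
  expect_equal(balanced_accuracy(bal), 1)
  expect_equal(aggregate_metrics(bal)$weighted$f1, 1)
})

test_that("ordinal MSE uses the CN=0/MCI=1/AD=2 coding", {
  d <- degenerate_predictions(test_dist, "AD")
  expect_equal(ordinal_mse(d$truth, d$predicted),
               (447 * 4 + 677 * 1) / 1983 * 100, tolerance = 1e-12)
  expect_identical(demgrid:::round_half_up(ordinal_mse(d$truth, d$predicted)), 124)
  m <- degenerate_predictions(test_dist, "MCI")
  expect_identical(demgrid:::round_half_up(ordinal_mse(m$truth, m$predicted)), 66)
  expect_identical(ordinal_mse(d$truth, d$truth), 0)
})

test_that("every tabulated metric agrees with a brute-force oracle on 1000 random matrices", {
  # independent oracle: explicit per-class TP/FP/FN/TN loops
  oracle <- function(cm) {
    lev <- diagnosis_levels()
    out <- list()
    n <- sum(cm)
    for (k in 1:3) {
      tp <- fp <- fn <- tn <- 0
      for (i in 1:3) for (j in 1:3) {
        if (i == k && j == k) tp <- tp + cm[i, j]
        else if (i != k && j == k) fp <- fp + cm[i, j]
        else if (i == k && j != k) fn <- fn + cm[i, j]
        else tn <- tn + cm[i, j]
      }
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
      spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
      f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
      out[[lev[k]]] <- c(prec = prec, sens = sens, spec = spec, f1 = f1,
                         support = tp + fn)
    }
    acc <- sum(diag(cm)) / n
    macro_sens <- mean(vapply(out, `[[`, numeric(1), "sens"))
    macro_spec <- mean(vapply(out, `[[`, numeric(1), "spec"))
    list(per = out, acc = acc, bal = (macro_sens + macro_spec) / 2)
  }
  set.seed(99)
  for (i in 1:1000) {
    cm <- random_cm()
    pc <- per_class_metrics(cm)
    orc <- oracle(cm)
    for (k in 1:3) {
      expect_equal(pc$precision[k], unname(orc$per[[k]]["prec"]))
      expect_equal(pc$sensitivity[k], unname(orc$per[[k]]["sens"]))
      expect_equal(pc$specificity[k], unname(orc$per[[k]]["spec"]))
      expect_equal(pc$f1[k], unname(orc$per[[k]]["f1"]))
      expect_identical(pc$support[k], as.integer(orc$per[[k]]["support"]))
    }
    ag <- aggregate_metrics(cm)
    expect_equal(ag$accuracy, orc$acc)
    expect_equal(balanced_accuracy(cm), orc$bal)
    # identities: weighted recall == accuracy; micro precision/recall/F1 ==
    # accuracy in single-label multiclass
    expect_equal(ag$weighted$sensitivity, ag$accuracy, tolerance = 1e-12)
    micro_tp <- sum(diag(cm))
    micro_fp <- sum(cm) - micro_tp
    expect_equal(micro_tp / (micro_tp + micro_fp), ag$accuracy)
  }
})

test_that("MCC matches the explicit covariance formula on random label vectors", {
  set.seed(17)
  for (i in 1:20) {
    truth <- sample(diagnosis_levels(), 60, replace = TRUE)
    pred <- sample(diagnosis_levels(), 60, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    # brute-force MCC over the binary indicator expansion
    t_num <- as.integer(factor(truth, diagnosis_levels()))
    p_num <- as.integer(factor(pred, diagnosis_levels()))
    n <- 60
    cov_xy <- sum(vapply(1:3, function(k) {
      sum((p_num == k) * (t_num == k)) - sum(p_num == k) * sum(t_num == k) / n
    }, numeric(1)))
    cov_xx <- sum(vapply(1:3, function(k) {
      sum(p_num == k) - sum(p_num == k)^2 / n
    }, numeric(1)))
    cov_yy <- sum(vapply(1:3, function(k) {
      sum(t_num == k) - sum(t_num == k)^2 / n
    }, numeric(1)))
    want <- if (cov_xx == 0 || cov_yy == 0) 0 else cov_xy / sqrt(cov_xx * cov_yy)
    expect_equal(demgrid:::mcc_from_cm(cm), want, tolerance = 1e-12)
  }
})

test_that("AUC metrics handle degenerate, perfect and null scores", {
  d <- degenerate_predictions(test_dist, "AD")
  am <- auc_metrics(d$scores, d$truth)
  # constant one-hot scores: every one-vs-rest AUC is all ties
  expect_equal(am$roc_auc_macro, 0.5)
  # the micro AUC of the flattened one-hot pairs has a closed form computed
  # from the tie structure: P(pos > neg) + P(tie)/2
  n <- sum(test_dist)
  pos_hi <- test_dist[["AD"]]; pos_lo <- n - pos_hi
  neg_hi <- n - test_dist[["AD"]]; neg_lo <- 2 * n - neg_hi
  micro_expected <- (pos_hi * neg_lo + 0.5 * (pos_hi * neg_hi + pos_lo * neg_lo)) /
    (n * 2 * n)
  expect_equal(am$roc_auc_micro, micro_expected, tolerance = 1e-9)
  expect_identical(demgrid:::as_percent(am$roc_auc_micro), 57)
  # perfectly separating scores
  truth <- rep(diagnosis_levels(), each = 4)
  perfect <- matrix(0.01, 12, 3)
  perfect[cbind(1:12, as.integer(factor(truth, diagnosis_levels())))] <- 0.98
  amp <- auc_metrics(perfect, truth)
  expect_equal(amp$roc_auc_macro, 1)
  expect_equal(amp$roc_auc_micro, 1)
  expect_equal(amp$auc_pr_macro, 1)
  expect_equal(amp$mcc, 1)
  # random uniform scores on balanced labels sit at the null
  set.seed(7)
  nn <- 10000
  truth_n <- rep(diagnosis_levels(), length.out = nn)
  rnd <- matrix(stats::runif(3 * nn), nn)
  amr <- auc_metrics(rnd, truth_n)
  expect_gt(amr$roc_auc_macro, 0.49)
  expect_lt(amr$roc_auc_macro, 0.51)
  # single-class truth: per-class AUC undefined, reported as 0.5 with warning
  w <- testthat::capture_warnings(
    am1 <- auc_metrics(matrix(stats::runif(15), 5), rep("AD", 5)))
  expect_true(all(grepl("0.5", w)))
  expect_gt(length(w), 0)
  expect_equal(am1$roc_auc_macro, 0.5)
})

test_that("bias index is 0 at match, 1 for any single-class collapse", {
  p <- c(CN = 0.225, MCI = 0.341, AD = 0.433)
  expect_equal(bias_index(p, p), 0)
  for (k in 1:3) {
    collapsed <- c(0, 0, 0); collapsed[k] <- 1
    expect_equal(bias_index(collapsed, p), 1)
  }
  u <- bias_index(rep(1 / 3, 3), p)
  expect_gt(u, 0); expect_lt(u, 1)
  # normalize = FALSE returns the raw total-variation distance
  expect_equal(bias_index(c(1, 0, 0), p, normalize = FALSE),
               1 - 0.225 / sum(p), tolerance = 1e-9)
  # property: always within [0, 1]
  set.seed(3)
  for (i in 1:100) {
    a <- stats::runif(3); b <- stats::runif(3)
    v <- bias_index(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("degenerate fixtures reproduce the printed single-class rows", {
  d <- degenerate_predictions(test_dist, "AD")
  expect_identical(length(d$truth), 1983L)
  expect_true(all(d$predicted == "AD"))
  expect_true(all(d$scores[, "AD"] == 1))
  # the all-MCI fixture evaluates to the printed MCI-collapse row
  m <- degenerate_predictions(test_dist, "MCI")
  pc <- per_class_metrics(confusion_matrix(m$truth, m$predicted))
  expect_identical(demgrid:::as_percent(pc$precision[2]), 34)
  expect_identical(demgrid:::as_percent(pc$sensitivity[2]), 100)
  # harmonic mean of 677/1983 and 1 is 0.509: rounds to 51
  expect_identical(demgrid:::as_percent(pc$f1[2]), 51)
  tiny <- degenerate_predictions(c(CN = 1, MCI = 1, AD = 1), "CN")
  expect_equal(aggregate_metrics(confusion_matrix(tiny$truth, tiny$predicted))$accuracy,
               1 / 3)
})

test_that("metric reports assemble all fields coherently", {
  d <- degenerate_predictions(test_dist, "AD")
  r <- metric_report(d$truth, d$predicted, d$scores)
  expect_s3_class(r, "metric_report")
  expect_equal(r$bias_index, 1)
  row <- report_row(r)
  expect_identical(row$accuracy, 43)
  expect_identical(row$balanced_accuracy, 50)
  expect_identical(row$mse, 124)
  expect_identical(row$roc_auc_micro, 57)
  expect_identical(row$roc_auc_macro, 50)
})

test_that("model ranking normalises, sorts and tie-breaks as specified", {
  one <- data.frame(top1 = 70, top5 = 90, param_count = 10,
                    performance_score = 0.5)
  r1 <- rank_models(one)
  expect_identical(r1$rank, 1L)
  expect_identical(r1$norm_top1, 0)       # constant column -> 0 by convention
  two <- data.frame(top1 = c(70, 71), top5 = c(90, 90),
                    param_count = c(30, 10), performance_score = c(0.5, 0.5))
  r2 <- rank_models(two)
  expect_identical(r2$param_count[1], 10) # smaller model first on ties
  set.seed(21)
  toy <- data.frame(top1 = stats::runif(5, 60, 80),
                    top5 = stats::runif(5, 85, 95),
                    param_count = sample(10:100, 5),
                    performance_score = stats::runif(5))
  rt <- rank_models(toy)
  # hand-sorted oracle
  o <- toy[order(-toy$performance_score, -toy$top5, toy$param_count), ]
  expect_identical(rt$performance_score, o$performance_score)
  expect_true(all(diff(rt$rank) == 1))
  # normalised columns live in [0, 1] with both extremes attained
  expect_equal(range(rt$norm_top1), c(0, 1))
  expect_error(rank_models(data.frame()), "nonempty")
})
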