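# Class-imbalance mitigation: plan arithmetic (weights, SMOTE synthesis,
# undersampling removals), Borderline-SMOTE-1 synthesis, random undersampling,
# and the focal / weighted cross-entropy / margin losses.

as_class_counts <- function(counts) {
  if (is.table(counts)) counts <- stats::setNames(as.integer(counts), names(counts))
  stopifnot(!is.null(names(counts)),
            all(names(counts) %in% diagnosis_levels()),
            all(counts >= 0), any(counts > 0))
  out <- stats::setNames(integer(3), diagnosis_levels())
  out[names(counts)] <- as.integer(counts)
  out
}

#' Inverse-frequency class weights
#'
#' The weight of each class is the ratio of the largest class count to its own
#' count, so the largest class has weight exactly 1. Weights are rounded to
#' two decimals, the reporting convention used throughout.
#'
#' @param counts Named class counts over (CN, MCI, AD); all must be positive.
#' @return Named numeric weights.
#' @export
class_weights <- function(counts) {
  counts <- as_class_counts(counts)
  if (any(counts == 0)) stop("all class counts must be positive", call. = FALSE)
  round_half_up(max(counts) / counts, 2)
}

new_mitigation_plan <- function(strategy, counts, synthesize = NULL,
                                remove = NULL, weights = NULL) {
  zero <- stats::setNames(integer(3), diagnosis_levels())
  structure(list(strategy = strategy, counts = counts,
                 synthesize = if (is.null(synthesize)) zero else synthesize,
                 remove = if (is.null(remove)) zero else remove,
                 weights = weights),
            class = "mitigation_plan")
}

#' @export
print.mitigation_plan <- function(x, ...) {
  cat(sprintf("<mitigation_plan> strategy %s\n", x$strategy))
  df <- data.frame(count = x$counts, synthesize = x$synthesize,
                   remove = x$remove)
  if (!is.null(x$weights)) df$weight <- x$weights
  print(df)
  invisible(x)
}

#' Oversampling plan: balance up to the majority class
#'
#' Plans `max(counts) - count_c` synthetic samples per class so every class
#' reaches the majority count.
#'
#' @param counts Named class counts.
#' @return A `mitigation_plan` with per-class `synthesize` counts.
#' @export
smote_plan <- function(counts) {
  counts <- as_class_counts(counts)
  new_mitigation_plan("smote", counts, synthesize = max(counts) - counts)
}

#' Undersampling plan: trim down to the minority class
#'
#' Plans `count_c - min(counts)` removals per class.
#'
#' @param counts Named class counts.
#' @return A `mitigation_plan` with per-class `remove` counts.
#' @export
undersample_plan <- function(counts) {
  counts <- as_class_counts(counts)
  new_mitigation_plan("undersample", counts, remove = counts - min(counts))
}

#' Borderline-SMOTE-1 oversampling
#'
#' Synthesises the planned number of samples per minority class by linear
#' interpolation between a minority point and one of its k nearest minority
#' neighbours, `x_new = x + u (x_nn - x)`, `u ~ U(0, 1)`. Seeds are drawn from
#' the DANGER set: minority points whose m nearest neighbours (over all
#' classes) contain a majority of other-class points but are not entirely
#' other-class (count in `[m/2, m)`). If no DANGER points exist the whole
#' minority class is eligible (vanilla interpolation fallback). Real rows are
#' never modified or dropped; synthetic rows are flagged. Apply to
#' training-split data only — synthetic samples must never reach validation or
#' test sets.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Class labels over (CN, MCI, AD), length `nrow(features)`.
#' @param plan A [smote_plan()] result.
#' @param m_neighbors Neighbourhood size for DANGER detection (default 10).
#' @param k_neighbors Minority neighbourhood for interpolation (default 5).
#' @param seed Integer seed.
#' @return List with `features`, `labels`, `synthetic` (logical flag vector).
#' @export
borderline_smote <- function(features, labels, plan, m_neighbors = 10,
                             k_neighbors = 5, seed = 1) {
  stopifnot(inherits(plan, "mitigation_plan"), is.matrix(features))
  labels <- as_diagnosis(labels)
  stopifnot(length(labels) == nrow(features))
  set.seed(derive_seed(seed, 21))
  new_feats <- list()
  new_labs <- character(0)
  for (cls in diagnosis_levels()) {
    n_syn <- plan$synthesize[[cls]]
    if (n_syn == 0) next
    idx <- which(labels == cls)
    if (length(idx) <= k_neighbors) {
      stop(sprintf("class %s has %d samples; need more than k_neighbors = %d",
                   cls, length(idx), k_neighbors), call. = FALSE)
    }
    X <- features[idx, , drop = FALSE]
    # distances minority -> everyone
    d_all <- outer(rowSums(X^2), rowSums(features^2), `+`) -
      2 * X %*% t(features)
    danger <- logical(length(idx))
    m_use <- min(m_neighbors, nrow(features) - 1)
    for (i in seq_along(idx)) {
      di <- d_all[i, ]
      di[idx[i]] <- Inf
      nn <- order(di)[seq_len(m_use)]
      n_maj <- sum(labels[nn] != cls)
      danger[i] <- n_maj >= m_use / 2 && n_maj < m_use
    }
    eligible <- if (any(danger)) which(danger) else seq_along(idx)
    # minority-internal k nearest neighbours
    d_min <- d_all[, idx, drop = FALSE]
    diag(d_min) <- Inf
    seeds <- eligible[sample.int(length(eligible), n_syn, replace = TRUE)]
    u <- stats::runif(n_syn)
    pick <- sample.int(k_neighbors, n_syn, replace = TRUE)
    syn <- matrix(0, n_syn, ncol(features))
    for (s in seq_len(n_syn)) {
      i <- seeds[s]
      nn <- order(d_min[i, ])[pick[s]]
      syn[s, ] <- X[i, ] + u[s] * (X[nn, ] - X[i, ])
    }
    new_feats[[cls]] <- syn
    new_labs <- c(new_labs, rep(cls, n_syn))
  }
  if (length(new_feats) == 0) {
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, nrow(features))))
  }
  aug <- rbind(features, do.call(rbind, new_feats))
  list(features = aug,
       labels = factor(c(as.character(labels), new_labs),
                       levels = diagnosis_levels()),
       synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, length(new_labs))))
}

#' Random undersampling
#'
#' Removes exactly the planned number of rows per class, sampled without
#' replacement under the seed. Never invents rows.
#'
#' @inheritParams borderline_smote
#' @param plan An [undersample_plan()] result.
#' @return List with `features`, `labels`, `kept` (row indices retained).
#' @export
random_undersample <- function(features, labels, plan, seed = 1) {
  stopifnot(inherits(plan, "mitigation_plan"), is.matrix(features))
  labels <- as_diagnosis(labels)
  set.seed(derive_seed(seed, 22))
  drop <- integer(0)
  for (cls in diagnosis_levels()) {
    n_rm <- plan$remove[[cls]]
    if (n_rm == 0) next
    idx <- which(labels == cls)
    if (n_rm > length(idx)) {
      stop(sprintf("cannot remove %d of %d %s samples", n_rm, length(idx), cls),
           call. = FALSE)
    }
    drop <- c(drop, idx[sample.int(length(idx), n_rm)])
  }
  kept <- setdiff(seq_len(nrow(features)), drop)
  list(features = features[kept, , drop = FALSE], labels = labels[kept],
       kept = kept)
}

# --- losses -----------------------------------------------------------------

#' Focal loss parameters
#'
#' @param gamma Focusing exponent, >= 0; default 2.
#' @param alpha Per-class weights over (CN, MCI, AD); default
#'   `c(0.45, 0.34, 0.22)` — inverse class proportions, largest weight on the
#'   rarest class (CN).
#' @return Object of class `focal_params`.
#' @export
focal_params <- function(gamma = 2, alpha = c(CN = 0.45, MCI = 0.34, AD = 0.22)) {
  stopifnot(gamma >= 0, length(alpha) == 3, all(alpha > 0))
  alpha <- stats::setNames(as.numeric(alpha), diagnosis_levels())
  structure(list(gamma = gamma, alpha = alpha), class = "focal_params")
}

#' Margin loss parameters
#'
#' @param m_plus,m_minus Positive/negative margins, `0 < m_minus < m_plus < 1`;
#'   defaults 0.9 and 0.1.
#' @param lambda Down-weight on absent classes; default 0.5.
#' @param reconstruction_weight Reconstruction loss weight; default 5e-4.
#' @return Object of class `margin_params`.
#' @export
margin_params <- function(m_plus = 0.9, m_minus = 0.1, lambda = 0.5,
                          reconstruction_weight = 0.0005) {
  stopifnot(0 < m_minus, m_minus < m_plus, m_plus < 1, lambda >= 0,
            reconstruction_weight >= 0)
  structure(list(m_plus = m_plus, m_minus = m_minus, lambda = lambda,
                 reconstruction_weight = reconstruction_weight),
            class = "margin_params")
}

check_simplex <- function(prob, labels) {
  stopifnot(is.matrix(prob), ncol(prob) == 3)
  labels <- as_diagnosis(labels)
  stopifnot(length(labels) == nrow(prob))
  if (any(prob < -1e-9) || any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("probability rows must lie on the simplex (sum to 1 within 1e-6)",
         call. = FALSE)
  }
  labels
}

#' Focal loss
#'
#' Mean over samples of `-alpha_y (1 - p_y)^gamma log(p_y)`. Probabilities are
#' clipped to `[1e-7, 1 - 1e-7]` for numerical safety. With `gamma = 0` and
#' unit `alpha` this is the mean cross-entropy.
#'
#' @param prob n x 3 matrix of class probabilities (rows on the simplex,
#'   columns in CN, MCI, AD order).
#' @param labels True class labels.
#' @param params A [focal_params()] bundle.
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(prob, labels, params = focal_params()) {
  labels <- check_simplex(prob, labels)
  p <- pmin(pmax(prob[cbind(seq_len(nrow(prob)), as.integer(labels))], 1e-7),
            1 - 1e-7)
  a <- params$alpha[as.integer(labels)]
  mean(-a * (1 - p)^params$gamma * log(p))
}

#' Weighted cross-entropy
#'
#' Mean over samples of `-w_y log(p_y)`.
#'
#' @inheritParams focal_loss
#' @param weights Named per-class weights (e.g. from [class_weights()]).
#' @return Nonnegative scalar.
#' @export
weighted_cross_entropy <- function(prob, labels, weights) {
  labels <- check_simplex(prob, labels)
  stopifnot(length(weights) == 3)
  w <- weights[as.integer(labels)]
  p <- pmin(pmax(prob[cbind(seq_len(nrow(prob)), as.integer(labels))], 1e-7),
            1 - 1e-7)
  mean(-w * log(p))
}

#' Capsule margin loss
#'
#' Per sample, summed over classes:
#' `T_k max(0, m_plus - v_k)^2 + lambda (1 - T_k) max(0, v_k - m_minus)^2`,
#' with `T_k = 1` for the true class, averaged over samples. `v_k` are capsule
#' lengths (class confidences) in \[0, 1\].
#'
#' @param lengths n x 3 matrix of capsule lengths in \[0, 1\].
#' @param labels True class labels.
#' @param params A [margin_params()] bundle.
#' @return Nonnegative scalar.
#' @export
margin_loss <- function(lengths, labels, params = margin_params()) {
  stopifnot(is.matrix(lengths), ncol(lengths) == 3)
  labels <- as_diagnosis(labels)
  stopifnot(length(labels) == nrow(lengths))
  if (any(lengths < 0) || any(lengths > 1)) {
    stop("capsule lengths must lie in [0, 1]", call. = FALSE)
  }
  t_k <- matrix(0, nrow(lengths), 3)
  t_k[cbind(seq_len(nrow(lengths)), as.integer(labels))] <- 1
  pos <- pmax(0, params$m_plus - lengths)^2
  neg <- pmax(0, lengths - params$m_minus)^2
  mean(rowSums(t_k * pos + params$lambda * (1 - t_k) * neg))
}
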