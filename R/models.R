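# Desk-scale model harness: a small convolutional baseline classifier and the
# shared training loop (Adam, learning-rate decay, gradient clipping, early
# stopping) used for both the CNN and the capsule network.

#' Build the baseline convolutional classifier
#'
#' A deliberately small architecture standing in for the full-scale pretrained
#' backbones: one convolutional layer (ReLU, stride 2) followed by a dense
#' softmax head, emitting 3-class probability rows on the simplex.
#'
#' @param input_side Image side length, >= 32.
#' @param seed Integer seed for weight initialisation.
#' @param n_filters Convolution filters; default 8.
#' @param kernel Convolution kernel side; default 5.
#' @param stride Convolution stride; default 2.
#' @return Object of class `demgrid_model` (type `"cnn"`).
#' @export
build_baseline_cnn <- function(input_side, seed = 1, n_filters = 8,
                               kernel = 5, stride = 2) {
  stopifnot(input_side >= 32)
  set.seed(derive_seed(seed, 41))
  m1 <- conv_index(input_side, input_side, kernel, stride)
  o <- attr(m1, "out")
  feat <- prod(o) * n_filters
  w <- list(
    conv_w = matrix(stats::rnorm(kernel^2 * n_filters, 0, 1 / kernel),
                    kernel^2, n_filters),
    conv_b = numeric(n_filters),
    fc_w = matrix(stats::rnorm(feat * 3, 0, 1 / sqrt(feat)), feat, 3),
    fc_b = numeric(3))
  structure(list(type = "cnn", input_side = input_side, weights = w,
                 idx1 = m1, n_out = prod(o), n_filters = n_filters),
            class = "demgrid_model")
}

#' @export
print.demgrid_model <- function(x, ...) {
  cat(sprintf("<demgrid_model> %s, %s parameters%s\n", x$type,
              format(n_params(x), big.mark = ","),
              if (x$type == "capsnet")
                sprintf(", input %d, r = %d", x$spec$input_side,
                        x$spec$routing_iters)
              else sprintf(", input %d", x$input_side)))
  invisible(x)
}

# Coerce features to an [side, side, n] array.
as_image_batch <- function(x, side) {
  if (is.matrix(x) && ncol(x) == side^2) {
    x <- array(t(x), c(side, side, nrow(x)))
  }
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[1] == side,
            dim(x)[2] == side)
  x
}

model_side <- function(model) {
  if (model$type == "cnn") model$input_side else model$spec$input_side
}

# Forward pass for a batch. Returns scores (n x 3) and caches.
model_forward <- function(model, x) {
  side <- model_side(model)
  x <- as_image_batch(x, side)
  n <- dim(x)[3]
  if (model$type == "cnn") {
    w <- model$weights
    hw <- side^2
    p <- do.call(rbind, lapply(seq_len(n), function(t) {
      matrix(x[, , t][model$idx1], nrow(model$idx1))
    }))
    z1 <- sweep(p %*% w$conv_w, 2, w$conv_b, `+`)
    a1 <- pmax(z1, 0)
    feat <- matrix(0, n, model$n_out * model$n_filters)
    for (t in seq_len(n)) {
      rows <- ((t - 1) * model$n_out + 1):(t * model$n_out)
      feat[t, ] <- as.vector(a1[rows, ])
    }
    logits <- sweep(feat %*% w$fc_w, 2, w$fc_b, `+`)
    prob <- softmax_rows(logits)
    colnames(prob) <- diagnosis_levels()
    list(scores = prob, cache = list(p = p, z1 = z1, feat = feat, prob = prob))
  } else {
    caches <- lapply(seq_len(n), function(t) caps_forward_one(model, x[, , t]))
    scores <- do.call(rbind, lapply(caches, `[[`, "lengths"))
    colnames(scores) <- diagnosis_levels()
    list(scores = scores, cache = caches)
  }
}

# Gradient of the configured loss with respect to the model scores.
# Returns list(loss, dscores).
loss_and_grad <- function(scores, y, loss, loss_params) {
  n <- nrow(scores)
  yi <- as.integer(y)
  onehot <- matrix(0, n, 3)
  onehot[cbind(seq_len(n), yi)] <- 1
  if (loss %in% c("ce", "wce", "focal")) {
    p <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
    py <- p[cbind(seq_len(n), yi)]
    if (loss == "ce") {
      val <- mean(-log(py))
      dlogits <- (scores - onehot) / n
    } else if (loss == "wce") {
      w <- unname(loss_params$weights)[yi]
      val <- mean(-w * log(py))
      dlogits <- w * (scores - onehot) / n
    } else {
      fp <- loss_params
      a <- unname(fp$alpha)[yi]
      g <- fp$gamma
      val <- mean(-a * (1 - py)^g * log(py))
      # dL_i/dp_y, then through the softmax jacobian
      dpy <- -a * (-g * (1 - py)^(pmax(g - 1, 0)) * log(py) + (1 - py)^g / py)
      dlogits <- matrix(0, n, 3)
      for (c in 1:3) {
        dlogits[, c] <- dpy * py * ((c == yi) - scores[, c]) / n
      }
    }
    dimnames(dlogits) <- NULL
    list(loss = val, dscores = dlogits, wrt = "logits")
  } else if (loss == "margin") {
    mp <- loss_params
    pos <- pmax(mp$m_plus - scores, 0)
    neg <- pmax(scores - mp$m_minus, 0)
    val <- mean(rowSums(onehot * pos^2 + mp$lambda * (1 - onehot) * neg^2))
    dsc <- (onehot * (-2 * pos) + mp$lambda * (1 - onehot) * 2 * neg) / n
    dimnames(dsc) <- NULL
    list(loss = val, dscores = dsc, wrt = "scores")
  } else stop("unknown loss", call. = FALSE)
}

# Backward pass: weight gradients for a batch given dscores.
model_backward <- function(model, x, fw, lg) {
  side <- model_side(model)
  x <- as_image_batch(x, side)
  n <- dim(x)[3]
  if (model$type == "cnn") {
    cache <- fw$cache
    if (lg$wrt == "logits") {
      dlogits <- lg$dscores
    } else {
      # chain d(scores) through the softmax jacobian
      p <- cache$prob
      dv <- lg$dscores
      dlogits <- p * (dv - rowSums(dv * p))
      dimnames(dlogits) <- NULL
    }
    dfc_w <- crossprod(cache$feat, dlogits)
    dfc_b <- colSums(dlogits)
    dfeat <- dlogits %*% t(model$weights$fc_w)
    da1 <- matrix(0, n * model$n_out, model$n_filters)
    for (t in seq_len(n)) {
      rows <- ((t - 1) * model$n_out + 1):(t * model$n_out)
      da1[rows, ] <- matrix(dfeat[t, ], model$n_out, model$n_filters)
    }
    dz1 <- da1 * (cache$z1 > 0)
    list(conv_w = crossprod(cache$p, dz1), conv_b = colSums(dz1),
         fc_w = dfc_w, fc_b = dfc_b)
  } else {
    stopifnot(lg$wrt == "scores")
    grads <- NULL
    for (t in seq_len(n)) {
      g <- caps_backward_one(model, fw$cache[[t]], lg$dscores[t, ])
      grads <- if (is.null(grads)) g else add_grads(grads, g)
    }
    grads
  }
}

add_grads <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]] <- if (is.list(a[[nm]])) Map(`+`, a[[nm]], b[[nm]])
               else a[[nm]] + b[[nm]]
  }
  a
}

# Flatten a (possibly nested) gradient list into a single numeric vector, and
# the inverse update of weights from such a vector.
flatten_grads <- function(g) {
  unlist(g, use.names = FALSE)
}

scale_grads <- function(g, f) {
  rapply(g, function(x) x * f, how = "replace")
}

#' Training configuration
#'
#' @param learning_rate Initial Adam learning rate; default 0.001.
#' @param lr_decay Multiplicative decay factor; default 0.9.
#' @param lr_decay_every Epoch interval for the decay; default 100.
#' @param clip_norm Global gradient-norm clip; default 0.5.
#' @param batch_size Minibatch size; default 16.
#' @param max_epochs Training budget; default 100.
#' @param patience Early-stopping patience in epochs (0 stops at the first
#'   non-improving epoch); default 50.
#' @param seed Integer seed for shuffling.
#' @return Object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, lr_decay = 0.9,
                            lr_decay_every = 100, clip_norm = 0.5,
                            batch_size = 16, max_epochs = 100, patience = 50,
                            seed = 42) {
  stopifnot(learning_rate > 0, lr_decay > 0, lr_decay_every >= 1,
            clip_norm > 0, batch_size >= 1, max_epochs >= 1, patience >= 0,
            patience <= max_epochs)
  structure(list(learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_decay_every = lr_decay_every, clip_norm = clip_norm,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, seed = as.integer(seed)),
            class = "training_config")
}

# Resolve default loss parameters.
resolve_loss_params <- function(loss, loss_params, y) {
  if (!is.null(loss_params)) return(loss_params)
  switch(loss,
         ce = list(),
         wce = list(weights = class_weights(table(y))),
         focal = focal_params(),
         margin = margin_params())
}

#' Train a model
#'
#' Minibatch Adam with the configured loss (plain/weighted cross-entropy,
#' focal, or capsule margin loss), learning-rate decay, global gradient-norm
#' clipping and early stopping on the validation loss (best weights are
#' restored). Training refuses to start if a failing leakage report is
#' supplied.
#'
#' @param model A `demgrid_model` from [build_baseline_cnn()] or
#'   [build_capsnet()].
#' @param x,y Training images (n x side^2 matrix or side x side x n array)
#'   and labels.
#' @param x_val,y_val Validation set (defaults to the training set when
#'   omitted, e.g. for memorisation checks).
#' @param loss One of `"ce"`, `"wce"`, `"focal"`, `"margin"`.
#' @param loss_params Loss parameter bundle ([focal_params()],
#'   [margin_params()], or `list(weights = ...)`); sensible defaults derived
#'   from the training labels when `NULL`.
#' @param config A [training_config()].
#' @param leakage Optional [verify_no_leakage()] report gating the run.
#' @return List with `model` (trained), `history` (per-epoch data frame) and
#'   `best_epoch`.
#' @export
train_model <- function(model, x, y, x_val = NULL, y_val = NULL,
                        loss = c("ce", "wce", "focal", "margin"),
                        loss_params = NULL, config = training_config(),
                        leakage = NULL) {
  loss <- match.arg(loss)
  stopifnot(inherits(config, "training_config"))
  if (!is.null(leakage)) {
    stopifnot(inherits(leakage, "leakage_report"))
    if (!leakage$pass) {
      stop("refusing to train: leakage verification failed", call. = FALSE)
    }
  }
  y <- as_diagnosis(y)
  if (length(y) == 0) stop("empty training set", call. = FALSE)
  side <- model_side(model)
  x <- as_image_batch(x, side)
  if (is.null(x_val)) { x_val <- x; y_val <- y }
  y_val <- as_diagnosis(y_val)
  x_val <- as_image_batch(x_val, side)
  lp <- resolve_loss_params(loss, loss_params, y)

  set.seed(derive_seed(config$seed, 51))
  n <- dim(x)[3]
  adam_m <- scale_grads(model$weights, 0)
  adam_v <- scale_grads(model$weights, 0)
  step <- 0
  hist <- list()
  best <- list(val = Inf, weights = model$weights, epoch = 0)
  bad_epochs <- 0
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate *
      config$lr_decay^((epoch - 1) %/% config$lr_decay_every)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x[, , idx, drop = FALSE]
      yb <- y[idx]
      fw <- model_forward(model, xb)
      lg <- loss_and_grad(fw$scores, yb, loss, lp)
      gr <- model_backward(model, xb, fw, lg)
      gnorm <- sqrt(sum(flatten_grads(gr)^2))
      if (gnorm > config$clip_norm) {
        gr <- scale_grads(gr, config$clip_norm / gnorm)
      }
      step <- step + 1
      upd <- function(w, g, m, v) {
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g^2
        mh <- m / (1 - 0.9^step)
        vh <- v / (1 - 0.999^step)
        list(w = w - lr * mh / (sqrt(vh) + 1e-8), m = m, v = v)
      }
      for (nm in names(gr)) {
        if (is.list(gr[[nm]])) {
          for (k in seq_along(gr[[nm]])) {
            r <- upd(model$weights[[nm]][[k]], gr[[nm]][[k]],
                     adam_m[[nm]][[k]], adam_v[[nm]][[k]])
            model$weights[[nm]][[k]] <- r$w
            adam_m[[nm]][[k]] <- r$m; adam_v[[nm]][[k]] <- r$v
          }
        } else {
          r <- upd(model$weights[[nm]], gr[[nm]], adam_m[[nm]], adam_v[[nm]])
          model$weights[[nm]] <- r$w
          adam_m[[nm]] <- r$m; adam_v[[nm]] <- r$v
        }
      }
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    val_scores <- model_forward(model, x_val)$scores
    val_loss <- loss_and_grad(val_scores, y_val, loss, lp)$loss
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss / nb,
                                val_loss = val_loss)
    if (val_loss < best$val - 1e-9) {
      best <- list(val = val_loss, weights = model$weights, epoch = epoch)
      bad_epochs <- 0
    } else {
      bad_epochs <- bad_epochs + 1
      if (bad_epochs > config$patience) break
    }
  }
  model$weights <- best$weights
  list(model = model, history = do.call(rbind, hist), best_epoch = best$epoch)
}

#' Predict class scores
#'
#' Per-sample class scores: softmax probabilities (rows on the simplex) for
#' the CNN, capsule lengths in \[0, 1) for the capsule network. Argmax over a
#' row gives the predicted label.
#'
#' @param model A trained `demgrid_model`.
#' @param x Images (n x side^2 matrix or side x side x n array).
#' @return n x 3 score matrix with class column names.
#' @export
predict_scores <- function(model, x) {
  model_forward(model, x)$scores
}

#' Predicted labels from a score matrix
#'
#' @param scores n x 3 score matrix.
#' @return Factor over the diagnosis levels.
#' @export
scores_to_labels <- function(scores) {
  factor(diagnosis_levels()[max.col(scores, ties.method = "first")],
         levels = diagnosis_levels())
}
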