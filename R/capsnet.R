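# Capsule primitives: squash nonlinearity, routing-by-agreement, and the
# capsule network head geometry.

#' Squash nonlinearity
#'
#' Maps a vector to the same direction with norm in \[0, 1):
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`, with `squash(0) = 0`. Capsule
#' length thereby encodes confidence.
#'
#' @param s Numeric vector.
#' @return Vector of the same length with norm < 1.
#' @export
squash <- function(s) {
  n2 <- sum(s^2)
  if (n2 == 0) return(s * 0)
  s * sqrt(n2) / (1 + n2)
}

# Row-wise squash of a matrix of capsule vectors; returns the squashed matrix
# and the input norms (cached for backprop).
squash_rows <- function(m) {
  n2 <- rowSums(m^2)
  coef <- ifelse(n2 == 0, 0, sqrt(n2) / (1 + n2))
  list(out = m * coef, norm = sqrt(n2))
}

# Jacobian-transpose product of squash at input s (norm n) applied to dv.
squash_backprop <- function(s, dv) {
  n2 <- sum(s^2)
  if (n2 == 0) return(dv)               # squash is ~identity near 0
  n <- sqrt(n2)
  h <- n / (1 + n2)
  hp <- (1 - n2) / (1 + n2)^2
  h * dv + (hp / n) * s * sum(s * dv)
}

#' Dynamic routing by agreement
#'
#' Iterative soft assignment of primary-capsule predictions to output
#' capsules. Routing logits start at zero (uniform couplings); each of the `r`
#' iterations computes couplings `c = softmax(b)` over output capsules,
#' coupled sums `s_j = sum_i c_ij u_hat_ij`, outputs `v_j = squash(s_j)`, and
#' agreement updates `b_ij <- b_ij + u_hat_ij . v_j`.
#'
#' @param predictions 3D array `u_hat` of shape (n_primary, n_out, d_out).
#' @param r Number of routing iterations, >= 1 (default 3).
#' @return Object of class `routing_state`: `predictions`, `logits`,
#'   `couplings` (rows sum to 1), `outputs` (n_out x d_out), `agreements`.
#' @export
dynamic_routing <- function(predictions, r = 3) {
  stopifnot(is.array(predictions), length(dim(predictions)) == 3, r >= 1)
  if (any(!is.finite(predictions))) stop("NaN in predictions", call. = FALSE)
  d <- dim(predictions)
  n_in <- d[1]; n_out <- d[2]; d_out <- d[3]
  b <- matrix(0, n_in, n_out)
  v <- matrix(0, n_out, d_out)
  a <- matrix(0, n_in, n_out)
  cmat <- matrix(1 / n_out, n_in, n_out)
  for (it in seq_len(r)) {
    cmat <- softmax_rows(b)
    for (j in seq_len(n_out)) {
      s_j <- colSums(cmat[, j] * predictions[, j, , drop = TRUE])
      v[j, ] <- squash(s_j)
      a[, j] <- predictions[, j, , drop = TRUE] %*% v[j, ]
    }
    b <- b + a
  }
  structure(list(predictions = predictions, logits = b, couplings = cmat,
                 outputs = v, agreements = a, iterations = r),
            class = "routing_state")
}

#' Capsule network specification
#'
#' The head geometry: a convolutional stem (`conv_filters` filters,
#' `conv_kernel` x `conv_kernel`, stride 1, ReLU), primary capsules
#' (`primary_channels` channels of `primary_dim`-dimensional capsules from a
#' `primary_kernel` x `primary_kernel` stride-`primary_stride` convolution),
#' and one `digit_dim`-dimensional output capsule per class, coupled by
#' `routing_iters` routing iterations. Digit-capsule transform weights are
#' shared across spatial positions within each primary channel (the standard
#' variant for large inputs). The optional reconstruction decoder follows the
#' original capsule formulation (512 and 1024 hidden units) and reconstructs a
#' `recon_side` x `recon_side` downsampled view of the input.
#'
#' @param input_side Input image side length (512 at full scale, 64 at desk
#'   scale).
#' @param conv_filters,conv_kernel Stem geometry; defaults 256 and 9.
#' @param primary_channels,primary_dim,primary_kernel,primary_stride Primary
#'   capsule geometry; defaults 32, 8, 6, 2.
#' @param digit_dim Output capsule dimension; default 16.
#' @param n_classes Number of output capsules; default 3.
#' @param routing_iters Routing iterations `r`; default 3.
#' @param reconstruction Include the decoder; default `TRUE`.
#' @param decoder_hidden Hidden sizes of the decoder; default `c(512, 1024)`.
#' @param recon_side Side of the reconstruction target; default 64.
#' @return Object of class `capsnet_spec` with derived shape fields.
#' @export
capsnet_spec <- function(input_side = 64, conv_filters = 256, conv_kernel = 9,
                         primary_channels = 32, primary_dim = 8,
                         primary_kernel = 6, primary_stride = 2,
                         digit_dim = 16, n_classes = 3, routing_iters = 3,
                         reconstruction = TRUE, decoder_hidden = c(512, 1024),
                         recon_side = 64) {
  stopifnot(routing_iters >= 1, primary_dim > 0, digit_dim > 0)
  conv_out <- input_side - conv_kernel + 1
  if (conv_out < primary_kernel) {
    stop(sprintf("input side %d too small: conv output %d < primary kernel %d",
                 input_side, conv_out, primary_kernel), call. = FALSE)
  }
  if ((conv_out - primary_kernel) %% primary_stride != 0) {
    stop(sprintf(paste0("incompatible stem/stride arithmetic: conv output %d, ",
                        "primary kernel %d, stride %d leaves a remainder"),
                 conv_out, primary_kernel, primary_stride), call. = FALSE)
  }
  primary_grid <- (conv_out - primary_kernel) / primary_stride + 1
  structure(list(input_side = input_side, conv_filters = conv_filters,
                 conv_kernel = conv_kernel, primary_channels = primary_channels,
                 primary_dim = primary_dim, primary_kernel = primary_kernel,
                 primary_stride = primary_stride, digit_dim = digit_dim,
                 n_classes = n_classes, routing_iters = routing_iters,
                 reconstruction = reconstruction,
                 decoder_hidden = decoder_hidden, recon_side = recon_side,
                 conv_out = conv_out, primary_grid = primary_grid,
                 n_primary = primary_grid^2 * primary_channels),
            class = "capsnet_spec")
}

#' Parameter count of a capsule network specification
#'
#' @param spec A [capsnet_spec()].
#' @return Total number of trainable scalars (weights + biases).
#' @export
capsnet_params_count <- function(spec) {
  stopifnot(inherits(spec, "capsnet_spec"))
  stem <- spec$conv_kernel^2 * spec$conv_filters + spec$conv_filters
  prim_ch <- spec$primary_channels * spec$primary_dim
  primary <- spec$primary_kernel^2 * spec$conv_filters * prim_ch + prim_ch
  digit <- spec$primary_channels * spec$n_classes * spec$primary_dim * spec$digit_dim
  total <- stem + primary + digit
  if (spec$reconstruction) {
    sizes <- c(spec$n_classes * spec$digit_dim, spec$decoder_hidden,
               spec$recon_side^2)
    for (i in seq_len(length(sizes) - 1)) {
      total <- total + sizes[i] * sizes[i + 1] + sizes[i + 1]
    }
  }
  total
}

# Linear-index map for im2col: rows are output positions, columns the k^2
# within-patch offsets, over an h x w single-channel image (column-major).
conv_index <- function(h, w, k, stride) {
  oh <- (h - k) %/% stride + 1
  ow <- (w - k) %/% stride + 1
  a0 <- rep(seq(0, by = stride, length.out = oh), times = ow)
  b0 <- rep(seq(0, by = stride, length.out = ow), each = oh)
  off_i <- rep(seq_len(k), times = k)
  off_j <- rep(seq_len(k), each = k)
  # linear index (column-major): (col - 1) * h + row, row = a0 + off_i
  m <- outer(b0, off_j - 1, `+`) * h + outer(a0, off_i, `+`)
  storage.mode(m) <- "integer"
  attr(m, "out") <- c(oh, ow)
  m
}

#' Build a capsule network model
#'
#' Instantiates the weights of a [capsnet_spec()] with seeded small-normal
#' initialisation. The model maps a grayscale image to `n_classes` capsule
#' lengths in \[0, 1).
#'
#' @param spec A [capsnet_spec()].
#' @param seed Integer seed for the initialisation.
#' @return Object of class `demgrid_model` (type `"capsnet"`).
#' @export
build_capsnet <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "capsnet_spec"))
  set.seed(derive_seed(seed, 31))
  rnd <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  prim_ch <- spec$primary_channels * spec$primary_dim
  w <- list(
    conv_w = rnd(spec$conv_kernel^2, spec$conv_filters,
                 1 / spec$conv_kernel),
    conv_b = numeric(spec$conv_filters),
    prim_w = rnd(spec$primary_kernel^2 * spec$conv_filters, prim_ch,
                 1 / sqrt(spec$primary_kernel^2 * spec$conv_filters)),
    prim_b = numeric(prim_ch))
  w$digit_w <- lapply(seq_len(spec$primary_channels), function(c) {
    rnd(spec$primary_dim, spec$n_classes * spec$digit_dim,
        1 / sqrt(spec$primary_dim))
  })
  if (spec$reconstruction) {
    sizes <- c(spec$n_classes * spec$digit_dim, spec$decoder_hidden,
               spec$recon_side^2)
    w$decoder <- lapply(seq_len(length(sizes) - 1), function(i) {
      list(w = rnd(sizes[i], sizes[i + 1], 1 / sqrt(sizes[i])),
           b = numeric(sizes[i + 1]))
    })
  }
  m1 <- conv_index(spec$input_side, spec$input_side, spec$conv_kernel, 1)
  m2 <- conv_index(spec$conv_out, spec$conv_out, spec$primary_kernel,
                   spec$primary_stride)
  structure(list(type = "capsnet", spec = spec, weights = w,
                 idx1 = m1, idx2 = m2),
            class = "demgrid_model")
}

#' Number of trainable parameters in a model
#'
#' @param model A `demgrid_model`.
#' @return Integer scalar.
#' @export
n_params <- function(model) {
  cnt <- function(x) {
    if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  }
  cnt(model$weights)
}

# Forward pass of the capsule network for ONE sample (img: side x side
# matrix). Returns lengths plus caches for backprop.
caps_forward_one <- function(model, img) {
  sp <- model$spec
  w <- model$weights
  p1 <- matrix(img[model$idx1], nrow(model$idx1))        # (o1^2) x k1^2
  z1 <- sweep(p1 %*% w$conv_w, 2, w$conv_b, `+`)
  a1 <- pmax(z1, 0)                                      # (o1^2) x F
  g2 <- nrow(model$idx2)
  k2sq <- ncol(model$idx2)
  p2 <- matrix(0, g2, k2sq * sp$conv_filters)            # cols: (q, f), f slow
  for (q in seq_len(k2sq)) {
    p2[, seq(q, by = k2sq, length.out = sp$conv_filters)] <- a1[model$idx2[, q], ]
  }
  z2 <- sweep(p2 %*% w$prim_w, 2, w$prim_b, `+`)         # g2 x (C*dp)
  u_arr <- array(z2, c(g2, sp$primary_dim, sp$primary_channels))  # [i, d, c]
  u <- matrix(aperm(u_arr, c(1, 3, 2)), g2 * sp$primary_channels,
              sp$primary_dim)                # rows: position i fastest, channel slow
  sq <- squash_rows(u)
  us <- sq$out
  n_pri <- nrow(us)
  dd <- sp$digit_dim
  uhat <- matrix(0, n_pri, sp$n_classes * dd)
  ch_of <- rep(seq_len(sp$primary_channels), each = g2)
  for (c in seq_len(sp$primary_channels)) {
    rows <- which(ch_of == c)
    uhat[rows, ] <- us[rows, , drop = FALSE] %*% w$digit_w[[c]]
  }
  uhat_arr <- array(uhat, c(n_pri, dd, sp$n_classes))
  rt <- dynamic_routing(aperm(uhat_arr, c(1, 3, 2)), r = sp$routing_iters)
  v <- rt$outputs                                        # n_classes x dd
  lengths <- sqrt(rowSums(v^2))
  list(lengths = lengths, v = v, couplings = rt$couplings, uhat = uhat,
       us = us, u = u, z2 = z2, p2 = p2, z1 = z1, p1 = p1, ch_of = ch_of)
}

# Backward pass for one sample given d(lengths); couplings treated as
# constants of the final routing iteration. Returns weight gradients.
caps_backward_one <- function(model, cache, dlengths) {
  dlengths <- as.numeric(dlengths)
  sp <- model$spec
  w <- model$weights
  dd <- sp$digit_dim
  v <- cache$v
  cmat <- cache$couplings
  n_pri <- nrow(cache$us)
  # through lengths and output squash
  duhat <- matrix(0, n_pri, sp$n_classes * dd)
  for (j in seq_len(sp$n_classes)) {
    len <- sqrt(sum(v[j, ]^2))
    dv <- if (len == 0) rep(0, dd) else dlengths[j] * v[j, ] / len
    # s_j = sum_i c_ij uhat_ij ; v_j = squash(s_j)
    cols <- ((j - 1) * dd + 1):(j * dd)
    s_j <- colSums(cmat[, j] * cache$uhat[, cols, drop = FALSE])
    ds <- squash_backprop(s_j, dv)
    duhat[, cols] <- outer(cmat[, j], ds)
  }
  # through digit transforms (shared per channel)
  dus <- matrix(0, n_pri, sp$primary_dim)
  d_digit <- vector("list", sp$primary_channels)
  for (c in seq_len(sp$primary_channels)) {
    rows <- which(cache$ch_of == c)
    d_digit[[c]] <- crossprod(cache$us[rows, , drop = FALSE],
                              duhat[rows, , drop = FALSE])
    dus[rows, ] <- duhat[rows, , drop = FALSE] %*% t(w$digit_w[[c]])
  }
  # through primary squash
  du <- t(vapply(seq_len(n_pri),
                 function(i) squash_backprop(cache$u[i, ], dus[i, ]),
                 numeric(sp$primary_dim)))
  g2 <- nrow(model$idx2)
  # rows of u were (position i fastest, channel slow): [i, c, d] -> [i, d, c]
  du_icd <- array(du, c(g2, sp$primary_channels, sp$primary_dim))
  dz2 <- matrix(aperm(du_icd, c(1, 3, 2)), g2,
                sp$primary_dim * sp$primary_channels)
  d_prim_w <- crossprod(cache$p2, dz2)
  d_prim_b <- colSums(dz2)
  dp2 <- dz2 %*% t(w$prim_w)
  # col2im back onto the stem activation
  k2sq <- ncol(model$idx2)
  da1 <- matrix(0, nrow(cache$z1), sp$conv_filters)
  for (q in seq_len(k2sq)) {
    cols <- seq(q, by = k2sq, length.out = sp$conv_filters)
    tgt <- model$idx2[, q]
    da1[tgt, ] <- da1[tgt, ] + dp2[, cols]
  }
  dz1 <- da1 * (cache$z1 > 0)
  list(conv_w = crossprod(cache$p1, dz1), conv_b = colSums(dz1),
       prim_w = d_prim_w, prim_b = d_prim_b, digit_w = d_digit)
}
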