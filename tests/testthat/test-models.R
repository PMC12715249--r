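# Capsule primitives, the model harness, and training behaviour.

test_that("squash has the documented norm profile", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(sqrt(sum(squash(c(1, 0))^2)), 0.5)
  expect_gt(sqrt(sum(squash(c(100, 0))^2)), 0.999)
  expect_lt(sqrt(sum(squash(c(100, 0))^2)), 1)
})

test_that("routing conserves coupling mass and honours symmetry", {
  set.seed(1)
  u <- array(stats::rnorm(5 * 3 * 4), c(5, 3, 4))
  for (r in 1:4) {
    st <- dynamic_routing(u, r)
    expect_equal(rowSums(st$couplings), rep(1, 5), tolerance = 1e-6)
    expect_true(all(sqrt(rowSums(st$outputs^2)) < 1))
  }
  # identical predictions for every output capsule leave couplings uniform
  u_sym <- u
  u_sym[, 2, ] <- u_sym[, 1, ]
  u_sym[, 3, ] <- u_sym[, 1, ]
  st <- dynamic_routing(u_sym, 3)
  expect_equal(st$couplings, matrix(1 / 3, 5, 3), tolerance = 1e-9)
  expect_error(dynamic_routing(array(NaN, c(2, 2, 2)), 2), "NaN")
})

test_that("one routing iteration equals the uniform-coupling hand computation", {
  # 2 primary capsules, 2 output capsules, 2 dims: oracle computed with
  # explicit loops
  u <- array(c(1, -1, 0.5, 2, 0, 1, 1, 0), c(2, 2, 2))
  st <- dynamic_routing(u, 1)
  for (j in 1:2) {
    s_j <- 0.5 * u[1, j, ] + 0.5 * u[2, j, ]
    n <- sqrt(sum(s_j^2))
    v_exp <- s_j * n / (1 + n^2)
    expect_equal(st$outputs[j, ], v_exp, tolerance = 1e-12)
  }
})

test_that("an aligned output capsule gains coupling between iterations", {
  # all primaries predict the same direction for capsule 1, noise elsewhere
  set.seed(2)
  u <- array(stats::rnorm(3 * 3 * 4, 0, 0.05), c(3, 3, 4))
  u[, 1, ] <- matrix(rep(c(2, 0, 0, 0), each = 3), 3)
  c1 <- dynamic_routing(u, 1)$couplings[, 1]   # uniform (pre-update)
  c2 <- dynamic_routing(u, 2)$couplings[, 1]   # after one agreement update
  expect_true(all(c2 > c1))
})

test_that("capsnet geometry validates and counts parameters correctly", {
  expect_error(capsnet_spec(input_side = 12), "too small")
  expect_error(capsnet_spec(input_side = 63), "remainder")
  sp <- capsnet_spec(input_side = 20, conv_filters = 8, conv_kernel = 5,
                     primary_channels = 4, primary_dim = 4, primary_kernel = 4,
                     primary_stride = 2, digit_dim = 6,
                     reconstruction = FALSE)
  m <- build_capsnet(sp, seed = 2)
  expect_identical(n_params(m), capsnet_params_count(sp))
  # the full-scale geometry lands within 15% of the published 8.2M figure
  full <- capsnet_spec(input_side = 512)
  expect_lt(abs(capsnet_params_count(full) - 8.2e6) / 8.2e6, 0.15)
})

test_that("capsnet forward emits per-class capsule lengths in [0, 1)", {
  sp <- capsnet_spec(input_side = 20, conv_filters = 8, conv_kernel = 5,
                     primary_channels = 4, primary_dim = 4, primary_kernel = 4,
                     primary_stride = 2, digit_dim = 6, reconstruction = FALSE)
  m <- build_capsnet(sp, seed = 2)
  set.seed(4)
  x <- array(stats::runif(20 * 20 * 5), c(20, 20, 5))
  sc <- predict_scores(m, x)
  expect_identical(dim(sc), c(5L, 3L))
  expect_true(all(sc >= 0 & sc < 1))
  expect_identical(sc, predict_scores(m, x))   # deterministic forward
})

test_that("baseline CNN emits simplex rows and learns separable data fast", {
  m <- build_baseline_cnn(32, seed = 1)
  set.seed(5)
  x <- array(stats::runif(32 * 32 * 6), c(32, 32, 6))
  sc <- predict_scores(m, x)
  expect_equal(rowSums(sc), rep(1, 6), tolerance = 1e-6)
  expect_identical(sc, predict_scores(m, x))
  d <- separable_images(60, seed = 1)
  fit <- train_model(m, d$x, d$y, loss = "ce",
                     config = training_config(max_epochs = 50, patience = 50,
                                              learning_rate = 0.01, seed = 7))
  acc <- mean(scores_to_labels(predict_scores(fit$model, d$x)) == d$y)
  expect_gt(acc, 0.9)
})

test_that("analytic gradients agree with central differences", {
  # CNN under each loss
  m <- build_baseline_cnn(32, seed = 2, n_filters = 3)
  set.seed(3)
  x <- array(stats::runif(32 * 32 * 4), c(32, 32, 4))
  y <- factor(c("CN", "MCI", "AD", "CN"), levels = diagnosis_levels())
  eps <- 1e-5
  for (loss in c("ce", "wce", "focal", "margin")) {
    lp <- demgrid:::resolve_loss_params(loss, NULL, y)
    fw <- demgrid:::model_forward(m, x)
    gr <- demgrid:::model_backward(m, x, fw,
                                   demgrid:::loss_and_grad(fw$scores, y, loss, lp))
    for (tgt in list(c("fc_w", 3, 2), c("conv_w", 7, 2))) {
      nm <- tgt[1]; i <- as.integer(tgt[2]); j <- as.integer(tgt[3])
      mm <- m
      mm$weights[[nm]][i, j] <- m$weights[[nm]][i, j] + eps
      l1 <- demgrid:::loss_and_grad(demgrid:::model_forward(mm, x)$scores, y, loss, lp)$loss
      mm$weights[[nm]][i, j] <- m$weights[[nm]][i, j] - eps
      l2 <- demgrid:::loss_and_grad(demgrid:::model_forward(mm, x)$scores, y, loss, lp)$loss
      expect_equal(gr[[nm]][i, j], (l1 - l2) / (2 * eps), tolerance = 1e-5)
    }
  }
  # capsnet with one routing iteration (couplings are exactly constant there,
  # so the routing-frozen gradient is exact)
  sp <- capsnet_spec(input_side = 20, conv_filters = 8, conv_kernel = 5,
                     primary_channels = 4, primary_dim = 4, primary_kernel = 4,
                     primary_stride = 2, digit_dim = 6, routing_iters = 1,
                     reconstruction = FALSE)
  mc <- build_capsnet(sp, seed = 2)
  set.seed(6)
  xc <- array(stats::runif(20 * 20 * 3), c(20, 20, 3))
  yc <- factor(diagnosis_levels(), levels = diagnosis_levels())
  lp <- margin_params()
  fw <- demgrid:::model_forward(mc, xc)
  gr <- demgrid:::model_backward(mc, xc, fw,
                                 demgrid:::loss_and_grad(fw$scores, yc, "margin", lp))
  for (tgt in list(c("conv_w", 3, 2), c("prim_w", 11, 5))) {
    nm <- tgt[1]; i <- as.integer(tgt[2]); j <- as.integer(tgt[3])
    mm <- mc
    mm$weights[[nm]][i, j] <- mc$weights[[nm]][i, j] + eps
    l1 <- demgrid:::loss_and_grad(demgrid:::model_forward(mm, xc)$scores, yc, "margin", lp)$loss
    mm$weights[[nm]][i, j] <- mc$weights[[nm]][i, j] - eps
    l2 <- demgrid:::loss_and_grad(demgrid:::model_forward(mm, xc)$scores, yc, "margin", lp)$loss
    expect_equal(gr[[nm]][i, j], (l1 - l2) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("the trainer honours patience, determinism and the leakage gate", {
  d <- separable_images(30, seed = 2)
  m <- build_baseline_cnn(32, seed = 1)
  cfg <- function(lr = 0.01, ...) training_config(learning_rate = lr, seed = 7, ...)
  # patience 0 stops after the first non-improving epoch
  fit0 <- train_model(m, d$x, d$y, loss = "ce",
                      config = cfg(max_epochs = 50, patience = 0, lr = 0.5))
  expect_lt(nrow(fit0$history), 50)
  # two runs with the same seed/config give identical histories
  f1 <- train_model(m, d$x, d$y, loss = "ce",
                    config = cfg(max_epochs = 8, patience = 8))
  f2 <- train_model(m, d$x, d$y, loss = "ce",
                    config = cfg(max_epochs = 8, patience = 8))
  expect_identical(f1$history, f2$history)
  # a memorizable 20-sample set is driven below 0.05 training loss
  d20 <- separable_images(20, seed = 3)
  fmem <- train_model(m, d20$x, d20$y, loss = "ce",
                      config = cfg(max_epochs = 120, patience = 120))
  expect_lt(min(fmem$history$train_loss), 0.05)
  # failing leakage report refuses to train
  bad <- structure(list(pass = FALSE, offenders = "P1"),
                   class = "leakage_report")
  expect_error(train_model(m, d$x, d$y, loss = "ce", leakage = bad),
               "leakage")
  # capsnet trains under the margin loss on a tiny memorisation set
  sp <- capsnet_spec(input_side = 32, conv_filters = 8, conv_kernel = 5,
                     primary_channels = 4, primary_dim = 4, primary_kernel = 4,
                     primary_stride = 2, digit_dim = 6, reconstruction = FALSE)
  mc <- build_capsnet(sp, seed = 2)
  d9 <- separable_images(9, seed = 4)
  fc <- train_model(mc, d9$x, d9$y, loss = "margin",
                    config = training_config(max_epochs = 60, patience = 60,
                                             learning_rate = 0.01,
                                             batch_size = 3, seed = 3))
  expect_gt(mean(scores_to_labels(predict_scores(fc$model, d9$x)) == d9$y),
            0.8)
})

test_that("the baseline CNN recovers diagnosis from synthetic cohorts well above chance", {
  d <- cohort_grid_features(300, seed = 11)
  split <- assign_splits(d$cohort$patients, seed = 42)
  tr <- d$cohort$scans$patient_id %in% split$train
  va <- d$cohort$scans$patient_id %in% split$validation
  te <- d$cohort$scans$patient_id %in% split$test
  m <- build_baseline_cnn(32, seed = 1)
  fit <- train_model(m, d$x[tr, ], d$y[tr], d$x[va, ], d$y[va], loss = "ce",
                     config = training_config(max_epochs = 40, patience = 15,
                                              learning_rate = 0.005, seed = 7))
  cm <- confusion_matrix(d$y[te],
                         scores_to_labels(predict_scores(fit$model, d$x[te, ])))
  macro_sens <- aggregate_metrics(cm)$macro$sensitivity
  expect_gte(macro_sens, 1 / 3 + 0.15)
})

test_that("combined mitigation does not hurt minority sensitivity across seeds", {
  sens_cn <- function(strategy, seed) {
    d <- cohort_grid_features(60, seed = seed)
    split <- assign_splits(d$cohort$patients, seed = 42)
    tr <- d$cohort$scans$patient_id %in% split$train
    ho <- !tr   # pooled validation + test for a stabler sensitivity estimate
    x_tr <- d$x[tr, ]; y_tr <- d$y[tr]
    if (strategy == "combined") {
      plan <- smote_plan(table(y_tr))
      k <- max(1, min(5, min(table(y_tr)) - 1))
      aug <- borderline_smote(x_tr, y_tr, plan, m_neighbors = 10,
                              k_neighbors = k, seed = seed)
      x_tr <- aug$features; y_tr <- aug$labels
      loss <- "focal"
    } else loss <- "ce"
    m <- build_baseline_cnn(32, seed = 1)
    fit <- train_model(m, x_tr, y_tr, d$x[tr, ], d$y[tr], loss = loss,
                       config = training_config(max_epochs = 12, patience = 12,
                                                learning_rate = 0.005,
                                                seed = seed))
    cm <- confusion_matrix(d$y[ho],
                           scores_to_labels(predict_scores(fit$model, d$x[ho, ])))
    per_class_metrics(cm)$sensitivity[1]
  }
  seeds <- c(101, 202, 303)
  base <- vapply(seeds, function(s) sens_cn("none", s), numeric(1))
  comb <- vapply(seeds, function(s) sens_cn("combined", s), numeric(1))
  expect_gte(mean(comb), mean(base))
})
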