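# Configuration-driven orchestration of the full analysis:
# generate -> preprocess -> split -> mitigate -> train -> evaluate.

#' Pipeline run configuration
#'
#' Layered defaults with overrides; every stochastic stage carries an explicit
#' seed. The configuration round-trips losslessly through serialisation and
#' its hash identifies the run.
#'
#' @param n_patients Cohort size; default 30.
#' @param cohort_seed Seed for cohort generation; default 42.
#' @param class_proportions Cohort class mix; default
#'   [default_class_proportions()].
#' @param scans_per_patient Scans per patient; default 1.
#' @param volume_shape Phantom lattice; default `c(96, 112, 96)` at 2 mm.
#' @param register Run affine registration to the template (`TRUE`) or treat
#'   phantoms as already template-aligned (`FALSE`, faster); default `TRUE`.
#' @param registration_subsample,registration_maxit Coarse registration
#'   controls passed to [spatial_normalization()].
#' @param offsets_mm Coronal grid offsets; default [grid_slice_offsets()].
#' @param ratios Split ratios; default `c(0.7, 0.2, 0.1)`.
#' @param split_seed Seed for the splitter; default 42.
#' @param arch Model architecture, `"cnn"` or `"capsnet"`.
#' @param loss Training loss, one of `"ce"`, `"wce"`, `"focal"`, `"margin"`.
#' @param mitigation One of `"none"`, `"smote"`, `"undersample"`,
#'   `"cost_sensitive"`, `"focal"`, `"combined"`. `cost_sensitive` and
#'   `focal` override `loss`; `combined` is SMOTE followed by focal-loss
#'   training.
#' @param model_side Side length the 512 grids are downsampled to for the
#'   model; default 32.
#' @param training A [training_config()].
#' @param out_dir Optional output directory for grids, reports and the
#'   manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_patients = 30, cohort_seed = 42,
                       class_proportions = default_class_proportions(),
                       scans_per_patient = 1,
                       volume_shape = c(96, 112, 96),
                       register = TRUE, registration_subsample = 3,
                       registration_maxit = 150,
                       offsets_mm = grid_slice_offsets(),
                       ratios = c(0.7, 0.2, 0.1), split_seed = 42,
                       arch = c("cnn", "capsnet"),
                       loss = c("ce", "wce", "focal", "margin"),
                       mitigation = c("none", "smote", "undersample",
                                      "cost_sensitive", "focal", "combined"),
                       model_side = 32,
                       training = training_config(max_epochs = 30,
                                                  patience = 10,
                                                  learning_rate = 0.003),
                       out_dir = NULL) {
  structure(list(n_patients = n_patients, cohort_seed = cohort_seed,
                 class_proportions = class_proportions,
                 scans_per_patient = scans_per_patient,
                 volume_shape = volume_shape,
                 register = register,
                 registration_subsample = registration_subsample,
                 registration_maxit = registration_maxit,
                 offsets_mm = offsets_mm, ratios = ratios,
                 split_seed = split_seed,
                 arch = match.arg(arch), loss = match.arg(loss),
                 mitigation = match.arg(mitigation),
                 model_side = model_side, training = training,
                 out_dir = out_dir),
            class = "run_config")
}

# Downsample a grid image to the model input side, scaled to [0, 1].
grid_to_feature <- function(grid, side) {
  as.vector(resize_bicubic(unclass(grid), side, side)) / 255
}

# Preprocess every scan of a cohort: QC -> extraction -> (registration) ->
# z-scoring -> reference histogram from the training split -> grids.
preprocess_cohort <- function(cohort, split, config, template = NULL) {
  if (config$register && is.null(template)) {
    template <- default_template(
      phantom_params(volume_shape = config$volume_shape, noise_sd = 0))
  }
  scans <- cohort$scans
  qc_rows <- list()
  zvols <- list()
  for (i in seq_len(nrow(scans))) {
    sid <- scans$scan_id[i]
    vol <- render_scan(cohort, sid)
    qc <- quality_control(vol)
    qc_rows[[sid]] <- data.frame(scan_id = sid, snr = qc$snr,
                                 motion_score = qc$motion_score,
                                 uniformity = qc$uniformity,
                                 quality_score = qc$quality_score,
                                 flag = qc$flag)
    if (qc$flag == "REJECT") next
    ext <- brain_extraction(vol)
    reg <- if (config$register) {
      spatial_normalization(ext$brain, template,
                            subsample = config$registration_subsample,
                            maxit = config$registration_maxit)$registered
    } else ext$brain
    zs <- wm_zscore(reg)
    zvols[[sid]] <- list(z = zs$z, mask = zs$mask, dims = dim(reg$data),
                         spacing = reg$spacing_mm, origin = reg$origin_voxel)
  }
  qc_table <- do.call(rbind, qc_rows)
  rownames(qc_table) <- NULL
  # reference histogram accumulated from the training-split scans of this run
  train_ids <- intersect(names(zvols),
                         scans$scan_id[scans$patient_id %in% split$train])
  ref_vals <- unlist(lapply(train_ids, function(sid) {
    z <- zvols[[sid]]$z
    if (length(z) > 5000) z[seq(1, length(z), length.out = 5000)] else z
  }))
  reference <- if (length(ref_vals) > 0) reference_histogram(ref_vals) else NULL
  grids <- list()
  for (sid in names(zvols)) {
    i <- match(sid, scans$scan_id)
    zv <- zvols[[sid]]
    norm <- finalize_intensity(zv$z, zv$mask, zv$dims, zv$spacing, zv$origin,
                               reference = reference)
    grids[[sid]] <- construct_grid(norm, offsets_mm = config$offsets_mm,
                                   scan_id = sid,
                                   patient_id = scans$patient_id[i],
                                   diagnosis = as.character(scans$diagnosis[i]))
  }
  list(qc = qc_table, grids = grids, reference = reference)
}

# Assemble model-ready features for a set of scan ids.
collect_features <- function(grids, ids, side) {
  feats <- t(vapply(ids, function(sid) grid_to_feature(grids[[sid]], side),
                    numeric(side^2)))
  rownames(feats) <- ids
  feats
}

# Apply the configured mitigation strategy to the training features/labels
# and resolve the effective loss + parameters.
apply_mitigation <- function(strategy, loss, x_train, y_train, seed) {
  counts <- table(y_train)
  out <- list(x = x_train, y = y_train, loss = loss, loss_params = NULL)
  if (strategy %in% c("smote", "combined")) {
    plan <- smote_plan(counts)
    k <- max(1, min(5, min(counts) - 1))
    m <- min(10, length(y_train) - 1)
    aug <- borderline_smote(x_train, y_train, plan, m_neighbors = m,
                            k_neighbors = k, seed = seed)
    out$x <- aug$features
    out$y <- aug$labels
  }
  if (strategy == "undersample") {
    plan <- undersample_plan(counts)
    red <- random_undersample(x_train, y_train, plan, seed = seed)
    out$x <- red$features
    out$y <- red$labels
  }
  if (strategy == "cost_sensitive") {
    out$loss <- "wce"
    out$loss_params <- list(weights = class_weights(counts))
  }
  if (strategy == "focal") {
    out$loss <- "focal"
    out$loss_params <- focal_params()
  }
  if (strategy == "combined") {
    # resample first, then focus the loss on hard examples during training
    out$loss <- "focal"
    out$loss_params <- focal_params()
  }
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Generates the synthetic cohort, preprocesses every scan (QC, extraction,
#' optional registration, intensity normalisation, grid construction), splits
#' patients 70/20/10 with stratification, verifies leakage (refusing to train
#' on failure), applies the configured mitigation, trains the model and
#' evaluates on the held-out test split. The returned manifest contains the
#' configuration, its hash, all stage outputs and a deterministic output hash.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-generated cohort (must match the config's
#'   cohort parameters); generated when `NULL`.
#' @param split_override Optional [assign_splits()]-like object replacing the
#'   computed split (used to exercise the leakage gate).
#' @param pre Optional cached preprocessing result from an earlier run on the
#'   same cohort, split and preprocessing options (used when comparing
#'   training strategies on identical inputs).
#' @return Object of class `run_manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL, split_override = NULL,
                         pre = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    spec <- cohort_spec(config$n_patients,
                        class_proportions = config$class_proportions,
                        scans_per_patient = config$scans_per_patient,
                        base_params = phantom_params(volume_shape = config$volume_shape),
                        seed = config$cohort_seed)
    cohort <- generate_cohort(spec, keep_volumes = FALSE)
  }
  split <- if (is.null(split_override)) {
    assign_splits(cohort$patients, ratios = config$ratios,
                  seed = config$split_seed)
  } else split_override
  leakage <- verify_no_leakage(split, cohort$scans)
  if (!leakage$pass) {
    stop(sprintf("pipeline aborted at stage 'leakage gate': offending patients %s",
                 paste(leakage$offenders, collapse = ", ")), call. = FALSE)
  }
  if (is.null(pre)) pre <- preprocess_cohort(cohort, split, config)
  kept <- names(pre$grids)
  scans <- cohort$scans[cohort$scans$scan_id %in% kept, ]
  scans$split <- split_of(split, scans$patient_id)
  side <- config$model_side

  ids <- function(s) scans$scan_id[scans$split == s]
  for (s in c("train", "validation", "test")) {
    if (length(ids(s)) == 0) {
      stop(sprintf("pipeline aborted at stage 'split': %s split is empty (increase n_patients)",
                   s), call. = FALSE)
    }
  }
  labs <- function(id) factor(scans$diagnosis[match(id, scans$scan_id)],
                              levels = diagnosis_levels())
  x_train <- collect_features(pre$grids, ids("train"), side)
  x_val <- collect_features(pre$grids, ids("validation"), side)
  x_test <- collect_features(pre$grids, ids("test"), side)
  y_train <- labs(ids("train")); y_val <- labs(ids("validation"))
  y_test <- labs(ids("test"))

  mit <- apply_mitigation(config$mitigation, config$loss, x_train, y_train,
                          seed = config$training$seed)
  model <- if (config$arch == "cnn") {
    build_baseline_cnn(side, seed = config$training$seed)
  } else {
    build_capsnet(capsnet_spec(input_side = side, conv_filters = 32,
                               reconstruction = FALSE),
                  seed = config$training$seed)
  }
  fit <- train_model(model, mit$x, mit$y, x_val, y_val, loss = mit$loss,
                     loss_params = mit$loss_params, config = config$training,
                     leakage = leakage)
  scores <- predict_scores(fit$model, x_test)
  report <- metric_report(y_test, scores_to_labels(scores), scores)

  summary_tab <- split_summary(split, cohort)
  manifest <- structure(list(
    config = config,
    config_hash = object_hash(config),
    qc = pre$qc,
    split = split,
    leakage = leakage,
    split_summary = summary_tab,
    n_trained = length(mit$y),
    best_epoch = fit$best_epoch,
    history = fit$history,
    report = report,
    model = fit$model,
    hash = object_hash(list(config, pre$qc, split$train, split$validation,
                            split$test, report$confusion,
                            report$balanced_accuracy))),
    class = "run_manifest")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in kept) write_grid_png(pre$grids[[sid]], config$out_dir)
    utils::write.csv(pre$qc, file.path(config$out_dir, "qc.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(config$out_dir, "split_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = manifest$config_hash, hash = manifest$hash,
           balanced_accuracy = report$balanced_accuracy,
           accuracy = report$accuracy),
      file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d patients, arch %s, mitigation %s\n",
              x$config$n_patients, x$config$arch, x$config$mitigation))
  cat(sprintf("  hash %s | balanced accuracy %d%%\n", substr(x$hash, 1, 8),
              as_percent(x$report$balanced_accuracy)))
  invisible(x)
}

#' Compare mitigation strategies on one cohort and split
#'
#' Trains one model per strategy on the identical split and seed and tabulates
#' balanced accuracy, macro AUC-PR, bias index and per-class sensitivities —
#' the layout used for mitigation comparison tables.
#'
#' @param config A [run_config()]; its `mitigation` field is ignored.
#' @param strategies Character vector of >= 2 strategies.
#' @return Data frame with one row per strategy.
#' @export
run_mitigation_experiment <- function(config,
                                      strategies = c("none", "combined")) {
  stopifnot(length(strategies) >= 2)
  spec <- cohort_spec(config$n_patients,
                      class_proportions = config$class_proportions,
                      scans_per_patient = config$scans_per_patient,
                      base_params = phantom_params(volume_shape = config$volume_shape),
                      seed = config$cohort_seed)
  cohort <- generate_cohort(spec, keep_volumes = FALSE)
  split <- assign_splits(cohort$patients, ratios = config$ratios,
                         seed = config$split_seed)
  pre <- preprocess_cohort(cohort, split, config)
  rows <- lapply(strategies, function(s) {
    cfg <- config
    cfg$mitigation <- s
    man <- run_pipeline(cfg, cohort = cohort, pre = pre)
    r <- man$report
    pc <- r$per_class
    data.frame(strategy = s,
               balanced_acc = as_percent(r$balanced_accuracy),
               auc_pr = round(r$auc_pr_macro, 2),
               bias_index = round(r$bias_index, 2),
               sens_CN = as_percent(pc$sensitivity[pc$class == "CN"]),
               sens_MCI = as_percent(pc$sensitivity[pc$class == "MCI"]),
               sens_AD = as_percent(pc$sensitivity[pc$class == "AD"]))
  })
  do.call(rbind, rows)
}
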