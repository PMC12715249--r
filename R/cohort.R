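#' Default per-class phantom effects
#'
#' Class-graded structural effects: hippocampal shrinkage and ventricular
#' enlargement increase from CN through MCI to AD. The magnitudes (linear
#' scales 1.00/0.85/0.70 for the hippocampus and 1.00/1.15/1.30 for the
#' ventricles) are chosen large enough that a small classifier can beat chance
#' on desk-scale cohorts; they are configuration, not estimates.
#'
#' @return Named list of per-diagnosis parameter overrides.
#' @export
default_class_effects <- function() {
  list(CN  = list(hippocampus_scale = 1.00, ventricle_scale = 1.00),
       MCI = list(hippocampus_scale = 0.85, ventricle_scale = 1.15),
       AD  = list(hippocampus_scale = 0.70, ventricle_scale = 1.30))
}

#' Default cohort class proportions
#'
#' Three-class prevalence matching the clinical composition used throughout the
#' package: 22.5\% CN, 34.1\% MCI, 43.3\% AD, taken as the exact image-count
#' fractions (3385, 5110, 6488) / 14983 so they sum to one.
#'
#' @return Named numeric 3-vector over (CN, MCI, AD).
#' @export
default_class_proportions <- function() {
  p <- c(CN = 3385, MCI = 5110, AD = 6488) / 14983
  p
}

#' Cohort generation specification
#'
#' @param n_patients Positive integer, >= 3 (at least one patient per class
#'   after apportionment).
#' @param class_proportions Named 3-vector over (CN, MCI, AD) summing to 1
#'   within 1e-9.
#' @param scans_per_patient Positive integer; every scan of a patient is
#'   rendered with the same diagnosis effects but an independent noise draw.
#' @param class_effect_table Per-diagnosis [phantom_params()] overrides.
#' @param base_params Baseline [phantom_params()] shared by all classes.
#' @param seed Integer master seed; generation is bit-reproducible for a fixed
#'   spec and seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        class_proportions = default_class_proportions(),
                        scans_per_patient = 1,
                        class_effect_table = default_class_effects(),
                        base_params = phantom_params(),
                        seed = 42) {
  stopifnot(n_patients == round(n_patients), n_patients >= 3,
            scans_per_patient >= 1, scans_per_patient == round(scans_per_patient))
  class_proportions <- as.numeric(class_proportions)
  if (length(class_proportions) != 3 || any(class_proportions < 0)) {
    stop("class_proportions must be a nonnegative 3-vector", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 within 1e-9", call. = FALSE)
  }
  names(class_proportions) <- diagnosis_levels()
  stopifnot(inherits(base_params, "phantom_params"))
  stopifnot(all(diagnosis_levels() %in% names(class_effect_table)))
  structure(list(n_patients = as.integer(n_patients),
                 class_proportions = class_proportions,
                 scans_per_patient = as.integer(scans_per_patient),
                 class_effect_table = class_effect_table,
                 base_params = base_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Age-group stratum of an age
#'
#' Deterministic banding used for stratified splitting: `<70`, `70-80`
#' (inclusive at both ends), `>80`.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor over `c("<70", "70-80", ">80")`.
#' @export
age_group <- function(age) {
  stopifnot(all(age > 0))
  g <- ifelse(age < 70, "<70", ifelse(age <= 80, "70-80", ">80"))
  factor(g, levels = c("<70", "70-80", ">80"))
}

# Phantom parameters for one diagnosis: base overridden by the class effects.
class_params <- function(spec, diagnosis) {
  p <- unclass(spec$base_params)
  for (nm in names(spec$class_effect_table[[diagnosis]])) {
    p[[nm]] <- spec$class_effect_table[[diagnosis]][[nm]]
  }
  do.call(phantom_params, p)
}

#' Generate a synthetic patient cohort
#'
#' Draws patient demographics and renders one phantom volume per scan.
#' Per-class patient counts follow largest-remainder apportionment of
#' `n_patients` by the class proportions. Ages are class-conditional normals
#' (CN 72, MCI 74, AD 77, sd 6), sex is Bernoulli(0.5), and each patient is
#' assigned one of three scanner identifiers — demographics exist so that the
#' stratified splitter has non-degenerate strata.
#'
#' Every scan's volume is rendered under a seed derived deterministically from
#' the spec seed and the scan index, so identical spec + seed reproduce
#' byte-identical volumes, whether rendered eagerly or on demand via
#' [render_scan()].
#'
#' @param spec A [cohort_spec()].
#' @param keep_volumes If `TRUE` (default) all volumes are rendered eagerly and
#'   returned in `$volumes`; with `FALSE` only metadata is generated and
#'   volumes are rendered lazily by [render_scan()] (recommended for cohorts of
#'   hundreds of patients).
#' @return An object of class `demgrid_cohort`: `patients` (data frame with
#'   patient_id, diagnosis, age, age_group, sex, scanner_id), `scans` (scan_id,
#'   patient_id, diagnosis, scan_seed), `volumes` (named list, possibly empty),
#'   and the `spec`.
#' @export
generate_cohort <- function(spec, keep_volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- apportion_largest_remainder(spec$n_patients, spec$class_proportions)
  if (any(counts == 0)) {
    # n >= 3 guarantees this cannot happen for non-degenerate proportions,
    # but guard against proportion vectors with a zero entry
    counts <- pmax(counts, 0L)
  }
  diagnosis <- rep(diagnosis_levels(), counts)
  n <- spec$n_patients
  set.seed(derive_seed(spec$seed, 1))
  age_mean <- c(CN = 72, MCI = 74, AD = 77)[diagnosis]
  age <- pmax(45, pmin(95, stats::rnorm(n, age_mean, 6)))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  scanner <- sample(sprintf("SC%02d", 1:3), n, replace = TRUE)
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    diagnosis = factor(diagnosis, levels = diagnosis_levels()),
    age = age,
    age_group = age_group(age),
    sex = factor(sex, levels = c("F", "M")),
    scanner_id = scanner,
    stringsAsFactors = FALSE)

  scans <- data.frame(
    scan_id = sprintf("%s_S%02d", rep(patients$patient_id, each = spec$scans_per_patient),
                      rep(seq_len(spec$scans_per_patient), times = n)),
    patient_id = rep(patients$patient_id, each = spec$scans_per_patient),
    diagnosis = rep(patients$diagnosis, each = spec$scans_per_patient),
    stringsAsFactors = FALSE)
  scans$scan_seed <- vapply(seq_len(nrow(scans)),
                            function(i) derive_seed(spec$seed, 1000L + i),
                            integer(1))
  stopifnot(!anyDuplicated(scans$scan_id))

  cohort <- structure(list(patients = patients, scans = scans,
                           volumes = list(), spec = spec),
                      class = "demgrid_cohort")
  if (keep_volumes) {
    vols <- lapply(seq_len(nrow(scans)), function(i) {
      render_phantom(class_params(spec, as.character(scans$diagnosis[i])),
                     seed = scans$scan_seed[i])
    })
    names(vols) <- scans$scan_id
    cohort$volumes <- vols
  }
  cohort
}

#' Render (or fetch) one scan of a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param scan_id Scan identifier.
#' @return The scan's [brain_volume()], identical to the eagerly rendered one.
#' @export
render_scan <- function(cohort, scan_id) {
  stopifnot(inherits(cohort, "demgrid_cohort"))
  if (!is.null(cohort$volumes[[scan_id]])) return(cohort$volumes[[scan_id]])
  i <- match(scan_id, cohort$scans$scan_id)
  if (is.na(i)) stop(sprintf("unknown scan_id '%s'", scan_id), call. = FALSE)
  render_phantom(class_params(cohort$spec, as.character(cohort$scans$diagnosis[i])),
                 seed = cohort$scans$scan_seed[i])
}

#' @export
print.demgrid_cohort <- function(x, ...) {
  tab <- table(x$patients$diagnosis)
  cat(sprintf("<demgrid_cohort> %d patients (%s), %d scans, seed %d\n",
              nrow(x$patients),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$scans), x$spec$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Volumes as NIfTI-1 (`<scan_id>.nii.gz`) and metadata as CSV with columns
#' patient_id, scan_id, diagnosis, age, age_group, sex, scanner_id.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return The metadata CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- merge(cohort$scans[, c("scan_id", "patient_id", "diagnosis")],
                cohort$patients, by = "patient_id", sort = FALSE)
  meta <- meta[, c("patient_id", "scan_id", "diagnosis.x", "age", "age_group",
                   "sex", "scanner_id")]
  names(meta)[3] <- "diagnosis"
  for (sid in cohort$scans$scan_id) {
    write_brain_volume(render_scan(cohort, sid),
                       file.path(dir, paste0(sid, ".nii.gz")))
  }
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}
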