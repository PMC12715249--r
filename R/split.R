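# Patient-level, stratified, seeded splitting with machine-checked leakage
# prevention. All scans of a patient follow the patient, so longitudinal
# sessions can never straddle a split boundary.

#' Assign patients to train/validation/test splits
#'
#' Patients are stratified by (diagnosis, age group, sex); strata with fewer
#' than 3 patients are merged into the largest stratum of the same diagnosis
#' (pooling age/sex) so apportionment stays meaningful. Within each stratum,
#' patients are sorted lexicographically by id (input-order invariance),
#' shuffled with the seed, and apportioned to the three splits by largest
#' remainder on patient counts.
#'
#' @param patients Data frame with columns `patient_id`, `diagnosis`,
#'   `age_group`, `sex` (a [generate_cohort()] result is also accepted).
#' @param ratios Numeric 3-vector (train, validation, test) summing to 1;
#'   default `c(0.7, 0.2, 0.1)`.
#' @param seed Integer seed; default 42. Fixed seed implies an identical
#'   split.
#' @return An object of class `cohort_split`: `train`, `validation`, `test`
#'   (disjoint character vectors of patient ids), `ratios`, `seed`,
#'   `stratum_table` (per-stratum, per-split patient counts).
#' @export
assign_splits <- function(patients, ratios = c(0.7, 0.2, 0.1), seed = 42) {
  if (inherits(patients, "demgrid_cohort")) patients <- patients$patients
  stopifnot(is.data.frame(patients), nrow(patients) >= 1,
            all(c("patient_id", "diagnosis", "age_group", "sex") %in% names(patients)))
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be a nonnegative 3-vector summing to 1", call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id", call. = FALSE)
  }
  key <- paste(patients$diagnosis, patients$age_group, patients$sex, sep = "|")
  if (length(unique(key)) == 0) stop("empty stratum set", call. = FALSE)
  # merge small strata into the largest stratum of the same diagnosis
  tab <- table(key)
  small <- names(tab)[tab < 3]
  if (length(small) > 0) {
    for (s in small) {
      dg <- strsplit(s, "|", fixed = TRUE)[[1]][1]
      same_dg <- grep(paste0("^", dg, "\\|"), names(tab), value = TRUE)
      big <- same_dg[which.max(tab[same_dg])]
      if (big == s) {                       # whole diagnosis is small: pool it
        big <- paste0(dg, "|pooled|pooled")
      }
      key[key == s] <- big
      tab <- table(key)
    }
  }
  strata <- sort(unique(key))
  set.seed(derive_seed(seed, 7))
  assign <- character(nrow(patients))
  names(assign) <- patients$patient_id
  rows <- list()
  for (s in strata) {
    ids <- sort(patients$patient_id[key == s])
    ids <- ids[sample.int(length(ids))]
    counts <- apportion_largest_remainder(length(ids), ratios)
    splits <- rep(c("train", "validation", "test"), counts)
    assign[ids] <- splits
    rows[[s]] <- data.frame(stratum = s, train = counts[1],
                            validation = counts[2], test = counts[3],
                            row.names = NULL)
  }
  structure(list(train = sort(names(assign)[assign == "train"]),
                 validation = sort(names(assign)[assign == "validation"]),
                 test = sort(names(assign)[assign == "test"]),
                 ratios = ratios, seed = as.integer(seed),
                 stratum_table = do.call(rbind, rows)),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> train %d / validation %d / test %d patients (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

# Split membership lookup for a set of patient ids.
split_of <- function(split, patient_id) {
  out <- rep(NA_character_, length(patient_id))
  out[patient_id %in% split$train] <- "train"
  out[patient_id %in% split$validation] <- "validation"
  out[patient_id %in% split$test] <- "test"
  out
}

#' Verify absence of patient-level leakage
#'
#' Passes iff the three patient sets are pairwise disjoint and no patient's
#' scans appear in more than one split. `scan_table` may carry an explicit
#' per-scan `split` column (e.g. a manually edited assignment); otherwise
#' scans inherit their patient's split.
#'
#' @param split A [assign_splits()] result.
#' @param scan_table Data frame with columns `scan_id`, `patient_id` and
#'   optionally `split`.
#' @return Object of class `leakage_report`: `pass` (logical) and `offenders`
#'   (character vector of offending patient ids).
#' @export
verify_no_leakage <- function(split, scan_table) {
  stopifnot(inherits(split, "cohort_split"),
            all(c("scan_id", "patient_id") %in% names(scan_table)))
  known <- c(split$train, split$validation, split$test)
  orphan <- setdiff(scan_table$patient_id, known)
  if (length(orphan) > 0) {
    stop(sprintf("scan(s) map to unknown patient(s): %s",
                 paste(utils::head(orphan, 5), collapse = ", ")), call. = FALSE)
  }
  # patient sets must be pairwise disjoint before any scan-level check
  dup <- c(intersect(split$train, split$validation),
           intersect(split$train, split$test),
           intersect(split$validation, split$test))
  if (length(dup) > 0) {
    return(structure(list(pass = FALSE, offenders = sort(unique(dup))),
                     class = "leakage_report"))
  }
  scan_split <- if ("split" %in% names(scan_table)) scan_table$split
                else split_of(split, scan_table$patient_id)
  nsplits <- tapply(scan_split, scan_table$patient_id,
                    function(s) length(unique(s)))
  offenders <- names(nsplits)[nsplits > 1]
  structure(list(pass = length(offenders) == 0, offenders = sort(offenders)),
            class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  if (x$pass) {
    cat("<leakage_report> PASS: splits are patient-disjoint\n")
  } else {
    cat(sprintf("<leakage_report> FAIL: %d offending patient(s): %s\n",
                length(x$offenders),
                paste(utils::head(x$offenders, 10), collapse = ", ")))
  }
  invisible(x)
}

#' Per-split composition summary
#'
#' @param split A [assign_splits()] result.
#' @param cohort A [generate_cohort()] result (or a list with `patients` and
#'   `scans` data frames).
#' @param file Optional CSV path to write the table to.
#' @return Data frame with per-split patient and image counts and class
#'   percentages.
#' @export
split_summary <- function(split, cohort, file = NULL) {
  stopifnot(inherits(split, "cohort_split"))
  pats <- cohort$patients
  scans <- cohort$scans
  pats$split <- split_of(split, pats$patient_id)
  scans$split <- split_of(split, scans$patient_id)
  out <- lapply(c("train", "validation", "test"), function(s) {
    ps <- pats[pats$split == s, ]
    ss <- scans[scans$split == s, ]
    cls <- table(factor(ss$diagnosis, levels = diagnosis_levels()))
    data.frame(split = s, n_patients = nrow(ps), n_images = nrow(ss),
               pct_CN = as_percent(cls[["CN"]] / max(1, nrow(ss))),
               pct_MCI = as_percent(cls[["MCI"]] / max(1, nrow(ss))),
               pct_AD = as_percent(cls[["AD"]] / max(1, nrow(ss))))
  })
  out <- do.call(rbind, out)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
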