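#' @keywords internal
"_PACKAGE"

#' Diagnostic class labels
#'
#' The three diagnostic classes, in canonical (ordinal) order: cognitively
#' normal, mild cognitive impairment, Alzheimer's disease. All label vectors in
#' the package are factors over these levels; the ordinal coding used by
#' [ordinal_mse()] is CN = 0, MCI = 1, AD = 2.
#'
#' @return Character vector `c("CN", "MCI", "AD")`.
#' @export
diagnosis_levels <- function() c("CN", "MCI", "AD")

# Coerce labels to a factor over the canonical class levels, erroring on
# anything unknown.
as_diagnosis <- function(x, arg = "labels") {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), diagnosis_levels())
  if (length(bad) > 0) {
    stop(sprintf("unknown label(s) in %s: %s", arg, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  factor(x, levels = diagnosis_levels())
}

# Round half away from zero (the convention used for all printed percentages;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Fraction -> integer percent, half away from zero.
as_percent <- function(x) round_half_up(100 * x)

#' Largest-remainder apportionment
#'
#' Distributes `n` integer units across categories proportionally to
#' `proportions` using the largest-remainder (Hamilton) method: each category
#' receives the floor of its quota `n * p`, and the remaining units go to the
#' categories with the largest fractional remainders (ties broken by category
#' order).
#'
#' @param n Positive integer total.
#' @param proportions Nonnegative numeric vector summing to 1 (within 1e-9).
#' @return Integer vector of counts summing to `n`, same names as
#'   `proportions`.
#' @export
apportion_largest_remainder <- function(n, proportions) {
  stopifnot(length(n) == 1, n >= 0, n == round(n))
  if (any(proportions < 0)) stop("proportions must be nonnegative", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  quota <- n * proportions
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    rem <- quota - base
    # order(): ties resolved by index order
    extra <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(proportions)
  counts
}

# Derive a stream-specific 32-bit seed from a master seed and integer tags.
# Keeps every stochastic component independently and reproducibly seeded.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 48271 + as.double(t) * 16807 + 11) %% 2147483647
  }
  as.integer(s)
}

# Softmax over the rows of a matrix.
softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Deterministic hash of an R object (used for run manifests).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
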