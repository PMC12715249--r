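# Five-stage structural preprocessing: quality control, brain extraction,
# affine spatial normalisation, intensity normalisation, and 10-slice coronal
# grid construction.

robust_range <- function(v) stats::quantile(v, c(0.02, 0.98), names = FALSE)

# Foreground mask by robust fractional threshold (BET-like behaviour:
# threshold at robust_min + frac * (robust_max - robust_min)).
fractional_mask <- function(v, frac) {
  r <- robust_range(v)
  v >= r[1] + frac * (r[2] - r[1])
}

# Nyquist-ghost motion estimator. A replica shifted by half the field of view
# along the phase axis scales even/odd spatial-frequency lines by (1 +/- a);
# the even/odd magnitude disparity therefore estimates the replica amplitude
# directly, independent of any background segmentation.
motion_score_spectral <- function(v) {
  d <- dim(v)
  m <- aperm(v, c(2, 1, 3))
  dim(m) <- c(d[2], d[1] * d[3])
  M <- rowMeans(Mod(stats::mvfft(m)))          # M[i] is |F| at k = i - 1
  n <- d[2]
  ks <- seq(3, max(4, floor(n / 4)), by = 2)   # odd k (0-based), mid band
  ks <- ks[ks + 2 <= n - 1]
  if (length(ks) < 3) return(0)
  odd <- M[ks + 1]
  even <- sqrt(M[ks] * M[ks + 2])              # geometric mean of neighbours
  est <- (even - odd) / (even + odd)
  clip01(stats::median(est))
}

#' Quality scoring rule
#'
#' The acceptance rule applied by [quality_control()]: reject when SNR < 20 or
#' motion score > 0.3 (score 0); otherwise
#' `0.4 * min(snr, 40)/40 + 0.3 * (1 - motion) + 0.3 * uniformity`.
#'
#' @param snr Nonnegative signal-to-noise ratio (raw, unbounded).
#' @param motion_score,uniformity Scores in \[0, 1\].
#' @return List with `flag` (`"ACCEPT"`/`"REJECT"`) and `quality_score`.
#' @export
quality_score <- function(snr, motion_score, uniformity) {
  stopifnot(snr >= 0, motion_score >= 0, motion_score <= 1,
            uniformity >= 0, uniformity <= 1)
  if (snr < 20 || motion_score > 0.3) {
    return(list(flag = "REJECT", quality_score = 0))
  }
  list(flag = "ACCEPT",
       quality_score = 0.4 * min(snr, 40) / 40 + 0.3 * (1 - motion_score) +
         0.3 * uniformity)
}

#' Quality control assessment
#'
#' Computes signal-to-noise ratio (mean foreground over background standard
#' deviation), a motion-ghost score in \[0, 1\] (spectral Nyquist-ghost
#' estimator), and an intensity-uniformity score
#' `1 - IQR/median` of the low-pass-filtered foreground. A scan is rejected
#' when SNR < 20 or motion score > 0.3, in which case the quality score is 0;
#' otherwise the quality score is
#' `0.4 * min(snr, 40)/40 + 0.3 * (1 - motion) + 0.3 * uniformity`.
#' Raw SNR is unbounded, so it enters the weighted score normalised by 40 —
#' twice the rejection threshold, which thus maps to 0.5.
#'
#' @param volume A [brain_volume()].
#' @return An object of class `qc_report` with fields `snr`, `motion_score`,
#'   `uniformity`, `quality_score`, `flag`.
#' @export
quality_control <- function(volume) {
  stopifnot(inherits(volume, "brain_volume"))
  v <- volume$data
  if (all(v == 0)) stop("empty volume", call. = FALSE)
  fg <- fractional_mask(v, 0.2)
  if (!any(fg) || all(fg)) stop("degenerate foreground segmentation", call. = FALSE)
  bg_sd <- stats::sd(v[!fg])
  snr <- if (bg_sd == 0) Inf else mean(v[fg]) / bg_sd
  motion <- motion_score_spectral(v)
  s <- box_smooth3(v, 2)
  sf <- s[fg]
  uniformity <- clip01(1 - stats::IQR(sf) / max(stats::median(sf), .Machine$double.eps))
  qs <- quality_score(min(snr, .Machine$double.xmax), motion, uniformity)
  structure(list(snr = snr, motion_score = motion, uniformity = uniformity,
                 quality_score = qs$quality_score, flag = qs$flag),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s | snr %.1f, motion %.3f, uniformity %.3f, quality %.3f\n",
              x$flag, x$snr, x$motion_score, x$uniformity, x$quality_score))
  invisible(x)
}

#' Brain extraction
#'
#' Skull-stripping stand-in: thresholds at
#' `robust_min + fractional_intensity * (robust_max - robust_min)` (2nd/98th
#' percentile robust range), keeps the largest 6-connected component, applies a
#' 3x3x3 morphological closing, fills interior holes, and multiplies the input
#' by a gradient-weighted soft mask (the binary mask box-smoothed once) so
#' edges fall off smoothly. Background voxels are exactly 0.
#'
#' @param volume A [brain_volume()] that passed QC.
#' @param fractional_intensity Fractional threshold, default 0.3.
#' @return List with `brain` (masked [brain_volume()]) and `mask` (logical
#'   array).
#' @export
brain_extraction <- function(volume, fractional_intensity = 0.3) {
  stopifnot(inherits(volume, "brain_volume"))
  v <- volume$data
  mask <- fractional_mask(v, fractional_intensity)
  if (!any(mask)) stop("extraction failed: empty mask", call. = FALSE)
  mask <- largest_component3(mask)
  mask <- close3(mask, 1)
  mask <- fill_holes3(mask)
  if (!any(mask)) stop("extraction failed: empty mask", call. = FALSE)
  soft <- box_smooth3(mask * 1, 1)
  soft[!mask & soft < 0.5] <- 0      # keep a thin soft rim just inside the mask
  brain <- v * soft
  brain[!mask] <- 0
  list(brain = brain_volume(brain, spacing_mm = volume$spacing_mm,
                            origin_voxel = volume$origin_voxel,
                            labels = volume$labels),
       mask = mask)
}

# --- affine registration ----------------------------------------------------

# Rotation matrix from xyz Euler angles (radians).
rot3 <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# 12-parameter vector -> 3x3 linear part + translation.
# p = (tx, ty, tz, rx, ry, rz, sx, sy, sz, hxy, hxz, hyz)
affine_from_params <- function(p) {
  Sh <- diag(3)
  Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  A <- rot3(p[4:6]) %*% Sh %*% diag(p[7:9])
  list(A = A, t = p[1:3])
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based, matrix n x 3). Out-of-bounds samples return `fill`.
trilinear <- function(v, pts, fill = 0) {
  d <- dim(v)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  id <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  out[ok] <-
    v[id(x0,     y0,     z0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
    v[id(x0 + 1, y0,     z0)]     * fx       * (1 - fy) * (1 - fz) +
    v[id(x0,     y0 + 1, z0)]     * (1 - fx) * fy       * (1 - fz) +
    v[id(x0 + 1, y0 + 1, z0)]     * fx       * fy       * (1 - fz) +
    v[id(x0,     y0,     z0 + 1)] * (1 - fx) * (1 - fy) * fz +
    v[id(x0 + 1, y0,     z0 + 1)] * fx       * (1 - fy) * fz +
    v[id(x0,     y0 + 1, z0 + 1)] * (1 - fx) * fy       * fz +
    v[id(x0 + 1, y0 + 1, z0 + 1)] * fx       * fy       * fz
  out
}

# mm coordinates (relative to origin) of every voxel centre on a grid.
grid_mm <- function(dims, spacing, origin, step = 1) {
  ix <- seq(1, dims[1], by = step)
  iy <- seq(1, dims[2], by = step)
  iz <- seq(1, dims[3], by = step)
  g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  sweep(sweep(g, 2, origin), 2, spacing, `*`)
}

# Correlation ratio of mov intensities conditional on binned ref intensities:
# 1 - sum_k n_k var_k / (N var). Returned as a cost (1 - eta^2, lower better).
corratio_cost <- function(ref_bin, mov, nbins) {
  tot <- stats::var(mov)
  if (!is.finite(tot) || tot == 0) return(1)
  n_k <- tabulate(ref_bin, nbins)
  s_k <- vapply(split(mov, ref_bin), stats::var, numeric(1))
  s_k[is.na(s_k)] <- 0
  keep <- n_k[as.integer(names(s_k))] > 1
  within <- sum(n_k[as.integer(names(s_k))][keep] * s_k[keep]) / length(mov)
  within / tot
}

# Intensity-weighted centre of mass in mm (relative to the volume's origin).
com_mm <- function(vol) {
  v <- pmax(vol$data, 0)
  d <- dim(v)
  w <- sum(v)
  cx <- sum(rowSums(v, dims = 1) * seq_len(d[1])) / w
  my <- apply(v, 2, sum)
  cy <- sum(my * seq_len(d[2])) / w
  mz <- apply(v, 3, sum)
  cz <- sum(mz * seq_len(d[3])) / w
  (c(cx, cy, cz) - vol$origin_voxel) * vol$spacing_mm
}

#' Affine spatial normalisation
#'
#' Estimates a 12-parameter affine transform (3 translations, 3 rotations,
#' 3 scales, 3 shears) mapping template coordinates to subject coordinates by
#' minimising one minus the correlation ratio between template intensities and
#' the subject resampled onto the template grid. Initialisation aligns the
#' intensity centres of mass; optimisation is Nelder-Mead on the 12 parameters
#' with a coarse-to-fine restart. The registered volume is the subject
#' resampled onto the template lattice by trilinear interpolation.
#'
#' If the optimiser fails to improve on the initial cost the best-so-far
#' parameters are returned with a warning.
#'
#' @param brain Subject [brain_volume()] (skull-stripped).
#' @param template Template [brain_volume()].
#' @param subsample Cost-evaluation grid stride in voxels (default 2).
#' @param maxit Nelder-Mead iteration budget per stage.
#' @param nbins Intensity bins for the correlation ratio.
#' @return An object of class `registration_result`: `registered`
#'   ([brain_volume()] on the template lattice), `transform` (parameter vector
#'   and 3x4 affine), `cost_value`, `cost_initial`, `converged`.
#' @export
spatial_normalization <- function(brain, template, subsample = 2,
                                  maxit = 300, nbins = 24) {
  stopifnot(inherits(brain, "brain_volume"), inherits(template, "brain_volume"))
  if (all(brain$data == 0) || all(template$data == 0)) {
    stop("volumes must be nonempty", call. = FALSE)
  }
  tpl_pts <- grid_mm(dim(template$data), template$spacing_mm,
                     template$origin_voxel, step = subsample)
  tv <- template$data[seq(1, dim(template$data)[1], by = subsample),
                      seq(1, dim(template$data)[2], by = subsample),
                      seq(1, dim(template$data)[3], by = subsample)]
  tv <- as.numeric(tv)
  keep <- tv > stats::quantile(tv, 0.5)   # evaluate over template foreground
  tpl_pts <- tpl_pts[keep, , drop = FALSE]
  tv <- tv[keep]
  rng <- range(tv)
  ref_bin <- pmin(nbins, 1L + floor((tv - rng[1]) / diff(rng) * nbins))

  to_subject_voxel <- function(pts_mm) {
    sweep(sweep(pts_mm, 2, brain$spacing_mm, `/`), 2, brain$origin_voxel, `+`)
  }
  cost <- function(p) {
    af <- affine_from_params(p)
    pts <- tpl_pts %*% t(af$A)
    pts <- sweep(pts, 2, af$t, `+`)
    mov <- trilinear(brain$data, to_subject_voxel(pts))
    corratio_cost(ref_bin, mov, nbins)
  }

  t0 <- com_mm(brain) - com_mm(template)
  p0 <- c(t0, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  c0 <- cost(p0)
  parscale <- c(4, 4, 4, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.03, 0.03, 0.03)
  fit <- stats::optim(p0, cost, method = "Nelder-Mead",
                      control = list(maxit = maxit, parscale = parscale))
  fit2 <- stats::optim(fit$par, cost, method = "Nelder-Mead",
                       control = list(maxit = maxit,
                                      parscale = parscale / 4))
  best <- if (fit2$value <= fit$value) fit2 else fit
  converged <- TRUE
  if (best$value > c0) {
    warning("registration did not improve on its initialisation; returning best-so-far")
    best <- list(par = p0, value = c0)
    converged <- FALSE
  }
  af <- affine_from_params(best$par)
  out_pts <- grid_mm(dim(template$data), template$spacing_mm,
                     template$origin_voxel, step = 1)
  pts <- sweep(out_pts %*% t(af$A), 2, af$t, `+`)
  reg <- trilinear(brain$data, to_subject_voxel(pts))
  registered <- brain_volume(array(reg, dim(template$data)),
                             spacing_mm = template$spacing_mm,
                             origin_voxel = template$origin_voxel)
  structure(list(registered = registered,
                 transform = list(params = best$par,
                                  affine = cbind(af$A, af$t)),
                 cost_value = best$value, cost_initial = c0,
                 converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  p <- x$transform$params
  cat(sprintf(paste0("<registration_result> cost %.4f (init %.4f)\n",
                     "  t = (%.2f, %.2f, %.2f) mm, rot = (%.2f, %.2f, %.2f) deg, ",
                     "scale = (%.3f, %.3f, %.3f)\n"),
              x$cost_value, x$cost_initial, p[1], p[2], p[3],
              p[4] * 180 / pi, p[5] * 180 / pi, p[6] * 180 / pi,
              p[7], p[8], p[9]))
  invisible(x)
}

#' Default registration template
#'
#' A clean (noise-free) cognitively-normal phantom on the default lattice,
#' skull-stripped; used where a population template would stand in a clinical
#' pipeline.
#'
#' @param params Optional [phantom_params()] override.
#' @return A [brain_volume()].
#' @export
default_template <- function(params = NULL) {
  if (is.null(params)) {
    params <- phantom_params(noise_sd = 0)
  }
  vol <- render_phantom(params, seed = 0)
  brain_extraction(vol)$brain
}

# --- intensity normalisation ------------------------------------------------

#' Reference intensity histogram
#'
#' Stores the quantile function of a reference intensity population for
#' histogram matching, as 101 evenly spaced quantiles.
#'
#' @param values Numeric vector of reference intensities (e.g. pooled
#'   brain-masked voxels of the training split).
#' @return Object of class `reference_histogram` with `probs` and `quantiles`
#'   (monotone non-decreasing).
#' @export
reference_histogram <- function(values) {
  probs <- seq(0, 1, by = 0.01)
  q <- stats::quantile(values, probs, names = FALSE)
  structure(list(probs = probs, quantiles = cummax(q)),
            class = "reference_histogram")
}

# Phase 1 of intensity normalisation: 3-class k-means segmentation of the
# masked voxels (highest-mean class = white matter) and z-scoring by the WM
# mean/sd. Returns the masked z values and the mask.
wm_zscore <- function(registered, mask = NULL) {
  stopifnot(inherits(registered, "brain_volume"))
  v <- registered$data
  if (is.null(mask)) mask <- v > 1e-8
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  vals <- v[mask]
  set.seed(1)                           # deterministic k-means subsample
  samp <- if (length(vals) > 20000) sample(vals, 20000) else vals
  km <- stats::kmeans(samp,
                      centers = sort(stats::quantile(samp, c(0.2, 0.55, 0.9))),
                      iter.max = 50)
  centers <- sort(km$centers[, 1])
  cls <- max.col(-abs(outer(vals, centers, `-`)), ties.method = "first")
  wm_vals <- vals[cls == 3]
  if (length(wm_vals) < 100) {
    stop("segmentation degenerate: WM class < 100 voxels", call. = FALSE)
  }
  list(z = (vals - mean(wm_vals)) / stats::sd(wm_vals), mask = mask)
}

# Phase 2: optional histogram matching to a reference quantile function, then
# 99.5th-percentile clipping and linear rescaling to [0, 255].
finalize_intensity <- function(z, mask, dims, spacing, origin,
                               reference = NULL) {
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "reference_histogram"))
    r <- rank(z, ties.method = "average") / (length(z) + 1)
    z <- stats::approx(reference$probs, reference$quantiles, xout = r,
                       rule = 2)$y
  }
  hi <- stats::quantile(z, 0.995, names = FALSE)
  z <- pmin(z, hi)
  lo <- min(z)
  scl <- if (hi > lo) 255 / (hi - lo) else 0
  out <- array(0, dims)
  out[mask] <- (z - lo) * scl
  brain_volume(out, spacing_mm = spacing, origin_voxel = origin)
}

#' Intensity normalisation
#'
#' Four sub-steps on the brain-masked voxels: (1) 3-class k-means intensity
#' segmentation, taking the highest-mean class as white matter; (2) z-scoring
#' by the WM mean and standard deviation; (3) optional histogram matching of
#' the masked voxels to a reference quantile function; (4) clipping at the
#' 99.5th percentile and linear rescaling to \[0, 255\]. Background stays 0.
#'
#' @param registered A [brain_volume()] on the template lattice.
#' @param mask Logical array of brain voxels (defaults to `registered > 0`).
#' @param reference Optional [reference_histogram()]; `NULL` skips matching.
#' @return A [brain_volume()] with intensities in \[0, 255\].
#' @export
intensity_normalization <- function(registered, mask = NULL, reference = NULL) {
  zs <- wm_zscore(registered, mask)
  finalize_intensity(zs$z, zs$mask, dim(registered$data),
                     registered$spacing_mm, registered$origin_voxel,
                     reference = reference)
}

# --- grid construction ------------------------------------------------------

# Catmull-Rom cubic kernel (a = -0.5), the classic bicubic filter.
.cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

# 1D bicubic resampling weight matrix (n_out x n_in), pixel-centre convention,
# edge-clamped, rows normalised so constants are preserved exactly.
.cubic_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * scale + 0.5   # centre of out pixel i, 1-based in coords
  w <- matrix(0, n_out, n_in)
  base <- floor(src)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 1), n_in)
    wt <- .cubic_kernel(src - (base + k))
    w[cbind(seq_len(n_out), idx)] <- w[cbind(seq_len(n_out), idx)] + wt
  }
  sweep(w, 1, rowSums(w), `/`)
}

#' Bicubic image resize
#'
#' Separable Catmull-Rom resampling with edge clamping; preserves constants
#' exactly.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output dimensions (rows, columns).
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  wr <- .cubic_weights(nrow(img), out_h)
  wc <- .cubic_weights(ncol(img), out_w)
  wr %*% img %*% t(wc)
}

#' Canonical coronal slice offsets
#'
#' The ten coronal offsets in mm from the anatomical origin, posterior
#' (negative) to anterior: -8 to +10 in 2 mm steps, an 18 mm span.
#'
#' @return Numeric 10-vector.
#' @export
grid_slice_offsets <- function() c(-8, -6, -4, -2, 0, 2, 4, 6, 8, 10)

#' Construct the 10-slice coronal grid image
#'
#' For each offset y (mm) the coronal plane at voxel
#' `origin_y + round(y / spacing_y)` is extracted, oriented with the superior
#' edge at the top and the anatomical left on a fixed horizontal side, and
#' bicubic-resized to 102 x 256 (width x height). Slices 1-5 (posterior)
#' form the top row and 6-10 (anterior) the bottom row; the 510 x 512 mosaic is
#' bicubic-resized to exactly 512 x 512 and quantised to 8-bit.
#'
#' @param volume A preprocessed [brain_volume()].
#' @param offsets_mm Slice offsets, default [grid_slice_offsets()].
#' @param scan_id,patient_id,diagnosis Optional provenance strings.
#' @return An object of class `grid_image`: integer 512 x 512 matrix in
#'   \[0, 255\] with attributes `slice_positions_mm`, `scan_id`, `patient_id`,
#'   `diagnosis`.
#' @export
construct_grid <- function(volume, offsets_mm = grid_slice_offsets(),
                           scan_id = NA_character_, patient_id = NA_character_,
                           diagnosis = NA_character_) {
  stopifnot(inherits(volume, "brain_volume"))
  d <- dim(volume$data)
  iy <- volume$origin_voxel[2] + round(offsets_mm / volume$spacing_mm[2])
  bad <- which(iy < 1 | iy > d[2])
  if (length(bad) > 0) {
    stop(sprintf("coronal offset %g mm falls outside the volume", offsets_mm[bad[1]]),
         call. = FALSE)
  }
  slices <- lapply(iy, function(j) {
    sl <- volume$data[, j, ]             # x (left-right) by z (inferior-superior)
    img <- t(sl)[d[3]:1, , drop = FALSE] # rows: superior at top; cols: x
    resize_bicubic(img, 256, 102)
  })
  top <- do.call(cbind, slices[1:5])
  bottom <- do.call(cbind, slices[6:10])
  grid <- resize_bicubic(rbind(top, bottom), 512, 512)
  grid <- round_half_up(pmin(pmax(grid, 0), 255))
  storage.mode(grid) <- "integer"
  structure(grid, class = "grid_image",
            slice_positions_mm = offsets_mm,
            scan_id = scan_id, patient_id = patient_id, diagnosis = diagnosis)
}

#' @export
print.grid_image <- function(x, ...) {
  cat(sprintf("<grid_image> %d x %d 8-bit, slices at (%s) mm%s\n",
              nrow(x), ncol(x),
              paste(attr(x, "slice_positions_mm"), collapse = ", "),
              if (is.na(attr(x, "scan_id"))) "" else
                sprintf(", scan %s", attr(x, "scan_id"))))
  invisible(x)
}

#' Write a grid image as 8-bit grayscale PNG
#'
#' @param grid A [construct_grid()] result.
#' @param path Output path; defaults to `<patient_id>_<scan_id>.png` naming
#'   when a directory is given.
#' @return The file path, invisibly.
#' @export
write_grid_png <- function(grid, path) {
  stopifnot(inherits(grid, "grid_image"))
  if (dir.exists(path)) {
    path <- file.path(path, sprintf("%s_%s.png", attr(grid, "patient_id"),
                                    attr(grid, "scan_id")))
  }
  png::writePNG(unclass(grid) / 255, path)
  invisible(path)
}
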