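# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# A small, fast phantom lattice used throughout the unit tests.
small_shape <- c(64, 80, 64)

small_params <- function(...) {
  phantom_params(volume_shape = small_shape, ...)
}

# Clean skull-stripped template on the small lattice (cached).
small_template <- function() {
  if (is.null(.fixtures$template)) {
    .fixtures$template <- default_template(small_params(noise_sd = 0))
  }
  .fixtures$template
}

# A default-parameter phantom with labels (cached).
small_phantom <- function() {
  if (is.null(.fixtures$phantom)) {
    .fixtures$phantom <- render_phantom(small_params(), seed = 3)
  }
  .fixtures$phantom
}

# Resample a volume under a known affine (linear part A, translation t, in
# mm relative to the origin voxel) — the synthetic-transform oracle for
# registration tests: the returned subject satisfies
# subject(x) = volume(A^{-1} (x - t)).
apply_known_affine <- function(vol, A = diag(3), t_mm = c(0, 0, 0)) {
  pts <- demgrid:::grid_mm(dim(vol$data), vol$spacing_mm, vol$origin_voxel)
  src <- sweep(pts, 2, t_mm) %*% t(solve(A))
  vox <- sweep(sweep(src, 2, vol$spacing_mm, `/`), 2, vol$origin_voxel, `+`)
  brain_volume(array(demgrid:::trilinear(vol$data, vox), dim(vol$data)),
               vol$spacing_mm, vol$origin_voxel)
}

# Linearly separable class-coded images: a bright bar whose vertical position
# encodes the class.
separable_images <- function(n, side = 32, seed = 1) {
  set.seed(seed)
  y <- factor(sample(diagnosis_levels(), n, replace = TRUE),
              levels = diagnosis_levels())
  x <- array(stats::runif(side^2 * n, 0, 0.2), c(side, side, n))
  for (i in seq_len(n)) {
    k <- as.integer(y[i])
    rows <- (k * side %/% 5):(k * side %/% 5 + side %/% 5 - 1)
    x[rows, (side %/% 3):(2 * side %/% 3), i] <-
      x[rows, (side %/% 3):(2 * side %/% 3), i] + 0.8
  }
  list(x = x, y = y)
}

# Grid-image features for a synthetic cohort, bypassing registration (the
# phantoms are generated on a common lattice). Returns the cohort plus
# model-ready features.
cohort_grid_features <- function(n_patients, seed, side = 32,
                                 proportions = default_class_proportions()) {
  spec <- cohort_spec(n_patients, class_proportions = proportions,
                      base_params = small_params(), seed = seed)
  co <- generate_cohort(spec, keep_volumes = FALSE)
  x <- matrix(0, nrow(co$scans), side^2)
  for (i in seq_len(nrow(co$scans))) {
    g <- construct_grid(render_scan(co, co$scans$scan_id[i]))
    x[i, ] <- as.vector(resize_bicubic(unclass(g), side, side)) / 255
  }
  list(cohort = co, x = x, y = co$scans$diagnosis)
}

# Random valid confusion matrix for oracle-equivalence sweeps.
random_cm <- function() {
  m <- matrix(sample(0:30, 9, replace = TRUE), 3, 3,
              dimnames = list(true = diagnosis_levels(),
                              predicted = diagnosis_levels()))
  if (sum(m) == 0) m[1, 1] <- 1
  structure(m, class = c("confusion_matrix", "matrix"))
}
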