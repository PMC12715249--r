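#' Phantom rendering parameters
#'
#' Parameter bundle for the synthetic head phantom. The phantom is a nested set
#' of ellipsoids with T1-like intensity tiers (WM > GM > CSF), two hippocampal
#' blobs whose linear size is controlled by `hippocampus_scale` and two
#' ventricular cavities controlled by `ventricle_scale`, so diagnostic classes
#' can be rendered with graded hippocampal atrophy and ventricular enlargement.
#'
#' @param volume_shape Voxel triple; default 96 x 112 x 96.
#' @param voxel_spacing_mm Positive triple in mm; default isotropic 2 mm (1 mm
#'   is supported but slow for routine testing).
#' @param hippocampus_scale Linear scale of the hippocampal blobs, in (0, 1].
#' @param ventricle_scale Linear scale of the ventricles, >= 1.
#' @param cortical_mean_intensity,wm_mean_intensity,csf_mean_intensity Tissue
#'   tier intensities (arbitrary units); must satisfy WM > GM > CSF.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param motion_severity Motion-ghost severity in \[0, 1\] applied at render
#'   time via [inject_artifact()].
#' @param bias_field_amplitude Bias-field severity in \[0, 1\] applied at
#'   render time.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(volume_shape = c(96, 112, 96),
                           voxel_spacing_mm = c(2, 2, 2),
                           hippocampus_scale = 1,
                           ventricle_scale = 1,
                           cortical_mean_intensity = 120,
                           wm_mean_intensity = 160,
                           csf_mean_intensity = 40,
                           noise_sd = 5,
                           motion_severity = 0,
                           bias_field_amplitude = 0) {
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 16),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            hippocampus_scale > 0, hippocampus_scale <= 1,
            ventricle_scale >= 1, noise_sd >= 0,
            motion_severity >= 0, motion_severity <= 1,
            bias_field_amplitude >= 0, bias_field_amplitude <= 1)
  if (!(wm_mean_intensity > cortical_mean_intensity &&
        cortical_mean_intensity > csf_mean_intensity)) {
    stop("T1-like contrast requires WM > GM > CSF mean intensities", call. = FALSE)
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 hippocampus_scale = hippocampus_scale,
                 ventricle_scale = ventricle_scale,
                 cortical_mean_intensity = cortical_mean_intensity,
                 wm_mean_intensity = wm_mean_intensity,
                 csf_mean_intensity = csf_mean_intensity,
                 noise_sd = noise_sd,
                 motion_severity = motion_severity,
                 bias_field_amplitude = bias_field_amplitude),
            class = "phantom_params")
}

# Structure labels used in rendered phantoms.
PHANTOM_LABELS <- c(air = 0L, scalp = 1L, gm = 2L, wm = 3L,
                    ventricle = 4L, hippocampus = 5L)

# Ellipsoid membership on precomputed mm coordinate grids.
.ellipsoid <- function(xg, yg, zg, center, semi) {
  ((xg - center[1]) / semi[1])^2 +
    ((yg - center[2]) / semi[2])^2 +
    ((zg - center[3]) / semi[3])^2 <= 1
}

#' Render a phantom brain volume
#'
#' Builds the ellipsoidal head phantom described in [phantom_params()] and adds
#' seeded Gaussian noise, then applies any configured motion ghost or bias
#' field. The returned volume carries a `labels` array with the ground-truth
#' structure of every voxel (air/scalp/GM/WM/ventricle/hippocampus), which the
#' test suite uses as an oracle for masks and structure volumes.
#'
#' Hippocampal and ventricular voxel counts scale approximately with the cube
#' of their linear scale parameters, emulating class-graded hippocampal volume
#' reduction and compensatory ventricular enlargement.
#'
#' @param params A [phantom_params()] bundle.
#' @param seed Integer seed controlling the noise and artifact draws.
#' @return A [brain_volume()] with attached `labels`.
#' @export
render_phantom <- function(params, seed = 1) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$volume_shape
  sp <- params$voxel_spacing_mm
  fov <- d * sp
  # head semi-axes leave a margin for background; structures sized relative
  # to a nominal 192 x 224 x 192 mm field of view
  head_semi <- pmin(c(75, 95, 80), fov / 2 - 3 * sp)
  if (any(head_semi < 24)) {
    stop("volume too small to contain the phantom head structures", call. = FALSE)
  }
  center <- fov / 2
  ax <- (seq_len(d[1]) - 0.5) * sp[1]
  ay <- (seq_len(d[2]) - 0.5) * sp[2]
  az <- (seq_len(d[3]) - 0.5) * sp[3]
  xg <- array(rep(ax, times = d[2] * d[3]), d)
  yg <- array(rep(rep(ay, each = d[1]), times = d[3]), d)
  zg <- array(rep(az, each = d[1] * d[2]), d)

  scl <- head_semi / c(75, 95, 80)      # isotropic-ish shrink if FOV is small
  brain_semi <- c(62, 80, 66) * scl
  brain_ctr <- center + c(0, 0, 6 * scl[3])
  wm_semi <- brain_semi * 0.72
  vs <- params$ventricle_scale
  hs <- params$hippocampus_scale

  lab <- array(PHANTOM_LABELS[["air"]], d)
  lab[.ellipsoid(xg, yg, zg, center, head_semi)] <- PHANTOM_LABELS[["scalp"]]
  lab[.ellipsoid(xg, yg, zg, brain_ctr, brain_semi)] <- PHANTOM_LABELS[["gm"]]
  lab[.ellipsoid(xg, yg, zg, brain_ctr, wm_semi)] <- PHANTOM_LABELS[["wm"]]
  for (sgn in c(-1, 1)) {
    vent_ctr <- brain_ctr + c(sgn * 13 * scl[1], 4 * scl[2], 6 * scl[3])
    lab[.ellipsoid(xg, yg, zg, vent_ctr, c(8, 26, 11) * scl * vs)] <-
      PHANTOM_LABELS[["ventricle"]]
    hip_ctr <- brain_ctr + c(sgn * 28 * scl[1], -8 * scl[2], -22 * scl[3])
    lab[.ellipsoid(xg, yg, zg, hip_ctr, c(10, 17, 9) * scl * hs)] <-
      PHANTOM_LABELS[["hippocampus"]]
  }

  tier <- c(0, 0.75 * params$cortical_mean_intensity,
            params$cortical_mean_intensity, params$wm_mean_intensity,
            params$csf_mean_intensity, 0.95 * params$cortical_mean_intensity)
  v <- array(tier[lab + 1L], d)
  if (params$noise_sd > 0) {
    set.seed(derive_seed(seed, 101))
    v <- v + array(stats::rnorm(prod(d), 0, params$noise_sd), d)
  }

  # anatomical origin: brain centre voxel (anterior-commissure analogue)
  origin <- pmin(pmax(round(brain_ctr / sp + 0.5), 1), d)
  vol <- brain_volume(v, spacing_mm = sp, origin_voxel = origin, labels = lab)
  if (params$motion_severity > 0) {
    vol <- inject_artifact(vol, "motion_ghost", params$motion_severity,
                           seed = derive_seed(seed, 102))
  }
  if (params$bias_field_amplitude > 0) {
    vol <- inject_artifact(vol, "bias_field", params$bias_field_amplitude,
                           seed = derive_seed(seed, 103))
  }
  vol
}

#' Inject an acquisition artifact into a volume
#'
#' Provides controlled positives for the quality-control stage:
#' \describe{
#'   \item{motion_ghost}{adds a half-field-of-view replica of the volume along
#'     the phase-encode (posterior-anterior) axis, attenuated to
#'     `0.6 * severity` of the original — the classic Nyquist ghost of
#'     inter-shot motion.}
#'   \item{bias_field}{multiplies by a smooth low-order polynomial field with
#'     relative amplitude `0.4 * severity`.}
#'   \item{noise_burst}{adds extra Gaussian noise with sd equal to
#'     `0.15 * severity` times the robust intensity maximum.}
#' }
#' `severity = 0` returns the input unchanged.
#'
#' @param volume A [brain_volume()].
#' @param kind One of `"motion_ghost"`, `"bias_field"`, `"noise_burst"`.
#' @param severity Real in \[0, 1\].
#' @param seed Integer seed (used by `noise_burst`).
#' @return A modified copy of `volume` (labels preserved).
#' @export
inject_artifact <- function(volume, kind, severity, seed = 1) {
  stopifnot(inherits(volume, "brain_volume"))
  kind <- match.arg(kind, c("motion_ghost", "bias_field", "noise_burst"))
  if (!is.numeric(severity) || severity < 0 || severity > 1) {
    stop("severity must lie in [0, 1]", call. = FALSE)
  }
  if (severity == 0) return(volume)
  v <- volume$data
  d <- dim(v)
  out <- switch(kind,
    motion_ghost = v + 0.6 * severity *
      shift3(v, axis = 2, by = d[2] %/% 2, circular = TRUE),
    bias_field = {
      xn <- (seq_len(d[1]) - 0.5) / d[1] * 2 - 1
      yn <- (seq_len(d[2]) - 0.5) / d[2] * 2 - 1
      zn <- (seq_len(d[3]) - 0.5) / d[3] * 2 - 1
      pol <- outer(outer(xn, yn), zn * 0 + 1) * 0.5 +
        outer(outer(xn * 0 + 1, yn * 0 + 1), zn) * 0.5
      v * (1 + 0.4 * severity * array(pol, d))
    },
    noise_burst = {
      set.seed(seed)
      v + array(stats::rnorm(prod(d), 0,
                             0.15 * severity * stats::quantile(v, 0.98)), d)
    })
  brain_volume(out, spacing_mm = volume$spacing_mm,
               origin_voxel = volume$origin_voxel, labels = volume$labels)
}
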