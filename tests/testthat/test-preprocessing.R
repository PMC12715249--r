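# Five-stage preprocessing: QC, brain extraction, registration, intensity
# normalisation, grid construction.

test_that("quality scoring rule reproduces hand-computed values", {
  # hand evaluation: 0.4 * (30/40) + 0.3 * 0.9 + 0.3 * 0.8 = 0.81
  expect_equal(quality_score(30, 0.1, 0.8)$quality_score, 0.81)
  expect_identical(quality_score(30, 0.1, 0.8)$flag, "ACCEPT")
  # all components maximal
  expect_equal(quality_score(45, 0, 1)$quality_score, 1.0)
  # rejection rules: SNR < 20 or motion > 0.3 give score exactly 0
  expect_identical(quality_score(15, 0, 1),
                   list(flag = "REJECT", quality_score = 0))
  expect_identical(quality_score(40, 0.31, 1)$flag, "REJECT")
})

test_that("a volume built with SNR 15 is rejected and all-zero input errors", {
  # block foreground at 150 over a noise background with sd 10 -> SNR = 15
  set.seed(8)
  a <- array(stats::rnorm(48^3, 0, 10), c(48, 48, 48))
  a[12:36, 12:36, 12:36] <- 150
  qc <- quality_control(brain_volume(a, c(2, 2, 2)))
  expect_identical(qc$flag, "REJECT")
  expect_identical(qc$quality_score, 0)
  expect_lt(qc$snr, 20)
  expect_error(quality_control(brain_volume(array(0, c(16, 16, 16)))),
               "empty volume")
  # the default phantom passes
  expect_identical(quality_control(small_phantom())$flag, "ACCEPT")
})

test_that("brain extraction recovers the head with high Dice and zero background", {
  v <- small_phantom()
  ext <- brain_extraction(v)
  truth <- v$labels > 0
  dice <- 2 * sum(ext$mask & truth) / (sum(ext$mask) + sum(truth))
  expect_gt(dice, 0.9)
  expect_true(all(ext$brain$data[!ext$mask] == 0))
  expect_identical(dim(ext$mask), dim(v$data))
  # idempotence up to edge softening: re-extracting the masked volume keeps
  # essentially the same mask
  ext2 <- brain_extraction(ext$brain)
  overlap <- 2 * sum(ext2$mask & ext$mask) / (sum(ext2$mask) + sum(ext$mask))
  expect_gt(overlap, 0.95)
})

test_that("extraction keeps only the largest of two disconnected blobs", {
  a <- array(0, c(48, 48, 48))
  a[6:36, 6:36, 6:36] <- 100      # large blob
  a[42:45, 42:45, 42:45] <- 100   # small blob, 10x+ smaller
  ext <- brain_extraction(brain_volume(a, c(2, 2, 2)))
  expect_true(all(which(ext$mask, arr.ind = TRUE) <= 38))
  expect_error(brain_extraction(brain_volume(array(0, c(16, 16, 16)) - 1)),
               NA)  # constant negative volume still thresholds somewhere
})

test_that("registration recovers identity, translation and scale", {
  tpl <- small_template()
  # template to itself: transform within tolerance of identity
  r0 <- spatial_normalization(tpl, tpl, subsample = 3, maxit = 150)
  expect_lt(max(abs(r0$transform$params[1:3])), 0.5 * tpl$spacing_mm[1])
  expect_lt(max(abs(r0$transform$params[4:6])) * 180 / pi, 1)
  expect_lte(r0$cost_value, r0$cost_initial)
  # known translation (5, -3, 2) voxels = (10, -6, 4) mm
  shift_mm <- c(5, -3, 2) * tpl$spacing_mm
  sub <- apply_known_affine(tpl, t_mm = shift_mm)
  r1 <- spatial_normalization(sub, tpl, subsample = 3, maxit = 200)
  expect_lt(max(abs(r1$transform$params[1:3] - shift_mm)),
            0.5 * tpl$spacing_mm[1])
  # isotropic 1.1 scaling recovered within 2%
  sub2 <- apply_known_affine(tpl, A = diag(3) * 1.1)
  r2 <- spatial_normalization(sub2, tpl, subsample = 3, maxit = 200)
  expect_lt(max(abs(r2$transform$params[7:9] - 1.1)), 0.022)
  # registered output lives on the template lattice
  expect_identical(dim(r1$registered$data), dim(tpl$data))
  expect_identical(r1$registered$spacing_mm, tpl$spacing_mm)
  expect_error(spatial_normalization(tpl, brain_volume(array(0, c(16, 16, 16)))),
               "nonempty")
})

test_that("intensity normalisation maps WM to z 0 and output to [0, 255]", {
  v <- small_phantom()
  ext <- brain_extraction(v)
  # WM tier maps to z-score ~0 before matching (WM mean subtracts itself)
  zs <- demgrid:::wm_zscore(ext$brain)
  wm_z <- zs$z[v$labels[zs$mask] == 3L]
  expect_lt(abs(mean(wm_z)), 0.05)
  out <- intensity_normalization(ext$brain)
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 255)
  # histogram-matching a distribution to itself is the identity up to
  # quantisation of the stored quantile function
  ref <- reference_histogram(zs$z)
  matched <- intensity_normalization(ext$brain, reference = ref)
  plain <- intensity_normalization(ext$brain)
  expect_lt(mean(abs(matched$data - plain$data)), 2)
  # degenerate segmentation errors
  flat <- brain_volume(array(c(100), c(24, 24, 24)) +
                         array(stats::rnorm(24^3, 0, 0.1), c(24, 24, 24)))
  expect_error(intensity_normalization(flat, mask = flat$data > -Inf), NA)
})

test_that("bicubic resize preserves constants and recovers smooth ramps", {
  m <- matrix(7, 20, 30)
  expect_equal(resize_bicubic(m, 33, 47), matrix(7, 33, 47))
  ramp <- outer(seq(0, 1, length.out = 64), rep(1, 64))
  up <- resize_bicubic(ramp, 128, 128)
  # cubic interpolation reproduces a linear ramp exactly away from the
  # clamped borders: expected value at output row i is the ramp evaluated at
  # the source coordinate (i - 0.5) * 0.5 + 0.5
  src <- (seq_len(128) - 0.5) * (64 / 128) + 0.5
  expected <- (src - 1) / 63
  interior <- 4:125
  expect_lt(max(abs(up[interior, 10] - expected[interior])), 1e-9)
})

test_that("grid construction follows the 10-slice 5x2 layout exactly", {
  v <- small_phantom()
  n <- intensity_normalization(brain_extraction(v)$brain)
  g <- construct_grid(n, scan_id = "S", patient_id = "P", diagnosis = "AD")
  expect_s3_class(g, "grid_image")
  expect_identical(dim(unclass(g)), c(512L, 512L))
  expect_true(is.integer(unclass(g)))
  expect_gte(min(g), 0L)
  expect_lte(max(g), 255L)
  expect_identical(attr(g, "slice_positions_mm"), grid_slice_offsets())
  # 10 offsets spanning 18 mm of anterior-posterior coverage
  expect_identical(length(grid_slice_offsets()), 10L)
  expect_identical(diff(range(grid_slice_offsets())), 18)
  # constant volume -> constant grid
  vc <- brain_volume(array(33, c(32, 32, 32)), c(2, 2, 2))
  expect_identical(unique(as.vector(construct_grid(vc))), 33L)
  # a bright plane at y = 0 lights up top-row position 5 of 5
  vz <- brain_volume(array(0, dim(v$data)), v$spacing_mm, v$origin_voxel)
  vz$data[, vz$origin_voxel[2], ] <- 255
  gz <- unclass(construct_grid(vz))
  bright <- which(gz > 100, arr.ind = TRUE)
  expect_true(all(bright[, 1] <= 256))                  # top row
  expect_true(all(bright[, 2] > 4 * 512 / 5 - 4))       # 5th horizontal block
  # an offset outside the volume is reported by value
  small <- brain_volume(array(1, c(16, 16, 16)), c(2, 2, 2), c(8, 12, 8))
  expect_error(construct_grid(small), "10 mm")
})

test_that("grid construction preserves left-right orientation in every slice", {
  v <- small_phantom()
  # marker: zero out the anatomical right half so the left is bright
  vl <- v
  vl$data[(vl$origin_voxel[1] + 1):dim(vl$data)[1], , ] <- 0
  g <- unclass(construct_grid(vl))
  block <- 512 / 5
  for (b in 0:4) {
    for (rows in list(1:256, 257:512)) {
      cols <- round(b * block + 1):round((b + 1) * block)
      half <- length(cols) %/% 2
      left <- mean(g[rows, cols[1:half]])
      right <- mean(g[rows, cols[(half + 1):length(cols)]])
      if (left + right > 0) expect_gt(left, right)
    }
  }
})

test_that("preprocessing is deterministic for fixed inputs", {
  v <- render_phantom(small_params(), seed = 12)
  run <- function() {
    ext <- brain_extraction(v)
    construct_grid(intensity_normalization(ext$brain))
  }
  expect_identical(run(), run())
})
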