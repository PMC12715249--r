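#' Brain volume container
#'
#' A minimal 3D image container: an intensity array with voxel spacing and an
#' anatomical origin voxel (the anterior-commissure analogue used as the
#' reference landmark for coronal slice offsets). Axes are fixed as
#' x = left-right, y = posterior-anterior, z = inferior-superior.
#'
#' @param data 3D numeric array of intensities; every dimension must be >= 16.
#' @param spacing_mm Positive numeric triple, voxel size in mm.
#' @param origin_voxel Integer triple (1-based voxel indices) marking the
#'   anatomical origin; must lie inside the array.
#' @param labels Optional integer array congruent with `data` carrying
#'   structure labels (used by the phantom generator for ground truth).
#' @return An object of class `brain_volume`: a list with elements `data`,
#'   `spacing_mm`, `origin_voxel` and optionally `labels`.
#' @export
brain_volume <- function(data, spacing_mm = c(1, 1, 1),
                         origin_voxel = ceiling(dim(data) / 2),
                         labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("data must be a 3D array", call. = FALSE)
  }
  d <- dim(data)
  if (any(d < 16)) stop("all volume dimensions must be >= 16", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("spacing_mm must be a positive triple", call. = FALSE)
  }
  origin_voxel <- as.integer(round(origin_voxel))
  if (length(origin_voxel) != 3 || any(origin_voxel < 1) || any(origin_voxel > d)) {
    stop("origin_voxel must lie inside the array", call. = FALSE)
  }
  if (!is.null(labels) && !identical(dim(labels), d)) {
    stop("labels must have the same shape as data", call. = FALSE)
  }
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_voxel = origin_voxel, labels = labels),
            class = "brain_volume")
}

#' @export
dim.brain_volume <- function(x) dim(x$data)

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_volume> %d x %d x %d voxels @ %s mm, origin (%s)\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm), collapse = " x "),
              paste(x$origin_voxel, collapse = ", ")))
  cat(sprintf("  intensity range [%.2f, %.2f]%s\n",
              min(x$data), max(x$data),
              if (is.null(x$labels)) "" else "; structure labels attached"))
  invisible(x)
}

#' Write a brain volume as NIfTI-1
#'
#' The affine encodes the voxel spacing and places the world origin at the
#' volume's anatomical origin voxel.
#'
#' @param volume A [brain_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_brain_volume <- function(volume, path) {
  stopifnot(inherits(volume, "brain_volume"))
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing_mm
  aff[1:3, 4] <- -(volume$origin_voxel - 1) * volume$spacing_mm
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a brain volume from NIfTI-1
#'
#' Recovers voxel spacing from the pixdim and the anatomical origin from the
#' affine translation (inverse of [write_brain_volume()]).
#'
#' @param path NIfTI file path.
#' @return A [brain_volume()].
#' @export
read_brain_volume <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  origin <- -aff[1:3, 4] / sp + 1
  origin <- pmin(pmax(round(origin), 1), dim(data))
  brain_volume(data, spacing_mm = sp, origin_voxel = origin)
}

# --- small 3D array helpers used across preprocessing -----------------------

# Shift a 3D array along one axis by `by` voxels, filling with `fill`
# (or wrapping circularly when circular = TRUE).
shift3 <- function(a, axis, by, fill = 0, circular = FALSE) {
  if (by == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  by <- as.integer(by)
  if (circular) {
    idx <- ((seq_len(n) - 1 - by) %% n) + 1
  } else {
    idx <- seq_len(n) - by
  }
  pick <- function(i) switch(axis, a[i, , , drop = FALSE],
                             a[, i, , drop = FALSE],
                             a[, , i, drop = FALSE])
  if (circular) return(pick(idx))
  out <- array(fill, dim = d)
  src <- idx >= 1 & idx <= n
  if (!any(src)) return(out)
  val <- pick(idx[src])
  if (axis == 1) out[src, , ] <- val
  if (axis == 2) out[, src, ] <- val
  if (axis == 3) out[, , src] <- val
  out
}

# Separable box smoothing (running mean of width 2*w+1 along each axis,
# renormalised at the borders by the number of in-bounds taps).
box_smooth3 <- function(a, w = 1) {
  ones <- array(1, dim(a))
  for (axis in 1:3) {
    num <- a
    den <- ones
    for (s in seq_len(w)) {
      num <- num + shift3(a, axis, s, 0) + shift3(a, axis, -s, 0)
      den <- den + shift3(ones, axis, s, 0) + shift3(ones, axis, -s, 0)
    }
    a <- num / den
  }
  a
}

# Separable binary dilation/erosion with a (2w+1)^3 box structuring element.
dilate3 <- function(mask, w = 1) {
  a <- mask * 1
  for (axis in 1:3) {
    b <- a
    for (s in seq_len(w)) {
      b <- pmax(b, shift3(a, axis, s, 0), shift3(a, axis, -s, 0))
    }
    a <- b
  }
  a > 0
}

erode3 <- function(mask, w = 1) !dilate3(!mask, w)

close3 <- function(mask, w = 1) erode3(dilate3(mask, w), w)

# 6-neighbourhood of a set of linear voxel indices (with boundary handling).
neighbours6 <- function(idx, d) {
  d12 <- d[1] * d[2]
  x <- ((idx - 1) %% d[1]) + 1
  y <- ((idx - 1) %/% d[1]) %% d[2] + 1
  z <- ((idx - 1) %/% d12) + 1
  c(idx[x > 1] - 1, idx[x < d[1]] + 1,
    idx[y > 1] - d[1], idx[y < d[2]] + d[1],
    idx[z > 1] - d12, idx[z < d[3]] + d12)
}

# BFS flood fill over `ok` voxels starting from `seeds`; returns the visited
# logical vector (length prod(d)).
flood3 <- function(ok, seeds, d) {
  visited <- logical(length(ok))
  frontier <- seeds[ok[seeds]]
  visited[frontier] <- TRUE
  while (length(frontier) > 0) {
    nb <- unique(neighbours6(frontier, d))
    nb <- nb[ok[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# Keep the largest 6-connected component of a binary mask.
largest_component3 <- function(mask) {
  if (!any(mask)) return(mask)
  d <- dim(mask)
  ok <- as.vector(mask)
  remaining <- which(ok)
  best <- NULL; best_n <- 0
  claimed <- logical(length(ok))
  while (length(remaining) > 0) {
    comp <- flood3(ok & !claimed, remaining[1], d)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    claimed <- claimed | comp
    remaining <- remaining[!claimed[remaining]]
  }
  array(best, d)
}

# Fill interior holes: background voxels not reachable from the array border.
fill_holes3 <- function(mask) {
  d <- dim(mask)
  bg <- as.vector(!mask)
  edge <- array(FALSE, d)
  edge[1, , ] <- TRUE; edge[d[1], , ] <- TRUE
  edge[, 1, ] <- TRUE; edge[, d[2], ] <- TRUE
  edge[, , 1] <- TRUE; edge[, , d[3]] <- TRUE
  outside <- flood3(bg, which(as.vector(edge) & bg), d)
  mask | array(bg & !outside, d)
}
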