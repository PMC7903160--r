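# NIfTI volume I/O and the standard preprocessing pipeline: cubic-spline
# resampling to a 1 mm isotropic 128-voxel field of view, retention of every
# fourth axial slice (32 slices), and zero-mean/unit-variance normalisation.

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return `list(volume = 3D array, voxel_sizes = numeric(3) in mm)`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop_unlearnr("unlearnr_error_missing_file",
                  sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_unlearnr("unlearnr_error_header",
                                  sprintf("unreadable NIfTI: %s", path)))
  vol <- as.array(img)
  if (length(dim(vol)) != 3L)
    stop_unlearnr("unlearnr_error_dims",
                  sprintf("expected a 3D volume, got %dD", length(dim(vol))))
  vox <- RNifti::pixdim(img)[seq_len(3)]
  list(volume = array(as.numeric(vol), dim(vol)),
       voxel_sizes = as.numeric(vox))
}

#' Write a volume as NIfTI
#'
#' @param volume numeric array (2D or 3D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_sizes voxel dimensions in mm (recycled to the array rank).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_sizes = rep(1, length(dim(volume)))) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep_len(voxel_sizes, length(dim(volume)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Linear operator resampling one axis to a centred `n_out`-point grid with
# `spacing` mm between points. method "spline" = natural cubic interpolating
# spline; "linear" = trilinear weights. Output points outside the input
# extent map to 0 (background).
.resample_operator <- function(n_in, vox, n_out = 128L, spacing = 1,
                               method = c("spline", "linear")) {
  method <- match.arg(method)
  xin <- (seq_len(n_in) - 1) * vox
  center <- (n_in - 1) * vox / 2
  xout <- center + (seq_len(n_out) - (n_out + 1) / 2) * spacing
  A <- matrix(0, n_out, n_in)
  inside <- xout >= min(xin) - 1e-9 & xout <= max(xin) + 1e-9
  if (n_in == 1L) {
    A[inside, 1] <- 1
    return(A)
  }
  for (j in seq_len(n_in)) {
    e <- numeric(n_in); e[j] <- 1
    if (method == "spline" && n_in >= 4L) {
      f <- stats::splinefun(xin, e, method = "natural")
      A[inside, j] <- f(xout[inside])
    } else {
      A[inside, j] <- stats::approx(xin, e, xout = xout[inside],
                                    rule = 2)$y
    }
  }
  A
}

.apply_axis <- function(vol, A, axis) {
  d <- dim(vol)
  perm <- c(axis, setdiff(seq_along(d), axis))
  v <- aperm(vol, perm)
  dp <- dim(v)
  out <- A %*% matrix(v, dp[1], prod(dp[-1]))
  out <- array(out, c(nrow(A), dp[-1]))
  aperm(out, order(perm))
}

#' Preprocess a volume to the network input grid
#'
#' Resamples the volume with cubic-spline interpolation to a 1 mm isotropic
#' grid over a centred 128 mm field of view (128x128x128 voxels), retains
#' every fourth axial slice (0-based indices 0, 4, ..., 124, leaving 32
#' slices), and normalises the result to zero mean and unit standard
#' deviation.
#'
#' @param volume 3D numeric array.
#' @param voxel_sizes numeric(3), voxel dimensions in mm (positive).
#' @return A 128x128x32 array with mean 0 and sd 1.
#' @export
preprocess_volume <- function(volume, voxel_sizes) {
  if (length(dim(volume)) != 3L)
    stop_unlearnr("unlearnr_error_dims", "volume must be 3D")
  if (any(voxel_sizes <= 0))
    stop_unlearnr("unlearnr_error_voxels", "voxel sizes must be positive")
  if (stats::sd(volume) == 0)
    stop_unlearnr("unlearnr_error_degenerate",
                  "zero-variance volume cannot be normalised")
  d <- dim(volume)
  v <- .apply_axis(volume, .resample_operator(d[1], voxel_sizes[1]), 1)
  v <- .apply_axis(v, .resample_operator(d[2], voxel_sizes[2]), 2)
  # z: sample only the 32 retained 1 mm slice positions (0-based 0,4,...,124
  # of the notional 128-slice grid)
  Az <- .resample_operator(d[3], voxel_sizes[3])[seq(1L, 125L, by = 4L), ,
                                                 drop = FALSE]
  v <- .apply_axis(v, Az, 3)
  normalise_volume(v)
}

#' Zero-mean unit-variance normalisation
#'
#' @param volume numeric array.
#' @return The normalised array; idempotent up to floating-point error.
#' @export
normalise_volume <- function(volume) {
  s <- stats::sd(volume)
  if (!is.finite(s) || s == 0)
    stop_unlearnr("unlearnr_error_degenerate",
                  "zero-variance volume cannot be normalised")
  (volume - mean(volume)) / s
}

#' Preprocess a one-hot label map to the network grid
#'
#' Each class channel is resampled with trilinear interpolation to the same
#' retained-slice grid as [preprocess_volume()], then thresholded at 0.5 to
#' give categorical labels. A voxel whose interpolated value ties at exactly
#' 0.5 in more than one channel (or reaches 0.5 in none) is assigned the
#' lowest qualifying class index (argmax with lowest-index ties when no
#' channel reaches 0.5).
#'
#' @param labelmap 4D array (X x Y x Z x classes), one-hot.
#' @param voxel_sizes numeric(3) in mm.
#' @return A 128x128x32 integer array of class indices (1-based).
#' @export
preprocess_labelmap <- function(labelmap, voxel_sizes) {
  if (length(dim(labelmap)) != 4L)
    stop_unlearnr("unlearnr_error_dims",
                  "labelmap must be 4D (x, y, z, class)")
  d <- dim(labelmap)
  A1 <- .resample_operator(d[1], voxel_sizes[1], method = "linear")
  A2 <- .resample_operator(d[2], voxel_sizes[2], method = "linear")
  Az <- .resample_operator(d[3], voxel_sizes[3],
                           method = "linear")[seq(1L, 125L, by = 4L), ,
                                              drop = FALSE]
  ch <- vector("list", d[4])
  for (c_ in seq_len(d[4])) {
    v <- labelmap[, , , c_]
    v <- .apply_axis(v, A1, 1)
    v <- .apply_axis(v, A2, 2)
    ch[[c_]] <- .apply_axis(v, Az, 3)
  }
  P <- vapply(ch, as.vector, numeric(length(ch[[1]])))
  lab <- .threshold_labels(P)
  array(lab, dim(ch[[1]]))
}

# P: voxels x classes matrix of interpolated channel values.
.threshold_labels <- function(P) {
  hit <- P >= 0.5 - 1e-12
  first_hit <- max.col(hit, ties.method = "first")  # lowest index with TRUE
  any_hit <- rowSums(hit) > 0
  fallback <- max.col(P, ties.method = "first")
  ifelse(any_hit, first_hit, fallback)
}
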