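test_that("sample construction enforces its invariants", {
  img <- matrix(rnorm(16), 4, 4)
  s <- new_sample(img, 2, main_label = 63.5, confounds = list(sex = "male"))
  expect_true(s$in_p)
  expect_true(s$in_c[["sex"]])
  expect_error(new_sample(matrix(c(1, NA, 1, 1), 2, 2), 1),
               class = "unlearnr_error_nonfinite")
  expect_error(new_sample(img, 0), class = "unlearnr_error_domain")
  expect_error(new_sample(img, 1, in_p = TRUE), class = "unlearnr_error_label")
})

test_that("multi-site datasets track per-domain counts", {
  img <- matrix(0.5, 4, 4)
  smp <- c(lapply(1:3, function(i) new_sample(img, 1, 50)),
           lapply(1:2, function(i) new_sample(img, 2, 60)))
  ds <- multisite_dataset(smp)
  expect_equal(ds$n_domains, 2L)
  expect_equal(ds$per_domain_counts, c(3L, 2L))
  expect_equal(length(ds), 5L)
  expect_error(multisite_dataset(smp[4:5], n_domains = 2),
               class = "unlearnr_error_domain")   # domain 1 empty
  expect_error(multisite_dataset(list()), class = "unlearnr_error_empty")
})

test_that("NIfTI volumes round-trip through disk", {
  vol <- array(rnorm(8), c(2, 2, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path, voxel_sizes = c(2, 2, 2))
  got <- load_volume(path)
  expect_equal(got$volume, vol, tolerance = 1e-7)
  expect_equal(got$voxel_sizes, c(2, 2, 2))
  expect_error(load_volume(tempfile()), class = "unlearnr_error_missing_file")
  p4 <- tempfile(fileext = ".nii.gz")
  write_volume(array(0, c(2, 2, 2, 2)), p4)
  expect_error(load_volume(p4), class = "unlearnr_error_dims")
})

test_that("preprocessing yields the 128x128x32 normalised grid", {
  vol <- array(rnorm(24 * 20 * 30), c(24, 20, 30))
  out <- preprocess_volume(vol, c(6, 7, 5))
  expect_equal(dim(out), c(128L, 128L, 32L))
  expect_equal(mean(out), 0, tolerance = 1e-6)
  expect_equal(stats::sd(out), 1, tolerance = 1e-6)
  # slice count is invariant to the input shape
  out2 <- preprocess_volume(array(runif(10^3), c(10, 10, 10)), c(14, 14, 14))
  expect_equal(dim(out2), c(128L, 128L, 32L))
  expect_error(preprocess_volume(array(1, c(5, 5, 5)), c(1, 1, 1)),
               class = "unlearnr_error_degenerate")
  expect_error(preprocess_volume(matrix(1, 4, 4), c(1, 1, 1)),
               class = "unlearnr_error_dims")
})

test_that("a native-grid input keeps axial planes 0, 4, ..., 124", {
  # constant-plus-gradient volume already on the 128^3 1 mm grid: the
  # resampling is the identity, so slice retention picks every fourth plane
  base <- array(0, c(128, 128, 128))
  for (z in 1:128) base[, , z] <- z + outer(seq_len(128) / 128, rep(1, 128))
  out <- preprocess_volume(base, c(1, 1, 1))
  ref <- normalise_volume(base[, , seq(1, 125, by = 4)])
  expect_equal(out, ref, tolerance = 1e-6)
})

test_that("normalisation is idempotent", {
  v <- array(runif(4^3, 1, 9), c(4, 4, 4))
  once <- normalise_volume(v)
  expect_equal(normalise_volume(once), once, tolerance = 1e-12)
})

test_that("label maps are trilinearly resampled then thresholded", {
  # identity-resolution input: labels unchanged on the retained grid
  lab <- array(0L, c(128, 128, 128))
  lab[1:64, , ] <- 1L
  onehot <- array(0, c(128, 128, 128, 2))
  onehot[, , , 1] <- lab == 0L
  onehot[, , , 2] <- lab == 1L
  out <- preprocess_labelmap(onehot, c(1, 1, 1))
  expect_equal(dim(out), c(128L, 128L, 32L))
  expect_equal(out[, , 1], lab[, , 1] + 1L)
  expect_error(preprocess_labelmap(array(0, c(4, 4, 4)), c(1, 1, 1)),
               class = "unlearnr_error_dims")
})

test_that("threshold ties go to the lowest class index", {
  th <- unlearnr:::.threshold_labels
  # exact 0.5 in two channels -> class 1
  expect_equal(th(matrix(c(0.5, 0.5), 1)), 1L)
  # no channel reaches 0.5 -> argmax with lowest-index ties
  expect_equal(th(matrix(c(0.4, 0.4, 0.2), 1)), 1L)
  expect_equal(th(matrix(c(0.2, 0.3, 0.45), 1)), 3L)
  # a 2-voxel checkerboard upsampled 2x: interpolated midpoints sit at 0.5
  # in both channels and follow the tie rule; pure voxels keep their class
  onehot <- array(0, c(2, 1, 1, 2))
  onehot[1, 1, 1, 1] <- 1; onehot[2, 1, 1, 2] <- 1
  A <- unlearnr:::.resample_operator(2, 1, n_out = 3, spacing = 0.5,
                                     method = "linear")
  ch <- vapply(1:2, function(k) as.numeric(A %*% onehot[, 1, 1, k]),
               numeric(3))
  expect_equal(ch[2, ], c(0.5, 0.5))       # hand-evaluated midpoint weights
  expect_equal(th(ch), c(1L, 1L, 2L))
})
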