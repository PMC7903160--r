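test_that("phantom rendering is deterministic and scales linearly", {
  a <- generate_phantom(60, "female", scanner_effect(), seed = 9)
  b <- generate_phantom(60, "female", scanner_effect(), seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a$image, generate_phantom(60, "female", scanner_effect(), seed = 10)$image))
  # doubling intensity_scale doubles the noise-free image
  e1 <- scanner_effect(intensity_scale = 1, noise_sd = 0)
  e2 <- scanner_effect(intensity_scale = 2, noise_sd = 0)
  i1 <- generate_phantom(50, "male", e1, seed = 1)$image
  i2 <- generate_phantom(50, "male", e2, seed = 1)$image
  expect_equal(i2, 2 * i1, tolerance = 1e-12)
  expect_error(generate_phantom(50, size = 8), class = "unlearnr_error_size")
  expect_error(scanner_effect(intensity_scale = 0),
               class = "unlearnr_error_effect")
})

test_that("the central cavity grows monotonically with age", {
  cavity_px <- function(age) {
    tm <- generate_phantom(age, "female", scanner_effect(), seed = 1)$tissue_map
    size <- nrow(tm)
    ctr <- (size + 1) / 2
    r <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
    sum(tm == 2L & r < size / 4)
  }
  counts <- vapply(seq(40, 90, by = 10), cavity_px, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("generated datasets match their design", {
  design <- study_design(n_sites = 3, per_site_n = c(8, 5, 7), size = 16,
                         seed = 11)
  ds <- generate_dataset(design)
  expect_equal(ds$per_domain_counts, c(8L, 5L, 7L))
  expect_equal(unlearnr:::dataset_domains(ds),
               rep(1:3, c(8, 5, 7)))
  # images are z-normalised
  expect_equal(mean(ds$samples[[1]]$image), 0, tolerance = 1e-9)
  expect_equal(stats::sd(ds$samples[[1]]$image), 1, tolerance = 1e-9)
  # identical call reproduces the dataset bit for bit
  expect_identical(generate_dataset(design)$samples[[3]]$image,
                   ds$samples[[3]]$image)
})

test_that("overlap designs share exactly the configured window", {
  r <- make_overlap_ranges(10, full_range = c(25, 85))
  expect_equal(r[[1]][2] - r[[2]][1], 10)
  expect_equal(r[[1]][1], 25); expect_equal(r[[2]][2], 85)
  ds <- generate_dataset(study_design(2, 200, age_ranges = r, size = 16,
                                      seed = 3))
  ages <- vapply(ds$samples, `[[`, numeric(1), "age")
  d <- unlearnr:::dataset_domains(ds)
  expect_gte(min(ages[d == 1]), 25); expect_lte(max(ages[d == 1]), 60)
  expect_gte(min(ages[d == 2]), 50); expect_lte(max(ages[d == 2]), 85)
  expect_error(make_overlap_ranges(100), class = "unlearnr_error_design")
})

test_that("site-correlated confounds hit the configured fraction", {
  n <- 400
  ds <- generate_dataset(study_design(
    2, n, size = 16, confound = list(name = "sex", correlate = "site",
                                     fraction = 0.8), seed = 5))
  d <- unlearnr:::dataset_domains(ds)
  sex <- vapply(ds$samples, function(s) s$confounds$sex, character(1))
  male1 <- mean(sex[d == 1] == "male")
  # within 3 binomial SDs of 0.8 at this n
  expect_lt(abs(male1 - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  expect_lt(abs(mean(sex[d == 2] == "male") - 0.2),
            3 * sqrt(0.8 * 0.2 / n))
  expect_error(study_design(2, 10, confound = list(name = "sex",
                                                   correlate = "site",
                                                   fraction = 0.3)),
               class = "unlearnr_error_design")
})

test_that("dataset summaries report the design's own quantities", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 30,
                     label_availability = c(1, 0),
                     confound = list(name = "sex", correlate = "none"))
  tab <- describe_dataset(ds)
  expect_equal(tab$n, c(30, 30))
  expect_equal(tab$labelled_fraction, c(1, 0))
  # balanced confound: fraction 0.5 within binomial error
  expect_lt(abs(tab$sex_mean[1] - 0.5), 3 * sqrt(0.25 / 30))
})

test_that("scanner signal exists iff site effects differ", {
  # raw-pixel probe: distinct effects -> far above chance;
  # identical effects -> within the binomial interval of chance
  flat_pixels <- function(ds) t(vapply(ds$samples, function(s)
    as.numeric(s$image), numeric(16 * 16)))
  ds1 <- tiny_dataset(n_sites = 2, per_site_n = 60, seed = 21)
  p1 <- probe_scanner_information(flat_pixels(ds1),
                                  unlearnr:::dataset_domains(ds1), seed = 1)
  expect_gt(p1$accuracy, 80)
  same <- rep(list(scanner_effect(bias_amplitude = 0.1)), 2)
  ds2 <- generate_dataset(study_design(2, 60, effects = same, size = 16,
                                       seed = 22))
  p2 <- probe_scanner_information(flat_pixels(ds2),
                                  unlearnr:::dataset_domains(ds2), seed = 1)
  n_eval <- p2$n_eval
  expect_lt(abs(p2$accuracy - 50), 100 * 2.6 * sqrt(0.25 / n_eval))
})

test_that("the age signal is recoverable from single-site phantoms", {
  ds <- generate_dataset(study_design(1, 120, size = 16, biological_sd = 6,
                                      seed = 31))
  ages <- vapply(ds$samples, `[[`, numeric(1), "age")
  # cavity area measured from the rendered tissue maps predicts age with an
  # error far below the age-range SD
  area <- vapply(ds$samples, function(s) sum(s$tissue_map == 2L &
    row(s$tissue_map) > 4 & row(s$tissue_map) < 13), numeric(1))
  fit <- stats::lm(ages ~ area)
  mae <- mean(abs(stats::residuals(fit)))
  expect_lt(mae, 0.5 * stats::sd(ages))
})

test_that("datasets round-trip through the on-disk layout", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 3)
  dir <- tempfile("dataset")
  meta <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  back <- read_dataset(dir)
  expect_equal(length(back), length(ds))
  expect_equal(back$samples[[1]]$image, ds$samples[[1]]$image,
               tolerance = 1e-6)
  expect_equal(unlearnr:::dataset_domains(back),
               unlearnr:::dataset_domains(ds))
})
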