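# Synthetic multi-scanner phantom generator. Produces 2D head-like phantoms
# with three tissue compartments (outer CSF ring, GM annulus, WM disc with a
# central CSF-filled cavity) whose geometry carries an age signal, plus
# per-site acquisition effects (gamma contrast, smooth multiplicative bias
# field, noise, global intensity scale) emulating scanner/protocol variance.

#' Describe one scanner's acquisition effect
#'
#' @param intensity_scale global multiplicative factor (> 0). Note that the
#'   per-image normalisation applied downstream removes a pure scale, so the
#'   durable scanner signatures are `contrast_gamma`, the bias field and the
#'   noise level.
#' @param bias_amplitude amplitude of the smooth low-frequency multiplicative
#'   bias field (0 disables it).
#' @param bias_coefs numeric(5) coefficients of the bias basis
#'   (x, y, xy, x^2-1/3, y^2-1/3 over [-1,1]^2); defaults to a fixed pattern.
#' @param noise_sd additive Gaussian noise sd (>= 0).
#' @param contrast_gamma exponent applied to normalised tissue intensities
#'   (> 0); changes relative tissue contrast.
#' @return An object of class `scanner_effect`.
#' @export
scanner_effect <- function(intensity_scale = 1, bias_amplitude = 0,
                           bias_coefs = c(1, -0.5, 0.3, 0.7, -0.6),
                           noise_sd = 0.02, contrast_gamma = 1) {
  if (intensity_scale <= 0 || contrast_gamma <= 0 || noise_sd < 0)
    stop_unlearnr("unlearnr_error_effect",
                  "require intensity_scale > 0, contrast_gamma > 0, noise_sd >= 0")
  structure(list(intensity_scale = intensity_scale,
                 bias_amplitude = bias_amplitude,
                 bias_coefs = rep_len(bias_coefs, 5),
                 noise_sd = noise_sd,
                 contrast_gamma = contrast_gamma),
            class = "scanner_effect")
}

#' Distinct default acquisition effects for N sites
#'
#' A fixed, deterministic family of clearly distinct scanner signatures
#' (increasing gamma, rotated bias patterns, increasing noise), used as the
#' default study condition in which scanner information is present and
#' recoverable from the images.
#'
#' @param n_sites number of sites.
#' @return List of [scanner_effect()] objects.
#' @export
default_site_effects <- function(n_sites) {
  # Moderate, realistic inter-scanner differences: harmonisation addresses
  # subtle protocol/hardware variation, not grossly different modalities.
  lapply(seq_len(n_sites), function(i) {
    rot <- c(1, -0.5, 0.3, 0.7, -0.6)
    rot <- rot[((seq_len(5) + i - 2) %% 5) + 1] * (-1)^i
    scanner_effect(intensity_scale = 0.9 + 0.1 * (i - 1),
                   bias_amplitude = 0.06 + 0.02 * (i - 1),
                   bias_coefs = rot,
                   noise_sd = 0.02 + 0.004 * (i - 1),
                   contrast_gamma = 0.92 + 0.08 * (i - 1))
  })
}

# Geometry of the phantom at a given age/sex; radii in pixels.
.phantom_geometry <- function(age, sex, size) {
  sex_num <- if (is.character(sex)) as.integer(sex == "male") else as.integer(sex)
  r_head <- 0.44 * size
  r_gm_outer <- r_head - 0.05 * size
  t_gm <- size * (0.14 - 0.0006 * age)
  r_wm_outer <- r_gm_outer - t_gm
  r_vent <- size * (0.04 + 0.0012 * age)
  # sex enters only as a lateral offset of the central cavity, orthogonal to
  # the radial age signal
  cx_off <- 0.03 * size * (sex_num - 0.5) * 2
  list(r_head = r_head, r_gm_outer = r_gm_outer,
       r_wm_outer = r_wm_outer, r_vent = r_vent, cx_off = cx_off)
}

#' Generate one synthetic head phantom
#'
#' Renders a 2D phantom with three tissue compartments (outer ring CSF,
#' annulus GM, inner disc WM with a central CSF-filled cavity). The central
#' cavity radius grows with age and the GM annulus thins with age, giving a
#' monotone, recoverable age signal; sex induces a small geometric offset.
#' The scanner effect is applied as gamma contrast, multiplicative bias
#' field and intensity scale, followed by additive Gaussian noise.
#'
#' @param age age in years.
#' @param sex `"male"`/`"female"` (or 1/0).
#' @param effect a [scanner_effect()].
#' @param size image side length in pixels (default 32; must be >= 16).
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments and the seed.
#' @return `list(image = size x size matrix, tissue_map = integer matrix)`
#'   with tissue codes 1 background, 2 CSF, 3 GM, 4 WM.
#' @export
generate_phantom <- function(age, sex = "female", effect = scanner_effect(),
                             size = 32, seed = 1) {
  if (size < 16)
    stop_unlearnr("unlearnr_error_size",
                  "size too small for the phantom geometry (min 16)")
  g <- .phantom_geometry(age, sex, size)
  ctr <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  r_out <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  r_in <- sqrt((xs - ctr - g$cx_off)^2 + (ys - ctr)^2)
  tissue <- matrix(1L, size, size)                 # background
  tissue[r_out <= g$r_head] <- 2L                  # CSF ring
  tissue[r_out <= g$r_gm_outer] <- 3L              # GM annulus
  tissue[r_out <= g$r_wm_outer] <- 4L              # WM disc
  tissue[r_in <= g$r_vent & tissue == 4L] <- 2L    # central CSF cavity
  base <- c(0.05, 0.25, 0.55, 0.85)[tissue]
  img <- matrix(base, size, size)^effect$contrast_gamma
  u <- (xs - ctr) / (size / 2)
  v <- (ys - ctr) / (size / 2)
  basis <- effect$bias_coefs[1] * u + effect$bias_coefs[2] * v +
    effect$bias_coefs[3] * u * v +
    effect$bias_coefs[4] * (u^2 - 1 / 3) +
    effect$bias_coefs[5] * (v^2 - 1 / 3)
  img <- img * (1 + effect$bias_amplitude * basis) * effect$intensity_scale
  img <- img + with_seed(seed,
                         matrix(stats::rnorm(size * size,
                                             sd = effect$noise_sd), size, size))
  list(image = img, tissue_map = tissue)
}

#' Define a multi-site study design
#'
#' @param n_sites number of sites N.
#' @param per_site_n sample count per site (recycled to N).
#' @param effects list of N [scanner_effect()]s
#'   (default [default_site_effects()]).
#' @param age_ranges list of N length-2 vectors of per-site age ranges
#'   (uniform sampling); default `c(25, 85)` everywhere.
#' @param confound optional confound specification:
#'   `list(name = "sex", correlate = "site"|"age"|"none", fraction = 0.8)`.
#'   `correlate = "site"` gives odd sites a male fraction of `fraction` and
#'   even sites `1 - fraction`; `correlate = "age"` flips the fraction at the
#'   design's median age; `"none"` is balanced (0.5).
#' @param label_availability fraction of samples per site with a main-task
#'   label (recycled; default 1).
#' @param biological_sd standard deviation (years) of the per-subject gap
#'   between chronological age and the "biological age" that drives the
#'   phantom geometry. Real brain-age models face an irreducible error of a
#'   few years because anatomy tracks chronological age only loosely; this
#'   term reproduces that floor (default 6 years).
#' @param size phantom side length in pixels.
#' @param seed master seed; all randomness derives from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_sites, per_site_n, effects = NULL,
                         age_ranges = NULL, confound = NULL,
                         label_availability = 1, biological_sd = 6,
                         size = 32, seed = 1) {
  per_site_n <- rep_len(as.integer(per_site_n), n_sites)
  if (any(per_site_n < 1))
    stop_unlearnr("unlearnr_error_design", "per_site_n must be >= 1")
  if (is.null(effects)) effects <- default_site_effects(n_sites)
  if (length(effects) != n_sites)
    stop_unlearnr("unlearnr_error_design", "one scanner_effect per site")
  if (is.null(age_ranges))
    age_ranges <- rep(list(c(25, 85)), n_sites)
  if (!is.null(confound)) {
    f <- confound$fraction %||% 0.5
    if (f < 0.5 || f > 1)
      stop_unlearnr("unlearnr_error_design",
                    "confound fraction must lie in [0.5, 1]")
  }
  structure(list(n_sites = as.integer(n_sites), per_site_n = per_site_n,
                 effects = effects, age_ranges = age_ranges,
                 confound = confound,
                 label_availability = rep_len(label_availability, n_sites),
                 biological_sd = biological_sd,
                 size = size, seed = as.integer(seed)),
            class = "study_design")
}

#' Age ranges for a two-site overlap design
#'
#' Splits a full age span symmetrically into two site ranges sharing exactly
#' `overlap_years` years, the biased-domain study condition.
#'
#' @param overlap_years width of the shared window in years.
#' @param full_range total span (default `c(25, 85)`).
#' @return List of two length-2 ranges.
#' @export
make_overlap_ranges <- function(overlap_years, full_range = c(25, 85)) {
  span <- diff(full_range)
  if (overlap_years < 0 || overlap_years > span)
    stop_unlearnr("unlearnr_error_design", "overlap outside [0, span]")
  w <- (span + overlap_years) / 2
  list(c(full_range[1], full_range[1] + w),
       c(full_range[2] - w, full_range[2]))
}

#' Generate a multi-site phantom dataset
#'
#' Samples ages per site from the design's age ranges, assigns the confound
#' with the configured site or age correlation, renders each phantom with its
#' site's scanner effect, z-normalises the images, and sets the main-label
#' availability flags. Fully deterministic given the design (seed included).
#'
#' @param design a [study_design()].
#' @return A [multisite_dataset()]; each sample carries the true age as
#'   `main_label`, the tissue map in `$tissue_map`, and the confound value.
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "study_design"))
  conf <- design$confound
  med_age <- stats::median(unlist(design$age_ranges))
  samples <- list()
  idx <- 0L
  for (site in seq_len(design$n_sites)) {
    rng <- design$age_ranges[[site]]
    n <- design$per_site_n[site]
    ages <- with_seed(split_seed(design$seed, site * 7919L),
                      stats::runif(n, rng[1], rng[2]))
    bio_ages <- with_seed(split_seed(design$seed, site * 7919L + 3L),
                          pmin(100, pmax(0, ages +
                            stats::rnorm(n, 0, design$biological_sd %||% 0))))
    sex <- .assign_confound(conf, site, ages, med_age,
                            split_seed(design$seed, site * 7919L + 1L))
    labelled <- with_seed(split_seed(design$seed, site * 7919L + 2L), {
      k <- round(design$label_availability[site] * n)
      sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    })
    for (j in seq_len(n)) {
      idx <- idx + 1L
      ph <- generate_phantom(bio_ages[j], sex[j], design$effects[[site]],
                             size = design$size,
                             seed = split_seed(design$seed, 100000L + idx))
      im <- ph$image
      s <- stats::sd(im)
      im <- (im - mean(im)) / s
      smp <- new_sample(im, domain_label = site,
                        main_label = if (labelled[j]) ages[j] else NULL,
                        confounds = if (is.null(conf)) list() else
                          stats::setNames(list(sex[j]), conf$name %||% "sex"),
                        in_p = labelled[j])
      smp$tissue_map <- ph$tissue_map
      smp$age <- ages[j]               # kept even when the label is withheld
      samples[[idx]] <- smp
    }
  }
  multisite_dataset(samples, design$n_sites)
}

.assign_confound <- function(conf, site, ages, med_age, seed) {
  n <- length(ages)
  if (is.null(conf)) return(rep("female", n))
  f <- conf$fraction %||% 0.5
  p_male <- switch(conf$correlate %||% "none",
    site = if (site %% 2L == 1L) f else 1 - f,
    age  = ifelse(ages > med_age, f, 1 - f),
    none = 0.5,
    stop_unlearnr("unlearnr_error_design", "unknown confound correlate"))
  with_seed(seed,
            ifelse(stats::runif(n) < p_male, "male", "female"))
}

#' Use tissue maps as the main-task labels
#'
#' Converts a generated phantom dataset to the segmentation task: each
#' sample's main label becomes its ground-truth tissue map; samples whose
#' label availability flag is off keep no label (`in_p = FALSE`) and
#' contribute only to scanner unlearning (semi-supervised training).
#'
#' @param dataset a [multisite_dataset()] from [generate_dataset()].
#' @return The converted dataset.
#' @export
as_segmentation_dataset <- function(dataset) {
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    if (is.null(s$tissue_map))
      stop_unlearnr("unlearnr_error_label", "samples carry no tissue maps")
    dataset$samples[[i]]$main_label <- if (s$in_p) s$tissue_map else NULL
  }
  dataset
}

#' Write a generated dataset to disk
#'
#' Images and tissue maps as NIfTI, metadata as a CSV sidecar (sample id,
#' site, age, confounds, label availability) — the same on-disk interface the
#' real-data path consumes.
#'
#' @param dataset a [multisite_dataset()].
#' @param dir output directory (created if needed).
#' @return The metadata data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    id <- sprintf("sub-%04d", i)
    write_volume(s$image, file.path(dir, paste0(id, "_img.nii.gz")))
    if (!is.null(s$tissue_map))
      write_volume(s$tissue_map, file.path(dir, paste0(id, "_tissue.nii.gz")))
    data.frame(id = id, site = s$domain_label,
               age = if (!is.null(s$age)) s$age else NA_real_,
               sex = if (length(s$confounds)) s$confounds[[1]] else NA,
               labelled = s$in_p)
  })
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  invisible(meta)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the NIfTI files and `participants.csv`.
#' @return A [multisite_dataset()].
#' @export
read_dataset <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "participants.csv"))
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    img <- as.array(RNifti::readNifti(
      file.path(dir, paste0(meta$id[i], "_img.nii.gz"))))
    img <- array(as.numeric(img), dim(img))
    s <- new_sample(img, domain_label = meta$site[i],
                    main_label = if (isTRUE(meta$labelled[i])) meta$age[i] else NULL,
                    confounds = if (!is.null(meta$sex)) list(sex = meta$sex[i])
                    else list(),
                    in_p = isTRUE(meta$labelled[i]))
    tp <- file.path(dir, paste0(meta$id[i], "_tissue.nii.gz"))
    if (file.exists(tp)) {
      tm <- as.array(RNifti::readNifti(tp))
      s$tissue_map <- array(as.integer(round(tm)), dim(tm))
    }
    s$age <- meta$age[i]
    s
  })
  multisite_dataset(samples)
}
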