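# Core data model: a Sample (one image with its site label, optional main-task
# label, optional confound labels, and subset-membership flags) and a
# MultiSiteDataset (ordered collection of Samples from N scanners).

#' Construct a sample
#'
#' One image together with its acquisition-site label, an optional main-task
#' label (age in years or a per-voxel class map), optional confound labels,
#' and the subset-membership flags that route the sample to the different
#' loss functions: `in_p` (main-task loss), `in_u` (scanner unlearning),
#' and per-confound `in_c` flags.
#'
#' @param image numeric matrix or array (finite values).
#' @param domain_label integer site label in 1..N.
#' @param main_label age (years), an integer class map, or `NULL`.
#' @param confounds named list of confound values (categorical or continuous).
#' @param in_p logical; must be `FALSE` when `main_label` is absent.
#' @param in_u logical; sample participates in scanner unlearning.
#' @param in_c named logical vector over confound names.
#' @return An object of class `unlearn_sample`.
#' @export
new_sample <- function(image, domain_label, main_label = NULL,
                       confounds = list(), in_p = !is.null(main_label),
                       in_u = TRUE, in_c = NULL) {
  if (!is.numeric(image) || !all(is.finite(image)))
    stop_unlearnr("unlearnr_error_nonfinite", "image must be finite numeric")
  domain_label <- as.integer(domain_label)
  if (is.na(domain_label) || domain_label < 1L)
    stop_unlearnr("unlearnr_error_domain", "domain_label must be >= 1")
  if (isTRUE(in_p) && is.null(main_label))
    stop_unlearnr("unlearnr_error_label",
                  "in_p requires a main-task label")
  if (is.null(in_c)) {
    in_c <- stats::setNames(rep(TRUE, length(confounds)), names(confounds))
  }
  structure(list(image = image, main_label = main_label,
                 domain_label = domain_label, confounds = confounds,
                 in_p = isTRUE(in_p), in_u = isTRUE(in_u), in_c = in_c),
            class = "unlearn_sample")
}

#' Construct a multi-site dataset
#'
#' @param samples list of [new_sample()] objects.
#' @param n_domains number of sites N; defaults to the largest domain label.
#' @return An object of class `multisite_dataset` with fields `samples`,
#'   `n_domains` and `per_domain_counts`.
#' @export
multisite_dataset <- function(samples, n_domains = NULL) {
  if (!length(samples))
    stop_unlearnr("unlearnr_error_empty", "dataset has no samples")
  d <- vapply(samples, function(s) s$domain_label, integer(1))
  if (is.null(n_domains)) n_domains <- max(d)
  n_domains <- as.integer(n_domains)
  counts <- tabulate(d, nbins = n_domains)
  if (any(counts == 0L))
    stop_unlearnr("unlearnr_error_domain",
                  "every domain in 1..N must have at least one sample")
  if (any(d > n_domains))
    stop_unlearnr("unlearnr_error_domain", "domain label exceeds n_domains")
  structure(list(samples = samples, n_domains = n_domains,
                 per_domain_counts = counts),
            class = "multisite_dataset")
}

#' @export
print.multisite_dataset <- function(x, ...) {
  cat(sprintf("<multisite_dataset> %d samples, %d sites (counts: %s)\n",
              length(x$samples), x$n_domains,
              paste(x$per_domain_counts, collapse = ", ")))
  invisible(x)
}

#' @export
length.multisite_dataset <- function(x) length(x$samples)

# Vector accessors over a dataset ---------------------------------------------

dataset_domains <- function(dataset)
  vapply(dataset$samples, function(s) s$domain_label, integer(1))

dataset_flags <- function(dataset, which = c("in_p", "in_u")) {
  which <- match.arg(which)
  vapply(dataset$samples, function(s) isTRUE(s[[which]]), logical(1))
}

dataset_confound_flags <- function(dataset, confound)
  vapply(dataset$samples,
         function(s) isTRUE(s$in_c[[confound]]), logical(1))

dataset_ages <- function(dataset)
  vapply(dataset$samples,
         function(s) if (is.numeric(s$main_label) && length(s$main_label) == 1)
           s$main_label else NA_real_, numeric(1))

dataset_confound <- function(dataset, confound)
  vapply(dataset$samples, function(s) {
    v <- s$confounds[[confound]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))

# Stack images into an (H, W, 1, n) tensor, z-normalising each image so the
# model input matches the volume-preprocessing contract.
dataset_tensor <- function(dataset, indices = NULL, normalise = TRUE) {
  if (is.null(indices)) indices <- seq_along(dataset$samples)
  img1 <- dataset$samples[[indices[1]]]$image
  d <- dim(img1)
  x <- array(0, c(d[1], d[2], 1L, length(indices)))
  for (i in seq_along(indices)) {
    im <- dataset$samples[[indices[i]]]$image
    if (normalise) {
      s <- stats::sd(im)
      im <- if (s > 0) (im - mean(im)) / s else im - mean(im)
    }
    x[, , 1L, i] <- im
  }
  x
}

# Stack per-voxel label maps into an (H, W, n) integer array.
dataset_labelmaps <- function(dataset, indices = NULL) {
  if (is.null(indices)) indices <- seq_along(dataset$samples)
  d <- dim(dataset$samples[[indices[1]]]$main_label)
  y <- array(NA_integer_, c(d[1], d[2], length(indices)))
  for (i in seq_along(indices)) {
    m <- dataset$samples[[indices[i]]]$main_label
    if (!is.null(m)) y[, , i] <- m
  }
  y
}

#' Summarise a multi-site dataset
#'
#' Per-site sample count, age statistics, confound fractions and main-label
#' availability — the generator's self-check surface.
#'
#' @param dataset a [multisite_dataset()].
#' @return A data.frame with one row per site.
#' @export
describe_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "multisite_dataset"))
  d <- dataset_domains(dataset)
  ages <- vapply(dataset$samples, function(s) {
    a <- s$age
    if (is.null(a)) a <- if (is.numeric(s$main_label) &&
                             length(s$main_label) == 1) s$main_label else NA
    as.numeric(a)
  }, numeric(1))
  labelled <- vapply(dataset$samples,
                     function(s) !is.null(s$main_label), logical(1))
  conf_names <- unique(unlist(lapply(dataset$samples,
                                     function(s) names(s$confounds))))
  out <- lapply(seq_len(dataset$n_domains), function(n) {
    idx <- which(d == n)
    row <- data.frame(site = n, n = length(idx),
                      age_mean = mean(ages[idx], na.rm = TRUE),
                      age_min = suppressWarnings(min(ages[idx], na.rm = TRUE)),
                      age_max = suppressWarnings(max(ages[idx], na.rm = TRUE)),
                      labelled_fraction = mean(labelled[idx]))
    for (cn in conf_names) {
      v <- lapply(dataset$samples[idx], function(s) s$confounds[[cn]])
      v <- v[!vapply(v, is.null, logical(1))]
      row[[paste0(cn, "_mean")]] <- if (!length(v)) NA_real_
        else if (is.character(v[[1]])) mean(unlist(v) == "male")
        else mean(as.numeric(unlist(v)))
    }
    row
  })
  do.call(rbind, out)
}
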