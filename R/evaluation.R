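# Harmonisation and task metrics: the frozen-feature scanner probe (post-hoc
# classification accuracy vs. chance — the success metric for unlearning),
# per-scanner MAE and per-tissue Dice.

#' Chance level of an N-way classifier
#'
#' @param n_domains number of classes (>= 2).
#' @return Percentage, `100 / n_domains` (e.g. 6.25 for 16 sites).
#' @export
chance_level <- function(n_domains) {
  if (n_domains < 2)
    stop_unlearnr("unlearnr_error_domain", "need at least 2 domains")
  100 / n_domains
}

#' Probe residual scanner (or confound) information in frozen features
#'
#' Trains a fresh classifier head — the same two-layer architecture as the
#' training-time domain classifier — on the frozen feature representation
#' and reports its held-out accuracy. Accuracy near 100 x (1/N) % (chance)
#' means the representation carries no class information; accuracy well
#' above chance means information remains. The split is stratified 80/20 by
#' class and seeded; features are standardised with training-split
#' statistics; the head is trained to convergence with early stopping.
#'
#' @param features matrix (samples x F) of frozen features (e.g. from
#'   [model_features()]).
#' @param labels integer class labels (1..N).
#' @param split training fraction (default 0.8).
#' @param seed seed for the split and head initialisation.
#' @param hidden hidden width of the probe head.
#' @param lr,max_epochs,patience optimiser settings for the probe fit.
#' @return An object of class `probe_result`: `accuracy` (% correct on the
#'   held-out split), `chance` (%), `confusion` (matrix of counts),
#'   `n_eval`.
#' @export
probe_scanner_information <- function(features, labels, split = 0.8,
                                      seed = 1, hidden = 16, lr = 5e-3,
                                      max_epochs = 400, patience = 20) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  N <- length(unique(labels))
  if (N < 2)
    stop_unlearnr("unlearnr_error_domain", "need at least 2 classes")
  K <- max(labels)
  tr <- unlist(lapply(sort(unique(labels)), function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2)
      stop_unlearnr("unlearnr_error_split",
                    sprintf("class %d has fewer than 2 samples", k))
    with_seed(split_seed(seed, 31L + k),
              sample(idx, max(1L, round(split * length(idx)))))
  }))
  te <- setdiff(seq_along(labels), tr)
  if (length(te) == 0 || !all(sort(unique(labels)) %in% labels[te]))
    stop_unlearnr("unlearnr_error_split",
                  "every class must appear in the evaluation split")
  mu <- colMeans(features[tr, , drop = FALSE])
  sdv <- pmax(apply(features[tr, , drop = FALSE], 2, stats::sd), 1e-8)
  Xtr <- sweep(sweep(features[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(features[te, , drop = FALSE], 2, mu), 2, sdv, "/")
  head <- with_seed(split_seed(seed, 997L),
                    list(fc1 = nn_dense(ncol(Xtr), hidden),
                         fc2 = nn_dense(hidden, K)))
  opt <- adam_state()
  ytr <- labels[tr]
  onehot <- .onehot(ytr, K)
  best <- Inf; wait <- 0L
  for (ep in seq_len(max_epochs)) {
    fwd <- forward_head(head, Xtr)
    loss <- domain_classification_loss(fwd$probs, ytr)
    dlogits <- (fwd$probs - onehot) / nrow(Xtr)
    bh <- backward_head(head, fwd, Xtr, dlogits)
    head <- adam_update(head, bh$grads, opt, lr, path = "probe")
    if (loss < best - 1e-6) { best <- loss; wait <- 0L }
    else { wait <- wait + 1L; if (wait >= patience) break }
  }
  pte <- forward_head(head, Xte)$probs
  predicted <- max.col(pte, ties.method = "first")
  acc <- 100 * mean(predicted == labels[te])
  confusion <- table(factor(labels[te], levels = seq_len(K)),
                     factor(predicted, levels = seq_len(K)))
  structure(list(accuracy = acc, chance = chance_level(N),
                 confusion = unclass(confusion), n_eval = length(te)),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe_result> accuracy %.1f%% (chance %.2f%%, n = %d)\n",
              x$accuracy, x$chance, x$n_eval))
  invisible(x)
}

#' Per-scanner mean absolute error
#'
#' @param predicted_ages,true_ages numeric vectors (years).
#' @param domain_labels integer site per sample.
#' @return `list(per_domain = named numeric (years), overall = pooled MAE)`.
#' @export
per_scanner_mae <- function(predicted_ages, true_ages, domain_labels) {
  if (length(predicted_ages) != length(true_ages) ||
      length(true_ages) != length(domain_labels))
    stop_unlearnr("unlearnr_error_shape", "inputs must share length")
  if (!length(true_ages))
    stop_unlearnr("unlearnr_error_empty", "no samples")
  err <- abs(predicted_ages - true_ages)
  per <- tapply(err, factor(domain_labels), mean)
  list(per_domain = stats::setNames(as.numeric(per), names(per)),
       overall = mean(err))
}

#' Hard Dice score per tissue class
#'
#' @param predicted_map,label_map integer categorical maps on the same grid.
#' @param classes integer class codes to score (default: all classes in the
#'   label map except the lowest, treated as background).
#' @return Named numeric of Dice coefficients in `[0, 1]`.
#' @export
per_tissue_dice <- function(predicted_map, label_map, classes = NULL) {
  if (!identical(dim(predicted_map), dim(label_map)))
    stop_unlearnr("unlearnr_error_shape", "maps must share a grid")
  if (is.null(classes)) {
    cls <- sort(unique(as.integer(label_map)))
    classes <- if (length(cls) > 1) cls[-1] else cls
  }
  out <- vapply(classes, function(k) {
    p <- predicted_map == k
    t_ <- label_map == k
    denom <- sum(p) + sum(t_)
    if (denom == 0) return(1)
    2 * sum(p & t_) / denom
  }, numeric(1))
  stats::setNames(out, paste0("class_", classes))
}

#' Tidy metric table for a trained model
#'
#' Computes the task metric (per-site MAE or mean Dice) and, when features
#' are supplied, the scanner probe, returned as one row per site x metric —
#' convenient for CSV export and plotting.
#'
#' @param fitted an `unlearn_fit`.
#' @param dataset evaluation [multisite_dataset()].
#' @param probe logical; run the scanner probe on Qrepr (default TRUE).
#' @param seed probe seed.
#' @return data.frame with columns `site`, `metric`, `value`.
#' @export
evaluate_model <- function(fitted, dataset, probe = TRUE, seed = 1) {
  model <- fitted$model
  d <- dataset_domains(dataset)
  rows <- list()
  if (model$task %in% c("regression", "softlabel")) {
    pr <- predict(model, dataset)
    ages_hat <- if (model$task == "regression") pr else pr$age
    ages <- vapply(dataset$samples, function(s) s$age, numeric(1))
    mae <- per_scanner_mae(ages_hat, ages, d)
    for (nm in names(mae$per_domain))
      rows[[length(rows) + 1L]] <-
        data.frame(site = nm, metric = "mae_years",
                   value = mae$per_domain[[nm]])
    rows[[length(rows) + 1L]] <-
      data.frame(site = "all", metric = "mae_years", value = mae$overall)
  } else if (model$task == "segmentation") {
    seg <- predict(model, dataset)
    for (site in sort(unique(d))) {
      idx <- which(d == site)
      dice <- vapply(idx, function(i)
        mean(per_tissue_dice(seg[, , i], dataset$samples[[i]]$tissue_map,
                             classes = 2:4)), numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(site = as.character(site), metric = "mean_dice",
                   value = mean(dice))
    }
  }
  if (probe) {
    q <- model_features(model, dataset)
    pr <- probe_scanner_information(q, d, seed = seed)
    rows[[length(rows) + 1L]] <-
      data.frame(site = "all", metric = "scanner_probe_accuracy",
                 value = pr$accuracy)
    rows[[length(rows) + 1L]] <-
      data.frame(site = "all", metric = "scanner_probe_chance",
                 value = pr$chance)
  }
  do.call(rbind, rows)
}
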