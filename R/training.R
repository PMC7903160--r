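# Training: batch composition with the one-per-site constraint, unlearning
# subset policies, pretraining (main task + domain classifier), and the
# three-stage per-batch iterative unlearning procedure.

#' Training configuration
#'
#' @param task `"regression"`, `"softlabel"`, `"classification"` or
#'   `"segmentation"`.
#' @param mode `"normal"` (main task only) or `"unlearn"`.
#' @param alpha,beta weights of the domain and confusion losses.
#' @param confounds named list `name = n_classes` of confound heads to attach.
#' @param gamma,phi named per-confound weights (default 1 each).
#' @param lr Adam learning rate for the feature extractor and label
#'   predictor (stages 1 and 3).
#' @param lr_head Adam learning rate for the domain/confound classifier
#'   heads (stage 2 and the confound classification sub-steps). Kept higher
#'   than `lr` so the classifier stays accurate while the representation
#'   drifts — the confusion step is only informative against a
#'   well-fitted classifier.
#' @param lr_conf Adam learning rate for the confusion updates of the
#'   feature extractor (stage 3 and the confound confusion sub-steps). Kept
#'   well below `lr_head`: because Adam normalises gradient magnitudes, the
#'   adversarial balance is set by the learning-rate ratio, and the
#'   classifier must win the inner game for unlearning to remove (rather
#'   than merely hide) the information.
#' @param batch_size batch size (>= number of sites).
#' @param pretrain_epochs maximum pretraining epochs.
#' @param patience early-stopping patience (epochs) on validation task loss.
#' @param unlearn_epochs number of unlearning epochs.
#' @param val_fraction fraction held out (stratified by site) for validation.
#' @param feature_dim,width_scale,hidden architecture sizes.
#' @param bin_range,sigma soft-label parameters.
#' @param n_classes segmentation classes (incl. background).
#' @param attach U-Net attach point.
#' @param unlearn_scope `"attach"` (default for the encoder models): during
#'   the unlearning phase the convolutional bank is frozen at its pretrained
#'   value and stages 1 and 3 update the fully connected projection that
#'   produces Qrepr (plus the label predictor); the adversarial game is then
#'   played over a stationary feature distribution, which makes the
#'   information removal converge reliably at small scale. `"full"`: stages
#'   1 and 3 update the whole extractor (always used for the U-Net).
#' @param head_steps number of domain-classifier (stage 2) updates per batch
#'   during unlearning; keeping the classifier close to its optimum makes
#'   the confusion gradients informative.
#' @param lr_task_unlearn stage-1 learning rate during the unlearning phase
#'   (attach scope). The task is already pretrained; gentle maintenance
#'   updates prevent the main-task stage from re-injecting scanner
#'   information faster than the confusion stage removes it.
#' @param head_steps_full full-batch stage-2 updates per unlearning epoch in
#'   attach scope (the domain classifier is trained close to its optimum
#'   before every confusion phase).
#' @param conf_steps full-batch stage-3 confusion updates per unlearning
#'   epoch in attach scope.
#' @param head_reinit re-initialise the domain classifier every this many
#'   unlearning epochs (attach scope). Fresh adversaries find residual
#'   information that a warm-started classifier, stuck in a stale basin,
#'   can miss — the post-hoc probe is itself freshly initialised, so the
#'   training-time adversary must be comparably strong.
#' @param check_every evaluate the validation probe and task loss every this
#'   many unlearning epochs and keep the best checkpoint (lowest residual
#'   scanner/confound probe accuracy among checkpoints whose validation
#'   task loss is acceptable).
#' @param task_tolerance checkpoint acceptance bound: a checkpoint qualifies
#'   when its validation task loss is at most this multiple of the
#'   pretrain-exit validation task loss (for squared-error losses a factor
#'   1.5 corresponds to roughly a 22% MAE increase). Among qualifying
#'   checkpoints the one with the lowest residual-information score is
#'   kept; if none qualifies, the least-degraded checkpoint is kept.
#' @param head_hidden hidden width of the training-time domain/confound
#'   classifiers during the attach-scope unlearning phase.
#' @param ema_decay exponential-moving-average decay for the Qrepr
#'   projection, label predictor and normalisation statistics during the
#'   unlearning phase. The adversarial equilibrium oscillates — the
#'   direction of the residual scanner information rotates from epoch to
#'   epoch — and the Polyak-averaged representation cancels much of this
#'   rotating residue; checkpoints are scored, and the final model taken,
#'   at the averaged weights.
#' @param eq1_weighting when `TRUE` (default) the main-task loss is the sum
#'   over sites of the within-site mean (every site weighs equally); when
#'   `FALSE` it is the plain pooled mean, in which large sites dominate —
#'   the conventional baseline against which the per-site weighting and the
#'   unlearning are compared.
#' @param seed seed for initialisation, splits and batch order.
#' @return A named list of class `train_config`.
#' @export
train_config <- function(task = "regression", mode = "unlearn",
                         alpha = 1, beta = 10, confounds = list(),
                         gamma = NULL, phi = NULL,
                         lr = 1e-3, lr_head = 1e-2, lr_conf = 3e-3,
                         batch_size = 32,
                         pretrain_epochs = 40, patience = 10,
                         unlearn_epochs = 100, val_fraction = 0.2,
                         feature_dim = 16, width_scale = 0.5, hidden = 16,
                         bin_range = c(0, 100), sigma = 10,
                         n_classes = 4, attach = "A",
                         unlearn_scope = "attach", head_steps = 3,
                         lr_task_unlearn = 3e-4, head_steps_full = 100,
                         conf_steps = 100, head_reinit = 5, check_every = 5,
                         task_tolerance = 1.3, head_hidden = 16,
                         ema_decay = 0.92, eq1_weighting = TRUE, seed = 1) {
  nms <- names(confounds)
  if (is.null(gamma)) gamma <- stats::setNames(rep(1, length(confounds)), nms)
  if (is.null(phi)) phi <- stats::setNames(rep(1, length(confounds)), nms)
  structure(as.list(environment()), class = "train_config")
}

#' Unlearning subset policy
#'
#' Controls which samples receive the `in_u` (scanner unlearning) or
#' per-confound `in_c` flags: `"all"` flags everything; `"overlap"` flags
#' only samples whose age lies in the window shared by all sites (the
#' biased-domain condition); `"balanced_subset"` flags, per site, an
#' equal-count subsample of each confound category; `"custom_flags"` leaves
#' existing flags untouched.
#'
#' @param mode policy mode.
#' @param age_window optional explicit overlap window `c(lo, hi)`.
#' @param confound confound name (required for `"balanced_subset"`).
#' @param seed seed for the balanced subsampling.
#' @return A named list of class `unlearning_policy`.
#' @export
unlearning_policy <- function(mode = c("all", "overlap", "balanced_subset",
                                       "custom_flags"),
                              age_window = NULL, confound = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "balanced_subset" && is.null(confound))
    stop_unlearnr("unlearnr_error_policy",
                  "balanced_subset requires a confound name")
  structure(list(mode = mode, age_window = age_window,
                 confound = confound, seed = seed),
            class = "unlearning_policy")
}

#' Flag the unlearning subset of a dataset
#'
#' Updates `in_u` (for `"all"`/`"overlap"`) or the per-confound `in_c`
#' flags (for `"balanced_subset"`) according to the policy; `in_p` flags are
#' never touched.
#'
#' @param dataset a [multisite_dataset()].
#' @param policy an [unlearning_policy()].
#' @return The dataset with updated flags.
#' @export
select_unlearning_subset <- function(dataset, policy) {
  stopifnot(inherits(policy, "unlearning_policy"))
  d <- dataset_domains(dataset)
  ages <- vapply(dataset$samples,
                 function(s) s$age %||% NA_real_, numeric(1))
  flags <- switch(policy$mode,
    all = rep(TRUE, length(d)),
    custom_flags = NULL,
    overlap = {
      win <- policy$age_window
      if (is.null(win)) {
        lo <- max(tapply(ages, d, min, na.rm = TRUE))
        hi <- min(tapply(ages, d, max, na.rm = TRUE))
        win <- c(lo, hi)
      }
      if (win[1] > win[2])
        stop_unlearnr("unlearnr_error_policy", "site age ranges do not overlap")
      ages >= win[1] & ages <= win[2]
    },
    balanced_subset = NULL)
  if (policy$mode %in% c("all", "overlap")) {
    if (!any(flags))
      stop_unlearnr("unlearnr_error_policy", "empty unlearning subset")
    for (i in seq_along(dataset$samples))
      dataset$samples[[i]]$in_u <- flags[i]
  } else if (policy$mode == "balanced_subset") {
    cn <- policy$confound
    vals <- vapply(dataset$samples,
                   function(s) as.character(s$confounds[[cn]] %||% NA),
                   character(1))
    keep <- rep(FALSE, length(d))
    for (site in unique(d)) {
      idx <- which(d == site)
      tab <- table(vals[idx])
      n_min <- min(tab)
      for (lv in names(tab)) {
        cand <- idx[vals[idx] == lv]
        take <- with_seed(split_seed(policy$seed, site * 131L + match(lv, names(tab))),
                          sample(cand, n_min))
        keep[take] <- TRUE
      }
    }
    if (!any(keep))
      stop_unlearnr("unlearnr_error_policy", "empty unlearning subset")
    for (i in seq_along(dataset$samples)) {
      ic <- dataset$samples[[i]]$in_c
      ic[[cn]] <- keep[i]
      dataset$samples[[i]]$in_c <- ic
    }
  }
  dataset
}

#' Compose batches with at least one sample per site
#'
#' Allocates `batch_size` slots across sites proportionally to site size
#' (minimum one slot each), cycles reshuffled per-site orders so smaller
#' sites are oversampled (without augmentation), and sizes the epoch by the
#' largest site so each of its samples appears at least once.
#'
#' @param dataset a [multisite_dataset()] (or an integer vector of site
#'   labels).
#' @param batch_size total batch size (>= N).
#' @param seed shuffle seed; batches are deterministic given it.
#' @return List of integer index vectors.
#' @export
make_batches <- function(dataset, batch_size, seed = 1) {
  d <- if (inherits(dataset, "multisite_dataset"))
    dataset_domains(dataset) else as.integer(dataset)
  sites <- sort(unique(d))
  N <- length(sites)
  if (batch_size < N)
    stop_unlearnr("unlearnr_error_batch",
                  sprintf("batch_size %d < number of sites %d", batch_size, N))
  counts <- vapply(sites, function(s) sum(d == s), integer(1))
  # proportional slots with a floor of 1 (largest-remainder rounding)
  raw <- counts / sum(counts) * batch_size
  slots <- pmax(1L, floor(raw))
  while (sum(slots) < batch_size) {
    i <- which.max(raw - slots)
    slots[i] <- slots[i] + 1L
  }
  while (sum(slots) > batch_size) {
    cand <- which(slots > 1L)
    i <- cand[which.min((raw - slots)[cand])]
    slots[i] <- slots[i] - 1L
  }
  i_max <- which.max(counts)
  n_batches <- ceiling(counts[i_max] / slots[i_max])
  streams <- lapply(seq_along(sites), function(i) {
    idx <- which(d == sites[i])
    need <- n_batches * slots[i]
    reps <- ceiling(need / length(idx))
    unlist(lapply(seq_len(reps), function(r)
      with_seed(split_seed(seed, i * 1009L + r), sample(idx))))[seq_len(need)]
  })
  lapply(seq_len(n_batches), function(b) {
    unlist(lapply(seq_along(sites), function(i)
      streams[[i]][((b - 1L) * slots[i] + 1L):(b * slots[i])]))
  })
}

# ---- training state ---------------------------------------------------------

#' Create a training state
#'
#' @param model an `unlearn_model`.
#' @param config a [train_config()].
#' @return An object of class `training_state` holding the model, one Adam
#'   optimiser per parameter group, the phase (`"pretrain"`/`"unlearn"`), the
#'   epoch counter and the loss history.
#' @export
new_training_state <- function(model, config) {
  opt <- list(stage1 = adam_state(), stage2 = adam_state(),
              stage3 = adam_state())
  for (nm in names(model$params$confounds)) {
    opt[[paste0("cls_", nm)]] <- adam_state()
    opt[[paste0("conf_", nm)]] <- adam_state()
  }
  structure(list(model = model, opt = opt, phase = "pretrain", epoch = 0L,
                 history = list(), config = config),
            class = "training_state")
}

# Per-sample Eq.-1 weights: 1 / (batch count of the sample's site).
.eq1_weights <- function(d) {
  tab <- table(d)
  1 / as.numeric(tab[as.character(d)])
}

# One-hot (n x K) from integer labels.
.onehot <- function(labels, K) {
  M <- matrix(0, length(labels), K)
  M[cbind(seq_along(labels), as.integer(labels))] <- 1
  M
}

# ---- stage updates ----------------------------------------------------------

# Stage 1: main-task loss on the labelled samples; updates theta_repr (all of
# it during pretraining; only the Qrepr projection when the unlearning phase
# runs in "attach" scope) plus theta_p.
stage1_update <- function(state, x, y, d) {
  model <- state$model
  feat <- forward_features(model, x, training = TRUE)
  if (!is.null(feat$bn)) model$bn <- feat$bn
  pred <- forward_predictor(model, feat)
  tg <- .task_loss_grad(model, pred, y, d,
                        pooled = !(state$config$eq1_weighting %||% TRUE))
  if (!is.finite(tg$loss))
    stop_unlearnr("unlearnr_error_nonfinite", "non-finite main-task loss")
  lr <- state$config$lr
  if (model$type == "cnn_reg") {
    bp <- backward_predictor(model, pred, feat$q, tg$dout)
    ge <- backward_extractor(model, feat, bp$dq)
    if (.attach_scope(state)) ge <- ge["fc"]
    model$params$predictor <- adam_update(model$params$predictor, bp$grads,
                                          state$opt$stage1, lr, path = "p")
  } else {
    gseg <- conv1x1_backward(tg$dout, pred$fwd, model$params$predictor$outconv)
    ge <- unet_backward(model, feat, d_dd = gseg$dx)
    model$params$predictor <- adam_update(
      model$params$predictor, list(outconv = list(W = gseg$dW, b = gseg$db)),
      state$opt$stage1, lr, path = "p")
  }
  model$params$extractor <- adam_update(model$params$extractor, ge,
                                        state$opt$stage1, lr, path = "r")
  state$model <- model
  list(state = state, loss = tg$loss)
}

# Stage 2: domain-classification loss on the unlearning samples; fresh
# forward pass; updates theta_d only.
stage2_update <- function(state, x, d, head_name = "domain",
                          labels = NULL, opt_name = "stage2") {
  model <- state$model
  labels <- labels %||% d
  head <- if (head_name == "domain") model$params$domain
          else model$params$confounds[[head_name]]
  feat <- forward_features(model, x, training = TRUE)
  fwd <- forward_head(head, feat$q)
  K <- ncol(fwd$probs)
  loss <- domain_classification_loss(fwd$probs, labels)
  wgt <- if (head_name == "domain") state$config$alpha
         else state$config$gamma[[head_name]] %||% 1
  dlogits <- wgt * (fwd$probs - .onehot(labels, K)) / nrow(fwd$probs)
  bh <- backward_head(head, fwd, feat$q, dlogits)
  upd <- adam_update(head, bh$grads, state$opt[[opt_name]],
                     state$config$lr_head %||% state$config$lr,
                     path = head_name)
  if (head_name == "domain") state$model$params$domain <- upd
  else state$model$params$confounds[[head_name]] <- upd
  list(state = state, loss = loss)
}

# Stage 3: confusion loss through the frozen head; fresh forward pass;
# updates theta_repr only.
stage3_update <- function(state, x, head_name = "domain",
                          opt_name = "stage3") {
  model <- state$model
  head <- if (head_name == "domain") model$params$domain
          else model$params$confounds[[head_name]]
  feat <- forward_features(model, x, training = TRUE)
  fwd <- forward_head(head, feat$q)
  K <- ncol(fwd$probs)
  loss <- confusion_loss(fwd$probs)
  wgt <- if (head_name == "domain") state$config$beta
         else state$config$phi[[head_name]] %||% 1
  dlogits <- wgt * (fwd$probs - 1 / K) / nrow(fwd$probs)
  bh <- backward_head(head, fwd, feat$q, dlogits)
  ge <- backward_extractor(model, feat, bh$dq)
  if (.attach_scope(state)) ge <- ge["fc"]
  state$model$params$extractor <- adam_update(model$params$extractor, ge,
                                              state$opt[[opt_name]],
                                              state$config$lr_conf %||%
                                                state$config$lr,
                                              path = "r3")
  list(state = state, loss = loss)
}

.attach_scope <- function(state) {
  state$phase == "unlearn" &&
    identical(state$config$unlearn_scope %||% "attach", "attach") &&
    state$model$type == "cnn_reg"
}

# Task loss value + gradient at the predictor output, with per-site
# weighting (or plain pooled weighting when pooled = TRUE). y: numeric ages,
# soft-label matrix, integer classes, or an (H, W, n) integer label map for
# segmentation.
.task_loss_grad <- function(model, pred, y, d, pooled = FALSE) {
  if (pooled) d <- rep(1L, length(d))
  w <- .eq1_weights(d)
  switch(model$task,
    regression = {
      # the model regresses the standardised target; predictions are mapped
      # back to years at predict() time
      yz <- (y - model$y_center) / model$y_scale
      err <- as.numeric(pred$out) - yz
      list(loss = sum(tapply(err^2, d, mean)),
           dout = matrix(2 * err * w, ncol = 1))
    },
    softlabel = {
      per <- rowSums(ifelse(y > 0,
                            y * (log(pmax(y, .prob_floor)) -
                                   log(pmax(pred$probs, .prob_floor))), 0))
      list(loss = sum(tapply(per, d, mean)),
           dout = (pred$probs - y) * w)
    },
    classification = {
      K <- ncol(pred$probs)
      per <- -log(pmax(pred$probs[cbind(seq_along(y), as.integer(y))],
                       .prob_floor))
      list(loss = sum(tapply(per, d, mean)),
           dout = (pred$probs - .onehot(y, K)) * w)
    },
    segmentation = .dice_loss_grad(pred, y, d, model$n_classes))
}

# Soft multi-class Dice loss per sample (foreground classes 2..K averaged)
# and its gradient at the segmentation logits.
.dice_loss_grad <- function(pred, y, d, K, eps = 1e-5) {
  p <- pred$probs                        # (H, W, K, n)
  dm <- dim(p); V <- dm[1] * dm[2]; n <- dm[4]
  pv <- array(aperm(p, c(1, 2, 4, 3)), c(V, n, K))
  tv <- array(0, c(V, n, K))
  yv <- matrix(y, V, n)
  for (k in seq_len(K)) tv[, , k] <- (yv == k)
  num <- 2 * apply(pv * tv, c(2, 3), sum) + eps     # n x K
  den <- apply(pv, c(2, 3), sum) + apply(tv, c(2, 3), sum) + eps
  fg <- 2:K
  dice <- num / den
  per <- 1 - rowMeans(dice[, fg, drop = FALSE])
  w <- .eq1_weights(d)
  # dL_s/dp_{v,c} = -(1/|fg|) (2 t den - num)/den^2, foreground classes only
  gp <- array(0, c(V, n, K))
  for (k in fg) {
    coef_t <- 2 / den[, k]; coef_c <- num[, k] / den[, k]^2
    gp[, , k] <- -(1 / length(fg)) *
      (tv[, , k] * matrix(coef_t, V, n, byrow = TRUE) -
         matrix(coef_c, V, n, byrow = TRUE))
  }
  gp <- gp * array(matrix(w, V, n, byrow = TRUE), c(V, n, K))
  # through the per-pixel softmax
  dotp <- array(0, c(V, n))
  for (k in seq_len(K)) dotp <- dotp + gp[, , k] * pv[, , k]
  gz <- array(0, c(V, n, K))
  for (k in seq_len(K)) gz[, , k] <- pv[, , k] * (gp[, , k] - dotp)
  dout <- aperm(array(gz, c(dm[1], dm[2], n, K)), c(1, 2, 4, 3))
  list(loss = sum(tapply(per, d, mean)), dout = dout)
}

# ---- batch assembly ---------------------------------------------------------

# Build the tensors/labels for a batch index set.
.prepare_batch <- function(dataset, idx, task, bins = NULL, sigma = 10) {
  x <- dataset_tensor(dataset, idx)
  d <- dataset_domains(dataset)[idx]
  in_p <- dataset_flags(dataset, "in_p")[idx]
  y <- switch(task,
    regression = vapply(dataset$samples[idx],
                        function(s) s$main_label %||% NA_real_, numeric(1)),
    softlabel = {
      ages <- vapply(dataset$samples[idx],
                     function(s) s$main_label %||% NA_real_, numeric(1))
      M <- matrix(0, length(idx), length(bins))
      for (i in which(!is.na(ages)))
        M[i, ] <- make_soft_label(ages[i], range(bins), sigma)$probs
      M
    },
    classification = vapply(dataset$samples[idx], function(s) {
      v <- s$main_label
      if (is.null(v)) NA_integer_
      else if (is.character(v)) as.integer(v == "male") + 1L
      else as.integer(v)
    }, integer(1)),
    segmentation = dataset_labelmaps(dataset, idx))
  list(x = x, y = y, d = d, in_p = in_p, idx = idx)
}

.subset_batch <- function(batch, keep) {
  list(x = batch$x[, , , keep, drop = FALSE],
       y = if (is.matrix(batch$y)) batch$y[keep, , drop = FALSE]
           else if (length(dim(batch$y)) == 3)
             batch$y[, , keep, drop = FALSE]
           else batch$y[keep],
       d = batch$d[keep], in_p = batch$in_p[keep], idx = batch$idx[keep])
}

#' One three-stage unlearning step on a batch
#'
#' Executes, in the fixed order, (1) the main-task update on the labelled
#' samples (theta_repr + theta_p), (2) the domain-classifier update on the
#' unlearning samples (theta_d only, fresh forward pass), (3) the
#' confusion-loss update (theta_repr only, fresh forward pass), followed by
#' the analogous classification/confusion sub-step pair for each attached
#' confound head. The domain classifier is always updated before the
#' confusion step.
#'
#' @param state a [new_training_state()] (phase `"unlearn"`).
#' @param dataset the training [multisite_dataset()].
#' @param idx integer indices forming the batch (one sample per site at
#'   least).
#' @return `list(state, losses)` where `losses` holds lp, ld, lconf and the
#'   per-confound terms for this batch.
#' @export
unlearning_step <- function(state, dataset, idx) {
  cfg <- state$config
  batch <- .prepare_batch(dataset, idx, cfg$task,
                          bins = state$model$bins, sigma = cfg$sigma)
  in_u <- dataset_flags(dataset, "in_u")[idx]
  losses <- list(lp = NA_real_, ld = NA_real_, lconf = NA_real_)
  if (any(batch$in_p)) {
    b1 <- .subset_batch(batch, batch$in_p)
    s1 <- stage1_update(state, b1$x, b1$y, b1$d)
    state <- s1$state; losses$lp <- s1$loss
  }
  if (!any(in_u))
    stop_unlearnr("unlearnr_error_empty", "batch has no unlearning samples")
  bu <- .subset_batch(batch, in_u)
  for (k in seq_len(max(1L, cfg$head_steps %||% 1L))) {
    s2 <- stage2_update(state, bu$x, bu$d)
    state <- s2$state
  }
  losses$ld <- s2$loss
  s3 <- stage3_update(state, bu$x)
  state <- s3$state; losses$lconf <- s3$loss
  for (nm in names(state$model$params$confounds)) {
    in_c <- dataset_confound_flags(dataset, nm)[idx]
    if (!any(in_c)) next
    bc <- .subset_batch(batch, in_c)
    clab <- .confound_labels(dataset, bc$idx, nm)
    sc <- stage2_update(state, bc$x, bc$d, head_name = nm, labels = clab,
                        opt_name = paste0("cls_", nm))
    state <- sc$state
    losses[[paste0("lc_", nm)]] <- sc$loss
    sf <- stage3_update(state, bc$x, head_name = nm,
                        opt_name = paste0("conf_", nm))
    state <- sf$state
    losses[[paste0("lcconf_", nm)]] <- sf$loss
  }
  list(state = state, losses = losses)
}

.confound_labels <- function(dataset, idx, nm) {
  vapply(dataset$samples[idx], function(s) {
    v <- s$confounds[[nm]]
    if (is.character(v)) as.integer(v == "male") + 1L else as.integer(v)
  }, integer(1))
}

# ---- pretraining and the full fit -------------------------------------------

# Validation task loss on a prepared hold-out batch.
.validation_loss <- function(model, vb) {
  feat <- forward_features(model, vb$x)
  pred <- forward_predictor(model, feat)
  keep <- vb$in_p
  if (!any(keep)) return(NA_real_)
  b <- .subset_batch(vb, keep)
  predk <- list(out = if (is.matrix(pred$out)) pred$out[keep, , drop = FALSE]
                else pred$out,
                probs = if (is.matrix(pred$probs))
                  pred$probs[keep, , drop = FALSE] else pred$probs)
  if (model$type == "unet") {
    predk <- list(probs = pred$probs[, , , keep, drop = FALSE])
    return(.dice_loss_grad(predk, b$y, b$d, model$n_classes)$loss)
  }
  if (model$type == "cnn_reg" && model$task == "regression")
    predk$out <- matrix(as.numeric(pred$out)[keep], ncol = 1)
  .task_loss_grad(model, predk, b$y, b$d)$loss
}

#' Pretrain the main task and the domain classifier
#'
#' Alternates the main-task update (theta_repr + theta_p) and the
#' domain-classifier update (theta_d) per batch until the validation task
#' loss stops improving (early stopping with the configured patience), so
#' that the domain classifier is accurate before unlearning begins.
#'
#' @param state a [new_training_state()] in phase `"pretrain"`.
#' @param dataset training [multisite_dataset()].
#' @param val_idx indices of the validation samples.
#' @return The updated state (phase advanced to `"unlearn"`), with the best
#'   validation model restored.
#' @export
pretrain <- function(state, dataset, val_idx) {
  if (state$phase != "pretrain")
    stop_unlearnr("unlearnr_error_phase", "state is not in pretrain phase")
  cfg <- state$config
  train_idx <- setdiff(seq_along(dataset$samples), val_idx)
  sub <- multisite_dataset(dataset$samples[train_idx], dataset$n_domains)
  vb <- .prepare_batch(dataset, val_idx, cfg$task,
                       bins = state$model$bins, sigma = cfg$sigma)
  best <- list(loss = Inf, params = state$model$params,
               bn = state$model$bn, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(cfg$pretrain_epochs)) {
    batches <- make_batches(sub, cfg$batch_size,
                            seed = split_seed(cfg$seed, 5000L + ep))
    lp_ep <- ld_ep <- 0
    for (b in batches) {
      batch <- .prepare_batch(sub, b, cfg$task,
                              bins = state$model$bins, sigma = cfg$sigma)
      if (any(batch$in_p)) {
        b1 <- .subset_batch(batch, batch$in_p)
        s1 <- stage1_update(state, b1$x, b1$y, b1$d)
        state <- s1$state; lp_ep <- lp_ep + s1$loss
      }
      if (cfg$mode == "unlearn") {
        in_u <- dataset_flags(sub, "in_u")[b]
        if (any(in_u)) {
          bu <- .subset_batch(batch, in_u)
          s2 <- stage2_update(state, bu$x, bu$d)
          state <- s2$state; ld_ep <- ld_ep + s2$loss
        }
      }
    }
    vloss <- .validation_loss(state$model, vb)
    state$epoch <- state$epoch + 1L
    state$history[[length(state$history) + 1L]] <-
      data.frame(phase = "pretrain", epoch = state$epoch,
                 lp = lp_ep / length(batches), ld = ld_ep / length(batches),
                 lconf = NA_real_, lp_val = vloss)
    if (is.finite(vloss) && vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, params = state$model$params,
                   bn = state$model$bn, epoch = state$epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (is.finite(best$loss)) {
    state$model$params <- best$params
    state$model$bn <- best$bn
  }
  state$phase <- "unlearn"
  state
}

# ---- unlearning phase, attach scope (cached convolutional features) --------

# Qrepr and backward cache from the frozen conv-bank features.
.q_attach <- function(model, flat, training = TRUE) {
  pre <- dense_forward(flat, model$params$extractor$fc)
  bn <- batchnorm_forward(pre, model$bn, training = training)
  list(q = relu(bn$y), bn = bn, flat = flat)
}

.q_attach_backward <- function(model, qc, dq) {
  dbn <- relu_backward(dq, qc$q)
  dpre <- batchnorm_backward(dbn, qc$bn)
  dense_backward(dpre, qc$flat, model$params$extractor$fc)
}

# Conv-bank output (flattened pooled features) for a stack of images; the
# conv parameters are frozen during the attach-scope unlearning phase, so
# this is computed once.
.conv_bank <- function(model, x) {
  p1 <- avgpool2(relu(conv_forward(x, model$params$extractor$conv1)$y))
  p2 <- avgpool2(relu(conv_forward(p1, model$params$extractor$conv2)$y))
  d <- dim(p2)
  t(matrix(p2, prod(d[1:3]), d[4]))
}

# The unlearning phase for the encoder models: the convolutional bank is
# frozen at its pretrained value and the three stages operate on cached
# features, which makes full-batch classifier fitting and many adversarial
# epochs affordable. Each epoch runs (1) gentle main-task maintenance of the
# Qrepr projection and label predictor, (2) the domain classifier trained
# close to its optimum (with periodic fresh re-initialisation), (3) repeated
# confusion updates of the projection; then the analogous pair per confound.
# Checkpoints are scored on a validation probe and validation task loss.
.unlearn_phase_attach <- function(state, dataset, val_idx) {
  cfg <- state$config
  model <- state$model
  train_idx <- setdiff(seq_along(dataset$samples), val_idx)
  sub <- multisite_dataset(dataset$samples[train_idx], dataset$n_domains)
  tb <- .prepare_batch(sub, seq_along(sub$samples), cfg$task,
                       bins = model$bins, sigma = cfg$sigma)
  vb <- .prepare_batch(dataset, val_idx, cfg$task,
                       bins = model$bins, sigma = cfg$sigma)
  flat_tr <- .conv_bank(model, tb$x)
  flat_va <- .conv_bank(model, vb$x)
  d_tr <- tb$d
  in_p <- tb$in_p
  in_u <- dataset_flags(sub, "in_u")
  if (!any(in_u))
    stop_unlearnr("unlearnr_error_empty", "no unlearning samples flagged")
  N <- model$n_domains
  oh_u <- .onehot(d_tr[in_u], N)
  # scoring subset for the scanner probe: restrict to the inter-site age
  # overlap so the age distribution cannot stand in for the site label in
  # the residual-information measurement (the unlearning stages themselves
  # keep using the policy's in_u subset)
  ages_tr <- vapply(sub$samples, function(sm) sm$age %||% NA_real_, numeric(1))
  score_idx <- which(in_u)
  if (all(is.finite(ages_tr))) {
    lo <- max(tapply(ages_tr, d_tr, min))
    hi <- min(tapply(ages_tr, d_tr, max))
    cand <- which(in_u & ages_tr >= lo & ages_tr <= hi)
    if (lo <= hi && all(tabulate(d_tr[cand], N) >= 5L)) score_idx <- cand
  }
  opts <- list(task = adam_state(), conf = adam_state())
  conf_names <- names(model$params$confounds)
  conf_info <- list()
  for (nm in conf_names) {
    inc <- dataset_confound_flags(sub, nm)[seq_along(sub$samples)]
    if (!any(inc)) next
    labs <- .confound_labels(sub, which(inc), nm)
    conf_info[[nm]] <- list(idx = which(inc), labels = labs,
                            K = ncol(model$params$confounds[[nm]]$fc2$W),
                            opt_conf = adam_state())
  }
  state$model <- model
  anchor <- .validation_loss(model, vb)      # pretrain-exit task loss
  if (!is.finite(anchor)) anchor <- Inf
  # the pretrained state is checkpoint 0: if no later checkpoint removes
  # information without violating the task guard, training falls back to it
  q0 <- .q_attach(model, flat_tr[score_idx, , drop = FALSE],
                  training = FALSE)$q
  pr0 <- probe_scanner_information(q0, d_tr[score_idx],
                                   seed = split_seed(cfg$seed, 4242L),
                                   hidden = model$hidden,
                                   max_epochs = 200, patience = 15)
  checkpoints <- list(list(score = pr0$accuracy - pr0$chance, vloss = anchor,
                           params = model$params, bn = model$bn))
  task_pen <- function(vl) {
    if (!is.finite(vl) || !is.finite(anchor) || anchor <= 0) return(0)
    50 * max(0, vl / anchor - 1)   # 10% task degradation ~ 5 probe points
  }
  ema_blend <- function(a, b, k) {
    if (is.list(a)) return(Map(function(x, y) ema_blend(x, y, k), a, b[names(a)]))
    k * a + (1 - k) * b
  }
  ema <- list(fc = model$params$extractor$fc,
              predictor = model$params$predictor, bn = model$bn)
  for (ep in seq_len(cfg$unlearn_epochs)) {
    # stage 1: task maintenance on labelled samples, minibatched
    lp_ep <- 0
    if (any(in_p)) {
      pidx <- which(in_p)
      batches <- make_batches(d_tr[pidx], cfg$batch_size,
                              seed = split_seed(cfg$seed, 9000L + ep))
      for (b in batches) {
        bi <- pidx[b]
        qc <- .q_attach(model, flat_tr[bi, , drop = FALSE])
        model$bn <- qc$bn$stats
        feat <- list(q = qc$q)
        pred <- forward_predictor(model, feat)
        yb <- if (is.matrix(tb$y)) tb$y[bi, , drop = FALSE] else tb$y[bi]
        tg <- .task_loss_grad(model, pred, yb, d_tr[bi])
        lp_ep <- lp_ep + tg$loss
        bp <- backward_predictor(model, pred, qc$q, tg$dout)
        gfc <- .q_attach_backward(model, qc, bp$dq)
        model$params$predictor <- adam_update(
          model$params$predictor, bp$grads, opts$task,
          cfg$lr_task_unlearn %||% 1e-4, path = "p")
        model$params$extractor$fc <- adam_update(
          model$params$extractor$fc, list(W = gfc$dW, b = gfc$db),
          opts$task, cfg$lr_task_unlearn %||% 1e-4, path = "rfc")
      }
      lp_ep <- lp_ep / length(batches)
    }
    # stage 2: domain classifier to (near) convergence, full batch
    if ((ep - 1L) %% max(1L, cfg$head_reinit %||% 5L) == 0L) {
      hh <- cfg$head_hidden %||% model$hidden
      model$params$domain <- with_seed(
        split_seed(cfg$seed, 600L + ep),
        list(fc1 = nn_dense(model$feature_dim, hh),
             fc2 = nn_dense(hh, N)))
      opts$head <- adam_state()
    }
    qc <- .q_attach(model, flat_tr[in_u, , drop = FALSE])
    for (s in seq_len(cfg$head_steps_full %||% 100L)) {
      fwd <- forward_head(model$params$domain, qc$q)
      bh <- backward_head(model$params$domain, fwd, qc$q,
                          (fwd$probs - oh_u) / nrow(qc$q))
      model$params$domain <- adam_update(model$params$domain, bh$grads,
                                         opts$head, cfg$lr_head, path = "d")
    }
    ld_ep <- domain_classification_loss(
      forward_head(model$params$domain, qc$q)$probs, d_tr[in_u])
    # stage 3: confusion updates of the projection, full batch
    lconf_ep <- NA_real_
    for (s in seq_len(cfg$conf_steps %||% 80L)) {
      qc <- .q_attach(model, flat_tr[in_u, , drop = FALSE])
      fwd <- forward_head(model$params$domain, qc$q)
      bh <- backward_head(model$params$domain, fwd, qc$q,
                          (fwd$probs - 1 / N) / nrow(qc$q))
      gfc <- .q_attach_backward(model, qc, bh$dq)
      model$params$extractor$fc <- adam_update(
        model$params$extractor$fc, list(W = gfc$dW, b = gfc$db),
        opts$conf, cfg$lr_conf %||% 3e-3, path = "r3")
      lconf_ep <- confusion_loss(fwd$probs)
    }
    # confound heads: classification then confusion, per declared confound
    conf_losses <- list()
    for (nm in names(conf_info)) {
      ci <- conf_info[[nm]]
      if ((ep - 1L) %% max(1L, cfg$head_reinit %||% 5L) == 0L) {
        hh <- cfg$head_hidden %||% model$hidden
        model$params$confounds[[nm]] <- with_seed(
          split_seed(cfg$seed, 700L + ep + match(nm, conf_names)),
          list(fc1 = nn_dense(model$feature_dim, hh),
               fc2 = nn_dense(hh, ci$K)))
        conf_info[[nm]]$opt_head <- adam_state()
      }
      oh_c <- .onehot(ci$labels, ci$K)
      qc <- .q_attach(model, flat_tr[ci$idx, , drop = FALSE])
      for (s in seq_len(cfg$head_steps_full %||% 100L)) {
        fwd <- forward_head(model$params$confounds[[nm]], qc$q)
        bh <- backward_head(model$params$confounds[[nm]], fwd, qc$q,
                            (fwd$probs - oh_c) / nrow(qc$q))
        model$params$confounds[[nm]] <- adam_update(
          model$params$confounds[[nm]], bh$grads, conf_info[[nm]]$opt_head,
          cfg$lr_head, path = paste0("c_", nm))
      }
      conf_losses[[paste0("lc_", nm)]] <- domain_classification_loss(
        forward_head(model$params$confounds[[nm]], qc$q)$probs, ci$labels)
      for (s in seq_len(cfg$conf_steps %||% 80L)) {
        qc <- .q_attach(model, flat_tr[ci$idx, , drop = FALSE])
        fwd <- forward_head(model$params$confounds[[nm]], qc$q)
        bh <- backward_head(model$params$confounds[[nm]], fwd, qc$q,
                            (fwd$probs - 1 / ci$K) / nrow(qc$q))
        gfc <- .q_attach_backward(model, qc, bh$dq)
        model$params$extractor$fc <- adam_update(
          model$params$extractor$fc, list(W = gfc$dW, b = gfc$db),
          ci$opt_conf, cfg$lr_conf %||% 3e-3, path = paste0("r3c_", nm))
        conf_losses[[paste0("lcconf_", nm)]] <- confusion_loss(fwd$probs)
      }
    }
    k_ema <- cfg$ema_decay %||% 0.92
    ema <- list(fc = ema_blend(ema$fc, model$params$extractor$fc, k_ema),
                predictor = ema_blend(ema$predictor, model$params$predictor,
                                      k_ema),
                bn = ema_blend(ema$bn, model$bn, k_ema))
    state$epoch <- state$epoch + 1L
    row <- data.frame(phase = "unlearn", epoch = state$epoch, lp = lp_ep,
                      ld = ld_ep, lconf = lconf_ep, lp_val = NA_real_)
    for (nm in names(conf_losses)) row[[nm]] <- conf_losses[[nm]]
    # checkpoint scoring on the validation split
    if (ep %% max(1L, cfg$check_every %||% 5L) == 0L ||
        ep == cfg$unlearn_epochs) {
      model_ema <- model
      model_ema$params$extractor$fc <- ema$fc
      model_ema$params$predictor <- ema$predictor
      model_ema$bn <- ema$bn
      qs <- .q_attach(model_ema, flat_tr[score_idx, , drop = FALSE],
                      training = FALSE)$q
      state$model <- model
      vloss <- .validation_loss(model_ema, vb)
      pr <- probe_scanner_information(qs, d_tr[score_idx],
                                      seed = split_seed(cfg$seed, 4242L),
                                      hidden = model$hidden,
                                      max_epochs = 200, patience = 15)
      score <- pr$accuracy - pr$chance
      for (nm in names(conf_info)) {
        ci <- conf_info[[nm]]
        qc_s <- .q_attach(model_ema, flat_tr[ci$idx, , drop = FALSE],
                          training = FALSE)$q
        prc <- probe_scanner_information(qc_s, ci$labels,
                                         seed = split_seed(cfg$seed, 4243L),
                                         hidden = model$hidden,
                                         max_epochs = 200, patience = 15)
        score <- score + prc$accuracy - prc$chance
      }
      checkpoints[[length(checkpoints) + 1L]] <-
        list(score = score + task_pen(vloss), vloss = vloss,
             params = model_ema$params, bn = model_ema$bn)
      row$lp_val <- vloss
      row$probe_val <- pr$accuracy
    }
    state$history[[length(state$history) + 1L]] <- row
  }
  # final selection: most harmonised checkpoint whose task loss stayed
  # within tolerance of the pretrain-exit anchor; fall back to the
  # least-degraded checkpoint when none qualifies
  tol <- cfg$task_tolerance %||% 1.5
  vl <- vapply(checkpoints, function(cp) cp$vloss, numeric(1))
  sc <- vapply(checkpoints, function(cp) cp$score, numeric(1))
  ok <- is.finite(vl) & vl <= tol * anchor + 1e-9
  pick <- if (any(ok)) which(ok)[which.min(sc[ok])] else which.min(vl)
  model$params <- checkpoints[[pick]]$params
  model$bn <- checkpoints[[pick]]$bn
  # refit the label predictor on the now-frozen representation: Qrepr (and
  # hence the probe) is untouched, but the task head recovers any accuracy
  # lost to averaging and to the adversarial drift. Checkpoint 1 is the
  # pretrained state, whose predictor is already validation-optimal.
  if (pick > 1L && any(in_p)) {
    opt_p <- adam_state()
    pidx <- which(in_p)
    best_p <- list(loss = Inf, predictor = model$params$predictor)
    for (ep in seq_len(10L)) {
      batches <- make_batches(d_tr[pidx], cfg$batch_size,
                              seed = split_seed(cfg$seed, 12000L + ep))
      for (b in batches) {
        bi <- pidx[b]
        qc <- .q_attach(model, flat_tr[bi, , drop = FALSE], training = FALSE)
        pred <- forward_predictor(model, list(q = qc$q))
        yb <- if (is.matrix(tb$y)) tb$y[bi, , drop = FALSE] else tb$y[bi]
        tg <- .task_loss_grad(model, pred, yb, d_tr[bi])
        bp <- backward_predictor(model, pred, qc$q, tg$dout)
        model$params$predictor <- adam_update(model$params$predictor,
                                              bp$grads, opt_p, 1e-3,
                                              path = "pf")
      }
      state$model <- model
      vloss <- .validation_loss(model, vb)
      if (is.finite(vloss) && vloss < best_p$loss) {
        best_p <- list(loss = vloss, predictor = model$params$predictor)
      }
    }
    model$params$predictor <- best_p$predictor
  }
  state$model <- model
  state
}

#' Fit a harmonised (or baseline) model
#'
#' Full training driver: builds the model for the configured task, splits a
#' stratified validation set, pretrains to convergence, then (in
#' `"unlearn"` mode) runs the configured number of three-stage unlearning
#' epochs. In `"normal"` mode only the main task is trained and the
#' adversarial weights are ignored. Samples lacking a main-task label
#' contribute only to the unlearning stages (semi-supervised training).
#'
#' @param dataset a [multisite_dataset()].
#' @param config a [train_config()].
#' @return An object of class `unlearn_fit`: `model`, `history` (one row per
#'   epoch of loss components), `config`, `partition`, `val_idx`.
#' @export
fit_unlearning <- function(dataset, config) {
  stopifnot(inherits(dataset, "multisite_dataset"),
            inherits(config, "train_config"))
  d <- dataset_domains(dataset)
  val_idx <- unlist(lapply(unique(d), function(s) {
    idx <- which(d == s)
    with_seed(split_seed(config$seed, 77L + s),
              sample(idx, max(1L, round(config$val_fraction * length(idx)))))
  }))
  H <- dim(dataset$samples[[1]]$image)[1]
  W <- dim(dataset$samples[[1]]$image)[2]
  model <- if (config$task == "segmentation") {
    build_unet_model(c(H, W), config$n_classes, dataset$n_domains,
                     attach = config$attach, width_scale = config$width_scale,
                     hidden = config$hidden, seed = config$seed)
  } else {
    build_regression_model(c(H, W), dataset$n_domains,
                           feature_dim = config$feature_dim,
                           width_scale = config$width_scale,
                           task = config$task, hidden = config$hidden,
                           bin_range = config$bin_range, sigma = config$sigma,
                           n_out = if (config$task == "classification") 2L else 1L,
                           seed = config$seed)
  }
  if (config$task == "regression") {
    lab <- unlist(lapply(dataset$samples,
                         function(s) s$main_label %||% NULL))
    model$y_center <- mean(lab)
    model$y_scale <- max(stats::sd(lab), 1e-8)
  }
  if (length(config$confounds) && config$mode == "unlearn")
    model <- attach_confound_classifiers(model, config$confounds,
                                         seed = config$seed + 13L)
  state <- new_training_state(model, config)
  state <- pretrain(state, dataset, val_idx)
  if (config$mode == "unlearn" && model$type == "cnn_reg" &&
      identical(config$unlearn_scope %||% "attach", "attach")) {
    state <- .unlearn_phase_attach(state, dataset, val_idx)
  } else if (config$mode == "unlearn") {
    train_idx <- setdiff(seq_along(dataset$samples), val_idx)
    sub <- multisite_dataset(dataset$samples[train_idx], dataset$n_domains)
    vb <- .prepare_batch(dataset, val_idx, config$task,
                         bins = state$model$bins, sigma = config$sigma)
    for (ep in seq_len(config$unlearn_epochs)) {
      batches <- make_batches(sub, config$batch_size,
                              seed = split_seed(config$seed, 9000L + ep))
      acc <- NULL
      for (b in batches) {
        st <- unlearning_step(state, sub, b)
        state <- st$state
        acc <- if (is.null(acc)) rapply(st$losses, function(z) z, how = "list")
               else Map(function(a, z) a + z, acc, st$losses)
      }
      state$epoch <- state$epoch + 1L
      row <- data.frame(phase = "unlearn", epoch = state$epoch,
                        lp = acc$lp / length(batches),
                        ld = acc$ld / length(batches),
                        lconf = acc$lconf / length(batches),
                        lp_val = .validation_loss(state$model, vb))
      for (nm in setdiff(names(acc), c("lp", "ld", "lconf")))
        row[[nm]] <- acc[[nm]] / length(batches)
      state$history[[length(state$history) + 1L]] <- row
    }
  }
  all_cols <- Reduce(union, lapply(state$history, names),
                     c("phase", "epoch", "lp", "ld", "lconf", "lp_val"))
  history <- do.call(rbind, lapply(state$history, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA_real_
    r[all_cols]
  }))
  structure(list(model = state$model, history = history, config = config,
                 partition = parameter_partition(state$model),
                 val_idx = val_idx),
            class = "unlearn_fit")
}

#' @export
print.unlearn_fit <- function(x, ...) {
  cat(sprintf("<unlearn_fit> task=%s mode=%s epochs=%d\n",
              x$config$task, x$config$mode, max(x$history$epoch)))
  invisible(x)
}
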