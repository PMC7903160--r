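# Architecture contracts. Two assembled models:
#  * a convolutional encoder + fully-connected feature layer (Qrepr) with a
#    label-predictor head and an N-way domain-classifier head, for the age
#    tasks (regression / soft-label / classification);
#  * a small 2D U-Net with skip connection, whose domain classifier can be
#    attached at the final convolution (A), the bottleneck (B), or both.
# Parameters are held in disjoint partitions (theta_repr, theta_p, theta_d,
# per-confound theta_c) so each training stage can update exactly one set.

#' Build the regression/classification model
#'
#' Convolutional encoder (two 3x3 conv + ReLU + 2x2 average-pool blocks)
#' ending in a fully connected layer whose ReLU activations form the feature
#' representation Qrepr of length `feature_dim`; a label-predictor head maps
#' Qrepr to the task output and a domain-classifier head maps it to an N-way
#' softmax.
#'
#' @param input_shape `c(H, W)`, both divisible by 4.
#' @param n_domains number of sites N (>= 2).
#' @param feature_dim length of Qrepr (> 0; default 32).
#' @param width_scale multiplier on channel counts for miniature variants.
#' @param task `"regression"` (scalar age, MSE), `"softlabel"` (distribution
#'   over age bins, KL), or `"classification"` (softmax over `n_out` classes).
#' @param n_out output dimension of the label predictor (ignored for
#'   `"softlabel"`, where it is the number of bins).
#' @param hidden hidden width of the predictor and domain heads.
#' @param bin_range,sigma soft-label parameters (see [make_soft_label()]).
#' @param seed initialisation seed.
#' @return An object of class `unlearn_model`.
#' @export
build_regression_model <- function(input_shape, n_domains, feature_dim = 32,
                                   width_scale = 1, task = "regression",
                                   n_out = 1, hidden = 16,
                                   bin_range = c(0, 100), sigma = 10,
                                   seed = 1) {
  if (feature_dim <= 0)
    stop_unlearnr("unlearnr_error_model", "feature_dim must be positive")
  if (n_domains < 2)
    stop_unlearnr("unlearnr_error_model", "need at least 2 domains")
  H <- input_shape[1]; W <- input_shape[2]
  if (H %% 4 != 0 || W %% 4 != 0)
    stop_unlearnr("unlearnr_error_model", "input sides must be divisible by 4")
  c1 <- max(2L, round(8 * width_scale))
  c2 <- max(4L, round(16 * width_scale))
  flat <- (H %/% 4) * (W %/% 4) * c2
  bins <- NULL
  if (task == "softlabel") {
    bins <- seq(bin_range[1], bin_range[2], by = 1)
    n_out <- length(bins)
  }
  params <- with_seed(seed, list(
    extractor = list(conv1 = nn_conv(1, c1), conv2 = nn_conv(c1, c2),
                     fc = nn_dense(flat, feature_dim)),
    predictor = list(fc1 = nn_dense(feature_dim, hidden),
                     fc2 = nn_dense(hidden, n_out)),
    domain = list(fc1 = nn_dense(feature_dim, hidden),
                  fc2 = nn_dense(hidden, n_domains)),
    confounds = list()
  ))
  structure(list(type = "cnn_reg", task = task, params = params,
                 input_shape = c(H, W), n_domains = as.integer(n_domains),
                 feature_dim = as.integer(feature_dim), hidden = hidden,
                 channels = c(c1, c2), n_out = n_out, bins = bins,
                 sigma = sigma, y_center = 0, y_scale = 1,
                 bn = list(mean = rep(0, feature_dim),
                           var = rep(1, feature_dim)),
                 confound_specs = list()),
            class = "unlearn_model")
}

#' Build the segmentation U-Net
#'
#' A small 2D U-Net: encoder conv block, 2x2 pooled bottleneck conv block,
#' nearest-neighbour upsampling, skip-connection concatenation, decoder conv
#' block, and a 1x1 convolution segmentation head with per-pixel softmax.
#' The domain classifier consumes the flattened activations at the final
#' convolution (`attach = "A"`), the bottleneck (`"B"`), or one fully
#' connected layer per branch concatenated (`"A+B"`).
#'
#' @param input_shape `c(H, W)`, divisible by 2.
#' @param n_classes number of segmentation classes (incl. background).
#' @param n_domains number of sites N.
#' @param attach `"A"`, `"B"` or `"A+B"`.
#' @param width_scale channel multiplier for miniature variants.
#' @param hidden hidden width of the domain head.
#' @param seed initialisation seed.
#' @return An object of class `unlearn_model`.
#' @export
build_unet_model <- function(input_shape, n_classes, n_domains,
                             attach = c("A", "B", "A+B"), width_scale = 1,
                             hidden = 16, seed = 1) {
  attach <- match.arg(attach)
  if (n_domains < 2)
    stop_unlearnr("unlearnr_error_model", "need at least 2 domains")
  H <- input_shape[1]; W <- input_shape[2]
  if (H %% 2 != 0 || W %% 2 != 0)
    stop_unlearnr("unlearnr_error_model", "input sides must be even")
  c1 <- max(2L, round(8 * width_scale))
  c2 <- max(4L, round(16 * width_scale))
  flatA <- H * W * c1
  flatB <- (H %/% 2) * (W %/% 2) * c2
  domain <- with_seed(seed + 1L, switch(attach,
    "A" = list(fc1 = nn_dense(flatA, hidden),
               fc2 = nn_dense(hidden, n_domains)),
    "B" = list(fc1 = nn_dense(flatB, hidden),
               fc2 = nn_dense(hidden, n_domains)),
    "A+B" = list(fcA = nn_dense(flatA, hidden),
                 fcB = nn_dense(flatB, hidden),
                 fc2 = nn_dense(2L * hidden, n_domains))))
  params <- with_seed(seed, list(
    extractor = list(enc1 = nn_conv(1, c1), bott = nn_conv(c1, c2),
                     dec = nn_conv(c1 + c2, c1)),
    predictor = list(outconv = nn_dense(c1, n_classes)),
    domain = domain,
    confounds = list()
  ))
  structure(list(type = "unet", task = "segmentation", params = params,
                 input_shape = c(H, W), n_domains = as.integer(n_domains),
                 n_classes = as.integer(n_classes), hidden = hidden,
                 channels = c(c1, c2), attach = attach,
                 feature_dim = switch(attach, "A" = flatA, "B" = flatB,
                                      "A+B" = flatA + flatB),
                 confound_specs = list()),
            class = "unlearn_model")
}

#' Attach confound-classifier heads
#'
#' Adds, for each named confound, one softmax classifier head on Qrepr with
#' its own disjoint parameter set theta_c, enabling the paired
#' classification/confusion sub-steps that remove the confound from the
#' representation. Continuous confounds must be pre-binned into categories.
#'
#' @param model an `unlearn_model`.
#' @param confound_specs named list: `name = n_classes`.
#' @param seed initialisation seed.
#' @return The extended model.
#' @export
attach_confound_classifiers <- function(model, confound_specs, seed = 2) {
  stopifnot(inherits(model, "unlearn_model"))
  nms <- names(confound_specs)
  if (anyDuplicated(nms) || any(nms %in% names(model$params$confounds)))
    stop_unlearnr("unlearnr_error_model", "duplicate confound names")
  for (i in seq_along(confound_specs)) {
    k <- confound_specs[[i]]
    model$params$confounds[[nms[i]]] <- with_seed(split_seed(seed, i), list(
      fc1 = nn_dense(model$feature_dim, model$hidden),
      fc2 = nn_dense(model$hidden, k)))
    model$confound_specs[[nms[i]]] <- k
  }
  model
}

#' Remove a confound head
#'
#' @param model an `unlearn_model`.
#' @param name confound name.
#' @return The model with the head (and its partition entry) removed.
#' @export
remove_confound_classifier <- function(model, name) {
  model$params$confounds[[name]] <- NULL
  model$confound_specs[[name]] <- NULL
  model
}

#' Parameter partition of a model
#'
#' @param model an `unlearn_model`.
#' @return Named list of flat parameter-path character vectors:
#'   `theta_repr`, `theta_p`, `theta_d`, and `theta_c_<name>` per confound.
#'   The sets are pairwise disjoint and jointly exhaustive.
#' @export
parameter_partition <- function(model) {
  paths <- function(group, prefix) {
    unlist(lapply(names(group), function(lname) {
      p <- group[[lname]]
      nm <- intersect(names(p), c("W", "b"))
      paste(prefix, lname, nm, sep = ".")
    }))
  }
  out <- list(theta_repr = paths(model$params$extractor, "extractor"),
              theta_p = paths(model$params$predictor, "predictor"),
              theta_d = paths(model$params$domain, "domain"))
  for (nm in names(model$params$confounds))
    out[[paste0("theta_c_", nm)]] <-
      paths(model$params$confounds[[nm]], paste0("confounds.", nm))
  out
}

# Fetch all numeric leaves of a partition for bitwise comparison in tests.
partition_values <- function(model, which) {
  part <- parameter_partition(model)[[which]]
  lapply(stats::setNames(part, part), function(p) {
    keys <- strsplit(p, ".", fixed = TRUE)[[1]]
    Reduce(`[[`, keys, model$params)
  })
}

# ---- forward passes ---------------------------------------------------------

# x: (H, W, 1, n). Returns Qrepr (n x F) and the cache needed for backprop.
# `training` selects batch vs running statistics for the Qrepr batch norm;
# the updated running statistics are returned as $bn for the caller to
# persist into the model.
forward_features <- function(model, x, training = FALSE) {
  if (model$type == "cnn_reg") {
    f1 <- conv_forward(x, model$params$extractor$conv1)
    a1 <- relu(f1$y)
    p1 <- avgpool2(a1)
    f2 <- conv_forward(p1, model$params$extractor$conv2)
    a2 <- relu(f2$y)
    p2 <- avgpool2(a2)
    d <- dim(p2)
    flat <- t(matrix(p2, prod(d[1:3]), d[4]))
    pre <- dense_forward(flat, model$params$extractor$fc)
    bn <- batchnorm_forward(pre, model$bn, training = training)
    q <- relu(bn$y)
    list(q = q, bn = bn$stats,
         cache = list(x = x, f1 = f1, a1 = a1, p1 = p1, f2 = f2,
                      a2 = a2, p2dim = d, flat = flat, bn = bn,
                      qact = q))
  } else {
    unet_forward(model, x)
  }
}

unet_forward <- function(model, x) {
  f1 <- conv_forward(x, model$params$extractor$enc1)
  e1 <- relu(f1$y)
  p1 <- avgpool2(e1)
  fb <- conv_forward(p1, model$params$extractor$bott)
  b <- relu(fb$y)
  u <- upsample2(b)
  d1 <- dim(e1); d2 <- dim(u)
  cat_ <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
  cat_[, , seq_len(d1[3]), ] <- e1
  cat_[, , d1[3] + seq_len(d2[3]), ] <- u
  fd <- conv_forward(cat_, model$params$extractor$dec)
  dd <- relu(fd$y)
  q <- switch(model$attach,
    "A" = t(matrix(dd, prod(dim(dd)[1:3]), dim(dd)[4])),
    "B" = t(matrix(b, prod(dim(b)[1:3]), dim(b)[4])),
    "A+B" = cbind(t(matrix(dd, prod(dim(dd)[1:3]), dim(dd)[4])),
                  t(matrix(b, prod(dim(b)[1:3]), dim(b)[4]))))
  list(q = q, cache = list(x = x, f1 = f1, e1 = e1, p1 = p1, fb = fb, b = b,
                           u = u, cat = cat_, fd = fd, dd = dd))
}

# Label-predictor forward. cnn_reg: Qrepr -> hidden -> output; unet: 1x1 conv
# over decoder features -> per-pixel softmax (H, W, K, n).
forward_predictor <- function(model, feat) {
  if (model$type == "cnn_reg") {
    h <- relu(dense_forward(feat$q, model$params$predictor$fc1))
    out <- dense_forward(h, model$params$predictor$fc2)
    probs <- if (model$task %in% c("softlabel", "classification"))
      softmax_rows(out) else NULL
    list(out = out, probs = probs, h = h)
  } else {
    dd <- feat$cache$dd
    d <- dim(dd)
    f <- conv1x1_forward(dd, model$params$predictor$outconv)
    K <- model$n_classes
    zm <- matrix(aperm(f$y, c(1, 2, 4, 3)), d[1] * d[2] * d[4], K)
    pm <- softmax_rows(zm)
    probs <- aperm(array(pm, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
    list(out = f$y, probs = probs, fwd = f, zdim = d)
  }
}

# Generic 2-layer softmax head (domain or confound) on a feature matrix q.
forward_head <- function(head, q) {
  if (!is.null(head$fcA)) {
    hA <- relu(dense_forward(q[, seq_len(nrow(head$fcA$W)), drop = FALSE],
                             head$fcA))
    hB <- relu(dense_forward(q[, -seq_len(nrow(head$fcA$W)), drop = FALSE],
                             head$fcB))
    h <- cbind(hA, hB)
    logits <- dense_forward(h, head$fc2)
    list(logits = logits, probs = softmax_rows(logits), h = h,
         hA = hA, hB = hB)
  } else {
    h <- relu(dense_forward(q, head$fc1))
    logits <- dense_forward(h, head$fc2)
    list(logits = logits, probs = softmax_rows(logits), h = h)
  }
}

# ---- backward passes --------------------------------------------------------

# dq: (n x F) gradient at Qrepr -> gradients for the extractor parameters.
backward_extractor <- function(model, feat, dq) {
  cc <- feat$cache
  if (model$type == "cnn_reg") {
    dbn <- relu_backward(dq, cc$qact)
    dpre <- batchnorm_backward(dbn, cc$bn)
    gfc <- dense_backward(dpre, cc$flat, model$params$extractor$fc)
    dflat <- gfc$dx
    dp2 <- array(t(dflat), cc$p2dim)
    da2 <- avgpool2_backward(dp2, dim(cc$a2))
    df2 <- relu_backward(da2, cc$a2)
    g2 <- conv_backward(df2, cc$f2, model$params$extractor$conv2)
    dp1 <- g2$dx
    da1 <- avgpool2_backward(dp1, dim(cc$a1))
    df1 <- relu_backward(da1, cc$a1)
    g1 <- conv_backward(df1, cc$f1, model$params$extractor$conv1)
    list(conv1 = list(W = g1$dW, b = g1$db),
         conv2 = list(W = g2$dW, b = g2$db),
         fc = list(W = gfc$dW, b = gfc$db))
  } else {
    dd_dim <- dim(cc$dd)
    b_dim <- dim(cc$b)
    nA <- prod(dd_dim[1:3])
    ddd <- array(0, dd_dim); dbx <- array(0, b_dim)
    if (model$attach %in% c("A", "A+B")) {
      dqA <- if (model$attach == "A") dq else dq[, seq_len(nA), drop = FALSE]
      ddd <- array(t(dqA), dd_dim)
    }
    if (model$attach %in% c("B", "A+B")) {
      dqB <- if (model$attach == "B") dq else dq[, -seq_len(nA), drop = FALSE]
      dbx <- array(t(dqB), b_dim)
    }
    unet_backward(model, feat, d_dd = ddd, d_b_extra = dbx)
  }
}

# Backprop through the U-Net trunk from gradients at the decoder activations
# (d_dd) and/or an extra gradient injected at the bottleneck activations.
unet_backward <- function(model, feat, d_dd, d_b_extra = NULL) {
  cc <- feat$cache
  dfd <- relu_backward(d_dd, cc$dd)
  gd <- conv_backward(dfd, cc$fd, model$params$extractor$dec)
  c1 <- dim(cc$e1)[3]
  de1 <- gd$dx[, , seq_len(c1), , drop = FALSE]
  du <- gd$dx[, , -seq_len(c1), , drop = FALSE]
  db <- upsample2_backward(du)
  if (!is.null(d_b_extra)) db <- db + d_b_extra
  dfb <- relu_backward(db, cc$b)
  gb <- conv_backward(dfb, cc$fb, model$params$extractor$bott)
  de1 <- de1 + avgpool2_backward(gb$dx, dim(cc$e1))
  df1 <- relu_backward(de1, cc$e1)
  g1 <- conv_backward(df1, cc$f1, model$params$extractor$enc1)
  list(enc1 = list(W = g1$dW, b = g1$db),
       bott = list(W = gb$dW, b = gb$db),
       dec = list(W = gd$dW, b = gd$db))
}

# Gradient of a head given dlogits; returns head-parameter grads and dq.
backward_head <- function(head, fwd, q, dlogits) {
  if (!is.null(head$fcA)) {
    g2 <- dense_backward(dlogits, fwd$h, head$fc2)
    hidden <- ncol(fwd$hA)
    dhA <- relu_backward(g2$dx[, seq_len(hidden), drop = FALSE], fwd$hA)
    dhB <- relu_backward(g2$dx[, -seq_len(hidden), drop = FALSE], fwd$hB)
    nA <- nrow(head$fcA$W)
    gA <- dense_backward(dhA, q[, seq_len(nA), drop = FALSE], head$fcA)
    gB <- dense_backward(dhB, q[, -seq_len(nA), drop = FALSE], head$fcB)
    dq <- cbind(gA$dx, gB$dx)
    list(grads = list(fcA = list(W = gA$dW, b = gA$db),
                      fcB = list(W = gB$dW, b = gB$db),
                      fc2 = list(W = g2$dW, b = g2$db)),
         dq = dq)
  } else {
    g2 <- dense_backward(dlogits, fwd$h, head$fc2)
    dh <- relu_backward(g2$dx, fwd$h)
    g1 <- dense_backward(dh, q, head$fc1)
    list(grads = list(fc1 = list(W = g1$dW, b = g1$db),
                      fc2 = list(W = g2$dW, b = g2$db)),
         dq = g1$dx)
  }
}

# Predictor backward for cnn_reg: dout (n x n_out) -> predictor grads and dq.
backward_predictor <- function(model, pred, q, dout) {
  g2 <- dense_backward(dout, pred$h, model$params$predictor$fc2)
  dh <- relu_backward(g2$dx, pred$h)
  g1 <- dense_backward(dh, q, model$params$predictor$fc1)
  list(grads = list(fc1 = list(W = g1$dW, b = g1$db),
                    fc2 = list(W = g2$dW, b = g2$db)),
       dq = g1$dx)
}

#' Extract the frozen feature representation
#'
#' Runs the feature extractor on a stack of images and returns Qrepr, the
#' fixed-length activation vector per sample at the unlearning attach point.
#'
#' @param model an `unlearn_model`.
#' @param x input tensor `(H, W, 1, n)` or a [multisite_dataset()].
#' @return Matrix (n x F).
#' @export
model_features <- function(model, x) {
  if (inherits(x, "multisite_dataset")) x <- dataset_tensor(x)
  forward_features(model, x)$q
}

#' Predict with the label-predictor head
#'
#' @param object an `unlearn_model`.
#' @param x input tensor `(H, W, 1, n)` or a [multisite_dataset()].
#' @param ... unused.
#' @return Task-dependent: numeric ages for `"regression"`; a list with
#'   `probs` and expectation ages for `"softlabel"`; class probabilities for
#'   `"classification"`; an `(H, W, n)` integer map for `"segmentation"`.
#' @export
predict.unlearn_model <- function(object, x, ...) {
  if (inherits(x, "multisite_dataset")) x <- dataset_tensor(x)
  feat <- forward_features(object, x)
  pred <- forward_predictor(object, feat)
  switch(object$task,
    regression = as.numeric(pred$out) * object$y_scale + object$y_center,
    softlabel = list(probs = pred$probs,
                     age = age_point_estimate(pred$probs, object$bins)),
    classification = pred$probs,
    segmentation = {
      d <- dim(pred$probs)
      pm <- matrix(aperm(pred$probs, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
      array(max.col(pm, ties.method = "first"), c(d[1], d[2], d[4]))
    })
}
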