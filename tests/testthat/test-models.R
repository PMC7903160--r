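test_that("the encoder model honours its shape and determinism contracts", {
  m <- tiny_model()
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 1, 3))
  q <- model_features(m, x)
  expect_equal(dim(q), c(3L, 8L))
  expect_all_finite(q)
  # fixed weights + fixed input -> identical outputs
  expect_identical(q, model_features(m, x))
  expect_error(build_regression_model(c(16, 16), 2, feature_dim = 0),
               class = "unlearnr_error_model")
  expect_error(build_regression_model(c(16, 16), 1),
               class = "unlearnr_error_model")
})

test_that("parameter partitions are disjoint and exhaustive", {
  m <- attach_confound_classifiers(tiny_model(), list(sex = 2))
  part <- parameter_partition(m)
  expect_setequal(names(part),
                  c("theta_repr", "theta_p", "theta_d", "theta_c_sex"))
  all_paths <- unlist(part)
  expect_equal(anyDuplicated(all_paths), 0L)
  # every trainable leaf is covered
  count_leaves <- function(g) sum(vapply(g, function(l)
    length(intersect(names(l), c("W", "b"))), integer(1)))
  n_leaves <- count_leaves(m$params$extractor) + count_leaves(m$params$predictor) +
    count_leaves(m$params$domain) + count_leaves(m$params$confounds$sex)
  expect_equal(length(all_paths), n_leaves)
  # removal restores the original partition
  m2 <- remove_confound_classifier(m, "sex")
  expect_setequal(names(parameter_partition(m2)),
                  c("theta_repr", "theta_p", "theta_d"))
  expect_error(attach_confound_classifiers(m, list(sex = 2)),
               class = "unlearnr_error_model")
})

test_that("U-Net attach points define Qrepr as specified", {
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  mA <- build_unet_model(c(8, 8), 4, 2, attach = "A", width_scale = 0.25)
  mB <- build_unet_model(c(8, 8), 4, 2, attach = "B", width_scale = 0.25)
  mAB <- build_unet_model(c(8, 8), 4, 2, attach = "A+B", width_scale = 0.25)
  qA <- model_features(mA, x); qB <- model_features(mB, x)
  qAB <- model_features(mAB, x)
  # A: final-convolution activations; B: bottleneck; A+B: concatenation
  expect_equal(ncol(qA), 8 * 8 * mA$channels[1])
  expect_equal(ncol(qB), 4 * 4 * mB$channels[2])
  expect_equal(ncol(qAB), ncol(qA) + ncol(qB))
  expect_equal(qAB[, seq_len(ncol(qA))], qA)
  # per-pixel class distributions sum to one
  pred <- unlearnr:::forward_predictor(mA, unlearnr:::forward_features(mA, x))
  sums <- apply(pred$probs, c(1, 2, 4), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-9)
  expect_error(build_unet_model(c(8, 8), 4, 2, attach = "C"))
})

test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("unlearnr")
  set.seed(4)
  m <- tiny_model(n_domains = 3, input = c(8, 8), feature_dim = 5)
  n <- 5
  x <- array(rnorm(8 * 8 * n), c(8, 8, 1, n))
  y <- runif(n, 30, 70)
  d <- c(1, 1, 2, 3, 3)
  loss_fn <- function(m) {
    feat <- ns$forward_features(m, x, training = TRUE)
    pred <- ns$forward_predictor(m, feat)
    ns$.task_loss_grad(m, pred, y, d)$loss
  }
  feat <- ns$forward_features(m, x, training = TRUE)
  pred <- ns$forward_predictor(m, feat)
  tg <- ns$.task_loss_grad(m, pred, y, d)
  bp <- ns$backward_predictor(m, pred, feat$q, tg$dout)
  ge <- ns$backward_extractor(m, feat, bp$dq)
  numgrad <- function(path, i, fn, eps = 1e-6) {
    bump <- function(m, delta) {
      v <- Reduce(`[[`, path, m$params)
      v[i] <- v[i] + delta
      m$params[[path[1]]][[path[2]]][[path[3]]] <- v
      m
    }
    (fn(bump(m, eps)) - fn(bump(m, -eps))) / (2 * eps)
  }
  for (pp in list(c("extractor", "conv1", "W"), c("extractor", "conv2", "W"),
                  c("extractor", "fc", "W"))) {
    ag <- ge[[pp[2]]][[pp[3]]]
    for (i in 1:3)
      expect_equal(numgrad(pp, i, loss_fn), ag[i], tolerance = 1e-4)
  }
  # confusion gradient through the frozen head into the extractor
  conf_fn <- function(m) {
    feat <- ns$forward_features(m, x, training = TRUE)
    confusion_loss(ns$forward_head(m$params$domain, feat$q)$probs)
  }
  fwd <- ns$forward_head(m$params$domain, feat$q)
  bh <- ns$backward_head(m$params$domain, fwd, feat$q,
                         (fwd$probs - 1 / 3) / n)
  gec <- ns$backward_extractor(m, feat, bh$dq)
  for (i in 1:3)
    expect_equal(numgrad(c("extractor", "fc", "W"), i, conf_fn),
                 gec$fc$W[i], tolerance = 1e-4)
})

test_that("U-Net gradients match finite differences through the skip path", {
  ns <- asNamespace("unlearnr")
  set.seed(5)
  m <- build_unet_model(c(8, 8), 3, 2, attach = "A+B", width_scale = 0.25,
                        hidden = 4, seed = 3)
  n <- 3
  x <- array(rnorm(8 * 8 * n), c(8, 8, 1, n))
  y <- array(sample(1:3, 8 * 8 * n, TRUE), c(8, 8, n))
  d <- c(1, 2, 2)
  seg_fn <- function(m) {
    feat <- ns$unet_forward(m, x)
    pred <- ns$forward_predictor(m, feat)
    ns$.dice_loss_grad(pred, y, d, 3)$loss
  }
  feat <- ns$unet_forward(m, x)
  pred <- ns$forward_predictor(m, feat)
  tg <- ns$.dice_loss_grad(pred, y, d, 3)
  gseg <- ns$conv1x1_backward(tg$dout, pred$fwd, m$params$predictor$outconv)
  ge <- ns$unet_backward(m, feat, d_dd = gseg$dx)
  numgrad <- function(path, i, fn, eps = 1e-6) {
    bump <- function(m, delta) {
      v <- Reduce(`[[`, path, m$params)
      v[i] <- v[i] + delta
      m$params[[path[1]]][[path[2]]][[path[3]]] <- v
      m
    }
    (fn(bump(m, eps)) - fn(bump(m, -eps))) / (2 * eps)
  }
  for (pp in list(c("extractor", "enc1", "W"), c("extractor", "bott", "W"),
                  c("extractor", "dec", "W"))) {
    ag <- ge[[pp[2]]][[pp[3]]]
    for (i in 1:3)
      expect_equal(numgrad(pp, i, seg_fn), ag[i], tolerance = 1e-4)
  }
})
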