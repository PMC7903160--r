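test_that("per-scanner task loss weighs every site equally", {
  # two sites: errors (1, 9) -> mean 5; (4) -> mean 4; sum 9
  expect_equal(per_scanner_task_loss(c(5, 7, 3), c(4, 4, 1), c(1, 1, 2)), 9)
  # perfect predictions
  expect_equal(per_scanner_task_loss(c(4, 4, 1), c(4, 4, 1), c(1, 1, 2)), 0)
  # a single site reduces to the plain mean
  expect_equal(per_scanner_task_loss(c(1, 2), c(0, 0), c(1, 1)), 2.5)
  # duplicating one site's samples leaves the value unchanged
  expect_equal(per_scanner_task_loss(c(5, 7, 3, 3), c(4, 4, 1, 1),
                                     c(1, 1, 2, 2)), 9)
  expect_error(per_scanner_task_loss(numeric(), numeric(), integer()),
               class = "unlearnr_error_empty")
})

test_that("domain classification loss is categorical cross-entropy", {
  # one-hot correct predictions
  expect_equal(domain_classification_loss(diag(3), 1:3), 0)
  # uniform predictions give log N for any labels
  expect_equal(domain_classification_loss(matrix(1 / 3, 5, 3),
                                          c(1, 2, 3, 1, 2)), log(3))
  expect_equal(domain_classification_loss(matrix(c(0.8, 0.2), 1), 1),
               -log(0.8), tolerance = 1e-12)
  # zero probability at the true class stays finite (floored log)
  p <- matrix(c(0, 1), 1)
  expect_true(is.finite(domain_classification_loss(p, 1)))
  expect_error(domain_classification_loss(matrix(c(0.7, 0.2), 1), 1),
               class = "unlearnr_error_probs")
})

test_that("confusion loss attains its log(N) minimum exactly at uniformity", {
  expect_equal(confusion_loss(matrix(0.5, 3, 2)), log(2))
  expect_equal(confusion_loss(matrix(0.25, 2, 4)), log(4))
  expect_equal(confusion_loss(matrix(c(0.9, 0.1), 1)),
               -(log(0.9) + log(0.1)) / 2, tolerance = 1e-12)
  # analytic lower bound on random inputs; equality only when uniform
  for (s in 1:20) {
    p <- random_probs(6, 3, seed = s)
    expect_gte(confusion_loss(p), log(3) - 1e-12)
  }
  p <- random_probs(4, 3, seed = 99)
  expect_gt(confusion_loss(p), log(3))
})

test_that("classification and confusion losses ignore sample order", {
  p <- random_probs(8, 3, seed = 5)
  lab <- rep(1:2, 4)
  perm <- sample(8)
  expect_equal(domain_classification_loss(p, lab),
               domain_classification_loss(p[perm, ], lab[perm]))
  expect_equal(confusion_loss(p), confusion_loss(p[perm, ]))
})

test_that("the combined objective aggregates weighted components", {
  expect_equal(total_unlearning_loss(5, 2, 3, loss_weights(0, 0)), 5)
  expect_equal(total_unlearning_loss(1, 2, 3, loss_weights(1, 10)), 33)
  w <- loss_weights(1, 10, gamma = c(sex = 2), phi = c(sex = 1))
  expect_equal(total_unlearning_loss(1, 2, 3, w,
                                     list(sex = list(lc = 0.5, lcconf = 0.7))),
               34.7)
  expect_error(loss_weights(-1, 1), class = "unlearnr_error_weights")
  expect_error(loss_weights(1, 1, gamma = c(a = 1), phi = c(b = 1)),
               class = "unlearnr_error_weights")
})

test_that("multi-class Dice loss matches hand-evaluated overlaps", {
  oh <- function(cls, K) diag(K)[cls, , drop = FALSE]
  # perfect overlap
  y <- oh(c(1, 2, 2, 1), 2)
  expect_equal(multiclass_dice_loss(y, y, eps = 0), 0)
  # fully disjoint single-class maps
  expect_equal(multiclass_dice_loss(oh(c(1, 1), 2), oh(c(2, 2), 2), eps = 0), 1)
  # 4-voxel toy: pred (A,A,B,B) vs truth (A,B,B,B)
  p <- oh(c(1, 1, 2, 2), 2); y <- oh(c(1, 2, 2, 2), 2)
  expect_equal(multiclass_dice_loss(p, y, eps = 0), 1 - mean(c(2 / 3, 4 / 5)),
               tolerance = 1e-12)
  # hard predictions stay in [0, 1] under random maps
  for (s in 1:10) {
    cls_p <- sample(1:3, 20, replace = TRUE)
    cls_y <- sample(1:3, 20, replace = TRUE)
    l <- multiclass_dice_loss(oh(cls_p, 3), oh(cls_y, 3), eps = 1e-12)
    expect_gte(l, 0); expect_lte(l, 1 + 1e-9)
  }
  # class absent from both maps contributes Dice 1 through eps
  expect_equal(multiclass_dice_loss(oh(c(1, 1), 3), oh(c(1, 1), 3)), 0,
               tolerance = 1e-4)
})

test_that("Gaussian soft labels keep relative age information", {
  sl <- make_soft_label(50)
  expect_s3_class(sl, "soft_age_label")
  expect_equal(sl$sigma, 10)
  expect_equal(sum(sl$probs), 1, tolerance = 1e-12)
  expect_equal(sl$bin_centers[which.max(sl$probs)], 50)
  # density ratio between bins 50 and 60 for mu = 50, sigma = 10
  expect_equal(sl$probs[sl$bin_centers == 50] / sl$probs[sl$bin_centers == 60],
               exp(0.5), tolerance = 1e-9)
  for (a in c(0, 13.7, 99)) {
    expect_equal(sum(make_soft_label(a)$probs), 1, tolerance = 1e-12)
  }
  expect_error(make_soft_label(120), class = "unlearnr_error_range")
})

test_that("KL task loss is a directed divergence", {
  expect_equal(kl_task_loss(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_task_loss(c(0.5, 0.5), c(0.75, 0.25)),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-9)
  # the argument order matters: swapping gives a different value
  expect_equal(kl_task_loss(c(0.75, 0.25), c(0.5, 0.5)),
               0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25),
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(kl_task_loss(c(0.5, 0.5), c(0.75, 0.25)),
                                kl_task_loss(c(0.75, 0.25), c(0.5, 0.5)))))
  # non-negativity on random pairs, zero only at equality
  for (s in 1:20) {
    t_ <- random_probs(1, 5, seed = s)
    p <- random_probs(1, 5, seed = s + 100)
    expect_gte(kl_task_loss(p, t_), 0)
  }
})

test_that("age point estimates reduce distributions to years", {
  centers <- 0:100
  onehot <- replace(numeric(101), 66, 1)
  expect_equal(age_point_estimate(onehot, centers), 65)
  expect_equal(age_point_estimate(rep(1 / 101, 101), centers), 50)
  expect_equal(age_point_estimate(c(0.5, 0.5), c(40, 60)), 50)
  expect_equal(age_point_estimate(c(0.5, 0.5), c(40, 60), method = "argmax"),
               40)
  expect_error(age_point_estimate(c(0.7, 0.7), c(1, 2)),
               class = "unlearnr_error_probs")
})
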