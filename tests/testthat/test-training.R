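test_that("batches always contain every site and cover the largest one", {
  d <- rep(1:3, c(100, 10, 5))
  batches <- make_batches(d, 32, seed = 3)
  for (b in batches) {
    expect_length(b, 32L)
    expect_setequal(unique(d[b]), 1:3)
  }
  # every sample of the largest site appears at least once per epoch
  expect_true(all(which(d == 1) %in% unlist(batches)))
  # deterministic given the seed; different seed changes the order
  expect_identical(batches, make_batches(d, 32, seed = 3))
  expect_false(identical(batches, make_batches(d, 32, seed = 4)))
  expect_error(make_batches(d, 2), class = "unlearnr_error_batch")
})

test_that("unlearning subset policies flag the intended samples", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 20,
                     age_ranges = list(c(40, 70), c(60, 90)))
  all_ds <- select_unlearning_subset(ds, unlearning_policy("all"))
  expect_true(all(vapply(all_ds$samples, `[[`, logical(1), "in_u")))
  ov <- select_unlearning_subset(ds, unlearning_policy("overlap"))
  ages <- vapply(ov$samples, `[[`, numeric(1), "age")
  in_u <- vapply(ov$samples, `[[`, logical(1), "in_u")
  win <- c(max(tapply(ages, unlearnr:::dataset_domains(ov), min)),
           min(tapply(ages, unlearnr:::dataset_domains(ov), max)))
  expect_identical(in_u, ages >= win[1] & ages <= win[2])
  expect_true(any(in_u) && !all(in_u))
  # in_p is never touched
  expect_identical(vapply(ov$samples, `[[`, logical(1), "in_p"),
                   vapply(ds$samples, `[[`, logical(1), "in_p"))
  expect_error(select_unlearning_subset(
    tiny_dataset(2, 10, age_ranges = list(c(20, 30), c(60, 90))),
    unlearning_policy("overlap")), class = "unlearnr_error_policy")
})

test_that("balanced subsets equalise confound counts per site", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 40,
                     confound = list(name = "sex", correlate = "site",
                                     fraction = 0.8))
  bal <- select_unlearning_subset(
    ds, unlearning_policy("balanced_subset", confound = "sex"))
  d <- unlearnr:::dataset_domains(bal)
  sex <- vapply(bal$samples, function(s) s$confounds$sex, character(1))
  inc <- vapply(bal$samples, function(s) isTRUE(s$in_c[["sex"]]), logical(1))
  for (site in 1:2) {
    tab <- table(sex[inc & d == site])
    expect_equal(unname(tab[["male"]]), unname(tab[["female"]]))
  }
})

test_that("stage 2 touches only theta_d and stage 3 only theta_repr", {
  ns <- asNamespace("unlearnr")
  ds <- tiny_dataset(n_sites = 2, per_site_n = 10)
  m <- tiny_model()
  cfg <- train_config(task = "regression", batch_size = 6, seed = 1)
  st <- new_training_state(m, cfg)
  st$phase <- "unlearn"
  x <- unlearnr:::dataset_tensor(ds, 1:8)
  d <- unlearnr:::dataset_domains(ds)[1:8]
  for (i in 1:5) {
    before <- st$model$params
    s2 <- ns$stage2_update(st, x, d)
    after2 <- s2$state$model$params
    expect_identical(after2$extractor, before$extractor)
    expect_identical(after2$predictor, before$predictor)
    expect_false(identical(after2$domain, before$domain))
    st <- s2$state
    before <- st$model$params
    s3 <- ns$stage3_update(st, x)
    after3 <- s3$state$model$params
    expect_identical(after3$domain, before$domain)
    expect_identical(after3$predictor, before$predictor)
    expect_false(identical(after3$extractor, before$extractor))
    st <- s3$state
  }
})

test_that("a full unlearning step runs the three stages in order", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 10)
  cfg <- train_config(task = "regression", batch_size = 8, head_steps = 1,
                      feature_dim = 8, width_scale = 0.25, seed = 2)
  m <- build_regression_model(c(16, 16), 2, feature_dim = 8,
                              width_scale = 0.25, seed = 2)
  st <- new_training_state(m, cfg)
  st$phase <- "unlearn"
  out <- unlearning_step(st, ds, 1:8)
  expect_true(all(is.finite(unlist(out$losses))))
  expect_named(out$losses, c("lp", "ld", "lconf"))
  # a batch with no unlearning samples is rejected
  ds2 <- ds
  for (i in seq_along(ds2$samples)) ds2$samples[[i]]$in_u <- FALSE
  expect_error(unlearning_step(st, ds2, 1:8), class = "unlearnr_error_empty")
})

test_that("pretraining improves the task and leaves theta_d learning to stage 2", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 25)
  cfg <- train_config(task = "regression", mode = "unlearn", batch_size = 10,
                      pretrain_epochs = 6, patience = 6, unlearn_epochs = 0,
                      feature_dim = 8, width_scale = 0.25, seed = 3)
  fit <- fit_unlearning(ds, cfg)
  h <- fit$history[fit$history$phase == "pretrain", ]
  expect_gt(nrow(h), 1)
  # validation task loss at exit is no worse than at the start
  expect_lte(min(h$lp_val, na.rm = TRUE), h$lp_val[1])
  # the domain classifier learned during pretraining
  expect_lt(h$ld[nrow(h)], h$ld[1])
})

test_that("normal mode ignores the adversarial losses entirely", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 15)
  cfg <- train_config(task = "regression", mode = "normal", batch_size = 10,
                      pretrain_epochs = 3, patience = 3,
                      feature_dim = 8, width_scale = 0.25, seed = 4)
  fit <- fit_unlearning(ds, cfg)
  expect_true(all(fit$history$phase == "pretrain"))
  expect_true(all(fit$history$ld == 0 | is.na(fit$history$ld)))
  expect_true(all(is.na(fit$history$lconf)))
})

test_that("samples without labels never enter the main-task loss", {
  ds <- as_segmentation_dataset(tiny_dataset(
    n_sites = 2, per_site_n = 10, label_availability = c(1, 0)))
  in_p <- vapply(ds$samples, `[[`, logical(1), "in_p")
  d <- unlearnr:::dataset_domains(ds)
  expect_true(all(!in_p[d == 2]))
  batch <- unlearnr:::.prepare_batch(ds, seq_along(ds$samples), "segmentation")
  # site-2 samples carry no label map, so the stage-1 mask excludes them
  expect_identical(batch$in_p, in_p)
  expect_true(all(is.na(batch$y[, , !in_p])))
  expect_true(all(!is.na(batch$y[, , in_p])))
})

test_that("soft-label regression and classification tasks train end to end", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 12)
  cfg <- train_config(task = "softlabel", mode = "normal", batch_size = 8,
                      pretrain_epochs = 2, patience = 2, feature_dim = 8,
                      width_scale = 0.25, seed = 9)
  fit <- fit_unlearning(ds, cfg)
  pred <- predict(fit$model, ds)
  expect_equal(rowSums(pred$probs), rep(1, length(ds)), tolerance = 1e-6)
  expect_true(all(pred$age >= 0 & pred$age <= 100))
  expect_true(all(is.finite(fit$history$lp)))
  # sex classification as the main task (the continuous-confound scenario
  # reframes the network this way)
  ds2 <- tiny_dataset(n_sites = 2, per_site_n = 12,
                      confound = list(name = "sex", correlate = "none"))
  for (i in seq_along(ds2$samples))
    ds2$samples[[i]]$main_label <- ds2$samples[[i]]$confounds$sex
  cfg2 <- train_config(task = "classification", mode = "normal",
                       batch_size = 8, pretrain_epochs = 2, patience = 2,
                       feature_dim = 8, width_scale = 0.25, seed = 9)
  fit2 <- fit_unlearning(ds2, cfg2)
  probs <- predict(fit2$model, ds2)
  expect_equal(rowSums(probs), rep(1, length(ds2)), tolerance = 1e-6)
})

test_that("identical config and seed reproduce the fit exactly", {
  ds <- tiny_dataset(n_sites = 2, per_site_n = 12)
  cfg <- train_config(task = "regression", mode = "normal", batch_size = 8,
                      pretrain_epochs = 2, patience = 2,
                      feature_dim = 8, width_scale = 0.25, seed = 5)
  f1 <- fit_unlearning(ds, cfg)
  f2 <- fit_unlearning(ds, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})
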