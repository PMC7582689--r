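test_that("subject splits partition at 60/20/20 with floor rounding", {
  subj10 <- sprintf("P%02d", 1:10)
  plan <- make_splits(subj10, n_divisions = 3, seed = 4)
  expect_length(plan, 3)
  for (d in plan) {
    expect_length(d$train, 6)
    expect_length(d$val, 2)
    expect_length(d$test, 2)
    expect_length(intersect(d$train, d$val), 0)
    expect_length(intersect(d$train, d$test), 0)
    expect_length(intersect(d$val, d$test), 0)
    expect_setequal(c(d$train, d$val, d$test), subj10)
  }
  plan122 <- make_splits(sprintf("P%03d", 1:122), n_divisions = 1, seed = 1)
  expect_length(plan122[[1]]$train, 74)
  expect_length(plan122[[1]]$val, 24)
  expect_length(plan122[[1]]$test, 24)
  expect_error(make_splits(letters[1:4]), "at least 5")
})

test_that("all clips of a subject stay in one fold", {
  ds <- small_dataset(n_subjects = 6, clips_per_subject = 4, frames = 3,
                      image_size = 24)
  subj <- unique(vapply(ds, `[[`, character(1), "subject_id"))
  plan <- make_splits(subj, n_divisions = 2, seed = 7)
  for (d in plan) {
    idx <- lapply(d, function(s) tsdnet:::clips_in_fold(ds, s))
    expect_length(Reduce(intersect, idx), 0)
    expect_length(unlist(idx), length(ds))
  }
})

test_that("the learning-rate schedule halves every period", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 0.01)
  expect_equal(lr_at_epoch(cfg, 14), 0.01)
  expect_equal(lr_at_epoch(cfg, 15), 0.005)
  expect_equal(lr_at_epoch(cfg, 119), 0.01 / 2^7)
  expect_error(lr_at_epoch(cfg, 120), "range")
  expect_error(lr_at_epoch(cfg, -1), "range")
})

test_that("metric formulas match hand counts", {
  # TP = 3, FP = 1, FN = 1, TN = 5
  truth <- c(rep("stressed", 4), rep("unstressed", 6))
  pred <- c("stressed", "stressed", "stressed", "unstressed",
            "stressed", rep("unstressed", 5))
  m <- metrics_report(truth, pred)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)
  expect_equal(unname(rowSums(m$confusion_pct)), c(100, 100))

  perfect <- metrics_report(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(sum(perfect$confusion) - sum(diag(perfect$confusion)), 0)

  # random prediction set against a hand-counted confusion oracle
  set.seed(9)
  tr <- sample(c("stressed", "unstressed"), 20, replace = TRUE)
  pr <- sample(c("stressed", "unstressed"), 20, replace = TRUE)
  m2 <- metrics_report(tr, pr)
  tp <- sum(tr == "stressed" & pr == "stressed")
  fp <- sum(tr == "unstressed" & pr == "stressed")
  fn <- sum(tr == "stressed" & pr == "unstressed")
  tn <- sum(tr == "unstressed" & pr == "unstressed")
  expect_equal(m2$accuracy, (tp + tn) / 20)
  expect_equal(m2$precision, tp / (tp + fp))
  expect_equal(m2$recall, tp / (tp + fn))
  expect_error(metrics_report(character(0), character(0)), "empty")
})

test_that("training is seeded, loss-decreasing and reproducible", {
  ds <- small_dataset(n_subjects = 6, clips_per_subject = 6, frames = 4,
                      face_signal = 1, action_signal = 1, seed = 17,
                      image_size = 20)
  cfg <- micro_config(n_frames = 4, seed = 5)
  cfg$view <- view_config(image_size = 18, crop_size = 16)
  cfg$train$epochs <- 6
  cfg$train$batch_size <- 6
  fit1 <- tsdnet_fit(ds, config = cfg)
  fit2 <- tsdnet_fit(ds, config = cfg)
  expect_equal(fit1$history$train_loss[1], fit2$history$train_loss[1],
               tolerance = 1e-12)
  expect_identical(fit1$history$val_accuracy, fit2$history$val_accuracy)
  # separable planted signal: the loss trend over training is downward
  h <- fit1$history$train_loss
  expect_lt(mean(tail(h, 2)), mean(head(h, 2)))
  # evaluation twice on the same clips is identical
  ti <- tsdnet:::clips_in_fold(ds, fit1$split$test)
  m1 <- evaluate(fit1, ds[ti])
  m2 <- evaluate(fit1, ds[ti])
  expect_identical(m1$confusion, m2$confusion)
  expect_true(m1$accuracy >= 0 && m1$accuracy <= 1)
  p <- predict(fit1, ds[ti][1:2])
  expect_identical(dim(p), c(2L, 2L))
  expect_equal(unname(rowSums(p)), c(1, 1), tolerance = 1e-9)
})

test_that("model summaries and history plots are well-formed", {
  ds <- small_dataset(n_subjects = 5, clips_per_subject = 4, frames = 3,
                      image_size = 20, seed = 23)
  cfg <- micro_config(n_frames = 3, seed = 2)
  cfg$train$epochs <- 2
  fit <- tsdnet_fit(ds, config = cfg)
  expect_s3_class(fit, "tsdnet")
  expect_output(print(fit), "streams")
  expect_output(summary(fit), "lr schedule")
  expect_named(fit$history, c("epoch", "lr", "train_loss", "val_accuracy"))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("face-only models never instantiate action parameters", {
  cfg <- micro_config(streams = "face")
  model <- tsdnet_init(cfg, seed = 1)
  expect_null(model$still)
  expect_null(model$motion)
  expect_false(is.null(model$face))
  cfg2 <- micro_config(streams = c("still", "motion"))
  model2 <- tsdnet_init(cfg2, seed = 1)
  expect_null(model2$face)
})
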