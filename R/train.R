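## Training recipe, subject-level splits, metrics, fitting and prediction.

#' Training configuration
#'
#' Defaults follow the published recipe: SGD with momentum 0.9 and weight
#' decay 0.01, learning rate 0.01 halved every 15 epochs, batch size 64,
#' 120 epochs, all parameters initialized from U(-0.001, 0.001).
#'
#' @param lr0 initial learning rate.
#' @param lr_halving_period epochs between halvings.
#' @param batch_size clips per SGD step.
#' @param epochs training epochs.
#' @param weight_decay L2 coefficient applied with the gradient.
#' @param momentum SGD momentum.
#' @param clip_grad global L2 gradient-norm ceiling per step (`Inf`
#'   disables clipping).
#' @param warmup_epochs linear learning-rate ramp over the first
#'   `warmup_epochs` epochs (0 disables). Guards the rectified layers
#'   against dying in the first large momentum steps.
#' @param gate_lr_scale learning-rate multiplier for the fusion gate
#'   parameters (local stream gates and the global gate). Gates adapt on
#'   the scale of whole-stream usefulness, which changes much more slowly
#'   than the representations being gated; at the full rate SGD can shut
#'   a not-yet-trained stream's ReLU gate permanently.
#' @param init_kind `"uniform"` or `"he"` (see [nn_init()]).
#' @param init_range range for `"uniform"` initialization.
#' @param seed RNG seed for initialization, shuffling and crop draws.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.01, lr_halving_period = 15, batch_size = 64,
                         epochs = 120, weight_decay = 0.01, momentum = 0.9,
                         init_kind = "uniform",
                         init_range = c(-0.001, 0.001), clip_grad = Inf,
                         warmup_epochs = 0, gate_lr_scale = 1, seed = 1) {
  stopifnot(lr0 > 0, lr_halving_period > 0, batch_size > 0, epochs > 0,
            weight_decay >= 0, momentum >= 0, clip_grad > 0,
            warmup_epochs >= 0, gate_lr_scale > 0)
  structure(list(lr0 = lr0, lr_halving_period = as.integer(lr_halving_period),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 momentum = momentum, init_kind = init_kind,
                 init_range = init_range, clip_grad = clip_grad,
                 warmup_epochs = warmup_epochs,
                 gate_lr_scale = gate_lr_scale, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at an epoch
#'
#' `lr = lr0 / 2^floor(epoch / period)` with a 0-based epoch index.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch, `0 <= epoch < cfg$epochs`.
#' @return the learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (epoch < 0 || epoch >= cfg$epochs) stop("epoch out of range")
  cfg$lr0 / 2^(epoch %/% cfg$lr_halving_period)
}

#' Subject-level split plan
#'
#' Partitions subjects (never clips) into train/validation/test folds at
#' the given ratios, repeated over independent random divisions. Fold
#' sizes use floor arithmetic with the remainder assigned to train.
#'
#' @param subjects character vector of unique subject ids (at least 5).
#' @param ratios train/val/test proportions summing to 1.
#' @param n_divisions number of independent divisions.
#' @param seed RNG seed.
#' @return an object of class `split_plan`: a list of divisions, each
#'   with `train`, `val`, `test` subject-id vectors.
#' @export
make_splits <- function(subjects, ratios = c(0.6, 0.2, 0.2),
                        n_divisions = 3, seed = 1) {
  subjects <- unique(as.character(subjects))
  n <- length(subjects)
  if (n < 5) stop("need at least 5 subjects for a 60/20/20 split")
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test
  divisions <- with_seed(seed, lapply(seq_len(n_divisions), function(d) {
    perm <- sample(subjects)
    list(train = sort(perm[seq_len(n_train)]),
         val = sort(perm[n_train + seq_len(n_val)]),
         test = sort(perm[n_train + n_val + seq_len(n_test)]))
  }))
  structure(divisions, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split plan> %d division(s); fold sizes %d/%d/%d subjects\n",
              length(x), length(x[[1]]$train), length(x[[1]]$val),
              length(x[[1]]$test)))
  invisible(x)
}

clips_in_fold <- function(clips, subject_ids) {
  keep <- vapply(clips, function(cl) cl$subject_id %in% subject_ids,
                 logical(1))
  which(keep)
}

#' Classification metrics report
#'
#' Confusion-matrix metrics with `"stressed"` as the positive class.
#' `average = "positive"` reports precision/recall/F1 for the positive
#' class; `"macro"` averages both classes.
#'
#' @param truth actual labels (`"stressed"` / `"unstressed"`).
#' @param pred predicted labels.
#' @param average `"positive"` or `"macro"`.
#' @return object of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, `confusion` (counts, actual x detected) and
#'   `confusion_pct` (row percentages).
#' @export
metrics_report <- function(truth, pred, average = c("positive", "macro")) {
  average <- match.arg(average)
  lv <- c("stressed", "unstressed")
  truth <- factor(as.character(truth), levels = lv)
  pred <- factor(as.character(pred), levels = lv)
  if (length(truth) == 0) stop("metrics_report: empty fold")
  cm <- table(actual = truth, detected = pred)
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f)
  }
  pos <- prf(tp, fp, fn)
  if (average == "macro") {
    neg <- prf(tn, fn, fp)
    pos <- (pos + neg) / 2
  }
  pct <- sweep(cm, 1, pmax(rowSums(cm), 1), `/`) * 100
  structure(list(accuracy = (tp + tn) / sum(cm),
                 precision = unname(pos["p"]), recall = unname(pos["r"]),
                 f1 = unname(pos["f"]), confusion = cm,
                 confusion_pct = pct, average = average),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f (%s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$average))
  print(x$confusion)
  invisible(x)
}

## clip preparation cache ----------------------------------------------------

# resize + subsample + flow once per clip; crops are drawn per epoch
prep_clip <- function(clip, cfg, scorer) {
  vc <- cfg$view
  n <- cfg$action$n_frames
  idx <- subsample_indices(length(clip$frames), n)
  stills_r <- lapply(clip$frames[idx], resize_image, target = vc$image_size)
  flows_r <- vector("list", length(stills_r) - 1)
  for (t in seq_along(flows_r)) {
    fl <- compute_flow(stills_r[[t]], stills_r[[t + 1]],
                       backend = vc$flow_backend, radius = vc$flow_max_disp)
    flows_r[[t]] <- render_flow(fl, max_disp = vc$flow_max_disp)
  }
  out <- list(stills = stills_r, flows = flows_r, label = clip$label)
  if ("face" %in% cfg$fusion$streams) {
    probs <- score_faces(scorer, clip$faces)
    kf <- select_key_faces(clip$faces, probs)
    out$face_e <- resize_image(kf$face_e, vc$image_size)
    out$face_l <- resize_image(kf$face_l, vc$image_size)
    out$key <- c(kf$idx_e, kf$idx_l)
  }
  out
}

prep_norm_stats <- function(prepped, train_idx, max_clips = 30) {
  use <- train_idx[seq_len(min(length(train_idx), max_clips))]
  acc <- list(face = NULL, still = NULL, flow = NULL)
  push <- function(a, img) {
    v <- apply(img, 3, function(ch) c(sum(ch), sum(ch^2), length(ch)))
    if (is.null(a)) v else a + v
  }
  for (i in use) {
    p <- prepped[[i]]
    if (!is.null(p$face_e)) {
      acc$face <- push(acc$face, p$face_e)
      acc$face <- push(acc$face, p$face_l)
    }
    for (im in p$stills) acc$still <- push(acc$still, im)
    for (im in p$flows) acc$flow <- push(acc$flow, im)
  }
  fin <- function(a) {
    if (is.null(a)) return(list(mean = c(0, 0, 0), sd = c(1, 1, 1)))
    m <- a[1, ] / a[3, ]
    s <- sqrt(pmax(a[2, ] / a[3, ] - m^2, 1e-8))
    list(mean = m, sd = pmax(s, 1e-3))
  }
  st <- lapply(acc, fin)
  list(norm_mean = lapply(st, `[[`, "mean"),
       norm_sd = lapply(st, `[[`, "sd"))
}

# crop + normalize a prepped clip into a model sample
materialize_sample <- function(p, cfg, mode = "eval") {
  vc <- cfg$view
  offset <- crop_window(vc$image_size, vc$crop_size, mode)
  nm <- function(v) vc$norm_mean[[v]] %||% 0
  ns <- function(v) vc$norm_sd[[v]] %||% 1
  cr <- function(img, v)
    crop_normalize(img, crop = vc$crop_size, mean = nm(v), sd = ns(v),
                   offset = offset)
  out <- list(stills = lapply(p$stills, cr, v = "still"),
              flows = lapply(p$flows, cr, v = "flow"))
  if (!is.null(p$face_e)) {
    out$face_e <- cr(p$face_e, "face")
    out$face_l <- cr(p$face_l, "face")
  }
  out
}

# slow down the fusion gates relative to the rest of the model
scale_gate_grads <- function(g, s) {
  if (s == 1 || is.null(g$fusion)) return(g)
  g$fusion$local <- tree_scale(g$fusion$local, s)
  g$fusion$W11 <- g$fusion$W11 * s
  g$fusion$b11 <- g$fusion$b11 * s
  g
}

## fitting --------------------------------------------------------------------

#' Fit a two-stream stress-detection model
#'
#' Trains the configured streams end to end with SGD (momentum, weight
#' decay, halved learning rate) on subject-level train/validation folds,
#' and keeps the parameters of the best validation epoch.
#'
#' @param clips list of `tsd_clip` objects (e.g. [generate_dataset()] or
#'   [read_clips()]).
#' @param config a [tsdnet_config()].
#' @param split a [make_splits()] plan over the clips' subjects, or `NULL`
#'   to draw one division with the config seed.
#' @param division which division of the plan to train on.
#' @param scorer expression scorer used to pick the key-face pair (a
#'   trained [train_expression_classifier()] model, the geometric
#'   [curvature_scorer()] default, or any `image -> prob` function).
#' @param verbose print per-epoch progress.
#' @return an object of class `tsdnet` with `model`, `history`
#'   (data.frame of epoch, lr, train_loss, val_accuracy), `split`
#'   (subject folds used), `config`, and the frozen normalization
#'   statistics.
#' @export
tsdnet_fit <- function(clips, config = tsdnet_config("tiny"), split = NULL,
                       division = 1, scorer = curvature_scorer(),
                       verbose = FALSE) {
  tc <- config$train
  subjects <- unique(vapply(clips, `[[`, character(1), "subject_id"))
  if (is.null(split))
    split <- make_splits(subjects, n_divisions = 1, seed = tc$seed)
  fold <- split[[division]]
  idx_train <- clips_in_fold(clips, fold$train)
  idx_val <- clips_in_fold(clips, fold$val)
  if (length(idx_train) == 0 || length(idx_val) == 0)
    stop("empty train or validation fold")
  labels <- vapply(clips, `[[`, character(1), "label")
  lab_idx <- label_index(labels)

  prepped <- lapply(clips, prep_clip, cfg = config, scorer = scorer)
  stats <- prep_norm_stats(prepped, idx_train)
  config$view$norm_mean <- stats$norm_mean
  config$view$norm_sd <- stats$norm_sd

  model <- tsdnet_init(config)
  params <- model_trainable(model)
  state <- sgd_state(params)
  set.seed(tc$seed + 1L)

  eval_samples <- lapply(prepped, materialize_sample, cfg = config,
                         mode = "eval")
  eval_acc <- function(idx) {
    pred <- vapply(idx, function(i) {
      y <- model_forward(model, eval_samples[[i]])$y
      which.max(y)
    }, integer(1))
    mean(pred == lab_idx[idx])
  }

  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(acc = -1, params = params)
  warmup_steps <- (tc$warmup_epochs %||% 0) *
    ceiling(length(idx_train) / tc$batch_size)
  step <- 0
  for (epoch in seq_len(tc$epochs)) {
    lr <- lr_at_epoch(tc, epoch - 1)
    ord <- sample(idx_train)
    tot <- 0
    for (b0 in seq(1, length(ord), by = tc$batch_size)) {
      step <- step + 1
      lr_eff <- if (step <= warmup_steps) lr * step / (warmup_steps + 1)
                else lr
      bidx <- ord[b0:min(b0 + tc$batch_size - 1, length(ord))]
      gacc <- NULL
      for (i in bidx) {
        smp <- materialize_sample(prepped[[i]], config, mode = "train")
        fw <- model_forward(model, smp, label_idx = lab_idx[i])
        if (!is.finite(fw$loss))
          stop("non-finite loss at epoch ", epoch, " (diverged)")
        tot <- tot + fw$loss
        gacc <- tree_add(gacc, model_backward(model, fw$cache))
      }
      gacc <- clip_gradients(tree_scale(gacc, 1 / length(bidx)),
                             tc$clip_grad)
      gacc <- scale_gate_grads(gacc, tc$gate_lr_scale %||% 1)
      st <- sgd_step(params, gacc, state, lr_eff, tc$momentum,
                     tc$weight_decay)
      params <- st$params
      state <- st$state
      model <- model_set_trainable(model, params)
    }
    vacc <- eval_acc(idx_val)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = tot / length(ord),
                                val_accuracy = vacc))
    if (vacc > best$acc) best <- list(acc = vacc, params = params)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val acc %.3f",
                      epoch, lr, tot / length(ord), vacc))
  }
  model <- model_set_trainable(model, best$params)
  structure(list(model = model, config = config, scorer = scorer,
                 history = history, split = fold,
                 best_val_accuracy = best$acc,
                 classes = c("stressed", "unstressed")),
            class = "tsdnet")
}

#' @export
print.tsdnet <- function(x, ...) {
  cat(sprintf("tsdnet fit: streams %s, strategy %s\n",
              paste(x$config$fusion$streams, collapse = "+"),
              x$config$fusion$strategy))
  cat(sprintf("  %d epochs, best validation accuracy %.3f\n",
              nrow(x$history), x$best_val_accuracy))
  cat(sprintf("  folds: %d/%d/%d subjects (train/val/test)\n",
              length(x$split$train), length(x$split$val),
              length(x$split$test)))
  invisible(x)
}

#' @export
summary.tsdnet <- function(object, ...) {
  cat("Two-stream stress detector\n")
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.4f, lr schedule %.4g -> %.4g\n",
              h$train_loss[nrow(h)], h$lr[1], h$lr[nrow(h)]))
  invisible(object)
}

#' @export
plot.tsdnet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "b", pch = 20, xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(h$epoch, h$val_accuracy, type = "b", pch = 20, xlab = "epoch",
       ylab = "validation accuracy", main = "validation", ylim = c(0, 1),
       ...)
  invisible(x)
}

#' Predict stress posteriors for clips
#'
#' @param object a fitted [tsdnet_fit()] model.
#' @param clips list of `tsd_clip` objects.
#' @param type `"prob"` for the posterior matrix, `"class"` for labels.
#' @param ... unused.
#' @return a matrix (clips x classes) of posteriors, or a character
#'   vector of labels.
#' @export
predict.tsdnet <- function(object, clips, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- t(vapply(clips, function(cl) {
    p <- prep_clip(cl, object$config, object$scorer)
    smp <- materialize_sample(p, object$config, mode = "eval")
    model_forward(object$model, smp)$y
  }, numeric(2)))
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else object$classes[max.col(probs, ties.method = "first")]
}

#' Evaluate a fitted model on a fold of clips
#'
#' @param fit a fitted [tsdnet_fit()] model.
#' @param clips clips to evaluate (e.g. the test fold).
#' @param average metric averaging, see [metrics_report()].
#' @return a [metrics_report()].
#' @export
evaluate <- function(fit, clips, average = "positive") {
  if (length(clips) == 0) stop("evaluate: empty fold")
  truth <- vapply(clips, `[[`, character(1), "label")
  pred <- predict(fit, clips, type = "class")
  metrics_report(truth, pred, average = average)
}
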