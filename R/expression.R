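## Expressive / expressionless scoring and key-face selection: the clip's
## most expressive and most expressionless faces are picked by ranking
## per-frame expressiveness probabilities (eProb).

#' Expression-scorer configuration
#'
#' @param backbone backbone architecture descriptor (default: the tiny
#'   face backbone).
#' @param image_size side faces are resized to before cropping.
#' @param crop_size network input side.
#' @return a `scorer_cfg` list.
#' @export
scorer_cfg <- function(backbone = NULL, image_size = 36, crop_size = 32) {
  if (is.null(backbone))
    backbone <- list(list(op = "conv", out = 16, stride = 2),
                     list(op = "conv", out = 32, stride = 2),
                     list(op = "res"),
                     # unnormalized final stage: see backbone notes
                     list(op = "conv", out = 32, stride = 1, norm = FALSE))
  structure(list(backbone = backbone, image_size = as.integer(image_size),
                 crop_size = as.integer(crop_size)),
            class = "scorer_cfg")
}

# per-image, per-channel standardization (no dataset statistics needed)
standardize_image <- function(img) {
  for (ch in seq_len(dim(img)[3])) {
    v <- img[, , ch]
    img[, , ch] <- (v - mean(v)) / max(stats::sd(v), 1e-3)
  }
  img
}

scorer_prep <- function(scfg, img, mode = "eval") {
  img <- resize_image(img, scfg$image_size)
  img <- crop_normalize(img, mode = mode, crop = scfg$crop_size)
  standardize_image(img)
}

scorer_fw <- function(sc, x) {
  bo <- backbone_forward(sc$backbone, x)
  pd <- dim(bo$y)
  pooled <- cpp_avgpool(bo$y, pd[1])
  v <- as.vector(pooled)
  lf <- linear_fw(sc$head, v)
  y <- softmax_vec(lf$y)
  list(y = y, cache = list(bb = bo$cache, pd = pd, v = v, yv = y))
}

scorer_bw <- function(sc, cache, label_idx) {
  dlogits <- cache$yv
  dlogits[label_idx] <- dlogits[label_idx] - 1
  gh <- list(W = outer(cache$v, dlogits), b = dlogits)
  dv <- drop(sc$head$W %*% dlogits)
  dmap <- cpp_avgpool_backward(array(dv, c(1, 1, length(dv))), cache$pd[1])
  gb <- backbone_backward(sc$backbone, cache$bb, dmap)
  list(backbone = gb$grads, head = gh)
}

#' Train the binary expression classifier
#'
#' A backbone + global-average-pool + softmax head trained with the
#' standard SGD recipe on an expressive/expressionless face corpus. Input
#' images are resized, cropped (randomly in training) and standardized
#' per image.
#'
#' @param corpus list with `images` and two-level `labels`
#'   (`expressionless` first), e.g. from [generate_expression_corpus()].
#' @param cfg a [scorer_cfg()].
#' @param train_cfg a [train_config()]; the tiny default trains in a few
#'   seconds on a 200-image corpus.
#' @param verbose print per-epoch loss.
#' @return an object of class `tsd_scorer` mapping face image -> eProb,
#'   the probability that the face is expressive.
#' @export
train_expression_classifier <- function(corpus, cfg = scorer_cfg(),
                                        train_cfg = train_config(
                                          epochs = 8, batch_size = 16,
                                          lr0 = 0.02, weight_decay = 1e-4,
                                          init_kind = "he", clip_grad = 5),
                                        verbose = FALSE) {
  labs <- as.integer(factor(corpus$labels,
                            levels = c("expressionless", "expressive")))
  if (length(unique(labs)) < 2)
    stop("corpus must contain both classes")
  init <- nn_init(train_cfg$init_kind, train_cfg$init_range)
  set.seed(train_cfg$seed)
  sc <- list(cfg = cfg,
             backbone = backbone_init(cfg$backbone, 3L, init),
             head = NULL)
  probe <- backbone_forward(sc$backbone,
                            array(0, c(cfg$crop_size, cfg$crop_size, 3)))$y
  sc$head <- linear_init(dim(probe)[3], 2L, init)
  params <- list(backbone = backbone_params(sc$backbone),
                 head = sc$head[c("W", "b")])
  state <- sgd_state(params)
  n <- length(corpus$images)
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- lr_at_epoch(train_cfg, epoch - 1)
    ord <- sample.int(n)
    tot <- 0
    for (b0 in seq(1, n, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1, n)]
      gacc <- NULL
      for (i in idx) {
        x <- scorer_prep(cfg, corpus$images[[i]], mode = "train")
        fw <- scorer_fw(sc, x)
        tot <- tot + cross_entropy(fw$y, labs[i])
        gacc <- tree_add(gacc, scorer_bw(sc, fw$cache, labs[i]))
      }
      gacc <- clip_gradients(tree_scale(gacc, 1 / length(idx)),
                             train_cfg$clip_grad)
      st <- sgd_step(params, gacc, state, lr, train_cfg$momentum,
                     train_cfg$weight_decay)
      params <- st$params
      state <- st$state
      sc$backbone <- backbone_set_params(sc$backbone, params$backbone)
      sc$head[c("W", "b")] <- params$head
    }
    if (verbose)
      message(sprintf("scorer epoch %d: loss %.4f", epoch, tot / n))
  }
  structure(list(cfg = cfg, backbone = sc$backbone, head = sc$head,
                 classes = c("expressionless", "expressive")),
            class = "tsd_scorer")
}

#' @export
print.tsd_scorer <- function(x, ...) {
  cat(sprintf("<expression scorer> %d-px input, %d backbone stages\n",
              x$cfg$crop_size, length(x$backbone$layers)))
  invisible(x)
}

#' Predict eProb for face images
#'
#' @param object a `tsd_scorer`.
#' @param images a single image or list of images.
#' @param ... unused.
#' @return numeric vector of expressive probabilities in `[0, 1]`.
#' @export
predict.tsd_scorer <- function(object, images, ...) {
  if (!is.list(images)) images <- list(images)
  vapply(images, function(im) {
    x <- scorer_prep(object$cfg, im, mode = "eval")
    scorer_fw(object, x)$y[2]
  }, numeric(1))
}

#' Geometry-based expressiveness scorer
#'
#' A training-free scorer for the synthetic face family: measures the
#' mouth-arc apex offset from pixels (dark pixels in the lower face) and
#' rescales it to `[0, 1]`. Useful as a fast default and as a reference
#' point for the learned scorer; it knows nothing about any individual
#' clip.
#'
#' @return a function `image -> eProb`.
#' @export
curvature_scorer <- function() {
  function(img) {
    g <- to_gray(img)
    s <- nrow(g)
    rows <- seq(max(1, floor(0.55 * s)), s)
    sub <- g[rows, , drop = FALSE]
    dark <- which(sub < 0.30, arr.ind = TRUE)
    if (nrow(dark) == 0) return(0)
    cmin <- min(dark[, 2]); cmax <- max(dark[, 2])
    cc <- round((cmin + cmax) / 2)
    center_rows <- dark[abs(dark[, 2] - cc) <= 1, 1]
    corner_rows <- dark[dark[, 2] <= cmin + 1 | dark[, 2] >= cmax - 1, 1]
    if (length(center_rows) == 0 || length(corner_rows) == 0) return(0)
    curv <- mean(range(corner_rows)) - min(center_rows)
    max(0, min(1, curv / (0.18 * s)))
  }
}

#' Oracle scorer for a planted synthetic clip
#'
#' Wraps the expressiveness series recorded by [generate_clip()] as a
#' scorer, for ground-truth key-frame experiments.
#'
#' @param clip a `tsd_clip` with an `expressiveness` field.
#' @return an object usable with [score_faces()].
#' @export
oracle_scorer <- function(clip) {
  if (is.null(clip$expressiveness))
    stop("clip carries no planted expressiveness series")
  structure(list(probs = clip$expressiveness), class = "tsd_oracle_scorer")
}

#' Score a face sequence
#'
#' Order-preserving map from face images to expressiveness probabilities.
#'
#' @param scorer a `tsd_scorer`, a plain function `image -> prob`, or an
#'   [oracle_scorer()].
#' @param face_seq non-empty list of face images.
#' @return numeric vector of probabilities, one per face.
#' @export
score_faces <- function(scorer, face_seq) {
  if (length(face_seq) == 0) stop("score_faces: empty face sequence")
  if (inherits(scorer, "tsd_scorer")) {
    predict(scorer, face_seq)
  } else if (inherits(scorer, "tsd_oracle_scorer")) {
    if (length(scorer$probs) != length(face_seq))
      stop("oracle scorer length mismatch")
    scorer$probs
  } else if (is.function(scorer)) {
    vapply(face_seq, function(im) scorer(im), numeric(1))
  } else {
    stop("unsupported scorer object")
  }
}

#' Select the key-face pair
#'
#' The most expressive face is the probability argmax, the most
#' expressionless the argmin; ties break toward the earliest frame, and
#' the two indices are forced distinct (under a full tie the pair is
#' frames 1 and 2).
#'
#' @param face_seq list of face images (length at least 2).
#' @param probs expressiveness probabilities, same length.
#' @return object of class `key_face_pair`: `face_e`, `face_l`, `prob_e`,
#'   `prob_l`, `idx_e`, `idx_l`.
#' @export
select_key_faces <- function(face_seq, probs) {
  n <- length(face_seq)
  if (n < 2) stop("select_key_faces: need at least 2 faces")
  if (length(probs) != n) stop("select_key_faces: length mismatch")
  idx_e <- which.max(probs)
  rest <- setdiff(seq_len(n), idx_e)
  idx_l <- rest[which.min(probs[rest])]
  structure(list(face_e = face_seq[[idx_e]], face_l = face_seq[[idx_l]],
                 prob_e = probs[idx_e], prob_l = probs[idx_l],
                 idx_e = idx_e, idx_l = idx_l),
            class = "key_face_pair")
}

#' @export
print.key_face_pair <- function(x, ...) {
  cat(sprintf("<key faces> expressive #%d (%.3f), expressionless #%d (%.3f)\n",
              x$idx_e, x$prob_e, x$idx_l, x$prob_l))
  invisible(x)
}
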