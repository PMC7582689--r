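## Model assembly: configuration presets and the clip-level forward /
## backward pass over the active streams.

backbone_tiny_face <- function() {
  list(list(op = "conv", out = 16, stride = 2),
       list(op = "conv", out = 32, stride = 2),
       list(op = "res"))
}

backbone_tiny_action <- function() {
  list(list(op = "conv", out = 16, stride = 2),
       list(op = "conv", out = 32, stride = 2),
       list(op = "res"),
       list(op = "conv", out = 32, stride = 2),
       # final stage unnormalized: global pooling of a spatially
       # normalized map would collapse every channel to a constant
       list(op = "conv", out = 32, stride = 2, norm = FALSE))
}

backbone_reference_face <- function() {
  list(list(op = "conv", out = 64, stride = 2),
       list(op = "conv", out = 128, stride = 2),
       list(op = "conv", out = 256, stride = 2),
       list(op = "res"),
       list(op = "conv", out = 512, stride = 1))
}

backbone_reference_action <- function() {
  c(backbone_reference_face(),
    list(list(op = "conv", out = 1024, stride = 2),
         list(op = "conv", out = 2048, stride = 2, norm = FALSE)))
}

#' Full model configuration
#'
#' Two presets: `"tiny"` is the desk-scale CPU configuration (36-px
#' resize, 32-px crops, 8 model frames, 32-channel backbones, 20 epochs,
#' He initialization); `"reference"` mirrors the published geometry and
#' recipe (70-px resize, 64-px crops, a 512x8x8 face map, 2048-long frame
#' features, 120 epochs of SGD from U(-0.001, 0.001)).
#'
#' @param preset `"tiny"` or `"reference"`.
#' @param streams subset of `c("still", "motion", "face")`.
#' @param strategy fusion strategy, see [fusion_cfg()].
#' @param n_frames frames fed to the action streams (clips with more
#'   frames are uniformly subsampled).
#' @param m stream representation length.
#' @param seed training seed stored in the train config.
#' @return an object of class `tsdnet_config` with components `view`
#'   ([view_config()]), `face` ([face_cfg()]), `action` ([action_cfg()]),
#'   `fusion` ([fusion_cfg()]) and `train` ([train_config()]); fields can
#'   be edited directly before fitting.
#' @export
tsdnet_config <- function(preset = c("tiny", "reference"),
                          streams = c("still", "motion", "face"),
                          strategy = "weighted_attention",
                          n_frames = NULL, m = 20, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    n_frames <- n_frames %||% 8L
    cfg <- list(
      view = view_config(image_size = 36, crop_size = 32),
      face = face_cfg(backbone_tiny_face(), m = m, crop_size = 32),
      action = action_cfg(backbone_tiny_action(), n_frames = n_frames,
                          m = m, crop_size = 32),
      fusion = fusion_cfg(strategy = strategy, streams = streams, m = m),
      train = train_config(lr0 = 0.01, epochs = 20, batch_size = 8,
                           weight_decay = 1e-4, init_kind = "he",
                           clip_grad = 5, warmup_epochs = 1,
                           gate_lr_scale = 0.1, seed = seed))
  } else {
    n_frames <- n_frames %||% 16L
    cfg <- list(
      view = view_config(image_size = 70, crop_size = 64),
      face = face_cfg(backbone_reference_face(), m = m, crop_size = 64),
      action = action_cfg(backbone_reference_action(), n_frames = n_frames,
                          m = m, crop_size = 64),
      fusion = fusion_cfg(strategy = strategy, streams = streams, m = m),
      train = train_config(seed = seed))
  }
  cfg$preset <- preset
  structure(cfg, class = "tsdnet_config")
}

#' Instantiate model parameters from a configuration
#'
#' Only the configured streams are instantiated (a face-only model holds
#' no action parameters). The still and motion streams share a structure
#' but have independent weights; the motion stream is built for
#' `n_frames - 1` flow images.
#'
#' @param config a [tsdnet_config()].
#' @param seed RNG seed for the initialization draw.
#' @return an object of class `tsdnet_model`.
#' @export
tsdnet_init <- function(config, seed = config$train$seed) {
  init <- nn_init(config$train$init_kind, config$train$init_range)
  set.seed(seed)
  streams <- config$fusion$streams
  model <- list(cfg = config, face = NULL, still = NULL, motion = NULL)
  if ("face" %in% streams) model$face <- face_params(config$face, init)
  if ("still" %in% streams)
    model$still <- action_params(config$action, config$action$n_frames, init)
  if ("motion" %in% streams)
    model$motion <- action_params(config$action, config$action$n_frames - 1L,
                                  init)
  model$fusion <- fusion_params(config$fusion, init)
  structure(model, class = "tsdnet_model")
}

model_trainable <- function(model) {
  tr <- list()
  if (!is.null(model$face)) tr$face <- face_trainable(model$face)
  if (!is.null(model$still)) tr$still <- action_trainable(model$still)
  if (!is.null(model$motion)) tr$motion <- action_trainable(model$motion)
  tr$fusion <- fusion_trainable(model$fusion)
  tr
}

model_set_trainable <- function(model, tr) {
  if (!is.null(model$face))
    model$face <- face_set_trainable(model$face, tr$face)
  if (!is.null(model$still))
    model$still <- action_set_trainable(model$still, tr$still)
  if (!is.null(model$motion))
    model$motion <- action_set_trainable(model$motion, tr$motion)
  model$fusion <- fusion_set_trainable(model$fusion, tr$fusion)
  model
}

# sample: list(face_e, face_l, stills (list n), flows (list n-1))
model_forward <- function(model, sample, label_idx = NULL) {
  streams <- model$cfg$fusion$streams
  us <- list()
  caches <- list()
  if ("still" %in% streams) {
    o <- action_forward(model$still, sample$stills)
    us$still <- o$u; caches$still <- o$cache
  }
  if ("motion" %in% streams) {
    o <- action_forward(model$motion, sample$flows)
    us$motion <- o$u; caches$motion <- o$cache
  }
  if ("face" %in% streams) {
    o <- face_forward(model$face, sample$face_e, sample$face_l)
    us$face <- o$u; caches$face <- o$cache
  }
  us <- us[streams[streams %in% names(us)]]
  fo <- fusion_fw(model$fusion, us, label_idx)
  list(y = fo$y, loss = fo$loss, weights = fo$weights,
       cache = list(streams = caches, fusion = fo$cache))
}

model_backward <- function(model, cache) {
  fb <- fusion_bw(model$fusion, cache$fusion)
  g <- list()
  if (!is.null(model$face))
    g$face <- face_backward(model$face, cache$streams$face,
                            fb$dus$face)$grads
  if (!is.null(model$still))
    g$still <- action_backward(model$still, cache$streams$still,
                               fb$dus$still)$grads
  if (!is.null(model$motion))
    g$motion <- action_backward(model$motion, cache$streams$motion,
                                fb$dus$motion)$grads
  g$fusion <- fb$grads
  # order leaves like model_trainable()
  g[intersect(c("face", "still", "motion", "fusion"), names(g))]
}

#' @export
print.tsdnet_model <- function(x, ...) {
  s <- x$cfg$fusion$streams
  cat(sprintf("<tsdnet model> streams: %s; strategy: %s; m = %d\n",
              paste(s, collapse = "+"), x$cfg$fusion$strategy,
              x$cfg$fusion$m))
  invisible(x)
}

subsample_indices <- function(n_total, n) {
  if (n_total <= n) return(seq_len(n_total))
  unique(round(seq(1, n_total, length.out = n)))
}
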