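## Stream-weighted integration with local and global attention, plus the
## three comparison integrators (early, loss-based early, late).

#' Fusion configuration
#'
#' @param strategy `"weighted_attention"` (local scalar gates per stream,
#'   an elementwise global gate with residual on the concatenation, then a
#'   softmax classifier), `"early"` (one classifier on the plain
#'   concatenation), `"loss_early"` (early head plus per-stream auxiliary
#'   heads whose losses are combined with weights `lambdas`), or `"late"`
#'   (independent per-stream classifiers whose posteriors are combined).
#' @param streams character subset of `c("still", "motion", "face")` in
#'   that order; single-stream ablations use a one-element subset.
#' @param attention_enabled disable for the ablation `w = 1`, `g = 0`
#'   (weighted_attention collapses to a residual-free early head).
#' @param gate_mode `"elementwise"`: `g = ReLU(W11 * U + b11)` with
#'   `W11, b11` of length `S*m`; `"scalar"`: `g = ReLU(sum(W11 * U) + b11)`
#'   broadcast.
#' @param lambdas loss weights for `"loss_early"`, one per stream plus one
#'   for the fused head (must sum to 1; default 0.2/0.2/0.2/0.4).
#' @param late_rule `"mean"` averages per-stream posteriors; `"vote"`
#'   majority vote with posterior-mean tie-break.
#' @param classnum number of classes (2: stressed / unstressed).
#' @param m stream representation length.
#' @return a `fusion_cfg` list.
#' @export
fusion_cfg <- function(strategy = c("weighted_attention", "early",
                                    "loss_early", "late"),
                       streams = c("still", "motion", "face"),
                       attention_enabled = TRUE,
                       gate_mode = c("elementwise", "scalar"),
                       lambdas = c(0.2, 0.2, 0.2, 0.4),
                       late_rule = c("mean", "vote"),
                       classnum = 2, m = 20) {
  strategy <- match.arg(strategy)
  streams <- match.arg(streams, c("still", "motion", "face"),
                       several.ok = TRUE)
  stopifnot(length(streams) >= 1, classnum == 2)
  lambdas <- lambdas / sum(lambdas)
  structure(list(strategy = strategy, streams = streams,
                 attention_enabled = attention_enabled,
                 gate_mode = match.arg(gate_mode), lambdas = lambdas,
                 late_rule = match.arg(late_rule),
                 classnum = as.integer(classnum), m = as.integer(m)),
            class = "fusion_cfg")
}

#' Initialize fusion parameters
#'
#' @param cfg a [fusion_cfg()].
#' @param init an [nn_init()].
#' @return an object of class `fusion_params`.
#' @export
fusion_params <- function(cfg, init = nn_init("he")) {
  m <- cfg$m; S <- length(cfg$streams)
  # Gate weights start near zero and local-gate biases at 1, so at
  # initialization every local gate is open (w ~ 1) for all inputs and the
  # global gate is the identity residual (g ~ 0, G = U). A ReLU gate that
  # closes for every input has zero gradient and never recovers, and the
  # stream representations are non-negative, so a generic init can close a
  # gate permanently on the whole data distribution.
  gate_init <- nn_init("uniform", c(-0.001, 0.001))
  local <- lapply(cfg$streams, function(s)
    list(W = drop(init_weights(gate_init, c(m), m)), b = 1))
  names(local) <- cfg$streams
  structure(list(
    cfg = cfg, S = S,
    local = local,
    W11 = drop(init_weights(gate_init, S * m, S * m)),
    b11 = if (cfg$gate_mode == "elementwise") numeric(S * m) else 0,
    W12 = init_weights(init, c(S * m, cfg$classnum), S * m),
    heads = lapply(stats::setNames(cfg$streams, cfg$streams), function(s)
      linear_init(m, cfg$classnum, init)),
    early = linear_init(S * m, cfg$classnum, init)
  ), class = "fusion_params")
}

#' Local stream attention weights
#'
#' One non-negative scalar per stream: `w_x = ReLU(W . U_x + b)`.
#'
#' @param u_sti,u_mot,u_fac length-m stream representations; pass only the
#'   streams the parameter object was built for.
#' @param params a [fusion_params()].
#' @return named numeric vector of per-stream weights.
#' @export
local_weights <- function(u_sti = NULL, u_mot = NULL, u_fac = NULL, params) {
  us <- stream_list(params$cfg, u_sti, u_mot, u_fac)
  vapply(names(us), function(s) {
    p <- params$local[[s]]
    max(sum(p$W * us[[s]]) + p$b, 0)
  }, numeric(1))
}

stream_list <- function(cfg, u_sti, u_mot, u_fac) {
  all <- list(still = u_sti, motion = u_mot, face = u_fac)
  us <- all[cfg$streams]
  for (s in cfg$streams) {
    if (is.null(us[[s]])) stop("missing representation for stream ", s)
    if (length(us[[s]]) != cfg$m)
      stop("stream ", s, ": expected length ", cfg$m)
    if (any(!is.finite(us[[s]]))) stop("non-finite stream representation")
  }
  us
}

as_prediction <- function(y, weights = NULL, classes = c("stressed",
                                                         "unstressed")) {
  names(y) <- classes
  structure(list(y = y, label = classes[which.max(y)], weights = weights),
            class = "tsd_prediction")
}

#' @export
print.tsd_prediction <- function(x, ...) {
  cat(sprintf("<prediction> %s  (p = %s)\n", x$label,
              paste(sprintf("%s %.3f", names(x$y), x$y), collapse = ", ")))
  invisible(x)
}

## weighted integration with local + global attention -----------------------

fusion_fw <- function(fp, us, label_idx = NULL) {
  cfg <- fp$cfg
  if (cfg$strategy == "weighted_attention") {
    if (cfg$attention_enabled) {
      pre_w <- vapply(names(us), function(s)
        sum(fp$local[[s]]$W * us[[s]]) + fp$local[[s]]$b, numeric(1))
      w <- pmax(pre_w, 0)
    } else {
      pre_w <- NULL
      w <- rep(1, fp$S); names(w) <- names(us)
    }
    U <- unlist(lapply(names(us), function(s) w[s] * us[[s]]),
                use.names = FALSE)
    if (cfg$attention_enabled) {
      if (cfg$gate_mode == "elementwise") {
        pre_g <- fp$W11 * U + fp$b11
        g <- pmax(pre_g, 0)
      } else {
        pre_g <- sum(fp$W11 * U) + fp$b11
        g <- rep(max(pre_g, 0), length(U))
      }
    } else {
      pre_g <- NULL
      g <- numeric(length(U))
    }
    G <- g * U + U
    logits <- drop(crossprod(fp$W12, G))
    y <- softmax_vec(logits)
    loss <- if (is.null(label_idx)) NA_real_ else cross_entropy(y, label_idx)
    list(y = y, loss = loss, weights = w,
         cache = list(us = us, w = w, pre_w = pre_w, U = U, g = g,
                      pre_g = pre_g, G = G, yv = y, label_idx = label_idx))
  } else if (cfg$strategy == "early") {
    U <- unlist(us, use.names = FALSE)
    lf <- linear_fw(fp$early, U)
    y <- softmax_vec(lf$y)
    loss <- if (is.null(label_idx)) NA_real_ else cross_entropy(y, label_idx)
    list(y = y, loss = loss, weights = NULL,
         cache = list(us = us, U = U, yv = y, label_idx = label_idx))
  } else if (cfg$strategy == "loss_early") {
    U <- unlist(us, use.names = FALSE)
    lf <- linear_fw(fp$early, U)
    y <- softmax_vec(lf$y)
    aux <- lapply(names(us), function(s) {
      hy <- linear_fw(fp$heads[[s]], us[[s]])
      softmax_vec(hy$y)
    })
    names(aux) <- names(us)
    loss <- NA_real_
    if (!is.null(label_idx)) {
      la <- vapply(aux, cross_entropy, numeric(1), label_idx = label_idx)
      lam <- loss_lambdas(fp$cfg)
      loss <- sum(lam[seq_along(la)] * la) +
        lam[length(lam)] * cross_entropy(y, label_idx)
    }
    list(y = y, loss = loss, weights = NULL,
         cache = list(us = us, U = U, yv = y, aux = aux,
                      label_idx = label_idx))
  } else { # late
    aux <- lapply(names(us), function(s) {
      hy <- linear_fw(fp$heads[[s]], us[[s]])
      softmax_vec(hy$y)
    })
    names(aux) <- names(us)
    if (cfg$late_rule == "mean") {
      y <- Reduce(`+`, aux) / length(aux)
    } else {
      votes <- vapply(aux, which.max, integer(1))
      tab <- tabulate(votes, nbins = cfg$classnum)
      if (max(tab) > sum(tab) / 2) {
        y <- numeric(cfg$classnum)
        y[which.max(tab)] <- 1
      } else {
        y <- Reduce(`+`, aux) / length(aux)
      }
    }
    loss <- if (is.null(label_idx)) NA_real_ else {
      mean(vapply(aux, cross_entropy, numeric(1), label_idx = label_idx))
    }
    list(y = y, loss = loss, weights = NULL,
         cache = list(us = us, aux = aux, label_idx = label_idx))
  }
}

# backward from the cross-entropy loss; returns grads + per-stream du
fusion_bw <- function(fp, cache) {
  cfg <- fp$cfg
  m <- cfg$m
  grads <- tree_zeros(fusion_trainable(fp))
  if (cfg$strategy == "weighted_attention") {
    dlogits <- cache$yv
    dlogits[cache$label_idx] <- dlogits[cache$label_idx] - 1
    grads$W12 <- outer(cache$G, dlogits)
    dG <- drop(fp$W12 %*% dlogits)
    dU <- dG * (1 + cache$g)
    if (cfg$attention_enabled) {
      dg <- dG * cache$U
      if (cfg$gate_mode == "elementwise") {
        dpre_g <- dg * (cache$pre_g > 0)
        grads$W11 <- dpre_g * cache$U
        grads$b11 <- dpre_g
        dU <- dU + dpre_g * fp$W11
      } else {
        dpre_g <- sum(dg) * (cache$pre_g > 0)
        grads$W11 <- dpre_g * cache$U
        grads$b11 <- dpre_g
        dU <- dU + dpre_g * fp$W11
      }
    }
    dus <- list()
    for (i in seq_along(cfg$streams)) {
      s <- cfg$streams[i]
      idx <- (i - 1) * m + seq_len(m)
      dUs <- dU[idx]
      if (cfg$attention_enabled) {
        dw <- sum(dUs * cache$us[[s]])
        dpre_w <- dw * (cache$pre_w[i] > 0)
        grads$local[[s]]$W <- dpre_w * cache$us[[s]]
        grads$local[[s]]$b <- dpre_w
        dus[[s]] <- dUs * cache$w[i] + dpre_w * fp$local[[s]]$W
      } else {
        dus[[s]] <- dUs
      }
    }
    list(grads = grads, dus = dus)
  } else if (cfg$strategy == "early") {
    dlogits <- cache$yv
    dlogits[cache$label_idx] <- dlogits[cache$label_idx] - 1
    grads$early$W <- outer(cache$U, dlogits)
    grads$early$b <- dlogits
    dU <- drop(fp$early$W %*% dlogits)
    dus <- split_streams(dU, cfg)
    list(grads = grads, dus = dus)
  } else if (cfg$strategy == "loss_early") {
    lam <- loss_lambdas(cfg)
    S <- length(cfg$streams)
    dlogits <- lam[S + 1] * {
      d <- cache$yv; d[cache$label_idx] <- d[cache$label_idx] - 1; d
    }
    grads$early$W <- outer(cache$U, dlogits)
    grads$early$b <- dlogits
    dU <- drop(fp$early$W %*% dlogits)
    dus <- split_streams(dU, cfg)
    for (i in seq_len(S)) {
      s <- cfg$streams[i]
      dl <- lam[i] * {
        d <- cache$aux[[s]]
        d[cache$label_idx] <- d[cache$label_idx] - 1
        d
      }
      grads$heads[[s]]$W <- outer(cache$us[[s]], dl)
      grads$heads[[s]]$b <- dl
      dus[[s]] <- dus[[s]] + drop(fp$heads[[s]]$W %*% dl)
    }
    list(grads = grads, dus = dus)
  } else { # late: train through the mean of per-head losses
    S <- length(cfg$streams)
    dus <- list()
    for (s in cfg$streams) {
      dl <- {
        d <- cache$aux[[s]]
        d[cache$label_idx] <- d[cache$label_idx] - 1
        d / S
      }
      grads$heads[[s]]$W <- outer(cache$us[[s]], dl)
      grads$heads[[s]]$b <- dl
      dus[[s]] <- drop(fp$heads[[s]]$W %*% dl)
    }
    list(grads = grads, dus = dus)
  }
}

# per-stream loss weights plus the fused-head weight (last element),
# renormalized when fewer streams than lambdas are active
loss_lambdas <- function(cfg) {
  S <- length(cfg$streams)
  lam <- c(cfg$lambdas[seq_len(S)], cfg$lambdas[length(cfg$lambdas)])
  lam / sum(lam)
}

split_streams <- function(dU, cfg) {
  m <- cfg$m
  dus <- list()
  for (i in seq_along(cfg$streams))
    dus[[cfg$streams[i]]] <- dU[(i - 1) * m + seq_len(m)]
  dus
}

fusion_trainable <- function(fp) {
  list(local = lapply(fp$local, function(p) list(W = p$W, b = p$b)),
       W11 = fp$W11, b11 = fp$b11, W12 = fp$W12,
       heads = lapply(fp$heads, function(h) h[c("W", "b")]),
       early = fp$early[c("W", "b")])
}

fusion_set_trainable <- function(fp, tr) {
  for (s in names(fp$local)) fp$local[[s]][c("W", "b")] <- tr$local[[s]]
  fp$W11 <- tr$W11; fp$b11 <- tr$b11; fp$W12 <- tr$W12
  for (s in names(fp$heads)) fp$heads[[s]][c("W", "b")] <- tr$heads[[s]]
  fp$early[c("W", "b")] <- tr$early
  fp
}

#' Stream-weighted integration with local and global attention
#'
#' Scales each stream by its local weight, concatenates, applies the
#' global gate with a residual connection (`G = g * U + U`; zero gate
#' parameters give `G = U`), and classifies with a softmax layer.
#'
#' @param u_sti,u_mot,u_fac length-m stream representations (only those
#'   the parameter object was built for).
#' @param params a [fusion_params()] with strategy `"weighted_attention"`.
#' @return a `tsd_prediction`: 2-class posterior `y`, `label`, and the
#'   per-stream local `weights`.
#' @export
integrate <- function(u_sti = NULL, u_mot = NULL, u_fac = NULL, params) {
  us <- stream_list(params$cfg, u_sti, u_mot, u_fac)
  out <- fusion_fw(params, us)
  as_prediction(out$y, weights = out$weights)
}

#' Early integration
#'
#' One affine + softmax classifier on the plain concatenation of the
#' stream representations (no local/global attention).
#'
#' @inheritParams integrate
#' @return a `tsd_prediction`.
#' @export
integrate_early <- function(u_sti = NULL, u_mot = NULL, u_fac = NULL,
                            params) {
  us <- stream_list(params$cfg, u_sti, u_mot, u_fac)
  fp <- params
  fp$cfg$strategy <- "early"
  out <- fusion_fw(fp, us)
  as_prediction(out$y)
}

#' Loss-based early integration
#'
#' The early head plus one auxiliary classifier per stream; the total
#' training loss is `sum(lambda_i * loss_i)` over the per-stream losses
#' and the fused loss (weights 0.2/0.2/0.2/0.4 by default). The prediction
#' comes from the fused head.
#'
#' @inheritParams integrate
#' @param label `"stressed"` or `"unstressed"` (training target).
#' @return list with `prediction` (a `tsd_prediction`) and `loss`.
#' @export
integrate_loss_based <- function(u_sti = NULL, u_mot = NULL, u_fac = NULL,
                                 params, label) {
  if (missing(label) || is.null(label))
    stop("integrate_loss_based: training labels required")
  us <- stream_list(params$cfg, u_sti, u_mot, u_fac)
  fp <- params
  fp$cfg$strategy <- "loss_early"
  out <- fusion_fw(fp, us, label_idx = label_index(label))
  list(prediction = as_prediction(out$y), loss = out$loss)
}

#' Late integration
#'
#' Independent per-stream softmax classifiers combined by posterior
#' averaging (or majority vote via `late_rule = "vote"`).
#'
#' @inheritParams integrate
#' @return a `tsd_prediction`.
#' @export
integrate_late <- function(u_sti = NULL, u_mot = NULL, u_fac = NULL,
                           params) {
  us <- stream_list(params$cfg, u_sti, u_mot, u_fac)
  fp <- params
  fp$cfg$strategy <- "late"
  out <- fusion_fw(fp, us)
  as_prediction(out$y)
}

label_index <- function(label) {
  idx <- match(label, c("stressed", "unstressed"))
  if (any(is.na(idx))) stop("labels must be 'stressed' or 'unstressed'")
  idx
}
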