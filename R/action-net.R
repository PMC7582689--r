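## Action-level representation: per-frame backbone features, frame
## attention (softmax contribution weights with a residual connection),
## LSTM encoding, and projection of the final cell state to U_sti / U_mot.
## One network structure, instantiated twice with independent weights for
## the still and motion streams.

#' Action-stream configuration
#'
#' @param backbone backbone architecture descriptor.
#' @param n_frames number of frames fed to the model (the frame-attention
#'   matrix is `n_frames x n_frames`, which fixes the sequence length;
#'   longer clips are uniformly subsampled). The motion stream of a model
#'   with `n` still frames uses `n - 1` flow images.
#' @param hidden LSTM hidden size; `NULL` defaults to the feature length d.
#' @param frame_attention_enabled disable for the ablation `F_tilde = F`.
#' @param m length of the stream representation.
#' @param crop_size input image side.
#' @return an `action_cfg` list.
#' @export
action_cfg <- function(backbone, n_frames = 16, hidden = NULL,
                       frame_attention_enabled = TRUE, m = 20,
                       crop_size = 64) {
  structure(list(backbone = backbone, n_frames = as.integer(n_frames),
                 hidden = hidden,
                 frame_attention_enabled = frame_attention_enabled,
                 m = as.integer(m), crop_size = as.integer(crop_size)),
            class = "action_cfg")
}

#' Initialize action-stream parameters
#'
#' @param cfg an [action_cfg()].
#' @param n sequence length this instance is built for (still stream:
#'   `cfg$n_frames`; motion stream: `cfg$n_frames - 1`).
#' @param init an [nn_init()].
#' @return an object of class `action_params`.
#' @export
action_params <- function(cfg, n = cfg$n_frames, init = nn_init("he")) {
  bb <- backbone_init(cfg$backbone, in_ch = 3L, init = init)
  probe <- backbone_forward(bb, array(0, c(cfg$crop_size, cfg$crop_size, 3)))$y
  pd <- dim(probe)
  if (pd[1] != pd[2]) stop("action backbone output must be square")
  d <- pd[3]
  hidden <- if (is.null(cfg$hidden)) d else as.integer(cfg$hidden)
  structure(list(
    cfg = cfg, n = as.integer(n), d = d, hidden = hidden,
    pool_k = pd[1],
    backbone = bb,
    W1 = init_weights(init, c(d, 1), d), b1 = numeric(n),
    W2 = init_weights(init, c(n, n), n), b2 = numeric(n),
    lstm = lstm_init(d, hidden, init),
    proj = linear_init(hidden, cfg$m, init)
  ), class = "action_params")
}

#' Per-frame backbone features
#'
#' Each frame goes through the backbone; the resulting map is average-
#' pooled over its full spatial extent and flattened to a length-d row.
#'
#' @param seq list of `crop_size`-sided images.
#' @param params an [action_params()].
#' @return `n x d` matrix, one row per frame in temporal order.
#' @export
frame_features <- function(seq, params) {
  if (length(seq) == 0) stop("frame_features: empty sequence")
  ff <- frame_features_fw(params, seq)
  ff$F
}

frame_features_fw <- function(ap, seq) {
  n <- length(seq)
  F <- matrix(0, n, ap$d)
  caches <- vector("list", n)
  for (t in seq_len(n)) {
    bo <- backbone_forward(ap$backbone, seq[[t]])
    pooled <- cpp_avgpool(bo$y, ap$pool_k)
    F[t, ] <- as.vector(pooled)
    caches[[t]] <- bo$cache
  }
  list(F = F, cache = caches)
}

frame_features_bw <- function(ap, cache, dF) {
  gb <- NULL
  for (t in seq_len(nrow(dF))) {
    dpool <- array(dF[t, ], c(1, 1, ap$d))
    dmap <- cpp_avgpool_backward(dpool, ap$pool_k)
    bb <- backbone_backward(ap$backbone, cache[[t]], dmap)
    gb <- tree_add(gb, bb$grads)
  }
  gb
}

#' Frame attention
#'
#' `F' = ReLU(F W1 + b1)` (one scalar per frame), `AttF = Softmax(W2 F' +
#' b2)` over frames, and `F_tilde = AttF * F + F` where frame i's feature
#' row is scaled by `1 + AttF[i]`.
#'
#' @param F `n x d` frame-feature matrix.
#' @param params an [action_params()] built for this `n`.
#' @return list with `F_tilde` (`n x d`) and `att` (the length-n softmax
#'   weights; uniform `1/n` weights when `W2 = 0, b2 = 0`).
#' @export
frame_attention <- function(F, params) {
  if (nrow(F) != params$n)
    stop("frame_attention: expected ", params$n, " frames")
  fa <- frame_att_fw(params, F)
  list(F_tilde = fa$Ft, att = fa$att)
}

frame_att_fw <- function(ap, F) {
  if (!ap$cfg$frame_attention_enabled) {
    return(list(Ft = F, att = NULL, cache = list(enabled = FALSE, F = F)))
  }
  pre1 <- drop(F %*% ap$W1) + ap$b1          # n
  Fp <- pmax(pre1, 0)
  z <- drop(ap$W2 %*% Fp) + ap$b2
  att <- softmax_vec(z)
  Ft <- F * (1 + att)                        # row i scaled by 1 + att_i
  list(Ft = Ft, att = att,
       cache = list(enabled = TRUE, F = F, Fp = Fp, m1 = pre1 > 0,
                    att = att))
}

frame_att_bw <- function(ap, cache, dFt) {
  if (!cache$enabled) {
    return(list(dF = dFt, grads = list(W1 = ap$W1 * 0, b1 = ap$b1 * 0,
                                       W2 = ap$W2 * 0, b2 = ap$b2 * 0)))
  }
  F <- cache$F
  dF <- dFt * (1 + cache$att)
  datt <- rowSums(dFt * F)
  dz <- softmax_vec_bw(cache$att, datt)
  dW2 <- outer(dz, cache$Fp)
  db2 <- dz
  dFp <- drop(t(ap$W2) %*% dz)
  dpre1 <- dFp * cache$m1
  dW1 <- matrix(colSums(F * dpre1), ncol = 1)
  db1 <- dpre1
  dF <- dF + outer(dpre1, ap$W1[, 1])
  list(dF = dF, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Recurrent sequence encoding
#'
#' Runs the weighted frame rows through a single-layer LSTM
#' (zero-initialized states) and projects the final cell state:
#' `U = ReLU(W3 c_n + b3)`.
#'
#' @param F_tilde `n x d` matrix of (attention-weighted) frame features.
#' @param params an [action_params()].
#' @return list with `u` (length-m non-negative vector) and `c_n` (final
#'   cell state).
#' @export
encode_sequence <- function(F_tilde, params) {
  enc <- encode_fw(params, F_tilde)
  list(u = enc$u, c_n = enc$c_n)
}

encode_fw <- function(ap, Ft) {
  lf <- lstm_fw(ap$lstm, Ft)
  pj <- linear_fw(ap$proj, lf$c_n)
  rl <- relu_fw(pj$y)
  list(u = rl$y, c_n = lf$c_n,
       cache = list(lstm = lf$cache, pj = pj$cache, rl = rl$cache))
}

encode_bw <- function(ap, cache, du) {
  dpj <- relu_bw(cache$rl, du)
  pb <- linear_bw(ap$proj, cache$pj, dpj)
  lb <- lstm_bw(ap$lstm, cache$lstm, pb$dx)
  list(dFt = lb$dx, grads = list(lstm = lb$grads, proj = pb$grads))
}

#' Full action-stream representation of an image sequence
#'
#' Composition of [frame_features()], [frame_attention()] and
#' [encode_sequence()]. Deterministic given the inputs; the still and
#' motion streams hold independent parameter sets.
#'
#' @param view_seq list of images (still frames or rendered flow images).
#' @param params an [action_params()].
#' @param stream_tag `"still"` or `"motion"`, recorded on the result.
#' @return object of class `stream_representation`: `u`, `att`,
#'   `stream_tag`.
#' @export
action_representation <- function(view_seq, params,
                                  stream_tag = c("still", "motion")) {
  stream_tag <- match.arg(stream_tag)
  out <- action_forward(params, view_seq)
  structure(list(u = out$u, att = out$att, stream_tag = stream_tag),
            class = "stream_representation")
}

action_forward <- function(ap, seq) {
  if (length(seq) != ap$n)
    stop("action stream built for n = ", ap$n, ", got ", length(seq),
         " frames")
  ff <- frame_features_fw(ap, seq)
  fa <- frame_att_fw(ap, ff$F)
  enc <- encode_fw(ap, fa$Ft)
  list(u = enc$u, att = fa$att,
       cache = list(ff = ff$cache, fa = fa$cache, enc = enc$cache))
}

action_backward <- function(ap, cache, du) {
  eb <- encode_bw(ap, cache$enc, du)
  fb <- frame_att_bw(ap, cache$fa, eb$dFt)
  gbb <- frame_features_bw(ap, cache$ff, fb$dF)
  list(grads = list(backbone = gbb,
                    W1 = fb$grads$W1, b1 = fb$grads$b1,
                    W2 = fb$grads$W2, b2 = fb$grads$b2,
                    lstm = eb$grads$lstm, proj = eb$grads$proj))
}

action_trainable <- function(ap) {
  list(backbone = backbone_params(ap$backbone),
       W1 = ap$W1, b1 = ap$b1, W2 = ap$W2, b2 = ap$b2,
       lstm = ap$lstm[c("Wx", "Wh", "b")],
       proj = ap$proj[c("W", "b")])
}

action_set_trainable <- function(ap, tr) {
  ap$backbone <- backbone_set_params(ap$backbone, tr$backbone)
  ap$W1 <- tr$W1; ap$b1 <- tr$b1; ap$W2 <- tr$W2; ap$b2 <- tr$b2
  ap$lstm[c("Wx", "Wh", "b")] <- tr$lstm
  ap$proj[c("W", "b")] <- tr$proj
  ap
}
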