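# Independent brute-force oracles used to verify the network operations.
# These are written as naive scalar loops, deliberately sharing no code
# with the implementation.

oracle_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# non-overlapping average pooling of an (H, W, C) map, kernel = stride = k
oracle_avgpool <- function(x, k) {
  d <- dim(x)
  out <- array(0, c(d[1] / k, d[2] / k, d[3]))
  for (c in seq_len(d[3]))
    for (i in seq_len(d[1] / k))
      for (j in seq_len(d[2] / k)) {
        s <- 0
        for (a in seq_len(k))
          for (b in seq_len(k))
            s <- s + x[(i - 1) * k + a, (j - 1) * k + b, c]
        out[i, j, c] <- s / (k * k)
      }
  out
}

# channel self-attention: r (C x K), W* (K x K), b* (C x K)
oracle_self_attention <- function(r, W4, b4, W5, b5, W6, b6, scale) {
  C <- nrow(r); K <- ncol(r)
  Rq <- pmax(r %*% W4 + b4, 0)
  Rk <- pmax(r %*% W5 + b5, 0)
  Rv <- pmax(r %*% W6 + b6, 0)
  A <- matrix(0, C, C)
  for (i in seq_len(C)) {
    z <- numeric(C)
    for (j in seq_len(C)) z[j] <- sum(Rq[i, ] * Rk[j, ]) / scale
    A[i, ] <- oracle_softmax(z)
  }
  S <- matrix(0, C, K)
  for (i in seq_len(C))
    for (k in seq_len(K))
      S[i, k] <- sum(A[i, ] * Rv[, k])
  list(A = A, S = S, s_prime = as.vector(S))
}

# frame attention: F (n x d), W1 (d x 1), b1 (n), W2 (n x n), b2 (n)
oracle_frame_attention <- function(F, W1, b1, W2, b2) {
  n <- nrow(F)
  Fp <- numeric(n)
  for (i in seq_len(n)) Fp[i] <- max(sum(F[i, ] * W1[, 1]) + b1[i], 0)
  z <- numeric(n)
  for (i in seq_len(n)) z[i] <- sum(W2[i, ] * Fp) + b2[i]
  att <- oracle_softmax(z)
  Ft <- F
  for (i in seq_len(n)) Ft[i, ] <- att[i] * F[i, ] + F[i, ]
  list(att = att, F_tilde = Ft)
}

# LSTM by explicit gate equations; Wx (d x 4h), Wh (h x 4h), b (4h),
# gate order i, f, g, o; returns final cell state
oracle_lstm_cn <- function(x, Wx, Wh, b, h) {
  sig <- function(v) 1 / (1 + exp(-v))
  ht <- numeric(h); ct <- numeric(h)
  for (t in seq_len(nrow(x))) {
    z <- as.vector(x[t, ] %*% Wx) + as.vector(ht %*% Wh) + b
    i <- sig(z[1:h]); f <- sig(z[h + 1:h])
    g <- tanh(z[2 * h + 1:h]); o <- sig(z[3 * h + 1:h])
    ct <- f * ct + i * g
    ht <- o * tanh(ct)
  }
  ct
}

# stream-weighted fusion: per-stream scalar ReLU gates, concatenation,
# elementwise global gate with residual, softmax classifier
oracle_fusion <- function(us, local, W11, b11, W12) {
  w <- numeric(length(us))
  for (i in seq_along(us))
    w[i] <- max(sum(local[[i]]$W * us[[i]]) + local[[i]]$b, 0)
  U <- c()
  for (i in seq_along(us)) U <- c(U, w[i] * us[[i]])
  g <- pmax(W11 * U + b11, 0)
  G <- g * U + U
  logits <- numeric(ncol(W12))
  for (j in seq_len(ncol(W12))) logits[j] <- sum(W12[, j] * G)
  list(w = w, U = U, G = G, y = oracle_softmax(logits))
}

# re-measure the drawn mouth-arc apex offset (pixels) from an image:
# dark pixels in the lower face, apex row at the horizontal center vs the
# corner rows at the arc ends
oracle_mouth_curvature <- function(img) {
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  s <- nrow(g)
  lower <- g[floor(0.55 * s):s, , drop = FALSE]
  dark <- which(lower < 0.2, arr.ind = TRUE)
  cols <- dark[, 2]
  cmid <- round((min(cols) + max(cols)) / 2)
  apex <- min(dark[cols == cmid, 1])
  corner <- max(dark[cols == min(cols), 1])
  corner - apex
}

# micro network configuration used by the unit tests (16-px inputs)
micro_config <- function(streams = c("still", "motion", "face"),
                         n_frames = 3, m = 5, seed = 1) {
  bb_face <- list(list(op = "conv", out = 4, stride = 2),
                  list(op = "conv", out = 8, stride = 2),
                  list(op = "res"))
  bb_act <- list(list(op = "conv", out = 4, stride = 2),
                 list(op = "conv", out = 8, stride = 2),
                 list(op = "res"),
                 list(op = "conv", out = 8, stride = 2, norm = FALSE))
  cfg <- tsdnet_config("tiny", streams = streams, m = m, seed = seed)
  cfg$view <- view_config(image_size = 18, crop_size = 16)
  cfg$face <- face_cfg(bb_face, pool_scales = c(1, 2, 4), m = m,
                       crop_size = 16)
  cfg$action <- action_cfg(bb_act, n_frames = n_frames, m = m,
                           crop_size = 16)
  cfg$fusion <- fusion_cfg(streams = streams, m = m)
  cfg
}

rand_img <- function(side = 16) array(runif(side * side * 3),
                                      c(side, side, 3))

# tiny synthetic dataset helper
small_dataset <- function(n_subjects = 6, clips_per_subject = 4,
                          frames = 6, face_signal = 1, action_signal = 1,
                          noise_sd = 0.02, seed = 1, image_size = 36) {
  generate_dataset(synth_config(
    n_subjects = n_subjects, clips_per_subject = clips_per_subject,
    frames_per_clip = frames, image_size = image_size,
    face_signal = face_signal, action_signal = action_signal,
    noise_sd = noise_sd, seed = seed))
}

expect_tree_nonzero <- function(tree) {
  expect_gt(tsdnet:::tree_max_abs(tree), 0)
}
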