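#' @useDynLib tsdnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm predict
NULL

## ---------------------------------------------------------------------------
## Parameter trees
##
## Model parameters are nested named lists whose leaves are numeric arrays.
## Gradients mirror the tree shape; the optimizer walks both in lockstep.
## ---------------------------------------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_zeros <- function(x) tree_map(function(a) a * 0, x)

tree_add <- function(x, y) {
  if (is.null(x)) return(y)
  if (is.null(y)) return(x)
  tree_map2(`+`, x, y)
}

tree_scale <- function(x, s) tree_map(function(a) a * s, x)

tree_max_abs <- function(x) {
  if (is.list(x)) max(0, vapply(x, tree_max_abs, numeric(1))) else max(0, abs(x))
}

## ---------------------------------------------------------------------------
## Initialization
## ---------------------------------------------------------------------------

#' Parameter initializer
#'
#' `"uniform"` draws every weight from U(lo, hi) — the published recipe uses
#' U(-0.001, 0.001). `"he"` draws from a fan-in-scaled uniform
#' U(-sqrt(6/fan_in), +sqrt(6/fan_in)), the usual choice for ReLU stacks
#' trained on a short epoch budget.
#'
#' @param kind `"uniform"` or `"he"`.
#' @param range length-2 numeric, only used for `"uniform"`.
#' @return an initializer object consumed by the model constructors.
#' @export
nn_init <- function(kind = c("uniform", "he"), range = c(-0.001, 0.001)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, range = range), class = "nn_init")
}

init_weights <- function(init, dims, fan_in) {
  n <- prod(dims)
  w <- switch(init$kind,
    uniform = runif(n, init$range[1], init$range[2]),
    he = {
      b <- sqrt(6 / fan_in)
      runif(n, -b, b)
    }
  )
  if (length(dims) > 1) array(w, dims) else w
}

## ---------------------------------------------------------------------------
## Layers: each has  <layer>_init(), <layer>_fw(params, x) -> list(y, cache),
## <layer>_bw(params, cache, dy) -> list(dx, grads)
## Feature maps are (H, W, C) arrays; vectors are plain numerics.
## ---------------------------------------------------------------------------

conv_init <- function(cin, cout, k = 3L, stride = 1L, pad = 1L, init) {
  list(W = init_weights(init, c(k * k * cin, cout), fan_in = k * k * cin),
       b = numeric(cout),
       meta = list(cin = cin, cout = cout, k = k, stride = stride, pad = pad))
}

conv_fw <- function(p, x) {
  m <- p$meta
  d <- dim(x)
  out <- cpp_conv_fw(x, p$W, p$b, m$k, m$stride, m$pad)
  list(y = out$y, cache = list(cols = out$cols, din = d))
}

conv_bw <- function(p, cache, dy) {
  m <- p$meta
  out <- cpp_conv_bw(cache$cols, p$W, dy, cache$din[1], cache$din[2],
                     m$cin, m$k, m$stride, m$pad)
  list(dx = out$dx, grads = list(W = out$dW, b = drop(out$db)))
}

# Per-sample, per-channel normalization over spatial positions with learned
# scale/shift; stateless stand-in for batch normalization that is exact at
# batch size one and deterministic at eval time.
chnorm_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

chnorm_fw <- function(p, x, eps = 1e-5) {
  out <- cpp_chnorm_fw(x, p$gamma, p$beta, eps)
  list(y = out$y, cache = list(xhat = out$xhat, istd = drop(out$istd)))
}

chnorm_bw <- function(p, cache, dy) {
  out <- cpp_chnorm_bw(cache$xhat, cache$istd, p$gamma, dy)
  list(dx = out$dx, grads = list(gamma = drop(out$dgamma),
                                 beta = drop(out$dbeta)))
}

relu_fw <- function(x) {
  y <- pmax(x, 0)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  list(y = y, cache = x > 0)
}

relu_bw <- function(cache, dy) {
  dx <- dy * cache
  if (!is.null(dim(dy))) dim(dx) <- dim(dy)
  dx
}

linear_init <- function(din, dout, init) {
  list(W = init_weights(init, c(din, dout), fan_in = din), b = numeric(dout))
}

# x: vector (length din) or matrix (n x din)
linear_fw <- function(p, x) {
  if (is.matrix(x)) {
    y <- sweep(x %*% p$W, 2, p$b, `+`)
  } else {
    y <- drop(x %*% p$W) + p$b
  }
  list(y = y, cache = x)
}

linear_bw <- function(p, cache, dy) {
  if (is.matrix(cache)) {
    dW <- crossprod(cache, dy)
    db <- colSums(dy)
    dx <- dy %*% t(p$W)
  } else {
    dW <- outer(cache, dy)
    db <- dy
    dx <- drop(p$W %*% dy)
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# backward of y = softmax(z): dz = y * (dy - sum(dy * y))
softmax_vec_bw <- function(y, dy) y * (dy - sum(dy * y))

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

softmax_rows_bw <- function(y, dy) y * (dy - rowSums(dy * y))

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---------------------------------------------------------------------------
## LSTM (single layer, unidirectional). Gates ordered i, f, g, o.
## ---------------------------------------------------------------------------

lstm_init <- function(din, dhid, init) {
  # under the "he" scheme recurrent layers use the conventional
  # U(-1/sqrt(h), 1/sqrt(h)) draw: fan-in He bounds saturate the gates
  # within a few timesteps
  if (init$kind == "he") {
    b <- 1 / sqrt(dhid)
    list(Wx = array(runif(din * 4 * dhid, -b, b), c(din, 4 * dhid)),
         Wh = array(runif(dhid * 4 * dhid, -b, b), c(dhid, 4 * dhid)),
         b = numeric(4 * dhid),
         meta = list(din = din, dhid = dhid))
  } else {
    list(Wx = init_weights(init, c(din, 4 * dhid), fan_in = din),
         Wh = init_weights(init, c(dhid, 4 * dhid), fan_in = dhid),
         b = numeric(4 * dhid),
         meta = list(din = din, dhid = dhid))
  }
}

# x: n x din matrix, one row per time step; h0 = c0 = 0
lstm_fw <- function(p, x) {
  h <- p$meta$dhid
  n <- nrow(x)
  idx <- list(i = 1:h, f = h + 1:h, g = 2 * h + 1:h, o = 3 * h + 1:h)
  ht <- numeric(h); ct <- numeric(h)
  steps <- vector("list", n)
  for (t in seq_len(n)) {
    z <- drop(x[t, ] %*% p$Wx) + drop(ht %*% p$Wh) + p$b
    i <- sigmoid(z[idx$i]); f <- sigmoid(z[idx$f])
    g <- tanh(z[idx$g]);    o <- sigmoid(z[idx$o])
    cprev <- ct
    ct <- f * cprev + i * g
    tc <- tanh(ct)
    hprev <- ht
    ht <- o * tc
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c = ct, tc = tc,
                       cprev = cprev, hprev = hprev)
  }
  list(h_n = ht, c_n = ct, cache = list(x = x, steps = steps, idx = idx))
}

# dc_n: gradient wrt final cell state (dh_n assumed 0: only c_n is consumed)
lstm_bw <- function(p, cache, dc_n) {
  x <- cache$x; steps <- cache$steps; idx <- cache$idx
  n <- nrow(x); h <- p$meta$dhid
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- numeric(4 * h)
  dx <- x * 0
  dh <- numeric(h); dc <- dc_n
  for (t in rev(seq_len(n))) {
    s <- steps[[t]]
    dct <- dc + dh * s$o * (1 - s$tc^2)
    do <- dh * s$tc
    di <- dct * s$g
    df <- dct * s$cprev
    dg <- dct * s$i
    dz <- numeric(4 * h)
    dz[idx$i] <- di * s$i * (1 - s$i)
    dz[idx$f] <- df * s$f * (1 - s$f)
    dz[idx$g] <- dg * (1 - s$g^2)
    dz[idx$o] <- do * s$o * (1 - s$o)
    dWx <- dWx + outer(x[t, ], dz)
    dWh <- dWh + outer(s$hprev, dz)
    db <- db + dz
    dx[t, ] <- drop(p$Wx %*% dz)
    dh <- drop(p$Wh %*% dz)
    dc <- dct * s$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---------------------------------------------------------------------------
## Sequential backbone: a list of layer descriptors run in order.
## Descriptor ops: conv (implies norm + relu), res (residual block:
## conv-conv-norm-relu with identity skip), pool (non-overlapping avg).
## ---------------------------------------------------------------------------

backbone_init <- function(arch, in_ch = 3L, init) {
  layers <- list()
  c_now <- in_ch
  for (d in arch) {
    if (d$op == "conv") {
      use_norm <- d$norm %||% TRUE
      layers[[length(layers) + 1]] <- list(
        op = "conv",
        conv = conv_init(c_now, d$out, k = 3L, stride = d$stride, pad = 1L,
                         init = init),
        norm = if (use_norm) chnorm_init(d$out) else NULL)
      c_now <- d$out
    } else if (d$op == "res") {
      layers[[length(layers) + 1]] <- list(
        op = "res",
        conv1 = conv_init(c_now, c_now, init = init),
        conv2 = conv_init(c_now, c_now, init = init),
        norm = chnorm_init(c_now))
    } else if (d$op == "pool") {
      layers[[length(layers) + 1]] <- list(op = "pool", k = d$k)
    } else {
      stop("unknown backbone op: ", d$op)
    }
  }
  structure(list(layers = layers, out_channels = c_now), class = "tsd_backbone")
}

backbone_forward <- function(bb, x) {
  caches <- vector("list", length(bb$layers))
  for (j in seq_along(bb$layers)) {
    l <- bb$layers[[j]]
    if (l$op == "conv") {
      cv <- conv_fw(l$conv, x)
      if (is.null(l$norm)) {
        rl <- relu_fw(cv$y)
        caches[[j]] <- list(cv = cv$cache, nm = NULL, rl = rl$cache)
      } else {
        nm <- chnorm_fw(l$norm, cv$y)
        rl <- relu_fw(nm$y)
        caches[[j]] <- list(cv = cv$cache, nm = nm$cache, rl = rl$cache)
      }
      x <- rl$y
    } else if (l$op == "res") {
      cv1 <- conv_fw(l$conv1, x)
      cv2 <- conv_fw(l$conv2, cv1$y)
      nm <- chnorm_fw(l$norm, cv2$y)
      rl <- relu_fw(nm$y)
      y <- x + rl$y
      caches[[j]] <- list(cv1 = cv1$cache, cv2 = cv2$cache,
                          nm = nm$cache, rl = rl$cache)
      x <- y
    } else { # pool
      y <- cpp_avgpool(x, l$k)
      caches[[j]] <- list(k = l$k)
      x <- y
    }
  }
  list(y = x, cache = caches)
}

backbone_backward <- function(bb, cache, dy) {
  grads <- vector("list", length(bb$layers))
  for (j in rev(seq_along(bb$layers))) {
    l <- bb$layers[[j]]
    cc <- cache[[j]]
    if (l$op == "conv") {
      d1 <- relu_bw(cc$rl, dy)
      if (is.null(l$norm)) {
        cb <- conv_bw(l$conv, cc$cv, d1)
        grads[[j]] <- list(conv = cb$grads)
      } else {
        nb <- chnorm_bw(l$norm, cc$nm, d1)
        cb <- conv_bw(l$conv, cc$cv, nb$dx)
        grads[[j]] <- list(conv = cb$grads, norm = nb$grads)
      }
      dy <- cb$dx
    } else if (l$op == "res") {
      d1 <- relu_bw(cc$rl, dy)
      nb <- chnorm_bw(l$norm, cc$nm, d1)
      cb2 <- conv_bw(l$conv2, cc$cv2, nb$dx)
      cb1 <- conv_bw(l$conv1, cc$cv1, cb2$dx)
      grads[[j]] <- list(conv1 = cb1$grads, conv2 = cb2$grads,
                         norm = nb$grads)
      dy <- dy + cb1$dx
    } else {
      dy <- cpp_avgpool_backward(dy, cc$k)
      grads[[j]] <- list()
    }
  }
  list(dx = dy, grads = grads)
}

# trainable leaves of a backbone, for the optimizer
backbone_params <- function(bb) {
  lapply(bb$layers, function(l) {
    switch(l$op,
      conv = if (is.null(l$norm)) list(conv = l$conv[c("W", "b")])
             else list(conv = l$conv[c("W", "b")], norm = l$norm),
      res = list(conv1 = l$conv1[c("W", "b")], conv2 = l$conv2[c("W", "b")],
                 norm = l$norm),
      pool = list())
  })
}

backbone_set_params <- function(bb, params) {
  for (j in seq_along(bb$layers)) {
    l <- bb$layers[[j]]
    p <- params[[j]]
    if (l$op == "conv") {
      bb$layers[[j]]$conv[c("W", "b")] <- p$conv
      if (!is.null(p$norm)) bb$layers[[j]]$norm <- p$norm
    } else if (l$op == "res") {
      bb$layers[[j]]$conv1[c("W", "b")] <- p$conv1
      bb$layers[[j]]$conv2[c("W", "b")] <- p$conv2
      bb$layers[[j]]$norm <- p$norm
    }
  }
  bb
}

## ---------------------------------------------------------------------------
## SGD with momentum and weight decay
## ---------------------------------------------------------------------------

sgd_state <- function(params) tree_zeros(params)

sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 0) {
  state <- tree_map2(function(v, g) momentum * v - lr * g, state,
                     tree_map2(function(g, p) g + weight_decay * p,
                               grads, params))
  params <- tree_add(params, state)
  list(params = params, state = state)
}

tree_sq_sum <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_sq_sum, numeric(1))) else sum(x^2)
}

# rescale the gradient tree so its global L2 norm is at most max_norm
clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  nrm <- sqrt(tree_sq_sum(grads))
  if (nrm > max_norm) grads <- tree_scale(grads, max_norm / nrm)
  grads
}

cross_entropy <- function(y, label_idx, eps = 1e-12) {
  -log(min(y[label_idx] + eps, 1))
}

## ---------------------------------------------------------------------------
## Seed substreams: clip i of a dataset is reproducible in isolation.
## ---------------------------------------------------------------------------

substream_seed <- function(seed, i) {
  s <- (as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
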