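## Face-level representation: the feature difference between a clip's most
## expressive and most expressionless face, refined by a residual block,
## multi-scale pooling attention, channel self-attention, and a projection
## to the length-m stream representation U_fac.

#' Face-stream configuration
#'
#' @param backbone backbone architecture descriptor (list of layer specs;
#'   see [tsdnet_config()] presets).
#' @param pool_scales subset of `c(1, 2, 4, 8)`: kernel sizes of the
#'   multi-scale average pooling. The feature width K is
#'   `sum(H*W / s^2)` over the chosen scales (84 at the reference 8x8 with
#'   scales 1/2/4).
#' @param attention_enabled disable to bypass the pooling attention branch
#'   (ablation: `AD_s = D_s`).
#' @param self_attention_scale `"sqrt"` divides the attention logits by
#'   `sqrt(C)` (the conventional scaled dot product); `"as_printed"`
#'   divides by `C`.
#' @param m length of the stream representation.
#' @param crop_size input image side.
#' @return a `face_cfg` list.
#' @export
face_cfg <- function(backbone, pool_scales = c(1, 2, 4),
                     attention_enabled = TRUE,
                     self_attention_scale = c("sqrt", "as_printed"),
                     m = 20, crop_size = 64) {
  stopifnot(all(pool_scales %in% c(1, 2, 4, 8)), length(pool_scales) >= 1)
  structure(list(backbone = backbone, pool_scales = sort(pool_scales),
                 attention_enabled = attention_enabled,
                 self_attention_scale = match.arg(self_attention_scale),
                 m = as.integer(m), crop_size = as.integer(crop_size)),
            class = "face_cfg")
}

#' Initialize face-stream parameters
#'
#' The backbone is applied to both key faces with the same weights
#' (parameter-shared twin application). Dimensions C, H, W are probed with
#' a dummy forward pass.
#'
#' @param cfg a [face_cfg()].
#' @param init an [nn_init()].
#' @return an object of class `face_params`.
#' @export
face_params <- function(cfg, init = nn_init("he")) {
  bb <- backbone_init(cfg$backbone, in_ch = 3L, init = init)
  probe <- backbone_forward(bb, array(0, c(cfg$crop_size, cfg$crop_size, 3)))$y
  H <- dim(probe)[1]; W <- dim(probe)[2]; C <- dim(probe)[3]
  smax <- max(cfg$pool_scales)
  if (H %% smax != 0 || W %% smax != 0)
    stop("backbone output ", H, "x", W, " not divisible by pool scale ", smax)
  K <- sum(H * W / cfg$pool_scales^2)
  att <- lapply(cfg$pool_scales, function(s) {
    list(conv0 = conv_init(C, C, init = init),
         blocks = lapply(1:3, function(j)
           list(norm = chnorm_init(C), conv = conv_init(C, C, init = init))))
  })
  names(att) <- paste0("s", cfg$pool_scales)
  structure(list(
    cfg = cfg, C = C, H = H, W = W, K = K,
    backbone = bb,
    res = list(conv1 = conv_init(C, C, init = init),
               conv2 = conv_init(C, C, init = init),
               norm = chnorm_init(C)),
    att = att,
    W4 = init_weights(init, c(K, K), K), b4 = matrix(0, C, K),
    W5 = init_weights(init, c(K, K), K), b5 = matrix(0, C, K),
    W6 = init_weights(init, c(K, K), K), b6 = matrix(0, C, K),
    proj = linear_init(C * K, cfg$m, init)
  ), class = "face_params")
}

#' Apply the shared face backbone to one image
#'
#' @param params a [face_params()].
#' @param img `crop_size x crop_size x 3` array.
#' @return `H x W x C` feature map.
#' @export
backbone_face <- function(params, img) {
  d <- dim(img)
  if (d[1] != params$cfg$crop_size || d[2] != params$cfg$crop_size)
    stop("backbone_face: expected ", params$cfg$crop_size, "-sided input")
  backbone_forward(params$backbone, img)$y
}

#' Fine-grained feature difference of the key-face pair
#'
#' `d0` is the element-wise difference of the two feature maps; `d` adds a
#' residual refinement `d0 + ReLU(Norm(Conv(Conv(d0))))`.
#'
#' @param fe,fl equal-shaped feature maps (most expressive / most
#'   expressionless face).
#' @param params a [face_params()] supplying the residual-block weights.
#' @return list with `d0` and `d`, both `H x W x C`.
#' @export
fine_difference <- function(fe, fl, params) {
  if (!identical(dim(fe), dim(fl))) stop("fine_difference: shape mismatch")
  fd <- fine_diff_fw(params, fe, fl)
  list(d0 = fd$d0, d = fd$y)
}

fine_diff_fw <- function(fp, fe, fl) {
  d0 <- fe - fl
  c1 <- conv_fw(fp$res$conv1, d0)
  c2 <- conv_fw(fp$res$conv2, c1$y)
  nm <- chnorm_fw(fp$res$norm, c2$y)
  rl <- relu_fw(nm$y)
  list(d0 = d0, y = d0 + rl$y,
       cache = list(c1 = c1$cache, c2 = c2$cache, nm = nm$cache,
                    rl = rl$cache))
}

fine_diff_bw <- function(fp, cache, dy) {
  d1 <- relu_bw(cache$rl, dy)
  nb <- chnorm_bw(fp$res$norm, cache$nm, d1)
  cb2 <- conv_bw(fp$res$conv2, cache$c2, nb$dx)
  cb1 <- conv_bw(fp$res$conv1, cache$c1, cb2$dx)
  list(dd0 = dy + cb1$dx,
       grads = list(conv1 = cb1$grads, conv2 = cb2$grads, norm = nb$grads))
}

# softmax over rows (spatial positions) of each column (channel)
softmax_cols <- function(z) {
  e <- exp(sweep(z, 2, apply(z, 2, max)))
  sweep(e, 2, colSums(e), `/`)
}

softmax_cols_bw <- function(y, dy) y * sweep(dy, 2, colSums(dy * y))

# one attention branch: Att = softmax_spatial(AttB(AttB(AttB(Conv(D)))))
att_branch_fw <- function(ap, D) {
  c0 <- conv_fw(ap$conv0, D)
  x <- c0$y
  bl <- vector("list", 3)
  for (j in 1:3) {
    nm <- chnorm_fw(ap$blocks[[j]]$norm, x)
    rl <- relu_fw(nm$y)
    cv <- conv_fw(ap$blocks[[j]]$conv, rl$y)
    bl[[j]] <- list(nm = nm$cache, rl = rl$cache, cv = cv$cache)
    x <- cv$y
  }
  d <- dim(x)
  zm <- matrix(x, d[1] * d[2], d[3])
  att <- softmax_cols(zm)
  list(att = att, cache = list(c0 = c0$cache, bl = bl, d = d, att = att))
}

att_branch_bw <- function(ap, cache, datt) {
  d <- cache$d
  dz <- softmax_cols_bw(cache$att, datt)
  dy <- array(dz, d)
  g_bl <- vector("list", 3)
  for (j in 3:1) {
    cc <- cache$bl[[j]]
    cb <- conv_bw(ap$blocks[[j]]$conv, cc$cv, dy)
    d1 <- relu_bw(cc$rl, cb$dx)
    nb <- chnorm_bw(ap$blocks[[j]]$norm, cc$nm, d1)
    g_bl[[j]] <- list(norm = nb$grads, conv = cb$grads)
    dy <- nb$dx
  }
  cb0 <- conv_bw(ap$conv0, cache$c0, dy)
  list(dD = cb0$dx, grads = list(conv0 = cb0$grads, blocks = g_bl))
}

msp_fw <- function(fp, d) {
  cfg <- fp$cfg
  scales <- cfg$pool_scales
  per <- vector("list", length(scales))
  rparts <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    s <- scales[i]
    Ds <- if (s == 1) d else cpp_avgpool(d, s)
    dd <- dim(Ds)
    Dm <- matrix(Ds, dd[1] * dd[2], dd[3])       # spatial x channel
    if (cfg$attention_enabled) {
      ab <- att_branch_fw(fp$att[[i]], Ds)
      ADm <- Dm * ab$att + Dm
      per[[i]] <- list(s = s, dd = dd, Dm = Dm, ab = ab$cache, att = ab$att)
    } else {
      ADm <- Dm
      per[[i]] <- list(s = s, dd = dd, Dm = Dm, ab = NULL, att = NULL)
    }
    rparts[[i]] <- t(ADm)                         # channel x spatial
  }
  r <- do.call(cbind, rparts)                     # C x K
  list(r = r, cache = per,
       widths = vapply(per, function(p) p$dd[1] * p$dd[2], numeric(1)))
}

msp_bw <- function(fp, cache, widths, dr) {
  cfg <- fp$cfg
  grads_att <- vector("list", length(cache))
  col0 <- 0
  dd_total <- NULL
  for (i in seq_along(cache)) {
    pc <- cache[[i]]
    w <- widths[i]
    dADm <- t(dr[, col0 + seq_len(w), drop = FALSE])   # spatial x channel
    col0 <- col0 + w
    if (cfg$attention_enabled) {
      dDm <- dADm * (pc$att + 1)
      datt <- dADm * pc$Dm
      ab <- att_branch_bw(fp$att[[i]], pc$ab, datt)
      grads_att[[i]] <- ab$grads
      dDs <- array(dDm, pc$dd) + ab$dD
    } else {
      grads_att[[i]] <- NULL
      dDs <- array(dADm, pc$dd)
    }
    dd_i <- if (pc$s == 1) dDs else cpp_avgpool_backward(dDs, pc$s)
    dd_total <- if (is.null(dd_total)) dd_i else dd_total + dd_i
  }
  if (!cfg$attention_enabled) {
    grads_att <- NULL
  } else {
    names(grads_att) <- names(fp$att)[seq_along(cache)]
  }
  list(dd = dd_total, grads_att = grads_att)
}

#' Multi-scale pooling attention over the difference map
#'
#' Average-pools the refined difference map at each configured kernel size,
#' runs a convolutional attention branch per scale (softmax over the
#' spatial positions of each channel), reweights with a residual connection
#' (`AD_s = D_s * Att_s + D_s`), flattens and concatenates channel-wise.
#'
#' @param d `H x W x C` refined difference map.
#' @param params a [face_params()].
#' @return list with `r` (`C x K` matrix), `ad` (per-scale reweighted
#'   maps), `att` (per-scale attention distributions, `NULL` when the
#'   branch is ablated).
#' @export
multiscale_pool_attention <- function(d, params) {
  smax <- max(params$cfg$pool_scales)
  dd <- dim(d)
  if (dd[1] %% smax != 0 || dd[2] %% smax != 0)
    stop("map size not divisible by pool scale ", smax)
  out <- msp_fw(params, d)
  ad <- lapply(out$cache, function(pc) {
    m <- if (is.null(pc$att)) pc$Dm else pc$Dm * pc$att + pc$Dm
    array(m, pc$dd)
  })
  att <- lapply(out$cache, function(pc)
    if (is.null(pc$att)) NULL else array(pc$att, pc$dd))
  names(ad) <- names(att) <- paste0("s", params$cfg$pool_scales)
  list(r = out$r, ad = ad, att = att)
}

sa_scale_value <- function(fp) {
  if (fp$cfg$self_attention_scale == "sqrt") sqrt(fp$C) else fp$C
}

sa_fw <- function(fp, r) {
  sc <- sa_scale_value(fp)
  pre_q <- r %*% fp$W4 + fp$b4
  pre_k <- r %*% fp$W5 + fp$b5
  pre_v <- r %*% fp$W6 + fp$b6
  Rq <- pmax(pre_q, 0); Rk <- pmax(pre_k, 0); Rv <- pmax(pre_v, 0)
  A <- softmax_rows(Rq %*% t(Rk) / sc)
  S <- A %*% Rv
  list(s_prime = as.vector(S),
       cache = list(r = r, Rq = Rq, Rk = Rk, Rv = Rv, A = A,
                    mq = pre_q > 0, mk = pre_k > 0, mv = pre_v > 0, sc = sc))
}

sa_bw <- function(fp, cache, ds_prime) {
  dS <- matrix(ds_prime, fp$C, fp$K)
  dA <- dS %*% t(cache$Rv)
  dRv <- t(cache$A) %*% dS
  dZ <- softmax_rows_bw(cache$A, dA) / cache$sc
  dRq <- dZ %*% cache$Rk
  dRk <- t(dZ) %*% cache$Rq
  dpq <- dRq * cache$mq; dpk <- dRk * cache$mk; dpv <- dRv * cache$mv
  dr <- dpq %*% t(fp$W4) + dpk %*% t(fp$W5) + dpv %*% t(fp$W6)
  list(dr = dr,
       grads = list(W4 = crossprod(cache$r, dpq), b4 = dpq,
                    W5 = crossprod(cache$r, dpk), b5 = dpk,
                    W6 = crossprod(cache$r, dpv), b6 = dpv))
}

#' Channel self-attention over the concatenated difference representation
#'
#' Query/key/value maps are rectified affine transforms of `r`; the
#' attention matrix is a row-wise softmax of the scaled dot product between
#' channel representations, applied twice (Q against K, then against V).
#'
#' @param r `C x K` matrix from [multiscale_pool_attention()].
#' @param params a [face_params()].
#' @return list with `s_prime` (length `C * K` vector) and `attention`
#'   (the `C x C` row-stochastic matrix).
#' @export
diff_self_attention <- function(r, params) {
  if (any(!is.finite(r))) stop("diff_self_attention: non-finite input")
  out <- sa_fw(params, r)
  list(s_prime = out$s_prime, attention = out$cache$A)
}

#' Project the self-attention output to the face representation
#'
#' `U_fac = ReLU(s' W7 + b7)`, a non-negative length-m vector.
#'
#' @param s_prime length `C * K` vector.
#' @param params a [face_params()].
#' @return numeric vector of length `m`.
#' @export
project_face <- function(s_prime, params) {
  if (length(s_prime) != params$C * params$K)
    stop("project_face: expected length ", params$C * params$K)
  lf <- linear_fw(params$proj, s_prime)
  pmax(lf$y, 0)
}

# full face stream: two backbone applications (shared weights), difference,
# multi-scale attention, self-attention, projection
face_forward <- function(fp, face_e, face_l) {
  be <- backbone_forward(fp$backbone, face_e)
  bl <- backbone_forward(fp$backbone, face_l)
  fd <- fine_diff_fw(fp, be$y, bl$y)
  ms <- msp_fw(fp, fd$y)
  sa <- sa_fw(fp, ms$r)
  pj <- linear_fw(fp$proj, sa$s_prime)
  rl <- relu_fw(pj$y)
  list(u = rl$y,
       cache = list(be = be$cache, bl = bl$cache, fd = fd$cache,
                    ms = ms$cache, widths = ms$widths, sa = sa$cache,
                    pj = pj$cache, rl = rl$cache))
}

face_backward <- function(fp, cache, du) {
  dpj <- relu_bw(cache$rl, du)
  pb <- linear_bw(fp$proj, cache$pj, dpj)
  sb <- sa_bw(fp, cache$sa, pb$dx)
  mb <- msp_bw(fp, cache$ms, cache$widths, sb$dr)
  fb <- fine_diff_bw(fp, cache$fd, mb$dd)
  bbe <- backbone_backward(fp$backbone, cache$be, fb$dd0)
  bbl <- backbone_backward(fp$backbone, cache$bl, -fb$dd0)
  g <- list(backbone = tree_add(bbe$grads, bbl$grads),
            res = fb$grads,
            W4 = sb$grads$W4, b4 = sb$grads$b4,
            W5 = sb$grads$W5, b5 = sb$grads$b5,
            W6 = sb$grads$W6, b6 = sb$grads$b6,
            proj = pb$grads)
  if (!is.null(mb$grads_att)) g$att <- mb$grads_att
  list(grads = g)
}

# trainable leaves matching face_backward()'s grads tree
face_trainable <- function(fp) {
  tr <- list(backbone = backbone_params(fp$backbone),
             res = list(conv1 = fp$res$conv1[c("W", "b")],
                        conv2 = fp$res$conv2[c("W", "b")],
                        norm = fp$res$norm),
             W4 = fp$W4, b4 = fp$b4, W5 = fp$W5, b5 = fp$b5,
             W6 = fp$W6, b6 = fp$b6,
             proj = fp$proj[c("W", "b")])
  if (fp$cfg$attention_enabled)
    tr$att <- lapply(fp$att, function(a)
      list(conv0 = a$conv0[c("W", "b")],
           blocks = lapply(a$blocks, function(b)
             list(norm = b$norm, conv = b$conv[c("W", "b")]))))
  tr
}

face_set_trainable <- function(fp, tr) {
  fp$backbone <- backbone_set_params(fp$backbone, tr$backbone)
  fp$res$conv1[c("W", "b")] <- tr$res$conv1
  fp$res$conv2[c("W", "b")] <- tr$res$conv2
  fp$res$norm <- tr$res$norm
  if (!is.null(tr$att)) {
    for (i in seq_along(fp$att)) {
      fp$att[[i]]$conv0[c("W", "b")] <- tr$att[[i]]$conv0
      for (j in 1:3) {
        fp$att[[i]]$blocks[[j]]$norm <- tr$att[[i]]$blocks[[j]]$norm
        fp$att[[i]]$blocks[[j]]$conv[c("W", "b")] <- tr$att[[i]]$blocks[[j]]$conv
      }
    }
  }
  fp$W4 <- tr$W4; fp$b4 <- tr$b4
  fp$W5 <- tr$W5; fp$b5 <- tr$b5
  fp$W6 <- tr$W6; fp$b6 <- tr$b6
  fp$proj[c("W", "b")] <- tr$proj
  fp
}
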