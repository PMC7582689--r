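make_face <- function(scales = c(1, 2, 4), m = 5, attention = TRUE,
                      sa_scale = "sqrt", seed = 1) {
  set.seed(seed)
  face_params(face_cfg(list(list(op = "conv", out = 4, stride = 2),
                            list(op = "conv", out = 8, stride = 2),
                            list(op = "res")),
                       pool_scales = scales, attention_enabled = attention,
                       self_attention_scale = sa_scale, m = m,
                       crop_size = 16),
              init = nn_init("he"))
}

test_that("the backbone is parameter-shared and shape-stable", {
  fp <- make_face()
  img <- rand_img(16)
  expect_identical(backbone_face(fp, img), backbone_face(fp, img))
  expect_identical(dim(backbone_face(fp, img)), c(4L, 4L, 8L))
  expect_error(backbone_face(fp, rand_img(20)), "input")
})

test_that("fine difference is antisymmetric and matches a loop oracle", {
  fp <- make_face()
  fe <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  fl <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  fd <- fine_difference(fe, fl, fp)
  # element-loop subtraction oracle
  d0 <- array(0, dim(fe))
  for (i in 1:4) for (j in 1:4) for (c in 1:8)
    d0[i, j, c] <- fe[i, j, c] - fl[i, j, c]
  expect_equal(fd$d0, d0, tolerance = 1e-12)
  swapped <- fine_difference(fl, fe, fp)
  expect_equal(swapped$d0, -fd$d0, tolerance = 1e-12)
  same <- fine_difference(fe, fe, fp)
  expect_true(all(same$d0 == 0))
  expect_identical(dim(fd$d), dim(fd$d0))
  expect_error(fine_difference(fe, array(0, c(2, 2, 8)), fp), "mismatch")
})

test_that("multi-scale pooling matches the sliding-window oracle", {
  for (side in c(4, 8)) {
    x <- array(rnorm(side * side), c(side, side, 1))
    for (k in c(2, 4)) {
      if (side %% k != 0) next
      expect_equal(tsdnet:::cpp_avgpool(x, k), oracle_avgpool(x, k),
                   tolerance = 1e-6)
    }
  }
  x3 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(tsdnet:::cpp_avgpool(x3, 2), oracle_avgpool(x3, 2),
               tolerance = 1e-6)
})

test_that("pooling attention normalizes, keeps constants and residuals", {
  fp <- make_face()
  d <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  out <- multiscale_pool_attention(d, fp)
  # attention distributions sum to 1 over spatial positions per channel
  for (att in out$att) {
    sums <- apply(att, 3, sum)
    expect_equal(sums, rep(1, 8), tolerance = 1e-5)
  }
  # constant map: every pooled scale is the same constant
  dc <- array(2.5, c(4, 4, 8))
  outc <- multiscale_pool_attention(dc, fp)
  for (s in c("s2", "s4")) {
    pooled <- outc$ad[[s]] / (1 + outc$att[[s]]) # undo residual reweighting
    expect_equal(as.vector(pooled), rep(2.5, length(pooled)),
                 tolerance = 1e-8)
  }
  # ablation: disabled attention passes the pooled maps through
  fp0 <- make_face(attention = FALSE)
  out0 <- multiscale_pool_attention(d, fp0)
  expect_null(out0$att$s1)
  expect_equal(out0$ad$s1, d, tolerance = 1e-12)
  expect_equal(out0$ad$s2, oracle_avgpool(d, 2), tolerance = 1e-6)
  expect_identical(dim(out0$r), dim(out$r))
})

test_that("pooling combinations produce the forced feature widths", {
  HW <- 16 # 4x4 micro backbone output
  widths <- list(`1` = HW, `1,2` = HW + HW / 4)
  fp1 <- make_face(scales = 1)
  expect_identical(fp1$K, HW)
  fp12 <- make_face(scales = c(1, 2))
  expect_identical(fp12$K, HW + HW / 4)
  fp124 <- make_face(scales = c(1, 2, 4))
  expect_identical(fp124$K, 21 * HW / 16)
  # 8x8 map admits the four-scale combination
  set.seed(1)
  fp8 <- face_params(face_cfg(list(list(op = "conv", out = 4, stride = 2),
                                   list(op = "conv", out = 8, stride = 2)),
                              pool_scales = c(1, 2, 4, 8), m = 5,
                              crop_size = 32), nn_init("he"))
  expect_identical(fp8$K, 21 * 64 / 16 + 64 / 64)
})

test_that("self-attention matches a double-loop oracle at both scalings", {
  for (sa in c("sqrt", "as_printed")) {
    fp <- make_face(sa_scale = sa, seed = 3)
    r <- matrix(rnorm(fp$C * fp$K), fp$C, fp$K)
    out <- diff_self_attention(r, fp)
    expect_equal(rowSums(out$attention), rep(1, fp$C), tolerance = 1e-5)
    sc <- if (sa == "sqrt") sqrt(fp$C) else fp$C
    orc <- oracle_self_attention(r, fp$W4, fp$b4, fp$W5, fp$b5,
                                 fp$W6, fp$b6, sc)
    expect_equal(out$s_prime, orc$s_prime, tolerance = 1e-6)
    expect_equal(out$attention, orc$A, tolerance = 1e-6)
  }
})

test_that("degenerate self-attention weights give uniform attention", {
  # zero W4-W6 and a bias shared across channels make every key row
  # identical, so each attention row is the uniform 1/C distribution and
  # every output row is the (common) column mean of ReLU(b)
  fp <- make_face(seed = 5)
  b <- matrix(rnorm(fp$K), fp$C, fp$K, byrow = TRUE)
  fp$W4 <- fp$W5 <- fp$W6 <- matrix(0, fp$K, fp$K)
  fp$b4 <- fp$b5 <- fp$b6 <- b
  r <- matrix(rnorm(fp$C * fp$K), fp$C, fp$K)
  out <- diff_self_attention(r, fp)
  expect_equal(out$attention,
               matrix(1 / fp$C, fp$C, fp$C), tolerance = 1e-6)
  S <- matrix(out$s_prime, fp$C, fp$K)
  cm <- colMeans(pmax(b, 0))
  for (i in seq_len(fp$C)) expect_equal(S[i, ], cm, tolerance = 1e-6)
})

test_that("the face projection is a rectified affine map of length m", {
  fp <- make_face(m = 5)
  u <- project_face(rnorm(fp$C * fp$K), fp)
  expect_length(u, 5)
  expect_true(all(u >= 0))
  s <- rnorm(fp$C * fp$K)
  expect_equal(project_face(s, fp),
               pmax(drop(s %*% fp$proj$W) + fp$proj$b, 0),
               tolerance = 1e-9)
  fp$proj$b <- rep(-1, 5)
  expect_identical(project_face(numeric(fp$C * fp$K), fp), rep(0, 5))
  expect_error(project_face(numeric(3), fp), "length")
})

test_that("face-stream gradients match finite differences", {
  fp <- make_face(seed = 9)
  fe <- rand_img(16); fl <- rand_img(16)
  fw <- tsdnet:::face_forward(fp, fe, fl)
  du <- rnorm(length(fw$u))
  g <- tsdnet:::face_backward(fp, fw$cache, du)$grads
  # check self-attention weights and projection numerically
  eps <- 1e-6
  lossat <- function(fpm) sum(tsdnet:::face_forward(fpm, fe, fl)$u * du)
  for (nm in c("W4", "W6")) {
    for (k in c(1, 7)) {
      fp1 <- fp; fp1[[nm]][k] <- fp1[[nm]][k] + eps
      fp2 <- fp; fp2[[nm]][k] <- fp2[[nm]][k] - eps
      num <- (lossat(fp1) - lossat(fp2)) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-3)
    }
  }
  k <- 3
  fp1 <- fp; fp1$proj$W[k] <- fp1$proj$W[k] + eps
  fp2 <- fp; fp2$proj$W[k] <- fp2$proj$W[k] - eps
  expect_equal(g$proj$W[k],
               (lossat(fp1) - lossat(fp2)) / (2 * eps), tolerance = 1e-3)
})
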