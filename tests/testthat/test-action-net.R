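make_action <- function(n = 3, m = 5, attention = TRUE, seed = 1) {
  set.seed(seed)
  action_params(action_cfg(list(list(op = "conv", out = 4, stride = 2),
                                list(op = "conv", out = 8, stride = 2),
                                list(op = "res"),
                                list(op = "conv", out = 8, stride = 2,
                                     norm = FALSE)),
                           n_frames = n, frame_attention_enabled = attention,
                           m = m, crop_size = 16),
                n = n, init = nn_init("he"))
}

test_that("frame features are per-frame rows pooled from the backbone", {
  ap <- make_action()
  img <- rand_img(16)
  F <- frame_features(list(img, img, img), ap)
  expect_identical(dim(F), c(3L, 8L))
  expect_equal(F[1, ], F[2, ], tolerance = 1e-12)
  expect_equal(F[1, ], F[3, ], tolerance = 1e-12)
  # pooled row = arithmetic mean of the final map per channel
  map <- tsdnet:::backbone_forward(ap$backbone, img)$y
  expect_equal(F[1, ], apply(map, 3, mean), tolerance = 1e-9)
  expect_error(frame_features(list(), ap), "empty")
})

test_that("frame attention has the forced uniform closed form", {
  ap <- make_action(n = 4)
  F <- matrix(rnorm(4 * 8), 4, 8)
  ap$W2 <- matrix(0, 4, 4); ap$b2 <- numeric(4)
  out <- frame_attention(F, ap)
  expect_equal(out$att, rep(1 / 4, 4), tolerance = 1e-9)
  expect_equal(out$F_tilde, (1 + 1 / 4) * F, tolerance = 1e-9)
})

test_that("frame attention matches the scalar-by-scalar oracle", {
  ap <- make_action(n = 3, seed = 4)
  F <- matrix(rnorm(3 * 8), 3, 8)
  out <- frame_attention(F, ap)
  expect_equal(sum(out$att), 1, tolerance = 1e-6)
  orc <- oracle_frame_attention(F, ap$W1, ap$b1, ap$W2, ap$b2)
  expect_equal(out$att, orc$att, tolerance = 1e-6)
  expect_equal(out$F_tilde, orc$F_tilde, tolerance = 1e-6)
  expect_error(frame_attention(matrix(0, 5, 8), ap), "frames")
})

test_that("sequence encoding reduces to ReLU(b3) on zero input", {
  ap <- make_action(n = 3)
  ap$proj$b <- c(-1, 0.5, 2, -0.2, 0)
  Ft <- matrix(0, 3, 8)
  enc <- encode_sequence(Ft, ap)
  expect_equal(enc$c_n, numeric(ap$hidden), tolerance = 1e-12)
  expect_equal(enc$u, pmax(ap$proj$b, 0), tolerance = 1e-12)
  expect_length(enc$u, 5)
})

test_that("the recurrent cell matches the explicit gate-equation oracle", {
  set.seed(8)
  for (rep in 1:3) {
    init <- nn_init("he")
    lp <- tsdnet:::lstm_init(4, 2, init)
    lp$b <- rnorm(8, sd = 0.3)
    x <- matrix(rnorm(2 * 4), 2, 4)
    got <- tsdnet:::lstm_fw(lp, x)$c_n
    want <- oracle_lstm_cn(x, lp$Wx, lp$Wh, lp$b, 2)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("encoding is order-sensitive", {
  ap <- make_action(n = 3, seed = 2)
  Ft <- matrix(rnorm(3 * 8), 3, 8)
  u1 <- encode_sequence(Ft, ap)$c_n
  u2 <- encode_sequence(Ft[3:1, ], ap)$c_n
  expect_gt(max(abs(u1 - u2)), 1e-8)
})

test_that("still and motion streams are independent and deterministic", {
  sti <- make_action(seed = 1)
  mot <- make_action(seed = 2)
  seqs <- replicate(3, rand_img(16), simplify = FALSE)
  u_sti <- action_representation(seqs, sti, "still")
  u_mot <- action_representation(seqs, mot, "motion")
  expect_s3_class(u_sti, "stream_representation")
  expect_gt(max(abs(u_sti$u - u_mot$u)), 0)
  expect_true(all(u_sti$u >= 0))
  again <- action_representation(seqs, sti, "still")
  expect_identical(u_sti$u, again$u)
})

test_that("the frame-attention ablation passes features through", {
  ap <- make_action(n = 3, attention = FALSE, seed = 3)
  seqs <- replicate(3, rand_img(16), simplify = FALSE)
  out <- action_representation(seqs, ap, "still")
  expect_null(out$att)
  F <- frame_features(seqs, ap)
  fa <- frame_attention(F, ap)
  expect_identical(fa$F_tilde, F)
  expect_true(all(is.finite(out$u)))
})

test_that("action-stream gradients match finite differences", {
  ap <- make_action(n = 3, seed = 6)
  seqs <- replicate(3, rand_img(16), simplify = FALSE)
  fw <- tsdnet:::action_forward(ap, seqs)
  du <- rnorm(length(fw$u))
  g <- tsdnet:::action_backward(ap, fw$cache, du)$grads
  lossat <- function(apm) sum(tsdnet:::action_forward(apm, seqs)$u * du)
  eps <- 1e-6
  for (nm in c("W1", "W2", "b2")) {
    for (k in c(1, 2)) {
      a1 <- ap; a1[[nm]][k] <- a1[[nm]][k] + eps
      a2 <- ap; a2[[nm]][k] <- a2[[nm]][k] - eps
      expect_equal(g[[nm]][k], (lossat(a1) - lossat(a2)) / (2 * eps),
                   tolerance = 1e-3)
    }
  }
  k <- 5
  a1 <- ap; a1$lstm$Wx[k] <- a1$lstm$Wx[k] + eps
  a2 <- ap; a2$lstm$Wx[k] <- a2$lstm$Wx[k] - eps
  expect_equal(g$lstm$Wx[k], (lossat(a1) - lossat(a2)) / (2 * eps),
               tolerance = 1e-3)
})
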