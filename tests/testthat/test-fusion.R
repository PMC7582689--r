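make_fusion <- function(m = 4, streams = c("still", "motion", "face"),
                        attention = TRUE, seed = 1) {
  set.seed(seed)
  fusion_params(fusion_cfg(streams = streams,
                           attention_enabled = attention, m = m),
                init = nn_init("he"))
}

rand_us <- function(m = 4) list(u_sti = pmax(rnorm(m), 0),
                                u_mot = pmax(rnorm(m), 0),
                                u_fac = pmax(rnorm(m), 0))

test_that("local weights are rectified dot products per stream", {
  fp <- make_fusion()
  us <- rand_us()
  w <- local_weights(us$u_sti, us$u_mot, us$u_fac, fp)
  for (i in seq_along(fp$cfg$streams)) {
    s <- fp$cfg$streams[i]
    expect_equal(w[[s]],
                 max(sum(fp$local[[s]]$W * us[[i]]) + fp$local[[s]]$b, 0),
                 tolerance = 1e-9)
  }
  fp$local$still$W <- numeric(4); fp$local$still$b <- 2
  w2 <- local_weights(us$u_sti, us$u_mot, us$u_fac, fp)
  expect_equal(unname(w2["still"]), 2)
  for (s in names(fp$local)) {
    fp$local[[s]]$W <- numeric(4); fp$local[[s]]$b <- 0
  }
  w0 <- local_weights(us$u_sti, us$u_mot, us$u_fac, fp)
  expect_true(all(w0 == 0))
  expect_error(local_weights(numeric(3), us$u_mot, us$u_fac, fp),
               "length")
})

test_that("weighted integration matches the brute-force loop oracle", {
  for (seed in 1:3) {
    fp <- make_fusion(seed = seed)
    set.seed(seed + 100)
    us <- rand_us()
    pred <- integrate(us$u_sti, us$u_mot, us$u_fac, fp)
    expect_length(pred$y, 2)
    expect_equal(sum(pred$y), 1, tolerance = 1e-9)
    orc <- oracle_fusion(unname(us),
                         list(fp$local$still, fp$local$motion,
                              fp$local$face),
                         fp$W11, fp$b11, fp$W12)
    expect_equal(unname(pred$y), orc$y, tolerance = 1e-6)
    expect_equal(unname(pred$weights), orc$w, tolerance = 1e-6)
  }
})

test_that("a zero global gate is a pure residual", {
  fp <- make_fusion(seed = 2)
  fp$W11 <- numeric(12); fp$b11 <- numeric(12)
  us <- rand_us()
  pred <- integrate(us$u_sti, us$u_mot, us$u_fac, fp)
  # with g = 0, G = U and the posterior is softmax(W12' U)
  w <- local_weights(us$u_sti, us$u_mot, us$u_fac, fp)
  U <- c(w["still"] * us$u_sti, w["motion"] * us$u_mot,
         w["face"] * us$u_fac)
  expect_equal(unname(pred$y), oracle_softmax(drop(crossprod(fp$W12, U))),
               tolerance = 1e-9)
})

test_that("early integration reduces to the attention path when disabled", {
  fp <- make_fusion(seed = 3)
  us <- rand_us()
  early <- integrate_early(us$u_sti, us$u_mot, us$u_fac, fp)
  expect_length(early$y, 2)
  expect_equal(sum(early$y), 1, tolerance = 1e-9)
  expect_identical(early$y, integrate_early(us$u_sti, us$u_mot,
                                            us$u_fac, fp)$y)
  # structural reduction: w = 1, g = 0, shared classifier weights
  fp2 <- make_fusion(seed = 3, attention = FALSE)
  fp2$early$W <- fp2$W12
  fp2$early$b <- c(0, 0)
  att <- integrate(us$u_sti, us$u_mot, us$u_fac, fp2)
  ear <- integrate_early(us$u_sti, us$u_mot, us$u_fac, fp2)
  expect_equal(unname(att$y), unname(ear$y), tolerance = 1e-9)
})

test_that("loss-based integration combines head losses with the lambdas", {
  fp <- make_fusion(seed = 4)
  expect_equal(sum(tsdnet:::loss_lambdas(fp$cfg)), 1, tolerance = 1e-12)
  us <- rand_us()
  out <- integrate_loss_based(us$u_sti, us$u_mot, us$u_fac, fp,
                              label = "stressed")
  expect_length(out$prediction$y, 2)
  # recompute the weighted sum from the per-head posteriors
  aux <- lapply(fp$cfg$streams, function(s) {
    p <- oracle_softmax(drop(us[[match(s, fp$cfg$streams)]] %*%
                               fp$heads[[s]]$W) + fp$heads[[s]]$b)
    -log(p[1])
  })
  fused <- -log(out$prediction$y[[1]])
  lam <- fp$cfg$lambdas
  expect_equal(out$loss,
               sum(lam[1:3] * unlist(aux)) + lam[4] * fused,
               tolerance = 1e-9)
  # the published weighting applied to fixed per-head losses
  expect_equal(sum(lam * c(0.1, 0.2, 0.3, 0.4)), 0.28, tolerance = 1e-12)
  # equal head losses leave the total unchanged (convex combination)
  expect_equal(sum(lam * rep(0.37, 4)), 0.37, tolerance = 1e-12)
  expect_error(integrate_loss_based(us$u_sti, us$u_mot, us$u_fac, fp,
                                    label = NULL), "label")
})

test_that("late integration averages per-stream posteriors", {
  fp <- make_fusion(seed = 5)
  us <- rand_us()
  pred <- integrate_late(us$u_sti, us$u_mot, us$u_fac, fp)
  expect_equal(sum(pred$y), 1, tolerance = 1e-9)
  # identical per-stream posteriors: force all heads to the same output
  for (s in names(fp$heads)) {
    fp$heads[[s]]$W <- matrix(0, 4, 2)
    fp$heads[[s]]$b <- c(1.3, -0.2)
  }
  p <- oracle_softmax(c(1.3, -0.2))
  pred2 <- integrate_late(us$u_sti, us$u_mot, us$u_fac, fp)
  expect_equal(unname(pred2$y), p, tolerance = 1e-9)
  # posteriors ~ (1,0), (0,1), (.5,.5) average to (.5,.5)
  fp$heads$still$b <- c(60, 0)
  fp$heads$motion$b <- c(0, 60)
  fp$heads$face$b <- c(0, 0)
  pred3 <- integrate_late(us$u_sti, us$u_mot, us$u_fac, fp)
  expect_equal(unname(pred3$y), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("every integrator emits a valid two-class posterior", {
  us <- rand_us()
  for (seed in 1:2) {
    fp <- make_fusion(seed = seed)
    preds <- list(integrate(us$u_sti, us$u_mot, us$u_fac, fp),
                  integrate_early(us$u_sti, us$u_mot, us$u_fac, fp),
                  integrate_loss_based(us$u_sti, us$u_mot, us$u_fac, fp,
                                       "unstressed")$prediction,
                  integrate_late(us$u_sti, us$u_mot, us$u_fac, fp))
    for (p in preds) {
      expect_true(all(p$y >= 0))
      expect_equal(sum(p$y), 1, tolerance = 1e-8)
      expect_true(p$label %in% c("stressed", "unstressed"))
    }
  }
})

test_that("fusion gradients flow into all three streams", {
  cfg <- micro_config(seed = 2)
  model <- tsdnet_init(cfg, seed = 2)
  smp <- list(face_e = rand_img(), face_l = rand_img(),
              stills = replicate(3, rand_img(), simplify = FALSE),
              flows = replicate(2, rand_img(), simplify = FALSE))
  fw <- tsdnet:::model_forward(model, smp, label_idx = 1L)
  g <- tsdnet:::model_backward(model, fw$cache)
  expect_tree_nonzero(g$face)
  expect_tree_nonzero(g$still)
  expect_tree_nonzero(g$motion)
  expect_tree_nonzero(g$fusion)
  # one SGD step changes parameters in every stream
  params <- tsdnet:::model_trainable(model)
  st <- tsdnet:::sgd_step(params, g, tsdnet:::sgd_state(params), lr = 0.01)
  for (s in c("face", "still", "motion", "fusion"))
    expect_gt(tsdnet:::tree_max_abs(
      tsdnet:::tree_add(st$params[[s]], tsdnet:::tree_scale(params[[s]], -1))),
      0)
})

test_that("disabled fusion attention fixes open gates", {
  fp <- make_fusion(seed = 6, attention = FALSE)
  us <- rand_us()
  pred <- integrate(us$u_sti, us$u_mot, us$u_fac, fp)
  expect_true(all(pred$weights == 1))
  U <- c(us$u_sti, us$u_mot, us$u_fac)
  expect_equal(unname(pred$y), oracle_softmax(drop(crossprod(fp$W12, U))),
               tolerance = 1e-9)
})
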