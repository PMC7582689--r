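test_that("face rendering is deterministic and monotone in expressiveness", {
  neutral1 <- render_face(0, 70)
  neutral2 <- render_face(0, 70)
  expect_identical(neutral1, neutral2)

  expressive <- render_face(1, 70)
  expect_gt(mean(abs(expressive - neutral1)), 0)

  # re-extract the drawn mouth-arc apex offset from pixels
  curv <- vapply(c(0, 0.5, 1),
                 function(e) oracle_mouth_curvature(render_face(e, 70)),
                 numeric(1))
  expect_true(all(diff(curv) > 0))

  expect_error(render_face(0.5, size = 8), "size")
})

test_that("clip generation is seeded, planted and class-separable", {
  cfg <- synth_config(n_subjects = 4, clips_per_subject = 2,
                      frames_per_clip = 8, image_size = 36,
                      face_signal = 1, noise_sd = 0, seed = 7)
  a <- generate_clip("stressed", cfg, subject = 2, clip_index = 5)
  b <- generate_clip("stressed", cfg, subject = 2, clip_index = 5)
  expect_identical(a, b)
  expect_identical(a$key_frame, which.max(a$expressiveness))
  expect_length(a$faces, 8)
  expect_identical(dim(a$frames[[1]]), c(36L, 36L, 3L))

  # linear probe on per-clip mean images separates the classes
  cfg2 <- synth_config(n_subjects = 10, clips_per_subject = 20,
                       frames_per_clip = 4, image_size = 24,
                       face_signal = 1, action_signal = 1,
                       noise_sd = 0.02, seed = 3)
  ds <- generate_dataset(cfg2)
  X <- t(vapply(ds, function(cl)
    as.vector(Reduce(`+`, cl$faces) / length(cl$faces)),
    numeric(24 * 24 * 3)))
  y <- vapply(ds, `[[`, character(1), "label") == "stressed"
  mu1 <- colMeans(X[y, ]); mu0 <- colMeans(X[!y, ])
  proj <- X %*% (mu1 - mu0)
  thr <- mean(c(mean(proj[y]), mean(proj[!y])))
  expect_gt(mean((proj > thr) == y), 0.9)
})

test_that("datasets are balanced within subject and seed-sensitive", {
  cfg <- synth_config(n_subjects = 5, clips_per_subject = 4,
                      frames_per_clip = 4, image_size = 24, seed = 1)
  ds <- generate_dataset(cfg)
  expect_length(ds, 20)
  labs <- vapply(ds, `[[`, character(1), "label")
  subj <- vapply(ds, `[[`, character(1), "subject_id")
  for (s in unique(subj)) {
    expect_identical(sum(labs[subj == s] == "stressed"), 2L)
    expect_identical(sum(labs[subj == s] == "unstressed"), 2L)
  }
  ds2 <- generate_dataset(synth_config(n_subjects = 5,
                                       clips_per_subject = 4,
                                       frames_per_clip = 4,
                                       image_size = 24, seed = 2))
  expect_length(ds2, 20)
  expect_false(identical(ds[[1]]$frames[[1]], ds2[[1]]$frames[[1]]))

  # overall label proportions are exactly balanced by construction
  big <- synth_config(n_subjects = 25, clips_per_subject = 40,
                      frames_per_clip = 2, image_size = 16, seed = 4)
  labs <- unlist(lapply(generate_dataset(big), `[[`, "label"))
  expect_identical(sum(labs == "stressed"), 500L)
})

test_that("expression corpus is balanced, thresholdable and reproducible", {
  co <- generate_expression_corpus(10, seed = 3, noise_sd = 0)
  expect_length(co$images, 20)
  expect_identical(as.integer(table(co$labels)), c(10L, 10L))
  # a threshold on the re-measured mouth curvature separates perfectly
  curv <- vapply(co$images, oracle_mouth_curvature, numeric(1))
  lo <- max(curv[co$labels == "expressionless"])
  hi <- min(curv[co$labels == "expressive"])
  expect_lt(lo, hi)
  co2 <- generate_expression_corpus(10, seed = 3, noise_sd = 0)
  expect_identical(co, co2)
})

test_that("separability is non-decreasing in the face signal", {
  probe_acc <- function(fs) {
    ds <- small_dataset(n_subjects = 8, clips_per_subject = 10,
                        frames = 3, face_signal = fs, action_signal = 0,
                        noise_sd = 0.02, seed = 11, image_size = 24)
    X <- t(vapply(ds, function(cl)
      as.vector(Reduce(`+`, cl$faces) / length(cl$faces)),
      numeric(24 * 24 * 3)))
    y <- vapply(ds, `[[`, character(1), "label") == "stressed"
    mu1 <- colMeans(X[y, ]); mu0 <- colMeans(X[!y, ])
    proj <- X %*% (mu1 - mu0)
    thr <- mean(c(mean(proj[y]), mean(proj[!y])))
    mean((proj > thr) == y)
  }
  acc <- vapply(c(0, 0.5, 1), probe_acc, numeric(1))
  expect_lte(acc[1], acc[2] + 0.05)
  expect_lte(acc[2], acc[3] + 0.05)
  expect_gt(acc[3], acc[1])
})

test_that("clips round-trip through the PNG directory layout", {
  cfg <- synth_config(n_subjects = 2, clips_per_subject = 2,
                      frames_per_clip = 3, image_size = 24, seed = 5)
  ds <- generate_dataset(cfg)
  dir <- file.path(tempdir(), "clips-rt")
  write_clips(ds, dir)
  back <- read_clips(dir)
  expect_length(back, length(ds))
  orig <- ds[order(vapply(ds, `[[`, character(1), "subject_id"))]
  expect_setequal(vapply(back, `[[`, character(1), "label"),
                  vapply(ds, `[[`, character(1), "label"))
  # key-frame metadata and pixels survive (8-bit quantization tolerance)
  b1 <- back[[1]]
  match_orig <- Filter(function(cl)
    cl$subject_id == b1$subject_id && cl$label == b1$label, ds)
  errs <- vapply(match_orig, function(cl)
    mean(abs(cl$frames[[1]] - b1$frames[[1]])), numeric(1))
  expect_lt(min(errs), 1 / 255)
  expect_true(all(vapply(back, function(cl) is.finite(cl$key_frame),
                         logical(1))))
  unlink(dir, recursive = TRUE)
})
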