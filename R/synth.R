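## Synthetic stress-video generator.
##
## Emulates the statistical structure of a clip-level stress dataset: short
## frame sequences per subject, binary labels, a face channel whose
## expressiveness amplitude separates the classes, and an action channel
## whose blob-trajectory family separates them. Both signal strengths are
## dials in [0, 1]; at 0 the classes are exchangeable by construction.

#' Synthetic dataset configuration
#'
#' @param n_subjects number of synthetic subjects.
#' @param clips_per_subject clips generated per subject (labels balanced
#'   within subject; alternating assignment when odd).
#' @param frames_per_clip frames per clip, at least 2 (optical flow needs
#'   consecutive pairs). Default 16 — a desk-scale stand-in for full-length
#'   15-s/30-fps clips.
#' @param image_size side of the square frames and face crops, in pixels.
#' @param face_signal in `[0, 1]`: how strongly the peak expressiveness
#'   amplitude separates stressed from unstressed clips. 0 removes the face
#'   class signal entirely.
#' @param action_signal in `[0, 1]`: how strongly the blob trajectory family
#'   (hand-to-head arc for stressed, hand-to-side arc for unstressed)
#'   separates the classes. 0 collapses both families onto their midpoint.
#' @param noise_sd additive Gaussian pixel noise (images live in `[0, 1]`).
#' @param seed base seed; every clip draws from its own substream so clip i
#'   is reproducible in isolation.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10, clips_per_subject = 8,
                         frames_per_clip = 16, image_size = 70,
                         face_signal = 1, action_signal = 1,
                         noise_sd = 0.02, seed = 1) {
  stopifnot(n_subjects >= 1, clips_per_subject >= 1,
            frames_per_clip >= 2, image_size >= 16,
            face_signal >= 0, face_signal <= 1,
            action_signal >= 0, action_signal <= 1,
            noise_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 clips_per_subject = as.integer(clips_per_subject),
                 frames_per_clip = as.integer(frames_per_clip),
                 image_size = as.integer(image_size),
                 face_signal = face_signal, action_signal = action_signal,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Subject appearance style
#'
#' Per-subject geometry offsets applied to every rendered face and scene of
#' that subject, giving clips an identity structure that subject-level
#' splits must respect. The default (all zeros) is the canonical face.
#' @param head_dx,head_dy,eye_gap,shade small numeric offsets.
#' @return a list of style fields.
#' @export
face_style <- function(head_dx = 0, head_dy = 0, eye_gap = 0, shade = 0) {
  list(head_dx = head_dx, head_dy = head_dy, eye_gap = eye_gap, shade = shade)
}

subject_style <- function(cfg, subject) {
  with_seed(substream_seed(cfg$seed, 1000003L * subject), {
    face_style(head_dx = runif(1, -0.02, 0.02),
               head_dy = runif(1, -0.02, 0.02),
               eye_gap = runif(1, -0.02, 0.02),
               shade = runif(1, -0.05, 0.05))
  })
}

#' Render a parametric cartoon face
#'
#' Draws an elliptical head with eyes, brows and a mouth whose curvature,
#' brow raise and eye opening increase monotonically with `expressiveness`.
#' `expressiveness = 0` with `noise_sd = 0` and the default style is the
#' canonical neutral face, pixel-identical across calls. The mouth apex is
#' displaced by `round(0.18 * size * expressiveness)` pixels above the mouth
#' corners, so the drawn curvature can be re-measured from pixels.
#'
#' @param expressiveness in `[0, 1]`.
#' @param size image side in pixels, at least 16.
#' @param noise_sd additive Gaussian noise (drawn from the current RNG).
#' @param style a [face_style()].
#' @return a `size x size x 3` array in `[0, 1]`.
#' @export
render_face <- function(expressiveness, size = 70, noise_sd = 0,
                        style = face_style()) {
  stopifnot(expressiveness >= 0, expressiveness <= 1)
  if (size < 16) stop("size too small to draw facial features (need >= 16)")
  s <- size
  img <- matrix(0.95 + style$shade, s, s)
  px <- function(u) pmin(pmax(as.integer(round(u * (s - 1))) + 1L, 1L), s)
  X <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  Y <- matrix(rep(seq_len(s), s), s, s)          # row index
  cx <- (0.5 + style$head_dx) * s
  cy <- (0.52 + style$head_dy) * s
  # head
  inside <- ((X - cx) / (0.40 * s))^2 + ((Y - cy) / (0.46 * s))^2 <= 1
  img[inside] <- 0.75 + style$shade
  # eyes: radius grows with expressiveness
  gap <- 0.15 + style$eye_gap
  r_eye <- s * 0.035 * (1 + 0.5 * expressiveness)
  for (ex in c(cx - gap * s, cx + gap * s)) {
    eye <- (X - ex)^2 + (Y - 0.40 * s)^2 <= r_eye^2
    img[eye] <- 0.10
  }
  # brows: inner end raised with expressiveness
  for (side in c(-1, 1)) {
    x_in <- cx + side * (gap - 0.06) * s
    x_out <- cx + side * (gap + 0.06) * s
    cols <- px(seq(min(x_in, x_out), max(x_in, x_out)) / s)
    frac <- if (side < 0) seq(1, 0, length.out = length(cols))
            else seq(0, 1, length.out = length(cols))
    rows <- pmin(pmax(as.integer(round((0.31 - 0.05 * expressiveness * frac) *
                                         s)), 1L), s)
    img[cbind(rows, cols)] <- 0.20
    img[cbind(pmin(rows + 1L, s), cols)] <- 0.20
  }
  # mouth: parabolic arc, apex raised by curv pixels above the corners
  curv <- round(0.18 * s * expressiveness)
  w <- max(3L, as.integer(round(0.18 * s)))
  y0 <- as.integer(round(0.74 * s))
  ccx <- as.integer(round(cx))
  cols <- (ccx - w):(ccx + w)
  cols <- cols[cols >= 1 & cols <= s]
  dxn <- (cols - ccx) / w
  rows <- as.integer(round(y0 - curv * (1 - dxn^2)))
  rows <- pmin(pmax(rows, 1L), s)
  img[cbind(rows, cols)] <- 0.05
  img[cbind(pmin(rows + 1L, s), cols)] <- 0.05
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(s * s, 0, noise_sd), s, s)
    img <- pmin(pmax(img, 0), 1)
  }
  array(rep(img, 3), c(s, s, 3))
}

# trajectory families for the moving blob (normalized (x, y) coordinates);
# u in [0, 1] along the path
path_stressed <- function(u) {
  cbind(x = 0.5 - 0.3 * u, y = 0.88 - 0.62 * u - 0.15 * sin(pi * u))
}
path_unstressed <- function(u) {
  cbind(x = 0.5 + 0.32 * u, y = 0.88 - 0.30 * u + 0.05 * sin(pi * u))
}
path_neutral <- function(u) {
  (path_stressed(u) + path_unstressed(u)) / 2
}

render_scene <- function(pos, size, noise_sd, style) {
  s <- size
  img <- matrix(0.90 + style$shade, s, s)
  X <- matrix(rep(seq_len(s), each = s), s, s)
  Y <- matrix(rep(seq_len(s), s), s, s)
  # static torso block at the bottom
  img[Y > 0.78 * s & abs(X - 0.5 * s) < 0.30 * s] <- 0.55 + style$shade
  # moving blob (the acting hand)
  r <- 0.07 * s
  blob <- (X - pos[1] * s)^2 + (Y - pos[2] * s)^2 <= r^2
  img[blob] <- 0.15
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(s * s, 0, noise_sd), s, s)
    img <- pmin(pmax(img, 0), 1)
  }
  array(rep(img, 3), c(s, s, 3))
}

#' Generate one labeled synthetic clip
#'
#' Stressed clips draw a per-frame expressiveness series with a higher peak
#' amplitude (the gap scaled by `face_signal`) and a blob trajectory from
#' the stressed motion family (pulled toward the family midpoint as
#' `action_signal` decreases). Exactly one frame attains the clip's maximum
#' expressiveness; its index is recorded as `key_frame` ground truth.
#'
#' @param label `"stressed"` or `"unstressed"`.
#' @param cfg a [synth_config()].
#' @param subject integer subject index (drives the subject style and id).
#' @param clip_index integer substream counter; the same
#'   `(cfg, label, subject, clip_index)` always yields the identical clip.
#' @return an object of class `tsd_clip` with fields `frames`, `faces`
#'   (lists of `size x size x 3` arrays), `subject_id`, `label`,
#'   `key_frame`, `expressiveness`.
#' @export
generate_clip <- function(label = c("stressed", "unstressed"), cfg,
                          subject = 1L, clip_index = 1L) {
  label <- match.arg(label)
  stopifnot(inherits(cfg, "synth_config"))
  style <- subject_style(cfg, subject)
  n <- cfg$frames_per_clip
  with_seed(substream_seed(cfg$seed, clip_index), {
    sgn <- if (label == "stressed") 1 else -1
    amp <- 0.5 + sgn * 0.45 * cfg$face_signal
    t0 <- runif(1, 0.25, 0.75) * n
    tau <- n / 4
    tt <- seq_len(n)
    e <- amp * (0.1 + 0.9 * exp(-((tt - t0) / tau)^2))
    # enforce a unique maximum under degenerate placements
    if (sum(e == max(e)) > 1) e[which.max(e)] <- min(1, max(e) + 1e-6)
    e <- pmin(pmax(e, 0), 1)
    key <- which.max(e)
    u0 <- runif(1, 0, 0.25)
    u <- u0 + (1 - u0) * (tt - 1) / (n - 1)
    p_class <- if (label == "stressed") path_stressed(u) else path_unstressed(u)
    p_neut <- path_neutral(u)
    pos <- p_neut + cfg$action_signal * (p_class - p_neut)
    pos <- pos + matrix(rnorm(2 * n, 0, 0.01), n, 2)
    faces <- lapply(tt, function(t)
      render_face(e[t], cfg$image_size, cfg$noise_sd, style))
    frames <- lapply(tt, function(t)
      render_scene(pos[t, ], cfg$image_size, cfg$noise_sd, style))
    structure(list(frames = frames, faces = faces,
                   subject_id = sprintf("S%03d", subject), label = label,
                   key_frame = key, expressiveness = e),
              class = "tsd_clip")
  })
}

#' Generate a full synthetic dataset
#'
#' `n_subjects * clips_per_subject` clips with labels balanced within each
#' subject (alternating assignment when `clips_per_subject` is odd, so the
#' global balance stays within one clip of exact).
#'
#' @param cfg a [synth_config()].
#' @return a list of [generate_clip()] objects with attribute `cfg`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  clips <- vector("list", cfg$n_subjects * cfg$clips_per_subject)
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    labs <- rep(c("stressed", "unstressed"), length.out = cfg$clips_per_subject)
    if (s %% 2 == 0) labs <- rev(labs)
    for (k in seq_len(cfg$clips_per_subject)) {
      i <- i + 1L
      clips[[i]] <- generate_clip(labs[k], cfg, subject = s, clip_index = i)
    }
  }
  attr(clips, "cfg") <- cfg
  clips
}

#' Generate an expressive/expressionless face corpus
#'
#' A balanced two-class image corpus standing in for a neutral-vs-emotional
#' face dataset: expressionless images use expressiveness in `[0, 0.1]`,
#' expressive images in `[0.6, 1]`.
#'
#' @param n_per_class images per class, at least 1.
#' @param seed RNG seed.
#' @param size image side in pixels.
#' @param noise_sd additive pixel noise.
#' @return list with `images` (list of arrays), `labels` (factor with
#'   levels `expressionless`, `expressive`) and `expressiveness`.
#' @export
generate_expression_corpus <- function(n_per_class, seed = 1, size = 70,
                                       noise_sd = 0.02) {
  stopifnot(n_per_class >= 1)
  with_seed(seed, {
    e_less <- runif(n_per_class, 0, 0.1)
    e_more <- runif(n_per_class, 0.6, 1)
    e <- c(e_less, e_more)
    labels <- factor(rep(c("expressionless", "expressive"),
                         each = n_per_class),
                     levels = c("expressionless", "expressive"))
    styles <- replicate(2 * n_per_class,
                        face_style(head_dx = runif(1, -0.02, 0.02),
                                   head_dy = runif(1, -0.02, 0.02),
                                   eye_gap = runif(1, -0.02, 0.02),
                                   shade = runif(1, -0.05, 0.05)),
                        simplify = FALSE)
    images <- lapply(seq_along(e), function(i)
      render_face(e[i], size, noise_sd, styles[[i]]))
    list(images = images, labels = labels, expressiveness = e)
  })
}

#' Write clips to a directory layout
#'
#' Layout: `<subject>/<clip_id>/frame_%04d.png`, `faces/face_%04d.png` and
#' `meta.json` holding the label, subject and planted key-frame index.
#'
#' @param clips list of `tsd_clip` objects.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_clips <- function(clips, dir) {
  counts <- list()
  for (clip in clips) {
    sid <- clip$subject_id
    counts[[sid]] <- (counts[[sid]] %||% 0L) + 1L
    cdir <- file.path(dir, sid, sprintf("clip_%04d", counts[[sid]]))
    dir.create(file.path(cdir, "faces"), recursive = TRUE,
               showWarnings = FALSE)
    for (t in seq_along(clip$frames)) {
      png::writePNG(clip$frames[[t]],
                    file.path(cdir, sprintf("frame_%04d.png", t)))
      png::writePNG(clip$faces[[t]],
                    file.path(cdir, "faces", sprintf("face_%04d.png", t)))
    }
    jsonlite::write_json(list(label = clip$label, subject = sid,
                              key_frame = clip$key_frame,
                              n_frames = length(clip$frames)),
                         file.path(cdir, "meta.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read clips from the directory layout written by [write_clips()]
#'
#' Also accepts externally produced trees with the same shape; a clip
#' directory needs `frame_*.png` files, a `faces/` subdirectory and a
#' `meta.json` with at least `label` and `subject`.
#'
#' @param dir dataset root.
#' @return list of `tsd_clip` objects.
#' @export
read_clips <- function(dir) {
  metas <- sort(list.files(dir, pattern = "^meta\\.json$", recursive = TRUE,
                           full.names = TRUE))
  lapply(metas, function(mf) {
    cdir <- dirname(mf)
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    ff <- sort(list.files(cdir, pattern = "^frame_.*\\.png$",
                          full.names = TRUE))
    gf <- sort(list.files(file.path(cdir, "faces"), pattern = "\\.png$",
                          full.names = TRUE))
    as_rgb <- function(p) {
      x <- png::readPNG(p)
      if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
      x[, , 1:3, drop = FALSE]
    }
    structure(list(frames = lapply(ff, as_rgb), faces = lapply(gf, as_rgb),
                   subject_id = meta$subject, label = meta$label,
                   key_frame = meta$key_frame %||% NA_integer_,
                   expressiveness = NULL),
              class = "tsd_clip")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tsd_clip <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<tsd_clip> subject %s, label %s, %d frames of %dx%d, key frame %d\n",
              x$subject_id, x$label, length(x$frames), d[1], d[2],
              x$key_frame))
  invisible(x)
}
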