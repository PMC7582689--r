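## Preprocessing: turn a clip into the three model views — normalized face
## crops, normalized still frames, and optical-flow images.

#' View-pipeline configuration
#'
#' @param image_size side to which every input image is resized.
#' @param crop_size side of the square crop taken after resizing (random
#'   top-left in train mode, centered in eval mode).
#' @param norm_mean,norm_sd per-view, per-channel normalization statistics:
#'   named lists with entries `face`, `still`, `flow`, each a length-3
#'   numeric. `NULL` means mean 0 / sd 1 (no-op). Compute them once from a
#'   training split with [compute_norm_stats()] and freeze them.
#' @param flow_backend dense-flow callable `(gray_a, gray_b) -> H x W x 2`
#'   displacement field in pixels; `NULL` uses the built-in block-matching
#'   flow [flow_block_match()].
#' @param flow_max_disp displacement bound (pixels) used both as the search
#'   radius of the default backend and the scale when rendering flow to an
#'   image.
#' @return an object of class `view_config`.
#' @export
view_config <- function(image_size = 70, crop_size = 64,
                        norm_mean = NULL, norm_sd = NULL,
                        flow_backend = NULL, flow_max_disp = 4) {
  stopifnot(crop_size <= image_size)
  structure(list(image_size = as.integer(image_size),
                 crop_size = as.integer(crop_size),
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 flow_backend = flow_backend,
                 flow_max_disp = flow_max_disp),
            class = "view_config")
}

#' Bilinear image resize
#'
#' @param img `H x W x C` array (or `H x W` matrix) in `[0, 1]`.
#' @param target output side in pixels.
#' @return `target x target x C` array; inputs already at the target size
#'   are returned unchanged.
#' @export
resize_image <- function(img, target = 70) {
  d <- dim(img)
  if (is.null(d) || length(d) < 2 || any(d[1:2] == 0) || length(img) == 0)
    stop("resize_image: empty image")
  if (d[1] == target && d[2] == target) return(img)
  out <- EBImage::resize(img, w = target, h = target)
  as.array(out)
}

crop_window <- function(side, crop, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (crop > side) stop("crop larger than image side")
  if (mode == "eval") {
    off <- as.integer((side - crop) %/% 2)
    c(off, off)
  } else {
    c(sample.int(side - crop + 1, 1) - 1L, sample.int(side - crop + 1, 1) - 1L)
  }
}

#' Crop and normalize an image
#'
#' Train mode takes a uniformly random top-left window (from the current
#' RNG), eval mode the centered window at offset `floor((side - crop) / 2)`.
#' Normalization subtracts `mean` and divides by `sd` per channel.
#'
#' @param img `H x W x C` array.
#' @param mode `"train"` or `"eval"`.
#' @param crop output side.
#' @param mean,sd per-channel statistics (recycled); defaults leave values
#'   untouched.
#' @param offset optional explicit `c(row, col)` 0-based window offset,
#'   overriding `mode` (used to share one window across views).
#' @return cropped, normalized array with attribute `"offset"`.
#' @export
crop_normalize <- function(img, mode = c("eval", "train"), crop = 64,
                           mean = 0, sd = 1, offset = NULL) {
  mode <- match.arg(mode)
  d <- dim(img)
  if (crop > min(d[1:2])) stop("crop larger than image side")
  if (is.null(offset)) offset <- crop_window(d[1], crop, mode)
  r <- offset[1] + seq_len(crop)
  c_ <- offset[2] + seq_len(crop)
  out <- img[r, c_, , drop = FALSE]
  nc <- dim(out)[3]
  mean <- rep(mean, length.out = nc)
  sd <- rep(sd, length.out = nc)
  for (ch in seq_len(nc)) out[, , ch] <- (out[, , ch] - mean[ch]) / sd[ch]
  attr(out, "offset") <- offset
  out
}

#' Dense optical flow by block matching
#'
#' For every pixel, the integer displacement within `radius` minimizing the
#' sum of squared differences over a `window`-sized neighborhood (computed
#' with an integral image; borders use replicate padding). Ties are broken
#' toward the smallest displacement, so identical frames give a zero field.
#'
#' @param a,b equal-sized grayscale matrices; the field maps `a` onto `b`
#'   (positive dx = rightward motion).
#' @param radius maximum displacement searched, in pixels.
#' @param window odd neighborhood side for the matching cost.
#' @return `H x W x 2` array: `[, , 1]` = dx (columns), `[, , 2]` = dy (rows).
#' @export
flow_block_match <- function(a, b, radius = 4, window = 5) {
  stopifnot(identical(dim(a), dim(b)))
  H <- nrow(a); W <- ncol(a)
  boxsum <- function(x, h) {
    # sum over (2h+1)^2 border-clamped windows via an integral image
    Sp <- matrix(0, H + 1, W + 1)
    Sp[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
    r1 <- pmax(seq_len(H) - h, 1); r2 <- pmin(seq_len(H) + h, H)
    c1 <- pmax(seq_len(W) - h, 1); c2 <- pmin(seq_len(W) + h, W)
    Sp[r2 + 1, c2 + 1] - Sp[r1, c2 + 1] - Sp[r2 + 1, c1] + Sp[r1, c1]
  }
  shift_rep <- function(x, dv, du) {
    ri <- pmin(pmax(seq_len(H) + dv, 1), H)
    ci <- pmin(pmax(seq_len(W) + du, 1), W)
    x[ri, ci, drop = FALSE]
  }
  h <- (window - 1) %/% 2
  disp <- expand.grid(u = -radius:radius, v = -radius:radius)
  disp <- disp[order(abs(disp$u) + abs(disp$v), disp$u^2 + disp$v^2), ]
  best <- matrix(Inf, H, W)
  dx <- matrix(0, H, W); dy <- matrix(0, H, W)
  for (i in seq_len(nrow(disp))) {
    u <- disp$u[i]; v <- disp$v[i]
    diff2 <- (a - shift_rep(b, v, u))^2
    cost <- boxsum(diff2, h)
    upd <- cost < best - 1e-12
    if (any(upd)) {
      best[upd] <- cost[upd]
      dx[upd] <- u
      dy[upd] <- v
    }
  }
  out <- array(0, c(H, W, 2))
  out[, , 1] <- dx
  out[, , 2] <- dy
  out
}

to_gray <- function(img) {
  if (is.matrix(img)) img else (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Dense optical flow between two frames
#'
#' @param frame_a,frame_b equal-sized images (RGB arrays or gray matrices).
#' @param backend flow callable `(gray_a, gray_b) -> H x W x 2`; default is
#'   [flow_block_match()].
#' @param ... passed to the backend.
#' @return `H x W x 2` displacement field in pixels.
#' @export
compute_flow <- function(frame_a, frame_b, backend = NULL, ...) {
  da <- dim(frame_a); db <- dim(frame_b)
  if (!identical(da[1:2], db[1:2]))
    stop("compute_flow: frame size mismatch")
  ga <- to_gray(frame_a); gb <- to_gray(frame_b)
  if (is.null(backend)) backend <- flow_block_match
  flow <- backend(ga, gb, ...)
  stopifnot(identical(dim(flow)[1:2], dim(ga)), dim(flow)[3] == 2L)
  flow
}

#' Render a flow field as a 3-channel image
#'
#' Channels are (dx, dy, magnitude), affinely scaled to `[0, 1]` by
#' `max_disp` so both action streams share one backbone input convention.
#'
#' @param flow `H x W x 2` displacement field.
#' @param max_disp displacement mapped to the ends of the channel range.
#' @return `H x W x 3` array in `[0, 1]`; zero flow maps to (0.5, 0.5, 0).
#' @export
render_flow <- function(flow, max_disp = 4) {
  d <- dim(flow)
  out <- array(0, c(d[1], d[2], 3))
  out[, , 1] <- pmin(pmax(flow[, , 1] / (2 * max_disp) + 0.5, 0), 1)
  out[, , 2] <- pmin(pmax(flow[, , 2] / (2 * max_disp) + 0.5, 0), 1)
  out[, , 3] <- pmin(sqrt(flow[, , 1]^2 + flow[, , 2]^2) /
                       (max_disp * sqrt(2)), 1)
  out
}

#' Assemble the three model views of a clip
#'
#' Faces and stills are resized then cropped/normalized; flow is computed
#' on the resized (pre-crop) stills and cropped with the same window as the
#' stills of its frame pair, so spatial correspondence across the three
#' views is preserved. In train mode one random window is drawn per clip
#' and shared by all views.
#'
#' @param clip a `tsd_clip` (or any list with `frames` and `faces` image
#'   lists; supply `face_provider` when `faces` is absent).
#' @param mode `"train"` or `"eval"`.
#' @param cfg a [view_config()].
#' @param face_provider optional callable `frame -> face image or NULL`.
#' @return object of class `tsd_views`: `face_seq`, `still_seq`,
#'   `flow_seq` (length `n - 1`) of `crop_size`-sided arrays, plus the
#'   shared crop `offset`.
#' @export
make_views <- function(clip, mode = c("eval", "train"), cfg = view_config(),
                       face_provider = NULL) {
  mode <- match.arg(mode)
  if (length(clip$frames) < 2) stop("make_views: clip needs >= 2 frames")
  faces <- clip$faces
  if (is.null(faces) || length(faces) == 0) {
    if (is.null(face_provider))
      stop("clip has no face crops and no face_provider given")
    faces <- lapply(clip$frames, face_provider)
  }
  stills_r <- lapply(clip$frames, resize_image, target = cfg$image_size)
  faces_r <- lapply(faces, resize_image, target = cfg$image_size)
  flows <- vector("list", length(stills_r) - 1)
  for (t in seq_along(flows)) {
    fl <- compute_flow(stills_r[[t]], stills_r[[t + 1]],
                       backend = cfg$flow_backend,
                       radius = cfg$flow_max_disp)
    flows[[t]] <- render_flow(fl, max_disp = cfg$flow_max_disp)
  }
  offset <- crop_window(cfg$image_size, cfg$crop_size, mode)
  nm <- function(view) cfg$norm_mean[[view]] %||% 0
  ns <- function(view) cfg$norm_sd[[view]] %||% 1
  crop1 <- function(img, view)
    crop_normalize(img, crop = cfg$crop_size, mean = nm(view),
                   sd = ns(view), offset = offset)
  structure(list(face_seq = lapply(faces_r, crop1, view = "face"),
                 still_seq = lapply(stills_r, crop1, view = "still"),
                 flow_seq = lapply(flows, crop1, view = "flow"),
                 offset = offset),
            class = "tsd_views")
}

#' Per-channel normalization statistics from a training split
#'
#' Computes frozen per-view channel means and standard deviations over the
#' resized (pre-crop) images of the given clips.
#'
#' @param clips list of `tsd_clip` objects (the training fold).
#' @param cfg a [view_config()].
#' @param max_clips cap on clips sampled for the estimate.
#' @return list with `norm_mean` and `norm_sd`, each holding `face`,
#'   `still`, `flow` length-3 numerics, ready to splice into
#'   [view_config()].
#' @export
compute_norm_stats <- function(clips, cfg = view_config(), max_clips = 20) {
  clips <- clips[seq_len(min(length(clips), max_clips))]
  acc <- list(face = NULL, still = NULL, flow = NULL)
  push <- function(acc_v, img) {
    v <- apply(img, 3, function(ch) c(sum(ch), sum(ch^2), length(ch)))
    if (is.null(acc_v)) v else acc_v + v
  }
  for (clip in clips) {
    stills_r <- lapply(clip$frames, resize_image, target = cfg$image_size)
    faces_r <- lapply(clip$faces, resize_image, target = cfg$image_size)
    for (im in faces_r) acc$face <- push(acc$face, im)
    for (im in stills_r) acc$still <- push(acc$still, im)
    for (t in seq_len(length(stills_r) - 1)) {
      fl <- render_flow(compute_flow(stills_r[[t]], stills_r[[t + 1]],
                                     backend = cfg$flow_backend,
                                     radius = cfg$flow_max_disp),
                        max_disp = cfg$flow_max_disp)
      acc$flow <- push(acc$flow, fl)
    }
  }
  fin <- function(a) {
    m <- a[1, ] / a[3, ]
    s <- sqrt(pmax(a[2, ] / a[3, ] - m^2, 1e-8))
    list(mean = m, sd = pmax(s, 1e-3))
  }
  st <- lapply(acc, fin)
  list(norm_mean = lapply(st, `[[`, "mean"),
       norm_sd = lapply(st, `[[`, "sd"))
}
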