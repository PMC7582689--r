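## Ablation and integration-strategy comparison runners.

ablation_variants <- function() {
  c("full", "no_face_attention", "no_frame_attention",
    "no_fusion_attention", "pool_1", "pool_1_2", "pool_1_2_4",
    "pool_1_2_4_8", "face_only", "action_only")
}

apply_variant <- function(config, variant) {
  switch(variant,
    full = config,
    no_face_attention = { config$face$attention_enabled <- FALSE; config },
    no_frame_attention = {
      config$action$frame_attention_enabled <- FALSE; config },
    no_fusion_attention = {
      config$fusion$attention_enabled <- FALSE; config },
    pool_1 = { config$face$pool_scales <- 1; config },
    pool_1_2 = { config$face$pool_scales <- c(1, 2); config },
    pool_1_2_4 = { config$face$pool_scales <- c(1, 2, 4); config },
    pool_1_2_4_8 = { config$face$pool_scales <- c(1, 2, 4, 8); config },
    face_only = {
      config$fusion <- fusion_cfg(strategy = config$fusion$strategy,
                                  streams = "face",
                                  m = config$fusion$m)
      config
    },
    action_only = {
      config$fusion <- fusion_cfg(strategy = config$fusion$strategy,
                                  streams = c("still", "motion"),
                                  m = config$fusion$m)
      config
    },
    stop("unknown variant: ", variant)
  )
}

fit_and_test <- function(clips, config, split, division, scorer,
                         verbose = FALSE) {
  fit <- tsdnet_fit(clips, config = config, split = split,
                    division = division, scorer = scorer,
                    verbose = verbose)
  test_clips <- clips[clips_in_fold(clips, fit$split$test)]
  list(fit = fit, metrics = evaluate(fit, test_clips))
}

run_over_divisions <- function(clips, config, split, scorer, verbose) {
  rows <- lapply(seq_along(split), function(d) {
    m <- fit_and_test(clips, config, split, d, scorer, verbose)$metrics
    c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      f1 = m$f1)
  })
  colMeans(do.call(rbind, rows))
}

#' Run the attention / pooling / stream ablation suite
#'
#' Retrains one model per variant (attention mechanisms removed one at a
#' time, pooling-scale combinations, and single-level face-only /
#' action-only models) and reports test metrics averaged over the
#' divisions of the split plan.
#'
#' @param clips dataset of `tsd_clip` objects.
#' @param config base [tsdnet_config()].
#' @param variants character subset of the built-in variant names
#'   (default: all of them).
#' @param split a [make_splits()] plan (default: one division drawn with
#'   the config seed).
#' @param scorer expression scorer (see [tsdnet_fit()]).
#' @param verbose print per-epoch progress.
#' @return data.frame with one row per variant and columns
#'   accuracy/precision/recall/f1.
#' @export
run_ablations <- function(clips, config = tsdnet_config("tiny"),
                          variants = ablation_variants(), split = NULL,
                          scorer = curvature_scorer(), verbose = FALSE) {
  stopifnot(all(variants %in% ablation_variants()))
  subjects <- unique(vapply(clips, `[[`, character(1), "subject_id"))
  if (is.null(split))
    split <- make_splits(subjects, n_divisions = 1,
                         seed = config$train$seed)
  rows <- lapply(variants, function(v) {
    cfgv <- apply_variant(config, v)
    run_over_divisions(clips, cfgv, split, scorer, verbose)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(variant = variants, out)
  rownames(out) <- NULL
  out
}

#' Compare the four integration strategies
#'
#' Retrains the full model once per fusion strategy (weighted attention,
#' early, loss-based early, late) and reports test metrics averaged over
#' the divisions of the split plan.
#'
#' @inheritParams run_ablations
#' @param strategies strategies to compare.
#' @return data.frame with one row per strategy.
#' @export
compare_integrations <- function(clips, config = tsdnet_config("tiny"),
                                 strategies = c("early", "loss_early",
                                                "late",
                                                "weighted_attention"),
                                 split = NULL,
                                 scorer = curvature_scorer(),
                                 verbose = FALSE) {
  subjects <- unique(vapply(clips, `[[`, character(1), "subject_id"))
  if (is.null(split))
    split <- make_splits(subjects, n_divisions = 1,
                         seed = config$train$seed)
  rows <- lapply(strategies, function(s) {
    cfgs <- config
    cfgs$fusion$strategy <- s
    run_over_divisions(clips, cfgs, split, scorer, verbose)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(strategy = strategies, out)
  rownames(out) <- NULL
  out
}
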