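#' Pipeline configuration
#'
#' Collects every stage parameter with reduced-cost defaults suitable for
#' routine runs (100 decoding splits, 500 count bootstraps, 1000 onset
#' bootstraps); `paper_scale = TRUE` switches to the study's full values
#' (1000 splits, 1000 count bootstraps, 10000 onset bootstraps). Every
#' stochastic stage derives its seed deterministically from the global seed.
#'
#' @param seed Global seed.
#' @param n_channels Channels in the simulated session.
#' @param truth `"paper_like"` (default), `"null"` (no planted signal), or a
#'   `ground_truth` object.
#' @param n_splits,n_boot,onset_boot Stage iteration counts.
#' @param window_width Decoding/RSA/tuning bin width (s).
#' @param decode_span Time span for the decoders (default \[-1, 2\] s).
#' @param alpha Tuning family-wise error rate.
#' @param paper_scale Use full study-scale iteration counts?
#' @param out_dir Optional output directory for per-stage CSVs and the
#'   summary JSON.
#' @param design_overrides Named list passed to [make_task_design()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_channels = 96, truth = "paper_like",
                            n_splits = 100, n_boot = 500, onset_boot = 1000,
                            window_width = 0.5, decode_span = c(-1, 2),
                            alpha = 0.05, paper_scale = FALSE,
                            out_dir = NULL, design_overrides = list()) {
  if (paper_scale) {
    n_splits <- 1000; n_boot <- 1000; onset_boot <- 10000
  }
  structure(list(seed = as.integer(seed), n_channels = as.integer(n_channels),
                 truth = truth, n_splits = n_splits, n_boot = n_boot,
                 onset_boot = onset_boot, window_width = window_width,
                 decode_span = decode_span, alpha = alpha,
                 paper_scale = paper_scale, out_dir = out_dir,
                 design_overrides = design_overrides),
            class = "pipeline_config")
}

#' Run the full simulate - preprocess - decode - RSA - tune pipeline
#'
#' Simulates a session from the configured ground truth, normalizes it,
#' runs pairwise identity decoding, location-generalization decoding across
#' physical touch types, the crossnobis RDM series, the tuning analysis with
#' bootstrap counts and overlap sets, and the onset/offset estimates for the
#' physically touched conditions, and scores recovery against the planted
#' truth. Identical configurations (including seed) produce byte-identical
#' summaries.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `bundle`, `truth`, `decoding`,
#'   `generalization`, `rdms`, `tuning`, `tuned_counts`, `overlap`,
#'   `onsets`, `scorecard`, `summary` (plain list mirrored to JSON),
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- do.call(make_task_design, config$design_overrides)
  truth <- config$truth
  if (identical(truth, "paper_like")) {
    truth <- paper_like_truth(design, n_channels = config$n_channels)
  } else if (identical(truth, "null")) {
    truth <- make_ground_truth(design, n_channels = config$n_channels)
  }
  stopifnot(inherits(truth, "ground_truth"))

  sim <- simulate_session(design, truth, seed = derive_seed(config$seed, "sim"))
  bundle <- normalize_by_baseline(drop_catch_trials(sim$bundle))

  decoding <- run_pairwise(bundle, window_width = config$window_width,
                           span = config$decode_span,
                           n_splits = config$n_splits,
                           seed = derive_seed(config$seed, "decode"))

  generalization <- NULL
  has_phys <- all(c("FPa", "FPf", "BLa", "BLf") %in% design$conditions)
  if (has_phys) {
    gen1 <- run_generalization(bundle, "BLa", "BLf", "FPa", "FPf",
                               window_width = config$window_width,
                               span = c(0, 1), n_splits = config$n_splits,
                               seed = derive_seed(config$seed, "gen1"))
    gen1$direction <- "train_BL_test_FP_location"
    gen2 <- run_generalization(bundle, "FPa", "FPf", "BLa", "BLf",
                               window_width = config$window_width,
                               span = c(0, 1), n_splits = config$n_splits,
                               seed = derive_seed(config$seed, "gen2"))
    gen2$direction <- "train_FP_test_BL_location"
    generalization <- dplyr::bind_rows(tidy(gen1), tidy(gen2))
  }

  rdms <- run_rsa(bundle, window_width = config$window_width,
                  span = config$decode_span)

  tuning <- run_tuning(bundle, window_width = config$window_width,
                       alpha = config$alpha)
  counts <- bootstrap_tuned_counts(bundle, n_iter = config$n_boot,
                                   seed = derive_seed(config$seed, "boot"),
                                   window_width = config$window_width,
                                   alpha = config$alpha)
  overlap <- overlap_sets(tuning)

  onset_conds <- intersect(c("FPa", "FPf", "BLa", "BLf"), design$conditions)
  tuned_any <- dplyr::summarise(
    dplyr::group_by(tuning, .data$channel, .data$condition),
    tuned = any(.data$tuned), .groups = "drop")
  onsets <- purrr::map_dfr(onset_conds, function(cc) {
    ch <- tuned_any$channel[tuned_any$condition == cc & tuned_any$tuned]
    if (!length(ch)) {
      return(tibble::tibble(condition = cc, onset_ms = NA_real_,
                            onset_lo = NA_real_, onset_hi = NA_real_,
                            offset_ms = NA_real_, offset_lo = NA_real_,
                            offset_hi = NA_real_, threshold = NA_real_,
                            n_tuned = 0L, n_trials = 0L))
    }
    detect_onset_offset(bundle, ch, cc, n_boot = config$onset_boot,
                        seed = derive_seed(config$seed, paste0("on", cc)))
  })

  scorecard <- recovery_scorecard(tuning, truth, design, onsets)

  config_echo <- unclass(config)[setdiff(names(config), "out_dir")]
  if (!is.character(config_echo$truth)) config_echo$truth <- "custom"
  summary <- list(
    config = config_echo,
    decoding = as.list(tidy(decoding)),
    generalization = if (!is.null(generalization)) as.list(generalization),
    rdms = as.list(tidy(rdms)),
    tuned_counts = as.list(counts$counts),
    count_pairs = as.list(counts$pairs),
    overlap_counts = as.list(overlap$counts),
    onsets = as.list(onsets),
    scorecard = scorecard
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tidy(decoding),
                     file.path(config$out_dir, "decoding.csv"), row.names = FALSE)
    if (!is.null(generalization)) {
      utils::write.csv(generalization,
                       file.path(config$out_dir, "generalization.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(tidy(rdms), file.path(config$out_dir, "rdms.csv"),
                     row.names = FALSE)
    utils::write.csv(counts$counts,
                     file.path(config$out_dir, "tuned_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(onsets, file.path(config$out_dir, "onsets.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }

  structure(list(bundle = bundle, truth = truth, decoding = decoding,
                 generalization = generalization, rdms = rdms,
                 tuning = tuning, tuned_counts = counts, overlap = overlap,
                 onsets = onsets, scorecard = scorecard, summary = summary,
                 config = config),
            class = "pipeline_result")
}

# Score recovered structure against the planted ground truth.
recovery_scorecard <- function(tuning, truth, design, onsets) {
  tuned_any <- dplyr::summarise(
    dplyr::group_by(tuning, .data$channel, .data$condition),
    tuned = any(.data$tuned), .groups = "drop")
  est <- matrix(FALSE, truth$n_channels, length(truth$conditions),
                dimnames = list(NULL, truth$conditions))
  est[cbind(tuned_any$channel,
            match(tuned_any$condition, truth$conditions))] <- tuned_any$tuned
  planted <- truth$tuned_mask
  tp <- sum(est & planted); fp <- sum(est & !planted)
  fn <- sum(!est & planted); tn <- sum(!est & !planted)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_

  onset_err <- NULL
  if (nrow(onsets)) {
    w <- design$bin_width
    expected <- vapply(onsets$condition, function(cc) {
      ci <- match(cc, truth$conditions)
      lat <- truth$latency[, ci][truth$tuned_mask[, ci]]
      if (!length(lat)) return(NA_real_)
      l <- stats::median(lat)
      (floor((l - design$epoch[1]) / w + 1e-9) * w + design$epoch[1] + w / 2) * 1000
    }, numeric(1))
    onset_err <- list(condition = onsets$condition,
                      expected_ms = unname(expected),
                      estimated_ms = onsets$onset_ms,
                      abs_error_ms = abs(onsets$onset_ms - unname(expected)))
  }
  list(tuning_sensitivity = sens, tuning_false_positive_rate = fpr,
       tuning_specificity = if (!is.na(fpr)) 1 - fpr else NA_real_,
       onset = onset_err)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  decoders: %d (%d significant)\n", nrow(x$decoding),
              sum(x$decoding$tier != "ns")))
  cat(sprintf("  tuning sensitivity %.3f, FPR %.3f\n",
              x$scorecard$tuning_sensitivity,
              x$scorecard$tuning_false_positive_rate))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_decoders = nrow(x$decoding),
    n_significant = sum(x$decoding$tier != "ns"),
    tuning_sensitivity = x$scorecard$tuning_sensitivity,
    tuning_fpr = x$scorecard$tuning_false_positive_rate,
    seed = x$config$seed
  )
}
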