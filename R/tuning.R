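#' Bonferroni-Holm step-down correction
#'
#' Sorts the p-values ascending and rejects while
#' \eqn{p_{(i)} \le \alpha / (m - i + 1)}, stopping at the first failure.
#' Holm controls the family-wise error rate at `alpha` and is uniformly at
#' least as powerful as plain Bonferroni.
#'
#' @param p_values Numeric vector of p-values (finite; `NA` never rejected).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical rejection vector in the original order.
#' @export
holm_correct <- function(p_values, alpha = 0.05) {
  m <- sum(!is.na(p_values))
  reject <- rep(FALSE, length(p_values))
  if (m == 0) return(reject)
  ord <- order(p_values, na.last = TRUE)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= alpha / (m - i + 1)) {
      reject[ord[i]] <- TRUE
    } else break
  }
  reject
}

# Per-trial baseline means (trials x channels): mean over the baseline window.
baseline_trial_means <- function(bundle) {
  window_features(bundle, bundle$design$baseline_window)
}

# Closed-form OLS for the tuning regression F = b0 + sum_c bc Xc with
# `n_base` appended baseline rows (all equal to the channel's across-trial
# mean baseline). With one-hot condition coding and baseline rows carrying
# only the intercept, OLS gives b0 = baseline mean, bc = condition mean -
# baseline mean, with the identical baseline rows contributing 0 to the RSS
# (they deflate residual variance; this mirrors the study's augmentation and
# is deliberately not "fixed"). Returns per channel x condition t statistics.
tuning_fit_closed <- function(feats, cond_labels, base_value, n_base) {
  conds <- sort(unique(cond_labels))
  C <- length(conds)
  P <- ncol(feats)
  n_c <- as.vector(table(factor(cond_labels, levels = conds)))
  sums <- rowsum(feats, factor(cond_labels, levels = conds))
  means <- sums / n_c
  ss <- rowsum(feats^2, factor(cond_labels, levels = conds))
  rss <- colSums(ss - n_c * means^2)              # per channel
  N <- nrow(feats) + n_base
  df <- N - (C + 1)
  s2 <- rss / df
  beta <- sweep(means, 2, base_value)             # C x P
  se <- sqrt(outer(1 / n_c + 1 / n_base, s2))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- s2 <= 0 | !is.finite(s2)
  if (any(zero_var)) p[, zero_var] <- NA_real_
  list(conditions = conds, beta = beta, t = tstat, p = p, df = df,
       zero_variance = zero_var)
}

#' Fit the per-channel condition-tuning regression in one time bin
#'
#' Normalized rates of every analyzable trial in the bin form the response
#' vector F, augmented with one baseline entry per design trial-count
#' (identical copies of the channel's across-trial mean baseline); condition
#' identity is one-hot coded. OLS on this system yields a per-condition
#' coefficient equal to the condition mean minus baseline, tested against 0
#' with a two-sided t-test. Channels with zero residual variance are flagged
#' (`p = NA`).
#'
#' @param bundle A normalized `session_bundle`.
#' @param window Length-2 time window (s) of the bin.
#' @param channels Optional channel subset (default all).
#' @return Tibble: `channel`, `condition`, `beta`, `t`, `p`, `df`.
#' @export
fit_channel_tuning <- function(bundle, window, channels = NULL) {
  if (!bundle$normalized) stop("bundle must be normalized first", call. = FALSE)
  bundle <- drop_catch_trials(bundle)
  channels <- channels %||% seq_len(dim(bundle$rates)[1])
  feats <- window_features(bundle, window)[, channels, drop = FALSE]
  base <- colMeans(baseline_trial_means(bundle)[, channels, drop = FALSE])
  n_base <- bundle$design$runs_per_condition * bundle$design$trials_per_run
  fit <- tuning_fit_closed(feats, bundle$trials$condition, base, n_base)
  tibble::tibble(
    channel = rep(channels, each = length(fit$conditions)),
    condition = rep(fit$conditions, times = length(channels)),
    beta = as.vector(fit$beta),
    t = as.vector(fit$t),
    p = as.vector(fit$p),
    df = fit$df
  )
}

#' Channel tuning across conditions and time bins, Holm-corrected
#'
#' Runs the tuning regression in every `window_width` bin across `span`
#' (study convention: 0.5 s bins, -1 to 2 s) and applies Bonferroni-Holm
#' within each channel. The default family is all condition-by-bin tests of
#' the channel (the conservative reading); `family = "condition"` corrects
#' within each bin separately instead.
#'
#' @param bundle A normalized `session_bundle`.
#' @param window_width Bin width in seconds (default 0.5).
#' @param span Analysis span (default \[-1, 2\] s).
#' @param alpha Family-wise error rate per channel (default 0.05).
#' @param family `"condition_bin"` (default) or `"condition"`.
#' @return A `tuning_table` tibble: `channel`, `condition`, `bin_start`,
#'   `bin_end`, `beta`, `t`, `p`, `tuned`.
#' @export
run_tuning <- function(bundle, window_width = 0.5, span = c(-1, 2),
                       alpha = 0.05, family = c("condition_bin", "condition")) {
  family <- match.arg(family)
  windows <- decoding_windows(span, window_width)
  fits <- purrr::map_dfr(windows, function(w) {
    out <- fit_channel_tuning(bundle, w)
    out$bin_start <- w[1]
    out$bin_end <- w[2]
    out
  })
  grp_vars <- if (family == "condition_bin") "channel" else c("channel", "bin_start")
  fits <- dplyr::mutate(dplyr::group_by(fits, dplyr::across(dplyr::all_of(grp_vars))),
                        tuned = holm_correct(.data$p, alpha = alpha))
  fits <- dplyr::ungroup(fits)
  fits <- fits[, c("channel", "condition", "bin_start", "bin_end",
                   "beta", "t", "p", "tuned")]
  attr(fits, "alpha") <- alpha
  attr(fits, "family") <- family
  class(fits) <- c("tuning_table", class(fits))
  fits
}

#' Summarize a tuning table per condition
#'
#' @param tuning A `tuning_table` from [run_tuning()].
#' @return Tibble per condition: `n_tuned` channels (tuned in any bin) and
#'   `max_bins_tuned` (longest per-channel tuned-bin count).
#' @export
tuning_counts <- function(tuning) {
  per_chan <- dplyr::summarise(
    dplyr::group_by(tuning, .data$channel, .data$condition),
    n_bins_tuned = sum(.data$tuned), .groups = "drop")
  dplyr::summarise(dplyr::group_by(per_chan, .data$condition),
                   n_tuned = sum(.data$n_bins_tuned > 0),
                   max_bins_tuned = max(.data$n_bins_tuned),
                   .groups = "drop")
}

#' Bootstrap distribution of tuned-channel counts per condition
#'
#' Per iteration, trials are resampled with replacement within each
#' condition (keeping the design's per-condition trial count), the tuning
#' regressions are refit in every bin, Holm is reapplied per channel, and
#' channels tuned to each condition in any bin are counted. Percentile CIs
#' summarize the counts; condition pairs are flagged at the 95/97.5/99%
#' tiers when their count CIs do not overlap.
#'
#' @param bundle A normalized `session_bundle`.
#' @param n_iter Bootstrap iterations (study value 1000).
#' @param seed Integer seed.
#' @param window_width,span,alpha,family As in [run_tuning()].
#' @return A `tuned_counts` list: `counts` (per-condition tibble with
#'   observed count and CI), `pairs` (pairwise tier flags), `draws`
#'   (iteration x condition count matrix).
#' @export
bootstrap_tuned_counts <- function(bundle, n_iter = 1000, seed = 1,
                                   window_width = 0.5, span = c(-1, 2),
                                   alpha = 0.05,
                                   family = c("condition_bin", "condition")) {
  family <- match.arg(family)
  if (!bundle$normalized) stop("bundle must be normalized first", call. = FALSE)
  bundle <- drop_catch_trials(bundle)
  windows <- decoding_windows(span, window_width)
  feats <- lapply(windows, function(w) window_features(bundle, w))
  base_tm <- baseline_trial_means(bundle)
  n_base <- bundle$design$runs_per_condition * bundle$design$trials_per_run
  labels <- bundle$trials$condition
  conds <- sort(unique(labels))
  idx_by_cond <- lapply(conds, function(cc) which(labels == cc))

  count_once <- function(idx) {
    lab <- labels[idx]
    base <- colMeans(base_tm[idx, , drop = FALSE])
    pmat <- do.call(rbind, lapply(feats, function(f) {
      tuning_fit_closed(f[idx, , drop = FALSE], lab, base, n_base)$p
    }))  # (bins*C) x channels
    cond_of_row <- rep(conds, times = length(windows))
    tuned <- matrix(FALSE, nrow(pmat), ncol(pmat))
    for (ch in seq_len(ncol(pmat))) {
      if (family == "condition_bin") {
        tuned[, ch] <- holm_correct(pmat[, ch], alpha = alpha)
      } else {
        for (w in seq_along(windows)) {
          rows <- (w - 1) * length(conds) + seq_along(conds)
          tuned[rows, ch] <- holm_correct(pmat[rows, ch], alpha = alpha)
        }
      }
    }
    vapply(conds, function(cc) sum(colSums(tuned[cond_of_row == cc, , drop = FALSE]) > 0),
           integer(1))
  }

  observed <- unname(count_once(seq_along(labels)))
  draws <- with_local_seed(seed, {
    t(vapply(seq_len(n_iter), function(it) {
      idx <- unlist(lapply(idx_by_cond, function(ix)
        sample(ix, length(ix), replace = TRUE)))
      count_once(idx)
    }, integer(length(conds))))
  })
  colnames(draws) <- conds
  counts <- tibble::tibble(
    condition = conds,
    n_tuned = observed,
    boot_mean = colMeans(draws),
    ci_lo = apply(draws, 2, function(x) percentile_ci(x, 0.95)[1]),
    ci_hi = apply(draws, 2, function(x) percentile_ci(x, 0.95)[2])
  )
  pair_idx <- utils::combn(conds, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(pair_idx)), function(k) {
    a <- pair_idx[1, k]; b <- pair_idx[2, k]
    tibble::tibble(cond_a = a, cond_b = b,
                   tier = significance_tier(draws[, a], draws[, b]))
  })
  structure(list(counts = counts, pairs = pairs, draws = draws,
                 n_iter = n_iter), class = "tuned_counts")
}

#' @export
print.tuned_counts <- function(x, ...) {
  cat(sprintf("<tuned_counts> %d bootstrap iterations\n", x$n_iter))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.tuned_counts <- function(x, ...) x$counts

#' Channel membership sets across arm and finger conditions
#'
#' Per channel, the exact set of conditions with any tuned bin, aggregated
#' into arm-only / finger-only / both counts overall and within each touch
#' type, plus channel positions on the two electrode-array grids.
#'
#' @param tuning A `tuning_table` from [run_tuning()].
#' @param array_layout Optional tibble `channel`, `array`, `row`, `col`;
#'   default lays consecutive channels on two `nrow x ncol` grids.
#' @param grid Dimensions of each array grid (default `c(6, 8)` for 48
#'   channels per array).
#' @return An `overlap_report`: list with `membership` (per-channel tibble:
#'   tuned condition set, location class), `counts` (overall and per touch
#'   type), `array_map`.
#' @export
overlap_sets <- function(tuning, array_layout = NULL, grid = c(6, 8)) {
  channels <- sort(unique(tuning$channel))
  tuned_any <- dplyr::summarise(
    dplyr::group_by(tuning, .data$channel, .data$condition),
    tuned = any(.data$tuned), .groups = "drop")
  membership <- dplyr::summarise(
    dplyr::group_by(tuned_any, .data$channel),
    conditions = list(sort(.data$condition[.data$tuned])),
    .groups = "drop")
  loc_class <- function(conds, restrict_type = NULL) {
    if (!is.null(restrict_type)) {
      conds <- conds[condition_touch_type(conds) %in% restrict_type]
    }
    loc <- condition_location(conds)
    arm <- "arm" %in% loc
    fin <- "finger" %in% loc
    dplyr::case_when(arm && fin ~ "both", arm ~ "arm_only",
                     fin ~ "finger_only", TRUE ~ "none")
  }
  membership$class_all <- vapply(membership$conditions, loc_class, character(1))
  membership$class_FP <- vapply(membership$conditions, loc_class, character(1),
                                restrict_type = "FP")
  membership$class_BL <- vapply(membership$conditions, loc_class, character(1),
                                restrict_type = "BL")

  count_classes <- function(cl, scope) {
    out <- table(factor(cl, levels = c("arm_only", "finger_only", "both", "none")))
    tibble::tibble(scope = scope, class = names(out),
                   n_channels = as.integer(out))
  }
  counts <- dplyr::bind_rows(
    count_classes(membership$class_all, "all"),
    count_classes(membership$class_FP, "FP"),
    count_classes(membership$class_BL, "BL")
  )

  n_per_array <- prod(grid)
  if (is.null(array_layout)) {
    if (max(channels) > 2 * n_per_array) {
      stop("default layout holds ", 2 * n_per_array,
           " channels; supply array_layout", call. = FALSE)
    }
    i <- channels - 1L
    array_layout <- tibble::tibble(
      channel = channels,
      array = i %/% n_per_array + 1L,
      row = (i %% n_per_array) %/% grid[2] + 1L,
      col = (i %% n_per_array) %% grid[2] + 1L
    )
  }
  if (!all(channels %in% array_layout$channel)) {
    stop("array_layout does not cover all channels", call. = FALSE)
  }
  array_map <- dplyr::left_join(array_layout,
                                membership[, c("channel", "class_all")],
                                by = "channel")
  structure(list(membership = membership, counts = counts,
                 array_map = array_map), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  print(tidyr::pivot_wider(x$counts, names_from = "class",
                           values_from = "n_channels"))
  invisible(x)
}

#' @export
autoplot.overlap_report <- function(object, ...) {
  df <- object$array_map
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class_all)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_wrap(~array, labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tuned to") +
    ggplot2::theme_minimal()
}

#' Onset and offset of the tuned-channel response to a condition
#'
#' Averages normalized rates over the channels tuned to a condition and its
#' trials on the 50 ms grid; the onset is the middle of the first bin (in
#' the search window) rising above the 95th percentile of the distribution
#' of channel-averaged baseline-window rates, and the offset is the middle
#' of the first bin after the trace's peak that falls back below the same
#' threshold (`offset_from = "onset"` searches from the onset instead).
#' Trial-level bootstrap (recomputing both trace and threshold per resample)
#' yields the confidence intervals. A trace that never crosses the threshold
#' has an undefined onset (`NA`).
#'
#' @param bundle A normalized `session_bundle` on the fine (50 ms) grid.
#' @param tuned_channels Channels tuned to the condition.
#' @param condition Condition code.
#' @param n_boot Bootstrap resamples (study value 10000).
#' @param seed Integer seed.
#' @param threshold_quantile Baseline quantile (default 0.95).
#' @param search_window Window searched for crossings (default \[-1, 2\] s).
#' @param offset_from `"peak"` (default) or `"onset"`.
#' @return An `onset_estimate` one-row tibble: `condition`, `onset_ms`,
#'   `onset_lo`, `onset_hi`, `offset_ms`, `offset_lo`, `offset_hi`,
#'   `threshold`, `n_tuned`, `n_trials`.
#' @export
detect_onset_offset <- function(bundle, tuned_channels, condition,
                                n_boot = 10000, seed = 1,
                                threshold_quantile = 0.95,
                                search_window = c(-1, 2),
                                offset_from = c("peak", "onset")) {
  offset_from <- match.arg(offset_from)
  if (!length(tuned_channels)) stop(">= 1 tuned channel required", call. = FALSE)
  bundle <- drop_catch_trials(bundle)
  idx <- which(bundle$trials$condition == condition)
  if (!length(idx)) stop("no trials for condition ", condition, call. = FALSE)
  x <- bundle$rates[tuned_channels, idx, , drop = FALSE]
  Tm <- apply(x, c(2, 3), mean)                   # trial x bin, channel-avg
  base_bins <- bins_in_window(bundle, bundle$design$baseline_window)
  search_bins <- bins_in_window(bundle, search_window)
  mids <- (bundle$bin_edges[-length(bundle$bin_edges)] + bundle$bin_width / 2)

  one_pass <- function(rows) {
    thr <- stats::quantile(Tm[rows, base_bins], threshold_quantile,
                           names = FALSE)
    trace <- colMeans(Tm[rows, , drop = FALSE])
    above <- trace[search_bins] > thr
    if (!any(above)) return(c(NA_real_, NA_real_, thr))
    on_bin <- search_bins[which(above)[1]]
    start <- if (offset_from == "peak") {
      cand <- search_bins[search_bins >= on_bin]
      cand[which.max(trace[cand])]
    } else on_bin
    after <- search_bins[search_bins > start]
    below <- trace[after] < thr
    off_bin <- if (any(below)) after[which(below)[1]] else NA_integer_
    # round to ns precision: bin midpoints are exact multiples of width/2
    c(round(mids[on_bin] * 1000, 6),
      if (is.na(off_bin)) NA_real_ else round(mids[off_bin] * 1000, 6),
      thr)
  }

  obs <- one_pass(seq_len(nrow(Tm)))
  boots <- with_local_seed(derive_seed(seed, paste("onset", condition)), {
    vapply(seq_len(n_boot), function(b) {
      one_pass(sample.int(nrow(Tm), nrow(Tm), replace = TRUE))
    }, numeric(3))
  })
  ci_on <- percentile_ci(boots[1, ], 0.95)
  ci_off <- percentile_ci(boots[2, ], 0.95)
  out <- tibble::tibble(
    condition = condition,
    onset_ms = obs[1], onset_lo = ci_on[1], onset_hi = ci_on[2],
    offset_ms = obs[2], offset_lo = ci_off[1], offset_hi = ci_off[2],
    threshold = obs[3],
    n_tuned = length(tuned_channels), n_trials = nrow(Tm)
  )
  class(out) <- c("onset_estimate", class(out))
  out
}
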