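#' Session bundle: trial-aligned binned firing rates plus labels
#'
#' The central container all analyses consume: a channel x trial x bin array
#' of firing rates (Hz before normalization, unitless after), the half-open
#' bin grid `[t, t + width)` in seconds relative to touch onset, and a trials
#' tibble with one row per trial (`trial_id`, `condition`, `run` =
#' within-condition run index, `run_id`, `set`, `is_catch`, `onset_time`).
#'
#' @param rates channel x trial x bin numeric array.
#' @param design A `task_design` (supplies the bin grid and windows).
#' @param trials Trials tibble, one row per trial, in tensor order.
#' @param normalized Has baseline normalization been applied?
#' @param seed Generating seed, if simulated (metadata only).
#' @return A `session_bundle` object.
#' @export
new_session_bundle <- function(rates, design, trials, normalized = FALSE,
                               seed = NULL) {
  stopifnot(length(dim(rates)) == 3, nrow(trials) == dim(rates)[2],
            dim(rates)[3] == design$n_bins)
  structure(list(
    rates = rates,
    bin_edges = design$bin_edges,
    bin_width = design$bin_width,
    design = design,
    trials = tibble::as_tibble(trials),
    normalized = isTRUE(normalized),
    seed = seed
  ), class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  d <- dim(x$rates)
  cat("<session_bundle>\n")
  cat(sprintf("  %d channels x %d trials x %d bins (%g s each, epoch [%g, %g] s)\n",
              d[1], d[2], d[3], x$bin_width, x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)]))
  cat(sprintf("  conditions: %s\n",
              paste(sort(unique(x$trials$condition[!x$trials$is_catch])),
                    collapse = " ")))
  cat(sprintf("  normalized: %s; catch trials: %d\n",
              x$normalized, sum(x$trials$is_catch)))
  invisible(x)
}

#' Number of channels / trials / bins of a bundle
#' @param bundle A `session_bundle`.
#' @return Named integer vector.
#' @export
bundle_dim <- function(bundle) {
  d <- dim(bundle$rates)
  c(channels = d[1], trials = d[2], bins = d[3])
}

#' Drop catch trials from a bundle
#'
#' Catch trials (one per run in the study design) are never analyzed; all
#' analysis entry points call this first.
#'
#' @param bundle A `session_bundle`.
#' @return The bundle restricted to analyzable trials.
#' @export
drop_catch_trials <- function(bundle) {
  keep <- !bundle$trials$is_catch
  if (all(keep)) return(bundle)
  bundle$rates <- bundle$rates[, keep, , drop = FALSE]
  bundle$trials <- bundle$trials[keep, ]
  bundle
}

#' Subset a bundle to selected trials
#' @param bundle A `session_bundle`.
#' @param idx Logical or integer trial index.
#' @return The subset bundle.
#' @export
subset_trials <- function(bundle, idx) {
  bundle$rates <- bundle$rates[, idx, , drop = FALSE]
  bundle$trials <- bundle$trials[idx, ]
  bundle
}

# Indices of bins whose [start, end) interval lies inside `window`.
bins_in_window <- function(bundle, window) {
  starts <- bundle$bin_edges[-length(bundle$bin_edges)]
  ends <- bundle$bin_edges[-1]
  which(starts >= window[1] - 1e-9 & ends <= window[2] + 1e-9)
}

#' Average rates over a time window, as a trials x channels matrix
#'
#' The feature matrix used by the decoding and RSA stages: each trial's mean
#' rate per channel across all bins inside `window` (half-open bins fully
#' contained in the window).
#'
#' @param bundle A `session_bundle`.
#' @param window Length-2 window in seconds relative to touch onset.
#' @return trials x channels numeric matrix.
#' @export
window_features <- function(bundle, window) {
  bi <- bins_in_window(bundle, window)
  if (!length(bi)) stop("window contains no complete bins", call. = FALSE)
  x <- bundle$rates[, , bi, drop = FALSE]
  # mean over bins, then transpose channel x trial -> trial x channel
  t(rowMeans(x, dims = 2))
}

#' Tidy a session bundle into long format
#'
#' @param x A `session_bundle`.
#' @param ... Unused.
#' @return Tibble with columns channel, trial_id, condition, run, set,
#'   is_catch, bin_start, rate. Large for full sessions; intended for small
#'   bundles and plotting.
#' @export
tidy.session_bundle <- function(x, ...) {
  d <- dim(x$rates)
  starts <- x$bin_edges[-length(x$bin_edges)]
  tibble::tibble(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial_id = rep(rep(x$trials$trial_id, each = d[1]), times = d[3]),
    condition = rep(rep(x$trials$condition, each = d[1]), times = d[3]),
    run = rep(rep(x$trials$run, each = d[1]), times = d[3]),
    set = rep(rep(x$trials$set, each = d[1]), times = d[3]),
    is_catch = rep(rep(x$trials$is_catch, each = d[1]), times = d[3]),
    bin_start = rep(starts, each = d[1] * d[2]),
    rate = as.vector(x$rates)
  )
}

#' Condition-average time courses
#'
#' @param bundle A `session_bundle`.
#' @param channels Optional channel subset (default all).
#' @return Tibble: condition, bin_mid, mean_rate, sem.
#' @export
condition_psth <- function(bundle, channels = NULL) {
  bundle <- drop_catch_trials(bundle)
  d <- dim(bundle$rates)
  channels <- channels %||% seq_len(d[1])
  mids <- bundle$bin_edges[-length(bundle$bin_edges)] + bundle$bin_width / 2
  purrr::map_dfr(sort(unique(bundle$trials$condition)), function(cond) {
    idx <- which(bundle$trials$condition == cond)
    # trial x bin matrix of channel-averaged rates
    m <- apply(bundle$rates[channels, idx, , drop = FALSE], c(2, 3), mean)
    tibble::tibble(
      condition = cond,
      bin_mid = mids,
      mean_rate = colMeans(m),
      sem = apply(m, 2, stats::sd) / sqrt(nrow(m))
    )
  })
}

#' Plot condition-average time courses of a bundle
#'
#' @param object A `session_bundle`.
#' @param channels Optional channel subset.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.session_bundle <- function(object, channels = NULL, ...) {
  df <- condition_psth(object, channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$mean_rate,
                                   colour = .data$condition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from touch onset (s)",
                  y = if (object$normalized) "normalized rate" else "rate (Hz)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
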