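#' Detect multi-unit threshold crossings in a broadband trace
#'
#' Events are negative crossings of `k` times the noise RMS of the continuous
#' signal (study convention: k = -3.5). The event time is the first sample
#' below threshold; a refractory lockout (default 1 ms) suppresses further
#' detections while one waveform is in flight. The RMS is estimated from the
#' raw trace; a robust median-based estimator
#' (`median(|x|)/0.6745`) is available behind `robust`.
#'
#' A flat all-zero trace has RMS 0 and yields no events.
#'
#' @param snippet A `broadband_snippet`, or a bare numeric trace (then `fs`
#'   must be supplied).
#' @param k Negative threshold multiplier (default -3.5).
#' @param lockout_s Refractory lockout in seconds (default 0.001).
#' @param robust Use the median-based RMS estimator?
#' @param fs Sampling rate, required when `snippet` is a bare vector.
#' @return Integer vector of event sample indices (1-based), with attributes
#'   `threshold` and `rms`.
#' @export
detect_threshold_crossings <- function(snippet, k = -3.5, lockout_s = 0.001,
                                       robust = FALSE, fs = NULL) {
  if (inherits(snippet, "broadband_snippet")) {
    trace <- snippet$trace
    fs <- snippet$fs
  } else {
    trace <- as.numeric(snippet)
    if (is.null(fs)) stop("fs required for a bare trace", call. = FALSE)
  }
  if (!length(trace)) stop("empty trace", call. = FALSE)
  if (k >= 0) stop("k must be negative", call. = FALSE)
  rms <- if (robust) stats::median(abs(trace)) / 0.6745
         else sqrt(mean(trace^2))
  if (rms == 0) {
    return(structure(integer(0), threshold = 0, rms = 0))
  }
  thr <- k * rms
  below <- trace < thr
  lock <- max(1L, as.integer(round(lockout_s * fs)))
  events <- integer(0)
  i <- 1L
  n <- length(trace)
  while (i <= n) {
    if (below[i]) {
      events <- c(events, i)
      i <- i + lock
    } else {
      i <- i + 1L
    }
  }
  structure(events, threshold = thr, rms = rms)
}

#' Bin event times into firing rates aligned to touch onset
#'
#' Counts per half-open bin `[t, t + width)` relative to each trial's onset,
#' divided by the bin width to give Hz. A bin boundary falls exactly at
#' t = 0, so an event at the onset itself lands in the first post-onset bin.
#' Events outside the epoch are silently dropped.
#'
#' @param event_times List with one numeric vector of event times (seconds,
#'   same clock as `onset_times`) per trial.
#' @param onset_times Numeric vector of per-trial touch-onset times.
#' @param epoch Length-2 window in seconds relative to onset.
#' @param bin_width Bin width in seconds; must divide the epoch evenly and
#'   place a boundary at 0.
#' @return trials x bins matrix of rates in Hz, with bin start times as
#'   column names.
#' @export
bin_events <- function(event_times, onset_times, epoch = c(-4, 2),
                       bin_width = 0.05) {
  stopifnot(length(event_times) == length(onset_times))
  nb <- (epoch[2] - epoch[1]) / bin_width
  if (abs(nb - round(nb)) > 1e-9) {
    stop("bin_width must divide the epoch evenly", call. = FALSE)
  }
  nb <- as.integer(round(nb))
  out <- matrix(0, length(event_times), nb)
  for (tr in seq_along(event_times)) {
    t_rel <- event_times[[tr]] - onset_times[tr]
    idx <- floor((t_rel - epoch[1]) / bin_width) + 1
    idx <- idx[idx >= 1 & idx <= nb &
                 t_rel >= epoch[1] - 1e-12 & t_rel < epoch[2] - 1e-12]
    if (length(idx)) out[tr, ] <- tabulate(idx, nbins = nb)
  }
  colnames(out) <- sprintf("%g", epoch[1] + bin_width * (seq_len(nb) - 1))
  out / bin_width
}

#' Normalize a bundle by its per-run baseline firing rate
#'
#' Within each run and each channel, the mean rate over the baseline window
#' (default \[-4, -2.5\] s before touch onset) is averaged across the run's
#' analyzable trials; every bin of every trial in the run is divided by this
#' baseline. After normalization the across-trial mean of the baseline-window
#' bins is exactly 1 per channel per run.
#'
#' Channels whose baseline mean is 0 in a run cannot be normalized there;
#' they are set to `NA` for that run and recorded in the `excluded`
#' attribute (a tibble of channel/run pairs).
#'
#' @param bundle An unnormalized `session_bundle` whose epoch contains the
#'   baseline window.
#' @return The normalized bundle (`normalized = TRUE`).
#' @export
normalize_by_baseline <- function(bundle) {
  if (bundle$normalized) stop("bundle is already normalized", call. = FALSE)
  bw <- bundle$design$baseline_window
  bi <- bins_in_window(bundle, bw)
  if (!length(bi)) stop("bundle does not contain the baseline window", call. = FALSE)
  analyzable <- !bundle$trials$is_catch
  excluded <- list()
  for (r in unique(bundle$trials$run_id)) {
    in_run <- bundle$trials$run_id == r
    base_trials <- which(in_run & analyzable)
    if (!length(base_trials)) base_trials <- which(in_run)
    # per-channel mean over baseline bins and the run's trials
    b <- rowMeans(bundle$rates[, base_trials, bi, drop = FALSE], dims = 1)
    zero <- b == 0
    b[zero] <- NA_real_
    bundle$rates[, in_run, ] <- bundle$rates[, in_run, , drop = FALSE] / b
    if (any(zero)) {
      excluded[[length(excluded) + 1]] <-
        tibble::tibble(channel = which(zero), run_id = r)
    }
  }
  bundle$normalized <- TRUE
  attr(bundle, "excluded") <- if (length(excluded)) dplyr::bind_rows(excluded)
                              else tibble::tibble(channel = integer(),
                                                  run_id = integer())
  bundle
}

#' Rebin a bundle to a coarser bin width
#'
#' The new width must be an integer multiple of the current one; each new bin
#' is the mean (not the sum) of its constituent bins, so normalized values
#' keep their scale. Rebinning twice equals rebinning once to the final
#' width.
#'
#' @param bundle A `session_bundle`.
#' @param new_width New bin width in seconds.
#' @return The rebinned bundle.
#' @export
rebin <- function(bundle, new_width) {
  ratio <- new_width / bundle$bin_width
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("new_width must be an integer multiple of the current bin width",
         call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(bundle)
  d <- dim(bundle$rates)
  nb_new <- d[3] %/% ratio
  if (nb_new * ratio != d[3]) {
    stop("epoch does not divide evenly into the new bin width", call. = FALSE)
  }
  x <- array(bundle$rates[, , seq_len(nb_new * ratio), drop = FALSE],
             dim = c(d[1], d[2], ratio, nb_new))
  bundle$rates <- apply(x, c(1, 2, 4), mean)
  bundle$bin_width <- new_width
  bundle$design$bin_width <- new_width
  bundle$design <- validate_task_design(bundle$design)
  bundle$bin_edges <- bundle$design$bin_edges
  bundle
}

#' Session-stability report across two collection sets
#'
#' Checks that the fundamentals of the signal are unchanged across the two
#' collection epochs, mirroring the study's controls: (1) per-channel signal-
#' to-noise ratios computed from spike waveforms (mean-waveform trough over
#' noise RMS, and mean-waveform trough over the across-event SD at the
#' trough), and (2) inter-trial-interval firing-rate stability (per-channel
#' mean and SD of run-baseline-normalized ITI rates, window \[-4, -1\] s).
#' Each per-channel quantity is compared across sets with a paired Wilcoxon
#' sign-rank test.
#'
#' When every per-channel difference is zero (e.g. set 2 is a copy of set 1)
#' the sign-rank statistic is degenerate and the p-value is reported as 1.
#'
#' @param bundle_set1,bundle_set2 Unnormalized `session_bundle`s with
#'   matched channels.
#' @param waveforms_set1,waveforms_set2 Optional per-channel lists of
#'   event x sample waveform matrices (one matrix per channel).
#' @param noise_rms_set1,noise_rms_set2 Optional per-channel noise RMS
#'   estimates accompanying the waveforms.
#' @param iti_window ITI window in seconds relative to touch onset
#'   (default \[-4, -1\]).
#' @return An `snr_report`: list with `channels` (per-channel tibble) and
#'   `tests` (tibble of paired sign-rank p-values per metric).
#' @export
stability_report <- function(bundle_set1, bundle_set2,
                             waveforms_set1 = NULL, waveforms_set2 = NULL,
                             noise_rms_set1 = NULL, noise_rms_set2 = NULL,
                             iti_window = c(-4, -1)) {
  d1 <- dim(bundle_set1$rates)[1]
  d2 <- dim(bundle_set2$rates)[1]
  if (d1 != d2) stop("channel mismatch across sets", call. = FALSE)

  iti_stats <- function(bundle) {
    nb <- if (bundle$normalized) bundle else normalize_by_baseline(bundle)
    nb <- drop_catch_trials(nb)
    bi <- bins_in_window(nb, iti_window)
    x <- nb$rates[, , bi, drop = FALSE]               # ch x trial x bin
    m <- apply(x, 1, mean, na.rm = TRUE)
    s <- apply(x, 1, stats::sd, na.rm = TRUE)
    list(mean = m, sd = s)
  }
  s1 <- iti_stats(bundle_set1)
  s2 <- iti_stats(bundle_set2)

  signrank_p <- function(a, b) {
    dd <- a - b
    dd <- dd[is.finite(dd)]
    if (!length(dd) || all(dd == 0)) return(1)
    stats::wilcox.test(a[is.finite(a - b)], b[is.finite(a - b)],
                       paired = TRUE, exact = FALSE)$p.value
  }

  channels <- tibble::tibble(
    channel = seq_len(d1),
    iti_mean_set1 = s1$mean, iti_mean_set2 = s2$mean,
    iti_sd_set1 = s1$sd, iti_sd_set2 = s2$sd
  )
  tests <- tibble::tibble(
    metric = c("iti_mean", "iti_sd"),
    p_value = c(signrank_p(s1$mean, s2$mean), signrank_p(s1$sd, s2$sd))
  )

  if (!is.null(waveforms_set1) && !is.null(waveforms_set2)) {
    snr <- function(wf, rms) {
      m1 <- m2 <- rep(NA_real_, length(wf))
      for (ch in seq_along(wf)) {
        w <- wf[[ch]]
        if (is.null(w) || !nrow(w)) next
        mw <- colMeans(w)
        tr <- which.max(abs(mw))
        m1[ch] <- abs(mw[tr]) / rms[ch]
        sd_tr <- stats::sd(w[, tr])
        m2[ch] <- if (nrow(w) > 1 && sd_tr > 0) abs(mw[tr]) / sd_tr else NA_real_
      }
      list(m1 = m1, m2 = m2)
    }
    a <- snr(waveforms_set1, noise_rms_set1)
    b <- snr(waveforms_set2, noise_rms_set2)
    channels$snr_peak_rms_set1 <- a$m1
    channels$snr_peak_rms_set2 <- b$m1
    channels$snr_mean_sd_set1 <- a$m2
    channels$snr_mean_sd_set2 <- b$m2
    tests <- dplyr::bind_rows(tests, tibble::tibble(
      metric = c("snr_peak_rms", "snr_mean_sd"),
      p_value = c(signrank_p(a$m1, b$m1), signrank_p(a$m2, b$m2))
    ))
  }

  structure(list(channels = channels, tests = tests), class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat("<snr_report>\n")
  print(x$tests)
  invisible(x)
}

#' @export
glance.snr_report <- function(x, ...) {
  tidyr::pivot_wider(x$tests, names_from = "metric", values_from = "p_value",
                     names_prefix = "p_")
}

#' @export
tidy.snr_report <- function(x, ...) x$channels
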