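#' Construct the generative ground truth for a simulated session
#'
#' Holds the planted parameters the analysis stages are scored against:
#' per-channel baseline rates, per channel x condition response gains,
#' latencies and decay time constants, and the shared across-channel noise
#' covariance. Untuned channel x condition entries have gain exactly 1
#' (no modulation); the planted tuned mask is `gain > tuned_threshold`.
#'
#' @param design A [make_task_design()] object.
#' @param n_channels Number of recording channels (default 96, conceptually
#'   two 48-channel arrays).
#' @param baseline_rate Baseline firing rate in Hz; scalar or per-channel
#'   vector (default 10 Hz).
#' @param gain Channel x condition matrix of multiplicative response gains
#'   (1 = no response). Defaults to 1 everywhere (signal-free session).
#' @param latency Channel x condition matrix of response onset latencies in
#'   seconds relative to touch onset; may be negative down to
#'   `-design$visual_lead` for visually cued conditions. Scalars recycle.
#' @param decay_tau Channel x condition matrix (or scalar) of exponential
#'   decay time constants (s) applied after touch offset. Default 0.3 s.
#' @param noise_sd Marginal standard deviation (Hz) of the additive rate noise
#'   per 50 ms bin, used when `noise_cov` is not given. Default 2 Hz.
#' @param noise_rho Shared pairwise correlation of the default noise
#'   covariance `sd^2 * ((1-rho) I + rho 11')`. Default 0.1.
#' @param noise_cov Optional full channel x channel positive semi-definite
#'   noise covariance; overrides `noise_sd`/`noise_rho`.
#' @param tuned_threshold Gain above which a channel x condition entry counts
#'   as planted-tuned (default 1, i.e. any modulation).
#' @param arrays Integer vector assigning each channel to an array (default
#'   splits channels in two consecutive blocks).
#' @return A `ground_truth` object.
#' @export
make_ground_truth <- function(design,
                              n_channels = 96L,
                              baseline_rate = 10,
                              gain = NULL,
                              latency = 0.025,
                              decay_tau = 0.3,
                              noise_sd = 2,
                              noise_rho = 0.1,
                              noise_cov = NULL,
                              tuned_threshold = 1,
                              arrays = NULL) {
  stopifnot(inherits(design, "task_design"))
  n_channels <- as.integer(n_channels)
  conds <- design$conditions
  C <- length(conds)

  expand <- function(x, what) {
    if (is.null(dim(x))) {
      if (length(x) == 1) {
        x <- matrix(x, n_channels, C)
      } else if (length(x) == n_channels) {
        x <- matrix(x, n_channels, C)
      } else stop(what, " must be scalar, per-channel, or channel x condition",
                  call. = FALSE)
    }
    if (!all(dim(x) == c(n_channels, C))) {
      stop(what, " must be ", n_channels, " x ", C, call. = FALSE)
    }
    dimnames(x) <- list(NULL, conds)
    x
  }

  if (is.null(gain)) gain <- 1
  gain <- expand(gain, "gain")
  latency <- expand(latency, "latency")
  decay_tau <- expand(decay_tau, "decay_tau")
  baseline_rate <- rep_len(baseline_rate, n_channels)

  if (any(latency < -design$visual_lead - 1e-12)) {
    stop("latency must be >= -visual_lead", call. = FALSE)
  }
  if (any(baseline_rate < 0)) stop("baseline_rate must be >= 0", call. = FALSE)

  if (is.null(noise_cov)) {
    noise_cov <- noise_sd^2 *
      ((1 - noise_rho) * diag(n_channels) +
         noise_rho * matrix(1, n_channels, n_channels))
  }
  if (!isSymmetric(unname(noise_cov), tol = 1e-8)) {
    stop("noise_cov must be symmetric", call. = FALSE)
  }
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("noise_cov must be positive semi-definite", call. = FALSE)
  }

  if (is.null(arrays)) {
    arrays <- rep(1:2, each = ceiling(n_channels / 2), length.out = n_channels)
  }

  structure(list(
    n_channels = n_channels,
    conditions = conds,
    baseline_rate = baseline_rate,
    gain = gain,
    latency = latency,
    decay_tau = decay_tau,
    noise_cov = unname(noise_cov),
    tuned_threshold = tuned_threshold,
    tuned_mask = gain > tuned_threshold,
    arrays = as.integer(arrays)
  ), class = "ground_truth")
}

#' Ground truth mirroring the study's qualitative response structure
#'
#' A ready-made planted configuration for end-to-end runs: physical arm
#' touches recruit the most channels with the strongest gains, seen physical
#' touches (`FP*`) recruit a superset of the blind-touch (`BL*`) channels,
#' finger conditions recruit fewer channels with weaker gains, arm latencies
#' precede finger latencies, and purely visual conditions (`VrFP*`, `TP*`,
#' `Obj`) have gain 1 (no modulation). Defaults: 34 FPa channels (gain 3),
#' 13 BLa channels (subset, gain 2.5), 21 FPf channels (gain 2.5, mostly
#' overlapping FPa plus 2 finger-only channels on the second array),
#' 8 BLf channels (subset of FPf, gain 2); latencies FPa -25 ms, BLa 25 ms,
#' BLf 75 ms, FPf 125 ms.
#'
#' @param design A [make_task_design()] object (9 standard conditions).
#' @param n_channels Number of channels (default 96).
#' @param ... Passed on to [make_ground_truth()] (e.g. `noise_sd`).
#' @return A `ground_truth` object.
#' @export
paper_like_truth <- function(design, n_channels = 96L, ...) {
  stopifnot(all(c("FPa", "FPf", "BLa", "BLf") %in% design$conditions))
  if (n_channels < 64) {
    stop("paper_like_truth needs >= 64 channels for its channel sets",
         call. = FALSE)
  }
  conds <- design$conditions
  gain <- matrix(1, n_channels, length(conds), dimnames = list(NULL, conds))
  latency <- matrix(0.025, n_channels, length(conds))
  colnames(latency) <- conds

  fpa <- 1:34
  bla <- 1:13
  fpf <- c(14:32, 63:64)   # 19 overlapping arm channels + 2 finger-only on array 2
  blf <- 25:32
  gain[fpa, "FPa"] <- 3
  gain[bla, "BLa"] <- 2.5
  gain[fpf, "FPf"] <- 2.5
  gain[blf, "BLf"] <- 2
  latency[, "FPa"] <- -0.025
  latency[, "BLa"] <- 0.025
  latency[, "BLf"] <- 0.075
  latency[, "FPf"] <- 0.125

  make_ground_truth(design, n_channels = n_channels,
                    gain = gain, latency = latency, ...)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d channels, %d conditions\n",
              x$n_channels, length(x$conditions)))
  cat(sprintf("  planted tuned entries: %d (threshold gain > %g)\n",
              sum(x$tuned_mask), x$tuned_threshold))
  invisible(x)
}

#' Tidy the planted tuning structure of a ground truth
#'
#' @param x A `ground_truth`.
#' @param ... Unused.
#' @return A tibble with one row per channel x condition: gain, latency,
#'   decay, planted tuned flag.
#' @export
tidy.ground_truth <- function(x, ...) {
  tibble::tibble(
    channel = rep(seq_len(x$n_channels), times = length(x$conditions)),
    condition = rep(x$conditions, each = x$n_channels),
    gain = as.vector(x$gain),
    latency = as.vector(x$latency),
    decay_tau = as.vector(x$decay_tau),
    tuned = as.vector(x$tuned_mask)
  )
}
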