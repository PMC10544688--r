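#' Simulate a trial-structured multi-unit recording session
#'
#' Generates a session bundle of binned firing rates (channel x trial x bin)
#' with the planted structure declared in a [make_ground_truth()] object.
#' The noise-free rate of channel i on a trial of condition c is
#' \deqn{r_i(t) = b_i [1 + (g_{ic} - 1) k(t - l_{ic})]}
#' where b is the baseline rate, g the condition gain, l the latency and k a
#' rectangular-rise kernel that holds at 1 until touch offset and then decays
#' exponentially with time constant `decay_tau`. Each 50 ms bin receives the
#' exact time-average of the kernel over the bin, so fractional bin overlap
#' at onset is represented faithfully. Correlated Gaussian noise with the
#' declared channel covariance is added independently per bin, rates are
#' floored at 0, and counts can optionally be Poisson-resampled.
#'
#' Each run additionally carries one catch trial (flagged, drawn from a
#' different condition) which all analysis stages exclude. Conditions are
#' assigned to two collection "sets" mirroring the study's two epochs
#' (FP/TP/Obj in set 1, BL/VrFP in set 2). An optional `set2_drift` factor
#' scales the noise amplitude of set-2 trials to exercise the stability
#' checks; a uniform multiplicative gain drift would cancel exactly under
#' per-run baseline normalization, so noise-amplitude drift is the planted
#' instability the ITI checks can meaningfully detect.
#'
#' @param design A [make_task_design()] object.
#' @param truth A [make_ground_truth()] object with matching dimensions.
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @param poisson If `TRUE`, bin counts are Poisson-resampled around the
#'   noisy rate (default `FALSE`: Gaussian rates keep the covariance
#'   analytically checkable).
#' @param set2_drift Noise-amplitude factor applied to set-2 trials
#'   (default 1: no drift).
#' @return A list of class `simulated_session` with elements `bundle`
#'   (a `session_bundle`) and `truth` (the `ground_truth`, echoed).
#' @examples
#' d <- make_task_design(conditions = c("FPa", "BLa"), runs_per_condition = 2)
#' s <- simulate_session(d, make_ground_truth(d, n_channels = 8), seed = 1)
#' dim(s$bundle$rates)
#' @export
simulate_session <- function(design, truth, seed,
                             poisson = FALSE, set2_drift = 1) {
  stopifnot(inherits(design, "task_design"), inherits(truth, "ground_truth"))
  if (!identical(truth$conditions, design$conditions)) {
    stop("truth conditions must match design conditions", call. = FALSE)
  }
  conds <- design$conditions
  P <- truth$n_channels
  nb <- design$n_bins
  mids <- bin_midpoints(design)

  with_local_seed(seed, {
    trials <- build_trial_table(design)
    nt <- nrow(trials)

    # noise-free condition templates: channel x bin per condition
    templates <- lapply(seq_along(conds), function(ci) {
      K <- t(vapply(seq_len(P), function(ch) {
        kernel_bin_average(design$bin_edges,
                           latency = truth$latency[ch, ci],
                           touch_end = design$touch_duration,
                           tau = truth$decay_tau[ch, ci])
      }, numeric(nb)))
      truth$baseline_rate * (1 + (truth$gain[, ci] - 1) * K)
    })
    names(templates) <- conds

    # correlated Gaussian rate noise, iid across bins and trials
    noise <- if (all(truth$noise_cov == 0)) {
      matrix(0, nt * nb, P)
    } else {
      cs <- chol(truth$noise_cov + diag(1e-10 * mean(diag(truth$noise_cov)), P))
      matrix(stats::rnorm(nt * nb * P), nt * nb, P) %*% cs
    }

    rates <- array(0, dim = c(P, nt, nb))
    for (tr in seq_len(nt)) {
      nz <- t(noise[(tr - 1L) * nb + seq_len(nb), , drop = FALSE])
      if (trials$set[tr] == 2L && set2_drift != 1) nz <- nz * set2_drift
      rates[, tr, ] <- pmax(templates[[trials$condition[tr]]] + nz, 0)
    }
    if (poisson) {
      w <- design$bin_width
      rates[] <- stats::rpois(length(rates), lambda = rates * w) / w
    }

    bundle <- new_session_bundle(rates, design, trials, normalized = FALSE,
                                 seed = seed)
    structure(list(bundle = bundle, truth = truth),
              class = "simulated_session")
  })
}

# Exact time-average of the response kernel over each bin.
# Kernel: 0 before `latency`, 1 on [latency, touch_end), exponential decay
# exp(-(t - touch_end)/tau) afterwards.
kernel_bin_average <- function(bin_edges, latency, touch_end, tau) {
  a <- bin_edges[-length(bin_edges)]
  b <- bin_edges[-1]
  w <- b - a
  rect <- pmax(0, pmin(b, touch_end) - pmax(a, latency))
  lo <- pmax(a, touch_end)
  dec <- ifelse(b > touch_end & tau > 0,
                tau * (exp(-(pmax(lo, latency) - touch_end) / tau) -
                         exp(-(b - touch_end) / tau)),
                0)
  dec <- pmax(dec, 0)
  (rect + dec) / w
}

build_trial_table <- function(design) {
  conds <- design$conditions
  C <- length(conds)
  R <- design$runs_per_condition
  n_in_run <- design$trials_per_run + design$catch_per_run
  n_runs <- C * R
  # runs interleaved across conditions (condition-major is equivalent for all
  # analyses; fold bookkeeping uses the within-condition run index)
  run_rep <- rep(seq_len(R), each = C * n_in_run)
  ci <- rep(rep(seq_len(C), each = n_in_run), times = R)
  run_id <- rep(seq_len(n_runs), each = n_in_run)
  within_run <- rep(seq_len(n_in_run), times = n_runs)
  is_catch <- rep(FALSE, n_runs * n_in_run)
  if (design$catch_per_run > 0) {
    for (r in seq_len(n_runs)) {
      pos <- sample.int(n_in_run, design$catch_per_run)
      is_catch[(r - 1L) * n_in_run + pos] <- TRUE
    }
  }
  condition <- conds[ci]
  if (any(is_catch) && C > 1) {
    condition[is_catch] <- vapply(ci[is_catch], function(i)
      sample(setdiff(conds, conds[i]), 1), character(1))
  }
  jitter <- stats::runif(n_runs * n_in_run,
                         design$iti_jitter[1], design$iti_jitter[2])
  onset_time <- cumsum(design$iti + jitter) +
    (seq_len(n_runs * n_in_run) - 1) * (design$touch_duration + 1)
  tibble::tibble(
    trial_id = seq_len(n_runs * n_in_run),
    condition = condition,
    run_condition = conds[ci],
    run = run_rep,
    run_id = run_id,
    set = condition_set(conds[ci]),
    is_catch = is_catch,
    onset_time = onset_time
  )
}

condition_set <- function(condition) {
  ifelse(condition_touch_type(condition) %in% c("BL", "VrFP"), 2L, 1L)
}

#' @export
print.simulated_session <- function(x, ...) {
  cat("<simulated_session>\n")
  print(x$bundle)
  print(x$truth)
  invisible(x)
}
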