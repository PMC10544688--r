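#' Write a session bundle to a directory
#'
#' Plain-text bundle format: `metadata.json` (design fields, bin edges,
#' normalization flag, generating seed), `trials.csv` (one row per trial)
#' and `rates.csv` (long format: `channel`, `trial`, `bin`, `rate`). The
#' format round-trips losslessly through [read_session_bundle()]. Long-form
#' CSV is verbose for full-size sessions; it favours portability and
#' diff-ability over compactness.
#'
#' @param bundle A `session_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- bundle$design
  meta <- list(
    design = design[setdiff(names(design), c("bin_edges"))],
    normalized = bundle$normalized,
    seed = bundle$seed,
    bin_edges = bundle$bin_edges
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  d <- dim(bundle$rates)
  long <- data.frame(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    bin = rep(seq_len(d[3]), each = d[1] * d[2]),
    rate = as.vector(bundle$rates)
  )
  utils::write.csv(long, file.path(dir, "rates.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `session_bundle`.
#' @export
read_session_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  dsn <- meta$design
  design <- make_task_design(
    conditions = dsn$conditions,
    runs_per_condition = dsn$runs_per_condition,
    trials_per_run = dsn$trials_per_run,
    catch_per_run = dsn$catch_per_run,
    bin_width = dsn$bin_width,
    epoch = dsn$epoch,
    iti = dsn$iti,
    iti_jitter = dsn$iti_jitter,
    touch_duration = dsn$touch_duration,
    visual_lead = dsn$visual_lead,
    baseline_window = dsn$baseline_window,
    analysis_window = dsn$analysis_window
  )
  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv"),
                                              stringsAsFactors = FALSE))
  long <- utils::read.csv(file.path(dir, "rates.csv"))
  nc <- max(long$channel); nt <- max(long$trial); nb <- max(long$bin)
  rates <- array(NA_real_, dim = c(nc, nt, nb))
  rates[cbind(long$channel, long$trial, long$bin)] <- long$rate
  new_session_bundle(rates, design, trials,
                     normalized = isTRUE(meta$normalized), seed = meta$seed)
}
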