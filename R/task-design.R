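#' Condition codes of the visuotactile touch task
#'
#' Nine conditions crossing touch type and body location: seen physical touch
#' (`FPa`, `FPf`), blindfolded physical touch (`BLa`, `BLf`), virtual-reality
#' visual-only touch (`VrFPa`, `VrFPf`), observed third-person touch
#' (`TPa`, `TPf`) and observed object touch (`Obj`). Suffix `a` = arm,
#' `f` = finger.
#'
#' @format Character vector of length 9.
#' @export
touch_conditions <- c("FPa", "FPf", "BLa", "BLf",
                      "VrFPa", "VrFPf", "TPa", "TPf", "Obj")

#' Look up the body location of a condition code
#'
#' @param condition Character vector of condition codes.
#' @return Character vector: `"arm"`, `"finger"` or `"object"`.
#' @export
condition_location <- function(condition) {
  dplyr::case_when(
    condition == "Obj" ~ "object",
    grepl("a$", condition) ~ "arm",
    grepl("f$", condition) ~ "finger",
    TRUE ~ NA_character_
  )
}

#' Look up the touch type of a condition code
#'
#' @param condition Character vector of condition codes.
#' @return Character vector: `"FP"`, `"BL"`, `"VrFP"`, `"TP"` or `"Obj"`.
#' @export
condition_touch_type <- function(condition) {
  sub("[af]$", "", condition)
}

#' Construct a task design
#'
#' Describes the trial structure of a recording session: the condition set,
#' run/trial counts, the bin grid and the epoch around touch onset. Defaults
#' reproduce the study design: 9 conditions, 7 runs of 10 analyzable trials
#' plus 1 catch trial each, 50 ms bins over an epoch of \[-4, +2\] s around
#' touch onset, an inter-trial interval of 5 s with 0-3 s jitter, a 1 s touch
#' and, in visually cued conditions, approach information starting ~0.5 s
#' before contact.
#'
#' The epoch must contain both the baseline window \[-4, -2.5\] s and the
#' analysis window \[-1, +2\] s, and the bin width must divide the epoch into
#' whole bins with a bin boundary at t = 0.
#'
#' @param ... Named overrides for any design field: `conditions`,
#'   `runs_per_condition`, `trials_per_run`, `catch_per_run`, `bin_width`,
#'   `epoch` (length-2 numeric, seconds relative to touch onset), `iti`,
#'   `iti_jitter` (length-2 range), `touch_duration`, `visual_lead`,
#'   `baseline_window`, `analysis_window`.
#' @return A `task_design` object (a list with the fields above plus
#'   `n_bins` and `bin_edges`).
#' @examples
#' d <- make_task_design()
#' d$n_bins                       # 120
#' length(d$conditions)           # 9
#' make_task_design(bin_width = 0.1, epoch = c(-2, 2))$n_bins
#' @export
make_task_design <- function(...) {
  design <- list(
    conditions = touch_conditions,
    runs_per_condition = 7L,
    trials_per_run = 10L,
    catch_per_run = 1L,
    bin_width = 0.05,
    epoch = c(-4, 2),
    iti = 5,
    iti_jitter = c(0, 3),
    touch_duration = 1,
    visual_lead = 0.5,
    baseline_window = c(-4, -2.5),
    analysis_window = c(-1, 2)
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all design overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(design))
    if (length(unknown)) {
      stop("unknown design field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    design[names(overrides)] <- overrides
    # default windows follow a user-shrunk epoch
    clip <- function(w) c(max(w[1], design$epoch[1]), min(w[2], design$epoch[2]))
    if (!"baseline_window" %in% names(overrides)) {
      design$baseline_window <- clip(design$baseline_window)
    }
    if (!"analysis_window" %in% names(overrides)) {
      design$analysis_window <- clip(design$analysis_window)
    }
  }
  validate_task_design(structure(design, class = "task_design"))
}

validate_task_design <- function(design) {
  with(design, {
    if (anyDuplicated(conditions)) stop("conditions must be unique", call. = FALSE)
    if (length(conditions) < 1) stop("at least one condition required", call. = FALSE)
    if (trials_per_run < 1) stop("trials_per_run must be >= 1", call. = FALSE)
    if (runs_per_condition < 1) stop("runs_per_condition must be >= 1", call. = FALSE)
    if (catch_per_run < 0) stop("catch_per_run must be >= 0", call. = FALSE)
    if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
    if (length(epoch) != 2 || epoch[2] <= epoch[1]) {
      stop("epoch must be an increasing length-2 window", call. = FALSE)
    }
    n_bins <- (epoch[2] - epoch[1]) / bin_width
    if (abs(n_bins - round(n_bins)) > 1e-9) {
      stop("bin_width must divide the epoch into whole bins", call. = FALSE)
    }
    # a bin boundary must fall exactly at touch onset (t = 0)
    k0 <- -epoch[1] / bin_width
    if (abs(k0 - round(k0)) > 1e-9) {
      stop("a bin boundary must fall at t = 0", call. = FALSE)
    }
    if (baseline_window[2] <= baseline_window[1] ||
        epoch[1] > baseline_window[1] || epoch[2] < baseline_window[2]) {
      stop("epoch must contain a nonempty baseline window", call. = FALSE)
    }
    if (analysis_window[2] <= analysis_window[1] ||
        epoch[1] > analysis_window[1] || epoch[2] < analysis_window[2]) {
      stop("epoch must contain a nonempty analysis window", call. = FALSE)
    }
  })
  design$n_bins <- as.integer(round((design$epoch[2] - design$epoch[1]) / design$bin_width))
  design$bin_edges <- design$epoch[1] + design$bin_width * seq(0, design$n_bins)
  design
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design>\n")
  cat("  conditions:", paste(x$conditions, collapse = " "), "\n")
  cat(sprintf("  %d runs x %d trials (+%d catch) per condition\n",
              x$runs_per_condition, x$trials_per_run, x$catch_per_run))
  cat(sprintf("  epoch [%g, %g] s, %d bins of %g s\n",
              x$epoch[1], x$epoch[2], x$n_bins, x$bin_width))
  invisible(x)
}

#' Total number of analyzable (non-catch) trials in a design
#'
#' @param design A `task_design`.
#' @return Integer count.
#' @export
n_analyzable_trials <- function(design) {
  length(design$conditions) * design$runs_per_condition * design$trials_per_run
}

#' Bin midpoints of a design's grid
#'
#' @param design A `task_design`.
#' @return Numeric vector of bin centres (seconds relative to touch onset).
#' @export
bin_midpoints <- function(design) {
  design$bin_edges[-length(design$bin_edges)] + design$bin_width / 2
}
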