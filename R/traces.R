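#' Baseline- and vehicle-normalize kinetic traces
#'
#' Two-step normalization used for NanoBiT/BRET kinetic reads: each well is
#' first divided by its own pre-agonist baseline mean, then by the mean
#' baseline-normalized vehicle signal at the matching time point (a serial
#' record, not a scalar). A vehicle trace processed against itself and
#' identical peers is 1.0 everywhere.
#'
#' Wells whose baseline mean is not positive are flagged and excluded with a
#' warning rather than aborting the run.
#'
#' @param traces Long tibble with columns `well`, `time_min`, `channel`,
#'   `signal`, `is_vehicle` and optionally `block` (vehicle matching is done
#'   within block when present).
#' @param baseline_duration Minutes of pre-agonist reads defining the
#'   baseline window (`time_min < baseline_duration`).
#' @return The input tibble with `signal` replaced by the normalized signal;
#'   flagged wells removed.
#' @export
normalize_trace <- function(traces, baseline_duration) {
  req <- c("well", "time_min", "channel", "signal", "is_vehicle")
  if (!all(req %in% names(traces))) {
    abort(paste("`traces` must have columns:", paste(req, collapse = ", ")))
  }
  grp <- intersect(c("block", "receptor", "channel"), names(traces))

  # identical timebase across wells within each channel
  tb <- traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("well", "channel")))) |>
    dplyr::summarise(key = paste(signif(.data$time_min, 10), collapse = ","),
                     .groups = "drop")
  if (length(unique(tb$key)) > 1) abort("Wells have mismatched timebases.")

  base <- traces |>
    dplyr::filter(.data$time_min < baseline_duration) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("well", "channel")))) |>
    dplyr::summarise(baseline_mean = mean(.data$signal), .groups = "drop")
  if (nrow(base) == 0) abort("No reads fall inside the baseline window.")

  bad <- base$well[base$baseline_mean <= 0]
  if (length(bad) > 0) {
    warn(paste0("Excluding wells with non-positive baseline: ",
                paste(unique(bad), collapse = ", ")))
  }
  out <- traces |>
    dplyr::inner_join(dplyr::filter(base, .data$baseline_mean > 0),
                      by = c("well", "channel")) |>
    dplyr::mutate(signal = .data$signal / .data$baseline_mean)

  veh <- out |>
    dplyr::filter(.data$is_vehicle) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "time_min")))) |>
    dplyr::summarise(vehicle_mean = mean(.data$signal), .groups = "drop")
  if (nrow(veh) == 0) abort("No vehicle wells available for normalization.")

  out |>
    dplyr::inner_join(veh, by = c(grp, "time_min")) |>
    dplyr::mutate(signal = .data$signal / .data$vehicle_mean) |>
    dplyr::select(-"baseline_mean", -"vehicle_mean")
}

#' Ratiometric channel combination with optional blank subtraction
#'
#' Computes, per time point, (numerator - blank_num) / (denominator -
#' blank_den), the BRET 575/460 or DERET 620/520 convention; DERET blanks are
#' the fluorescein-only well constants. Points where the blank-subtracted
#' denominator is not positive are masked (set `NA`) with a warning instead of
#' discarding the well.
#'
#' @param traces Long tibble with two channels per well.
#' @param numerator,denominator Channel labels.
#' @param blank Named per-channel constants to subtract (default none).
#' @return Single-channel tibble (`channel = "ratio"`), annotations preserved.
#' @export
ratiometric <- function(traces, numerator = "num", denominator = "den",
                        blank = NULL) {
  chans <- unique(traces$channel)
  if (!all(c(numerator, denominator) %in% chans)) {
    abort("Both `numerator` and `denominator` channels must be present.")
  }
  b_num <- if (is.null(blank)) 0 else blank[[numerator]] %||% 0
  b_den <- if (is.null(blank)) 0 else blank[[denominator]] %||% 0

  keys <- setdiff(names(traces), c("channel", "signal"))
  wide <- traces |>
    dplyr::filter(.data$channel %in% c(numerator, denominator)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(keys),
                       names_from = "channel", values_from = "signal")
  den <- wide[[denominator]] - b_den
  num <- wide[[numerator]] - b_num
  masked <- den <= 0
  if (any(masked)) {
    warn(sprintf("Masking %d time point(s) with non-positive denominator.",
                 sum(masked)))
    den[masked] <- NA_real_
  }
  wide$channel <- "ratio"
  wide$signal <- num / den
  dplyr::select(wide, dplyr::all_of(c(keys, "channel", "signal")))
}

trapz <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Trapezoidal area under kinetic traces
#'
#' Integrates each well's signal over the post-agonist window
#' (`time_min >= baseline_duration`) on the native time grid. With
#' `baseline_correct = TRUE` the well's baseline mean (reads before
#' `baseline_duration`) is subtracted from the series before integrating.
#'
#' @param traces Long tibble of kinetic reads.
#' @param baseline_correct Subtract the baseline mean before integrating?
#' @param baseline_duration Minutes of baseline; 0 integrates the full trace
#'   (and leaves nothing to correct against).
#' @return One row per (well, channel) with column `auc` plus any constant
#'   per-well annotation columns.
#' @export
trace_auc <- function(traces, baseline_correct = FALSE, baseline_duration = 0) {
  ann <- intersect(c("receptor", "ligand", "conc_M", "is_vehicle", "block"),
                   names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("well", "channel", ann)))) |>
    dplyr::summarise(
      auc = {
        post <- .data$time_min >= baseline_duration
        if (sum(post) < 2) abort("AUC needs at least two post-agonist reads.")
        base <- if (baseline_correct && any(!post)) {
          mean(.data$signal[!post])
        } else 0
        trapz(.data$time_min[post], .data$signal[post] - base)
      },
      .groups = "drop"
    )
}

#' Half-time of a rising response
#'
#' First time (minutes after agonist addition) at which the signal crosses
#' halfway between baseline and peak, by linear interpolation between the
#' bracketing samples. Traces with no peak above baseline return `NA` (a
#' missing half-time, not an error). `method = "fit"` instead fits a
#' one-phase association `baseline + span (1 - e^{-kt})` and reports
#' `log(2)/k`.
#'
#' @param traces Long tibble of kinetic reads.
#' @param baseline_duration Minutes of pre-agonist baseline; the baseline
#'   level is the mean over this window (first read if the window is empty)
#'   and times are measured from the end of the window.
#' @param method `"interpolate"` (default, assumption-free) or `"fit"`.
#' @return One row per (well, channel) with column `t_half` (min) plus
#'   annotations.
#' @export
response_t_half <- function(traces, baseline_duration = 0,
                            method = c("interpolate", "fit")) {
  method <- match.arg(method)
  ann <- intersect(c("receptor", "ligand", "conc_M", "is_vehicle", "block"),
                   names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("well", "channel", ann)))) |>
    dplyr::summarise(
      t_half = t_half_one(.data$time_min, .data$signal, baseline_duration,
                          method),
      .groups = "drop"
    )
}

t_half_one <- function(time_min, signal, baseline_duration, method) {
  pre <- time_min < baseline_duration
  baseline <- if (any(pre)) mean(signal[pre]) else signal[1]
  t <- time_min[!pre] - baseline_duration
  y <- signal[!pre]
  peak <- max(y)
  span <- peak - baseline
  if (!is.finite(span) || span <= 0 ||
      isTRUE(all.equal(peak, baseline, tolerance = 1e-12))) {
    return(NA_real_)
  }
  if (method == "fit") {
    fit <- try(minpack.lm::nlsLM(
      y ~ baseline + span_p * (1 - exp(-k * t)),
      start = list(span_p = span, k = log(2) / max(t[which(y >= baseline + span / 2)][1], 1e-6)),
      lower = c(0, 1e-8), upper = c(Inf, Inf),
      data = data.frame(t = t, y = y)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    return(log(2) / coef(fit)[["k"]])
  }
  half <- baseline + span / 2
  above <- which(y >= half)
  i <- above[1]
  if (i == 1) return(t[1])
  # linear interpolation between the bracketing samples
  t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Normalize endpoint responses to a per-block control condition
#'
#' Divides each response by its block's control-condition mean: forskolin
#' normalization for cAMP (`mode = "percent"`, control maps to 100),
#' fold-of-unstimulated for ERK HTRF ratios, or fold-of-glucose-only for
#' insulin secretion (`mode = "fold"`, control maps to 1). Blocks whose
#' control mean is not positive are excluded with a warning.
#'
#' @param responses Tibble with columns `condition`, `response` and
#'   optionally `block`.
#' @param control Condition label of the control wells.
#' @param mode `"fold"` (control = 1) or `"percent"` (control = 100).
#' @return Input tibble with `response` replaced by the normalized value.
#' @export
normalize_to_control <- function(responses, control,
                                 mode = c("fold", "percent")) {
  mode <- match.arg(mode)
  if (!all(c("condition", "response") %in% names(responses))) {
    abort("`responses` must have columns `condition` and `response`.")
  }
  grp <- intersect("block", names(responses))
  ctl <- responses |>
    dplyr::filter(.data$condition == control) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(control_mean = mean(.data$response), .groups = "drop")
  if (nrow(ctl) == 0) abort("Control condition absent from `responses`.")
  bad <- ctl$control_mean <= 0
  if (any(bad)) {
    warn(sprintf("Excluding %d block(s) with non-positive control mean.",
                 sum(bad)))
    ctl <- ctl[!bad, , drop = FALSE]
  }
  scale <- if (mode == "percent") 100 else 1
  joined <- if (length(grp) > 0) {
    dplyr::inner_join(responses, ctl, by = grp)
  } else {
    dplyr::cross_join(responses, ctl)
  }
  joined |>
    dplyr::mutate(response = scale * .data$response / .data$control_mean) |>
    dplyr::select(-"control_mean")
}

#' Relative expression by the 2^-dCt method
#'
#' @param ct_target,ct_reference Threshold cycles for the target gene and the
#'   endogenous control gene (e.g. 18S). Missing Ct gives missing output.
#' @return `2^-(ct_target - ct_reference)`, vectorized.
#' @export
delta_ct_expression <- function(ct_target, ct_reference) {
  2^-(ct_target - ct_reference)
}
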