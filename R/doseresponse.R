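#' Fit a 3- or 4-parameter logistic concentration–response curve
#'
#' Least-squares fit of `basal + (e_max - basal) / (1 + 10^(hill (log_ec50 -
#' log10 A)))` performed on the log10-concentration scale. The 3-parameter
#' model fixes the Hill slope at 1; when vehicle (0 M) rows are present they
#' are excluded from the fit and instead anchor `basal` at the vehicle mean.
#' The 4-parameter model fits all four parameters with the Hill slope bounded
#' in (0.1, 5).
#'
#' When a `block` column is present each replicate block is also fitted
#' separately and the per-parameter mean ± SEM across blocks is reported, the
#' convention used for plate-reader parameter tables.
#'
#' @param data Tibble with columns `conc_M`, `response` and optionally
#'   `block`; vehicle rows have `conc_M = 0`.
#' @param n_params 3 or 4.
#' @return An object of class `"logistic_fit"`; see [tidy()], [glance()],
#'   [summarize_fits()], [autoplot()].
#' @export
fit_logistic <- function(data, n_params = 4) {
  stopifnot(n_params %in% c(3, 4))
  if (!all(c("conc_M", "response") %in% names(data))) {
    abort("`data` must have columns `conc_M` and `response`.")
  }
  if (any(!is.finite(data$response))) abort("Responses must be finite.")
  if (any(data$conc_M < 0)) abort("Concentrations must be non-negative.")
  n_conc <- length(unique(data$conc_M[data$conc_M > 0]))
  need <- if (n_params == 3) 4 else 5
  if (n_conc < need) {
    abort(sprintf("%d-parameter fits need >= %d distinct concentrations.",
                  n_params, need))
  }

  pooled <- fit_logistic_one(data$conc_M, data$response, n_params)

  per_block <- NULL
  if ("block" %in% names(data) && length(unique(data$block)) > 1) {
    per_block <- data |>
      dplyr::group_by(.data$block) |>
      dplyr::group_modify(function(d, key) {
        f <- fit_logistic_one(d$conc_M, d$response, n_params)
        tibble(basal = f$basal, e_max = f$e_max, log_ec50 = f$log_ec50,
               hill = f$hill, converged = f$converged, flag = f$flag)
      }) |>
      dplyr::ungroup()
  }

  structure(
    list(pooled = pooled, per_block = per_block, n_params = n_params,
         data = as_tibble(data)),
    class = "logistic_fit"
  )
}

# single logistic least-squares fit; returns a plain list
fit_logistic_one <- function(conc, resp, n_params) {
  veh <- conc == 0
  basal_fix <- NULL
  if (n_params == 3 && any(veh)) basal_fix <- mean(resp[veh])
  conc_f <- conc[!veh]
  resp_f <- resp[!veh]
  lc <- log10(conc_f)

  span <- diff(range(resp_f))
  scale <- max(abs(resp_f), 1e-12)
  if (span <= 1e-8 * scale) {
    b <- basal_fix %||% mean(resp_f)
    return(list(basal = b, e_max = b, log_ec50 = NA_real_,
                hill = if (n_params == 3) 1 else NA_real_,
                sigma = 0, converged = TRUE, flag = "unidentifiable"))
  }

  basal0 <- basal_fix %||% min(resp_f)
  emax0 <- max(resp_f)
  lec0 <- half_crossing(lc, resp_f, basal0, emax0)
  free_hill <- n_params == 4
  free_basal <- is.null(basal_fix)

  obj <- function(p) {
    i <- 0
    basal <- if (free_basal) p[i <- i + 1] else basal_fix
    e_max <- p[i <- i + 1]
    lec <- p[i <- i + 1]
    hill <- if (free_hill) p[i + 1] else 1
    pred <- basal + (e_max - basal) / (1 + 10^(hill * (lec - lc)))
    sum((resp_f - pred)^2)
  }
  lo_r <- min(resp_f); hi_r <- max(resp_f)
  lower <- c(if (free_basal) lo_r - span, lo_r, min(lc) - 3,
             if (free_hill) 0.1)
  upper <- c(if (free_basal) hi_r, hi_r + 2 * span, max(lc) + 3,
             if (free_hill) 5)
  starts <- list(c(if (free_basal) basal0, emax0, lec0, if (free_hill) 1))
  for (h in c(0.5, 2)) {
    for (dl in c(-1, 1)) {
      starts <- c(starts, list(c(if (free_basal) basal0, emax0, lec0 + dl,
                                 if (free_hill) h)))
    }
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    ans <- try(optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500, factr = 1e1)), silent = TRUE)
    if (inherits(ans, "try-error")) next
    if (is.null(best) || ans$value < best$value) best <- ans
    if (!is.null(best) && best$value < 1e-20 * scale^2) break
  }
  if (is.null(best)) {
    return(list(basal = NA_real_, e_max = NA_real_, log_ec50 = NA_real_,
                hill = NA_real_, sigma = NA_real_, converged = FALSE,
                flag = "non-convergence"))
  }
  p <- best$par
  i <- 0
  basal <- if (free_basal) p[i <- i + 1] else basal_fix
  e_max <- p[i <- i + 1]
  lec <- p[i <- i + 1]
  hill <- if (free_hill) p[i + 1] else 1
  dof <- max(length(resp_f) - length(p), 1)
  sigma <- sqrt(best$value / dof)
  flag <- if ((e_max - basal) < 2 * sigma) "unidentifiable" else NA_character_
  list(basal = basal, e_max = e_max, log_ec50 = lec, hill = hill,
       sigma = sigma, converged = best$convergence == 0, flag = flag)
}

# interpolated log-concentration at which the response crosses halfway
half_crossing <- function(lc, resp, basal, emax) {
  o <- order(lc)
  lc <- lc[o]; resp <- resp[o]
  m <- tapply(resp, lc, mean)
  u <- as.numeric(names(m))
  half <- (basal + emax) / 2
  above <- which(m >= half)
  if (length(above) == 0 || above[1] == 1) return(stats::median(u))
  i <- above[1]
  unname(u[i - 1] + (half - m[i - 1]) / (m[i] - m[i - 1]) * (u[i] - u[i - 1]))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("%d-parameter logistic fit\n", x$n_params))
  p <- x$pooled
  cat(sprintf("  basal %.4g  e_max %.4g  logEC50 %.4g  hill %.4g\n",
              p$basal, p$e_max, p$log_ec50, p$hill))
  if (!is.null(x$per_block)) {
    cat(sprintf("  %d replicate blocks (see summarize_fits())\n",
                nrow(x$per_block)))
  }
  if (!is.na(p$flag)) cat("  flag:", p$flag, "\n")
  invisible(x)
}

#' @rdname fit_logistic
#' @param x,object A `logistic_fit`.
#' @param ... Unused.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  p <- x$pooled
  tibble(
    term = c("basal", "e_max", "log_ec50", "hill"),
    estimate = c(p$basal, p$e_max, p$log_ec50, p$hill)
  )
}

#' @rdname fit_logistic
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  p <- x$pooled
  tibble(
    n_params = x$n_params, sigma = p$sigma, converged = p$converged,
    flag = p$flag,
    n_blocks = if (is.null(x$per_block)) 1L else nrow(x$per_block),
    n_obs = nrow(x$data)
  )
}

#' Mean ± SEM parameter summaries across replicate blocks
#'
#' Summarizes per-block logistic parameter estimates as mean ± SEM with the
#' block count, the convention of per-replicate parameter tables. With a
#' single block the mean is returned and the SEM is missing.
#'
#' @param fits A `logistic_fit` (with per-block fits) or a tibble of
#'   per-block estimates with one column per parameter and one row per block.
#' @return Tibble with columns `parameter`, `mean`, `sem`, `n_blocks`.
#' @export
summarize_fits <- function(fits) {
  tbl <- if (inherits(fits, "logistic_fit")) {
    if (is.null(fits$per_block)) {
      p <- fits$pooled
      tibble(basal = p$basal, e_max = p$e_max,
             log_ec50 = p$log_ec50, hill = p$hill)
    } else {
      fits$per_block
    }
  } else {
    as_tibble(fits)
  }
  params <- intersect(c("basal", "e_max", "log_ec50", "hill"), names(tbl))
  tbl |>
    dplyr::select(dplyr::all_of(params)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value), sem = sem(.data$value),
      n_blocks = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, params))
}

#' Assemble an AUC-based concentration–response table from kinetic traces
#'
#' The PKA-FRET style endpoint: each well's signal is first normalized to its
#' own baseline mean, the trapezoidal AUC over the post-agonist window is
#' computed, and each well's AUC is expressed as a fold of the mean vehicle
#' AUC within its block. Vehicle wells therefore map to 1.0 by construction,
#' and the table is ready for `fit_logistic(n_params = 3)`. Blocks lacking a
#' vehicle well are excluded with a warning.
#'
#' @param traces Long tibble of kinetic reads annotated with `ligand`,
#'   `conc_M`, `is_vehicle`, `block`.
#' @param baseline_duration Minutes of pre-agonist baseline.
#' @return Tibble with columns `ligand`, `conc_M`, `response`, `block`.
#' @export
auc_concentration_response <- function(traces, baseline_duration) {
  req <- c("well", "time_min", "channel", "signal", "conc_M", "is_vehicle",
           "block")
  if (!all(req %in% names(traces))) {
    abort(paste("`traces` must have columns:", paste(req, collapse = ", ")))
  }
  base <- traces |>
    dplyr::filter(.data$time_min < baseline_duration) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("well", "channel")))) |>
    dplyr::summarise(baseline_mean = mean(.data$signal), .groups = "drop")
  normed <- traces |>
    dplyr::inner_join(dplyr::filter(base, .data$baseline_mean > 0),
                      by = c("well", "channel")) |>
    dplyr::mutate(signal = .data$signal / .data$baseline_mean) |>
    dplyr::select(-"baseline_mean")
  aucs <- trace_auc(normed, baseline_correct = FALSE,
                    baseline_duration = baseline_duration)

  veh <- aucs |>
    dplyr::filter(.data$is_vehicle) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(vehicle_auc = mean(.data$auc), .groups = "drop")
  missing_blocks <- setdiff(unique(aucs$block), veh$block)
  if (length(missing_blocks) > 0) {
    warn(paste0("Excluding block(s) without vehicle wells: ",
                paste(missing_blocks, collapse = ", ")))
  }
  aucs |>
    dplyr::inner_join(veh, by = "block") |>
    dplyr::mutate(response = .data$auc / .data$vehicle_auc) |>
    dplyr::select(dplyr::any_of(c("ligand", "conc_M", "response", "block",
                                  "is_vehicle", "well")))
}
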