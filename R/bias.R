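#' Global operational-model fit for one pathway and one assay replicate
#'
#' Least-squares fit of the Black–Leff operational model (see
#' [operational_response()]) to concentration–response data for one or more
#' ligands measured in the same assay: the system parameters `Em`, `n_hill`
#' and `basal` are shared across ligands while `(log_tau, log_KA)` are
#' estimated per ligand. The derived transduction coefficient
#' `log_R = log_tau - log_KA` is returned per ligand with a standard error
#' from the fit's local covariance (Jacobian-based, pseudo-inverted so that
#' weakly identified directions inflate rather than crash the error).
#'
#' For a full agonist `Em` and `tau` trade off along a near-flat ridge, so
#' absolute `log_R` values are only anchored when `Em` is supplied; the
#' within-assay differences `delta_log_r()` used for bias quantification are
#' ridge-invariant and need no anchor. Ligands with no detectable response
#' above basal are flagged `weak` and carry very wide `log_R` errors — the
#' known limitation of transduction-coefficient bias estimation for extremely
#' weak partial agonists.
#'
#' @param data Tibble with columns `ligand`, `conc_M`, `response`, all from
#'   one pathway and one replicate block. Vehicle rows (`conc_M = 0`) help
#'   anchor `basal`.
#' @param Em,n_hill,basal Optional fixed values for the shared system
#'   parameters; `NULL` (default) estimates them. `n_hill` is bounded in
#'   (0.3, 3) when estimated.
#' @param n_starts Extra jittered starts tried when the first optimization
#'   stalls.
#' @return Object of class `"operational_fit"` with methods [tidy()]
#'   (per-ligand estimates), [glance()] (shared parameters and diagnostics)
#'   and [autoplot()].
#' @export
fit_operational <- function(data, Em = NULL, n_hill = NULL, basal = NULL,
                            n_starts = 4) {
  if (!all(c("ligand", "conc_M", "response") %in% names(data))) {
    abort("`data` must have columns `ligand`, `conc_M`, `response`.")
  }
  ligands <- unique(data$ligand)
  for (lg in ligands) {
    if (length(unique(data$conc_M[data$ligand == lg & data$conc_M > 0])) < 5) {
      abort(sprintf("Ligand '%s' has fewer than 5 distinct concentrations.", lg))
    }
  }
  conc <- data$conc_M
  resp <- data$response
  lig_idx <- match(data$ligand, ligands)
  nlig <- length(ligands)

  max_r <- max(resp); min_r <- min(resp); span <- max(max_r - min_r, 1e-12)
  free_Em <- is.null(Em); free_n <- is.null(n_hill); free_b <- is.null(basal)

  # per-ligand data heuristics for initialization
  m_i <- vapply(ligands, function(lg) max(resp[data$ligand == lg]), 0,
                USE.NAMES = FALSE)
  basal0 <- basal %||% min_r
  Em0 <- Em %||% (max_r + 0.1 * span)
  tau0 <- pmin(pmax((m_i - basal0) / pmax(Em0 - m_i, 0.01 * span), 1e-3), 1e3)
  lec0 <- vapply(ligands, function(lg) {
    sel <- data$ligand == lg & data$conc_M > 0
    half_crossing(log10(conc[sel]), resp[sel], basal0, max(resp[sel]))
  }, 0, USE.NAMES = FALSE)
  lKA0 <- lec0 + log10(1 + tau0)

  unpack <- function(p) {
    i <- 0
    list(
      Em = if (free_Em) p[i <- i + 1] else Em,
      n = if (free_n) p[i <- i + 1] else n_hill,
      basal = if (free_b) p[i <- i + 1] else basal,
      log_tau = p[i + seq_len(nlig)],
      log_KA = p[i + nlig + seq_len(nlig)]
    )
  }
  resid_fun <- function(p) {
    q <- unpack(p)
    tau <- 10^q$log_tau[lig_idx]
    KA <- 10^q$log_KA[lig_idx]
    num <- (tau * conc)^q$n
    pred <- q$basal + (q$Em - q$basal) * num / ((conc + KA)^q$n + num)
    resp - pred
  }
  obj <- function(p) sum(resid_fun(p)^2)

  lower <- c(if (free_Em) max_r + 1e-4 * span, if (free_n) 0.3,
             if (free_b) min_r - 0.5 * span,
             rep(-6, nlig), rep(-14, nlig))
  upper <- c(if (free_Em) max_r + 20 * span, if (free_n) 3,
             if (free_b) min_r + 0.5 * span,
             rep(6, nlig), rep(-3, nlig))
  start0 <- c(if (free_Em) Em0, if (free_n) 1, if (free_b) basal0,
              log10(tau0), lKA0)
  start0 <- pmin(pmax(start0, lower), upper)

  run_opt <- function(s, factr = 1e7) {
    try(optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 1000, factr = factr)), silent = TRUE)
  }
  best <- run_opt(start0)
  if (inherits(best, "try-error")) best <- NULL
  tol <- 1e-12 * max(span^2, 1)
  if (is.null(best) || best$convergence != 0 || best$value > 0.5 * span^2) {
    # multi-start with jittered efficacy/affinity initializations
    jit <- withr::with_seed(1L, replicate(n_starts, {
      start0 + c(rep(0, length(start0) - 2 * nlig),
                 stats::runif(nlig, -1, 1), stats::runif(nlig, -1, 1))
    }, simplify = FALSE))
    for (s in jit) {
      s <- pmin(pmax(s, lower), upper)
      ans <- run_opt(s)
      if (inherits(ans, "try-error")) next
      if (is.null(best) || ans$value < best$value) best <- ans
      if (best$value < tol) break
    }
  }
  if (is.null(best)) abort("Operational fit failed to converge from any start.")
  if (best$value < 1e-6 * span^2) {
    # essentially noise-free data: polish to closed-form precision
    polished <- run_opt(best$par, factr = 1e1)
    if (!inherits(polished, "try-error") && polished$value <= best$value) {
      best <- polished
    }
  }

  q <- unpack(best$par)
  nfree <- length(best$par)
  dof <- max(length(resp) - nfree, 1)
  sigma <- sqrt(best$value / dof)

  # local covariance from the residual Jacobian, pseudo-inverted
  J <- num_jacobian(resid_fun, best$par)
  covm <- sigma^2 * pseudo_solve(crossprod(J))
  i0 <- nfree - 2 * nlig
  se_log_R <- vapply(seq_len(nlig), function(k) {
    it <- i0 + k; ik <- i0 + nlig + k
    v <- covm[it, it] + covm[ik, ik] - 2 * covm[it, ik]
    sqrt(max(v, 0))
  }, 0)

  weak <- (m_i - q$basal) < 3 * sigma
  obs <- operational_observed(q$Em, q$log_tau, q$log_KA, q$n, q$basal)

  structure(
    list(
      estimates = tibble(
        ligand = ligands, log_tau = q$log_tau, log_KA = q$log_KA,
        log_R = q$log_tau - q$log_KA, se_log_R = se_log_R,
        emax_obs = obs$emax_obs, ec50_obs = obs$ec50_obs, weak = weak
      ),
      shared = tibble(Em = q$Em, n_hill = q$n, basal = q$basal,
                      Em_fixed = !free_Em, n_fixed = !free_n,
                      basal_fixed = !free_b),
      sse = best$value, sigma = sigma, converged = best$convergence == 0,
      data = as_tibble(data)
    ),
    class = "operational_fit"
  )
}

num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pp <- p; pp[j] <- pp[j] + h
    pm <- p; pm[j] <- pm[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  J
}

# pseudo-inverse via SVD; near-singular directions get very large variance
pseudo_solve <- function(A, rcond = 1e-10) {
  s <- svd(A)
  d <- ifelse(s$d > rcond * max(s$d), 1 / s$d, 1 / (rcond * max(s$d)))
  s$v %*% (d * t(s$u))
}

#' @export
print.operational_fit <- function(x, ...) {
  cat("Operational-model fit:", nrow(x$estimates), "ligand(s)\n")
  cat(sprintf("  shared: Em %.4g, n_hill %.3g, basal %.4g (sigma %.3g)\n",
              x$shared$Em, x$shared$n_hill, x$shared$basal, x$sigma))
  print(x$estimates)
  invisible(x)
}

#' @rdname fit_operational
#' @param x,object An `operational_fit`.
#' @param ... Unused.
#' @method tidy operational_fit
#' @export
tidy.operational_fit <- function(x, ...) x$estimates

#' @rdname fit_operational
#' @method glance operational_fit
#' @export
glance.operational_fit <- function(x, ...) {
  dplyr::bind_cols(x$shared,
                   tibble(sse = x$sse, sigma = x$sigma,
                          converged = x$converged, n_obs = nrow(x$data)))
}

#' Per-block operational fits across pathways
#'
#' Runs [fit_operational()] independently for every (pathway, block)
#' combination and stacks the per-ligand estimates, ready for
#' [delta_log_r()].
#'
#' @param data Tibble with columns `ligand`, `pathway`, `conc_M`, `response`,
#'   `block`.
#' @inheritParams fit_operational
#' @return Tibble with one row per (pathway, block, ligand): `log_R`,
#'   `se_log_R`, `weak`, `converged`.
#' @export
fit_operational_blocks <- function(data, Em = NULL, n_hill = NULL,
                                   basal = NULL) {
  req <- c("ligand", "pathway", "conc_M", "response", "block")
  if (!all(req %in% names(data))) {
    abort(paste("`data` must have columns:", paste(req, collapse = ", ")))
  }
  data |>
    dplyr::group_by(.data$pathway, .data$block) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_operational(d, Em = Em, n_hill = n_hill, basal = basal)
      dplyr::mutate(fit$estimates, converged = fit$converged)
    }) |>
    dplyr::ungroup()
}

#' Transduction-coefficient differences versus the reference ligand
#'
#' Computes, within each (pathway, block) stratum present in the table,
#' `delta_log_R = log_R(ligand) - log_R(reference)` — the per-assay
#' normalization of log(tau/K_A) to the endogenous reference agonist. The
#' reference ligand's own delta is exactly zero in every stratum.
#'
#' @param estimates Tibble with columns `ligand`, `log_R` and optionally
#'   `pathway`, `block` (e.g. from [fit_operational_blocks()]).
#' @param reference_ligand Label of the reference (endogenous) ligand; must
#'   be present in every stratum.
#' @return Input tibble with an added `delta_log_R` column.
#' @export
delta_log_r <- function(estimates, reference_ligand) {
  grp <- intersect(c("pathway", "block"), names(estimates))
  out <- estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      ref <- d$log_R[d$ligand == reference_ligand]
      if (length(ref) != 1) {
        abort(sprintf("Reference ligand '%s' missing (or duplicated) in a stratum.",
                      reference_ligand))
      }
      dplyr::mutate(d, delta_log_R = .data$log_R - ref)
    }) |>
    dplyr::ungroup()
  out
}

#' Pathway-normalized bias: per-block delta-delta-log(tau/K_A)
#'
#' Second normalization step of the bias pipeline: within each matched block,
#' `delta_delta = delta_log_R(reference pathway) - delta_log_R(comparator)`,
#' computed separately against every comparator pathway present. Positive
#' values mean bias toward the reference pathway (cAMP by convention). Blocks
#' present in only one pathway are dropped with a message.
#'
#' @param deltas Tibble from [delta_log_r()] with columns `ligand`,
#'   `pathway`, `block`, `delta_log_R`.
#' @param reference_pathway Pathway against which bias is oriented
#'   (default `"cAMP"`).
#' @return Tibble with columns `ligand`, `pathway_pair`, `block`,
#'   `delta_delta`.
#' @export
delta_delta_log_r <- function(deltas, reference_pathway = "cAMP") {
  req <- c("ligand", "pathway", "block", "delta_log_R")
  if (!all(req %in% names(deltas))) {
    abort(paste("`deltas` must have columns:", paste(req, collapse = ", ")))
  }
  if (!reference_pathway %in% deltas$pathway) {
    abort(sprintf("Reference pathway '%s' absent.", reference_pathway))
  }
  ref <- deltas |>
    dplyr::filter(.data$pathway == reference_pathway) |>
    dplyr::select("ligand", "block", ref_delta = "delta_log_R")
  comp <- deltas |>
    dplyr::filter(.data$pathway != reference_pathway)
  joined <- dplyr::inner_join(comp, ref, by = c("ligand", "block"))
  blocks_ref <- unique(ref$block)
  blocks_comp <- unique(comp$block)
  unmatched <- union(setdiff(blocks_ref, blocks_comp),
                     setdiff(blocks_comp, blocks_ref))
  if (length(unmatched) > 0 || nrow(joined) < nrow(comp)) {
    inform(sprintf("Using only blocks matched across pathways (%d not matched).",
                   length(unmatched)))
  }
  joined |>
    dplyr::mutate(
      pathway_pair = paste(reference_pathway, "vs", .data$pathway),
      delta_delta = .data$ref_delta - .data$delta_log_R
    ) |>
    dplyr::select("ligand", "pathway_pair", "block", "delta_delta")
}

#' Bias summary with 95% confidence interval and significance call
#'
#' Summarizes per-block delta-delta-log(tau/K_A) values per ligand (and
#' pathway pair) as mean ± t-based 95% confidence interval over blocks,
#' anti-logs the mean into a bias factor, and calls bias statistically
#' significant when the interval does not cross zero. A single block gives an
#' undefined interval and a missing significance call.
#'
#' @param dd Tibble from [delta_delta_log_r()].
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble of class `"bias_result"`: `ligand`, `pathway_pair`,
#'   `n_blocks`, `delta_delta` (mean), `sem`, `ci_lo`, `ci_hi`,
#'   `bias_factor`, `significant`; per-block values in
#'   `attr(, "per_block")`.
#' @export
bias_interval <- function(dd, conf_level = 0.95) {
  if (!all(c("ligand", "delta_delta") %in% names(dd))) {
    abort("`dd` must have columns `ligand` and `delta_delta`.")
  }
  grp <- intersect(c("ligand", "pathway_pair"), names(dd))
  out <- dd |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_blocks = dplyr::n(),
      sem = sem(.data$delta_delta),
      delta_delta = mean(.data$delta_delta),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      tcrit = dplyr::if_else(.data$n_blocks > 1,
                             qt(1 - (1 - conf_level) / 2,
                                pmax(.data$n_blocks - 1, 1)), NA_real_),
      ci_lo = .data$delta_delta - .data$tcrit * .data$sem,
      ci_hi = .data$delta_delta + .data$tcrit * .data$sem,
      bias_factor = 10^.data$delta_delta,
      significant = dplyr::if_else(
        is.na(.data$ci_lo), NA,
        !(.data$ci_lo <= 0 & .data$ci_hi >= 0)
      )
    ) |>
    dplyr::select(-"tcrit") |>
    dplyr::relocate("delta_delta", .before = "sem")
  structure(out, class = c("bias_result", class(out)), per_block = as_tibble(dd))
}

#' @rdname bias_interval
#' @param x A `bias_result`.
#' @param ... Unused.
#' @method tidy bias_result
#' @export
tidy.bias_result <- function(x, ...) attr(x, "per_block")

#' End-to-end transduction-coefficient bias analysis
#'
#' The full per-assay bias pipeline: operational fits per (pathway, block)
#' with shared system parameters, normalization to the reference ligand
#' (delta), normalization to the reference pathway (delta-delta), and the
#' between-block t-interval with significance call.
#'
#' @param data Tibble with columns `ligand`, `pathway`, `conc_M`, `response`,
#'   `block`, with matched blocks across the two pathways.
#' @param reference_ligand Endogenous reference agonist label.
#' @param reference_pathway Reference pathway (default `"cAMP"`); positive
#'   bias points toward it.
#' @inheritParams fit_operational
#' @return A [bias_interval()] result; the per-(pathway, block) operational
#'   estimates are attached as `attr(, "fits")`.
#' @export
bias_analysis <- function(data, reference_ligand, reference_pathway = "cAMP",
                          Em = NULL, n_hill = NULL, basal = NULL) {
  fits <- fit_operational_blocks(data, Em = Em, n_hill = n_hill, basal = basal)
  dd <- fits |>
    delta_log_r(reference_ligand) |>
    delta_delta_log_r(reference_pathway)
  res <- bias_interval(dd)
  attr(res, "fits") <- fits
  res
}
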