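#' Ground-truth operational parameters for one ligand at one pathway
#'
#' Constructs a one-row tibble of operational-model parameters for a single
#' ligand/pathway combination. Rows are combined with [dplyr::bind_rows()] to
#' describe a multi-ligand, multi-pathway study.
#'
#' @param ligand,pathway Labels (e.g. `"GLP-1"`, `"cAMP"`, `"barr2"`).
#' @inheritParams operational_response
#' @return A tibble with one row and columns `ligand`, `pathway`, `Em`,
#'   `log_tau`, `log_KA`, `n_hill`, `basal` and the derived `log_R =
#'   log_tau - log_KA`.
#' @export
ligand_params <- function(ligand, pathway, Em, log_tau, log_KA,
                          n_hill = 1, basal = 0) {
  if (Em <= basal) abort("`Em` must exceed `basal`.")
  if (n_hill <= 0) abort("`n_hill` must be positive.")
  if (!is.finite(log_KA)) abort("`log_KA` must be finite.")
  tibble(
    ligand = ligand, pathway = pathway, Em = Em,
    log_tau = log_tau, log_KA = log_KA, n_hill = n_hill, basal = basal,
    log_R = log_tau - log_KA
  )
}

#' Kinetic scenario: the temporal shape of a plate-reader response
#'
#' Describes how a well's signal evolves after agonist addition. The shape is
#' the two-exponential rise–decay \eqn{e^{-k_{off}t} - e^{-k_{on}t}}, rescaled
#' to unit peak; `decay_rate = 0` gives the sustained limit
#' \eqn{1 - e^{-k_{on}t}} (mini-G-like), while `decay_rate > 0` gives a
#' transient peak-then-decline (beta-arrestin-like) response.
#'
#' @param onset_rate Rise rate constant, 1/min. A sustained response with
#'   `onset_rate = log(2) / t_half` reaches half its plateau at `t_half`.
#' @param decay_rate Decay rate constant, 1/min; 0 for sustained responses.
#'   Must be strictly less than `onset_rate` when positive.
#' @param plateau Peak normalized amplitude multiplier (default 1).
#' @param channel_model `"single"` for one luminescence/fluorescence channel,
#'   or `"ratiometric"` for a two-wavelength acceptor/donor pair (BRET/DERET
#'   style: the numerator channel gains signal while the denominator loses it).
#' @param baseline_duration Minutes of pre-agonist baseline reads.
#' @param read_interval Minutes between reads, > 0.
#' @param total_duration Total minutes recorded (baseline + stimulation).
#' @param channel_base Named base intensities for ratiometric channels.
#' @return A list of class `"kinetic_scenario"`.
#' @export
kinetic_scenario <- function(onset_rate, decay_rate = 0, plateau = 1,
                             channel_model = c("single", "ratiometric"),
                             baseline_duration = 5, read_interval = 0.5,
                             total_duration = 35,
                             channel_base = c(num = 1000, den = 10000)) {
  channel_model <- match.arg(channel_model)
  if (onset_rate < 0 || decay_rate < 0) abort("Rates must be non-negative.")
  if (decay_rate > 0 && decay_rate >= onset_rate) {
    abort("Transient scenarios need `decay_rate` < `onset_rate`.")
  }
  if (read_interval <= 0) abort("`read_interval` must be positive.")
  structure(
    list(
      onset_rate = onset_rate, decay_rate = decay_rate, plateau = plateau,
      channel_model = channel_model, baseline_duration = baseline_duration,
      read_interval = read_interval, total_duration = total_duration,
      channel_base = channel_base
    ),
    class = "kinetic_scenario"
  )
}

#' Unit-peak rise–decay shape
#'
#' @param t Minutes since agonist addition (>= 0).
#' @param onset_rate,decay_rate Rate constants, 1/min.
#' @return Shape values in \[0, 1\]; peak value exactly 1 for transient
#'   shapes (at `t = log(onset/decay)/(onset - decay)`), asymptote 1 for
#'   sustained shapes.
#' @export
kinetic_shape <- function(t, onset_rate, decay_rate = 0) {
  if (decay_rate == 0) {
    1 - exp(-onset_rate * t)
  } else {
    raw <- exp(-decay_rate * t) - exp(-onset_rate * t)
    t_peak <- log(onset_rate / decay_rate) / (onset_rate - decay_rate)
    raw / (exp(-decay_rate * t_peak) - exp(-onset_rate * t_peak))
  }
}

#' Plate-reader noise model
#'
#' Multiplicative Gaussian noise (coefficient of variation) plus an additive
#' Gaussian floor on every read, and a between-replicate-assay (block) offset
#' applied to each ligand's log transduction coefficient, shared by all wells
#' of a block within one assay.
#'
#' @param cv_multiplicative Fractional CV of each read (default 0.05).
#' @param sd_additive Additive noise SD, response units (default 1 on the
#'   default 100-unit system-maximum scale).
#' @param block_sd Between-assay SD of log_R, log10 units (default 0.1).
#' @param seed Optional integer; identical seed implies identical output.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(cv_multiplicative = 0.05, sd_additive = 1,
                        block_sd = 0.1, seed = NULL) {
  if (cv_multiplicative < 0 || sd_additive < 0 || block_sd < 0) {
    abort("Noise scatter parameters must be non-negative.")
  }
  structure(
    list(
      cv_multiplicative = cv_multiplicative, sd_additive = sd_additive,
      block_sd = block_sd, seed = seed
    ),
    class = "noise_model"
  )
}

#' Noise-free noise model (all scatter parameters zero)
#' @export
no_noise <- function() noise_model(0, 0, 0, seed = NULL)

# run expr under the noise model's seed (if any) without disturbing the
# caller's RNG stream more than one draw sequence
with_noise_seed <- function(noise, expr) {
  if (!is.null(noise$seed)) {
    withr::with_seed(noise$seed, expr)
  } else {
    expr
  }
}

add_read_noise <- function(x, noise) {
  n <- length(x)
  x * (1 + stats::rnorm(n, 0, noise$cv_multiplicative)) +
    stats::rnorm(n, 0, noise$sd_additive)
}

#' Simulate a single kinetic plate-reader trace
#'
#' The well reads at `basal` signal during the baseline window, then (for a
#' non-vehicle well) rises by the operational-model response at the given
#' concentration, shaped in time by the scenario's rise–decay kinetics.
#' Ratiometric scenarios emit two channels in which the numerator wavelength
#' gains the energy the denominator wavelength loses (DERET-style).
#'
#' @param params One-row tibble from [ligand_params()].
#' @param scenario A [kinetic_scenario()].
#' @param concentration Agonist concentration, molar; 0 simulates a vehicle
#'   well.
#' @param noise A [noise_model()]; use [no_noise()] for deterministic means.
#' @param well,block Well label and replicate-block id annotations.
#' @return A long tibble with columns `well`, `time_min`, `channel`, `signal`,
#'   `receptor`, `ligand`, `conc_M`, `is_vehicle`, `block`.
#' @export
simulate_kinetic_trace <- function(params, scenario, concentration,
                                   noise = no_noise(), well = "A1", block = 1L) {
  if (concentration < 0) abort("`concentration` must be non-negative.")
  stopifnot(inherits(scenario, "kinetic_scenario"))
  times <- seq(0, scenario$total_duration, by = scenario$read_interval)
  t_post <- pmax(0, times - scenario$baseline_duration)
  shape <- kinetic_shape(t_post, scenario$onset_rate, scenario$decay_rate)
  shape[times < scenario$baseline_duration] <- 0

  resp <- operational_response(
    concentration, params$Em, params$log_tau, params$log_KA,
    params$n_hill, params$basal
  )
  amp <- (resp - params$basal) * scenario$plateau
  # fraction of the system span, used to drive ratiometric channel transfer
  frac <- amp / (params$Em - params$basal)

  out <- with_noise_seed(noise, {
    if (scenario$channel_model == "single") {
      signal <- params$basal + amp * shape
      tibble(
        well = well, time_min = times, channel = "lum",
        signal = add_read_noise(signal, noise)
      )
    } else {
      base <- scenario$channel_base
      num <- base[["num"]] * (1 + frac * shape)
      den <- base[["den"]] * (1 - 0.5 * frac * shape)
      dplyr::bind_rows(
        tibble(well = well, time_min = times, channel = "num",
               signal = add_read_noise(num, noise)),
        tibble(well = well, time_min = times, channel = "den",
               signal = add_read_noise(den, noise))
      )
    }
  })
  out$receptor <- if ("receptor" %in% names(params)) params$receptor else NA_character_
  out$ligand <- params$ligand
  out$conc_M <- concentration
  out$is_vehicle <- concentration == 0
  out$block <- block
  out
}

#' Default concentration grid
#'
#' Nine concentrations spanning 1 pM to 1 uM, evenly spaced in log10,
#' mirroring typical concentration–response axes.
#'
#' @param from,to Molar endpoints.
#' @param n Number of concentrations.
#' @return Strictly increasing numeric vector, molar.
#' @export
default_conc_grid <- function(from = 1e-12, to = 1e-6, n = 9) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Simulate a randomized-block concentration–response study
#'
#' One response record per (ligand, pathway, concentration, block). Each
#' (block, pathway) draws a single Gaussian offset of SD `block_sd` that
#' shifts every ligand's `log_tau` (hence `log_R`) within that assay
#' replicate, emulating day-to-day assay scale drift; read noise is then
#' applied per record. With [no_noise()] the output equals the
#' operational-model mean exactly.
#'
#' @param params Tibble of [ligand_params()] rows (one or more ligands and
#'   pathways).
#' @param conc_grid Strictly increasing molar concentrations.
#' @param n_blocks Number of replicate blocks (assay days).
#' @param noise A [noise_model()].
#' @return Tibble with columns `ligand`, `pathway`, `conc_M`, `response`,
#'   `block`.
#' @export
simulate_cr_study <- function(params, conc_grid = default_conc_grid(),
                              n_blocks = 5, noise = noise_model()) {
  if (length(conc_grid) == 0) abort("`conc_grid` must be non-empty.")
  if (is.unsorted(conc_grid, strictly = TRUE)) {
    abort("`conc_grid` must be strictly increasing.")
  }
  with_noise_seed(noise, {
    pathways <- unique(params$pathway)
    offsets <- tidyr::expand_grid(block = seq_len(n_blocks), pathway = pathways)
    offsets$block_offset <- stats::rnorm(nrow(offsets), 0, noise$block_sd)

    grid <- tidyr::expand_grid(
      params,
      conc_M = conc_grid,
      block = seq_len(n_blocks)
    )
    grid <- dplyr::left_join(grid, offsets, by = c("block", "pathway"))
    grid$mean_response <- operational_response(
      grid$conc_M, grid$Em, grid$log_tau + grid$block_offset,
      grid$log_KA, grid$n_hill, grid$basal
    )
    grid$response <- add_read_noise(grid$mean_response, noise)
    dplyr::select(grid, "ligand", "pathway", "conc_M", "response", "block")
  })
}

#' Ground-truth parameter set for a two-pathway bias study
#'
#' A reference full-ish agonist and one analog measured in matched cAMP and
#' beta-arrestin-2 assays. The analog's transduction coefficient is reduced by
#' 0.5 log10 units for cAMP and by `0.5 + delta_delta` for barr2, so the true
#' bias toward cAMP is exactly `delta_delta` log units.
#'
#' @param delta_delta True ΔΔlog(τ/K_A) toward cAMP (default 0.5, bias
#'   factor 10^0.5 ≈ 3.16).
#' @param analog_shift Drop in the analog's Δlog(τ/K_A) for cAMP (default 0.5).
#' @return Tibble of [ligand_params()] rows.
#' @export
bias_scenario_params <- function(delta_delta = 0.5, analog_shift = 0.5) {
  dplyr::bind_rows(
    ligand_params("reference", "cAMP", Em = 100, log_tau = 0.7, log_KA = -8.5),
    ligand_params("analog", "cAMP", Em = 100, log_tau = 0.7 - analog_shift,
                  log_KA = -8.5),
    ligand_params("reference", "barr2", Em = 100, log_tau = 0.5, log_KA = -8),
    ligand_params("analog", "barr2",
                  log_tau = 0.5 - analog_shift - delta_delta,
                  log_KA = -8, Em = 100)
  )
}

#' Simulate a Mesna-cleavage internalization plate
#'
#' Generative rule per block: wells not treated with Mesna read the full
#' surface-label signal; Mesna + vehicle wells read only nonspecific signal;
#' Mesna + agonist wells read nonspecific plus the internalized (protected)
#' fraction of the specific signal.
#'
#' @param surface_signal Mean intensity of the labeled surface pool.
#' @param internalized_fraction Named numeric vector, one fraction in
#'   \[0, 1\] per agonist.
#' @param nonspecific_signal Residual intensity after Mesna with no agonist;
#'   must be below `surface_signal`.
#' @param noise A [noise_model()] (`block_sd` unused here).
#' @param n_blocks Number of replicate blocks.
#' @param receptor Receptor annotation.
#' @return Tibble with columns `well`, `receptor`, `ligand`, `mesna`
#'   (logical), `intensity`, `block`.
#' @export
simulate_internalization_plate <- function(surface_signal, internalized_fraction,
                                           nonspecific_signal,
                                           noise = no_noise(), n_blocks = 5,
                                           receptor = "GLP-1R") {
  if (any(internalized_fraction < 0 | internalized_fraction > 1)) {
    abort("`internalized_fraction` values must lie in [0, 1].")
  }
  if (nonspecific_signal >= surface_signal) {
    abort("`nonspecific_signal` must be below `surface_signal`.")
  }
  agonists <- names(internalized_fraction)
  if (is.null(agonists)) abort("`internalized_fraction` must be named by agonist.")

  design <- dplyr::bind_rows(
    tidyr::expand_grid(ligand = c("vehicle", agonists), mesna = FALSE),
    tidyr::expand_grid(ligand = c("vehicle", agonists), mesna = TRUE)
  )
  plate <- tidyr::expand_grid(block = seq_len(n_blocks), design)
  frac <- c(setNames(0, "vehicle"), internalized_fraction)
  specific <- surface_signal - nonspecific_signal
  plate$mean_intensity <- ifelse(
    plate$mesna,
    nonspecific_signal + frac[plate$ligand] * specific,
    surface_signal
  )
  with_noise_seed(noise, {
    plate$intensity <- add_read_noise(plate$mean_intensity, noise)
    plate$receptor <- receptor
    plate$well <- sprintf("W%02d", seq_len(nrow(plate)))
    dplyr::select(plate, "well", "receptor", "ligand", "mesna", "intensity", "block")
  })
}
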