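#' Black–Leff operational model of agonism
#'
#' Mean response of the operational model
#' \deqn{E(A) = basal + (E_m - basal)\,\frac{\tau^n A^n}{(A + K_A)^n + \tau^n A^n}}
#' where \eqn{\tau} is the operational efficacy (the capacity of the
#' agonist–receptor complex to generate response) and \eqn{K_A} the functional
#' affinity of the agonist for the receptor in molar units. The ratio
#' \eqn{\tau/K_A} is the transduction coefficient; its log10,
#' `log_tau - log_KA`, is the scale on which biased agonism is quantified.
#'
#' @param conc Agonist concentration(s), molar. Zero gives `basal`.
#' @param Em Maximal system response (response units).
#' @param log_tau log10 operational efficacy (dimensionless).
#' @param log_KA log10 functional affinity (molar).
#' @param n_hill Transducer slope, > 0.
#' @param basal Response at zero agonist.
#'
#' @return Numeric vector of mean responses, same length as `conc`.
#'
#' @examples
#' # tau = 1, KA = 10 nM, Em = 100: response at conc = KA is Em/3
#' operational_response(1e-8, Em = 100, log_tau = 0, log_KA = -8)
#' @export
operational_response <- function(conc, Em, log_tau, log_KA, n_hill = 1, basal = 0) {
  stopifnot(all(conc >= 0), Em > basal, n_hill > 0, is.finite(log_KA))
  tau <- 10^log_tau
  KA <- 10^log_KA
  num <- (tau * conc)^n_hill
  basal + (Em - basal) * num / ((conc + KA)^n_hill + num)
}

#' Observed maximal response and EC50 implied by operational parameters
#'
#' For the operational model the asymptotic (observed) maximum is
#' \eqn{E_{max} = basal + (E_m - basal)\tau^n/(1+\tau^n)} and the
#' half-maximal concentration is \eqn{EC_{50} = K_A/((2+\tau^n)^{1/n} - 1)},
#' which reduce to \eqn{E_m\tau/(1+\tau)} and \eqn{K_A/(1+\tau)} when
#' `n_hill = 1`.
#'
#' @inheritParams operational_response
#' @return A tibble with columns `emax_obs` and `ec50_obs` (molar).
#' @export
operational_observed <- function(Em, log_tau, log_KA, n_hill = 1, basal = 0) {
  tau_n <- 10^(log_tau * n_hill)
  tibble(
    emax_obs = basal + (Em - basal) * tau_n / (1 + tau_n),
    ec50_obs = 10^log_KA / ((2 + tau_n)^(1 / n_hill) - 1)
  )
}

#' Logistic (Hill) concentration–response curve
#'
#' Standard 4-parameter logistic evaluated on the log10 concentration scale:
#' \deqn{E(A) = basal + \frac{e_{max} - basal}{1 + 10^{hill\,(logEC_{50} - \log_{10} A)}}}
#'
#' @param conc Agonist concentration(s), molar, > 0.
#' @param basal Lower asymptote.
#' @param e_max Upper asymptote.
#' @param log_ec50 log10 EC50 (molar).
#' @param hill Hill slope, > 0.
#' @return Numeric vector of responses.
#' @export
logistic_response <- function(conc, basal, e_max, log_ec50, hill = 1) {
  stopifnot(all(conc > 0))
  basal + (e_max - basal) / (1 + 10^(hill * (log_ec50 - log10(conc))))
}
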