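# Independent brute-force oracles used to validate the fitting paths.

# dense grid search for the logistic fit: for each (log_ec50, hill) the model
# is linear in (basal, e_max), solved exactly by least squares
logistic_grid_oracle <- function(conc, resp, lec_range, hill_range, step = 0.01) {
  lecs <- seq(lec_range[1], lec_range[2], by = step)
  hills <- seq(hill_range[1], hill_range[2], by = step)
  lc <- log10(conc)
  best <- list(sse = Inf)
  for (h in hills) {
    for (le in lecs) {
      w <- 1 / (1 + 10^(h * (le - lc)))
      X <- cbind(1 - w, w)
      fit <- stats::lm.fit(X, resp)
      sse <- sum(fit$residuals^2)
      if (sse < best$sse) {
        best <- list(sse = sse, log_ec50 = le, hill = h,
                     basal = fit$coefficients[1], e_max = fit$coefficients[2])
      }
    }
  }
  best
}

# dense grid search over (log_tau, log_KA) for the operational model with
# fixed shared parameters
operational_grid_oracle <- function(conc, resp, Em, n_hill, basal,
                                    lt_range, lk_range, step = 0.01) {
  lts <- seq(lt_range[1], lt_range[2], by = step)
  lks <- seq(lk_range[1], lk_range[2], by = step)
  best <- list(sse = Inf)
  for (lt in lts) {
    for (lk in lks) {
      pred <- operational_response(conc, Em, lt, lk, n_hill, basal)
      sse <- sum((resp - pred)^2)
      if (sse < best$sse) best <- list(sse = sse, log_tau = lt, log_KA = lk)
    }
  }
  best
}
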