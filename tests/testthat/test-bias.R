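noise_free_cr <- function(params, conc = default_conc_grid()) {
  simulate_cr_study(params, conc_grid = conc, n_blocks = 1, noise = no_noise())
}

test_that("operational fit reproduces the closed-form n=1 reduction", {
  # tau = 1, KA = 10 nM, Em = 100: observed Emax = 50, EC50 = 5 nM, log_R = 8
  p <- ligand_params("L", "cAMP", Em = 100, log_tau = 0, log_KA = -8)
  cr <- noise_free_cr(p)
  fit <- fit_operational(cr, Em = 100, n_hill = 1, basal = 0)
  est <- tidy(fit)
  expect_equal(est$emax_obs, 50, tolerance = 1e-6)
  expect_equal(est$ec50_obs, 5e-9, tolerance = 1e-6)
  expect_equal(est$log_R, 8, tolerance = 1e-3)
})

test_that("high-efficacy limit approaches the full-agonist observables", {
  # tau = 1000 at fixed KA: observed Emax -> Em, EC50 -> KA/1001
  p <- ligand_params("L", "cAMP", Em = 100, log_tau = 3, log_KA = -8)
  cr <- noise_free_cr(p, conc = 10^seq(-13, -8, by = 0.5))
  fit <- fit_operational(cr, n_hill = 1, basal = 0)
  est <- tidy(fit)
  expect_equal(est$emax_obs, 100 * 1000 / 1001, tolerance = 1e-5)
  expect_equal(est$ec50_obs, 1e-8 / 1001, tolerance = 1e-5)
})

test_that("ligands with identical generating parameters get identical log_R", {
  p <- dplyr::bind_rows(
    ligand_params("A", "cAMP", Em = 100, log_tau = 0.3, log_KA = -8),
    ligand_params("B", "cAMP", Em = 100, log_tau = 0.3, log_KA = -8)
  )
  fit <- fit_operational(noise_free_cr(p), n_hill = 1, basal = 0)
  est <- tidy(fit)
  expect_equal(est$log_R[1], est$log_R[2], tolerance = 1e-6)
})

test_that("noise-free round trip recovers log_R when Em is anchored", {
  p <- bias_scenario_params(0.5)
  for (pw in c("cAMP", "barr2")) {
    cr <- noise_free_cr(p[p$pathway == pw, ])
    fit <- fit_operational(cr, Em = 100)
    est <- dplyr::inner_join(tidy(fit), p[p$pathway == pw, c("ligand", "log_R")],
                             by = "ligand", suffix = c("", "_true"))
    expect_equal(est$log_R, est$log_R_true, tolerance = 1e-3)
  }
})

test_that("global fit objective matches a dense grid-search oracle", {
  conc <- 10^seq(-10, -6, by = 1)  # 5-concentration toy design
  resp <- operational_response(conc, 100, 0.24, -7.87) +
    c(0.8, -1.1, 0.5, -0.3, 0.9)
  d <- tibble::tibble(ligand = "L", conc_M = conc, response = resp)
  fit <- fit_operational(d, Em = 100, n_hill = 1, basal = 0)
  oracle <- operational_grid_oracle(conc, resp, Em = 100, n_hill = 1,
                                    basal = 0, lt_range = c(-0.5, 1),
                                    lk_range = c(-9, -7), step = 0.01)
  est <- tidy(fit)
  expect_lt(abs(est$log_tau - oracle$log_tau), 0.011)
  expect_lt(abs(est$log_KA - oracle$log_KA), 0.011)
  expect_lte(fit$sse, oracle$sse + 1e-8)
})

test_that("delta log_R subtracts the reference ligand within each stratum", {
  tbl <- tibble::tibble(
    ligand = c("ref", "analog", "weakling"),
    pathway = "cAMP", block = 1L,
    log_R = c(8.5, 8.0, 6.5)
  )
  d <- delta_log_r(tbl, "ref")
  expect_equal(d$delta_log_R[d$ligand == "analog"], -0.5)
  expect_equal(d$delta_log_R[d$ligand == "ref"], 0)
  expect_equal(d$delta_log_R[d$ligand == "weakling"], -2)
  expect_error(delta_log_r(tbl, "absent"), "missing")
})

test_that("delta-delta normalizes to the reference pathway with the stated sign", {
  deltas <- tidyr::expand_grid(
    ligand = c("ref", "analog"), pathway = c("cAMP", "barr2"), block = 1:2
  )
  deltas$delta_log_R <- ifelse(deltas$ligand == "ref", 0,
                               ifelse(deltas$pathway == "cAMP", -0.5, -1.0))
  dd <- delta_delta_log_r(deltas, "cAMP")
  a <- dd[dd$ligand == "analog", ]
  expect_equal(a$delta_delta, c(0.5, 0.5))
  expect_equal(10^mean(a$delta_delta), 3.16, tolerance = 1e-3)
  expect_equal(dd$delta_delta[dd$ligand == "ref"], c(0, 0))

  # swapping pathway roles flips the sign
  swapped <- delta_delta_log_r(deltas, "barr2")
  expect_equal(swapped$delta_delta[swapped$ligand == "analog"], c(-0.5, -0.5))

  # unmatched blocks are dropped with a message
  partial <- deltas[!(deltas$pathway == "barr2" & deltas$block == 2), ]
  expect_message(dd2 <- delta_delta_log_r(partial, "cAMP"), "not matched")
  expect_equal(unique(dd2$block), 1L)
})

test_that("bias interval applies the between-block t-interval and significance rule", {
  dd <- tibble::tibble(ligand = "analog", pathway_pair = "cAMP vs barr2",
                       block = 1:5, delta_delta = c(0.4, 0.5, 0.6, 0.5, 0.5))
  res <- bias_interval(dd)
  expect_equal(res$delta_delta, 0.5)
  expect_equal(res$sem, 0.0316, tolerance = 1e-2)
  expect_equal(res$ci_lo, 0.5 - qt(0.975, 4) * res$sem)
  expect_equal(res$ci_lo, 0.412, tolerance = 1e-2)
  expect_equal(res$ci_hi, 0.588, tolerance = 1e-2)
  expect_true(res$significant)
  expect_equal(res$bias_factor, 10^0.5)

  sym <- bias_interval(tibble::tibble(ligand = "x", delta_delta = c(-0.4, 0.4)))
  expect_false(sym$significant)

  const <- bias_interval(tibble::tibble(ligand = "x", delta_delta = rep(0.3, 4)))
  expect_equal(const$ci_lo, 0.3)
  expect_equal(const$ci_hi, 0.3)
  expect_true(const$significant)

  single <- bias_interval(tibble::tibble(ligand = "x", delta_delta = 0.3))
  expect_true(is.na(single$sem))
  expect_true(is.na(single$significant))
})

test_that("reference ligand zeroes exactly in every block of a full analysis", {
  nm <- noise_model(0.05, 1, 0.1, seed = 11L)
  cr <- simulate_cr_study(bias_scenario_params(0.5), n_blocks = 4, noise = nm)
  res <- suppressMessages(bias_analysis(cr, "reference", "cAMP"))
  per_block <- tidy(res)
  ref <- per_block[per_block$ligand == "reference", ]
  expect_equal(nrow(ref), 4L)
  expect_identical(ref$delta_delta, rep(0, 4))
  tbl <- tibble::as_tibble(res)
  expect_identical(tbl$delta_delta[tbl$ligand == "reference"], 0)
  expect_identical(tbl$sem[tbl$ligand == "reference"], 0)
})

test_that("bias is invariant to rescaling all responses in one pathway", {
  cr <- simulate_cr_study(bias_scenario_params(0.5), n_blocks = 2,
                          noise = no_noise())
  res1 <- bias_analysis(cr, "reference", "cAMP")
  scaled <- dplyr::mutate(
    cr, response = ifelse(pathway == "barr2", response * 3.7, response)
  )
  res2 <- bias_analysis(scaled, "reference", "cAMP")
  a1 <- tibble::as_tibble(res1)
  a2 <- tibble::as_tibble(res2)
  expect_equal(a2$delta_delta[a2$ligand == "analog"],
               a1$delta_delta[a1$ligand == "analog"], tolerance = 1e-3)
})

test_that("log_R standard error grows as the agonist becomes weaker", {
  taus <- c(1, 0.3, 0.1, 0.03)
  ses <- vapply(taus, function(tau) {
    p <- ligand_params("L", "cAMP", Em = 100, log_tau = log10(tau),
                       log_KA = -8.5)
    nm <- noise_model(0.05, 1, 0, seed = 314L)
    cr <- simulate_cr_study(p, n_blocks = 3, noise = nm)
    fits <- fit_operational_blocks(cr, Em = 100, n_hill = 1, basal = 0)
    mean(fits$se_log_R)
  }, 0)
  expect_true(all(diff(ses) >= 0))
})

test_that("weak partial agonists are flagged with wide errors", {
  p <- dplyr::bind_rows(
    ligand_params("full", "cAMP", Em = 100, log_tau = 0.7, log_KA = -8.5),
    ligand_params("feeble", "cAMP", Em = 100, log_tau = -2.5, log_KA = -8.5)
  )
  nm <- noise_model(0.05, 1, 0, seed = 8L)
  cr <- simulate_cr_study(p, n_blocks = 1, noise = nm)
  fit <- fit_operational(cr, n_hill = 1)
  est <- tidy(fit)
  expect_true(est$weak[est$ligand == "feeble"])
  expect_false(est$weak[est$ligand == "full"])
  expect_gt(est$se_log_R[est$ligand == "feeble"],
            est$se_log_R[est$ligand == "full"])
})

test_that("operational fit rejects sparse designs", {
  d <- tibble::tibble(ligand = "L", conc_M = 10^seq(-9, -6, by = 1),
                      response = c(1, 5, 20, 40))
  expect_error(fit_operational(d), "5 distinct")
})
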