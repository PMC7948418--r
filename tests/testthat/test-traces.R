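make_trace <- function(well, signal, times = 0:10, is_vehicle = FALSE,
                       block = 1L, channel = "lum") {
  tibble::tibble(well = well, time_min = times, channel = channel,
                 signal = signal, is_vehicle = is_vehicle, block = block)
}

test_that("two-step baseline/vehicle normalization follows hand arithmetic", {
  # identity: everything constant at 100 -> 1.0 everywhere
  tr <- dplyr::bind_rows(
    make_trace("A1", rep(100, 11)),
    make_trace("V1", rep(100, 11), is_vehicle = TRUE)
  )
  out <- normalize_trace(tr, baseline_duration = 3)
  expect_true(all(out$signal == 1))

  # baseline 100, post-agonist 150, flat vehicles -> 1.5 after agonist
  sig <- c(rep(100, 3), rep(150, 8))
  tr2 <- dplyr::bind_rows(
    make_trace("A1", sig),
    make_trace("V1", rep(100, 11), is_vehicle = TRUE),
    make_trace("V2", rep(200, 11), is_vehicle = TRUE)
  )
  out2 <- normalize_trace(tr2, baseline_duration = 3)
  a <- out2[out2$well == "A1", ]
  expect_equal(a$signal[a$time_min >= 3], rep(1.5, 8))
  expect_equal(a$signal[a$time_min < 3], rep(1, 3))

  # agonist trace identical to the vehicle mean -> 1.0 everywhere
  tr3 <- dplyr::bind_rows(
    make_trace("A1", sig),
    make_trace("V1", sig, is_vehicle = TRUE)
  )
  out3 <- normalize_trace(tr3, baseline_duration = 3)
  expect_equal(out3$signal[out3$well == "A1"], rep(1, 11))
})

test_that("normalization is idempotent on vehicle-normalized traces", {
  sig <- 100 * (1 + kinetic_shape(0:10, 0.3))
  tr <- dplyr::bind_rows(
    make_trace("A1", sig),
    make_trace("V1", rep(100, 11), is_vehicle = TRUE)
  )
  once <- normalize_trace(tr, baseline_duration = 1)
  twice <- normalize_trace(once, baseline_duration = 1)
  veh <- twice[twice$is_vehicle, ]
  expect_equal(veh$signal, rep(1, nrow(veh)))
  # renormalizing scales by the (constant) baseline only; vehicle mean is 1
  expect_equal(twice$signal[twice$well == "A1"],
               once$signal[once$well == "A1"] / once$signal[once$well == "A1"][1])
})

test_that("wells with non-positive baseline are flagged and excluded", {
  tr <- dplyr::bind_rows(
    make_trace("BAD", c(rep(0, 3), rep(10, 8))),
    make_trace("A1", rep(100, 11)),
    make_trace("V1", rep(100, 11), is_vehicle = TRUE)
  )
  expect_warning(out <- normalize_trace(tr, baseline_duration = 3), "BAD")
  expect_false("BAD" %in% out$well)
  expect_true("A1" %in% out$well)
})

test_that("mismatched timebases are rejected", {
  tr <- dplyr::bind_rows(
    make_trace("A1", rep(100, 11), times = 0:10),
    make_trace("V1", rep(100, 11), times = seq(0, 5, by = 0.5),
               is_vehicle = TRUE)
  )
  expect_error(normalize_trace(tr, 3), "timebase")
})

test_that("ratiometric combination subtracts blanks and masks bad points", {
  tr <- dplyr::bind_rows(
    make_trace("A1", rep(200, 5), times = 0:4, channel = "num"),
    make_trace("A1", rep(1000, 5), times = 0:4, channel = "den")
  )
  out <- ratiometric(tr, "num", "den", blank = c(num = 20, den = 100))
  expect_equal(out$signal, rep(0.2, 5))

  # equal channels, no blank -> 1.0
  eq <- dplyr::bind_rows(
    make_trace("A1", 1:5, times = 0:4, channel = "num"),
    make_trace("A1", 1:5, times = 0:4, channel = "den")
  )
  expect_equal(ratiometric(eq)$signal, rep(1, 5))

  # blank >= denominator masks the point rather than dropping the well
  low <- dplyr::bind_rows(
    make_trace("A1", c(200, 200), times = 0:1, channel = "num"),
    make_trace("A1", c(1000, 50), times = 0:1, channel = "den")
  )
  expect_warning(m <- ratiometric(low, blank = c(num = 0, den = 100)),
                 "Masking 1")
  expect_equal(m$signal, c(200 / 900, NA))
})

test_that("ratiometric commutes with common positive channel rescaling", {
  tr <- dplyr::bind_rows(
    make_trace("A1", c(5, 10, 20), times = 0:2, channel = "num"),
    make_trace("A1", c(50, 40, 30), times = 0:2, channel = "den")
  )
  scaled <- dplyr::mutate(tr, signal = signal * 7.3)
  expect_equal(ratiometric(tr)$signal, ratiometric(scaled)$signal)
})

test_that("DERET-style drift gives a strictly increasing ratio", {
  p <- ligand_params("GLP-1", "DERET", Em = 100, log_tau = 1, log_KA = -8)
  sc <- kinetic_scenario(0.2, channel_model = "ratiometric",
                         baseline_duration = 0, total_duration = 30)
  tr <- simulate_kinetic_trace(p, sc, concentration = 1e-6)
  ratio <- ratiometric(tr, "num", "den")
  expect_true(all(diff(ratio$signal) > 0))
})

test_that("trapezoidal AUC is exact for simple shapes and near-exact for exponentials", {
  flat <- make_trace("A1", rep(1, 61), times = seq(0, 30, by = 0.5))
  expect_equal(trace_auc(flat)$auc, 30)

  ramp <- make_trace("A1", seq(0, 1, length.out = 21),
                     times = seq(0, 10, by = 0.5))
  expect_equal(trace_auc(ramp)$auc, 5)

  t <- seq(0, 30, by = 0.5)
  expo <- make_trace("A1", 1 - exp(-t / 5), times = t)
  analytic <- 30 - 5 * (1 - exp(-6))
  expect_lt(abs(trace_auc(expo)$auc - analytic) / analytic, 0.001)

  expect_error(trace_auc(make_trace("A1", 1, times = 0)), "two")
})

test_that("AUC is additive over contiguous intervals and baseline-correctable", {
  t <- seq(0, 20, by = 0.5)
  y <- 2 + kinetic_shape(t, 0.4)
  tr <- make_trace("A1", y, times = t)
  whole <- trace_auc(tr)$auc
  left <- trace_auc(dplyr::filter(tr, time_min <= 10))$auc
  right <- trace_auc(dplyr::filter(tr, time_min >= 10))$auc
  expect_equal(left + right, whole)

  # baseline correction subtracts the pre-window mean exactly
  tr2 <- make_trace("A1", c(rep(2, 10), rep(5, 31)),
                    times = seq(0, 20, by = 0.5))
  bc <- trace_auc(tr2, baseline_correct = TRUE, baseline_duration = 5)
  expect_equal(bc$auc, 3 * 15)
})

test_that("interpolated half-time matches closed forms and handles degenerate traces", {
  k <- log(2) / 1.5
  t <- seq(0, 30, by = 0.5)
  tr <- make_trace("A1", 1 - exp(-k * t), times = t)
  expect_equal(response_t_half(tr)$t_half, 1.5, tolerance = 0.02)

  # step between consecutive samples interpolates to the midpoint
  st <- make_trace("A1", c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1),
                   times = seq(0, 6, by = 0.5))
  expect_equal(response_t_half(st)$t_half, 5.25)

  flat <- make_trace("A1", rep(3, 11))
  expect_true(is.na(response_t_half(flat)$t_half))
})

test_that("interpolated half-time converges to log(2)/k as sampling refines", {
  k <- 0.31
  err <- vapply(c(2, 1, 0.5, 0.1, 0.01), function(dt) {
    t <- seq(0, 40, by = dt)
    tr <- make_trace("A1", 1 - exp(-k * t), times = t)
    abs(response_t_half(tr)$t_half - log(2) / k)
  }, 0)
  expect_true(all(diff(err) <= 1e-12))
  expect_lt(err[length(err)], 1e-3)
})

test_that("exponential-fit half-time agrees with interpolation on clean data", {
  k <- 0.4
  t <- seq(0, 30, by = 0.5)
  tr <- make_trace("A1", 1 - exp(-k * t), times = t)
  expect_equal(response_t_half(tr, method = "fit")$t_half, log(2) / k,
               tolerance = 1e-6)
})

test_that("control normalization supports percent-of-forskolin and fold modes", {
  resp <- tibble::tibble(
    condition = c("GLP-1", "FSK", "FSK"),
    response = c(5.4, 9, 11),
    block = 1L
  )
  out <- normalize_to_control(resp, "FSK", mode = "percent")
  expect_equal(out$response[out$condition == "GLP-1"], 54)
  expect_equal(out$response[out$condition == "FSK"], c(90, 110))

  erk <- tibble::tibble(condition = c("GLP-1", "unstim"),
                        response = c(0.06, 0.05), block = 1L)
  fold <- normalize_to_control(erk, "unstim", mode = "fold")
  expect_equal(fold$response, c(1.2, 1))

  bad <- tibble::tibble(condition = c("x", "ctl", "x", "ctl"),
                        response = c(1, 0, 2, 5), block = c(1L, 1L, 2L, 2L))
  expect_warning(keep <- normalize_to_control(bad, "ctl"), "non-positive")
  expect_true(all(keep$block == 2L))
})

test_that("2^-dCt expression follows the qPCR convention", {
  expect_equal(delta_ct_expression(20, 10), 2^-10)
  expect_equal(delta_ct_expression(15, 15), 1)
  expect_equal(delta_ct_expression(14, 15), 2)
  expect_true(is.na(delta_ct_expression(NA, 15)))
})
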