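test_that("input resistance recovers exact and simulated ground truth", {
  # exact line: -2.5 mV at -25 pA and -5.0 mV at -50 pA -> 100 MOhm
  sweeps <- list(flat_step_sweep(-2.5, -25), flat_step_sweep(-5.0, -50))
  expect_equal(input_resistance(sweeps), 100, tolerance = 1e-6)
  # smallest-step-only variant uses the -25 pA sweep alone
  expect_equal(input_resistance(sweeps, smallest_only = TRUE), 100,
               tolerance = 1e-6)
  # ground-truth recovery on a passive simulated cell
  p <- neuron_params(g_leak = 1000 / 150, g_hcn_max = 0)
  sws <- simulate_protocol(p, stim_step_family(amplitudes = c(-25, -50, -75)))
  expect_equal(input_resistance(sws), 150, tolerance = 1 / 150)
  expect_error(input_resistance(list(sweeps[[1]])), "at least two")
})

test_that("AP detection respects the dV/dt and zero-crossing criteria", {
  n <- 10000; dt <- 5e-5
  flat <- new_sweep(rep(-60, n), numeric(n), dt, "current_clamp")
  expect_equal(nrow(detect_aps(flat)), 0)
  # 10 mV EPSP with slow rise (dV/dt well under 20 V/s) -> no AP
  tt <- (seq_len(n) - 1) * dt
  epsp <- -60 + 10 * pmax(0, (tt - 0.1)) / 0.05 * exp(1 - (tt - 0.1) / 0.05)
  expect_equal(nrow(detect_aps(new_sweep(epsp, numeric(n), dt,
                                         "current_clamp"))), 0)
  # simulated suprathreshold step: detected count equals simulator markers
  p <- neuron_params()
  sw <- simulate_protocol(p, stim_step_family(amplitudes = 125),
                          spiking = TRUE)[[1]]
  truth <- sum(sw$markers$label == "spike")
  expect_gt(truth, 0)
  aps <- detect_aps(sw)
  expect_equal(nrow(aps), truth)
  expect_true(all(aps$amplitude > 40))
})

test_that("rheobase is the smallest step evoking an AP, censored when none does", {
  p <- neuron_params()
  sws <- simulate_protocol(p, stim_step_family(), spiking = TRUE)
  rf <- rheobase_and_fi(sws)
  expect_false(rf$censored)
  expect_true(rf$rheobase %in% seq(25, 125, 25))
  # the F-I curve is the per-amplitude AP count and is non-decreasing
  expect_true(all(diff(rf$fi_curve$n_ap) >= 0))
  # no spiking mechanism -> no APs -> censored at the maximum amplitude
  sws0 <- simulate_protocol(p, stim_step_family(amplitudes = c(25, 50)))
  rf0 <- rheobase_and_fi(sws0)
  expect_true(rf0$censored)
  expect_equal(rf0$rheobase, 50)
})

test_that("constructed sweeps return the published sag percentages exactly", {
  for (tgt in c(10.9, 7.6)) {
    sw <- synthetic_sag_sweep(tgt / 100)
    sr <- sag_and_rebound(list(sw))
    expect_equal(sr$sag_pct, tgt, tolerance = 1e-4)
  }
  # passive monotone relaxation: peak equals steady -> 0% sag
  sw0 <- synthetic_sag_sweep(0)
  expect_equal(sag_and_rebound(list(sw0))$sag_pct, 0, tolerance = 1e-6)
})

test_that("sag is invariant to a constant baseline shift", {
  sw <- synthetic_sag_sweep(0.109)
  sw2 <- new_sweep(sw$samples + 7.3, sw$stimulus, sw$dt, sw$mode,
                   sw$markers, sw$holding)
  expect_equal(sag_and_rebound(list(sw2))$sag_pct,
               sag_and_rebound(list(sw))$sag_pct, tolerance = 1e-9)
})

test_that("rebound pairs on an exact -0.11 line return slope -0.11", {
  amps <- c(-125, -100, -75, -50)
  sweeps <- lapply(amps, function(a) {
    defl <- -a * 0.16                      # peak deflection magnitude
    synthetic_sag_sweep(0.109, peak_deflection = defl, amp = a,
                        rebound = 0.11 * defl * (1 - 0.109))
  })
  sr <- sag_and_rebound(sweeps)
  expect_equal(sr$rebound_slope, -0.11, tolerance = 1e-3)
})

test_that("chirp impedance matches the analytic RC low-pass within 2%", {
  R <- 0.1; C <- 100
  p <- neuron_params(C_m = C, g_leak = 1 / R, g_hcn_max = 0)
  im <- impedance_profile(simulate_protocol(p, stim_chirp())[[1]])
  zr <- 1000 * R / sqrt(1 + (2 * pi * im$profile$freq * R * C / 1000)^2)
  expect_lt(max(abs(im$profile$Z - zr) / zr), 0.02)
  expect_lt(im$f_res, 0.3)
  expect_lt(abs(im$Q - 1), 0.05)
})

test_that("FFT impedance agrees with a sine-by-sine steady-state oracle", {
  p <- neuron_params(g_hcn_max = 0, C_m = 120, g_leak = 8)
  im <- impedance_profile(simulate_protocol(p, stim_chirp())[[1]])
  ib <- spinephys:::.bias_current(p, -60)
  for (f in c(0.5, 2, 8)) {
    # inject a pure sine, measure the steady-state amplitude ratio
    n_cyc <- max(8, ceiling(4 * f))
    t_ms <- seq(0.025, n_cyc / f * 1000, by = 0.025)
    stim <- 50 * sin(2 * pi * f * t_ms / 1000)
    r <- spinephys:::.run_core(p, stim, "current_clamp", -60, ib)
    v <- r$rec; nn <- length(v)
    tail_i <- (nn - round(2 / f / 5e-5)):nn        # final two cycles
    z_sine <- 1000 * (max(v[tail_i]) - min(v[tail_i])) / 2 / 50
    z_fft <- im$profile$Z[which.min(abs(im$profile$freq - f))]
    expect_lt(abs(z_fft - z_sine) / z_sine, 0.03)
  }
})

test_that("chirp analysis rejects non-chirp stimuli", {
  p <- neuron_params(g_hcn_max = 0)
  sw <- simulate_protocol(p, stim_step_family(amplitudes = -50))[[1]]
  sw$markers <- tibble::tibble(label = c("chirp_on", "chirp_off"),
                               time = c(0.1, 0.6))
  expect_error(impedance_profile(sw), "chirp")
})

test_that("resonance recovery: analytic peak placement is recovered by the pipeline", {
  for (f_tgt in c(0.8, 1.1)) {
    p <- resonant_membrane(f_tgt)
    expect_equal(attr(p, "f_peak_analytic"), f_tgt, tolerance = 1e-4)
    im <- impedance_profile(simulate_protocol(p, stim_chirp())[[1]])
    expect_lt(abs(im$f_res - f_tgt), 0.1)
  }
})

test_that("ground-truth recovery across random parameter draws", {
  set.seed(5)
  for (i in 1:5) {
    R <- runif(1, 0.12, 0.3); C <- runif(1, 50, 120)
    p <- neuron_params(C_m = C, g_leak = 1 / R, g_hcn_max = 0)
    sws <- simulate_protocol(p, stim_step_family(amplitudes = c(-25, -50)))
    expect_equal(input_resistance(sws), 1000 * R, tolerance = 0.01)
  }
})
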