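test_that("passive cell matches the analytic RC charging curve within 0.5%", {
  R <- 0.150; C <- 100                     # GOhm, pF -> tau 15 ms
  p <- neuron_params(C_m = C, g_leak = 1 / R, g_hcn_max = 0, E_leak = -65)
  sw <- simulate_protocol(p, stim_step_family(amplitudes = -100))[[1]]
  tt <- sweep_time(sw)
  i_on <- round(0.1 / sw$dt) + 1
  base <- mean(sw$samples[1:(i_on - 1)])
  tau_s <- R * C / 1000
  seg <- tt >= 0.11 & tt < 0.6
  analytic <- base - 100 * R * (1 - exp(-(tt[seg] - 0.1) / tau_s))
  dv_max <- 100 * R                        # 15 mV scale
  expect_lt(max(abs(sw$samples[seg] - analytic)) / dv_max, 0.005)
})

test_that("without HCN there is no sag; with the WT parameters there is sag and rebound", {
  passive <- neuron_params(g_hcn_max = 0)
  sr0 <- sag_and_rebound(simulate_protocol(passive,
                                           stim_step_family(amplitudes = -100)))
  expect_lt(sr0$sag_pct, 0.5)
  wt <- neuron_params()
  sw <- simulate_protocol(wt, stim_step_family(amplitudes = -125))
  sr <- sag_and_rebound(sw)
  expect_gt(sr$sag_pct, 5)
  expect_gt(sr$per_step$rebound[1], 0.5)   # depolarising overshoot on release
})

test_that("identical parameters, stimulus and seed give bit-identical sweeps", {
  p <- neuron_params()
  a <- simulate_protocol(p, stim_step_family(amplitudes = c(-50, 50)),
                         seed = 42)
  b <- simulate_protocol(p, stim_step_family(amplitudes = c(-50, 50)),
                         seed = 42)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
})

test_that("unstable integration aborts with a diagnostic", {
  p <- neuron_params(C_m = 0.5, g_leak = 0.01, g_hcn_max = 0)
  expect_error(
    simulate_protocol(p, stim_step_family(amplitudes = 5000)),
    "unstable")
})

test_that("a pure low-pass membrane has monotone non-increasing impedance", {
  p <- neuron_params(g_hcn_max = 0, C_m = 120, g_leak = 5)
  im <- impedance_profile(simulate_protocol(p, stim_chirp())[[1]])
  z <- im$profile$Z_smooth
  # allow tiny numerical ripple
  expect_true(all(diff(z) < 0.02 * max(z)))
  expect_lt(im$f_res, 0.3)                 # peak at the lowest frequency
  expect_lt(abs(im$Q - 1), 0.05)
})

test_that("increasing the HCN conductance decreases steady-state input resistance", {
  ri <- vapply(c(0, 0.7, 2), function(g) {
    p <- neuron_params(g_hcn_max = g)
    input_resistance(simulate_protocol(
      p, stim_step_family(amplitudes = c(-25, -50))))
  }, numeric(1))
  expect_true(all(diff(ri) < 0))
})

test_that("voltage-clamp I_h matches the algebraic steady-state oracle", {
  p <- room_temp_kinetics(neuron_params())
  curve <- extract_ih(simulate_protocol(
    p, stim_vstep_family(targets = -120, dur = 8)))
  minf <- function(v) 1 / (1 + exp((v - p$hcn_V12) / p$hcn_k))
  oracle <- p$g_hcn_max * (minf(-120) - minf(-50)) * abs(-120 - p$E_hcn)
  expect_lt(abs(curve$ih_amp - oracle) / oracle, 0.02)
})

test_that("drug transforms behave as documented", {
  p <- neuron_params()
  zd <- apply_drug(p, "ZD")
  expect_equal(zd$g_hcn_max, 0)
  sr <- sag_and_rebound(simulate_protocol(zd,
                                          stim_step_family(amplitudes = -125)))
  expect_lt(sr$sag_pct, 0.5)
  expect_identical(apply_drug(p, "ZD", block = 0), p)
  fk <- apply_drug(neuron_params(hcn_V12 = -92), "forskolin", dv = 6)
  expect_equal(fk$hcn_V12, -86)
})

test_that("cohort generation is deterministic and draws match the presets", {
  a <- generate_cohort(n_animals = 2, cells_per_animal = 1,
                       protocols = "steps", seed = 9)
  b <- generate_cohort(n_animals = 2, cells_per_animal = 1,
                       protocols = "steps", seed = 9)
  expect_identical(a$sweeps[[1]][[1]]$samples, b$sweeps[[1]][[1]]$samples)
  expect_identical(a$params, b$params)
  # Monte-Carlo oracle: large draw of spine amplitudes hits the preset mean
  set.seed(1)
  wt <- genotype_preset("WT")
  amps <- r_uepsc_amp(1000, wt$uepsc_mean, wt$uepsc_cv)
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - wt$uepsc_mean), 3 * se)
  # silent draws follow the preset fraction (binomial 3-sigma)
  ko <- genotype_preset("KO")
  syn <- draw_synapses(ko, 1000)
  expect_lt(abs(mean(syn$silent) - ko$silent_frac),
            3 * sqrt(ko$silent_frac * (1 - ko$silent_frac) / 1000))
})
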