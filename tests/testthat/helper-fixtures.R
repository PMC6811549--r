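# Shared fixture builders; everything is generated in code at test time.

# minimal two-cell cohort with one short synthetic sweep per cell
tiny_cohort <- function(seed = 1) {
  set.seed(seed)
  mk_sweep <- function() {
    n <- 2000
    new_sweep(rnorm(n, -60, 0.2), numeric(n), 5e-5, "current_clamp",
              markers = tibble::tibble(label = "step_on", time = 0.01),
              holding = -60)
  }
  new_cohort(tibble::tibble(
    cell_id = c("C1", "C2"), genotype = c("WT", "KO"),
    animal_id = c("A1", "A2"), litter_id = c("L1", "L1"),
    slice_id = c("S1", "S2"), protocol = "steps",
    sweeps = list(list(mk_sweep(), mk_sweep()), list(mk_sweep()))),
    seed = seed)
}

# constructed step sweep with exact deflections (no dynamics)
flat_step_sweep <- function(dv_steady, amp, baseline = -60, dt = 5e-5,
                            pre = 0.1, dur = 0.5, post = 0.25) {
  n <- round((pre + dur + post) / dt)
  v <- rep(baseline, n)
  i_on <- round(pre / dt) + 1; i_off <- round((pre + dur) / dt)
  v[i_on:i_off] <- baseline + dv_steady
  stim <- numeric(n); stim[i_on:i_off] <- amp
  new_sweep(v, stim, dt, "current_clamp",
            markers = tibble::tibble(label = c("step_on", "step_off"),
                                     time = c(pre, pre + dur)),
            holding = baseline)
}

# voltage-clamp sweep of noise with template-shaped events injected at
# known times
injected_event_sweep <- function(times, amps, noise_sd = 2, dur = 30,
                                 template = default_template("ampa"),
                                 dt = 5e-5, seed = 1) {
  set.seed(seed)
  n <- round(dur / dt)
  y <- rnorm(n, 0, noise_sd)
  tv <- template_vector(template, dt)
  for (i in seq_along(times)) {
    i0 <- round(times[i] / dt) + 1
    idx <- i0:min(i0 + length(tv) - 1, n)
    y[idx] <- y[idx] + amps[i] * tv[seq_along(idx)]
  }
  new_sweep(y, numeric(n), dt, "voltage_clamp", holding = -70)
}

# exhaustive two-sided Fisher p-value by direct hypergeometric
# enumeration (point-probability rule), independent of stats::fisher.test
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  logp <- function(x) lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  lp <- vapply(lo:hi, logp, numeric(1))
  p_obs <- lp[a - lo + 1]
  sum(exp(lp[lp <= p_obs + 1e-7]))
}
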