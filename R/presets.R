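#' Genotype presets for the synthetic-cohort generator
#'
#' Distribution parameters that define the simulated study conditions for
#' wild-type (`"WT"`) and Fmr1 knockout (`"KO"`) layer-4 stellate cells.
#' Group means are taken from the printed study values: single-spine
#' AMPA uEPSC amplitude 6.9 vs 9.8 pA, silent-spine fraction 0.064 vs
#' 0.176, HCN activation midpoint -86 vs -92 mV, multi-innervated-spine
#' fraction 0.072 vs 0.205, AMPA mEPSC rate 3.9 vs 4.9 Hz (amplitude
#' 13.1 vs 12.7 pA), NMDA mEPSC rate 1.7 vs 2.6 Hz (amplitude 16.9 vs
#' 14.4 pA), spine head width 0.48 vs 0.48 um, neck length 1.36 vs
#' 1.27 um, spine density 6.8 vs 6.1 per 10 um. Dispersions and the
#' cell-level passive parameters are chosen once as physiologically
#' realistic for immature stellate cells and are documented in the
#' methods vignette.
#'
#' @param genotype `"WT"` or `"KO"`.
#' @return A `genotype_preset` list.
#' @export
genotype_preset <- function(genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  wt <- genotype == "WT"
  p <- list(
    genotype = genotype,
    # cell-level parameter distributions (log-normal unless noted)
    g_leak_mean = if (wt) 3.7 else 3.55,     # nS; KO slightly higher R_I
    g_leak_cv = 0.15,
    g_hcn_mean = 0.7, g_hcn_cv = 0.15,       # same channel complement
    hcn_V12_mean = if (wt) -86 else -92,     # mV (normal, sd below)
    hcn_V12_sd = 1.5,
    C_m_mean = 70, C_m_cv = 0.10,
    # single-spine synapse distributions
    uepsc_mean = if (wt) 6.9 else 9.8,       # pA at -70 mV
    uepsc_cv = 0.40, uepsc_family = "log-normal",
    silent_frac = if (wt) 0.064 else 0.176,
    nmda_g_ratio = if (wt) 2.0 else 2.7,     # g_nmda / g_ampa
    nmda_ratio_cv = 0.25,
    n_spines = 8L,
    # mEPSC generator
    mepsc_ampa_rate = if (wt) 3.9 else 4.9,  # Hz
    mepsc_ampa_amp = if (wt) 13.1 else 12.7, # pA
    mepsc_nmda_rate = if (wt) 1.7 else 2.6,  # Hz
    mepsc_nmda_amp = if (wt) 16.9 else 14.4, # pA
    mepsc_dur = 60,                          # s recorded per holding
    # multi-spine summation (near-simultaneous protocol)
    ensemble_gain = 28,                      # conductance gain vs sequential
    ensemble_nmda_ratio = if (wt) 0.3 else 0.5,  # NMDA weight in ensembles
    n_ensemble = 10L,
    # thalamocortical train
    tca_epsc = if (wt) 181 else 159,         # pA target EPSC
    tca_nmda_ratio = if (wt) 1.2 else 2.4,
    tca_scale = 0.7,                         # dendritic conductance per pA
    tca_nmda_decay = 150,                    # ms; GluN2B-slow at P10-14
    tca_trial_cv = 0.25,
    # structure tables
    mis_frac = if (wt) 0.072 else 0.205,
    head_width_mean = 0.48, head_width_sd = 0.13,
    neck_len_mean = if (wt) 1.36 else 1.27, neck_len_cv = 0.35,
    density_mean = if (wt) 6.8 else 6.1, density_sd = 1.6,  # per 10 um
    sf_slope = 7.8, sf_sigma = 6.0           # structure-function regression
  )
  class(p) <- "genotype_preset"
  p
}

#' Draw ground-truth cell parameters from a preset
#'
#' @param preset A [genotype_preset()].
#' @return A [neuron_params()] object with the drawn values.
#' @export
draw_cell_params <- function(preset) {
  ln <- function(m, cv) stats::rlnorm(1, log(m) - log(1 + cv^2) / 2,
                                      sqrt(log(1 + cv^2)))
  neuron_params(
    C_m = ln(preset$C_m_mean, preset$C_m_cv),
    g_leak = ln(preset$g_leak_mean, preset$g_leak_cv),
    g_hcn_max = ln(preset$g_hcn_mean, preset$g_hcn_cv),
    hcn_V12 = stats::rnorm(1, preset$hcn_V12_mean, preset$hcn_V12_sd))
}

#' Draw a synapse table for one cell
#'
#' Spines are silent (no AMPA conductance, NMDA present) with the preset
#' probability; responsive spines draw their AMPA conductance from the
#' preset uEPSC amplitude distribution (amplitude / 70 mV driving force at
#' -70 mV) and their NMDA conductance as a log-normal multiple of AMPA.
#'
#' @param preset A [genotype_preset()].
#' @param n Number of spines.
#' @return A synapse table ([synapse_spec()] rows) with a `silent` column.
#' @export
draw_synapses <- function(preset, n = preset$n_spines) {
  ln <- function(k, m, cv) stats::rlnorm(k, log(m) - log(1 + cv^2) / 2,
                                         sqrt(log(1 + cv^2)))
  silent <- stats::runif(n) < preset$silent_frac
  amp <- r_uepsc_amp(n, preset$uepsc_mean, preset$uepsc_cv)
  g_a <- ifelse(silent, 0, amp / 70)
  ratio <- ln(n, preset$nmda_g_ratio, preset$nmda_ratio_cv)
  # silent spines carry a full NMDA complement (a clear current at +40 mV
  # is what makes them classifiable as silent rather than unresponsive)
  g_n <- ifelse(silent, pmax(amp, preset$uepsc_mean) / 70 * ratio,
                amp / 70 * ratio)
  tab <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    synapse_spec(sprintf("sp%02d", i), g_ampa = g_a[i], g_nmda = g_n[i])))
  tab$silent <- silent
  tab
}

#' Draw responsive-spine uEPSC amplitudes
#'
#' Responsive spines carry amplitudes from a log-normal left-truncated at
#' the measurement floor (an unresolvable AMPA response is what defines a
#' spine as silent or unresponsive, so the responsive-amplitude
#' distribution has no mass there). The log-mean is solved so that the
#' truncated distribution has exactly the requested mean.
#'
#' @param n Number of draws.
#' @param mean Target mean amplitude (pA) of the truncated distribution.
#' @param cv Coefficient of variation of the underlying log-normal.
#' @param floor Truncation point (pA), the typical 3x-noise resolution
#'   limit after repetition averaging.
#' @return Numeric vector of amplitudes (all > `floor`).
#' @export
r_uepsc_amp <- function(n, mean, cv, floor = 4.5) {
  sdl <- sqrt(log(1 + cv^2))
  tmean <- function(mu) {     # mean of the left-truncated log-normal
    exp(mu + sdl^2 / 2) *
      stats::pnorm((mu + sdl^2 - log(floor)) / sdl) /
      stats::pnorm((mu - log(floor)) / sdl)
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       c(log(mean) - 2, log(mean) + 1), tol = 1e-10)$root
  # inverse-CDF sampling of the truncated distribution
  p0 <- stats::plnorm(floor, mu, sdl)
  stats::qlnorm(p0 + stats::runif(n) * (1 - p0), mu, sdl)
}

#' Apply a bath drug to ground-truth parameters
#'
#' `"ZD"` (ZD-7288, HCN blocker) scales the maximal HCN conductance by
#' `1 - block` (default full block). `"forskolin"` (adenylyl cyclase
#' activator) shifts the activation midpoint depolarised by `dv` mV; the
#' default +6 mV restores a KO midpoint of -92 mV to the WT -86 mV,
#' matching the normalisation of the activation curves seen with raised
#' cyclic-AMP.
#'
#' @param params A [neuron_params()] object.
#' @param drug `"ZD"` or `"forskolin"`.
#' @param block Fractional HCN block for ZD, in \[0, 1\].
#' @param dv Depolarising midpoint shift (mV) for forskolin.
#' @return Modified [neuron_params()].
#' @export
apply_drug <- function(params, drug = c("ZD", "forskolin"), block = 1,
                       dv = 6) {
  drug <- match.arg(drug)
  if (drug == "ZD") {
    stopifnot(block >= 0, block <= 1)
    params$g_hcn_max <- params$g_hcn_max * (1 - block)
  } else {
    params$hcn_V12 <- params$hcn_V12 + dv
  }
  params
}

#' Build a linearized resonant membrane with a chosen impedance peak
#'
#' Constructs an R-C membrane in parallel with a phenomenological
#' inductive branch (series resistance `r` GOhm, inductance `L` GOhm ms)
#' whose closed-form impedance
#' \eqn{Z(\omega) = 1 / (g_L + i\omega C + 1/(r + i\omega L))}
#' peaks at the requested frequency. `L` is solved from the analytic
#' expression by root finding; the result is independent of the
#' time-domain simulator and so can serve as its oracle.
#'
#' @param f_peak Target resonant frequency (Hz).
#' @param C_m Capacitance (pF).
#' @param R_input Leak-only input resistance (MOhm).
#' @param ind_r Inductive-branch series resistance (GOhm).
#' @return A [neuron_params()] with `use_ind = TRUE`, no HCN conductance,
#'   and an `f_peak_analytic` attribute with the achieved analytic peak.
#' @export
resonant_membrane <- function(f_peak, C_m = 500, R_input = 250,
                              ind_r = 0.05) {
  g_leak <- 1000 / R_input               # nS
  peak_of <- function(L) {
    f <- function(fr) Mod(impedance_analytic_(fr, g_leak, C_m, ind_r, L))
    stats::optimize(f, c(0.02, 25), maximum = TRUE, tol = 1e-7)$maximum
  }
  stopifnot(f_peak > 0.15, f_peak < 6)   # resonant regime of this branch
  sol <- stats::uniroot(function(lgL) peak_of(exp(lgL)) - f_peak,
                        c(log(5), log(2e4)), tol = 1e-9)
  L <- exp(sol$root)
  p <- neuron_params(C_m = C_m, g_leak = g_leak, E_leak = -60,
                     g_hcn_max = 0, use_ind = TRUE, ind_r = ind_r,
                     ind_L = L)
  attr(p, "f_peak_analytic") <- peak_of(L)
  p
}

# closed-form impedance (GOhm) of the R-C + inductive-branch membrane
impedance_analytic_ <- function(f, g_leak, C_m, ind_r, ind_L) {
  w <- 2 * pi * f / 1000                 # rad/ms
  1 / (g_leak + 1i * w * C_m + 1 / (ind_r + 1i * w * ind_L))
}

#' Analytic impedance of a parameter set
#'
#' Closed-form impedance magnitude (MOhm) of the passive membrane plus,
#' when enabled, the phenomenological inductive branch. Used as the
#' independent oracle for the chirp-based impedance estimate.
#'
#' @param params A [neuron_params()] object (HCN is ignored; this is the
#'   linear(ized) membrane).
#' @param f Frequencies (Hz).
#' @return Numeric vector of impedance magnitudes (MOhm).
#' @export
impedance_analytic <- function(params, f) {
  w <- 2 * pi * f / 1000
  y <- params$g_leak + 1i * w * params$C_m
  if (params$use_ind) y <- y + 1 / (params$ind_r + 1i * w * params$ind_L)
  1000 * Mod(1 / y)
}

## ---- cohort generation --------------------------------------------------

.protocols_all <- c("steps", "chirp", "vsteps", "uncaging", "ensemble",
                    "mepsc", "train")

#' Generate a synthetic two-genotype cohort
#'
#' Draws per-cell ground-truth parameters from the genotype presets,
#' simulates every requested protocol, and assembles a cohort tibble with
#' the nesting structure used by the hierarchical statistics (litters
#' containing animals of both genotypes, one slice per cell). Ground
#' truth is stored in the `params` list-column; uncaging synapse tables
#' in `synapses` rows.
#'
#' @param preset_wt,preset_ko [genotype_preset()] objects.
#' @param n_animals Animals per genotype (>= 2).
#' @param cells_per_animal Cells recorded per animal.
#' @param protocols Character subset of
#'   `c("steps","chirp","vsteps","uncaging","ensemble","mepsc","train")`.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   (presets, sizes, protocols, seed).
#' @return A cohort tibble (see [new_cohort()]).
#' @export
generate_cohort <- function(preset_wt = genotype_preset("WT"),
                            preset_ko = genotype_preset("KO"),
                            n_animals = 3, cells_per_animal = 2,
                            protocols = c("steps", "vsteps", "uncaging"),
                            seed = 1) {
  stopifnot(n_animals >= 2)
  protocols <- match.arg(protocols, .protocols_all, several.ok = TRUE)
  set.seed(seed)
  rows <- list()
  animals <- tibble::tibble(
    genotype = rep(c("WT", "KO"), each = n_animals),
    animal_id = sprintf("A%02d", seq_len(2 * n_animals)),
    litter_id = sprintf("L%02d", rep(seq_len(n_animals), times = 2)))
  cellno <- 0L
  for (a in seq_len(nrow(animals))) {
    preset <- if (animals$genotype[a] == "WT") preset_wt else preset_ko
    for (ci in seq_len(cells_per_animal)) {
      cellno <- cellno + 1L
      cell_id <- sprintf("C%03d", cellno)
      prm <- draw_cell_params(preset)
      syn <- draw_synapses(preset)
      meta <- tibble::tibble(
        cell_id = cell_id, genotype = animals$genotype[a],
        animal_id = animals$animal_id[a], litter_id = animals$litter_id[a],
        slice_id = sprintf("S%03d", cellno))
      for (pr in protocols) {
        sw <- .sim_protocol(pr, prm, syn, preset,
                            seed = seed * 10000L + cellno * 20L +
                              match(pr, .protocols_all))
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          meta, protocol = pr, sweeps = list(sw), params = list(unclass(prm)),
          synapses = list(syn))
      }
    }
  }
  new_cohort(dplyr::bind_rows(rows), seed = seed,
             preset = c(WT = "WT", KO = "KO"))
}

# simulate one named protocol for one cell
.sim_protocol <- function(protocol, prm, syn, preset, seed) {
  switch(
    protocol,
    steps = simulate_protocol(prm, stim_step_family(), seed = seed,
                              spiking = TRUE),
    chirp = simulate_protocol(prm, stim_chirp(), seed = seed),
    vsteps = simulate_protocol(room_temp_kinetics(prm), stim_vstep_family(),
                               seed = seed),
    uncaging = {
      # three repetitions per holding potential; spines 2 s apart
      reps <- list()
      for (hold in c(-70, 40)) for (r in 1:3) {
        times <- stats::setNames(as.list(0.1 + 2 * (seq_len(nrow(syn)) - 1)),
                                 syn$spine_id)
        st <- stim_uncaging(times, total = 2 * nrow(syn) + 0.2,
                            holding = hold)
        reps[[length(reps) + 1L]] <-
          simulate_protocol(prm, st, synapses = syn,
                            seed = seed + 7L * r + (hold > 0))[[1]]
      }
      reps
    },
    ensemble = .sim_ensemble(prm, syn, preset, seed),
    mepsc = .sim_mepsc(prm, preset, seed),
    train = .sim_train(prm, preset, seed))
}

# near-simultaneous multi-spine protocol: per-spine singles, then
# cumulative ensembles of 1..n spines (0.5 ms between spines)
.sim_ensemble <- function(prm, syn, preset, seed) {
  prm2 <- prm
  prm2$compartments <- 2
  n <- preset$n_ensemble
  syn_e <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    j <- ((i - 1L) %% nrow(syn)) + 1L
    s <- syn[j, ]
    s$spine_id <- sprintf("es%02d", i)
    s$g_ampa <- s$g_ampa * preset$ensemble_gain
    s$g_nmda <- s$g_ampa * preset$ensemble_nmda_ratio
    s
  }))
  out <- list()
  # singles (subthreshold; measured for the expected linear sum)
  for (i in seq_len(n)) {
    st <- stim_uncaging(stats::setNames(list(0.1), syn_e$spine_id[i]),
                        total = 0.5, holding = -60)
    out[[length(out) + 1L]] <- simulate_protocol(
      prm2, st, synapses = syn_e, mode = "current_clamp",
      seed = seed + i, spiking = FALSE)[[1]]
  }
  # cumulative ensembles with stylized spiking enabled
  for (k in seq_len(n)) {
    times <- stats::setNames(as.list(0.1 + 5e-4 * (seq_len(k) - 1)),
                             syn_e$spine_id[seq_len(k)])
    st <- stim_uncaging(times, total = 0.5, holding = -60)
    sw <- simulate_protocol(prm2, st, synapses = syn_e,
                            mode = "current_clamp", seed = seed + 100L + k,
                            spiking = TRUE)[[1]]
    attr(sw, "ensemble_count") <- k
    out[[length(out) + 1L]] <- sw
  }
  attr(out, "n_singles") <- n
  out
}

.sim_mepsc <- function(prm, preset, seed) {
  g_a <- preset$mepsc_ampa_amp / 70
  # +40 mV: NMDA driving force 40 mV with near-complete Mg unblock
  unblock <- 1 / (1 + prm$mg_mM * prm$mg_scale * exp(-prm$mg_slope * 40))
  g_n <- preset$mepsc_nmda_amp / (40 * unblock)
  # kinetics match the default detection templates (somatic mEPSCs are
  # slower than the uncaging responses)
  syn_a <- synapse_spec("mA", g_ampa = g_a, g_nmda = 0,
                        ampa_rise = 0.4, ampa_decay = 4)
  syn_n <- synapse_spec("mN", g_ampa = 0, g_nmda = g_n,
                        nmda_rise = 3, nmda_decay = 40)
  c(simulate_protocol(prm, stim_poisson(preset$mepsc_ampa_rate,
                                        preset$mepsc_dur, holding = -70),
                      synapses = syn_a, seed = seed),
    simulate_protocol(prm, stim_poisson(preset$mepsc_nmda_rate,
                                        preset$mepsc_dur, holding = 40),
                      synapses = syn_n, seed = seed + 1L))
}

.sim_train <- function(prm, preset, seed) {
  prm2 <- prm
  prm2$compartments <- 2
  g_a <- preset$tca_epsc / 70 * preset$tca_scale
  syn <- synapse_spec("tca", g_ampa = g_a,
                      g_nmda = g_a * preset$tca_nmda_ratio,
                      nmda_decay = preset$tca_nmda_decay)
  out <- list()
  for (fr in c(5, 10)) for (trial in 1:10) {
    st <- stim_train(fr, holding = -60)
    tt <- st$start + (seq_len(st$n_stim) - 1) / fr
    set.seed(seed + 1000L * fr + trial)
    w <- exp(stats::rnorm(1, 0, preset$tca_trial_cv))
    ev <- tibble::tibble(spine_id = "tca", time_s = tt, weight = w)
    sw <- simulate_protocol(prm2, st, synapses = syn, events = ev,
                            seed = seed + 100L * fr + trial,
                            spiking = TRUE)[[1]]
    attr(sw, "train_freq") <- fr
    attr(sw, "trial") <- trial
    out[[length(out) + 1L]] <- sw
  }
  out
}

#' Generate per-spine morphology and per-animal ultrastructure tables
#'
#' Morphology: per-animal spine head widths and neck lengths (STED-style
#' measurement tables), with uncaged spines carrying a linked uEPSC
#' amplitude generated with the preset structure-function slope and noise
#' (the weak-correlation regime). Ultrastructure: per-animal dendrite
#' records with spine and multi-innervated-spine counts.
#'
#' @param preset A [genotype_preset()].
#' @param n_animals Number of animals.
#' @param spines_per_animal,dendrites_per_animal Table sizes.
#' @param seed Integer seed.
#' @return A list with tibbles `morphology` (spine_id, animal_id,
#'   genotype, head_width, neck_length, uncaged, ampa_amp, dendrite_length)
#'   and `ultrastructure` (animal_id, genotype, dendrite_id, n_spines,
#'   n_mis).
#' @export
generate_structure <- function(preset, n_animals, spines_per_animal = 30,
                               dendrites_per_animal = 8, seed = 1) {
  set.seed(seed)
  morph <- list(); ultra <- list()
  for (a in seq_len(n_animals)) {
    aid <- sprintf("%s_A%02d", preset$genotype, a)
    n <- spines_per_animal
    hw <- pmax(stats::rnorm(n, preset$head_width_mean, preset$head_width_sd),
               0.12)
    nl <- stats::rlnorm(n, log(preset$neck_len_mean) -
                          log(1 + preset$neck_len_cv^2) / 2,
                        sqrt(log(1 + preset$neck_len_cv^2)))
    uncaged <- seq_len(n) <= round(n / 3)
    amp <- ifelse(uncaged,
                  preset$sf_slope * hw +
                    (preset$uepsc_mean - preset$sf_slope *
                       preset$head_width_mean) +
                    stats::rnorm(n, 0, preset$sf_sigma), NA_real_)
    dlen <- 10 * n / stats::rnorm(1, preset$density_mean, preset$density_sd)
    morph[[a]] <- tibble::tibble(
      spine_id = sprintf("%s_sp%03d", aid, seq_len(n)), animal_id = aid,
      genotype = preset$genotype, head_width = hw, neck_length = nl,
      uncaged = uncaged, ampa_amp = pmax(amp, 0.5),
      dendrite_length = dlen / n)
    nsp <- pmax(stats::rpois(dendrites_per_animal, 4.4), 1)
    ultra[[a]] <- tibble::tibble(
      animal_id = aid, genotype = preset$genotype,
      dendrite_id = sprintf("%s_d%02d", aid, seq_len(dendrites_per_animal)),
      n_spines = nsp, n_mis = stats::rbinom(dendrites_per_animal, nsp,
                                            preset$mis_frac))
  }
  list(morphology = dplyr::bind_rows(morph),
       ultrastructure = dplyr::bind_rows(ultra))
}
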