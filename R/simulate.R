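#' Conductance-based point-neuron parameters
#'
#' Ground-truth parameter set for the simulator: passive membrane, an HCN
#' conductance with first-order Boltzmann gating
#' \eqn{m_\infty(V) = 1/(1+\exp((V-V_{1/2})/k))} and a voltage-dependent
#' time constant (logistic between `hcn_tau_min` and `hcn_tau_max`), an
#' optional lumped dendritic compartment coupled by `g_c`, an optional
#' phenomenological inductive branch for building linearized resonant
#' membranes, and a stylized spike mechanism (threshold crossing pastes a
#' stereotyped action-potential waveform and resets).
#'
#' Units: capacitance pF, conductance nS, voltage mV, time constants ms.
#'
#' @param C_m Somatic capacitance (pF).
#' @param g_leak Somatic leak conductance (nS); input resistance of the
#'   passive soma is `1000/g_leak` MOhm.
#' @param E_leak Leak reversal (mV).
#' @param g_hcn_max Maximal HCN conductance (nS).
#' @param hcn_V12,hcn_k Activation midpoint (mV) and slope (mV, > 0).
#' @param hcn_tau_min,hcn_tau_max,hcn_tau_V12,hcn_tau_k Gating time constant
#'   (ms): logistic in V, fast when hyperpolarized, slow when depolarized.
#' @param E_hcn HCN reversal (mV).
#' @param compartments 1 (soma only) or 2 (soma + lumped dendrite).
#' @param C_dend,g_leak_dend,g_c Dendritic capacitance, leak, and coupling
#'   conductance (used when `compartments = 2`).
#' @param hcn_dend_frac Fraction of `g_hcn_max` placed on the dendrite in
#'   the two-compartment model.
#' @param mg_mM,mg_scale,mg_slope NMDA receptor magnesium block constants:
#'   block factor \eqn{1/(1+[Mg] \cdot scale \cdot e^{-slope \cdot V})}.
#' @param v_th,v_reset,spike_refrac Spike threshold, reset (mV) and
#'   refractory period (ms) of the stylized spike mechanism.
#' @param use_ind,ind_r,ind_L Phenomenological inductive branch: series
#'   resistance (GOhm) and inductance (GOhm ms) in parallel with the
#'   membrane, anchored at the initial potential.
#' @param noise_sd_mV,noise_sd_pA Additive Gaussian recording noise SD for
#'   the two clamp modes.
#' @return A `neuron_params` list.
#' @export
neuron_params <- function(C_m = 70, g_leak = 3.7, E_leak = -65,
                          g_hcn_max = 0.7, hcn_V12 = -86, hcn_k = 8,
                          hcn_tau_min = 40, hcn_tau_max = 250,
                          hcn_tau_V12 = -86, hcn_tau_k = 12,
                          E_hcn = -30, compartments = 1,
                          C_dend = 8, g_leak_dend = 0.8, g_c = 2,
                          hcn_dend_frac = 0.3,
                          mg_mM = 1, mg_scale = 1 / 3.57, mg_slope = 0.062,
                          v_th = -49, v_reset = -58, spike_refrac = 3,
                          use_ind = FALSE, ind_r = 0.3, ind_L = 60,
                          noise_sd_mV = 0.2, noise_sd_pA = 2) {
  stopifnot(C_m > 0, g_leak >= 0, g_hcn_max >= 0, hcn_k > 0,
            compartments %in% c(1, 2))
  p <- as.list(environment())
  class(p) <- "neuron_params"
  p
}

#' Synapse specification
#'
#' One dendritic spine synapse: an AMPA and an NMDA receptor component,
#' each a difference-of-exponentials conductance normalised to unit peak
#' and scaled by its maximal conductance. A silent spine is `g_ampa = 0`
#' with `g_nmda > 0`. `n_contacts > 1` models multi-innervated spines
#' (independent boutons on one spine) by scaling both conductances.
#'
#' @param spine_id Identifier.
#' @param g_ampa,g_nmda Peak conductances (nS), >= 0.
#' @param ampa_rise,ampa_decay,nmda_rise,nmda_decay Kinetics (ms).
#' @param E_syn Reversal potential (mV).
#' @param n_contacts Integer >= 1.
#' @param current_based If `TRUE` the AMPA component injects a fixed
#'   current waveform with peak `g_ampa` pA (a perfectly linear input used
#'   by superposition oracles) and the NMDA component is ignored.
#' @param comp `"soma"` or `"dend"` (placement in the two-compartment
#'   model; ignored for one compartment).
#' @return A one-row tibble; rows from several calls bind into a synapse
#'   table.
#' @export
synapse_spec <- function(spine_id, g_ampa, g_nmda = 0,
                         ampa_rise = 0.2, ampa_decay = 2.5,
                         nmda_rise = 3, nmda_decay = 40,
                         E_syn = 0, n_contacts = 1L,
                         current_based = FALSE, comp = "dend") {
  stopifnot(g_ampa >= 0, g_nmda >= 0, n_contacts >= 1)
  tibble::tibble(spine_id = as.character(spine_id),
                 g_ampa = g_ampa, g_nmda = g_nmda,
                 ampa_rise = ampa_rise, ampa_decay = ampa_decay,
                 nmda_rise = nmda_rise, nmda_decay = nmda_decay,
                 E_syn = E_syn, n_contacts = as.integer(n_contacts),
                 current_based = current_based, comp = comp)
}

#' Room-temperature gating kinetics for the I_h voltage-clamp protocol
#'
#' The dedicated I_h voltage-clamp recordings are made at room
#' temperature, where HCN gating is several-fold slower than at the
#' near-physiological temperature of the current-clamp protocols. This
#' helper returns the parameter set with correspondingly slow gating time
#' constants, chosen so that 5-s steps still reach steady state while
#' negligible activation develops inside the 10-60 ms instantaneous
#' measurement window.
#'
#' @param params A [neuron_params()] object.
#' @param tau_min,tau_max Replacement gating time constants (ms).
#' @return Modified [neuron_params()].
#' @export
room_temp_kinetics <- function(params, tau_min = 300, tau_max = 700) {
  params$hcn_tau_min <- tau_min
  params$hcn_tau_max <- tau_max
  params
}

# peak of (exp(-t/td) - exp(-t/tr)), used to normalise to unit peak
.dexp_peak <- function(tr, td) {
  tp <- tr * td / (td - tr) * log(td / tr)
  exp(-tp / td) - exp(-tp / tr)
}

## ---- stimulus specifications -------------------------------------------

#' Stimulus specifications for the standard protocols
#'
#' Constructors for the protocol family run in the study: 500-ms current
#' step families, 20-s 0.2-20 Hz chirps, 5-s voltage-clamp step families,
#' uncaging schedules (markers driving synapse events rather than injected
#' current), and stimulus trains. Times in seconds, currents pA,
#' voltages mV.
#'
#' @param amplitudes Step amplitudes (pA).
#' @param dur,pre,post Step duration and flanking baseline (s).
#' @return A `stim_spec` list consumed by [simulate()].
#' @export
stim_step_family <- function(amplitudes = seq(-125, 125, by = 25),
                             dur = 0.5, pre = 0.1, post = 0.25) {
  structure(list(kind = "step_family", amplitudes = amplitudes, dur = dur,
                 pre = pre, post = post), class = "stim_spec")
}

#' @rdname stim_step_family
#' @param f0,f1 Chirp start and end frequency (Hz).
#' @param amp Chirp amplitude (pA).
#' @param settle Baseline before the chirp (s).
#' @export
stim_chirp <- function(f0 = 0.2, f1 = 20, amp = 50, dur = 20, settle = 1) {
  structure(list(kind = "chirp", f0 = f0, f1 = f1, amp = amp, dur = dur,
                 settle = settle), class = "stim_spec")
}

#' @rdname stim_step_family
#' @param holding Voltage-clamp holding potential (mV).
#' @param targets Step target potentials (mV).
#' @export
stim_vstep_family <- function(holding = -50, targets = seq(-60, -120, by = -10),
                              dur = 5, pre = 0.5, post = 0.5) {
  structure(list(kind = "vstep_family", holding = holding, targets = targets,
                 dur = dur, pre = pre, post = post), class = "stim_spec")
}

#' @rdname stim_step_family
#' @param times Named list: `times[[spine_id]]` gives the uncaging times
#'   (s) for that spine within the sweep.
#' @param total Sweep duration (s).
#' @param holding Holding level (mV command in voltage clamp; target
#'   membrane potential held by bias current in current clamp).
#' @export
stim_uncaging <- function(times, total, holding = -70) {
  structure(list(kind = "uncaging_schedule", times = times, total = total,
                 holding = holding), class = "stim_spec")
}

#' @rdname stim_step_family
#' @param freq Train frequency (Hz).
#' @param n_stim Number of stimuli in the train.
#' @param start Time of the first stimulus (s).
#' @export
stim_train <- function(freq, n_stim = 5, start = 0.2, total = NULL,
                       holding = -60) {
  if (is.null(total)) total <- start + (n_stim - 1) / freq + 0.4
  structure(list(kind = "train", freq = freq, n_stim = n_stim, start = start,
                 total = total, holding = holding), class = "stim_spec")
}

#' @rdname stim_step_family
#' @param rate Poisson event rate (Hz).
#' @export
stim_poisson <- function(rate, dur = 60, holding = -70) {
  structure(list(kind = "poisson_events", rate = rate, dur = dur,
                 holding = holding), class = "stim_spec")
}

## ---- core simulation ----------------------------------------------------

.sim_dt_ms <- 0.025   # integration step; output decimated to the sweep dt

.spike_wave <- function(v_th, v_reset, dt_ms) {
  # stereotyped action potential: 0.3 ms rise to +35 mV, 0.9 ms fall
  t_up <- seq(0, 0.3, by = dt_ms)
  t_dn <- seq(dt_ms, 0.9, by = dt_ms)
  c(v_th + (35 - v_th) * t_up / 0.3,
    35 + (v_reset - 35) * (1 - exp(-t_dn / 0.25)) / (1 - exp(-0.9 / 0.25)))
}

.prm_for_core <- function(p, v_init, i_bias) {
  list(C_m = p$C_m, g_leak = p$g_leak, E_leak = p$E_leak,
       g_hcn_max = p$g_hcn_max, hcn_V12 = p$hcn_V12, hcn_k = p$hcn_k,
       E_hcn = p$E_hcn, hcn_tau_min = p$hcn_tau_min,
       hcn_tau_max = p$hcn_tau_max, hcn_tau_V12 = p$hcn_tau_V12,
       hcn_tau_k = p$hcn_tau_k, two_comp = p$compartments == 2,
       C_dend = p$C_dend, g_leak_dend = p$g_leak_dend, g_c = p$g_c,
       hcn_dend_frac = p$hcn_dend_frac, v_init = v_init, i_bias = i_bias,
       use_ind = p$use_ind, ind_r = p$ind_r, ind_L = p$ind_L,
       mg_mM = p$mg_mM, mg_scale = p$mg_scale, mg_slope = p$mg_slope)
}

# steady-state dendritic potential given a clamped/steady soma potential
.dend_steady <- function(p, vs) {
  if (p$compartments != 2) return(vs)
  ghd <- p$g_hcn_max * p$hcn_dend_frac
  f <- function(vd) p$g_leak_dend * (vd - p$E_leak) +
    ghd * (1 / (1 + exp((vd - p$hcn_V12) / p$hcn_k))) * (vd - p$E_hcn) -
    p$g_c * (vs - vd)
  stats::uniroot(f, c(-150, 50))$root
}

# bias current holding the soma at v_hold at rest
.bias_current <- function(p, v_hold) {
  ghs <- p$g_hcn_max * (if (p$compartments == 2) 1 - p$hcn_dend_frac else 1)
  minf <- 1 / (1 + exp((v_hold - p$hcn_V12) / p$hcn_k))
  ib <- p$g_leak * (v_hold - p$E_leak) + ghs * minf * (v_hold - p$E_hcn)
  if (p$compartments == 2) {
    vd <- .dend_steady(p, v_hold)
    ib <- ib - p$g_c * (vd - v_hold)
  }
  ib
}

.syn_for_core <- function(synapses, events, p) {
  # events: tibble(spine_id, time_s, weight); expanded to receptor indices
  if (is.null(synapses) || !nrow(synapses)) {
    return(list(gbar = numeric(), tau_rise = numeric(), tau_decay = numeric(),
                E_rev = numeric(), is_nmda = integer(),
                current_based = integer(), comp = integer(),
                peak_norm = numeric(), ev_receptor = integer(),
                ev_time = numeric(), ev_weight = numeric()))
  }
  rec <- list(); map <- list()
  for (i in seq_len(nrow(synapses))) {
    s <- synapses[i, ]
    sc <- s$n_contacts
    idx <- integer()
    if (s$g_ampa > 0) {
      rec[[length(rec) + 1L]] <- c(gbar = s$g_ampa * sc, tr = s$ampa_rise,
                                   td = s$ampa_decay, E = s$E_syn, nmda = 0,
                                   cur = as.integer(s$current_based),
                                   comp = as.integer(s$comp == "dend"))
      idx <- c(idx, length(rec))
    }
    if (s$g_nmda > 0 && !s$current_based) {
      rec[[length(rec) + 1L]] <- c(gbar = s$g_nmda * sc, tr = s$nmda_rise,
                                   td = s$nmda_decay, E = s$E_syn, nmda = 1,
                                   cur = 0L,
                                   comp = as.integer(s$comp == "dend"))
      idx <- c(idx, length(rec))
    }
    map[[s$spine_id]] <- idx
  }
  if (!length(rec)) return(.syn_for_core(NULL, NULL, p))
  m <- do.call(rbind, rec)
  ev_r <- integer(); ev_t <- numeric(); ev_w <- numeric()
  if (!is.null(events) && nrow(events)) {
    if (!"weight" %in% names(events)) events$weight <- 1
    for (j in seq_len(nrow(events))) {
      for (r in map[[as.character(events$spine_id[j])]]) {
        ev_r <- c(ev_r, r - 1L)
        ev_t <- c(ev_t, events$time_s[j] * 1000)
        ev_w <- c(ev_w, events$weight[j])
      }
    }
    o <- order(ev_t)
    ev_r <- ev_r[o]; ev_t <- ev_t[o]; ev_w <- ev_w[o]
  }
  list(gbar = m[, "gbar"], tau_rise = m[, "tr"], tau_decay = m[, "td"],
       E_rev = m[, "E"], is_nmda = as.integer(m[, "nmda"]),
       current_based = as.integer(m[, "cur"]), comp = as.integer(m[, "comp"]),
       peak_norm = mapply(.dexp_peak, m[, "tr"], m[, "td"]),
       ev_receptor = ev_r, ev_time = ev_t, ev_weight = ev_w)
}

.run_core <- function(p, stim_ms, mode, v_init, i_bias = 0, synapses = NULL,
                      events = NULL, spiking = FALSE, dt_out = 5e-5) {
  decim <- as.integer(round(dt_out * 1000 / .sim_dt_ms))
  syn <- .syn_for_core(synapses, events, p)
  spk <- list(enabled = spiking, v_th = p$v_th, v_reset = p$v_reset,
              refrac = p$spike_refrac,
              wave = .spike_wave(p$v_th, p$v_reset, .sim_dt_ms))
  prm <- .prm_for_core(p, v_init, i_bias)
  out <- sim_core(.sim_dt_ms, decim, as.integer(mode == "voltage_clamp"),
                  stim_ms, prm, syn, spk)
  out$dt_out <- dt_out
  out$stim_out <- stim_ms[seq(1, length(stim_ms), by = decim)]
  out
}

# expand events with per-event weights into the core's flat arrays
# (weights are folded into duplicated unit events inside sim_core via ev_w)

#' Simulate a recording protocol
#'
#' Integrates the conductance-based model under one of the standard
#' stimulus specifications and returns sweeps sampled at 20 kHz, with the
#' stimulus trace, uncaging/stimulus markers, simulator spike times as
#' `"spike"` markers, and additive Gaussian recording noise. Identical
#' `(params, stim, seed)` give bit-identical output.
#'
#' @param params A [neuron_params()] object.
#' @param stim A `stim_spec` from [stim_step_family()] and friends.
#' @param synapses Synapse table ([synapse_spec()] rows) for uncaging,
#'   train and Poisson protocols.
#' @param mode Override clamp mode (defaults to the protocol's natural
#'   mode).
#' @param dt Output sampling interval (s); default 20 kHz.
#' @param seed Integer seed for the recording noise (and Poisson event
#'   times); `NULL` leaves the RNG state alone and adds no noise.
#' @param noise Add recording noise (`TRUE` when a seed is given).
#' @param events Optional explicit event table
#'   (`spine_id`, `time_s`, `weight`) overriding the schedule in `stim`.
#' @param spiking Enable the stylized spike mechanism (current clamp).
#' @return A list of [new_sweep()] objects, one per step/trial.
#' @export
simulate_protocol <- function(params, stim, synapses = NULL, mode = NULL,
                              dt = 5e-5, seed = NULL,
                              noise = !is.null(seed), events = NULL,
                              spiking = FALSE) {
  stopifnot(inherits(stim, "stim_spec"))
  if (!is.null(seed)) set.seed(seed)
  dtm <- .sim_dt_ms
  ms <- function(s) as.integer(round(s * 1000 / dtm))
  add_noise <- function(x, sd) if (noise) x + stats::rnorm(length(x), 0, sd) else x

  out <- list()
  if (stim$kind == "step_family") {
    mode <- mode %||% "current_clamp"
    hold <- -60
    ib <- .bias_current(params, hold)
    n <- ms(stim$pre + stim$dur + stim$post)
    for (a in stim$amplitudes) {
      I <- numeric(n)
      I[(ms(stim$pre) + 1):ms(stim$pre + stim$dur)] <- a
      r <- .run_core(params, I, mode, hold, ib, spiking = spiking, dt_out = dt)
      mk <- tibble::tibble(label = c("step_on", "step_off"),
                           time = c(stim$pre, stim$pre + stim$dur))
      if (length(r$spikes))
        mk <- dplyr::bind_rows(mk, tibble::tibble(label = "spike",
                                                  time = r$spikes / 1000))
      out[[length(out) + 1L]] <- new_sweep(
        add_noise(r$rec, params$noise_sd_mV), r$stim_out, dt, mode,
        markers = mk, holding = hold)
    }
  } else if (stim$kind == "chirp") {
    mode <- "current_clamp"
    hold <- -60
    ib <- .bias_current(params, hold)
    t_ch <- seq(0, stim$dur, by = dtm / 1000)[-1]
    ch <- stim$amp * sin(2 * pi * (stim$f0 * t_ch +
                                   (stim$f1 - stim$f0) * t_ch^2 / (2 * stim$dur)))
    I <- c(numeric(ms(stim$settle)), ch, numeric(ms(0.5)))
    r <- .run_core(params, I, mode, hold, ib, dt_out = dt)
    mk <- tibble::tibble(label = c("chirp_on", "chirp_off"),
                         time = c(stim$settle, stim$settle + stim$dur))
    out[[1]] <- new_sweep(add_noise(r$rec, params$noise_sd_mV), r$stim_out,
                          dt, mode, markers = mk, holding = hold)
  } else if (stim$kind == "vstep_family") {
    mode <- "voltage_clamp"
    n <- ms(stim$pre + stim$dur + stim$post)
    for (v in stim$targets) {
      V <- rep(stim$holding, n)
      V[(ms(stim$pre) + 1):ms(stim$pre + stim$dur)] <- v
      r <- .run_core(params, V, mode, stim$holding, dt_out = dt)
      mk <- tibble::tibble(label = c("step_on", "step_off"),
                           time = c(stim$pre, stim$pre + stim$dur))
      out[[length(out) + 1L]] <- new_sweep(
        add_noise(r$rec, params$noise_sd_pA), r$stim_out, dt, mode,
        markers = mk, holding = stim$holding)
    }
  } else if (stim$kind == "uncaging_schedule") {
    mode <- mode %||% "voltage_clamp"
    n <- ms(stim$total)
    if (is.null(events)) {
      events <- dplyr::bind_rows(lapply(names(stim$times), function(id)
        tibble::tibble(spine_id = id, time_s = stim$times[[id]], weight = 1)))
    }
    mk <- tibble::tibble(label = paste0("uncage_", events$spine_id),
                         time = events$time_s)
    if (mode == "voltage_clamp") {
      V <- rep(stim$holding, n)
      r <- .run_core(params, V, mode, stim$holding, synapses = synapses,
                     events = events, dt_out = dt)
      out[[1]] <- new_sweep(add_noise(r$rec, params$noise_sd_pA), r$stim_out,
                            dt, mode, markers = mk, holding = stim$holding)
    } else {
      ib <- .bias_current(params, stim$holding)
      I <- numeric(n)
      r <- .run_core(params, I, mode, stim$holding, ib, synapses = synapses,
                     events = events, spiking = spiking, dt_out = dt)
      if (length(r$spikes))
        mk <- dplyr::bind_rows(mk, tibble::tibble(label = "spike",
                                                  time = r$spikes / 1000))
      out[[1]] <- new_sweep(add_noise(r$rec, params$noise_sd_mV), r$stim_out,
                            dt, mode, markers = mk, holding = stim$holding)
    }
  } else if (stim$kind == "train") {
    mode <- "current_clamp"
    n <- ms(stim$total)
    tt <- stim$start + (seq_len(stim$n_stim) - 1) / stim$freq
    if (is.null(events))
      events <- tibble::tibble(spine_id = synapses$spine_id[1], time_s = tt,
                               weight = 1)
    ib <- .bias_current(params, stim$holding)
    r <- .run_core(params, numeric(n), mode, stim$holding, ib,
                   synapses = synapses, events = events, spiking = spiking,
                   dt_out = dt)
    mk <- tibble::tibble(label = "stim", time = tt)
    if (length(r$spikes))
      mk <- dplyr::bind_rows(mk, tibble::tibble(label = "spike",
                                                time = r$spikes / 1000))
    out[[1]] <- new_sweep(add_noise(r$rec, params$noise_sd_mV), r$stim_out,
                          dt, mode, markers = mk, holding = stim$holding)
  } else if (stim$kind == "poisson_events") {
    mode <- "voltage_clamp"
    n <- ms(stim$dur)
    ev <- list()
    for (i in seq_len(nrow(synapses))) {
      k <- stats::rpois(1, stim$rate * stim$dur / nrow(synapses))
      if (k > 0)
        ev[[length(ev) + 1L]] <- tibble::tibble(
          spine_id = synapses$spine_id[i],
          time_s = sort(stats::runif(k, 0.01, stim$dur - 0.06)),
          weight = exp(stats::rnorm(k, 0, 0.25)))
    }
    events <- if (length(ev)) dplyr::bind_rows(ev) else
      tibble::tibble(spine_id = character(), time_s = numeric(),
                     weight = numeric())
    V <- rep(stim$holding, n)
    r <- .run_core(params, V, mode, stim$holding, synapses = synapses,
                   events = events, dt_out = dt)
    mk <- tibble::tibble(label = paste0("event_", events$spine_id),
                         time = events$time_s)
    out[[1]] <- new_sweep(add_noise(r$rec, params$noise_sd_pA), r$stim_out,
                          dt, mode, markers = mk, holding = stim$holding)
  } else stop("unknown stimulus kind: ", stim$kind, call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
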