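#' Input resistance from a hyperpolarizing step family
#'
#' Steady-state voltage deflection (mean of the final 100 ms of the step)
#' regressed on step current across subthreshold hyperpolarizing sweeps;
#' the least-squares slope is the input resistance. Sweeps containing an
#' action potential are excluded. With `smallest_only = TRUE` only the
#' smallest-amplitude step is used and R_I is the single-step ratio.
#'
#' @param sweeps List of current-clamp step sweeps (markers `step_on` /
#'   `step_off`).
#' @param steady_win Steady-state window before step offset (s).
#' @param smallest_only Use only the smallest hyperpolarizing step.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweeps, steady_win = 0.1,
                             smallest_only = FALSE) {
  tab <- .step_table(sweeps, steady_win)
  tab <- tab[tab$amp < 0 & tab$n_ap == 0, , drop = FALSE]
  if (smallest_only) tab <- tab[which.max(tab$amp), , drop = FALSE]
  if (nrow(tab) < 1 || (!smallest_only && nrow(tab) < 2))
    stop("need at least two usable hyperpolarizing sweeps ",
         "(or one with smallest_only)", call. = FALSE)
  if (smallest_only || nrow(tab) == 1)
    return(1000 * tab$dv_steady / tab$amp)   # mV/pA -> GOhm -> MOhm? see below
  fit <- stats::lm(dv_steady ~ amp, data = tab)
  unname(stats::coef(fit)["amp"]) * 1000     # mV/pA = GOhm; *1000 = MOhm
}

# per-sweep step measurements shared by R_I, sag, F-I
.step_table <- function(sweeps, steady_win = 0.1, peak_win = 0.2,
                        rebound_win = 0.2) {
  rows <- lapply(sweeps, function(sw) {
    t_on <- marker_times(sw, "step_on"); t_off <- marker_times(sw, "step_off")
    if (!length(t_on) || !length(t_off))
      stop("step sweep lacks step_on/step_off markers", call. = FALSE)
    i_on <- round(t_on / sw$dt) + 1; i_off <- round(t_off / sw$dt)
    if (i_off - i_on < round(steady_win / sw$dt))
      stop("step too short for the measurement windows", call. = FALSE)
    amp <- stats::median(sw$stimulus[i_on:i_off]) -
      stats::median(sw$stimulus[1:(i_on - 1)])
    base <- mean(sw$samples[1:(i_on - 1)])
    aps <- detect_aps(sw)
    v <- sw$samples
    ipk <- i_on:min(i_on + round(peak_win / sw$dt), i_off)
    ist <- (i_off - round(steady_win / sw$dt)):i_off
    irb <- (i_off + 1):min(i_off + round(rebound_win / sw$dt), length(v))
    tibble::tibble(
      amp = amp, baseline = base,
      dv_peak = min(v[ipk]) - base,
      dv_steady = mean(v[ist]) - base,
      rebound = max(v[irb]) - base,
      n_ap = nrow(aps))
  })
  dplyr::bind_rows(rows)
}

#' Detect action potentials in a current-clamp sweep
#'
#' Onset is the first sample where dV/dt exceeds `dvdt_thresh` (V/s) and
#' the voltage subsequently crosses 0 mV within 5 ms; events within the
#' refractory period of the previous AP are ignored. The threshold
#' voltage is the value at onset, amplitude is peak minus threshold, and
#' half-width is measured at half amplitude.
#'
#' @param sweep A current-clamp sweep.
#' @param dvdt_thresh Onset criterion, V/s.
#' @param refractory Minimum inter-AP interval (s).
#' @return Tibble with one row per AP: `time`, `threshold`, `peak`,
#'   `amplitude`, `half_width` (s). Zero rows when none detected.
#' @export
detect_aps <- function(sweep, dvdt_thresh = 20, refractory = 2e-3) {
  v <- sweep$samples; dt <- sweep$dt
  dvdt <- c(diff(v) / dt / 1000, 0)       # mV/s -> V/s
  cand <- which(dvdt > dvdt_thresh)
  out <- list(); last <- -Inf
  w5 <- round(5e-3 / dt)
  for (i in cand) {
    t <- (i - 1) * dt
    if (t < last + refractory) next
    j <- i:min(i + w5, length(v))
    if (!any(v[j] > 0)) next
    peak_i <- j[which.max(v[j])]
    thr <- v[i]; peak <- v[peak_i]; half <- thr + (peak - thr) / 2
    above <- which(v[i:min(peak_i + 4 * w5, length(v))] >= half)
    hw <- if (length(above) > 1) (max(above) - min(above)) * dt else NA_real_
    out[[length(out) + 1L]] <- tibble::tibble(
      time = t, threshold = thr, peak = peak, amplitude = peak - thr,
      half_width = hw)
    last <- t
  }
  if (!length(out))
    return(tibble::tibble(time = numeric(), threshold = numeric(),
                          peak = numeric(), amplitude = numeric(),
                          half_width = numeric()))
  dplyr::bind_rows(out)
}

#' Rheobase and frequency-current curve from a step family
#'
#' @param sweeps Current-clamp step family.
#' @return A list: `rheobase` (pA; smallest step amplitude evoking at
#'   least one AP, censored at the maximum tested amplitude with
#'   `censored = TRUE` when none does) and `fi_curve` (tibble `amp`,
#'   `n_ap` over depolarizing steps).
#' @export
rheobase_and_fi <- function(sweeps) {
  tab <- .step_table(sweeps)
  fi <- tab[tab$amp > 0, c("amp", "n_ap")]
  fi <- fi[order(fi$amp), ]
  firing <- fi$amp[fi$n_ap >= 1]
  if (length(firing)) {
    list(rheobase = min(firing), censored = FALSE, fi_curve = fi)
  } else {
    list(rheobase = max(fi$amp), censored = TRUE, fi_curve = fi)
  }
}

#' Sag and rebound from hyperpolarizing steps
#'
#' Per step (deflections measured from the pre-step baseline): the peak
#' deflection is the most negative voltage within the first
#' `peak_win` seconds of the step, the steady-state deflection the mean
#' of the final `steady_win` seconds, and
#' `sag_pct = 100 (peak - steady) / peak`. The rebound is the maximal
#' depolarisation above baseline within `rebound_win` seconds of step
#' offset; the rebound slope is the least-squares slope of rebound
#' against steady-state deflection across steps (mV/mV, negative when
#' deeper hyperpolarisation yields larger rebound). Depolarizing steps
#' are ignored.
#'
#' @param sweeps Current-clamp step family from a -60 mV holding level.
#' @param peak_win,steady_win,rebound_win Analysis windows (s).
#' @return A list: `per_step` tibble (`amp`, `dv_peak`, `dv_steady`,
#'   `sag_pct`, `rebound`), `sag_pct` (at the largest step),
#'   `rebound_slope`.
#' @export
sag_and_rebound <- function(sweeps, peak_win = 0.2, steady_win = 0.1,
                            rebound_win = 0.2) {
  tab <- .step_table(sweeps, steady_win = steady_win, peak_win = peak_win,
                     rebound_win = rebound_win)
  tab <- tab[tab$amp < 0, , drop = FALSE]
  if (!nrow(tab)) stop("no hyperpolarizing steps", call. = FALSE)
  tab$sag_pct <- 100 * (tab$dv_peak - tab$dv_steady) / tab$dv_peak
  tab$sag_pct[tab$dv_peak >= 0] <- NA_real_
  per <- tab[order(tab$amp), c("amp", "dv_peak", "dv_steady", "sag_pct",
                               "rebound")]
  slope <- if (nrow(per) >= 2) {
    unname(stats::coef(stats::lm(rebound ~ dv_steady, data = per))[2])
  } else NA_real_
  list(per_step = tibble::as_tibble(per),
       sag_pct = per$sag_pct[1],          # largest (most negative) step
       rebound_slope = slope)
}

#' Construct a step sweep with an exact sag fraction
#'
#' Builds a noiseless hyperpolarizing step response whose peak deflection
#' and steady-state deflection are set exactly: the voltage drops
#' instantaneously to the peak at step onset and relaxes exponentially
#' (tau 30 ms) to the steady level, so the default sag windows recover
#' `100 * sag_frac` percent to the printed precision. Used as the worked
#' example for the sag measurement.
#'
#' @param sag_frac Sag as a fraction of the peak deflection, in \[0, 1).
#' @param peak_deflection Peak deflection (mV, positive magnitude).
#' @param baseline Pre-step potential (mV).
#' @param amp Step current (pA), recorded in the stimulus trace.
#' @param rebound Rebound overshoot above baseline after release (mV).
#' @return A current-clamp [new_sweep()].
#' @export
synthetic_sag_sweep <- function(sag_frac, peak_deflection = 20,
                                baseline = -60, amp = -125, rebound = 0) {
  dt <- 5e-5
  pre <- 0.1; dur <- 0.5; post <- 0.25
  tt <- seq(0, pre + dur + post - dt, by = dt)
  v <- rep(baseline, length(tt))
  steady <- peak_deflection * (1 - sag_frac)
  instep <- tt >= pre & tt < pre + dur
  ts <- tt[instep] - pre
  v[instep] <- baseline - steady -
    (peak_deflection - steady) * exp(-ts / 0.03)
  if (rebound > 0) {
    ipost <- tt >= pre + dur
    tp <- tt[ipost] - (pre + dur)
    v[ipost] <- baseline +
      rebound * (tp / 0.02) * exp(1 - tp / 0.02) *
      (tp < 0.2)
  }
  stim <- numeric(length(tt)); stim[instep] <- amp
  new_sweep(v, stim, dt, "current_clamp",
            markers = tibble::tibble(label = c("step_on", "step_off"),
                                     time = c(pre, pre + dur)),
            holding = baseline)
}

#' Membrane impedance profile from a chirp sweep
#'
#' The impedance magnitude is the ratio of the Fourier amplitude spectra
#' of voltage and injected current over the chirp segment, restricted to
#' the analysed band and smoothed with a Gaussian kernel in log frequency
#' (sigma in decades). The resonant frequency is the (quadratically
#' interpolated) argmax and the Q factor the ratio of the peak impedance
#' to the impedance at the low edge of the band.
#'
#' @param sweep Current-clamp chirp sweep (markers `chirp_on`/`chirp_off`;
#'   without markers the stimulus-active segment is detected from the
#'   stimulus trace).
#' @param f_lo,f_hi Analysed band (Hz).
#' @param sigma_decade Gaussian smoothing width in log10 frequency.
#' @return An object of class `impedance_profile`: list with `profile`
#'   (tibble `freq`, `Z` in MOhm), `f_res` (Hz), `Q`.
#' @export
impedance_profile <- function(sweep, f_lo = 0.2, f_hi = 20,
                              sigma_decade = 0.05) {
  t_on <- marker_times(sweep, "chirp_on")
  t_off <- marker_times(sweep, "chirp_off")
  if (!length(t_on) || !length(t_off)) {
    act <- which(abs(sweep$stimulus - stats::median(sweep$stimulus)) >
                   1e-9 + 1e-6 * max(abs(sweep$stimulus)))
    if (!length(act)) stop("no stimulus-active segment found", call. = FALSE)
    t_on <- (min(act) - 1) * sweep$dt; t_off <- max(act) * sweep$dt
  }
  i0 <- round(t_on / sweep$dt) + 1; i1 <- round(t_off / sweep$dt)
  v <- sweep$samples[i0:i1]; cur <- sweep$stimulus[i0:i1]
  n <- length(v)
  freq <- (seq_len(n) - 1) / (n * sweep$dt)
  keep <- freq >= f_lo & freq <= f_hi
  if (!any(keep)) stop("analysed band outside spectral range", call. = FALSE)
  Vf <- stats::fft(v - mean(v)); If <- stats::fft(cur - mean(cur))
  # chirp check: a linear sweep spends proportional time (hence power) in
  # the top half of the band, where step and low-frequency stimuli have
  # almost none
  pow <- Mod(If)^2
  top <- sum(pow[freq >= f_hi / 2 & freq <= f_hi * 1.25])
  all_band <- sum(pow[freq > 0 & freq <= f_hi * 1.25])
  if (all_band == 0 || top < 0.15 * all_band)
    stop("stimulus does not sweep the analysed band; not a chirp?",
         call. = FALSE)
  Z <- 1000 * Mod(Vf[keep]) / Mod(If[keep])   # mV/pA = GOhm -> MOhm
  f <- freq[keep]
  # Gaussian smoothing in log10(f)
  lf <- log10(f)
  Zs <- vapply(seq_along(lf), function(i) {
    w <- exp(-0.5 * ((lf - lf[i]) / sigma_decade)^2)
    sum(w * Z) / sum(w)
  }, numeric(1))
  ipk <- which.max(Zs)
  f_res <- f[ipk]
  if (ipk > 1 && ipk < length(f)) {
    # quadratic interpolation of the peak on the log-frequency axis
    y <- Zs[(ipk - 1):(ipk + 1)]; x <- lf[(ipk - 1):(ipk + 1)]
    den <- (y[1] - 2 * y[2] + y[3])
    if (is.finite(den) && den < 0) {
      xs <- x[2] - 0.5 * ((x[3] - x[1]) / 2) * (y[3] - y[1]) / den
      f_res <- 10^xs
    }
  }
  Q <- max(Zs) / Zs[1]
  structure(list(profile = tibble::tibble(freq = f, Z = Z, Z_smooth = Zs),
                 f_res = f_res, Q = Q), class = "impedance_profile")
}

#' @export
print.impedance_profile <- function(x, ...) {
  cat(sprintf("<impedance_profile> f_res = %.2f Hz, Q = %.2f\n", x$f_res, x$Q))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.impedance_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$freq)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$Z), alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$Z_smooth), colour = "red") +
    ggplot2::geom_vline(xintercept = object$f_res, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "|Z| (MOhm)")
}

#' Full intrinsic profile of one cell
#'
#' Convenience wrapper combining [input_resistance()], [rheobase_and_fi()],
#' [sag_and_rebound()] and (when a chirp sweep is given)
#' [impedance_profile()] into a one-row tibble.
#'
#' @param step_sweeps Current-clamp step family.
#' @param chirp_sweep Optional chirp sweep.
#' @return One-row tibble of intrinsic features.
#' @export
intrinsic_profile <- function(step_sweeps, chirp_sweep = NULL) {
  ri <- input_resistance(step_sweeps)
  rf <- rheobase_and_fi(step_sweeps)
  sg <- sag_and_rebound(step_sweeps)
  out <- tibble::tibble(
    R_I = ri, rheobase = rf$rheobase, rheobase_censored = rf$censored,
    sag_pct = sg$sag_pct, rebound_slope = sg$rebound_slope,
    fi_curve = list(rf$fi_curve))
  if (!is.null(chirp_sweep)) {
    im <- impedance_profile(chirp_sweep)
    out$f_res <- im$f_res; out$Q <- im$Q
  }
  out
}
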