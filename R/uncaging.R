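#' Measure an uncaging-evoked EPSC amplitude
#'
#' AMPA window: the extremum of the trace within 0-10 ms after the
#' uncaging marker, averaged over a 0.5-ms window centred on it, minus the
#' 5-ms pre-marker baseline (absolute value, pA). NMDA window
#' (`window = "nmda"`, +40 mV holding): the mean over 20-50 ms
#' post-marker minus baseline. uEPSP (`window = "uepsp"`, current clamp):
#' peak depolarisation within 20 ms of the marker minus baseline (mV).
#'
#' @param sweep A sweep containing the uncaging response (typically the
#'   average of >= 3 repetitions, see [average_sweeps()]).
#' @param uncage_time Marker time (s); defaults to the sweep's first
#'   `uncage_*` marker.
#' @param window `"ampa"`, `"nmda"` or `"uepsp"`.
#' @param baseline_win Pre-marker baseline length (s).
#' @return Amplitude (pA for current windows, mV for `"uepsp"`), with the
#'   baseline SD attached as attribute `noise_sd`.
#' @export
measure_uepsc <- function(sweep, uncage_time = NULL,
                          window = c("ampa", "nmda", "uepsp"),
                          baseline_win = 5e-3) {
  window <- match.arg(window)
  if (is.null(uncage_time)) {
    lab <- grep("^uncage_", sweep$markers$label)
    if (!length(lab)) stop("no uncaging marker in sweep", call. = FALSE)
    uncage_time <- sweep$markers$time[lab[1]]
  }
  dt <- sweep$dt; v <- sweep$samples
  i0 <- round(uncage_time / dt) + 1
  win_end <- switch(window, ampa = 0.010, nmda = 0.050, uepsp = 0.020)
  if (i0 + round(win_end / dt) > length(v))
    stop("uncaging marker too close to sweep end", call. = FALSE)
  ib <- max(1, i0 - round(baseline_win / dt)):(i0 - 1)
  base <- mean(v[ib]); nsd <- stats::sd(v[ib])
  amp <- if (window == "nmda") {
    iw <- (i0 + round(0.020 / dt)):(i0 + round(0.050 / dt))
    abs(mean(v[iw]) - base)
  } else if (window == "uepsp") {
    iw <- i0:(i0 + round(0.020 / dt))
    max(v[iw]) - base
  } else {
    iw <- i0:(i0 + round(0.010 / dt))
    ext <- iw[which.max(abs(v[iw] - base))]
    h <- round(0.25e-3 / dt)
    abs(mean(v[max(min(iw), ext - h):min(max(iw), ext + h)]) - base)
  }
  attr(amp, "noise_sd") <- nsd
  amp
}

#' Classify a spine from its AMPA and NMDA amplitudes
#'
#' Uses a common noise floor of `3 * noise_sd`: responsive if the AMPA
#' amplitude reaches the floor; silent if AMPA is below floor while NMDA
#' reaches it; unresponsive if both are below floor (excluded from ratio
#' statistics).
#'
#' @param ampa_amp,nmda_amp Measured amplitudes (pA).
#' @param noise_sd Baseline noise SD (pA).
#' @return `"responsive"`, `"silent"` or `"unresponsive"` (vectorised).
#' @export
classify_spine <- function(ampa_amp, nmda_amp, noise_sd) {
  floor <- 3 * noise_sd
  dplyr::case_when(ampa_amp >= floor ~ "responsive",
                   nmda_amp >= floor ~ "silent",
                   TRUE ~ "unresponsive")
}

#' Per-spine uncaging results for one cell
#'
#' Averages the repetitions at each holding potential, measures the AMPA
#' (-70 mV) and NMDA (+40 mV) amplitudes at every uncaging marker, and
#' classifies each spine.
#'
#' @param sweeps List of uncaging sweeps (voltage clamp; holding -70 and
#'   +40 mV repetitions, markers `uncage_<spine>`).
#' @return Tibble: `spine_id`, `ampa_amp`, `nmda_amp`, `noise_sd`, `call`,
#'   `ratio` (NMDA/AMPA, `NA` unless responsive).
#' @export
spine_results <- function(sweeps) {
  hold <- vapply(sweeps, `[[`, numeric(1), "holding")
  avg_at <- function(h) {
    sel <- sweeps[abs(hold - h) < 1e-6]
    if (!length(sel)) stop("no sweeps at holding ", h, " mV", call. = FALSE)
    average_sweeps(sel)
  }
  neg <- avg_at(-70); pos <- avg_at(40)
  labs <- grep("^uncage_", neg$markers$label, value = TRUE)
  rows <- lapply(unique(labs), function(lb) {
    tn <- neg$markers$time[neg$markers$label == lb][1]
    tp <- pos$markers$time[pos$markers$label == lb][1]
    a <- measure_uepsc(neg, tn, "ampa")
    nn <- measure_uepsc(pos, tp, "nmda")
    tibble::tibble(spine_id = sub("^uncage_", "", lb),
                   ampa_amp = as.numeric(a), nmda_amp = as.numeric(nn),
                   noise_sd = attr(a, "noise_sd"))
  })
  out <- dplyr::bind_rows(rows)
  out$call <- classify_spine(out$ampa_amp, out$nmda_amp, out$noise_sd)
  out$ratio <- ifelse(out$call == "responsive",
                      out$nmda_amp / out$ampa_amp, NA_real_)
  out
}

#' NMDA/AMPA ratio summaries over a spine population
#'
#' Returns the per-spine ratios of responsive spines and the population
#' slope from a regression of NMDA on AMPA amplitude through the origin
#' (the population-average convention); spines whose AMPA amplitude sits
#' below the noise floor are excluded with a message.
#'
#' @param spines Tibble from [spine_results()] (columns `ampa_amp`,
#'   `nmda_amp`, `call`).
#' @return List: `per_spine` tibble, `mean_ratio`, `slope`
#'   (origin-regression), `n`.
#' @export
nmda_ampa_ratio <- function(spines) {
  excl <- spines$call != "responsive"
  if (any(excl))
    message(sum(excl), " spine(s) excluded from ratio statistics")
  sp <- spines[!excl, , drop = FALSE]
  fit <- stats::lm(nmda_amp ~ 0 + ampa_amp, data = sp)
  list(per_spine = tibble::tibble(spine_id = sp$spine_id,
                                  ratio = sp$nmda_amp / sp$ampa_amp),
       mean_ratio = mean(sp$nmda_amp / sp$ampa_amp),
       slope = unname(stats::coef(fit)[1]), n = nrow(sp))
}

#' Multi-spine summation analysis
#'
#' Compares near-simultaneous ensemble responses against the expected
#' linear sum of the constituent single-spine uEPSPs. Peaks are measured
#' over the 20 ms following the first uncaging marker of each ensemble.
#' Counts whose response is truncated by an action potential are kept for
#' the spines-to-AP statistic but excluded from the regressions. The
#' normalized-summation slope regresses (observed / first single uEPSP)
#' on spine count; the linearity slope regresses observed on expected sum
#' through the origin (zero input, zero response).
#'
#' @param ensemble_sweeps List of current-clamp ensemble sweeps, each with
#'   attribute `ensemble_count` (or supply `counts`).
#' @param single_amps Single-spine uEPSP amplitudes (mV), in uncaging
#'   order.
#' @param counts Optional integer vector of ensemble sizes.
#' @param silent Optional logical vector flagging silent spines (used for
#'   the `excluding_silent` spines-to-AP variant: silent spines do not
#'   count towards the number of spines activated).
#' @return Object of class `summation_result`: `per_count` tibble
#'   (`count`, `expected`, `observed`, `normalized`, `ap_fired`),
#'   `norm_slope`, `linearity_slope`, `spines_to_ap`,
#'   `spines_to_ap_excl_silent`, `censored`.
#' @export
summation_analysis <- function(ensemble_sweeps, single_amps, counts = NULL,
                               silent = NULL) {
  if (is.null(counts))
    counts <- vapply(ensemble_sweeps, function(s)
      as.integer(attr(s, "ensemble_count") %||% NA_integer_), integer(1))
  stopifnot(length(counts) == length(ensemble_sweeps),
            max(counts) <= length(single_amps))
  rows <- purrr::map2(ensemble_sweeps, counts, function(sw, k) {
    m <- sw$markers[grepl("^uncage_", sw$markers$label), , drop = FALSE]
    t0 <- min(m$time)
    ap <- any(sw$markers$label == "spike")
    obs <- if (ap) NA_real_ else measure_uepsc(sw, t0, "uepsp")
    tibble::tibble(count = k, expected = sum(single_amps[seq_len(k)]),
                   observed = as.numeric(obs), ap_fired = ap)
  })
  per <- dplyr::arrange(dplyr::bind_rows(rows), .data$count)
  per$normalized <- per$observed / single_amps[1]
  sub <- per[!per$ap_fired, , drop = FALSE]
  norm_slope <- if (nrow(sub) >= 2)
    unname(stats::coef(stats::lm(normalized ~ count, data = sub))[2]) else
      NA_real_
  lin_slope <- if (nrow(sub) >= 2)
    unname(stats::coef(stats::lm(observed ~ 0 + expected, data = sub))[1]) else
      NA_real_
  fired <- per$count[per$ap_fired]
  sta <- if (length(fired)) min(fired) else NA_integer_
  sta_ex <- if (length(fired) && !is.null(silent)) {
    k <- min(fired)
    k - sum(silent[seq_len(k)])
  } else sta
  structure(list(per_count = per, norm_slope = norm_slope,
                 linearity_slope = lin_slope, spines_to_ap = sta,
                 spines_to_ap_excl_silent = sta_ex,
                 censored = !length(fired)),
            class = "summation_result")
}

#' @export
print.summation_result <- function(x, ...) {
  cat(sprintf(paste0("<summation_result> linearity slope %.2f, ",
                     "normalized slope %.2f, spines to AP %s\n"),
              x$linearity_slope, x$norm_slope,
              if (x$censored) "censored" else x$spines_to_ap))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.summation_result <- function(object, ...) {
  df <- object$per_count[!object$per_count$ap_fired, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ 0 + x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "expected linear sum (mV)", y = "observed uEPSP (mV)")
}

#' EPSP decay constant versus summation level
#'
#' Fits a single-exponential decay from the peak of each subthreshold
#' ensemble response back towards baseline and regresses log(decay tau)
#' on the normalized summation level. A point whose tail is poorly fit
#' (R-squared below 0.5) is flagged.
#'
#' @param ensemble_sweeps As in [summation_analysis()].
#' @param counts Optional ensemble sizes.
#' @param fit_win Tail length fitted after the peak (s).
#' @return List: `per_count` tibble (`count`, `normalized`, `tau`,
#'   `r2`, `flagged`), `trend_slope` (d log tau / d normalized),
#'   `trend_p`.
#' @export
decay_vs_summation <- function(ensemble_sweeps, counts = NULL,
                               fit_win = 0.15) {
  if (is.null(counts))
    counts <- vapply(ensemble_sweeps, function(s)
      as.integer(attr(s, "ensemble_count") %||% NA_integer_), integer(1))
  rows <- purrr::map2(ensemble_sweeps, counts, function(sw, k) {
    if (any(sw$markers$label == "spike")) return(NULL)
    m <- sw$markers[grepl("^uncage_", sw$markers$label), , drop = FALSE]
    t0 <- min(m$time); dt <- sw$dt
    i0 <- round(t0 / dt) + 1
    base <- mean(sw$samples[max(1, i0 - round(5e-3 / dt)):(i0 - 1)])
    iw <- i0:min(i0 + round(0.020 / dt), length(sw$samples))
    ipk <- iw[which.max(sw$samples[iw])]
    amp0 <- sw$samples[ipk] - base
    itail <- ipk:min(ipk + round(fit_win / dt), length(sw$samples))
    y <- sw$samples[itail] - base
    tt <- (itail - ipk) * dt
    ok <- y > 0.02 * amp0
    if (sum(ok) < 10) return(NULL)
    fit <- stats::lm(log(y[ok]) ~ tt[ok])
    tau <- -1 / stats::coef(fit)[2]
    r2 <- summary(fit)$r.squared
    tibble::tibble(count = k, peak = amp0, tau = unname(tau), r2 = r2,
                   flagged = r2 < 0.5)
  })
  per <- dplyr::bind_rows(rows)
  if (!nrow(per)) stop("no usable subthreshold responses", call. = FALSE)
  per$normalized <- per$peak / per$peak[per$count == min(per$count)][1]
  use <- !per$flagged & per$tau > 0
  trend <- if (sum(use) >= 3) {
    f <- stats::lm(log(tau) ~ normalized, data = per[use, ])
    list(slope = unname(stats::coef(f)[2]),
         p = summary(f)$coefficients[2, 4])
  } else list(slope = NA_real_, p = NA_real_)
  list(per_count = per, trend_slope = trend$slope, trend_p = trend$p)
}

#' Spike probability over stimulus-train trials
#'
#' @param train_sweeps List of current-clamp train sweeps for one
#'   frequency (one per trial, `spike` markers from [detect_aps()] or the
#'   simulator).
#' @param freq Train frequency (Hz), recorded in the output.
#' @return Tibble: `frequency`, `p_spike` (fraction of trials with >= 1
#'   AP in the train window), `n_trials`.
#' @export
train_spike_probability <- function(train_sweeps, freq = NA_real_) {
  n <- length(train_sweeps)
  if (n < 10)
    warning("spike probability computed from ", n, " trials (< 10)")
  fired <- vapply(train_sweeps, function(sw) {
    stim <- sw$markers$time[sw$markers$label == "stim"]
    win <- if (length(stim)) c(min(stim), max(stim) + 0.2) else
      c(0, sweep_duration(sw))
    sp <- sw$markers$time[sw$markers$label == "spike"]
    if (!length(sp)) sp <- detect_aps(sw)$time
    any(sp >= win[1] & sp <= win[2])
  }, logical(1))
  tibble::tibble(frequency = freq, p_spike = mean(fired), n_trials = n)
}
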