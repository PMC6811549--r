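#' Miniature-EPSC event template
#'
#' Tri-exponential template \eqn{T(t) = (1 - e^{-t/\tau_r})(w e^{-t/\tau_1}
#' + (1-w) e^{-t/\tau_2})}, normalised to unit peak, with negative
#' polarity for inward currents at -70 mV and positive for outward
#' currents at +40 mV.
#'
#' @param tau_rise Rise time constant (ms).
#' @param tau1,tau2 Fast and slow decay constants (ms), `tau_rise < tau1 <
#'   tau2`.
#' @param w Weight of the fast decay component, in \[0, 1\].
#' @param duration Template length (ms).
#' @param polarity `-1` (inward) or `+1` (outward).
#' @return An `event_template` object.
#' @export
event_template <- function(tau_rise, tau1, tau2, w, duration = 20,
                           polarity = -1) {
  stopifnot(tau_rise < tau1, tau1 <= tau2, w >= 0, w <= 1,
            polarity %in% c(-1, 1))
  structure(list(tau_rise = tau_rise, tau1 = tau1, tau2 = tau2, w = w,
                 duration = duration, polarity = polarity),
            class = "event_template")
}

#' Default templates for the two holding potentials
#' @param kind `"ampa"` (-70 mV, fast) or `"nmda"` (+40 mV, slow).
#' @return An [event_template()].
#' @export
default_template <- function(kind = c("ampa", "nmda")) {
  kind <- match.arg(kind)
  if (kind == "ampa") event_template(0.4, 4, 12, 0.9, duration = 20,
                                     polarity = -1)
  else event_template(3, 40, 120, 0.9, duration = 150, polarity = 1)
}

#' Realise a template as a sampled waveform
#' @param template An [event_template()].
#' @param dt Sampling interval (s).
#' @return Numeric vector with unit peak magnitude and the template's
#'   polarity.
#' @export
template_vector <- function(template, dt) {
  t_ms <- seq(0, template$duration, by = dt * 1000)
  y <- (1 - exp(-t_ms / template$tau_rise)) *
    (template$w * exp(-t_ms / template$tau1) +
       (1 - template$w) * exp(-t_ms / template$tau2))
  template$polarity * y / max(abs(y))
}

#' Fit a template to aligned exemplar events
#'
#' Averages the exemplars and fits the tri-exponential template shape by
#' nonlinear least squares. If the fit does not converge the configured
#' default kinetics are returned with a warning.
#'
#' @param exemplars Numeric matrix (rows = samples, columns = events),
#'   aligned to onset, or a numeric vector (one exemplar/average).
#' @param dt Sampling interval (s).
#' @param polarity Event polarity.
#' @param fallback Template returned on fit failure.
#' @return An [event_template()].
#' @export
build_template <- function(exemplars, dt, polarity = -1,
                           fallback = default_template(
                             if (polarity < 0) "ampa" else "nmda")) {
  y <- if (is.matrix(exemplars)) rowMeans(exemplars) else as.numeric(exemplars)
  y <- polarity * y / max(abs(y))        # unit-peak, positive working copy
  t_ms <- (seq_along(y) - 1) * dt * 1000
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-t_ms / tr)) * (w * exp(-t_ms / t1) +
                                       (1 - w) * exp(-t_ms / t2)),
      start = list(A = 1.2, tr = 0.5, t1 = 4, t2 = 20, w = 0.8),
      lower = c(0.1, 0.02, 0.1, 0.1, 0), upper = c(10, 20, 200, 500, 1),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # single-exponential decay limit: refit with w fixed at 1
    fit1 <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (1 - exp(-t_ms / tr)) * exp(-t_ms / t1),
        start = list(A = 1.2, tr = 0.5, t1 = 5),
        lower = c(0.1, 0.02, 0.1), upper = c(10, 20, 500),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) e)
    if (!inherits(fit1, "error")) {
      co <- as.list(stats::coef(fit1))
      return(event_template(min(co$tr, co$t1 * 0.95), co$t1, co$t1, 1,
                            duration = max(t_ms), polarity = polarity))
    }
    warning("template fit did not converge; using default kinetics")
    return(fallback)
  }
  co <- as.list(stats::coef(fit))
  t1 <- min(co$t1, co$t2); t2 <- max(co$t1, co$t2)
  w <- if (co$t1 <= co$t2) co$w else 1 - co$w
  tr <- min(co$tr, t1 * 0.95)
  event_template(tr, t1, t2, w, duration = max(t_ms), polarity = polarity)
}

#' Detect miniature EPSCs with a moving template
#'
#' Slides the template along the sweep, fitting scale and offset by least
#' squares at every position; the detection criterion is the fitted scale
#' divided by the residual SD. Local criterion maxima above the threshold
#' become candidate events, which must then exceed an amplitude floor of
#' 3x the SD of the 5 ms preceding baseline; finally a refractory period
#' is enforced, keeping the event with the higher criterion (7.5 ms for
#' -70 mV recordings, 25 ms at +40 mV).
#'
#' @param sweep Voltage-clamp sweep.
#' @param template An [event_template()]; default chosen from the sweep's
#'   holding potential.
#' @param threshold Detection-criterion threshold.
#' @param refractory Minimum inter-event interval (s); default by holding
#'   potential.
#' @return Tibble of class `event_list`: `time` (onset, s), `amplitude`
#'   (pA, positive), `criterion`.
#' @export
detect_events <- function(sweep, template = NULL, threshold = 3,
                          refractory = NULL) {
  if (is.null(template))
    template <- default_template(
      if (!is.na(sweep$holding) && sweep$holding > 0) "nmda" else "ampa")
  if (is.null(refractory))
    refractory <- if (template$polarity > 0) 25e-3 else 7.5e-3
  y <- sweep$samples; dt <- sweep$dt
  Tv <- template_vector(template, dt)
  m <- length(Tv); n <- length(y)
  if (m > n) stop("template longer than sweep", call. = FALSE)
  St <- sum(Tv); Stt <- sum(Tv^2)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  nw <- n - m + 1
  Sy <- cs[(m + 1):(n + 1)] - cs[1:nw]
  Syy <- cs2[(m + 1):(n + 1)] - cs2[1:nw]
  # FFT cross-correlation: Sty[w] = sum_k T[k] * y[w + k - 1]
  N <- stats::nextn(n + m)
  fy <- stats::fft(c(y, numeric(N - n)))
  ft <- stats::fft(c(Tv, numeric(N - m)))
  Sty <- Re(stats::fft(fy * Conj(ft), inverse = TRUE))[seq_len(nw)] / N
  s <- (Sty - Sy * St / m) / (Stt - St^2 / m)
  b <- (Sy - s * St) / m
  sse <- Syy + s^2 * Stt + m * b^2 -
    2 * (s * Sty + b * Sy - s * b * St)
  sse[sse < 0] <- 0
  crit <- s / sqrt(sse / (m - 1))
  # candidate events: local maxima of suprathreshold runs
  above <- crit > threshold
  if (!any(above)) return(.empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  cand <- integer()
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    cand <- c(cand, seg[which.max(crit[seg])])
  }
  # amplitude floor: 3x SD of the 5 ms preceding baseline
  nb <- round(5e-3 / dt)
  keep <- vapply(cand, function(i) {
    if (i <= nb) return(FALSE)
    abs(s[i]) > 3 * stats::sd(y[(i - nb):(i - 1)])
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) return(.empty_events())
  # refractory: keep the higher-criterion event of any close pair
  o <- order(crit[cand], decreasing = TRUE)
  sel <- integer()
  for (i in cand[o]) {
    if (!length(sel) || all(abs(i - sel) * dt >= refractory))
      sel <- c(sel, i)
  }
  sel <- sort(sel)
  out <- tibble::tibble(time = (sel - 1) * dt, amplitude = abs(s[sel]),
                        criterion = crit[sel])
  class(out) <- c("event_list", class(out))
  out
}

.empty_events <- function() {
  out <- tibble::tibble(time = numeric(), amplitude = numeric(),
                        criterion = numeric())
  class(out) <- c("event_list", class(out))
  out
}

#' Summary statistics of a detected event list
#'
#' @param events Tibble from [detect_events()].
#' @param duration Recording duration (s).
#' @return One-row tibble: `n_events`, `frequency` (Hz), `amp_mean`,
#'   `amp_median` (pA; `NA` when no events).
#' @export
event_stats <- function(events, duration) {
  stopifnot(duration > 0)
  tibble::tibble(
    n_events = nrow(events), frequency = nrow(events) / duration,
    amp_mean = if (nrow(events)) mean(events$amplitude) else NA_real_,
    amp_median = if (nrow(events)) stats::median(events$amplitude) else
      NA_real_)
}
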