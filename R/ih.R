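#' Extract I_h amplitudes from a voltage-clamp step family
#'
#' For each hyperpolarizing step the instantaneous current is the mean
#' over 10-60 ms after step onset (after the capacitive transient, before
#' appreciable HCN relaxation) and the steady-state current the mean of
#' the final 500 ms of the step. I_h is the absolute difference between
#' the two (the slowly developing inward relaxation), reported as a
#' positive magnitude. Steps whose final two 250-ms bins differ by more
#' than 5% of the developed amplitude are flagged `unsettled` but kept.
#'
#' @param sweeps Voltage-clamp step family (5-s steps from -50 mV; markers
#'   `step_on`/`step_off`).
#' @param inst_win Instantaneous window after onset, seconds (start, end).
#' @param steady_win Steady-state window length before offset (s).
#' @return A tibble of class `ih_curve_tbl`: `step_v` (mV), `ih_amp` (pA),
#'   `unsettled`.
#' @export
extract_ih <- function(sweeps, inst_win = c(0.010, 0.060),
                       steady_win = 0.5) {
  rows <- lapply(sweeps, function(sw) {
    stopifnot(sw$mode == "voltage_clamp")
    t_on <- marker_times(sw, "step_on"); t_off <- marker_times(sw, "step_off")
    if (!length(t_on) || !length(t_off))
      stop("voltage-step sweep lacks step_on/step_off markers", call. = FALSE)
    i_on <- round(t_on / sw$dt) + 1; i_off <- round(t_off / sw$dt)
    step_v <- stats::median(sw$stimulus[i_on:i_off])
    # instantaneous level: linear extrapolation of the window back to the
    # step onset, removing what little relaxation develops inside it
    iw <- (i_on + round(inst_win[1] / sw$dt)):(i_on + round(inst_win[2] / sw$dt))
    tw <- (iw - i_on) * sw$dt
    cf <- stats::coef(stats::lm.fit(cbind(1, tw), sw$samples[iw]))
    inst <- cf[1]
    steady <- mean(sw$samples[(i_off - round(steady_win / sw$dt)):i_off])
    b <- round(0.25 / sw$dt)
    bin1 <- mean(sw$samples[(i_off - 2 * b):(i_off - b - 1)])
    bin2 <- mean(sw$samples[(i_off - b):i_off])
    amp <- abs(steady - inst)
    tibble::tibble(step_v = step_v, ih_amp = amp,
                   unsettled = amp > 0 && abs(bin2 - bin1) > 0.05 * amp)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(step_v))
  class(out) <- c("ih_curve_tbl", class(out))
  out
}

#' Fit the I_h activation curve with a variable-slope sigmoid
#'
#' Fits \eqn{A(V) = A_{max} / (1 + \exp((V - V_{1/2}) / k))} by nonlinear
#' least squares with a multi-start over midpoint initial values. By
#' default the amplitudes are first normalised by the HCN driving force
#' (`(V - E_rev)`, chord-conductance transform) so the fitted midpoint
#' estimates the gating midpoint; `response = "current"` fits the raw
#' amplitude-vs-voltage curve as plotted in activation figures (its
#' midpoint is then shifted by the voltage-dependent driving force).
#'
#' @param curve Tibble from [extract_ih()] (`step_v`, `ih_amp`), or any
#'   data frame with those columns.
#' @param response `"conductance"` (default) or `"current"`.
#' @param E_rev HCN reversal used for the driving-force normalisation (mV).
#' @param starts Midpoint start values for the multi-start.
#' @return Object of class `ih_fit`: list with `V12`, `k`, `I_max` (on the
#'   fitted response scale), `response`, `fit` (the nls object), `data`.
#' @export
fit_activation <- function(curve, response = c("conductance", "current"),
                           E_rev = -30, starts = c(-70, -85, -100)) {
  response <- match.arg(response)
  df <- tibble::tibble(v = curve$step_v, a = curve$ih_amp)
  if (nrow(df) < 5)
    stop("need at least 5 points spanning the activation range",
         call. = FALSE)
  if (response == "conductance") df$a <- df$a / abs(df$v - E_rev)
  best <- NULL; errs <- character()
  for (v0 in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(a ~ Amax / (1 + exp((v - V12) / k)), data = df,
                        start = list(Amax = max(df$a), V12 = v0, k = 8),
                        lower = c(0, -140, 0.5), upper = c(Inf, -40, 40),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(f, "error")) { errs <- c(errs, conditionMessage(f)); next }
    if (is.null(best) || stats::deviance(f) < stats::deviance(best)) best <- f
  }
  if (is.null(best))
    stop("activation fit failed from all starts: ",
         paste(unique(errs), collapse = "; "), call. = FALSE)
  co <- stats::coef(best)
  structure(list(V12 = unname(co["V12"]), k = unname(co["k"]),
                 I_max = unname(co["Amax"]), response = response,
                 E_rev = E_rev, fit = best, data = df),
            class = "ih_fit")
}

#' @export
print.ih_fit <- function(x, ...) {
  cat(sprintf("<ih_fit> V1/2 = %.1f mV, k = %.2f mV (%s fit)\n",
              x$V12, x$k, x$response))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ih_fit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(stats::vcov(x$fit))), error = function(e)
    rep(NA_real_, 3))
  tibble::tibble(term = c("I_max", "V12", "k"),
                 estimate = c(x$I_max, x$V12, x$k),
                 std.error = unname(se[c("Amax", "V12", "k")]))
}

#' @exportS3Method generics::glance
glance.ih_fit <- function(x, ...) {
  tibble::tibble(V12 = x$V12, k = x$k, I_max = x$I_max,
                 sigma = stats::sigma(x$fit),
                 deviance = stats::deviance(x$fit),
                 nobs = nrow(x$data), response = x$response)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ih_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(v = seq(min(df$v), max(df$v), length.out = 200))
  grid$a <- stats::predict(object$fit, newdata = grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v, y = .data$a)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_vline(xintercept = object$V12, linetype = 2) +
    ggplot2::labs(x = "step potential (mV)",
                  y = if (object$response == "conductance")
                    "I_h / driving force (nS)" else "I_h (pA)")
}

#' P/N leak subtraction of voltage-clamp sweeps
#'
#' Subtracts the linearly scaled response to a small step from the
#' response to a larger step from the same holding potential; passive
#' (leak and capacitive) components cancel and the voltage-dependent
#' relaxation is isolated. The scale is the ratio of the step amplitudes
#' (e.g. 5 for a -50 mV target step against a -10 mV subtraction step).
#'
#' @param sweep_target,sweep_small Voltage-clamp sweeps sharing holding
#'   potential and geometry.
#' @return A sweep whose samples are the subtracted current trace.
#' @export
pn_subtract <- function(sweep_target, sweep_small) {
  stopifnot(length(sweep_target) == length(sweep_small))
  d_t <- sweep_target$stimulus - sweep_target$stimulus[1]
  d_s <- sweep_small$stimulus - sweep_small$stimulus[1]
  a_t <- max(abs(d_t)); a_s <- max(abs(d_s))
  if (a_s == 0) stop("subtraction step has zero amplitude", call. = FALSE)
  scale <- a_t / a_s
  # responses are measured relative to each sweep's pre-step holding
  # current, so the common holding level does not enter the subtraction
  base_of <- function(sw) {
    i_on <- which(abs(sw$stimulus - sw$stimulus[1]) > 1e-12)[1]
    if (is.na(i_on) || i_on < 2) i_on <- length(sw$samples) %/% 10 + 1
    mean(sw$samples[1:(i_on - 1)])
  }
  resp_t <- sweep_target$samples - base_of(sweep_target)
  resp_s <- sweep_small$samples - base_of(sweep_small)
  new_sweep(resp_t - scale * resp_s,
            sweep_target$stimulus, sweep_target$dt, sweep_target$mode,
            sweep_target$markers, sweep_target$holding)
}
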