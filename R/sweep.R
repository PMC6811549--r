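#' Construct a single recording sweep
#'
#' A sweep is the atomic unit of an intracellular recording: one recorded
#' time series (membrane potential in current clamp, pipette current in
#' voltage clamp), the stimulus delivered alongside it, and event markers
#' (uncaging times, stimulus times, simulator spike times).
#'
#' Units are fixed package-wide: time in seconds, voltage in mV, current in
#' pA, conductance in nS. `dt` is the sampling interval in seconds
#' (5e-5 s for the standard 20 kHz acquisition).
#'
#' @param samples Numeric vector of recorded values (mV or pA).
#' @param stimulus Numeric vector, same length as `samples` (pA command in
#'   current clamp, mV command in voltage clamp).
#' @param dt Sampling interval, seconds per sample.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param markers A tibble with columns `label` (character) and `time`
#'   (seconds from sweep start), or `NULL`.
#' @param holding Holding level: mV in current clamp, pA in voltage clamp.
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(samples, stimulus, dt,
                      mode = c("current_clamp", "voltage_clamp"),
                      markers = NULL, holding = NA_real_) {
  mode <- match.arg(mode)
  if (!is.numeric(samples) || !is.numeric(stimulus))
    stop("samples and stimulus must be numeric", call. = FALSE)
  if (length(samples) != length(stimulus))
    stop("samples and stimulus must have the same length", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds/sample)", call. = FALSE)
  if (is.null(markers)) {
    markers <- tibble::tibble(label = character(), time = numeric())
  } else {
    markers <- tibble::as_tibble(markers)
    stopifnot(all(c("label", "time") %in% names(markers)))
    dur <- length(samples) * dt
    if (nrow(markers) && any(markers$time < 0 | markers$time >= dur))
      stop("marker times must lie within [0, duration)", call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), stimulus = as.numeric(stimulus),
         dt = dt, mode = mode, markers = markers, holding = holding),
    class = "sweep"
  )
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s, %d samples @ %.0f kHz (%.3f s), %d marker(s)\n",
              x$mode, length(x$samples), 1e-3 / x$dt,
              length(x$samples) * x$dt, nrow(x$markers)))
  invisible(x)
}

#' @export
length.sweep <- function(x) length(x$samples)

#' Sweep duration in seconds
#' @param sweep A [new_sweep()] object.
#' @return Duration in seconds.
#' @export
sweep_duration <- function(sweep) length(sweep$samples) * sweep$dt

#' Time axis of a sweep
#' @param sweep A [new_sweep()] object.
#' @return Numeric vector of sample times in seconds (starting at 0).
#' @export
sweep_time <- function(sweep) (seq_along(sweep$samples) - 1) * sweep$dt

#' Marker times with a given label
#' @param sweep A [new_sweep()] object.
#' @param label Marker label to select; `NULL` selects all.
#' @return Numeric vector of times (s).
#' @export
marker_times <- function(sweep, label = NULL) {
  m <- sweep$markers
  if (!is.null(label)) m <- m[m$label == label, , drop = FALSE]
  m$time
}

#' Convert a sweep to a tidy tibble
#'
#' @param x A [new_sweep()] object.
#' @param ... Unused.
#' @return A tibble with columns `time`, `value`, `stimulus`.
#' @exportS3Method tibble::as_tibble
as_tibble.sweep <- function(x, ...) {
  tibble::tibble(time = sweep_time(x), value = x$samples, stimulus = x$stimulus)
}

#' Average a list of repetition sweeps sample-by-sample
#'
#' Repetitions of the same protocol are averaged before amplitude
#' measurement (uncaging responses are measured on the mean of at least
#' three repetitions). Markers are taken from the first sweep.
#'
#' @param sweeps List of [new_sweep()] objects with identical geometry.
#' @return A single averaged sweep.
#' @export
average_sweeps <- function(sweeps) {
  stopifnot(length(sweeps) >= 1L)
  n <- lengths(lapply(sweeps, `[[`, "samples"))
  if (length(unique(n)) != 1L)
    stop("sweeps must have identical lengths to be averaged", call. = FALSE)
  s1 <- sweeps[[1]]
  samp <- rowMeans(vapply(sweeps, `[[`, numeric(n[1]), "samples"))
  new_sweep(samp, s1$stimulus, s1$dt, s1$mode, s1$markers, s1$holding)
}

#' Quick base plot of a sweep (diagnostic)
#'
#' @param object A [new_sweep()] object.
#' @param ... Unused.
#' @return A ggplot object: recorded trace over time with markers as rug.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep <- function(object, ...) {
  df <- as_tibble.sweep(object)
  ylab <- if (object$mode == "current_clamp") "V (mV)" else "I (pA)"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ylab)
  if (nrow(object$markers))
    p <- p + ggplot2::geom_rug(
      data = object$markers, ggplot2::aes(x = .data$time), inherit.aes = FALSE,
      sides = "t", colour = "red")
  p
}
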