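#' Uniformly sampled membrane-potential trace
#'
#' @param values numeric vector, mV.
#' @param dt sample interval, s.
#' @param t0 time of the first sample, s.
#' @param node_id morphology node the trace belongs to (optional).
#' @param windows optional [analysis_windows()] annotation.
#' @param v_rest resting potential annotation, mV.
#' @return object of class `vm_trace`.
#' @export
vm_trace <- function(values, dt, t0 = 0, node_id = NA_integer_,
                     windows = NULL, v_rest = NA_real_) {
  if (!all(is.finite(values))) stop("vm_trace values must be finite")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(values = as.numeric(values), dt = dt, t0 = t0,
                 node_id = node_id, windows = windows, v_rest = v_rest),
            class = "vm_trace")
}

#' Inhibitory postsynaptic current trace
#'
#' Outward-positive IPSC of a DSGC held at 0 mV; baseline is ~0 pA before
#' the first release event.
#'
#' @param values numeric vector, pA.
#' @param dt sample interval, s.
#' @param t0 time of the first sample, s.
#' @param windows optional [analysis_windows()] annotation.
#' @return object of class `ipsc_trace`.
#' @export
ipsc_trace <- function(values, dt, t0 = 0, windows = NULL) {
  if (!all(is.finite(values))) stop("ipsc_trace values must be finite")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(values = as.numeric(values), dt = dt, t0 = t0,
                 windows = windows),
            class = "ipsc_trace")
}

#' Sample times of a trace
#' @param x a `vm_trace` or `ipsc_trace`.
#' @return numeric vector of times, s.
#' @export
trace_times <- function(x) x$t0 + (seq_along(x$values) - 1) * x$dt

# index range of a (t0, t1) window on the trace grid
window_index <- function(x, window) {
  t <- trace_times(x)
  idx <- which(t >= window[1] & t < window[2])
  if (!length(idx)) stop("window [", window[1], ", ", window[2],
                         ") contains no samples")
  idx
}

#' @export
print.vm_trace <- function(x, ...) {
  cat(sprintf("Vm trace: %d samples at %g kHz, %.3g-%.3g s, range [%.1f, %.1f] mV\n",
              length(x$values), 1e-3 / x$dt, x$t0,
              x$t0 + length(x$values) * x$dt,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.ipsc_trace <- function(x, ...) {
  cat(sprintf("IPSC trace: %d samples at %g kHz, peak %.1f pA\n",
              length(x$values), 1e-3 / x$dt, max(x$values)))
  invisible(x)
}

#' @export
plot.vm_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l", xlab = "time (s)",
                 ylab = "Vm (mV)", ...)
  if (!is.null(x$windows)) {
    graphics::abline(v = unlist(x$windows), lty = 3, col = "grey50")
  }
  invisible(x)
}

#' @export
plot.ipsc_trace <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l", xlab = "time (s)",
                 ylab = "IPSC (pA)", ...)
  if (!is.null(x$windows)) {
    graphics::abline(v = unlist(x$windows), lty = 3, col = "grey50")
  }
  invisible(x)
}
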