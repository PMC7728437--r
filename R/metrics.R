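#' Direction-selectivity index
#'
#' `DSI = (pref - null) / (pref + null)` on spike counts; 1 means spiking
#' only in the preferred direction, 0 no selectivity.
#'
#' @param pref_count,null_count nonnegative spike counts (vectorised).
#' @return DSI in [-1, 1].
#' @export
dsi <- function(pref_count, null_count) {
  if (any(pref_count < 0 | null_count < 0)) stop("spike counts must be >= 0")
  tot <- pref_count + null_count
  if (any(tot == 0)) stop("DSI undefined: pref + null must be > 0")
  (pref_count - null_count) / tot
}

#' Analysis windows of a moving-bar sweep
#'
#' Three ordered, non-overlapping time windows: `baseline` (bar outside
#' the receptive field), `surround` (bar in the RF surround) and
#' `center` (bar in the RF center), in seconds from sweep start.
#'
#' @param baseline,surround,center numeric `c(t0, t1)` pairs, s.
#' @return object of class `analysis_windows` (a named list).
#' @export
analysis_windows <- function(baseline, surround, center) {
  w <- list(baseline = as.numeric(baseline), surround = as.numeric(surround),
            center = as.numeric(center))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || w[[nm]][2] <= w[[nm]][1]) {
      stop(nm, " window must be an increasing (t0, t1) pair")
    }
  }
  if (w$baseline[2] > w$surround[1] || w$surround[2] > w$center[1]) {
    stop("windows must be ordered baseline < surround < center without overlap")
  }
  structure(w, class = "analysis_windows")
}

#' Window metrics of a SAC membrane-potential trace
#'
#' The three summary statistics used for moving-bar sweeps: mean Vm over
#' the baseline window, mean Vm over the surround window relative to
#' rest (hyperpolarisation is negative), and peak Vm over the center
#' window relative to rest.
#'
#' @param v a [vm_trace].
#' @param w an [analysis_windows].
#' @param v_rest resting potential, mV; defaults to the trace's `v_rest`
#'   annotation, else the baseline mean.
#' @return list with `baseline_mean_mV`, `surround_mean_rel_mV`,
#'   `center_peak_rel_mV` and `v_rest`.
#' @export
window_metrics <- function(v, w, v_rest = NULL) {
  base <- mean(v$values[window_index(v, w$baseline)])
  if (is.null(v_rest)) {
    v_rest <- if (is.finite(v$v_rest)) v$v_rest else base
  }
  list(baseline_mean_mV = base,
       surround_mean_rel_mV = mean(v$values[window_index(v, w$surround)]) - v_rest,
       center_peak_rel_mV = max(v$values[window_index(v, w$center)]) - v_rest,
       v_rest = v_rest)
}

#' Peak and charge transfer of an IPSC within a window
#'
#' The trace is baseline-subtracted first (baseline = mean over the
#' `baseline_s` seconds preceding the window, clipped to the trace
#' start); the peak is the maximum and the charge the time integral of
#' the subtracted trace within the window.
#'
#' @param i an [ipsc_trace].
#' @param window `c(t0, t1)`, s.
#' @param baseline_s length of the pre-window baseline segment, s.
#' @return list with `peak` (pA) and `charge` (pA s).
#' @export
ipsc_metrics <- function(i, window, baseline_s = 0.5) {
  idx <- window_index(i, window)
  t <- trace_times(i)
  bidx <- which(t >= window[1] - baseline_s & t < window[1])
  b <- if (length(bidx)) mean(i$values[bidx]) else 0
  vals <- i$values[idx] - b
  list(peak = max(vals), charge = sum(vals) * i$dt)
}

#' Normalise cKO-waveform metrics to the control waveform
#'
#' Per-window ratio of a metric evoked by the cKO waveform to the same
#' metric evoked by the control waveform of the same pair; window 1
#' (baseline) is the internal control and window 3 (center/motion) the
#' effect readout.
#'
#' @param cko,control named numeric vectors (or lists) of per-window
#'   metrics; names must match.
#' @return named numeric vector of ratios cko/control.
#' @export
normalize_to_control <- function(cko, control) {
  cko <- unlist(cko); control <- unlist(control)
  control <- control[names(cko)]
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop("control metric must be positive in every window")
  }
  cko / control
}

#' Noise-induced suppression of the motion-evoked IPSC
#'
#' Percentage decrease of the motion-evoked response under the cKO
#' waveform relative to the control waveform:
#' `100 * (control - cko) / control`. Negative values (cKO larger than
#' control) are reported, not clipped.
#'
#' @param control_peak,cko_peak response amplitudes, pA (control > 0).
#' @return suppression in percent.
#' @export
noise_induced_suppression <- function(control_peak, cko_peak) {
  if (any(control_peak <= 0)) stop("control peak must be > 0")
  100 * (control_peak - cko_peak) / control_peak
}

#' Duration of the surround-suppression window at a given bar speed
#'
#' Geometric counterpart of the measured hyperpolarisation window: the
#' time the bar needs to cross the RF surround,
#' `surround_extent / speed`. At the default 200-um surround extent this
#' gives about 150 ms at 1320 um/s, the protective window preceding the
#' motion response.
#'
#' @param surround_extent radial extent of the RF surround, um.
#' @param bar_width bar width along motion, um (carried for interface
#'   completeness; the leading edge defines the window).
#' @param speed bar speed, um/s.
#' @return duration, s.
#' @export
surround_window_duration <- function(surround_extent = 200, bar_width = 110,
                                     speed = 440) {
  if (any(speed <= 0)) stop("speed must be > 0")
  if (any(surround_extent <= 0) || any(bar_width <= 0)) {
    stop("geometry must be positive")
  }
  surround_extent / speed
}
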