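#' Construct the control command waveform from a cKO trace
#'
#' Replaces the noisy cKO membrane-potential pattern inside the
#' surround-suppression window (window 2) by the mean control-group
#' pattern, leaving every sample outside the window bit-identical to the
#' input; a short linear cross-fade at each seam keeps the waveform
#' continuous. The result is the "control pattern" of the paired
#' recording protocol: identical to the cKO pattern except for the
#' surround window.
#'
#' @param cko_trace a [vm_trace].
#' @param window2 `c(t0, t1)` replacement window, s.
#' @param control_mean replacement values spanning `window2` on the same
#'   grid: a numeric vector or a [vm_trace] (its values are used).
#' @param blend_ms seam cross-fade length, ms (<= 5 keeps the blend
#'   negligible relative to the window).
#' @return a [vm_trace] equal to the input outside `window2`.
#' @export
construct_control_waveform <- function(cko_trace, window2, control_mean,
                                       blend_ms = 5) {
  idx <- window_index(cko_trace, window2)
  seg <- if (inherits(control_mean, "vm_trace")) control_mean$values
         else as.numeric(control_mean)
  if (length(seg) != length(idx)) {
    stop("replacement segment length ", length(seg),
         " does not match the ", length(idx), "-sample window")
  }
  nb <- min(round(blend_ms * 1e-3 / cko_trace$dt), floor(length(idx) / 2))
  wgt <- rep(1, length(idx))
  if (nb > 0) {
    ramp <- seq_len(nb) / (nb + 1)
    wgt[seq_len(nb)] <- ramp
    wgt[length(idx) - nb + seq_len(nb)] <- rev(ramp)
  }
  out <- cko_trace
  out$values[idx] <- (1 - wgt) * cko_trace$values[idx] + wgt * seg
  out
}

#' Scale a command waveform about an anchor potential
#'
#' `out = anchor + factor * (v - anchor)`: deviations from the anchor are
#' multiplied by `factor`, compensating the soma-to-dendrite attenuation
#' so the distal membrane reaches visual-stimulation levels. The anchor
#' defaults to the trace's baseline mean (its annotated baseline window
#' if present, else the annotated resting potential, else the trace
#' mean).
#'
#' @param v a [vm_trace].
#' @param factor scale factor (> 0).
#' @param anchor anchor potential, mV, or `NULL` for the default.
#' @return a scaled [vm_trace].
#' @export
scale_waveform <- function(v, factor, anchor = NULL) {
  if (factor <= 0) stop("scale factor must be > 0")
  if (is.null(anchor)) {
    anchor <- if (!is.null(v$windows)) {
      mean(v$values[window_index(v, v$windows$baseline)])
    } else if (is.finite(v$v_rest)) v$v_rest else mean(v$values)
  }
  out <- v
  out$values <- anchor + factor * (v$values - anchor)
  out
}

#' Run the paired-waveform protocol on the depressing synapse
#'
#' For each scale factor: builds the control waveform (cKO trace with the
#' surround window replaced by the mean control pattern), scales both
#' waveforms, drives the depressing synapse with each, and quantifies the
#' DSGC IPSC in window 1 (baseline, the internal control) and window 3
#' (motion response). Reports the cKO/control peak ratios per window and
#' the noise-induced suppression of the motion response.
#'
#' @param cko_trace a [vm_trace] with flicker structure (typically from
#'   [generate_sac_vm()] with a cKO genotype and noisy background).
#' @param windows an [analysis_windows]; defaults to the trace's own.
#' @param control_mean replacement segment for the surround window (see
#'   [construct_control_waveform()]).
#' @param scale_factors command scale factors (default 4; 3 and 5 probe
#'   robustness).
#' @param p a [depression_params].
#' @param keep_traces retain the IPSC traces in the result.
#' @return object of class `motif_experiment` with a `table` (one row
#'   per scale factor: window-1 and window-3 ratios, suppression %) and
#'   provenance.
#' @export
run_paired_protocol <- function(cko_trace, windows = NULL, control_mean,
                                scale_factors = 4,
                                p = depression_params(),
                                keep_traces = FALSE) {
  if (is.null(windows)) windows <- cko_trace$windows
  if (is.null(windows)) stop("no analysis windows supplied or annotated")
  ctrl_trace <- construct_control_waveform(cko_trace, windows$surround,
                                           control_mean)
  rows <- vector("list", length(scale_factors))
  traces <- list()
  for (k in seq_along(scale_factors)) {
    f <- scale_factors[k]
    anchor <- mean(cko_trace$values[window_index(cko_trace, windows$baseline)])
    cko_cmd <- scale_waveform(cko_trace, f, anchor)
    ctrl_cmd <- scale_waveform(ctrl_trace, f, anchor)
    cko_ipsc <- simulate_release(cko_cmd, p)
    ctrl_ipsc <- simulate_release(ctrl_cmd, p)
    m_cko <- c(window1 = ipsc_metrics(cko_ipsc, windows$baseline)$peak,
               window3 = ipsc_metrics(cko_ipsc, windows$center)$peak)
    m_ctrl <- c(window1 = ipsc_metrics(ctrl_ipsc, windows$baseline)$peak,
                window3 = ipsc_metrics(ctrl_ipsc, windows$center)$peak)
    ratios <- normalize_to_control(m_cko, m_ctrl)
    rows[[k]] <- data.frame(
      scale_factor = f,
      window1_ratio = unname(ratios["window1"]),
      window3_ratio = unname(ratios["window3"]),
      control_peak_pA = unname(m_ctrl["window3"]),
      cko_peak_pA = unname(m_cko["window3"]),
      suppression_pct = unname(noise_induced_suppression(
        m_ctrl["window3"], m_cko["window3"])))
    if (keep_traces) {
      traces[[as.character(f)]] <- list(cko = cko_ipsc, control = ctrl_ipsc)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, windows = windows,
                 params = p, traces = if (keep_traces) traces else NULL),
            class = "motif_experiment")
}

#' Mean control-group surround pattern
#'
#' Averages the surround-window segment of `n` seeded control-group
#' traces under the given background and speed: the "mean Vm pattern of
#' SACs in the control group" used to build the control waveform.
#'
#' @param windows an [analysis_windows] matching the target trace grid.
#' @param background,speed,p generator settings (see
#'   [generate_sac_vm()]).
#' @param n number of control cells averaged.
#' @param seed integer seed.
#' @return numeric vector spanning the surround window.
#' @export
mean_control_pattern <- function(windows, background = "noisy", speed = 440,
                                 p = sac_vm_gen_params(), n = 10,
                                 seed = 1L) {
  segs <- lapply(seq_len(n), function(i) {
    tr <- generate_sac_vm("control", background, speed, p,
                          seed = seed + 1000L * i)
    tr$values[window_index(tr, windows$surround)]
  })
  rowMeans(do.call(cbind, segs))
}

#' Paired protocol across bar speeds
#'
#' For each speed, generates a cKO-style noisy trace (surround-window
#' duration scaling as extent/speed), the matching mean control pattern,
#' and runs [run_paired_protocol()]; tabulates the window-3 suppression
#' against speed.
#'
#' @param speeds bar speeds, um/s.
#' @param genotype cKO genotype driving the noisy waveform.
#' @param scale_factor command scale factor.
#' @param p_syn a [depression_params].
#' @param p_gen a [sac_vm_gen_params].
#' @param seed integer seed.
#' @return `motif_experiment` whose `table` has one row per speed.
#' @export
run_speed_series <- function(speeds = c(110, 440, 1320),
                             genotype = "gabra2_cko", scale_factor = 4,
                             p_syn = depression_params(),
                             p_gen = sac_vm_gen_params(), seed = 1L) {
  if (any(speeds <= 0)) stop("speeds must be > 0")
  rows <- vector("list", length(speeds))
  for (k in seq_along(speeds)) {
    sp <- speeds[k]
    cko <- representative_cko_trace(genotype, "noisy", sp, p_gen,
                                    seed = seed + k)
    ctrl_mean <- mean_control_pattern(cko$windows, "noisy", sp, p_gen,
                                      seed = seed + 100L * k)
    res <- run_paired_protocol(cko, cko$windows, ctrl_mean,
                               scale_factors = scale_factor, p = p_syn)
    rows[[k]] <- cbind(speed_um_s = sp,
                       window2_duration_s = diff(cko$windows$surround),
                       res$table)
  }
  structure(list(table = do.call(rbind, rows), params = p_syn,
                 seed = seed),
            class = "motif_experiment")
}

#' DSGC readout parameters
#'
#' Deliberately minimal spiking readout of the DSGC: spike count per
#' direction is a Poisson draw with rate
#' `gain * max(E - w(theta) * Q, 0)`, where `Q` is the motion-window
#' IPSC charge from the null-side SAC pathway, `w(theta)` a
#' cosine-shaped directional weight peaking in the null direction, and
#' `E` a direction-independent excitatory drive (DSGC excitation is
#' unaffected by the SAC genotypes).
#'
#' @param e_ratio excitatory drive as a multiple of the reference
#'   (control, noisy) motion-window inhibitory charge.
#' @param pref_rate expected preferred-direction spike count.
#' @param n_ref control traces averaged for the reference charge.
#' @return list of readout parameters.
#' @export
dsgc_readout_params <- function(e_ratio = 1.3, pref_rate = 25, n_ref = 5) {
  list(e_ratio = e_ratio, pref_rate = pref_rate, n_ref = n_ref)
}

# motion-window IPSC charge of one generated SAC trace
motion_charge <- function(genotype, background, speed, p_gen, p_syn,
                          scale_factor, seed) {
  tr <- generate_sac_vm(genotype, background, speed, p_gen, seed = seed)
  cmd <- scale_waveform(tr, scale_factor)
  ipsc <- simulate_release(cmd, p_syn)
  max(ipsc_metrics(ipsc, tr$windows$center)$charge, 0)
}

#' Simulate DSGC spike counts per direction
#'
#' One generated SAC trace per trial sets the trial's null-pathway
#' inhibitory charge; each direction then draws a Poisson spike count
#' from the rectified-linear readout (see [dsgc_readout_params()]).
#' The reference excitatory drive is computed from control-group traces
#' at the same settings, so it is identical across genotypes for a given
#' seed.
#'
#' @param genotype a [genotype_config] or name.
#' @param background `"noise_free"` or `"noisy"`.
#' @param n_directions 8 or 12 (must include the preferred/null axis).
#' @param n_trials trials per direction.
#' @param readout a [dsgc_readout_params()].
#' @param p_gen,p_syn generator and synapse parameters.
#' @param scale_factor command scaling for the synapse drive.
#' @param speed bar speed, um/s.
#' @param seed integer seed.
#' @return data frame: `trial`, `direction_deg`, `count`.
#' @export
generate_dsgc_counts <- function(genotype = "control",
                                 background = c("noise_free", "noisy"),
                                 n_directions = 8, n_trials = 5,
                                 readout = dsgc_readout_params(),
                                 p_gen = sac_vm_gen_params(),
                                 p_syn = depression_params(),
                                 scale_factor = 4, speed = 440,
                                 seed = 1L) {
  background <- match.arg(background)
  if (!n_directions %in% c(8L, 12L)) stop("n_directions must be 8 or 12")
  if (is.character(genotype)) genotype <- genotype_config(genotype)
  dirs <- seq(0, 360, length.out = n_directions + 1)[-(n_directions + 1)]
  # genotype-independent reference: control charge at the same settings
  q_ref <- mean(vapply(seq_len(readout$n_ref), function(i) {
    motion_charge("control", background, speed, p_gen, p_syn, scale_factor,
                  seed = seed + 33000L + 7L * i)
  }, numeric(1)))
  e_drive <- readout$e_ratio * q_ref
  gain <- readout$pref_rate / e_drive
  gt_off <- switch(genotype$name, control = 0L, gabra2_cko = 500000L,
                   vgat_cko = 250000L)
  rng <- local_rng(seed + gt_off + 1L)
  on.exit(rng())
  out <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    q <- motion_charge(genotype, background, speed, p_gen, p_syn,
                       scale_factor, seed = seed + gt_off + 101L * tr)
    wdir <- (1 - cos(dirs * pi / 180)) / 2   # 0 at pref, 1 at null
    lambda <- gain * pmax(e_drive - wdir * q, 0)
    out[[tr]] <- data.frame(trial = tr, direction_deg = dirs,
                            count = stats::rpois(n_directions, lambda))
  }
  do.call(rbind, out)
}

#' Direction-selectivity experiment
#'
#' Simulates DSGC spiking over directions and trials for one genotype
#' and background and computes the DSI from the preferred (0 deg) /
#' null (180 deg) direction pair, per trial and pooled.
#'
#' @inheritParams generate_dsgc_counts
#' @return object of class `motif_experiment` with the spike-count
#'   table, per-trial DSI, mean DSI, and pooled-count DSI.
#' @export
run_dsi_experiment <- function(genotype = "control",
                               background = c("noise_free", "noisy"),
                               n_directions = 8, n_trials = 5,
                               readout = dsgc_readout_params(),
                               p_gen = sac_vm_gen_params(),
                               p_syn = depression_params(),
                               seed = 1L) {
  background <- match.arg(background)
  counts <- generate_dsgc_counts(genotype, background, n_directions,
                                 n_trials, readout, p_gen, p_syn,
                                 seed = seed)
  pref <- counts$count[counts$direction_deg == 0]
  null <- counts$count[counts$direction_deg == 180]
  ok <- (pref + null) > 0
  dsi_trials <- rep(NA_real_, length(pref))
  dsi_trials[ok] <- dsi(pref[ok], null[ok])
  structure(list(counts = counts,
                 dsi_per_trial = dsi_trials,
                 mean_dsi = mean(dsi_trials, na.rm = TRUE),
                 pooled_dsi = dsi(sum(pref), sum(null)),
                 genotype = if (is.character(genotype)) genotype
                            else genotype$name,
                 background = background, seed = seed),
            class = "motif_experiment")
}

#' @export
print.motif_experiment <- function(x, ...) {
  if (!is.null(x$table)) {
    cat("motif experiment\n")
    print(x$table, row.names = FALSE)
  } else {
    cat(sprintf("DSI experiment [%s, %s]: mean DSI %.3f (pooled %.3f, %d trials)\n",
                x$genotype, x$background, x$mean_dsi, x$pooled_dsi,
                length(x$dsi_per_trial)))
  }
  invisible(x)
}
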