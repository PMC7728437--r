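#' Genotype configuration for the disinhibitory motif
#'
#' Encodes which inhibitory inputs onto SACs are intact. `control` keeps
#' both SAC-SAC and wide-field (WAC) inhibition; `gabra2_cko` removes all
#' GABAergic input to SACs; `vgat_cko` removes only SAC-SAC inhibition,
#' leaving the (weaker) wide-field input. The genotype acts purely on the
#' generated SAC membrane potential (strength of the motion-evoked
#' surround suppression), not on the depressing synapse: the residual
#' suppression fraction is 0.9 for control, 0 for `gabra2_cko`, and 0.15
#' (the wide-field share) for `vgat_cko`.
#'
#' @param name one of `"control"`, `"gabra2_cko"`, `"vgat_cko"`.
#' @return object of class `genotype_config`.
#' @export
genotype_config <- function(name = c("control", "gabra2_cko", "vgat_cko")) {
  name <- match.arg(name)
  cfg <- switch(name,
    control = list(sac_sac_inhibition = TRUE, wac_sac_inhibition = TRUE,
                   suppression_frac = 0.9),
    gabra2_cko = list(sac_sac_inhibition = FALSE, wac_sac_inhibition = FALSE,
                      suppression_frac = 0.0),
    vgat_cko = list(sac_sac_inhibition = FALSE, wac_sac_inhibition = TRUE,
                    suppression_frac = 0.15))
  structure(c(list(name = name), cfg), class = "genotype_config")
}

#' Parameters of the synthetic SAC membrane-potential generator
#'
#' Stylised generative model of somatic SAC recordings during a moving
#' bar: a flat resting baseline; under a noisy background, depolarising
#' "flicker response" events locked to the 15-Hz checkerboard frames
#' (one Bernoulli draw per frame, lognormal amplitudes); a
#' surround-suppression window whose duration scales with bar speed, in
#' which the genotype multiplicatively suppresses the flicker events and
#' hyperpolarises the membrane; and a motion-evoked center
#' depolarisation shared by all genotypes.
#'
#' @param v_rest resting potential, mV.
#' @param flicker_rate_hz checker refresh rate the events are locked to.
#' @param flicker_p probability of an event per frame.
#' @param flicker_amp_mean,flicker_amp_sd lognormal event amplitude
#'   moments, mV.
#' @param flicker_event_ms event duration, ms.
#' @param suppression_depth full surround hyperpolarisation, mV
#'   (scaled by the genotype's residual suppression fraction).
#' @param surround_extent RF surround extent, um (window-2 duration =
#'   extent / speed).
#' @param center_peak motion-evoked peak depolarisation, mV.
#' @param center_tau_ms alpha-function time constant of the center
#'   response, ms.
#' @param noise_sd white measurement noise, mV.
#' @param baseline_s,tail_s baseline and post-motion durations, s.
#' @param dt sample interval, s.
#' @return object of class `sac_vm_gen_params`.
#' @export
sac_vm_gen_params <- function(v_rest = -70, flicker_rate_hz = 15,
                              flicker_p = 0.5, flicker_amp_mean = 6,
                              flicker_amp_sd = 3, flicker_event_ms = 40,
                              suppression_depth = 3, surround_extent = 200,
                              center_peak = 12, center_tau_ms = 80,
                              noise_sd = 0.3, baseline_s = 2, tail_s = 0.5,
                              dt = 1e-3) {
  stopifnot(flicker_amp_mean >= 0, flicker_amp_sd >= 0, flicker_event_ms > 0,
            suppression_depth >= 0, center_peak >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "sac_vm_gen_params")
}

# lognormal meanlog/sdlog from arithmetic mean/sd
lnorm_pars <- function(m, s) {
  if (m <= 0) return(c(meanlog = -Inf, sdlog = 0))
  v <- s^2
  c(meanlog = log(m^2 / sqrt(v + m^2)), sdlog = sqrt(log(1 + v / m^2)))
}

#' Generate one synthetic SAC membrane-potential trace
#'
#' @param genotype a [genotype_config] (or its name).
#' @param background `"noise_free"` or `"noisy"`.
#' @param speed bar speed, um/s; sets the surround-window duration.
#' @param p a [sac_vm_gen_params].
#' @param seed integer seed; identical arguments give identical traces.
#' @return a [vm_trace] with `windows` ([analysis_windows]) and `v_rest`
#'   annotations; attribute `gen_params` records the generating
#'   parameters and genotype.
#' @export
generate_sac_vm <- function(genotype = genotype_config("control"),
                            background = c("noise_free", "noisy"),
                            speed = 440, p = sac_vm_gen_params(),
                            seed = 1L) {
  if (is.character(genotype)) genotype <- genotype_config(genotype)
  background <- match.arg(background)
  rng <- local_rng(seed)
  on.exit(rng())
  sur_dur <- surround_window_duration(p$surround_extent, speed = speed)
  center_dur <- max(0.3, 2 * (110 + p$surround_extent / 4) / speed)
  t_sur <- p$baseline_s
  t_cen <- t_sur + sur_dur
  t_end <- t_cen + center_dur + p$tail_s
  n <- ceiling(t_end / p$dt)
  t <- seq_len(n) * p$dt
  w <- analysis_windows(baseline = c(0, t_sur), surround = c(t_sur, t_cen),
                        center = c(t_cen, t_cen + center_dur))
  frac <- genotype$suppression_frac
  v <- p$v_rest + stats::rnorm(n, 0, p$noise_sd)
  # surround hyperpolarisation (lateral inhibition), scaled by genotype
  in_sur <- t >= t_sur & t < t_cen
  v[in_sur] <- v[in_sur] - p$suppression_depth * frac
  ev_tab <- NULL
  if (background == "noisy") {
    frame_dt <- 1 / p$flicker_rate_hz
    ev_len <- max(2L, round(p$flicker_event_ms * 1e-3 / p$dt))
    shape <- sin(pi * seq_len(ev_len) / (ev_len + 1))
    lp <- lnorm_pars(p$flicker_amp_mean, p$flicker_amp_sd)
    n_frames <- floor(t_end / frame_dt)
    ev_on <- stats::rbinom(n_frames, 1L, p$flicker_p) == 1L
    ev_amp <- stats::rlnorm(n_frames, lp["meanlog"], lp["sdlog"])
    onsets <- numeric(0); amps <- numeric(0); in_sur_ev <- logical(0)
    for (f in which(ev_on)) {
      i0 <- round((f - 1) * frame_dt / p$dt) + 1L
      amp <- ev_amp[f]
      # events inside the surround window are suppressed by the genotype
      sur_ev <- t[i0] >= t_sur && t[i0] < t_cen
      if (sur_ev) amp <- amp * (1 - frac)
      idx <- i0:min(n, i0 + ev_len - 1L)
      v[idx] <- v[idx] + amp * shape[seq_along(idx)]
      onsets <- c(onsets, t[i0]); amps <- c(amps, amp)
      in_sur_ev <- c(in_sur_ev, sur_ev)
    }
    ev_tab <- data.frame(onset_s = onsets, amp_mV = amps,
                         in_surround = in_sur_ev)
  }
  # motion-evoked center response: alpha function, genotype-independent
  tau_c <- p$center_tau_ms * 1e-3
  after <- t >= t_cen
  ta <- t[after] - t_cen
  v[after] <- v[after] +
    p$center_peak * (ta / tau_c) * exp(1 - ta / tau_c)
  out <- vm_trace(v, dt = p$dt, t0 = p$dt, windows = w, v_rest = p$v_rest)
  attr(out, "gen_params") <- list(genotype = genotype$name,
                                  background = background, speed = speed,
                                  params = p, seed = seed)
  attr(out, "events") <- ev_tab
  out
}

#' Representative cKO-style waveform for paired protocols
#'
#' The paired-recording protocol uses representative command waveforms
#' that match the average number and amplitude of flicker events inside
#' the surround-suppression window. This helper draws seeded candidate
#' traces until one matches: the window-2 event count equals the
#' expectation `round(window_frames * flicker_p)` (at least one) and the
#' mean unsuppressed window-2 event amplitude is at least three quarters
#' of the population mean.
#'
#' @inheritParams generate_sac_vm
#' @param max_tries candidate seeds examined before giving up.
#' @return a [vm_trace] as from [generate_sac_vm()]; attribute
#'   `selected_seed` records the accepted candidate.
#' @export
representative_cko_trace <- function(genotype = "gabra2_cko",
                                     background = "noisy", speed = 440,
                                     p = sac_vm_gen_params(), seed = 1L,
                                     max_tries = 200L) {
  sur_dur <- surround_window_duration(p$surround_extent, speed = speed)
  target <- max(1L, round(sur_dur * p$flicker_rate_hz * p$flicker_p))
  for (k in seq_len(max_tries)) {
    cand_seed <- seed + 7919L * (k - 1L)
    tr <- generate_sac_vm(genotype, background, speed, p, seed = cand_seed)
    ev <- attr(tr, "events")
    sur_ev <- ev[ev$in_surround, , drop = FALSE]
    if (nrow(sur_ev) == target &&
        mean(sur_ev$amp_mV) >= 0.75 * p$flicker_amp_mean *
          (1 - genotype_config(if (is.character(genotype)) genotype
                               else genotype$name)$suppression_frac)) {
      attr(tr, "selected_seed") <- cand_seed
      return(tr)
    }
  }
  stop("no representative waveform found in ", max_tries, " candidates")
}

#' Generate a population of synthetic SAC traces
#'
#' Per-cell parameters (flicker amplitude, suppression depth, center
#' peak) are jittered with a 10% coefficient of variation; the window-2
#' structure is the only element the genotype touches.
#'
#' @param n_cells number of cells.
#' @param group a [genotype_config] (or name).
#' @param background `"noise_free"` or `"noisy"`.
#' @param speed bar speed, um/s.
#' @param p a [sac_vm_gen_params].
#' @param cv per-cell parameter coefficient of variation.
#' @param seed integer seed.
#' @return list of [vm_trace]s (one per cell).
#' @export
generate_population <- function(n_cells = 15, group = "control",
                                background = "noisy", speed = 440,
                                p = sac_vm_gen_params(), cv = 0.1,
                                seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  rng <- local_rng(seed)
  jit <- matrix(pmax(0.2, stats::rnorm(3 * n_cells, 1, cv)), ncol = 3)
  cell_seeds <- sample.int(2^30, n_cells)
  rng()
  lapply(seq_len(n_cells), function(i) {
    pi_ <- p
    pi_$flicker_amp_mean <- p$flicker_amp_mean * jit[i, 1]
    pi_$suppression_depth <- p$suppression_depth * jit[i, 2]
    pi_$center_peak <- p$center_peak * jit[i, 3]
    generate_sac_vm(group, background, speed, pi_, seed = cell_seeds[i])
  })
}

#' Synthetic paired-pulse-ratio dataset
#'
#' Draws PPR observations from the closed-form recovery curve
#' `1 - U exp(-interval/tau_rec)` with multiplicative noise, for testing
#' parameter recovery with [fit_depression()].
#'
#' @param true_params a [depression_params].
#' @param intervals_s inter-pulse intervals, s.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param n_reps replicates per interval.
#' @param seed integer seed.
#' @return data frame with columns `interval_s`, `rep`, `ppr`.
#' @export
generate_ppr_dataset <- function(true_params = depression_params(),
                                 intervals_s = c(0.2, 0.4, 1.6),
                                 noise_cv = 0, n_reps = 1, seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  grid <- expand.grid(rep = seq_len(n_reps), interval_s = intervals_s)
  mu <- 1 - true_params$U * exp(-grid$interval_s / true_params$tau_rec)
  ppr <- mu * (1 + noise_cv * stats::rnorm(nrow(grid)))
  data.frame(interval_s = grid$interval_s, rep = grid$rep,
             ppr = pmin(pmax(ppr, 1e-6), 1))
}
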