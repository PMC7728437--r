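#' Parameters of the depressing SAC-DSGC synapse
#'
#' Single-pool resource-depletion model of the GABAergic SAC-to-DSGC
#' synapse. A presynaptic dendritic-equivalent command potential `V(t)`
#' engages release at the instantaneous rate
#' `r(t) = (exp((V - drive_threshold)/drive_gain) - 1)+ * U * R(t)`,
#' depleting the available resource `R` (recovering with time constant
#' `tau_rec`); the DSGC IPSC is the release flux convolved with a
#' bi-exponential kernel. `U` is the fraction of available resource
#' released by one standard activation (see
#' [calibrate_pulse_amplitude()]).
#'
#' @param U release fraction per activation, in (0, 1].
#' @param tau_rec recovery time constant, s.
#' @param drive_threshold presynaptic potential above which release is
#'   engaged, mV. The default -55 mV reflects the low activation
#'   threshold of the calcium channels that couple dendritic
#'   depolarisation to GABA release, so that scaled flicker events
#'   engage release as they do in recordings.
#' @param drive_gain e-fold gain of the release nonlinearity, mV.
#' @param kernel_rise_ms,kernel_decay_ms IPSC kernel time constants, ms.
#' @param g_unit IPSC scale factor, pA per unit of released resource.
#' @return object of class `depression_params`.
#' @export
depression_params <- function(U = 0.5, tau_rec = 0.7, drive_threshold = -55,
                              drive_gain = 6, kernel_rise_ms = 1,
                              kernel_decay_ms = 20, g_unit = 500) {
  if (U <= 0 || U > 1) stop("U must lie in (0, 1]")
  if (tau_rec <= 0) stop("tau_rec must be > 0")
  if (kernel_rise_ms <= 0 || kernel_decay_ms <= 0) {
    stop("kernel time constants must be > 0")
  }
  structure(list(U = U, tau_rec = tau_rec,
                 drive_threshold = drive_threshold, drive_gain = drive_gain,
                 kernel_rise_ms = kernel_rise_ms,
                 kernel_decay_ms = kernel_decay_ms, g_unit = g_unit),
            class = "depression_params")
}

# unit-peak bi-exponential kernel sampled at dt
ipsc_kernel <- function(p, dt) {
  tr <- p$kernel_rise_ms * 1e-3
  td <- p$kernel_decay_ms * 1e-3
  tt <- seq(0, 8 * td, by = dt)
  k <- exp(-tt / td) - exp(-tt / tr)
  k / max(k)
}

#' Simulate release and the DSGC IPSC from a command waveform
#'
#' Integrates the depletion dynamics
#' `dR/dt = (1 - R)/tau_rec - r(t)` with
#' `r(t) = (exp((V - thr)/gain) - 1)+ * U * R` exactly over each sample
#' (the drive is treated as constant within a step, for which the linear
#' resource equation has a closed-form update), and convolves the
#' release flux with the bi-exponential IPSC kernel. Deterministic.
#'
#' @param drive a [vm_trace]: presynaptic dendritic-equivalent command
#'   waveform, mV.
#' @param p a [depression_params].
#' @return an [ipsc_trace] (pA) with attribute `resource` (the R(t)
#'   series, in [0, 1]).
#' @export
simulate_release <- function(drive, p = depression_params()) {
  if (!inherits(drive, "vm_trace")) stop("drive must be a vm_trace")
  dt <- drive$dt
  v <- drive$values
  d <- pmax(exp((v - p$drive_threshold) / p$drive_gain) - 1, 0) * p$U  # 1/s
  n <- length(v)
  R <- numeric(n)
  flux <- numeric(n)  # released resource per second
  r_prev <- 1
  inv_tau <- 1 / p$tau_rec
  for (i in seq_len(n)) {
    k <- inv_tau + d[i]
    r_inf <- inv_tau / k
    e <- exp(-k * dt)
    r_new <- r_inf + (r_prev - r_inf) * e
    # exact integral of d * R over the step
    released <- d[i] * (r_inf * dt + (r_prev - r_inf) * (1 - e) / k)
    flux[i] <- released / dt
    R[i] <- r_new
    r_prev <- r_new
  }
  ker <- ipsc_kernel(p, dt)
  ipsc <- conv_causal(flux, ker) * dt * p$g_unit
  out <- ipsc_trace(ipsc, dt = dt, t0 = drive$t0, windows = drive$windows)
  attr(out, "resource") <- R
  out
}

# causal linear convolution, output trimmed to length(x)
conv_causal <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  out[seq_len(n)]
}

#' Pulse amplitude that releases exactly fraction U
#'
#' One "activation" of the synapse is defined as a brief pulse that
#' releases the fraction `U` of the currently available resource. For a
#' rectangular pulse of width `width_ms` the depletion is
#' `1 - exp(-h * w)` with `h` the engaged release rate, so the amplitude
#' solving `1 - exp(-h w) = U` is
#' `thr + gain * log(1 - log(1 - U) / (U * w))`.
#'
#' @param p a [depression_params].
#' @param width_ms pulse width, ms.
#' @return pulse amplitude, mV.
#' @export
calibrate_pulse_amplitude <- function(p, width_ms = 10) {
  w <- width_ms * 1e-3
  h_needed <- -log(1 - p$U) / w        # engaged rate, 1/s (includes U)
  d_needed <- h_needed / p$U            # drive term exp(.)-1
  p$drive_threshold + p$drive_gain * log(1 + d_needed)
}

#' Paired-pulse ratio of the depressing synapse
#'
#' Drives the synapse with two identical rectangular pulses separated by
#' `interval` and returns the ratio of the second to the first IPSC
#' peak. For a pure-depression synapse the ratio lies in (0, 1], grows
#' monotonically with the interval, and approaches
#' `1 - U * exp(-interval/tau_rec)` in the brief-pulse limit.
#'
#' @param p a [depression_params].
#' @param interval inter-pulse interval (onset to onset), s; must exceed
#'   the pulse width.
#' @param pulse list with `amplitude` (mV) and `width_ms`; by default a
#'   10-ms pulse at the [calibrate_pulse_amplitude()] level.
#' @param dt simulation step, s.
#' @return paired-pulse ratio (dimensionless).
#' @export
paired_pulse_ratio <- function(p = depression_params(), interval,
                               pulse = NULL, dt = 2e-4) {
  if (is.null(pulse)) {
    pulse <- list(amplitude = calibrate_pulse_amplitude(p, 10), width_ms = 10)
  }
  w <- pulse$width_ms * 1e-3
  if (interval <= w) stop("pulses overlap: interval must exceed pulse width")
  t1 <- 0.05
  t_end <- t1 + interval + w + 10 * p$kernel_decay_ms * 1e-3
  n <- ceiling(t_end / dt)
  t <- seq_len(n) * dt
  v <- rep(p$drive_threshold - 20, n)
  v[t >= t1 & t < t1 + w] <- pulse$amplitude
  v[t >= t1 + interval & t < t1 + interval + w] <- pulse$amplitude
  ipsc <- simulate_release(vm_trace(v, dt = dt, t0 = dt), p)
  peak1 <- max(ipsc$values[t < t1 + interval])
  peak2 <- max(ipsc$values[t >= t1 + interval])
  peak2 / peak1
}

#' Paired-pulse protocol table
#'
#' Runs [paired_pulse_ratio()] over a set of inter-pulse intervals
#' (default the experimental 200, 400 and 1600 ms) and tabulates the
#' peaks and ratios.
#'
#' @param p a [depression_params].
#' @param intervals_s inter-pulse intervals, s.
#' @param ... passed to [paired_pulse_ratio()].
#' @return data frame with columns `interval_s` and `ppr`.
#' @export
paired_pulse_protocol <- function(p = depression_params(),
                                  intervals_s = c(0.2, 0.4, 1.6), ...) {
  data.frame(interval_s = intervals_s,
             ppr = vapply(intervals_s, function(iv) {
               paired_pulse_ratio(p, iv, ...)
             }, numeric(1)))
}

#' Fit depression parameters to paired-pulse data
#'
#' Least-squares fit of the recovery curve
#' `ppr = 1 - U * exp(-interval / tau_rec)` to observed paired-pulse
#' ratios, via [stats::nls()] with a log-linear starting estimate.
#'
#' @param ppr_points data frame with columns `interval_s` (or `interval`)
#'   and `ppr`; at least two points with `0 < ppr <= 1`.
#' @return object of class `depression_fit` with components `U`,
#'   `tau_rec`, `fitted`, `residual_norm` and the underlying `nls` fit;
#'   supports `coef()`, `predict()` and `print()`.
#' @export
fit_depression <- function(ppr_points) {
  nm <- if ("interval_s" %in% names(ppr_points)) "interval_s" else "interval"
  iv <- ppr_points[[nm]]
  ppr <- ppr_points$ppr
  if (length(iv) < 2) stop("at least two (interval, ppr) points are required")
  if (any(ppr <= 0 | ppr > 1 + 1e-9)) stop("ppr values must lie in (0, 1]")
  depressed <- ppr < 1 - 1e-9
  if (!any(depressed)) {
    warning("all ppr values are 1: no measurable depression, U -> 0")
    return(structure(list(U = 0, tau_rec = NA_real_, fitted = rep(1, length(iv)),
                          residual_norm = 0, fit = NULL),
                     class = "depression_fit"))
  }
  # log-linearise: log(1 - ppr) = log(U) - interval / tau
  ly <- log(1 - ppr[depressed])
  lf <- stats::lm(ly ~ iv[depressed])
  tau0 <- -1 / min(stats::coef(lf)[2], -1e-6)
  u0 <- min(max(exp(stats::coef(lf)[1]), 1e-3), 1)
  rss <- function(th) sum((ppr - (1 - th[1] * exp(-iv / th[2])))^2)
  cf <- c(U = u0, tau = tau0)
  fit <- NULL
  if (rss(cf) > 1e-20) {  # nls cannot iterate from an exact start
    dat <- data.frame(iv = iv, ppr = ppr)
    fit <- tryCatch(
      stats::nls(ppr ~ 1 - U * exp(-iv / tau), data = dat,
                 start = list(U = u0, tau = tau0)),
      error = function(e) NULL)
    cf <- if (!is.null(fit)) stats::coef(fit) else {
      op <- stats::optim(cf, rss)
      c(U = unname(op$par[1]), tau = unname(op$par[2]))
    }
  }
  fitted_vals <- 1 - cf["U"] * exp(-iv / cf["tau"])
  structure(list(U = unname(cf["U"]), tau_rec = unname(cf["tau"]),
                 fitted = unname(fitted_vals),
                 residual_norm = sqrt(rss(cf)),
                 fit = fit),
            class = "depression_fit")
}

#' @export
coef.depression_fit <- function(object, ...) {
  c(U = object$U, tau_rec = object$tau_rec)
}

#' @export
predict.depression_fit <- function(object, interval_s, ...) {
  1 - object$U * exp(-interval_s / object$tau_rec)
}

#' @export
print.depression_fit <- function(x, ...) {
  cat(sprintf("depression fit: U = %.3f, tau_rec = %.3f s (residual norm %.3g)\n",
              x$U, x$tau_rec, x$residual_norm))
  invisible(x)
}
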