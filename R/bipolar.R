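#' Place bipolar-cell inputs on the SAC dendritic tree
#'
#' Bipolar cells contact the SAC in a semi-random pattern within
#' `extent` um of the soma, roughly `per_dendrite` per primary dendrite:
#' contact loci are evenly spaced in path distance along each primary
#' subtree with seeded jitter, and each synapse draws a maximal
#' conductance uniformly from [20, 50] pS.
#'
#' @param m a [sac_morphology].
#' @param per_dendrite contacts per primary dendrite.
#' @param extent maximal radial distance of contacts from the soma, um;
#'   clipped (with a warning) to the morphology's radial extent.
#' @param rf_halfwidth half-side of the square receptive field of each
#'   bipolar cell, um (default half a 12.5-um model check).
#' @param v_threshold release threshold of the bipolar terminal, mV.
#' @param v_step_above step depolarisation above threshold while the
#'   stimulus covers the receptive field, mV.
#' @param v_off_below resting level below threshold, mV (tonic drive).
#' @param gain_mv release-function gain, mV per e-fold.
#' @param g_max_range range of per-synapse maximal conductance, pS.
#' @param e_rev excitatory reversal potential, mV.
#' @param seed integer seed.
#' @return data frame of class `bipolar_population`: one row per cell
#'   with position, target node and synaptic parameters.
#' @export
place_bipolars <- function(m, per_dendrite = 10, extent = 100,
                           rf_halfwidth = 6.25, v_threshold = -45,
                           v_step_above = 7, v_off_below = 7,
                           gain_mv = 6, g_max_range = c(20, 50),
                           e_rev = 0, seed = 1L) {
  rex <- attr(m, "radial_extent")
  if (extent > rex) {
    warning("bipolar extent ", extent, " um exceeds morphology radial extent ",
            rex, " um; clipped")
    extent <- rex
  }
  rng <- local_rng(seed)
  on.exit(rng())
  root <- m$id[m$parent_id == -1L]
  primaries <- m$id[m$parent_id == root]
  pd <- path_distance(m)
  radial <- sqrt(m$x^2 + m$y^2)
  # assign every node to the primary subtree it descends from
  pidx <- match(m$parent_id, m$id)
  subtree <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (m$parent_id[i] == -1L) subtree[i] <- 0L
    else if (m$id[i] %in% primaries) subtree[i] <- m$id[i]
    else subtree[i] <- subtree[pidx[i]]
  }
  cells <- vector("list", length(primaries))
  for (k in seq_along(primaries)) {
    nodes_k <- which(subtree == primaries[k] & radial <= extent)
    if (!length(nodes_k)) next
    pd_k <- pd[nodes_k]
    lo <- min(pd_k); hi <- max(pd_k)
    loci <- seq(lo, hi, length.out = per_dendrite + 2)[-c(1, per_dendrite + 2)]
    loci <- loci + stats::rnorm(per_dendrite, 0, (hi - lo) / (4 * per_dendrite))
    tgt <- vapply(loci, function(d) nodes_k[which.min(abs(pd_k - d))],
                  integer(1))
    cells[[k]] <- data.frame(
      x = m$x[tgt] + stats::rnorm(per_dendrite, 0, 1),
      y = m$y[tgt] + stats::rnorm(per_dendrite, 0, 1),
      target_node = m$id[tgt])
  }
  out <- do.call(rbind, cells)
  out <- data.frame(id = seq_len(nrow(out)), out,
                    rf_halfwidth = rf_halfwidth,
                    v_threshold = v_threshold,
                    v_step_above = v_step_above,
                    v_off_below = v_off_below,
                    gain_mv = gain_mv,
                    g_max = stats::runif(nrow(out), g_max_range[1],
                                         g_max_range[2]),
                    e_rev = e_rev)
  class(out) <- c("bipolar_population", "data.frame")
  out
}

# exact overlap test: rotated bar rectangle vs axis-aligned RF square
# (separating-axis theorem on the two rectangles' axes), vectorised over t
bar_overlaps_square <- function(spec, t, cx, cy, hw) {
  th <- spec$direction_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  lead <- bar_lead(spec, t)                     # vector over t
  s_lo <- lead - spec$bar_width; s_hi <- lead   # motion-axis interval
  u_half <- spec$bar_length / 2
  # square projected on bar axes
  sc <- cx * ct + cy * st
  uc <- -cx * st + cy * ct
  half_s <- hw * (abs(ct) + abs(st))
  ok1 <- (sc + half_s) >= s_lo & (sc - half_s) <= s_hi
  ok2 <- (uc + half_s) >= -u_half & (uc - half_s) <= u_half
  # bar corners projected on square (x, y) axes
  cs <- rbind(s_lo, s_hi, s_lo, s_hi)
  cu <- c(-u_half, -u_half, u_half, u_half)
  bx <- cs * ct - cu * st                       # 4 x length(t)
  by <- cs * st + cu * ct
  ok3 <- apply(bx, 2, max) >= cx - hw & apply(bx, 2, min) <= cx + hw
  ok4 <- apply(by, 2, max) >= cy - hw & apply(by, 2, min) <= cy + hw
  ok1 & ok2 & ok3 & ok4
}

# does any on-check overlap the RF square in the given frame?
check_on_over_square <- function(frames, f, cx, cy, hw) {
  ck <- attr(frames, "check_um")
  org <- attr(frames, "origin")
  nck <- nrow(frames[[1]])
  i0 <- max(1L, floor((cx - hw - org[1]) / ck) + 1L)
  i1 <- min(nck, floor((cx + hw - org[1]) / ck) + 1L)
  j0 <- max(1L, floor((cy - hw - org[2]) / ck) + 1L)
  j1 <- min(nck, floor((cy + hw - org[2]) / ck) + 1L)
  if (i0 > i1 || j0 > j1) return(FALSE)
  any(frames[[f]][i0:i1, j0:j1] == 1L)
}

#' Bipolar-cell membrane potential under a stimulus
#'
#' Step activation: the terminal sits `v_step_above` mV above the release
#' threshold for as long as the bar or an "on" check overlaps the cell's
#' square receptive field, and `v_off_below` mV below threshold
#' otherwise. Transitions are instantaneous (no temporal filtering).
#'
#' @param cell one row of a [place_bipolars()] population.
#' @param spec a [stimulus_spec].
#' @param dt sample interval, s.
#' @param t_end trace length, s (from `spec$t_start`).
#' @param frames [checker_frames()] sequence when the checker is enabled.
#' @return a [vm_trace] in mV.
#' @export
bipolar_vm <- function(cell, spec, dt = 1e-4, t_end = NULL, frames = NULL) {
  if (is.null(t_end)) t_end <- spec$t_end - spec$t_start
  n_steps <- ceiling(t_end / dt)
  t <- spec$t_start + seq_len(n_steps) * dt
  on <- bar_overlaps_square(spec, t, cell$x, cell$y, cell$rf_halfwidth)
  if (!is.null(spec$checker)) {
    if (is.null(frames)) stop("checker enabled: supply frames")
    nf <- length(frames)
    on_frame <- vapply(seq_len(nf), function(f) {
      check_on_over_square(frames, f, cell$x, cell$y, cell$rf_halfwidth)
    }, logical(1))
    on <- on | on_frame[frame_index(frames, t)]
  }
  v <- ifelse(on, cell$v_threshold + cell$v_step_above,
              cell$v_threshold - cell$v_off_below)
  vm_trace(v, dt = dt, t0 = spec$t_start + dt)
}

#' Exponential release drive of a bipolar terminal
#'
#' Tonic release with an exponential voltage dependence:
#' `rate = exp((v - v_threshold) / gain_mv)`, dimensionless relative to
#' the rate at threshold (so the rate is 1 at threshold and increases
#' e-fold per `gain_mv` millivolts).
#'
#' @param v membrane potential(s), mV.
#' @param cell one row of a bipolar population (uses `v_threshold`,
#'   `gain_mv`).
#' @return relative release rate (dimensionless), same length as `v`.
#' @export
release_drive <- function(v, cell) {
  exp((v - cell$v_threshold) / cell$gain_mv)
}

#' Excitatory conductance evoked by a bipolar cell
#'
#' Maps the release drive through a saturating function
#' `g = g_max * drive / (1 + drive)` so the conductance never exceeds
#' the per-synapse ceiling `g_max` (drawn from 20-50 pS at placement);
#' `saturating = FALSE` selects the linear map `g = g_max * drive`
#' instead.
#'
#' @param cell one row of a bipolar population.
#' @param vm a [vm_trace] from [bipolar_vm()].
#' @param saturating use the saturating map (default) or linear.
#' @return a [syn_input()] conductance trace in pS.
#' @export
excitatory_conductance <- function(cell, vm, saturating = TRUE) {
  drive <- release_drive(vm$values, cell)
  g <- if (saturating) cell$g_max * drive / (1 + drive) else cell$g_max * drive
  syn_input(cell$target_node, g, e_rev = cell$e_rev)
}

#' Simulate the SAC response to a stimulus
#'
#' End-to-end wrapper: renders the bipolar drive for every placed cell
#' under the stimulus and integrates the compartmental model, recording
#' the soma and the terminal varicosities (or `record` nodes).
#'
#' @param model a `cable_model`.
#' @param bipolars a [place_bipolars()] population.
#' @param spec a [stimulus_spec].
#' @param frames [checker_frames()] when the checker is enabled.
#' @param dt time step, s.
#' @param t_end simulated duration, s.
#' @param record node ids to record (default soma + terminals).
#' @return list of [vm_trace]s as from [simulate_cable()].
#' @export
simulate_sac_response <- function(model, bipolars, spec, frames = NULL,
                                  dt = 1e-4, t_end = NULL, record = NULL) {
  if (is.null(t_end)) t_end <- spec$t_end - spec$t_start
  inputs <- lapply(seq_len(nrow(bipolars)), function(i) {
    cell <- bipolars[i, ]
    excitatory_conductance(cell, bipolar_vm(cell, spec, dt, t_end, frames))
  })
  simulate_cable(model, inputs = inputs, dt = dt, t_end = t_end,
                 record = record)
}
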