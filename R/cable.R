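#' Passive membrane parameters of the SAC model
#'
#' Experimentally constrained passive properties: resting potential
#' -70 mV, axial resistivity 40 Ohm cm, specific membrane resistance
#' 9.2e3 Ohm cm^2 for proximal dendrites and 20e3 Ohm cm^2 for the distal
#' varicosity zone, specific capacitance 0.9 uF/cm^2. Sodium and
#' potassium conductances are absent: the membrane is purely passive.
#'
#' @param v_rest resting potential, mV.
#' @param r_i axial (cytoplasmic) resistivity, Ohm cm.
#' @param r_m_proximal,r_m_distal specific membrane resistance,
#'   Ohm cm^2, for the proximal and distal membrane classes.
#' @param c_m specific membrane capacitance, uF/cm^2.
#' @param proximal_distal_threshold path distance (um) separating the two
#'   membrane classes; `NULL` means 2/3 of the morphology's radial extent,
#'   resolved at discretisation time.
#' @return object of class `passive_params`.
#' @export
passive_params <- function(v_rest = -70, r_i = 40, r_m_proximal = 9.2e3,
                           r_m_distal = 20e3, c_m = 0.9,
                           proximal_distal_threshold = NULL) {
  stopifnot(r_i > 0, r_m_proximal > 0, r_m_distal > 0, c_m > 0)
  structure(list(v_rest = v_rest, r_i = r_i,
                 r_m_proximal = r_m_proximal, r_m_distal = r_m_distal,
                 c_m = c_m,
                 proximal_distal_threshold = proximal_distal_threshold),
            class = "passive_params")
}

#' Discretise a morphology into a passive compartmental model
#'
#' Splits every edge of the tree into cylindrical pieces no longer than
#' `dx_max`, assigns each piece a membrane area, conductance and
#' capacitance, and couples adjacent pieces with the axial conductance of
#' two half-cylinders in series, `g = pi a^2 / (R_i l)` per half. The
#' soma is a single isopotential spherical compartment. Specific membrane
#' resistance is chosen per piece by its mid-point path distance:
#' proximal below `proximal_distal_threshold`, distal above. Varicosity
#' nodes whose bead radius exceeds the local cable radius contribute
#' their sphere surface as extra membrane area (the cable itself stays at
#' dendritic calibre); terminals are sealed ends.
#'
#' @param m a [sac_morphology].
#' @param p a [passive_params].
#' @param dx_max maximum compartment length, um.
#' @return object of class `cable_model`: compartment table, sparse
#'   conductance structure, and a map from morphology node ids to
#'   compartments.
#' @export
discretize <- function(m, p = passive_params(), dx_max = 2) {
  if (dx_max <= 0) stop("dx_max must be > 0")
  um <- 1e-4  # cm per um
  thr <- p$proximal_distal_threshold
  if (is.null(thr)) thr <- 2 / 3 * attr(m, "radial_extent")
  pd <- path_distance(m)
  pidx <- match(m$parent_id, m$id)
  root <- which(m$parent_id == -1L)
  if (length(root) != 1L) stop("morphology must have exactly one root")
  if (any(is.na(pidx[-root]))) stop("disconnected morphology")

  # cable radius: varicosity beads ride on the dendrite, so their axial
  # calibre is that of the nearest non-varicosity ancestor
  cable_r <- m$radius
  for (i in seq_len(nrow(m))) {
    if (m$kind[i] == "varicosity") {
      j <- i
      while (m$kind[j] == "varicosity" && m$parent_id[j] != -1L) j <- pidx[j]
      if (m$kind[j] != "varicosity") cable_r[i] <- cable_r[j]
    }
  }

  n_pieces <- sum(pmax(1L, ceiling(sqrt((m$x - m$x[pidx])^2 +
                                        (m$y - m$y[pidx])^2 +
                                        (m$z - m$z[pidx])^2)[-root] / dx_max)))
  n_max <- n_pieces + 1L
  area <- numeric(n_max); rad <- numeric(n_max); len <- numeric(n_max)
  rm_class <- character(n_max); pd_mid <- numeric(n_max)
  ei <- integer(n_pieces); ej <- integer(n_pieces); eg <- numeric(n_pieces)

  # soma: isopotential sphere, zero internal axial resistance
  d_soma <- 2 * m$radius[root] * um
  area[1] <- pi * d_soma^2
  rad[1] <- NA_real_; len[1] <- 0
  rm_class[1] <- "proximal"; pd_mid[1] <- 0
  node2comp <- integer(nrow(m)); node2comp[root] <- 1L
  half_res <- function(k) {
    if (is.na(rad[k]) || len[k] == 0) 0 else
      (p$r_i * len[k] / 2) / (pi * rad[k]^2)
  }

  nc <- 1L; ne <- 0L
  order_idx <- seq_len(nrow(m))[-root]  # parents precede children by invariant
  for (i in order_idx) {
    q <- pidx[i]
    ell <- sqrt((m$x[i] - m$x[q])^2 + (m$y[i] - m$y[q])^2 +
                (m$z[i] - m$z[q])^2)
    if (ell == 0) { node2comp[i] <- node2comp[q]; next }
    npc <- max(1L, ceiling(ell / dx_max))
    prev <- node2comp[q]
    for (s in seq_len(npc)) {
      nc <- nc + 1L
      fr <- (s - 0.5) / npc
      a <- (cable_r[q] + fr * (cable_r[i] - cable_r[q])) * um
      lp <- (ell / npc) * um
      area[nc] <- 2 * pi * a * lp
      rad[nc] <- a; len[nc] <- lp
      pd_mid[nc] <- pd[q] + fr * ell
      rm_class[nc] <- if (pd_mid[nc] > thr) "distal" else "proximal"
      ne <- ne + 1L
      r_ax <- half_res(prev) + half_res(nc)
      ei[ne] <- prev; ej[ne] <- nc; eg[ne] <- 1 / r_ax
      prev <- nc
    }
    # bead membrane: sphere surface in excess of the cable it sits on
    if (m$kind[i] == "varicosity" && m$radius[i] > cable_r[i]) {
      area[nc] <- area[nc] + pi * (2 * m$radius[i] * um)^2
    }
    node2comp[i] <- nc
  }
  n <- nc
  area <- area[seq_len(n)]; rm_class <- rm_class[seq_len(n)]
  pd_mid <- pd_mid[seq_len(n)]
  ei <- ei[seq_len(ne)]; ej <- ej[seq_len(ne)]; eg <- eg[seq_len(ne)]

  r_m <- ifelse(rm_class == "distal", p$r_m_distal, p$r_m_proximal)
  g_m <- area / r_m                    # S
  c_m <- p$c_m * 1e-6 * area           # F
  lap <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = -c(eg, eg),
                              dims = c(n, n))
  Matrix::diag(lap) <- -Matrix::rowSums(lap)

  term_nodes <- morphology_terminals(m)
  names(node2comp) <- m$id
  structure(list(n = n, area = area, g_m = g_m, c_m = c_m,
                 rm_class = rm_class, pd_mid = pd_mid,
                 laplacian = lap, params = p,
                 node2comp = node2comp,
                 terminal_comps = node2comp[as.character(term_nodes)],
                 dx_max = dx_max, n_edges = ne),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat(sprintf(paste0("passive cable model: %d compartments (%d distal), ",
                     "%d terminals, total area %.1f um^2\n"),
              x$n, sum(x$rm_class == "distal"), length(x$terminal_comps),
              sum(x$area) / 1e-8))
  invisible(x)
}

#' Voltage- or current-clamp specification
#'
#' @param node_id morphology node to clamp.
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param command command waveform: scalar or vector (mV for voltage
#'   clamp, pA for current clamp), recycled or sampled on the simulation
#'   grid.
#' @param series_resistance pipette series resistance, MOhm; 0 requests
#'   an effectively ideal clamp (implemented as a 0.01-MOhm access).
#' @return object of class `clamp_spec`.
#' @export
clamp_spec <- function(node_id, mode = c("voltage_clamp", "current_clamp"),
                       command, series_resistance = 0) {
  mode <- match.arg(mode)
  structure(list(node_id = node_id, mode = mode, command = command,
                 series_resistance = series_resistance),
            class = "clamp_spec")
}

#' Synaptic conductance input onto the model
#'
#' @param target_node morphology node receiving the synapse.
#' @param g_pS conductance waveform in pS (scalar or vector, sampled on
#'   the simulation grid).
#' @param e_rev reversal potential, mV.
#' @return object of class `syn_input`.
#' @export
syn_input <- function(target_node, g_pS, e_rev = 0) {
  if (any(!is.finite(g_pS)) || any(g_pS < 0)) {
    stop("synaptic conductance must be finite and nonnegative")
  }
  structure(list(target_node = target_node, g_pS = g_pS, e_rev = e_rev),
            class = "syn_input")
}

# expand a scalar-or-vector command onto an n_steps grid
on_grid <- function(x, n_steps) {
  if (length(x) == 1L) rep(as.numeric(x), n_steps)
  else if (length(x) == n_steps) as.numeric(x)
  else stop("command/conductance length ", length(x),
            " does not match the ", n_steps, "-step grid")
}

#' Simulate the passive cable model
#'
#' Backward-Euler (implicit, unconditionally stable) integration of the
#' branched passive cable system
#' `C dV/dt = -(V - E_L) A / R_m + axial + synaptic + clamp` on a uniform
#' grid. Voltage clamps are modelled as an access conductance
#' `1/R_s` from the command potential to the clamped compartment, which
#' for the default near-zero series resistance tracks the command to
#' solver tolerance while keeping the system symmetric. With no inputs
#' and no clamps every compartment stays at rest to machine tolerance.
#'
#' @param model a [discretize()]d `cable_model`.
#' @param inputs list of [syn_input()] conductances.
#' @param clamps list of [clamp_spec()]s.
#' @param dt time step, s (default 0.1 ms).
#' @param t_end simulation length, s.
#' @param record morphology node ids to record (default: soma and all
#'   terminals).
#' @return list of [vm_trace] objects named by node id, with attribute
#'   `clamp_current_pA` (per-clamp current traces) when clamps are
#'   present.
#' @export
simulate_cable <- function(model, inputs = list(), clamps = list(),
                           dt = 1e-4, t_end = 1, record = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  n_steps <- ceiling(t_end / dt)
  n <- model$n
  p <- model$params
  if (is.null(record)) {
    record <- as.integer(c(names(model$node2comp)[model$node2comp == 1L][1],
                           names(model$terminal_comps)))
  }
  rec_comp <- model$node2comp[as.character(record)]
  if (anyNA(rec_comp)) stop("unknown record node id")

  # per-step synaptic conductance (S) and driving term (S*mV) per target
  syn_g <- matrix(0, nrow = length(inputs), ncol = n_steps)
  syn_comp <- integer(length(inputs)); syn_ge <- matrix(0, length(inputs), n_steps)
  for (k in seq_along(inputs)) {
    s <- inputs[[k]]
    comp <- model$node2comp[as.character(s$target_node)]
    if (is.na(comp)) stop("synapse targets unknown node ", s$target_node)
    g <- on_grid(s$g_pS, n_steps) * 1e-12
    if (any(!is.finite(g))) stop("non-finite synaptic conductance")
    syn_comp[k] <- comp; syn_g[k, ] <- g; syn_ge[k, ] <- g * s$e_rev
  }
  # clamps
  vc <- Filter(function(cl) cl$mode == "voltage_clamp", clamps)
  ic <- Filter(function(cl) cl$mode == "current_clamp", clamps)
  vc_comp <- vapply(vc, function(cl) {
    cc <- model$node2comp[as.character(cl$node_id)]
    if (is.na(cc)) stop("clamp targets unknown node ", cl$node_id)
    cc
  }, integer(1))
  vc_g <- vapply(vc, function(cl) {
    rs <- cl$series_resistance
    1 / (max(rs, 0.01) * 1e6)  # S; 0.01 MOhm floor = near-ideal clamp
  }, numeric(1))
  vc_cmd <- lapply(vc, function(cl) on_grid(cl$command, n_steps))
  ic_comp <- vapply(ic, function(cl) {
    cc <- model$node2comp[as.character(cl$node_id)]
    if (is.na(cc)) stop("clamp targets unknown node ", cl$node_id)
    cc
  }, integer(1))
  ic_cmd <- lapply(ic, function(cl) on_grid(cl$command, n_steps) * 1e-9)
  # pA -> S*mV units (1 S*mV = 1e-3 A)

  gL <- model$g_m
  base_diag_add <- numeric(n)
  if (length(vc_comp)) {
    for (k in seq_along(vc_comp)) {
      base_diag_add[vc_comp[k]] <- base_diag_add[vc_comp[k]] + vc_g[k]
    }
  }
  cdt <- model$c_m / dt
  A_base <- model$laplacian + Matrix::Diagonal(n, x = gL + cdt + base_diag_add)

  v <- rep(p$v_rest, n)
  out <- matrix(NA_real_, nrow = n_steps, ncol = length(rec_comp))
  iclamp_out <- if (length(vc_comp)) {
    matrix(NA_real_, nrow = n_steps, ncol = length(vc_comp))
  } else NULL

  prev_gsyn <- NULL
  ch <- NULL
  for (st in seq_len(n_steps)) {
    gsyn_vec <- numeric(n); gesyn_vec <- numeric(n)
    if (length(inputs)) {
      for (k in seq_along(inputs)) {
        gsyn_vec[syn_comp[k]] <- gsyn_vec[syn_comp[k]] + syn_g[k, st]
        gesyn_vec[syn_comp[k]] <- gesyn_vec[syn_comp[k]] + syn_ge[k, st]
      }
    }
    if (is.null(prev_gsyn) || any(gsyn_vec != prev_gsyn)) {
      A <- A_base + Matrix::Diagonal(n, x = gsyn_vec)
      ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                             LDL = FALSE)
      prev_gsyn <- gsyn_vec
    }
    b <- cdt * v + gL * p$v_rest + gesyn_vec
    if (length(vc_comp)) {
      for (k in seq_along(vc_comp)) {
        b[vc_comp[k]] <- b[vc_comp[k]] + vc_g[k] * vc_cmd[[k]][st]
      }
    }
    if (length(ic_comp)) {
      for (k in seq_along(ic_comp)) {
        b[ic_comp[k]] <- b[ic_comp[k]] + ic_cmd[[k]][st]
      }
    }
    v <- as.numeric(Matrix::solve(ch, b))
    out[st, ] <- v[rec_comp]
    if (length(vc_comp)) {
      for (k in seq_along(vc_comp)) {
        # S * mV = 1e-3 A -> pA
        iclamp_out[st, k] <- vc_g[k] * (vc_cmd[[k]][st] - v[vc_comp[k]]) * 1e9
      }
    }
  }
  traces <- lapply(seq_along(rec_comp), function(k) {
    vm_trace(out[, k], dt = dt, t0 = dt, node_id = record[k],
             v_rest = p$v_rest)
  })
  names(traces) <- record
  if (!is.null(iclamp_out)) attr(traces, "clamp_current_pA") <- iclamp_out
  traces
}

#' Steady-state soma-to-terminal voltage attenuation
#'
#' Applies an ideal steady voltage clamp `clamp_dv` above rest at the
#' soma with all synaptic inputs removed, solves the passive steady
#' state, and reports the ratio of terminal-varicosity depolarisation to
#' somatic depolarisation. Because the passive system is linear and
#' homogeneous in the deviation from rest, the ratios are independent of
#' `clamp_dv`. The mean over terminal varicosities is the model
#' counterpart of the figure used to set the somatic command scaling in
#' paired recordings.
#'
#' @param model a `cable_model`.
#' @param clamp_dv clamp depolarisation above rest, mV.
#' @return list with `ratios` (data frame: node, ratio), `mean_ratio`,
#'   and `percent` (= 100 * mean_ratio).
#' @export
steady_state_attenuation <- function(model, clamp_dv = 10) {
  n <- model$n
  if (n == 1L) {
    # degenerate soma-only model: the soma is its own terminal
    return(list(ratios = data.frame(node = 1L, ratio = 1), mean_ratio = 1,
                percent = 100))
  }
  tc <- model$terminal_comps
  if (!length(tc)) stop("model has no terminal varicosities")
  G <- model$laplacian + Matrix::Diagonal(n, x = model$g_m)
  soma <- 1L
  free <- setdiff(seq_len(n), soma)
  # deviation u from rest: G u = 0 with u_soma = clamp_dv (Dirichlet)
  b <- -as.numeric(G[free, soma]) * clamp_dv
  u_free <- as.numeric(Matrix::solve(G[free, free], b))
  u <- numeric(n); u[soma] <- clamp_dv; u[free] <- u_free
  ratios <- u[tc] / clamp_dv
  list(ratios = data.frame(node = as.integer(names(tc)), ratio = ratios),
       mean_ratio = mean(ratios), percent = 100 * mean(ratios))
}
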