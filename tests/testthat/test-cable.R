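test_that("discretisation splits segments at dx_max and counts compartments", {
  m <- chain_morphology(c(10, 15))
  cm <- discretize(m, passive_params(), dx_max = 2)
  # soma + sum(ceiling(length/dx)) pieces
  expect_identical(cm$n, 1L + 5L + 8L)
  cm4 <- discretize(m, passive_params(), dx_max = 4)
  expect_identical(cm4$n, 1L + 3L + 4L)
  expect_error(discretize(m, passive_params(), dx_max = 0), "dx_max")
})

test_that("with no inputs and no clamps the model stays at rest", {
  cm <- default_sac_model(dx_max = 8)
  tr <- simulate_cable(cm, dt = 2e-4, t_end = 0.05, record = 1L)[[1]]
  expect_lt(max(abs(tr$values - (-70))), 1e-9)
})

test_that("lumped compartment charges with tau = R_m * C_m", {
  cm <- discretize(soma_only_morphology(), passive_params(), 2)
  tr <- simulate_cable(cm,
                       clamps = list(clamp_spec(1L, "current_clamp", 10)),
                       dt = 2e-5, t_end = 0.06, record = 1L)[[1]]
  t <- trace_times(tr)
  v_inf <- tr$values[length(tr$values)]
  sel <- t < 0.025
  fit <- stats::lm(log(v_inf - tr$values[sel]) ~ t[sel])
  tau_fit <- -1 / unname(coef(fit)[2])
  tau_expect <- 9.2e3 * 0.9e-6      # R_m C_m, proximal class
  expect_lt(abs(tau_fit - tau_expect) / tau_expect, 0.01)
})

test_that("uniform sealed cylinder matches the analytic cosh profile", {
  L <- 500; a_um <- 0.5; n_nodes <- 101
  cyl <- chain_morphology(rep(L / (n_nodes - 1), n_nodes - 1), radius = a_um)
  pp <- passive_params(proximal_distal_threshold = 1e6)  # single Rm class
  cm <- discretize(cyl, pp, dx_max = 2)
  att <- steady_state_attenuation(cm, clamp_dv = 10)
  lambda <- sqrt(pp$r_m_proximal * (a_um * 1e-4) / (2 * pp$r_i)) / 1e-4
  # tip value against cosh((L-x)/lambda)/cosh(L/lambda) at x = L
  expect_lt(abs(att$mean_ratio - 1 / cosh(L / lambda)) * cosh(L / lambda),
            0.01)
  # interior profile via a transient run settling to steady state
  mid_node <- 51L   # x = 250 um
  tr <- simulate_cable(cm,
                       clamps = list(clamp_spec(1L, "voltage_clamp", -60)),
                       dt = 5e-4, t_end = 0.4, record = mid_node)[[1]]
  u_mid <- tr$values[length(tr$values)] + 70
  pred <- 10 * cosh((L - 250) / lambda) / cosh(L / lambda)
  expect_lt(abs(u_mid - pred) / pred, 0.01)
})

test_that("attenuation is independent of clamp size (linearity)", {
  cm <- default_sac_model(dx_max = 8)
  a10 <- steady_state_attenuation(cm, clamp_dv = 10)
  a20 <- steady_state_attenuation(cm, clamp_dv = 20)
  expect_equal(a10$ratios$ratio, a20$ratios$ratio, tolerance = 1e-12)
  expect_true(all(a10$ratios$ratio > 0 & a10$ratios$ratio <= 1))
})

test_that("a soma-only model attenuates nothing", {
  cm <- discretize(soma_only_morphology(), passive_params(), 2)
  expect_equal(steady_state_attenuation(cm)$mean_ratio, 1)
})

test_that("attenuation converges under grid refinement", {
  a2 <- steady_state_attenuation(default_sac_model(2))$mean_ratio
  a1 <- steady_state_attenuation(default_sac_model(1))$mean_ratio
  expect_lt(abs(a2 - a1) / a2, 0.01)
})

test_that("passive responses scale linearly with input current", {
  cm <- discretize(soma_only_morphology(), passive_params(), 2)
  v1 <- simulate_cable(cm, clamps = list(clamp_spec(1L, "current_clamp", 5)),
                       dt = 1e-4, t_end = 0.05, record = 1L)[[1]]$values + 70
  v2 <- simulate_cable(cm, clamps = list(clamp_spec(1L, "current_clamp", 10)),
                       dt = 1e-4, t_end = 0.05, record = 1L)[[1]]$values + 70
  expect_equal(v2, 2 * v1, tolerance = 1e-9)
})

test_that("clamp current balances membrane and capacitive current", {
  cm <- discretize(soma_only_morphology(), passive_params(), 2)
  dt <- 1e-4
  res <- simulate_cable(cm,
                        clamps = list(clamp_spec(1L, "voltage_clamp", -50)),
                        dt = dt, t_end = 0.05, record = 1L)
  v <- res[[1]]$values
  iclamp <- attr(res, "clamp_current_pA")[, 1]
  # backward-Euler balance: I_clamp = C dV/dt + g_m (V - E), in pA
  dv <- diff(c(-70, v)) / dt
  balance <- (cm$c_m[1] * dv + cm$g_m[1] * (v - (-70))) * 1e9
  expect_equal(iclamp, balance, tolerance = 1e-8)
})

test_that("an ideal voltage clamp tracks its command", {
  cm <- default_sac_model(dx_max = 8)
  tr <- simulate_cable(cm,
                       clamps = list(clamp_spec(1L, "voltage_clamp", -55)),
                       dt = 2e-4, t_end = 0.05, record = 1L)[[1]]
  expect_lt(max(abs(tr$values[-(1:5)] - (-55))), 0.01)
})

test_that("simulation rejects invalid numerics", {
  cm <- discretize(soma_only_morphology(), passive_params(), 2)
  expect_error(simulate_cable(cm, dt = 0, t_end = 1), "dt")
  expect_error(syn_input(1L, c(1, NA)), "finite")
  expect_error(syn_input(1L, -1), "nonnegative")
})
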