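test_that("DSI arithmetic and bounds", {
  expect_equal(dsi(10, 10), 0)
  expect_equal(dsi(10, 0), 1)
  expect_equal(dsi(30, 10), 0.5)
  expect_error(dsi(0, 0), "undefined")
  expect_error(dsi(-1, 2), ">= 0")
  # antisymmetry and range over random counts
  set.seed(1)
  a <- rpois(50, 8); b <- rpois(50, 3)
  ok <- a + b > 0
  expect_equal(dsi(a[ok], b[ok]), -dsi(b[ok], a[ok]))
  expect_true(all(abs(dsi(a[ok], b[ok])) <= 1))
})

test_that("window metrics read baseline, surround and center correctly", {
  w <- analysis_windows(c(0, 1), c(1, 1.5), c(1.5, 2.5))
  dt <- 1e-3
  n <- 3000
  t <- (seq_len(n) - 1) * dt   # matches trace_times() with t0 = 0
  # constant trace at rest
  v0 <- vm_trace(rep(-70, n), dt = dt, v_rest = -70)
  m0 <- window_metrics(v0, w)
  expect_equal(m0$baseline_mean_mV, -70)
  expect_equal(m0$surround_mean_rel_mV, 0)
  expect_equal(m0$center_peak_rel_mV, 0)
  # 3 mV hyperpolarisation through the surround
  v1 <- rep(-70, n); v1[t >= 1 & t < 1.5] <- -73
  m1 <- window_metrics(vm_trace(v1, dt = dt, v_rest = -70), w)
  expect_equal(m1$surround_mean_rel_mV, -3)
  # triangular 12-mV peak inside the center window
  v2 <- rep(-70, n)
  tri <- which(t >= 1.8 & t <= 2.0)   # odd count: apex sampled exactly
  v2[tri] <- -70 + 12 * (1 - abs(seq(-1, 1, length.out = length(tri))))
  m2 <- window_metrics(vm_trace(v2, dt = dt, v_rest = -70), w)
  expect_equal(m2$center_peak_rel_mV, 12, tolerance = 1e-6)
})

test_that("window metrics are translation-covariant", {
  w <- analysis_windows(c(0, 1), c(1, 1.5), c(1.5, 2.5))
  set.seed(2)
  v <- -70 + cumsum(rnorm(3000, 0, 0.05))
  tr <- vm_trace(v, dt = 1e-3, v_rest = -70)
  m <- window_metrics(tr, w, v_rest = -70)
  shifted <- vm_trace(v + 5, dt = 1e-3, v_rest = -65)
  ms <- window_metrics(shifted, w, v_rest = -65)
  expect_equal(ms$baseline_mean_mV, m$baseline_mean_mV + 5)
  expect_equal(ms$surround_mean_rel_mV, m$surround_mean_rel_mV)
  expect_equal(ms$center_peak_rel_mV, m$center_peak_rel_mV)
  # shifting the trace but not v_rest moves the relative metrics
  m_bad <- window_metrics(shifted, w, v_rest = -70)
  expect_equal(m_bad$surround_mean_rel_mV, m$surround_mean_rel_mV + 5)
})

test_that("analysis windows must be ordered and non-overlapping", {
  expect_error(analysis_windows(c(0, 1.2), c(1, 1.5), c(1.5, 2)), "ordered")
  expect_error(analysis_windows(c(0, 1), c(1.5, 1.2), c(2, 3)), "increasing")
})

test_that("IPSC peak and charge follow the analytic rectangle", {
  dt <- 1e-3
  vals <- c(rep(0, 500), rep(100, 500), rep(0, 500))
  ip <- ipsc_trace(vals, dt = dt)
  m <- ipsc_metrics(ip, c(0.5, 1.0))
  expect_equal(m$peak, 100)
  expect_equal(m$charge, 50, tolerance = 0.2)   # edge-sample quantisation
  z <- ipsc_metrics(ipsc_trace(rep(0, 1500), dt = dt), c(0.5, 1.0))
  expect_equal(z$peak, 0)
  expect_equal(z$charge, 0)
  # charge is additive over a window partition
  m1 <- ipsc_metrics(ip, c(0.5, 0.75), baseline_s = 0.4)
  m2 <- ipsc_metrics(ip, c(0.75, 1.0), baseline_s = 0)
  expect_equal(m1$charge + m2$charge,
               ipsc_metrics(ip, c(0.5, 1.0), baseline_s = 0.4)$charge,
               tolerance = 1e-9)
})

test_that("control normalisation is scale-invariant ratio arithmetic", {
  cko <- c(window1 = 50, window3 = 100)
  ctrl <- c(window1 = 50, window3 = 200)
  r <- normalize_to_control(cko, ctrl)
  expect_equal(unname(r["window1"]), 1)
  expect_equal(unname(r["window3"]), 0.5)
  expect_equal(normalize_to_control(cko * 3.7, ctrl * 3.7), r)
  expect_error(normalize_to_control(cko, c(window1 = 0, window3 = 1)),
               "positive")
})

test_that("noise-induced suppression is a signed percentage", {
  expect_equal(noise_induced_suppression(100, 100), 0)
  expect_equal(noise_induced_suppression(100, 70), 30)
  expect_equal(noise_induced_suppression(100, 130), -30)
  expect_error(noise_induced_suppression(0, 10), "> 0")
})

test_that("surround window duration scales as extent over speed", {
  expect_equal(surround_window_duration(200, speed = 1320), 200 / 1320)
  expect_equal(surround_window_duration(200, speed = 1320), 0.1515,
               tolerance = 1e-3)
  expect_equal(surround_window_duration(200, speed = 110), 1.818,
               tolerance = 1e-3)
  expect_equal(surround_window_duration(200, speed = 440) / 4,
               surround_window_duration(200, speed = 1760))
  expect_error(surround_window_duration(200, speed = 0), "speed")
})
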