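test_that("bipolar placement matches the connectomic layout constraints", {
  m <- generate_sac_morphology(n_primary = 4, branch_order = 3, seed = 2)
  bp <- place_bipolars(m, per_dendrite = 10, extent = 100, seed = 1)
  expect_identical(nrow(bp), 40L)
  expect_true(all(sqrt(bp$x^2 + bp$y^2) <= 100 + 3))  # position jitter <= 3 um
  r_target <- with(m[match(bp$target_node, m$id), ], sqrt(x^2 + y^2))
  expect_true(all(r_target <= 100))
  # reproducible placement
  expect_identical(as.data.frame(bp),
                   as.data.frame(place_bipolars(m, seed = 1,
                                                per_dendrite = 10)))
  expect_warning(place_bipolars(m, extent = 150, seed = 1), "clipped")
})

test_that("synaptic ceilings are uniform on [20, 50] pS", {
  m <- generate_sac_morphology(n_primary = 4, branch_order = 2, seed = 2)
  g <- unlist(lapply(1:25, function(s) {
    place_bipolars(m, per_dendrite = 10, seed = s)$g_max
  }))
  expect_gte(min(g), 20)
  expect_lte(max(g), 50)
  n <- length(g)
  expect_gte(n, 1000)
  se <- (30 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(g) - 35), 3 * se)
})

test_that("bipolar Vm steps 7 mV above threshold while the bar covers the RF", {
  m <- generate_sac_morphology(seed = 1)
  spec <- stimulus_spec(t_end = 3)
  cell <- data.frame(x = 50, y = 0, target_node = 1L, rf_halfwidth = 6.25,
                     v_threshold = -45, v_step_above = 7, v_off_below = 7,
                     gain_mv = 6, g_max = 35, e_rev = 0)
  vm <- bipolar_vm(cell, spec, dt = 1e-4, t_end = 3)
  expect_setequal(unique(vm$values), c(-38, -52))
  on_dur <- sum(vm$values == -38) * vm$dt
  expect_equal(on_dur, (110 + 12.5) / 440, tolerance = 2e-3)
  # off the bar path, no checker: flat sub-threshold trace
  cell_off <- transform(cell, y = 400)
  vm_off <- bipolar_vm(cell_off, spec, dt = 1e-3, t_end = 3)
  expect_true(all(vm_off$values == -52))
})

test_that("release drive is exponential with 6 mV per e-fold", {
  cell <- data.frame(v_threshold = -45, gain_mv = 6)
  expect_equal(release_drive(-45, cell), 1)
  expect_equal(release_drive(-39, cell), exp(1))
  expect_equal(release_drive(-38, cell), exp(7 / 6))
  v <- seq(-70, -20, by = 0.5)
  expect_true(all(diff(release_drive(v, cell)) > 0))
})

test_that("conductance saturates below g_max and grows with depolarisation", {
  cell <- data.frame(x = 0, y = 0, target_node = 1L, rf_halfwidth = 6.25,
                     v_threshold = -45, v_step_above = 7, v_off_below = 7,
                     gain_mv = 6, g_max = 40, e_rev = 0)
  vm1 <- vm_trace(seq(-70, -20, length.out = 200), dt = 1e-3)
  g1 <- excitatory_conductance(cell, vm1)
  expect_true(all(g1$g_pS >= 0 & g1$g_pS <= 40))
  expect_true(all(diff(g1$g_pS) > 0))
  # stepping up 6 mV strictly increases g everywhere
  vm2 <- vm_trace(vm1$values + 6, dt = 1e-3)
  g2 <- excitatory_conductance(cell, vm2)
  expect_true(all(g2$g_pS > g1$g_pS))
  # flat sub-threshold drive: constant and below half-max
  vmf <- vm_trace(rep(-52, 50), dt = 1e-3)
  gf <- excitatory_conductance(cell, vmf)
  expect_length(unique(gf$g_pS), 1L)
  expect_lt(gf$g_pS[1], 20)
  # linear mode exceeds the ceiling at high drive
  glin <- excitatory_conductance(cell, vm1, saturating = FALSE)
  expect_gt(max(glin$g_pS), 40)
})

test_that("moving bar drives comparable somatic and distal-tip depolarisation", {
  # full stimulus -> bipolar -> cable chain on the default SAC model
  m <- default_sac_morphology()
  cm <- default_sac_model(dx_max = 4)
  spec <- stimulus_spec(checker = checker_spec(check_um = 12.5),
                        t_end = 2.2, start_offset = -220)
  frames <- checker_frames(spec, seed = 5)
  bp <- place_bipolars(m, seed = 2)
  term <- morphology_terminals(m)
  tx <- m$x[match(term, m$id)]; ty <- m$y[match(term, m$id)]
  tip <- term[which.max(tx - abs(ty))]   # centrifugal dendrite for a +x bar
  res <- simulate_sac_response(cm, bp, spec, frames, dt = 2e-4,
                               t_end = 2.2, record = c(1L, tip))
  peak_soma <- max(res[["1"]]$values) + 70
  peak_tip <- max(res[[as.character(tip)]]$values) + 70
  expect_gt(peak_soma, 3)    # the bar must actually excite the cell
  ratio <- peak_tip / peak_soma
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
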