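test_that("generated traces carry windows, rest and seeded determinism", {
  tr1 <- generate_sac_vm("control", "noisy", 440, seed = 7)
  tr2 <- generate_sac_vm("control", "noisy", 440, seed = 7)
  expect_identical(tr1$values, tr2$values)
  expect_s3_class(tr1$windows, "analysis_windows")
  expect_equal(diff(tr1$windows$surround), 200 / 440, tolerance = 1e-9)
  expect_false(identical(tr1$values,
                         generate_sac_vm("control", "noisy", 440,
                                         seed = 8)$values))
})

test_that("noise-free surround hyperpolarisation follows the genotype", {
  reps <- 1:10
  sur_mean <- function(gt) {
    mean(vapply(reps, function(s) {
      tr <- generate_sac_vm(gt, "noise_free", 440, seed = s)
      window_metrics(tr, tr$windows)$surround_mean_rel_mV
    }, numeric(1)))
  }
  ctrl <- sur_mean("control")
  cko <- sur_mean("gabra2_cko")
  vgat <- sur_mean("vgat_cko")
  expect_lt(ctrl, 0)                 # genuine hyperpolarisation
  expect_lt(abs(cko), abs(ctrl))     # cKO closer to rest
  expect_lt(abs(vgat), abs(ctrl))    # residual wide-field only
  expect_gt(abs(vgat), abs(cko))
})

test_that("flicker events persist in the cKO surround but not in control", {
  thr <- -66   # 4 mV above rest picks out genuine events
  count_sur <- function(gt, s) {
    tr <- generate_sac_vm(gt, "noisy", 440, seed = s)
    idx <- window_index(tr, tr$windows$surround)
    sum(tr$values[idx] > thr)
  }
  ctrl <- sum(vapply(1:12, function(s) count_sur("control", s), numeric(1)))
  cko <- sum(vapply(1:12, function(s) count_sur("gabra2_cko", s), numeric(1)))
  expect_gt(cko, ctrl)
})

test_that("the center response is genotype-independent", {
  peaks <- vapply(c("control", "gabra2_cko", "vgat_cko"), function(gt) {
    tr <- generate_sac_vm(gt, "noise_free", 440, seed = 21)
    window_metrics(tr, tr$windows)$center_peak_rel_mV
  }, numeric(1))
  expect_lt(max(peaks) - min(peaks), 1)   # within the 0.3-mV noise floor
})

test_that("population generation is sized, jittered and reproducible", {
  pop <- generate_population(15, "control", "noisy", seed = 5)
  expect_length(pop, 15)
  expect_identical(pop[[3]]$values,
                   generate_population(15, "control", "noisy",
                                       seed = 5)[[3]]$values)
  # cells differ from one another
  expect_false(identical(pop[[1]]$values, pop[[2]]$values))
  # group separation in the surround window (effect direction fixed)
  sur <- function(pop) mean(vapply(pop, function(tr) {
    window_metrics(tr, tr$windows)$surround_mean_rel_mV
  }, numeric(1)))
  pop_cko <- generate_population(15, "gabra2_cko", "noisy", seed = 5)
  expect_gt(sur(pop_cko), sur(pop))   # cKO less hyperpolarised/more events
  expect_error(generate_population(0), "n_cells")
})

test_that("ppr dataset matches the closed form when noiseless", {
  p <- depression_params(U = 0.45, tau_rec = 0.8)
  d <- generate_ppr_dataset(p, intervals_s = c(0.2, 0.4, 1.6), noise_cv = 0,
                            n_reps = 2)
  expect_identical(nrow(d), 6L)
  expect_equal(d$ppr, 1 - 0.45 * exp(-d$interval_s / 0.8), tolerance = 1e-12)
  dn <- generate_ppr_dataset(p, noise_cv = 0.05, n_reps = 3, seed = 9)
  expect_identical(nrow(dn), 9L)
  expect_identical(dn, generate_ppr_dataset(p, noise_cv = 0.05, n_reps = 3,
                                            seed = 9))
})

test_that("representative waveforms contain the expected surround events", {
  for (sp in c(110, 440, 1320)) {
    tr <- representative_cko_trace("gabra2_cko", "noisy", sp, seed = 3)
    ev <- attr(tr, "events")
    n_sur <- sum(ev$in_surround)
    target <- max(1, round(surround_window_duration(200, speed = sp) *
                             15 * 0.5))
    expect_identical(n_sur, as.integer(target))
  }
})

test_that("dsgc counts are nonnegative integers over the direction grid", {
  counts <- generate_dsgc_counts("control", "noisy", n_directions = 8,
                                 n_trials = 3, seed = 2)
  expect_identical(nrow(counts), 24L)
  expect_true(all(counts$count >= 0))
  expect_true(all(counts$count == round(counts$count)))
  expect_setequal(unique(counts$direction_deg), seq(0, 315, by = 45))
  expect_error(generate_dsgc_counts(n_directions = 7), "8 or 12")
})
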