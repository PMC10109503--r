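test_that("scenario configuration validates fields and ranges", {
  expect_error(scenario_config(g_asic_ns = 20), "0, 15")
  expect_error(scenario_config(g_asic_ns = -1), "0, 15")
  expect_error(scenario_config(ca_fraction = 1.5), "ca_fraction")
  expect_error(scenario_config(dt = 0.05), "dt")
  expect_error(scenario_config(cleft = list()), "cleft")
  expect_error(build_scenario(list()), "scenario_config")

  sc <- build_scenario(scenario_config())
  expect_s3_class(sc, "wdr_scenario")
  expect_null(sc$asic)                       # control carries no ASIC
  expect_equal(sum(sc$synapses$fiber == "c" &
                   sc$synapses$receptor == "ampa"), 20)

  scm <- build_scenario(scenario_config(asic_variant = "homomeric",
                                        g_asic_ns = 0.2, mittx = TRUE))
  expect_equal(scm$asic$variant, "homomeric")
})

test_that("protocol timing follows the 1 Hz convention", {
  p <- stim_protocol()
  expect_equal(p$n_stims, 15L)
  expect_equal(p$stim_times, seq(1000, 15000, by = 1000))
  expect_equal(p$total_duration, 16000)
  p2 <- stim_protocol(n_stims = 16)
  expect_equal(length(p2$stim_times), 16)
})

test_that("identical configuration and seed reproduce the run exactly", {
  a <- ctrl_sim()
  b <- run_windup(scenario_config(), stim_protocol())
  expect_identical(a$spike_times, b$spike_times)
  expect_identical(a$v$soma, b$v$soma)
  expect_identical(a$ph, b$ph)
})

test_that("the control windup curve rises to a late plateau", {
  s <- windup_summary(ctrl_sim())
  counts <- s$curve$n_spikes
  expect_lt(counts[1], 10)                    # stimulus-intensity criterion
  sm <- smooth_counts(counts)
  expect_true(all(diff(sm) > -1e-9))          # smoothed curve non-decreasing
  expect_gte(which.max(counts), 13)           # maximal windup at stim 13-16
  expect_gt(counts[15], 2 * counts[1])        # substantial facilitation
  expect_gt(s$auc, 0)
})

test_that("windup requires NK1: removing it flattens the curve", {
  s0 <- cached_summary("nk1_0", scenario_config(nk1_scale = 0))
  counts <- s0$curve$n_spikes
  expect_lte(counts[15], 1.2 * counts[1])
  s <- windup_summary(ctrl_sim())
  expect_lt(s0$auc, 0.2 * s$auc)
})

test_that("cleft acidification accumulates over the protocol", {
  sim <- ctrl_sim()
  ph1 <- sim$ph[, 1]
  expect_equal(ph1[1], 7.4, tolerance = 1e-6)
  expect_lt(min(ph1), 7.25)                   # cumulative acidification
  expect_gt(min(ph1), 7.0)                    # within physiological range
  # pH declines across the protocol toward a quasi-steady level
  mid <- ph1[sim$time_ms == 8000]
  late <- ph1[sim$time_ms == 15000]
  expect_lt(late, mid)
  expect_lt(abs(late - min(ph1)), 0.1)
})

test_that("mittx mode makes the ASIC current pH-independent", {
  # identical runs except for cleft parameters: with mittx the spike output
  # must be identical because the open fraction ignores pH
  base <- scenario_config(asic_variant = "homomeric", g_asic_ns = 0.2,
                          mittx = TRUE)
  alt <- scenario_config(asic_variant = "homomeric", g_asic_ns = 0.2,
                         mittx = TRUE,
                         cleft = cleft_params(q_amp = 1, tau = 0.01))
  p_short <- stim_protocol(n_stims = 3)
  a <- run_windup(base, p_short)
  b <- run_windup(alt, p_short)
  expect_identical(a$spike_times, b$spike_times)
  expect_equal(a$asic_open, rep(1, length(a$asic_open)))
})

test_that("conductance sweeps emit ordered summaries", {
  sw <- cached_sweep_moderate()
  expect_equal(sw$g_ns, c(0, 0.05, 0.2))
  expect_true(all(diff(sw$auc) > 0))          # windup grows with g here
  expect_equal(nrow(sw), 3)
  curves <- attr(sw, "curves")
  expect_length(curves, 3)
  expect_s3_class(curves[[1]], "windup_curve")
})

test_that("the parameter grid search classifies the default cell as valid", {
  scan <- cached_scan_default()
  row <- scan[scan$q == 0.3 & scan$tau == 0.1, ]
  expect_true(row$ph_ok)
  expect_true(row$auc_ok)
  expect_true(row$count_ok)
  expect_true(row$all_ok)
  expect_error(parameter_scan(q_grid = 3, tau_grid = 0.1), "cap")
})

test_that("a q of zero removes all acidification-driven ASIC modulation", {
  cfg <- scenario_config(asic_variant = "homomeric", g_asic_ns = 0.2,
                         cleft = cleft_params(q_amp = 0))
  sim <- cached_sim("homo02_q0", cfg)
  # the cleft never acidifies
  expect_equal(min(sim$ph), 7.4, tolerance = 1e-6)
  expect_equal(max(sim$ph), 7.4, tolerance = 1e-6)
  # the open fraction stays pinned at its resting-pH window value, so the
  # channel contributes only a constant leak-like term (the homomeric
  # window current at pH 7.4 is small but not zero)
  p <- asic_params("homomeric")
  rest_open <- asic_minf(7.4, p) * asic_hinf(7.4, p)
  expect_equal(max(abs(sim$asic_open - rest_open)), 0, tolerance = 1e-9)
})
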