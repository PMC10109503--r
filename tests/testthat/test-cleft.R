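test_that("buffering relation and its inverse are consistent", {
  cp <- cleft_params()
  expect_equal(buffered_total(0, cp), 0)
  # resting free protons (pH 7.4) give the printed total
  expect_equal(buffered_total(10^-4.4, cp), 1.618, tolerance = 1e-3)

  # inverse pair round-trips to machine-level accuracy
  for (x in c(1e-6, 1e-4, 1e-2)) {
    expect_equal(free_from_total(buffered_total(x, cp), cp), x,
                 tolerance = 1e-10)
  }
  expect_equal(buffered_total(free_from_total(1.618, cp), cp), 1.618,
               tolerance = 1e-10)

  # monotonicity of the buffered total
  xs <- 10^seq(-8, 0, length.out = 200)
  expect_true(all(diff(buffered_total(xs, cp)) > 0))

  expect_error(buffered_total(-1, cp), ">= 0")
  expect_error(free_from_total(-1, cp), ">= 0")
})

test_that("free_from_total matches a bisection root-finding oracle", {
  cp <- cleft_params()
  # bisection on log10(h_free) keeps relative precision at tiny roots
  bisect_free <- function(ht) {
    lo <- -16; hi <- log10(ht) + 1e-12
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (buffered_total(10^mid, cp) > ht) hi <- mid else lo <- mid
    }
    10^((lo + hi) / 2)
  }
  totals <- 10^seq(-6, 1, length.out = 100)
  for (ht in totals) {
    expect_equal(free_from_total(ht, cp), bisect_free(ht),
                 tolerance = 1e-12)
  }
})

test_that("cleft state at rest is an equilibrium and recovers to pH 7.4", {
  cp <- cleft_params()
  st <- cleft_state(cp)
  st2 <- cleft_step(st, 0, 0.025, cp)
  expect_equal(st2$ph, 7.4, tolerance = 1e-12)
  expect_equal(st2$h_total, st$h_total, tolerance = 1e-12)

  # acidified cleft relaxes monotonically toward 7.4
  st <- cleft_state(cp, ph = 7.0)
  phs <- numeric(40)
  for (i in seq_len(40)) {
    st <- cleft_step(st, (i - 1) * 0.025, 0.025, cp)
    phs[i] <- st$ph
  }
  expect_true(all(diff(phs) > 0))
  expect_true(all(phs < 7.4))

  expect_error(cleft_step(st, 0, 0.05, cp), "dt")
})

test_that("proton pulses follow the presynaptic trigger with coalescing", {
  cp <- cleft_params()
  st <- cleft_state(cp)
  st <- cleft_add_event(st, 1000, cp)
  expect_equal(nrow(st$pending_pulses), 1)
  expect_equal(unname(st$pending_pulses[1, ]), c(1000, 1001))

  # a second event 0.2 ms later is coalesced into the same pulse
  st <- cleft_add_event(st, 1000.2, cp)
  expect_equal(nrow(st$pending_pulses), 1)

  # a later event opens its own pulse window
  st <- cleft_add_event(st, 1002, cp)
  expect_equal(nrow(st$pending_pulses), 2)

  # no events means no influx
  expect_equal(cleft_influx(cleft_state(cp), 500, cp), 0)
  expect_equal(cleft_influx(st, 1000.5, cp), cp$q_amp)
})

test_that("one default pulse matches a fine-step reference integration", {
  cp <- cleft_params()
  # R-level stepper through the pulse
  st <- cleft_state(cp)
  st <- cleft_add_event(st, 0.1, cp)
  t <- 0
  while (t < 1.2) {
    st <- cleft_step(st, t, 0.025, cp)
    t <- t + 0.025
  }
  # reference explicit integration at dt = 1e-4 ms
  h <- 1e-4
  htot <- buffered_total(cp$h0, cp)
  hfree <- cp$h0
  for (k in seq_len(1.2 / h)) {
    tk <- (k - 1) * h
    q <- if (tk >= 0.1 && tk < 1.1) cp$q_amp else 0
    htot <- htot + h * (q - (hfree - cp$h0) / cp$tau)
    hfree <- free_from_total(htot, cp)
  }
  expect_equal(st$ph, ph_from_free(hfree), tolerance = 1e-4)

  # compiled driver agrees with the R stepper
  tr <- simulate_cleft(cp, events = 0.1, duration = 1.2, record_dt = 1.2)
  expect_equal(tr$ph[nrow(tr)], st$ph, tolerance = 1e-6)
})

test_that("cleft equilibrates at pH 7.4 and conserves protons at 1 Hz", {
  cp <- cleft_params()
  # long pulse-free relaxation from an acidified state
  tr <- simulate_cleft(cp, events = numeric(0), duration = 120e3,
                       record_dt = 1000, ph0 = 7.0)
  expect_equal(tr$ph[nrow(tr)], 7.4, tolerance = 1e-6)
  expect_true(all(tr$h_free_mm > 0))

  # 1 Hz pulsing reaches a quasi-steady cycle: per-period input equals
  # per-period recovery within 1% after 15 periods
  ev <- seq(1000, 20000, by = 1000)
  tr <- simulate_cleft(cp, events = ev, duration = 21e3, record_dt = 1)
  per_period_in <- cp$q_amp * cp$pulse_dur
  i1 <- which(tr$time_ms == 19000)
  i2 <- which(tr$time_ms == 20000)
  recovery <- per_period_in - (tr$h_total_mm[i2] - tr$h_total_mm[i1])
  expect_equal(recovery / per_period_in, 1, tolerance = 0.01)
  expect_true(all(tr$h_free_mm > 0))
})

test_that("parameter validation enforces the physiological q cap", {
  expect_error(cleft_params(q_amp = 2.5), "cap")
  expect_error(cleft_params(b0 = -1))
  expect_silent(cleft_params(q_amp = 1, tau = 0.01))
  expect_silent(cleft_params(q_amp = 0.05, tau = 1))
})
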