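test_that("steady-state gating curves evaluate to their analytic values", {
  p <- asic_params("homomeric")
  ph <- asic_params("heteromeric")

  # midpoints of the sigmoids
  expect_equal(asic_minf(6.46, p), 0.5)
  expect_equal(asic_minf(6.03, ph), 0.5)
  expect_equal(asic_hinf(7.3, p), 1.3 / 2)
  expect_equal(asic_hinf(6.74, ph), 0.5)

  # saturation limits
  expect_equal(asic_minf(4.0, p), 0.99980, tolerance = 1e-5)
  expect_equal(asic_hinf(9.0, p), 1.3, tolerance = 1e-6)

  # time constants: direct arithmetic on the printed fits
  expect_equal(asic_tauh(7.144, p), 49.196 + 0.95 * 7.144 - 3.77,
               tolerance = 1e-10)
  expect_equal(asic_tauh(7.144, p), 52.213, tolerance = 0.01)
  expect_equal(asic_tauh(6.6, ph), 42.862 + 1.645, tolerance = 1e-3)
  expect_equal(round(asic_tauh(4.0, ph), 3), 1.645)
})

test_that("gating curves are monotone and reject invalid input", {
  grid <- seq(4, 9, by = 0.01)
  for (v in c("homomeric", "heteromeric")) {
    p <- asic_params(v)
    expect_true(all(diff(asic_minf(grid, p)) < 0))
    expect_true(all(diff(asic_hinf(grid, p)) > 0))
    expect_true(all(asic_tauh(grid, p) > 0))
  }
  p <- asic_params("homomeric")
  expect_error(asic_minf(NaN, p), "finite")
  expect_error(asic_hinf(Inf, p), "finite")
  expect_error(asic_tauh(3.5, p), "range")
  expect_error(asic_tauh(9.5, p), "range")
})

test_that("bisection on the implemented curves recovers the half-points", {
  for (v in c("homomeric", "heteromeric")) {
    p <- asic_params(v)
    hp <- asic_half_points(p, tol = 1e-8)
    expect_equal(unname(hp["ph_half_m"]), p$ph_half_m, tolerance = 1e-6)
    expect_equal(unname(hp["ph_half_h"]), p$ph_half_h, tolerance = 1e-6)
  }
})

test_that("alternative tau_h fits stay positive over the validated range", {
  grid <- seq(4, 9, by = 0.01)
  for (form in c("affine", "piecewise_affine")) {
    p <- asic_params("homomeric", tau_h_form = form)
    expect_true(all(asic_tauh(grid, p) > 0))
  }
  # heteromeric form peaks at its center
  ph <- asic_params("heteromeric")
  expect_equal(grid[which.max(asic_tauh(grid, ph))], 6.6, tolerance = 0.011)
})

test_that("inactivation update is the exact exponential relaxation", {
  p <- asic_params("homomeric")
  st <- asic_state(p, ph = 7.4)

  # fixed point: h = h_inf is invariant
  st_fp <- st; st_fp$h <- asic_hinf(6.9, p)
  expect_equal(asic_step(st_fp, 6.9, 0.5, p)$h, st_fp$h, tolerance = 1e-12)

  # 1000 steps of 0.1 ms equal one 100 ms exponential update
  st2 <- st; st2$h <- 0
  for (i in 1:1000) st2 <- asic_step(st2, 6.9, 0.1, p)
  tau_ms <- asic_tauh(6.9, p) * 1000
  hinf <- asic_hinf(6.9, p)
  expect_equal(st2$h, hinf + (0 - hinf) * exp(-100 / tau_ms),
               tolerance = 1e-9)

  # five time constants bring h within 1% of h_inf
  tau74 <- asic_tauh(7.4, p) * 1000
  st3 <- st; st3$h <- 0
  n <- ceiling(5 * tau74)           # 1 ms steps
  # closed form of the same exact update over n steps
  h_n <- asic_hinf(7.4, p) * (1 - exp(-n / tau74))
  expect_lt(abs(h_n - asic_hinf(7.4, p)) / asic_hinf(7.4, p), 0.01)

  # agreement with a brute-force explicit-Euler recurrence at dt = 1e-4 ms
  # over 10 s (the recurrence solved in closed form at fixed pH)
  dt <- 1e-4; total <- 1e4; nstep <- total / dt
  h_euler <- hinf + (0 - hinf) * exp(nstep * log1p(-dt / tau_ms))
  st4 <- st; st4$h <- 0
  h_exact <- hinf + (0 - hinf) * exp(-total / tau_ms)
  expect_equal(h_euler, h_exact, tolerance = 1e-4)

  expect_error(asic_step(st, 7.0, 0, p), "dt")
})

test_that("current law and calcium split follow g*m*h*(V - E)", {
  p <- asic_params("homomeric")
  st <- asic_state(p, ph = 7.4)
  cur <- asic_current(st, 7.0, -60, 0.5, p)
  expect_equal(cur$i_total,
               0.5 * asic_minf(7.0, p) * st$h * (-60 - 50))
  expect_equal(cur$i_ca, 0.1 * cur$i_total)

  # mittx mode: open fraction exactly 1, pH-independent
  stm <- asic_state(p, mode = "mittx")
  m1 <- asic_current(stm, 5.0, -80, 0.2, p)
  m2 <- asic_current(stm, 7.4, -80, 0.2, p)
  expect_equal(m1$i_total, 0.2 * (-80 - 50))
  expect_identical(m1$i_total, m2$i_total)
  expect_equal(m1$i_ca, -2.6)

  # calcium-free variant zeroes only the booked calcium
  p0 <- asic_params("homomeric", ca_fraction = 0)
  cur0 <- asic_current(st, 7.0, -60, 0.5, p0)
  expect_equal(cur0$i_total, cur$i_total)
  expect_equal(cur0$i_ca, 0)

  expect_error(asic_current(st, 7.0, -60, -1, p), "g_max")
})

test_that("characterization protocols match brute-force expectations", {
  for (v in c("homomeric", "heteromeric")) {
    p <- asic_params(v)
    curves <- asic_curves(p)
    # peak of the window current by brute-force scan at 0.001 pH resolution
    grid <- seq(4, 9, by = 0.001)
    prod <- asic_minf(grid, p) * asic_hinf(grid, p)
    expect_equal(curves$pH[which.max(curves$g_rel)], grid[which.max(prod)])
    expect_equal(max(curves$g_rel), 1)
  }

  # recovery from inactivation: no recovery at zero interval, complete
  # recovery for the heteromeric model (alpha = 1) at long intervals
  ph <- asic_params("heteromeric")
  rec <- asic_recovery_protocol(ph, intervals = c(0, 1e6),
                                cond_dur = 20000)
  h_cond <- rec$h[1]
  expect_equal(rec$recovery[1], h_cond / asic_hinf(7.4, ph))
  expect_lt(rec$recovery[1], 0.1)   # conditioning at pH 6 inactivates
  expect_equal(rec$recovery[2], 1, tolerance = 1e-3)

  # activation protocol: monotone loss of response toward alkaline test pH
  act <- asic_activation_protocol(asic_params("homomeric"))
  expect_equal(max(act$g_rel), 1)
  expect_true(all(act$peak_open >= 0))
})

test_that("whole-cell conductance estimate reproduces the printed scale", {
  # 242 pA at -80 mV holding with E = +50 mV is about 2 nS
  expect_equal(round(conductance_from_current(242, -80, 50)), 2)
})
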