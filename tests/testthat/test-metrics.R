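mk_table <- function(df, n_stims = 16) {
  as_spike_table(df, n_stims = n_stims)
}

test_that("latency windows partition [0, 1000) with half-open bounds", {
  w <- latency_windows()
  expect_equal(w$lo_ms, c(0, 20, 90, 350))
  expect_equal(w$hi_ms, c(20, 90, 350, 1000))
  # no overlap, no gap
  expect_equal(w$lo_ms[-1], w$hi_ms[-4])

  tb <- data.frame(neuron_id = 1, stim_index = 1,
                   latency_ms = c(10, 150, 19.999, 20, 89.999, 90, 349.99,
                                  350, 999.9))
  lab <- classify_spikes(mk_table(tb))$window
  expect_equal(as.character(lab),
               c("Abeta", "C", "Abeta", "Adelta", "Adelta", "C", "C",
                 "postdischarge", "postdischarge"))
  expect_error(classify_spikes(data.frame(neuron_id = 1, stim_index = 1,
                                          latency_ms = -5)), "negative")
})

test_that("windup curves count C plus post-discharge spikes per stimulus", {
  tb <- mk_table(data.frame(
    neuron_id = 1,
    stim_index = c(3, 3, 3, 3, 5),
    latency_ms = c(100, 200, 400, 30, 10)), n_stims = 6)
  wc <- windup_curve(classify_spikes(tb))
  expect_equal(wc$n_spikes, c(0, 0, 3, 0, 0, 0))   # 2 C + 1 post at stim 3
  expect_equal(attr(wc, "total"), 3)
  expect_equal(attr(wc, "input"), 0)

  # empty table
  wc0 <- windup_curve(classify_spikes(mk_table(data.frame(
    neuron_id = integer(0), stim_index = integer(0),
    latency_ms = numeric(0)), n_stims = 4)))
  expect_equal(wc0$n_spikes, rep(0, 4))
  expect_equal(attr(wc0, "auc"), 0)

  # invariance to row order
  perm <- tb[sample(nrow(tb)), ]
  wc2 <- windup_curve(classify_spikes(mk_table(perm, n_stims = 6)))
  expect_equal(wc2$n_spikes, wc$n_spikes)
})

test_that("AUC is the baseline-clipped trapezoidal area", {
  expect_equal(windup_auc(c(2, 4, 6, 8)), 9)
  expect_equal(windup_auc(c(5, 5, 5, 5)), 0)       # constant curve
  expect_equal(windup_auc(c(5, 3, 3, 3)), 0)       # all below baseline
  expect_equal(windup_auc(c(5, 3, 3, 3), clip = FALSE), -5)
  # invariance under adding a constant
  x <- c(3, 5, 9, 14, 14)
  expect_equal(windup_auc(x + 7), windup_auc(x))
  expect_error(windup_auc(5), "two")
})

test_that("percent inhibition is linear and guards zero denominators", {
  ctrl <- windup_curve(classify_spikes(mk_table(data.frame(
    neuron_id = 1, stim_index = rep(1:4, times = c(2, 4, 6, 8)),
    latency_ms = 100), n_stims = 4)))
  expect_equal(unname(percent_inhibition(ctrl, ctrl)),
               list(0, 0), ignore_attr = TRUE)

  # halved drug counts: 50% on totals; AUC scales the same way here
  drug <- windup_curve(classify_spikes(mk_table(data.frame(
    neuron_id = 1, stim_index = rep(1:4, times = c(1, 2, 3, 4)),
    latency_ms = 100), n_stims = 4)))
  pi <- percent_inhibition(ctrl, drug)
  expect_equal(pi$pct_total, 50)
  expect_equal(pi$pct_auc, 50)

  empty <- windup_curve(classify_spikes(mk_table(data.frame(
    neuron_id = integer(0), stim_index = integer(0),
    latency_ms = numeric(0)), n_stims = 4)))
  expect_true(is.na(percent_inhibition(empty, drug)$pct_total))
})

test_that("PSTH bins, conserves counts, and is neuron-order invariant", {
  tb <- mk_table(data.frame(neuron_id = 1, stim_index = 1,
                            latency_ms = 30))
  h <- psth(tb, binwidth = 20, stims = 1)
  expect_equal(h$mean_count[h$t_lo == 20], 1)
  expect_equal(sum(h$mean_count), 1)

  tb2 <- mk_table(data.frame(neuron_id = c(1, 1, 2, 2, 2),
                             stim_index = 1,
                             latency_ms = c(30, 130, 30, 500, 999)))
  h2 <- psth(tb2, stims = 1)
  expect_equal(sum(h2$mean_count), nrow(tb2) / 2)  # total / n_neurons
  tb3 <- tb2[order(-tb2$neuron_id), ]
  expect_equal(psth(mk_table(tb3), stims = 1)$mean_count, h2$mean_count)
})

test_that("PSTH distance is a metric sensitive to shifts", {
  tb <- mk_table(data.frame(neuron_id = 1, stim_index = 1,
                            latency_ms = c(110, 130, 210)))
  h <- psth(tb, stims = 1)
  expect_equal(compare_psth(h, h), 0)

  set.seed(42)
  hs <- lapply(1:3, function(i) {
    t <- mk_table(data.frame(neuron_id = 1, stim_index = 1,
                             latency_ms = runif(20, 0, 999)))
    psth(t, stims = 1)
  })
  d12 <- compare_psth(hs[[1]], hs[[2]])
  d13 <- compare_psth(hs[[1]], hs[[3]])
  d23 <- compare_psth(hs[[2]], hs[[3]])
  expect_lte(d13, d12 + d23 + 1e-12)
  expect_equal(d12, compare_psth(hs[[2]], hs[[1]]))

  # shifting a histogram by one bin increases the distance from itself
  tb_shift <- mk_table(data.frame(neuron_id = 1, stim_index = 1,
                                  latency_ms = c(130, 150, 230)))
  expect_gt(compare_psth(h, psth(tb_shift, stims = 1)), 0)

  h_coarse <- psth(tb, binwidth = 50, stims = 1)
  expect_error(compare_psth(h, h_coarse), "mismatch")
})

test_that("spike tables survive a CSV round trip with identical metrics", {
  sim <- ctrl_sim()
  f <- tempfile(fileext = ".csv")
  write_spike_table(sim$spike_table, f)
  back <- read_spike_table(f, n_stims = 15)
  wc1 <- windup_curve(classify_spikes(sim$spike_table))
  wc2 <- windup_curve(classify_spikes(back))
  expect_equal(wc1$n_spikes, wc2$n_spikes)
  expect_equal(attr(wc1, "auc"), attr(wc2, "auc"))
  unlink(f)
})

test_that("spike table validation rejects out-of-range latencies", {
  expect_error(as_spike_table(data.frame(neuron_id = 1, stim_index = 1,
                                         latency_ms = -1), 4), "negative")
  expect_error(as_spike_table(data.frame(neuron_id = 1, stim_index = 1,
                                         latency_ms = 1000), 4), "period")
})
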