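#' Configuration for surrogate in vivo WDR recordings
#'
#' Parameters of the synthetic-recording generator, which emulates the
#' statistical structure of extracellular windup recordings: per-stimulus
#' spike counts following a saturating growth law across the 16-stimulus
#' 1 Hz train, spikes placed in the C latency window with extra spikes in
#' the post-discharge and A-delta windows, Poisson (optionally
#' negative-binomial) count noise, and paired control/drug conditions with a
#' programmed multiplicative inhibition.
#'
#' The expected C-window count at stimulus i is the saturating exponential
#' \deqn{\mu_i = N_1 + (N_{max} - N_1)(1 - e^{-(i-1)/\kappa}),}
#' which with the default \eqn{\kappa} plateaus between the 13th and 16th
#' stimulation; the default \eqn{N_1} respects the stimulus-intensity
#' criterion of fewer than 10 APs at the first stimulation.
#'
#' @param n_neurons neurons per cohort (default 13).
#' @param n_stims stimuli per train (default 16).
#' @param n1 expected C-count at stimulus 1 (default 4).
#' @param nmax plateau expected C-count (default 20).
#' @param kappa growth constant in stimuli (default 3).
#' @param post_frac expected post-discharge count as a fraction of the
#'   C count (default 0.3).
#' @param adelta_rate expected A-delta-window count per stimulus (default 2).
#' @param noise "poisson", "nbinom" (over-dispersed) or "none" (counts are
#'   round(mu)).
#' @param nb_size negative-binomial size parameter when \code{noise =
#'   "nbinom"}.
#' @param lat_meanlog,lat_sdlog log-normal latency shape within each window
#'   (offset from the window start, truncated to the window).
#' @param seed integer seed.
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(n_neurons = 13, n_stims = 16, n1 = 4, nmax = 20,
                         kappa = 3, post_frac = 0.3, adelta_rate = 2,
                         noise = c("poisson", "nbinom", "none"),
                         nb_size = 10, lat_meanlog = log(60),
                         lat_sdlog = 0.6, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(n_neurons >= 1, n_stims >= 2, n1 >= 0, nmax >= n1, kappa > 0,
            post_frac >= 0, adelta_rate >= 0)
  if (n1 >= 10)
    warning("n1 >= 10 violates the first-stimulation intensity criterion")
  structure(list(n_neurons = n_neurons, n_stims = n_stims, n1 = n1,
                 nmax = nmax, kappa = kappa, post_frac = post_frac,
                 adelta_rate = adelta_rate, noise = noise, nb_size = nb_size,
                 lat_meanlog = lat_meanlog, lat_sdlog = lat_sdlog,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Expected windup growth law
#' @param config a \code{\link{synth_config}}.
#' @return expected C-window count per stimulus.
#' @export
synth_growth_law <- function(config) {
  i <- seq_len(config$n_stims)
  config$n1 + (config$nmax - config$n1) * (1 - exp(-(i - 1) / config$kappa))
}

# counts with the configured noise model
draw_counts <- function(mu, noise, nb_size) {
  switch(noise,
    none = round(mu),
    poisson = stats::rpois(length(mu), mu),
    nbinom = stats::rnbinom(length(mu), size = nb_size, mu = mu))
}

# truncated log-normal latencies within [lo, hi)
draw_latencies <- function(n, lo, hi, meanlog, sdlog) {
  if (n == 0) return(numeric(0))
  x <- lo + stats::rlnorm(n, meanlog, sdlog)
  while (any(bad <- x >= hi))
    x[bad] <- lo + stats::rlnorm(sum(bad), meanlog, sdlog)
  x
}

#' Generate one surrogate recording cohort
#'
#' Draws a spike table for \code{n_neurons} neurons under the windup growth
#' law, fully reproducible from the seed.  Latencies are truncated
#' log-normal within their window (C window offsets scaled to [90, 350),
#' post-discharge to [350, 1000), A-delta to [20, 90)).
#'
#' @param config a \code{\link{synth_config}}.
#' @param inhibition multiplicative inhibition fraction in [0, 1) applied to
#'   the expected counts (0 = control condition).
#' @return a \code{\link{as_spike_table}} with attribute \code{"mu"} (the
#'   expected C-count schedule actually used).
#' @export
gen_recording <- function(config, inhibition = 0) {
  stopifnot(inhibition >= 0, inhibition < 1)
  rng <- local_rng(config$seed)
  on.exit(rng())
  mu <- synth_growth_law(config) * (1 - inhibition)
  rows <- vector("list", config$n_neurons)
  for (nr in seq_len(config$n_neurons)) {
    n_c <- draw_counts(mu, config$noise, config$nb_size)
    n_post <- draw_counts(mu * config$post_frac, config$noise,
                          config$nb_size)
    n_ad <- draw_counts(rep(config$adelta_rate * (1 - inhibition),
                            config$n_stims),
                        config$noise, config$nb_size)
    per_stim <- lapply(seq_len(config$n_stims), function(i) {
      lat <- c(
        draw_latencies(n_c[i], 90, 350, config$lat_meanlog,
                       config$lat_sdlog),
        draw_latencies(n_post[i], 350, 1000, config$lat_meanlog + log(2),
                       config$lat_sdlog),
        draw_latencies(n_ad[i], 20, 90, config$lat_meanlog - log(3),
                       config$lat_sdlog))
      if (!length(lat)) return(NULL)
      data.frame(neuron_id = nr, stim_index = i, latency_ms = lat)
    })
    rows[[nr]] <- do.call(rbind, per_stim)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(neuron_id = integer(0), stim_index = integer(0),
                      latency_ms = numeric(0))
  out <- as_spike_table(out, n_stims = config$n_stims)
  attr(out, "mu") <- mu
  out
}

#' Generate a paired control/drug cohort
#'
#' Same neurons and growth law in both conditions; the drug condition scales
#' the expected counts by \code{1 - inhibition_total} with fresh noise draws
#' (the paired control/toxin design of the in vivo experiments).
#'
#' @param config a \code{\link{synth_config}}.
#' @param inhibition_total programmed inhibition fraction in [0, 1).
#' @return list with spike tables \code{control} and \code{drug} and the
#'   programmed \code{inhibition_total}.
#' @export
gen_paired_cohort <- function(config, inhibition_total) {
  stopifnot(inhibition_total >= 0, inhibition_total < 1)
  ctrl_cfg <- config
  drug_cfg <- config
  drug_cfg$seed <- config$seed + 1000003L
  list(control = gen_recording(ctrl_cfg, 0),
       drug = gen_recording(drug_cfg, inhibition_total),
       inhibition_total = inhibition_total)
}

#' Cohort-level percent inhibition
#'
#' Pools the paired spike tables across neurons into cohort windup curves
#' and applies \code{\link{percent_inhibition}} — the estimator used on the
#' recorded cohorts.
#'
#' @param pair output of \code{\link{gen_paired_cohort}} (or any list with
#'   \code{control} and \code{drug} spike tables).
#' @return list with \code{pct_total} and \code{pct_auc}.
#' @export
cohort_inhibition <- function(pair) {
  wc_c <- windup_curve(classify_spikes(pair$control))
  wc_d <- windup_curve(classify_spikes(pair$drug))
  percent_inhibition(wc_c, wc_d)
}
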