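#' Receptor kinetic defaults
#'
#' Per-receptor dual-exponential kinetics and maximal conductances of the
#' synaptic inputs to the WDR dendrite.  The per-receptor maximal
#' conductances on C-fiber synapses (AMPA 6 nS, NMDA 4 nS, GABA_A 0.3 nS,
#' NK1 3 pS) and the NK1 rise time constant (150 ms) are the model's stated
#' values; the remaining rise/decay constants and reversals are canonical.
#' NMDA and NK1 carry a 10 percent calcium fraction into the dendritic pool.
#'
#' @return data.frame, one row per receptor, with columns receptor, g_max_ns,
#'   tau_rise_ms, tau_decay_ms, e_rev_mv, ca_fraction.
#' @export
receptor_defaults <- function() {
  data.frame(
    receptor    = c("ampa", "nmda", "gaba_a", "nk1"),
    g_max_ns    = c(6, 4, 0.3, 0.003),
    tau_rise_ms = c(0.5, 5, 1, 150),
    tau_decay_ms = c(3, 80, 10, 9000),
    e_rev_mv    = c(0, 0, -70, 0),
    ca_fraction = c(0, 0.1, 0, 0.1),
    stringsAsFactors = FALSE)
}

#' Peak time of a dual-exponential conductance
#' @param tau_rise,tau_decay rise and decay time constants, ms.
#' @return time of the kernel peak, ms.
#' @export
dual_exp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Dual-exponential receptor conductance kernel
#'
#' Conductance at time \code{t} after a single activation at t = 0, for a
#' dual-exponential kernel normalized so its peak equals \code{g_max}.
#' Successive activations summate linearly.
#'
#' @param t time since activation, ms (>= 0, vectorized).
#' @param g_max maximal (peak) conductance, nS.
#' @param tau_rise,tau_decay time constants, ms (tau_rise < tau_decay).
#' @return conductance, nS.
#' @export
receptor_conductance <- function(t, g_max, tau_rise, tau_decay) {
  if (any(t < 0)) stop("t must be >= 0")
  stopifnot(tau_rise > 0, tau_decay > tau_rise)
  tp <- dual_exp_peak_time(tau_rise, tau_decay)
  norm <- 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
  g_max * norm * (exp(-t / tau_decay) - exp(-t / tau_rise))
}

#' NMDA magnesium block
#'
#' Voltage dependence of the NMDA receptor conductance under physiological
#' extracellular magnesium (Jahr-Stevens form):
#' \deqn{B(V) = 1 / (1 + [Mg]/3.57 \cdot e^{-0.062 V}).}
#' Monotone increasing in V, in (0, 1) everywhere; block is nearly complete
#' at strongly hyperpolarized potentials and relieved by depolarization —
#' the substrate of activity-dependent NMDA recruitment during windup.
#'
#' @param v membrane potential, mV (vectorized).
#' @param mg extracellular magnesium, mM (default 1).
#' @return unblocked fraction in (0, 1).
#' @export
nmda_mg_block <- function(v, mg = 1) {
  if (any(!is.finite(v))) stop("v must be finite")
  1 / (1 + mg / 3.57 * exp(-0.062 * v))
}

#' Draw per-synapse conduction delays
#'
#' Reproducible delays placing monosynaptically evoked somatic spikes inside
#' the conventional latency windows: A-delta delays uniform on [20, 60) ms,
#' C delays uniform on [120, 260) ms, so every C delay exceeds every A-delta
#' delay and evoked spikes classify as A-delta- or C-input, not A-beta.
#'
#' @param n number of synapses.
#' @param fiber "adelta" or "c".
#' @param seed integer seed (delays are a pure function of seed).
#' @return delays in ms.
#' @export
assign_delays <- function(n, fiber = c("adelta", "c"), seed = 1) {
  fiber <- match.arg(fiber)
  stopifnot(n >= 1)
  rng <- local_rng(seed + switch(fiber, adelta = 0L, c = 1L))
  on.exit(rng())
  switch(fiber,
    adelta = stats::runif(n, 20, 60),
    c      = stats::runif(n, 120, 260))
}

# Scoped RNG: seeds the global RNG and returns a restorer, so package
# functions are reproducible without clobbering the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build the synapse table of a scenario
#'
#' 20 A-delta-fiber synapses (AMPA + NMDA) and 20 C-fiber synapses (AMPA +
#' NMDA + GABA_A + NK1), each with its own conduction delay; ASIC channels
#' and a synaptic cleft sit at every C synapse (handled by the engine).
#'
#' @param n_adelta,n_c synapse counts (defaults 20 and 20).
#' @param seed integer seed for the delay draw.
#' @param nk1_scale multiplier on the NK1 maximal conductance (0 disables
#'   NK1, the classic windup-abolition manipulation).
#' @param receptors receptor kinetics table (see
#'   \code{\link{receptor_defaults}}).
#' @return data.frame of class \code{synapse_table}: one row per synapse and
#'   receptor, columns synapse_id, fiber, delay_ms, receptor, g_max_ns,
#'   tau_rise_ms, tau_decay_ms, e_rev_mv, ca_fraction.
#' @export
synapse_table <- function(n_adelta = 20, n_c = 20, seed = 1,
                          nk1_scale = 1, receptors = receptor_defaults()) {
  d_ad <- assign_delays(n_adelta, "adelta", seed)
  d_c <- assign_delays(n_c, "c", seed)
  rec_ad <- receptors[receptors$receptor %in% c("ampa", "nmda"), ]
  rec_c <- receptors
  rec_c$g_max_ns[rec_c$receptor == "nk1"] <-
    rec_c$g_max_ns[rec_c$receptor == "nk1"] * nk1_scale
  one <- function(id, fiber, delay, rec) {
    cbind(data.frame(synapse_id = id, fiber = fiber, delay_ms = delay), rec)
  }
  rows <- c(
    lapply(seq_len(n_adelta), function(i)
      one(i, "adelta", d_ad[i], rec_ad)),
    lapply(seq_len(n_c), function(i)
      one(n_adelta + i, "c", d_c[i], rec_c)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("synapse_table", "data.frame")
  out
}
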