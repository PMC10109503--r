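#' Stimulation protocol
#'
#' Windup protocol timing: \code{n_stims} electrical stimuli delivered
#' \code{period} ms apart starting at \code{first_stim} ms (defaults: 15
#' stimulations 1 s apart starting at 1 s, the simulation protocol; in vivo
#' recordings use 16).  The simulated duration extends one full period past
#' the last stimulus so the final post-discharge window is complete.
#'
#' @param n_stims number of stimuli.
#' @param period inter-stimulus interval, ms.
#' @param first_stim time of the first stimulus, ms.
#' @param total_duration total simulated time, ms (default
#'   \code{first_stim + n_stims * period}).
#' @return object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(n_stims = 15, period = 1000, first_stim = 1000,
                          total_duration = NULL) {
  stopifnot(n_stims >= 1, period > 0, first_stim >= 0)
  if (is.null(total_duration))
    total_duration <- first_stim + n_stims * period
  structure(list(n_stims = as.integer(n_stims), period = period,
                 first_stim = first_stim, total_duration = total_duration,
                 stim_times = first_stim + (seq_len(n_stims) - 1) * period),
            class = "stim_protocol")
}

#' Scenario configuration
#'
#' Assembles every knob of one simulated pharmacological condition:
#' which ASIC parameterisation sits at the C-fiber synapses and at what
#' per-synapse maximal conductance, whether its calcium fraction is carried
#' (\code{ca_fraction = 0} is the calcium-free variant), MitTx mode
#' (constitutive full opening), KCa and NK1 scaling, the cleft proton
#' parameters, and numerical settings.
#'
#' @param asic_variant "none" (control), "homomeric" or "heteromeric".
#' @param g_asic_ns per-synapse maximal ASIC conductance, nS (0 to 15).
#' @param ca_fraction calcium fraction of the ASIC current (default 0.1).
#' @param mittx constitutive full activation (open fraction 1, pH-independent)?
#' @param kca_scale multiplier on both KCa densities (0 = apamin +
#'   iberiotoxin-style block).
#' @param nk1_scale multiplier on the NK1 conductance (0 abolishes windup).
#' @param cleft a \code{\link{cleft_params}}.
#' @param neuron a \code{\link{neuron_params}}.
#' @param n_adelta,n_c synapse counts.
#' @param shared_cleft one global cleft driven by all C synapses instead of
#'   one cleft per C synapse (default FALSE, per-synapse clefts).
#' @param seed integer seed (controls the synaptic delay draw).
#' @param dt engine step, ms (default 0.025).
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(asic_variant = c("none", "homomeric",
                                             "heteromeric"),
                            g_asic_ns = 0, ca_fraction = 0.1, mittx = FALSE,
                            kca_scale = 1, nk1_scale = 1,
                            cleft = cleft_params(), neuron = neuron_params(),
                            n_adelta = 20, n_c = 20, shared_cleft = FALSE,
                            seed = 1, dt = 0.025) {
  asic_variant <- match.arg(asic_variant)
  if (!is.numeric(g_asic_ns) || g_asic_ns < 0 || g_asic_ns > 15)
    stop("g_asic_ns must lie in [0, 15] nS")
  if (ca_fraction < 0 || ca_fraction > 1)
    stop("ca_fraction must lie in [0, 1]")
  if (kca_scale < 0) stop("kca_scale must be >= 0")
  if (nk1_scale < 0) stop("nk1_scale must be >= 0")
  if (!inherits(cleft, "cleft_params")) stop("cleft must be cleft_params()")
  if (!inherits(neuron, "neuron_params"))
    stop("neuron must be neuron_params()")
  if (dt <= 0 || dt > 0.025) stop("dt must be in (0, 0.025] ms")
  structure(list(asic_variant = asic_variant, g_asic_ns = g_asic_ns,
                 ca_fraction = ca_fraction, mittx = mittx,
                 kca_scale = kca_scale, nk1_scale = nk1_scale,
                 cleft = cleft, neuron = neuron,
                 n_adelta = n_adelta, n_c = n_c,
                 shared_cleft = shared_cleft,
                 seed = as.integer(seed), dt = dt),
            class = "scenario_config")
}

#' Build a runnable scenario
#'
#' Resolves a \code{\link{scenario_config}} into the concrete model pieces:
#' the synapse table (with delays drawn deterministically from the seed),
#' the ASIC parameter set (or none), and the neuron with scaled KCa.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return object of class \code{wdr_scenario}.
#' @export
build_scenario <- function(config) {
  if (!inherits(config, "scenario_config"))
    stop("config must be a scenario_config")
  syn <- synapse_table(config$n_adelta, config$n_c, seed = config$seed,
                       nk1_scale = config$nk1_scale)
  asic <- if (config$asic_variant == "none") NULL
          else asic_params(config$asic_variant,
                           ca_fraction = config$ca_fraction)
  structure(list(config = config, synapses = syn, asic = asic),
            class = "wdr_scenario")
}

#' @export
print.wdr_scenario <- function(x, ...) {
  cfg <- x$config
  cat("WDR windup scenario\n")
  cat(sprintf("  ASIC: %s%s, g = %g nS/synapse, Ca fraction %g%s\n",
              cfg$asic_variant, if (cfg$mittx) " (MitTx mode)" else "",
              cfg$g_asic_ns, cfg$ca_fraction,
              if (cfg$kca_scale != 1)
                sprintf(", KCa x%g", cfg$kca_scale) else ""))
  cat(sprintf("  %d A-delta + %d C synapses (seed %d), dt %g ms\n",
              cfg$n_adelta, cfg$n_c, cfg$seed, cfg$dt))
  invisible(x)
}

tau_form_id <- function(form) {
  match(form, c("biased_gaussian", "symmetrized_exponential", "affine",
                "piecewise_affine")) - 1L
}

# Marshals a scenario into the compiled co-simulation and wraps the result.
run_engine_scenario <- function(scenario, stim_times, duration,
                                record_dt = 1, i_inj_pa = 0,
                                inj_window = c(0, 0)) {
  cfg <- scenario$config
  np <- cfg$neuron
  syn <- scenario$synapses
  areas <- compartment_areas(np)
  nS <- function(dens) density_to_ns(dens, areas)

  syn_rows <- unique(syn[, c("synapse_id", "fiber", "delay_ms")])
  syn_rows <- syn_rows[order(syn_rows$synapse_id), ]
  # per receptor-instance arrays
  inst <- syn[order(syn$synapse_id), ]
  tp <- dual_exp_peak_time(inst$tau_rise_ms, inst$tau_decay_ms)
  norm <- 1 / (exp(-tp / inst$tau_decay_ms) - exp(-tp / inst$tau_rise_ms))
  # activation times: every synapse fires once per stimulus, after its delay
  ev_t <- as.numeric(outer(syn_rows$delay_ms, stim_times, `+`))
  ev_syn <- rep(syn_rows$synapse_id, times = length(stim_times))
  ord <- order(ev_t)
  c_ids <- syn_rows$synapse_id[syn_rows$fiber == "c"]

  asic <- scenario$asic
  has_asic <- !is.null(asic) && (cfg$g_asic_ns > 0)
  asic_coeffs <- numeric(5)
  asic_form <- 0L
  if (has_asic) {
    asic_coeffs[seq_along(asic$tau_h_coeffs)] <-
      as.numeric(asic$tau_h_coeffs)
    asic_form <- tau_form_id(asic$tau_h_form)
  }

  res <- engine_run_cpp(
    dt = cfg$dt, duration = duration, record_dt = record_dt,
    cap_pf = as.numeric(areas * np$cm_uf_cm2 * 1e6),
    g_axial = as.numeric(np$g_axial_ns),
    e_leak = np$e_leak, e_na = np$e_na, e_k = np$e_k,
    e_ca = np$e_ca, e_can = np$e_can,
    g_leak = as.numeric(nS(np$g_leak)),
    g_na = as.numeric(nS(np$g_na)),
    g_kdr = as.numeric(nS(np$g_kdr)),
    g_kca = as.numeric(nS(np$g_kca)) * cfg$kca_scale,
    g_cal = as.numeric(nS(np$g_cal)),
    g_can = as.numeric(nS(np$g_can)),
    cal_vhalf = np$cal_vhalf, cal_k = np$cal_k, cal_tau = np$cal_tau_ms,
    kd_kca = np$kd_kca_um, n_kca = np$n_kca, tau_kca = np$tau_kca_ms,
    kd_can = np$kd_can_um, n_can = np$n_can, tau_can = np$tau_can_ms,
    ca_rest = np$ca_rest_um,
    tau_ca = as.numeric(np$tau_ca_ms), ca_gain = as.numeric(np$ca_gain),
    v_init = np$v_init,
    syn_comp_id = as.integer(inst$synapse_id - 1L),
    syn_is_nmda = as.integer(inst$receptor == "nmda"),
    syn_gmax = as.numeric(inst$g_max_ns),
    syn_norm = as.numeric(norm),
    syn_tau_r = as.numeric(inst$tau_rise_ms),
    syn_tau_d = as.numeric(inst$tau_decay_ms),
    syn_erev = as.numeric(inst$e_rev_mv),
    syn_cafrac = as.numeric(inst$ca_fraction),
    syn_rec_kind = match(inst$receptor,
                         c("ampa", "nmda", "gaba_a", "nk1")) - 1L,
    ev_time = ev_t[ord], ev_synapse = as.integer(ev_syn[ord] - 1L),
    c_synapse_ids = as.integer(c_ids - 1L),
    shared_cleft = as.integer(cfg$shared_cleft),
    cleft_b0 = cfg$cleft$b0, cleft_kd = cfg$cleft$kd,
    cleft_h0 = cfg$cleft$h0, cleft_q = cfg$cleft$q_amp,
    cleft_pulse_dur = cfg$cleft$pulse_dur, cleft_tau = cfg$cleft$tau,
    has_asic = as.integer(has_asic),
    asic_mittx = as.integer(isTRUE(cfg$mittx)),
    asic_g = cfg$g_asic_ns,
    asic_nm = if (has_asic) asic$n_m else 0,
    asic_ph05m = if (has_asic) asic$ph_half_m else 0,
    asic_nh = if (has_asic) asic$n_h else 0,
    asic_ph05h = if (has_asic) asic$ph_half_h else 0,
    asic_alpha = if (has_asic) asic$alpha else 1,
    asic_tau_form = asic_form, asic_tau_coeffs = asic_coeffs,
    asic_erev = if (has_asic) asic$e_rev else 50,
    asic_cafrac = if (has_asic) asic$ca_fraction else 0,
    i_inj = i_inj_pa, inj_start = inj_window[1], inj_end = inj_window[2])

  spikes <- res$spike_times
  st <- if (length(stim_times)) {
    period <- if (length(stim_times) > 1) diff(stim_times[1:2]) else 1000
    idx <- findInterval(spikes, stim_times)
    keep <- idx >= 1 & (spikes - stim_times[pmax(idx, 1)]) < period
    data.frame(neuron_id = rep(1L, sum(keep)), stim_index = idx[keep],
               latency_ms = spikes[keep] - stim_times[idx[keep]])
  } else {
    data.frame(neuron_id = integer(0), stim_index = integer(0),
               latency_ms = numeric(0))
  }
  structure(list(
    scenario = scenario, stim_times = stim_times,
    spike_times = spikes, spike_table = as_spike_table(st,
      n_stims = length(stim_times), period =
        if (length(stim_times) > 1) diff(stim_times[1:2]) else 1000),
    time_ms = res$time,
    v = data.frame(time_ms = res$time, dend = res$v_dend,
                   soma = res$v_soma, axon = res$v_axon),
    ca = data.frame(time_ms = res$time, dend = res$ca_dend,
                    soma = res$ca_soma),
    ph = res$ph, asic_open = res$asic_open,
    currents = data.frame(time_ms = res$time, i_kca = res$i_kca,
                          i_can = res$i_can, i_cal = res$i_cal,
                          i_asic = res$i_asic, i_ampa = res$i_ampa,
                          i_nmda = res$i_nmda, i_gaba = res$i_gaba,
                          i_nk1 = res$i_nk1)),
    class = "windup_sim")
}

#' @export
print.windup_sim <- function(x, ...) {
  cat("WDR windup simulation:", length(x$spike_times), "spikes over",
      max(x$time_ms), "ms\n")
  if (nrow(x$spike_table)) {
    wc <- windup_curve(classify_spikes(x$spike_table))
    cat("  C+post-discharge counts:",
        paste(wc$n_spikes, collapse = " "), "\n")
    cat(sprintf("  AUC %.1f, total %d, input %d\n",
                attr(wc, "auc"), attr(wc, "total"), attr(wc, "input")))
  }
  invisible(x)
}

#' Run the windup protocol on a scenario
#'
#' Fixed-step co-simulation of the neuron, the 40 synapses, the per-C-synapse
#' clefts and ASIC populations under the 1 Hz stimulation protocol.  Each
#' stimulus triggers one presynaptic event per fiber, fanned to its 20
#' synapses after the per-synapse conduction delays; C-synapse activations
#' also deliver the 1-ms proton pulse into their cleft.  Fully deterministic
#' given the configuration and seed.
#'
#' @param scenario a \code{\link{wdr_scenario}} (or a
#'   \code{\link{scenario_config}}, which is built first).
#' @param protocol a \code{\link{stim_protocol}}.
#' @param record_dt trace sampling interval, ms (default 1).
#' @return object of class \code{windup_sim} with spike times, the
#'   stimulus-aligned \code{spike_table}, per-cleft pH traces (\code{ph}),
#'   voltage, calcium and dendritic current traces.
#' @export
run_windup <- function(scenario, protocol = stim_protocol(),
                       record_dt = 1) {
  if (inherits(scenario, "scenario_config"))
    scenario <- build_scenario(scenario)
  if (!inherits(scenario, "wdr_scenario")) stop("not a wdr_scenario")
  run_engine_scenario(scenario, stim_times = protocol$stim_times,
                      duration = protocol$total_duration,
                      record_dt = record_dt)
}

#' Windup summary of a simulation
#'
#' @param sim a \code{windup_sim}.
#' @return list with the windup curve (C + post-discharge counts per
#'   stimulus), auc, total and input (first-stimulus count).
#' @export
windup_summary <- function(sim) {
  wc <- windup_curve(classify_spikes(sim$spike_table),
                     n_stims = length(sim$stim_times))
  list(curve = wc, auc = attr(wc, "auc"), total = attr(wc, "total"),
       input = attr(wc, "input"))
}

#' ASIC conductance sweep
#'
#' Runs the windup protocol once per conductance value (identical seed and
#' protocol throughout) and summarises windup per run — the numerical
#' counterpart of the conductance-series simulation figures.
#'
#' @param variant "homomeric" or "heteromeric".
#' @param g_list per-synapse maximal conductances, nS.
#' @param base_config a \code{\link{scenario_config}} supplying everything
#'   except the ASIC settings.
#' @param protocol a \code{\link{stim_protocol}}.
#' @param ... further overrides passed to each run's config (e.g.
#'   \code{ca_fraction = 0}).
#' @return data.frame with one row per conductance: g_ns, auc, total, input,
#'   last (last-stimulus count); the per-run windup curves are attached as
#'   attribute \code{"curves"}.
#' @export
conductance_sweep <- function(variant, g_list,
                              base_config = scenario_config(),
                              protocol = stim_protocol(), ...) {
  stopifnot(length(g_list) >= 1)
  curves <- vector("list", length(g_list))
  rows <- lapply(seq_along(g_list), function(i) {
    g <- g_list[i]
    cfg <- modify_config(base_config,
                         asic_variant = if (g > 0) variant else "none",
                         g_asic_ns = g, ...)
    s <- windup_summary(run_windup(cfg, protocol))
    curves[[i]] <<- s$curve
    data.frame(g_ns = g, auc = s$auc, total = s$total, input = s$input,
               last = s$curve$n_spikes[nrow(s$curve)])
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}

# rebuild a config with field overrides
modify_config <- function(config, ...) {
  dots <- list(...)
  fields <- unclass(config)
  fields[names(dots)] <- dots
  do.call(scenario_config, fields)
}

#' (q, tau) validity grid search
#'
#' Scans the two least-constrained cleft parameters — the proton influx
#' amplitude q and the homeostatic time constant tau — and classifies each
#' cell by three validity criteria: (i) the cleft pH stays above a
#' physiological floor over a long (default 100-stimulation) protocol,
#' (ii) the windup AUC stays within a tolerance of the reference run and
#' (iii) the last-stimulus spike count stays within a tolerance of the
#' reference run.  The thresholds are configurable (the source criteria are
#' interpretive); q is capped at 2 mM/ms.
#'
#' @param q_grid proton influx values, mM/ms (all <= 2).
#' @param tau_grid homeostatic time constants, ms.
#' @param base_config a \code{\link{scenario_config}}; its own (q, tau) pair
#'   defines the reference run.  The scan inherits its ASIC settings (use a
#'   moderate homomeric conductance, e.g. 0.2 nS, for the standard scan).
#' @param protocol windup protocol for the AUC / count criteria.
#' @param ph_floor physiological pH floor (default 7.0).
#' @param ph_n_stims protocol length for the pH criterion (default 100;
#'   reduced lengths are acceptable for quick scans).
#' @param auc_tol relative AUC tolerance (default 0.25).
#' @param count_tol relative last-count tolerance (default 0.30).
#' @return data.frame with columns q, tau, ph_min, auc, last, ph_ok,
#'   auc_ok, count_ok, all_ok.
#' @export
parameter_scan <- function(q_grid, tau_grid,
                           base_config = scenario_config(
                             asic_variant = "homomeric", g_asic_ns = 0.2),
                           protocol = stim_protocol(),
                           ph_floor = 7.0, ph_n_stims = 100,
                           auc_tol = 0.25, count_tol = 0.30) {
  stopifnot(length(q_grid) >= 1, length(tau_grid) >= 1)
  if (any(q_grid > 2)) stop("q values above the 2 mM/ms cap")
  ref <- windup_summary(run_windup(base_config, protocol))
  cells <- expand.grid(q = q_grid, tau = tau_grid)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    q <- cells$q[i]; tau <- cells$tau[i]
    cl <- cleft_params(q_amp = q, tau = tau)
    cfg <- modify_config(base_config, cleft = cl)
    s <- windup_summary(run_windup(cfg, protocol))
    long <- run_windup(cfg, stim_protocol(n_stims = ph_n_stims))
    ph_min <- min(long$ph)
    auc_ok <- if (ref$auc > 0)
      abs(s$auc - ref$auc) <= auc_tol * ref$auc else s$auc == ref$auc
    ref_last <- ref$curve$n_spikes[nrow(ref$curve)]
    last <- s$curve$n_spikes[nrow(s$curve)]
    count_ok <- if (ref_last > 0)
      abs(last - ref_last) <= count_tol * ref_last else last == ref_last
    data.frame(q = q, tau = tau, ph_min = ph_min, auc = s$auc, last = last,
               ph_ok = ph_min >= ph_floor, auc_ok = auc_ok,
               count_ok = count_ok)
  })
  out <- do.call(rbind, res)
  out$all_ok <- out$ph_ok & out$auc_ok & out$count_ok
  out
}
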