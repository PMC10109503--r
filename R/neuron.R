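#' WDR neuron parameters
#'
#' Parameter set of the three-compartment (dendrite, soma, axon initial
#' segment) conductance-based WDR projection neuron.  The channel complement
#' follows the windup literature: transient Na and delayed-rectifier K for
#' spiking (soma and axon), a high-threshold non-inactivating L-type Ca
#' current, a calcium-activated K current (KCa, the windup brake; densities
#' 2 mS/cm2 in the soma and 2.5 mS/cm2 in the dendrite), a
#' calcium-activated nonspecific cation current (CaAN, the depolarizing
#' plateau/post-discharge generator) and leak, plus one lumped intracellular
#' calcium pool per compartment with first-order extrusion.  Specific
#' capacitance is 2.4 uF/cm2.  The shipped values are the package's
#' calibrated reference set; every entry can be overridden.
#'
#' Hill-type calcium dependence is used for KCa and CaAN activation,
#' \eqn{w_\infty = Ca^n / (Ca^n + K_d^n)}: a broad KCa (n = 4, Kd 5 uM,
#' engaged by the sustained calcium loads of strong ASIC activity) and a
#' steep CaAN (n = 6, Kd 2.5 uM, the windup ignition switch tipped by slow
#' NK1 summation).
#'
#' @param ... named overrides of any default listed below.
#' @return object of class \code{neuron_params}.
#' @export
neuron_params <- function(...) {
  p <- list(
    # geometry [um] and passive properties
    len_um  = c(dend = 500, soma = 30, axon = 50),
    diam_um = c(dend = 4, soma = 30, axon = 2),
    cm_uf_cm2 = 2.4,
    g_axial_ns = c(dend_soma = 33, soma_axon = 80),
    e_leak = -70, e_na = 50, e_k = -90, e_ca = 80, e_can = 0,
    # channel densities [mS/cm2] per compartment (dend, soma, axon)
    g_leak = c(0.4, 0.2, 0.1),
    g_na   = c(0, 50, 80),
    g_kdr  = c(0, 40, 60),
    g_kca  = c(2.5, 2, 0),
    g_cal  = c(0.4, 0.05, 0),
    g_can  = c(0.8, 0, 0),
    # L-type Ca activation (Boltzmann, brief opening at spike potentials)
    cal_vhalf = -15, cal_k = 5, cal_tau_ms = 1.5,
    # calcium-dependent gating (Hill; KCa broad, CaAN steep)
    kd_kca_um = 5, n_kca = 4, tau_kca_ms = 20,
    kd_can_um = 2.5, n_can = 6, tau_can_ms = 50,
    # calcium pools: resting level, extrusion tau, influx gain
    ca_rest_um = 0.05,
    tau_ca_ms = c(dend = 1500, soma = 1000),
    ca_gain = c(dend = 9e-5, soma = 1e-3),  # uM per pA*ms
    v_init = -70)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown neuron_params field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (length(v) == length(p[[nm]])) {
      if (!is.null(names(p[[nm]])) && is.null(names(v)))
        names(v) <- names(p[[nm]])
      p[[nm]] <- v
    } else stop("length mismatch for field ", nm)
  }
  stopifnot(all(p$g_leak >= 0), all(p$g_na >= 0), all(p$g_kdr >= 0),
            all(p$g_kca >= 0), all(p$g_cal >= 0), all(p$g_can >= 0))
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("WDR neuron (dendrite / soma / axon initial segment)\n")
  a <- compartment_areas(x)
  cat(sprintf("  areas: %.3g / %.3g / %.3g cm2; Cm %.2g uF/cm2\n",
              a[1], a[2], a[3], x$cm_uf_cm2))
  cat(sprintf("  gKCa %.3g / %.3g mS/cm2 (Kd %.3g uM); gCaAN %.3g mS/cm2\n",
              x$g_kca[1], x$g_kca[2], x$kd_kca_um, x$g_can[1]))
  invisible(x)
}

#' Membrane areas of the three compartments
#' @param params a \code{\link{neuron_params}}.
#' @return named vector of areas in cm2 (cylinder side surface).
#' @export
compartment_areas <- function(params) {
  a <- pi * params$diam_um * params$len_um * 1e-8  # um2 -> cm2
  names(a) <- c("dend", "soma", "axon")
  a
}

# density [mS/cm2] * area [cm2] -> nS
density_to_ns <- function(density, area_cm2) density * area_cm2 * 1e6

#' Hill activation of the calcium-gated conductances
#' @param ca intracellular calcium, uM.
#' @param kd half-activation calcium, uM.
#' @param n Hill coefficient (default 2).
#' @return activation in [0, 1); monotone increasing in \code{ca}.
#' @export
hill_activation <- function(ca, kd, n = 2) ca^n / (ca^n + kd^n)

#' Instantaneous channel currents at a given state
#'
#' Evaluates the calcium- and voltage-gated currents of one compartment at
#' steady-state activation, for inspection and testing: KCa (hyperpolarizing,
#' reversal E_K), CaAN (depolarizing, reversal near 0 mV), L-type Ca
#' (high-threshold) and leak.  Conductance scales come from the compartment's
#' densities and area.
#'
#' @param v membrane potential, mV.
#' @param ca intracellular calcium, uM.
#' @param params a \code{\link{neuron_params}}.
#' @param compartment "dend", "soma" or "axon".
#' @return list with currents (pA) \code{i_kca}, \code{i_can}, \code{i_cal},
#'   \code{i_leak} and activations \code{kca_act}, \code{can_act},
#'   \code{cal_act}.
#' @export
channel_currents <- function(v, ca, params, compartment = "dend") {
  ic <- match(compartment, c("dend", "soma", "axon"))
  if (is.na(ic)) stop("unknown compartment")
  area <- compartment_areas(params)[ic]
  w <- hill_activation(ca, params$kd_kca_um, params$n_kca)
  m_can <- hill_activation(ca, params$kd_can_um, params$n_can)
  m_cal <- 1 / (1 + exp(-(v - params$cal_vhalf) / params$cal_k))
  list(
    i_kca = density_to_ns(params$g_kca[ic], area) * w * (v - params$e_k),
    i_can = density_to_ns(params$g_can[ic], area) * m_can *
      (v - params$e_can),
    i_cal = density_to_ns(params$g_cal[ic], area) * m_cal *
      (v - params$e_ca),
    i_leak = density_to_ns(params$g_leak[ic], area) * (v - params$e_leak),
    kca_act = w, can_act = m_can, cal_act = m_cal)
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a threshold with a refractory lockout.
#'
#' @param v membrane potential samples, mV.
#' @param dt sampling interval, ms.
#' @param threshold crossing threshold, mV (default 0).
#' @param refractory lockout after a detected spike, ms (default 2).
#' @param t0 time of the first sample, ms (default 0).
#' @return spike times in ms.
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory = 2, t0 = 0) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(numeric(0))
  times <- t0 + up * dt
  keep <- times[1]
  for (tt in times[-1]) if (tt - keep[length(keep)] >= refractory)
    keep <- c(keep, tt)
  keep
}

#' Simulate the neuron without synaptic input
#'
#' Runs the compiled co-simulation engine with all synapses removed,
#' optionally injecting a square current pulse into the soma: the basic
#' stability / excitability probe for the host neuron.
#'
#' @param params a \code{\link{neuron_params}}.
#' @param duration total time, ms.
#' @param dt step, ms (default 0.025).
#' @param i_inj_pa injected somatic current amplitude, pA (default 0;
#'   positive = depolarizing).
#' @param inj_window c(start, end) of the pulse, ms.
#' @param record_dt trace sampling, ms.
#' @return a \code{windup_sim} object (see \code{\link{run_windup}}).
#' @export
simulate_neuron <- function(params = neuron_params(), duration = 1000,
                            dt = 0.025, i_inj_pa = 0,
                            inj_window = c(0, duration), record_dt = 1) {
  cfg <- scenario_config(neuron = params, dt = dt)
  sc <- build_scenario(cfg)
  run_engine_scenario(sc, stim_times = numeric(0), duration = duration,
                      record_dt = record_dt, i_inj_pa = i_inj_pa,
                      inj_window = inj_window)
}
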