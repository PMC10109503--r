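#' Synaptic cleft proton-buffer parameters
#'
#' Parameters of the buffered synaptic-cleft acidification model.  The state
#' variable is the total proton concentration (free plus buffer-bound),
#' \deqn{[H]_{tot} = [H^+]\left(1 + \frac{[B]_0}{[H^+] + K_d}\right),}
#' which obeys
#' \deqn{\frac{d}{dt}[H]_{tot} = q(t) - \frac{[H^+] - [H]_0}{\tau},}
#' where \eqn{q(t)} is a square proton influx pulse of amplitude
#' \code{q_amp} and duration \code{pulse_dur} delivered at each presynaptic
#' activation (presynaptic membrane crossing \code{spike_threshold}), and the
#' second term is the homeostatic return toward the physiological
#' \eqn{[H]_0 = 10^{-7.4}} M.  Concentrations are held in mM and time in ms
#' internally; constructor arguments for \code{kd} and \code{h0} are in molar
#' as conventionally printed.
#'
#' @param b0 buffer concentration, mM (default 22).
#' @param kd buffer dissociation constant, M (default 10^-6.3).
#' @param h0 baseline free proton concentration, M (default 10^-7.4, pH 7.4).
#' @param q_amp proton influx during a pulse, mM/ms (default 0.3; capped at
#'   2 mM/ms, the physiological maximum for a 20 nm cleft).
#' @param pulse_dur pulse duration, ms (default 1).
#' @param tau homeostatic time constant, ms (default 0.1).
#' @param spike_threshold presynaptic voltage defining an activation, mV.
#' @return object of class \code{cleft_params} (concentrations in mM).
#' @export
cleft_params <- function(b0 = 22, kd = 10^-6.3, h0 = 10^-7.4,
                         q_amp = 0.3, pulse_dur = 1, tau = 0.1,
                         spike_threshold = -30) {
  stopifnot(b0 > 0, kd > 0, h0 > 0, tau > 0, pulse_dur > 0, q_amp >= 0)
  if (q_amp > 2)
    stop("q_amp exceeds the 2 mM/ms physiological cap")
  structure(list(b0 = b0, kd = kd * 1e3, h0 = h0 * 1e3,
                 q_amp = q_amp, pulse_dur = pulse_dur, tau = tau,
                 spike_threshold = spike_threshold),
            class = "cleft_params")
}

#' @export
print.cleft_params <- function(x, ...) {
  cat("Synaptic cleft proton model\n")
  cat(sprintf("  buffer: B0 = %g mM, Kd = %.3g mM\n", x$b0, x$kd))
  cat(sprintf("  baseline pH %.2f; q = %g mM/ms x %g ms; tau = %g ms\n",
              -log10(x$h0 * 1e-3), x$q_amp, x$pulse_dur, x$tau))
  invisible(x)
}

#' pH of a free proton concentration in mM
#' @param h_free free proton concentration, mM.
#' @return pH (dimensionless).
#' @export
ph_from_free <- function(h_free) -log10(h_free * 1e-3)

#' Total (buffered) proton concentration from the free concentration
#'
#' @param h_free free proton concentration, mM (>= 0).
#' @param params a \code{\link{cleft_params}}.
#' @return total proton concentration, mM; strictly increasing in
#'   \code{h_free}.
#' @export
buffered_total <- function(h_free, params) {
  if (any(h_free < 0)) stop("h_free must be >= 0")
  h_free * (1 + params$b0 / (h_free + params$kd))
}

#' Free proton concentration from the total
#'
#' Inverts the buffering relation.  The free concentration is the unique
#' non-negative root of
#' \eqn{H^2 + H (K_d + B_0 - T) - K_d T = 0};
#' computed with the cancellation-safe form of the quadratic formula (the
#' linear coefficient dwarfs the product term at physiological pH).
#'
#' @param h_total total proton concentration, mM (>= 0).
#' @param params a \code{\link{cleft_params}}.
#' @return free proton concentration, mM.
#' @export
free_from_total <- function(h_total, params) {
  if (any(h_total < 0)) stop("h_total must be >= 0")
  b <- params$kd + params$b0 - h_total
  c0 <- -params$kd * h_total
  disc <- sqrt(b^2 - 4 * c0)
  # root = (-b + disc)/2; when b > 0 use the conjugate form to avoid
  # subtracting nearly equal numbers
  ifelse(b >= 0, -2 * c0 / (b + disc), (-b + disc) / 2)
}

#' Synaptic cleft state
#'
#' @param params a \code{\link{cleft_params}}.
#' @param ph initial pH (default 7.4).
#' @return object of class \code{cleft_state} with fields \code{h_total},
#'   \code{h_free}, \code{ph} and a two-column matrix \code{pending_pulses}
#'   of pulse windows (start, end) in ms.
#' @export
cleft_state <- function(params, ph = 7.4) {
  h_free <- 10^(-ph) * 1e3
  structure(list(h_total = buffered_total(h_free, params),
                 h_free = h_free, ph = ph,
                 pending_pulses = matrix(numeric(0), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))),
            class = "cleft_state")
}

#' Register a presynaptic activation
#'
#' Appends a proton pulse window [t, t + pulse_dur) to the cleft.  Activations
#' falling within 1 ms of the start of an already-registered pulse are
#' coalesced (one pulse), mirroring the refractoriness of the presynaptic
#' voltage-threshold trigger.
#'
#' @param state a \code{\link{cleft_state}}.
#' @param t event time, ms.
#' @param params a \code{\link{cleft_params}}.
#' @return updated state.
#' @export
cleft_add_event <- function(state, t, params) {
  stopifnot(is.finite(t))
  p <- state$pending_pulses
  if (nrow(p) > 0 && any(abs(p[, "start"] - t) < 1)) return(state)
  state$pending_pulses <- rbind(p, c(start = t, end = t + params$pulse_dur))
  state
}

#' Proton influx at a given time
#' @param state a \code{\link{cleft_state}}.
#' @param t time, ms.
#' @param params a \code{\link{cleft_params}}.
#' @return q(t) in mM/ms (q_amp inside a pulse window, else 0).
#' @export
cleft_influx <- function(state, t, params) {
  p <- state$pending_pulses
  if (nrow(p) > 0 && any(t >= p[, "start"] & t < p[, "end"]))
    params$q_amp else 0
}

#' Advance the cleft by one engine step
#'
#' Integrates the total-proton ODE over [t, t + dt) by explicit sub-steps of
#' at most \code{max_substep} ms, then refreshes the derived free
#' concentration and pH.  The total concentration evolves slowly (the buffer
#' factor at rest is ~4e4) so the explicit scheme is accurate; accuracy is
#' guarded by a fine-step oracle test.
#'
#' @param state a \code{\link{cleft_state}}.
#' @param t step start time, ms.
#' @param dt step, ms (<= 0.025).
#' @param params a \code{\link{cleft_params}}.
#' @param max_substep sub-step ceiling, ms (default 0.005).
#' @return updated state.
#' @export
cleft_step <- function(state, t, dt, params, max_substep = 0.005) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.025)
    stop("dt must be in (0, 0.025] ms")
  n_sub <- max(1L, ceiling(dt / max_substep))
  h <- dt / n_sub
  htot <- state$h_total
  hfree <- state$h_free
  for (k in seq_len(n_sub)) {
    tk <- t + (k - 1) * h
    q <- cleft_influx(state, tk, params)
    htot <- htot + h * (q - (hfree - params$h0) / params$tau)
    hfree <- free_from_total(htot, params)
  }
  state$h_total <- htot
  state$h_free <- hfree
  state$ph <- ph_from_free(hfree)
  # drop pulses that have fully elapsed
  p <- state$pending_pulses
  if (nrow(p) > 0) state$pending_pulses <- p[p[, "end"] > t + dt, ,
                                             drop = FALSE]
  state
}

#' Simulate a single cleft over a pulse train
#'
#' Convenience driver (compiled) for the cleft model alone: delivers proton
#' pulses at the given event times and records the pH trace.
#'
#' @param params a \code{\link{cleft_params}}.
#' @param events presynaptic activation times, ms.
#' @param duration total simulated time, ms.
#' @param dt integration sub-step, ms (default 0.005).
#' @param record_dt trace sampling interval, ms (default 1).
#' @param ph0 initial pH (default 7.4).
#' @return data.frame with columns time_ms, ph, h_free_mm, h_total_mm.
#' @export
simulate_cleft <- function(params, events = numeric(0), duration,
                           dt = 0.005, record_dt = 1, ph0 = 7.4) {
  res <- cleft_run_cpp(as.numeric(params$b0), as.numeric(params$kd),
                       as.numeric(params$h0), as.numeric(params$q_amp),
                       as.numeric(params$pulse_dur), as.numeric(params$tau),
                       as.numeric(sort(events)), as.numeric(duration),
                       as.numeric(dt), as.numeric(record_dt),
                       as.numeric(ph0))
  data.frame(time_ms = res$time, ph = res$ph, h_free_mm = res$h_free,
             h_total_mm = res$h_total)
}
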