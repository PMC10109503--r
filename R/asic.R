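#' ASIC1a gating parameter sets
#'
#' Builds the parameter set for one population of acid-sensing ion channels
#' (ASIC1a-containing), in either the native homomeric or the native
#' heteromeric (ASIC1a/ASIC2) parameterisation fitted to "Type 1" and
#' "Type 2" spinal currents.  The gating model is Hodgkin-Huxley-like with
#' activation \eqn{m} and inactivation \eqn{h} driven by extracellular pH
#' only:
#' \deqn{m_\infty(pH) = 1 / (1 + 10^{n_m (pH - pH_{0.5m})})}
#' \deqn{h_\infty(pH) = \alpha / (1 + 10^{-n_h (pH - pH_{0.5h})})}
#' Activation is treated as instantaneous (its time constant is negligible on
#' windup timescales); inactivation relaxes with a pH-dependent time constant
#' \code{tau_h} (seconds), a biased Gaussian for the homomeric fit and a
#' symmetrized exponential for the heteromeric fit.
#'
#' @param variant "homomeric" (native Type 1) or "heteromeric" (native Type 2).
#' @param e_rev reversal potential in mV (default +50 mV).
#' @param ca_fraction fraction of the ASIC current treated as calcium current
#'   entering the postsynaptic pool (default 0.1).
#' @param tau_h_form functional form of the inactivation time constant.  The
#'   homomeric default is \code{"biased_gaussian"}; \code{"affine"} and
#'   \code{"piecewise_affine"} are the alternative homomeric fits used in the
#'   robustness grid searches.  The heteromeric variant always uses the
#'   symmetrized exponential.
#' @param ... overrides for individual gating fields (\code{n_m},
#'   \code{ph_half_m}, \code{n_h}, \code{ph_half_h}, \code{alpha}).
#' @return an object of class \code{asic_params}.
#' @examples
#' p <- asic_params("homomeric")
#' asic_minf(6.46, p)   # 0.5 at the activation midpoint
#' @export
asic_params <- function(variant = c("homomeric", "heteromeric"),
                        e_rev = 50, ca_fraction = 0.1,
                        tau_h_form = NULL, ...) {
  variant <- match.arg(variant)
  base <- switch(variant,
    homomeric = list(n_m = 1.5, ph_half_m = 6.46, n_h = 4.6,
                     ph_half_h = 7.3, alpha = 1.3),
    heteromeric = list(n_m = 1.94, ph_half_m = 6.03, n_h = 3.82,
                       ph_half_h = 6.74, alpha = 1))
  dots <- list(...)
  bad <- setdiff(names(dots), names(base))
  if (length(bad)) stop("unknown asic_params field(s): ",
                        paste(bad, collapse = ", "))
  base[names(dots)] <- dots
  if (is.null(tau_h_form)) {
    tau_h_form <- if (variant == "homomeric") "biased_gaussian"
                  else "symmetrized_exponential"
  }
  tau_h_form <- match.arg(tau_h_form,
    c("biased_gaussian", "symmetrized_exponential", "affine",
      "piecewise_affine"))
  tau_h_coeffs <- switch(tau_h_form,
    # tau_h = a1 exp(-a2 (pH - b2)^2) + a3 pH - b3   [seconds]
    biased_gaussian = c(a1 = 49.196, a2 = 34.632, b2 = 7.144,
                        a3 = 0.95, b3 = 3.77),
    # tau_h = amp exp(-rate |pH - center|) + offset  [seconds]
    symmetrized_exponential = c(amp = 42.862, rate = 5.375,
                                center = 6.6, offset = 1.645),
    # tau_h = max(0, -a pH + b)
    affine = c(a = 160.4, b = 1195.32),
    # two affine pieces meeting at pH 7.37
    piecewise_affine = c(a1 = 10.18, b1 = 49.92, a2 = -558.3, b2 = 4143,
                         ph_break = 7.37))
  p <- c(list(variant = variant), base,
         list(tau_h_form = tau_h_form, tau_h_coeffs = tau_h_coeffs,
              e_rev = e_rev, ca_fraction = ca_fraction))
  stopifnot(p$n_m > 0, p$n_h > 0, p$alpha > 0,
            p$ca_fraction >= 0, p$ca_fraction <= 1)
  structure(p, class = "asic_params")
}

#' @export
print.asic_params <- function(x, ...) {
  cat("ASIC1a gating parameters (", x$variant, " native)\n", sep = "")
  cat(sprintf("  m_inf: n_m = %.3g, pH0.5m = %.3g\n", x$n_m, x$ph_half_m))
  cat(sprintf("  h_inf: n_h = %.3g, pH0.5h = %.3g, alpha = %.3g\n",
              x$n_h, x$ph_half_h, x$alpha))
  cat(sprintf("  tau_h: %s; E_rev = %g mV; Ca fraction = %g\n",
              x$tau_h_form, x$e_rev, x$ca_fraction))
  invisible(x)
}

check_ph <- function(ph) {
  if (!is.numeric(ph) || any(!is.finite(ph)))
    stop("pH must be finite numeric")
  invisible(ph)
}

#' Steady-state ASIC activation
#'
#' \eqn{m_\infty(pH)}: strictly decreasing sigmoid in pH (channels activate
#' upon acidification).
#'
#' @param ph extracellular pH (vectorized).
#' @param params an \code{\link{asic_params}} object.
#' @return activation fraction in (0, 1).
#' @export
asic_minf <- function(ph, params) {
  check_ph(ph)
  1 / (1 + 10^(params$n_m * (ph - params$ph_half_m)))
}

#' Steady-state ASIC inactivation
#'
#' \eqn{h_\infty(pH)}: strictly increasing sigmoid with ceiling \code{alpha}
#' (1.3 for the homomeric fit, following the source data fit; 1 for the
#' heteromeric fit).
#'
#' @inheritParams asic_minf
#' @return availability in (0, alpha).
#' @export
asic_hinf <- function(ph, params) {
  check_ph(ph)
  params$alpha / (1 + 10^(-params$n_h * (ph - params$ph_half_h)))
}

#' ASIC inactivation time constant
#'
#' pH-dependent inactivation time constant in seconds.  The fits are validated
#' over pH 4-9; outside that range the function errors unless
#' \code{check_range = FALSE}, in which case the raw expression is evaluated
#' and floored at 1 ms to guarantee positivity.
#'
#' @inheritParams asic_minf
#' @param check_range reject pH outside [4, 9]?
#' @return time constant in seconds (vectorized).
#' @export
asic_tauh <- function(ph, params, check_range = TRUE) {
  check_ph(ph)
  if (check_range && any(ph < 4 | ph > 9))
    stop("pH outside the validated range [4, 9] for tau_h")
  cf <- params$tau_h_coeffs
  tau <- switch(params$tau_h_form,
    biased_gaussian =
      cf[["a1"]] * exp(-cf[["a2"]] * (ph - cf[["b2"]])^2) +
      cf[["a3"]] * ph - cf[["b3"]],
    symmetrized_exponential =
      cf[["amp"]] * exp(-cf[["rate"]] * abs(ph - cf[["center"]])) +
      cf[["offset"]],
    affine = pmax(0, -cf[["a"]] * ph + cf[["b"]]),
    piecewise_affine =
      ifelse(ph <= cf[["ph_break"]],
             pmax(0, cf[["a1"]] * ph - cf[["b1"]]),
             pmax(0, cf[["a2"]] * ph + cf[["b2"]])))
  pmax(tau, 1e-3)
}

#' ASIC channel state
#'
#' Holds the inactivation level \code{h} of one ASIC population and its
#' operating mode.  In \code{"dynamic"} mode gating follows pH; in
#' \code{"mittx"} mode the channel is held constitutively fully open
#' (effective open fraction \eqn{m h = 1} regardless of pH), emulating the
#' sustained, inactivation-free activation produced by the Texas coral snake
#' toxin MitTx.
#'
#' @param params an \code{\link{asic_params}} object.
#' @param ph initial pH; \code{h} is initialised at \code{asic_hinf(ph)}
#'   (resting pH 7.4 by default).
#' @param mode "dynamic" or "mittx".
#' @return an object of class \code{asic_state}.
#' @export
asic_state <- function(params, ph = 7.4, mode = c("dynamic", "mittx")) {
  mode <- match.arg(mode)
  structure(list(h = asic_hinf(ph, params), mode = mode),
            class = "asic_state")
}

#' Advance ASIC inactivation by one time step
#'
#' Exact exponential relaxation of \code{h} toward \code{asic_hinf(ph)} with
#' time constant \code{asic_tauh(ph)}; activation \code{m} is instantaneous
#' and carried implicitly.  In mittx mode the state is left untouched.
#'
#' @param state an \code{\link{asic_state}}.
#' @param ph current cleft pH.
#' @param dt step in ms (0 < dt <= 1).
#' @param params an \code{\link{asic_params}}.
#' @return the updated state.
#' @export
asic_step <- function(state, ph, dt, params) {
  if (!is.numeric(dt) || dt <= 0 || dt > 1)
    stop("dt must be in (0, 1] ms")
  if (state$mode == "mittx") return(state)
  hinf <- asic_hinf(ph, params)
  tau_ms <- asic_tauh(ph, params) * 1000
  state$h <- hinf + (state$h - hinf) * exp(-dt / tau_ms)
  state
}

#' ASIC current
#'
#' \eqn{I = g\, m\, h\, (V - E)} with instantaneous \eqn{m = m_\infty(pH)};
#' a fixed fraction of the total current is booked as calcium current.  In
#' mittx mode the open fraction is exactly 1 and the current is pH-independent.
#'
#' @param state an \code{\link{asic_state}}.
#' @param ph cleft pH.
#' @param v membrane potential, mV.
#' @param g_max maximal conductance, nS (>= 0).
#' @param params an \code{\link{asic_params}}.
#' @return list with \code{i_total} and \code{i_ca}, both pA (negative =
#'   inward).
#' @export
asic_current <- function(state, ph, v, g_max, params) {
  if (g_max < 0) stop("g_max must be >= 0")
  open <- if (state$mode == "mittx") 1
          else asic_minf(ph, params) * state$h
  i_total <- g_max * open * (v - params$e_rev)
  list(i_total = i_total, i_ca = params$ca_fraction * i_total)
}

#' Whole-cell conductance from a peak current
#'
#' Ohmic conductance estimate \eqn{g = I / (V - E)} used to place native
#' whole-cell ASIC current amplitudes on the model's conductance scale
#' (e.g. 242 pA at -80 mV with E = +50 mV gives ~2 nS).
#'
#' @param i_pa peak current amplitude, pA (magnitude).
#' @param v holding potential, mV.
#' @param e_rev reversal potential, mV.
#' @return conductance in nS.
#' @export
conductance_from_current <- function(i_pa, v, e_rev = 50) {
  abs(i_pa / (v - e_rev))
}

#' Bisection for gating half-points
#'
#' Solves \code{f(ph) = target} for a monotone gating curve by plain interval
#' bisection; used to recover the half-activation and half-inactivation pH of
#' an implemented parameter set from the curve itself.
#'
#' @param f monotone function of pH.
#' @param target level to solve for.
#' @param lower,upper bracketing pH values.
#' @param tol absolute tolerance on pH.
#' @return the root pH.
#' @export
bisect_ph <- function(f, target, lower, upper, tol = 1e-6) {
  flo <- f(lower) - target
  fhi <- f(upper) - target
  if (flo * fhi > 0) stop("target not bracketed by [lower, upper]")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    fm <- f(mid) - target
    if (fm * flo <= 0) upper <- mid else { lower <- mid; flo <- fm }
  }
  (lower + upper) / 2
}

#' Half-activation and half-inactivation pH of an ASIC parameter set
#'
#' Recovers the pH at which the implemented \code{asic_minf} curve crosses
#' one half, and the pH at which \code{asic_hinf} crosses \code{alpha/2}, by
#' bisection on the curves themselves.
#'
#' @param params an \code{\link{asic_params}}.
#' @param tol bisection tolerance.
#' @return named vector \code{c(ph_half_m, ph_half_h)}.
#' @export
asic_half_points <- function(params, tol = 1e-6) {
  phm <- bisect_ph(function(p) -asic_minf(p, params), -0.5, 4, 9, tol)
  phh <- bisect_ph(function(p) asic_hinf(p, params), params$alpha / 2,
                   4, 9, tol)
  c(ph_half_m = phm, ph_half_h = phh)
}

#' ASIC characterization curves
#'
#' Steady-state curves over a pH grid: activation \code{m_inf}, availability
#' \code{h_inf}, time constant \code{tau_h_s} and the window-current relative
#' conductance \code{g_rel = m_inf * h_inf / max(m_inf * h_inf)}.
#'
#' @param params an \code{\link{asic_params}}.
#' @param ph pH grid (default 4 to 9 in steps of 0.001).
#' @return data.frame with columns pH, m_inf, h_inf, tau_h_s, g_rel.
#' @export
asic_curves <- function(params, ph = seq(4, 9, by = 0.001)) {
  m <- asic_minf(ph, params)
  h <- asic_hinf(ph, params)
  w <- m * h
  data.frame(pH = ph, m_inf = m, h_inf = h,
             tau_h_s = asic_tauh(ph, params), g_rel = w / max(w))
}

#' pH-step activation protocol
#'
#' Peak relative conductance upon stepping from a conditioning pH (at which
#' the channel has fully equilibrated) to a test pH.  Activation is
#' instantaneous and inactivation monotone, so the peak open fraction is
#' \eqn{m_\infty(test) \cdot \max(h_{cond}, h_\infty(test))}; values are
#' normalized to the largest peak over the test grid.
#'
#' @param params an \code{\link{asic_params}}.
#' @param test_ph test pH grid.
#' @param cond_ph conditioning pH (default 7.4).
#' @return data.frame with columns test_ph, peak_open, g_rel.
#' @export
asic_activation_protocol <- function(params,
                                     test_ph = seq(4, 7.4, by = 0.05),
                                     cond_ph = 7.4) {
  h0 <- asic_hinf(cond_ph, params)
  peak <- asic_minf(test_ph, params) * pmax(h0, asic_hinf(test_ph, params))
  data.frame(test_ph = test_ph, peak_open = peak, g_rel = peak / max(peak))
}

#' Steady-state inactivation protocol
#'
#' Relative peak response to a fixed acid test stimulus after long
#' conditioning at each pH of a grid (availability curve).
#'
#' @param params an \code{\link{asic_params}}.
#' @param cond_ph conditioning pH grid.
#' @param test_ph test pH (default 6.0).
#' @return data.frame with columns cond_ph, peak_open, g_rel.
#' @export
asic_inactivation_protocol <- function(params,
                                       cond_ph = seq(6, 8.5, by = 0.05),
                                       test_ph = 6.0) {
  peak <- asic_minf(test_ph, params) * asic_hinf(cond_ph, params)
  data.frame(cond_ph = cond_ph, peak_open = peak, g_rel = peak / max(peak))
}

#' Recovery from inactivation
#'
#' Two-pulse protocol: the channel is inactivated by a conditioning
#' acidification, returned to the resting pH for a variable interval, and
#' probed again.  The recovered fraction is \eqn{h(\Delta)/h_\infty(rest)}
#' with the exact exponential relaxation at the resting-pH time constant.
#'
#' @param params an \code{\link{asic_params}}.
#' @param intervals recovery intervals, ms.
#' @param cond_ph conditioning pH (default 6.0).
#' @param rest_ph resting pH between pulses (default 7.4).
#' @param cond_dur conditioning duration, ms (default 5000, long enough to
#'   approach steady-state inactivation).
#' @return data.frame with columns interval_ms, h, recovery.
#' @export
asic_recovery_protocol <- function(params, intervals = c(0, 2^(0:7) * 250),
                                   cond_ph = 6.0, rest_ph = 7.4,
                                   cond_dur = 5000) {
  h_rest <- asic_hinf(rest_ph, params)
  hinf_c <- asic_hinf(cond_ph, params)
  tau_c <- asic_tauh(cond_ph, params) * 1000
  h_cond <- hinf_c + (h_rest - hinf_c) * exp(-cond_dur / tau_c)
  tau_r <- asic_tauh(rest_ph, params) * 1000
  h <- h_rest + (h_cond - h_rest) * exp(-intervals / tau_r)
  data.frame(interval_ms = intervals, h = h, recovery = h / h_rest)
}
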