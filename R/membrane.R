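#' Single-compartment membrane specification
#'
#' A minimal isopotential compartment for current-clamp simulation: membrane
#' capacitance, a passive leak, an optional delayed-rectifier potassium
#' conductance (a single gate raised to an integer power; defaults to the
#' classical n^4 squid delayed rectifier, since the sodium-channel tuning
#' carries no potassium parameters of its own), and one sodium channel
#' model (HH or Markov).
#'
#' @param sodium a \code{nav_channel}.
#' @param Cm membrane capacitance, uF/cm^2.
#' @param area membrane area, um^2 (converts injected nA to mA/cm^2).
#' @param g_L,E_L leak conductance (S/cm^2) and reversal (mV).
#' @param K potassium conductance: list with \code{gbar} (S/cm^2), \code{E}
#'   (mV), \code{alpha}, \code{beta} (\code{\link{rate_law}}s) and
#'   \code{exponent}; or \code{NULL} for none.
#' @param V0 initial/resting potential, mV.
#' @return object of class \code{membrane_spec}.
#' @export
membrane_spec <- function(sodium, Cm = 1, area = 10000,
                          g_L = 3e-4, E_L = -100,
                          K = hh_k_conductance(), V0 = -100) {
  stopifnot(inherits(sodium, "nav_channel"), Cm > 0, area > 0, g_L >= 0)
  structure(list(sodium = sodium, Cm = Cm, area = area,
                 g_L = g_L, E_L = E_L, K = K, V0 = V0),
            class = "membrane_spec")
}

#' @rdname membrane_spec
#' @param gbar,E potassium maximal conductance (S/cm^2) and reversal (mV).
#' @return \code{hh_k_conductance}: the default delayed-rectifier spec.
#' @export
hh_k_conductance <- function(gbar = 0.036, E = -77) {
  list(gbar = gbar, E = E,
       alpha = rate_law("linoid", A = 0.01, V12 = -55, k = 10),
       beta = rate_law("exponential", A = 0.125, V12 = -65, k = -80),
       exponent = 4)
}

#' Piecewise-constant current stimulus
#'
#' @param onset,duration pulse onset(s) and duration(s), ms (vectors recycle).
#' @param amp_nA pulse amplitude(s), nA.
#' @return data.frame with columns \code{onset}, \code{duration},
#'   \code{amp_nA} usable as the \code{stimulus} of
#'   \code{\link{simulate_current_clamp}}.
#' @export
step_stimulus <- function(onset, duration, amp_nA) {
  data.frame(onset = onset, duration = duration, amp_nA = amp_nA)
}

#' @rdname step_stimulus
#' @param n number of pulses.
#' @param freq_Hz pulse repetition frequency.
#' @return \code{pulse_train_stimulus}: a pulse-train stimulus data.frame.
#' @export
pulse_train_stimulus <- function(onset, n, amp_nA, freq_Hz = 25,
                                 duration = 2) {
  step_stimulus(onset + (seq_len(n) - 1) * 1000 / freq_Hz, duration, amp_nA)
}

#' Current-clamp simulation of the single compartment
#'
#' Integrates the membrane equation
#' \code{Cm dV/dt = I_stim - g_L (V - E_L) - I_Na(V) - I_K(V)} jointly with
#' the sodium-channel states (HH gate ODEs or the Markov master equation)
#' and the potassium gate by the classical fourth-order Runge-Kutta method.
#' The kinetics at 0.025 ms steps are non-stiff for both bundled channel
#' families, and halving the step changes spike times by far less than
#' 0.1 ms.
#'
#' @param membrane a \code{\link{membrane_spec}}.
#' @param stimulus data.frame of current pulses (see
#'   \code{\link{step_stimulus}}); pulses may overlap (amplitudes add).
#' @param duration total simulated time, ms.
#' @param dt integration/sampling step, ms.
#' @return data.frame with columns \code{t_ms}, \code{V_mV},
#'   \code{I_stim_mA_cm2}, \code{I_Na_mA_cm2}, \code{I_K_mA_cm2},
#'   \code{I_L_mA_cm2} plus the channel state columns; attribute
#'   \code{aborted} is TRUE if the voltage left [-500, 500] mV (numerical
#'   blow-up guard).
#' @export
simulate_current_clamp <- function(membrane, stimulus, duration,
                                   dt = 0.025) {
  stopifnot(inherits(membrane, "membrane_spec"), duration > 0, dt > 0)
  ch <- membrane$sodium
  q10 <- q10_factor(ch$temperature)
  area_cm2 <- membrane$area * 1e-8
  stim_density <- function(t) {           # nA -> mA/cm^2
    on <- stimulus$onset <= t & t < stimulus$onset + stimulus$duration
    sum(stimulus$amp_nA[on]) * 1e-6 / area_cm2
  }
  is_hh <- inherits(ch, "hh_channel")
  has_K <- !is.null(membrane$K)
  na0 <- steady_state(ch, membrane$V0)
  n0 <- if (has_K) {
    with(membrane$K, gate_infty_tau(alpha, beta, membrane$V0)$x_infty)
  }
  y <- c(membrane$V0, na0, if (has_K) n0)
  nna <- length(na0)

  deriv <- function(y, istim) {
    V <- y[1]
    na <- y[1 + seq_len(nna)]
    if (is_hh) {
      dna <- vapply(ch$gates, function(g)
        (eval_rate_law(g$alpha, V) * (1 - na[[g$name]]) -
           eval_rate_law(g$beta, V) * na[[g$name]]) * q10, numeric(1))
      open <- prod(vapply(ch$gates, function(g) na[[g$name]]^g$exponent,
                          numeric(1)))
    } else {
      Q <- build_generator(ch, V)
      dna <- as.numeric(Q %*% na)
      open <- na[[ch$open_state]]
    }
    i_na <- ch$gbar * open * (V - ch$E_rev)
    i_l <- membrane$g_L * (V - membrane$E_L)
    if (has_K) {
      n <- y[length(y)]
      K <- membrane$K
      dn <- eval_rate_law(K$alpha, V) * (1 - n) - eval_rate_law(K$beta, V) * n
      i_k <- K$gbar * n^K$exponent * (V - K$E)
    } else {
      dn <- NULL; i_k <- 0
    }
    dV <- 1000 * (istim - i_na - i_k - i_l) / membrane$Cm
    list(dy = c(dV, dna, dn), i_na = i_na, i_k = i_k, i_l = i_l)
  }

  nt <- ceiling(duration / dt) + 1
  out <- matrix(NA_real_, nt, length(y) + 5)
  aborted <- FALSE
  t <- 0
  for (i in seq_len(nt)) {
    istim <- stim_density(t)
    d1 <- deriv(y, istim)
    out[i, ] <- c(t, y[1], istim, d1$i_na, d1$i_k, d1$i_l, y[-1])
    if (abs(y[1]) > 500) { aborted <- TRUE; break }
    if (i == nt) break
    # RK4; the stimulus is piecewise constant, evaluated at the step start
    k1 <- d1$dy
    k2 <- deriv(y + dt / 2 * k1, istim)$dy
    k3 <- deriv(y + dt / 2 * k2, istim)$dy
    k4 <- deriv(y + dt * k3, istim)$dy
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    names(y) <- c("", names(na0), if (has_K) "n")
    t <- t + dt
  }
  out <- as.data.frame(out[!is.na(out[, 1]), , drop = FALSE])
  names(out) <- c("t_ms", "V_mV", "I_stim_mA_cm2", "I_Na_mA_cm2",
                  "I_K_mA_cm2", "I_L_mA_cm2", names(na0),
                  if (has_K) "n")
  attr(out, "aborted") <- aborted
  if (aborted)
    warning("simulation aborted: |V| exceeded 500 mV (numerical blow-up)",
            call. = FALSE)
  out
}

#' Count action potentials in a voltage trace
#'
#' Counts upward crossings of a voltage threshold separated by at least a
#' refractory guard interval.
#'
#' @param trace data.frame with \code{t_ms} and \code{V_mV} (as returned by
#'   \code{\link{simulate_current_clamp}}), or a numeric voltage vector.
#' @param threshold spike-detection threshold, mV.
#' @param refractory minimal separation between counted crossings, ms.
#' @param dt sample interval when \code{trace} is a bare vector.
#' @return integer spike count.
#' @export
count_spikes <- function(trace, threshold = 0, refractory = 1, dt = 0.025) {
  if (is.data.frame(trace)) {
    V <- trace$V_mV; t <- trace$t_ms
  } else {
    V <- trace; t <- (seq_along(V) - 1) * dt
  }
  stopifnot(length(V) >= 1)
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1
  if (!length(up)) return(0L)
  kept <- up[1]
  for (i in up[-1]) if (t[i] - t[kept[length(kept)]] >= refractory)
    kept <- c(kept, i)
  length(kept)
}
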