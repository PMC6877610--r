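#' Hodgkin-Huxley channel specification
#'
#' A channel whose conductance is a product of independent first-order gating
#' particles raised to integer exponents (e.g. m^3*h, or m^3*h*s when a slow
#' inactivation gate is present), each gate governed by voltage-dependent
#' forward (alpha) and backward (beta) rate laws.
#'
#' @param gates list of gates; each gate is a list with elements \code{name},
#'   \code{exponent} (positive integer), \code{alpha} and \code{beta}
#'   (\code{\link{rate_law}} objects).
#' @param gbar maximal conductance density, S/cm^2.
#' @param E_rev reversal potential, mV.
#' @param temperature a \code{\link{temperature_spec}}.
#' @param name optional preset name carried in metadata.
#' @return object of classes \code{hh_channel}, \code{nav_channel}.
#' @export
hh_channel <- function(gates, gbar = 0.1, E_rev = 65,
                       temperature = temperature_spec(), name = NULL) {
  stopifnot(is.list(gates), length(gates) >= 1, gbar > 0,
            inherits(temperature, "temperature_spec"))
  for (g in gates) {
    stopifnot(is.character(g$name),
              g$exponent >= 1, g$exponent == round(g$exponent))
    validate_rate_law(g$alpha); validate_rate_law(g$beta)
  }
  names(gates) <- vapply(gates, `[[`, character(1), "name")
  structure(list(family = "hh", gates = gates, gbar = gbar, E_rev = E_rev,
                 temperature = temperature, name = name),
            class = c("hh_channel", "nav_channel"))
}

#' Markov kinetic scheme specification
#'
#' A channel modelled as a set of discrete states with voltage-dependent
#' transition rates; the macroscopic current is proportional to the occupancy
#' of the single open state. The bundled Na_V_1.5 scheme has five states
#' (two closed C1, C2; one open O1; two inactivated I1, I2) with ten
#' transitions.
#'
#' @param states character vector of state names (order fixes the occupancy
#'   vector layout).
#' @param open_state name of the conducting state.
#' @param transitions list of transitions, each a list with \code{from},
#'   \code{to} (state names) and \code{rate} (a \code{\link{rate_law}}).
#' @param gbar maximal conductance density, S/cm^2.
#' @param E_rev reversal potential, mV.
#' @param temperature a \code{\link{temperature_spec}}.
#' @param name optional preset name.
#' @return object of classes \code{markov_channel}, \code{nav_channel}.
#' @export
markov_channel <- function(states, open_state, transitions, gbar = 0.1,
                           E_rev = 65, temperature = temperature_spec(),
                           name = NULL) {
  stopifnot(is.character(states), length(states) >= 2,
            !anyDuplicated(states), open_state %in% states,
            length(transitions) >= 1, gbar > 0,
            inherits(temperature, "temperature_spec"))
  for (tr in transitions) {
    stopifnot(tr$from %in% states, tr$to %in% states, tr$from != tr$to)
    validate_rate_law(tr$rate)
  }
  # connectivity (undirected): every state reachable from the first
  adj <- matrix(FALSE, length(states), length(states),
                dimnames = list(states, states))
  for (tr in transitions) {
    adj[tr$from, tr$to] <- TRUE
    adj[tr$to, tr$from] <- TRUE
  }
  seen <- states[1]
  repeat {
    nxt <- unique(c(seen, unlist(lapply(seen, function(s) states[adj[s, ]]))))
    if (length(nxt) == length(seen)) break
    seen <- nxt
  }
  if (length(seen) != length(states))
    stop("disconnected Markov scheme: state(s) ",
         paste(setdiff(states, seen), collapse = ", "),
         " unreachable", call. = FALSE)
  structure(list(family = "markov", states = states, open_state = open_state,
                 transitions = transitions, gbar = gbar, E_rev = E_rev,
                 temperature = temperature, name = name),
            class = c("markov_channel", "nav_channel"))
}

#' @export
print.nav_channel <- function(x, ...) {
  if (x$family == "hh") {
    cat("<hh_channel>", if (!is.null(x$name)) x$name else "",
        "gates:", paste(sprintf("%s^%d", names(x$gates),
                                vapply(x$gates, `[[`, numeric(1), "exponent")),
                        collapse = " * "), "\n")
  } else {
    cat("<markov_channel>", if (!is.null(x$name)) x$name else "",
        "states:", paste(x$states, collapse = ", "),
        sprintf("(open: %s, %d transitions)", x$open_state,
                length(x$transitions)), "\n")
  }
  cat("  gbar =", x$gbar, "S/cm^2, E_rev =", x$E_rev, "mV, T =",
      x$temperature$T, "C (base", x$temperature$T_base, "C)\n")
  invisible(x)
}

#' Replace the temperature block of a channel
#'
#' @param channel a \code{nav_channel}.
#' @param T temperature (degrees C); if \code{NULL} keep current.
#' @param T_base reference temperature; if \code{NULL} keep current.
#' @return the channel with the updated \code{temperature_spec}.
#' @export
set_temperature <- function(channel, T = NULL, T_base = NULL) {
  stopifnot(inherits(channel, "nav_channel"))
  tp <- channel$temperature
  channel$temperature <- temperature_spec(
    T = if (is.null(T)) tp$T else T,
    T_base = if (is.null(T_base)) tp$T_base else T_base,
    q10_base = tp$q10_base)
  channel
}

#' Infinitesimal generator of a Markov scheme at fixed voltage
#'
#' Builds the conservative rate matrix Q (1/ms) such that the occupancy vector
#' p obeys dp/dt = Q p at clamped voltage V. Off-diagonal entry (j, i) is the
#' Q10-scaled rate of the transition from state i to state j; columns sum to
#' zero, so total occupancy is conserved exactly.
#'
#' @param scheme a \code{\link{markov_channel}}.
#' @param V voltage (mV).
#' @return a square matrix with state names on both dimensions.
#' @export
build_generator <- function(scheme, V) {
  stopifnot(inherits(scheme, "markov_channel"), is.finite(V))
  q10 <- q10_factor(scheme$temperature)
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (tr in scheme$transitions) {
    r <- eval_rate_law(tr$rate, V) * q10
    Q[tr$to, tr$from] <- Q[tr$to, tr$from] + r
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Steady state of a channel at fixed voltage
#'
#' For an HH channel, every gate sits at its steady-state value
#' alpha/(alpha+beta). For a Markov scheme, the steady state is the
#' normalized null vector of the generator (unique when the scheme is
#' connected); both are independent of temperature.
#'
#' @param channel a \code{nav_channel}.
#' @param V voltage (mV).
#' @return named numeric vector: gate values (HH) or state occupancies
#'   summing to one (Markov).
#' @export
steady_state <- function(channel, V) UseMethod("steady_state")

#' @export
steady_state.hh_channel <- function(channel, V) {
  vapply(channel$gates, function(g)
    gate_infty_tau(g$alpha, g$beta, V)$x_infty, numeric(1))
}

#' @export
steady_state.markov_channel <- function(channel, V) {
  Q <- build_generator(channel, V)
  dec <- svd(Q)
  n <- ncol(Q)
  # nullity check: exactly one singular value numerically zero
  tol <- max(dim(Q)) * dec$d[1] * 1e-12
  if (sum(dec$d < tol) != 1L)
    stop("degenerate Markov scheme: non-unique steady state at V = ", V,
         call. = FALSE)
  p <- dec$v[, n]
  p <- p / sum(p)
  if (any(p < -1e-10))
    stop("invalid steady state (negative occupancy) at V = ", V,
         call. = FALSE)
  p <- pmax(p, 0); p <- p / sum(p)
  names(p) <- channel$states
  p
}

# eigendecomposition of a generator with a guard for defective matrices;
# returns NULL if the eigenvector basis is too ill-conditioned to invert
generator_eigen <- function(Q) {
  E <- eigen(Q)
  Vc <- E$vectors
  if (rcond(Mod(Vc)) < 1e-12 || abs(det(Vc)) < 1e-300) return(NULL)
  Vi <- tryCatch(solve(Vc), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  list(values = E$values, vectors = Vc, inv = Vi)
}

# closed-form Markov occupancy trajectory at constant V on times tvec (>= 0)
markov_trajectory <- function(Q, p0, tvec, eig = NULL) {
  if (is.null(eig)) eig <- generator_eigen(Q)
  if (!is.null(eig)) {
    co <- eig$inv %*% p0
    lt <- outer(eig$values, tvec)          # n x nt
    traj <- eig$vectors %*% (exp(lt) * as.vector(co))
    traj <- Re(traj)
  } else {
    # defective generator: scaling-and-squaring matrix exponential stepping
    nt <- length(tvec)
    traj <- matrix(0, nrow(Q), nt)
    traj[, 1] <- as.numeric(Matrix::expm(Q * tvec[1]) %*% p0)
    if (nt > 1) for (i in 2:nt) {
      P <- as.matrix(Matrix::expm(Q * (tvec[i] - tvec[i - 1])))
      traj[, i] <- P %*% traj[, i - 1]
    }
  }
  rownames(traj) <- rownames(Q)
  traj
}

#' Propagate channel state through a constant-voltage epoch
#'
#' Advances the channel state exactly (no time-stepping error): HH gates
#' relax as \code{x(t) = x_inf - (x_inf - x0) exp(-t/tau)}; Markov occupancies
#' follow the matrix-exponential solution of the linear master equation,
#' computed by eigendecomposition of the generator (with a dense
#' matrix-exponential fallback for defective generators). The trajectory is
#' sampled on the requested grid; the endpoint is always included so that
#' concatenated epochs are continuous.
#'
#' @param channel a \code{nav_channel}.
#' @param state0 named state vector (gates or occupancies) at epoch start.
#' @param V clamped voltage (mV).
#' @param duration epoch length (ms), > 0.
#' @param dt sampling interval (ms), > 0. Sampling never affects the
#'   solution, only where it is recorded.
#' @param eig optional precomputed eigendecomposition (internal cache).
#' @param times optional explicit sample times (ms, increasing, from 0 to
#'   \code{duration}); overrides \code{dt}.
#' @return list with \code{t} (sample times from 0 to \code{duration}),
#'   \code{states} (matrix, one row per sample) and \code{end} (named state
#'   vector at \code{duration}).
#' @export
propagate_epoch <- function(channel, state0, V, duration, dt = 0.025,
                            eig = NULL, times = NULL) {
  stopifnot(duration > 0, dt > 0)
  if (is.null(times)) {
    tvec <- seq(0, duration, by = dt)
    if (tvec[length(tvec)] < duration) tvec <- c(tvec, duration)
  } else {
    stopifnot(!is.unsorted(times), times[1] >= 0,
              times[length(times)] <= duration)
    tvec <- times
    if (tvec[length(tvec)] < duration) tvec <- c(tvec, duration)
  }
  if (inherits(channel, "hh_channel")) {
    q10 <- q10_factor(channel$temperature)
    states <- matrix(0, length(tvec), length(channel$gates),
                     dimnames = list(NULL, names(channel$gates)))
    for (g in channel$gates) {
      it <- gate_infty_tau(g$alpha, g$beta, V, q10)
      states[, g$name] <-
        it$x_infty - (it$x_infty - state0[[g$name]]) * exp(-tvec / it$tau)
    }
  } else {
    Q <- build_generator(channel, V)
    tr <- markov_trajectory(Q, state0[channel$states], tvec, eig = eig)
    states <- t(tr)
  }
  list(t = tvec, states = states,
       end = stats::setNames(states[nrow(states), ], colnames(states)))
}

#' Macroscopic current density of a channel
#'
#' Ohmic current: \code{gbar * open_fraction * (V - E_rev)} where the open
#' fraction is the gate product (HH) or the open-state occupancy (Markov).
#' Inward current is negative for V below the reversal potential.
#'
#' @param channel a \code{nav_channel}.
#' @param state named state vector, or a matrix with one row per sample.
#' @param V voltage (mV), scalar or one per row.
#' @return current density in mA/cm^2.
#' @export
channel_current <- function(channel, state, V) {
  channel$gbar * open_fraction(channel, state) * (V - channel$E_rev)
}

#' @rdname channel_current
#' @return \code{open_fraction}: the conducting fraction in [0, 1].
#' @export
open_fraction <- function(channel, state) {
  if (is.matrix(state)) {
    if (inherits(channel, "hh_channel")) {
      out <- rep(1, nrow(state))
      for (g in channel$gates) out <- out * state[, g$name]^g$exponent
      out
    } else state[, channel$open_state]
  } else {
    if (inherits(channel, "hh_channel")) {
      prod(vapply(channel$gates,
                  function(g) state[[g$name]]^g$exponent, numeric(1)))
    } else state[[channel$open_state]]
  }
}
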