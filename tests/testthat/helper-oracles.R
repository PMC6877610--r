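# independent oracles used across the suite

# stiff ODE integration of the five-state master equation, written out
# transition by transition (independent of build_generator/propagate_epoch)
markov5_ode_oracle <- function(channel, p0, V, times) {
  q10 <- channel$temperature$q10_base ^
    ((channel$temperature$T - channel$temperature$T_base) / 10)
  r <- sapply(channel$transitions, function(tr) eval_rate_law(tr$rate, V)) * q10
  names(r) <- sapply(channel$transitions, function(tr) paste0(tr$from, tr$to))
  f <- function(t, y, parms) {
    with(as.list(c(y, r)), list(c(
      I1C1 * I1 + C2C1 * C2 - (C1C2 + C1I1) * C1,
      C1C2 * C1 + O1C2 * O1 - (C2C1 + C2O1) * C2,
      C2O1 * C2 + I1O1 * I1 - (O1C2 + O1I1) * O1,
      I2I1 * I2 + C1I1 * C1 + O1I1 * O1 - (I1C1 + I1I2 + I1O1) * I1,
      I1I2 * I1 - I2I1 * I2)))
  }
  out <- deSolve::lsoda(p0[c("C1", "C2", "O1", "I1", "I2")], times, f,
                        rtol = 1e-10, atol = 1e-12)
  out[, c("C1", "C2", "O1", "I1", "I2")]
}

# generic ODE oracle for either channel family at clamped voltage
ode_oracle_epoch <- function(channel, state0, V, times) {
  q10 <- channel$temperature$q10_base ^
    ((channel$temperature$T - channel$temperature$T_base) / 10)
  if (inherits(channel, "hh_channel")) {
    f <- function(t, y, parms) {
      list(vapply(channel$gates, function(g)
        q10 * (eval_rate_law(g$alpha, V) * (1 - y[[g$name]]) -
                 eval_rate_law(g$beta, V) * y[[g$name]]), numeric(1)))
    }
    nm <- names(channel$gates)
  } else {
    Q <- build_generator(channel, V)
    f <- function(t, y, parms) list(as.numeric(Q %*% y))
    nm <- channel$states
  }
  out <- deSolve::lsoda(state0[nm], times, f, rtol = 1e-10, atol = 1e-12)
  out[, nm, drop = FALSE]
}

# coarse grid-search least squares for the double-exponential recovery:
# amplitudes solved linearly at each tau pair
grid_search_recovery_double <- function(x, y, taus = 10^seq(-1, 4, by = 0.05)) {
  best <- NULL
  for (t1 in taus) for (t2 in taus[taus > t1]) {
    X <- cbind(1 - exp(-x / t1), 1 - exp(-x / t2))
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(cf)) next
    ssr <- sum((y - X %*% cf)^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(A1 = cf[1], tau1 = t1, A2 = cf[2], tau2 = t2, ssr = ssr)
  }
  best
}

# a minimal two-state scheme with constant rates
two_state_scheme <- function(c_close = 1, c_open = 1, T = 20, T_base = 20) {
  markov_channel(states = c("O", "C"), open_state = "O",
                 transitions = list(
                   list(from = "O", to = "C",
                        rate = rate_law("constant", A = c_close)),
                   list(from = "C", to = "O",
                        rate = rate_law("constant", A = c_open))),
                 gbar = 0.1, E_rev = 65,
                 temperature = temperature_spec(T = T, T_base = T_base))
}

# the Markov preset with some transitions removed; states not touched by any
# remaining transition are dropped so the scheme stays connected
preset_without <- function(drop) {
  mk <- nav_preset("nav15_markov")
  keep <- !sapply(mk$transitions, function(tr) paste0(tr$from, tr$to)) %in% drop
  kept <- mk$transitions[keep]
  used <- unique(unlist(lapply(kept, function(tr) c(tr$from, tr$to))))
  markov_channel(states = intersect(mk$states, used),
                 open_state = mk$open_state, transitions = kept,
                 gbar = mk$gbar, E_rev = mk$E_rev,
                 temperature = mk$temperature)
}
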