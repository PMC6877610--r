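mk <- nav_preset("nav15_markov")

test_that("the generator is conservative and carries Q10-scaled rates", {
  for (V in c(-150, -120, -65, -20, 40, 80)) {
    Q <- build_generator(mk, V)
    expect_lt(max(abs(colSums(Q))), 1e-14)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
  # I1 -> C1 entry at -120 mV, 24 C: rate law value times the Q10 factor
  Q <- build_generator(mk, -120)
  expect_equal(Q["C1", "I1"], 0.35 / (1 + exp(2 / 9)) * 3^0.4,
               tolerance = 1e-12)
  # two-state constant scheme
  Q2 <- build_generator(two_state_scheme(0.7, 0.7), 0)
  expect_equal(unname(Q2), matrix(c(-0.7, 0.7, 0.7, -0.7), 2))
})

test_that("steady states come from gate ratios and the generator null space", {
  # polarized rest puts essentially all channels in the first closed state
  ss <- steady_state(mk, -120)
  expect_gt(ss[["C1"]], 0.99)
  expect_equal(sum(ss), 1, tolerance = 1e-12)
  # the steady state is a fixed point of the dynamics
  expect_lt(max(abs(build_generator(mk, -120) %*% ss)), 1e-12)

  expect_equal(unname(steady_state(two_state_scheme(1, 1), 0)), c(0.5, 0.5))

  hh <- nav_preset("hh_squid_original")
  m40 <- steady_state(hh, -40)[["m"]]
  expect_equal(m40, 1 / (1 + 4 * exp(25 / -18)), tolerance = 1e-12)
})

test_that("disconnected schemes are rejected at construction", {
  expect_error(
    markov_channel(states = c("A", "B", "C"), open_state = "A",
                   transitions = list(list(from = "A", to = "B",
                                           rate = rate_law("constant", A = 1))),
                   temperature = temperature_spec()),
    "disconnected")
})

test_that("closed-form propagation matches the explicit five-ODE oracle", {
  skip_if_not_installed("deSolve")
  p0 <- steady_state(mk, -120)
  for (V in c(-120, -60, -20, 30)) {
    tr <- propagate_epoch(mk, p0, V, 10, dt = 0.5)
    orc <- markov5_ode_oracle(mk, p0, V, tr$t)
    expect_lt(max(abs(tr$states[, colnames(orc)] - orc)), 1e-6)
  }
})

test_that("HH gates follow the exponential relaxation closed form", {
  g <- list(name = "x", exponent = 1,
            alpha = rate_law("constant", A = 0.5),
            beta = rate_law("constant", A = 0.5))
  ch <- hh_channel(list(g), temperature = temperature_spec(T = 20))
  tr <- propagate_epoch(ch, c(x = 0), 0, 1, dt = 1)
  expect_equal(unname(tr$end[["x"]]), 0.5 * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("long propagation relaxes to the steady state", {
  p0 <- steady_state(mk, -120)
  end <- propagate_epoch(mk, p0, -20, 60000, dt = 1000)$end
  expect_lt(max(abs(end - steady_state(mk, -20))), 1e-6)
})

test_that("occupancies stay conserved and bounded over multi-epoch runs", {
  state <- steady_state(mk, -120)
  worst <- 0
  for (ep in list(c(-20, 30), c(-120, 5), c(-20, 20), c(0, 2), c(-120, 500))) {
    tr <- propagate_epoch(mk, state, ep[1], ep[2], dt = 0.25)
    worst <- max(worst, abs(rowSums(tr$states) - 1))
    expect_true(all(tr$states >= -1e-12 & tr$states <= 1 + 1e-12))
    state <- tr$end
  }
  expect_lt(worst, 1e-10)
})

test_that("propagation has the semigroup property at fixed voltage", {
  p0 <- steady_state(mk, -120)
  one <- propagate_epoch(mk, p0, -30, 7, dt = 7)$end
  a <- propagate_epoch(mk, p0, -30, 3, dt = 3)$end
  two <- propagate_epoch(mk, a, -30, 4, dt = 4)$end
  expect_lt(max(abs(one - two)), 1e-10)
})

test_that("temperature acts as a pure rescaling of time", {
  p0 <- steady_state(mk, -120)
  mk3 <- set_temperature(mk, T = 30, T_base = 20)   # q10 = 3 vs preset 3^0.4
  scale <- 3 / 3^0.4
  tv <- seq(0, 12, by = 0.4)
  base <- propagate_epoch(mk, p0, -25, 12, times = tv)
  fast <- propagate_epoch(mk3, p0, -25, 12 / scale, times = tv / scale)
  expect_lt(max(abs(base$states - fast$states)), 1e-8)
  # steady states are temperature-free
  expect_equal(steady_state(mk3, -70), steady_state(mk, -70),
               tolerance = 1e-12)
})

test_that("the open-to-inactivated transition is effectively irreversible", {
  V <- seq(-150, 80, by = 1)
  fwd <- eval_rate_law(mk$transitions[[5]]$rate, V)   # O1 -> I1
  bwd <- eval_rate_law(mk$transitions[[6]]$rate, V)   # I1 -> O1
  expect_equal(sapply(mk$transitions[5:6], function(tr)
    paste0(tr$from, tr$to)), c("O1I1", "I1O1"))
  expect_lt(max(bwd / fwd), 1e-4)
})

test_that("channel current follows Ohm's law through the open fraction", {
  st <- c(C1 = 0.5, C2 = 0.2, O1 = 0.1, I1 = 0.1, I2 = 0.1)
  expect_equal(channel_current(mk, st, -10), 0.1 * 0.1 * (-10 - 65))
  expect_equal(channel_current(mk, st, 65), 0)
  st0 <- c(C1 = 1, C2 = 0, O1 = 0, I1 = 0, I2 = 0)
  expect_equal(channel_current(mk, st0, -10), 0)
  # HH: gate product with exponents
  hh <- nav_preset("nav15_hh_row_h")
  sth <- c(m = 0.5, h = 0.8, s = 0.9)
  expect_equal(channel_current(hh, sth, -10),
               0.1 * 0.5^3 * 0.8 * 0.9 * (-75))
})
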