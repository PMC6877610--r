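test_that("zero-noise synthetic data recovers generating parameters", {
  cases <- list(
    list(model = "boltzmann", x = seq(-90, 60, 5),
         par = c(V12 = -34.1, k = -6.9)),
    list(model = "boltzmann_offset", x = seq(-120, 0, 5),
         par = c(A = 0.05, V12 = -89.5, k = 5.4)),
    list(model = "mono_exp", x = seq(0.025, 5, 0.025),
         par = c(A = -1.2, tau = 0.8)),
    list(model = "hh_m3h", x = seq(0.025, 14, 0.025),
         par = c(A = -2, tau_m = 0.5, tau_h = 2)),
    list(model = "recovery_single", x = log_grid(0.1, 1000),
         par = c(A1 = 0.95, tau1 = 5)),
    list(model = "slow_onset_exp", x = log_grid(10, 10000),
         par = c(A1 = 0.5, A2 = 0.5, tau = 1780)),
    list(model = "recovery_double", x = log_grid(0.1, 7000),
         par = c(A1 = 0.8, tau1 = 5, A2 = 0.2, tau2 = 600)))
  predict_truth <- function(model, p, x) {
    switch(model,
      boltzmann = 1 / (1 + exp((x - p["V12"]) / p["k"])),
      boltzmann_offset = p["A"] + (1 - p["A"]) /
        (1 + exp((x - p["V12"]) / p["k"])),
      mono_exp = p["A"] * exp(-x / p["tau"]),
      hh_m3h = p["A"] * (1 - exp(-x / p["tau_m"]))^3 * exp(-x / p["tau_h"]),
      recovery_single = p["A1"] * (1 - exp(-x / p["tau1"])),
      slow_onset_exp = p["A1"] + p["A2"] * exp(-x / p["tau"]),
      recovery_double = p["A1"] * (1 - exp(-x / p["tau1"])) +
        p["A2"] * (1 - exp(-x / p["tau2"])))
  }
  for (cs in cases) {
    y <- as.numeric(predict_truth(cs$model, cs$par, cs$x))
    fit <- fit_curve(cs$model, cs$x, y)
    expect_true(fit$converged, info = cs$model)
    expect_equal(fit$par[names(cs$par)], cs$par, tolerance = 1e-3,
                 info = cs$model)
    # optimality: the fitted ssr never exceeds the ssr at the truth (zero)
    expect_lte(fit$ssr, sum((y - predict_truth(cs$model, cs$par, cs$x))^2)
               + 1e-10)
    expect_lt(fit$ssr, 1e-10)
  }
})

test_that("the double-exponential fit matches a coarse grid-search oracle", {
  x <- log_grid(0.1, 7000)
  y <- 0.8 * (1 - exp(-x / 5)) + 0.2 * (1 - exp(-x / 600))
  fit <- fit_curve("recovery_double", x, y)
  orc <- grid_search_recovery_double(x, y)
  expect_lte(fit$ssr, orc$ssr + 1e-12)
  expect_equal(fit$par[["tau1"]], 5, tolerance = 0.01)
  expect_equal(fit$par[["tau2"]], 600, tolerance = 0.01)
  expect_equal(orc$tau1, 5, tolerance = 0.2)     # oracle grid is coarse
  expect_equal(orc$tau2, 600, tolerance = 0.2)
})

test_that("fit_curve reports failure through the flag, not an error", {
  expect_error(fit_curve("boltzmann", 1:2, 1:3))
  expect_error(fit_curve("mono_exp", 1, 1), "at least")
  f <- fit_curve("mono_exp", c(1, 2, 3), c(0, 0, 0))
  expect_s3_class(f, "fit_result")   # degenerate data still returns a result
})

mk <- nav_preset("nav15_markov")

test_that("activation features convert peaks through the driving force", {
  ss <- run_protocol(mk, make_protocol("activation"))
  fa <- activation_features(ss, fit_tau = TRUE)
  expect_equal(fa$features$V12, -33.30, tolerance = 0.01)
  expect_equal(fa$features$k, -7.26, tolerance = 0.01)
  gv <- fa$tables$gv
  expect_true(all(gv$used))          # grid stops 5 mV short of E_Na
  expect_equal(max(gv$G_norm, na.rm = TRUE), 1)
  # time constants: activation speeds up with depolarization
  tau <- fa$tables$tau
  expect_gt(nrow(tau), 10)
  expect_lt(tau$tau_m[nrow(tau)], tau$tau_m[1])
  # synthetic Boltzmann conductance with fixed-kinetics current recovers
  # the generator to well under 0.1 mV
  prot <- make_protocol("activation")
  v <- prot$sweep$values
  g <- 1 / (1 + exp((v + 38) / -6.5))
  t <- seq(0, 14, 0.025)
  fake <- structure(list(protocol = prot, channel = list(E_rev = 65),
    dt = 0.025, sweeps = lapply(seq_along(v), function(i) {
      I <- g[i] * (v[i] - 65) * (1 - exp(-t / 0.4))^3 * exp(-t / 3) * 0.1
      list(value = v[i], t = t, V = rep(v[i], length(t)), I = I,
           epoch = rep(2L, length(t)))
    })), class = "sweep_set")
  ffa <- activation_features(fake, fit_tau = FALSE)
  expect_equal(ffa$features$V12, -38, tolerance = 0.1)
  expect_equal(ffa$features$k, -6.5, tolerance = 0.01)
})

test_that("steady-state features are invariant under temperature changes", {
  # warmer temperatures only: at colder ones the 500 ms conditioning is no
  # longer much longer than the inactivation time constant, so the protocol
  # itself (not the features) departs from steady state
  for (Tother in c(29, 34)) {
    f24 <- availability_features(run_protocol(mk, make_protocol("availability")))
    fT <- availability_features(run_protocol(set_temperature(mk, T = Tother),
                                             make_protocol("availability")))
    expect_lt(abs(f24$features$V12 - fT$features$V12), 0.05)
    expect_lt(abs(f24$features$k - fT$features$k), 0.05)
    a24 <- activation_features(run_protocol(mk, make_protocol("activation")),
                               fit_tau = FALSE)
    aT <- activation_features(
      run_protocol(set_temperature(mk, T = Tother),
                   make_protocol("activation")), fit_tau = FALSE)
    expect_lt(abs(a24$features$V12 - aT$features$V12), 0.05)
  }
})

test_that("feature extraction is pure", {
  ss <- run_protocol(mk, make_protocol("availability"))
  expect_identical(availability_features(ss), availability_features(ss))
})

test_that("a channel without inactivation yields a flagged flat availability", {
  noin <- preset_without(c("C1I1", "O1I1", "I1O1", "I1C1", "I1I2", "I2I1"))
  expect_equal(noin$states, c("C1", "C2", "O1"))
  fs <- availability_features(run_protocol(noin, make_protocol("availability")))
  expect_match(fs$flags, "degenerate")
  expect_equal(fs$features$A, 1)
})

test_that("removing the deep inactivated state flattens the onset curve", {
  no_i2 <- preset_without(c("I1I2", "I2I1"))
  fs <- slow_onset_features(run_protocol(no_i2, make_protocol("slow_onset")))
  expect_match(fs$flags, "degenerate")
  expect_gt(fs$features$plateau, 0.97)
})

test_that("slow-onset plateau matches the steady-state non-I2 fraction", {
  fs <- slow_onset_features(run_protocol(mk, make_protocol("slow_onset")))
  non_i2 <- 1 - steady_state(mk, -20)[["I2"]]
  expect_lt(abs(fs$features$plateau - non_i2), 0.05)
})

test_that("slow-recovery tau2 matches the slow eigenvalue of the generator", {
  fs <- repriming_features(run_protocol(mk, make_protocol("slow_repriming")),
                           "slow")
  ev <- eigen(build_generator(mk, -120), only.values = TRUE)$values
  lam_slow <- sort(abs(Re(ev[abs(ev) > 1e-12])))[1]
  expect_equal(fs$features$tau2 * lam_slow, 1, tolerance = 0.05)
})

test_that("deactivation tails decay at the closed-form rate", {
  # constant-rate two-state pair: tau is exactly 1/((open+close) * q10)
  ch <- two_state_scheme(1.2, 1e-9, T = 30, T_base = 20)   # q10 = 3
  tr <- propagate_epoch(ch, c(O = 1, C = 0), -100, 4, dt = 0.025)
  I <- channel_current(ch, tr$states, -100)
  f <- fit_curve("mono_exp", tr$t[-1], I[-1])
  expect_equal(f$par[["tau"]], 1 / (1.2 * 3), tolerance = 1e-6)

  # full protocol on the kinetic preset: tails shorten with hyperpolarization
  fs <- deactivation_features(run_protocol(mk, make_protocol("deactivation")))
  tau <- fs$tables$tau
  expect_true(all(diff(tau$tau[tau$V <= -50]) >= 0))

  # HH tails decay at about three times the gate relaxation rate (m^3)
  hh <- nav_preset("nav15_hh_row_d")
  fh <- deactivation_features(run_protocol(hh, make_protocol("deactivation")))
  q10 <- q10_factor(hh$temperature)
  g <- hh$gates$m
  pred <- 1 / (3 * (eval_rate_law(g$alpha, -100) +
                      eval_rate_law(g$beta, -100)) * q10)
  got <- fh$tables$tau$tau[fh$tables$tau$V == -100]
  expect_equal(got, pred, tolerance = 0.15)
})
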