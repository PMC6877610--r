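mk <- nav_preset("nav15_markov")

test_that("protocol presets encode the published sweep families", {
  act <- make_protocol("activation")
  expect_equal(length(act$sweep$values), 31)
  expect_equal(range(act$sweep$values), c(-90, 60))
  de <- make_protocol("deactivation")
  expect_equal(length(de$sweep$values), 8)
  av <- make_protocol("availability")
  expect_equal(length(av$sweep$values), 25)
  expect_equal(av$epochs[[1]]$dur, 500)
  fr <- make_protocol("fast_repriming", recovery_V = -100)
  expect_equal(fr$epochs[[2]]$V, -100)
  expect_equal(range(fr$sweep$values), c(0.1, 1000))
  expect_equal(length(fr$sweep$values), 33)   # 8 per decade inclusive
  so <- make_protocol("slow_onset")
  expect_equal(range(so$sweep$values), c(10, 10000))
  expect_error(make_protocol("activation", sweep_values = c(1, 1, 2)),
               "monotone")
  expect_error(make_protocol("nonexistent"))
})

test_that("run_protocol is deterministic and respects the clamp structure", {
  a <- run_protocol(mk, make_protocol("deactivation"))
  b <- run_protocol(mk, make_protocol("deactivation"))
  expect_identical(a, b)
  sw <- a$sweeps[[1]]
  # piecewise-constant command voltage matching the epochs
  expect_equal(unique(sw$V[sw$epoch == 1]), -120)
  expect_equal(unique(sw$V[sw$epoch == 2]), -10)
  expect_equal(unique(sw$V[sw$epoch == 3]), -100)
  # initial state is the holding steady state
  expect_equal(sw$states[1, ], steady_state(mk, -120), tolerance = 1e-12)
  # long-format export
  df <- as.data.frame(a)
  expect_true(all(c("sweep_id", "t_ms", "V_mV", "I_mA_cm2", "O1") %in%
                    names(df)))
  expect_equal(nrow(df), sum(sapply(a$sweeps, function(s) length(s$t))))
})

test_that("a test step at the reversal potential carries zero current", {
  ss <- run_protocol(mk, make_protocol("activation",
                                       sweep_values = c(0, 65)))
  sw <- ss$sweeps[[2]]
  expect_true(all(abs(sw$I[sw$epoch == 2]) < 1e-15))
  expect_true(peak_current(sw, 2)$flagged)
})

test_that("peak_current guards the step discontinuity and flags zero traces", {
  t <- seq(0, 14, by = 0.025)
  tau_m <- 0.5; tau_h <- 2
  sweep <- list(value = -20, t = t, V = rep(-20, length(t)),
                I = -(1 - exp(-t / tau_m))^3 * exp(-t / tau_h),
                epoch = rep(1L, length(t)))
  pk <- peak_current(sweep, 1)
  t_star <- tau_m * log((tau_m + 3 * tau_h) / tau_m)  # analytic maximizer
  expect_lt(abs(pk$t_peak - t_star), 0.025 + 1e-12)
  expect_false(pk$flagged)

  # monotone decay peaks at the first admissible sample
  dec <- list(value = 0, t = t, V = rep(0, length(t)),
              I = -exp(-t / 3), epoch = rep(1L, length(t)))
  expect_equal(peak_current(dec, 1)$t_peak, 0.025)

  zero <- list(value = 0, t = t, V = t * 0, I = t * 0,
               epoch = rep(1L, length(t)))
  pz <- peak_current(zero, 1)
  expect_true(pz$flagged)
  expect_equal(pz$I_peak, 0)
  expect_error(peak_current(zero, 3), "not present")
})

test_that("availability peaks fall monotonically with conditioning voltage", {
  for (ch in list(mk, nav_preset("nav15_hh_variant_c"))) {
    pk <- sweep_peaks(run_protocol(ch, make_protocol("availability")), 2)
    expect_true(all(diff(abs(pk$I_peak)) <= 1e-9))
    # the -120 mV conditioning sweep carries the maximal peak
    expect_equal(which.max(abs(pk$I_peak)), 1)
  }
})

test_that("repriming ratios are bounded and monotone for both families", {
  for (ch in list(mk, nav_preset("nav15_hh_variant_c"))) {
    ss <- run_protocol(ch, make_protocol("fast_repriming", per_decade = 4))
    p1 <- sweep_peaks(ss, 1); p2 <- sweep_peaks(ss, 3)
    ratio <- abs(p2$I_peak) / abs(p1$I_peak)
    expect_true(all(ratio >= 0 & ratio <= 1 + 1e-6))
    # non-decreasing throughout; strictly rising until saturation
    expect_true(all(diff(ratio) > -1e-9))
    expect_true(all(diff(ratio[ratio < 0.99]) > 0))
  }
})

test_that("peak conductance of activation sweeps is temperature-invariant", {
  # steady-state/peak features must not depend on the Q10 factor
  pk1 <- sweep_peaks(run_protocol(mk, make_protocol("activation")), 2)
  pk2 <- sweep_peaks(run_protocol(set_temperature(mk, T = 14),
                                  make_protocol("activation")), 2)
  G1 <- pk1$I_peak / (pk1$sweep_value - 65)
  G2 <- pk2$I_peak / (pk2$sweep_value - 65)
  expect_equal(G1, G2, tolerance = 2e-3)
})
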