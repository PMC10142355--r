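test_that("outward traces factorize exactly and saturate at p_act * damping", {
  for (phi in c(-30, 10, 30)) {
    tr <- outward_current(phi, duration = 0.05, dt = 1e-5, scale = 2)
    expect_true(all(tr$current >= 0))
    expect_identical(tr$current[1L], 0)
    expect_true(all(diff(tr$current) >= 0))
    # exact factorization: trace / (scale * theta * p * damping) == S
    expect_lt(max(abs(tr$current / (2 * tr$p * tr$damping) - tr$S)), 1e-12)
    lim <- 2 * tr$p * tr$damping
    expect_equal(tr$current[length(tr$current)], lim, tolerance = 5e-3)
  }
  # hand arithmetic at +30 mV with unit scale: 0.9657 * 0.1888
  tr30 <- outward_current(30, duration = 0.05, dt = 1e-5)
  expect_equal(tr30$current[length(tr30$current)], 0.1823, tolerance = 1e-3)
})

test_that("outward trace is identically zero with a warning when damping vanishes", {
  expect_warning(tr <- outward_current(60, duration = 0.01, dt = 1e-5),
                 "identically zero")
  expect_true(all(tr$current == 0))
  # closed channel at the holding potential
  hold <- outward_current(-110, duration = 0.01, dt = 1e-5)
  expect_lt(max(abs(hold$current)), 1e-6)
})

test_that("inward traces vanish at both ends with the predicted interior peak factor", {
  # fine grid to resolve the fast rise for the peak-factor comparison
  tr <- inward_current(30, duration = 1e-3, dt = 1e-7, k_h = 1, scale = 1.5)
  expect_true(all(tr$current <= 0))
  expect_identical(tr$current[1L], 0)
  pk <- peak_and_time(tr)
  expect_gt(pk$time, 0)
  expect_lt(pk$time, 1e-3)
  # the slow algebraic tail needs a long pulse to fade out
  long <- inward_current(30, duration = 0.05, dt = 1e-5, k_h = 1)
  expect_lt(abs(long$current[length(long$current)]),
            0.01 * abs(peak_and_time(long)$peak))
  orc <- oracle_peak_factor(1)
  expect_equal(orc$gmax, 0.199, tolerance = 3e-3)
  expect_equal(orc$S_at, 0.557, tolerance = 1e-3)
  expect_lt(abs(abs(pk$peak) / (1.5 * tr$p) - orc$gmax), 1e-3)
  expect_error(inward_current(30, duration = 1e-3, dt = 1e-7, k_h = -1),
               "k_h")
})

test_that("normalized inward peak factor increases with the blocker constant", {
  khs <- c(0.5, 1, 2, 4)
  grid_fac <- sapply(khs, function(k) oracle_peak_factor(k, n = 1e5)$gmax)
  trace_fac <- sapply(khs, function(k) {
    tr <- inward_current(30, duration = 1e-3, dt = 1e-7, k_h = k)
    abs(peak_and_time(tr)$peak) / tr$p
  })
  expect_true(all(diff(grid_fac) > 0))
  expect_true(all(diff(trace_fac) > 0))
  expect_equal(trace_fac, grid_fac, tolerance = 1e-2)
  # magnitude bound: |I| <= scale * p * (1 - exp(-k_h)) everywhere
  for (k in khs) {
    tr <- inward_current(10, duration = 0.01, dt = 1e-6, k_h = k)
    expect_true(all(abs(tr$current) <= tr$p * (1 - exp(-k)) + 1e-12))
  }
})

test_that("current families share a grid and preserve the expected orderings", {
  proto <- voltage_step_protocol(duration = 0.05, dt = 1e-5)
  out_fam <- current_family(proto, "outward")
  expect_length(out_fam$traces, 5L)
  for (tr in out_fam$traces)
    expect_identical(tr$times, out_fam$traces[[1L]]$times)
  ends <- sapply(out_fam$traces, function(tr) tr$current[length(tr$current)])
  prods <- sapply(out_fam$traces, function(tr) tr$p * tr$damping)
  expect_identical(order(ends), order(prods))
  # bell shape: the +30 mV limit is below the family maximum over phi
  expect_lt(ends[5L], max(ends))
  in_fam <- current_family(proto, "inward")
  peaks <- sapply(in_fam$traces, function(tr) abs(peak_and_time(tr)$peak))
  expect_true(all(diff(peaks) > 0))  # increasing with depolarization
  expect_error(voltage_step_protocol(phi_steps = numeric()), "non-empty")
})

test_that("scale acts linearly on every sample", {
  a <- outward_current(10, duration = 0.01, dt = 1e-5, scale = 1)
  b <- outward_current(10, duration = 0.01, dt = 1e-5, scale = 2)
  expect_identical(b$current, 2 * a$current)
  ia <- inward_current(10, duration = 0.01, dt = 1e-5, scale = 1)
  ib <- inward_current(10, duration = 0.01, dt = 1e-5, scale = 3)
  expect_identical(ib$current, 3 * ia$current)
})

test_that("inactivation correction scales inward traces by the recovery fraction", {
  tr <- inward_current(-82, duration = 0.05, dt = 1e-5)
  cor <- apply_inactivation_correction(tr)
  expect_equal(cor$current, 0.5 * tr$current)  # Boltzmann midpoint
  hi <- inward_current(30, duration = 0.01, dt = 1e-5)
  cor_hi <- apply_inactivation_correction(hi)
  fac_hi <- 1 - eval_boltzmann(herg_curves()$inactivation, 30)
  expect_gt(fac_hi, 0.99)  # correction negligible when depolarized
  expect_equal(cor_hi$current, fac_hi * hi$current)
  lo <- inward_current(-200, duration = 0.05, dt = 1e-5)
  expect_lt(max(abs(apply_inactivation_correction(lo)$current)),
            0.01 * max(abs(lo$current), 1e-300))
  out <- outward_current(10, duration = 0.01, dt = 1e-5)
  expect_error(apply_inactivation_correction(out), "inward")
})

test_that("peak_and_time follows the sign convention and flags flat traces", {
  out <- outward_current(10, duration = 0.01, dt = 1e-5)
  pk <- peak_and_time(out)
  expect_identical(pk$time, out$times[length(out$times)])  # monotone rise
  expect_false(pk$flat)
  zero <- suppressWarnings(outward_current(60, duration = 0.01, dt = 1e-5))
  expect_identical(peak_and_time(zero), list(peak = 0, time = 0, flat = TRUE))
})
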