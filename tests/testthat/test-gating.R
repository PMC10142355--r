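test_that("gating derivatives vanish in the closed, saturated and empty limits", {
  rates <- kinetic_rates()
  # empty membrane: only nucleation is active
  d0 <- gating_derivatives(c(S = 0, S_x = 0, f2 = 0, f3 = 0), p = 0.7, rates)
  expect_equal(unname(d0), c(0, 0, 0, rates$k_N * 0.7 * rates$theta))
  # closed channel: p = 0 freezes everything
  d1 <- gating_derivatives(c(S = 0.3, S_x = 0.5, f2 = 2, f3 = 4), p = 0, rates)
  expect_equal(unname(d1), rep(0, 4L))
  # saturation: S = 1 gives f1 = 0
  d2 <- gating_derivatives(c(S = 1, S_x = 9, f2 = 2, f3 = 4), p = 1, rates)
  expect_equal(unname(d2), rep(0, 4L))
  expect_error(gating_derivatives(c(S = -0.1, S_x = 0, f2 = 0, f3 = 0), 0.5),
               "state")
  expect_error(gating_derivatives(c(S = 0, S_x = 0, f2 = 0, f3 = 0), 1.5),
               "p")
})

test_that("trajectories satisfy the Avrami identity and monotone saturation at every step potential", {
  for (phi in c(-50, -30, -10, 10, 30)) {
    tr <- solve_gating(phi = phi, duration = 0.05, dt = 2e-6,
                       check_convergence = FALSE)
    expect_lt(max(abs(tr$S - (1 - exp(-tr$S_x)))), 1e-6)
    expect_identical(tr$S[1L], 0)
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(diff(tr$S) >= 0))
    expect_true(all(tr$dS_dt >= 0))
    expect_true(all(tr$S <= 1))
    expect_gt(tr$S[length(tr$S)], 0.97)  # S -> 1 for any p > 0
  }
  # frozen channel at far-negative potential
  frozen <- solve_gating(phi = -110, duration = 0.05, dt = 1e-5,
                         check_convergence = FALSE)
  expect_lt(frozen$S[length(frozen$S)], 1e-4)
})

test_that("short-time behaviour follows the cubic aggregation law in its asymptotic regime", {
  st <- solve_gating(p = 1, rates = kinetic_rates(), duration = 2.2e-5,
                     dt = 1e-8, check_convergence = FALSE)
  cubic <- (pi / 3) * 1e12 * st$times^3
  # hand value at t = 1e-5 s: (pi/3)*1e12*(1e-5)^3 = 1.047e-3
  i <- which.min(abs(st$times - 1e-5))
  expect_equal(st$S[i], 1.047e-3, tolerance = 5e-3)
  # within the asymptotic window the law holds to 1%; its error grows
  # like (5/4)S, so the window is bounded away from S = 1e-2
  sel <- st$S > 1e-6 & st$S < 5e-3
  expect_gt(sum(sel), 100L)
  expect_lt(max(abs(st$S[sel] - cubic[sel]) / st$S[sel]), 0.01)
  # and the ratio tends to 1 as S -> 0
  first <- which(st$S > 1e-6)[1L]
  expect_equal(st$S[first] / cubic[first], 1, tolerance = 1e-3)
})

test_that("time to half-saturation is non-increasing in the open probability", {
  t_half <- sapply(seq(0.1, 1, by = 0.1), function(p) {
    tr <- solve_gating(p = p, duration = 0.02, dt = 2e-6,
                       check_convergence = FALSE)
    tr$times[which(tr$S >= 0.5)[1L]]
  })
  expect_true(all(is.finite(t_half)))
  expect_true(all(diff(t_half) <= 0))
})

test_that("fixed-step RK4 matches an independent adaptive ODE solution", {
  for (phi in c(-30, 10)) {
    tr <- solve_gating(phi = phi, duration = 0.05, dt = 1e-5,
                       check_convergence = FALSE)
    p <- eval_boltzmann(herg_curves()$activation, phi)
    orc <- oracle_gating_lsoda(p, tr$rates, tr$times)
    expect_lt(max(abs(tr$S - orc$S)), 1e-5)
  }
})

test_that("jointly rescaling k_N and k_R rescales time exactly", {
  a <- 10
  base <- solve_gating(p = 0.5, rates = kinetic_rates(1e2, 1e5),
                       duration = 0.02, dt = 2e-6,
                       check_convergence = FALSE)
  fast <- solve_gating(p = 0.5, rates = kinetic_rates(a * 1e2, a * 1e5),
                       duration = 0.02 / a, dt = 2e-6 / a,
                       check_convergence = FALSE)
  expect_equal(fast$S, base$S, tolerance = 1e-10)
  expect_equal(fast$S_x, base$S_x, tolerance = 1e-10)
})

test_that("solver validates inputs and reports its convergence diagnostic", {
  expect_error(solve_gating(phi = -10, duration = 0.05, dt = 0.01),
               "duration/100")
  expect_error(solve_gating(duration = 0.05), "phi")
  expect_error(solve_gating(phi = NaN, duration = 0.05), "finite")
  tr <- solve_gating(phi = -10, duration = 0.05, dt = 1e-5)
  expect_true(tr$converged)
  expect_lt(tr$step_halving_delta, 1e-6)
  off <- solve_gating(phi = -10, duration = 0.05, dt = 1e-5,
                      check_convergence = FALSE)
  expect_identical(off$converged, NA)
})

test_that("gating current integrates back to the charge moved and starts at zero", {
  tr <- solve_gating(phi = -10, duration = 0.05, dt = 2e-6,
                     check_convergence = FALSE)
  gc <- gating_current(tr)
  expect_identical(gc$dS_dt[1L], 0)  # no clusters yet at t = 0
  expect_lt(abs(gating_charge(tr) - tr$S[length(tr$S)]), 1e-8)
  expect_identical(n_interior_modes(tr$dS_dt), 1L)  # unimodal transient
})

test_that("square-wave pulse yields a biphasic gating current with balanced charge", {
  sw <- square_wave_gating(-110, -10, step_duration = 0.3, dt = 1e-5)
  expect_true(all(sw$current[sw$segment == "on"] >= 0))
  expect_true(all(sw$current[sw$segment == "off"] <= 0))
  expect_gt(max(sw$current), 0)
  expect_lt(min(sw$current), 0)
  expect_equal(abs(sw$charge_off), sw$charge_on, tolerance = 1e-4)
  expect_equal(sw$charge_on, sw$on$S[length(sw$on$S)])
  # no perturbation, no gating current
  flat <- square_wave_gating(-110, -110, step_duration = 0.05, dt = 1e-5)
  expect_true(all(flat$current == 0))
})
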