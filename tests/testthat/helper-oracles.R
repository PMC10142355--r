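# Independent oracles used across the suite.

# Adaptive-step solution of the gating system via deSolve::lsoda,
# independent of the package's fixed-step RK4.
oracle_gating_lsoda <- function(p, rates, times) {
  rhs <- function(t, y, parms) {
    f1 <- parms[["theta"]] * (1 - y[1L])
    dSx <- 2 * pi * parms[["k_R"]] * parms[["p"]] * f1 * y[3L]
    list(c((1 - y[1L]) * dSx, dSx,
           parms[["k_R"]] * parms[["p"]] * f1 * y[4L],
           parms[["k_N"]] * parms[["p"]] * f1))
  }
  out <- deSolve::lsoda(c(0, 0, 0, 0), times, rhs,
                        c(k_N = rates$k_N, k_R = rates$k_R,
                          theta = rates$theta, p = p),
                        rtol = 1e-10, atol = 1e-12)
  list(S = out[, 2L], S_x = out[, 3L])
}

# Brute-force 1-D maximization of the normalized inward-current shape
# factor g(S) = S * (1 - exp(-k_h * (1 - S))) over S in [0, 1].
oracle_peak_factor <- function(k_h, n = 1e6) {
  S <- seq(0, 1, length.out = n + 1L)
  g <- S * (1 - exp(-k_h * (1 - S)))
  list(gmax = max(g), S_at = S[which.max(g)])
}

default_inward_protocol <- function()
  voltage_step_protocol(duration = 0.05, dt = 1e-5)

# number of strict slope sign changes, ignoring a near-zero tail
n_interior_modes <- function(y, eps = 1e-12) {
  keep <- abs(y) > eps * max(abs(y))
  sum(diff(sign(diff(y[keep]))) != 0)
}
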