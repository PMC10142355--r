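#' Step-voltage protocol
#'
#' A family of depolarising steps from one holding potential.  Defaults
#' are the standard hERG set: hold at -110 mV, steps at -50, -30, -10,
#' +10 and +30 mV, 50 ms per step sampled at 10 us.
#'
#' @param phi_hold holding potential, mV.
#' @param phi_steps step potentials, mV; non-empty.
#' @param duration step length in seconds, > 0.
#' @param dt sample interval in seconds.
#' @return An object of class `"voltage_step_protocol"`.
#' @export
voltage_step_protocol <- function(phi_hold = -110,
                                  phi_steps = c(-50, -30, -10, 10, 30),
                                  duration = 0.05, dt = duration / 5000) {
  if (length(phi_steps) == 0L)
    stop("'phi_steps' must be non-empty", call. = FALSE)
  stopifnot(is.numeric(phi_hold), length(phi_hold) == 1L,
            is.numeric(phi_steps), all(is.finite(phi_steps)),
            is.numeric(duration), duration > 0, dt > 0)
  structure(list(phi_hold = phi_hold, phi_steps = phi_steps,
                 duration = duration, dt = dt),
            class = "voltage_step_protocol")
}

#' @export
print.voltage_step_protocol <- function(x, ...) {
  cat(sprintf(
    "Step protocol: hold %g mV, steps {%s} mV, %g s @ dt = %g s\n",
    x$phi_hold, paste(x$phi_steps, collapse = ", "), x$duration, x$dt))
  invisible(x)
}

new_current_trace <- function(times, current, phi, direction, scale,
                              rates, k_h = NA_real_, p = NA_real_,
                              damping = NA_real_, S = NULL) {
  structure(list(times = times, current = current, phi = phi,
                 direction = direction, scale = scale, rates = rates,
                 k_h = k_h, p = p, damping = damping, S = S),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  pk <- peak_and_time(x)
  cat(sprintf(
    "%s current trace: phi = %g mV, %d samples over %g s\n",
    x$direction, x$phi, length(x$times), x$times[length(x$times)]))
  cat(sprintf("  peak %.6g a.u. at t = %.4g s (scale = %g)\n",
              pk$peak, pk$time, x$scale))
  invisible(x)
}

#' @export
plot.current_trace <- function(x, ...) {
  graphics::plot(x$times, x$current, type = "l", xlab = "time (s)",
                 ylab = "current (a.u.)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Outward potassium current at one step potential
#'
#' The outward current is proportional to the coverage by open ('out')
#' subunits, damped by fast inactivation:
#' \deqn{I_{out}(t) = \mathrm{scale}\;\theta\, p_{act}(\phi)\, S(t)
#'       \times y(\phi),}
#' where `p_act` is the steady-state activation curve (used both to
#' drive the gating ODE and as the algebraic prefactor), `S(t)` the
#' normalized gating charge from [solve_gating()], and `y` the
#' fast-inactivation [damping_factor()].  Traces are non-negative, start
#' at 0 and rise monotonically to `scale * theta * p_act * y`.
#'
#' @param phi step potential, mV.
#' @param rates a [kinetic_rates()] object.
#' @param duration pulse length in seconds.
#' @param dt time step in seconds.
#' @param scale amplitude conversion factor (arbitrary units), default 1.
#' @param curve activation [boltzmann_curve()].
#' @param damping a [damping_line()].
#' @return A `"current_trace"` object (direction `"outward"`).
#' @examples
#' tr <- outward_current(30, duration = 0.02, dt = 1e-5)
#' utils::tail(tr$current, 1)  # ~ p_act(30) * damping(30) = 0.182
#' @export
outward_current <- function(phi, rates = kinetic_rates(), duration = 0.05,
                            dt = duration / 5000, scale = 1,
                            curve = herg_curves()$activation,
                            damping = damping_line()) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  d <- suppressWarnings(damping_factor(phi, damping))
  if (d <= 0)
    warning(sprintf(
      "damping factor is 0 at phi = %g mV; outward trace is identically zero",
      phi), call. = FALSE)
  traj <- solve_gating(phi = phi, curve = curve, rates = rates,
                       duration = duration, dt = dt,
                       check_convergence = FALSE)
  cur <- scale * (rates$theta * traj$p * traj$S * d)
  new_current_trace(traj$times, cur, phi, "outward", scale, rates,
                    p = traj$p, damping = d, S = traj$S)
}

#' Inward potassium current at one step potential
#'
#' The inward current combines the open coverage with the driving force
#' of slow deactivation by the endogenous blocker (the channel's
#' N-terminal domain progressively plugging the pore):
#' \deqn{I_{in}(t) = -\mathrm{scale}\;\theta\, p_{in}(\phi)\, S(t)
#'       \left(1 - e^{-k_h (1 - S(t))}\right),}
#' with `p_in` the open probability of the inward current (driving both
#' the ODE and the prefactor) and `k_h` the dimensionless decay constant
#' of the blocker interaction.  The trace is <= 0, vanishes at t = 0 and
#' as S -> 1, with an interior peak (at S ~ 0.557 and normalized peak
#' factor ~ 0.199 for k_h = 1).
#'
#' @param phi step potential, mV.
#' @param rates a [kinetic_rates()] object.
#' @param k_h blocker decay constant, dimensionless, > 0; default 1.
#' @param duration pulse length in seconds.
#' @param dt time step in seconds.
#' @param scale amplitude conversion factor, default 1.
#' @param curve inward open-probability [boltzmann_curve()].
#' @return A `"current_trace"` object (direction `"inward"`).
#' @export
inward_current <- function(phi, rates = kinetic_rates(), k_h = 1,
                           duration = 0.05, dt = duration / 5000,
                           scale = 1,
                           curve = herg_curves()$inward_open_probability) {
  if (!is.numeric(k_h) || length(k_h) != 1L || !is.finite(k_h) || k_h <= 0)
    stop("'k_h' must be a positive scalar", call. = FALSE)
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  traj <- solve_gating(phi = phi, curve = curve, rates = rates,
                       duration = duration, dt = dt,
                       check_convergence = FALSE)
  cur <- -scale * (rates$theta * traj$p * traj$S *
                     (1 - exp(-k_h * (1 - traj$S))))
  new_current_trace(traj$times, cur, phi, "inward", scale, rates,
                    k_h = k_h, p = traj$p, S = traj$S)
}

#' Family of current traces over a step protocol
#'
#' One [outward_current()] or [inward_current()] trace per step
#' potential, on a shared time grid.
#'
#' @param protocol a [voltage_step_protocol()].
#' @param direction `"outward"` or `"inward"`.
#' @param rates a [kinetic_rates()] object.
#' @param k_h blocker decay constant (inward only).
#' @param scale amplitude conversion factor.
#' @return An object of class `"current_family"`: list of traces plus
#'   the protocol.
#' @examples
#' fam <- current_family(voltage_step_protocol(duration = 0.02),
#'                       direction = "inward")
#' sapply(fam$traces, function(tr) peak_and_time(tr)$peak)
#' @export
current_family <- function(protocol = voltage_step_protocol(),
                           direction = c("outward", "inward"),
                           rates = kinetic_rates(), k_h = 1, scale = 1) {
  stopifnot(inherits(protocol, "voltage_step_protocol"))
  direction <- match.arg(direction)
  traces <- lapply(protocol$phi_steps, function(phi) {
    if (direction == "outward")
      outward_current(phi, rates, protocol$duration, protocol$dt, scale)
    else
      inward_current(phi, rates, k_h, protocol$duration, protocol$dt, scale)
  })
  structure(list(traces = traces, protocol = protocol,
                 direction = direction, rates = rates, k_h = k_h,
                 scale = scale),
            class = "current_family")
}

#' @export
print.current_family <- function(x, ...) {
  cat(sprintf("%s current family, %d traces:\n", x$direction,
              length(x$traces)))
  for (tr in x$traces) {
    pk <- peak_and_time(tr)
    cat(sprintf("  phi = %+4g mV: peak %+.5g a.u. at t = %.4g s\n",
                tr$phi, pk$peak, pk$time))
  }
  invisible(x)
}

#' @export
plot.current_family <- function(x, col = seq_along(x$traces), ...) {
  rng <- range(unlist(lapply(x$traces, `[[`, "current")))
  graphics::plot(NA, xlim = range(x$traces[[1L]]$times), ylim = rng,
                 xlab = "time (s)", ylab = "current (a.u.)", ...)
  for (i in seq_along(x$traces))
    graphics::lines(x$traces[[i]]$times, x$traces[[i]]$current,
                    col = col[(i - 1L) %% length(col) + 1L])
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", bty = "n", lty = 1, col = col,
                   legend = sprintf("%+g mV", x$protocol$phi_steps))
  invisible(x)
}

#' Optional steady-state inactivation correction for inward traces
#'
#' The recovery from inactivation is incomplete at negative potentials;
#' the fraction lost can be removed from inward currents estimated upon
#' ignoring it by scaling with `1 - p_inact(phi)` where `p_inact` is the
#' steady-state inactivation curve (which tends to 1 at far negative
#' potentials).  Disabled by default in all simulations: at the
#' potentials where the channel conducts, the inactivation curve is
#' already small, and the correction is exposed as an explicit optional
#' step rather than applied silently.
#'
#' @param trace an inward `"current_trace"`.
#' @param inactivation the steady-state inactivation [boltzmann_curve()].
#' @return The corrected trace (same class).
#' @export
apply_inactivation_correction <- function(trace,
    inactivation = herg_curves()$inactivation) {
  stopifnot(inherits(trace, "current_trace"))
  if (!identical(trace$direction, "inward"))
    stop("inactivation correction applies to inward traces only",
         call. = FALSE)
  factor <- 1 - eval_boltzmann(inactivation, trace$phi)
  trace$current <- trace$current * factor
  trace
}

#' Peak value and time of a current trace
#'
#' The extremum under the trace's sign convention (maximum for outward,
#' minimum for inward); ties are broken toward the earliest time.  An
#' all-zero trace returns `(0, 0)` with `flat = TRUE`.
#'
#' @param trace a `"current_trace"`.
#' @return List with `peak` (signed, a.u.), `time` (s) and `flat`.
#' @export
peak_and_time <- function(trace) {
  stopifnot(inherits(trace, "current_trace"),
            length(trace$times) > 0L)
  if (all(trace$current == 0))
    return(list(peak = 0, time = 0, flat = TRUE))
  i <- if (identical(trace$direction, "inward"))
    which.min(trace$current) else which.max(trace$current)
  list(peak = trace$current[i], time = trace$times[i], flat = FALSE)
}
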