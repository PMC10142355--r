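#' Boltzmann steady-state probability curve
#'
#' Constructs a single-gate Boltzmann sigmoid used as a steady-state open
#' probability in voltage-clamp electrophysiology.  The curve is
#' parameterised by an effective gating valence `z` (in elementary
#' charges), a half-activation potential `phi_half` (mV) and a thermal
#' voltage (mV, kT/e at the recording temperature).  `orientation`
#' decides whether the probability rises (`"increasing"`, e.g. an
#' activation curve) or falls (`"decreasing"`, e.g. a steady-state
#' inactivation curve measured as relative inactivation) with
#' depolarisation.
#'
#' The increasing form is \eqn{p(\phi) = 1/(1 + e^{-z(\phi -
#' \phi_{1/2})/V_T})}; the decreasing form flips the sign in the
#' exponent.  Both evaluate to exactly 0.5 at `phi_half`.  The equivalent
#' pre-exponential parameterisation \eqn{a = e^{-z\phi_{1/2}/V_T}} (so
#' that \eqn{p = 1/(1 + e^{-z\phi/V_T}/a)} for the increasing form) is
#' available through [boltzmann_prefactor()].
#'
#' @param z effective gating valence, dimensionless, > 0.
#' @param phi_half half-activation potential in mV.
#' @param thermal_voltage thermal voltage kT/e in mV; default 25.6.
#' @param orientation `"increasing"` or `"decreasing"` with potential.
#' @param label free-text label carried along for printing.
#' @return An object of class `"boltzmann_curve"`.
#' @seealso [eval_boltzmann()], [boltzmann_prefactor()], [herg_curves()]
#' @examples
#' act <- boltzmann_curve(z = 2.4, phi_half = -5.6, label = "activation")
#' eval_boltzmann(act, c(-5.6, 0, 30))
#' @export
boltzmann_curve <- function(z, phi_half, thermal_voltage = 25.6,
                            orientation = c("increasing", "decreasing"),
                            label = "") {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z), z > 0,
            is.numeric(phi_half), length(phi_half) == 1L, is.finite(phi_half),
            is.numeric(thermal_voltage), length(thermal_voltage) == 1L,
            is.finite(thermal_voltage), thermal_voltage > 0)
  structure(list(z = z, phi_half = phi_half,
                 thermal_voltage = thermal_voltage,
                 orientation = orientation, label = as.character(label)[1L]),
            class = "boltzmann_curve")
}

#' @export
print.boltzmann_curve <- function(x, ...) {
  cat("Boltzmann curve", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat(sprintf("  z = %g e0, phi_1/2 = %g mV, V_T = %g mV, %s with potential\n",
              x$z, x$phi_half, x$thermal_voltage, x$orientation))
  cat(sprintf("  prefactor a = exp(-z*phi_1/2/V_T) = %.4g\n",
              boltzmann_prefactor(x)))
  invisible(x)
}

#' Evaluate a Boltzmann curve at one or more potentials
#'
#' @param curve a [boltzmann_curve()].
#' @param phi transmembrane potential(s) in mV; must be finite.
#' @return Probabilities in (0, 1), same length as `phi`.
#' @examples
#' eval_boltzmann(herg_curves()$activation, 30)
#' @export
eval_boltzmann <- function(curve, phi) {
  stopifnot(inherits(curve, "boltzmann_curve"))
  if (!is.numeric(phi) || length(phi) == 0L || any(!is.finite(phi)))
    stop("'phi' must be finite numeric potential(s) in mV", call. = FALSE)
  sgn <- if (curve$orientation == "increasing") -1 else 1
  1 / (1 + exp(sgn * curve$z * (phi - curve$phi_half) / curve$thermal_voltage))
}

#' Pre-exponential parameter of a Boltzmann curve
#'
#' Returns \eqn{a = \exp(-z \phi_{1/2} / V_T)}, the pre-exponential
#' constant commonly quoted alongside fitted (z, phi_half) pairs.
#'
#' @param curve a [boltzmann_curve()].
#' @return Positive scalar.
#' @examples
#' boltzmann_prefactor(herg_curves()$activation)  # 1.69
#' @export
boltzmann_prefactor <- function(curve) {
  stopifnot(inherits(curve, "boltzmann_curve"))
  exp(-curve$z * curve$phi_half / curve$thermal_voltage)
}

#' Linear fast-inactivation damping line
#'
#' The ratio of the end-of-pulse (bell-shaped) current-potential curve to
#' the steady-state activation curve falls almost linearly with
#' potential; that ratio is the empirical damping factor representing
#' fast inactivation.  The default slope and intercept are
#' `y = -0.00944 * phi + 0.472`.  Because the raw line leaves \[0, 1\]
#' outside roughly -56 to +50 mV, evaluation clamps to
#' `[clamp_lo, clamp_hi]` (see [damping_factor()]).
#'
#' @param slope per mV; default -0.00944.
#' @param intercept dimensionless; default 0.472.
#' @param clamp_lo,clamp_hi clamping bounds, defaults 0 and 1.
#' @return An object of class `"damping_line"`.
#' @export
damping_line <- function(slope = -0.00944, intercept = 0.472,
                         clamp_lo = 0, clamp_hi = 1) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            slope < 0,
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept),
            clamp_lo < clamp_hi)
  structure(list(slope = slope, intercept = intercept,
                 clamp_lo = clamp_lo, clamp_hi = clamp_hi),
            class = "damping_line")
}

#' @export
print.damping_line <- function(x, ...) {
  cat(sprintf("Damping line: y = %g * phi + %g, clamped to [%g, %g]\n",
              x$slope, x$intercept, x$clamp_lo, x$clamp_hi))
  invisible(x)
}

#' Evaluate the fast-inactivation damping factor
#'
#' Evaluates the linear damping line at potential(s) `phi` and clamps the
#' result to the line's `[clamp_lo, clamp_hi]` bounds.  A warning (class
#' `"hergng_clamp_warning"`) is emitted whenever clamping occurred, since
#' the line is an empirical fit over roughly -40..+40 mV.
#'
#' @param phi potential(s) in mV.
#' @param line a [damping_line()]; default the standard hERG line.
#' @return Damping factor(s) in `[clamp_lo, clamp_hi]`.
#' @examples
#' damping_factor(0)     # 0.472
#' damping_factor(-40)   # 0.8496
#' @export
damping_factor <- function(phi, line = damping_line()) {
  stopifnot(inherits(line, "damping_line"))
  if (!is.numeric(phi) || length(phi) == 0L || any(!is.finite(phi)))
    stop("'phi' must be finite numeric potential(s) in mV", call. = FALSE)
  raw <- line$slope * phi + line$intercept
  out <- pmin(pmax(raw, line$clamp_lo), line$clamp_hi)
  if (any(out != raw)) {
    warning(warningCondition(
      sprintf("damping factor clamped to [%g, %g] at %d of %d potential(s)",
              line$clamp_lo, line$clamp_hi, sum(out != raw), length(raw)),
      class = "hergng_clamp_warning"))
  }
  out
}

#' Built-in hERG Boltzmann parameter sets
#'
#' The three experimental steady-state curves used throughout the
#' package, as fitted for hERG under physiological potassium:
#' \describe{
#'   \item{activation}{z = 2.4, phi_half = -5.6 mV, increasing
#'     (a = 1.69); the open probability driving the outward current.}
#'   \item{inactivation}{z = 1.1, phi_half = -82 mV, decreasing
#'     (a = 33.9); tends to 1 at far negative potentials.}
#'   \item{inward_open_probability}{z = 2.2, phi_half = -9 mV,
#'     increasing (a = 2.16); the open probability of the inward current.}
#' }
#'
#' @return Named list of three [boltzmann_curve()] objects.
#' @examples
#' sapply(herg_curves(), boltzmann_prefactor)
#' @export
herg_curves <- function() {
  list(
    activation = boltzmann_curve(2.4, -5.6, orientation = "increasing",
                                 label = "activation"),
    inactivation = boltzmann_curve(1.1, -82, orientation = "decreasing",
                                   label = "inactivation"),
    inward_open_probability = boltzmann_curve(
      2.2, -9, orientation = "increasing",
      label = "inward open probability")
  )
}
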