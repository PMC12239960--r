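#' Reduced unit system for the simulation
#'
#' The integrator works in reduced Lennard-Jones-style units built from an
#' energy unit `epsilon`, a length unit `sigma` (the particle diameter) and a
#' time unit `tau`. Derived units follow: force `epsilon/sigma`, torque
#' `epsilon`, drag coefficient `epsilon * tau / sigma^2`. Magnetic moments are
#' nondimensionalized so that the reduced pair potential
#' `U = [m_i . m_j - 3 (m_i . r^)(m_j . r^)] / r^3` (in units of `epsilon`,
#' distances in `sigma`) equals the physical point-dipole interaction with
#' the `mu0/4pi` prefactor: `m* = mu * sqrt(mu0 / (4 pi epsilon sigma^3))`.
#' Fields are nondimensionalized so that the Zeeman energy `m* B*` (in
#' `epsilon`) equals `mu B` in joules: `B* = B * sqrt(4 pi sigma^3 / (mu0
#' epsilon))`.
#'
#' @param epsilon Energy unit in joules. Default `4.0694e-10`.
#' @param sigma Length unit (particle diameter) in meters. Default `6e-4`.
#' @param tau Time unit in seconds. Default `1/60`.
#' @param gamma Reduced translational drag coefficient (dimensionless).
#'   Default 0.3.
#' @param gamma_r Reduced rotational drag coefficient. Default `gamma/3`
#'   (in reduced units with `sigma = 1` this is the `gamma sigma^3 / 3`
#'   convention).
#' @param dt Integration timestep in units of `tau`. Default 0.001.
#' @return Object of class `unit_system` with converter functions
#'   `to_reduced(value, quantity)` and `to_physical(value, quantity)` for
#'   quantities `"length"`, `"time"`, `"energy"`, `"force"`, `"torque"`,
#'   `"velocity"`, `"drag"`, `"moment"`, `"field"`, `"frequency"`.
#' @examples
#' us <- unit_system()
#' us$drag_physical                       # 5.65e-6 kg/s at gamma = 0.3
#' us$to_reduced(1.08e-6, "moment")       # reduced dipole magnitude ~1.15
#' us$to_physical(us$to_reduced(1e-6, "force"), "force")  # round trip
#' @export
unit_system <- function(epsilon = 4.0694e-10, sigma = 6e-4, tau = 1 / 60,
                        gamma = 0.3, gamma_r = gamma / 3, dt = 0.001) {
  if (any(c(epsilon, sigma, tau, gamma, gamma_r, dt) <= 0)) {
    stop("all unit-system parameters must be positive")
  }
  force_unit <- epsilon / sigma
  drag_unit <- epsilon * tau / sigma^2
  moment_unit <- sqrt(4 * pi * epsilon * sigma^3 / .mu0)  # A m^2 per reduced unit
  field_unit <- epsilon / moment_unit                     # tesla per reduced unit

  scale_of <- function(quantity) {
    switch(quantity,
      length = sigma,
      time = tau,
      energy = epsilon,
      force = force_unit,
      torque = epsilon,
      velocity = sigma / tau,
      drag = drag_unit,
      moment = moment_unit,
      field = field_unit,
      frequency = 1 / tau,
      stop("unknown quantity '", quantity, "'")
    )
  }

  us <- list(
    epsilon = epsilon, sigma = sigma, tau = tau,
    gamma = gamma, gamma_r = gamma_r, dt = dt,
    force_unit = force_unit, drag_unit = drag_unit,
    moment_unit = moment_unit, field_unit = field_unit,
    drag_physical = gamma * drag_unit,
    to_reduced = function(value, quantity) value / scale_of(quantity),
    to_physical = function(value, quantity) value * scale_of(quantity)
  )
  class(us) <- "unit_system"
  us
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Reduced unit system\n")
  cat(sprintf("  epsilon : %.4g J\n", x$epsilon))
  cat(sprintf("  sigma   : %.4g m\n", x$sigma))
  cat(sprintf("  tau     : %.4g s\n", x$tau))
  cat(sprintf("  gamma   : %.3g (physical drag %.3g kg/s)\n",
              x$gamma, x$drag_physical))
  cat(sprintf("  gamma_r : %.3g\n", x$gamma_r))
  cat(sprintf("  dt      : %.4g tau\n", x$dt))
  invisible(x)
}
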