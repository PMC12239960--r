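# R-level surfaces for the individual force/torque terms. These call the
# same compiled kernels the integrator uses, so unit and gradient tests
# exercise the production implementation.

#' WCA pair force between two particle centers
#'
#' Purely repulsive excluded-volume interaction: `U = 4 eps [(sigma/r)^12 -
#' (sigma/r)^6] + eps` for `r < 2^(1/6) sigma`, zero beyond. The `+eps` shift
#' makes both the potential and the force vanish continuously at the cutoff.
#'
#' @param r_i,r_j Center positions (length-3, any consistent length unit).
#' @param sigma Particle diameter in the same unit.
#' @param eps Energy scale.
#' @return List with `force_i`, `force_j` (equal and opposite, central) and
#'   `energy`.
#' @export
wca_pair_force <- function(r_i, r_j, sigma = 1, eps = 1) {
  cpp_wca_pair(as.numeric(r_i), as.numeric(r_j), sigma, eps)
}

#' WCA pair potential
#' @param r Center distance.
#' @param sigma Particle diameter.
#' @param eps Energy scale.
#' @return Potential energy (zero beyond `2^(1/6) sigma`).
#' @export
wca_energy <- function(r, sigma = 1, eps = 1) {
  vapply(r, cpp_wca_energy, numeric(1), sigma = sigma, eps = eps)
}

#' Point-dipole pair interaction
#'
#' Interaction of two dipoles `m_i`, `m_j` located at `r_mi`, `r_mj`:
#' `U = eps [m_i . m_j / r^3 - 3 (m_i . r)(m_j . r) / r^5]`. Forces act at
#' the dipole positions (equal and opposite); torques are `m x B_partner`
#' about the dipole positions. The lever-arm contribution from the offset of
#' the dipole point relative to the particle center is added by
#' [gravity_buoyancy_loads()]-style composition inside the integrator.
#'
#' @param r_mi,r_mj Dipole positions (length-3).
#' @param m_i,m_j Dipole moment vectors (reduced units).
#' @param eps Energy scale.
#' @return List with `force_i`, `force_j`, `torque_i`, `torque_j`, `energy`.
#' @export
dipole_pair_interaction <- function(r_mi, r_mj, m_i, m_j, eps = 1) {
  cpp_dipole_pair(as.numeric(r_mi), as.numeric(r_mj),
                  as.numeric(m_i), as.numeric(m_j), eps)
}

#' Dipole pair potential
#' @inheritParams dipole_pair_interaction
#' @return Potential energy.
#' @export
dipole_energy <- function(r_mi, r_mj, m_i, m_j, eps = 1) {
  cpp_dipole_energy(as.numeric(r_mi), as.numeric(r_mj),
                    as.numeric(m_i), as.numeric(m_j), eps)
}

#' Torque from a uniform external field
#'
#' `T = m x B`, the torque rotating the dipole toward alignment with the
#' field (Zeeman energy `-m . B`). A uniform field exerts no net force.
#'
#' @param m Dipole moment vector.
#' @param B Field vector.
#' @return Torque vector.
#' @export
external_field_torque <- function(m, B) {
  pracma_cross(as.numeric(m), as.numeric(B))
}

#' Gravity and buoyancy loads on a Janus particle
#'
#' The net buoyant weight is split between the sphere center (hydrogel minus
#' displaced water over the whole sphere) and the cap centroid (magnetic
#' composite minus hydrogel over the cap). The cap load, applied at
#' `r_m = r_c - s u`, contributes a torque `(r_m - r_c) x G_m` about the
#' center that rights the particle cap-down.
#'
#' @param particle A [make_particle()] result.
#' @param u Unit symmetry axis (pointing from the cap toward the hydrogel
#'   pole).
#' @return List with `force_center`, `force_cap`, `force_total` (N) and
#'   `torque` (N m, about the particle center).
#' @export
gravity_buoyancy_loads <- function(particle, u = c(0, 0, 1)) {
  stopifnot(inherits(particle, "janus_particle"))
  u <- unit_vec(as.numeric(u))
  f_c <- c(0, 0, -particle$G_center)
  f_m <- c(0, 0, -particle$G_cap)
  lever <- -particle$geometry$s * u
  list(force_center = f_c, force_cap = f_m, force_total = f_c + f_m,
       torque = pracma_cross(lever, f_m))
}

#' Wall normal response
#'
#' WCA-type repulsion from a planar wall as a function of the distance `d`
#' from the particle center to the closest point of the wall. Implemented as
#' the interaction with a virtual particle half-embedded in the wall,
#' `U_wall(d) = U_WCA(d + sigma/2)`, which gives surface contact near
#' `gap = 0` with the same contact stiffness as a particle-particle contact;
#' the force vanishes for `d > (2^(1/6) - 1/2) sigma`.
#'
#' @param d Center-to-wall distance (same unit as `sigma`).
#' @param sigma Particle diameter.
#' @param eps Energy scale.
#' @return List with `N` (normal force magnitude, `>= 0`) and `energy`.
#' @export
wall_response <- function(d, sigma = 1, eps = 1) {
  if (any(d <= 0)) stop("particle center is behind the wall plane")
  list(N = vapply(d, cpp_wall_force, numeric(1), sigma = sigma, eps = eps),
       energy = vapply(d, cpp_wall_energy, numeric(1), sigma = sigma,
                       eps = eps))
}

#' Coulomb stick-slip wall friction
#'
#' Friction applied to particles that are part of a chain (particles with at
#' least one bonded neighbor); single particles roll instead of sliding and
#' get no friction. In the overdamped equations the tangential velocity is
#' proportional to the tangential applied force, so the stick state is
#' detected directly on the force: if the tangential component of the
#' applied force does not exceed `lambda_static * N` the contact sticks and
#' friction cancels it exactly; otherwise the contact slides and kinetic
#' friction `lambda_dynamic * N` opposes the sliding direction. Yaw rotation
#' about the contact normal is resisted analogously with an effective
#' contact radius of half a particle diameter.
#'
#' @param force Applied force vector on the particle (including the wall
#'   normal force).
#' @param torque Applied torque vector about the particle center.
#' @param normal Contact normal (unit vector).
#' @param N Normal force magnitude (`>= 0`).
#' @param lambda_static,lambda_dynamic Friction coefficients.
#' @param in_chain Logical; `FALSE` returns zero friction.
#' @param contact_radius Effective lever arm for the yaw friction torque, in
#'   the same length unit as the force system (default 0.5, i.e. sigma/2 in
#'   reduced units).
#' @return List with `force` and `torque`: the friction contributions to be
#'   added to the applied loads.
#' @export
coulomb_friction <- function(force, torque, normal, N,
                             lambda_static = 0.5, lambda_dynamic = 0.4,
                             in_chain = TRUE, contact_radius = 0.5) {
  if (N < 0) stop("normal force N must be nonnegative")
  zero <- list(force = c(0, 0, 0), torque = c(0, 0, 0))
  if (!in_chain || N == 0) return(zero)
  normal <- unit_vec(as.numeric(normal))
  force <- as.numeric(force)
  torque <- as.numeric(torque)
  f_t <- force - sum(force * normal) * normal
  ft <- sqrt(sum(f_t^2))
  f_fric <- if (ft <= lambda_static * N) {
    -f_t
  } else {
    -lambda_dynamic * N * f_t / ft
  }
  t_n <- sum(torque * normal)
  cap_s <- lambda_static * N * contact_radius
  cap_d <- lambda_dynamic * N * contact_radius
  t_fric <- if (abs(t_n) <= cap_s) {
    -t_n * normal
  } else {
    -sign(t_n) * cap_d * normal
  }
  list(force = f_fric, torque = t_fric)
}
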