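# Simulation configuration, initial-state helpers and the overdamped
# integrator driver.

#' Place particles upright on the floor
#'
#' Particles start standing upright (symmetry axis `u = +z`, heavy cap down)
#' at given in-plane positions, at the height where the wall normal force
#' balances the net buoyant weight, with optional seeded jitter in the plane
#' and a seeded random in-plane dipole direction.
#'
#' @param xy An `N x 2` matrix of in-plane positions (m).
#' @param particle A [make_particle()] result.
#' @param units A [unit_system()]; defaults to one with `sigma` equal to the
#'   particle diameter.
#' @param jitter Uniform jitter half-width applied to x and y, in units of
#'   the particle diameter. Default 0.
#' @param mu_angle In-plane dipole angles (radians from +x), recycled to N;
#'   `NULL` draws them uniformly.
#' @param seed Integer seed for jitter and dipole angles.
#' @return List with `pos`, `u`, `mu` (`N x 3` matrices, SI).
#' @export
init_upright <- function(xy, particle, units = NULL, jitter = 0,
                         mu_angle = NULL, seed = 1) {
  stopifnot(inherits(particle, "janus_particle"))
  geom <- particle$geometry
  if (is.null(units)) units <- unit_system(sigma = geom$sigma)
  xy <- matrix(xy, ncol = 2)
  n <- nrow(xy)
  set.seed(seed)
  if (jitter > 0) {
    xy <- xy + matrix(runif(2 * n, -jitter, jitter) * geom$sigma, ncol = 2)
  }
  if (is.null(mu_angle)) mu_angle <- runif(n, 0, 2 * pi)
  mu_angle <- rep_len(mu_angle, n)
  z <- rest_height(particle, units) * geom$sigma
  list(
    pos = cbind(xy, rep(z, n)),
    u = matrix(rep(c(0, 0, 1), each = n), ncol = 3),
    mu = cbind(cos(mu_angle), sin(mu_angle), rep(0, n))
  )
}

#' Place a preformed chain on the floor
#'
#' A straight head-to-tail chain along an axis, all particles upright with
#' their dipoles aligned along the chain (a configuration close to the
#' assembled state; a short equilibration under the working field relaxes it
#' into the zigzag equilibrium).
#'
#' @param n Number of particles.
#' @param particle A [make_particle()] result.
#' @param units Optional [unit_system()].
#' @param spacing Center-to-center spacing in particle diameters. Default
#'   1.06 (near the dipole/WCA bond equilibrium).
#' @param axis Chain axis, `"y"` or `"x"`.
#' @param origin In-plane position of the chain midpoint (length-2, m).
#' @return List with `pos`, `u`, `mu`.
#' @export
init_chain <- function(n, particle, units = NULL, spacing = 1.06,
                       axis = "y", origin = c(0, 0)) {
  stopifnot(inherits(particle, "janus_particle"), n >= 1)
  geom <- particle$geometry
  if (is.null(units)) units <- unit_system(sigma = geom$sigma)
  coords <- (seq_len(n) - (n + 1) / 2) * spacing * geom$sigma
  z <- rest_height(particle, units) * geom$sigma
  dir <- switch(axis, y = c(0, 1, 0), x = c(1, 0, 0),
                stop("axis must be 'x' or 'y'"))
  pos <- cbind(origin[1] + coords * dir[1], origin[2] + coords * dir[2],
               rep(z, n))
  list(
    pos = pos,
    u = matrix(rep(c(0, 0, 1), each = n), ncol = 3),
    mu = matrix(rep(dir, each = n), ncol = 3)
  )
}

# Resting center height above a floor, in sigma: wall force balances weight
rest_height <- function(particle, units) {
  w_red <- units$to_reduced(particle$weight, "force")
  if (w_red <= 0) return(0.56)
  f <- function(d) cpp_wall_force(d, 1, 1) - w_red
  upper <- 2^(1 / 6) - 0.5 - 1e-9
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(0.505, upper), tol = 1e-12)$root
}

#' Simulation configuration
#'
#' Bundles everything needed for a reproducible run. Physical inputs (SI,
#' mT, Hz, seconds) are converted to reduced units internally.
#'
#' @param particle A [make_particle()] result (geometry + materials).
#' @param init Initial state from [init_upright()], [init_chain()], or a
#'   list with `pos`, `u`, `mu` (`N x 3`, SI).
#' @param field A `field_program`.
#' @param arena An `arena` (default flat floor).
#' @param duration Simulated time in seconds.
#' @param dt Timestep in units of tau. Default 0.001.
#' @param stride Store every `stride`-th step. Default 100.
#' @param units A [unit_system()]; defaults to one whose length unit is the
#'   particle diameter.
#' @param seed Integer seed recorded with the run (initial-state helpers
#'   consume their own seeds; the integrator itself is deterministic).
#' @param friction Logical: apply chain wall friction (default `TRUE`).
#' @param bond_cutoff Chain bond cutoff in particle diameters (default 1.1);
#'   used both for the in-chain friction flag and by the analysis helpers.
#' @param r_sat Saturation radius of the dipole kernel in particle diameters
#'   (default 0.85): below it the kernel magnitudes are frozen, bounding the
#'   near-contact force of the offset point dipoles at the scale where the
#'   point approximation of the distributed cap magnetization breaks down.
#' @param f_dip_max Upper bound on the saturated dipole contact force in
#'   reduced units (default 25, the force scale the excluded-volume contact
#'   can balance); for strong moments the saturation radius widens to
#'   respect it.
#' @return Object of class `janus_config`.
#' @export
simulation_config <- function(particle, init, field, arena = arena_flat(),
                              duration, dt = 0.001, stride = 100,
                              units = NULL, seed = 1, friction = TRUE,
                              bond_cutoff = 1.1, r_sat = 0.85,
                              f_dip_max = 25) {
  stopifnot(inherits(particle, "janus_particle"),
            inherits(field, "field_program"))
  arena <- build_arena(arena)
  geom <- particle$geometry
  if (is.null(units)) units <- unit_system(sigma = geom$sigma, dt = dt)
  if (dt <= 0) stop("dt must be positive")
  if (duration < dt * units$tau) stop("duration must cover at least one step")
  init <- lapply(init[c("pos", "u", "mu")], function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 3)
    m
  })
  structure(
    list(particle = particle, init = init, field = field, arena = arena,
         duration = duration, dt = dt, stride = stride, units = units,
         seed = seed, friction = friction, bond_cutoff = bond_cutoff,
         r_sat = r_sat, f_dip_max = f_dip_max),
    class = "janus_config"
  )
}

#' Run a simulation
#'
#' Integrates the overdamped equations of motion: translations follow
#' `gamma dr/dt = F` and orientations `gamma_r omega = T`, advanced by
#' explicit Euler at the configured timestep, with the body frame rotated
#' rigidly by the exponential map of `omega dt` and re-orthonormalized each
#' step. The run is deterministic: repeating the same configuration
#' reproduces the trajectory bitwise.
#'
#' @param config A [simulation_config()].
#' @param t_start Start time offset in seconds (used when continuing a
#'   schedule; default 0).
#' @return Object of class `janus_trajectory`: `times` (s), `pos`, `u`,
#'   `mu` (`frames x N x 3`; positions in m), `field` (`frames x 3`, mT),
#'   and the `config`.
#' @export
run_simulation <- function(config, t_start = 0) {
  stopifnot(inherits(config, "janus_config"))
  us <- config$units
  geom <- config$particle$geometry
  n_steps <- max(1, round(config$duration / (us$tau * config$dt)))
  params <- list(
    dt = config$dt,
    n_steps = as.double(n_steps),
    stride = as.integer(config$stride),
    gamma = us$gamma,
    gamma_r = us$gamma_r,
    m_star = us$to_reduced(config$particle$dipole, "moment"),
    s_off = geom$s / us$sigma,
    Gc = us$to_reduced(config$particle$G_center, "force"),
    Gm = us$to_reduced(config$particle$G_cap, "force"),
    bond_cut = config$bond_cutoff,
    t0 = t_start / us$tau,
    friction_on = config$friction,
    r_sat = config$r_sat,
    f_dip_max = config$f_dip_max
  )
  res <- cpp_sim_run(
    config$init$pos / us$sigma,
    config$init$u,
    config$init$mu,
    compile_arena(config$arena, us),
    compile_field_program(config$field, us),
    params
  )
  structure(
    list(
      times = res$times * us$tau,
      pos = res$pos * us$sigma,
      u = res$u,
      mu = res$mu,
      field = res$field * us$field_unit * 1e3,  # mT
      config = config
    ),
    class = "janus_trajectory"
  )
}

#' @export
print.janus_trajectory <- function(x, ...) {
  d <- dim(x$pos)
  cat(sprintf("Trajectory: %d frames, %d particle(s), t = %.3g..%.3g s\n",
              d[1], d[2], x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `janus_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$times)

#' Extract one frame of a trajectory
#'
#' @param trajectory A `janus_trajectory`.
#' @param i Frame index (1-based; negative counts from the end, `-1` is the
#'   last frame).
#' @return List with `t` (s), `pos`, `u`, `mu` (`N x 3`), `B` (mT).
#' @export
trajectory_frame <- function(trajectory, i) {
  nf <- n_frames(trajectory)
  if (i < 0) i <- nf + 1 + i
  if (i < 1 || i > nf) stop("frame index out of range")
  list(
    t = trajectory$times[i],
    pos = matrix(trajectory$pos[i, , ], ncol = 3),
    u = matrix(trajectory$u[i, , ], ncol = 3),
    mu = matrix(trajectory$mu[i, , ], ncol = 3),
    B = trajectory$field[i, ]
  )
}

#' Advance a state by one (or a few) integration steps
#'
#' Thin wrapper over the integrator for stepwise use. States are SI
#' (`pos` in meters); the field program clock starts at `t` seconds.
#'
#' @param state List with `pos`, `u`, `mu` (`N x 3`).
#' @param config A [simulation_config()] providing particle, field, arena
#'   and units (its `init` is ignored).
#' @param n_steps Number of timesteps to take. Default 1.
#' @param t Current time in seconds.
#' @return Updated state list with `pos`, `u`, `mu`, `t`.
#' @export
integrate_step <- function(state, config, n_steps = 1, t = 0) {
  cfg <- config
  cfg$init <- state
  cfg$duration <- n_steps * cfg$dt * cfg$units$tau
  cfg$stride <- n_steps
  traj <- run_simulation(cfg, t_start = t)
  f <- trajectory_frame(traj, -1)
  list(pos = f$pos, u = f$u, mu = f$mu, t = f$t)
}

#' Continue a trajectory with a new field program
#'
#' Runs a new simulation starting from the final frame of `trajectory`,
#' keeping the particle, arena and units, with the field program's clock
#' restarted at zero (the experimental "switch the field" operation).
#'
#' @param trajectory A `janus_trajectory`.
#' @param field The new `field_program`.
#' @param duration Additional simulated seconds.
#' @param ... Overrides passed to [simulation_config()].
#' @return A new `janus_trajectory` whose `times` continue from the end of
#'   the input.
#' @export
continue_simulation <- function(trajectory, field, duration, ...) {
  f <- trajectory_frame(trajectory, -1)
  cfg0 <- trajectory$config
  cfg <- simulation_config(
    particle = cfg0$particle,
    init = list(pos = f$pos, u = f$u, mu = f$mu),
    field = field, arena = cfg0$arena, duration = duration,
    dt = cfg0$dt, stride = cfg0$stride, units = cfg0$units,
    seed = cfg0$seed, friction = cfg0$friction,
    bond_cutoff = cfg0$bond_cutoff, r_sat = cfg0$r_sat,
    f_dip_max = cfg0$f_dip_max, ...)
  traj <- run_simulation(cfg)
  traj$times <- traj$times + f$t
  traj
}
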