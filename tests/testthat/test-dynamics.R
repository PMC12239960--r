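# Overdamped integrator: drift, rotation, determinism, convergence.

test_that("a free particle under constant force drifts at F/gamma exactly", {
  p <- ref_particle()
  us <- unit_system()
  # high above the floor, no field: the only force is gravity/buoyancy
  init <- list(pos = matrix(c(0, 0, 50 * us$sigma), 1, 3),
               u = matrix(c(0, 0, 1), 1, 3),
               mu = matrix(c(0, 1, 0), 1, 3))
  n_steps <- 500
  cfg <- simulation_config(p, init, field_static(0, c(0, 0, 1)),
                           arena_flat(),
                           duration = n_steps * 0.001 * us$tau, stride = 500)
  f <- trajectory_frame(run_simulation(cfg), -1)
  w_red <- us$to_reduced(p$weight, "force")
  expected_drop <- n_steps * 0.001 * w_red / us$gamma * us$sigma
  expect_equal(50 * us$sigma - f$pos[1, 3], expected_drop,
               tolerance = 1e-12)
  expect_equal(f$pos[1, 1:2], c(0, 0))
})

test_that("field alignment follows the closed-form overdamped decay", {
  # dtheta/dt = -(m B / gamma_r) sin(theta)  =>
  # tan(theta/2) = tan(theta0/2) exp(-m B t / gamma_r)
  p <- ref_particle()
  us <- unit_system()
  B_mT <- 0.2  # weak field keeps the per-step rotation small
  th0 <- 2
  init <- list(pos = matrix(c(0, 0, 50 * us$sigma), 1, 3),
               u = matrix(c(0, 0, 1), 1, 3),
               mu = matrix(c(sin(th0), cos(th0), 0), 1, 3))
  # field along +y in the horizontal plane: gravity torque stays zero
  cfg <- simulation_config(p, init, field_static(B_mT, c(0, 1, 0)),
                           arena_flat(), duration = 1.5, stride = 100)
  tr <- run_simulation(cfg)
  rate <- us$to_reduced(p$dipole, "moment") *
    us$to_reduced(B_mT * 1e-3, "field") / us$gamma_r
  th_obs <- vapply(seq_len(n_frames(tr)), function(i) {
    f <- trajectory_frame(tr, i)
    acos(max(-1, min(1, f$mu[1, 2])))
  }, numeric(1))
  t_red <- tr$times / us$tau
  th_exact <- 2 * atan(tan(th0 / 2) * exp(-rate * t_red))
  expect_lt(max(abs(th_obs - th_exact)), 1e-3)
})

test_that("identical configurations reproduce trajectories bitwise", {
  p <- ref_particle()
  mk <- function() {
    init <- init_upright(rbind(c(0, -9e-4), c(0, 9e-4)), p, jitter = 0.1,
                         seed = 42)
    cfg <- simulation_config(p, init, field_preset("assemble_precession"),
                             arena_flat(), duration = 0.5, stride = 50)
    run_simulation(cfg)
  }
  t1 <- mk()
  t2 <- mk()
  expect_identical(t1$pos, t2$pos)
  expect_identical(t1$mu, t2$mu)
})

test_that("frame bookkeeping: times strictly increase, count matches", {
  p <- ref_particle()
  cfg <- simulation_config(p, init_chain(2, p), field_preset("walking"),
                           arena_flat(), duration = 0.2, stride = 30)
  tr <- run_simulation(cfg)
  n_steps <- round(0.2 / (unit_system()$tau * 0.001))
  expect_equal(n_frames(tr), floor(n_steps / 30) + 1)
  expect_true(all(diff(tr$times) > 0))
  expect_error(trajectory_frame(tr, 10 * n_frames(tr)), "out of range")
})

test_that("stored field vectors match the R-side program evaluation", {
  p <- ref_particle()
  pr <- field_schedule(list(0.1, field_rotating(4, 3)),
                       list(0.1, field_oscillating(6, 2, c(-1, 1))))
  cfg <- simulation_config(p, init_chain(2, p), pr, arena_flat(),
                           duration = 0.19, stride = 17)
  tr <- run_simulation(cfg)
  for (i in seq_len(n_frames(tr))) {
    f <- trajectory_frame(tr, i)
    expect_equal(f$B, unname(evaluate_field(pr, f$t)), tolerance = 1e-9)
  }
})

test_that("body frames stay orthonormal through long runs", {
  p <- ref_particle()
  cfg <- simulation_config(p, init_chain(4, p), field_preset("walking"),
                           arena_flat(), duration = 6, stride = 2000)
  tr <- run_simulation(cfg)
  f <- trajectory_frame(tr, -1)
  expect_lt(max(abs(rowSums(f$u^2) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(f$mu^2) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(f$u * f$mu))), 1e-9)
})

test_that("internal forces do not move the center of mass", {
  p <- ref_particle()
  us <- unit_system()
  # two interacting dipoles far above the floor, no field, friction off
  init <- list(pos = rbind(c(0, 0, 200 * us$sigma),
                           c(0, 1.3 * us$sigma, 200 * us$sigma)),
               u = rbind(c(0, 0, 1), c(0, 0, 1)),
               mu = rbind(c(0, 1, 0), c(0, 1, 0)))
  cfg <- simulation_config(p, init, field_static(0, c(0, 0, 1)),
                           arena_flat(), duration = 0.15, stride = 100,
                           friction = FALSE)
  tr <- run_simulation(cfg)
  com_xy <- apply(tr$pos[, , 1:2], c(1, 3), mean)
  expect_lt(max(abs(com_xy - rep(com_xy[1, ], each = nrow(com_xy)))), 1e-18)
  # vertical COM follows the known constant-force drift
  com_z <- apply(tr$pos[, , 3, drop = FALSE], 1, mean)
  w_red <- us$to_reduced(p$weight, "force")
  drop_expected <- (tr$times - tr$times[1]) / us$tau * w_red / us$gamma *
    us$sigma
  expect_equal(com_z[1] - com_z, drop_expected, tolerance = 1e-10)
})

test_that("oversized timesteps abort with a diagnostic", {
  p <- ref_particle()
  init <- init_chain(2, p, spacing = 0.8)  # deep overlap
  cfg <- simulation_config(p, init, field_static(0, c(0, 0, 1)),
                           arena_flat(), duration = 0.01, dt = 0.05)
  expect_error(run_simulation(cfg), "timestep too large")
})

test_that("halving the timestep barely changes a two-particle endpoint", {
  # assembly under a static field settles to a stationary bonded pair, so
  # the endpoint isolates discretization error from rotation-phase drift
  p <- ref_particle()
  run_dt <- function(dt) {
    init <- init_upright(rbind(c(0, -9e-4), c(0, 9e-4)), p, jitter = 0.1,
                         seed = 9, mu_angle = pi / 2)
    cfg <- simulation_config(p, init, field_static(6, c(0, 1, 0)),
                             arena_flat(), duration = 1, stride = 1000,
                             dt = dt)
    trajectory_frame(run_simulation(cfg), -1)$pos
  }
  d <- abs(run_dt(0.001) - run_dt(0.0005)) / ref_particle()$geometry$sigma
  expect_lt(max(d), 1e-3)
})

test_that("integrate_step advances a state like the full driver", {
  p <- ref_particle()
  init <- init_chain(2, p)
  cfg <- simulation_config(p, init, field_preset("walking"), arena_flat(),
                           duration = 1)
  s1 <- integrate_step(init, cfg, n_steps = 100)
  cfg2 <- simulation_config(p, init, field_preset("walking"), arena_flat(),
                            duration = 100 * 0.001 * unit_system()$tau,
                            stride = 100)
  f <- trajectory_frame(run_simulation(cfg2), -1)
  expect_equal(s1$pos, f$pos, tolerance = 1e-14)
})
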