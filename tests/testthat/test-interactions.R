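# Pairwise, field, body and wall force/torque terms.

test_that("WCA force and potential vanish continuously at the cutoff", {
  rc <- 2^(1 / 6)
  expect_equal(wca_energy(rc), 0)
  expect_equal(wca_energy(rc - 1e-9), 0, tolerance = 1e-6)
  f <- wca_pair_force(c(0, 0, 0), c(rc - 1e-9, 0, 0))
  expect_lt(sqrt(sum(f$force_i^2)), 1e-6)
  expect_equal(wca_energy(1.5), 0)
})

test_that("WCA repulsion at contact distance equals 24 eps/sigma", {
  f <- wca_pair_force(c(1, 0, 0), c(0, 0, 0), sigma = 1, eps = 1)
  expect_equal(f$force_i, c(24, 0, 0), tolerance = 1e-12)
  # and the energy there is eps (shifted minimum of the 12-6 form)
  expect_equal(wca_energy(1), 1)
})

test_that("WCA force is central, antisymmetric and equals -grad U", {
  set.seed(1)
  for (k in 1:20) {
    r1 <- runif(3, -1, 1)
    r2 <- r1 + runit() * runif(1, 0.9, 1.12)
    f <- wca_pair_force(r1, r2)
    expect_equal(f$force_i, -f$force_j)
    g <- num_grad(function(x) cpp_wca_energy(sqrt(sum((x - r2)^2)), 1, 1), r1)
    expect_equal(f$force_i, -g, tolerance = 1e-5 * max(1, sqrt(sum(g^2))))
  }
})

test_that("dipole pair energies match hand-substituted configurations", {
  # head-to-tail unit dipoles at unit distance: U = -2 eps
  e <- dipole_energy(c(1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(e, -2)
  # side-by-side parallel dipoles: U = +eps
  e2 <- dipole_energy(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 0))
  expect_equal(e2, 1)
})

test_that("head-to-tail dipole attraction has magnitude 6 eps/sigma", {
  p <- dipole_pair_interaction(c(1, 0, 0), c(0, 0, 0),
                               c(1, 0, 0), c(1, 0, 0))
  expect_equal(p$force_i, c(-6, 0, 0), tolerance = 1e-12)
  # cross-check against a central-difference gradient of the potential
  g <- num_grad(function(x) cpp_dipole_energy(x, c(0, 0, 0),
                                              c(1, 0, 0), c(1, 0, 0), 1),
                c(1, 0, 0))
  expect_equal(p$force_i, -g, tolerance = 1e-5)
})

test_that("dipole forces equal -grad U outside the saturation radius", {
  set.seed(7)
  for (k in 1:25) {
    cfgp <- random_dipole_config()
    p <- dipole_pair_interaction(cfgp$r1, cfgp$r2, cfgp$m1, cfgp$m2)
    g <- num_grad(function(x) cpp_dipole_energy(x, cfgp$r2, cfgp$m1,
                                                cfgp$m2, 1), cfgp$r1)
    scale <- max(1, sqrt(sum(g^2)))
    expect_equal(p$force_i, -g, tolerance = 1e-5 * scale)
  }
})

test_that("dipole pairs conserve linear and angular momentum", {
  set.seed(11)
  for (k in 1:25) {
    cfgp <- random_dipole_config()
    p <- dipole_pair_interaction(cfgp$r1, cfgp$r2, cfgp$m1, cfgp$m2)
    expect_lt(max(abs(p$force_i + p$force_j)), 1e-12)
    # total torque about the origin, including moments of the forces
    lt <- janusim:::pracma_cross(cfgp$r1, p$force_i) + p$torque_i +
      janusim:::pracma_cross(cfgp$r2, p$force_j) + p$torque_j
    expect_lt(max(abs(lt)), 1e-10)
  }
})

test_that("field torque aligns the dipole and vanishes when aligned", {
  expect_equal(external_field_torque(c(0, 0, 2), c(0, 0, 5)), c(0, 0, 0))
  expect_equal(external_field_torque(c(1, 0, 0), c(0, 0, 2)), c(0, -2, 0))
  # torque-only dynamics relaxes mu toward B (energy minimum at alignment)
  m <- c(1, 0, 0)
  B <- c(0, 0, 1)
  for (i in 1:2000) {
    m <- m + 0.01 * janusim:::pracma_cross(external_field_torque(m, B), m)
    m <- m / sqrt(sum(m^2))
  }
  expect_gt(sum(m * B), 0.999)
})

test_that("gravity/buoyancy loads split correctly and right the particle", {
  p <- ref_particle()
  # cap straight down (or up): lever parallel to gravity, no torque
  for (u in list(c(0, 0, 1), c(0, 0, -1))) {
    expect_equal(gravity_buoyancy_loads(p, u)$torque, c(0, 0, 0))
  }
  l <- gravity_buoyancy_loads(p, c(0, 0, 1))
  expect_equal(l$force_total, l$force_center + l$force_cap)
  expect_equal(-l$force_center[3] * 1e6, 0.133, tolerance = 2e-3)
  # tilted particle: torque rotates u toward +z
  u <- c(0, sin(0.5), cos(0.5))
  tq <- gravity_buoyancy_loads(p, u)$torque
  # resulting du/dt = omega x u must have positive z component
  dudt <- janusim:::pracma_cross(tq, u)
  expect_gt(dudt[3], 0)
})

test_that("wall response is repulsive, short-ranged and -dU/dd", {
  cutoff <- 2^(1 / 6) - 0.5
  expect_equal(wall_response(cutoff + 0.01)$N, 0)
  expect_gt(wall_response(0.5)$N, 0)
  for (d in c(0.52, 0.55, 0.6)) {
    g <- (cpp_wall_energy(d + 1e-6, 1, 1) - cpp_wall_energy(d - 1e-6, 1, 1)) /
      2e-6
    expect_equal(wall_response(d)$N, -g, tolerance = 1e-4 * abs(g))
  }
  # continuity at the cutoff
  expect_lt(wall_response(cutoff - 1e-9)$N, 1e-6)
  expect_error(wall_response(-0.1), "behind the wall")
})

test_that("a resting particle's wall force balances its weight", {
  p <- ref_particle()
  us <- unit_system()
  d <- janusim:::rest_height(p, us)
  expect_equal(wall_response(d)$N, us$to_reduced(p$weight, "force"),
               tolerance = 1e-9)
})

test_that("coulomb friction obeys the stick/slip law and the friction cone", {
  n <- c(0, 0, 1)
  # no friction for single (rolling) particles
  z <- coulomb_friction(c(5, 0, -3), c(0, 0, 2), n, N = 3, in_chain = FALSE)
  expect_equal(z$force, c(0, 0, 0))
  expect_equal(z$torque, c(0, 0, 0))
  # stick: tangential force below lambda_s N is cancelled exactly
  fr <- coulomb_friction(c(0.2 * 0.5 * 3, 0, -3), c(0, 0, 0), n, N = 3)
  expect_equal(fr$force, c(-0.2 * 0.5 * 3, 0, 0))
  # slide: kinetic friction of magnitude lambda_d N opposes the motion
  fr2 <- coulomb_friction(c(10, 0, -3), c(0, 0, 0), n, N = 1)
  expect_equal(fr2$force, c(-0.4, 0, 0))
  # friction cone: |friction| never exceeds lambda_s N
  set.seed(3)
  for (k in 1:50) {
    F <- rnorm(3, sd = 5)
    N <- runif(1, 0, 4)
    fr <- coulomb_friction(F, rnorm(3), n, N)
    expect_lte(sqrt(sum(fr$force^2)), 0.5 * N + 1e-12)
  }
  expect_error(coulomb_friction(c(1, 0, 0), c(0, 0, 0), n, N = -1),
               "nonnegative")
})

test_that("a tilted particle settles upright with its cap down", {
  p <- ref_particle()
  init <- init_upright(matrix(c(0, 0), 1, 2), p, seed = 1)
  th <- 70 * pi / 180
  init$u[1, ] <- c(0, sin(th), cos(th))
  init$mu[1, ] <- c(1, 0, 0)
  cfg <- simulation_config(p, init, field_static(0, c(0, 0, 1)),
                           arena_flat(), duration = 100 / 60, stride = 1000)
  f <- trajectory_frame(run_simulation(cfg), -1)
  # within 1 degree of vertical after 100 tau
  expect_gt(f$u[1, 3], cos(pi / 180))
})
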