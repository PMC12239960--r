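# Geometry closed forms, mass/weight derivation and the reduced-unit system.

test_that("cap volume matches limits, symmetry and a numerical integral", {
  expect_equal(cap_volume(0, 1), 0)
  expect_equal(cap_volume(0, 2.7), 0)
  # hemisphere is half the sphere
  expect_equal(cap_volume(0.5, 1), pi / 12)
  # numerical integration of circular cross-sections as independent oracle
  sigma <- 6e-4
  R <- sigma / 2
  for (h in c(0.2, 0.33, 0.7)) {
    a <- h * sigma
    oracle <- stats::integrate(function(z) pi * (R^2 - z^2), R - a, R,
                               rel.tol = 1e-12)$value
    expect_equal(cap_volume(h, sigma), oracle, tolerance = 1e-10)
  }
  expect_error(cap_volume(-0.1, 1), "cap fraction")
  expect_error(cap_volume(0.5, 0), "sigma")
})

test_that("complementary caps fill the sphere for all h", {
  h <- seq(0.05, 0.95, by = 0.05)
  expect_equal(cap_volume(h, 1) + cap_volume(1 - h, 1),
               rep((1 / 6) * pi, length(h)))
})

test_that("cap centroid offset has the classical limits and integral value", {
  expect_equal(cap_centroid_offset(1, 1), 0)
  expect_equal(cap_centroid_offset(0.5, 1), 3 / 8)  # hemisphere centroid
  # numerical centroid of the cap as independent oracle
  R <- 3e-4
  for (h in c(0.2, 0.32, 0.6)) {
    a <- h * 2 * R
    num <- stats::integrate(function(z) z * pi * (R^2 - z^2), R - a, R,
                            rel.tol = 1e-12)$value
    den <- stats::integrate(function(z) pi * (R^2 - z^2), R - a, R,
                            rel.tol = 1e-12)$value
    expect_equal(cap_centroid_offset(h, R), num / den, tolerance = 1e-9)
  }
  # strictly decreasing in h
  h <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(cap_centroid_offset(h, 1)) < 0))
  expect_error(cap_centroid_offset(0, 1), "cap fraction")
})

test_that("particle masses and weights reproduce the reference estimates", {
  p <- ref_particle()
  # displaced water mass of a 600-um sphere: 0.113 mg
  expect_equal(p$m_water * 1e6, 0.113, tolerance = 1e-3)
  # particle mass ~0.314 mg and net buoyant weight 1.97 uN at h = 0.33
  expect_equal(p$m_particle * 1e6, 0.314, tolerance = 2e-3)
  expect_equal(p$weight * 1e6, 1.97, tolerance = 3e-3)
  # pure hydrogel sphere limit: rho_hydrogel * V_sphere
  g0 <- janus_geometry(cap_fraction = 1e-6)
  p0 <- make_particle(g0, material_params())
  expect_equal(p0$m_particle * 1e6, 1120 * g0$V_sphere * 1e6,
               tolerance = 1e-6)
  expect_equal(p0$m_particle * 1e6, 0.1267, tolerance = 1e-3)
})

test_that("the center/cap load split conserves the buoyant weight exactly", {
  for (h in c(0.1, 0.33, 0.5, 0.9)) {
    p <- make_particle(janus_geometry(cap_fraction = h), material_params())
    expect_equal(p$G_center + p$G_cap, p$weight, tolerance = 1e-14)
  }
})

test_that("material parameter validation and presets", {
  expect_error(material_params(rho_hydrogel = 900), "densities")
  expect_equal(material_params(preset = "remanent")$dipole, 0.87e-6)
  expect_equal(material_params()$dipole, 1.08e-6)
})

test_that("unit system reproduces the printed drag coefficient", {
  us <- unit_system()
  expect_equal(us$drag_physical, 5.65e-6, tolerance = 1e-3)
})

test_that("reduced dipole moment and field match their defining relations", {
  us <- unit_system()
  mu0 <- 1.25663706e-6
  mu <- 1.08e-6
  # m* = mu sqrt(mu0 / (4 pi eps sigma^3)), evaluated independently
  m_star <- mu * sqrt(mu0 / (4 * pi * us$epsilon * us$sigma^3))
  expect_equal(us$to_reduced(mu, "moment"), m_star, tolerance = 1e-12)
  expect_equal(m_star, 1.152, tolerance = 1e-3)
  # reduced contact energy converts back to the physical dipole energy
  u_phys <- (mu0 / (4 * pi)) * mu^2 / us$sigma^3
  expect_equal(m_star^2 * us$epsilon, u_phys, tolerance = 1e-12)
  # Zeeman energy consistency: eps * m* B* = mu B
  B <- 4e-3
  expect_equal(us$epsilon * m_star * us$to_reduced(B, "field"), mu * B,
               tolerance = 1e-12)
})

test_that("unit conversions round-trip for every quantity", {
  us <- unit_system()
  for (q in c("length", "time", "energy", "force", "torque", "velocity",
              "drag", "moment", "field", "frequency")) {
    x <- 1.2345e-6
    expect_equal(us$to_physical(us$to_reduced(x, q), q), x,
                 tolerance = 1e-15)
  }
  expect_error(us$to_reduced(1, "banana"), "unknown quantity")
  expect_error(unit_system(sigma = -1), "positive")
})

test_that("reduced net weight of the reference robot is about 2.9", {
  us <- unit_system()
  expect_equal(us$to_reduced(ref_particle()$weight, "force"), 2.9,
               tolerance = 0.01)
})

test_that("fabricated robot scales the dipole with particle volume", {
  p <- fabricated_particle(radius = 2.875e-4)  # 575-um robot
  expect_equal(p$dipole, 1.08e-6, tolerance = 1e-12)
  p5 <- fabricated_particle()  # 0.5-mm robot
  expect_equal(p5$dipole, 1.08e-6 * (5e-4 / 5.75e-4)^3, tolerance = 1e-12)
})
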