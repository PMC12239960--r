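# Chain detection, assembly metrics, kinematics, fragmentation, release.

test_that("chain detection handles singletons and a collinear chain", {
  pos <- matrix(rnorm(24), 8, 3) * 10  # all far apart
  part <- detect_chains(pos, 1.1)
  expect_equal(part$sizes, rep(1L, 8))
  chain <- cbind(0, seq_len(8) * 1.0, 0)
  part2 <- detect_chains(chain, 1.1)
  expect_length(part2$chains, 1)
  expect_equal(part2$sizes, 8L)
  # ordered along the principal axis
  expect_equal(part2$chains[[1]], 1:8)
  expect_error(detect_chains(chain, -1), "positive")
})

test_that("chain detection equals brute-force components on random sets", {
  set.seed(13)
  for (k in 1:200) {
    n <- sample(5:20, 1)
    pos <- matrix(runif(3 * n, 0, 4), n, 3)
    cutoff <- runif(1, 0.5, 1.5)
    part <- detect_chains(pos, cutoff)
    oracle <- brute_components(pos, cutoff)
    got <- lapply(part$chains, sort)
    want <- unname(lapply(oracle, sort))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    # permutation invariance
    perm <- sample(n)
    part_p <- detect_chains(pos[perm, , drop = FALSE], cutoff)
    got_p <- lapply(part_p$chains, function(ids) sort(perm[ids]))
    expect_setequal(lapply(got_p, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("assembly efficiency is the largest-chain fraction", {
  chain <- cbind(0, seq_len(8) * 1.0, 0)
  expect_equal(assembly_efficiency(detect_chains(chain, 1.1)), 1)
  two <- rbind(cbind(0, seq_len(5) * 1.0, 0),
               cbind(50, seq_len(3) * 1.0, 0))
  expect_equal(assembly_efficiency(detect_chains(two, 1.1)), 0.625)
  solo <- matrix(seq_len(8) * 10, 8, 3)
  expect_equal(assembly_efficiency(detect_chains(solo, 1.1)), 1 / 8)
})

test_that("offset angle distinguishes head-to-tail from staggered dimers", {
  f <- list(pos = rbind(c(0, 0, 0), c(1, 0, 0)),
            mu = rbind(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(offset_angle(f), 0)
  f90 <- list(pos = rbind(c(0, 0, 0), c(0, 1, 0)),
              mu = rbind(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(offset_angle(f90), 90)
  expect_error(offset_angle(list(pos = rbind(c(0, 0, 0), c(5, 0, 0)),
                                 mu = f$mu), bond_cutoff = 1.1),
               "not bonded")
})

test_that("centroid kinematics recovers stationary and linear motion", {
  mk_traj <- function(centroids, times) {
    nf <- length(times)
    pos <- array(0, c(nf, 2, 3))
    for (i in seq_len(nf)) {
      pos[i, 1, ] <- centroids[i, ] + c(0, -0.5, 0)
      pos[i, 2, ] <- centroids[i, ] + c(0, 0.5, 0)
    }
    structure(list(times = times, pos = pos,
                   u = array(0, c(nf, 2, 3)), mu = array(0, c(nf, 2, 3)),
                   field = matrix(0, nf, 3), config = NULL),
              class = "janus_trajectory")
  }
  t <- seq(0, 1, by = 0.01)
  still <- mk_traj(matrix(rep(c(1, 2, 3), each = length(t)), ncol = 3), t)
  k <- centroid_kinematics(still)
  expect_equal(max(k$speed), 0)
  v <- c(0.3, -0.2, 0)
  lin <- mk_traj(outer(t, v), t)
  k2 <- centroid_kinematics(lin)
  expect_equal(k2$velocity[5, ], v, tolerance = 1e-12)
  expect_equal(mean_speed(lin, f_Hz = 10, transient_periods = 2),
               sqrt(sum(v^2)), tolerance = 1e-12)
})

test_that("an analytic tumbling rod walks at 2 L f", {
  # end-over-end tumble: pivot alternates between the rod ends, each half
  # period advances the centroid by L (the end separation)
  L <- 1
  f <- 2
  times <- seq(0, 2, by = 1 / (40 * f))
  nf <- length(times)
  pos <- array(0, c(nf, 2, 3))
  for (i in seq_len(nf)) {
    ph <- times[i] * f  # tumbles per unit time
    n_half <- floor(2 * ph)
    theta <- pi * (2 * ph - n_half) / 2 * 2  # angle within current half turn
    pivot_y <- n_half * L
    swing <- c(0, pivot_y + L * cos(pi - theta), L * sin(pi - theta))
    base <- c(0, pivot_y, 0)
    if (n_half %% 2 == 0) {
      pos[i, 1, ] <- base
      pos[i, 2, ] <- swing
    } else {
      pos[i, 2, ] <- base
      pos[i, 1, ] <- swing
    }
  }
  traj <- structure(list(times = times, pos = pos,
                         u = array(0, c(nf, 2, 3)),
                         mu = array(0, c(nf, 2, 3)),
                         field = matrix(0, nf, 3), config = NULL),
                    class = "janus_trajectory")
  v <- mean_speed(traj, f_Hz = f, transient_periods = 0,
                  direction = c(0, 1, 0))
  expect_equal(v, 2 * L * f, tolerance = 1e-9)
})

test_that("fragmentation time finds the first split or reports Inf", {
  mk <- function(split_frame) {
    nf <- 10
    pos <- array(0, c(nf, 3, 3))
    for (i in seq_len(nf)) {
      pos[i, , 2] <- c(0, 1, 2)
      if (!is.na(split_frame) && i >= split_frame) pos[i, 3, 2] <- 10
    }
    structure(list(times = seq_len(nf) * 0.1, pos = pos,
                   u = array(0, c(nf, 3, 3)), mu = array(0, c(nf, 3, 3)),
                   field = matrix(0, nf, 3), config = NULL),
              class = "janus_trajectory")
  }
  expect_equal(fragmentation_time(mk(NA), 1.1), Inf)
  expect_equal(fragmentation_time(mk(6), 1.1), 0.5)
  broken <- mk(1)
  expect_error(fragmentation_time(broken, 1.1), "single chain")
})

test_that("release percentage follows the area-loss definition", {
  expect_equal(as.numeric(release_percent(100, 100)), 0)
  expect_equal(as.numeric(release_percent(100, 0)), 100)
  expect_equal(as.numeric(release_percent(200, 50)), 75)
  r <- release_percent(100, c(120, 80))
  expect_equal(attr(r, "clipped"), c(TRUE, FALSE))
  expect_error(release_percent(0, 10), "positive")
})

test_that("trajectories round-trip through extended XYZ within 1e-9", {
  p <- ref_particle()
  cfg <- simulation_config(p, init_chain(3, p), field_preset("walking"),
                           arena_flat(), duration = 0.05, stride = 10)
  tr <- run_simulation(cfg)
  path <- tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, path)
  back <- read_trajectory_xyz(path)
  expect_equal(back$times, tr$times, tolerance = 1e-9)
  expect_equal(back$pos, tr$pos, tolerance = 1e-9)
  expect_equal(back$mu, tr$mu, tolerance = 1e-9)
  expect_equal(back$field, unname(tr$field), tolerance = 1e-9)
  unlink(path)
})

test_that("metrics tables carry one row per stored frame", {
  p <- ref_particle()
  cfg <- simulation_config(p, init_chain(3, p), field_preset("walking"),
                           arena_flat(), duration = 0.05, stride = 10)
  tr <- run_simulation(cfg)
  m <- trajectory_metrics(tr)
  expect_equal(nrow(m), n_frames(tr))
  expect_true(all(c("time_s", "n_chains", "efficiency") %in% names(m)))
})

test_that("scenario configs are validated with named errors", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: walking", "f_Hz: 2"), path)
  cfg <- read_scenario_config(path)
  expect_equal(cfg$f_Hz, 2)
  writeLines(c("scenario: walking", "warp_speed: 9"), path)
  expect_error(read_scenario_config(path), "warp_speed")
  writeLines("seed: 3", path)
  expect_error(read_scenario_config(path), "field")
  unlink(path)
})
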