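# Shared fixtures and small numerical oracles for the test suite.

ref_particle <- function() make_particle(janus_geometry(), material_params())

fab_particle <- function() fabricated_particle()

sigma_ref <- 6e-4

# central-difference gradient of a scalar function of a 3-vector
num_grad <- function(f, x, h = 1e-6) {
  vapply(1:3, function(k) {
    e <- numeric(3)
    e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# brute-force connected components over a full distance matrix (union-find)
brute_components <- function(pos, cutoff) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  d <- as.matrix(stats::dist(pos))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d[i, j] < cutoff) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# a random dipole-pair configuration outside the saturation radius
random_dipole_config <- function(r_min = 0.9, r_max = 2.5) {
  r1 <- stats::runif(3, -1, 1)
  dir <- runit()
  r2 <- r1 + stats::runif(1, r_min, r_max) * dir
  list(r1 = r1, r2 = r2, m1 = runit() * stats::runif(1, 0.5, 2),
       m2 = runit() * stats::runif(1, 0.5, 2))
}
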