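# Trajectory post-processing: chain detection, assembly metrics, gait
# kinematics, fragmentation timing and the cargo-release statistic.

#' Detect chains in a frame
#'
#' Partitions the particles of one frame into chains: connected components
#' of the contact graph with an edge wherever the center-to-center distance
#' is below `bond_cutoff`. Each component is ordered by its projection onto
#' the component's principal axis, with ties broken by particle id, so the
#' output is permutation-invariant and deterministic.
#'
#' @param frame A frame from [trajectory_frame()], or an `N x 3` position
#'   matrix.
#' @param bond_cutoff Bond distance cutoff in meters (must exceed the
#'   particle diameter used in the run).
#' @return Object of class `chain_partition`: list with `chains` (list of
#'   integer id vectors), `sizes`, and `n` (total particles).
#' @export
detect_chains <- function(frame, bond_cutoff) {
  pos <- if (is.list(frame)) frame$pos else frame
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (bond_cutoff <= 0) stop("bond_cutoff must be positive")
  comp <- seq_len(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(pos))
    adj <- d < bond_cutoff
    # label propagation (union-find light); n is small
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        nb <- which(adj[i, ])
        m <- min(comp[nb])
        if (m < comp[i]) {
          comp[comp %in% comp[nb]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  labels <- unique(comp)
  chains <- lapply(labels, function(l) {
    ids <- which(comp == l)
    if (length(ids) > 2) {
      p <- pos[ids, , drop = FALSE]
      cen <- colMeans(p)
      ax <- svd(sweep(p, 2, cen))$v[, 1]
      proj <- as.numeric(sweep(p, 2, cen) %*% ax)
      ids <- ids[order(proj, ids)]
    }
    ids
  })
  # deterministic chain order: by smallest member id
  chains <- chains[order(vapply(chains, min, integer(1)))]
  structure(list(chains = chains,
                 sizes = vapply(chains, length, integer(1)),
                 n = n),
            class = "chain_partition")
}

#' @export
print.chain_partition <- function(x, ...) {
  cat(sprintf("%d chain(s) over %d particles; sizes: %s\n",
              length(x$chains), x$n, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Assembly efficiency
#'
#' Fraction of the particle population incorporated into the single largest
#' chain.
#'
#' @param partition A [detect_chains()] result.
#' @return A fraction in `[1/N, 1]`.
#' @export
assembly_efficiency <- function(partition) {
  stopifnot(inherits(partition, "chain_partition"))
  if (partition$n == 0) stop("empty partition")
  max(partition$sizes) / partition$n
}

#' Offset angle of a bonded dimer
#'
#' Angle between the center-to-center vector of two bonded particles and
#' their common dipole direction (the mean of the two unit dipoles). A
#' perfect head-to-tail dimer has offset 0 deg; centers displaced
#' perpendicular to the dipoles give 90 deg. The zigzag stagger of assembled
#' chains is this angle at the pair level.
#'
#' @param frame A frame from [trajectory_frame()] containing exactly the two
#'   particles, or a list with `pos` (`2 x 3`) and `mu` (`2 x 3`).
#' @param bond_cutoff Optional bond cutoff (m); when given, an unbonded pair
#'   is rejected.
#' @return Offset angle in degrees, in `[0, 90]`.
#' @export
offset_angle <- function(frame, bond_cutoff = NULL) {
  pos <- as.matrix(frame$pos)
  mu <- as.matrix(frame$mu)
  if (nrow(pos) != 2) stop("offset_angle expects exactly two particles")
  dvec <- pos[2, ] - pos[1, ]
  dn <- sqrt(sum(dvec^2))
  if (!is.null(bond_cutoff) && dn >= bond_cutoff) {
    stop("particles are not bonded (distance exceeds bond_cutoff)")
  }
  mbar <- mu[1, ] + mu[2, ]
  if (sqrt(sum(mbar^2)) < 1e-12) stop("dipoles are antiparallel; no common direction")
  cosang <- abs(sum(dvec * mbar)) / (dn * sqrt(sum(mbar^2)))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Centroid displacement and velocity of a trajectory
#'
#' Centroid of all particles per frame, displacement from the first frame,
#' and central-difference velocity.
#'
#' @param trajectory A `janus_trajectory`.
#' @return List with `times` (s), `centroid` (`frames x 3`, m),
#'   `displacement` (m, from frame 1), `velocity` (`frames x 3`, m/s,
#'   central differences; one-sided at the ends), `speed` (m/s).
#' @export
centroid_kinematics <- function(trajectory) {
  nf <- n_frames(trajectory)
  if (nf < 2) stop("need at least two frames")
  cen <- apply(trajectory$pos, c(1, 3), mean)
  t <- trajectory$times
  vel <- matrix(NA_real_, nf, 3)
  vel[1, ] <- (cen[2, ] - cen[1, ]) / (t[2] - t[1])
  vel[nf, ] <- (cen[nf, ] - cen[nf - 1, ]) / (t[nf] - t[nf - 1])
  if (nf > 2) {
    idx <- 2:(nf - 1)
    vel[idx, ] <- (cen[idx + 1, ] - cen[idx - 1, ]) / (t[idx + 1] - t[idx - 1])
  }
  disp <- sqrt(rowSums(sweep(cen, 2, cen[1, ])^2))
  list(times = t, centroid = cen, displacement = disp, velocity = vel,
       speed = sqrt(rowSums(vel^2)))
}

#' Mean locomotion speed over whole field periods
#'
#' Net centroid displacement divided by elapsed time, measured over the
#' largest whole number of field periods that fits after discarding an
#' initial transient. Using whole periods removes the within-cycle wobble of
#' the gaits; using net displacement measures transport rather than body
#' motion.
#'
#' @param trajectory A `janus_trajectory`.
#' @param f_Hz Field frequency defining the period (Hz).
#' @param transient_periods Number of initial periods to discard. Default 2.
#' @param direction Optional length-3 vector: project the displacement onto
#'   this direction (signed speed); `NULL` uses the unsigned net
#'   displacement.
#' @return Mean speed in m/s.
#' @export
mean_speed <- function(trajectory, f_Hz, transient_periods = 2,
                       direction = NULL) {
  t <- trajectory$times
  period <- 1 / f_Hz
  t_begin <- t[1] + transient_periods * period
  n_per <- floor((t[length(t)] - t_begin) / period)
  if (n_per < 1) stop("trajectory shorter than transient + one field period")
  t_end <- t_begin + n_per * period
  i0 <- which.min(abs(t - t_begin))
  i1 <- which.min(abs(t - t_end))
  cen <- apply(trajectory$pos, c(1, 3), mean)
  d <- cen[i1, ] - cen[i0, ]
  dt <- t[i1] - t[i0]
  if (is.null(direction)) {
    sqrt(sum(d^2)) / dt
  } else {
    sum(d * unit_vec(direction)) / dt
  }
}

#' Time to chain fragmentation
#'
#' Scans a trajectory whose initial frame is a single chain and returns the
#' elapsed time until the chain first splits into two or more connected
#' components (`Inf` if it never does). With `complete = TRUE`, returns the
#' time until the chain has fully dispersed into singletons instead.
#'
#' @param trajectory A `janus_trajectory`.
#' @param bond_cutoff Bond cutoff in meters.
#' @param complete If `TRUE`, time to full dispersal rather than first split.
#' @return Elapsed seconds from the first frame, or `Inf`.
#' @export
fragmentation_time <- function(trajectory, bond_cutoff, complete = FALSE) {
  nf <- n_frames(trajectory)
  first <- detect_chains(trajectory_frame(trajectory, 1), bond_cutoff)
  if (length(first$chains) != 1) {
    stop("initial frame is not a single chain")
  }
  for (i in 2:nf) {
    part <- detect_chains(trajectory_frame(trajectory, i), bond_cutoff)
    hit <- if (complete) all(part$sizes == 1) else length(part$chains) >= 2
    if (hit) return(trajectory$times[i] - trajectory$times[1])
  }
  Inf
}

#' Cumulative cargo release percentage
#'
#' Image-based release statistic: with `A0` the initial fluorescence area of
#' a microrobot and `At` its area at time t, the cumulative release is
#' `100 * (A0 - At) / A0`. Values of `At` exceeding `A0` yield negative
#' release; these are flagged via the `"clipped"` attribute rather than
#' silently clipped.
#'
#' @param A0 Initial area (arbitrary units, `> 0`).
#' @param At Area(s) at later time points.
#' @return Release percentage(s) with attribute `clipped` marking entries
#'   where `At > A0`.
#' @export
release_percent <- function(A0, At) {
  if (A0 <= 0) stop("A0 must be positive")
  out <- 100 * (A0 - At) / A0
  attr(out, "clipped") <- At > A0
  out
}
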