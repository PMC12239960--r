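# Time-dependent external field programs B(t). All constructors store
# amplitudes in mT, frequencies in Hz, angles in radians; evaluation returns
# mT. The integrator consumes a compiled reduced-unit segment table.

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector cannot be normalized")
  v / n
}

# Rodrigues rotation of vector v about unit axis by angle (radians)
rotate_about <- function(v, axis, angle) {
  axis <- unit_vec(axis)
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_field_program <- function(variant, B0_mT, f_Hz = 0, phase = 0,
                              e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                              e3 = c(0, 0, 1), a1 = 0, a2 = 0,
                              segments = NULL, label = variant) {
  structure(
    list(variant = variant, B0_mT = B0_mT, f_Hz = f_Hz, phase = phase,
         e1 = e1, e2 = e2, e3 = e3, a1 = a1, a2 = a2,
         segments = segments, label = label),
    class = "field_program"
  )
}

#' Static uniform field
#'
#' @param B0_mT Field amplitude in mT.
#' @param direction 3-vector giving the field direction (normalized
#'   internally).
#' @return A `field_program`.
#' @export
field_static <- function(B0_mT, direction = c(0, 0, 1)) {
  new_field_program("static", B0_mT, e1 = unit_vec(direction),
                    label = "static")
}

#' Rotating field in a plane
#'
#' `B(t) = B0 (e1 cos(2 pi f t + phase) + e2 sin(2 pi f t + phase))`.
#' For the `"yz"` plane with zero phase, `B(0)` points along +y and a quarter
#' period later along +z, so the field rolls like a wheel advancing along +y.
#'
#' @param B0_mT Amplitude, mT.
#' @param f_Hz Rotation frequency, Hz.
#' @param plane `"yz"`, `"xy"`, `"xz"`, or a list `list(e1 =, e2 =)` of two
#'   orthonormal vectors spanning the rotation plane.
#' @param phase Initial phase, rad.
#' @return A `field_program`.
#' @export
field_rotating <- function(B0_mT, f_Hz, plane = "yz", phase = 0) {
  if (is.character(plane)) {
    basis <- switch(plane,
      yz = list(e1 = c(0, 1, 0), e2 = c(0, 0, 1)),
      xy = list(e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
      xz = list(e1 = c(1, 0, 0), e2 = c(0, 0, 1)),
      stop("unknown plane '", plane, "'")
    )
  } else {
    basis <- plane
  }
  new_field_program("rotating", B0_mT, f_Hz, phase,
                    e1 = unit_vec(basis$e1), e2 = unit_vec(basis$e2),
                    label = "rotating")
}

#' Bounded oscillating field
#'
#' The field direction sweeps sinusoidally between two angular bounds in the
#' plane spanned by `e1` and `e2`: the realized angle (measured from `e1`
#' toward `e2`) is `theta(t) = theta_mid + theta_half * sin(2 pi f t +
#' phase)` with `theta_mid = mean(bounds)` and `theta_half = diff(bounds)/2`,
#' so the sweep exactly attains both bounds once per period.
#'
#' @param B0_mT Amplitude, mT.
#' @param f_Hz Sweep frequency, Hz.
#' @param bounds Length-2 numeric, angular bounds in radians.
#' @param e1,e2 Orthonormal vectors spanning the oscillation plane; the angle
#'   is measured from `e1`.
#' @param phase Initial phase of the sinusoidal sweep, rad.
#' @return A `field_program`.
#' @export
field_oscillating <- function(B0_mT, f_Hz, bounds,
                              e1 = c(0, 1, 0), e2 = c(0, 0, 1),
                              phase = 0) {
  stopifnot(length(bounds) == 2, bounds[2] > bounds[1])
  new_field_program("oscillating", B0_mT, f_Hz, phase,
                    e1 = unit_vec(e1), e2 = unit_vec(e2),
                    a1 = mean(bounds), a2 = diff(bounds) / 2,
                    label = "oscillating")
}

#' Conical (precessing) field
#'
#' The field rotates on a cone of half-angle `half_angle` about `axis` at
#' frequency `f_Hz`; its magnitude is constant `B0_mT`.
#'
#' @param B0_mT Amplitude, mT.
#' @param f_Hz Precession frequency, Hz.
#' @param axis Cone axis (3-vector).
#' @param half_angle Cone half-angle from the axis, rad.
#' @param phase Initial phase, rad.
#' @return A `field_program`.
#' @export
field_conical <- function(B0_mT, f_Hz, axis = c(0, 0, 1),
                          half_angle = 80 * pi / 180, phase = 0) {
  axis <- unit_vec(axis)
  # orthonormal in-plane basis perpendicular to the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit_vec(pracma_cross(ref, axis))
  e2 <- unit_vec(pracma_cross(axis, e1))
  new_field_program("conical", B0_mT, f_Hz, phase, e1 = e1, e2 = e2,
                    e3 = axis, a1 = cos(half_angle), a2 = sin(half_angle),
                    label = "conical")
}

#' Piecewise field schedule
#'
#' Concatenates field programs in time. Each element runs for its stated
#' duration with its own clock starting at zero; past the end of the final
#' segment, that segment keeps running (the schedule holds its last program).
#'
#' @param ... Alternating pairs via `list(duration_s, program)`, or a single
#'   list of such pairs.
#' @return A `field_program` of variant `"schedule"`.
#' @examples
#' sched <- field_schedule(
#'   list(2, field_rotating(4, 1, "yz")),
#'   list(1, field_rotating(4, 20, "yz"))
#' )
#' @export
field_schedule <- function(...) {
  segs <- list(...)
  if (length(segs) == 1 && !inherits(segs[[1]][[2]], "field_program")) {
    segs <- segs[[1]]
  }
  for (s in segs) {
    stopifnot(length(s) == 2, is.numeric(s[[1]]), s[[1]] > 0,
              inherits(s[[2]], "field_program"))
    if (s[[2]]$variant == "schedule") stop("schedules cannot be nested")
  }
  new_field_program("schedule", B0_mT = NA_real_, segments = segs,
                    label = "schedule")
}

#' Evaluate a field program
#'
#' @param program A `field_program`.
#' @param t Time(s) in seconds, `t >= 0`.
#' @return A length-3 vector (mT) for scalar `t`, or an `n x 3` matrix for
#'   vector `t`.
#' @export
evaluate_field <- function(program, t) {
  stopifnot(inherits(program, "field_program"))
  if (any(t < 0)) stop("t must be nonnegative")
  if (length(t) > 1) {
    return(t(vapply(t, function(tt) evaluate_field(program, tt),
                    numeric(3))))
  }
  p <- program
  switch(p$variant,
    static = p$B0_mT * p$e1,
    rotating = {
      ang <- 2 * pi * p$f_Hz * t + p$phase
      p$B0_mT * (p$e1 * cos(ang) + p$e2 * sin(ang))
    },
    oscillating = {
      theta <- p$a1 + p$a2 * sin(2 * pi * p$f_Hz * t + p$phase)
      p$B0_mT * (p$e1 * cos(theta) + p$e2 * sin(theta))
    },
    conical = {
      ang <- 2 * pi * p$f_Hz * t + p$phase
      p$B0_mT * (p$a1 * p$e3 + p$a2 * (p$e1 * cos(ang) + p$e2 * sin(ang)))
    },
    schedule = {
      tt <- t
      for (i in seq_along(p$segments)) {
        dur <- p$segments[[i]][[1]]
        last <- i == length(p$segments)
        if (tt < dur || last) return(evaluate_field(p$segments[[i]][[2]], tt))
        tt <- tt - dur
      }
    },
    stop("unknown field variant '", p$variant, "'")
  )
}

#' Reverse the direction of a field program
#'
#' Negates the field at every instant (used by the chain-to-ring reversal
#' protocol, where flipping a static field makes the chain ends curl around).
#'
#' @param program A `field_program`.
#' @return The negated program.
#' @export
field_reverse <- function(program) {
  stopifnot(inherits(program, "field_program"))
  if (program$variant == "schedule") {
    program$segments <- lapply(program$segments,
                               function(s) list(s[[1]], field_reverse(s[[2]])))
    return(program)
  }
  program$e1 <- -program$e1
  program$e2 <- -program$e2
  program$e3 <- -program$e3
  program
}

#' Named actuation presets
#'
#' Fully parameterized field programs for the standard protocols:
#' \describe{
#'   \item{walking}{4 mT field rotating in the yz plane at 1 Hz; the chain
#'     tumbles end over end along +y.}
#'   \item{crawling}{6 mT field oscillating in the yz plane at 3 Hz between
#'     -2pi/3 and +pi/3 measured from +y; the asymmetric sweep drags the
#'     chain forward.}
#'   \item{swinging}{6 mT field oscillating at 2 Hz through a full -pi..pi
#'     sweep about +x, with the oscillation plane tilted by alpha = -30 deg
#'     about x; the tilt lifts the leading end.}
#'   \item{lateral}{6 mT field oscillating at 3 Hz between -pi/3 and +pi/3
#'     about +x with a 6 deg pitch and the sweep plane tilted -30 deg from
#'     vertical.}
#'   \item{assemble_precession}{6 mT conical field precessing about +z at
#'     32 Hz with an 80 deg cone half-angle (near-horizontal precession);
#'     synchronizes upright spinning and pulls particles together.}
#'   \item{assemble_rotating}{4 mT yz rotating field at 1 Hz; the
#'     low-frequency protocol under which walking fragments catch up and
#'     merge into longer chains.}
#'   \item{assemble_oscillating}{6 mT horizontal field oscillating at 2 Hz
#'     between -pi/3 and +pi/3 about +y in the xy plane; time-averaged
#'     dipolar attraction is strongest along y, so chains condense along it.}
#'   \item{disassemble_20Hz}{4 mT yz rotating field at 20 Hz, beyond the
#'     chain step-out frequency; chains fragment.}
#'   \item{ring_reversal}{4 mT static +y field for 1 s, then the reversed
#'     field; chain ends follow the reversal faster than the middle.}
#' }
#'
#' @param name Preset name (see Details).
#' @param B0_mT,f_Hz Optional overrides of the preset amplitude/frequency.
#' @return A `field_program`.
#' @export
field_preset <- function(name, B0_mT = NULL, f_Hz = NULL) {
  known <- c("walking", "crawling", "swinging", "lateral",
             "assemble_precession", "assemble_rotating",
             "assemble_oscillating", "disassemble_20Hz", "ring_reversal")
  if (!name %in% known) {
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  p <- switch(name,
    walking = field_rotating(4, 1, "yz"),
    crawling = field_oscillating(6, 3, bounds = c(-2 * pi / 3, pi / 3),
                                 e1 = c(0, 1, 0), e2 = c(0, 0, 1)),
    swinging = {
      alpha <- -30 * pi / 180
      e2 <- rotate_about(c(0, 1, 0), c(1, 0, 0), alpha)
      field_oscillating(6, 2, bounds = c(-pi, pi),
                        e1 = c(1, 0, 0), e2 = e2)
    },
    lateral = {
      tilt <- -30 * pi / 180
      pitch <- 6 * pi / 180
      n <- rotate_about(c(0, 0, 1), c(1, 0, 0), tilt)   # tilted sweep axis
      e1 <- unit_vec(cos(pitch) * c(1, 0, 0) + sin(pitch) * n)
      e2 <- unit_vec(pracma_cross(n, e1))
      field_oscillating(6, 3, bounds = c(-pi / 3, pi / 3), e1 = e1, e2 = e2)
    },
    assemble_precession = field_conical(6, 32, axis = c(0, 0, 1),
                                        half_angle = 80 * pi / 180),
    assemble_rotating = field_rotating(4, 1, "yz"),
    assemble_oscillating = field_oscillating(6, 2, bounds = c(-pi / 3, pi / 3),
                                             e1 = c(0, 1, 0),
                                             e2 = c(1, 0, 0)),
    disassemble_20Hz = field_rotating(4, 20, "yz"),
    ring_reversal = field_schedule(
      list(1, field_static(4, c(0, 1, 0))),
      list(1, field_static(4, c(0, -1, 0)))
    )
  )
  if (!is.null(B0_mT)) {
    if (p$variant == "schedule") {
      p$segments <- lapply(p$segments, function(s) {
        s[[2]]$B0_mT <- B0_mT
        s
      })
    } else {
      p$B0_mT <- B0_mT
    }
  }
  if (!is.null(f_Hz) && p$variant != "schedule") p$f_Hz <- f_Hz
  p$label <- name
  p
}

# Compile a field program into the reduced-unit segment table consumed by the
# C++ integrator. Columns: t0, t1 (tau), variant code, B0*, f (1/tau), phase,
# e1 (3), e2 (3), e3 (3), a1, a2.
compile_field_program <- function(program, units) {
  stopifnot(inherits(program, "field_program"), inherits(units, "unit_system"))
  code <- c(static = 0, rotating = 1, oscillating = 2, conical = 3)
  one <- function(p, t0, t1) {
    B0_red <- units$to_reduced(p$B0_mT * 1e-3, "field")
    f_red <- p$f_Hz * units$tau
    c(t0, t1, code[[p$variant]], B0_red, f_red, p$phase,
      p$e1, p$e2, p$e3, p$a1, p$a2)
  }
  if (program$variant == "schedule") {
    rows <- list()
    t0 <- 0
    for (i in seq_along(program$segments)) {
      seg <- program$segments[[i]]
      t1 <- if (i == length(program$segments)) Inf else t0 + seg[[1]] / units$tau
      rows[[i]] <- one(seg[[2]], t0, t1)
      t0 <- t0 + seg[[1]] / units$tau
    }
    mat <- do.call(rbind, rows)
  } else {
    mat <- matrix(one(program, 0, Inf), nrow = 1)
  }
  colnames(mat) <- c("t0", "t1", "variant", "B0", "f", "phase",
                     "e1x", "e1y", "e1z", "e2x", "e2y", "e2z",
                     "e3x", "e3y", "e3z", "a1", "a2")
  mat
}
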