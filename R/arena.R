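# Arena construction: planar walls (finite rectangles or infinite planes)
# with per-wall friction coefficients. Coordinate convention: z up, gravity
# along -z, floor at z = 0, stairs and inclines ascend along +y (the gait
# fields act in the yz plane, so chains advance along +y).

#' Construct a planar wall
#'
#' A wall is a (possibly infinite) rectangle given by a center point, an
#' outward unit normal, two in-plane axes and half-extents along them.
#' Particles interact with the closest point of the rectangle, so edges and
#' corners are handled by closest-feature contact.
#'
#' @param point Center point of the rectangle (m).
#' @param normal Outward unit normal.
#' @param e1,e2 In-plane axes (orthonormal with `normal`); chosen
#'   automatically when `NULL`.
#' @param half1,half2 Half-extents along `e1`, `e2` in meters (`Inf` for an
#'   unbounded direction).
#' @param lambda_static,lambda_dynamic Coulomb friction coefficients for
#'   particles in chain contact with this wall.
#' @param id Wall identifier string.
#' @return Object of class `wall`.
#' @export
make_wall <- function(point, normal, e1 = NULL, e2 = NULL,
                      half1 = Inf, half2 = Inf,
                      lambda_static = 0.5, lambda_dynamic = 0.4,
                      id = "wall") {
  normal <- unit_vec(normal)
  if (is.null(e1)) {
    ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit_vec(pracma_cross(ref, normal))
  } else {
    e1 <- unit_vec(e1)
  }
  if (is.null(e2)) e2 <- unit_vec(pracma_cross(normal, e1))
  else e2 <- unit_vec(e2)
  if (is.finite(half1) && half1 <= 0 || is.finite(half2) && half2 <= 0) {
    stop("wall half-extents must be positive")
  }
  structure(
    list(point = point, normal = normal, e1 = e1, e2 = e2,
         half1 = half1, half2 = half2,
         lambda_static = lambda_static, lambda_dynamic = lambda_dynamic,
         id = id),
    class = "wall"
  )
}

new_arena <- function(walls, label) {
  nz <- vapply(walls, function(w) w$normal[3], numeric(1))
  if (!any(nz > 0)) stop("arena must contain at least one floor-like wall")
  structure(list(walls = walls, label = label), class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("Arena '%s' with %d wall(s)\n", x$label, length(x$walls)))
  invisible(x)
}

#' Flat floor arena
#' @param lambda_static,lambda_dynamic Floor friction coefficients.
#' @return An `arena` with one infinite floor at z = 0.
#' @export
arena_flat <- function(lambda_static = 0.5, lambda_dynamic = 0.4) {
  new_arena(list(make_wall(c(0, 0, 0), c(0, 0, 1),
                           lambda_static = lambda_static,
                           lambda_dynamic = lambda_dynamic, id = "floor")),
            "flat")
}

#' Inclined plane arena
#'
#' A single infinite plane through the origin, ascending along +y with slope
#' `angle`; its normal is `(0, -sin angle, cos angle)`.
#'
#' @param angle Incline angle in radians.
#' @param lambda_static,lambda_dynamic Friction coefficients.
#' @return An `arena`.
#' @export
arena_incline <- function(angle, lambda_static = 0.5, lambda_dynamic = 0.4) {
  if (angle <= 0 || angle >= pi / 2) stop("incline angle must be in (0, pi/2)")
  new_arena(list(make_wall(c(0, 0, 0), c(0, -sin(angle), cos(angle)),
                           lambda_static = lambda_static,
                           lambda_dynamic = lambda_dynamic, id = "incline")),
            sprintf("incline_%.0fdeg", angle * 180 / pi))
}

#' Staircase arena
#'
#' Axis-aligned stairs ascending along +y starting at y = 0: `count` risers
#' (outward normal -y) of height `rise` at y = 0, tread, 2 tread, ... and the
#' treads between them at heights rise, 2 rise, .... The final tread extends
#' far along +y as a top platform, and an infinite base floor at z = 0 covers
#' the approach.
#'
#' @param tread Tread depth (m).
#' @param rise Riser height (m).
#' @param count Number of steps.
#' @param width Half-width of the staircase along x (m).
#' @param lambda_static,lambda_dynamic Friction coefficients.
#' @return An `arena`.
#' @export
arena_stairs <- function(tread = 2e-3, rise = 2e-3, count = 3,
                         width = 0.05,
                         lambda_static = 0.5, lambda_dynamic = 0.4) {
  if (tread <= 0 || rise <= 0 || count < 1) {
    stop("stairs require positive tread, rise and count")
  }
  walls <- list(make_wall(c(0, 0, 0), c(0, 0, 1),
                          lambda_static = lambda_static,
                          lambda_dynamic = lambda_dynamic, id = "base_floor"))
  top_len <- 0.05
  for (k in seq_len(count)) {
    walls[[length(walls) + 1]] <- make_wall(
      point = c(0, (k - 1) * tread, (k - 0.5) * rise),
      normal = c(0, -1, 0), e1 = c(1, 0, 0), e2 = c(0, 0, 1),
      half1 = width, half2 = rise / 2,
      lambda_static = lambda_static, lambda_dynamic = lambda_dynamic,
      id = sprintf("riser_%d", k))
    last <- k == count
    half_t <- if (last) top_len / 2 else tread / 2
    yc <- (k - 1) * tread + half_t
    walls[[length(walls) + 1]] <- make_wall(
      point = c(0, yc, k * rise),
      normal = c(0, 0, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
      half1 = width, half2 = half_t,
      lambda_static = lambda_static, lambda_dynamic = lambda_dynamic,
      id = if (last) "top_platform" else sprintf("tread_%d", k))
  }
  new_arena(walls, sprintf("stairs_%dx", count))
}

#' Single tall step
#'
#' One riser of height `height` at y = 0 with an elevated platform behind it
#' (a staircase with `count = 1`). Used by the merge-to-climb scenario where
#' the obstacle exceeds the length of short chain fragments.
#'
#' @param height Step height (m).
#' @param ... Passed to [arena_stairs()].
#' @return An `arena`.
#' @export
arena_step <- function(height, ...) {
  a <- arena_stairs(tread = 0.05, rise = height, count = 1, ...)
  a$label <- sprintf("step_%.1fmm", height * 1e3)
  a
}

#' Channel arena
#'
#' Two parallel vertical walls on an infinite floor forming a channel of
#' inner width `width` along y, centered on x = 0, spanning y in
#' `[y0, y0 + length]`.
#'
#' @param width Inner channel width (m).
#' @param wall_height Height of the channel walls (m).
#' @param length Channel length along y (m).
#' @param y0 Channel entrance coordinate (m).
#' @param lambda_static,lambda_dynamic Friction coefficients.
#' @return An `arena`.
#' @export
arena_channel <- function(width = 1.5e-3, wall_height = 5e-3,
                          length = 6e-3, y0 = 0,
                          lambda_static = 0.5, lambda_dynamic = 0.4) {
  if (width <= 0 || wall_height <= 0 || length <= 0) {
    stop("channel dimensions must be positive")
  }
  yc <- y0 + length / 2
  walls <- list(
    make_wall(c(0, 0, 0), c(0, 0, 1),
              lambda_static = lambda_static,
              lambda_dynamic = lambda_dynamic, id = "floor"),
    make_wall(c(-width / 2, yc, wall_height / 2), c(1, 0, 0),
              e1 = c(0, 1, 0), e2 = c(0, 0, 1),
              half1 = length / 2, half2 = wall_height / 2,
              lambda_static = lambda_static,
              lambda_dynamic = lambda_dynamic, id = "wall_left"),
    make_wall(c(width / 2, yc, wall_height / 2), c(-1, 0, 0),
              e1 = c(0, 1, 0), e2 = c(0, 0, 1),
              half1 = length / 2, half2 = wall_height / 2,
              lambda_static = lambda_static,
              lambda_dynamic = lambda_dynamic, id = "wall_right")
  )
  new_arena(walls, "channel")
}

#' Railing obstacle
#'
#' A box-shaped railing of height `height` and thickness `thickness` across
#' the path at y = `y0`, on an infinite floor.
#'
#' @param height Railing height (m).
#' @param thickness Railing thickness along y (m).
#' @param y0 Railing center position (m).
#' @param width Half-width along x (m).
#' @param lambda_static,lambda_dynamic Friction coefficients.
#' @return An `arena`.
#' @export
arena_railing <- function(height = 3e-3, thickness = 1e-3, y0 = 5e-3,
                          width = 0.05,
                          lambda_static = 0.5, lambda_dynamic = 0.4) {
  if (height <= 0 || thickness <= 0) stop("railing dimensions must be positive")
  walls <- list(
    make_wall(c(0, 0, 0), c(0, 0, 1),
              lambda_static = lambda_static,
              lambda_dynamic = lambda_dynamic, id = "floor"),
    make_wall(c(0, y0 - thickness / 2, height / 2), c(0, -1, 0),
              e1 = c(1, 0, 0), e2 = c(0, 0, 1),
              half1 = width, half2 = height / 2,
              lambda_static = lambda_static,
              lambda_dynamic = lambda_dynamic, id = "railing_front"),
    make_wall(c(0, y0 + thickness / 2, height / 2), c(0, 1, 0),
              e1 = c(1, 0, 0), e2 = c(0, 0, 1),
              half1 = width, half2 = height / 2,
              lambda_static = lambda_static,
              lambda_dynamic = lambda_dynamic, id = "railing_back"),
    make_wall(c(0, y0, height), c(0, 0, 1),
              e1 = c(1, 0, 0), e2 = c(0, 1, 0),
              half1 = width, half2 = thickness / 2,
              lambda_static = lambda_static,
              lambda_dynamic = lambda_dynamic, id = "railing_top")
  )
  new_arena(walls, "railing")
}

#' Column array obstacle course
#'
#' A row of square columns (side `side`, height `height`) spaced `spacing`
#' apart along x, centered at y = `y0`, on an infinite floor.
#'
#' @param height Column height (m).
#' @param spacing Center-to-center spacing along x (m).
#' @param count Number of columns.
#' @param side Column cross-section side length (m).
#' @param y0 Row position (m).
#' @param lambda_static,lambda_dynamic Friction coefficients.
#' @return An `arena`.
#' @export
arena_columns <- function(height = 2e-3, spacing = 2e-3, count = 3,
                          side = 1e-3, y0 = 5e-3,
                          lambda_static = 0.5, lambda_dynamic = 0.4) {
  walls <- list(make_wall(c(0, 0, 0), c(0, 0, 1),
                          lambda_static = lambda_static,
                          lambda_dynamic = lambda_dynamic, id = "floor"))
  xs <- (seq_len(count) - (count + 1) / 2) * spacing
  for (i in seq_len(count)) {
    x <- xs[i]
    faces <- list(
      list(c(x, y0 - side / 2, height / 2), c(0, -1, 0), c(1, 0, 0), side / 2),
      list(c(x, y0 + side / 2, height / 2), c(0, 1, 0), c(1, 0, 0), side / 2),
      list(c(x - side / 2, y0, height / 2), c(-1, 0, 0), c(0, 1, 0), side / 2),
      list(c(x + side / 2, y0, height / 2), c(1, 0, 0), c(0, 1, 0), side / 2)
    )
    for (j in seq_along(faces)) {
      f <- faces[[j]]
      walls[[length(walls) + 1]] <- make_wall(
        f[[1]], f[[2]], e1 = f[[3]], e2 = c(0, 0, 1),
        half1 = f[[4]], half2 = height / 2,
        lambda_static = lambda_static, lambda_dynamic = lambda_dynamic,
        id = sprintf("column_%d_face_%d", i, j))
    }
    walls[[length(walls) + 1]] <- make_wall(
      c(x, y0, height), c(0, 0, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
      half1 = side / 2, half2 = side / 2,
      lambda_static = lambda_static, lambda_dynamic = lambda_dynamic,
      id = sprintf("column_%d_top", i))
  }
  new_arena(walls, "columns")
}

#' Build an arena from a descriptor
#'
#' Dispatcher over the arena constructors: `list(type = "flat")`,
#' `list(type = "incline", angle = )`, `list(type = "stairs", tread = ,
#' rise = , count = )`, `list(type = "channel", width = , ...)`,
#' `list(type = "railing", height = )`, `list(type = "columns", ...)`,
#' `list(type = "step", height = )`.
#'
#' @param spec A list with a `type` element and constructor arguments.
#' @return An `arena`.
#' @export
build_arena <- function(spec) {
  if (inherits(spec, "arena")) return(spec)
  stopifnot(is.list(spec), !is.null(spec$type))
  type <- spec$type
  spec$type <- NULL
  fn <- switch(type,
    flat = arena_flat, incline = arena_incline, stairs = arena_stairs,
    channel = arena_channel, railing = arena_railing,
    columns = arena_columns, step = arena_step,
    stop("unknown arena type '", type, "'")
  )
  do.call(fn, spec)
}

#' Particle-wall contact query
#'
#' Returns the walls within interaction range of a particle center, with the
#' closest-feature contact normal (face, edge or corner of each rectangle)
#' and the signed gap between the particle surface and the wall.
#'
#' @param pos Particle center position (length-3, m).
#' @param R Particle radius (m).
#' @param arena An `arena`.
#' @param margin Gap threshold for reporting a contact, in units of the
#'   particle diameter. Default 0.13 (slightly beyond the wall-force cutoff).
#' @return A list of contacts, each `list(wall_id, normal, gap, dist)`;
#'   empty when the particle is free.
#' @export
nearest_contacts <- function(pos, R, arena, margin = 0.13) {
  stopifnot(inherits(arena, "arena"), length(pos) == 3)
  sigma <- 2 * R
  out <- list()
  for (w in arena$walls) {
    rel <- pos - w$point
    c1 <- sum(rel * w$e1)
    c2 <- sum(rel * w$e2)
    c1 <- max(min(c1, w$half1), -w$half1)
    c2 <- max(min(c2, w$half2), -w$half2)
    q <- w$point + c1 * w$e1 + c2 * w$e2
    v <- pos - q
    dist <- sqrt(sum(v^2))
    if (dist == 0) next
    gap <- dist - R
    if (gap < margin * sigma) {
      out[[length(out) + 1]] <- list(wall_id = w$id, normal = v / dist,
                                     gap = gap, dist = dist,
                                     lambda_static = w$lambda_static,
                                     lambda_dynamic = w$lambda_dynamic)
    }
  }
  out
}

# Compile an arena into the reduced-unit wall table for the C++ integrator.
# Columns: center (3), normal (3), e1 (3), half1, e2 (3), half2, lam_s, lam_d.
compile_arena <- function(arena, units) {
  stopifnot(inherits(arena, "arena"), inherits(units, "unit_system"))
  rows <- lapply(arena$walls, function(w) {
    big <- 1e6  # effectively infinite extent, in sigma
    h1 <- if (is.finite(w$half1)) w$half1 / units$sigma else big
    h2 <- if (is.finite(w$half2)) w$half2 / units$sigma else big
    c(w$point / units$sigma, w$normal, w$e1, h1, w$e2, h2,
      w$lambda_static, w$lambda_dynamic)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("cx", "cy", "cz", "nx", "ny", "nz",
                     "e1x", "e1y", "e1z", "h1", "e2x", "e2y", "e2z", "h2",
                     "lam_s", "lam_d")
  mat
}
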