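# Figure-level scenario registry: named, reproducible experiments combining
# a particle parameterization, initial placement, field schedule and arena,
# each with its own summary metrics. Two particle parameterizations appear:
# the 600-um robot carrying the measured dipole (used for the analytic
# force-scale estimates and the assembly protocols) and the 0.5-mm
# fabricated robot with the volume-scaled dipole (used for the gait and
# terrain scenarios, where the bond-to-weight ratio controls the quality of
# the walking tumble).

# rotating yz field whose handedness drives the walking tumble toward +y
walking_field_forward <- function(f_Hz = 1, B0_mT = 4) {
  field_rotating(B0_mT, f_Hz, plane = list(e1 = c(0, 1, 0), e2 = c(0, 0, -1)))
}

# place a chain on an incline of the given angle (ascending along +y)
init_chain_on_incline <- function(n, particle, angle) {
  init <- init_chain(n, particle)
  rot <- rbind(c(1, 0, 0),
               c(0, cos(angle), -sin(angle)),
               c(0, sin(angle), cos(angle)))
  list(pos = init$pos %*% t(rot), u = init$u %*% t(rot),
       mu = init$mu %*% t(rot))
}

#' Names of the shipped scenarios
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() {
  c("dimer_assembly", "chain_assembly_8", "walking", "crawling", "swinging",
    "lateral", "incline", "stairs", "channel_split",
    "disassemble_reassemble", "merge_to_climb", "ring_reversal")
}

#' Run a named scenario
#'
#' Builds and runs one of the shipped figure-level experiments, computes its
#' summary metrics, and (optionally) writes the trajectory (extended XYZ),
#' per-frame metrics (CSV), the summary (JSON) and the resolved
#' configuration (YAML) to an output directory. Runs are deterministic for a
#' fixed `seed` and parameter set.
#'
#' @param name A scenario name from [scenario_names()], or a config file
#'   path readable by [read_scenario_config()].
#' @param seed Integer seed for the initial placement jitter.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param ... Scenario parameter overrides. Common ones: `n_s` (chain
#'   length), `f_Hz`, `B0_mT`, `duration` (s), `angle_deg` (incline),
#'   `rise`, `tread` (stairs, m), `dt`, `stride`.
#' @return List with `trajectory` (the full run; phases concatenated),
#'   `summary` (named list of metrics), and `config` (resolved parameters).
#' @examples
#' \donttest{
#' res <- run_scenario("walking", seed = 1)
#' res$summary$mean_speed_mm_s
#' }
#' @export
run_scenario <- function(name, seed = 1, out_dir = NULL, ...) {
  overrides <- list(...)
  if (file.exists(name) && grepl("\\.(ya?ml|json)$", name)) {
    cfg <- read_scenario_config(name)
    nm <- cfg$scenario
    if (!is.null(cfg$seed)) seed <- cfg$seed
    cfg <- cfg[setdiff(names(cfg), c("scenario", "seed", "out_dir"))]
    alias <- c(n_particles = "n_s", duration_s = "duration",
               dt_tau = "dt")
    for (a in names(alias)) {
      if (!is.null(cfg[[a]])) {
        cfg[[alias[[a]]]] <- cfg[[a]]
        cfg[[a]] <- NULL
      }
    }
    overrides <- utils::modifyList(cfg, overrides)
    name <- nm
  }
  if (!name %in% scenario_names()) {
    stop("unknown scenario '", name, "'; available: ",
         paste(scenario_names(), collapse = ", "))
  }
  res <- switch(name,
    dimer_assembly = scenario_dimer_assembly(seed, overrides),
    chain_assembly_8 = scenario_chain_assembly_8(seed, overrides),
    walking = scenario_gait("walking", seed, overrides),
    crawling = scenario_gait("crawling", seed, overrides),
    swinging = scenario_gait("swinging", seed, overrides),
    lateral = scenario_gait("lateral", seed, overrides),
    incline = scenario_incline(seed, overrides),
    stairs = scenario_stairs(seed, overrides),
    channel_split = scenario_channel_split(seed, overrides),
    disassemble_reassemble = scenario_disassemble_reassemble(seed, overrides),
    merge_to_climb = scenario_merge_to_climb(seed, overrides),
    ring_reversal = scenario_ring_reversal(seed, overrides)
  )
  res$summary <- c(list(scenario = name, seed = seed,
                        package_version =
                          as.character(utils::packageVersion("janusim"))),
                   res$summary, res$config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_xyz(res$trajectory, file.path(out_dir,
                                                   paste0(name, ".xyz")))
    utils::write.csv(trajectory_metrics(res$trajectory),
                     file.path(out_dir, paste0(name, "_metrics.csv")),
                     row.names = FALSE)
    jsonlite::write_json(res$summary,
                         file.path(out_dir, paste0(name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(res$config, file.path(out_dir,
                                           paste0(name, "_config.yaml")))
  }
  res
}

opt <- function(overrides, key, default) {
  if (!is.null(overrides[[key]])) overrides[[key]] else default
}

bond_m <- function(particle) 1.1 * particle$geometry$sigma

# -- individual scenarios ----------------------------------------------------

# Two robots released upright 6 R apart under the precessing field; they
# synchronize, approach and dimerize with an offset.
scenario_dimer_assembly <- function(seed, ov) {
  p <- make_particle(janus_geometry(), material_params())
  sep <- opt(ov, "separation_m", 6 * p$geometry$radius)
  dur <- opt(ov, "duration", 10)
  init <- init_upright(rbind(c(0, -sep / 2), c(0, sep / 2)), p,
                       jitter = 0.1, seed = seed)
  cfg <- simulation_config(p, init, field_preset("assemble_precession"),
                           arena_flat(), duration = dur,
                           stride = opt(ov, "stride", 200),
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr <- run_simulation(cfg)
  d <- vapply(seq_len(n_frames(tr)), function(i) {
    f <- trajectory_frame(tr, i)
    sqrt(sum((f$pos[1, ] - f$pos[2, ])^2))
  }, numeric(1))
  contact <- 2^(1 / 6) * p$geometry$sigma
  t_bond <- tr$times[which(d < contact)[1]]
  # relax under a static field for a well-defined offset angle
  tr2 <- continue_simulation(tr, field_static(5, c(0, 1, 0)), 2)
  f2 <- trajectory_frame(tr2, -1)
  list(trajectory = tr,
       summary = list(
         bonded = unname(d[length(d)] < contact),
         time_to_contact_s = unname(t_bond),
         final_separation_sigma = unname(d[length(d)] / p$geometry$sigma),
         offset_angle_deg = tryCatch(offset_angle(f2),
                                     error = function(e) NA_real_)),
       config = list(separation_m = sep, duration = dur))
}

# Eight robots in a jittered row condense into a single zigzag chain under
# the precessing field.
scenario_chain_assembly_8 <- function(seed, ov) {
  p <- make_particle(janus_geometry(), material_params())
  n <- opt(ov, "n_s", 8)
  dur <- opt(ov, "duration", 15)
  sig <- p$geometry$sigma
  xy <- cbind(rep(0, n), (seq_len(n) - (n + 1) / 2) * 2 * sig)
  init <- init_upright(xy, p, jitter = 0.1, seed = seed)
  cfg <- simulation_config(p, init, field_preset("assemble_precession"),
                           arena_flat(), duration = dur,
                           stride = opt(ov, "stride", 400),
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr <- run_simulation(cfg)
  part <- detect_chains(trajectory_frame(tr, -1), bond_m(p))
  effs <- vapply(seq(1, n_frames(tr), by = 5), function(i) {
    assembly_efficiency(detect_chains(trajectory_frame(tr, i), bond_m(p)))
  }, numeric(1))
  t_eff <- tr$times[seq(1, n_frames(tr), by = 5)][which(effs == 1)[1]]
  list(trajectory = tr,
       summary = list(
         assembly_efficiency = assembly_efficiency(part),
         n_chains = length(part$chains),
         time_to_full_assembly_s = unname(t_eff)),
       config = list(n_s = n, duration = dur))
}

# Gait scenarios on a flat floor. Walking uses the 0.5-mm fabricated-robot
# parameterization (clean tumbling); crawling/swinging/lateral use the
# 600-um reference robot.
scenario_gait <- function(gait, seed, ov) {
  defaults <- switch(gait,
    walking = list(n_s = 2, f_Hz = 1, B0_mT = 4, axis = "y",
                   dir = c(0, -1, 0), fab = TRUE),
    crawling = list(n_s = 2, f_Hz = 3, B0_mT = 6, axis = "y",
                    dir = c(0, -1, 0), fab = FALSE),
    swinging = list(n_s = 4, f_Hz = 2, B0_mT = 6, axis = "x",
                    dir = c(0, -1, 0), fab = FALSE),
    lateral = list(n_s = 4, f_Hz = 3, B0_mT = 6, axis = "x",
                   dir = c(0, -1, 0), fab = FALSE))
  n_s <- opt(ov, "n_s", defaults$n_s)
  f <- opt(ov, "f_Hz", defaults$f_Hz)
  B0 <- opt(ov, "B0_mT", defaults$B0_mT)
  transient <- opt(ov, "transient_periods", 2)
  n_per <- opt(ov, "n_periods", 10)
  dur <- opt(ov, "duration", (transient + n_per) / f)
  p <- if (defaults$fab) fabricated_particle() else
    make_particle(janus_geometry(), material_params())
  init <- init_chain(n_s, p, axis = defaults$axis)
  cfg <- simulation_config(p, init, field_preset(gait, B0_mT = B0, f_Hz = f),
                           arena_flat(), duration = dur,
                           stride = opt(ov, "stride", 100),
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr <- run_simulation(cfg)
  v_dir <- mean_speed(tr, f, transient, defaults$dir)
  v_net <- mean_speed(tr, f, transient)
  part <- detect_chains(trajectory_frame(tr, -1), bond_m(p))
  list(trajectory = tr,
       summary = list(
         mean_speed_mm_s = v_net * 1e3,
         signed_speed_mm_s = v_dir * 1e3,
         body_lengths_per_s = v_net / (n_s * p$geometry$sigma),
         final_chain_sizes = paste(part$sizes, collapse = ",")),
       config = list(n_s = n_s, f_Hz = f, B0_mT = B0, duration = dur,
                     radius_m = p$geometry$radius))
}

# Walking dimer ascending an inclined plane.
scenario_incline <- function(seed, ov) {
  angle <- opt(ov, "angle_deg", 20) * pi / 180
  n_s <- opt(ov, "n_s", 2)
  f <- opt(ov, "f_Hz", 1)
  dur <- opt(ov, "duration", 10)
  p <- fabricated_particle()
  init <- init_chain_on_incline(n_s, p, angle)
  cfg <- simulation_config(p, init, walking_field_forward(f),
                           arena_incline(angle), duration = dur,
                           stride = opt(ov, "stride", 200),
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr <- run_simulation(cfg)
  k <- centroid_kinematics(tr)
  disp <- k$centroid[nrow(k$centroid), ] - k$centroid[1, ]
  v_up <- sum(disp * c(0, cos(angle), sin(angle))) / diff(range(k$times))
  list(trajectory = tr,
       summary = list(ascending_speed_mm_s = v_up * 1e3,
                      ascended = unname(v_up > 0)),
       config = list(angle_deg = angle * 180 / pi, n_s = n_s, f_Hz = f,
                     duration = dur))
}

# Walking dimer climbing a staircase; risers must be shorter than the chain
# for the tumble to top them.
scenario_stairs <- function(seed, ov) {
  rise <- opt(ov, "rise", 4e-4)
  tread <- opt(ov, "tread", 1.2e-3)
  count <- opt(ov, "count", 3)
  n_s <- opt(ov, "n_s", 2)
  dur <- opt(ov, "duration", 20)
  p <- fabricated_particle()
  init <- init_chain(n_s, p, origin = c(0, -2.5e-3))
  cfg <- simulation_config(p, init, walking_field_forward(opt(ov, "f_Hz", 1)),
                           arena_stairs(tread, rise, count),
                           duration = dur, stride = opt(ov, "stride", 200),
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr <- run_simulation(cfg)
  top <- count * rise
  zmin <- vapply(seq_len(n_frames(tr)), function(i) {
    min(trajectory_frame(tr, i)$pos[, 3])
  }, numeric(1))
  climbed <- any(zmin > top)
  t_climb <- tr$times[which(zmin > top)[1]]
  k <- centroid_kinematics(tr)
  list(trajectory = tr,
       summary = list(climbed_all_treads = unname(climbed),
                      time_to_top_s = unname(t_climb),
                      final_centroid_z_mm =
                        unname(k$centroid[nrow(k$centroid), 3] * 1e3)),
       config = list(rise = rise, tread = tread, count = count, n_s = n_s,
                     duration = dur))
}

# Chain at a narrow channel: swinging entry, a high-frequency split, then
# swinging again; fragments pass where the full chain struggled. Uses a
# finer timestep: the lateral sweep presses chain ends hard into the channel
# walls, and that contact needs dt <= 2.5e-4 tau for a stable explicit-Euler
# step.
scenario_channel_split <- function(seed, ov) {
  p <- make_particle(janus_geometry(), material_params())
  width <- opt(ov, "width", 1.5e-3)
  n_s <- opt(ov, "n_s", 4)
  swing_y <- field_oscillating(6, 2, c(-pi, pi), e1 = c(0, 1, 0),
                               e2 = c(cos(-pi / 6), 0, sin(-pi / 6)))
  init <- init_chain(n_s, p, origin = c(0, -3e-3))
  arena <- arena_channel(width = width, wall_height = 4e-3, length = 9e-3,
                         y0 = -11e-3)
  cfg <- simulation_config(p, init, swing_y, arena,
                           duration = opt(ov, "t_swing1", 3),
                           stride = opt(ov, "stride", 800),
                           dt = opt(ov, "dt", 2.5e-4), seed = seed)
  tr1 <- run_simulation(cfg)
  tr2 <- continue_simulation(tr1, field_preset("disassemble_20Hz"),
                             opt(ov, "t_split", 0.5))
  tr3 <- continue_simulation(tr2, swing_y, opt(ov, "t_swing2", 5))
  part <- detect_chains(trajectory_frame(tr3, -1), bond_m(p))
  ymin <- min(tr3$pos[, , 2])
  list(trajectory = tr3,
       summary = list(n_chains_after_split = length(part$chains),
                      max_progress_mm = -ymin * 1e3),
       config = list(width = width, n_s = n_s))
}

# Assembled 8-chain: low-frequency rotation, switch to 20 Hz (fragmentation),
# revert to 1 Hz (reassembly).
scenario_disassemble_reassemble <- function(seed, ov) {
  p <- make_particle(janus_geometry(), material_params())
  n_s <- opt(ov, "n_s", 8)
  t_high <- opt(ov, "t_high", 0.25)
  t_re <- opt(ov, "t_reassemble", 6)
  stride <- opt(ov, "stride", 40)
  init <- init_chain(n_s, p)
  cfg <- simulation_config(p, init, field_static(4, c(0, 1, 0)),
                           arena_flat(), duration = 0.5, stride = stride,
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr1 <- run_simulation(cfg)
  tr2 <- continue_simulation(tr1, field_preset("disassemble_20Hz"), t_high)
  frag <- fragmentation_time(tr2, bond_m(p))
  frag_full <- fragmentation_time(tr2, bond_m(p), complete = TRUE)
  part_mid <- detect_chains(trajectory_frame(tr2, -1), bond_m(p))
  nfrag_max <- max(vapply(seq_len(n_frames(tr2)), function(i) {
    length(detect_chains(trajectory_frame(tr2, i), bond_m(p))$chains)
  }, numeric(1)))
  tr3 <- continue_simulation(tr2, field_preset("assemble_rotating"), t_re)
  effs <- vapply(seq_len(n_frames(tr3)), function(i) {
    assembly_efficiency(detect_chains(trajectory_frame(tr3, i), bond_m(p)))
  }, numeric(1))
  t_full <- (tr3$times - tr3$times[1])[which(effs == 1)[1]]
  list(trajectory = tr3,
       summary = list(
         fragmentation_time_s = unname(frag),
         full_dispersal_time_s = unname(frag_full),
         n_fragments_at_switch = length(part_mid$chains),
         n_fragments_max = unname(nfrag_max),
         reassembly_max_efficiency = max(effs),
         time_to_full_reassembly_s = unname(t_full)),
       config = list(n_s = n_s, t_high = t_high, t_reassemble = t_re))
}

# Two single robots before a step neither can climb alone, under the
# walking field: single robots have no chain friction and cannot walk, but
# their dipolar attraction merges them into a dimer, which then tumbles
# forward and climbs the step. The placement is planar (all on x = 0) so
# the walking tumble stays in the yz plane.
scenario_merge_to_climb <- function(seed, ov) {
  p <- fabricated_particle()
  rise <- opt(ov, "rise", 3.5e-4)
  n_s <- opt(ov, "n_s", 2)
  spacing <- opt(ov, "spacing", 2.8)
  dur <- opt(ov, "duration", 20)
  init <- init_chain(n_s, p, spacing = spacing, origin = c(0, -2.5e-3))
  cfg <- simulation_config(p, init, walking_field_forward(opt(ov, "f_Hz", 1)),
                           arena_step(rise), duration = dur,
                           stride = opt(ov, "stride", 200),
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr <- run_simulation(cfg)
  f <- trajectory_frame(tr, -1)
  part <- detect_chains(f, bond_m(p))
  zmin <- vapply(seq_len(n_frames(tr)), function(i) {
    min(trajectory_frame(tr, i)$pos[, 3])
  }, numeric(1))
  list(trajectory = tr,
       summary = list(merged = length(part$chains) == 1 && n_s > 1,
                      climbed = unname(any(zmin > rise))),
       config = list(rise = rise, n_s = n_s, spacing = spacing,
                     duration = dur))
}

# Static field, then the reversed field: protocol of the chain-to-ring
# transformation (the model's body-fixed dipoles mostly rotate in place, so
# the curling is weak; reported, not asserted).
scenario_ring_reversal <- function(seed, ov) {
  p <- make_particle(janus_geometry(), material_params())
  n_s <- opt(ov, "n_s", 6)
  init <- init_chain(n_s, p)
  cfg <- simulation_config(p, init, field_preset("ring_reversal"),
                           arena_flat(), duration = opt(ov, "duration", 3),
                           stride = opt(ov, "stride", 200),
                           dt = opt(ov, "dt", 0.001), seed = seed)
  tr <- run_simulation(cfg)
  e2e <- function(f) {
    o <- order(f$pos[, 2])
    sqrt(sum((f$pos[o[n_s], ] - f$pos[o[1], ])^2))
  }
  before <- e2e(trajectory_frame(tr, round(n_frames(tr) / 3)))
  after <- e2e(trajectory_frame(tr, -1))
  list(trajectory = tr,
       summary = list(end_to_end_before_mm = before * 1e3,
                      end_to_end_after_mm = after * 1e3),
       config = list(n_s = n_s))
}
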