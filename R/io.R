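# Trajectory and configuration I/O: extended-XYZ frames, per-frame metrics
# CSV, YAML/JSON scenario configuration.

#' Write a trajectory as extended XYZ
#'
#' One block per frame: particle count, a comment line carrying
#' `Time=<s>`, the instantaneous field `B="<mT>"` and a `Properties`
#' descriptor, then one row per particle with species, position (m),
#' symmetry axis and dipole direction.
#'
#' @param trajectory A `janus_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  nf <- n_frames(trajectory)
  np <- dim(trajectory$pos)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nf)) {
    f <- trajectory_frame(trajectory, i)
    writeLines(as.character(np), con)
    writeLines(sprintf(
      "Time=%.9e B=\"%.9e %.9e %.9e\" Properties=species:S:1:pos:R:3:axis:R:3:dipole:R:3",
      f$t, f$B[1], f$B[2], f$B[3]), con)
    rows <- sprintf(
      "J %.9e %.9e %.9e %.9e %.9e %.9e %.9e %.9e %.9e",
      f$pos[, 1], f$pos[, 2], f$pos[, 3],
      f$u[, 1], f$u[, 2], f$u[, 3],
      f$mu[, 1], f$mu[, 2], f$mu[, 3])
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory_xyz()]. The returned object carries frames
#' and times but no simulation configuration.
#'
#' @param path File written by [write_trajectory_xyz()].
#' @return A `janus_trajectory` (without `config`).
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1
  times <- c()
  fields <- list()
  pos <- list()
  uu <- list()
  mm <- list()
  while (i <= length(lines)) {
    np <- as.integer(lines[i])
    header <- lines[i + 1]
    tm <- as.numeric(sub(".*Time=([-+0-9.eE]+).*", "\\1", header))
    bstr <- sub('.*B="([^"]+)".*', "\\1", header)
    B <- as.numeric(strsplit(trimws(bstr), "\\s+")[[1]])
    block <- lines[(i + 2):(i + 1 + np)]
    vals <- do.call(rbind, lapply(strsplit(block, "\\s+"), function(x) {
      as.numeric(x[-1])
    }))
    times <- c(times, tm)
    fields[[length(fields) + 1]] <- B
    pos[[length(pos) + 1]] <- vals[, 1:3, drop = FALSE]
    uu[[length(uu) + 1]] <- vals[, 4:6, drop = FALSE]
    mm[[length(mm) + 1]] <- vals[, 7:9, drop = FALSE]
    i <- i + 2 + np
  }
  nf <- length(times)
  np <- nrow(pos[[1]])
  pack <- function(lst) {
    arr <- array(NA_real_, c(nf, np, 3))
    for (k in seq_len(nf)) arr[k, , ] <- lst[[k]]
    arr
  }
  structure(
    list(times = times, pos = pack(pos), u = pack(uu), mu = pack(mm),
         field = do.call(rbind, fields), config = NULL),
    class = "janus_trajectory"
  )
}

#' Per-frame metrics table
#'
#' One row per stored frame: time, centroid position, chain count, largest
#' chain size, assembly efficiency, and the instantaneous field.
#'
#' @param trajectory A `janus_trajectory`.
#' @param bond_cutoff Bond cutoff in meters; defaults to 1.1 particle
#'   diameters from the run configuration.
#' @return A data.frame.
#' @export
trajectory_metrics <- function(trajectory, bond_cutoff = NULL) {
  if (is.null(bond_cutoff)) {
    cfg <- trajectory$config
    if (is.null(cfg)) stop("bond_cutoff required for configless trajectories")
    bond_cutoff <- cfg$bond_cutoff * cfg$particle$geometry$sigma
  }
  nf <- n_frames(trajectory)
  rows <- lapply(seq_len(nf), function(i) {
    f <- trajectory_frame(trajectory, i)
    part <- detect_chains(f, bond_cutoff)
    data.frame(
      time_s = f$t,
      centroid_x = mean(f$pos[, 1]),
      centroid_y = mean(f$pos[, 2]),
      centroid_z = mean(f$pos[, 3]),
      n_chains = length(part$chains),
      largest_chain = max(part$sizes),
      efficiency = assembly_efficiency(part),
      B_x_mT = f$B[1], B_y_mT = f$B[2], B_z_mT = f$B[3]
    )
  })
  do.call(rbind, rows)
}

# --- scenario configuration files ------------------------------------------

config_schema <- list(
  scenario = "character", seed = "numeric", out_dir = "character",
  radius_m = "numeric", cap_fraction = "numeric", dipole_Am2 = "numeric",
  epsilon_J = "numeric", tau_s = "numeric", gamma = "numeric",
  gamma_r = "numeric", dt_tau = "numeric", duration_s = "numeric",
  stride = "numeric", n_particles = "numeric", f_Hz = "numeric",
  B0_mT = "numeric", densities = "list", field = "list", arena = "list",
  angle_deg = "numeric", rise = "numeric", tread = "numeric",
  count = "numeric", width = "numeric"
)

#' Read and validate a scenario configuration file
#'
#' YAML (or JSON) file with either a `scenario` name plus parameter
#' overrides, or a fully explicit `field`/`arena` description. Unknown or
#' mistyped keys raise an error naming the offending key.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A named list of configuration values.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) stop("config must be a mapping")
  for (key in names(cfg)) {
    if (!key %in% names(config_schema)) {
      stop("unknown config key '", key, "'")
    }
    expected <- config_schema[[key]]
    ok <- switch(expected,
      character = is.character(cfg[[key]]),
      numeric = is.numeric(cfg[[key]]),
      list = is.list(cfg[[key]]))
    if (!ok) {
      stop("config key '", key, "' must be of type ", expected)
    }
  }
  if (is.null(cfg$scenario) && is.null(cfg$field)) {
    stop("config must provide either 'scenario' or an explicit 'field' block")
  }
  cfg
}

# Build a field_program from a config 'field' block
field_from_config <- function(block) {
  stopifnot(is.list(block))
  if (is.null(block$variant)) stop("field block requires 'variant'")
  switch(block$variant,
    static = field_static(block$B0_mT, unlist(block$direction)),
    rotating = field_rotating(block$B0_mT, block$f_Hz,
                              plane = if (is.null(block$plane)) "yz" else block$plane),
    oscillating = field_oscillating(block$B0_mT, block$f_Hz,
                                    bounds = unlist(block$bounds_rad),
                                    e1 = unlist(block$e1), e2 = unlist(block$e2)),
    conical = field_conical(block$B0_mT, block$f_Hz,
                            axis = unlist(block$axis),
                            half_angle = block$half_angle_rad),
    schedule = field_schedule(lapply(block$segments, function(s) {
      list(s$duration_s, field_from_config(s$field))
    })),
    stop("unknown field variant '", block$variant, "'")
  )
}
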