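#' Spherical-cap volume of the magnetic segment
#'
#' Volume of a spherical cap of height `h * sigma` cut from a sphere of
#' diameter `sigma`. The cap fraction `h` is the sedimentation height of the
#' ferromagnetic microparticles expressed as a fraction of the particle
#' diameter.
#'
#' @param h Cap fraction in `[0, 1]` (cap height / particle diameter).
#' @param sigma Particle diameter (m, or any length unit; the result is in
#'   that unit cubed).
#' @return Cap volume, `(1/6) * pi * h^2 * (3 - 2 h) * sigma^3`.
#' @examples
#' cap_volume(0.5, 1)           # hemisphere: half of pi/6
#' cap_volume(0.33, 6e-4)       # default microrobot cap, m^3
#' @export
cap_volume <- function(h, sigma) {
  if (any(h < 0 | h > 1)) stop("cap fraction h must lie in [0, 1]")
  if (any(sigma <= 0)) stop("particle diameter sigma must be positive")
  (1 / 6) * pi * h^2 * (3 - 2 * h) * sigma^3
}

#' Distance from sphere center to cap centroid
#'
#' Closed-form centroid of a spherical cap of height `h * 2R` measured from
#' the sphere center: `s = 3 R (1 - h)^2 / (3 - 2 h)`. This is the offset
#' between the geometric center of the particle and the reference point that
#' carries both the cap's excess weight and the magnetic dipole. It satisfies
#' the classical limits `s -> R` as `h -> 0` (point cap at the surface) and
#' `s -> 0` as `h -> 1` (full sphere), with `s = 3R/8` for a hemisphere.
#'
#' @param h Cap fraction in `(0, 1]`.
#' @param R Particle radius (length).
#' @return Center-to-cap-centroid distance in the unit of `R`.
#' @export
cap_centroid_offset <- function(h, R) {
  if (any(h <= 0 | h > 1)) stop("cap fraction h must lie in (0, 1]")
  if (any(R <= 0)) stop("radius R must be positive")
  3 * R * (1 - h)^2 / (3 - 2 * h)
}

#' Janus particle geometry
#'
#' Bundles the geometric description of a magnetic Janus microrobot: a sphere
#' of radius `radius` whose lower spherical cap (height fraction
#' `cap_fraction` of the diameter) is loaded with ferromagnetic
#' microparticles. Derived quantities (sphere volume, cap volume, centroid
#' offset) are computed once and stored.
#'
#' @param radius Particle radius in meters. Default `3e-4` (600-um robot).
#' @param cap_fraction Cap height as a fraction of the diameter, in (0, 1).
#'   Default 0.33, which reproduces the reference particle mass of ~0.314 mg
#'   with the default densities.
#' @return An object of class `janus_geometry` with fields `radius`, `sigma`
#'   (diameter), `cap_fraction`, `V_sphere`, `V_cap`, and `s` (centroid
#'   offset, m).
#' @examples
#' geom <- janus_geometry()
#' geom$V_sphere  # (1/6) pi sigma^3
#' @export
janus_geometry <- function(radius = 3e-4, cap_fraction = 0.33) {
  if (radius <= 0) stop("radius must be positive")
  if (cap_fraction <= 0 || cap_fraction >= 1) {
    stop("cap_fraction must lie strictly between 0 and 1")
  }
  sigma <- 2 * radius
  structure(
    list(
      radius = radius,
      sigma = sigma,
      cap_fraction = cap_fraction,
      V_sphere = (1 / 6) * pi * sigma^3,
      V_cap = cap_volume(cap_fraction, sigma),
      s = cap_centroid_offset(cap_fraction, radius)
    ),
    class = "janus_geometry"
  )
}

#' @export
print.janus_geometry <- function(x, ...) {
  cat("Janus particle geometry\n")
  cat(sprintf("  radius        : %.4g m (diameter %.4g m)\n", x$radius, x$sigma))
  cat(sprintf("  cap fraction h: %.3f\n", x$cap_fraction))
  cat(sprintf("  V_sphere      : %.4g m^3\n", x$V_sphere))
  cat(sprintf("  V_cap         : %.4g m^3 (%.1f%% of sphere)\n",
              x$V_cap, 100 * x$V_cap / x$V_sphere))
  cat(sprintf("  cap centroid s: %.4g m (%.3f R)\n", x$s, x$s / x$radius))
  invisible(x)
}

#' Material parameters for Janus microrobots
#'
#' Densities of the three phases (surrounding water, PEGDA hydrogel body,
#' NdFeB-loaded magnetic composite), gravitational acceleration, and the
#' permanent magnetic dipole magnitude of one particle.
#'
#' @param rho_water Density of water, kg/m^3.
#' @param rho_hydrogel Density of the PEGDA hydrogel phase, kg/m^3.
#' @param rho_magnetic Density of the NdFeB composite cap, kg/m^3.
#' @param g Gravitational acceleration, m/s^2.
#' @param dipole Permanent dipole magnitude, A m^2. Default `1.08e-6` (the
#'   measured dipole strength used in the force-scale estimates); the
#'   remanent-magnetization value `0.87e-6` from hysteresis-loop
#'   characterization is available via `preset = "remanent"`.
#' @param preset Either `"measured"` (default) or `"remanent"`, selecting the
#'   dipole magnitude when `dipole` is not given explicitly.
#' @return Object of class `janus_materials`.
#' @export
material_params <- function(rho_water = 1000, rho_hydrogel = 1120,
                            rho_magnetic = 7600, g = 9.81,
                            dipole = NULL,
                            preset = c("measured", "remanent")) {
  preset <- match.arg(preset)
  if (is.null(dipole)) {
    dipole <- switch(preset, measured = 1.08e-6, remanent = 0.87e-6)
  }
  if (!(rho_magnetic > rho_hydrogel && rho_hydrogel > rho_water && rho_water > 0)) {
    stop("densities must satisfy rho_magnetic > rho_hydrogel > rho_water > 0")
  }
  if (dipole < 0) stop("dipole magnitude must be nonnegative")
  structure(
    list(rho_water = rho_water, rho_hydrogel = rho_hydrogel,
         rho_magnetic = rho_magnetic, g = g, dipole = dipole),
    class = "janus_materials"
  )
}

#' Derive masses, weights and dipole of a Janus particle
#'
#' Combines geometry and materials into the quantities entering the equations
#' of motion: total particle mass, displaced water mass, net buoyant weight,
#' and the two body-load magnitudes applied at the sphere center (hydrogel
#' minus water over the whole sphere) and at the cap centroid (magnetic
#' composite minus hydrogel over the cap). The two loads sum exactly to the
#' net buoyant weight.
#'
#' @param geom A [janus_geometry()].
#' @param mat A [material_params()].
#' @param scale_dipole_with_cap If `TRUE`, the dipole magnitude is scaled by
#'   the ratio of the cap volume to the cap volume at the reference fraction
#'   `h = 0.33` (more ferromagnetic material, proportionally stronger moment).
#'   Used by the cap-fraction sweeps; default `FALSE` keeps the measured value.
#' @return Object of class `janus_particle` with fields `geometry`,
#'   `materials`, `m_particle` (kg), `m_water` (kg), `weight` (N, net buoyant
#'   weight), `G_center` (N, magnitude of the center load), `G_cap` (N,
#'   magnitude of the cap load), `dipole` (A m^2).
#' @examples
#' p <- make_particle(janus_geometry(), material_params())
#' p$m_water * 1e6   # displaced water mass in mg
#' p$weight * 1e6    # net buoyant weight in uN
#' @export
make_particle <- function(geom, mat = material_params(),
                          scale_dipole_with_cap = FALSE) {
  stopifnot(inherits(geom, "janus_geometry"), inherits(mat, "janus_materials"))
  m_particle <- mat$rho_hydrogel * geom$V_sphere +
    (mat$rho_magnetic - mat$rho_hydrogel) * geom$V_cap
  m_water <- mat$rho_water * geom$V_sphere
  G_center <- (mat$rho_hydrogel - mat$rho_water) * geom$V_sphere * mat$g
  G_cap <- (mat$rho_magnetic - mat$rho_hydrogel) * geom$V_cap * mat$g
  dipole <- mat$dipole
  if (scale_dipole_with_cap) {
    v_ref <- cap_volume(0.33, geom$sigma)
    dipole <- dipole * geom$V_cap / v_ref
  }
  structure(
    list(geometry = geom, materials = mat,
         m_particle = m_particle, m_water = m_water,
         weight = mat$g * (m_particle - m_water),
         G_center = G_center, G_cap = G_cap,
         dipole = dipole),
    class = "janus_particle"
  )
}

#' @export
print.janus_particle <- function(x, ...) {
  cat("Janus microrobot\n")
  cat(sprintf("  particle mass  : %.4g mg\n", x$m_particle * 1e6))
  cat(sprintf("  displaced water: %.4g mg\n", x$m_water * 1e6))
  cat(sprintf("  buoyant weight : %.4g uN (center %.4g + cap %.4g)\n",
              x$weight * 1e6, x$G_center * 1e6, x$G_cap * 1e6))
  cat(sprintf("  dipole moment  : %.4g A m^2\n", x$dipole))
  invisible(x)
}

#' Fabricated-robot parameterization
#'
#' The printed force-scale estimates pair a 600-um robot with the measured
#' dipole moment; the fabricated robots used in the locomotion experiments
#' are a little smaller (mean diameter 575 um, and the fastest climbing
#' dimer had 500-um bodies). This helper builds a particle of the requested
#' size whose dipole is scaled from the measured value by particle volume at
#' fixed ferromagnetic loading: `mu = 1.08e-6 * (2 R / 5.75e-4)^3` A m^2.
#'
#' @param radius Particle radius in meters (default `2.5e-4`, a 0.5-mm
#'   robot).
#' @param cap_fraction Cap fraction (default 0.33).
#' @param ... Additional arguments to [material_params()].
#' @return A `janus_particle`.
#' @examples
#' p <- fabricated_particle()          # 0.5-mm robot, mu ~ 7.1e-7 A m^2
#' @export
fabricated_particle <- function(radius = 2.5e-4, cap_fraction = 0.33, ...) {
  mu <- 1.08e-6 * (2 * radius / 5.75e-4)^3
  make_particle(janus_geometry(radius, cap_fraction),
                material_params(dipole = mu, ...))
}
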