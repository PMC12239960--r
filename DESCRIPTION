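Package: janusim
Title: Particle-Based Simulation of Magnetic Janus Microrobot Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Overdamped particle-based simulator for permanent-magnetic Janus
    droplet microrobots: hydrogel spheres carrying a dense ferromagnetic
    spherical cap with an in-plane permanent dipole. Implements
    Weeks-Chandler-Andersen excluded volume, offset point-dipole interactions,
    coupling to programmed external magnetic fields (static, rotating,
    bounded-oscillation, conical, piecewise schedules), gravity/buoyancy with
    anisotropic mass distribution, hard walls with Coulomb stick-slip friction,
    and an explicit-Euler overdamped integrator. Ships figure-level scenarios
    (chain self-assembly, walking/crawling/swinging/lateral gaits, inclines,
    stairs, channel splitting, frequency-triggered disassembly and reassembly)
    together with trajectory analysis tools (chain detection, assembly
    efficiency, offset angles, centroid kinematics, fragmentation timing,
    cargo-release statistics) and closed-form magnetostatic force-scale
    estimates in a reduced-unit system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
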