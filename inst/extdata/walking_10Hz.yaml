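# Walking dimer at 10 Hz: the fastest recorded climbing configuration
# (0.5-mm bodies, 1-mm chain). Run with:
#   run_scenario(system.file("extdata", "walking_10Hz.yaml", package = "janusim"))
scenario: walking
seed: 1
n_particles: 2
f_Hz: 10
B0_mT: 4
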