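# Shared fixtures: all data are generated in code at test time.

# Narrow grid around the H-alpha / Li region; fast for single-line tests.
tinyInstrument <- function(wavelength_min = 640, wavelength_max = 700,
                           grid_step = 0.02, ...) {
    instrumentConfig(wavelength_min = wavelength_min,
                     wavelength_max = wavelength_max,
                     grid_step = grid_step, ...)
}

# Full-range grid at the default step but cheap to simulate (counts only).
stubInstrument <- function() {
    instrumentConfig(wavelength_min = 190, wavelength_max = 200,
                     grid_step = 0.1)
}

# Deterministic signal: flat continuum, no noise, no ambient H/N/O,
# no biological-replicate variability.
exactNoise <- function(continuum_level = 10, ...) {
    noiseConfig(continuum_level = continuum_level, continuum_decay = Inf,
                noise_a = 0, noise_b = 0, bio_sdlog = 0,
                ambient = c(H = 0, N = 0, O = 0), ...)
}

# Single-feature concentration profile.
onlyFeature <- function(feature, conc) {
    setNames(conc, feature)
}

# A small raw study: 2 bio reps, default full grid, deterministic unless
# noise is supplied.
smallStudy <- function(seed = 1, noise = exactNoise(), n_biological = 2,
                       instrument = instrumentConfig(), ...) {
    generateStudy(studyDesign("custom", n_biological = n_biological,
                              n_technical = 1, seed = seed),
                  noise = noise, instrument = instrument, ...)
}

# Build a SpectraSet holding one simulated shot.
asSpectraSet <- function(shot, label = list()) {
    meta <- data.frame(sample_id = "s1", species = "Hf", medium = "PDB",
                       bio_rep = 1, tech_rep = 1, shot = 1)
    meta[names(label)] <- label
    SpectraSet(matrix(shot$intensity, ncol = 1), shot$wavelength, meta)
}
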