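#' Instrument configuration for the synthetic spectrometer
#'
#' Describes the simulated 8-channel LIBS spectrometer. Only the wavelength
#' grid and the emission-line width enter the signal model; delay time,
#' integration time, laser pulse energy and spot size are descriptive
#' acquisition metadata carried through to run manifests.
#'
#' @param wavelength_min,wavelength_max spectrometer range in nm (178-1022).
#' @param grid_step wavelength sampling step, nm.
#' @param line_width_fwhm full width at half maximum of the Gaussian emission
#'   line profile, nm; must be at least \code{grid_step}.
#' @param delay_time_us,integration_time_us,laser_energy_mJ,spot_size_um
#'   acquisition metadata (microseconds, microseconds, mJ, micrometers).
#' @return A validated list of class \code{"InstrumentConfig"}.
#' @export
instrumentConfig <- function(wavelength_min = 178, wavelength_max = 1022,
                             grid_step = 0.1, line_width_fwhm = 0.15,
                             delay_time_us = 3, integration_time_us = 50,
                             laser_energy_mJ = 100, spot_size_um = 100) {
    stopifnot(wavelength_min < wavelength_max, grid_step > 0,
              line_width_fwhm >= grid_step)
    structure(list(wavelength_min = wavelength_min,
                   wavelength_max = wavelength_max,
                   grid_step = grid_step,
                   line_width_fwhm = line_width_fwhm,
                   delay_time_us = delay_time_us,
                   integration_time_us = integration_time_us,
                   laser_energy_mJ = laser_energy_mJ,
                   spot_size_um = spot_size_um),
              class = "InstrumentConfig")
}

#' Noise and background model for the synthetic spectra
#'
#' The simulated signal is a smooth continuum that decays exponentially with
#' wavelength, plus Gaussian emission lines, plus heteroscedastic additive
#' shot noise with variance \code{noise_a + noise_b * signal} (clipped at zero
#' intensity). Biological replicates share a lognormal multiplier on the
#' biological element profile; moisture and entrained air contribute a
#' class-independent ambient concentration of H, N and O so those emissions
#' are always present, as expected when LIBS is run without an inert cover
#' gas.
#'
#' @param continuum_level continuum intensity at the low-wavelength end of the
#'   grid, detector counts.
#' @param continuum_decay exponential decay constant of the continuum, nm;
#'   \code{Inf} gives a flat continuum.
#' @param noise_a additive noise variance floor (counts^2).
#' @param noise_b signal-proportional noise variance coefficient (counts).
#' @param bio_sdlog sdlog of the shared lognormal biological-replicate
#'   multiplier.
#' @param ambient named vector of ambient (moisture/atmosphere) concentrations
#'   added to every profile; default covers H, N, O.
#' @return A validated list of class \code{"NoiseConfig"}.
#' @export
noiseConfig <- function(continuum_level = 10, continuum_decay = 300,
                        noise_a = 0.02, noise_b = 0.002, bio_sdlog = 0.1,
                        ambient = c(H = 25, N = 20, O = 25)) {
    stopifnot(continuum_level >= 0, continuum_decay > 0,
              noise_a >= 0, noise_b >= 0, bio_sdlog >= 0,
              all(ambient >= 0))
    structure(list(continuum_level = continuum_level,
                   continuum_decay = continuum_decay,
                   noise_a = noise_a, noise_b = noise_b,
                   bio_sdlog = bio_sdlog, ambient = ambient),
              class = "NoiseConfig")
}

#' Crossed study design for the synthetic experiment
#'
#' Two fungal species (\emph{Hyaloscypha finlandica}, Hf; \emph{Mucor
#' hiemalis}, Mh) crossed with two growth media (potato dextrose broth, PDB;
#' glucose minimal medium, GMM), five biological replicates per condition,
#' each mount sampled on a 4 x 4 grid with one laser shot per spot. Two named
#' presets cover the two readings of the replicate structure:
#' \describe{
#'   \item{paper_n80}{one technical replicate (mount) per biological
#'     specimen: 20 mounts x 16 shots = 320 raw shots, i.e. 80 analysis
#'     spectra after 4-shot averaging.}
#'   \item{specimen20}{five mounts per biological specimen: 80 shots and 20
#'     averaged spectra per specimen (400 in total).}
#' }
#'
#' @param preset \code{"paper_n80"}, \code{"specimen20"} or \code{"custom"}.
#' @param n_biological biological replicates per species x medium condition.
#' @param n_technical mounts per biological specimen; defaults to the
#'   preset's value (1 or 5), required for \code{"custom"}.
#' @param shots_per_mount laser shots per mount (the 4 x 4 grid).
#' @param seed integer seed controlling every random draw of the study.
#' @return A validated list of class \code{"StudyDesign"}.
#' @export
studyDesign <- function(preset = c("paper_n80", "specimen20", "custom"),
                        n_biological = 5, n_technical = NULL,
                        shots_per_mount = 16, seed = 1) {
    preset <- match.arg(preset)
    if (is.null(n_technical))
        n_technical <- switch(preset, paper_n80 = 1L, specimen20 = 5L,
                              custom = stop("custom design needs n_technical"))
    stopifnot(n_biological >= 1, n_technical >= 1, shots_per_mount >= 1)
    structure(list(preset = preset,
                   species_levels = c("Hf", "Mh"),
                   media_levels = c("PDB", "GMM"),
                   n_biological = as.integer(n_biological),
                   n_technical = as.integer(n_technical),
                   shots_per_mount = as.integer(shots_per_mount),
                   seed = as.integer(seed)),
              class = "StudyDesign")
}

#' Baseline element concentrations of the simulated fungal biomass
#'
#' Dimensionless relative abundances before any species or medium effect is
#' applied; chosen to mimic the qualitative intensity ordering of organic
#' LIBS spectra (CHNO-dominated matrix, intermediate nutrient elements,
#' trace Li/Al).
#'
#' @return Named numeric vector over the 16 canonical features.
#' @export
defaultElementProfile <- function() {
    c(C = 100, Zn = 8, P = 25, Mn = 6, Mg = 20, Si = 8, Fe = 10, Ca = 15,
      Al = 5, Na = 12, H = 60, Li = 3, K = 30, O = 70, N = 35, CN = 25)
}

#' Species and growth-medium effect directions
#'
#' Encodes the reported contrasts between the two fungi and the two media as
#' multiplicative effect directions used by the generator: Hf shows more
#' intense Zn, P, Mn, Mg, Fe, H and O emissions (and higher Al than Mh in the
#' same medium); Mh shows more intense Li and Ca; growth in PDB elevates Ca
#' and Al while growth in GMM elevates C. All other features are neutral.
#'
#' @param effect_size multiplicative fold applied per matching effect
#'   (must be > 1).
#' @return A list of class \code{"EffectDirectionTable"} with
#'   \code{species_effects}, \code{media_effects} (named character vectors
#'   over all 16 features) and \code{effect_size}.
#' @export
defaultEffectDirections <- function(effect_size = 2.0) {
    stopifnot(effect_size > 1)
    feats <- .FEATURE_ORDER
    sp <- setNames(rep("neutral", length(feats)), feats)
    sp[c("Zn", "P", "Mn", "Mg", "Fe", "H", "O", "Al")] <- "higher_in_Hf"
    sp[c("Li", "Ca")] <- "higher_in_Mh"
    md <- setNames(rep("neutral", length(feats)), feats)
    md[c("Ca", "Al")] <- "higher_in_PDB"
    md["C"] <- "higher_in_GMM"
    structure(list(species_effects = sp, media_effects = md,
                   effect_size = effect_size),
              class = "EffectDirectionTable")
}

#' Element profile of one species x medium class
#'
#' Multiplies the base concentration by \code{effect_size} for every feature
#' whose species or medium effect direction favors the given class; species
#' and medium effects compose multiplicatively. Deterministic.
#'
#' @param species \code{"Hf"} or \code{"Mh"}.
#' @param medium \code{"PDB"} or \code{"GMM"}.
#' @param base named concentration vector (the element profile).
#' @param effects an \code{EffectDirectionTable}.
#' @return Named concentration vector of the same length as \code{base}.
#' @export
classProfile <- function(species, medium, base = defaultElementProfile(),
                         effects = defaultEffectDirections()) {
    species <- match.arg(species, c("Hf", "Mh"))
    medium <- match.arg(medium, c("PDB", "GMM"))
    mult <- rep(1, length(base))
    names(mult) <- names(base)
    se <- effects$species_effects[names(base)]
    me <- effects$media_effects[names(base)]
    mult[(se == "higher_in_Hf" & species == "Hf") %in% TRUE] <-
        effects$effect_size
    mult[(se == "higher_in_Mh" & species == "Mh") %in% TRUE] <-
        effects$effect_size
    sel <- ((me == "higher_in_PDB" & medium == "PDB") |
            (me == "higher_in_GMM" & medium == "GMM")) %in% TRUE
    mult[sel] <- mult[sel] * effects$effect_size
    base * mult
}

## Gaussian emission-line superposition for one concentration profile,
## evaluated on `grid`. Peak height of each line = concentration x
## relative_strength; exactly linear in the profile. Lines are evaluated on a
## +/- 8 sigma window (truncation < 1e-13 of peak height).
.lineSum <- function(grid, profile, library, fwhm) {
    sdv <- fwhm / (2 * sqrt(2 * log(2)))
    out <- numeric(length(grid))
    ln <- library@lines
    ln <- ln[ln$feature_label %in% names(profile), , drop = FALSE]
    for (i in seq_len(nrow(ln))) {
        conc <- profile[[ln$feature_label[i]]]
        if (conc <= 0) next
        ctr <- ln$center_wavelength[i]
        amp <- conc * ln$relative_strength[i]
        win <- which(abs(grid - ctr) <= 8 * sdv)
        if (length(win) == 0) next
        out[win] <- out[win] + amp * exp(-0.5 * ((grid[win] - ctr) / sdv)^2)
    }
    out
}

.continuum <- function(grid, noise, wl_min) {
    if (is.infinite(noise$continuum_decay))
        rep(noise$continuum_level, length(grid))
    else
        noise$continuum_level * exp(-(grid - wl_min) / noise$continuum_decay)
}

.instrumentGrid <- function(instrument) {
    seq(instrument$wavelength_min, instrument$wavelength_max,
        by = instrument$grid_step)
}

#' Simulate one laser shot
#'
#' Evaluates the signal model on the instrument grid:
#' \code{intensity = continuum + sum over lines of concentration x
#' relative_strength x gaussian(center, fwhm) + noise}, with intensities
#' clipped at zero. At zero noise the background-corrected peak response is
#' exactly linear in concentration. Random draws come from the caller's RNG
#' state (use \code{set.seed} for reproducibility).
#'
#' @param profile named nonnegative concentration vector; names must be
#'   features of \code{library}.
#' @param library a \linkS4class{LineLibrary}.
#' @param instrument an \code{InstrumentConfig}.
#' @param noise a \code{NoiseConfig}; the ambient term is \emph{not} added
#'   here (it is a study-level property, see \code{\link{generateStudy}}).
#' @return data.frame with columns \code{wavelength} and \code{intensity}.
#' @export
simulateShot <- function(profile, library = defaultLineLibrary(),
                         instrument = instrumentConfig(),
                         noise = noiseConfig()) {
    unknown <- setdiff(names(profile), library@featureOrder)
    if (length(unknown) > 0)
        stop("unknown feature label(s) in profile: ",
             paste(unknown, collapse = ", "))
    if (any(profile < 0))
        stop("concentrations must be nonnegative")
    grid <- .instrumentGrid(instrument)
    signal <- .continuum(grid, noise, instrument$wavelength_min) +
        .lineSum(grid, profile, library, instrument$line_width_fwhm)
    y <- signal
    if (noise$noise_a > 0 || noise$noise_b > 0)
        y <- y + stats::rnorm(length(grid), 0,
                              sqrt(noise$noise_a +
                                   noise$noise_b * pmax(signal, 0)))
    data.frame(wavelength = grid, intensity = pmax(y, 0))
}

#' Generate a full synthetic LIBS study
#'
#' Simulates every shot of the crossed species x medium design: each
#' biological specimen receives a shared lognormal multiplier on its class
#' element profile (\code{bio_sdlog}), the ambient H/N/O contribution is added
#' unscaled, and each shot gets independent heteroscedastic noise. All
#' randomness derives from \code{design$seed}, so the same design yields a
#' bit-identical \linkS4class{SpectraSet}.
#'
#' @param design a \code{StudyDesign}.
#' @param effects an \code{EffectDirectionTable}.
#' @param library a \linkS4class{LineLibrary}.
#' @param instrument an \code{InstrumentConfig}.
#' @param noise a \code{NoiseConfig}.
#' @param baseProfile named base concentration vector.
#' @return A \linkS4class{SpectraSet} of raw per-shot spectra with colData
#'   columns sample_id, species, medium, bio_rep, tech_rep, shot.
#' @examples
#' shots <- generateStudy(studyDesign("paper_n80", seed = 1))
#' ncol(shots)  # 2 x 2 x 5 mounts x 16 shots = 320
#' @export
generateStudy <- function(design = studyDesign(),
                          effects = defaultEffectDirections(),
                          library = defaultLineLibrary(),
                          instrument = instrumentConfig(),
                          noise = noiseConfig(),
                          baseProfile = defaultElementProfile()) {
    grid <- .instrumentGrid(instrument)
    cont <- .continuum(grid, noise, instrument$wavelength_min)
    amb <- .lineSum(grid, noise$ambient, library, instrument$line_width_fwhm)
    nshot <- design$shots_per_mount
    ncols <- length(design$species_levels) * length(design$media_levels) *
        design$n_biological * design$n_technical * nshot
    mat <- matrix(0, nrow = length(grid), ncol = ncols)
    meta <- vector("list", ncols %/% nshot)
    set.seed(design$seed)
    col <- 0L; mnt <- 0L
    for (sp in design$species_levels) {
        for (md in design$media_levels) {
            prof <- classProfile(sp, md, baseProfile, effects)
            lineC <- .lineSum(grid, prof, library, instrument$line_width_fwhm)
            for (b in seq_len(design$n_biological)) {
                m <- stats::rlnorm(1, 0, noise$bio_sdlog)
                specimen <- cont + m * lineC + amb
                sdvec <- sqrt(noise$noise_a +
                              noise$noise_b * pmax(specimen, 0))
                for (t in seq_len(design$n_technical)) {
                    mnt <- mnt + 1L
                    meta[[mnt]] <- data.frame(
                        sample_id = sprintf("%s_%s_b%d_t%d", sp, md, b, t),
                        species = sp, medium = md, bio_rep = b, tech_rep = t,
                        shot = seq_len(nshot))
                    for (s in seq_len(nshot)) {
                        col <- col + 1L
                        y <- specimen
                        if (noise$noise_a > 0 || noise$noise_b > 0)
                            y <- y + stats::rnorm(length(grid), 0, sdvec)
                        mat[, col] <- pmax(y, 0)
                    }
                }
            }
        }
    }
    cd <- do.call(rbind, meta)
    colnames(mat) <- sprintf("%s_s%02d", cd$sample_id, cd$shot)
    out <- SpectraSet(mat, grid, cd, stage = "raw")
    metadata(out)$design <- design
    metadata(out)$instrument <- instrument
    metadata(out)$noise <- noise
    out
}
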