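#' @importFrom data.table fread fwrite as.data.table data.table setorder
NULL

.SPECTRA_COLS <- c("sample_id", "species", "medium", "bio_rep", "tech_rep",
                   "shot", "wavelength", "intensity")

#' Read / write spectra as long-format delimited text
#'
#' The on-disk format is a tab-separated long table with one row per
#' (spectrum, wavelength) pair and columns \code{sample_id}, \code{species},
#' \code{medium}, \code{bio_rep}, \code{tech_rep}, \code{shot} (or
#' \code{group} for averaged spectra), \code{wavelength}, \code{intensity};
#' lines starting with \code{#} are comments. Rows may arrive in any order:
#' reading normalizes the order by metadata sort, so
#' \code{readSpectra(writeSpectra(x))} reproduces \code{x} within
#' text-representation precision.
#'
#' @param path file path.
#' @return \code{readSpectra} returns a \linkS4class{SpectraSet};
#'   \code{writeSpectra} returns \code{path} invisibly.
#' @export
readSpectra <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    shotcol <- if ("shot" %in% names(dt)) "shot" else "group"
    req <- c(setdiff(.SPECTRA_COLS, "shot"), shotcol)
    miss <- setdiff(req, names(dt))
    if (length(miss) > 0)
        stop("spectrum table is missing column(s): ",
             paste(miss, collapse = ", "))
    data.table::setorderv(dt, c("sample_id", shotcol, "wavelength"))
    key <- paste(dt$sample_id, dt[[shotcol]])
    specs <- unique(key)
    grids <- split(dt$wavelength, key)
    wl <- grids[[specs[1]]]
    for (s in specs)
        if (!isTRUE(all.equal(grids[[s]], wl)))
            stop("ragged wavelength grid: spectrum '", s,
                 "' does not match the first spectrum's grid")
    mat <- matrix(dt$intensity, nrow = length(wl),
                  ncol = length(specs))
    first <- dt[!duplicated(key),
                c("sample_id", "species", "medium", "bio_rep", "tech_rep",
                  shotcol), with = FALSE]
    cd <- as.data.frame(first)
    stage <- if (shotcol == "shot") "raw" else "averaged"
    SpectraSet(mat, wl, cd, stage = stage)
}

#' @rdname readSpectra
#' @param x a \linkS4class{SpectraSet}.
#' @export
writeSpectra <- function(x, path) {
    stopifnot(is(x, "SpectraSet"))
    cd <- as.data.frame(colData(x))
    shotcol <- if ("shot" %in% names(cd)) "shot" else "group"
    wl <- wavelengths(x)
    mat <- spectraMatrix(x)
    n <- length(wl)
    dt <- data.table::data.table(
        sample_id = rep(cd$sample_id, each = n),
        species = rep(cd$species, each = n),
        medium = rep(cd$medium, each = n),
        bio_rep = rep(cd$bio_rep, each = n),
        tech_rep = rep(cd$tech_rep, each = n),
        shot = rep(cd[[shotcol]], each = n),
        wavelength = rep(wl, ncol(mat)),
        intensity = as.numeric(mat))
    data.table::setnames(dt, "shot", shotcol)
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' Read / write an intensity table as delimited text
#'
#' Tab-separated, one row per analysis spectrum: metadata columns
#' (\code{sample_id}, \code{species}, \code{medium}, \code{bio_rep},
#' \code{tech_rep}, \code{group}) followed by one column per feature in the
#' canonical feature order.
#'
#' @param path file path.
#' @param featureOrder canonical feature order used to identify the feature
#'   columns on read.
#' @return \code{readIntensityTable} returns an \linkS4class{IntensityTable};
#'   \code{writeIntensityTable} returns \code{path} invisibly.
#' @export
readIntensityTable <- function(path, featureOrder = .FEATURE_ORDER) {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
    feats <- intersect(featureOrder, names(df))
    if (length(feats) == 0)
        stop("no feature columns found in '", path, "'")
    metaCols <- setdiff(names(df), feats)
    mat <- t(as.matrix(df[, feats, drop = FALSE]))
    colnames(mat) <- if ("sample_id" %in% metaCols && "group" %in% metaCols)
        sprintf("%s_g%s", df$sample_id, df$group) else rownames(df)
    se <- SummarizedExperiment(
        assays = list(intensity = mat),
        colData = S4Vectors::DataFrame(df[, metaCols, drop = FALSE],
                                       row.names = colnames(mat)))
    new("IntensityTable", se)
}

#' @rdname readIntensityTable
#' @param x an \linkS4class{IntensityTable}.
#' @export
writeIntensityTable <- function(x, path) {
    stopifnot(is(x, "IntensityTable"))
    df <- cbind(as.data.frame(colData(x)),
                as.data.frame(t(spectraMatrix(x))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a correlation matrix (and its category labels) as delimited text
#'
#' @param r numeric correlation matrix with dimnames.
#' @param path file path for the coefficients; the category-label matrix is
#'   written next to it with suffix \code{"_categories"}.
#' @return \code{path}, invisibly.
#' @export
writeCorrelationMatrix <- function(r, path) {
    utils::write.table(cbind(feature = rownames(r), as.data.frame(r)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    cats <- correlationCategoryMatrix(r)
    cpath <- sub("(\\.[^.]+)?$", "_categories\\1", path)
    utils::write.table(cbind(feature = rownames(cats), as.data.frame(cats)),
                       cpath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble a full run configuration
#'
#' @param preset study-design preset (\code{"paper_n80"},
#'   \code{"specimen20"}, \code{"custom"}).
#' @param seed master seed: drives the generator and the train/test split.
#' @param out_dir output directory for stage artifacts (created if missing).
#' @param design,instrument,noise,aggregation,peak,pca sub-configurations;
#'   defaults are the package defaults.
#' @param effects an \code{EffectDirectionTable}.
#' @param write_raw also write the raw per-shot long table (large); default
#'   FALSE.
#' @return A validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(preset = "paper_n80", seed = 1, out_dir = tempdir(),
                      design = studyDesign(preset, seed = seed),
                      instrument = instrumentConfig(),
                      noise = noiseConfig(),
                      aggregation = aggregationConfig(),
                      peak = peakConfig(),
                      pca = pcaConfig(),
                      effects = defaultEffectDirections(),
                      write_raw = FALSE) {
    structure(list(preset = preset, seed = as.integer(seed),
                   out_dir = out_dir, design = design,
                   instrument = instrument, noise = noise,
                   aggregation = aggregation, peak = peak, pca = pca,
                   effects = effects, write_raw = write_raw),
              class = "RunConfig")
}

#' Run the end-to-end pipeline
#'
#' Executes simulate -> preprocess -> extract -> correlate -> PCA ->
#' classify, writes every stage artifact to \code{config$out_dir} as
#' delimited text, and records a JSON run manifest (configuration snapshot,
#' package version, per-stage shapes and timings, seeds). Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config a \code{RunConfig}.
#' @return Invisibly, a list with the in-memory stage results
#'   (\code{shots}, \code{spectra}, \code{intensity}, \code{correlations},
#'   \code{pca}, \code{reports}) and the \code{manifest}.
#' @export
runPipeline <- function(config = runConfig()) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(config$out_dir, 2) != 0)
        stop("output directory '", config$out_dir, "' is not writable")
    manifest <- list(package_version =
                         as.character(utils::packageVersion("libsionome")),
                     config = .configSnapshot(config),
                     stages = list(), warnings = character(0))
    tick <- function(expr) {
        t0 <- proc.time()[["elapsed"]]
        value <- withCallingHandlers(expr, warning = function(w) {
            manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
        list(value = value, secs = proc.time()[["elapsed"]] - t0)
    }
    lib <- defaultLineLibrary()
    path <- function(f) file.path(config$out_dir, f)

    st <- tick(generateStudy(config$design, config$effects, lib,
                             config$instrument, config$noise))
    shots <- st$value
    manifest$stages$simulate <- list(seconds = st$secs,
                                     n_shots = ncol(shots),
                                     n_grid = nrow(shots))
    if (isTRUE(config$write_raw))
        writeSpectra(shots, path("shots_raw.tsv"))

    st <- tick(preprocessSpectra(shots, config$aggregation))
    spectra <- st$value
    manifest$stages$preprocess <- list(seconds = st$secs,
                                       n_spectra = ncol(spectra),
                                       n_grid = nrow(spectra))
    writeSpectra(spectra, path("spectra_preprocessed.tsv"))

    st <- tick(buildIntensityTable(spectra, lib, config$peak))
    intensity <- st$value
    manifest$stages$extract <- list(seconds = st$secs,
                                    n_features = nrow(intensity),
                                    n_spectra = ncol(intensity))
    writeIntensityTable(intensity, path("intensity_table.tsv"))

    st <- tick({
        cors <- list(all = pearsonMatrix(intensity))
        for (sp in unique(colData(intensity)$species))
            cors[[sp]] <- pearsonMatrix(
                intensity, colData(intensity)$species == sp)
        cors
    })
    correlations <- st$value
    for (nm in names(correlations))
        writeCorrelationMatrix(correlations[[nm]],
                               path(sprintf("pearson_%s.tsv", nm)))
    manifest$stages$correlate <- list(seconds = st$secs,
                                      matrices = names(correlations))

    st <- tick(fitSpectralPCA(
        if (config$pca$input_mode == "full_spectrum") spectra else intensity,
        config$pca))
    pca <- st$value
    k <- ncol(pcScores(pca))
    manifest$stages$pca <- list(
        seconds = st$secs, n_components = k,
        explained_variance_ratio = explainedVariance(pca)[seq_len(k)],
        cumulative_pct = 100 * sum(explainedVariance(pca)[seq_len(k)]))
    utils::write.table(
        cbind(spectrum = rownames(pcScores(pca)),
              as.data.frame(pcScores(pca))),
        path("pc_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    pcCor <- pcCorrelations(intensity, pca)
    utils::write.table(
        cbind(feature = rownames(pcCor), as.data.frame(pcCor)),
        path("pc_feature_correlations.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)

    st <- tick({
        reports <- list()
        for (task in c("media", "species", "combined")) {
            labels <- classLabels(spectra, task)
            reports[[task]] <- classifyTask(
                pca, labels, task = task, seed = config$seed,
                meta = as.data.frame(colData(spectra)))
        }
        reports
    })
    reports <- st$value
    summ <- do.call(rbind, lapply(names(reports), function(t) data.frame(
        task = t, k = config$aggregation$shots_per_average,
        seed = config$seed,
        n_train = length(reports[[t]]@trainIndex),
        n_test = length(reports[[t]]@testIndex),
        accuracy = accuracy(reports[[t]]))))
    utils::write.table(summ, path("classifier_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (t in names(reports))
        utils::write.table(
            cbind(true = rownames(confusionMatrix(reports[[t]])),
                  as.data.frame(confusionMatrix(reports[[t]]))),
            path(sprintf("confusion_%s.tsv", t)), sep = "\t",
            quote = FALSE, row.names = FALSE)
    manifest$stages$classify <- list(
        seconds = st$secs,
        accuracy = lapply(reports, accuracy))

    jsonlite::write_json(manifest, path("run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(shots = shots, spectra = spectra, intensity = intensity,
                   correlations = correlations, pca = pca,
                   reports = reports, manifest = manifest))
}

## Flatten the configuration into plain lists for the JSON manifest.
.configSnapshot <- function(config) {
    strip <- function(x) {
        if (is.list(x)) lapply(unclass(x), strip) else x
    }
    strip(config)
}
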