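# Subcommand pipeline tying the analysis stages together with config
# merging, logging and deterministic artifacts. A thin command-line
# wrapper lives in inst/scripts/motif-contrast.R; tests and interactive
# use call runPipeline() directly.

EXIT_OK <- 0L
EXIT_USAGE <- 2L
EXIT_INPUT <- 3L
EXIT_ANALYSIS <- 4L

#' Default pipeline configuration
#'
#' All thresholds with their documented defaults: contrast taus
#' (0.97/0.03 strict, 0.90/0.10 high), covariation tau (0.3 bits),
#' classifier margin (2 bits), element occupancy minimum (6 residues),
#' generator sizes and seed, and the output directory.
#'
#' @return named list.
#' @export
defaultConfig <- function() {
    list(
        seed = 42L,
        outdir = "motifcontrast_out",
        tau_hi = 0.97, tau_lo = 0.03,
        tau_hi2 = 0.90, tau_lo2 = 0.10,
        tau_mi = 0.3,
        delta_min = 2,
        min_residues = 6L,
        min_run = 4L,
        top_k = 6L,
        n_a = 200L, n_b = 200L,
        background_gut = 50L, background_non_gut = 50L,
        aln_a = NULL, aln_b = NULL,
        fasta = NULL, band_csv = NULL, term_csv = NULL,
        calib_csv = NULL, sample_absorbances = NULL
    )
}

.mergeConfig <- function(config = list(), configFile = NULL) {
    cfg <- defaultConfig()
    if (!is.null(configFile)) {
        if (!file.exists(configFile))
            stop("config file not found: ", configFile)
        fromFile <- yaml::read_yaml(configFile)
        cfg[names(fromFile)] <- fromFile
    }
    cfg[names(config)] <- config
    stopifnot(cfg$tau_hi > cfg$tau_lo, cfg$tau_hi2 > cfg$tau_lo2,
        cfg$tau_hi <= 1, cfg$tau_lo >= 0, cfg$delta_min >= 0,
        cfg$min_residues >= 1, cfg$min_run >= 1)
    cfg
}

#' Write a pipeline configuration to YAML
#'
#' The written file round-trips: reading it back with
#' \code{yaml::read_yaml()} reproduces the configuration.
#'
#' @param config named list (defaults filled in).
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writeConfig <- function(config, path) {
    cfg <- .mergeConfig(config)
    yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
    invisible(path)
}

.logLines <- function(outdir, subcommand, cfg) {
    ver <- tryCatch(
        as.character(utils::packageVersion("MotifContrast")),
        error = function(e) "dev")
    shown <- cfg[!vapply(cfg, is.null, logical(1))]
    lines <- c(
        sprintf("MotifContrast %s", ver),
        sprintf("subcommand: %s", subcommand),
        sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
        sprintf("%s: %s", names(shown),
            vapply(shown, function(v) paste(v, collapse = ","),
                character(1))))
    writeLines(lines, file.path(outdir, "run.log"))
    message(paste(lines[1:2], collapse = " | "))
}

.needFile <- function(path, what) {
    if (is.null(path))
        stop("missing required input: ", what, call. = FALSE)
    if (!file.exists(path))
        stop("input file not found (", what, "): ", path, call. = FALSE)
    path
}

.loadPair <- function(cfg) {
    alnA <- readStockholm(.needFile(cfg$aln_a, "aln_a"))
    alnB <- readStockholm(.needFile(cfg$aln_b, "aln_b"))
    list(alnA = alnA, alnB = alnB,
        modelA = buildConsensus(alnA, tauMI = cfg$tau_mi),
        modelB = buildConsensus(alnB, tauMI = cfg$tau_mi))
}

.cmdSimulate <- function(cfg, outdir) {
    profile <- generatorProfile(seed = cfg$seed)
    sim <- generateMotifPair(profile, nA = cfg$n_a, nB = cfg$n_b,
        seed = cfg$seed)
    writeStockholm(sim$alnA, file.path(outdir, "motifA.sto"))
    writeStockholm(sim$alnB, file.path(outdir, "motifB.sto"))
    jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
        auto_unbox = TRUE, digits = NA, na = "null")
}

.cmdConsensus <- function(cfg, outdir) {
    aln <- readStockholm(.needFile(cfg$aln_a, "aln_a"))
    model <- buildConsensus(aln, tauMI = cfg$tau_mi)
    writeConsensusTSV(model, file.path(outdir, "consensus.tsv"))
    writeConsensusJSON(model, file.path(outdir, "consensus.json"))
}

.cmdCompare <- function(cfg, outdir) {
    x <- .loadPair(cfg)
    map <- mapColumns(x$modelA, x$modelB)
    feats <- findDiscriminatingFeatures(x$alnA, x$alnB, x$modelA,
        x$modelB, map, tauHi = cfg$tau_hi, tauLo = cfg$tau_lo,
        tauHi2 = cfg$tau_hi2, tauLo2 = cfg$tau_lo2,
        minRun = cfg$min_run, minResidues = cfg$min_residues)
    writeFeatures(feats, file.path(outdir, "features.tsv"))
    writeFeatures(feats, file.path(outdir, "features.json"))
    utils::write.table(as.data.frame(map$matches),
        file.path(outdir, "column_map.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
}

.cmdContext <- function(cfg, outdir) {
    x <- .loadPair(cfg)
    tab <- geneFrequencyTable(x$alnA, x$alnB, topK = cfg$top_k)
    utils::write.table(tab, file.path(outdir, "gene_context.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
}

.cmdEnrich <- function(cfg, outdir) {
    aln <- readStockholm(.needFile(cfg$aln_a, "aln_a"))
    res <- environmentEnrichment(aln,
        c(gut = cfg$background_gut, non_gut = cfg$background_non_gut))
    writeEnrichmentJSON(res, file.path(outdir, "enrichment.json"))
}

.cmdClassify <- function(cfg, outdir) {
    x <- .loadPair(cfg)
    map <- mapColumns(x$modelA, x$modelB)
    feats <- findDiscriminatingFeatures(x$alnA, x$alnB, x$modelA,
        x$modelB, map, tauHi = cfg$tau_hi, tauLo = cfg$tau_lo,
        tauHi2 = cfg$tau_hi2, tauLo2 = cfg$tau_lo2,
        minRun = cfg$min_run, minResidues = cfg$min_residues)
    res <- classifyFasta(x$modelA, x$modelB, feats,
        .needFile(cfg$fasta, "fasta"), deltaMin = cfg$delta_min)
    utils::write.table(res, file.path(outdir, "classification.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
}

.cmdProbeQuant <- function(cfg, outdir) {
    tab <- readBandTable(.needFile(cfg$band_csv, "band_csv"))
    ric <- relativeIntensityChange(tab)
    curve <- fitBindingCurve(ric$concs, ric$relChange)
    obj <- list(
        concs_molar = curve@concs,
        rel_change = curve@relChange,
        normalized = curve@normalized,
        kd_molar = if (curve@saturated) curve@kd else NULL,
        hill_n = curve@hillN,
        f_max = curve@fMax,
        saturated = curve@saturated,
        fit_residual = curve@fitResidual,
        flags = curve@flags)
    jsonlite::write_json(obj, file.path(outdir, "binding_curve.json"),
        auto_unbox = TRUE, digits = NA, na = "null")
}

.cmdTermQuant <- function(cfg, outdir) {
    path <- .needFile(cfg$term_csv, "term_csv")
    tab <- utils::read.csv(path)
    need <- c("term", "full", "a_term", "a_full")
    if (!all(need %in% colnames(tab)))
        stop("termination CSV needs columns: ",
            paste(need, collapse = ", "))
    res <- lapply(seq_len(nrow(tab)), function(k)
        terminatedFraction(tab$term[k], tab$full[k], tab$a_term[k],
            tab$a_full[k]))
    obj <- data.frame(tab,
        frac_terminated = vapply(res, `[[`, numeric(1),
            "fracTerminated"))
    jsonlite::write_json(obj, file.path(outdir, "termination.json"),
        auto_unbox = TRUE, digits = NA)
}

.cmdCalibrate <- function(cfg, outdir) {
    path <- .needFile(cfg$calib_csv, "calib_csv")
    tab <- utils::read.csv(path)
    if (!all(c("conc_molar", "absorbance") %in% colnames(tab)))
        stop("calibration CSV needs columns conc_molar, absorbance")
    cal <- dtnbCalibrate(tab$conc_molar, tab$absorbance)
    obj <- list(slope = cal@slope, intercept = cal@intercept,
        r_squared = cal@rSquared, n = cal@n)
    if (!is.null(cfg$sample_absorbances))
        obj$coa_released_molar <- activityFromAbsorbance(
            as.numeric(cfg$sample_absorbances), cal)
    jsonlite::write_json(obj, file.path(outdir, "calibration.json"),
        auto_unbox = TRUE, digits = NA)
}

#' Run a pipeline subcommand
#'
#' Subcommands: \code{simulate}, \code{consensus}, \code{compare},
#' \code{context}, \code{enrich}, \code{classify}, \code{probe-quant},
#' \code{term-quant}, \code{calibrate}. Each writes TSV/JSON artifacts
#' into the output directory plus a \code{run.log} echoing the package
#' version, seed and every effective parameter. Identical configuration
#' and seed produce identical artifacts.
#'
#' @param subcommand one of the subcommand names above.
#' @param config named list of overrides (see [defaultConfig()]).
#' @param configFile optional YAML configuration file; explicit
#'   \code{config} entries override it.
#' @return exit status, invisibly: 0 success, 2 usage error, 3 input
#'   error, 4 analysis error.
#' @export
runPipeline <- function(subcommand, config = list(), configFile = NULL) {
    handlers <- list(
        "simulate" = .cmdSimulate, "consensus" = .cmdConsensus,
        "compare" = .cmdCompare, "context" = .cmdContext,
        "enrich" = .cmdEnrich, "classify" = .cmdClassify,
        "probe-quant" = .cmdProbeQuant, "term-quant" = .cmdTermQuant,
        "calibrate" = .cmdCalibrate)
    if (length(subcommand) != 1L || !subcommand %in% names(handlers)) {
        message("unknown subcommand: ", paste(subcommand, collapse = " "),
            "\navailable: ", paste(names(handlers), collapse = ", "))
        return(invisible(EXIT_USAGE))
    }
    cfg <- tryCatch(.mergeConfig(config, configFile),
        error = function(e) {
            message("configuration error: ", conditionMessage(e))
            NULL
        })
    if (is.null(cfg)) return(invisible(EXIT_USAGE))
    outdir <- cfg$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .logLines(outdir, subcommand, cfg)
    status <- tryCatch({
        handlers[[subcommand]](cfg, outdir)
        EXIT_OK
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        if (grepl("missing required input|file not found",
            conditionMessage(e))) EXIT_INPUT else EXIT_ANALYSIS
    })
    invisible(status)
}
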