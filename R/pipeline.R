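#' Build a SimulationConfig from a plain list
#'
#' Maps the structured-text (YAML) configuration keys onto
#' [simulationConfig()]; planted effects are given as a list of
#' \code{(gene, variants, beta, mode)} entries.
#'
#' @param x named list, e.g. parsed from the \code{simulate:} section of a
#'   pipeline config file.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfigFromList <- function(x) {
    pe <- lapply(x$planted_effects, function(e) {
        plantedEffect(e$gene, unlist(e$variants), e$beta,
                      if (is.null(e$mode)) "joint_additive" else e$mode)
    })
    covSpec <- if (is.null(x$covariates)) defaultCovariateSpec()
    else if (identical(x$covariates, "none"))
        defaultCovariateSpec()[0, ]
    else defaultCovariateSpec(unlist(x$covariates))
    args <- list(
        nIndividuals = x$n_individuals, nVariants = x$n_variants,
        nGenes = x$n_genes, plantedEffects = pe, covariateSpec = covSpec
    )
    if (!is.null(x$maf_range)) args$mafRange <- unlist(x$maf_range)
    if (!is.null(x$noise_sd)) args$noiseSd <- x$noise_sd
    if (!is.null(x$or_range)) args$orRange <- unlist(x$or_range)
    if (!is.null(x$seed)) args$seed <- x$seed
    do.call(simulationConfig, args)
}

#' Read a pipeline configuration file
#'
#' @param path YAML file accepted by [runPipeline()] and the command-line
#'   front-end.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

.fileDigests <- function(paths) {
    paths <- unlist(paths)
    paths <- paths[!is.null(paths) & file.exists(paths)]
    if (!length(paths)) return(list())
    as.list(tools::md5sum(paths))
}

#' Run the full combinatorial GRS eQTL pipeline
#'
#' End-to-end orchestration of one test series: obtain a cohort (simulated
#' from the \code{simulate:} section, or loaded and aligned from the
#' \code{inputs:} files), select the variant panel (optionally one
#' annotation category), optionally calibrate the risk-group fraction
#' against known eGenes, scan every combination against every gene, apply
#' the series-level significance rule (BH FDR or a fixed p threshold), and
#' write association records, eGene summaries, QQ data and a reproducible
#' run manifest to the output directory. One pipeline invocation is one FDR
#' scope. All randomness flows from the single master seed recorded in the
#' manifest; rerunning an identical configuration reproduces identical
#' outputs.
#'
#' @param config named list (see \code{readPipelineConfig()}) or path to a
#'   YAML config file. Recognized top-level keys: \code{seed},
#'   \code{output_dir}, \code{simulate}, \code{inputs}, \code{maf_floor},
#'   \code{category}, \code{variants}, \code{calibrate}, \code{scan}
#'   (\code{q}, \code{max_size}, \code{mode} = \code{fdr}/\code{pthresh},
#'   \code{threshold}, \code{genes}), \code{report}
#'   (\code{min_combinations}).
#' @param outputDir overrides \code{config$output_dir}.
#' @return invisibly, a list with \code{records}, \code{egenes},
#'   \code{calibration} (or NULL), \code{manifest} and \code{dir}.
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config)) config <- readPipelineConfig(config)
    dir <- if (!is.null(outputDir)) outputDir else config$output_dir
    if (is.null(dir)) stop("no output directory configured")
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", dir)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    mafFloor <- if (is.null(config$maf_floor)) 0.05 else config$maf_floor

    # --- stage 1: cohort -----------------------------------------------------
    digests <- list()
    truth <- NULL
    if (!is.null(config$simulate)) {
        simSpec <- config$simulate
        if (is.null(simSpec$seed)) simSpec$seed <- seed
        simConfig <- simulationConfigFromList(simSpec)
        sim <- simulateCohort(simConfig)
        cohort <- sim$cohort
        weights <- sim$weights
        truth <- sim$truth
        categories <- NULL
    } else if (!is.null(config$inputs)) {
        ins <- config$inputs
        for (need in c("genotypes", "expression", "weights"))
            if (is.null(ins[[need]]))
                stop("inputs require at least genotypes, expression, weights ",
                     "(missing: ", need, ")")
        weights <- readWeights(ins$weights)
        geno <- readGenotypes(ins$genotypes, mafFloor = mafFloor,
                              weights = weights)
        expr <- readExpression(ins$expression)
        cov <- if (is.null(ins$covariates)) NULL else readCovariates(ins$covariates)
        cohort <- alignCohort(geno, expr, cov)
        categories <- if (is.null(ins$categories)) NULL
                      else readCategories(ins$categories, weights)
        digests <- .fileDigests(ins)
    } else stop("config must provide either 'simulate' or 'inputs'")

    # --- stage 2: variant panel ---------------------------------------------
    panel <- intersect(variantIDs(cohort), variantIDs(weights))
    if (!is.null(config$category)) {
        if (is.null(categories))
            stop("config selects category '", config$category,
                 "' but no category annotation was provided")
        if (!config$category %in% names(categories))
            stop("unknown category: ", config$category)
        panel <- intersect(panel, categories[[config$category]])
    }
    if (!is.null(config$variants)) panel <- intersect(panel, unlist(config$variants))
    if (!length(panel))
        stop("stage 'variant selection': no variants survive filtering")

    scanCfg <- if (is.null(config$scan)) list() else config$scan
    q <- if (is.null(scanCfg$q)) 0.3 else scanCfg$q
    maxSize <- scanCfg$max_size
    mode <- if (is.null(scanCfg$mode)) "fdr" else scanCfg$mode
    threshold <- if (is.null(scanCfg$threshold)) {
        if (mode == "fdr") 0.05 else 1e-5
    } else scanCfg$threshold

    # --- stage 3: optional group-size calibration ----------------------------
    calibration <- NULL
    if (!is.null(config$calibrate)) {
        cal <- config$calibrate
        qGrid <- if (is.null(cal$q_grid)) seq(0.05, 0.35, by = 0.05)
                 else unlist(cal$q_grid)
        calibration <- calibrateGroupSize(cohort, weights, panel,
                                          unlist(cal$known_egenes), qGrid)
        if (!is.na(calibration$selected)) q <- calibration$selected
        utils::write.table(calibration$table,
                           file.path(dir, "calibration.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # --- stage 4: scan + significance ---------------------------------------
    records <- runScan(cohort, weights, panel, q = q, maxSize = maxSize,
                       genes = scanCfg$genes)
    runLog <- attr(records, "runLog")
    records <- adjustSeries(records)
    sigStat <- if (mode == "fdr") "q" else "p"

    # --- stage 5: reports + manifest ----------------------------------------
    minComb <- if (is.null(config$report$min_combinations)) 1L
               else config$report$min_combinations
    egenes <- summarizeEgenes(records, threshold, statistic = sigStat,
                              minCombinations = minComb)
    writeAssociations(records, file.path(dir, "associations.tsv"))
    utils::write.table(egenes, file.path(dir, "egenes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    qq <- qqData(records$p)
    utils::write.table(qq[seq(1, nrow(qq), length.out = min(nrow(qq), 10000)), ],
                       file.path(dir, "qq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth))
        utils::write.table(truth, file.path(dir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

    manifest <- list(
        package_version = as.character(utils::packageVersion("grsQTL")),
        seed = seed,
        config = config,
        input_digests = digests,
        n_samples = length(sampleIDs(cohort)),
        n_variants_panel = length(panel),
        n_genes = runLog$n_genes,
        genotype_load_report = loadReport(genotypes(cohort)),
        q_fraction = q,
        group_size = runLog$group_size,
        n_combinations = runLog$n_combinations,
        n_tests = runLog$n_tests,
        planned_tests = plannedTests(length(panel), runLog$n_genes,
                                     maxSize = maxSize),
        significance_mode = mode,
        threshold = threshold,
        n_significant = sum(!is.na(records[[sigStat]]) &
                                records[[sigStat]] < threshold),
        n_egenes = nrow(egenes),
        selected_q = if (is.null(calibration)) NULL else calibration$selected,
        n_failed_combinations = length(runLog$failed_combinations)
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(records = records, egenes = egenes,
                   calibration = calibration, manifest = manifest, dir = dir))
}
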