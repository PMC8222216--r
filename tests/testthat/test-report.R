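test_that("eGene summaries apply thresholds and combination-count filters", {
    recs <- makeRecords(
        combination = c("a", "a+b", "a+b+c", "b", "b+c", "c"),
        gene_id = c("gA", "gA", "gA", "gB", "gB", "gC"),
        es = c(0.5, 0.9, -1.1, 0.4, 0.6, 0.2),
        p = c(1e-8, 1e-9, 1e-10, 1e-8, 1e-9, 0.5))
    out <- summarizeEgenes(recs, 1e-7, "p", minCombinations = 3)
    expect_equal(out$gene_id, "gA")
    expect_true(out$single_variant_sufficient)
    expect_equal(out$n_significant, 3)
    expect_equal(out$min_size, 1)
    expect_equal(out$max_size, 3)
    expect_equal(out$strongest_combination, "a+b+c")
    expect_equal(out$strongest_es, -1.1)

    # both genes at a looser filter; monotone in the threshold
    out2 <- summarizeEgenes(recs, 1e-7, "p", minCombinations = 2)
    expect_setequal(out2$gene_id, c("gA", "gB"))
    loose <- summarizeEgenes(recs, 1e-6, "p")
    strict <- summarizeEgenes(recs, 1e-9, "p")
    expect_true(all(strict$gene_id %in% loose$gene_id))

    # empty input and all-filtered input give empty summaries
    expect_equal(nrow(summarizeEgenes(recs[0, ], 0.05, "p")), 0)
    expect_equal(nrow(summarizeEgenes(recs, 1e-20, "p")), 0)
})

test_that("contribution profiles reproduce printed-style percentages", {
    # toy record tables built with the published counts
    buildRecs <- function(total, containing, variant = "rsX") {
        combos <- character(total)
        combos[seq_len(containing)] <- paste0(variant, "+f", seq_len(containing))
        if (containing < total)
            combos[(containing + 1):total] <- paste0("fA+g", seq_len(total - containing))
        makeRecords(combos, "gene1", es = 1, p = 1e-9)
    }
    prof <- contributionProfile(buildRecs(40903, 40366), "gene1", 1e-7, "p")
    expect_equal(prof$percent[prof$variant_id == "rsX"], 98.7)
    expect_equal(prof$n_combinations[prof$variant_id == "rsX"], 40366)
    # 36873/40903 = 0.901474: half-up rounding at one decimal gives 90.1
    prof2 <- contributionProfile(buildRecs(40903, 36873), "gene1", 1e-7, "p")
    expect_equal(prof2$fraction[prof2$variant_id == "rsX"], 36873 / 40903)
    expect_equal(prof2$percent[prof2$variant_id == "rsX"], 90.1)
    prof3 <- contributionProfile(buildRecs(192, 182), "gene1", 1e-7, "p")
    expect_equal(prof3$percent[prof3$variant_id == "rsX"], 94.8)
    # a variant present in every combination has fraction exactly 1
    prof4 <- contributionProfile(buildRecs(50, 50), "gene1", 1e-7, "p")
    expect_equal(prof4$fraction[prof4$variant_id == "rsX"], 1)
    expect_equal(prof4$percent[prof4$variant_id == "rsX"], 100.0)
})

test_that("contribution fractions partition the combination count", {
    set.seed(8)
    ids <- paste0("rs", 1:6)
    combos <- replicate(200, paste(sort(sample(ids, sample(2:5, 1))),
                                   collapse = "+"))
    recs <- makeRecords(unique(combos), "g1", es = 1, p = 1e-9)
    prof <- contributionProfile(recs, "g1", 1e-7, "p")
    total <- attr(prof, "n_total")
    for (v in prof$variant_id) {
        contains <- grepl(paste0("(^|\\+)", v, "($|\\+)"), recs$combination)
        expect_equal(prof$n_combinations[prof$variant_id == v], sum(contains))
        expect_equal(sum(contains) + sum(!contains), total)
    }
})

test_that("combination trees carry the covering relations of tested subsets", {
    recs <- makeRecords(
        combination = c("a", "a+b", "a+c", "a+b+c"),
        gene_id = "g1", es = c(1, 1.2, 0.8, 1.5),
        p = c(1e-3, 1e-6, 0.2, 1e-8))
    tree <- buildCombinationTree(recs, "g1", "a", threshold = 1e-5, statistic = "p")
    expect_equal(nrow(tree$nodes), 4)
    expect_equal(nrow(tree$edges), 4)
    got <- paste(tree$edges$parent, tree$edges$child, sep = ">")
    expect_setequal(got, c("a>a+b", "a>a+c", "a+b>a+b+c", "a+c>a+b+c"))
    expect_equal(tree$nodes$significant[tree$nodes$combination == "a"], FALSE)
    expect_equal(tree$nodes$significant[tree$nodes$combination == "a+b+c"], TRUE)

    # root = full set, or no supersets tested -> single node, no edges
    t2 <- buildCombinationTree(recs, "g1", c("a", "b", "c"))
    expect_equal(nrow(t2$nodes), 1)
    expect_equal(nrow(t2$edges), 0)
    expect_error(buildCombinationTree(recs, "g1", "z"), "not tested")
})

test_that("trees match a brute-force lattice builder on small panels", {
    set.seed(15)
    ids <- letters[1:5]
    all <- oraclePowerset(ids)
    keep <- all[runif(length(all)) < 0.7]
    keep <- c(list("a"), keep)  # ensure root tested
    keys <- unique(vapply(keep, paste, character(1), collapse = "+"))
    recs <- makeRecords(keys, "g1", es = 1, p = 1e-4)
    tree <- buildCombinationTree(recs, "g1", "a")
    # oracle: reachable-from-root closure, then all covering pairs
    memb <- strsplit(keys, "+", fixed = TRUE)
    names(memb) <- keys
    reach <- "a"
    repeat {
        add <- Filter(function(k) {
            any(vapply(reach, function(r)
                length(memb[[k]]) == length(memb[[r]]) + 1 &&
                    all(memb[[r]] %in% memb[[k]]), logical(1)))
        }, setdiff(keys, reach))
        if (!length(add)) break
        reach <- c(reach, add)
    }
    edges <- character()
    for (p1 in reach) for (c1 in reach)
        if (length(memb[[c1]]) == length(memb[[p1]]) + 1 &&
            all(memb[[p1]] %in% memb[[c1]]))
            edges <- c(edges, paste(p1, c1, sep = ">"))
    expect_setequal(tree$nodes$combination, reach)
    expect_setequal(paste(tree$edges$parent, tree$edges$child, sep = ">"), edges)

    f <- withr::local_tempfile(fileext = ".json")
    writeCombinationTree(tree, f)
    parsed <- jsonlite::read_json(f)
    expect_equal(parsed[[1]]$combination, "a")
})

test_that("cross-dataset overlap counts shared eGenes", {
    expect_equal(crossDatasetOverlap(c("g1", "g2"), c("g3"))$n_shared, 0)
    same <- crossDatasetOverlap(c("g1", "g2"), c("g2", "g1"))
    expect_equal(same$n_shared, 2)
    ab <- crossDatasetOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
    expect_equal(ab$shared, c("g2", "g3"))
    expect_equal(unlist(ab[c("n_a", "n_b", "n_shared")]),
                 c(n_a = 3, n_b = 3, n_shared = 2))
})

test_that("replication in the same cohort reproduces discovery effects", {
    sim <- simulateCohort(simulationConfig(
        nIndividuals = 100, nVariants = 3, nGenes = 10, noiseSd = 0.3,
        plantedEffects = list(plantedEffect("gene00004", paste0("snp00", 1:3),
                                            0.6)),
        seed = 44))
    recs <- adjustSeries(runScan(sim$cohort, sim$weights, q = 0.3))
    rep <- replicateTopCombinations(recs, sim$cohort, sim$weights,
                                    topK = 3, threshold = 0.05, statistic = "q")
    expect_true(all(rep$testable))
    expect_equal(rep$es_b, rep$es_a, tolerance = 1e-10)
    expect_true(all(rep$same_sign))
})

test_that("replication flags untestable combinations and keeps sign concordance", {
    cfgA <- simulationConfig(
        nIndividuals = 250, nVariants = 4, nGenes = 20, noiseSd = 0.5,
        plantedEffects = list(plantedEffect("gene00002", paste0("snp00", 1:3),
                                            0.5)),
        seed = 60)
    simA <- simulateCohort(cfgA)
    recsA <- adjustSeries(runScan(simA$cohort, simA$weights, q = 0.3))
    # independent draw from the same generative configuration
    cfgB <- cfgA; cfgB@seed <- 61L
    simB <- simulateCohort(cfgB)
    rep <- replicateTopCombinations(recsA, simB$cohort, simA$weights,
                                    topK = 5, threshold = 0.05, statistic = "q")
    planted <- rep[rep$gene_id == "gene00002" & rep$testable, ]
    expect_gt(nrow(planted), 0)
    expect_gt(mean(planted$same_sign), 0.9)

    # drop a variant from cohort B: combinations using it become untestable
    dB <- dosages(genotypes(simB$cohort))[, 1:2]
    genoB <- grsQTL:::newGenotypeMatrix(dB)
    cohortB2 <- alignCohort(genoB, exprMatrix(simB$cohort),
                            covariates(simB$cohort))
    rep2 <- replicateTopCombinations(recsA, cohortB2, simA$weights,
                                     topK = 5, threshold = 0.05, statistic = "q")
    uses34 <- grepl("snp003|snp004", rep2$combination)
    expect_true(all(!rep2$testable[uses34]))
    expect_true(all(is.na(rep2$es_b[uses34])))
})
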