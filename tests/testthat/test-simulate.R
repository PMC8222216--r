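test_that("simulated genotypes are deterministic and follow HWE expectations", {
    g1 <- simulateGenotypes(1000, 6, c(0.5, 0.5), seed = 1)
    g2 <- simulateGenotypes(1000, 6, c(0.5, 0.5), seed = 1)
    expect_identical(dosages(g1), dosages(g2))
    expect_identical(variantMeta(g1), variantMeta(g2))
    # MAF fixed at 0.5: dosage mean 2*MAF = 1, binomial sd per variant
    mu <- colMeans(dosages(g1))
    sdv <- sqrt(2 * 0.5 * 0.5 / 1000)
    expect_true(all(abs(mu - 1) < 3 * sdv))
    g3 <- simulateGenotypes(1000, 6, c(0.5, 0.5), seed = 2)
    expect_false(identical(dosages(g1), dosages(g3)))
})

test_that("genotype frequencies pass a HWE goodness-of-fit screen", {
    n <- 5000
    geno <- simulateGenotypes(n, 40, c(0.2, 0.2), seed = 9)
    # oracle: exact HWE genotype frequencies (1-p)^2, 2p(1-p), p^2
    p <- 0.2
    expFreq <- c((1 - p)^2, 2 * p * (1 - p), p^2) * n
    pvals <- apply(dosages(geno), 2, function(d) {
        obs <- tabulate(d + 1L, nbins = 3)
        suppressWarnings(chisq.test(obs, p = expFreq / n)$p.value)
    })
    expect_gte(mean(pvals > 0.001), 0.95)
})

test_that("simulated covariates honor the spec and are reproducible", {
    spec <- defaultCovariateSpec()
    cv <- simulateCovariates(200, spec, seed = 4)
    expect_identical(colnames(cv), c("age", "sex", "study", paste0("pc", 1:5)))
    expect_equal(nrow(cv), 200)
    expect_s3_class(cv$sex, "factor")
    expect_equal(nlevels(cv$study), 4)
    # balanced categorical labels
    expect_true(max(abs(table(cv$study) - 50)) <= 1)
    expect_true(abs(mean(cv$age)) < 0.25 && abs(sd(cv$age) - 1) < 0.2)
    expect_identical(cv, simulateCovariates(200, spec, seed = 4))
    empty <- simulateCovariates(50, spec[0, ], seed = 1)
    expect_equal(ncol(empty), 0)
    expect_equal(nrow(empty), 50)
})

test_that("a strong planted cis effect is recovered by direct regression", {
    geno <- simulateGenotypes(300, 3, c(0.3, 0.4), seed = 6)
    cfg <- simulationConfig(nIndividuals = 300, nVariants = 3, nGenes = 10,
                            noiseSd = 0.01,
                            covariateSpec = defaultCovariateSpec()[0, ],
                            plantedEffects = list(
                                plantedEffect("gene00003", "snp002", 1,
                                              mode = "single_cis")),
                            seed = 6)
    cov <- simulateCovariates(300, cfg@covariateSpec, seed = 8)
    sim <- simulateExpression(geno, cov, cfg)
    slope <- coef(lm(sim$expression["gene00003", ] ~ dosages(geno)[, "snp002"]))[2]
    expect_equal(unname(slope), 1, tolerance = 0.02)
    expect_equal(sim$truth$variant_set, "snp002")
    expect_equal(sim$truth$mode, "single_cis")
})

test_that("all-null expression variance matches the analytic sum", {
    n <- 4000
    geno <- simulateGenotypes(n, 2, c(0.2, 0.3), seed = 12)
    spec <- defaultCovariateSpec()
    cfg <- simulationConfig(nIndividuals = n, nVariants = 2, nGenes = 60,
                            noiseSd = 0.8, covariateSpec = spec, seed = 12)
    cov <- simulateCovariates(n, spec, seed = cfg@seed + 4L)
    sim <- simulateExpression(geno, cov, cfg)
    # oracle: var(y) = var(covariate contribution) + noiseSd^2
    contrib <- covariateContribution(cov, spec, seed = cfg@seed + 1L)
    wantVar <- var(contrib) + 0.8^2
    gotVar <- apply(sim$expression, 1, var)
    expect_equal(mean(gotVar), wantVar, tolerance = 0.05)
    expect_equal(nrow(sim$truth), 0)
})

test_that("joint additive effects separate GRS groups better than single variants", {
    # brute-force recomputation of group mean differences from the model
    betas <- 0.3
    diffJoint <- diffSingleMax <- numeric(20)
    for (s in 1:20) {
        geno <- simulateGenotypes(400, 3, c(0.2, 0.4), seed = 100 + s)
        cfg <- simulationConfig(nIndividuals = 400, nVariants = 3, nGenes = 2,
                                noiseSd = 1,
                                covariateSpec = defaultCovariateSpec()[0, ],
                                plantedEffects = list(
                                    plantedEffect("gene00001",
                                                  paste0("snp00", 1:3), betas)),
                                seed = 100 + s)
        cov <- simulateCovariates(400, cfg@covariateSpec, seed = 1)
        sim <- simulateExpression(geno, cov, cfg)
        w <- grsWeights(simulateWeights(geno, seed = 200 + s))
        y <- sim$expression["gene00001", ]
        groupDiff <- function(scores) {
            ord <- order(scores, names(scores), method = "radix")
            gs <- groupSize(length(scores), 0.3)
            mean(y[ord[seq.int(length(scores) - gs + 1, length(scores))]]) -
                mean(y[ord[seq_len(gs)]])
        }
        g <- computeGRS(geno, w, paste0("snp00", 1:3))
        diffJoint[s] <- groupDiff(g)
        diffSingleMax[s] <- max(vapply(paste0("snp00", 1:3), function(v)
            groupDiff(computeGRS(geno, w, v)), numeric(1)))
    }
    expect_true(all(diffJoint > 0))
    expect_gt(mean(diffJoint), mean(diffSingleMax))
})

test_that("fixtures round-trip losslessly and reproduce byte-identically", {
    cfg <- simulationConfig(nIndividuals = 40, nVariants = 6, nGenes = 12,
                            seed = 33)
    d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
    p1 <- writeFixture(cfg, d1)
    p2 <- writeFixture(cfg, d2)
    expect_length(p1, 6)
    for (k in names(p1))
        expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                         info = paste("fixture file", k))
    # round trip through the readers
    w <- readWeights(p1["weights"])
    gv <- readGenotypes(p1["vcf"], mafFloor = 0, weights = w)
    gt <- readGenotypes(p1["genotypes"], mafFloor = 0)
    expect_identical(dosages(gv)[, variantIDs(gt)], dosages(gt))
    sim <- simulateCohort(cfg)
    expect_equal(readExpression(p1["expression"]), exprMatrix(sim$cohort),
                 tolerance = 1e-12)
    cv <- readCovariates(p1["covariates"])
    expect_equal(cv$age, covariates(sim$cohort)$age, tolerance = 1e-12)
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulation config validates its invariants", {
    expect_error(simulationConfig(nIndividuals = 2), "nIndividuals")
    expect_error(simulationConfig(mafRange = c(0.1, 0.6)), "mafRange")
    expect_error(simulationConfig(noiseSd = 0), "noiseSd")
    expect_error(simulateGenotypes(10, 2, c(0.4, 0.1)), "mafRange")
    expect_error(
        simulateExpression(
            simulateGenotypes(20, 2, c(0.2, 0.3), seed = 1),
            simulateCovariates(20, defaultCovariateSpec()[0, ], seed = 1),
            simulationConfig(nIndividuals = 20, nVariants = 2, nGenes = 5,
                             covariateSpec = defaultCovariateSpec()[0, ],
                             plantedEffects = list(
                                 plantedEffect("gene00001", "snp999", 1)))),
        "unknown variant")
})
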