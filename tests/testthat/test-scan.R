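test_that("group association without covariates equals the two-sample t-test", {
    set.seed(41)
    for (i in 1:10) {
        nl <- sample(5:20, 1); nh <- sample(5:20, 1)
        y <- c(rnorm(nl), rnorm(nh, mean = 0.7))
        lab <- c(rep("low", nl), rep("high", nh))
        fit <- fitGroupAssociation(y, lab)
        tt <- t.test(y[lab == "high"], y[lab == "low"], var.equal = TRUE)
        expect_equal(fit$es, mean(y[lab == "high"]) - mean(y[lab == "low"]),
                     tolerance = 1e-12)
        expect_equal(fit$p, tt$p.value, tolerance = 1e-12)
    }
})

test_that("perfect group separation reports es 1 and a floored p-value", {
    y <- c(rep(0, 6), rep(1, 6))
    lab <- rep(c("low", "high"), each = 6)
    fit <- fitGroupAssociation(y, lab)
    expect_equal(fit$es, 1)
    expect_equal(fit$p, 1e-300)
    expect_identical(fit$flag, "underflow")
})

test_that("covariate-adjusted fits match the normal-equations oracle", {
    set.seed(42)
    for (i in 1:100) {
        n <- sample(20:50, 1)
        nl <- n %/% 2; nh <- n - nl
        lab <- c(rep("low", nl), rep("high", nh))
        cov <- data.frame(age = rnorm(n),
                          sex = factor(sample(c("f", "m"), n, replace = TRUE)),
                          pc1 = rnorm(n))
        X <- cbind(1, as.numeric(lab == "high"), cov$age,
                   as.numeric(cov$sex == "m"), cov$pc1)
        y <- rnorm(n) + 0.4 * X[, 2] + 0.3 * cov$age
        fit <- fitGroupAssociation(y, lab, cov)
        want <- oracleOLS(y, X)
        expect_equal(fit$es, want$es, tolerance = 1e-8)
        expect_equal(fit$se, want$se, tolerance = 1e-8)
        expect_equal(fit$p, want$p, tolerance = 1e-8)
    }
})

test_that("swapping group labels negates es and preserves se and p", {
    set.seed(7)
    y <- rnorm(30)
    lab <- rep(c("low", "high"), 15)
    cov <- data.frame(age = rnorm(30))
    a <- fitGroupAssociation(y, lab, cov)
    b <- fitGroupAssociation(y, ifelse(lab == "low", "high", "low"), cov)
    expect_equal(a$es, -b$es, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("degenerate genes and rank-deficient designs are handled explicitly", {
    y <- rep(3, 12)
    lab <- rep(c("low", "high"), each = 6)
    fit <- fitGroupAssociation(y, lab)
    expect_equal(fit$es, 0)
    expect_equal(fit$p, 1)
    expect_identical(fit$flag, "degenerate")

    cov <- data.frame(a = rep(1:2, 6), b = rep(1:2, 6) * 2)  # collinear
    expect_error(fitGroupAssociation(rnorm(12), lab, cov), "collinear.*b")
})

test_that("confounding by a covariate is removed when it is adjusted for", {
    set.seed(13)
    n <- 200
    grs <- rnorm(n)
    lab <- ifelse(rank(grs) <= 60, "low", ifelse(rank(grs) > n - 60, "high",
                                                 "excluded"))
    age <- grs + rnorm(n, sd = 0.3)     # age tracks the risk score
    y <- 0.8 * age + rnorm(n, sd = 0.5) # expression driven purely by age
    unadj <- fitGroupAssociation(y, lab)
    adj <- fitGroupAssociation(y, lab, data.frame(age = age))
    expect_lt(unadj$p, 1e-6)
    expect_gt(adj$p, 0.01)
})

test_that("the scan enumerates all combination x gene records in order", {
    sim <- simulateCohort(simulationConfig(nIndividuals = 60, nVariants = 3,
                                           nGenes = 8, seed = 19))
    rec <- runScan(sim$cohort, sim$weights, q = 0.3)
    log <- attr(rec, "runLog")
    expect_equal(log$n_combinations, 7)
    expect_equal(log$n_tests, 56)
    expect_equal(nrow(rec), 56)
    expect_equal(unique(rec$n_low), groupSize(60, 0.3))
    keys <- unique(rec$combination)
    want <- vapply(enumerateCombinations(variantIDs(sim$cohort)), paste,
                   character(1), collapse = "+")
    expect_identical(keys, want)
    # single combination x single gene
    rec1 <- runScan(sim$cohort, sim$weights, variantSubset = "snp001",
                    genes = "gene00001", maxSize = 1)
    expect_equal(nrow(rec1), 1)
})

test_that("scan records match per-gene fitGroupAssociation results", {
    sim <- simulateCohort(simulationConfig(nIndividuals = 80, nVariants = 3,
                                           nGenes = 5, seed = 23))
    rec <- runScan(sim$cohort, sim$weights, q = 0.25)
    for (i in sample(nrow(rec), 8)) {
        ra <- stratify(computeGRS(genotypes(sim$cohort), sim$weights,
                                  splitCombination(rec$combination[i])), 0.25)
        fit <- fitGroupAssociation(exprMatrix(sim$cohort)[rec$gene_id[i], ],
                                   ra, covariates(sim$cohort))
        expect_equal(rec$es[i], fit$es, tolerance = 1e-10)
        expect_equal(rec$p[i], fit$p, tolerance = 1e-10)
    }
})

test_that("BH adjustment matches hand-worked vectors and the naive oracle", {
    expect_equal(adjustFdr(0.01), 0.01)
    # hand BH: p*m/rank then cumulative min from the top
    expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustFdr(rep(0.2, 5)), rep(0.2, 5))
    set.seed(77)
    for (i in 1:50) {
        p <- runif(sample(5:40, 1))
        expect_equal(adjustFdr(p), oracleBH(p), tolerance = 1e-12)
    }
    expect_error(adjustFdr(c(0.1, 0)), "0, 1")
})

test_that("series q-values are a monotone transform of p-value ranks", {
    set.seed(5)
    p <- runif(500)^2
    q <- adjustFdr(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    expect_true(all(q >= p - 1e-15))
})

test_that("qq data pairs sorted p-values with uniform order statistics", {
    m <- 100
    p <- (1:m) / (m + 1)
    qq <- qqData(sample(p))
    expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
    # a planted extreme p-value stands out above the diagonal
    qq2 <- qqData(c(runif(999), 1e-9))
    top <- qq2[nrow(qq2), ]
    expect_gt(top$observed, top$expected + 4)
    # uniform draws hug the diagonal in the bulk
    set.seed(3)
    qq3 <- qqData(runif(10000))
    bulk <- qq3[seq_len(9900), ]
    expect_lt(max(abs(bulk$observed - bulk$expected)), 0.2)
})

test_that("group-size calibration selects the smallest replicating fraction", {
    # effects enormous -> every grid fraction replicates -> smallest selected
    sim <- simulateCohort(simulationConfig(
        nIndividuals = 300, nVariants = 4, nGenes = 20, noiseSd = 0.05,
        plantedEffects = list(
            plantedEffect("gene00001", paste0("snp00", 1:4), 0.5),
            plantedEffect("gene00002", paste0("snp00", 1:4), 0.5)),
        seed = 31))
    cal <- calibrateGroupSize(sim$cohort, sim$weights,
                              knownEgenes = c("gene00001", "gene00002"))
    expect_equal(cal$selected, 0.05)
    expect_true(all(cal$table$all_replicated))

    # all genes null -> nothing replicates, selected unset with a warning
    simN <- simulateCohort(simulationConfig(nIndividuals = 300, nVariants = 4,
                                            nGenes = 20, seed = 37))
    expect_warning(
        calN <- calibrateGroupSize(simN$cohort, simN$weights,
                                   knownEgenes = c("gene00001", "gene00002")),
        "no grid fraction")
    expect_true(is.na(calN$selected))
})

test_that("all-null scans keep the nominal type-I rate", {
    # fraction of raw p < 0.05 on all-null cohorts (31 combinations x 200
    # genes per replicate), averaged over 10 replicates; bounded by three
    # single-replicate binomial standard errors, which is conservative for
    # the averaged fraction
    fracs <- vapply(1:10, function(s) {
        sim <- simulateCohort(simulationConfig(nIndividuals = 400,
                                               nVariants = 5, nGenes = 200,
                                               seed = 500 + s))
        rec <- runScan(sim$cohort, sim$weights, q = 0.3)
        mean(rec$p < 0.05)
    }, numeric(1))
    se1 <- sqrt(0.05 * 0.95 / (31 * 200))
    expect_lt(abs(mean(fracs) - 0.05), 3 * se1)
})
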