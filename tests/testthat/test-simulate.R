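test_that("identical seeds reproduce identical compendia", {
    s1 <- simulateCompendium(smallSimConfig(rngSeed = 7L))
    s2 <- simulateCompendium(smallSimConfig(rngSeed = 7L))
    expect_identical(SummarizedExperiment::assay(s1$human),
                     SummarizedExperiment::assay(s2$human))
    expect_identical(SummarizedExperiment::assay(s1$mouse),
                     SummarizedExperiment::assay(s2$mouse))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateCompendium(smallSimConfig(rngSeed = 8L))
    expect_false(identical(SummarizedExperiment::assay(s1$human),
                           SummarizedExperiment::assay(s3$human)))
})

test_that("every simulated probe appears exactly once in the truth table", {
    sim <- simulateCompendium(smallSimConfig())
    expect_identical(sort(sim$truth$probeId),
                     sort(c(rownames(sim$human), rownames(sim$mouse))))
    expect_false(anyDuplicated(sim$truth$probeId) > 0)
})

test_that("empirical quadrant frequencies match the configured joint", {
    n <- 6000L
    cfg <- simulationConfig(nSamplesHuman = n, nSamplesMouse = 100L,
                            pairsPerClass = 1L, eps = 0.02,
                            conservedPerClass = 0L, nBackground = 0L,
                            nFlat = 0L, rngSeed = 31L)
    sim <- simulateCompendium(cfg)
    st <- ifelse(SummarizedExperiment::assay(sim$human) > 8, 1L, 0L)
    z <- st["SEEDG_1_at", ]
    eps <- 0.02; cross <- 0.1
    joint <- list(  # quadrant probabilities (00, 01, 10, 11) per class
        LOW_LOW = c(0.5 - eps, eps, cross, 0.5 - cross),
        HIGH_HIGH = c(0.5 - cross, cross, eps, 0.5 - eps),
        LOW_HIGH = c(eps, 0.5 - eps, 0.5 - cross, cross),
        HIGH_LOW = c(cross, 0.5 - cross, 0.5 - eps, eps),
        EQUIVALENT = c(0.5 - eps, eps, eps, 0.5 - eps),
        OPPOSITE = c(eps, 0.5 - eps, 0.5 - eps, eps))
    partners <- sim$truth[sim$truth$species == "human" &
                          sim$truth$role == "partner", ]
    for (i in seq_len(nrow(partners))) {
        w <- st[partners$probeId[i], ]
        emp <- c(mean(z == 0 & w == 0), mean(z == 0 & w == 1),
                 mean(z == 1 & w == 0), mean(z == 1 & w == 1))
        want <- joint[[partners$class[i]]]
        tol <- 3 * sqrt(want * (1 - want) / n) + 3 * sqrt(0.25 / n)
        expect_true(all(abs(emp - want) < tol),
                    info = partners$class[i])
    }
})

test_that("eps = 0 plants an exactly empty sparse quadrant", {
    cfg <- simulationConfig(nSamplesHuman = 500L, nSamplesMouse = 100L,
                            pairsPerClass = 1L, eps = 0,
                            conservedPerClass = 0L, nBackground = 2L,
                            nFlat = 0L, rngSeed = 32L)
    sim <- simulateCompendium(cfg)
    be <- binarizeMatrix(sim$human)
    rel <- booleanRelation(be, "SEEDG_1_at", "GENE1_at", sthr = 3,
                           pthr = 0.1)
    expect_identical(rel$class, "LOW_LOW")
    expect_identical(rel$counts[["n01"]], 0L)
    expect_equal(rel$stats$p[rel$stats$quadrant == "01"], 0)
})

test_that("flat probes are ineligible after binarization", {
    sim <- simulateCompendium(smallSimConfig())
    be <- binarizeMatrix(sim$human)
    flats <- sim$truth$probeId[sim$truth$role == "flat"]
    expect_false(any(eligibleProbes(be)[flats]))
    expect_true(all(is.na(stateMatrix(be)[flats, ])))
})

test_that("inconsistent sparse mass is rejected before sampling", {
    expect_error(simulationConfig(eps = 0.3), "eps")
    expect_error(simulationConfig(eps = 0.15, crossFrac = 0.1),
                 "crossFrac")
    expect_error(simulationConfig(sigma = 2), "separability")
})

test_that("planted promoter sites are exactly recoverable", {
    sim <- simulatePromoters(4, 400, c(3, 0, 2, 1), rngSeed = 33L)
    expect_identical(nchar(as.character(sim$seqs[[1]])), 400L)
    for (s in seq_len(4)) {
        id <- sprintf("promoter%d", s)
        hits <- scanMotif(as.character(sim$seqs[[s]]))
        truth <- sim$truth[sim$truth$seqId == id, ]
        expect_identical(nrow(hits), nrow(truth))
        if (nrow(truth)) {
            o <- order(truth$start)
            expect_identical(hits$start, truth$start[o])
            expect_identical(hits$strand, truth$strand[o])
        }
    }
    expect_true(any(sim$truth$strand == "-"))   # reverse sites do occur
    # determinism and infeasible packing
    sim2 <- simulatePromoters(4, 400, c(3, 0, 2, 1), rngSeed = 33L)
    expect_identical(as.character(sim$seqs), as.character(sim2$seqs))
    expect_error(simulatePromoters(1, 30, 10, rngSeed = 1),
                 "infeasible packing")
})
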