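# shared small compendium: 12 planted pairs (2 per class), 20 background,
# thresholds at the small-n operating point S > 10, p < 0.1
sim <- simulateCompendium(smallSimConfig())
be <- binarizeMatrix(sim$human)
tbl <- discoverCandidates(be, "SEEDG_1_at", sim$annotationHuman,
                          sthr = 10, pthr = 0.1)
partners <- sim$truth[sim$truth$species == "human" &
                      sim$truth$role == "partner", ]

test_that("discovery recovers planted classes and rejects background", {
    rec <- as.data.frame(candidateRecords(tbl))
    found <- rec$class[match(partners$probeId, rec$probeId)]
    expect_identical(found, partners$class)
    expect_false(any(grepl("^BG", rec$probeId)))
    expect_false(any(grepl("^SEEDG", rec$probeId)))  # seed gene excluded
    expect_true(all(rec$nPairs <= ncol(be)))
    expect_error(discoverCandidates(be, "FLAT1_at"), "FLAT1_at")
})

test_that("a duplicated seed probe under another id comes back EQUIVALENT", {
    m <- SummarizedExperiment::assay(sim$human, 1L)[1:10, ]
    m <- rbind(m, SEEDCOPY_at = m["SEEDG_1_at", ])
    be2 <- binarizeMatrix(m)
    t2 <- discoverCandidates(be2, "SEEDG_1_at", sthr = 10, pthr = 0.1)
    rec <- as.data.frame(candidateRecords(t2))
    expect_identical(rec$class[rec$probeId == "SEEDCOPY_at"], "EQUIVALENT")
})

test_that("a matrix with no eligible partners yields an empty table", {
    m <- matrix(5 + rnorm(40, 0, 0.05), 4, 10,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
    m <- rbind(m, seed = c(rep(1, 5), rep(9, 5)))
    be3 <- binarizeMatrix(m, minN = 2)
    t3 <- discoverCandidates(be3, "seed", sthr = 1, pthr = 0.5,
                             minPairs = 2)
    expect_identical(nrow(candidateRecords(t3)), 0L)
})

test_that("ranking is by S, then p, then probe id", {
    t0 <- makeCandidateTable(c("a_at", "b_at", "c_at", "d_at"),
                             c("A", "B", "C", "D"),
                             S = c(41.2, 48.06, 41.2, 41.2),
                             p = c(0.15, 0.08, 0.08, 0.08))
    r <- as.data.frame(candidateRecords(rankCandidates(t0)))
    expect_identical(r$probeId, c("b_at", "c_at", "d_at", "a_at"))
    expect_identical(r$rank, 1:4)
    t1 <- makeCandidateTable("x_at", "X", 12, 0.01)
    expect_identical(candidateRecords(rankCandidates(t1))$rank, 1L)
})

test_that("filters annotate without touching class, statistics or order", {
    ranked <- rankCandidates(tbl)
    out <- concordanceFilter(ranked, paste0("SEEDG_", 2:4, "_at"), be)
    out <- conservationFilter(out, binarizeMatrix(sim$mouse), "m_Seedg_at",
                              sim$orthologs, sim$annotationMouse,
                              sthr = 10, pthr = 0.1)
    out <- noveltyAnnotate(out, c("VEGFA"))
    a <- as.data.frame(candidateRecords(ranked))
    b <- as.data.frame(candidateRecords(out))
    expect_identical(a$probeId, b$probeId)
    expect_identical(a$class, b$class)
    expect_equal(a$bestS, b$bestS)
    expect_equal(a$bestP, b$bestP)
    expect_identical(a$rank, b$rank)
})

test_that("concordance follows alternate-probeset directionality", {
    # faithful alternates agree with every planted candidate
    out <- concordanceFilter(tbl, paste0("SEEDG_", 2:4, "_at"), be,
                             mode = "all")
    rec <- as.data.frame(candidateRecords(out))
    expect_true(all(rec$concordant[rec$probeId %in% partners$probeId]))
    # an inverted alternate flips directionality: all fails, majority holds
    simD <- simulateCompendium(smallSimConfig(
        rngSeed = 202L,
        altSeedBehavior = c("same", "same", "inverted")))
    beD <- binarizeMatrix(simD$human)
    tD <- discoverCandidates(beD, "SEEDG_1_at", simD$annotationHuman,
                             sthr = 10, pthr = 0.1)
    pD <- simD$truth[simD$truth$species == "human" &
                     simD$truth$role == "partner", ]
    recAll <- as.data.frame(candidateRecords(
        concordanceFilter(tD, paste0("SEEDG_", 2:4, "_at"), beD,
                          mode = "all")))
    recMaj <- as.data.frame(candidateRecords(
        concordanceFilter(tD, paste0("SEEDG_", 2:4, "_at"), beD,
                          mode = "majority")))
    onP <- recAll$probeId %in% pD$probeId
    expect_false(any(recAll$concordant[onP]))
    expect_true(all(recMaj$concordant[recMaj$probeId %in% pD$probeId]))
    expect_false(unique(pD$concordantAll))
    expect_true(unique(pD$concordantMajority))
    # no eligible alternates: flags stay unset with a warning
    expect_warning(
        concordanceFilter(tbl, "FLAT1_at", be),
        "no eligible alternate")
})

test_that("conservation compares directionality through the ortholog map", {
    mouseBe <- binarizeMatrix(sim$mouse)
    out <- conservationFilter(rankCandidates(tbl), mouseBe, "m_Seedg_at",
                              sim$orthologs, sim$annotationMouse,
                              sthr = 10, pthr = 0.1)
    rec <- as.data.frame(candidateRecords(out))
    idx <- match(partners$probeId, rec$probeId)
    expect_identical(rec$conserved[idx], partners$conserved)
    # conserved pairs were planted with the LOW/HIGH-swapped mouse class,
    # so a strict-class comparison must reject them
    strict <- conservationFilter(rankCandidates(tbl), mouseBe,
                                 "m_Seedg_at", sim$orthologs,
                                 sim$annotationMouse, strictClass = TRUE,
                                 sthr = 10, pthr = 0.1)
    sRec <- as.data.frame(candidateRecords(strict))
    asym <- partners$probeId[partners$conserved &
        partners$class %in% c("LOW_LOW", "HIGH_HIGH",
                              "LOW_HIGH", "HIGH_LOW")]
    expect_false(any(sRec$conserved[match(asym, sRec$probeId)]))
    # a candidate without any ortholog is not conserved, with the reason
    orth2 <- sim$orthologs[sim$orthologs$human != partners$gene[1], ]
    out2 <- conservationFilter(rankCandidates(tbl), mouseBe, "m_Seedg_at",
                               orth2, sim$annotationMouse,
                               sthr = 10, pthr = 0.1)
    r2 <- as.data.frame(candidateRecords(out2))
    i <- match(partners$probeId[1], r2$probeId)
    expect_false(r2$conserved[i])
    expect_identical(r2$conservedBy[i], "no_ortholog")
    expect_error(conservationFilter(tbl, mouseBe, "m_Bg1_at",
                                    sim$orthologs, sim$annotationMouse),
                 NA)
    expect_error(conservationFilter(tbl, mouseBe, "nope",
                                    sim$orthologs, sim$annotationMouse),
                 "nope")
})

test_that("novelty is a case-insensitive absence from the known list", {
    t0 <- makeCandidateTable(c("a_at", "b_at"), c("VEGFA", "FAM114A1"),
                             c(48, 41), c(0.05, 0.08))
    out <- noveltyAnnotate(t0, c("vegfa", "EPO"))
    rec <- as.data.frame(candidateRecords(out))
    expect_identical(rec$novel, c(FALSE, TRUE))
    allNovel <- noveltyAnnotate(t0, character(0))
    expect_true(all(candidateRecords(allNovel)$novel))
})

test_that("top-k intersection keeps only genes shared by every run", {
    mk <- function(genes) rankCandidates(makeCandidateTable(
        paste0(genes, "_at"), genes, S = rev(seq_along(genes)) + 10,
        p = rep(0.01, length(genes))))
    tabs <- list(mk(c("A", "B", "C")), mk(c("B", "C", "D")),
                 mk(c("C", "E", "F")))
    expect_identical(topKIntersection(tabs, 3), "C")
    expect_identical(topKIntersection(list(mk(c("A", "B")),
                                           mk(c("C", "D"))), 2),
                     character(0))
    ws <- capture_warnings(res <- topKIntersection(tabs, 10))
    expect_true(length(ws) == 3L && all(grepl("exceeds", ws)))
    expect_identical(res, "C")
    # rank cutoff is honored: B is outside run 1's top-1
    expect_identical(topKIntersection(list(mk(c("A", "B")),
                                           mk(c("B", "A"))), 1),
                     character(0))
})

test_that("survivor selection honors flags and the top cutoff", {
    t0 <- makeCandidateTable(paste0(letters[1:3], "_at"),
                             c("G1", "G2", "G3"),
                             c(50, 40, 30), c(0.01, 0.02, 0.03))
    t0 <- rankCandidates(t0)
    rec <- candidateRecords(t0)
    rec$concordant <- c(TRUE, TRUE, FALSE)
    rec$conserved <- c(TRUE, TRUE, TRUE)
    rec$novel <- c(TRUE, FALSE, TRUE)
    t0@records <- rec
    surv <- selectSurvivors(t0)
    expect_identical(surv$probeId, "a_at")
    surv2 <- selectSurvivors(t0, requireNovel = FALSE, top = 1)
    expect_identical(surv2$probeId, "a_at")
})
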