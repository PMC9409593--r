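sc <- stateCodes()

test_that("quadrant tally keeps only committed states", {
    a <- c(sc[["LOW"]], sc[["LOW"]], sc[["HIGH"]], sc[["HIGH"]],
           sc[["INTERMEDIATE"]])
    b <- c(sc[["LOW"]], sc[["HIGH"]], sc[["LOW"]], sc[["HIGH"]],
           sc[["LOW"]])
    cnt <- countQuadrants(a, b)
    expect_identical(cnt, c(n00 = 1L, n01 = 1L, n10 = 1L, n11 = 1L,
                            n = 4L))
    allInt <- rep(sc[["INTERMEDIATE"]], 5)
    expect_identical(countQuadrants(allInt, allInt)[["n"]], 0L)
    expect_error(countQuadrants(a, b[-1]), "equal length")
    set.seed(21)
    for (i in 1:5) {
        a <- randomStates(1000)
        b <- randomStates(1000)
        expect_identical(countQuadrants(a, b), bruteQuadrants(a, b))
    }
})

test_that("implication statistics match direct arithmetic", {
    s <- implicationStats(quadrantCounts(50, 0, 25, 25))
    expect_equal(s$expected[s$quadrant == "01"], 12.5)
    expect_equal(s$S[s$quadrant == "01"], sqrt(12.5))
    expect_equal(s$p[s$quadrant == "01"], 0)
    s <- implicationStats(quadrantCounts(40, 2, 30, 28))
    expect_equal(s$expected[s$quadrant == "01"], 12.6)
    expect_equal(s$S[s$quadrant == "01"], (12.6 - 2) / sqrt(12.6),
                 tolerance = 1e-12)
    expect_equal(s$S[s$quadrant == "01"], 2.986, tolerance = 1e-3)
    expect_equal(s$p[s$quadrant == "01"], 0.5 * (2 / 42 + 2 / 30),
                 tolerance = 1e-12)
    s <- implicationStats(quadrantCounts(25, 25, 25, 25))
    expect_true(all(s$S == 0))
    # a zeroed row makes two quadrants undefined: S 0, p 1
    s <- implicationStats(quadrantCounts(0, 0, 30, 30))
    expect_identical(s$defined, c(FALSE, FALSE, TRUE, TRUE))
    expect_true(all(s$S[1:2] == 0) && all(s$p[1:2] == 1))
})

test_that("classification maps sparse quadrants to the six classes", {
    cnt <- quadrantCounts(50, 0, 0, 50)
    expect_identical(classifyPair(implicationStats(cnt), cnt, 4, 0.1),
                     "EQUIVALENT")
    cnt <- quadrantCounts(0, 50, 50, 0)
    expect_identical(classifyPair(implicationStats(cnt), cnt, 4, 0.1),
                     "OPPOSITE")
    cnt <- quadrantCounts(40, 2, 30, 28)
    expect_identical(classifyPair(implicationStats(cnt), cnt, 2.5, 0.1),
                     "LOW_LOW")
    cnt <- quadrantCounts(25, 25, 25, 25)
    expect_identical(classifyPair(implicationStats(cnt), cnt, 0.001, 0.99),
                     "NONE")
    # below min_pairs everything is NONE
    cnt <- quadrantCounts(10, 0, 0, 9)
    expect_identical(classifyPair(implicationStats(cnt), cnt, 1, 0.5,
                                  minPairs = 20), "NONE")
})

test_that("transposition swaps asymmetric classes and fixes symmetric ones",
{
    swap <- c(LOW_LOW = "HIGH_HIGH", HIGH_HIGH = "LOW_LOW",
              LOW_HIGH = "LOW_HIGH", HIGH_LOW = "HIGH_LOW",
              EQUIVALENT = "EQUIVALENT", OPPOSITE = "OPPOSITE",
              NONE = "NONE")
    set.seed(22)
    for (i in 1:200) {
        cnt <- quadrantCounts(rpois(1, 30), rpois(1, 5), rpois(1, 5),
                              rpois(1, 30))
        tcnt <- quadrantCounts(cnt[["n00"]], cnt[["n10"]], cnt[["n01"]],
                               cnt[["n11"]])
        cab <- classifyPair(implicationStats(cnt), cnt, 2, 0.25)
        cba <- classifyPair(implicationStats(tcnt), tcnt, 2, 0.25)
        expect_identical(cba, unname(swap[cab]))
        # statistics transpose quadrant-wise
        sab <- implicationStats(cnt)
        sba <- implicationStats(tcnt)
        expect_equal(sab$S[sab$quadrant == "01"],
                     sba$S[sba$quadrant == "10"], tolerance = 1e-12)
    }
})

test_that("an eligible probe against itself is EQUIVALENT with p = 0", {
    set.seed(23)
    s <- randomStates(500, pInt = 0.1)
    cnt <- countQuadrants(s, s)
    stats <- implicationStats(cnt)
    expect_identical(cnt[["n01"]], 0L)
    expect_identical(cnt[["n10"]], 0L)
    expect_equal(stats$p[stats$quadrant %in% c("01", "10")], c(0, 0))
    eMin <- min(stats$expected[stats$quadrant %in% c("01", "10")])
    expect_identical(classifyPair(stats, cnt, sqrt(eMin) * 0.9, 0.1),
                     "EQUIVALENT")
})

test_that("tightening thresholds only moves calls toward NONE", {
    symDegrade <- list(EQUIVALENT = c("LOW_LOW", "HIGH_HIGH"),
                       OPPOSITE = c("LOW_HIGH", "HIGH_LOW"))
    set.seed(24)
    for (i in 1:300) {
        cnt <- quadrantCounts(rpois(1, 40), rpois(1, 3), rpois(1, 3),
                              rpois(1, 40))
        stats <- implicationStats(cnt)
        s1 <- runif(1, 0, 4); s2 <- s1 + runif(1, 0, 3)
        p1 <- runif(1, 0.05, 0.4); p2 <- p1 * runif(1, 0.2, 1)
        loose <- classifyPair(stats, cnt, s1, p1)
        strict <- classifyPair(stats, cnt, s2, p2)
        if (loose == "NONE") next
        ok <- strict == loose || strict == "NONE" ||
            (loose %in% names(symDegrade) &&
             strict %in% symDegrade[[loose]])
        expect_true(ok, info = sprintf("loose=%s strict=%s", loose, strict))
    }
})

test_that("pair query wires states, statistics and class together", {
    sim <- simulateCompendium(smallSimConfig())
    be <- binarizeMatrix(sim$human)
    partners <- sim$truth[sim$truth$species == "human" &
                          sim$truth$role == "partner", ]
    probe <- partners$probeId[partners$class == "EQUIVALENT"][1]
    rel <- booleanRelation(be, "SEEDG_1_at", probe, sthr = 10, pthr = 0.1)
    expect_identical(rel$class, "EQUIVALENT")
    expect_error(booleanRelation(be, "SEEDG_1_at", "nope_at"), "nope_at")
})
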