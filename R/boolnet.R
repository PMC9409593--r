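#' Tally the 2x2 low/high contingency quadrants of a probe pair
#'
#' Each sample contributes to exactly one quadrant when both probes are in a
#' committed state (LOW or HIGH); samples where either probe is INTERMEDIATE
#' or missing are dropped. Quadrant (i, j) indexes state of A then state of
#' B, 0 = LOW and 1 = HIGH.
#'
#' @param statesA,statesB Integer state vectors per \code{\link{stateCodes}},
#'   equal length.
#'
#' @return Named integer vector \code{c(n00, n01, n10, n11, n)}.
#'
#' @examples
#' sc <- stateCodes()
#' a <- c(sc["LOW"], sc["LOW"], sc["HIGH"], sc["HIGH"], sc["INTERMEDIATE"])
#' b <- c(sc["LOW"], sc["HIGH"], sc["LOW"], sc["HIGH"], sc["LOW"])
#' countQuadrants(a, b)
#' @export
countQuadrants <- function(statesA, statesB) {
    if (length(statesA) != length(statesB))
        stop("state vectors must have equal length (",
             length(statesA), " vs ", length(statesB), ")")
    codes <- stateCodes()
    aL <- statesA == codes[["LOW"]]
    aH <- statesA == codes[["HIGH"]]
    bL <- statesB == codes[["LOW"]]
    bH <- statesB == codes[["HIGH"]]
    keep <- (aL | aH) & (bL | bH)
    keep[is.na(keep)] <- FALSE
    n00 <- sum(aL & bL & keep, na.rm = TRUE)
    n01 <- sum(aL & bH & keep, na.rm = TRUE)
    n10 <- sum(aH & bL & keep, na.rm = TRUE)
    n11 <- sum(aH & bH & keep, na.rm = TRUE)
    quadrantCounts(n00, n01, n10, n11)
}

#' Build a quadrant-count vector directly
#'
#' @param n00,n01,n10,n11 Non-negative integer counts; first index is the
#'   state of probe A, second of probe B (0 = LOW, 1 = HIGH).
#' @return Named integer vector \code{c(n00, n01, n10, n11, n)}.
#' @examples
#' quadrantCounts(50, 0, 25, 25)
#' @export
quadrantCounts <- function(n00, n01, n10, n11) {
    cnt <- c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
    if (any(is.na(cnt)) || any(cnt < 0))
        stop("quadrant counts must be non-negative")
    cnt <- as.integer(round(cnt))
    c(n00 = cnt[[1L]], n01 = cnt[[2L]], n10 = cnt[[3L]], n11 = cnt[[4L]],
      n = sum(cnt))
}

#' Sparse-quadrant implication statistics
#'
#' For every quadrant (i, j) of the 2x2 low/high table, computes the
#' independence expectation \eqn{e_{ij} = (n_{i0}+n_{i1})(n_{0j}+n_{1j})/n},
#' the sparseness statistic \eqn{S_{ij} = (e_{ij} - n_{ij})/\sqrt{e_{ij}}}
#' and the error rate
#' \eqn{p_{ij} = (n_{ij}/(n_{i0}+n_{i1}) + n_{ij}/(n_{0j}+n_{1j}))/2}.
#' A large positive S with small p marks the quadrant as sparsely populated
#' relative to independence, i.e. as evidence for a Boolean implication.
#' Quadrants with \eqn{e_{ij} = 0} carry no evidence and are flagged
#' undefined (S reported as 0, p as 1).
#'
#' @param counts Quadrant counts from \code{\link{countQuadrants}} or
#'   \code{\link{quadrantCounts}}.
#'
#' @return A data.frame with one row per quadrant (\code{"00"}, \code{"01"},
#'   \code{"10"}, \code{"11"}) and columns \code{quadrant}, \code{observed},
#'   \code{expected}, \code{S}, \code{p}, \code{defined}.
#'
#' @examples
#' implicationStats(quadrantCounts(50, 0, 25, 25))
#' @export
implicationStats <- function(counts) {
    o <- c(counts[["n00"]], counts[["n01"]], counts[["n10"]],
           counts[["n11"]])
    n <- counts[["n"]]
    rowTot <- c(o[1] + o[2], o[1] + o[2], o[3] + o[4], o[3] + o[4])
    colTot <- c(o[1] + o[3], o[2] + o[4], o[1] + o[3], o[2] + o[4])
    e <- if (n > 0) rowTot * colTot / n else rep(0, 4)
    defined <- e > 0
    S <- ifelse(defined, (e - o) / sqrt(e), 0)
    p <- ifelse(defined, 0.5 * (o / rowTot + o / colTot), 1)
    data.frame(quadrant = c("00", "01", "10", "11"),
               observed = o, expected = e, S = S, p = p,
               defined = defined, stringsAsFactors = FALSE)
}

#' Classify a probe pair into one of six Boolean relationship classes
#'
#' A quadrant is called sparse when it is defined, its statistic exceeds
#' \code{sthr} and its error rate is below \code{pthr}. One sparse quadrant
#' gives an asymmetric implication: sparse (0,1) means "A low => B low",
#' sparse (1,0) "A high => B high", sparse (0,0) "A low => B high", sparse
#' (1,1) "A high => B low". Both off-diagonal quadrants sparse give
#' EQUIVALENT, both diagonal quadrants OPPOSITE. Any other sparse
#' combination is a degenerate marginal and yields NONE, as does a pair
#' supported by fewer than \code{minPairs} committed samples.
#'
#' @param stats Output of \code{\link{implicationStats}} for \code{counts}.
#' @param counts The quadrant counts the statistics were computed from.
#' @param sthr Sparseness-statistic threshold (default 40, the stringent
#'   compendium-scale operating point).
#' @param pthr Error-rate threshold (default 0.2).
#' @param minPairs Minimum committed sample count n (default 20).
#'
#' @return A single class from \code{\link{relationshipClasses}}.
#'
#' @examples
#' cnt <- quadrantCounts(50, 0, 0, 50)
#' classifyPair(implicationStats(cnt), cnt, sthr = 4, pthr = 0.1)
#' @export
classifyPair <- function(stats, counts, sthr = 40, pthr = 0.2,
                         minPairs = 20L) {
    if (counts[["n"]] < minPairs) return("NONE")
    sparse <- stats$defined & stats$S > sthr & stats$p < pthr
    names(sparse) <- stats$quadrant
    k <- sum(sparse)
    if (k == 1L) {
        return(switch(names(sparse)[sparse],
                      "01" = "LOW_LOW", "10" = "HIGH_HIGH",
                      "00" = "LOW_HIGH", "11" = "HIGH_LOW"))
    }
    if (k == 2L) {
        if (sparse[["01"]] && sparse[["10"]]) return("EQUIVALENT")
        if (sparse[["00"]] && sparse[["11"]]) return("OPPOSITE")
    }
    "NONE"
}

#' Query the Boolean relationship of one probe pair
#'
#' Convenience wrapper: pulls both probes' states from a
#' \linkS4class{BinarizedExperiment}, tallies quadrants, computes the
#' implication statistics and classifies the ordered pair (A, B).
#'
#' @param be A \linkS4class{BinarizedExperiment}.
#' @param probeA,probeB Probe ids present in \code{be}.
#' @inheritParams classifyPair
#'
#' @return A list with \code{counts}, \code{stats}, \code{class}, and the
#'   thresholds used.
#'
#' @examples
#' sim <- simulateCompendium(simulationConfig(
#'     nSamplesHuman = 300, nSamplesMouse = 100, pairsPerClass = 1,
#'     nBackground = 2, nFlat = 0, rngSeed = 7))
#' be <- binarizeMatrix(sim$human)
#' booleanRelation(be, "SEEDG_1_at", "GENE1_at", sthr = 5, pthr = 0.1)$class
#' @export
booleanRelation <- function(be, probeA, probeB, sthr = 40, pthr = 0.2,
                            minPairs = 20L) {
    st <- stateMatrix(be)
    for (p in c(probeA, probeB))
        if (!p %in% rownames(st))
            stop("probe not found in matrix: ", p)
    cnt <- countQuadrants(st[probeA, ], st[probeB, ])
    stats <- implicationStats(cnt)
    list(counts = cnt, stats = stats,
         class = classifyPair(stats, cnt, sthr, pthr, minPairs),
         sthr = sthr, pthr = pthr, minPairs = minPairs)
}

# internal: directionality of a class ("positive", "negative" or "none")
.classDirection <- function(class) {
    pos <- c("LOW_LOW", "HIGH_HIGH", "EQUIVALENT")
    neg <- c("LOW_HIGH", "HIGH_LOW", "OPPOSITE")
    ifelse(class %in% pos, "positive",
           ifelse(class %in% neg, "negative", "none"))
}

# internal: vectorized seed-vs-all quadrant counts and classification.
# Returns a data.frame (one row per candidate probe) with counts, best
# sparse-quadrant statistics and class. Uses matrix products over state
# indicator matrices so a compendium-scale seed scan stays O(probes*samples).
.seedScan <- function(stateMat, seedStates, sthr, pthr, minPairs) {
    codes <- stateCodes()
    sL <- as.numeric(seedStates == codes[["LOW"]] & !is.na(seedStates))
    sH <- as.numeric(seedStates == codes[["HIGH"]] & !is.na(seedStates))
    bL <- stateMat == codes[["LOW"]]
    bH <- stateMat == codes[["HIGH"]]
    bL[is.na(bL)] <- FALSE
    bH[is.na(bH)] <- FALSE
    n00 <- as.vector(bL %*% sL)   # seed LOW (first index), candidate LOW
    n01 <- as.vector(bH %*% sL)   # seed LOW, candidate HIGH
    n10 <- as.vector(bL %*% sH)
    n11 <- as.vector(bH %*% sH)
    n <- n00 + n01 + n10 + n11

    res <- data.frame(probeId = rownames(stateMat), n00 = n00, n01 = n01,
                      n10 = n10, n11 = n11, n = n,
                      class = "NONE", bestS = NA_real_, bestP = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(res))) {
        cnt <- quadrantCounts(n00[i], n01[i], n10[i], n11[i])
        stats <- implicationStats(cnt)
        cls <- classifyPair(stats, cnt, sthr, pthr, minPairs)
        res$class[i] <- cls
        if (cls != "NONE") {
            sparse <- which(stats$defined & stats$S > sthr & stats$p < pthr)
            best <- sparse[order(-stats$S[sparse], stats$p[sparse])][1L]
            res$bestS[i] <- stats$S[best]
            res$bestP[i] <- stats$p[best]
        }
    }
    res
}
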