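# Independent oracles used across the suite. Each re-derives a quantity by
# the most direct route available (exhaustive enumeration, per-sample loops,
# direct arithmetic) so that the package implementation is checked against
# code that shares none of its structure.

# exhaustive one-step fit: try every split of the sorted values
bruteStepFit <- function(values) {
    v <- sort(values[!is.na(values)])
    n <- length(v)
    best <- NULL
    for (k in 1:(n - 1)) {
        lo <- v[1:k]
        hi <- v[(k + 1):n]
        sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
        if (is.null(best) || sse < best$sse - 1e-12)
            best <- list(k = k, sse = sse, lowMean = mean(lo),
                         highMean = mean(hi),
                         t = (mean(lo) + mean(hi)) / 2)
    }
    best
}

# per-sample loop tally of the committed-state quadrants
bruteQuadrants <- function(a, b) {
    n00 <- n01 <- n10 <- n11 <- 0L
    for (i in seq_along(a)) {
        if (is.na(a[i]) || is.na(b[i])) next
        if (!a[i] %in% c(0L, 2L) || !b[i] %in% c(0L, 2L)) next
        if (a[i] == 0L && b[i] == 0L) n00 <- n00 + 1L
        else if (a[i] == 0L && b[i] == 2L) n01 <- n01 + 1L
        else if (a[i] == 2L && b[i] == 0L) n10 <- n10 + 1L
        else n11 <- n11 + 1L
    }
    c(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
      n = n00 + n01 + n10 + n11)
}

# direct arithmetic for the four quadrant statistics
bruteStats <- function(n00, n01, n10, n11) {
    n <- n00 + n01 + n10 + n11
    obs <- c(n00, n01, n10, n11)
    rowTot <- c(n00 + n01, n00 + n01, n10 + n11, n10 + n11)
    colTot <- c(n00 + n10, n01 + n11, n00 + n10, n01 + n11)
    e <- S <- p <- numeric(4)
    for (q in 1:4) {
        e[q] <- if (n > 0) rowTot[q] * colTot[q] / n else 0
        if (e[q] > 0) {
            S[q] <- (e[q] - obs[q]) / sqrt(e[q])
            p[q] <- 0.5 * (obs[q] / rowTot[q] + obs[q] / colTot[q])
        } else {
            S[q] <- 0
            p[q] <- 1
        }
    }
    list(e = e, S = S, p = p)
}

# position-by-position motif scan with hand-coded IUPAC sets
bruteMotifScan <- function(seq, motif = "RCGTG", bothStrands = TRUE) {
    iupac <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    revcomp <- function(m) paste(rev(comp[strsplit(m, "")[[1]]]),
                                 collapse = "")
    chars <- strsplit(toupper(seq), "")[[1]]
    matchesAt <- function(i, pat) {
        ps <- strsplit(pat, "")[[1]]
        for (j in seq_along(ps)) {
            sc <- chars[i + j - 1]
            if (sc == "N") {
                if (ps[j] != "N") return(FALSE)
            } else if (!sc %in% iupac[[ps[j]]]) return(FALSE)
        }
        TRUE
    }
    m <- nchar(motif)
    hits <- data.frame(start = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)
    if (length(chars) < m) return(hits)
    for (i in 1:(length(chars) - m + 1)) {
        if (matchesAt(i, motif))
            hits <- rbind(hits, data.frame(start = i, strand = "+"))
        if (bothStrands && matchesAt(i, revcomp(motif)))
            hits <- rbind(hits, data.frame(start = i, strand = "-"))
    }
    hits[order(hits$start, hits$strand), , drop = FALSE]
}

# random committed-state vectors (0 = LOW, 2 = HIGH, 1 = INTERMEDIATE)
randomStates <- function(n, pInt = 0.1, pNA = 0.05) {
    s <- sample(c(0L, 2L), n, replace = TRUE)
    s[stats::runif(n) < pInt] <- 1L
    s[stats::runif(n) < pNA] <- NA_integer_
    s
}

# compact small-compendium config for fast tests; thresholds at this scale
# are sthr ~ 10, pthr 0.1 (the small-n operating point)
smallSimConfig <- function(rngSeed = 101L, ...) {
    simulationConfig(nSamplesHuman = 2000L, nSamplesMouse = 1500L,
                     pairsPerClass = 2L, eps = 0.004,
                     conservedPerClass = 1L, nBackground = 20L,
                     nFlat = 2L, rngSeed = rngSeed, ...)
}

# hand-built candidate table for rank/intersection tests
makeCandidateTable <- function(probeIds, genes, S, p,
                               class = rep("LOW_LOW", length(probeIds)),
                               seed = "SEED_at") {
    rec <- S4Vectors::DataFrame(
        probeId = probeIds, genes = genes, class = class, bestS = S,
        bestP = p, nPairs = rep(100L, length(probeIds)),
        concordant = rep(NA, length(probeIds)),
        conserved = rep(NA, length(probeIds)),
        conservedBy = rep(NA_character_, length(probeIds)),
        novel = rep(NA, length(probeIds)),
        rank = rep(NA_integer_, length(probeIds)))
    BooleanImplications:::.newCandidateTable(seed, 40, 0.2, 20, rec)
}
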