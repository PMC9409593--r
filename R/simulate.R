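#' Configuration for the synthetic compendium generator
#'
#' Describes a two-species (human/mouse) log2 expression compendium with a
#' seed gene carrying several probesets, partner genes planted to hold a
#' chosen Boolean relationship with the seed, independent background probes
#' and flat (no-dynamic-range) probes. Expression values are drawn from a
#' two-component Gaussian (means \code{muLow}/\code{muHigh}, sd
#' \code{sigma}); the gap of 4 log2 units at sd 0.5 keeps the intermediate
#' zone nearly empty so the quadrant statistics, not the discretization, are
#' what a recovery test exercises.
#'
#' For a planted pair the sparse quadrant gets probability mass \code{eps};
#' for the four asymmetric classes the contrapositive corner gets
#' \code{crossFrac} (both marginals cannot sit at 0.5 for an asymmetric
#' pair, since that forces both off-diagonal quadrants sparse, i.e. an
#' equivalence). At the defaults (n = 10,000 samples, eps = 0.002,
#' crossFrac = 0.10) a planted sparse quadrant scores S of roughly 44-50
#' while the contrapositive corner stays near 36, so the stringent
#' compendium-scale operating point S > 40, p < 0.2 cleanly separates the
#' two.
#'
#' @param nSamplesHuman,nSamplesMouse Sample counts (defaults 10000, 5000).
#' @param muLow,muHigh Component means in log2 units (defaults 6, 10).
#' @param sigma Component sd in log2 units (default 0.5).
#' @param pSeedHigh Marginal probability the seed is HIGH (default 0.5).
#' @param crossFrac Contrapositive-corner mass for asymmetric classes
#'   (default 0.10).
#' @param pairsPerClass Planted pairs per relationship class (default 10).
#' @param eps Sparse-quadrant probability for planted pairs (default 0.002).
#' @param conservedPerClass How many of each class's pairs are also planted
#'   in the mouse compendium (default 8; the rest are independent in mouse).
#' @param nBackground Independent bimodal background probes (default 200).
#' @param nFlat Flat probes with no dynamic range (default 5).
#' @param nSeedProbes Probesets of the seed gene (default 4, the first is
#'   the primary).
#' @param altSeedBehavior Behavior of each alternate seed probeset:
#'   \code{"same"} (faithful copy of the seed state), \code{"inverted"} or
#'   \code{"independent"}; length \code{nSeedProbes - 1}.
#' @param mouseClassMode \code{"analog"} plants the directionality-preserving
#'   LOW/HIGH-swapped class in mouse (the cross-species pattern where a
#'   human "low => low" partner shows "high => high" in mouse);
#'   \code{"same"} plants the identical class.
#' @param rngSeed Integer seed; all randomness flows from it.
#' @param pairs Optional data.frame(gene, class, eps, conserved) overriding
#'   the default planted-pair layout.
#'
#' @return A \code{SimulationConfig} object.
#' @seealso \code{\link{simulateCompendium}}
#' @export
simulationConfig <- function(nSamplesHuman = 10000L, nSamplesMouse = 5000L,
                             muLow = 6, muHigh = 10, sigma = 0.5,
                             pSeedHigh = 0.5, crossFrac = 0.10,
                             pairsPerClass = 10L, eps = 0.002,
                             conservedPerClass = 8L,
                             nBackground = 200L, nFlat = 5L,
                             nSeedProbes = 4L,
                             altSeedBehavior = rep("same",
                                                   max(nSeedProbes - 1L, 0L)),
                             mouseClassMode = c("analog", "same"),
                             rngSeed = 1L, pairs = NULL) {
    mouseClassMode <- match.arg(mouseClassMode)
    if (is.null(pairs)) {
        cls <- setdiff(relationshipClasses(), "NONE")
        pairs <- do.call(rbind, lapply(seq_along(cls), function(ci) {
            k <- pairsPerClass
            data.frame(
                gene = sprintf("GENE%d", (ci - 1L) * k + seq_len(k)),
                class = cls[ci], eps = eps,
                conserved = seq_len(k) <= conservedPerClass,
                stringsAsFactors = FALSE)
        }))
    }
    cfg <- new("SimulationConfig",
               nSamplesHuman = as.integer(nSamplesHuman),
               nSamplesMouse = as.integer(nSamplesMouse),
               muLow = muLow, muHigh = muHigh, sigma = sigma,
               pSeedHigh = pSeedHigh, crossFrac = crossFrac,
               nBackground = as.integer(nBackground),
               nFlat = as.integer(nFlat),
               nSeedProbes = as.integer(nSeedProbes),
               altSeedBehavior = altSeedBehavior,
               mouseClassMode = mouseClassMode,
               rngSeed = as.integer(rngSeed), pairs = pairs)
    validObject(cfg)
    cfg
}

#' @rdname simulationConfig
#' @export
setClass("SimulationConfig",
    representation(nSamplesHuman = "integer", nSamplesMouse = "integer",
                   muLow = "numeric", muHigh = "numeric", sigma = "numeric",
                   pSeedHigh = "numeric", crossFrac = "numeric",
                   nBackground = "integer", nFlat = "integer",
                   nSeedProbes = "integer", altSeedBehavior = "character",
                   mouseClassMode = "character", rngSeed = "integer",
                   pairs = "data.frame"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@muHigh - object@muLow <= 4 * object@sigma)
        msg <- c(msg, "separability requires muHigh - muLow > 4*sigma")
    if (object@pSeedHigh <= 0 || object@pSeedHigh >= 1)
        msg <- c(msg, "pSeedHigh must be in (0, 1)")
    p <- object@pairs
    need <- c("gene", "class", "eps", "conserved")
    if (!all(need %in% names(p)))
        msg <- c(msg, "pairs must have columns gene, class, eps, conserved")
    else {
        if (anyDuplicated(p$gene))
            msg <- c(msg, "planted partner genes must be unique")
        if (!all(p$class %in% setdiff(relationshipClasses(), "NONE")))
            msg <- c(msg, "planted classes must be one of the six classes")
        if (any(p$eps < 0 | p$eps >= 0.25))
            msg <- c(msg, "eps must lie in [0, 0.25)")
        asym <- p$class %in% c("LOW_LOW", "LOW_HIGH", "HIGH_LOW",
                               "HIGH_HIGH")
        if (any(asym & p$eps >= object@crossFrac))
            msg <- c(msg,
                "eps must be below crossFrac (the smallest non-sparse quadrant)")
    }
    if (length(object@altSeedBehavior) != max(object@nSeedProbes - 1L, 0L))
        msg <- c(msg, "altSeedBehavior must have length nSeedProbes - 1")
    if (!all(object@altSeedBehavior %in%
             c("same", "inverted", "independent")))
        msg <- c(msg, "altSeedBehavior entries must be same/inverted/independent")
    if (object@nSeedProbes < 1L)
        msg <- c(msg, "need at least one seed probeset")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d human / %d mouse samples, %d planted pairs,\n",
        object@nSamplesHuman, object@nSamplesMouse, nrow(object@pairs)))
    cat(sprintf(
        "  %d background + %d flat probes, seed with %d probesets, seed %d\n",
        object@nBackground, object@nFlat, object@nSeedProbes,
        object@rngSeed))
})

# internal: P(partner HIGH | seed LOW) and P(partner HIGH | seed HIGH) that
# place mass eps on the class's sparse quadrant(s) and crossFrac on the
# contrapositive corner of an asymmetric class
.pairConditionals <- function(class, eps, crossFrac, pSeedHigh) {
    pL <- 1 - pSeedHigh
    pH <- pSeedHigh
    ab <- switch(class,
        LOW_LOW   = c(a = eps / pL,      b = 1 - crossFrac / pH),
        HIGH_HIGH = c(a = crossFrac / pL, b = 1 - eps / pH),
        LOW_HIGH  = c(a = 1 - eps / pL,  b = crossFrac / pH),
        HIGH_LOW  = c(a = 1 - crossFrac / pL, b = eps / pH),
        EQUIVALENT = c(a = eps / pL,     b = 1 - eps / pH),
        OPPOSITE  = c(a = 1 - eps / pL,  b = eps / pH),
        stop("unknown class: ", class))
    if (any(ab < 0 | ab > 1))
        stop("inconsistent eps/crossFrac for class ", class,
             ": conditional probabilities leave [0, 1]")
    ab
}

# internal: directionality-preserving LOW/HIGH-swapped analog of a class
.directionalAnalog <- function(class) {
    switch(class,
           LOW_LOW = "HIGH_HIGH", HIGH_HIGH = "LOW_LOW",
           LOW_HIGH = "HIGH_LOW", HIGH_LOW = "LOW_HIGH",
           class)
}

# internal: draw log2 values for a binary state vector
.stateValues <- function(state, muLow, muHigh, sigma) {
    stats::rnorm(length(state),
                 mean = ifelse(state == 1L, muHigh, muLow), sd = sigma)
}

# internal: mouse-case a human symbol: "GENE7" -> "Gene7"
.mouseSymbol <- function(human) {
    paste0(substr(human, 1L, 1L),
           tolower(substr(human, 2L, nchar(human))))
}

#' Simulate a two-species compendium with planted Boolean relationships
#'
#' Generates matched human and mouse log2 expression matrices in which a
#' seed gene (several probesets) and planted partner genes follow configured
#' joint low/high distributions, alongside independent background probes and
#' flat probes; emits the probe annotations, the human/mouse ortholog map
#' (mouse symbols in mixed case to exercise case-insensitive matching) and a
#' planted-truth table for recovery testing.
#'
#' @param cfg A \code{\link{simulationConfig}}.
#'
#' @return A list with elements \code{human} and \code{mouse}
#'   (SummarizedExperiments with assay \code{"exprs"} and a \code{gene}
#'   rowData column), \code{orthologs}, \code{annotationHuman},
#'   \code{annotationMouse} (data.frames), \code{truth} (one row per
#'   simulated probe in either species) and \code{config}.
#'
#' @examples
#' sim <- simulateCompendium(simulationConfig(
#'     nSamplesHuman = 200, nSamplesMouse = 100, pairsPerClass = 1,
#'     nBackground = 5, nFlat = 1, rngSeed = 42))
#' dim(sim$human)
#' head(sim$truth)
#' @export
simulateCompendium <- function(cfg) {
    stopifnot(is(cfg, "SimulationConfig"))
    validObject(cfg)
    for (i in seq_len(nrow(cfg@pairs)))       # fail before any sampling
        .pairConditionals(cfg@pairs$class[i], cfg@pairs$eps[i],
                          cfg@crossFrac, cfg@pSeedHigh)
    set.seed(cfg@rngSeed)
    nH <- cfg@nSamplesHuman
    nM <- cfg@nSamplesMouse
    pairs <- cfg@pairs

    ## ---- human ----
    z <- stats::rbinom(nH, 1L, cfg@pSeedHigh)
    probes <- list(); states <- list(); genes <- character(0)
    roles <- character(0)
    addProbe <- function(id, gene, role, state) {
        probes[[length(probes) + 1L]] <<- id
        states[[length(states) + 1L]] <<- state
        genes[length(genes) + 1L] <<- gene
        roles[length(roles) + 1L] <<- role
    }
    addProbe("SEEDG_1_at", "SEEDG", "seed_primary", z)
    if (cfg@nSeedProbes > 1L) {
        for (j in seq_len(cfg@nSeedProbes - 1L)) {
            beh <- cfg@altSeedBehavior[j]
            s <- switch(beh,
                        same = z,
                        inverted = 1L - z,
                        independent = stats::rbinom(nH, 1L, cfg@pSeedHigh))
            addProbe(sprintf("SEEDG_%d_at", j + 1L), "SEEDG",
                     paste0("seed_alternate_", beh), s)
        }
    }
    for (i in seq_len(nrow(pairs))) {
        ab <- .pairConditionals(pairs$class[i], pairs$eps[i],
                                cfg@crossFrac, cfg@pSeedHigh)
        w <- stats::rbinom(nH, 1L, ifelse(z == 1L, ab[["b"]], ab[["a"]]))
        addProbe(paste0(pairs$gene[i], "_at"), pairs$gene[i], "partner", w)
    }
    for (i in seq_len(cfg@nBackground))
        addProbe(sprintf("BG%d_at", i), sprintf("BG%d", i), "background",
                 stats::rbinom(nH, 1L, 0.5))
    valueRows <- lapply(states, .stateValues, cfg@muLow, cfg@muHigh,
                        cfg@sigma)
    for (i in seq_len(cfg@nFlat)) {
        probes[[length(probes) + 1L]] <- sprintf("FLAT%d_at", i)
        valueRows[[length(valueRows) + 1L]] <-
            cfg@muLow + stats::rnorm(nH, 0, 0.1)
        genes[length(genes) + 1L] <- sprintf("FLAT%d", i)
        roles[length(roles) + 1L] <- "flat"
    }
    humanMat <- do.call(rbind, valueRows)
    rownames(humanMat) <- unlist(probes)
    colnames(humanMat) <- sprintf("GSM%05d", seq_len(nH))
    humanSe <- SummarizedExperiment(
        assays = list(exprs = humanMat),
        rowData = DataFrame(gene = genes, role = roles))
    annotationHuman <- data.frame(probeId = unlist(probes), gene = genes,
                                  stringsAsFactors = FALSE)
    humanTruth <- data.frame(
        species = "human", probeId = unlist(probes), gene = genes,
        role = roles,
        class = NA_character_, eps = NA_real_, conserved = NA,
        stringsAsFactors = FALSE)
    idx <- match(paste0(pairs$gene, "_at"), humanTruth$probeId)
    humanTruth$class[idx] <- pairs$class
    humanTruth$eps[idx] <- pairs$eps
    humanTruth$conserved[idx] <- pairs$conserved

    ## ---- mouse ----
    zm <- stats::rbinom(nM, 1L, cfg@pSeedHigh)
    mProbes <- "m_Seedg_at"; mGenes <- "Seedg"; mRoles <- "seed_primary"
    mStates <- list(zm)
    mouseClass <- rep(NA_character_, nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        mg <- .mouseSymbol(pairs$gene[i])
        if (pairs$conserved[i]) {
            cls <- if (cfg@mouseClassMode == "analog")
                .directionalAnalog(pairs$class[i]) else pairs$class[i]
            ab <- .pairConditionals(cls, pairs$eps[i], cfg@crossFrac,
                                    cfg@pSeedHigh)
            w <- stats::rbinom(nM, 1L,
                               ifelse(zm == 1L, ab[["b"]], ab[["a"]]))
            mouseClass[i] <- cls
        } else {
            w <- stats::rbinom(nM, 1L, 0.5)
        }
        mProbes <- c(mProbes, paste0("m_", mg, "_at"))
        mGenes <- c(mGenes, mg)
        mRoles <- c(mRoles,
                    if (pairs$conserved[i]) "partner" else
                        "partner_nonconserved")
        mStates[[length(mStates) + 1L]] <- w
    }
    nMouseBg <- min(20L, cfg@nBackground)
    for (i in seq_len(nMouseBg)) {
        mProbes <- c(mProbes, sprintf("m_Bg%d_at", i))
        mGenes <- c(mGenes, sprintf("Bg%d", i))
        mRoles <- c(mRoles, "background")
        mStates[[length(mStates) + 1L]] <- stats::rbinom(nM, 1L, 0.5)
    }
    mouseMat <- do.call(rbind, lapply(mStates, .stateValues, cfg@muLow,
                                      cfg@muHigh, cfg@sigma))
    rownames(mouseMat) <- mProbes
    colnames(mouseMat) <- sprintf("GSM%05d", seq_len(nM))
    mouseSe <- SummarizedExperiment(
        assays = list(exprs = mouseMat),
        rowData = DataFrame(gene = mGenes, role = mRoles))
    annotationMouse <- data.frame(probeId = mProbes, gene = mGenes,
                                  stringsAsFactors = FALSE)
    mouseTruth <- data.frame(
        species = "mouse", probeId = mProbes, gene = mGenes, role = mRoles,
        class = NA_character_, eps = NA_real_, conserved = NA,
        stringsAsFactors = FALSE)
    mIdx <- match(paste0("m_", .mouseSymbol(pairs$gene), "_at"),
                  mouseTruth$probeId)
    mouseTruth$class[mIdx] <- mouseClass
    mouseTruth$eps[mIdx] <- ifelse(pairs$conserved, pairs$eps, NA_real_)
    mouseTruth$conserved[mIdx] <- pairs$conserved

    truth <- rbind(humanTruth, mouseTruth)
    # expected concordance flags, derived from alternate-probeset behavior
    shares <- cfg@altSeedBehavior == "same"
    truth$concordantAll <- NA
    truth$concordantMajority <- NA
    hp <- truth$species == "human" & truth$role == "partner"
    if (length(shares)) {
        truth$concordantAll[hp] <- all(shares)
        truth$concordantMajority[hp] <- mean(shares) > 0.5
    }

    orthologs <- data.frame(
        human = c("SEEDG", pairs$gene),
        mouse = c("Seedg", .mouseSymbol(pairs$gene)),
        stringsAsFactors = FALSE)

    list(human = humanSe, mouse = mouseSe, orthologs = orthologs,
         annotationHuman = annotationHuman,
         annotationMouse = annotationMouse,
         truth = truth, config = cfg)
}

# internal: overlap-aware regex scan used only by the promoter generator, a
# route independent of scanMotif
.regexScan <- function(seqChar, motif) {
    codes <- Biostrings::IUPAC_CODE_MAP
    toClass <- function(m) paste0(vapply(strsplit(m, "")[[1L]],
        function(ch) paste0("[", codes[[ch]], "]"), character(1)),
        collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    fwd <- gregexpr(paste0("(?=", toClass(motif), ")"), seqChar,
                    perl = TRUE)[[1L]]
    rev <- gregexpr(paste0("(?=", toClass(rc), ")"), seqChar,
                    perl = TRUE)[[1L]]
    fwd <- fwd[fwd > 0]; rev <- rev[rev > 0]
    data.frame(start = c(fwd, rev),
               strand = rep(c("+", "-"), c(length(fwd), length(rev))),
               stringsAsFactors = FALSE)
}

#' Simulate promoter sequences with planted HRE-like motif sites
#'
#' Draws uniform-random A/C/G/T backgrounds, disrupts every accidental
#' occurrence of the motif (default the hypoxia-response element consensus
#' RCGTG) on either strand, then inserts the requested number of
#' non-overlapping sites per sequence, each on a randomly chosen strand,
#' recording their exact positions as ground truth.
#'
#' @param nSeqs Number of sequences.
#' @param length Sequence length in bases; must accommodate the planted
#'   sites with spacing (at least 7 bases per site plus one).
#' @param plantedSiteCounts Integer vector (recycled to \code{nSeqs}) of
#'   sites to plant per sequence.
#' @param rngSeed Integer seed.
#' @param motif IUPAC motif to plant (default \code{"RCGTG"}).
#'
#' @return A list with \code{seqs} (a named
#'   \link[Biostrings]{DNAStringSet}, names \code{"promoter1"}, ...) and
#'   \code{truth} (data.frame: \code{seqId}, \code{start}, \code{end},
#'   \code{strand}, \code{site}).
#'
#' @examples
#' sim <- simulatePromoters(2, 300, c(3, 0), rngSeed = 11)
#' sim$truth
#' @export
simulatePromoters <- function(nSeqs, length, plantedSiteCounts,
                              rngSeed, motif = "RCGTG") {
    counts <- rep_len(as.integer(plantedSiteCounts), nSeqs)
    mlen <- nchar(motif)
    if (any(counts * (mlen + 2L) + 1L > length))
        stop("infeasible packing: ", max(counts), " sites of length ", mlen,
             " with flanks do not fit in ", length, " bases")
    set.seed(rngSeed)
    bases <- c("A", "C", "G", "T")
    seqOut <- character(nSeqs)
    truth <- list()
    for (s in seq_len(nSeqs)) {
        success <- FALSE
        for (attempt in 1:25) {
            ch <- sample(bases, length, replace = TRUE)
            # scrub accidental sites on either strand
            ok <- FALSE
            for (iter in 1:50) {
                hits <- .regexScan(paste(ch, collapse = ""), motif)
                if (!nrow(hits)) { ok <- TRUE; break }
                for (h in hits$start)
                    ch[h:(h + mlen - 1L)] <- "T"
            }
            if (!ok) next
            k <- counts[s]
            placed <- NULL
            if (k > 0L) {
                cand <- sample(2:(length - mlen))
                pos <- integer(0)
                for (p in cand) {
                    if (all(abs(p - pos) >= mlen + 2L)) pos <- c(pos, p)
                    if (length(pos) == k) break
                }
                if (length(pos) < k) next
                pos <- sort(pos)
                strand <- sample(c("+", "-"), k, replace = TRUE)
                site <- character(k)
                for (j in seq_len(k)) {
                    site[j] <- if (strand[j] == "+")
                        paste0(sample(c("A", "G"), 1L), "CGTG")
                    else paste0("CACG", sample(c("T", "C"), 1L))
                    ch[(pos[j] - 1L)] <- "T"          # flank guards
                    ch[(pos[j] + mlen)] <- "T"
                    ch[pos[j]:(pos[j] + mlen - 1L)] <-
                        strsplit(site[j], "")[[1L]]
                }
                placed <- data.frame(
                    seqId = sprintf("promoter%d", s), start = pos,
                    end = pos + mlen - 1L, strand = strand, site = site,
                    stringsAsFactors = FALSE)
            }
            # verify planted truth is exactly what a scan finds
            found <- .regexScan(paste(ch, collapse = ""), motif)
            wantStart <- if (is.null(placed)) integer(0) else placed$start
            wantStrand <- if (is.null(placed)) character(0)
                          else placed$strand
            if (nrow(found) == length(wantStart) &&
                all(sort(found$start) == sort(wantStart)) &&
                identical(found$strand[order(found$start)],
                          wantStrand[order(wantStart)])) {
                seqOut[s] <- paste(ch, collapse = "")
                if (!is.null(placed)) truth[[length(truth) + 1L]] <- placed
                success <- TRUE
                break
            }
        }
        if (!success)
            stop("infeasible packing: could not realize ", counts[s],
                 " clean sites in sequence ", s)
    }
    seqs <- Biostrings::DNAStringSet(seqOut)
    names(seqs) <- sprintf("promoter%d", seq_len(nSeqs))
    truthDf <- if (length(truth)) do.call(rbind, truth) else
        data.frame(seqId = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   site = character(0), stringsAsFactors = FALSE)
    list(seqs = seqs, truth = truthDf)
}
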