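#' Discover Boolean-implication partners of a seed probe
#'
#' Pairs the seed probe against every other eligible probe of a binarized
#' compendium, computes the sparse-quadrant statistics for each ordered pair
#' (seed, candidate), and keeps probes whose relationship class is not NONE.
#' The returned table carries the statistics of the best qualifying sparse
#' quadrant (\code{bestS}, \code{bestP}; for symmetric classes the quadrant
#' with the larger S), the committed-sample count and unset filter flags.
#'
#' @param be A \linkS4class{BinarizedExperiment}.
#' @param seed Probe id of the seed; must be eligible.
#' @param annotation Optional data.frame (\code{probeId}, \code{gene}); used
#'   to attach gene symbols and to exclude the seed gene's other probesets
#'   from the candidate list.
#' @param sthr,pthr,minPairs Implication thresholds (defaults 40, 0.2, 20 --
#'   the stringent compendium-scale operating point).
#'
#' @return A \linkS4class{CandidateTable}.
#'
#' @examples
#' sim <- simulateCompendium(simulationConfig(
#'     nSamplesHuman = 500, nSamplesMouse = 100, pairsPerClass = 2,
#'     nBackground = 10, nFlat = 1, rngSeed = 3))
#' be <- binarizeMatrix(sim$human)
#' tbl <- discoverCandidates(be, "SEEDG_1_at", sim$annotationHuman,
#'                           sthr = 8, pthr = 0.1)
#' classTally(tbl)
#' @export
discoverCandidates <- function(be, seed, annotation = NULL,
                               sthr = 40, pthr = 0.2, minPairs = 20L) {
    st <- stateMatrix(be)
    if (!seed %in% rownames(st))
        stop("seed probe not found: ", seed)
    el <- eligibleProbes(be)
    if (!el[[seed]])
        stop("seed probe is not eligible: ", seed)

    geneOf <- function(probes) {
        if (is.null(annotation)) return(rep(NA_character_, length(probes)))
        vapply(probes, function(p) {
            g <- annotation$gene[annotation$probeId == p]
            if (length(g)) paste(g, collapse = ",") else NA_character_
        }, character(1))
    }
    seedGenes <- if (is.null(annotation)) character(0) else
        annotation$gene[annotation$probeId == seed]
    cand <- setdiff(names(el)[el], seed)
    if (length(seedGenes)) {
        candGenes <- annotation$gene[match(cand, annotation$probeId)]
        cand <- cand[is.na(candGenes) |
                     !toupper(candGenes) %in% toupper(seedGenes)]
    }
    if (!length(cand)) {
        return(.newCandidateTable(seed, sthr, pthr, as.numeric(minPairs),
                                  .emptyRecords()))
    }
    scan <- .seedScan(st[cand, , drop = FALSE], st[seed, ],
                      sthr, pthr, minPairs)
    hit <- scan[scan$class != "NONE", , drop = FALSE]
    rec <- DataFrame(
        probeId = hit$probeId,
        genes = geneOf(hit$probeId),
        class = hit$class,
        bestS = hit$bestS,
        bestP = hit$bestP,
        nPairs = as.integer(hit$n),
        concordant = rep(NA, nrow(hit)),
        conserved = rep(NA, nrow(hit)),
        conservedBy = rep(NA_character_, nrow(hit)),
        novel = rep(NA, nrow(hit)),
        rank = rep(NA_integer_, nrow(hit)))
    tbl <- .newCandidateTable(seed, sthr, pthr, as.numeric(minPairs), rec)
    validObject(tbl)
    tbl
}

#' Rank candidates by implication strength
#'
#' Orders records by descending best sparse-quadrant statistic S, breaking
#' ties by ascending error rate p and then lexicographic probe id, and
#' assigns ranks 1..k. This is the "strong relationship" layer of the
#' multilayer filter cascade.
#'
#' @param tbl A \linkS4class{CandidateTable}.
#' @return The table with records reordered and \code{rank} filled in.
#' @export
rankCandidates <- function(tbl) {
    rec <- tbl@records
    if (nrow(rec)) {
        o <- order(-rec$bestS, rec$bestP, rec$probeId)
        rec <- rec[o, , drop = FALSE]
        rec$rank <- seq_len(nrow(rec))
    }
    tbl@records <- rec
    validObject(tbl)
    tbl
}

#' Concordance across alternate probesets of the seed gene
#'
#' Re-classifies every candidate against each eligible alternate probeset of
#' the seed gene and flags it concordant when the required fraction of those
#' classes shares the candidate's directionality (positive = low=>low,
#' high=>high, equivalent; negative = low=>high, high=>low, opposite).
#' Arrays carry several probesets per gene; a partner whose implication
#' holds only against one probeset is suspect.
#'
#' @param tbl A \linkS4class{CandidateTable} from
#'   \code{\link{discoverCandidates}}.
#' @param altSeedProbes Probe ids of the seed gene's other probesets.
#' @param be The \linkS4class{BinarizedExperiment} the table came from.
#' @param mode \code{"all"} (every eligible alternate must agree, default)
#'   or \code{"majority"} (more than half).
#' @param strictClass Require the identical class rather than shared
#'   directionality (default FALSE).
#'
#' @return The table with the \code{concordant} flag filled in. Flags stay
#'   NA (with a warning) when no alternate probe is eligible.
#' @export
concordanceFilter <- function(tbl, altSeedProbes, be,
                              mode = c("all", "majority"),
                              strictClass = FALSE) {
    mode <- match.arg(mode)
    st <- stateMatrix(be)
    el <- eligibleProbes(be)
    missing <- setdiff(altSeedProbes, rownames(st))
    if (length(missing))
        stop("alternate seed probes not in matrix: ",
             paste(missing, collapse = ", "))
    alts <- altSeedProbes[el[altSeedProbes]]
    rec <- tbl@records
    if (!length(alts)) {
        warning("no eligible alternate seed probes; concordance left unset")
        return(tbl)
    }
    if (!nrow(rec)) return(tbl)
    altClasses <- matrix(NA_character_, nrow(rec), length(alts))
    for (j in seq_along(alts)) {
        scan <- .seedScan(st[rec$probeId, , drop = FALSE], st[alts[j], ],
                          tbl@sthr, tbl@pthr, tbl@minPairs)
        altClasses[, j] <- scan$class
    }
    for (i in seq_len(nrow(rec))) {
        agree <- if (strictClass)
            altClasses[i, ] == rec$class[i]
        else
            .classDirection(altClasses[i, ]) ==
                .classDirection(rec$class[i])
        rec$concordant[i] <- if (mode == "all") all(agree)
                             else mean(agree) > 0.5
    }
    tbl@records <- rec
    tbl
}

#' Cross-species conservation of the implication
#'
#' Maps each candidate's gene symbol(s) through the human/mouse ortholog map
#' (case-insensitively), finds the mouse probes of those orthologs, and
#' flags the candidate conserved when at least one eligible mouse probe's
#' relationship with the mouse seed shares the candidate's directionality.
#' Directionality rather than identical class is compared: a human
#' "low => low" partner whose mouse ortholog shows "high => high" counts as
#' conserved. The best-S supporting mouse probe is recorded in
#' \code{conservedBy}; candidates without an ortholog, mouse probe or
#' matching relationship get \code{conserved = FALSE} with the reason in
#' \code{conservedBy}.
#'
#' @param tbl A \linkS4class{CandidateTable}.
#' @param mouseBe Binarized mouse compendium.
#' @param mouseSeed Mouse seed probe id; must be eligible.
#' @param orthologs data.frame (\code{human}, \code{mouse}) of gene-symbol
#'   pairs, many-to-many.
#' @param mouseAnnotation data.frame (\code{probeId}, \code{gene}) for the
#'   mouse compendium.
#' @param strictClass Require the identical class instead of shared
#'   directionality (default FALSE).
#' @param sthr,pthr,minPairs Thresholds for the mouse-side classification;
#'   default to the table's. The sparseness statistic grows as the square
#'   root of the sample count, so a compendium of a different size calls
#'   for a rescaled S threshold (e.g. \code{sthr * sqrt(nMouse/nHuman)})
#'   to apply the same implication stringency.
#'
#' @return The table with \code{conserved}/\code{conservedBy} filled in.
#' @export
conservationFilter <- function(tbl, mouseBe, mouseSeed, orthologs,
                               mouseAnnotation, strictClass = FALSE,
                               sthr = NULL, pthr = NULL, minPairs = NULL) {
    if (is.null(sthr)) sthr <- tbl@sthr
    if (is.null(pthr)) pthr <- tbl@pthr
    if (is.null(minPairs)) minPairs <- tbl@minPairs
    st <- stateMatrix(mouseBe)
    el <- eligibleProbes(mouseBe)
    if (!mouseSeed %in% rownames(st))
        stop("mouse seed probe not found: ", mouseSeed)
    if (!el[[mouseSeed]])
        stop("mouse seed probe is not eligible: ", mouseSeed)
    rec <- tbl@records
    if (!nrow(rec)) return(tbl)

    mouseProbesOf <- function(humanGenes) {
        hg <- toupper(unlist(strsplit(humanGenes, ",")))
        mg <- orthologs$mouse[toupper(orthologs$human) %in% hg]
        if (!length(mg)) return(NULL)
        mp <- mouseAnnotation$probeId[
            toupper(mouseAnnotation$gene) %in% toupper(mg)]
        list(genes = mg, probes = mp)
    }
    mouseScan <- .seedScan(st, st[mouseSeed, ], sthr, pthr, minPairs)
    rownames(mouseScan) <- mouseScan$probeId
    for (i in seq_len(nrow(rec))) {
        if (is.na(rec$genes[i])) {
            rec$conserved[i] <- FALSE
            rec$conservedBy[i] <- "no_gene_annotation"
            next
        }
        om <- mouseProbesOf(rec$genes[i])
        if (is.null(om)) {
            rec$conserved[i] <- FALSE
            rec$conservedBy[i] <- "no_ortholog"
            next
        }
        probes <- intersect(om$probes, rownames(st))
        probes <- probes[el[probes]]
        probes <- setdiff(probes, mouseSeed)
        if (!length(probes)) {
            rec$conserved[i] <- FALSE
            rec$conservedBy[i] <- "no_eligible_mouse_probe"
            next
        }
        cls <- mouseScan[probes, "class"]
        support <- if (strictClass) cls == rec$class[i]
                   else .classDirection(cls) ==
                        .classDirection(rec$class[i])
        if (any(support)) {
            sup <- probes[support]
            best <- sup[order(-mouseScan[sup, "bestS"])][1L]
            rec$conserved[i] <- TRUE
            rec$conservedBy[i] <- best
        } else {
            rec$conserved[i] <- FALSE
            rec$conservedBy[i] <- "no_matching_relationship"
        }
    }
    tbl@records <- rec
    tbl
}

#' Novelty annotation against a known-gene list
#'
#' Flags a candidate novel when none of its gene symbols appears
#' (case-insensitively) in the supplied list of already-known genes.
#'
#' @param tbl A \linkS4class{CandidateTable}.
#' @param known Character vector of known gene symbols (e.g. genes already
#'   reported as hypoxia-related).
#' @return The table with the \code{novel} flag filled in.
#' @export
noveltyAnnotate <- function(tbl, known) {
    rec <- tbl@records
    knownUp <- toupper(known)
    for (i in seq_len(nrow(rec))) {
        if (is.na(rec$genes[i])) { rec$novel[i] <- NA; next }
        genes <- toupper(unlist(strsplit(rec$genes[i], ",")))
        rec$novel[i] <- !any(genes %in% knownUp)
    }
    tbl@records <- rec
    tbl
}

#' Genes common to the top-k candidates of several seed runs
#'
#' Takes ranked candidate tables from different seed genes (or different
#' compendia) and returns the gene symbols that appear in the top-k records
#' of every table, compared case-insensitively. When k exceeds a table's
#' size that table contributes all its genes, with a warning.
#'
#' @param tables List of ranked \linkS4class{CandidateTable}s.
#' @param k Cutoff rank (e.g. 100).
#' @return Character vector of common gene symbols, in the casing of the
#'   first table, sorted.
#' @export
topKIntersection <- function(tables, k) {
    stopifnot(length(tables) >= 1L)
    topGenes <- lapply(tables, function(t) {
        rec <- t@records
        if (is.null(rec$rank) || (nrow(rec) && all(is.na(rec$rank))))
            stop("tables must be ranked (call rankCandidates first)")
        if (k > nrow(rec))
            warning("k = ", k, " exceeds table size ", nrow(rec),
                    "; using all its genes")
        rec <- rec[!is.na(rec$rank) & rec$rank <= k, , drop = FALSE]
        g <- unlist(strsplit(rec$genes[!is.na(rec$genes)], ","))
        unique(g)
    })
    commonUp <- Reduce(intersect, lapply(topGenes, toupper))
    first <- topGenes[[1L]]
    sort(first[toupper(first) %in% commonUp])
}

#' Apply the full multilayer filter cascade
#'
#' Convenience wrapper chaining \code{\link{rankCandidates}},
#' \code{\link{concordanceFilter}}, \code{\link{conservationFilter}} and
#' \code{\link{noveltyAnnotate}}. Filters only annotate; the surviving
#' shortlist (concordant, conserved, novel, optionally top-\code{top}) can
#' be selected from the flags afterwards with \code{\link{selectSurvivors}}.
#'
#' @inheritParams concordanceFilter
#' @inheritParams conservationFilter
#' @inheritParams noveltyAnnotate
#' @param mouseSthr,mousePthr Mouse-side thresholds passed to
#'   \code{\link{conservationFilter}} (default: the table's).
#' @return The annotated, ranked \linkS4class{CandidateTable}.
#' @export
filterCascade <- function(tbl, altSeedProbes, be, mouseBe, mouseSeed,
                          orthologs, mouseAnnotation, known,
                          mode = c("all", "majority"), strictClass = FALSE,
                          mouseSthr = NULL, mousePthr = NULL) {
    tbl <- rankCandidates(tbl)
    tbl <- concordanceFilter(tbl, altSeedProbes, be, mode = mode,
                             strictClass = strictClass)
    tbl <- conservationFilter(tbl, mouseBe, mouseSeed, orthologs,
                              mouseAnnotation, strictClass = strictClass,
                              sthr = mouseSthr, pthr = mousePthr)
    noveltyAnnotate(tbl, known)
}

#' Select the surviving shortlist from an annotated candidate table
#'
#' @param tbl An annotated, ranked \linkS4class{CandidateTable}.
#' @param requireConcordant,requireConserved,requireNovel Which flags must
#'   be TRUE (NA flags fail the requirement).
#' @param top Optional cutoff on rank after filtering.
#' @return A data.frame of surviving records.
#' @export
selectSurvivors <- function(tbl, requireConcordant = TRUE,
                            requireConserved = TRUE, requireNovel = TRUE,
                            top = NULL) {
    rec <- as.data.frame(tbl@records)
    keep <- rep(TRUE, nrow(rec))
    if (requireConcordant) keep <- keep & rec$concordant %in% TRUE
    if (requireConserved) keep <- keep & rec$conserved %in% TRUE
    if (requireNovel) keep <- keep & rec$novel %in% TRUE
    rec <- rec[keep, , drop = FALSE]
    if (!is.null(top) && nrow(rec) > top)
        rec <- rec[order(rec$rank)[seq_len(top)], , drop = FALSE]
    rec
}
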