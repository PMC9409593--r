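#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData
NULL

#' Discrete expression states
#'
#' Integer codes used for per-sample probe states after StepMiner
#' binarization: \code{LOW = 0}, \code{INTERMEDIATE = 1}, \code{HIGH = 2}.
#' Missing measurements stay \code{NA}.
#'
#' @return Named integer vector of the three state codes.
#' @examples
#' stateCodes()
#' @export
stateCodes <- function() {
    c(LOW = 0L, INTERMEDIATE = 1L, HIGH = 2L)
}

#' The six Boolean relationship classes (plus NONE)
#'
#' @return Character vector of the seven possible pair calls.
#' @examples
#' relationshipClasses()
#' @export
relationshipClasses <- function() {
    c("NONE", "LOW_LOW", "LOW_HIGH", "HIGH_LOW", "HIGH_HIGH",
      "EQUIVALENT", "OPPOSITE")
}

#' BinarizedExperiment: a compendium with StepMiner states
#'
#' Extends \linkS4class{SummarizedExperiment} with two assays:
#' \code{"exprs"} (the log2 expression values the object was built from) and
#' \code{"state"} (integer states per \code{\link{stateCodes}}, \code{NA} for
#' missing or for probes that failed eligibility). Per-probe fit results
#' (threshold, segment means, SSE, low/high fractions, eligibility) live in
#' \code{rowData}; the intermediate-zone margin is kept in a slot.
#'
#' @slot margin numeric(1), half-width of the intermediate zone in log2 units.
#'
#' @seealso \code{\link{binarizeMatrix}}, \code{\link{fitStep}}
#' @export
setClass("BinarizedExperiment",
    contains = "SummarizedExperiment",
    representation(margin = "numeric"))

setValidity("BinarizedExperiment", function(object) {
    msg <- NULL
    if (!all(c("exprs", "state") %in% names(assays(object))))
        msg <- c(msg, "assays must contain 'exprs' and 'state'")
    if (length(object@margin) != 1L || is.na(object@margin) ||
        object@margin < 0)
        msg <- c(msg, "margin must be a single non-negative number")
    need <- c("threshold", "lowMean", "highMean", "sse", "splitIndex",
              "fracLow", "fracHigh", "eligible")
    if (!all(need %in% colnames(rowData(object))))
        msg <- c(msg, paste("rowData must contain:",
                            paste(need, collapse = ", ")))
    if ("state" %in% names(assays(object))) {
        st <- assay(object, "state")
        bad <- st[!is.na(st)]
        if (length(bad) && !all(bad %in% stateCodes()))
            msg <- c(msg, "state assay must contain only 0/1/2 or NA")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn BinarizedExperiment intermediate-zone margin (log2 units)
#' @param object A \code{BinarizedExperiment}.
#' @export
setGeneric("intermediateMargin", function(object)
    standardGeneric("intermediateMargin"))

#' @export
setMethod("intermediateMargin", "BinarizedExperiment",
          function(object) object@margin)

#' @describeIn BinarizedExperiment integer state matrix (probes x samples)
#' @export
setGeneric("stateMatrix", function(object) standardGeneric("stateMatrix"))

#' @export
setMethod("stateMatrix", "BinarizedExperiment",
          function(object) assay(object, "state"))

#' @describeIn BinarizedExperiment per-probe step-fit table
#' @export
setGeneric("stepFits", function(object) standardGeneric("stepFits"))

#' @export
setMethod("stepFits", "BinarizedExperiment",
          function(object) rowData(object))

#' @describeIn BinarizedExperiment logical vector of probe eligibility
#' @export
setGeneric("eligibleProbes", function(object)
    standardGeneric("eligibleProbes"))

#' @export
setMethod("eligibleProbes", "BinarizedExperiment", function(object) {
    el <- rowData(object)$eligible
    names(el) <- rownames(object)
    el
})

setMethod("show", "BinarizedExperiment", function(object) {
    callNextMethod()
    el <- rowData(object)$eligible
    cat(sprintf("margin: %.3g log2 units; eligible probes: %d/%d\n",
                object@margin, sum(el), length(el)))
})

#' CandidateTable: seed-paired probes with implication calls and filter flags
#'
#' Result container of \code{\link{discoverCandidates}} and the filter
#' cascade. Holds the seed probe, the thresholds used, and one record per
#' candidate probe with its relationship class, best quadrant statistics,
#' filter flags (\code{concordant}, \code{conserved}, \code{novel}) and rank.
#'
#' @slot seedProbe character(1), the primary seed probe id.
#' @slot sthr,pthr,minPairs numeric(1), the implication thresholds used.
#' @slot records \link[S4Vectors]{DataFrame} of candidate records.
#'
#' @seealso \code{\link{discoverCandidates}}, \code{\link{rankCandidates}},
#'   \code{\link{concordanceFilter}}, \code{\link{conservationFilter}},
#'   \code{\link{noveltyAnnotate}}
#' @export
setClass("CandidateTable",
    representation(seedProbe = "character",
                   sthr = "numeric",
                   pthr = "numeric",
                   minPairs = "numeric",
                   records = "DataFrame"))

setValidity("CandidateTable", function(object) {
    msg <- NULL
    need <- c("probeId", "genes", "class", "bestS", "bestP", "nPairs",
              "concordant", "conserved", "conservedBy", "novel", "rank")
    if (!all(need %in% colnames(object@records)))
        msg <- c(msg, paste("records must contain columns:",
                            paste(need, collapse = ", ")))
    if (length(object@seedProbe) != 1L)
        msg <- c(msg, "seedProbe must be a single probe id")
    cls <- object@records$class
    if (length(cls) && (any(cls == "NONE") ||
                        !all(cls %in% relationshipClasses())))
        msg <- c(msg, "record classes must be non-NONE relationship classes")
    if (length(cls) && object@seedProbe %in% object@records$probeId)
        msg <- c(msg, "seed probe must not appear among its own candidates")
    rk <- object@records$rank
    rk <- rk[!is.na(rk)]
    if (anyDuplicated(rk))
        msg <- c(msg, "ranks must be unique")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CandidateTable candidate records as a DataFrame
#' @param object A \code{CandidateTable}.
#' @export
setGeneric("candidateRecords", function(object)
    standardGeneric("candidateRecords"))

#' @export
setMethod("candidateRecords", "CandidateTable",
          function(object) object@records)

#' @describeIn CandidateTable the primary seed probe id
#' @export
setGeneric("seedProbe", function(object) standardGeneric("seedProbe"))

#' @export
setMethod("seedProbe", "CandidateTable", function(object) object@seedProbe)

#' @describeIn CandidateTable thresholds (sthr, pthr, minPairs) used
#' @export
setGeneric("implicationThresholds", function(object)
    standardGeneric("implicationThresholds"))

#' @export
setMethod("implicationThresholds", "CandidateTable", function(object)
    c(sthr = object@sthr, pthr = object@pthr, minPairs = object@minPairs))

#' @describeIn CandidateTable tally of candidates per relationship class
#' @export
setGeneric("classTally", function(object) standardGeneric("classTally"))

#' @export
setMethod("classTally", "CandidateTable", function(object) {
    lv <- setdiff(relationshipClasses(), "NONE")
    table(factor(object@records$class, levels = lv))
})

setMethod("show", "CandidateTable", function(object) {
    cat(sprintf("CandidateTable: %d candidates for seed %s\n",
                nrow(object@records), object@seedProbe))
    cat(sprintf("thresholds: S > %g, p < %g, min pairs %g\n",
                object@sthr, object@pthr, object@minPairs))
    tl <- classTally(object)
    tl <- tl[tl > 0]
    if (length(tl))
        cat("classes:", paste(sprintf("%s=%d", names(tl), tl),
                              collapse = ", "), "\n")
    if (nrow(object@records)) {
        cat("top records:\n")
        print(utils::head(as.data.frame(object@records), 5L))
    }
})

# internal: construct a CandidateTable with canonical record columns
.newCandidateTable <- function(seedProbe, sthr, pthr, minPairs, records) {
    new("CandidateTable", seedProbe = seedProbe, sthr = sthr, pthr = pthr,
        minPairs = minPairs, records = records)
}

# internal: an empty canonical records DataFrame
.emptyRecords <- function() {
    DataFrame(probeId = character(0), genes = character(0),
              class = character(0), bestS = numeric(0), bestP = numeric(0),
              nPairs = integer(0), concordant = logical(0),
              conserved = logical(0), conservedBy = character(0),
              novel = logical(0), rank = integer(0))
}
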