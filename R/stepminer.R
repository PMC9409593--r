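#' Fit a one-step threshold to a probe's expression values
#'
#' Least-squares StepMiner fit: the values are sorted ascending and, over all
#' split points k in 1..(n-1), the two-segment fit minimizing the total
#' squared error around the segment means is chosen. The low/high threshold
#' is the midpoint of the two segment means. Among equal-SSE splits the
#' smallest split index wins, so the fit is deterministic.
#'
#' A probe is eligible only when it has at least \code{minN} non-missing
#' values and the fitted dynamic range \code{highMean - lowMean} reaches
#' \code{rangeFloor}; constant probes are never eligible.
#'
#' @param values Numeric vector of log2 expression values; \code{NA} allowed.
#' @param minN Minimum number of non-missing values (default 20).
#' @param rangeFloor Minimum \code{highMean - lowMean} in log2 units for
#'   eligibility (default 1.0).
#'
#' @return A list with elements \code{threshold}, \code{lowMean},
#'   \code{highMean}, \code{sse}, \code{splitIndex} (samples in the low
#'   segment), \code{nUsed} and \code{eligible}.
#'
#' @examples
#' fitStep(c(1, 1, 1, 5, 5, 5), minN = 2)
#' @export
fitStep <- function(values, minN = 20L, rangeFloor = 1.0) {
    v <- values[!is.na(values)]
    n <- length(v)
    ineligible <- list(threshold = NA_real_, lowMean = NA_real_,
                       highMean = NA_real_, sse = NA_real_,
                       splitIndex = NA_integer_, nUsed = n, eligible = FALSE)
    if (n < max(2L, minN)) return(ineligible)
    sv <- sort(v)
    cs <- cumsum(sv)
    css <- cumsum(sv * sv)
    k <- seq_len(n - 1L)
    lowSse <- css[k] - cs[k]^2 / k
    highSse <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
    sse <- lowSse + highSse
    # guard tiny negative residuals from floating-point cancellation
    sse[sse < 0] <- 0
    kBest <- which.min(sse)                 # first minimum: smallest split
    lowMean <- cs[kBest] / kBest
    highMean <- (cs[n] - cs[kBest]) / (n - kBest)
    if (highMean - lowMean < rangeFloor) {
        ineligible$nUsed <- n
        return(ineligible)
    }
    list(threshold = (lowMean + highMean) / 2,
         lowMean = lowMean, highMean = highMean,
         sse = sse[kBest], splitIndex = as.integer(kBest),
         nUsed = n, eligible = TRUE)
}

#' Binarize a log2 expression matrix into low/intermediate/high states
#'
#' Fits a StepMiner threshold t to every probe (row) and assigns per-sample
#' states: LOW when value < t - margin, HIGH when value > t + margin,
#' INTERMEDIATE otherwise (values exactly at t +/- margin are INTERMEDIATE);
#' missing values stay missing. A probe is kept eligible only when its step
#' fit is eligible and at least \code{minSideFrac} of its non-missing samples
#' fall on each side after binarization; ineligible probes have all states
#' set missing.
#'
#' @param x Numeric matrix (probes x samples) with dimnames, or a
#'   \link[SummarizedExperiment]{SummarizedExperiment} whose first assay
#'   holds the log2 values.
#' @param margin Half-width of the intermediate zone in log2 units
#'   (default 0.5).
#' @param minSideFrac Minimum fraction of non-missing samples required in
#'   each of the LOW and HIGH states (default 0.05); must be < 0.5.
#' @param minN,rangeFloor Passed to \code{\link{fitStep}}.
#'
#' @return A \linkS4class{BinarizedExperiment}.
#'
#' @examples
#' m <- rbind(p1 = c(2, 2.1, 2, 6, 6.2, 6.1),
#'            p2 = c(5, 5.1, 5, 5.05, 5.1, 5))
#' colnames(m) <- paste0("s", 1:6)
#' be <- binarizeMatrix(m, minN = 3)
#' stateMatrix(be)
#' @export
binarizeMatrix <- function(x, margin = 0.5, minSideFrac = 0.05,
                           minN = 20L, rangeFloor = 1.0) {
    if (is(x, "SummarizedExperiment")) {
        mat <- assay(x, 1L)
        rd <- rowData(x)
    } else {
        mat <- as.matrix(x)
        rd <- NULL
    }
    if (is.null(rownames(mat)))
        stop("expression matrix must have probe ids as rownames")
    if (margin < 0) stop("margin must be >= 0")
    if (minSideFrac < 0 || minSideFrac >= 0.5)
        stop("minSideFrac must be in [0, 0.5)")

    np <- nrow(mat)
    st <- matrix(NA_integer_, np, ncol(mat), dimnames = dimnames(mat))
    fit <- data.frame(threshold = rep(NA_real_, np), lowMean = NA_real_,
                      highMean = NA_real_, sse = NA_real_,
                      splitIndex = NA_integer_, fracLow = NA_real_,
                      fracHigh = NA_real_, eligible = FALSE,
                      row.names = rownames(mat))
    codes <- stateCodes()
    for (i in seq_len(np)) {
        f <- fitStep(mat[i, ], minN = minN, rangeFloor = rangeFloor)
        fit$threshold[i] <- f$threshold
        fit$lowMean[i] <- f$lowMean
        fit$highMean[i] <- f$highMean
        fit$sse[i] <- f$sse
        fit$splitIndex[i] <- f$splitIndex
        if (!f$eligible) next
        v <- mat[i, ]
        s <- rep(codes[["INTERMEDIATE"]], length(v))
        s[v < f$threshold - margin] <- codes[["LOW"]]
        s[v > f$threshold + margin] <- codes[["HIGH"]]
        s[is.na(v)] <- NA_integer_
        nOk <- sum(!is.na(v))
        fracLow <- sum(s == codes[["LOW"]], na.rm = TRUE) / nOk
        fracHigh <- sum(s == codes[["HIGH"]], na.rm = TRUE) / nOk
        fit$fracLow[i] <- fracLow
        fit$fracHigh[i] <- fracHigh
        if (fracLow >= minSideFrac && fracHigh >= minSideFrac) {
            fit$eligible[i] <- TRUE
            st[i, ] <- s
        }
    }
    rowDat <- DataFrame(fit)
    if (!is.null(rd) && ncol(rd))
        rowDat <- cbind(rd, rowDat)
    se <- SummarizedExperiment(
        assays = list(exprs = mat, state = st), rowData = rowDat)
    out <- new("BinarizedExperiment", se, margin = margin)
    metadata(out)$binarizeParams <- list(
        margin = margin, minSideFrac = minSideFrac, minN = minN,
        rangeFloor = rangeFloor)
    validObject(out)
    out
}
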