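#' Read a tab-delimited log2 expression matrix
#'
#' Expects a header line (first cell is the probe-id column name, remaining
#' cells are sample ids) followed by one probe per row. Lines starting with
#' the comment prefix are skipped. Values are assumed already normalized and
#' log2-scaled; \code{log2Transform = TRUE} applies \code{log2(v + 1)} for
#' linear-scale inputs.
#'
#' @param path Path to the matrix file.
#' @param missingToken Token read as a missing value (default \code{"NA"}).
#' @param commentPrefix Lines starting with this prefix are skipped
#'   (default \code{"#"}).
#' @param log2Transform Apply \code{log2(v + 1)} on ingest (default FALSE).
#' @param platformLabel Free-text platform label stored in metadata.
#'
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with one
#'   assay \code{"exprs"}; probe ids as rownames, sample ids as colnames.
#'
#' @details Duplicated probe or sample ids, ragged rows and non-numeric
#'   non-missing cells are hard errors that name the offending id, line or
#'   cell; rows are never silently dropped.
#' @export
readExpressionMatrix <- function(path, missingToken = "NA",
                                 commentPrefix = "#",
                                 log2Transform = FALSE,
                                 platformLabel = "") {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    keep <- !startsWith(lines, commentPrefix) & nzchar(trimws(lines))
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) stop("no header line in ", path)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1L]]
    sampleIds <- header[-1L]
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id: ",
             sampleIds[duplicated(sampleIds)][1L])
    body <- cells[-1L]
    probeIds <- vapply(body, `[`, character(1), 1L)
    if (anyDuplicated(probeIds))
        stop("duplicate probe id: ", probeIds[duplicated(probeIds)][1L])
    nS <- length(sampleIds)
    vals <- matrix(NA_real_, length(body), nS,
                   dimnames = list(probeIds, sampleIds))
    for (i in seq_along(body)) {
        row <- body[[i]]
        if (length(row) != nS + 1L)
            stop("ragged row at line ", lineNo[i + 1L], ": expected ",
                 nS + 1L, " fields, found ", length(row))
        raw <- row[-1L]
        miss <- raw == missingToken
        num <- suppressWarnings(as.numeric(raw))
        bad <- which(!miss & is.na(num))
        if (length(bad))
            stop("non-numeric value '", raw[bad[1L]], "' at probe ",
                 probeIds[i], ", sample ", sampleIds[bad[1L]])
        num[miss] <- NA_real_
        vals[i, ] <- num
    }
    if (any(!is.finite(vals) & !is.na(vals)))
        stop("non-finite values present in ", path)
    if (log2Transform) vals <- log2(vals + 1)
    se <- SummarizedExperiment(assays = list(exprs = vals))
    metadata(se)$platformLabel <- platformLabel
    se
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of \code{\link{readExpressionMatrix}}; optional comment lines
#' (prefixed \code{"#"}) record the provenance/configuration.
#'
#' @param x Numeric matrix or SummarizedExperiment (first assay written).
#' @param path Output path.
#' @param idColumn Name of the probe-id header cell (default "probeId").
#' @param headerComments Character vector written as "#" lines before the
#'   header.
#' @return Invisibly, the path.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "probeId",
                                  headerComments = character(0)) {
    mat <- if (is(x, "SummarizedExperiment")) assay(x, 1L) else as.matrix(x)
    con <- file(path, "w")
    on.exit(close(con))
    if (length(headerComments))
        writeLines(paste0("# ", headerComments), con)
    writeLines(paste(c(idColumn, colnames(mat)), collapse = "\t"), con)
    body <- apply(mat, 1L, function(v)
        paste(ifelse(is.na(v), "NA", sprintf("%.10g", v)), collapse = "\t"))
    writeLines(paste(rownames(mat), body, sep = "\t"), con)
    invisible(path)
}

#' Read probe annotations, ortholog maps or gene lists
#'
#' One reader for the three mapping-table formats: two-column tab-delimited
#' probe-to-gene annotation, two-column human/mouse ortholog pairs, or a
#' one-column gene list. Blank and "#" comment lines are skipped; an empty
#' file returns an empty table with a warning.
#'
#' @param path Path to the tab-delimited file.
#' @param kind One of \code{"annotation"}, \code{"ortholog"},
#'   \code{"genelist"}.
#'
#' @return For \code{"annotation"} a data.frame with columns \code{probeId},
#'   \code{gene} (a probe may map to several genes across rows); for
#'   \code{"ortholog"} a data.frame with \code{human}, \code{mouse}
#'   (many-to-many, duplicate pairs collapsed); for \code{"genelist"} a
#'   character vector deduplicated case-insensitively.
#' @export
readMappingTable <- function(path,
                             kind = c("annotation", "ortholog",
                                      "genelist")) {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    wantCols <- if (kind == "genelist") 1L else 2L
    if (!length(lines)) {
        warning("empty ", kind, " file: ", path)
        return(switch(kind,
            annotation = data.frame(probeId = character(0),
                                    gene = character(0)),
            ortholog = data.frame(human = character(0),
                                  mouse = character(0)),
            genelist = character(0)))
    }
    cells <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(cells)
    if (any(nc != wantCols))
        stop(kind, " file must have ", wantCols, " tab-delimited column(s);",
             " line ", which(nc != wantCols)[1L], " has ",
             nc[nc != wantCols][1L])
    if (kind == "genelist") {
        g <- trimws(vapply(cells, `[`, character(1), 1L))
        if (any(!nzchar(g))) stop("empty gene symbol in ", path)
        return(g[!duplicated(toupper(g))])
    }
    a <- trimws(vapply(cells, `[`, character(1), 1L))
    b <- trimws(vapply(cells, `[`, character(1), 2L))
    if (any(!nzchar(a)) || any(!nzchar(b)))
        stop("empty field in ", kind, " file ", path)
    if (kind == "annotation")
        return(unique(data.frame(probeId = a, gene = b,
                                 stringsAsFactors = FALSE)))
    unique(data.frame(human = a, mouse = b, stringsAsFactors = FALSE))
}

#' Read a FASTA file of nucleotide sequences
#'
#' Wraps \code{\link[Biostrings]{readDNAStringSet}}: sequences are
#' uppercased, wrapped lines joined, record order preserved. Characters
#' outside the IUPAC nucleotide alphabet are a hard error naming the record.
#'
#' @param path Path to the FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}.
#' @export
readFastaRecords <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    txt <- readLines(path)
    heads <- which(startsWith(txt, ">"))
    if (!length(heads))
        stop("not a FASTA file (no '>' header): ", path)
    # readDNAStringSet only warns and drops invalid letters; the contract
    # here is a hard error naming the offending record
    ok <- c(names(Biostrings::IUPAC_CODE_MAP), "-")
    for (i in seq_along(heads)) {
        from <- heads[i] + 1L
        to <- if (i < length(heads)) heads[i + 1L] - 1L else length(txt)
        body <- toupper(gsub("\\s", "",
                             paste(txt[from:to], collapse = "")))
        letters <- strsplit(body, "")[[1L]]
        if (any(!letters %in% ok))
            stop("invalid nucleotide characters in record ",
                 sub("^>\\s*", "", txt[heads[i]]), " of ", path)
    }
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    Biostrings::DNAStringSet(toupper(seqs))
}

# internal: format a data.frame for TSV output, numerics at >= 6 significant
# digits
.formatTsv <- function(df) {
    for (j in seq_along(df)) {
        if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
            df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                              sprintf("%.8g", df[[j]]))
        else
            df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                              as.character(df[[j]]))
    }
    df
}

#' Write a result table (candidates, motif hits, ...) as TSV
#'
#' Writes a tab-delimited file with a header row, preceded by "#" comment
#' lines that record the column order and any configuration handed in.
#' Floating-point values are rendered with at least 6 significant digits so
#' a write/read round trip preserves them.
#'
#' @param x A \linkS4class{CandidateTable} or data.frame.
#' @param path Output path.
#' @param headerComments Extra "#" comment lines (e.g. the effective
#'   configuration).
#' @return Invisibly, the path.
#' @export
writeResultTable <- function(x, path, headerComments = character(0)) {
    if (is(x, "CandidateTable")) {
        headerComments <- c(headerComments,
            sprintf("seedProbe=%s", seedProbe(x)),
            sprintf("sthr=%g pthr=%g minPairs=%g",
                    x@sthr, x@pthr, x@minPairs))
        x <- as.data.frame(candidateRecords(x))
    }
    x <- as.data.frame(x)
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write: ", path),
                    warning = function(w) stop("cannot write: ", path))
    on.exit(close(con))
    if (length(headerComments))
        writeLines(paste0("# ", headerComments), con)
    writeLines(paste0("# columns: ", paste(names(x), collapse = "\t")), con)
    writeLines(paste(names(x), collapse = "\t"), con)
    if (nrow(x)) {
        fm <- .formatTsv(x)
        writeLines(do.call(paste, c(unname(as.list(fm)), sep = "\t")), con)
    }
    invisible(path)
}

#' Read back a TSV result table written by \code{\link{writeResultTable}}
#'
#' @param path Path to the TSV file.
#' @return A data.frame; "#" comment lines are skipped and column types
#'   re-inferred.
#' @export
readResultTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, comment.char = "#", sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a binarized state matrix written by the binarize step
#'
#' @param path Path to a TSV with probe ids in the first column and integer
#'   states (0 low, 1 intermediate, 2 high, NA missing) per sample.
#' @return Integer matrix with probe/sample dimnames.
#' @export
readStateMatrix <- function(path) {
    df <- readResultTable(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- df[[1L]]
    bad <- m[!is.na(m)]
    if (length(bad) && !all(bad %in% stateCodes()))
        stop("state matrix must contain only 0/1/2 or NA: ", path)
    m
}
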