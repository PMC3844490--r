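## Readers and writers.  Native dialect: plain TSV, features in rows with a
## leading id column, header row of sample ids; labels in a separate
## two-column TSV (sample_id <TAB> class), matched to matrix columns by id.
## A best-effort GEO series-matrix reader strips "!"-prefixed metadata lines.

#' Read a sample-label table
#'
#' @param path two-column delimited file with a header: sample id, class.
#' @param sep field delimiter (default tab).
#' @return named character vector, class per sample id.
#' @export
readSampleLabels <- function(path, sep = "\t") {
    df <- read.delim(path, sep = sep, header = TRUE,
                     colClasses = "character", check.names = FALSE)
    if (ncol(df) < 2L)
        stop("label file must have two columns (sample id, class): ", path)
    setNames(df[[2L]], df[[1L]])
}

#' Read a labelled expression table
#'
#' Reads a features-in-rows expression matrix (first column feature ids,
#' header row sample ids) plus its label file, validates, and returns a
#' [HEMExperiment-class].  Labels are matched to matrix columns by sample id
#' (order-insensitive); missing or extra ids, duplicate feature ids, and
#' non-numeric or missing cells are rejected with coordinates.
#'
#' @param path expression matrix file.
#' @param labels path of a two-column label file, or a named character
#'   vector (class per sample id).
#' @param sep field delimiter of the matrix file (default tab; use "," for
#'   CSV).
#' @param format `"table"` for plain TSV/CSV, `"geo"` for a GEO
#'   series-matrix file ("!"-prefixed metadata lines are stripped and the
#'   table between the series-matrix markers is used).
#' @return a [HEMExperiment-class].
#' @export
readExpressionTable <- function(path, labels, sep = "\t",
                                format = c("table", "geo")) {
    format <- match.arg(format)
    if (format == "geo") {
        lines <- readLines(path)
        begin <- grep("^!series_matrix_table_begin", lines)
        end <- grep("^!series_matrix_table_end", lines)
        lines <- if (length(begin) == 1L && length(end) == 1L && end > begin)
            lines[(begin + 1L):(end - 1L)]
        else
            lines[!startsWith(lines, "!")]
        lines <- lines[nzchar(lines)]
        con <- textConnection(lines)
        on.exit(close(con))
        df <- read.delim(con, sep = "\t", header = TRUE,
                         check.names = FALSE, quote = "\"")
    } else {
        df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
    }
    if (ncol(df) < 2L)
        stop("expression table needs an id column plus at least one sample: ",
             path)
    featureIds <- as.character(df[[1L]])
    if (anyDuplicated(featureIds))
        stop("duplicate feature id(s) in ", path, ": ",
             paste(unique(featureIds[duplicated(featureIds)]), collapse = ", "))
    body <- df[, -1L, drop = FALSE]
    values <- matrix(NA_real_, nrow(body), ncol(body))
    for (j in seq_len(ncol(body))) {
        col <- body[[j]]
        num <- if (is.numeric(col)) col
               else suppressWarnings(as.numeric(as.character(col)))
        bad <- which(!is.finite(num))
        if (length(bad))
            stop(sprintf("non-numeric or missing value at feature '%s', sample column '%s'",
                         featureIds[bad[1L]], colnames(body)[j]))
        values[, j] <- num
    }
    sampleIds <- colnames(body)

    if (is.character(labels) && length(labels) == 1L && is.null(names(labels)))
        labels <- readSampleLabels(labels)
    if (is.null(names(labels)))
        stop("'labels' must be a label file path or a named vector")
    missing <- setdiff(sampleIds, names(labels))
    if (length(missing))
        stop("label file is missing sample id(s): ",
             paste(missing, collapse = ", "))
    HEMExperiment(values, labels = unname(labels[sampleIds]),
                  featureIds = featureIds, sampleIds = sampleIds)
}

#' Write a labelled expression table
#'
#' Writes the native TSV dialect (matrix with id column and header, plus a
#' two-column label file) at full double precision, so
#' `readExpressionTable()` round-trips the dataset bit-exactly.
#'
#' @param x a [HEMExperiment-class].
#' @param path output matrix file.
#' @param labelsPath output label file.
#' @export
writeExpressionTable <- function(x, path, labelsPath) {
    vals <- exprValues(x)
    out <- cbind(feature_id = rownames(vals),
                 as.data.frame(matrix(sprintf("%.17g", vals), nrow(vals),
                                      dimnames = dimnames(vals)),
                               check.names = FALSE))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = colnames(x),
                           class = as.character(sampleClasses(x))),
                labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(path, labelsPath))
}

#' Write a ranked selection as TSV
#'
#' Columns: rank, feature_id, relevance, avg_significance, objective
#' (6 significant digits).
#'
#' @param result a [SelectionResult-class].
#' @param path output file.
#' @export
writeRanking <- function(result, path) {
    df <- data.frame(rank = seq_along(result@selected),
                     feature_id = result@selected,
                     relevance = signif(result@relevance, 6),
                     avg_significance = signif(result@avgSignificance, 6),
                     objective = signif(result@objective, 6))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write an error report or curve as TSV
#'
#' @param report an [ErrorReport-class] or the data.frame from
#'   [errorCurve()].
#' @param path output file.
#' @export
writeErrorReport <- function(report, path) {
    df <- if (methods::is(report, "ErrorReport"))
        data.frame(AE = report@AE, B1 = report@B1, gamma = report@gamma,
                   r = report@r, omega_tilde = report@omegaTilde,
                   B632plus = report@B632plus, gap = report@gap)
    else as.data.frame(lapply(report, function(z) signif(z, 6)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
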