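#' Construct a labelled expression experiment
#'
#' Builds the central data object of the package from a feature-by-sample
#' numeric matrix and a vector of per-sample class labels.  The class order
#' used throughout (partition-matrix rows, no-information class proportions)
#' is the factor level order: levels of `labels` if it is already a factor,
#' otherwise order of first appearance.
#'
#' @param values numeric matrix, features in rows, samples in columns.  All
#'   entries must be finite; missing values are rejected, not imputed.
#' @param labels vector of class labels, one per column of `values`.
#' @param featureIds,sampleIds optional character vectors of ids; default to
#'   the dimnames of `values` or to `F1..Fm` / `S1..Sn`.
#' @return A [HEMExperiment-class] object.
#' @examples
#' x <- HEMExperiment(rbind(a = c(1, 2, 3, 10, 11, 12)),
#'                    labels = c("A", "A", "A", "B", "B", "B"))
#' dependencyDegree(x, "a")
#' @export
HEMExperiment <- function(values, labels, featureIds = NULL,
                          sampleIds = NULL) {
    if (!is.matrix(values))
        values <- matrix(values, nrow = 1L)
    storage.mode(values) <- "double"
    m <- nrow(values); n <- ncol(values)
    if (n < 1L || m < 1L)
        stop("expression matrix must have at least 1 feature and 1 sample")
    if (length(labels) != n)
        stop("need one class label per sample: got ", length(labels),
             " labels for ", n, " samples")
    if (anyNA(labels)) stop("class labels contain NA")
    if (any(!is.finite(values))) {
        bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing/non-finite expression value at feature row %d, sample column %d",
                     bad[1L], bad[2L]))
    }
    if (is.null(featureIds)) featureIds <- rownames(values)
    if (is.null(featureIds)) featureIds <- paste0("F", seq_len(m))
    if (is.null(sampleIds)) sampleIds <- colnames(values)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(n))
    if (anyDuplicated(featureIds))
        stop("duplicate feature ids: ",
             paste(unique(featureIds[duplicated(featureIds)]), collapse = ", "))
    if (anyDuplicated(sampleIds))
        stop("duplicate sample ids: ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    dimnames(values) <- list(featureIds, sampleIds)
    cl <- if (is.factor(labels)) droplevels(labels)
          else factor(as.character(labels), levels = unique(as.character(labels)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values),
        colData = S4Vectors::DataFrame(class = cl, row.names = sampleIds))
    methods::new("HEMExperiment", se)
}

#' @describeIn HEMExperiment expression matrix (features x samples).
#' @param x a `HEMExperiment`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "expr")

#' @describeIn HEMExperiment factor of per-sample class labels.
#' @export
sampleClasses <- function(x) SummarizedExperiment::colData(x)$class

#' @describeIn HEMExperiment class names, in the row order used by partition
#'   matrices.
#' @export
classLevels <- function(x) levels(sampleClasses(x))

#' @describeIn HEMExperiment number of distinct classes `c`.
#' @export
nClasses <- function(x) nlevels(sampleClasses(x))

setMethod("show", "HEMExperiment", function(object) {
    cat(sprintf("HEMExperiment: %d features x %d samples, %d class(es)\n",
                nrow(object), ncol(object), nClasses(object)))
    tab <- table(sampleClasses(object))
    cat("  classes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

# resolve feature ids/indices to integer row indices, with validation
.resolveFeatures <- function(x, features) {
    if (length(features) < 1L) stop("empty attribute set")
    if (is.character(features)) {
        idx <- match(features, rownames(x))
        if (anyNA(idx))
            stop("unknown feature id(s): ",
                 paste(features[is.na(idx)], collapse = ", "))
    } else {
        idx <- as.integer(features)
        if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(x)))
            stop("feature index out of range 1..", nrow(x))
    }
    idx
}
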