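#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats predict rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

#' Labelled expression experiment for rough-hypercuboid analysis
#'
#' `HEMExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a mandatory
#' per-sample class label (the decision attribute).  Rows are features
#' (miRNAs, genes), columns are samples; the single assay `"expr"` holds the
#' real-valued expression matrix (the condition attributes).  Missing or
#' non-finite values are rejected at construction: the hypercuboid algebra is
#' defined on a complete matrix.
#'
#' @slot .   See `SummarizedExperiment`; the class adds no slots, only the
#'   validity requirement that `colData(x)$class` exists, is a factor with at
#'   least one level, and has no missing entries.
#'
#' @seealso [HEMExperiment()] the constructor, [sampleClasses()],
#'   [exprValues()]
#' @export
setClass("HEMExperiment", contains = "SummarizedExperiment")

setValidity("HEMExperiment", function(object) {
    msg <- NULL
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "expr")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'expr' must be numeric")
        else if (any(!is.finite(v)))
            msg <- c(msg, "assay 'expr' contains missing or non-finite values")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"class" %in% colnames(cd))
        msg <- c(msg, "colData column 'class' (sample labels) is required")
    else {
        cl <- cd$class
        if (!is.factor(cl))
            msg <- c(msg, "colData(x)$class must be a factor")
        else if (anyNA(cl))
            msg <- c(msg, "sample class labels contain NA")
        else if (nlevels(droplevels(cl)) < nlevels(cl))
            msg <- c(msg, "every class level must have at least one sample")
    }
    if (nrow(object) < 1L) msg <- c(msg, "at least one feature is required")
    if (ncol(object) < 1L) msg <- c(msg, "at least one sample is required")
    if (is.null(msg)) TRUE else msg
})

#' Hypercuboid equivalence partition matrix
#'
#' A c-by-n binary matrix `H(A)` for an attribute set `A`: entry `(i, j)` is 1
#' when sample `j`'s value(s) on `A` fall inside class `i`'s value interval(s)
#' (one interval per attribute, boundaries inclusive).  Rows are classes in
#' `classOrder`; columns are samples.
#'
#' @slot entries integer matrix of 0/1 memberships, `c` rows, `n` columns.
#' @slot classOrder character vector naming the `c` classes, in row order.
#' @slot attributeSet character vector of the feature id(s) the matrix was
#'   built from.
#'
#' @seealso [partitionMatrix()], [jointPartitionMatrix()], [confusionVector()]
#' @export
setClass("EquivalencePartitionMatrix",
    representation(entries = "matrix",
                   classOrder = "character",
                   attributeSet = "character"))

setValidity("EquivalencePartitionMatrix", function(object) {
    e <- object@entries
    msg <- NULL
    if (!is.numeric(e) && !is.integer(e))
        msg <- c(msg, "entries must be a numeric 0/1 matrix")
    else if (length(e) && !all(e %in% c(0L, 1L)))
        msg <- c(msg, "entries must be binary")
    if (nrow(e) != length(object@classOrder))
        msg <- c(msg, "row count must equal length(classOrder)")
    if (length(object@attributeSet) < 1L)
        msg <- c(msg, "attributeSet must name at least one feature")
    if (is.null(msg)) TRUE else msg
})

#' Result of the greedy relevance-significance selection
#'
#' Ordered record of one selector run: the selected feature ids, the
#' per-feature relevance (dependency of the class labels on that feature
#' alone), the average significance of each feature against the features
#' selected before it (undefined for the first pick, stored as `NA`), the
#' greedy objective value at admission (`NA` for the seed pick, which is
#' chosen by relevance only), and the features discarded as dispensable
#' (zero significance with respect to an already-selected feature).
#'
#' @slot selected character, selected feature ids in selection order.
#' @slot relevance numeric, dependency of each selected feature.
#' @slot avgSignificance numeric, mean significance of each selected feature
#'   versus the earlier picks (`NA` for the first).
#' @slot objective numeric, weighted objective at admission (`NA` for the
#'   first).
#' @slot removedDispensable character, feature ids removed by the
#'   zero-significance rule, in removal order.
#' @slot omega numeric scalar, the relevance weight used.
#' @slot d integer scalar, the requested number of features.
#'
#' @seealso [selectFeatures()], [averageSignificanceProfile()]
#' @export
setClass("SelectionResult",
    representation(selected = "character",
                   relevance = "numeric",
                   avgSignificance = "numeric",
                   objective = "numeric",
                   removedDispensable = "character",
                   omega = "numeric",
                   d = "integer"))

setValidity("SelectionResult", function(object) {
    n <- length(object@selected)
    msg <- NULL
    if (length(object@relevance) != n ||
        length(object@avgSignificance) != n ||
        length(object@objective) != n)
        msg <- c(msg, "per-feature slots must match length(selected)")
    if (length(object@omega) != 1L || object@omega < 0 || object@omega > 1)
        msg <- c(msg, "omega must be a scalar in [0, 1]")
    if (any(object@removedDispensable %in% object@selected))
        msg <- c(msg, "removedDispensable and selected must be disjoint")
    if (n > length(unique(object@selected)))
        msg <- c(msg, "selected ids must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Pluggable classifier contract
#'
#' A classifier is a pair of functions: `fit(values, labels)` taking a
#' feature-by-sample numeric matrix and a factor of training labels and
#' returning an opaque model, and `predict(model, values)` returning a vector
#' of predicted labels for new columns.  Both must be deterministic given
#' identical inputs, so that the bootstrap harness is reproducible.
#'
#' @slot fitFun function(values, labels) -> model.
#' @slot predictFun function(model, values) -> labels.
#' @slot description character, a short human-readable label.
#'
#' @seealso [makeClassifier()], [linearSVMClassifier()]
#' @export
setClass("Classifier",
    representation(fitFun = "function",
                   predictFun = "function",
                   description = "character"))

#' Bootstrap error report
#'
#' Holds the error estimates of one selector + classifier configuration:
#' apparent (resubstitution) error `AE`, leave-one-out bootstrap error `B1`,
#' no-information error `gamma`, the relative overfitting rate `r`, the
#' weight `omegaTilde = 0.632 / (1 - 0.368 r)`, the bias-corrected
#' `B632plus = (1 - omegaTilde) AE + omegaTilde B1'` (with `B1' = min(B1,
#' gamma)`), and the gap estimate `gamma - B1`.
#'
#' @slot AE,B1,gamma,r,omegaTilde,B632plus numeric scalars in [0, 1].
#' @slot gap numeric scalar in [-1, 1].
#'
#' @seealso [errorReport()], [b632plus()], [gapEstimate()]
#' @export
setClass("ErrorReport",
    representation(AE = "numeric", B1 = "numeric", gamma = "numeric",
                   r = "numeric", omegaTilde = "numeric",
                   B632plus = "numeric", gap = "numeric"))

setValidity("ErrorReport", function(object) {
    inunit <- function(z) length(z) == 1L && is.finite(z) && z >= 0 && z <= 1
    msg <- NULL
    for (s in c("AE", "B1", "gamma", "r", "B632plus"))
        if (!inunit(slot(object, s)))
            msg <- c(msg, sprintf("slot '%s' must be a scalar in [0, 1]", s))
    if (!(length(object@gap) == 1L && is.finite(object@gap) &&
          abs(object@gap) <= 1))
        msg <- c(msg, "gap must be a scalar in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})
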