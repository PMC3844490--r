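## Rough-hypercuboid algebra: class value intervals, equivalence partition
## matrices, confusion vectors, approximations, dependency, significance.
## All comparisons are plain floating-point order comparisons: interval
## membership is L <= x <= U with no tolerance, so equal stored values are
## equal.  Confusion is counted in integers, which makes zero-significance
## tests exact (significance is a rational with denominator n).

#' Per-class value intervals of one feature
#'
#' For each class, the interval spanned by the training samples of that class
#' on the given feature: lower bound = class minimum, upper bound = class
#' maximum.  These intervals are the one-dimensional faces of the class
#' hypercuboids.
#'
#' @param x a [HEMExperiment-class].
#' @param feature a single feature id or row index.
#' @return data.frame with one row per class: `class`, `lower`, `upper`.
#' @examples
#' x <- HEMExperiment(rbind(a = c(1, 2, 3, 10, 11, 12)),
#'                    labels = rep(c("A", "B"), each = 3))
#' classIntervals(x, "a")
#' @export
classIntervals <- function(x, feature) {
    idx <- .resolveFeatures(x, feature)
    if (length(idx) != 1L) stop("'feature' must be a single feature")
    v <- exprValues(x)[idx, ]
    cl <- sampleClasses(x)
    lower <- vapply(levels(cl), function(g) min(v[cl == g]), numeric(1))
    upper <- vapply(levels(cl), function(g) max(v[cl == g]), numeric(1))
    data.frame(class = levels(cl), lower = lower, upper = upper,
               row.names = NULL)
}

# c x n logical membership matrix for one feature (internal fast path)
.Hlogical <- function(v, cl) {
    lev <- levels(cl)
    H <- matrix(FALSE, length(lev), length(v))
    for (i in seq_along(lev)) {
        vi <- v[cl == lev[i]]
        H[i, ] <- v >= min(vi) & v <= max(vi)
    }
    H
}

#' Hypercuboid equivalence partition matrix of a feature
#'
#' Builds the c-by-n binary matrix whose entry `(i, j)` is 1 exactly when
#' sample `j`'s value on the feature lies inside class `i`'s interval
#' (inclusive on both ends).  On training data every column has at least one
#' 1 (each sample lies in its own class interval) and every row at least one.
#'
#' @inheritParams classIntervals
#' @return an [EquivalencePartitionMatrix-class].
#' @export
partitionMatrix <- function(x, feature) {
    idx <- .resolveFeatures(x, feature)
    if (length(idx) != 1L) stop("'feature' must be a single feature")
    cl <- sampleClasses(x)
    H <- .Hlogical(exprValues(x)[idx, ], cl)
    e <- matrix(as.integer(H), nrow(H), ncol(H),
                dimnames = list(levels(cl), colnames(x)))
    methods::new("EquivalencePartitionMatrix", entries = e,
                 classOrder = levels(cl), attributeSet = rownames(x)[idx])
}

#' Joint partition matrix of several features
#'
#' The partition matrix of an attribute set is the entrywise logical AND of
#' the single-attribute matrices: a sample lies in a class's joint
#' hypercuboid only if it lies in every one-dimensional interval.  The fold
#' is associative, so the input order is irrelevant.
#'
#' @param Hs a list of [EquivalencePartitionMatrix-class] objects sharing
#'   dimensions and class order.
#' @return an [EquivalencePartitionMatrix-class] for the combined set.
#' @export
jointPartitionMatrix <- function(Hs) {
    if (!is.list(Hs) || length(Hs) < 1L)
        stop("'Hs' must be a non-empty list of partition matrices")
    for (h in Hs)
        if (!methods::is(h, "EquivalencePartitionMatrix"))
            stop("all elements must be EquivalencePartitionMatrix objects")
    ref <- Hs[[1L]]
    e <- ref@entries
    for (h in Hs[-1L]) {
        if (!identical(dim(h@entries), dim(e)) ||
            !identical(h@classOrder, ref@classOrder))
            stop("partition matrices differ in shape or class order")
        e <- e * h@entries
    }
    methods::new("EquivalencePartitionMatrix", entries = e,
                 classOrder = ref@classOrder,
                 attributeSet = unique(unlist(lapply(Hs, methods::slot,
                                                     "attributeSet"))))
}

#' Confusion vector of a partition matrix
#'
#' Per-sample indicator of membership in an implicit hypercuboid (the
#' intersection of two or more class hypercuboids):
#' `v_j = min(1, sum_i h_ij - 1)`.  Samples with `v_j = 1` lie in the rough
#' boundary region; samples with `v_j = 0` are classified unambiguously.
#'
#' @param H an [EquivalencePartitionMatrix-class].
#' @return integer vector of length n with values in \{0, 1\}, named by
#'   sample when the matrix carries column names.
#' @export
confusionVector <- function(H) {
    stopifnot(methods::is(H, "EquivalencePartitionMatrix"))
    cs <- colSums(H@entries)
    if (any(cs == 0))
        stop("partition matrix has a column with no class membership; ",
             "confusion is only defined for training data")
    v <- as.integer(pmin(1L, cs - 1L))
    names(v) <- colnames(H@entries)
    v
}

# joint membership + confusion count for a set of row indices (internal)
.jointConfusionCount <- function(Hlist, idx) {
    H <- Hlist[[idx[1L]]]
    for (k in idx[-1L]) H <- H & Hlist[[k]]
    cs <- colSums(H)
    if (any(cs == 0))
        stop("sample outside every class hypercuboid; ",
             "dependency requires training-data columns")
    sum(cs >= 2L)
}

# per-feature logical membership matrices for all rows (internal cache)
.allH <- function(x) {
    vals <- exprValues(x)
    cl <- sampleClasses(x)
    lapply(seq_len(nrow(vals)), function(i) .Hlogical(vals[i, ], cl))
}

#' Dependency (relevance) of the class labels on an attribute set
#'
#' The fraction of samples outside every implicit hypercuboid:
#' `gamma_A(D) = 1 - mean(v)`, where `v` is the confusion vector of the joint
#' partition matrix of `A`.  `gamma = 1` means the class label is fully
#' determined by `A`; `gamma = 0` means every sample is ambiguous.  Adding an
#' attribute can never decrease dependency.
#'
#' @param x a [HEMExperiment-class] with at least two classes.
#' @param features feature ids or row indices (non-empty).
#' @return numeric scalar in [0, 1].
#' @examples
#' x <- HEMExperiment(rbind(a = c(1, 2, 3, 2.5, 4, 5)),
#'                    labels = rep(c("A", "B"), each = 3))
#' dependencyDegree(x, "a")  # 1 - 2/6
#' @export
dependencyDegree <- function(x, features) {
    if (nClasses(x) < 2L)
        stop("dependency requires at least 2 classes")
    idx <- .resolveFeatures(x, features)
    cnt <- .jointConfusionCount(.allH(x)[idx], seq_along(idx))
    1 - cnt / ncol(x)
}

#' Significance of an attribute within a set
#'
#' The drop in dependency when `feature` is removed from the set `features`:
#' `sigma_A(D, A_k) = gamma_A(D) - gamma_{A - {A_k}}(D)`.  Always
#' non-negative; exactly zero means `A_k` is dispensable within `A`.  The
#' difference is computed from integer confusion counts, so a zero is exact.
#'
#' @param x a [HEMExperiment-class] with at least two classes.
#' @param features the attribute set `A` (at least two features).
#' @param feature the member of `A` whose significance is measured.
#' @return numeric scalar `>= 0`.
#' @export
attributeSignificance <- function(x, features, feature) {
    if (nClasses(x) < 2L)
        stop("significance requires at least 2 classes")
    idx <- unique(.resolveFeatures(x, features))
    k <- .resolveFeatures(x, feature)
    if (length(k) != 1L) stop("'feature' must be a single feature")
    if (!k %in% idx)
        stop("'feature' must be a member of 'features'")
    if (length(idx) < 2L)
        stop("significance needs an attribute set of size >= 2")
    Hlist <- .allH(x)
    cntAll <- .jointConfusionCount(Hlist, idx)
    cntRest <- .jointConfusionCount(Hlist, setdiff(idx, k))
    n <- ncol(x)
    # evaluated as the dependency difference so the identity
    # sigma = gamma(A) - gamma(A \ {k}) holds bit-exactly; equal confusion
    # counts still give an exact zero
    (1 - cntAll / n) - (1 - cntRest / n)
}

#' Rough approximations of a class under one feature
#'
#' The lower approximation of class `beta_i` contains the samples that lie in
#' class `i`'s interval and in no implicit hypercuboid; the upper
#' approximation contains every sample in the interval; the boundary is their
#' difference.
#'
#' @inheritParams classIntervals
#' @param classId one of `classLevels(x)`.
#' @return list with character vectors `lower`, `upper`, `boundary` of sample
#'   ids.
#' @export
classApproximations <- function(x, feature, classId) {
    if (!classId %in% classLevels(x))
        stop("unknown class: ", classId)
    H <- partitionMatrix(x, feature)
    v <- confusionVector(H)
    h <- H@entries[match(classId, H@classOrder), ]
    ids <- colnames(x)
    list(lower = ids[h == 1L & v == 0L],
         upper = ids[h == 1L],
         boundary = ids[h == 1L & v == 1L])
}

setMethod("show", "EquivalencePartitionMatrix", function(object) {
    cat(sprintf("EquivalencePartitionMatrix: %d class(es) x %d sample(s) for {%s}\n",
                nrow(object@entries), ncol(object@entries),
                paste(object@attributeSet, collapse = ", ")))
    cat(sprintf("  confused samples (column sum >= 2): %d\n",
                sum(colSums(object@entries) >= 2L)))
})
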