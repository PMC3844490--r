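## B.632+ bootstrap evaluation around a pluggable selector + classifier.
## Feature selection is re-run inside every bootstrap resample, and the
## classifier sees only the selected rows; out-of-bag samples provide the
## leave-one-out bootstrap error B1.

#' Build a classifier from fit/predict functions
#'
#' @param fit function(values, labels) -> model, with `values` a
#'   feature-by-sample numeric matrix and `labels` a factor.
#' @param predict function(model, values) -> predicted labels.
#' @param description short label for printing.
#' @return a [Classifier-class].
#' @export
makeClassifier <- function(fit, predict, description = "custom classifier") {
    methods::new("Classifier", fitFun = fit, predictFun = predict,
                 description = description)
}

#' Linear support vector machine classifier
#'
#' The default evaluation classifier: a margin classifier with a linear
#' kernel (libsvm via \pkg{e1071}), cost `C`, no input scaling so that
#' constant selected features and repeated runs behave deterministically.
#'
#' @param cost regularization parameter (default 1).
#' @return a [Classifier-class].
#' @export
linearSVMClassifier <- function(cost = 1) {
    makeClassifier(
        fit = function(values, labels)
            e1071::svm(x = t(values), y = labels, kernel = "linear",
                       cost = cost, scale = FALSE),
        predict = function(model, values)
            as.character(stats::predict(model, newdata = t(values))),
        description = sprintf("linear SVM (cost = %g)", cost))
}

# fit on (dataset restricted to features), predict columns of newValues
.fitPredict <- function(classifier, trainValues, trainLabels, newValues) {
    model <- classifier@fitFun(trainValues, droplevels(trainLabels))
    as.character(classifier@predictFun(model, newValues))
}

#' Apparent (resubstitution) error
#'
#' Selects features on the full dataset, fits the classifier on the full
#' dataset restricted to the selected features, and reports the error on
#' those same samples.
#'
#' @param x a [HEMExperiment-class].
#' @param omega,d selector configuration, passed to [selectFeatures()].
#' @param classifier a [Classifier-class] (default [linearSVMClassifier()]).
#' @return numeric scalar in [0, 1].
#' @export
apparentError <- function(x, omega = 0.5, d = 50L,
                          classifier = linearSVMClassifier()) {
    sel <- selectFeatures(x, omega = omega, d = d)
    vals <- exprValues(x)[sel@selected, , drop = FALSE]
    pred <- .fitPredict(classifier, vals, sampleClasses(x), vals)
    mean(pred != as.character(sampleClasses(x)))
}

# resample n indices with replacement, redrawing until all classes appear
.classCompleteResample <- function(n, cl) {
    repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (nlevels(droplevels(cl[idx])) == nlevels(cl)) return(idx)
    }
}

#' Leave-one-out bootstrap error from indicator matrices
#'
#' Given `I[j, k] = 1` when sample `j` is out of bag for resample `k`, and
#' `Q[j, k] = 1` when it was then misclassified, returns the mean over
#' samples of the per-sample out-of-bag misclassification fraction.  Samples
#' never out of bag contribute a 0/0 term and are dropped from the outer
#' mean.
#'
#' @param I,Q binary n-by-M matrices; entries of `Q` where `I` is 0 are
#'   ignored.
#' @return numeric scalar in [0, 1].
#' @examples
#' I <- rbind(c(1, 1), c(1, 0), c(0, 1))
#' Q <- rbind(c(1, 0), c(0, 0), c(0, 1))
#' b1FromIndicators(I, Q)  # (0.5 + 0 + 1) / 3
#' @export
b1FromIndicators <- function(I, Q) {
    stopifnot(is.matrix(I), identical(dim(I), dim(Q)))
    oob <- rowSums(I)
    keep <- oob > 0
    if (!any(keep))
        stop("no sample was ever out of bag; increase the number of resamples")
    mean(rowSums(I * Q)[keep] / oob[keep])
}

#' Leave-one-out bootstrap error (B1)
#'
#' Draws `M` bootstrap resamples of size n (with replacement; resamples
#' missing an entire class are redrawn).  For each resample, features are
#' selected on the resample alone, the classifier is fitted on it, and the
#' out-of-bag samples are predicted.  The error is averaged per sample over
#' its out-of-bag predictions, then over samples ([b1FromIndicators()]).
#'
#' @inheritParams apparentError
#' @param M number of bootstrap resamples (default 50).
#' @param seed integer seed controlling the resampling.
#' @return numeric scalar in [0, 1].
#' @export
bootstrapB1 <- function(x, omega = 0.5, d = 50L, M = 50L, seed = 1L,
                        classifier = linearSVMClassifier()) {
    M <- as.integer(M)
    if (is.na(M) || M < 1L) stop("'M' must be a positive integer")
    n <- ncol(x)
    cl <- sampleClasses(x)
    vals <- exprValues(x)
    I <- matrix(0L, n, M)
    Q <- matrix(0L, n, M)
    withr_seed <- .withSeed(seed)
    on.exit(withr_seed())
    for (k in seq_len(M)) {
        idx <- .classCompleteResample(n, cl)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob) == 0L) next
        train <- x[, idx]
        sel <- selectFeatures(train, omega = omega, d = d)
        pred <- .fitPredict(classifier,
                            exprValues(train)[sel@selected, , drop = FALSE],
                            sampleClasses(train),
                            vals[sel@selected, oob, drop = FALSE])
        I[oob, k] <- 1L
        Q[oob, k] <- as.integer(pred != as.character(cl[oob]))
    }
    b1FromIndicators(I, Q)
}

# run expr under a temporary RNG state; returns a restore function
.withSeed <- function(seed) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    function() {
        if (is.null(old))
            rm(".Random.seed", envir = globalenv())
        else
            assign(".Random.seed", old, envir = globalenv())
    }
}

#' No-information error rate
#'
#' Estimates the error that would apply if labels were independent of the
#' expression values: the sample labels are randomly permuted (seeded),
#' feature selection and classifier training are run on the permuted-label
#' data, the trained rule predicts all original samples, and
#' `gamma = sum_i p_i (1 - q_i)` is computed from the true class proportions
#' `p_i` and the proportions `q_i` of samples the rule assigns to class `i`.
#'
#' @inheritParams bootstrapB1
#' @return numeric scalar in [0, 1].
#' @export
noInformationError <- function(x, omega = 0.5, d = 50L, seed = 1L,
                               classifier = linearSVMClassifier()) {
    restore <- .withSeed(seed)
    on.exit(restore())
    cl <- sampleClasses(x)
    perm <- sample.int(ncol(x))
    xPerm <- HEMExperiment(exprValues(x), labels = cl[perm],
                           featureIds = rownames(x), sampleIds = colnames(x))
    sel <- selectFeatures(xPerm, omega = omega, d = d)
    pred <- .fitPredict(classifier,
                        exprValues(xPerm)[sel@selected, , drop = FALSE],
                        sampleClasses(xPerm),
                        exprValues(x)[sel@selected, , drop = FALSE])
    p <- as.numeric(table(cl)) / ncol(x)
    q <- vapply(levels(cl), function(g) mean(pred == g), numeric(1))
    sum(p * (1 - q))
}

#' B.632+ combination of apparent and bootstrap errors
#'
#' Computes the relative overfitting rate `r = (B1' - AE) / (gamma - AE)`
#' with `B1' = min(B1, gamma)` and `r` set to 0 when `gamma <= AE`, clamped
#' to [0, 1]; the weight `omegaTilde = 0.632 / (1 - 0.368 r)`; and the
#' estimate `(1 - omegaTilde) AE + omegaTilde B1'`.
#'
#' @param AE,B1,gamma numeric scalars in [0, 1].
#' @return list with `r`, `omegaTilde`, `B632plus`.
#' @examples
#' b632plus(AE = 0, B1 = 0.2, gamma = 0.5)  # r = 0.4, estimate ~ 0.1482
#' @export
b632plus <- function(AE, B1, gamma) {
    for (z in list(AE = AE, B1 = B1, gamma = gamma))
        if (length(z) != 1L || !is.finite(z) || z < 0 || z > 1)
            stop("AE, B1 and gamma must be scalars in [0, 1]")
    B1p <- min(B1, gamma)
    r <- if (gamma > AE) (B1p - AE) / (gamma - AE) else 0
    r <- min(1, max(0, r))
    wt <- 0.632 / (1 - 0.368 * r)
    list(r = r, omegaTilde = wt,
         B632plus = (1 - wt) * AE + wt * B1p)
}

#' Gap estimate
#'
#' Difference between the no-information error and the bootstrap error,
#' `gamma - B1`.  Values near the no-information error's distance from
#' chance indicate genuine signal; negative values flag worse-than-chance
#' prediction.
#'
#' @param gamma,B1 numeric scalars in [0, 1].
#' @return numeric scalar in [-1, 1].
#' @export
gapEstimate <- function(gamma, B1) {
    stopifnot(gamma >= 0, gamma <= 1, B1 >= 0, B1 <= 1)
    gamma - B1
}

#' Full bootstrap error report for one configuration
#'
#' Convenience wrapper computing AE, B1 (seeded), the no-information error
#' (an independent seeded permutation), the B.632+ combination and the gap,
#' all with feature selection re-run where the procedure demands it.
#'
#' @inheritParams bootstrapB1
#' @return an [ErrorReport-class].
#' @export
errorReport <- function(x, omega = 0.5, d = 50L, M = 50L, seed = 1L,
                        classifier = linearSVMClassifier()) {
    AE <- apparentError(x, omega = omega, d = d, classifier = classifier)
    B1 <- bootstrapB1(x, omega = omega, d = d, M = M, seed = seed,
                      classifier = classifier)
    gamma <- noInformationError(x, omega = omega, d = d,
                                seed = as.integer(seed) + 1L,
                                classifier = classifier)
    bb <- b632plus(AE, B1, gamma)
    methods::new("ErrorReport", AE = AE, B1 = B1, gamma = gamma,
                 r = bb$r, omegaTilde = bb$omegaTilde,
                 B632plus = bb$B632plus, gap = gapEstimate(gamma, B1))
}

#' Error rates along the ranked feature list
#'
#' Evaluates the selector + classifier pipeline at every prefix size 1 ..
#' `dMax` of the ranked selection: apparent error from the full-data ranking,
#' B1 from per-resample rankings (each resample reuses its own ranking's
#' prefixes), the no-information error from one permuted-label ranking, and
#' the derived B.632+ and gap.  When a ranking is shorter than `dMax` (the
#' candidate pool can empty), its last prefix is reused for larger sizes.
#'
#' @inheritParams bootstrapB1
#' @param dMax largest prefix size to evaluate (`<= nrow(x)`).
#' @return data.frame with columns `d`, `AE`, `B1`, `gamma`, `B632plus`,
#'   `gap`, and attribute `minima`: the prefix size minimizing each error
#'   type (first minimum).
#' @export
errorCurve <- function(x, omega = 0.5, dMax = 10L, M = 50L, seed = 1L,
                       classifier = linearSVMClassifier()) {
    dMax <- as.integer(dMax)
    stopifnot(dMax >= 1L, dMax <= nrow(x))
    n <- ncol(x)
    cl <- sampleClasses(x)
    vals <- exprValues(x)
    clch <- as.character(cl)

    prefixError <- function(ranking, trainVals, trainLab, testVals, testLab, p) {
        feats <- ranking[seq_len(min(p, length(ranking)))]
        pred <- .fitPredict(classifier,
                            trainVals[feats, , drop = FALSE], trainLab,
                            testVals[feats, , drop = FALSE])
        pred != testLab
    }

    selFull <- selectFeatures(x, omega = omega, d = dMax)
    AE <- vapply(seq_len(dMax), function(p)
        mean(prefixError(selFull@selected, vals, cl, vals, clch, p)),
        numeric(1))

    restore <- .withSeed(seed)
    on.exit(restore())
    I <- array(0L, c(n, M))
    Qp <- array(0L, c(n, M, dMax))
    for (k in seq_len(M)) {
        idx <- .classCompleteResample(n, cl)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob) == 0L) next
        train <- x[, idx]
        sel <- selectFeatures(train, omega = omega, d = dMax)
        I[oob, k] <- 1L
        for (p in seq_len(dMax))
            Qp[oob, k, p] <- as.integer(
                prefixError(sel@selected, exprValues(train),
                            sampleClasses(train),
                            vals[, oob, drop = FALSE], clch[oob], p))
    }
    B1 <- vapply(seq_len(dMax), function(p) b1FromIndicators(I, Qp[, , p]),
                 numeric(1))

    perm <- sample.int(n)
    xPerm <- HEMExperiment(vals, labels = cl[perm],
                           featureIds = rownames(x), sampleIds = colnames(x))
    selPerm <- selectFeatures(xPerm, omega = omega, d = dMax)
    p_i <- as.numeric(table(cl)) / n
    gamma <- vapply(seq_len(dMax), function(p) {
        feats <- selPerm@selected[seq_len(min(p, length(selPerm@selected)))]
        pred <- .fitPredict(classifier,
                            vals[feats, , drop = FALSE], sampleClasses(xPerm),
                            vals[feats, , drop = FALSE])
        q <- vapply(levels(cl), function(g) mean(pred == g), numeric(1))
        sum(p_i * (1 - q))
    }, numeric(1))

    B632 <- mapply(function(a, b, g) b632plus(a, b, g)$B632plus, AE, B1, gamma)
    out <- data.frame(d = seq_len(dMax), AE = AE, B1 = B1, gamma = gamma,
                      B632plus = B632, gap = gamma - B1)
    attr(out, "minima") <- vapply(c("AE", "B1", "gamma", "B632plus"),
                                  function(colname) which.min(out[[colname]]),
                                  integer(1))
    out
}

setMethod("show", "ErrorReport", function(object) {
    cat("ErrorReport (B.632+ bootstrap)\n")
    cat(sprintf("  AE = %.4f  B1 = %.4f  gamma = %.4f\n",
                object@AE, object@B1, object@gamma))
    cat(sprintf("  r = %.4f  omegaTilde = %.4f  B.632+ = %.4f  gap = %.4f\n",
                object@r, object@omegaTilde, object@B632plus, object@gap))
})

setMethod("show", "Classifier", function(object) {
    cat("Classifier:", object@description, "\n")
})
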