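## Greedy relevance-significance selection and the coefficient-of-variation
## tuning of the relevance weight omega.
##
## The selector seeds with the most relevant feature, then repeatedly (a)
## discards any candidate whose significance with respect to some already
## selected feature is exactly zero (it is dispensable: permanently removed),
## and (b) admits the candidate maximizing
##     omega * gamma(A_j) + (1 - omega)/|S| * sum_{A_i in S} sigma_{A_i,A_j}(D, A_j).
## Ties are broken toward the lower input row index, both at seeding and at
## each admission, so results are reproducible and input-order permutations
## matter only within exact ties.  Significance is accumulated as integer
## confusion counts, so the zero test in (a) is exact.

#' Greedy objective for one candidate
#'
#' The score used at each admission step: `omega` times the candidate's own
#' relevance plus `1 - omega` times the mean of its significances with
#' respect to the already selected features.
#'
#' @param relevance numeric scalar, dependency of the candidate.
#' @param significances numeric vector, the candidate's significance versus
#'   each already-selected feature (non-empty).
#' @param omega numeric scalar in [0, 1].
#' @return numeric scalar.
#' @examples
#' candidateScore(0.8, 0.2, omega = 0.5)  # 0.5
#' @export
candidateScore <- function(relevance, significances, omega) {
    if (length(significances) < 1L)
        stop("'significances' must be non-empty (the selected set is never empty here)")
    stopifnot(length(omega) == 1L, omega >= 0, omega <= 1)
    omega * relevance + (1 - omega) * mean(significances)
}

#' Select relevant and significant features
#'
#' Runs the greedy forward search.  The first feature is the one with maximal
#' relevance (dependency of the labels on it alone).  Each subsequent step
#' first removes permanently every remaining candidate with exactly zero
#' significance with respect to any already-selected feature — such a
#' candidate adds nothing to that feature (exact duplicates are the
#' archetype) — and then admits the candidate with maximal weighted score
#' (see [candidateScore()]).  Selection stops when `d` features are selected
#' or no candidates remain; in the latter case fewer than `d` features are
#' returned.  Note that a feature with total dependency (`gamma = 1`) makes
#' every other feature dispensable, so selection stops right after it.
#'
#' @param x a [HEMExperiment-class] with at least two classes.
#' @param omega relevance weight in [0, 1]; 1 means pure relevance ranking
#'   (modulo the dispensability filter), 0 pure significance.
#' @param d target number of features (default 50, capped at `nrow(x)`).
#' @return a [SelectionResult-class].
#' @examples
#' x <- HEMExperiment(rbind(a = c(1, 2, 3, 2.5, 4, 5),
#'                          b = c(5, 4, 3.5, 1, 2, 3)),
#'                    labels = rep(c("A", "B"), each = 3))
#' selectFeatures(x, omega = 0.5, d = 2)
#' @export
selectFeatures <- function(x, omega = 0.5, d = 50L) {
    stopifnot(length(omega) == 1L, is.finite(omega), omega >= 0, omega <= 1)
    if (nClasses(x) < 2L)
        stop("feature selection requires at least 2 classes")
    d <- as.integer(d)
    if (is.na(d) || d < 1L) stop("'d' must be a positive integer")
    d <- min(d, nrow(x))
    n <- ncol(x)
    m <- nrow(x)
    ids <- rownames(x)

    Hlist <- .allH(x)
    conf <- vapply(Hlist, function(H) {
        cs <- colSums(H)
        if (any(cs == 0)) stop("sample outside every class hypercuboid")
        sum(cs >= 2L)
    }, numeric(1))
    gam <- 1 - conf / n

    seedIdx <- which.max(gam)              # ties: lowest input index
    selected <- seedIdx
    avail <- setdiff(seq_len(m), seedIdx)
    removed <- integer(0)
    # running sum of significance counts of each candidate vs selected set
    sigCountSum <- numeric(m)
    avgSig <- NA_real_
    objective <- NA_real_

    while (length(selected) < d && length(avail) > 0L) {
        s <- selected[length(selected)]     # newest selected feature
        keep <- logical(length(avail))
        for (t in seq_along(avail)) {
            j <- avail[t]
            jointCnt <- sum(colSums(Hlist[[s]] & Hlist[[j]]) >= 2L)
            dCnt <- conf[s] - jointCnt      # n * sigma_{As,Aj}(D, Aj), integer
            if (dCnt == 0) {                # dispensable w.r.t. As: drop
                removed <- c(removed, j)
            } else {
                sigCountSum[j] <- sigCountSum[j] + dCnt
                keep[t] <- TRUE
            }
        }
        avail <- avail[keep]
        if (length(avail) == 0L) break
        nsel <- length(selected)
        scores <- omega * gam[avail] +
            (1 - omega) * (sigCountSum[avail] / n) / nsel
        best <- avail[which.max(scores)]    # ties: lowest input index
        avgSig <- c(avgSig, (sigCountSum[best] / n) / nsel)
        objective <- c(objective, max(scores))
        selected <- c(selected, best)
        avail <- setdiff(avail, best)
    }

    methods::new("SelectionResult",
                 selected = ids[selected],
                 relevance = unname(gam[selected]),
                 avgSignificance = avgSig,
                 objective = objective,
                 removedDispensable = ids[removed],
                 omega = omega, d = d)
}

#' @describeIn selectFeatures selected feature ids, in order.
#' @param result a [SelectionResult-class].
#' @export
selectedFeatures <- function(result) result@selected

#' @describeIn selectFeatures feature ids removed as dispensable.
#' @export
removedDispensable <- function(result) result@removedDispensable

#' Average significance profile of a selection
#'
#' For each selected feature beyond the first, the mean significance versus
#' all features selected before it (`Omega_j`).  The first feature has no
#' earlier picks, so its value is undefined and excluded.
#'
#' @param result a [SelectionResult-class].
#' @return named numeric vector, one value per selected feature from the
#'   second on; empty when fewer than two features were selected.
#' @export
averageSignificanceProfile <- function(result) {
    if (length(result@selected) < 2L)
        return(setNames(numeric(0), character(0)))
    setNames(result@avgSignificance[-1L], result@selected[-1L])
}

#' Coefficient of variation of a significance profile
#'
#' The quotient of the population standard deviation (divisor = length) and
#' the mean of the average-significance values.  Low values indicate that
#' admitted features contribute evenly.
#'
#' @param profile numeric vector of average significances (non-empty, with
#'   positive mean).
#' @return numeric scalar `>= 0`.
#' @examples
#' cvIndex(c(0.1, 0.3))  # 0.5
#' @export
cvIndex <- function(profile) {
    if (length(profile) < 1L || anyNA(profile))
        stop("'profile' must be a non-empty numeric vector without NA")
    mu <- mean(profile)
    if (mu <= 0)
        stop("coefficient of variation undefined: profile mean is not positive")
    sqrt(mean((profile - mu)^2)) / mu
}

#' Argmin step of the omega tuning
#'
#' Given a coefficient-of-variation value per omega, returns the omega with
#' the smallest value; exact ties go to the smaller omega.
#'
#' @param omegas numeric vector of candidate weights.
#' @param cv numeric vector of the same length.
#' @return numeric scalar, the chosen omega.
#' @export
omegaArgmin <- function(omegas, cv) {
    stopifnot(length(omegas) == length(cv), length(omegas) >= 1L)
    o <- order(omegas)
    omegas <- omegas[o]; cv <- cv[o]
    omegas[which.min(cv)]
}

#' Tune the relevance weight by the coefficient-of-variation index
#'
#' Runs the selector once per grid value of omega, computes the coefficient
#' of variation of the resulting average-significance profile, and returns
#' the omega minimizing it (ties toward smaller omega).
#'
#' @inheritParams selectFeatures
#' @param omegaGrid numeric vector of weights to try (default 0, 0.1, ..., 1).
#' @return list with `omegaStar` (the argmin), `cv` (named numeric vector of
#'   the index per omega), and `results` (the [SelectionResult-class] per
#'   omega).
#' @export
optimizeOmega <- function(x, d = 50L, omegaGrid = seq(0, 1, by = 0.1)) {
    if (length(omegaGrid) < 1L) stop("'omegaGrid' must be non-empty")
    results <- lapply(omegaGrid, function(w) selectFeatures(x, omega = w, d = d))
    cv <- vapply(results, function(r) cvIndex(averageSignificanceProfile(r)),
                 numeric(1))
    names(cv) <- format(omegaGrid)
    names(results) <- format(omegaGrid)
    list(omegaStar = omegaArgmin(omegaGrid, cv), cv = cv, results = results)
}

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d feature(s) selected (omega = %g, d = %d)\n",
                length(object@selected), object@omega, object@d))
    k <- min(length(object@selected), 10L)
    df <- data.frame(rank = seq_len(k),
                     feature = object@selected[seq_len(k)],
                     relevance = signif(object@relevance[seq_len(k)], 4),
                     avgSignificance = signif(object@avgSignificance[seq_len(k)], 4))
    print(df, row.names = FALSE)
    if (length(object@selected) > k) cat("  ...\n")
    cat(sprintf("  removed as dispensable: %d feature(s)\n",
                length(object@removedDispensable)))
})
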