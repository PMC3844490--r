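## Seeded generator of expression fixtures with the structure the
## rough-hypercuboid method assumes: features whose per-class value ranges
## are disjoint (fully relevant), features with partially overlapping
## ranges, exact duplicates (redundant), and class-independent noise.
## Within-interval values are drawn uniformly, so the class value ranges --
## the only quantity the algebra uses -- are controlled directly.

#' Generate a synthetic labelled expression dataset
#'
#' Samples are balanced across `nClasses` classes (`nPerClass` each).
#' Feature blocks, in row order:
#' \describe{
#'   \item{separable}{class `i` values drawn uniformly from
#'     `[2(i-1), 2(i-1) + 1]` — disjoint ranges with gap 1, so the
#'     dependency of the labels on each such feature is exactly 1.}
#'   \item{overlap}{unit-length class intervals whose adjacent overlap is
#'     `overlapFraction` (0 = touching, 1 = identical), so dependency is
#'     below 1 with probability growing in n.}
#'   \item{duplicate}{exact value copies of the separable features, cycled;
#'     pairwise significance with their source is exactly 0.}
#'   \item{noise}{Gaussian with mean 0 and SD `noiseSd`, identical for all
#'     classes.}
#' }
#' The generator restores the caller's RNG state, and the same seed yields a
#' byte-identical dataset.
#'
#' @param nPerClass samples per class (default 20).
#' @param nClasses number of classes (default 2).
#' @param kSeparable,kOverlap,kDuplicate,kNoise block sizes (defaults 3, 0,
#'   2, 45; total must be >= 1; duplicates require `kSeparable >= 1`).
#' @param overlapFraction overlap of adjacent class intervals in [0, 1]
#'   (default 0.5).
#' @param noiseSd standard deviation of the noise block (default 1).
#' @param seed integer seed.
#' @return a [HEMExperiment-class]; `rowData` carries `role` (one of
#'   `separable`, `overlap`, `duplicate`, `noise`) and `sourceFeature` (the
#'   copied feature id, for duplicates).
#' @examples
#' x <- syntheticExpressionData(nPerClass = 5, kSeparable = 1, kNoise = 2,
#'                              kDuplicate = 0, seed = 7)
#' dependencyDegree(x, "sep1")  # 1 by construction
#' @export
syntheticExpressionData <- function(nPerClass = 20L, nClasses = 2L,
                                    kSeparable = 3L, kOverlap = 0L,
                                    kDuplicate = 2L, kNoise = 45L,
                                    overlapFraction = 0.5, noiseSd = 1,
                                    seed = 1L) {
    stopifnot(nPerClass >= 1L, nClasses >= 1L,
              kSeparable >= 0L, kOverlap >= 0L, kDuplicate >= 0L,
              kNoise >= 0L,
              overlapFraction >= 0, overlapFraction <= 1, noiseSd >= 0)
    m <- kSeparable + kOverlap + kDuplicate + kNoise
    if (m < 1L) stop("design has no features")
    if (kDuplicate > 0L && kSeparable < 1L)
        stop("duplicates need at least one separable source feature")
    n <- nPerClass * nClasses
    restore <- .withSeed(seed)
    on.exit(restore())

    cls <- rep(paste0("C", seq_len(nClasses)), each = nPerClass)
    classIdx <- rep(seq_len(nClasses), each = nPerClass)

    drawBlock <- function(k, starts, width) {
        # k features; class i uniform on [starts[i], starts[i] + width]
        if (k == 0L) return(NULL)
        t(vapply(seq_len(k),
                 function(i) starts[classIdx] + width * runif(n),
                 numeric(n)))
    }
    sep <- drawBlock(kSeparable, starts = 2 * (seq_len(nClasses) - 1), width = 1)
    ovl <- drawBlock(kOverlap,
                     starts = (seq_len(nClasses) - 1) * (1 - overlapFraction),
                     width = 1)
    dup <- if (kDuplicate > 0L)
        sep[((seq_len(kDuplicate) - 1L) %% kSeparable) + 1L, , drop = FALSE]
    else NULL
    noise <- if (kNoise > 0L)
        matrix(rnorm(kNoise * n, 0, noiseSd), nrow = kNoise)
    else NULL

    values <- rbind(sep, ovl, dup, noise)
    role <- rep(c("separable", "overlap", "duplicate", "noise"),
                c(kSeparable, kOverlap, kDuplicate, kNoise))
    ids <- c(if (kSeparable) paste0("sep", seq_len(kSeparable)),
             if (kOverlap) paste0("ovl", seq_len(kOverlap)),
             if (kDuplicate) paste0("dup", seq_len(kDuplicate)),
             if (kNoise) paste0("ns", seq_len(kNoise)))
    src <- rep(NA_character_, m)
    if (kDuplicate > 0L)
        src[role == "duplicate"] <-
            paste0("sep", ((seq_len(kDuplicate) - 1L) %% kSeparable) + 1L)

    x <- HEMExperiment(values, labels = cls, featureIds = ids,
                       sampleIds = paste0("S", seq_len(n)))
    SummarizedExperiment::rowData(x)$role <- role
    SummarizedExperiment::rowData(x)$sourceFeature <- src
    x
}
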