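test_that("B.632+ arithmetic: overfitting rate, weight, convex combination", {
    res <- b632plus(AE = 0, B1 = 0.2, gamma = 0.5)
    expect_equal(res$r, 0.4)
    expect_equal(res$omegaTilde, 0.632 / (1 - 0.368 * 0.4))
    expect_equal(res$B632plus, res$omegaTilde * 0.2, tolerance = 1e-12)
    expect_equal(res$B632plus, 0.1482, tolerance = 1e-3)

    noOverfit <- b632plus(AE = 0.1, B1 = 0.1, gamma = 0.4)
    expect_equal(noOverfit$r, 0)
    expect_equal(noOverfit$omegaTilde, 0.632)
    expect_equal(noOverfit$B632plus, 0.1)

    clamped <- b632plus(AE = 0.05, B1 = 0.6, gamma = 0.4)
    expect_equal(clamped$r, 1)
    expect_equal(clamped$omegaTilde, 1)
    expect_equal(clamped$B632plus, 0.4)   # equals gamma in the clamped limit

    degenerate <- b632plus(AE = 0.5, B1 = 0.2, gamma = 0.3)  # gamma <= AE
    expect_equal(degenerate$r, 0)
    expect_error(b632plus(AE = -0.1, B1 = 0.2, gamma = 0.5), "\\[0, 1\\]")

    # convexity and weight range over a grid of valid inputs
    for (AE in c(0, 0.2, 0.5)) for (B1 in c(0, 0.3, 0.9))
        for (g in c(0.1, 0.5, 0.9)) {
            z <- b632plus(AE, B1, g)
            B1p <- min(B1, g)
            expect_gte(z$omegaTilde, 0.632); expect_lte(z$omegaTilde, 1)
            expect_gte(z$r, 0); expect_lte(z$r, 1)
            expect_gte(z$B632plus, min(AE, B1p) - 1e-12)
            expect_lte(z$B632plus, max(AE, B1p) + 1e-12)
        }
})

test_that("gap estimate is the no-information minus bootstrap error", {
    expect_equal(gapEstimate(0.5, 0.2), 0.3)
    expect_equal(gapEstimate(0.4, 0.4), 0)
    expect_equal(gapEstimate(0.4, 0.5), -0.1)
})

test_that("B1 from indicators averages per-sample out-of-bag error", {
    I <- rbind(c(1, 1), c(1, 0), c(0, 1))
    Q <- rbind(c(1, 0), c(0, 0), c(0, 1))
    expect_equal(b1FromIndicators(I, Q), 0.5)
    expect_equal(b1FromIndicators(I, matrix(0L, 3, 2)), 0)
    # M = 1, single out-of-bag sample misclassified
    expect_equal(b1FromIndicators(matrix(c(1, 0, 0)), matrix(c(1, 0, 0))), 1)
    # never-out-of-bag samples are excluded from the outer mean
    expect_equal(b1FromIndicators(rbind(c(0, 0), c(1, 1)),
                                  rbind(c(0, 0), c(1, 0))), 0.5)
    expect_error(b1FromIndicators(matrix(0L, 2, 2), matrix(0L, 2, 2)),
                 "out of bag")

    # brute-force oracle: explicit double loop over samples and resamples
    set.seed(4)
    for (rep in 1:20) {
        n <- sample(3:10, 1); M <- sample(1:5, 1)
        I <- matrix(rbinom(n * M, 1, 0.6), n, M)
        if (all(rowSums(I) == 0)) I[1, 1] <- 1L
        Q <- matrix(rbinom(n * M, 1, 0.4), n, M) * I
        perSample <- numeric(0)
        for (j in seq_len(n)) {
            si <- 0; sq <- 0
            for (k in seq_len(M)) {
                si <- si + I[j, k]
                sq <- sq + I[j, k] * Q[j, k]
            }
            if (si > 0) perSample <- c(perSample, sq / si)
        }
        expect_identical(b1FromIndicators(I, Q), mean(perSample))
    }
})

test_that("apparent error is the resubstitution misclassification fraction", {
    sep <- syntheticExpressionData(nPerClass = 10, kSeparable = 2,
                                   kDuplicate = 0, kNoise = 3, seed = 5)
    expect_equal(apparentError(sep, omega = 0.5, d = 2), 0)

    x <- syntheticExpressionData(nPerClass = 5, kSeparable = 1,
                                 kDuplicate = 0, kNoise = 1, seed = 6)
    expect_equal(apparentError(x, d = 1, classifier = constantClassifier("C1")),
                 0.5)
    wrongOne <- c(rep("C1", 4), "C2", rep("C2", 5))  # one C1 sample flipped
    expect_equal(apparentError(x, d = 1,
                               classifier = fixedPredictionClassifier(wrongOne)),
                 0.1)
})

test_that("no-information error follows sum p_i (1 - q_i)", {
    x <- syntheticExpressionData(nPerClass = 5, kSeparable = 1,
                                 kDuplicate = 0, kNoise = 1, seed = 7)
    expect_equal(noInformationError(x, d = 1, seed = 1,
                                    classifier = constantClassifier("C1")),
                 0.5)

    y <- HEMExperiment(rbind(f = c(1, 2, 3, 4, 5, 6, 7, 8)),
                       labels = c(rep("C1", 6), rep("C2", 2)))
    # rule assigns 6 of 8 samples to C1: p = q = (0.75, 0.25)
    cls <- fixedPredictionClassifier(c(rep("C1", 6), rep("C2", 2)))
    expect_equal(noInformationError(y, d = 1, seed = 3, classifier = cls),
                 0.375)
})

test_that("bootstrap B1 is exact for constant rules and zero on separable data", {
    x <- syntheticExpressionData(nPerClass = 10, kSeparable = 1,
                                 kDuplicate = 0, kNoise = 2, seed = 8)
    # constant rule errs exactly on the other class, for every o.o.b. event
    expect_equal(bootstrapB1(x, d = 1, M = 20, seed = 11,
                             classifier = constantClassifier("C1")),
                 0.5)
    expect_equal(bootstrapB1(x, omega = 0.5, d = 1, M = 5, seed = 11), 0)
})

test_that("the harness is reproducible under a fixed seed", {
    x <- syntheticExpressionData(nPerClass = 8, kSeparable = 0, kOverlap = 3,
                                 kDuplicate = 0, kNoise = 3,
                                 overlapFraction = 0.7, seed = 12)
    r1 <- errorReport(x, omega = 0.5, d = 2, M = 5, seed = 42)
    r2 <- errorReport(x, omega = 0.5, d = 2, M = 5, seed = 42)
    for (s in c("AE", "B1", "gamma", "r", "omegaTilde", "B632plus", "gap"))
        expect_identical(slot(r1, s), slot(r2, s))
    expect_equal(r1@B632plus,
                 (1 - r1@omegaTilde) * r1@AE +
                     r1@omegaTilde * min(r1@B1, r1@gamma))
    expect_equal(r1@gap, r1@gamma - r1@B1)
})

test_that("error curve prefixes agree with direct evaluation", {
    x <- syntheticExpressionData(nPerClass = 10, kSeparable = 0, kOverlap = 4,
                                 kDuplicate = 0, kNoise = 2,
                                 overlapFraction = 0.5, seed = 13)
    curve <- errorCurve(x, omega = 0.5, dMax = 2, M = 5, seed = 99)
    expect_identical(curve$d, 1:2)
    expect_equal(curve$AE[2], apparentError(x, omega = 0.5, d = 2))
    expect_equal(curve$B1[2], bootstrapB1(x, omega = 0.5, d = 2, M = 5,
                                          seed = 99))
    expect_equal(curve$B632plus,
                 mapply(function(a, b, g) b632plus(a, b, g)$B632plus,
                        curve$AE, curve$B1, curve$gamma))
    expect_equal(curve$gap, curve$gamma - curve$B1)
    expect_named(attr(curve, "minima"), c("AE", "B1", "gamma", "B632plus"))

    single <- errorCurve(x, omega = 0.5, dMax = 1, M = 5, seed = 99)
    expect_equal(single$AE, apparentError(x, omega = 0.5, d = 1))
    expect_equal(single$B1, bootstrapB1(x, omega = 0.5, d = 1, M = 5,
                                        seed = 99))
})

test_that("separable markers keep the apparent-error minimizing prefix short", {
    x <- syntheticExpressionData(nPerClass = 10, kSeparable = 2,
                                 kDuplicate = 0, kNoise = 8, seed = 14)
    curve <- errorCurve(x, omega = 0.5, dMax = 3, M = 3, seed = 5)
    expect_lte(attr(curve, "minima")[["AE"]], 2)
    expect_equal(curve$AE[1], 0)
})
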