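# Independent brute-force oracles: explicit per-sample / per-class loops,
# no shared code with the package's vectorized paths.

oracleH <- function(v, labels) {
    lev <- levels(factor(labels, levels = unique(labels)))
    H <- matrix(0L, length(lev), length(v))
    for (i in seq_along(lev)) {
        lo <- Inf; hi <- -Inf
        for (j in seq_along(v)) {
            if (labels[j] == lev[i]) {
                if (v[j] < lo) lo <- v[j]
                if (v[j] > hi) hi <- v[j]
            }
        }
        for (j in seq_along(v))
            if (v[j] >= lo && v[j] <= hi) H[i, j] <- 1L
    }
    rownames(H) <- lev
    H
}

oracleAnd <- function(Hs) {
    H <- Hs[[1L]]
    if (length(Hs) > 1L)
        for (k in 2:length(Hs))
            for (i in seq_len(nrow(H)))
                for (j in seq_len(ncol(H)))
                    H[i, j] <- if (H[i, j] == 1L && Hs[[k]][i, j] == 1L) 1L else 0L
    H
}

oracleV <- function(H) {
    v <- integer(ncol(H))
    for (j in seq_len(ncol(H))) {
        s <- 0L
        for (i in seq_len(nrow(H))) s <- s + H[i, j]
        v[j] <- min(1L, s - 1L)
    }
    v
}

oracleGamma <- function(values, labels, rows) {
    Hs <- lapply(rows, function(r) oracleH(values[r, ], labels))
    v <- oracleV(oracleAnd(Hs))
    1 - sum(v) / ncol(values)
}

oracleSigma <- function(values, labels, rows, removed) {
    oracleGamma(values, labels, rows) -
        oracleGamma(values, labels, setdiff(rows, removed))
}

# small random dataset with ties and occasional duplicate rows
randomSmallDataset <- function(seed) {
    set.seed(seed)
    n <- sample(4:12, 1)
    m <- sample(2:4, 1)
    c <- sample(2:3, 1)
    labels <- character(0)
    while (length(unique(labels)) < c)
        labels <- sample(paste0("K", seq_len(c)), n, replace = TRUE)
    values <- matrix(sample(0:5, m * n, replace = TRUE) +
                         round(runif(m * n), 1), m, n)
    if (m >= 2 && runif(1) < 0.3) values[m, ] <- values[1L, ]  # duplicate row
    list(values = values, labels = labels,
         x = HEMExperiment(values, labels))
}

# fixed six-sample overlap example reused across tests
overlapPairExperiment <- function() {
    HEMExperiment(rbind(a = c(1, 2, 3, 2.5, 4, 5),
                        b = c(5, 4, 3.5, 1, 2, 3)),
                  labels = rep(c("A", "B"), each = 3))
}

# classifier stubs (deterministic)
constantClassifier <- function(label) {
    makeClassifier(fit = function(values, labels) label,
                   predict = function(model, values)
                       rep(model, ncol(values)),
                   description = paste("always", label))
}

fixedPredictionClassifier <- function(labels) {
    makeClassifier(fit = function(values, lab) labels,
                   predict = function(model, values)
                       model[seq_len(ncol(values))],
                   description = "fixed predictions")
}
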