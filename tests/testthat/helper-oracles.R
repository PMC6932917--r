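# Independent oracles used across the suite. Each one recomputes a
# quantity by a route different from the implementation under test.

# Upper-tail hypergeometric probability by exhaustive enumeration of
# all n-subsets of an N-element universe whose first K elements are
# the target set.
enumUpperTail <- function(k, n, K, N) {
    if (n == 0L)
        return(as.numeric(k <= 0))
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)
    mean(hits >= k)
}

# Venn partition by per-gene membership bitmask grouping.
bitmaskPartition <- function(sets) {
    lv <- names(sets)
    genes <- unique(unlist(sets, use.names = FALSE))
    key <- vapply(genes, function(g)
        paste(lv[vapply(sets, function(s) g %in% s, TRUE)],
              collapse = " & "), "")
    lapply(split(genes, key), sort)
}

# Full-rank cross-modal cosine via the eigendecomposition of W W'
# (never via svd): cos(t, g) = (U D^2 V')[t, g] / sqrt((WW')_tt (W'W)_gg)
# and U D^2 V' = (W W')^{1/2} W.
eigenCosOracle <- function(W) {
    WWt <- W %*% t(W)
    E <- eigen(WWt, symmetric = TRUE)
    sqrtWWt <- E$vectors %*% (sqrt(pmax(E$values, 0)) * t(E$vectors))
    S <- sqrtWWt %*% W
    tn <- sqrt(diag(WWt))
    gn <- sqrt(diag(t(W) %*% W))
    S / outer(tn, gn)
}

# Equal-variance two-sample t statistic and two-sided p by the
# textbook pooled-variance formula.
textbookT <- function(x, y) {
    n1 <- length(x)
    n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    list(statistic = t, p.value = 2 * pt(-abs(t), df))
}

# Shared fixture: a small deterministic hub collection over an
# explicit universe.
toyHubs <- function() {
    GeneSetCollection(
        list(H1 = c("A", "B", "C", "D", "E"),
             H2 = c("F", "G", "H", "I"),
             H3 = c("A", "F", "J")),
        universe = LETTERS[1:10])
}

# Shared fixture: a tiny planted corpus plus its fitted full-rank
# model, small enough for fast unit tests.
toyPlantedModel <- function(planted, seed = 1, nGenes = 60,
                            vocabSize = 600, ...) {
    g <- generateCorpus(nGenes = nGenes, vocabSize = vocabSize,
                        planted = planted, seed = seed, ...)
    w <- weightMatrix(buildGeneDocuments(g$corpus))
    list(model = fitLsi(w, min(dim(w))), truth = g$truth)
}
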