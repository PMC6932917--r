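test_that("gene pseudo-documents sum token counts over tagged docs", {
    cp <- Corpus(list(
        list(doc_id = "d1", genes = "GA", tokens = c("aa", "aa", "bb")),
        list(doc_id = "d2", genes = c("GA", "GB"), tokens = c("bb", "cc")),
        list(doc_id = "d3", genes = character(0), tokens = "zz")))
    m <- buildGeneDocuments(cp)
    expect_identical(m["aa", "GA"], 2L)
    expect_identical(m["bb", "GA"], 2L)
    # a doc tagged with two genes contributes fully to both
    expect_identical(m["bb", "GB"], 1L)
    expect_identical(m["cc", "GB"], 1L)
    # untagged docs are excluded entirely
    expect_false("zz" %in% rownames(m))

    # conservation: column sums equal total token counts of the
    # contributing documents (single-tag corpus)
    g <- generateCorpus(nGenes = 6, vocabSize = 80, nDocsPerGene = 4,
                        seed = 3)
    counts <- buildGeneDocuments(g$corpus)
    perGene <- vapply(corpusDocs(g$corpus), function(d)
        length(d$tokens), 0L)
    expect_identical(unname(colSums(counts)),
                     as.numeric(tapply(perGene,
                         vapply(corpusDocs(g$corpus), `[[`, "", "genes"),
                         sum)[colnames(counts)]))

    expect_error(buildGeneDocuments(Corpus(list(
        list(doc_id = "d", genes = character(0), tokens = "a")))),
        "no gene-tagged")
})

test_that("log-entropy and tfidf weights match hand-computed values", {
    C <- matrix(c(2, 0, 1, 0, 3, 0, 1, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("t1", "t2", "t3"), c("g1", "g2", "g3")))
    w <- weightMatrix(C, "log_entropy")
    # uniform term t3 carries no information and is removed
    expect_identical(rownames(w), c("t1", "t2"))
    expect_equal(unname(w["t1", ]),
                 c(0.462098120373, 0, 0.291551453213), tolerance = 1e-9)
    # single-column term has global weight 1
    expect_equal(unname(w["t2", ]), c(0, 1.38629436112, 0),
                 tolerance = 1e-9)

    tf <- weightMatrix(C, "tfidf")
    expect_equal(unname(tf["t1", ]), c(2.5753641449, 0, 1.28768207245),
                 tolerance = 1e-9)
    expect_equal(unname(tf["t3", ]), c(1, 1, 1), tolerance = 1e-12)

    expect_error(weightMatrix(C, "boom"))
    expect_error(weightMatrix(matrix(0, 2, 2,
        dimnames = list(c("a", "b"), c("x", "y")))), "zero")
})

test_that("the truncated SVD factorization matches a dense oracle", {
    W <- withSeed(5, matrix(rnorm(12), 4, 3,
                            dimnames = list(paste0("t", 1:4),
                                            paste0("g", 1:3))))
    m <- fitLsi(W, 2)
    sv <- svd(W)
    expect_equal(singularValues(m), sv$d[1:2], tolerance = 1e-8)
    # rank-2 reconstruction from the scaled factors:
    # (U D)(V D)' = U D^2 V', compare against the dense oracle
    recon <- termVectors(m) %*% t(geneVectors(m))
    oracle <- sv$u[, 1:2] %*% diag(sv$d[1:2]^2) %*% t(sv$v[, 1:2])
    expect_equal(recon, oracle, tolerance = 1e-8, ignore_attr = TRUE)
    expect_false(is.unsorted(rev(singularValues(m))))
    expect_error(fitLsi(W, 4), "exceeds")
})

test_that("reconstruction error is non-increasing in the rank", {
    W <- withSeed(8, matrix(abs(rnorm(30 * 20)), 30, 20,
                            dimnames = list(sprintf("t%02d", 1:30),
                                            sprintf("g%02d", 1:20))))
    errs <- vapply(1:20, function(k) {
        m <- fitLsi(W, k)
        # unscale: U_k D_k V_k' approximates W itself
        U <- termVectors(m) / rep(singularValues(m),
                                  each = nrow(termVectors(m)))
        sqrt(sum((W - U %*% t(geneVectors(m)))^2))
    }, 0)
    expect_true(all(diff(errs) <= 1e-8))
    expect_lt(errs[20], 1e-8)
})

test_that("full-rank concept-space cosines equal the eigen oracle", {
    W <- withSeed(13, matrix(abs(rnorm(30 * 20)), 30, 20,
                             dimnames = list(sprintf("t%02d", 1:30),
                                             sprintf("g%02d", 1:20))))
    m <- fitLsi(W, 20)
    oracle <- eigenCosOracle(W)
    got <- vapply(rownames(W), function(t) queryCosine(m, t),
                  numeric(20))
    expect_equal(t(got), oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cosine interrogation recovers planted associations", {
    planted <- data.frame(gene = c("PGA", "PGB"),
                          term = c("senescence", "glycolysis"))
    fix <- toyPlantedModel(planted, seed = 2, coOccurrenceProb = 1,
                           backgroundTermProb = 0)
    sc <- queryCosine(fix$model, "senescence")
    expect_gt(sc[["PGA"]], 0.9)
    expect_lt(max(sc[setdiff(names(sc), "PGA")]), 0.1)

    expect_error(queryCosine(fix$model, "quux"), "unknown term")
    expect_warning(sc2 <- queryCosine(fix$model, "senescence quux"),
                   "out-of-vocabulary")
    expect_equal(sc2, sc, tolerance = 1e-12)
})

test_that("association classes follow the explicit/implicit convention", {
    expect_identical(classifyAssociation(c(0.25, 0.15, 0.05)),
                     c("explicit", "implicit", "none"))
    # boundaries are implicit: "larger than 0.2" is explicit
    expect_identical(classifyAssociation(c(0.2, 0.1)),
                     c("implicit", "implicit"))
    th <- associationThresholds(0.3, 0.6)
    expect_identical(classifyAssociation(0.5, th), "implicit")
    expect_error(associationThresholds(0.5, 0.2), "implicitCutoff")
    expect_error(classifyAssociation(1.5), "lie in")
})

test_that("interrogation and theoretical intersections recover planted sets", {
    planted <- data.frame(
        gene = c("PGA", "PGB", "PGC", "PGB", "PGC", "PGD"),
        term = c("signaling", "signaling", "signaling",
                 "adhesion", "adhesion", "adhesion"))
    fix <- toyPlantedModel(planted, seed = 6, coOccurrenceProb = 1,
                           backgroundTermProb = 0)
    sig <- interrogate(fix$model, "signaling")
    expect_identical(as.character(sig), c("PGA", "PGB", "PGC"))
    adh <- interrogate(fix$model, "adhesion")
    expect_identical(as.character(adh), c("PGB", "PGC", "PGD"))
    both <- theoreticalDataset(fix$model, "signaling", "adhesion")
    expect_identical(both, c("PGB", "PGC"))
    expect_true(all(both %in% sig) && all(both %in% adh))
})

test_that("frequency counting respects stop words, ties and bigrams", {
    expect_identical(countFrequencies(c("dna", "repair", "dna")),
                     data.frame(item = c("dna", "repair"),
                                count = c(2L, 1L)))
    expect_identical(
        countFrequencies(c("dna", "repair", "dna"),
                         mode = "bigram_phrase"),
        data.frame(item = c("dna repair", "repair dna"),
                   count = c(1L, 1L)))
    # stop words removed before counting; ties lexicographic
    out <- countFrequencies(c("the", "cell", "cycle", "the"))
    expect_identical(out$item, c("cell", "cycle"))
    expect_identical(countFrequencies(character(0))$item, character(0))
    top <- countFrequencies(c("aa", "bb", "aa", "cc"), topN = 2)
    expect_identical(top$item, c("aa", "bb"))

    # conservation on a random stream
    toks <- withSeed(3, sample(sprintf("w%02d", 1:20), 500, TRUE))
    expect_lte(sum(countFrequencies(toks)$count), length(toks))
    expect_identical(sum(countFrequencies(toks,
                                          stopWords = character(0))$count),
                     length(toks))
})
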