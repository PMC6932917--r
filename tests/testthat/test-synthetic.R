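test_that("quant generator plants recoverable significance and is deterministic", {
    g0 <- generateQuantTable(nProteins = 30, levels = c("L1", "L2"),
                             fracSignificantPerLevel = 0,
                             fracSharedAllLevels = 0, seed = 1)
    expect_true(all(lengths(g0$truth) == 0))

    g1 <- generateQuantTable(nProteins = 200, seed = 42)
    g2 <- generateQuantTable(nProteins = 200, seed = 42)
    expect_identical(quantData(g1$table), quantData(g2$table))
    g3 <- generateQuantTable(nProteins = 200, seed = 43)
    expect_false(identical(quantData(g1$table), quantData(g3$table)))

    expect_error(generateQuantTable(fracSignificantPerLevel = 0.1,
                                    fracSharedAllLevels = 0.2),
                 "must not exceed")
})

test_that("hub generator honors the default curated cardinalities", {
    hubs <- generateHubCollection(seed = 7)
    sz <- lengths(geneSets(hubs))
    expect_identical(sz[["MDC1"]], 198L)
    expect_identical(sz[["BRCA1"]], 301L)
    expect_identical(sz[["SIRT1"]], 251L)
    expect_identical(unname(sz),
                     c(299L, 251L, 294L, 283L, 300L, 299L, 198L, 300L, 301L))
    expect_length(universe(hubs), 20000)

    tiny <- generateHubCollection(hubSizes = c(ALL = 30),
                                  universeSize = 30, seed = 1)
    expect_setequal(geneSets(tiny)$ALL, universe(tiny))
})

test_that("overlap of independently sampled hubs matches K1*K2/N in expectation", {
    # closed-form expectation check over 150 seeds on a small universe
    N <- 500; K1 <- 60; K2 <- 80
    ov <- vapply(1:150, function(s) {
        h <- generateHubCollection(hubSizes = c(A = K1, B = K2),
                                   universeSize = N, seed = s)
        length(intersect(geneSets(h)$A, geneSets(h)$B))
    }, 0L)
    expected <- K1 * K2 / N
    se <- sd(ov) / sqrt(length(ov))
    expect_lt(abs(mean(ov) - expected), 3 * se + 1e-9)
})

test_that("interactome pairs carry exact planted overlaps across seeds", {
    hubs <- generateHubCollection(seed = 1)
    aging <- GeneSetCollection(
        c(geneSets(hubs),
          list(AGING = sort(sample_aging <- universe(hubs)[1:300]))),
        universe = universe(hubs))
    memberships <- lapply(1:50, function(s) {
        pair <- generateInteractomePair(collection = aging,
                                        stressOverlaps = c(AGING = 64),
                                        seed = s)
        expect_length(pair$control, 47)
        expect_length(pair$stress, 268)
        expect_length(intersect(pair$stress, geneSets(aging)$AGING), 64)
        expect_length(intersect(pair$control, geneSets(aging)$AGING), 0)
        pair$stress
    })
    expect_gt(length(unique(memberships)), 1)

    zeroes <- stats::setNames(rep(0L, 9), names(geneSets(hubs)))
    # hub sets overlap each other here, so plant against one only
    z <- generateInteractomePair(collection = hubs,
                                 stressOverlaps = zeroes["BRCA1"],
                                 controlOverlaps = zeroes["BRCA1"],
                                 seed = 3)
    expect_length(intersect(z$stress, geneSets(hubs)$BRCA1), 0)
    expect_length(intersect(z$control, geneSets(hubs)$BRCA1), 0)

    expect_error(generateInteractomePair(
        collection = hubs, stressOverlaps = c(BRCA1 = 400), seed = 1),
        "exceed")
})

test_that("planting into overlapping targets is rejected", {
    gsc <- GeneSetCollection(list(T1 = c("A", "B"), T2 = c("B", "C")),
                             universe = LETTERS)
    expect_error(generateInteractomePair(
        controlSize = 2, stressSize = 2, collection = gsc,
        stressOverlaps = c(T1 = 1, T2 = 1), seed = 1),
        "disjoint")
})

test_that("corpus generator plants deterministic co-occurrence structure", {
    planted <- data.frame(gene = "PG1", term = "repairterm")
    g <- generateCorpus(nGenes = 4, vocabSize = 40, nDocsPerGene = 5,
                        planted = planted, coOccurrenceProb = 1,
                        backgroundTermProb = 0, docLength = 5,
                        plantedMentions = 1, seed = 9)
    for (d in corpusDocs(g$corpus)) {
        n <- sum(d$tokens == "repairterm")
        expect_identical(n, if (d$genes == "PG1") 1L else 0L)
    }

    a <- generateCorpus(nGenes = 5, vocabSize = 50, nDocsPerGene = 3,
                        seed = 4)
    b <- generateCorpus(nGenes = 5, vocabSize = 50, nDocsPerGene = 3,
                        seed = 4)
    expect_identical(corpusDocs(a$corpus), corpusDocs(b$corpus))

    expect_error(generateCorpus(vocabSize = 1, planted = data.frame(
        gene = c("A", "B"), term = c("t1", "t2"))), "too small")
})

test_that("random gene sets are size-matched, reproducible and well mixed", {
    uni <- sprintf("U%03d", 1:100)
    full <- generateRandomGeneSets(100, 2, uni, seed = 1)
    expect_true(all(vapply(full, setequal, TRUE, uni)))

    three <- generateRandomGeneSets(47, 3, syntheticUniverse(20000),
                                    seed = 2)
    expect_length(unique(three), 3)
    expect_true(all(lengths(three) == 47))
    expect_identical(generateRandomGeneSets(47, 3, syntheticUniverse(20000),
                                            seed = 2), three)

    # closed-form hypergeometric mean of the overlap with a K-target
    target <- uni[1:20]
    sets <- generateRandomGeneSets(10, 2000, uni, seed = 3)
    ov <- vapply(sets, function(s) length(intersect(s, target)), 0L)
    expected <- 10 * 20 / 100
    se <- sd(ov) / sqrt(length(ov))
    expect_lt(abs(mean(ov) - expected), 3 * se)

    expect_error(generateRandomGeneSets(101, 1, uni), "exceeds")
})

test_that("constellation sets honor exact totals, uniques and core", {
    tot <- c(A = 20, B = 36, C = 28)
    uq <- c(A = 5, B = 12, C = 7)
    s <- generateConstellationSets(tot, uq, 4)
    expect_identical(lengths(s), c(A = 20L, B = 36L, C = 28L))
    p <- vennPartition(s)
    expect_length(commonCore(p), 4)
    cells <- partitionCells(p)
    expect_equal(vapply(names(tot), function(l)
        length(cells[[l]]), 0L, USE.NAMES = FALSE), unname(uq))

    expect_error(generateConstellationSets(c(A = 3, B = 3),
                                           c(A = 4, B = 1), 0),
                 "too small")
    # odd shared remainder with only 3 levels cannot be partitioned
    # without corrupting the core
    expect_error(generateConstellationSets(c(A = 20, B = 35, C = 28),
                                           c(A = 5, B = 12, C = 7), 4),
                 "no feasible partition")
})
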