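# Shared fixture: aging terms planted for a block of profile genes,
# non-aging terms planted for other genes, small corpus scale.
agingFixture <- function(seed) {
    agingGenes <- sprintf("AG%02d", 1:10)
    otherGenes <- sprintf("OG%02d", 1:10)
    aging <- c("neurodegeneration", "senescence", "dementia")
    nonAging <- c("asthma", "achondroplasia", "tuberculosis")
    planted <- rbind(
        expand.grid(gene = agingGenes, term = aging,
                    stringsAsFactors = FALSE),
        expand.grid(gene = otherGenes, term = nonAging,
                    stringsAsFactors = FALSE))
    fix <- toyPlantedModel(planted, seed = seed)
    list(model = fix$model, agingGenes = agingGenes,
         groups = list(aging = aging, nonaging = nonAging))
}

test_that("cosine profiles are consistent with single queries and stable", {
    fx <- agingFixture(1)
    prof <- cosineProfile(fx$model, fx$agingGenes, fx$groups)
    expect_identical(dim(profileScores(prof)), c(10L, 6L))
    one <- cosineProfile(fx$model, fx$agingGenes[1],
                         list(g = "senescence"))
    expect_equal(profileScores(one)[1, 1],
                 queryCosine(fx$model, "senescence")[[fx$agingGenes[1]]],
                 tolerance = 1e-12)

    # permuting interrogator groups permutes columns only
    prof2 <- cosineProfile(fx$model, fx$agingGenes, rev(fx$groups))
    expect_equal(profileScores(prof2)[, colnames(profileScores(prof))],
                 profileScores(prof), tolerance = 1e-12)

    expect_error(cosineProfile(fx$model, character(0), fx$groups),
                 "empty gene list")
})

test_that("group means separate planted from unplanted concept panels", {
    fx <- agingFixture(2)
    prof <- cosineProfile(fx$model, fx$agingGenes, fx$groups)
    gm <- groupMeanScores(prof)
    expect_identical(colnames(gm$geneMeans), c("aging", "nonaging"))
    expect_gt(gm$grandMeans[["aging"]], gm$grandMeans[["nonaging"]])

    # single-term group mean is the score itself; constant scores
    # give constant means
    one <- cosineProfile(fx$model, fx$agingGenes,
                         list(g1 = "senescence", g2 = "dementia"))
    gm1 <- groupMeanScores(one)
    expect_equal(gm1$geneMeans[, "g1"],
                 profileScores(one)[, "senescence"], tolerance = 1e-12)
})

test_that("the group contrast matches the textbook t-test", {
    fx <- agingFixture(3)
    prof <- cosineProfile(fx$model, fx$agingGenes, fx$groups)
    got <- groupDifferenceTest(prof, "aging", "nonaging")
    s <- profileScores(prof)
    oracle <- textbookT(rowSums(s[, fx$groups$aging]),
                        rowSums(s[, fx$groups$nonaging]))
    expect_equal(got$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(got$p.value, oracle$p.value, tolerance = 1e-10)

    # identical (constant) groups degenerate to t = 0, p = 1
    prof0 <- new("CosineProfile",
                 scores = matrix(0.3, 4, 2,
                                 dimnames = list(paste0("g", 1:4),
                                                 c("x", "y"))),
                 groups = list(a = "x", b = "y"),
                 thresholds = associationThresholds())
    deg <- groupDifferenceTest(prof0, "a", "b")
    expect_identical(deg$statistic, 0)
    expect_identical(deg$p.value, 1)
})

test_that("a planted aging contrast is detected in >= 95% of seeds", {
    hits <- vapply(1:40, function(s) {
        fx <- agingFixture(100 + s)
        prof <- cosineProfile(fx$model, fx$agingGenes, fx$groups)
        groupDifferenceTest(prof, "aging", "nonaging")$p.value < 0.05
    }, TRUE)
    expect_gte(mean(hits), 0.95)
})

test_that("the disease continuum is the union of per-term responders", {
    # exact bookkeeping under a noiseless corpus: two disease terms,
    # 10 planted genes each, 3 shared -> continuum of 17
    d1g <- sprintf("DA%02d", 1:10)
    d2g <- c(d1g[1:3], sprintf("DB%02d", 1:7))
    planted <- rbind(
        data.frame(gene = d1g, term = "neurodegeneration"),
        data.frame(gene = d2g, term = "sarcopenia"))
    fix <- toyPlantedModel(planted, seed = 5, coOccurrenceProb = 1,
                           backgroundTermProb = 0)
    cont <- buildDiseaseContinuum(fix$model,
                                  c("neurodegeneration", "sarcopenia"))
    expect_length(cont, 17)
    expect_setequal(cont, union(d1g, d2g))
    single <- buildDiseaseContinuum(fix$model, "sarcopenia")
    expect_identical(single,
                     as.character(interrogate(fix$model, "sarcopenia")))
})

test_that("therapeutic correlation counts are exact and bounded", {
    thGenes <- sprintf("TG%02d", 1:3)
    other <- sprintf("OX%02d", 1:5)
    terms <- c("autophagy", "proteostasis", "mitophagy", "hormesis")
    planted <- rbind(
        expand.grid(gene = thGenes, term = terms,
                    stringsAsFactors = FALSE),
        data.frame(gene = other, term = "autophagy"))
    fix <- toyPlantedModel(planted, seed = 7, coOccurrenceProb = 1,
                           backgroundTermProb = 0)
    counts <- therapeuticCorrelationCounts(
        fix$model, c(thGenes, other), terms)
    expect_identical(unname(counts[thGenes]), rep(4L, 3))
    expect_identical(unname(counts[other]), rep(1L, 5))
    expect_true(all(counts <= length(terms)))

    zero <- therapeuticCorrelationCounts(fix$model, thGenes, terms,
                                         countingCutoff = 1.01)
    expect_true(all(zero == 0L))
})

test_that("the percentile hit rule follows nearest-rank with strict excess", {
    counts <- stats::setNames(1:1000, sprintf("g%04d", 1:1000))
    ph <- percentileHits(counts, q = 0.99)
    expect_identical(ph$quantileValue, 990)
    expect_length(ph$hits, 10)
    expect_identical(ph$hits, sprintf("g%04d", 1000:991))

    tied <- stats::setNames(rep(3, 50), paste0("t", 1:50))
    expect_length(percentileHits(tied, 0.99)$hits, 0)

    low <- percentileHits(counts, q = 1e-6)
    expect_length(low$hits, 999)

    # hit fraction bound for all-distinct counts
    for (q in c(0.5, 0.9, 0.99)) {
        f <- length(percentileHits(counts, q)$hits) / length(counts)
        expect_lte(f, 1 - q + 1 / length(counts))
    }
    expect_error(percentileHits(counts, 1), "lie in")
})
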