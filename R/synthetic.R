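# Seeded generators that emulate the statistical structure of the
# study's inputs (iTRAQ-style per-level ratio tables, curated hub
# interactomes, control/stress interactome pairs, gene-tagged corpora,
# size-matched random null sets). Every generator is a pure function of
# its arguments including the seed, and returns the planted ground
# truth alongside the data so downstream stages can be tested for exact
# parameter recovery.

#' Generate a per-level quantification table with planted significance
#'
#' Emulates a multi-level perturbation experiment: a fraction of
#' proteins per level is planted significant (|log2 ratio| centred on
#' \code{effectLog2} and guaranteed past the generator's thresholds,
#' p below \code{maxP}), a sub-fraction is shared across all levels,
#' and the rest are null (ratio centred on 0, p uniform above
#' \code{maxP}). Ground truth is recovered exactly by
#' [filterSignificant()] at the generator's own thresholds.
#'
#' @param nProteins number of proteins (>= 1).
#' @param levels character vector of level labels.
#' @param fracSignificantPerLevel fraction of proteins significant at
#'   each level, in [0, 1].
#' @param fracSharedAllLevels fraction significant at every level;
#'   must not exceed \code{fracSignificantPerLevel}.
#' @param effectLog2 mean |log2 ratio| of planted proteins.
#' @param noiseSd standard deviation of the ratio noise.
#' @param maxP,minAbsLog2Ratio the generator's significance thresholds
#'   (defaults 0.05 and log2(1.2)).
#' @param seed integer seed.
#' @return list with components \code{table} (a [QuantTable-class]) and
#'   \code{truth} (named list, per-level character vectors of planted
#'   significant proteins).
#' @examples
#' g <- generateQuantTable(nProteins = 50, seed = 1)
#' g$table
#' @export
generateQuantTable <- function(nProteins = 1000,
                               levels = c("0.5ug", "1ug", "2ug",
                                          "5ug", "10ug"),
                               fracSignificantPerLevel = 0.25,
                               fracSharedAllLevels = 0.05,
                               effectLog2 = 1,
                               noiseSd = 0.25,
                               maxP = 0.05,
                               minAbsLog2Ratio = log2(1.2),
                               seed = 1) {
    nProteins <- checkCount(nProteins, "nProteins", 1L)
    levels <- as.character(levels)
    if (length(levels) < 1L || anyDuplicated(levels))
        stop("'levels' must be distinct labels")
    if (fracSignificantPerLevel < 0 || fracSignificantPerLevel > 1 ||
        fracSharedAllLevels < 0 || fracSharedAllLevels > 1)
        stop("fractions must lie in [0, 1]")
    if (fracSharedAllLevels > fracSignificantPerLevel)
        stop("fracSharedAllLevels must not exceed fracSignificantPerLevel")
    proteins <- syntheticUniverse(nProteins, prefix = "P")
    nSig <- round(fracSignificantPerLevel * nProteins)
    nShared <- round(fracSharedAllLevels * nProteins)
    withSeed(seed, {
        shared <- sample(proteins, nShared)
        truth <- lapply(levels, function(l) {
            extra <- sample(setdiff(proteins, shared), nSig - nShared)
            sort(c(shared, extra))
        })
        names(truth) <- levels
        recs <- lapply(levels, function(l) {
            sig <- proteins %in% truth[[l]]
            ratio <- stats::rnorm(nProteins, 0, noiseSd)
            p <- maxP + stats::runif(nProteins) * (1 - maxP)
            if (any(sig)) {
                ns <- sum(sig)
                sgn <- sample(c(-1, 1), ns, replace = TRUE)
                eff <- effectLog2 + stats::rnorm(ns, 0, noiseSd)
                # redraw until the planted effect clears the ratio cutoff
                while (any(bad <- abs(eff) < minAbsLog2Ratio))
                    eff[bad] <- effectLog2 +
                        stats::rnorm(sum(bad), 0, noiseSd)
                ratio[sig] <- sgn * eff
                p[sig] <- stats::runif(ns, 0, maxP)
            }
            data.frame(protein = proteins, level = l,
                       log2_ratio = ratio, p_value = p,
                       stringsAsFactors = FALSE)
        })
        list(table = QuantTable(do.call(rbind, recs)), truth = truth)
    })
}

#' Generate a collection of hub interactomes with fixed cardinalities
#'
#' Samples each named hub set without replacement from a synthetic
#' universe (labels \code{G000001...}, distinct from real symbols).
#' Default hub sizes mirror curated oxidative-stress and DNA-damage
#' hub interactomes of the sizes used in the comparative analysis.
#'
#' @param hubSizes named integer vector, hub name to cardinality.
#' @param universeSize size of the synthetic universe; every hub size
#'   must be <= this.
#' @param seed integer seed.
#' @return a [GeneSetCollection-class].
#' @examples
#' hubs <- generateHubCollection(seed = 1)
#' lengths(geneSets(hubs))
#' @export
generateHubCollection <- function(hubSizes = c(G3BP1 = 299, SIRT1 = 251,
                                               SOD1 = 294, PRKDC = 283,
                                               H2AFX = 300, MDM2 = 299,
                                               MDC1 = 198, TP53 = 300,
                                               BRCA1 = 301),
                                  universeSize = 20000,
                                  seed = 1) {
    universeSize <- checkCount(universeSize, "universeSize", 1L)
    if (is.null(names(hubSizes)) || any(!nzchar(names(hubSizes))))
        stop("'hubSizes' must be named")
    if (any(hubSizes > universeSize))
        stop("hub size exceeds universe size")
    uni <- syntheticUniverse(universeSize)
    withSeed(seed, {
        sets <- lapply(hubSizes, function(k) sort(sample(uni, k)))
        GeneSetCollection(sets, universe = uni)
    })
}

#' Generate a control/stress interactome pair with planted overlaps
#'
#' Builds two protein sets of fixed sizes whose intersections with
#' named target sets of \code{collection} are planted exactly. Targets
#' used for planting must be mutually disjoint (ambiguous ground truth
#' is rejected rather than silently resolved); non-planted members are
#' drawn from the universe outside all planting targets.
#'
#' @param controlSize,stressSize set cardinalities (defaults 47 and
#'   268, the unstressed and combined-stress interactome sizes).
#' @param controlOverlaps,stressOverlaps named integer vectors, target
#'   set name to planted overlap count.
#' @param collection a [GeneSetCollection-class] holding the targets.
#' @param seed integer seed.
#' @return list with character-vector components \code{control} and
#'   \code{stress}.
#' @examples
#' hubs <- generateHubCollection(seed = 1)
#' pair <- generateInteractomePair(collection = hubs,
#'                                 stressOverlaps = c(BRCA1 = 20),
#'                                 seed = 2)
#' length(intersect(pair$stress, geneSets(hubs)$BRCA1))
#' @export
generateInteractomePair <- function(controlSize = 47, stressSize = 268,
                                    controlOverlaps = integer(0),
                                    stressOverlaps = integer(0),
                                    collection, seed = 1) {
    stopifnot(is(collection, "GeneSetCollection"))
    controlSize <- checkCount(controlSize, "controlSize", 1L)
    stressSize <- checkCount(stressSize, "stressSize", 1L)
    targets <- union(names(controlOverlaps), names(stressOverlaps))
    sets <- geneSets(collection)
    if (length(bad <- setdiff(targets, names(sets))))
        stop("unknown planting target(s): ", paste(bad, collapse = ", "))
    if (length(targets) > 1L) {
        members <- unlist(sets[targets], use.names = FALSE)
        if (anyDuplicated(members))
            stop("planting targets must be mutually disjoint")
    }
    pool <- setdiff(universe(collection),
                    unlist(sets[targets], use.names = FALSE))
    drawOne <- function(size, overlaps) {
        planted <- sum(overlaps)
        if (planted > size)
            stop("planted overlaps exceed the set size")
        for (nm in names(overlaps)) {
            if (overlaps[[nm]] > length(sets[[nm]]))
                stop("planted overlap exceeds target size for ", nm)
        }
        picked <- unlist(lapply(names(overlaps), function(nm)
            sample(sets[[nm]], overlaps[[nm]])), use.names = FALSE)
        filler <- sample(pool, size - planted)
        sort(c(picked, filler))
    }
    withSeed(seed, {
        list(control = drawOne(controlSize, controlOverlaps),
             stress = drawOne(stressSize, stressOverlaps))
    })
}

#' Generate a gene-tagged corpus with planted gene-term associations
#'
#' Emulates, at toy scale, a literature corpus in which some genes
#' co-occur strongly with specific concept terms. Each gene tags
#' \code{nDocsPerGene} documents. Per document of gene g: each term
#' planted for g appears with probability \code{coOccurrenceProb} (and
#' then \code{plantedMentions} times, a concept central to a document
#' recurring); every planted term of the corpus (any gene's)
#' additionally appears once with the background probability; and
#' \code{docLength} filler tokens are drawn uniformly from the gene's
#' own slice of the filler vocabulary (each gene's literature context
#' is distinct, so filler is gene-specific rather than shared).
#'
#' @param nGenes number of genes; must cover the genes named in
#'   \code{planted}.
#' @param nDocsPerGene documents tagged per gene.
#' @param vocabSize vocabulary size; must cover the planted terms.
#' @param planted data.frame with columns \code{gene}, \code{term} and
#'   optionally \code{prob} (defaults to \code{coOccurrenceProb}).
#' @param coOccurrenceProb per-document probability that a planted term
#'   appears in its gene's documents (default 0.8).
#' @param backgroundTermProb per-document probability that any planted
#'   term appears as background noise (default 0.05); must be below
#'   \code{coOccurrenceProb}.
#' @param docLength filler tokens per document.
#' @param plantedMentions occurrences of a planted term within a
#'   document it appears in (default 3).
#' @param seed integer seed.
#' @return list with components \code{corpus} (a [Corpus-class]) and
#'   \code{truth} (the planted data.frame with normalized gene ids and
#'   tokenized terms).
#' @examples
#' g <- generateCorpus(planted = data.frame(gene = "GA", term = "repair"),
#'                     seed = 1)
#' g$corpus
#' @export
generateCorpus <- function(nGenes = 400, nDocsPerGene = 20,
                           vocabSize = 4000, planted = NULL,
                           coOccurrenceProb = 0.8,
                           backgroundTermProb = 0.05,
                           docLength = 20, plantedMentions = 3,
                           seed = 1) {
    nGenes <- checkCount(nGenes, "nGenes", 1L)
    nDocsPerGene <- checkCount(nDocsPerGene, "nDocsPerGene", 1L)
    vocabSize <- checkCount(vocabSize, "vocabSize", 1L)
    docLength <- checkCount(docLength, "docLength", 0L)
    plantedMentions <- checkCount(plantedMentions, "plantedMentions", 1L)
    if (coOccurrenceProb < 0 || coOccurrenceProb > 1 ||
        backgroundTermProb < 0 || backgroundTermProb > 1)
        stop("probabilities must lie in [0, 1]")
    if (is.null(planted))
        planted <- data.frame(gene = character(0), term = character(0),
                              stringsAsFactors = FALSE)
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    if (nrow(planted)) {
        planted$gene <- normalizeGeneId(planted$gene)
        planted$term <- vapply(planted$term, function(t) {
            tok <- tokenizeTerms(t)
            if (length(tok) != 1L)
                stop("planted terms must be single tokens: ", t)
            tok
        }, "", USE.NAMES = FALSE)
        if (!"prob" %in% names(planted))
            planted$prob <- coOccurrenceProb
        if (any(planted$prob < 0 | planted$prob > 1))
            stop("planted probabilities must lie in [0, 1]")
        if (any(planted$prob <= backgroundTermProb))
            stop("planted co-occurrence must exceed the background probability")
        if (anyDuplicated(paste(planted$gene, planted$term, sep = "\r")))
            stop("duplicate planted (gene, term) pairs")
    }
    plantedTerms <- unique(planted$term)
    if (length(plantedTerms) > vocabSize)
        stop("vocabulary too small for the planted terms")
    fillerTerms <- sprintf("term%04d", seq_len(vocabSize - length(plantedTerms)))
    plantedGenes <- unique(planted$gene)
    if (length(plantedGenes) > nGenes)
        stop("nGenes too small for the planted genes")
    genes <- c(plantedGenes,
               syntheticUniverse(nGenes - length(plantedGenes), "G"))
    # disjoint per-gene filler pools: gene i draws filler from its own
    # slice of the filler vocabulary
    pools <- if (length(fillerTerms))
        split(fillerTerms, cut(seq_along(fillerTerms), nGenes,
                               labels = FALSE))
    else vector("list", nGenes)
    withSeed(seed, {
        docs <- vector("list", length(genes) * nDocsPerGene)
        idx <- 0L
        for (gi in seq_along(genes)) {
            g <- genes[gi]
            mine <- planted[planted$gene == g, , drop = FALSE]
            others <- setdiff(plantedTerms, mine$term)
            pool <- pools[[gi]]
            for (j in seq_len(nDocsPerGene)) {
                toks <- character(0)
                if (nrow(mine)) {
                    hit <- stats::runif(nrow(mine)) < mine$prob
                    toks <- c(toks, rep(mine$term[hit],
                                        each = plantedMentions))
                }
                if (length(others)) {
                    bg <- stats::runif(length(others)) < backgroundTermProb
                    toks <- c(toks, others[bg])
                }
                if (docLength > 0L && length(pool))
                    toks <- c(toks, sample(pool, docLength,
                                           replace = TRUE))
                idx <- idx + 1L
                docs[[idx]] <-
                    list(doc_id = sprintf("%s_doc%03d", g, j),
                         genes = g, tokens = toks)
            }
        }
        list(corpus = Corpus(docs), truth = planted)
    })
}

#' Generate size-matched random gene sets
#'
#' Draws \code{nSets} sets of exactly \code{size} members without
#' replacement from \code{universe} - the size-matched random null
#' design used to judge observed interactome overlaps against chance.
#'
#' @param size set cardinality; must be <= |universe|.
#' @param nSets number of sets (>= 1).
#' @param universe character vector to sample from.
#' @param seed integer seed.
#' @return list of character vectors.
#' @examples
#' generateRandomGeneSets(3, 2, LETTERS, seed = 1)
#' @export
generateRandomGeneSets <- function(size, nSets, universe, seed = 1) {
    size <- checkCount(size, "size", 1L)
    nSets <- checkCount(nSets, "nSets", 1L)
    universe <- as.character(universe)
    if (size > length(universe))
        stop("size exceeds the universe")
    withSeed(seed, {
        lapply(seq_len(nSets), function(i) sample(universe, size))
    })
}

#' Construct per-level sets with prescribed Venn cell structure
#'
#' Builds level sets (synthetic labels) constrained to exact per-level
#' totals, exact per-level unique (singleton-cell) counts and an exact
#' all-levels common core - the printed summary of a multi-level
#' experiment used as input when the underlying protein lists are not
#' available. Genes not unique and not in the core are distributed over
#' two-level cells (with a single three-level cell if needed for
#' parity), always pairing the two levels with the largest remaining
#' demand; the construction is deterministic.
#'
#' @param levelTotals named integer vector of per-level set sizes.
#' @param uniqueCounts named integer vector (same names) of per-level
#'   unique counts.
#' @param coreSize size of the all-levels cell.
#' @return named list of character vectors satisfying the constraints;
#'   an error if no partition with pair/one-triple filling exists.
#' @examples
#' s <- generateConstellationSets(c(A = 5, B = 6), c(A = 2, B = 3), 1)
#' lengths(s)
#' @export
generateConstellationSets <- function(levelTotals, uniqueCounts,
                                      coreSize) {
    lv <- names(levelTotals)
    if (is.null(lv) || !identical(sort(lv), sort(names(uniqueCounts))))
        stop("levelTotals and uniqueCounts must share names")
    uniqueCounts <- uniqueCounts[lv]
    coreSize <- checkCount(coreSize, "coreSize", 0L)
    rest <- levelTotals - uniqueCounts - coreSize
    if (any(rest < 0))
        stop("totals too small for the requested unique counts and core")
    nGenes <- sum(uniqueCounts) + coreSize + sum(rest)  # upper bound
    pool <- syntheticUniverse(nGenes, "Q")
    nxt <- 0L
    take <- function(n) {
        ids <- pool[nxt + seq_len(n)]
        nxt <<- nxt + n
        ids
    }
    sets <- lapply(lv, function(l) character(0))
    names(sets) <- lv
    core <- take(coreSize)
    for (l in lv)
        sets[[l]] <- c(sets[[l]], core, take(uniqueCounts[[l]]))
    r <- as.integer(rest)
    names(r) <- lv
    if (sum(r) %% 2L == 1L) {
        pos <- names(sort(r[r > 0L], decreasing = TRUE))
        # a three-level cell fixes parity, but only as a proper subset
        # (with exactly 3 levels it would inflate the all-levels core)
        if (length(pos) < 3L || length(lv) <= 3L)
            stop("no feasible partition: odd shared remainder")
        g <- take(1L)
        for (l in pos[1:3]) {
            sets[[l]] <- c(sets[[l]], g)
            r[[l]] <- r[[l]] - 1L
        }
    }
    while (sum(r) > 0L) {
        pos <- names(sort(r[r > 0L], decreasing = TRUE))
        if (length(pos) < 2L)
            stop("no feasible partition: a level's remainder cannot be shared")
        g <- take(1L)
        for (l in pos[1:2]) {
            sets[[l]] <- c(sets[[l]], g)
            r[[l]] <- r[[l]] - 1L
        }
    }
    lapply(sets, sort)
}
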