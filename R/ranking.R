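# Multi-interrogator cosine profiling, group contrasts (e.g. aging vs
# non-aging concept panels) and the disease-continuum / therapeutic-
# interrogator percentile ranking.

#' Cosine profile of a gene set against grouped interrogators
#'
#' One [queryCosine()] column per interrogator phrase, restricted to
#' the requested genes, with group structure attached. Gene and
#' interrogator order are deterministic (input order); permuting the
#' interrogators permutes columns only.
#'
#' @param model a [SemanticModel-class].
#' @param genes non-empty character vector; members absent from the
#'   model are dropped with a warning.
#' @param interrogators named list mapping group name to a character
#'   vector of phrases, or a bare character vector (one anonymous
#'   group).
#' @param th an [AssociationThresholds-class] carried into the result.
#' @return a [CosineProfile-class].
#' @export
cosineProfile <- function(model, genes, interrogators,
                          th = associationThresholds()) {
    stopifnot(is(model, "SemanticModel"))
    genes <- unique(normalizeGeneId(as.character(genes)))
    if (!length(genes))
        stop("empty gene list")
    missing <- setdiff(genes, modelGenes(model))
    if (length(missing)) {
        warning(length(missing), " gene(s) not in the model were dropped")
        genes <- setdiff(genes, missing)
        if (!length(genes))
            stop("no requested gene is in the model")
    }
    if (!is.list(interrogators))
        interrogators <- list(terms = as.character(interrogators))
    if (is.null(names(interrogators)) || any(!nzchar(names(interrogators))))
        stop("'interrogators' groups must be named")
    terms <- unlist(interrogators, use.names = FALSE)
    if (anyDuplicated(terms))
        stop("an interrogator may belong to at most one group")
    scores <- vapply(terms, function(t)
        queryCosine(model, t)[genes], numeric(length(genes)))
    scores <- matrix(scores, nrow = length(genes),
                     dimnames = list(genes, terms))
    groups <- lapply(interrogators, as.character)
    new("CosineProfile", scores = scores, groups = groups,
        thresholds = th)
}

#' Per-gene and grand group mean cosine scores
#'
#' Arithmetic mean over each group's interrogator columns for every
#' gene, plus the grand mean of each group over genes (the summary
#' contrasted between e.g. aging and non-aging panels).
#'
#' @param profile a [CosineProfile-class] with non-empty groups.
#' @return list with \code{geneMeans} (matrix genes x groups) and
#'   \code{grandMeans} (named numeric).
#' @export
groupMeanScores <- function(profile) {
    stopifnot(is(profile, "CosineProfile"))
    groups <- profileGroups(profile)
    if (!length(groups) || any(!lengths(groups)))
        stop("profile groups must be non-empty")
    s <- profileScores(profile)
    geneMeans <- vapply(groups, function(terms)
        rowMeans(s[, terms, drop = FALSE]), numeric(nrow(s)))
    geneMeans <- matrix(geneMeans, nrow = nrow(s),
                        dimnames = list(rownames(s), names(groups)))
    list(geneMeans = geneMeans, grandMeans = colMeans(geneMeans))
}

#' Two-sample t-test between interrogator groups
#'
#' The observations are per-gene summed scores over each group's
#' interrogators (the groups' term results "added together" per gene);
#' the two resulting per-gene vectors are compared with a two-sided
#' Student's t-test (equal variance by default, Welch optional). When
#' both groups are constant with equal means the degenerate case is
#' reported as t = 0, p = 1.
#'
#' @param profile a [CosineProfile-class].
#' @param groupA,groupB group names present in the profile.
#' @param varEqual equal-variance Student's t (default TRUE) or Welch.
#' @return list with \code{statistic}, \code{parameter} (df),
#'   \code{p.value} and \code{method}.
#' @export
groupDifferenceTest <- function(profile, groupA, groupB,
                                varEqual = TRUE) {
    stopifnot(is(profile, "CosineProfile"))
    groups <- profileGroups(profile)
    if (length(bad <- setdiff(c(groupA, groupB), names(groups))))
        stop("unknown group(s): ", paste(bad, collapse = ", "))
    s <- profileScores(profile)
    x <- rowSums(s[, groups[[groupA]], drop = FALSE])
    y <- rowSums(s[, groups[[groupB]], drop = FALSE])
    if (length(x) < 2L || length(y) < 2L)
        stop("need >= 2 observations per group")
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (isTRUE(all.equal(mean(x), mean(y))))
            return(list(statistic = 0, parameter = length(x) +
                            length(y) - 2, p.value = 1,
                        method = "degenerate (zero variance)"))
        stop("zero variance with unequal means: t undefined")
    }
    tt <- stats::t.test(x, y, var.equal = varEqual)
    list(statistic = unname(tt$statistic),
         parameter = unname(tt$parameter),
         p.value = tt$p.value, method = tt$method)
}

#' Build the disease-continuum protein set
#'
#' Union over the disease interrogator terms of all genes explicitly or
#' implicitly associated (cosine at or above the implicit cutoff) -
#' the literature-wide set of proteins tied to a battery of
#' age-associated disease concepts.
#'
#' @param model a [SemanticModel-class].
#' @param diseaseTerms non-empty character vector of phrases.
#' @param th an [AssociationThresholds-class].
#' @return sorted character vector of gene identifiers.
#' @export
buildDiseaseContinuum <- function(model, diseaseTerms,
                                  th = associationThresholds()) {
    diseaseTerms <- as.character(diseaseTerms)
    if (!length(diseaseTerms))
        stop("need at least one disease term")
    sort(unique(unlist(lapply(diseaseTerms, function(t)
        interrogate(model, t, th)), use.names = FALSE)))
}

#' Count therapeutic-interrogator correlations per continuum gene
#'
#' For every continuum gene, the number of therapeutic interrogator
#' terms whose cosine reaches \code{countingCutoff} (default the
#' explicit threshold 0.2 - what counts as "a correlation" is
#' configuration, see the methods vignette).
#'
#' @param model a [SemanticModel-class].
#' @param continuum non-empty character vector (e.g. from
#'   [buildDiseaseContinuum()]).
#' @param therapeuticTerms non-empty character vector of phrases.
#' @param countingCutoff cosine threshold defining a correlation.
#' @return named integer vector, gene to count (bounded by the number
#'   of therapeutic terms).
#' @export
therapeuticCorrelationCounts <- function(model, continuum,
                                         therapeuticTerms,
                                         countingCutoff = 0.2) {
    continuum <- unique(normalizeGeneId(as.character(continuum)))
    if (!length(continuum))
        stop("empty continuum")
    therapeuticTerms <- as.character(therapeuticTerms)
    if (!length(therapeuticTerms))
        stop("need at least one therapeutic term")
    if (length(bad <- setdiff(continuum, modelGenes(model))))
        stop(length(bad), " continuum gene(s) not in the model")
    hits <- vapply(therapeuticTerms, function(t)
        queryCosine(model, t)[continuum] >= countingCutoff,
        logical(length(continuum)))
    hits <- matrix(hits, nrow = length(continuum))
    counts <- as.integer(rowSums(hits))
    names(counts) <- continuum
    counts
}

#' Percentile rule for top-ranked hits
#'
#' Nearest-rank q-quantile of the correlation counts (the value at
#' rank ceiling(q * n) of the sorted counts); hits are the genes whose
#' count STRICTLY exceeds that value, ordered by descending count then
#' gene label. On discrete counts this strict rule can return no hits
#' when all counts tie.
#'
#' @param counts named numeric vector (>= 1 gene).
#' @param q quantile in (0, 1), default 0.99.
#' @return list with \code{q}, \code{quantileValue}, \code{hits}
#'   (ordered character vector) and \code{counts}.
#' @examples
#' percentileHits(setNames(1:100, paste0("G", 1:100)), q = 0.9)
#' @export
percentileHits <- function(counts, q = 0.99) {
    if (!length(counts) || is.null(names(counts)))
        stop("'counts' must be a non-empty named vector")
    if (q <= 0 || q >= 1)
        stop("'q' must lie in (0, 1)")
    sorted <- sort(as.numeric(counts))
    qv <- sorted[ceiling(q * length(sorted))]
    sel <- counts > qv
    hits <- names(counts)[sel]
    hits <- hits[order(-counts[sel], hits)]
    list(q = q, quantileValue = qv, hits = hits, counts = counts)
}

#' Disease-continuum / therapeutic-interrogator pipeline
#'
#' Convenience wrapper chaining [buildDiseaseContinuum()],
#' [therapeuticCorrelationCounts()] and [percentileHits()]: build the
#' continuum from disease terms, count therapeutic correlations per
#' continuum gene, and return the genes whose count exceeds the
#' q-quantile.
#'
#' @param model a [SemanticModel-class].
#' @param diseaseTerms,therapeuticTerms character vectors of phrases.
#' @param th an [AssociationThresholds-class] for continuum membership.
#' @param countingCutoff cosine threshold defining a correlation.
#' @param q percentile for the hit rule.
#' @return list with \code{continuum}, \code{counts},
#'   \code{quantileValue} and \code{hits}.
#' @export
diseaseContinuumAnalysis <- function(model, diseaseTerms,
                                     therapeuticTerms,
                                     th = associationThresholds(),
                                     countingCutoff = 0.2, q = 0.99) {
    continuum <- buildDiseaseContinuum(model, diseaseTerms, th)
    if (!length(continuum))
        stop("empty disease continuum")
    counts <- therapeuticCorrelationCounts(model, continuum,
                                           therapeuticTerms,
                                           countingCutoff)
    ph <- percentileHits(counts, q)
    list(continuum = continuum, counts = counts,
         quantileValue = ph$quantileValue, hits = ph$hits)
}
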