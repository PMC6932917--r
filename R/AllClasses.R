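#' @import methods
NULL

#' Per-protein, per-level quantification table
#'
#' Container for ratiometric perturbation proteomics: one record per
#' (protein, level) pair holding the log2 expression ratio against the
#' control condition and its p-value. This is the input to the
#' constellation partitioning stage.
#'
#' @slot data a \code{data.frame} with columns \code{protein} (normalized
#'   gene identifier), \code{level} (expression-level label),
#'   \code{log2_ratio} (finite numeric) and \code{p_value} (in [0, 1]).
#'   (protein, level) pairs are unique.
#'
#' @seealso [QuantTable()], [readQuantTable()], [filterSignificant()]
#' @export
setClass("QuantTable", representation(data = "data.frame"))

setValidity("QuantTable", function(object) {
    d <- object@data
    need <- c("protein", "level", "log2_ratio", "p_value")
    if (!all(need %in% names(d)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(d)), collapse = ", ")))
    if (nrow(d) == 0L)
        return(TRUE)
    if (any(is.na(d$p_value)) || any(d$p_value < 0) || any(d$p_value > 1))
        return("p_value must lie in [0, 1]")
    if (any(!is.finite(d$log2_ratio)))
        return("log2_ratio must be finite")
    if (anyDuplicated(paste(d$protein, d$level, sep = "\r")))
        return("duplicate (protein, level) pairs")
    if (!identical(d$protein, normalizeGeneId(d$protein)))
        return("protein identifiers are not normalized")
    TRUE
})

#' Named gene sets over a background universe
#'
#' Holds a collection of named gene sets (hub interactomes, disease
#' signatures, per-level significance lists, ...) together with the
#' background universe used by enrichment and null-resampling stages.
#' Every member of every set belongs to the universe.
#'
#' @slot sets named list of character vectors of normalized gene
#'   identifiers; names are unique.
#' @slot universe character vector of normalized gene identifiers.
#'
#' @seealso [GeneSetCollection()], [readGmt()], [enrichSet()]
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    if (length(s)) {
        if (is.null(names(s)) || any(!nzchar(names(s))))
            return("all sets must be named")
        if (anyDuplicated(names(s)))
            return("duplicate set names")
        for (nm in names(s)) {
            if (!is.character(s[[nm]]))
                return(paste0("set '", nm, "' is not a character vector"))
            if (anyDuplicated(s[[nm]]))
                return(paste0("set '", nm, "' has duplicate members"))
            if (length(bad <- setdiff(s[[nm]], object@universe)))
                return(paste0("set '", nm, "' has ", length(bad),
                              " member(s) outside the universe"))
        }
    }
    TRUE
})

#' Gene-tagged document corpus
#'
#' A list of documents, each with a unique identifier, a set of gene tags
#' and a normalized token sequence. Feeds the latent-semantic-indexing
#' engine, where all documents tagged with a gene are concatenated into
#' that gene's pseudo-document.
#'
#' @slot docs list; each element is a list with components \code{doc_id}
#'   (character scalar), \code{genes} (character vector of normalized gene
#'   identifiers) and \code{tokens} (character vector of normalized tokens).
#'
#' @seealso [Corpus()], [readCorpusJsonl()], [buildGeneDocuments()]
#' @export
setClass("Corpus", representation(docs = "list"))

setValidity("Corpus", function(object) {
    if (!length(object@docs))
        return(TRUE)
    ids <- vapply(object@docs, function(d) as.character(d$doc_id)[1L], "")
    if (any(is.na(ids)) || any(!nzchar(ids)))
        return("every document needs a non-empty doc_id")
    if (anyDuplicated(ids))
        return("duplicate doc_id")
    for (d in object@docs) {
        if (!all(c("doc_id", "genes", "tokens") %in% names(d)))
            return("documents need doc_id, genes and tokens")
    }
    TRUE
})

#' Multi-set Venn partition of per-level significance sets
#'
#' The constellation partition: each gene in the union of the per-level
#' sets is assigned to exactly one cell, keyed by the subset of levels
#' containing it (cell keys join level labels with \code{" & "}).
#'
#' @slot perLevelSets named list of character vectors, one per level.
#' @slot cells named list of character vectors; keys are level subsets,
#'   cells are pairwise disjoint and cover the union of the level sets.
#' @slot levelTotals named integer vector, \code{|perLevelSets[[l]]|}.
#'
#' @seealso [vennPartition()], [uniquePercentages()], [commonCore()]
#' @export
setClass("ConstellationPartition",
         representation(perLevelSets = "list", cells = "list",
                        levelTotals = "integer"))

setValidity("ConstellationPartition", function(object) {
    lv <- names(object@perLevelSets)
    if (length(lv) < 2L)
        return("at least two levels required")
    if (!identical(names(object@levelTotals), lv))
        return("levelTotals must be named by level")
    if (!identical(unname(object@levelTotals),
                   vapply(object@perLevelSets, length, 0L, USE.NAMES = FALSE)))
        return("levelTotals inconsistent with perLevelSets")
    all_cells <- unlist(object@cells, use.names = FALSE)
    if (anyDuplicated(all_cells))
        return("cells are not pairwise disjoint")
    uni <- unique(unlist(object@perLevelSets, use.names = FALSE))
    if (!setequal(all_cells, uni))
        return("cells do not cover the union of the level sets")
    TRUE
})

#' Latent semantic concept space over genes and terms
#'
#' A rank-k truncated SVD of the weighted term-by-gene association matrix.
#' Both term and gene vectors carry the singular-value scaling
#' (symmetric convention), so cosine interrogation is reproducible from
#' the stored factors alone.
#'
#' @slot vocabulary ordered character vector of tokens (matrix rows).
#' @slot genes ordered character vector of gene identifiers (columns).
#' @slot rankK integer, the truncation rank.
#' @slot termVectors numeric matrix, |vocabulary| x rankK, rows = U_t * d.
#' @slot geneVectors numeric matrix, |genes| x rankK, rows = V_g * d.
#' @slot singularValues numeric vector of length rankK, non-increasing.
#' @slot weighting character scalar, \code{"log_entropy"} or \code{"tfidf"}.
#'
#' @seealso [fitLsi()], [queryCosine()], [interrogate()]
#' @export
setClass("SemanticModel",
         representation(vocabulary = "character", genes = "character",
                        rankK = "integer", termVectors = "matrix",
                        geneVectors = "matrix", singularValues = "numeric",
                        weighting = "character"))

setValidity("SemanticModel", function(object) {
    k <- object@rankK
    if (k < 1L || k > min(length(object@vocabulary), length(object@genes)))
        return("rankK must lie in [1, min(|vocabulary|, |genes|)]")
    if (!identical(dim(object@termVectors),
                   c(length(object@vocabulary), as.integer(k))))
        return("termVectors has wrong dimensions")
    if (!identical(dim(object@geneVectors),
                   c(length(object@genes), as.integer(k))))
        return("geneVectors has wrong dimensions")
    if (length(object@singularValues) != k)
        return("singularValues has wrong length")
    if (any(!is.finite(object@termVectors)) ||
        any(!is.finite(object@geneVectors)))
        return("vectors must be finite")
    if (is.unsorted(rev(object@singularValues)))
        return("singular values must be non-increasing")
    TRUE
})

#' Cosine association thresholds
#'
#' The literature-mining convention: a cosine similarity above the
#' explicit cutoff marks an explicit literature association, a score
#' between the implicit and explicit cutoffs an implied one, anything
#' below the implicit cutoff none.
#'
#' @slot implicitCutoff numeric scalar, default 0.1.
#' @slot explicitCutoff numeric scalar, default 0.2.
#'
#' @seealso [associationThresholds()], [classifyAssociation()]
#' @export
setClass("AssociationThresholds",
         representation(implicitCutoff = "numeric",
                        explicitCutoff = "numeric"))

setValidity("AssociationThresholds", function(object) {
    i <- object@implicitCutoff
    e <- object@explicitCutoff
    if (length(i) != 1L || length(e) != 1L || is.na(i) || is.na(e))
        return("cutoffs must be numeric scalars")
    if (i < 0 || e > 1 || i > e)
        return("need 0 <= implicitCutoff <= explicitCutoff <= 1")
    TRUE
})

#' Gene-by-interrogator cosine score matrix
#'
#' Full cosine profile of a gene set against grouped interrogator terms
#' (e.g. aging versus non-aging disease concepts), with the thresholds
#' used downstream.
#'
#' @slot scores numeric matrix, genes x interrogators, values in [-1, 1].
#' @slot groups named list mapping group name to interrogator labels
#'   (column names of \code{scores}); every interrogator belongs to at
#'   most one group.
#' @slot thresholds an [AssociationThresholds-class] object.
#'
#' @seealso [cosineProfile()], [groupMeanScores()], [groupDifferenceTest()]
#' @export
setClass("CosineProfile",
         representation(scores = "matrix", groups = "list",
                        thresholds = "AssociationThresholds"))

setValidity("CosineProfile", function(object) {
    s <- object@scores
    if (any(!is.finite(s)) || any(s < -1 - 1e-9) || any(s > 1 + 1e-9))
        return("scores must be finite cosines in [-1, 1]")
    members <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(members))
        return("an interrogator may belong to at most one group")
    if (length(bad <- setdiff(members, colnames(s))))
        return(paste("group members not in score columns:",
                     paste(bad, collapse = ", ")))
    TRUE
})
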