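#' Accessors for the package's S4 containers
#'
#' Small accessor generics so downstream code never touches slots
#' directly: `geneSets`/`universe` for [GeneSetCollection-class],
#' `quantData` for [QuantTable-class], `corpusDocs` for [Corpus-class],
#' `perLevelSets`/`partitionCells`/`levelTotals` for
#' [ConstellationPartition-class], `vocabulary`/`modelGenes`/`rankK`/
#' `singularValues`/`termVectors`/`geneVectors` for
#' [SemanticModel-class], `implicitCutoff`/`explicitCutoff` for
#' [AssociationThresholds-class] and `profileScores`/`profileGroups` for
#' [CosineProfile-class].
#'
#' @param x an object of the matching class.
#' @return The slot content (list, character vector, matrix or scalar).
#' @examples
#' gsc <- GeneSetCollection(list(DDR = c("BRCA1", "TP53")))
#' geneSets(gsc)
#' universe(gsc)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))
#' @rdname accessors
#' @export
setGeneric("quantData", function(x) standardGeneric("quantData"))
#' @rdname accessors
#' @export
setGeneric("corpusDocs", function(x) standardGeneric("corpusDocs"))
#' @rdname accessors
#' @export
setGeneric("perLevelSets", function(x) standardGeneric("perLevelSets"))
#' @rdname accessors
#' @export
setGeneric("partitionCells", function(x) standardGeneric("partitionCells"))
#' @rdname accessors
#' @export
setGeneric("levelTotals", function(x) standardGeneric("levelTotals"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))
#' @rdname accessors
#' @export
setGeneric("rankK", function(x) standardGeneric("rankK"))
#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("termVectors", function(x) standardGeneric("termVectors"))
#' @rdname accessors
#' @export
setGeneric("geneVectors", function(x) standardGeneric("geneVectors"))
#' @rdname accessors
#' @export
setGeneric("implicitCutoff", function(x) standardGeneric("implicitCutoff"))
#' @rdname accessors
#' @export
setGeneric("explicitCutoff", function(x) standardGeneric("explicitCutoff"))
#' @rdname accessors
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))
#' @rdname accessors
#' @export
setGeneric("profileGroups", function(x) standardGeneric("profileGroups"))

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @rdname accessors
setMethod("universe", "GeneSetCollection", function(x) x@universe)
#' @rdname accessors
setMethod("quantData", "QuantTable", function(x) x@data)
#' @rdname accessors
setMethod("corpusDocs", "Corpus", function(x) x@docs)
#' @rdname accessors
setMethod("perLevelSets", "ConstellationPartition", function(x) x@perLevelSets)
#' @rdname accessors
setMethod("partitionCells", "ConstellationPartition", function(x) x@cells)
#' @rdname accessors
setMethod("levelTotals", "ConstellationPartition", function(x) x@levelTotals)
#' @rdname accessors
setMethod("vocabulary", "SemanticModel", function(x) x@vocabulary)
#' @rdname accessors
setMethod("modelGenes", "SemanticModel", function(x) x@genes)
#' @rdname accessors
setMethod("rankK", "SemanticModel", function(x) x@rankK)
#' @rdname accessors
setMethod("singularValues", "SemanticModel", function(x) x@singularValues)
#' @rdname accessors
setMethod("termVectors", "SemanticModel", function(x) x@termVectors)
#' @rdname accessors
setMethod("geneVectors", "SemanticModel", function(x) x@geneVectors)
#' @rdname accessors
setMethod("implicitCutoff", "AssociationThresholds",
          function(x) x@implicitCutoff)
#' @rdname accessors
setMethod("explicitCutoff", "AssociationThresholds",
          function(x) x@explicitCutoff)
#' @rdname accessors
setMethod("profileScores", "CosineProfile", function(x) x@scores)
#' @rdname accessors
setMethod("profileGroups", "CosineProfile", function(x) x@groups)

setMethod("show", "QuantTable", function(object) {
    d <- object@data
    cat("QuantTable with", nrow(d), "records:",
        length(unique(d$protein)), "proteins x",
        length(unique(d$level)), "levels\n")
    if (nrow(d)) {
        cat("  levels:", paste(unique(d$level), collapse = ", "), "\n")
    }
    invisible(NULL)
})

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object@sets), "sets over a",
        length(object@universe), "gene universe\n")
    if (length(object@sets)) {
        sizes <- vapply(object@sets, length, 0L)
        n <- min(length(sizes), 8L)
        cat("  ", paste0(names(sizes)[seq_len(n)], " (", sizes[seq_len(n)],
                         ")", collapse = ", "),
            if (length(sizes) > n) ", ..." else "", "\n", sep = "")
    }
    invisible(NULL)
})

setMethod("show", "Corpus", function(object) {
    genes <- unique(unlist(lapply(object@docs, `[[`, "genes"),
                           use.names = FALSE))
    cat("Corpus with", length(object@docs), "documents tagging",
        length(genes), "genes\n")
    invisible(NULL)
})

setMethod("show", "ConstellationPartition", function(object) {
    cat("ConstellationPartition over", length(object@perLevelSets),
        "levels,", length(object@cells), "non-empty cells,",
        length(unlist(object@cells, use.names = FALSE)), "genes\n")
    tot <- object@levelTotals
    cat("  level totals:",
        paste(names(tot), tot, sep = "=", collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "SemanticModel", function(object) {
    cat("SemanticModel: rank-", object@rankK, " concept space (",
        object@weighting, " weighting)\n", sep = "")
    cat(" ", length(object@vocabulary), "terms x",
        length(object@genes), "genes\n")
    invisible(NULL)
})

setMethod("show", "AssociationThresholds", function(object) {
    cat("AssociationThresholds: implicit >=", object@implicitCutoff,
        "| explicit >", object@explicitCutoff, "\n")
    invisible(NULL)
})

setMethod("show", "CosineProfile", function(object) {
    cat("CosineProfile:", nrow(object@scores), "genes x",
        ncol(object@scores), "interrogators in",
        length(object@groups), "groups\n")
    invisible(NULL)
})
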