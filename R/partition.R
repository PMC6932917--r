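# The constellation stage: significance filtering of per-level
# quantification data and multi-set Venn partitioning into
# unique/common protein cells.

#' Filter a quantification table for significant proteins per level
#'
#' A protein belongs to a level's significance set iff its p-value is
#' <= \code{maxP} and |log2 ratio| >= \code{minAbsLog2Ratio} at that
#' level. The defaults (p <= 0.05, fold change >= 1.2) are the
#' conventional criteria for ratio-based quantitative proteomics and
#' are deliberately explicit configuration.
#'
#' @param qt a [QuantTable-class].
#' @param maxP significance p-value cutoff, in (0, 1].
#' @param minAbsLog2Ratio minimum absolute log2 ratio, >= 0.
#' @return named list of character vectors, one per level (in order of
#'   first appearance), sorted members.
#' @examples
#' qt <- QuantTable(data.frame(protein = c("A", "B"), level = "L1",
#'                             log2_ratio = c(1, 0.1),
#'                             p_value = c(0.01, 0.5)))
#' filterSignificant(qt)
#' @export
filterSignificant <- function(qt, maxP = 0.05,
                              minAbsLog2Ratio = log2(1.2)) {
    stopifnot(is(qt, "QuantTable"))
    if (maxP <= 0 || maxP > 1)
        stop("'maxP' must lie in (0, 1]")
    if (minAbsLog2Ratio < 0)
        stop("'minAbsLog2Ratio' must be >= 0")
    d <- quantData(qt)
    lv <- unique(d$level)
    hit <- d$p_value <= maxP & abs(d$log2_ratio) >= minAbsLog2Ratio
    out <- lapply(lv, function(l) sort(d$protein[hit & d$level == l]))
    names(out) <- lv
    out
}

#' Venn-partition per-level sets into disjoint cells
#'
#' Assigns every gene in the union of the level sets to the unique cell
#' keyed by the exact subset of levels containing it, mirroring a
#' multi-set Venn diagram. Cell keys join the level labels (in input
#' order) with \code{" & "}.
#'
#' @param sets named list (>= 2 entries) of character vectors.
#' @return a [ConstellationPartition-class].
#' @examples
#' p <- vennPartition(list(L1 = c("A", "B"), L2 = c("B", "C")))
#' partitionCells(p)
#' @export
vennPartition <- function(sets) {
    if (!is.list(sets) || length(sets) < 2L)
        stop("need at least 2 level sets")
    if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
        anyDuplicated(names(sets)))
        stop("level sets must have unique non-empty names")
    sets <- lapply(sets, function(s) unique(as.character(s)))
    lv <- names(sets)
    genes <- unique(unlist(sets, use.names = FALSE))
    if (length(genes)) {
        member <- vapply(sets, function(s) genes %in% s,
                         logical(length(genes)))
        member <- matrix(member, nrow = length(genes),
                         dimnames = list(genes, lv))
        key <- apply(member, 1L, function(m)
            paste(lv[m], collapse = " & "))
        cells <- split(genes, key)
        cells <- lapply(cells, sort)
        # deterministic cell order: by subset size then first level index
        ord <- order(vapply(strsplit(names(cells), " & ", fixed = TRUE),
                            length, 0L),
                     vapply(strsplit(names(cells), " & ", fixed = TRUE),
                            function(k) match(k[1L], lv), 0L))
        cells <- cells[ord]
    } else {
        cells <- list()
    }
    new("ConstellationPartition", perLevelSets = lapply(sets, sort),
        cells = cells,
        levelTotals = vapply(sets, length, 0L))
}

#' Percentage of uniquely-regulated genes per level
#'
#' 100 x |singleton cell of the level| / |level set|, rounded half-even
#' at the requested precision. Errors if any level set is empty (the
#' percentage is undefined there).
#'
#' @param p a [ConstellationPartition-class].
#' @param digits decimal places of the report (default 2).
#' @return named numeric vector, one percentage per level.
#' @examples
#' p <- vennPartition(list(L1 = c("A", "B"), L2 = c("B", "C")))
#' uniquePercentages(p)
#' @export
uniquePercentages <- function(p, digits = 2) {
    stopifnot(is(p, "ConstellationPartition"))
    tot <- levelTotals(p)
    if (any(tot == 0L))
        stop("undefined percentage: empty level set(s) ",
             paste(names(tot)[tot == 0L], collapse = ", "))
    cells <- partitionCells(p)
    out <- vapply(names(tot), function(l) {
        u <- if (l %in% names(cells)) length(cells[[l]]) else 0L
        round(100 * u / tot[[l]], digits)
    }, 0)
    names(out) <- names(tot)
    out
}

#' Genes significant at every level
#'
#' Returns the all-levels cell of the partition (empty if no gene is
#' shared by all levels).
#'
#' @param p a [ConstellationPartition-class].
#' @return sorted character vector.
#' @examples
#' p <- vennPartition(list(L1 = c("A", "B"), L2 = c("B", "C")))
#' commonCore(p)
#' @export
commonCore <- function(p) {
    stopifnot(is(p, "ConstellationPartition"))
    key <- paste(names(perLevelSets(p)), collapse = " & ")
    cells <- partitionCells(p)
    if (key %in% names(cells)) cells[[key]] else character(0)
}
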