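# Readers/writers for the formats the pipeline touches (GMT gene sets,
# TSV/CSV quantification tables, JSONL corpora) plus identifier
# normalization shared by every stage.

#' Normalize a gene/protein identifier
#'
#' Trims surrounding whitespace and uppercases (full Unicode
#' uppercasing, so e.g. a Greek gamma maps to its capital). The result
#' is stable under repeated application.
#'
#' @param raw character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @examples
#' normalizeGeneId(c("brca1 ", "BRCA1"))
#' @export
normalizeGeneId <- function(raw) {
    if (!length(raw))
        return(character(0))
    out <- toupper(trimws(as.character(raw)))
    if (any(is.na(out)) || any(!nzchar(out)))
        stop("invalid identifier: empty or whitespace-only input")
    out
}

#' Read a GMT gene-set file
#'
#' One set per line: name, free-text description, then members, all
#' tab-separated. Members are normalized and de-duplicated. The
#' universe defaults to the union of all members unless an explicit
#' universe file (one identifier per line) is supplied.
#'
#' @param path path to the GMT file.
#' @param universeFile optional path to a one-identifier-per-line
#'   universe file.
#' @return a [GeneSetCollection-class].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("DDR\tdesc\tBRCA1\tTP53", f)
#' readGmt(f)
#' @export
readGmt <- function(path, universeFile = NULL) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(fields) < 3L)
            stop("malformed GMT line ", i, ": fewer than 3 fields")
        nm <- trimws(fields[1L])
        if (!nzchar(nm))
            stop("malformed GMT line ", i, ": empty set name")
        if (nm %in% names(sets))
            stop("duplicate set name '", nm, "' at line ", i)
        members <- fields[-(1:2)]
        members <- members[nzchar(trimws(members))]
        sets[[nm]] <- unique(normalizeGeneId(members))
    }
    uni <- NULL
    if (!is.null(universeFile)) {
        uni <- readLines(universeFile, warn = FALSE)
        uni <- uni[nzchar(trimws(uni))]
    }
    GeneSetCollection(sets, universe = uni)
}

#' Write a GMT gene-set file
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @param descriptions optional named character vector of set
#'   descriptions (second GMT field); defaults to the set name.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(gsc, path, descriptions = NULL) {
    stopifnot(is(gsc, "GeneSetCollection"))
    sets <- geneSets(gsc)
    lines <- vapply(names(sets), function(nm) {
        desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
            descriptions[[nm]] else nm
        paste(c(nm, desc, sets[[nm]]), collapse = "\t")
    }, "", USE.NAMES = FALSE)
    writeLines(lines, path)
    invisible(path)
}

#' Read a per-protein, per-level quantification table
#'
#' Expects a header with protein, level, log2 ratio and p-value columns
#' (names configurable). Records are validated against the
#' [QuantTable-class] invariants: p-values in [0, 1], finite ratios,
#' unique (protein, level) pairs.
#'
#' @param path path to the delimited file.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param columns named character vector mapping the canonical names
#'   \code{protein}, \code{level}, \code{log2_ratio}, \code{p_value} to
#'   the file's column headers.
#' @return a [QuantTable-class].
#' @export
readQuantTable <- function(path, dialect = c("tsv", "csv"),
                           columns = c(protein = "protein",
                                       level = "level",
                                       log2_ratio = "log2_ratio",
                                       p_value = "p_value")) {
    dialect <- match.arg(dialect)
    raw <- if (dialect == "tsv")
        utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    else utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
    need <- c("protein", "level", "log2_ratio", "p_value")
    if (length(miss <- setdiff(need, names(columns))))
        stop("'columns' must map: ", paste(miss, collapse = ", "))
    if (length(miss <- setdiff(unname(columns[need]), names(raw))))
        stop("missing column(s) in ", path, ": ",
             paste(miss, collapse = ", "))
    d <- raw[unname(columns[need])]
    names(d) <- need
    QuantTable(d)
}

#' Write a quantification table
#'
#' @param qt a [QuantTable-class].
#' @param path output path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeQuantTable <- function(qt, path, dialect = c("tsv", "csv")) {
    stopifnot(is(qt, "QuantTable"))
    dialect <- match.arg(dialect)
    utils::write.table(quantData(qt), path,
                       sep = if (dialect == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene-tagged document corpus from JSON lines
#'
#' One JSON object per line with \code{doc_id}, \code{genes} and
#' \code{tokens} fields. Tokens are re-normalized under the package
#' tokenization rule and gene tags normalized; duplicate document ids
#' are an error.
#'
#' @param path path to the JSONL file.
#' @return a [Corpus-class].
#' @export
readCorpusJsonl <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    docs <- lapply(seq_along(lines), function(i) {
        obj <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
        if (length(miss <- setdiff(c("doc_id", "genes", "tokens"),
                                   names(obj))))
            stop("line ", i, ": missing field(s) ",
                 paste(miss, collapse = ", "))
        list(doc_id = as.character(obj$doc_id)[1L],
             genes = as.character(unlist(obj$genes)),
             tokens = as.character(unlist(obj$tokens)))
    })
    ids <- vapply(docs, `[[`, "", "doc_id")
    if (anyDuplicated(ids))
        stop("duplicate doc_id: ", ids[duplicated(ids)][1L])
    Corpus(docs)
}

#' Write a corpus as JSON lines
#'
#' @param corpus a [Corpus-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCorpusJsonl <- function(corpus, path) {
    stopifnot(is(corpus, "Corpus"))
    lines <- vapply(corpusDocs(corpus), function(d) {
        jsonlite::toJSON(list(doc_id = jsonlite::unbox(d$doc_id),
                              genes = d$genes, tokens = d$tokens))
    }, "")
    writeLines(lines, path)
    invisible(path)
}
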