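# Shared plumbing: seeded RNG scope, tokenization, constructors.

#' Evaluate an expression under a fixed, fully specified RNG
#'
#' All stochastic operations in the package run through this helper so a
#' seed pins down one documented bit stream (Mersenne-Twister with
#' inversion normals and rejection sampling) regardless of the caller's
#' RNG settings, and the caller's RNG state is restored afterwards.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @examples
#' a <- withSeed(7, runif(3))
#' b <- withSeed(7, runif(3))
#' identical(a, b)
#' @export
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else {
            assign(".Random.seed", old, envir = globalenv())
        }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    code
}

#' Tokenize free text into normalized terms
#'
#' Lowercases, splits on any non-alphanumeric run and drops tokens
#' shorter than two characters. This single rule is applied to corpus
#' tokens and interrogator phrases alike so queries and the vocabulary
#' always meet in the same token space.
#'
#' @param x character vector of raw text.
#' @return character vector of tokens (flattened over the input).
#' @examples
#' tokenizeTerms("Cellular Signaling!")
#' @export
tokenizeTerms <- function(x) {
    if (!length(x))
        return(character(0))
    toks <- unlist(strsplit(tolower(as.character(x)), "[^a-z0-9]+"),
                   use.names = FALSE)
    toks[nchar(toks) >= 2L]
}

#' Default English stop-word list
#'
#' Short function-word list removed before word/phrase frequency
#' counting; configurable in [countFrequencies()].
#'
#' @return character vector of stop words.
#' @export
defaultStopWords <- function() {
    c("a", "an", "and", "are", "as", "at", "be", "but", "by", "for",
      "from", "had", "has", "have", "in", "into", "is", "it", "its",
      "no", "not", "of", "on", "or", "such", "that", "the",
      "their", "then", "there", "these", "they", "this", "to", "was",
      "were", "which", "while", "with")
}

#' @describeIn QuantTable-class Construct from per-record vectors or a
#'   data.frame with the four canonical columns. Identifiers are
#'   normalized; invariants (p in [0,1], finite ratios, unique
#'   (protein, level)) are enforced.
#' @param data data.frame with columns \code{protein}, \code{level},
#'   \code{log2_ratio}, \code{p_value}.
#' @export
QuantTable <- function(data) {
    data <- as.data.frame(data, stringsAsFactors = FALSE)
    need <- c("protein", "level", "log2_ratio", "p_value")
    if (length(miss <- setdiff(need, names(data))))
        stop("missing columns: ", paste(miss, collapse = ", "))
    data <- data[need]
    data$protein <- normalizeGeneId(as.character(data$protein))
    data$level <- as.character(data$level)
    data$log2_ratio <- as.numeric(data$log2_ratio)
    data$p_value <- as.numeric(data$p_value)
    if (any(is.na(data$p_value)) || any(data$p_value < 0) ||
        any(data$p_value > 1))
        stop("p_value out of range [0, 1]")
    if (anyDuplicated(paste(data$protein, data$level, sep = "\r")))
        stop("duplicate (protein, level) records")
    rownames(data) <- NULL
    new("QuantTable", data = data)
}

#' @describeIn GeneSetCollection-class Construct from a named list of
#'   character vectors. Members are normalized and de-duplicated; the
#'   universe defaults to the union of all sets.
#' @param sets named list of character vectors.
#' @param universe optional character vector; defaults to the union of
#'   the sets. Members outside an explicit universe are an error.
#' @export
GeneSetCollection <- function(sets = list(), universe = NULL) {
    sets <- lapply(sets, function(s) unique(normalizeGeneId(as.character(s))))
    members <- unique(unlist(sets, use.names = FALSE))
    if (is.null(universe)) {
        universe <- members
    } else {
        universe <- unique(normalizeGeneId(as.character(universe)))
        if (length(bad <- setdiff(members, universe)))
            stop(length(bad), " set member(s) outside the supplied universe, ",
                 "e.g. ", bad[1L])
    }
    new("GeneSetCollection", sets = sets,
        universe = if (is.null(universe)) character(0) else universe)
}

#' @describeIn Corpus-class Construct from a list of documents. Gene
#'   tags are normalized and token sequences re-tokenized under the
#'   package rule.
#' @param docs list of lists with \code{doc_id}, \code{genes},
#'   \code{tokens}.
#' @export
Corpus <- function(docs = list()) {
    docs <- lapply(docs, function(d) {
        if (!all(c("doc_id", "genes", "tokens") %in% names(d)))
            stop("each document needs doc_id, genes and tokens")
        list(doc_id = as.character(d$doc_id)[1L],
             genes = unique(normalizeGeneId(as.character(d$genes))),
             tokens = tokenizeTerms(as.character(d$tokens)))
    })
    new("Corpus", docs = docs)
}

#' @describeIn AssociationThresholds-class Construct with the field's
#'   conventional defaults (implicit 0.1, explicit 0.2).
#' @param implicitCutoff,explicitCutoff numeric scalars,
#'   0 <= implicit <= explicit <= 1.
#' @export
associationThresholds <- function(implicitCutoff = 0.1,
                                  explicitCutoff = 0.2) {
    new("AssociationThresholds",
        implicitCutoff = as.numeric(implicitCutoff),
        explicitCutoff = as.numeric(explicitCutoff))
}

# internal: synthetic universe labels, deliberately unlike real symbols
syntheticUniverse <- function(n, prefix = "G") {
    sprintf("%s%06d", prefix, seq_len(n))
}

# internal: scalar count check
checkCount <- function(x, name, min = 0L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != floor(x))
        stop("'", name, "' must be a single integer >= ", min)
    as.integer(x)
}
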