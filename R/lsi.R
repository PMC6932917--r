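# Latent-semantic-indexing engine: gene pseudo-documents, weighted
# term-by-gene matrix, truncated SVD, cosine interrogation with
# explicit/implicit association thresholds, intersection ("theoretical")
# datasets and word/phrase frequency counting.

#' Build the term-by-gene count matrix from a corpus
#'
#' Concatenates all documents tagged with a gene into that gene's
#' pseudo-document: column g holds the summed token counts of every
#' document tagging g (a document tagged with two genes contributes
#' fully to both columns). Documents with no gene tags are ignored.
#'
#' @param corpus a [Corpus-class] with at least one gene-tagged
#'   document.
#' @return integer matrix, terms (rows, sorted vocabulary) x genes
#'   (columns, sorted).
#' @examples
#' cp <- Corpus(list(list(doc_id = "d1", genes = "GA",
#'                        tokens = c("aa", "aa", "bb"))))
#' buildGeneDocuments(cp)
#' @export
buildGeneDocuments <- function(corpus) {
    stopifnot(is(corpus, "Corpus"))
    docs <- Filter(function(d) length(d$genes) > 0, corpusDocs(corpus))
    if (!length(docs))
        stop("no gene-tagged documents in the corpus")
    genes <- sort(unique(unlist(lapply(docs, `[[`, "genes"),
                                use.names = FALSE)))
    vocab <- sort(unique(unlist(lapply(docs, `[[`, "tokens"),
                                use.names = FALSE)))
    # one (token, gene) pair per token occurrence per gene tag,
    # accumulated with a single tabulate pass
    tokAll <- unlist(lapply(docs, function(d)
        rep(d$tokens, times = length(d$genes))), use.names = FALSE)
    genAll <- unlist(lapply(docs, function(d)
        rep(d$genes, each = length(d$tokens))), use.names = FALSE)
    i <- match(tokAll, vocab)
    j <- match(genAll, genes)
    cnt <- tabulate((j - 1L) * length(vocab) + i,
                    nbins = length(vocab) * length(genes))
    matrix(as.integer(cnt), length(vocab), length(genes),
           dimnames = list(vocab, genes))
}

#' Weight a term-by-gene count matrix
#'
#' \code{log_entropy} (the classical LSI default): local weight
#' log(1 + count) times the global entropy weight
#' 1 + sum_g p_tg log(p_tg) / log(G), where p_tg is the term's count
#' share in column g and G the number of columns. A term spread
#' uniformly over all columns gets global weight 0 (no information); a
#' term confined to one column gets 1. \code{tfidf}: raw counts times
#' the smoothed inverse document frequency log((1 + G)/(1 + df)) + 1.
#' All-zero rows are removed in either scheme.
#'
#' @param counts non-empty numeric matrix (terms x genes) with
#'   dimnames.
#' @param scheme \code{"log_entropy"} (default) or \code{"tfidf"}.
#' @return weighted numeric matrix.
#' @export
weightMatrix <- function(counts, scheme = c("log_entropy", "tfidf")) {
    scheme <- match.arg(scheme)
    if (!is.matrix(counts) || !nrow(counts) || !ncol(counts))
        stop("'counts' must be a non-empty matrix")
    rs <- rowSums(counts)
    counts <- counts[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
    if (!nrow(counts))
        stop("all rows are zero")
    G <- ncol(counts)
    if (scheme == "log_entropy") {
        p <- counts / rs
        plogp <- ifelse(p > 0, p * log(p), 0)
        global <- if (G > 1) 1 + rowSums(plogp) / log(G)
                  else rep(1, nrow(counts))
        global[abs(global) < 1e-12] <- 0  # uniform terms carry none
        w <- log1p(counts) * global
    } else {
        df <- rowSums(counts > 0)
        idf <- log((1 + G) / (1 + df)) + 1
        w <- counts * idf
    }
    w[rowSums(abs(w)) > 0, , drop = FALSE]
}

#' Fit a rank-k latent semantic model
#'
#' Truncated SVD W = U D V' of the weighted term-by-gene matrix. Both
#' factors carry the singular-value scaling (symmetric convention):
#' term vectors are rows of U_k D_k, gene vectors rows of V_k D_k, so
#' stored vectors alone reproduce all cosines. Component signs are
#' fixed so the largest-magnitude term loading of each component is
#' positive, making the factorization reproducible across platforms.
#'
#' @param weighted numeric matrix from [weightMatrix()], with
#'   dimnames.
#' @param k truncation rank, 1 <= k <= min(dim(weighted)).
#' @param weighting label stored in the model (bookkeeping only).
#' @return a [SemanticModel-class].
#' @export
fitLsi <- function(weighted, k, weighting = "log_entropy") {
    if (!is.matrix(weighted) || is.null(rownames(weighted)) ||
        is.null(colnames(weighted)))
        stop("'weighted' must be a matrix with dimnames")
    k <- checkCount(k, "k", 1L)
    if (k > min(dim(weighted)))
        stop("k exceeds min(dim(weighted))")
    sv <- svd(weighted, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    U <- sv$u
    V <- sv$v
    for (j in seq_len(k)) {
        s <- sign(U[which.max(abs(U[, j])), j])
        if (s < 0) {
            U[, j] <- -U[, j]
            V[, j] <- -V[, j]
        }
    }
    new("SemanticModel",
        vocabulary = rownames(weighted), genes = colnames(weighted),
        rankK = k,
        termVectors = U * rep(d, each = nrow(U)),
        geneVectors = V * rep(d, each = nrow(V)),
        singularValues = d, weighting = as.character(weighting)[1L])
}

#' Cosine similarity of an interrogator phrase with every gene
#'
#' The query vector is the sum of the concept-space vectors of the
#' phrase's tokens (tokenized under the package rule; out-of-vocabulary
#' tokens are dropped with a warning, and a fully unknown phrase is an
#' error). Cosines are taken against every gene vector; a zero-norm
#' query or gene vector scores 0.
#'
#' @param model a [SemanticModel-class].
#' @param interrogator character scalar phrase.
#' @return named numeric vector of cosines over \code{modelGenes(model)}.
#' @export
queryCosine <- function(model, interrogator) {
    stopifnot(is(model, "SemanticModel"))
    toks <- tokenizeTerms(interrogator)
    if (!length(toks))
        stop("empty interrogator")
    known <- toks[toks %in% vocabulary(model)]
    if (!length(known))
        stop("unknown term: no interrogator token is in the vocabulary")
    if (length(known) < length(toks))
        warning(length(toks) - length(known),
                " out-of-vocabulary token(s) dropped")
    tv <- termVectors(model)
    q <- colSums(tv[match(known, vocabulary(model)), , drop = FALSE])
    gv <- geneVectors(model)
    qn <- sqrt(sum(q^2))
    gn <- sqrt(rowSums(gv^2))
    num <- as.numeric(gv %*% q)
    denom <- qn * gn
    out <- ifelse(denom > 0, num / denom, 0)
    names(out) <- modelGenes(model)
    out
}

#' Classify a cosine score as explicit/implicit/none
#'
#' Explicit association above the explicit cutoff (strictly), implicit
#' between the cutoffs (both boundaries inclusive: a score of exactly
#' 0.2 or 0.1 is implicit under the defaults), none below.
#'
#' @param score numeric vector of cosines in [-1, 1].
#' @param th an [AssociationThresholds-class] (default 0.1/0.2).
#' @return character vector in \code{c("explicit", "implicit", "none")}.
#' @examples
#' classifyAssociation(c(0.25, 0.15, 0.05))
#' @export
classifyAssociation <- function(score, th = associationThresholds()) {
    stopifnot(is(th, "AssociationThresholds"))
    if (any(score < -1 - 1e-9) || any(score > 1 + 1e-9))
        stop("scores must lie in [-1, 1]")
    ifelse(score > explicitCutoff(th), "explicit",
           ifelse(score >= implicitCutoff(th), "implicit", "none"))
}

#' Genes associated with an interrogator term
#'
#' All genes whose cosine with the interrogator reaches the implicit
#' cutoff (explicit or implicit association).
#'
#' @param model a [SemanticModel-class].
#' @param term character scalar phrase.
#' @param th an [AssociationThresholds-class].
#' @return sorted character vector of gene identifiers, with the query
#'   phrase attached as attribute \code{"term"}.
#' @export
interrogate <- function(model, term, th = associationThresholds()) {
    sc <- queryCosine(model, term)
    out <- sort(names(sc)[sc >= implicitCutoff(th)])
    attr(out, "term") <- term
    out
}

#' Intersection ("theoretical") dataset of two interrogations
#'
#' Genes associated with both interrogator phrases - the construction
#' used to derive a concept-specific signaling set from two literature
#' interrogations.
#'
#' @param model a [SemanticModel-class].
#' @param termA,termB character scalar phrases.
#' @param th an [AssociationThresholds-class].
#' @return sorted character vector of gene identifiers.
#' @export
theoreticalDataset <- function(model, termA, termB,
                               th = associationThresholds()) {
    sort(intersect(interrogate(model, termA, th),
                   interrogate(model, termB, th)))
}

#' Word or adjacent-bigram frequency counts
#'
#' Counts tokens (or adjacent token pairs) after stop-word removal,
#' mirroring a word/phrase frequency counter over text-mining output.
#' Bigrams are formed over the stream that remains after stop-word
#' removal. Ordered by descending count, ties broken lexicographically.
#'
#' @param tokens character vector of tokens (normalized internally).
#' @param topN number of items to report (default all).
#' @param mode \code{"word"} or \code{"bigram_phrase"}.
#' @param stopWords character vector to remove first.
#' @return data.frame with columns \code{item} and \code{count}.
#' @examples
#' countFrequencies(c("dna", "repair", "dna"))
#' @export
countFrequencies <- function(tokens, topN = Inf,
                             mode = c("word", "bigram_phrase"),
                             stopWords = defaultStopWords()) {
    mode <- match.arg(mode)
    if (!is.infinite(topN))
        topN <- checkCount(topN, "topN", 1L)
    toks <- tokenizeTerms(tokens)
    toks <- toks[!toks %in% stopWords]
    items <- if (mode == "word") {
        toks
    } else {
        if (length(toks) < 2L) character(0)
        else paste(toks[-length(toks)], toks[-1L])
    }
    if (!length(items))
        return(data.frame(item = character(0), count = integer(0),
                          stringsAsFactors = FALSE))
    tab <- table(items)
    out <- data.frame(item = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$item), , drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, topN)
}
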