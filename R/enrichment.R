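# Hub-protein enrichment with the hybrid score: exact hypergeometric
# upper-tail probabilities, hybrid = k * -log10(p), per-hub results and
# their per-level aggregation.

#' Exact hypergeometric upper-tail probability
#'
#' P[X >= k] for X ~ hypergeometric(N, K, n): the chance that a random
#' n-subset of an N-gene universe hits at least k of a K-gene hub set.
#' Computed exactly (no normal approximation); this one-sided tail is
#' the enrichment probability convention of Fisher's exact test as used
#' by gene-set enrichment servers.
#'
#' @param k observed overlap count, 0 <= k <= min(n, K).
#' @param n query size.
#' @param K hub (target set) size.
#' @param N universe size, with n, K <= N.
#' @return probability in (0, 1].
#' @examples
#' hypergeomUpperTail(4, 4, 5, 10)  # 5/210
#' @export
hypergeomUpperTail <- function(k, n, K, N) {
    if (any(c(k, n, K, N) < 0) || any(c(k, n, K, N) != floor(c(k, n, K, N))))
        stop("counts must be non-negative integers")
    if (n > N || K > N)
        stop("n and K must not exceed N")
    if (k > min(n, K))
        stop("k must not exceed min(n, K)")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hybrid enrichment score
#'
#' The overlap count multiplied by the negative log10 of the enrichment
#' probability, H = k * (-log10 p). Defined as 0 when k = 0 regardless
#' of p; p is clamped to \code{pFloor} before the log so scores stay
#' finite.
#'
#' @param k overlap count (>= 0).
#' @param p enrichment probability in (0, 1].
#' @param pFloor clamp floor for p (default 1e-300).
#' @return non-negative score (vectorized over k and p).
#' @examples
#' hybridScore(5, 0.01)  # 10
#' @export
hybridScore <- function(k, p, pFloor = 1e-300) {
    if (any(k < 0))
        stop("k must be >= 0")
    if (any(p <= 0) || any(p > 1))
        stop("p must lie in (0, 1]")
    ifelse(k == 0, 0, k * (-log10(pmax(p, pFloor))))
}

#' Enrich a query protein set against every hub of a collection
#'
#' One exact hypergeometric test per hub over the collection's
#' universe; query members outside the universe are dropped with a
#' warning. Results are sorted by ascending p, then descending hybrid
#' score, then hub name, so the order is deterministic.
#'
#' @param query character vector of protein identifiers.
#' @param hubs a [GeneSetCollection-class].
#' @param pFloor clamp floor passed to [hybridScore()].
#' @return data.frame with columns \code{hub}, \code{k}, \code{n},
#'   \code{K}, \code{N}, \code{p}, \code{hybrid}.
#' @examples
#' hubs <- GeneSetCollection(list(H1 = c("A", "B", "C")),
#'                           universe = LETTERS)
#' enrichSet(c("A", "B"), hubs)
#' @export
enrichSet <- function(query, hubs, pFloor = 1e-300) {
    stopifnot(is(hubs, "GeneSetCollection"))
    uni <- universe(hubs)
    if (!length(uni))
        stop("the collection has an empty universe")
    query <- unique(normalizeGeneId(as.character(query)))
    dropped <- setdiff(query, uni)
    if (length(dropped)) {
        warning(length(dropped), " query member(s) outside the universe ",
                "were dropped")
        query <- intersect(query, uni)
    }
    if (!length(query))
        stop("empty query after universe intersection")
    N <- length(uni)
    n <- length(query)
    sets <- geneSets(hubs)
    res <- data.frame(hub = names(sets),
                      k = vapply(sets, function(s)
                          length(intersect(query, s)), 0L),
                      n = n,
                      K = vapply(sets, length, 0L),
                      N = N, stringsAsFactors = FALSE)
    res$p <- mapply(hypergeomUpperTail, res$k, res$n, res$K,
                    MoreArgs = list(N = N))
    res$hybrid <- hybridScore(res$k, res$p, pFloor)
    res <- res[order(res$p, -res$hybrid, res$hub), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Summarize enrichment over a panel of target hubs
#'
#' Two aggregations over the chosen target hubs: the occurrence count
#' (number of targets enriched at \code{alpha}) and the hybrid-score
#' total (sum of their hybrid scores). Both are reported because either
#' reading of a "sum of hybrid score occurrences" is defensible; the
#' labels are explicit.
#'
#' @param results data.frame from [enrichSet()].
#' @param targetHubs character vector of hub names; must all appear in
#'   \code{results$hub}.
#' @param alpha enrichment significance level (default 0.05).
#' @return list with \code{occurrenceCount}, \code{hybridTotal} and
#'   \code{alpha}.
#' @export
summarizeHubs <- function(results, targetHubs, alpha = 0.05) {
    if (length(bad <- setdiff(targetHubs, results$hub)))
        stop("unknown hub name(s): ", paste(bad, collapse = ", "))
    sel <- results[match(targetHubs, results$hub), , drop = FALSE]
    list(occurrenceCount = sum(sel$p <= alpha),
         hybridTotal = sum(sel$hybrid),
         alpha = alpha)
}

#' Rank perturbation levels by target-hub enrichment
#'
#' Runs [enrichSet()] + [summarizeHubs()] on every level's
#' significance set and orders the levels by descending hybrid-score
#' total, ties broken by occurrence count then level label. Identifies
#' the level whose responders are most enriched for the target hub
#' panel (e.g. DNA-damage-response hubs).
#'
#' @param levelSets named list of character vectors (per-level
#'   significant proteins).
#' @param hubs a [GeneSetCollection-class].
#' @param targetHubs character vector of hub names to aggregate over;
#'   defaults to a canonical DNA-damage-response panel.
#' @param alpha enrichment significance level.
#' @return data.frame with columns \code{level},
#'   \code{occurrenceCount}, \code{hybridTotal}, best level first.
#' @export
rankLevels <- function(levelSets, hubs,
                       targetHubs = c("PRKDC", "TP53", "PARP1", "TOP1"),
                       alpha = 0.05) {
    if (!is.list(levelSets) || length(levelSets) < 1L ||
        is.null(names(levelSets)))
        stop("'levelSets' must be a named list with >= 1 level")
    targetHubs <- intersect(targetHubs, names(geneSets(hubs)))
    if (!length(targetHubs))
        stop("none of the target hubs are in the collection")
    rows <- lapply(names(levelSets), function(l) {
        s <- summarizeHubs(enrichSet(levelSets[[l]], hubs),
                           targetHubs, alpha)
        data.frame(level = l, occurrenceCount = s$occurrenceCount,
                   hybridTotal = s$hybridTotal,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$hybridTotal, -out$occurrenceCount, out$level),
               , drop = FALSE]
    rownames(out) <- NULL
    out
}
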