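# Comparative interactome analysis: exact set overlaps with
# percentages, size-matched random null distributions, and
# standardized/empirical-p comparison of observed overlaps with chance.

#' Overlap of two protein sets
#'
#' Exact intersection after identifier normalization, with the overlap
#' expressed as a percentage of the query set (rounded half-even to
#' \code{digits} places).
#'
#' @param query,target non-empty character vectors.
#' @param digits decimal places for the percentage (default 2).
#' @return list with \code{count}, \code{members} (sorted) and
#'   \code{percentOfQuery}.
#' @examples
#' setOverlap(c("A", "B", "C"), c("B", "C", "D"))
#' @export
setOverlap <- function(query, target, digits = 2) {
    query <- unique(normalizeGeneId(as.character(query)))
    target <- unique(normalizeGeneId(as.character(target)))
    if (!length(query))
        stop("undefined percentage: empty query set")
    if (!length(target))
        stop("empty target set")
    members <- sort(intersect(query, target))
    list(count = length(members), members = members,
         percentOfQuery = round(100 * length(members) / length(query),
                                digits))
}

#' Null distribution of overlap under size-matched random sets
#'
#' Draws \code{nSets} random sets of \code{size} members from
#' \code{universe} (without replacement, seeded) and records each one's
#' overlap count with \code{target}. Returns the empirical mean, sample
#' standard deviation and the raw samples. With fewer than two sets the
#' standard deviation is undefined (returned as NA with a warning).
#'
#' @param target character vector, a subset of \code{universe}.
#' @param universe character vector to resample from.
#' @param size cardinality of each random set.
#' @param nSets number of random sets (default 1000; a handful is too
#'   few for inference, see [compareWithNull()]).
#' @param seed integer seed.
#' @return list with \code{mean}, \code{sd} and \code{samples}.
#' @export
nullDistribution <- function(target, universe, size, nSets = 1000,
                             seed = 1) {
    target <- unique(normalizeGeneId(as.character(target)))
    universe <- normalizeGeneId(as.character(universe))
    if (length(setdiff(target, universe)))
        stop("target must be a subset of the universe")
    size <- checkCount(size, "size", 1L)
    nSets <- checkCount(nSets, "nSets", 1L)
    if (size > length(universe))
        stop("size exceeds the universe")
    inTarget <- universe %in% target
    samples <- withSeed(seed, {
        vapply(seq_len(nSets), function(i)
            sum(inTarget[sample.int(length(universe), size)]), 0L)
    })
    sdv <- if (nSets >= 2L) stats::sd(samples) else {
        warning("sd undefined with fewer than 2 null sets")
        NA_real_
    }
    list(mean = mean(samples), sd = sdv, samples = samples)
}

#' Compare an observed overlap with its size-matched null
#'
#' Resamples random sets of the query's own size and reports the
#' observed overlap's standardized deviation z = (count - mean)/sd and
#' the add-one empirical p-value (1 + #{samples >= count}) / (1 +
#' nSets), which can never be 0 and is bounded below by 1/(1 + nSets) -
#' with only 3 null sets the smallest attainable p is 0.25, so a small
#' null ensemble can at best be suggestive.
#'
#' @param query,target non-empty character vectors.
#' @param universe character vector the null sets are drawn from;
#'   target must be contained in it.
#' @param nSets number of null sets (default 1000).
#' @param seed integer seed; the null draw is seeded by
#'   \code{seed + |query|} so queries of equal size share the same
#'   null ensemble (consistent with [overlapMatrix()]).
#' @param queryName,targetName labels carried into the result.
#' @return list with \code{query}, \code{target}, \code{count},
#'   \code{members}, \code{percentOfQuery}, \code{nullMean},
#'   \code{nullSd}, \code{z} (NA when the null sd is 0 or undefined)
#'   and \code{pEmpirical}.
#' @export
compareWithNull <- function(query, target, universe, nSets = 1000,
                            seed = 1, queryName = "query",
                            targetName = "target") {
    ov <- setOverlap(query, target)
    size <- length(unique(normalizeGeneId(query)))
    nd <- nullDistribution(target, universe, size = size,
                           nSets = nSets, seed = seed + size)
    z <- if (!is.na(nd$sd) && nd$sd > 0) (ov$count - nd$mean) / nd$sd
         else NA_real_
    list(query = queryName, target = targetName,
         count = ov$count, members = ov$members,
         percentOfQuery = ov$percentOfQuery,
         nullMean = nd$mean, nullSd = nd$sd, z = z,
         pEmpirical = (1 + sum(nd$samples >= ov$count)) / (1 + nSets))
}

#' All query-by-target overlap comparisons
#'
#' Runs [compareWithNull()] for every query against every target set
#' of the collection. Queries of the same size share the same null
#' samples (one seeded draw of random sets per distinct query size), so
#' adding or permuting queries never changes another query's rows; row
#' order is queries in input order, targets in collection order.
#'
#' @param queries named list of character vectors.
#' @param targets a [GeneSetCollection-class]; its universe is the
#'   null-resampling universe.
#' @param nSets number of null sets per query size.
#' @param seed integer seed.
#' @return data.frame with columns \code{query}, \code{target},
#'   \code{count}, \code{percentOfQuery}, \code{nullMean},
#'   \code{nullSd}, \code{z}, \code{pEmpirical}.
#' @export
overlapMatrix <- function(queries, targets, nSets = 1000, seed = 1) {
    stopifnot(is(targets, "GeneSetCollection"))
    if (!is.list(queries) || is.null(names(queries)))
        stop("'queries' must be a named list")
    uni <- universe(targets)
    sets <- geneSets(targets)
    queries <- lapply(queries, function(q)
        unique(normalizeGeneId(as.character(q))))
    sizes <- vapply(queries, length, 0L)
    # one null ensemble per distinct query size; seed derived from size
    nullBySize <- lapply(unique(sizes), function(s)
        withSeed(seed + s, replicate(nSets,
            sample.int(length(uni), s), simplify = FALSE)))
    names(nullBySize) <- as.character(unique(sizes))
    rows <- list()
    for (qn in names(queries)) {
        q <- queries[[qn]]
        draws <- nullBySize[[as.character(length(q))]]
        for (tn in names(sets)) {
            inT <- uni %in% sets[[tn]]
            samples <- vapply(draws, function(idx) sum(inT[idx]), 0L)
            ov <- setOverlap(q, sets[[tn]])
            m <- mean(samples)
            s <- if (nSets >= 2L) stats::sd(samples) else NA_real_
            rows[[length(rows) + 1L]] <- data.frame(
                query = qn, target = tn, count = ov$count,
                percentOfQuery = ov$percentOfQuery,
                nullMean = m, nullSd = s,
                z = if (!is.na(s) && s > 0) (ov$count - m) / s
                    else NA_real_,
                pEmpirical = (1 + sum(samples >= ov$count)) / (1 + nSets),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
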