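#' @include AllClasses.R
NULL

#' Full outer join of clonotype tables
#'
#' Joins all samples of a collection on their match keys (absent = frequency
#' 0). Rows are ordered by descending mean frequency across samples, ties
#' broken lexicographically by key.
#'
#' @param collection a [RepCollection-class] with >= 2 samples.
#' @param rule a [MatchingRule-class] (`"aa!nt"` is pairwise-only and not
#'   meaningful for joins; it is treated as `"aa"`).
#' @return data.frame: `key`, `occurrence` (number of samples containing
#'   the key), then `freq.<id>` and `count.<id>` per sample; attribute
#'   `sampleIds`.
#' @export
joinSamples <- function(collection, rule = matchingRule("aa")) {
    if (length(collection) < 2L) stop("join requires at least 2 samples")
    effRule <- if (rule@level == "aa!nt")
        matchingRule("aa", includeV = rule@includeV) else rule
    ids <- names(collection)
    collapsed <- lapply(ids, function(id)
        collapseClonotypes(collection[[id]], effRule))
    keys <- sort(unique(unlist(lapply(collapsed, `[[`, "key"))))
    freq <- matrix(0, length(keys), length(ids),
                   dimnames = list(NULL, paste0("freq.", ids)))
    cnt <- matrix(0, length(keys), length(ids),
                  dimnames = list(NULL, paste0("count.", ids)))
    for (i in seq_along(ids)) {
        idx <- match(collapsed[[i]]$key, keys)
        freq[idx, i] <- collapsed[[i]]$freq
        cnt[idx, i] <- collapsed[[i]]$count
    }
    occurrence <- rowSums(freq > 0)
    out <- data.frame(key = keys, occurrence = occurrence, freq, cnt,
                      stringsAsFactors = FALSE, check.names = FALSE)
    ord <- order(-rowMeans(freq), keys)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sampleIds") <- ids
    out
}

#' Stacked top-N clonotype tracking table
#'
#' Keeps the `topN` joined clonotypes ranked by mean frequency across
#' samples and aggregates the rest into two bookkeeping rows: `"Not shown"`
#' (clonotypes observed in at least two samples but below the top-N) and
#' `"Not in overlap"` (clonotypes private to a single sample). Every sample
#' column therefore sums to 1.
#'
#' @param joined output of [joinSamples()].
#' @param topN number of named rows to keep (default 100).
#' @return numeric matrix (topN + 2 rows x samples) of frequencies, row
#'   names = clonotype keys plus the two aggregate rows.
#' @export
trackTop <- function(joined, topN = 100L) {
    if (topN <= 0L) stop("topN must be positive")
    ids <- attr(joined, "sampleIds")
    freq <- as.matrix(joined[, paste0("freq.", ids), drop = FALSE])
    nTop <- min(topN, nrow(joined))
    top <- freq[seq_len(nTop), , drop = FALSE]
    rownames(top) <- joined$key[seq_len(nTop)]
    rest <- seq_len(nrow(joined))[-seq_len(nTop)]
    shared <- rest[joined$occurrence[rest] >= 2L]
    private <- rest[joined$occurrence[rest] < 2L]
    out <- rbind(top,
                 "Not shown" = colSums(freq[shared, , drop = FALSE]),
                 "Not in overlap" = colSums(freq[private, , drop = FALSE]))
    colnames(out) <- ids
    out
}

#' Clonotype persistence between two samples
#'
#' Measures how much of the destination repertoire is occupied by
#' clonotypes already present in the source sample.
#'
#' @param joined output of [joinSamples()].
#' @param from,to sample ids present in the join.
#' @return list: `massTo` (total `to` frequency of keys detected in
#'   `from`), `nShared` (number of keys detected in both), `massFrom` (the
#'   symmetric `from` mass of keys detected in `to`).
#' @export
persistenceSummary <- function(joined, from, to) {
    ids <- attr(joined, "sampleIds")
    if (!from %in% ids) stop("unknown sample id: ", from)
    if (!to %in% ids) stop("unknown sample id: ", to)
    fFrom <- joined[[paste0("freq.", from)]]
    fTo <- joined[[paste0("freq.", to)]]
    list(massTo = sum(fTo[fFrom > 0]),
         nShared = sum(fFrom > 0 & fTo > 0),
         massFrom = sum(fFrom[fTo > 0]))
}
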