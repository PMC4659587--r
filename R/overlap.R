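#' @include AllClasses.R
NULL

#' Collapse a sample under a matching rule
#'
#' Builds the match keys of a sample: at the nucleotide level the key is the
#' CDR3 nt sequence, at the amino-acid level the CDR3 aa sequence with
#' counts summed over nucleotide variants (the variant set is retained per
#' key, which the "amino acid NOT nucleotide" pairwise rule needs). With
#' `includeV` the V segment name is appended to the key.
#'
#' @param sample a [RepSample-class].
#' @param rule a [MatchingRule-class].
#' @return data.frame(key, count, freq) with a list column `variants`
#'   holding the distinct CDR3 nt sequences behind each key.
#' @export
collapseClonotypes <- function(sample, rule = matchingRule("aa")) {
    cl <- clonotypes(sample)
    base <- if (rule@level == "nt") cl$cdr3nt else cl$cdr3aa
    key <- if (rule@includeV) paste(base, cl$v, sep = "|") else base
    agg <- tapply(cl$count, key, sum)
    keys <- names(agg)
    count <- as.numeric(agg)
    variants <- unname(lapply(split(cl$cdr3nt, key), unique))
    tot <- sum(cl$count)
    out <- data.frame(key = keys, count = count,
                      freq = if (tot > 0) count / tot else 0,
                      stringsAsFactors = FALSE)
    out$variants <- variants
    out
}

#' Overlap of two repertoires under a matching rule
#'
#' Levels `"nt"` and `"aa"`: shared keys are those present in both collapsed
#' samples. Level `"aa!nt"` ("amino acid NOT nucleotide"): an amino-acid key
#' is shared only if its nucleotide-variant sets in the two samples are
#' disjoint — any shared nucleotide variant disqualifies the key. The rule
#' removes cross-sample contamination, which is identical at the nucleotide
#' level, while keeping convergent amino-acid level sharing.
#'
#' @param s1,s2 non-empty [RepSample-class] objects.
#' @param rule a [MatchingRule-class].
#' @return An [OverlapResult-class].
#' @export
overlapPair <- function(s1, s2, rule = matchingRule("aa")) {
    if (observedDiversity(s1) == 0L || observedDiversity(s2) == 0L)
        stop("overlap requires two non-empty samples")
    effRule <- if (rule@level == "aa!nt")
        matchingRule("aa", includeV = rule@includeV) else rule
    c1 <- collapseClonotypes(s1, effRule)
    c2 <- collapseClonotypes(s2, effRule)
    i1 <- match(c2$key, c1$key)
    sharedIdx2 <- which(!is.na(i1))
    sharedIdx1 <- i1[sharedIdx2]
    if (rule@level == "aa!nt" && length(sharedIdx1)) {
        keep <- !mapply(function(a, b) any(a %in% b),
                        c1$variants[sharedIdx1], c2$variants[sharedIdx2])
        sharedIdx1 <- sharedIdx1[keep]
        sharedIdx2 <- sharedIdx2[keep]
    }
    shared <- data.frame(key = c1$key[sharedIdx1],
                         freq1 = c1$freq[sharedIdx1],
                         freq2 = c2$freq[sharedIdx2],
                         count1 = c1$count[sharedIdx1],
                         count2 = c2$count[sharedIdx2],
                         stringsAsFactors = FALSE)
    new("OverlapResult", rule = rule, shared = shared,
        s1 = nrow(c1), s2 = nrow(c2), d12 = nrow(shared),
        cross = sum(shared$count1 * shared$count2),
        sq1 = sum(c1$count^2), sq2 = sum(c2$count^2),
        n1 = sum(c1$count), n2 = sum(c2$count))
}

#' Repertoire similarity metrics
#'
#' Five pairwise measures over an [OverlapResult-class]:
#' * `metricF`: geometric mean of the total frequencies of overlapping
#'   clonotypes in the two samples, \eqn{\sqrt{(\sum f_1)(\sum f_2)}};
#'   frequencies are relative to the full samples, so F measures overlapping
#'   repertoire mass. Range 0 to 1.
#' * `metricR`: Pearson correlation of log10 frequencies over shared keys
#'   (log scale because clonotype frequencies span orders of magnitude);
#'   undefined (NA) when fewer than 3 keys are shared.
#' * `metricD`: normalized overlap size \eqn{d_{12}/(S_1 S_2)}.
#' * `metricJaccard`: \eqn{d_{12}/(S_1 + S_2 - d_{12})}.
#' * `metricMorisitaHorn`:
#'   \eqn{2\sum x_i y_i / [(\sum x^2/X^2 + \sum y^2/Y^2) X Y]} with the
#'   squared sums over all clonotypes of each sample.
#'
#' @param o an [OverlapResult-class].
#' @return numeric scalar (NA when undefined).
#' @name similarityMetrics
NULL

#' @rdname similarityMetrics
#' @export
metricF <- function(o) sqrt(sum(o@shared$freq1) * sum(o@shared$freq2))

#' @rdname similarityMetrics
#' @export
metricR <- function(o) {
    if (o@d12 < 3L) return(NA_real_)
    stats::cor(log10(o@shared$freq1), log10(o@shared$freq2))
}

#' @rdname similarityMetrics
#' @export
metricD <- function(o) o@d12 / (o@s1 * o@s2)

#' @rdname similarityMetrics
#' @export
metricJaccard <- function(o) o@d12 / (o@s1 + o@s2 - o@d12)

#' @rdname similarityMetrics
#' @export
metricMorisitaHorn <- function(o) {
    2 * o@cross / ((o@sq1 / o@n1^2 + o@sq2 / o@n2^2) * o@n1 * o@n2)
}

.METRICS <- list(F = metricF, R = metricR, D = metricD,
                 jaccard = metricJaccard, mh = metricMorisitaHorn)

#' Pairwise similarity matrix over a collection
#'
#' Computes the chosen metric for every unordered sample pair. Diagonal
#' entries hold the metric's self-similarity: 1 for F, R, Jaccard and
#' Morisita-Horn; 1/S for D (reported, but conventionally excluded from
#' clustering). Missing metric values (e.g. R with fewer than 3 shared
#' clonotypes) are recorded as NA, never imputed; if more than 20% of pairs
#' are undefined an error advises changing the rule or metric.
#'
#' @param collection a [RepCollection-class].
#' @param rule a [MatchingRule-class].
#' @param metric one of `"F"`, `"R"`, `"D"`, `"jaccard"`, `"mh"`.
#' @return symmetric numeric matrix with sample ids as dimnames and
#'   attributes `metric` and `rule`.
#' @export
pairwiseMatrix <- function(collection, rule = matchingRule("aa"),
                           metric = c("F", "R", "D", "jaccard", "mh")) {
    metric <- match.arg(metric)
    fn <- .METRICS[[metric]]
    ids <- names(collection)
    k <- length(ids)
    m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
    for (i in seq_len(k)) {
        m[i, i] <- if (metric == "D")
            1 / observedDiversity(collection[[i]]) else 1
        for (j in seq_len(k)[-seq_len(i)]) {
            o <- overlapPair(collection[[i]], collection[[j]], rule)
            m[i, j] <- m[j, i] <- fn(o)
        }
    }
    off <- m[upper.tri(m)]
    if (k >= 2 && mean(is.na(off)) > 0.2)
        stop("metric undefined for >20% of pairs; ",
             "consider a different matching rule or metric")
    attr(m, "metric") <- metric
    attr(m, "rule") <- rule@level
    m
}

#' Annotate clonotypes against a database
#'
#' Matches every clonotype key (at the rule's level) against a database of
#' (key, label) pairs; a clonotype matching several labels is reported under
#' each of them (no arbitration).
#'
#' @param sample a [RepSample-class].
#' @param database data.frame with columns `key` and `label`.
#' @param rule a [MatchingRule-class]; `"aa!nt"` is meaningless here and is
#'   treated as `"aa"`.
#' @return list with `hits` (key, label, count, freq per matched clonotype
#'   key) and `summary` (per label: number of matched keys and their total
#'   frequency).
#' @export
annotateClonotypes <- function(sample, database,
                               rule = matchingRule("aa")) {
    effRule <- if (rule@level == "aa!nt")
        matchingRule("aa", includeV = rule@includeV) else rule
    cc <- collapseClonotypes(sample, effRule)
    if (nrow(database) == 0L) {
        hits <- data.frame(key = character(0), label = character(0),
                           count = numeric(0), freq = numeric(0),
                           stringsAsFactors = FALSE)
    } else {
        idx <- match(database$key, cc$key)
        ok <- !is.na(idx)
        hits <- data.frame(key = database$key[ok],
                           label = database$label[ok],
                           count = cc$count[idx[ok]],
                           freq = cc$freq[idx[ok]],
                           stringsAsFactors = FALSE)
    }
    summary <- if (nrow(hits))
        do.call(rbind, lapply(split(hits, hits$label), function(h)
            data.frame(label = h$label[1], nKeys = nrow(h),
                       freq = sum(h$freq), stringsAsFactors = FALSE)))
    else data.frame(label = character(0), nKeys = integer(0),
                    freq = numeric(0), stringsAsFactors = FALSE)
    rownames(summary) <- NULL
    list(hits = hits, summary = summary)
}
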