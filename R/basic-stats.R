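#' @include AllClasses.R
NULL

#' Non-coding clonotype mask
#'
#' A clonotype is non-coding when its CDR3 amino-acid sequence contains a
#' stop (`*`) or frameshift marker (`_`), or its nucleotide length is not
#' divisible by 3.
#' @param cl clonotype data.frame.
#' @keywords internal
.noncoding <- function(cl) {
    grepl("[*_]", cl$cdr3aa) | nchar(cl$cdr3nt) %% 3L != 0L
}

#' Per-clonotype CDR3 junction features
#'
#' Germline and insert lengths derived from the 0-based half-open CDR3
#' markup: `vGerm = vEnd`, `jGerm = length(cdr3nt) - jStart`,
#' `ndnSize = jStart - vEnd`; when the D segment is marked,
#' `vdInsert = dStart - vEnd` and `djInsert = jStart - dEnd` (otherwise -1,
#' reported as NA). Clonotypes with undefined `vEnd` or `jStart` yield NA
#' rows and are excluded from aggregates.
#'
#' @param sample a [RepSample-class].
#' @return data.frame(vGerm, jGerm, ndnSize, vdInsert, djInsert) with one
#'   row per clonotype.
#' @export
junctionFeatures <- function(sample) {
    cl <- clonotypes(sample)
    len <- nchar(cl$cdr3nt)
    def <- cl$vEnd >= 0L & cl$jStart >= 0L
    dDef <- def & cl$dStart >= 0L & cl$dEnd >= 0L
    out <- data.frame(
        vGerm = ifelse(def, cl$vEnd, NA_integer_),
        jGerm = ifelse(def, len - cl$jStart, NA_integer_),
        ndnSize = ifelse(def, cl$jStart - cl$vEnd, NA_integer_),
        vdInsert = ifelse(dDef, cl$dStart - cl$vEnd, NA_integer_),
        djInsert = ifelse(dDef, cl$jStart - cl$dEnd, NA_integer_))
    out
}

.wmean <- function(x, w) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
}

#' Per-sample summary statistics
#'
#' Clonotype and molecule counts, mean clonotype frequency, non-coding
#' clonotype count and total frequency, frequency-weighted mean NDN / VD
#' insert / DJ insert sizes, and the convergence statistic (mean number of
#' distinct nucleotide variants per CDR3 amino-acid sequence).
#'
#' @param sample a [RepSample-class].
#' @return one-row data.frame.
#' @export
basicStats <- function(sample) {
    cl <- clonotypes(sample)
    if (nrow(cl) == 0L)
        return(data.frame(sample_id = sampleId(sample), clonotypeCount = 0L,
                          moleculeCount = 0L, meanClonotypeFreq = NA_real_,
                          noncodingCount = 0L, noncodingFreq = 0,
                          meanNdnSize = NA_real_, meanVdInsert = NA_real_,
                          meanDjInsert = NA_real_, convergence = NA_real_,
                          stringsAsFactors = FALSE))
    nc <- .noncoding(cl)
    jf <- junctionFeatures(sample)
    data.frame(sample_id = sampleId(sample),
               clonotypeCount = nrow(cl),
               moleculeCount = sum(cl$count),
               meanClonotypeFreq = mean(cl$freq),
               noncodingCount = sum(nc),
               noncodingFreq = sum(cl$freq[nc]),
               meanNdnSize = .wmean(jf$ndnSize, cl$freq),
               meanVdInsert = .wmean(jf$vdInsert, cl$freq),
               meanDjInsert = .wmean(jf$djInsert, cl$freq),
               convergence = nrow(cl) / length(unique(cl$cdr3aa)),
               stringsAsFactors = FALSE)
}

#' CDR3 length spectratype
#'
#' Distribution of repertoire weight over CDR3 length.
#'
#' @param sample a [RepSample-class].
#' @param unit `"nt"` or `"aa"` length.
#' @param weighted TRUE weights by clonotype frequency (molecule units);
#'   FALSE by unique clonotypes. Either way weights sum to 1.
#' @return data.frame(len, weight), sorted by length.
#' @export
spectratype <- function(sample, unit = c("nt", "aa"), weighted = TRUE) {
    unit <- match.arg(unit)
    cl <- clonotypes(sample)
    if (nrow(cl) == 0L)
        return(data.frame(len = integer(0), weight = numeric(0)))
    len <- nchar(if (unit == "nt") cl$cdr3nt else cl$cdr3aa)
    w <- if (weighted) cl$freq else rep(1 / nrow(cl), nrow(cl))
    agg <- tapply(w, len, sum)
    data.frame(len = as.integer(names(agg)), weight = as.numeric(agg))
}

#' V or J segment usage profile
#'
#' @param sample a [RepSample-class].
#' @param gene `"V"` or `"J"`.
#' @param weighted TRUE weights by clonotype frequency (the molecule-count
#'   weighting used throughout), FALSE by unique clonotypes.
#' @return named numeric vector of usage weights (sums to 1); only observed
#'   segments appear.
#' @export
segmentUsage <- function(sample, gene = c("V", "J"), weighted = TRUE) {
    gene <- match.arg(gene)
    cl <- clonotypes(sample)
    if (nrow(cl) == 0L) return(stats::setNames(numeric(0), character(0)))
    seg <- if (gene == "V") cl$v else cl$j
    w <- if (weighted) cl$freq else rep(1 / nrow(cl), nrow(cl))
    agg <- tapply(w, seg, sum)
    stats::setNames(as.numeric(agg), names(agg))
}

#' V-J pairing frequency matrix
#'
#' Entry (v, j) is the summed frequency of clonotypes rearranging that
#' segment pair; row sums equal the V usage profile and column sums the J
#' usage profile.
#'
#' @param sample a [RepSample-class].
#' @param weighted frequency (TRUE) or unique-clonotype (FALSE) weighting.
#' @return numeric matrix (V segments x J segments) summing to 1.
#' @export
vjPairing <- function(sample, weighted = TRUE) {
    cl <- clonotypes(sample)
    if (nrow(cl) == 0L) return(matrix(numeric(0), 0, 0))
    w <- if (weighted) cl$freq else rep(1 / nrow(cl), nrow(cl))
    tab <- tapply(w, list(cl$v, cl$j), sum, default = 0)
    m <- matrix(as.numeric(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
    m
}

## Frequency-weighted per-sample means of junction features.
.junctionMeans <- function(sample) {
    cl <- clonotypes(sample)
    jf <- junctionFeatures(sample)
    c(vGerm = .wmean(jf$vGerm, cl$freq),
      jGerm = .wmean(jf$jGerm, cl$freq),
      ndnSize = .wmean(jf$ndnSize, cl$freq),
      vdInsert = .wmean(jf$vdInsert, cl$freq),
      djInsert = .wmean(jf$djInsert, cl$freq))
}

#' Group comparison of CDR3 junction features
#'
#' Computes the frequency-weighted per-sample mean of each junction feature
#' (V germline, J germline, NDN size, VD/DJ inserts) and compares the two
#' groups of `factor` with an unpaired two-tailed t-test per feature
#' (Welch by default).
#'
#' @param collection a [RepCollection-class].
#' @param factor name of a two-level metadata column.
#' @param varEqual use the pooled-variance (Student) t-test.
#' @return list with `perSample` (sample x feature data.frame) and `tests`
#'   (per feature: group means, difference, p).
#' @export
groupJunctionSummary <- function(collection, factor, varEqual = FALSE) {
    md <- sampleMetadata(collection)
    if (!factor %in% colnames(md)) stop("unknown metadata factor: ", factor)
    g <- as.character(md[[factor]])
    lev <- unique(g[!is.na(g)])
    if (length(lev) != 2L) stop("factor must have exactly two groups")
    if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
    per <- t(vapply(names(collection),
                    function(id) .junctionMeans(collection[[id]]),
                    numeric(5)))
    perSample <- data.frame(sample_id = names(collection), group = g, per,
                            stringsAsFactors = FALSE, row.names = NULL)
    tests <- lapply(colnames(per), function(feat) {
        a <- per[g == lev[1], feat]
        b <- per[g == lev[2], feat]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        p <- if (length(a) >= 2 && length(b) >= 2 &&
                 (stats::sd(c(a, b)) > 0))
            stats::t.test(a, b, var.equal = varEqual)$p.value
        else if (length(a) >= 2 && length(b) >= 2) 1
        else NA_real_
        data.frame(feature = feat, mean1 = mean(a), mean2 = mean(b),
                   diff = mean(a) - mean(b), p = p,
                   stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
    attr(tests, "groups") <- lev
    list(perSample = perSample, tests = tests)
}

#' Paired within-donor junction comparison for a V-segment subset
#'
#' For each sample, the frequency-weighted mean of a junction feature is
#' computed over all clonotypes and over the clonotypes using one of the
#' listed V segments; the two series are compared with a paired two-tailed
#' t-test across samples. This is the all-V versus selected-V design used to
#' ask whether a segment subset is intrinsically biased toward, e.g., longer
#' VJ junctions.
#'
#' @param collection a [RepCollection-class] (>= 2 samples).
#' @param segments character vector of V segment names.
#' @param feature junction feature name (default "ndnSize").
#' @return list(perSample, p).
#' @export
junctionSubsetPairedTest <- function(collection, segments,
                                     feature = "ndnSize") {
    if (length(collection) < 2L) stop("need at least 2 samples")
    per <- t(vapply(names(collection), function(id) {
        s <- collection[[id]]
        cl <- clonotypes(s)
        jf <- junctionFeatures(s)
        sel <- cl$v %in% segments
        c(all = .wmean(jf[[feature]], cl$freq),
          subset = .wmean(jf[[feature]][sel], cl$freq[sel]))
    }, numeric(2)))
    d <- per[, "subset"] - per[, "all"]
    d <- d[!is.na(d)]
    if (length(d) < 2L) stop("fewer than 2 samples with the feature defined")
    p <- if (stats::sd(d) > 0) stats::t.test(d)$p.value
         else if (all(d == 0)) 1 else 0
    list(perSample = data.frame(sample_id = rownames(per), per,
                                row.names = NULL, stringsAsFactors = FALSE),
         p = p)
}
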