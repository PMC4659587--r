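#' @import methods
NULL

## Canonical clonotype table columns, in native file order.
.CLONO_COLS <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                 "vEnd", "dStart", "dEnd", "jStart")

.emptyClonotypes <- function() {
    data.frame(count = integer(0), freq = numeric(0),
               cdr3nt = character(0), cdr3aa = character(0),
               v = character(0), d = character(0), j = character(0),
               vEnd = integer(0), dStart = integer(0), dEnd = integer(0),
               jStart = integer(0), stringsAsFactors = FALSE)
}

#' RepSample: one repertoire sample
#'
#' A named collection of clonotype records. Each record carries a molecule
#' count, its frequency within the sample, CDR3 nucleotide and amino-acid
#' sequences, V/D/J segment names ("." when the D segment is undefined) and
#' the germline markup of the CDR3: 0-based half-open coordinates into
#' `cdr3nt` (`vEnd`/`dEnd` exclusive, `dStart`/`jStart` inclusive, -1 when
#' undefined).
#'
#' @slot sampleId single character identifier.
#' @slot clonotypes data.frame with columns `count`, `freq`, `cdr3nt`,
#'   `cdr3aa`, `v`, `d`, `j`, `vEnd`, `dStart`, `dEnd`, `jStart`.
#'
#' @exportClass RepSample
setClass("RepSample",
    representation(sampleId = "character", clonotypes = "data.frame"))

setValidity("RepSample", function(object) {
    msgs <- character(0)
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msgs <- c(msgs, "sampleId must be a single non-NA string")
    cl <- object@clonotypes
    missing <- setdiff(.CLONO_COLS, colnames(cl))
    if (length(missing))
        return(paste("missing clonotype columns:",
                     paste(missing, collapse = ", ")))
    if (nrow(cl)) {
        if (any(cl$count < 0)) msgs <- c(msgs, "counts must be non-negative")
        if (any(cl$freq < -1e-12 | cl$freq > 1 + 1e-12))
            msgs <- c(msgs, "frequencies must lie in [0, 1]")
        if (abs(sum(cl$freq) - 1) > 1e-6)
            msgs <- c(msgs, "frequencies must sum to 1 (within 1e-6)")
        len <- nchar(cl$cdr3nt)
        def <- cl$vEnd >= 0 & cl$jStart >= 0
        bad <- def & (cl$vEnd > cl$jStart | cl$jStart > len)
        dd <- def & cl$dStart >= 0 & cl$dEnd >= 0
        bad <- bad | (dd & (cl$dStart < cl$vEnd | cl$dEnd < cl$dStart |
                            cl$jStart < cl$dEnd))
        if (any(bad))
            msgs <- c(msgs, "germline markup violates 0 <= vEnd <= dStart <= dEnd <= jStart <= length(cdr3nt)")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a RepSample
#'
#' Frequencies are recomputed from counts; rows are sorted by descending
#' count with lexicographic `cdr3nt` as tie-break (the native table order).
#'
#' @param sampleId sample identifier.
#' @param clonotypes data.frame of clonotype records; missing markup columns
#'   are filled with -1 and a missing `d` column with ".".
#' @return A [RepSample-class] object.
#' @export
RepSample <- function(sampleId, clonotypes = .emptyClonotypes()) {
    cl <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
    if (!"d" %in% colnames(cl)) cl$d <- rep(".", nrow(cl))
    for (col in c("vEnd", "dStart", "dEnd", "jStart"))
        if (!col %in% colnames(cl)) cl[[col]] <- rep(-1L, nrow(cl))
    if (!"cdr3aa" %in% colnames(cl)) cl$cdr3aa <- translateCdr3(cl$cdr3nt)
    cl$count <- as.integer(round(cl$count))
    tot <- sum(cl$count)
    cl$freq <- if (tot > 0) cl$count / tot else rep(0, nrow(cl))
    cl <- cl[order(-cl$count, cl$cdr3nt), .CLONO_COLS, drop = FALSE]
    rownames(cl) <- NULL
    new("RepSample", sampleId = as.character(sampleId), clonotypes = cl)
}

#' RepCollection: an ordered set of samples plus metadata
#'
#' @slot samples list of [RepSample-class], named by sample id.
#' @slot metadata data.frame with one row per sample (column `sample_id`
#'   plus free-form factor columns such as `group` or `batch`).
#'
#' @exportClass RepCollection
setClass("RepCollection",
    representation(samples = "list", metadata = "data.frame"))

setValidity("RepCollection", function(object) {
    ids <- vapply(object@samples, function(s) s@sampleId, character(1))
    if (anyDuplicated(ids)) return("duplicate sample ids")
    if (!identical(names(object@samples), unname(ids)))
        return("sample list names must equal sample ids")
    if (nrow(object@metadata)) {
        if (!"sample_id" %in% colnames(object@metadata))
            return("metadata must have a sample_id column")
        if (!identical(object@metadata$sample_id, unname(ids)))
            return("metadata rows must match samples (same ids, same order)")
    }
    TRUE
})

#' Construct a RepCollection
#'
#' @param samples list of [RepSample-class] objects.
#' @param metadata optional data.frame with a `sample_id` column matching the
#'   samples (rows are re-ordered to sample order).
#' @return A [RepCollection-class].
#' @export
RepCollection <- function(samples, metadata = NULL) {
    ids <- vapply(samples, function(s) s@sampleId, character(1))
    names(samples) <- ids
    if (is.null(metadata))
        metadata <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    else {
        metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
        metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
        rownames(metadata) <- NULL
    }
    new("RepCollection", samples = samples, metadata = metadata)
}

#' CountSpectrum: abundance vector and counts-of-counts
#'
#' The substrate of all diversity estimators: the clonotype abundance vector
#' \eqn{x_i}, the total molecule count \eqn{n = \sum x_i}, the observed
#' richness \eqn{S_{obs}}, and the counts-of-counts \eqn{f_k} (number of
#' clonotypes observed exactly \eqn{k} times).
#'
#' @slot n total molecule count.
#' @slot x numeric abundance vector (one entry per clonotype).
#' @slot f named numeric vector; `f[["k"]]` = number of clonotypes with
#'   abundance k.
#' @slot sObs observed richness.
#'
#' @exportClass CountSpectrum
setClass("CountSpectrum",
    representation(n = "numeric", x = "numeric", f = "numeric",
                   sObs = "numeric"))

setValidity("CountSpectrum", function(object) {
    if (abs(sum(object@x) - object@n) > 1e-9) return("sum(x) != n")
    if (length(object@x) != object@sObs) return("length(x) != S_obs")
    k <- as.numeric(names(object@f))
    if (abs(sum(k * object@f) - object@n) > 1e-9)
        return("sum(k * f_k) != n")
    if (abs(sum(object@f) - object@sObs) > 1e-9)
        return("sum(f_k) != S_obs")
    TRUE
})

#' MatchingRule: how clonotypes are equated across samples
#'
#' Levels: `"nt"` (CDR3 nucleotide sequence), `"aa"` (CDR3 amino-acid
#' sequence, nucleotide variants pooled), `"aa!nt"` (amino acid NOT
#' nucleotide: amino-acid match whose nucleotide variant sets are disjoint —
#' robust to cross-sample contamination because a shared nucleotide variant
#' disqualifies the key). `includeV` adds the V segment name to the key.
#'
#' @slot level one of "nt", "aa", "aa!nt".
#' @slot includeV logical.
#'
#' @exportClass MatchingRule
setClass("MatchingRule",
    representation(level = "character", includeV = "logical"))

#' @param level matching level; `"aa-not-nt"` is accepted as an alias of
#'   `"aa!nt"`.
#' @param includeV include the V segment in the match key (default FALSE).
#' @return A [MatchingRule-class].
#' @rdname MatchingRule-class
#' @export
matchingRule <- function(level = c("nt", "aa", "aa!nt", "aa-not-nt"),
                         includeV = FALSE) {
    level <- match.arg(level)
    if (level == "aa-not-nt") level <- "aa!nt"
    new("MatchingRule", level = level, includeV = includeV)
}

#' OverlapResult: the shared-clonotype set of a sample pair
#'
#' Produced by [overlapPair()]; all pairwise similarity metrics derive from
#' it. `shared` holds per-key frequencies/counts in each sample; the slots
#' `cross`, `sq1`, `sq2`, `n1`, `n2` cache the count cross-product over
#' shared keys and the full-sample squared-count sums needed by the
#' Morisita-Horn index.
#'
#' @slot rule the [MatchingRule-class] used.
#' @slot shared data.frame(key, freq1, freq2, count1, count2).
#' @slot s1,s2 collapsed clonotype counts of each sample.
#' @slot d12 number of shared keys.
#' @slot cross sum of count1*count2 over shared keys.
#' @slot sq1,sq2 sums of squared counts over all clonotypes of each sample.
#' @slot n1,n2 total molecule counts.
#'
#' @exportClass OverlapResult
setClass("OverlapResult",
    representation(rule = "MatchingRule", shared = "data.frame",
                   s1 = "numeric", s2 = "numeric", d12 = "numeric",
                   cross = "numeric", sq1 = "numeric", sq2 = "numeric",
                   n1 = "numeric", n2 = "numeric"))

setValidity("OverlapResult", function(object) {
    if (object@d12 != nrow(object@shared)) return("d12 != nrow(shared)")
    if (object@d12 > min(object@s1, object@s2))
        return("d12 exceeds min(S1, S2)")
    if (nrow(object@shared) &&
        any(object@shared$freq1 <= 0 | object@shared$freq2 <= 0))
        return("shared keys must have positive frequency in both samples")
    TRUE
})

#' DiversityEstimate: a single diversity figure
#'
#' @slot name estimator name.
#' @slot value headline value (effective-number scale for Shannon/Simpson).
#' @slot sd resampling standard deviation, or NA.
#' @slot kind one of "observed", "lower-bound", "index", "interpolated",
#'   "extrapolated".
#' @slot details list of estimator-specific extras (e.g. raw Shannon entropy).
#'
#' @exportClass DiversityEstimate
setClass("DiversityEstimate",
    representation(name = "character", value = "numeric", sd = "numeric",
                   kind = "character", details = "list"))

.divEst <- function(name, value, kind, sd = NA_real_, details = list())
    new("DiversityEstimate", name = name, value = value, sd = sd,
        kind = kind, details = details)

#' FormatSpec: column mapping for third-party clonotype-table dialects
#'
#' Maps input column names onto the canonical clonotype fields. Only the
#' native dialect is guaranteed bit-exact; third-party dialects are handled
#' through presets of this mapping, not bespoke parsers.
#'
#' @slot mapping named character vector: canonical field -> input column
#'   name. Must cover at least count, cdr3nt, cdr3aa, v, j.
#' @slot hasHeader logical.
#' @slot missingToken token denoting a missing segment (default ".").
#'
#' @exportClass FormatSpec
setClass("FormatSpec",
    representation(mapping = "character", hasHeader = "logical",
                   missingToken = "character"))

setValidity("FormatSpec", function(object) {
    need <- c("count", "cdr3nt", "cdr3aa", "v", "j")
    missing <- setdiff(need, names(object@mapping))
    if (length(missing))
        return(paste("mapping must cover:", paste(missing, collapse = ", ")))
    TRUE
})

.NATIVE_MAPPING <- c(count = "count", freq = "freq", cdr3nt = "cdr3nt",
                     cdr3aa = "cdr3aa", v = "v", d = "d", j = "j",
                     vEnd = "VEnd", dStart = "DStart", dEnd = "DEnd",
                     jStart = "JStart")

#' Create a format specification
#'
#' @param preset `"native"` (this package's own dialect) or `"mixcr"`
#'   (MiXCR clone tables); ignored when `mapping` is given.
#' @param mapping optional named character vector overriding the preset.
#' @param hasHeader does the file carry a header row.
#' @param missingToken missing-segment token.
#' @return A [FormatSpec-class].
#' @rdname FormatSpec-class
#' @export
formatSpec <- function(preset = c("native", "mixcr"), mapping = NULL,
                       hasHeader = TRUE, missingToken = ".") {
    if (is.null(mapping)) {
        preset <- match.arg(preset)
        mapping <- switch(preset,
            native = .NATIVE_MAPPING,
            mixcr = c(count = "cloneCount", freq = "cloneFraction",
                      cdr3nt = "nSeqCDR3", cdr3aa = "aaSeqCDR3",
                      v = "allVHitsWithScore", d = "allDHitsWithScore",
                      j = "allJHitsWithScore"))
    }
    new("FormatSpec", mapping = mapping, hasHeader = hasHeader,
        missingToken = missingToken)
}
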