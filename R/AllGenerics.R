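#' @include AllClasses.R
NULL

#' Accessors for repertoire containers
#'
#' @param x a [RepSample-class] or [RepCollection-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))

#' @rdname accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname accessors
#' @export
setGeneric("observedDiversity", function(x) standardGeneric("observedDiversity"))

#' @rdname accessors
#' @export
setGeneric("repSamples", function(x) standardGeneric("repSamples"))

#' @rdname accessors
#' @export
setGeneric("sampleMetadata", function(x) standardGeneric("sampleMetadata"))

#' @rdname accessors
#' @export
setGeneric("estValue", function(x) standardGeneric("estValue"))

#' @rdname accessors
setMethod("sampleId", "RepSample", function(x) x@sampleId)

#' @rdname accessors
setMethod("clonotypes", "RepSample", function(x) x@clonotypes)

#' @rdname accessors
setMethod("totalCount", "RepSample", function(x) sum(x@clonotypes$count))

#' @rdname accessors
setMethod("observedDiversity", "RepSample", function(x) nrow(x@clonotypes))

#' @rdname accessors
setMethod("repSamples", "RepCollection", function(x) x@samples)

#' @rdname accessors
setMethod("sampleMetadata", "RepCollection", function(x) x@metadata)

#' @rdname accessors
setMethod("estValue", "DiversityEstimate", function(x) x@value)

#' @export
setMethod("length", "RepCollection", function(x) length(x@samples))

#' @export
setMethod("names", "RepCollection", function(x) names(x@samples))

#' @param i index or sample id
#' @rdname accessors
#' @export
setMethod("[[", "RepCollection", function(x, i) x@samples[[i]])

setMethod("show", "RepSample", function(object) {
    cat("RepSample '", object@sampleId, "': ",
        nrow(object@clonotypes), " clonotypes, ",
        sum(object@clonotypes$count), " molecules\n", sep = "")
    if (nrow(object@clonotypes))
        print(utils::head(object@clonotypes, 3))
})

setMethod("show", "RepCollection", function(object) {
    cat("RepCollection of", length(object@samples), "samples:",
        paste(utils::head(names(object@samples), 6), collapse = ", "),
        if (length(object@samples) > 6) "..." else "", "\n")
    extra <- setdiff(colnames(object@metadata), "sample_id")
    if (length(extra))
        cat("metadata factors:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "CountSpectrum", function(object) {
    cat("CountSpectrum: n =", object@n, ", S_obs =", object@sObs, "\n")
})

setMethod("show", "DiversityEstimate", function(object) {
    cat(object@name, " (", object@kind, "): ",
        format(object@value, digits = 6),
        if (!is.na(object@sd)) paste0(" +/- ", format(object@sd, digits = 3)),
        "\n", sep = "")
})

setMethod("show", "MatchingRule", function(object) {
    cat("MatchingRule:", object@level,
        if (object@includeV) "+V" else "", "\n")
})

setMethod("show", "OverlapResult", function(object) {
    cat("OverlapResult (", object@rule@level, "): d12 = ", object@d12,
        ", S1 = ", object@s1, ", S2 = ", object@s2, "\n", sep = "")
})
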