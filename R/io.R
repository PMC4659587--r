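#' @include AllClasses.R
NULL

#' Translate a CDR3 nucleotide sequence
#'
#' Single-frame left-to-right translation under the standard genetic code.
#' An incomplete 3' codon (length not divisible by 3) is rendered as a single
#' `'_'` marker; codons containing `N` translate to `'X'`; stop codons to
#' `'*'`.
#'
#' @param cdr3nt character vector of DNA strings over \{A,C,G,T,N\}.
#' @return character vector of amino-acid strings.
#' @examples
#' translateCdr3("TGTGCCAGCAGC")  # "CASS"
#' translateCdr3("TGTGCCAG")      # "CA_"
#' @export
translateCdr3 <- function(cdr3nt) {
    x <- as.character(cdr3nt)
    if (length(x) == 0L) return(character(0))
    bad <- grepl("[^ACGTN]", x) & !is.na(x)
    if (any(bad))
        stop("illegal character in CDR3 nucleotide sequence: ",
             x[which(bad)[1L]])
    n <- nchar(x)
    ok <- !is.na(x)
    out <- rep(NA_character_, length(x))
    full <- substr(x[ok], 1L, n[ok] - n[ok] %% 3L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(full),
                                             if.fuzzy.codon = "X"))
    out[ok] <- ifelse(n[ok] %% 3L > 0L, paste0(aa, "_"), aa)
    out
}

.NATIVE_HEADER <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                    "VEnd", "DStart", "DEnd", "JStart")

#' Read one clonotype table
#'
#' Reads a tab-delimited clonotype table into a [RepSample-class].
#' Frequencies are always recomputed as `count / total_count`; an input
#' frequency column disagreeing by more than 1% on any row triggers a
#' warning (upstream tools disagree on rounding), never an error. Rows are
#' sorted by descending count (ties: lexicographic CDR3 nt). Missing markup
#' coordinates become -1 and a missing D segment ".". Duplicate rows are
#' preserved as-is; merging is an explicit collapse operation.
#'
#' @param path file path.
#' @param spec a [FormatSpec-class]; defaults to the native dialect.
#' @param sampleId sample identifier; defaults to the file base name.
#' @return A [RepSample-class].
#' @export
readSample <- function(path, spec = formatSpec("native"),
                       sampleId = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path)) stop("cannot read clonotype table: ", path)
    tab <- utils::read.delim(path, header = spec@hasHeader, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character",
                             na.strings = character(0), quote = "")
    map <- spec@mapping
    absent <- setdiff(unname(map[c("count", "cdr3nt", "cdr3aa", "v", "j")]),
                      colnames(tab))
    if (nrow(tab) == 0L && !spec@hasHeader)
        absent <- character(0)
    if (length(absent))
        stop("column(s) absent from ", path, ": ",
             paste(absent, collapse = ", "))
    if (nrow(tab) == 0L)
        return(RepSample(sampleId))
    grab <- function(field, default) {
        col <- map[field]
        if (!is.na(col) && col %in% colnames(tab)) tab[[col]]
        else rep(default, nrow(tab))
    }
    count <- suppressWarnings(as.numeric(grab("count", NA)))
    if (anyNA(count)) {
        line <- which(is.na(count))[1L] + as.integer(spec@hasHeader)
        stop("non-numeric count on line ", line, " of ", path)
    }
    coord <- function(field) {
        raw <- grab(field, "-1")
        raw[raw == "" | raw == spec@missingToken] <- "-1"
        val <- suppressWarnings(as.integer(round(as.numeric(raw))))
        val[is.na(val)] <- -1L
        val
    }
    d <- grab("d", ".")
    d[d == "" | d == spec@missingToken] <- "."
    cl <- data.frame(count = count,
                     cdr3nt = grab("cdr3nt", ""),
                     cdr3aa = grab("cdr3aa", ""),
                     v = grab("v", "."), d = d, j = grab("j", "."),
                     vEnd = coord("vEnd"), dStart = coord("dStart"),
                     dEnd = coord("dEnd"), jStart = coord("jStart"),
                     stringsAsFactors = FALSE)
    inFreq <- suppressWarnings(as.numeric(grab("freq", NA)))
    out <- RepSample(sampleId, cl)
    if (!anyNA(inFreq) && sum(count) > 0) {
        recomputed <- count / sum(count)
        if (any(abs(inFreq - recomputed) > 0.01))
            warning("input frequencies in ", path,
                    " disagree with count/total by >1%; recomputed")
    }
    out
}

#' Write a clonotype table in the native dialect
#'
#' `readSample(writeSample(s))` reproduces every field exactly.
#'
#' @param sample a [RepSample-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSample <- function(sample, path) {
    stopifnot(is(sample, "RepSample"))
    cl <- sample@clonotypes
    out <- data.frame(count = cl$count,
                      freq = format(cl$freq, digits = 15, trim = TRUE,
                                    scientific = FALSE),
                      cdr3nt = cl$cdr3nt, cdr3aa = cl$cdr3aa,
                      v = cl$v, d = cl$d, j = cl$j,
                      VEnd = cl$vEnd, DStart = cl$dStart,
                      DEnd = cl$dEnd, JStart = cl$jStart,
                      stringsAsFactors = FALSE, check.names = FALSE)
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = .NATIVE_HEADER)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write clonotype table to ", path, ": ",
                          conditionMessage(ok))
    invisible(path)
}

#' Read a sample collection from a metadata table
#'
#' The metadata table is tab-delimited with header columns `file_name`,
#' `sample_id`, followed by free-form factor columns. File paths are resolved
#' relative to the metadata file's directory. Blank factor cells are stored
#' as missing values.
#'
#' @param metadataPath path to the metadata TSV.
#' @param spec a [FormatSpec-class] applied to every sample file.
#' @return A [RepCollection-class] with samples in metadata order.
#' @export
readCollection <- function(metadataPath, spec = formatSpec("native")) {
    if (!file.exists(metadataPath))
        stop("cannot read metadata table: ", metadataPath)
    md <- utils::read.delim(metadataPath, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            na.strings = c("", "NA"))
    need <- c("file_name", "sample_id")
    if (!all(need %in% colnames(md)))
        stop("metadata must have columns file_name and sample_id")
    if (anyDuplicated(md$sample_id))
        stop("duplicate sample_id in metadata: ",
             paste(unique(md$sample_id[duplicated(md$sample_id)]),
                   collapse = ", "))
    dir <- dirname(metadataPath)
    paths <- ifelse(grepl("^(/|[A-Za-z]:)", md$file_name), md$file_name,
                    file.path(dir, md$file_name))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("metadata references missing file(s): ",
             paste(missing, collapse = ", "))
    samples <- mapply(function(p, id) readSample(p, spec, sampleId = id),
                      paths, md$sample_id, SIMPLIFY = FALSE)
    meta <- md[, setdiff(colnames(md), "file_name"), drop = FALSE]
    RepCollection(samples, meta)
}

#' Write a collection as native tables plus a metadata table
#'
#' @param collection a [RepCollection-class].
#' @param dir output directory (created if absent).
#' @return the metadata file path, invisibly.
#' @export
writeCollection <- function(collection, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    md <- sampleMetadata(collection)
    files <- paste0(md$sample_id, ".txt")
    for (i in seq_along(collection))
        writeSample(collection[[i]], file.path(dir, files[i]))
    out <- cbind(data.frame(file_name = files, stringsAsFactors = FALSE), md)
    mdPath <- file.path(dir, "metadata.txt")
    utils::write.table(out, mdPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(mdPath)
}
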