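#' @include AllClasses.R
NULL

.DEFAULT_V <- c("TRBV5-1", "TRBV5-6", "TRBV5-8", "TRBV7-6", "TRBV7-8",
                "TRBV9", "TRBV12-3", "TRBV15", "TRBV19", "TRBV20-1",
                "TRBV28", "TRBV29-1")
.DEFAULT_J <- c("TRBJ2-7", "TRBJ2-1", "TRBJ2-3", "TRBJ1-1", "TRBJ1-2",
                "TRBJ2-5")

## Deterministic synthetic germline stub for a segment name (not a real
## IMGT sequence; biological realism is not required for algorithmic tests).
.segStub <- function(name, len = 12L, prefix = "") {
    codes <- utf8ToInt(name)
    k <- len - nchar(prefix)
    idx <- (cumsum(rep(codes, length.out = k)) + 7L * seq_len(k)) %% 4L + 1L
    paste0(prefix, paste(c("A", "C", "G", "T")[idx], collapse = ""))
}

#' Specification of a synthetic repertoire
#'
#' Defines the statistical structure of a simulated sample: Zipf (power-law)
#' clone sizes (heavy-tailed abundances keep rarefaction curves far from
#' saturation, as real repertoires are), V/J segment usage profiles,
#' germline + insert CDR3 construction (CDR3 = trimmed V stub + uniform
#' ACGT insert of geometric length + trimmed J stub, with consistent
#' 0-based half-open markup), between-sample usage noise, and optional
#' public-clonotype sharing.
#'
#' @param richness number of clones in the underlying population.
#' @param cloneSizeAlpha power-law exponent (> 1); clone i has frequency
#'   proportional to (i + cloneSizeShift)^-alpha. Default 1.5.
#' @param cloneSizeShift Zipf-Mandelbrot head-flattening parameter; 0 gives
#'   a pure Zipf law whose top clone dominates the sample, larger values
#'   temper the head so top clones carry a few percent of the mass, as in
#'   real repertoires. Default 20.
#' @param nMolecules molecules drawn per sample (multinomial).
#' @param vUsage,jUsage named probability vectors over segment names
#'   (normalized internally).
#' @param insertLenMean mean of the geometric insert length, nt (default 6,
#'   a typical NDN scale).
#' @param usageNoiseCv between-sample coefficient of variation of segment
#'   usage (lognormal multiplicative noise; default 0.2, a realistic
#'   inter-individual spread).
#' @param maxTrim maximum germline trimming of the V/J stubs inside the
#'   CDR3 (uniform on 0..maxTrim, default 3).
#' @param inFrameProb fraction of clones whose junction is constrained to
#'   an in-frame (length divisible by 3) CDR3, mimicking selection for
#'   productive rearrangements; the rest stay unconstrained and mostly
#'   non-coding. Default 0.9.
#' @param poolRichness number of clones in a shared public pool (used by
#'   [simulateCohort()] twin pairs; default 100).
#' @return a list of class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(richness = 3000L, cloneSizeAlpha = 1.5,
                          cloneSizeShift = 20, nMolecules = 50000L,
                          vUsage = NULL, jUsage = NULL,
                          insertLenMean = 6, usageNoiseCv = 0.2,
                          maxTrim = 3L, inFrameProb = 0.9,
                          poolRichness = 100L) {
    if (cloneSizeAlpha <= 1) stop("cloneSizeAlpha must exceed 1")
    if (is.null(vUsage)) {
        vUsage <- stats::setNames(
            seq(2, 1, length.out = length(.DEFAULT_V)), .DEFAULT_V)
    }
    if (is.null(jUsage)) {
        jUsage <- stats::setNames(
            seq(2, 1, length.out = length(.DEFAULT_J)), .DEFAULT_J)
    }
    if (any(vUsage < 0) || any(jUsage < 0) || sum(vUsage) == 0 ||
        sum(jUsage) == 0)
        stop("usage vectors must be non-negative with positive sum")
    if (cloneSizeShift < 0) stop("cloneSizeShift must be non-negative")
    spec <- list(richness = as.integer(richness),
                 cloneSizeAlpha = cloneSizeAlpha,
                 cloneSizeShift = cloneSizeShift,
                 nMolecules = as.integer(nMolecules),
                 vUsage = vUsage / sum(vUsage),
                 jUsage = jUsage / sum(jUsage),
                 insertLenMean = insertLenMean,
                 usageNoiseCv = usageNoiseCv,
                 maxTrim = as.integer(maxTrim),
                 inFrameProb = inFrameProb,
                 poolRichness = as.integer(poolRichness))
    class(spec) <- "syntheticSpec"
    spec
}

.applyEffect <- function(usage, effect) {
    if (is.null(effect)) return(usage)
    hit <- intersect(names(effect), names(usage))
    if (any(effect <= 0)) stop("fold multipliers must be positive")
    usage[hit] <- usage[hit] * effect[hit]
    usage / sum(usage)
}

.noisyUsage <- function(usage, cv) {
    if (cv <= 0) return(usage)
    sdlog <- sqrt(log(1 + cv^2))
    u <- usage * stats::rlnorm(length(usage), -sdlog^2 / 2, sdlog)
    u / sum(u)
}

## Draw clone-level attributes (segments, trims, inserts) and assemble
## CDR3 sequences with markup for `k` clones.
.makeClones <- function(k, vUsage, jUsage, insertLenMean, maxTrim,
                        inFrameProb = 0.9) {
    vSeg <- sample(names(vUsage), k, replace = TRUE, prob = vUsage)
    jSeg <- sample(names(jUsage), k, replace = TRUE, prob = jUsage)
    trimV <- sample.int(maxTrim + 1L, k, replace = TRUE) - 1L
    trimJ <- sample.int(maxTrim + 1L, k, replace = TRUE) - 1L
    insLen <- stats::rgeom(k, prob = 1 / (1 + insertLenMean))
    inFrame <- stats::runif(k) < inFrameProb
    pool <- sample(c("A", "C", "G", "T"), sum(insLen), replace = TRUE)
    ends <- cumsum(insLen)
    starts <- ends - insLen + 1L
    poolStr <- paste(pool, collapse = "")
    inserts <- substring(poolStr, starts, ends)
    inserts[insLen == 0L] <- ""
    vMap <- vapply(unique(vSeg), .segStub, character(1), prefix = "TGTGCC")
    jMap <- vapply(unique(jSeg), .segStub, character(1))
    vStub <- unname(vMap[vSeg])
    jStub <- unname(jMap[jSeg])
    vPart <- substr(vStub, 1L, nchar(vStub) - trimV)
    ## extra J trimming brings designated clones in frame
    total <- nchar(vPart) + insLen + nchar(jStub) - trimJ
    trimJ <- trimJ + ifelse(inFrame, total %% 3L, 0L)
    jPart <- substring(jStub, trimJ + 1L)
    cdr3nt <- paste0(vPart, inserts, jPart)
    vEnd <- nchar(vPart)
    jStart <- vEnd + insLen
    data.frame(cdr3nt = cdr3nt, cdr3aa = translateCdr3(cdr3nt),
               v = vSeg, d = ".", j = jSeg,
               vEnd = as.integer(vEnd), dStart = -1L, dEnd = -1L,
               jStart = as.integer(jStart), stringsAsFactors = FALSE)
}

## A shared public-clonotype pool: clone definitions plus Zipf weights.
.makePool <- function(spec, seed) {
    set.seed(seed)
    k <- spec$poolRichness
    def <- .makeClones(k, spec$vUsage, spec$jUsage, spec$insertLenMean,
                       spec$maxTrim, spec$inFrameProb)
    w <- (seq_len(k) + spec$cloneSizeShift)^(-spec$cloneSizeAlpha)
    def$weight <- w / sum(w)
    def
}

#' Simulate one repertoire sample
#'
#' Clone frequencies follow a Zipf law over `richness` clones; `nMolecules`
#' molecules are drawn multinomially; each observed clone gets V/J segments
#' from the (noisy, optionally fold-perturbed) usage profiles and a CDR3
#' assembled from germline stubs and a geometric-length insert. Output is
#' byte-identical for identical spec and seed.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @param groupEffect optional named vector of fold multipliers applied to
#'   usage probabilities (renormalized).
#' @param pool optional public pool from which `sharingMass` of the
#'   repertoire frequency is drawn (internal; used by [simulateCohort()]).
#' @param sharingMass fraction of repertoire mass drawn from `pool`
#'   (in \[0, 1)).
#' @return a [RepSample-class].
#' @export
simulateSample <- function(spec, seed, sampleId = "sim",
                           groupEffect = NULL, pool = NULL,
                           sharingMass = 0) {
    if (sharingMass < 0 || sharingMass >= 1)
        stop("sharingMass must lie in [0, 1)")
    set.seed(seed)
    vu <- .noisyUsage(.applyEffect(spec$vUsage, groupEffect),
                      spec$usageNoiseCv)
    ju <- .noisyUsage(.applyEffect(spec$jUsage, groupEffect),
                      spec$usageNoiseCv)
    p <- (seq_len(spec$richness) + spec$cloneSizeShift)^(-spec$cloneSizeAlpha)
    p <- p / sum(p)
    if (!is.null(pool) && sharingMass > 0)
        p <- c((1 - sharingMass) * p, sharingMass * pool$weight)
    counts <- as.vector(stats::rmultinom(1, spec$nMolecules, p))
    nPriv <- spec$richness
    privIdx <- which(counts[seq_len(nPriv)] > 0)
    def <- .makeClones(length(privIdx), vu, ju, spec$insertLenMean,
                       spec$maxTrim, spec$inFrameProb)
    def$count <- counts[privIdx]
    if (!is.null(pool) && sharingMass > 0) {
        poolIdx <- which(counts[-seq_len(nPriv)] > 0)
        if (length(poolIdx)) {
            pdef <- pool[poolIdx, setdiff(colnames(pool), "weight"),
                         drop = FALSE]
            pdef$count <- counts[nPriv + poolIdx]
            def <- rbind(def, pdef)
        }
    }
    RepSample(sampleId, def)
}

#' Simulate a cohort with planted structure
#'
#' Generates `sum(nPerGroup)` samples organized into named groups. Optional
#' planted structure: per-group segment-usage fold changes
#' (`groupEffects`), and twin pairs that draw `sharingMass` of their
#' repertoire frequency from a pair-specific public clone pool (the first
#' `2 * twinPairs` samples form the pairs). Per-sample seeds are derived as
#' `seed + sample index`, pool seeds as `seed + 100000 + pair`, so the
#' cohort is reproducible and order-independent.
#'
#' @param spec a [syntheticSpec()].
#' @param nPerGroup named integer vector, samples per group.
#' @param groupEffects optional list: group name -> named fold vector.
#' @param twinPairs number of twin pairs (default 0).
#' @param sharingMass shared pool mass per twin (in \[0, 1); default 0).
#' @param seed integer seed.
#' @return list with `collection` (a [RepCollection-class] whose metadata
#'   has columns `group` and `twin`) and `truth` (expected usage profiles
#'   with effects applied, pool definitions, planted parameters).
#' @export
simulateCohort <- function(spec, nPerGroup, groupEffects = NULL,
                           twinPairs = 0L, sharingMass = 0, seed = 1L) {
    if (sharingMass < 0 || sharingMass >= 1)
        stop("sharingMass must lie in [0, 1)")
    groups <- rep(names(nPerGroup), nPerGroup)
    nTot <- length(groups)
    if (2L * twinPairs > nTot)
        stop("twinPairs exceeds half the cohort size")
    ids <- paste0(groups, stats::ave(seq_len(nTot), groups, FUN = seq_along))
    twin <- rep(NA_character_, nTot)
    if (twinPairs > 0L)
        twin[seq_len(2L * twinPairs)] <-
            rep(paste0("pair", seq_len(twinPairs)), each = 2L)
    pools <- if (twinPairs > 0L)
        lapply(seq_len(twinPairs), function(k)
            .makePool(spec, seed + 100000L + k))
    else list()
    samples <- lapply(seq_len(nTot), function(i) {
        eff <- if (!is.null(groupEffects)) groupEffects[[groups[i]]]
        pairK <- if (!is.na(twin[i])) (i + 1L) %/% 2L else NA_integer_
        simulateSample(spec, seed + i, ids[i], groupEffect = eff,
                       pool = if (!is.na(pairK)) pools[[pairK]],
                       sharingMass = if (!is.na(pairK)) sharingMass else 0)
    })
    md <- data.frame(sample_id = ids, group = groups, twin = twin,
                     stringsAsFactors = FALSE)
    truthUsage <- lapply(seq_len(nTot), function(i) {
        eff <- if (!is.null(groupEffects)) groupEffects[[groups[i]]]
        list(v = .applyEffect(spec$vUsage, eff),
             j = .applyEffect(spec$jUsage, eff))
    })
    names(truthUsage) <- ids
    list(collection = RepCollection(samples, md),
         truth = list(usage = truthUsage, pools = pools,
                      sharingMass = sharingMass,
                      groupEffects = groupEffects, twin = twin))
}
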