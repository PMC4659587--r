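#' @include AllClasses.R
NULL

#' Build the abundance spectrum of a sample
#'
#' @param sample a [RepSample-class], non-empty.
#' @param matching `"nt"` keeps every clonotype record; `"aa"` first pools
#'   nucleotide variants sharing a CDR3 amino-acid sequence (convergent
#'   recombination), summing their counts.
#' @return A [CountSpectrum-class].
#' @export
countSpectrum <- function(sample, matching = c("nt", "aa")) {
    matching <- match.arg(matching)
    cl <- clonotypes(sample)
    if (nrow(cl) == 0L) stop("cannot build a spectrum from an empty sample")
    x <- if (matching == "aa")
        as.numeric(tapply(cl$count, cl$cdr3aa, sum))
    else as.numeric(cl$count)
    x <- x[x > 0]
    tab <- table(x)
    f <- as.numeric(tab)
    names(f) <- names(tab)
    new("CountSpectrum", n = sum(x), x = x, f = f, sObs = length(x))
}

.fk <- function(sp, k) {
    v <- unname(sp@f[as.character(k)])
    v[is.na(v)] <- 0
    v
}

.chao1Unseen <- function(sp) {
    f1 <- .fk(sp, 1); f2 <- .fk(sp, 2)
    if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / 2
}

#' Chao1 lower-bound richness estimate
#'
#' \eqn{S_{obs} + f_1^2/(2 f_2)}; when no doubletons are present the
#' bias-corrected fallback \eqn{S_{obs} + f_1(f_1-1)/2} is used.
#'
#' @param sp a [CountSpectrum-class].
#' @return A [DiversityEstimate-class] (kind "lower-bound").
#' @export
chao1 <- function(sp) {
    .divEst("chao1", sp@sObs + .chao1Unseen(sp), "lower-bound")
}

#' Efron-Thisted lower-bound richness estimate
#'
#' Truncated alternating series for the unseen-species count,
#' \eqn{\Delta = \sum_{k=1}^{K} (-1)^{k+1} f_k} with
#' `K = min(maxTerms, max abundance)`; the estimate is clamped below at
#' the observed richness.
#'
#' @param sp a [CountSpectrum-class].
#' @param maxTerms series truncation (default 20).
#' @return A [DiversityEstimate-class] (kind "lower-bound").
#' @export
efronThisted <- function(sp, maxTerms = 20L) {
    K <- min(maxTerms, max(as.numeric(names(sp@f))))
    ks <- seq_len(K)
    delta <- sum((-1)^(ks + 1) * vapply(ks, function(k) .fk(sp, k),
                                        numeric(1)))
    .divEst("efronThisted", max(sp@sObs, sp@sObs + delta), "lower-bound")
}

#' Shannon diversity (effective clonotype number)
#'
#' Headline value is \eqn{\exp(H)} with \eqn{H = -\sum p_i \ln p_i}, so that
#' it shares units with richness; the raw entropy is kept in `details$H`.
#'
#' @param sp a [CountSpectrum-class].
#' @return A [DiversityEstimate-class] (kind "index").
#' @export
shannonDiversity <- function(sp) {
    p <- sp@x / sp@n
    H <- -sum(p * log(p))
    .divEst("shannon", exp(H), "index", details = list(H = H))
}

#' Inverse Simpson diversity
#'
#' Headline value \eqn{1/\sum p_i^2}; the raw probability-of-identity
#' \eqn{\sum p_i^2} is kept in `details$sumP2`.
#'
#' @param sp a [CountSpectrum-class].
#' @return A [DiversityEstimate-class] (kind "index").
#' @export
simpsonDiversity <- function(sp) {
    p <- sp@x / sp@n
    sp2 <- sum(p^2)
    .divEst("simpson", 1 / sp2, "index", details = list(sumP2 = sp2))
}

#' Rarefaction: expected richness of a subsample
#'
#' Multinomial (hypergeometric) interpolation
#' \eqn{E[S(m)] = S_{obs} - \sum_i C(n - x_i, m)/C(n, m)}, evaluated with
#' log-gamma binomial coefficients so totals of order 1e6 are safe.
#'
#' @param sp a [CountSpectrum-class].
#' @param m subsample size, `0 <= m <= n`.
#' @return expected richness (numeric scalar).
#' @export
rarefyInterpolate <- function(sp, m) {
    if (m > sp@n) stop("m exceeds sample size; use rarefyExtrapolate")
    if (m < 0) stop("m must be non-negative")
    sp@sObs - sum(exp(lchoose(sp@n - sp@x, m) - lchoose(sp@n, m)))
}

#' Rarefaction: extrapolated richness beyond the sample size
#'
#' Chao1-anchored extrapolation: with unseen estimate
#' \eqn{\hat f_0} (Chao1 branch rule), the expected richness at
#' \eqn{n + m^*} additional molecules is
#' \eqn{S_{obs} + \hat f_0 [1 - (1 - f_1/(n \hat f_0 + f_1))^{m^*}]}.
#' Its \eqn{m^* \to \infty} asymptote equals the Chao1 estimate. When
#' \eqn{f_1 = 0} the curve is flat at the observed richness.
#'
#' @param sp a [CountSpectrum-class].
#' @param mStar number of additional molecules (>= 0).
#' @return expected richness (numeric scalar).
#' @export
rarefyExtrapolate <- function(sp, mStar) {
    if (mStar < 0) stop("mStar must be non-negative")
    f1 <- .fk(sp, 1)
    if (f1 == 0) return(sp@sObs)
    f0 <- .chao1Unseen(sp)
    sp@sObs + f0 * (1 - (1 - f1 / (sp@n * f0 + f1))^mStar)
}

## Multivariate hypergeometric draw: m molecules without replacement from
## the clonotype count vector.
.rmvhyper <- function(counts, m) {
    k <- length(counts)
    out <- integer(k)
    remaining <- sum(counts)
    need <- m
    for (i in seq_len(k)) {
        if (need == 0L) break
        remaining <- remaining - counts[i]
        xi <- stats::rhyper(1, counts[i], remaining, need)
        out[i] <- xi
        need <- need - xi
    }
    out
}

#' Downsample a repertoire to a fixed molecule count
#'
#' Draws `m` molecules without replacement (multivariate hypergeometric over
#' clonotype counts); clonotypes with zero drawn molecules are removed and
#' frequencies recomputed. Deterministic under a fixed seed.
#'
#' @param sample a [RepSample-class].
#' @param m target molecule count, `m <= totalCount(sample)`.
#' @param seed optional integer seed.
#' @return A [RepSample-class] with exactly `m` molecules.
#' @export
downSample <- function(sample, m, seed = NULL) {
    tot <- totalCount(sample)
    if (m > tot) stop("m exceeds the sample's total molecule count")
    if (!is.null(seed)) set.seed(seed)
    cl <- clonotypes(sample)
    drawn <- .rmvhyper(cl$count, as.integer(m))
    keep <- drawn > 0L
    cl <- cl[keep, , drop = FALSE]
    cl$count <- drawn[keep]
    RepSample(sampleId(sample), cl)
}

.ESTIMATORS <- list(
    observed = function(sp) .divEst("observed", sp@sObs, "observed"),
    chao1 = chao1,
    efronThisted = efronThisted,
    shannon = shannonDiversity,
    simpson = simpsonDiversity)

#' Size-normalized diversity across a collection
#'
#' Every included sample is downsampled to the smallest included sample's
#' molecule count; the estimator is averaged over `nResamples` independent
#' downsamples. Excluded samples contribute neither to the common size nor
#' to the results. Per-sample random streams are derived as `seed + sample
#' index`, so results do not depend on iteration order.
#'
#' @param collection a [RepCollection-class].
#' @param estimator one of `"observed"`, `"chao1"`, `"efronThisted"`,
#'   `"shannon"`, `"simpson"`.
#' @param nResamples number of downsamples averaged (default 3).
#' @param seed integer seed.
#' @param exclude character vector of sample ids to leave out.
#' @param matching clonotype matching for the spectrum (`"nt"` or `"aa"`).
#' @return data.frame(sample_id, estimator, m, value, sd).
#' @export
normalizedDiversity <- function(collection, estimator = "chao1",
                                nResamples = 3L, seed = 1L,
                                exclude = character(0),
                                matching = c("nt", "aa")) {
    matching <- match.arg(matching)
    est <- .ESTIMATORS[[estimator]]
    if (is.null(est)) stop("unknown estimator: ", estimator)
    ids <- setdiff(names(collection), exclude)
    if (length(ids) == 0L) stop("no samples left after exclusion")
    m <- min(vapply(ids, function(id) totalCount(collection[[id]]),
                    numeric(1)))
    res <- lapply(seq_along(ids), function(i) {
        s <- collection[[ids[i]]]
        set.seed(seed + i)
        vals <- vapply(seq_len(nResamples), function(r) {
            ds <- downSample(s, m)
            estValue(est(countSpectrum(ds, matching)))
        }, numeric(1))
        data.frame(sample_id = ids[i], estimator = estimator, m = m,
                   value = mean(vals),
                   sd = if (nResamples > 1) stats::sd(vals) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Rarefaction curve with extrapolation
#'
#' Interpolated expected richness on evenly spaced subsample sizes in
#' (0, n], anchored at (n, S_obs), optionally extended by extrapolated
#' points on (n, extrapolateTo].
#'
#' @param sample a [RepSample-class].
#' @param nPoints number of interpolated points (default 20).
#' @param extrapolateTo optional total size to extrapolate to (> n).
#' @param matching clonotype matching for the spectrum.
#' @return data.frame(m, estimate, kind) with kind "interpolated" or
#'   "extrapolated".
#' @export
rarefactionCurve <- function(sample, nPoints = 20L, extrapolateTo = NULL,
                             matching = c("nt", "aa")) {
    matching <- match.arg(matching)
    sp <- countSpectrum(sample, matching)
    n <- sp@n
    ms <- unique(pmax(1, round(seq(n / nPoints, n, length.out = nPoints))))
    curve <- data.frame(m = ms,
                        estimate = vapply(ms, function(m)
                            rarefyInterpolate(sp, m), numeric(1)),
                        kind = "interpolated", stringsAsFactors = FALSE)
    if (!is.null(extrapolateTo) && extrapolateTo > n) {
        mes <- unique(round(seq(n, extrapolateTo,
                                length.out = nPoints + 1L)[-1L]))
        curve <- rbind(curve, data.frame(
            m = mes,
            estimate = vapply(mes - n, function(ms2)
                rarefyExtrapolate(sp, ms2), numeric(1)),
            kind = "extrapolated", stringsAsFactors = FALSE))
    }
    curve
}
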