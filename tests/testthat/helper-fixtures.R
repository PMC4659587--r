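## Shared fixtures: small clonotype tables built in code.

.CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1, paste, collapse = "")

## Deterministic toy sample: k distinct in-frame CDR3s unless sequences are
## supplied explicitly.
toySample <- function(counts, cdr3nt = NULL, cdr3aa = NULL,
                      v = NULL, j = NULL, id = "toy",
                      vEnd = NULL, dStart = NULL, dEnd = NULL,
                      jStart = NULL) {
    k <- length(counts)
    if (is.null(cdr3nt)) {
        stopifnot(k <= 64)
        cdr3nt <- paste0("TGT", .CODONS[seq_len(k)], "TTC")
    }
    cl <- data.frame(count = counts, cdr3nt = cdr3nt,
                     v = if (is.null(v)) "TRBV1" else v,
                     j = if (is.null(j)) "TRBJ1" else j,
                     stringsAsFactors = FALSE)
    if (!is.null(cdr3aa)) cl$cdr3aa <- cdr3aa
    if (!is.null(vEnd)) cl$vEnd <- vEnd
    if (!is.null(dStart)) cl$dStart <- dStart
    if (!is.null(dEnd)) cl$dEnd <- dEnd
    if (!is.null(jStart)) cl$jStart <- jStart
    RepSample(id, cl)
}

toySpectrum <- function(counts) countSpectrum(toySample(counts))

randomSpectrum <- function(seed) {
    set.seed(seed)
    counts <- sample(1:8, sample(3:15, 1), replace = TRUE)
    toySpectrum(counts)
}

toyCollection <- function(samples, group = NULL) {
    ids <- vapply(samples, sampleId, character(1))
    md <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    if (!is.null(group)) md$group <- group
    RepCollection(samples, md)
}

## Brute-force average-linkage agglomeration: merge heights computed as the
## mean of the original pairwise distances between cluster members.
bruteAverageLinkHeights <- function(D) {
    clusters <- as.list(seq_len(nrow(D)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- Inf; bi <- bj <- NA
        for (i in seq_along(clusters)) {
            for (j in seq_len(i - 1L)) {
                d <- mean(D[clusters[[i]], clusters[[j]]])
                if (d < best) { best <- d; bi <- i; bj <- j }
            }
        }
        heights <- c(heights, best)
        clusters[[bj]] <- c(clusters[[bj]], clusters[[bi]])
        clusters[[bi]] <- NULL
    }
    sort(heights)
}

## Brute-force classical scaling: double-center squared distances, eigen.
bruteMds <- function(D, dims = 2L) {
    n <- nrow(D)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (D^2) %*% J
    e <- eigen(B, symmetric = TRUE)
    keep <- seq_len(dims)
    val <- pmax(e$values[keep], 0)
    e$vectors[, keep, drop = FALSE] %*% diag(sqrt(val), dims)
}

## Two-sided Fisher exact p by full hypergeometric enumeration for a 2x2
## table given as (a, b, c, d) row-wise.
enumFisherP <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
    probs <- dhyper(lo:hi, c1, n - c1, r1)
    pObs <- dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}
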