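#' @include AllClasses.R
NULL

#' Turn a similarity matrix into a distance matrix
#'
#' Metrics bounded in \[0, 1\] (F, Jaccard, Morisita-Horn, D) map as
#' `d = 1 - s`; the correlation metric R in \[-1, 1\] maps as
#' `d = (1 - R)/2`. The diagonal is forced to zero. Missing entries are an
#' error (they are never imputed).
#'
#' @param sim symmetric similarity matrix, typically from
#'   [pairwiseMatrix()] (its `metric` attribute selects the transform).
#' @return symmetric distance matrix with zero diagonal and attribute
#'   `provenance`.
#' @export
toDistance <- function(sim) {
    if (any(is.na(sim)))
        stop("similarity matrix has missing entries; cannot build distances")
    if (max(abs(sim - t(sim))) > 1e-9)
        stop("similarity matrix is not symmetric")
    metric <- attr(sim, "metric")
    d <- if (identical(metric, "R")) (1 - sim) / 2 else 1 - sim
    diag(d) <- 0
    d <- pmax(d, 0)
    attr(d, "provenance") <- paste0(if (is.null(metric)) "similarity"
                                    else metric, " -> distance")
    d
}

#' Hierarchical clustering of samples
#'
#' Standard agglomerative clustering (average linkage by default). Samples
#' are ordered lexicographically before clustering so that tie-breaking is
#' deterministic regardless of input order.
#'
#' @param dm square symmetric distance matrix with sample-id dimnames.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return an [stats::hclust] object.
#' @export
hcluster <- function(dm, linkage = c("average", "complete", "single")) {
    linkage <- match.arg(linkage)
    if (any(!is.finite(dm))) stop("non-finite distances")
    ord <- order(rownames(dm))
    dm <- dm[ord, ord, drop = FALSE]
    stats::hclust(stats::as.dist(dm), method = linkage)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering of squared distances followed by the top-eigenvector
#' embedding. A Euclidean input matrix is reproduced exactly (up to rigid
#' motion); when fewer positive eigenvalues than `dims` exist the remaining
#' coordinates are zero-padded with a warning. Coordinates are centered at
#' the origin.
#'
#' @param dm square symmetric distance matrix with sample-id dimnames.
#' @param dims embedding dimension (default 2).
#' @return coordinate matrix (samples x dims) with attributes `eig`
#'   (eigenvalues) and `gof` (share of positive eigenvalue mass captured).
#' @export
classicalMds <- function(dm, dims = 2L) {
    n <- nrow(as.matrix(dm))
    fit <- stats::cmdscale(stats::as.dist(dm), k = min(dims, n - 1L),
                           eig = TRUE)
    pts <- fit$points
    if (ncol(pts) < dims) {
        warning("only ", ncol(pts), " positive eigenvalue(s); ",
                "padding remaining coordinates with zeros")
        pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
    }
    rownames(pts) <- rownames(as.matrix(dm))
    attr(pts, "eig") <- fit$eig
    pos <- fit$eig[fit$eig > 0]
    attr(pts, "gof") <- if (length(pos))
        sum(utils::head(sort(pos, decreasing = TRUE), dims)) / sum(pos)
    else NA_real_
    pts
}

.euclidMatrix <- function(pts) as.matrix(stats::dist(pts))

.withinGroupStat <- function(D, labels, groups) {
    pooled <- 0; npairs <- 0
    per <- numeric(length(groups))
    for (gi in seq_along(groups)) {
        idx <- which(labels == groups[gi])
        sub <- D[idx, idx, drop = FALSE]
        vals <- sub[upper.tri(sub)]
        per[gi] <- mean(vals)
        pooled <- pooled + sum(vals)
        npairs <- npairs + length(vals)
    }
    list(pooled = pooled / npairs, perGroup = per)
}

#' Permutation test for within-group sample closeness
#'
#' Tests whether samples of the same group sit closer together than expected
#' under random group labels. The statistic is the average pairwise
#' Euclidean distance among same-group pairs, computed on the 2-D MDS plane
#' by default (`useMds = FALSE` uses the raw distance matrix). The null
#' distribution is generated by permuting group labels; the p-value uses the
#' add-one correction \eqn{p = (1 + \#\{perm \le obs\})/(1 + N)}, so ties
#' count as extreme and p is never 0.
#'
#' @param dm square symmetric distance matrix with sample-id dimnames.
#' @param labels group label per sample (named by sample id, or in matrix
#'   order).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param useMds compute the statistic on the MDS plane (default TRUE).
#' @return list: `observed` (pooled statistic), `p`, `perGroup`
#'   data.frame(group, observed, p), `nPerm`, `nUsed` samples.
#' @export
withinGroupPermTest <- function(dm, labels, nPerm = 10000L, seed = 1L,
                                useMds = TRUE) {
    dm <- as.matrix(dm)
    ids <- rownames(dm)
    if (!is.null(names(labels))) labels <- labels[ids]
    labels <- as.character(labels)
    sizes <- table(labels)
    drop <- names(sizes)[sizes < 2L]
    if (length(drop)) {
        warning("excluding singleton group(s): ",
                paste(drop, collapse = ", "))
        keep <- !labels %in% drop
        dm <- dm[keep, keep, drop = FALSE]
        labels <- labels[keep]
    }
    groups <- sort(unique(labels))
    if (length(groups) < 1L) stop("no group with >= 2 members")
    D <- if (useMds) .euclidMatrix(classicalMds(dm, 2L)) else dm
    obs <- .withinGroupStat(D, labels, groups)
    set.seed(seed)
    permPooled <- numeric(nPerm)
    permPer <- matrix(0, nPerm, length(groups))
    for (b in seq_len(nPerm)) {
        pl <- sample(labels)
        st <- .withinGroupStat(D, pl, groups)
        permPooled[b] <- st$pooled
        permPer[b, ] <- st$perGroup
    }
    eps <- 1e-12
    p <- (1 + sum(permPooled <= obs$pooled + eps)) / (1 + nPerm)
    perGroup <- data.frame(
        group = groups, observed = obs$perGroup,
        p = vapply(seq_along(groups), function(gi)
            (1 + sum(permPer[, gi] <= obs$perGroup[gi] + eps)) / (1 + nPerm),
            numeric(1)), stringsAsFactors = FALSE)
    list(observed = obs$pooled, p = p, perGroup = perGroup,
         nPerm = nPerm, nUsed = length(labels))
}

#' Euclidean distance between segment-usage profiles
#'
#' Usage profiles (frequency-weighted by default) are zero-filled over the
#' union of observed segment names and compared by Euclidean norm.
#'
#' @param collection a [RepCollection-class].
#' @param gene `"V"` or `"J"`.
#' @param weighted frequency weighting (default TRUE).
#' @return symmetric distance matrix over sample ids.
#' @export
usageDistance <- function(collection, gene = c("V", "J"), weighted = TRUE) {
    gene <- match.arg(gene)
    profiles <- lapply(names(collection), function(id)
        segmentUsage(collection[[id]], gene, weighted))
    segs <- sort(unique(unlist(lapply(profiles, names))))
    m <- t(vapply(profiles, function(p) {
        v <- stats::setNames(numeric(length(segs)), segs)
        v[names(p)] <- p
        v
    }, numeric(length(segs))))
    rownames(m) <- names(collection)
    d <- .euclidMatrix(m)
    attr(d, "provenance") <- paste0(gene, "-usage Euclidean")
    d
}

#' Cluster-group association by Fisher's exact test
#'
#' Cuts the dendrogram into `k` clusters, tabulates cluster membership
#' against the two group labels, and evaluates the association with a
#' two-tailed Fisher exact test. For k = 2 the cluster-to-group assignment
#' maximizing accuracy is also reported as per-group recall
#' (sensitivity/specificity).
#'
#' @param tree an [stats::hclust] over labeled leaves.
#' @param labels group label per leaf (named by sample id, or in leaf
#'   order).
#' @param k number of clusters to cut (default 2; must be >= 2).
#' @return list: `table` (cluster x group), `p`, `recall` (named per-group
#'   fraction assigned to its majority cluster under the best assignment,
#'   k = 2 only).
#' @export
clusterGroupAssociation <- function(tree, labels, k = 2L) {
    nLeaves <- length(tree$labels)
    if (k < 2L) stop("k must be at least 2 (k = 1 is degenerate)")
    if (k > nLeaves) stop("k exceeds the number of leaves")
    if (!is.null(names(labels))) labels <- labels[tree$labels]
    labels <- as.character(labels)
    cl <- stats::cutree(tree, k = k)
    tab <- table(cluster = cl, group = labels)
    p <- stats::fisher.test(tab)$p.value
    recall <- NULL
    if (k == 2L && ncol(tab) == 2L) {
        acc1 <- (tab[1, 1] + tab[2, 2]) / sum(tab)
        acc2 <- (tab[1, 2] + tab[2, 1]) / sum(tab)
        if (acc1 >= acc2)
            recall <- c(tab[1, 1] / sum(tab[, 1]),
                        tab[2, 2] / sum(tab[, 2]))
        else
            recall <- c(tab[2, 1] / sum(tab[, 1]),
                        tab[1, 2] / sum(tab[, 2]))
        names(recall) <- colnames(tab)
    }
    list(table = tab, p = p, recall = recall)
}

#' Per-segment usage comparison between two groups
#'
#' For every segment observed in the collection, per-sample usage
#' frequencies are compared between the two groups of `factor` with a
#' t-test (Welch by default), and p-values are adjusted across segments by
#' Benjamini-Hochberg step-up. The test direction must be supplied
#' explicitly: `"greater"` tests for higher usage in the first factor
#' level, mirroring an a-priori one-sided hypothesis; use `"two.sided"`
#' otherwise.
#'
#' @param collection a [RepCollection-class].
#' @param factor name of a two-level metadata column; the first level (in
#'   order of appearance) is "group 1".
#' @param tail `"greater"`, `"less"` or `"two.sided"` — no default.
#' @param gene `"V"` or `"J"`.
#' @param logFreq test log10 frequencies (zero frequencies dropped).
#' @param varEqual pooled-variance Student t-test instead of Welch.
#' @return data.frame(segment, mean1, mean2, fold, p, q), ordered by p;
#'   `fold = mean1/mean2` (Inf flagged when the segment is absent from
#'   group 2).
#' @export
segmentUsageTest <- function(collection, factor, tail, gene = c("V", "J"),
                             logFreq = FALSE, varEqual = FALSE) {
    if (missing(tail))
        stop("tail must be given explicitly ('greater', 'less' or 'two.sided')")
    tail <- match.arg(tail, c("greater", "less", "two.sided"))
    gene <- match.arg(gene)
    md <- sampleMetadata(collection)
    if (!factor %in% colnames(md)) stop("unknown metadata factor: ", factor)
    g <- as.character(md[[factor]])
    lev <- unique(g[!is.na(g)])
    if (length(lev) != 2L) stop("factor must have exactly two groups")
    if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
    profiles <- lapply(names(collection), function(id)
        segmentUsage(collection[[id]], gene, weighted = TRUE))
    segs <- sort(unique(unlist(lapply(profiles, names))))
    usage <- t(vapply(profiles, function(p) {
        v <- stats::setNames(numeric(length(segs)), segs)
        v[names(p)] <- p
        v
    }, numeric(length(segs))))
    res <- lapply(segs, function(s) {
        a <- usage[g == lev[1], s]
        b <- usage[g == lev[2], s]
        fold <- mean(a) / mean(b)
        if (logFreq) {
            a <- log10(a[a > 0]); b <- log10(b[b > 0])
        }
        p <- if (length(a) >= 2 && length(b) >= 2 && stats::sd(c(a, b)) > 0)
            stats::t.test(a, b, alternative = tail,
                          var.equal = varEqual)$p.value
        else NA_real_
        data.frame(segment = s, mean1 = mean(usage[g == lev[1], s]),
                   mean2 = mean(usage[g == lev[2], s]), fold = fold, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "groups") <- lev
    out
}

#' Cohen's d effect size
#'
#' \eqn{d = (\bar a - \bar b)/s_p} with the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}}.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return numeric scalar; NA with a warning when the pooled variance is 0.
#' @export
cohensD <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
        (na + nb - 2)
    if (sp2 == 0) {
        warning("zero pooled variance; Cohen's d undefined")
        return(NA_real_)
    }
    (mean(a) - mean(b)) / sqrt(sp2)
}

#' Paired segment-frequency test between two samples
#'
#' Paired two-tailed t-test on log10 usage frequencies of the listed
#' segments in two samples of the same donor (e.g. before/after
#' transplantation). Segments with zero frequency in either sample are
#' dropped with a warning (log undefined); at least 2 segments must remain.
#' When all paired differences are exactly zero the test is degenerate and
#' p = 1 is returned with `degenerate = TRUE`.
#'
#' @param sampleBefore,sampleAfter [RepSample-class] objects.
#' @param segments character vector of segment names (length >= 2).
#' @param gene `"V"` or `"J"`.
#' @return list(p, nSegments, dropped, degenerate).
#' @export
pairedSegmentTest <- function(sampleBefore, sampleAfter, segments,
                              gene = c("V", "J")) {
    gene <- match.arg(gene)
    u1 <- segmentUsage(sampleBefore, gene, weighted = TRUE)
    u2 <- segmentUsage(sampleAfter, gene, weighted = TRUE)
    f1 <- ifelse(segments %in% names(u1), u1[segments], 0)
    f2 <- ifelse(segments %in% names(u2), u2[segments], 0)
    ok <- f1 > 0 & f2 > 0
    dropped <- segments[!ok]
    if (length(dropped))
        warning("dropping segment(s) with zero frequency: ",
                paste(dropped, collapse = ", "))
    if (sum(ok) < 2L) stop("need at least 2 segments with nonzero frequency")
    d <- log10(f2[ok]) - log10(f1[ok])
    degenerate <- stats::sd(d) == 0
    p <- if (!degenerate) stats::t.test(d)$p.value
         else if (all(d == 0)) 1 else 0
    if (degenerate) warning("paired differences are constant; ",
                            "p-value reported by convention")
    list(p = p, nSegments = sum(ok), dropped = dropped,
         degenerate = degenerate)
}
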