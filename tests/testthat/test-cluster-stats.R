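test_that("similarity-to-distance transforms and guards behave", {
    m <- matrix(c(1, 0.36, 0.36, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    attr(m, "metric") <- "F"
    d <- toDistance(m)
    expect_equal(d["a", "b"], 0.64)
    expect_equal(diag(d), c(a = 0, b = 0))
    r <- matrix(c(1, -1, -1, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    attr(r, "metric") <- "R"
    expect_equal(toDistance(r)["a", "b"], 1)
    m[1, 2] <- NA
    expect_error(toDistance(m), "missing")
})

test_that("average-linkage clustering matches a brute-force oracle", {
    dm <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tree <- hcluster(dm)
    first <- sort(tree$labels[-tree$merge[1, ]])
    expect_equal(first, c("A", "B"))
    set.seed(31)
    for (rep in 1:3) {
        n <- 6
        pts <- matrix(rnorm(2 * n), n, 2)
        D <- as.matrix(dist(pts))
        dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
        tr <- hcluster(D, "average")
        expect_equal(sort(tr$height), bruteAverageLinkHeights(D),
                     tolerance = 1e-9)
    }
    dm[1, 2] <- dm[2, 1] <- Inf
    expect_error(hcluster(dm), "finite")
})

test_that("classical MDS reproduces Euclidean geometry", {
    ## 3-4-5 right triangle
    D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
                dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
    pts <- classicalMds(D)
    expect_equal(as.matrix(dist(pts)), D, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(colMeans(pts), c(0, 0), tolerance = 1e-9,
                 ignore_attr = TRUE)
    ## coincident points embed at the same location
    D2 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    p2 <- classicalMds(D2)
    expect_equal(p2["a", ], p2["b", ], tolerance = 1e-6)
    ## two samples span one dimension: second coordinate is zero-padded
    D1 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("u", "v"),
                                                      c("u", "v")))
    expect_warning(p1 <- classicalMds(D1), "padding")
    expect_equal(unname(p1[, 2]), c(0, 0))
    ## embedding distances are invariant to input permutation
    set.seed(8)
    pts0 <- matrix(rnorm(12), 6, 2,
                   dimnames = list(paste0("s", 1:6), NULL))
    D3 <- as.matrix(dist(pts0))
    e1 <- as.matrix(dist(classicalMds(D3)))
    perm <- sample(6)
    e2 <- as.matrix(dist(classicalMds(D3[perm, perm])))
    expect_equal(e2[rownames(e1), colnames(e1)], e1, tolerance = 1e-9)
})

test_that("within-group permutation test detects planted structure", {
    ## two tight, well-separated clusters matching the labels
    set.seed(14)
    pts <- rbind(matrix(rnorm(12, 0, 0.05), 6, 2),
                 matrix(rnorm(12, 5, 0.05), 6, 2))
    rownames(pts) <- paste0("s", 1:12)
    dm <- as.matrix(dist(pts))
    labels <- setNames(rep(c("g1", "g2"), each = 6), rownames(pts))
    res <- withinGroupPermTest(dm, labels, nPerm = 1000, seed = 3)
    expect_lte(res$p, 0.01)
    expect_gte(res$p, 1 / 1001)  # add-one correction: p never 0
    ## coincident points: observed = permuted = 0, ties count, p = 1
    z <- matrix(0, 6, 6, dimnames = list(paste0("z", 1:6), paste0("z", 1:6)))
    lz <- setNames(rep(c("a", "b"), each = 3), rownames(z))
    expect_equal(suppressWarnings(
        withinGroupPermTest(z, lz, nPerm = 200, seed = 1))$p, 1)
    ## singleton groups are excluded with a warning
    l1 <- setNames(c("a", "a", "a", "b", "b", "solo"), rownames(z))
    w <- capture_warnings(
        r1 <- withinGroupPermTest(z, l1, nPerm = 50, seed = 1))
    expect_true(any(grepl("solo", w)))
    expect_equal(r1$nUsed, 5)
})

test_that("usage distance equals the brute-force Euclidean norm", {
    a <- toySample(5, v = "V1", id = "a")
    b <- toySample(5, v = "V2", id = "b")
    cc <- toyCollection(list(a, b, toySample(5, v = "V1", id = "c")))
    d <- usageDistance(cc, "V")
    expect_equal(d["a", "b"], sqrt(2))  # (1,0) vs (0,1)
    expect_equal(d["a", "c"], 0)
    spec <- syntheticSpec(richness = 60, nMolecules = 400)
    sims <- lapply(1:4, function(i)
        simulateSample(spec, seed = 70 + i, paste0("s", i)))
    cs <- toyCollection(sims)
    dd <- usageDistance(cs, "V")
    segs <- sort(unique(unlist(lapply(sims, function(s)
        names(segmentUsage(s, "V"))))))
    prof <- function(s) {
        v <- setNames(numeric(length(segs)), segs)
        u <- segmentUsage(s, "V")
        v[names(u)] <- u
        v
    }
    for (i in 1:3) for (j in (i + 1):4)
        expect_equal(dd[i, j], sqrt(sum((prof(sims[[i]]) -
                                         prof(sims[[j]]))^2)),
                     tolerance = 1e-12)
})

test_that("cluster-group association reproduces the exact Fisher p", {
    set.seed(5)
    pts <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
    tree <- hcluster(D)
    labels <- setNames(rep(c("ctl", "ms"), each = 5), paste0("s", 1:10))
    assoc <- clusterGroupAssociation(tree, labels, k = 2)
    expect_equal(assoc$p, enumFisherP(5, 0, 0, 5), tolerance = 1e-9)
    expect_equal(assoc$p, 2 / 252, tolerance = 1e-9)
    expect_equal(unname(assoc$recall), c(1, 1))
    expect_error(clusterGroupAssociation(tree, labels, k = 1), "degenerate")
    expect_error(clusterGroupAssociation(tree, labels, k = 11), "exceeds")
})

test_that("segment usage test ranks a planted expansion first", {
    spec <- syntheticSpec(richness = 1500, cloneSizeShift = 250,
                          nMolecules = 8000)
    sim <- simulateCohort(spec, c(ctl = 12, ms = 12),
                          groupEffects = list(ms = c("TRBV5-6" = 1.6)),
                          seed = 2024)
    tt <- segmentUsageTest(sim$collection, "group", tail = "less")
    expect_equal(tt$segment[1], "TRBV5-6")
    expect_lt(tt$q[1], 0.05)
    expect_true(all(tt$q >= tt$p - 1e-12))
    expect_true(all(diff(tt$q[order(tt$p)]) >= -1e-12))  # BH monotone
    expect_error(segmentUsageTest(sim$collection, "group"), "explicitly")
    ## identical groups: all folds 1, nothing significant
    g <- lapply(1:4, function(i) toySample(c(3, 2), v = c("V1", "V2"),
                                           id = paste0("s", i)))
    cc <- toyCollection(g, group = rep(c("x", "y"), 2))
    t0 <- segmentUsageTest(cc, "group", tail = "two.sided")
    expect_true(all(t0$fold == 1))
    expect_true(all(is.na(t0$p)))  # zero variance: no test possible
})

test_that("Cohen's d matches its closed form and invariances", {
    expect_equal(cohensD(c(1, 2, 3), c(3, 4, 5)), -2)
    expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(cohensD(c(2, 4, 6), c(6, 8, 10)), -2)  # scale invariance
    expect_warning(d0 <- cohensD(c(1, 1), c(1, 1)), "variance")
    expect_true(is.na(d0))
    expect_error(cohensD(1, c(1, 2)), "at least 2")
})

test_that("paired segment test responds to a uniform frequency drop", {
    segs <- paste0("V", 1:5)
    before <- toySample(rep(20, 5), v = segs, id = "pre")
    ## same segments at ~half the frequency, the rest absorbed elsewhere
    after <- toySample(c(10, 11, 9, 10, 10, 50), v = c(segs, "V9"),
                       id = "post")
    res <- pairedSegmentTest(before, after, segs)
    expect_lt(res$p, 0.01)
    expect_equal(res$nSegments, 5)
    ## identical samples: degenerate, p = 1 by convention
    expect_warning(r0 <- pairedSegmentTest(before, before, segs), "constant")
    expect_equal(r0$p, 1)
    expect_true(r0$degenerate)
    expect_error(suppressWarnings(pairedSegmentTest(before, after, "V1")),
                 "at least 2")
    ## zero-frequency segments are dropped with a warning
    expect_warning(r1 <- pairedSegmentTest(before, after,
                                           c(segs, "V8")), "V8")
    expect_equal(r1$nSegments, 5)
})
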