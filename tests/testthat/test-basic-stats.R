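test_that("non-coding and convergence statistics follow their definitions", {
    ## one stop-containing clonotype at frequency 0.1
    s <- toySample(c(1, 2, 3, 4), cdr3aa = c("CA*", "CAS", "CAT", "CAV"),
                   cdr3nt = c("TGTGCCTGA", "TGTGCCAGC", "TGTGCCACC",
                              "TGTGCCGTC"))
    bs <- basicStats(s)
    expect_equal(bs$noncodingCount, 1)
    expect_equal(bs$noncodingFreq, 0.1)
    expect_equal(bs$clonotypeCount, 4)
    expect_equal(bs$moleculeCount, 10)
    ## 3 nt variants of one aa plus 1 unique aa: convergence (3+1)/2
    s2 <- toySample(c(1, 1, 1, 1),
                    cdr3nt = c("TGTGCAAGC", "TGTGCCAGC", "TGTGCGAGC",
                               "TGTGCCACC"))
    expect_equal(sort(clonotypes(s2)$cdr3aa), c("CAS", "CAS", "CAS", "CAT"))
    expect_equal(basicStats(s2)$convergence, 2)
    expect_equal(basicStats(s2)$noncodingFreq, 0)
    ## frameshift: length not divisible by 3 counts as non-coding
    s3 <- toySample(c(1, 1), cdr3nt = c("TGTGCCA", "TGTGCCAGC"))
    expect_equal(basicStats(s3)$noncodingCount, 1)
})

test_that("spectratype histograms are correctly weighted", {
    s <- toySample(c(2, 3, 5),
                   cdr3nt = c(strrep("TGTGCCAGCAGC", 3),          # 36 nt
                              paste0(strrep("TGTGCCAGCAGC", 3), "AAA"),
                              paste0(strrep("TGTGCCAGCAGC", 3), "CCC")))
    st <- spectratype(s, unit = "nt")
    expect_equal(st$len, c(36, 39))
    expect_equal(st$weight, c(0.2, 0.8))
    stu <- spectratype(s, unit = "nt", weighted = FALSE)
    expect_equal(stu$weight, c(1 / 3, 2 / 3))
    one <- spectratype(toySample(4), unit = "aa")
    expect_equal(one$weight, 1)
    expect_equal(nrow(spectratype(RepSample("e"))), 0)
})

test_that("segment usage profiles sum to one in both weightings", {
    s <- toySample(c(7, 3), v = c("TRBV5-1", "TRBV20-1"))
    u <- segmentUsage(s, "V")
    expect_equal(u[["TRBV5-1"]], 0.7)
    expect_equal(u[["TRBV20-1"]], 0.3)
    uu <- segmentUsage(s, "V", weighted = FALSE)
    expect_equal(unname(uu), c(0.5, 0.5))
    ## only observed segments appear
    expect_equal(sort(names(u)), c("TRBV20-1", "TRBV5-1"))
    expect_equal(sum(segmentUsage(
        simulateSample(syntheticSpec(richness = 80, nMolecules = 500),
                       seed = 2, "u"), "J")), 1, tolerance = 1e-9)
})

test_that("V-J pairing marginals equal the usage profiles", {
    s <- toySample(c(6, 4), v = c("V1", "V1"), j = c("J1", "J2"))
    m <- vjPairing(s)
    expect_equal(m["V1", "J1"], 0.6)
    expect_equal(m["V1", "J2"], 0.4)
    sim <- simulateSample(syntheticSpec(richness = 100, nMolecules = 800),
                          seed = 9, "vj")
    pm <- vjPairing(sim)
    expect_equal(sum(pm), 1, tolerance = 1e-9)
    expect_equal(rowSums(pm)[names(segmentUsage(sim, "V"))],
                 segmentUsage(sim, "V"), tolerance = 1e-12)
    expect_equal(colSums(pm)[names(segmentUsage(sim, "J"))],
                 segmentUsage(sim, "J"), tolerance = 1e-12)
})

test_that("junction features follow the half-open markup arithmetic", {
    s <- toySample(c(1, 1, 1),
                   cdr3nt = c(strrep("A", 15), strrep("C", 15), "TGTGCC"),
                   cdr3aa = c("X", "X", "CA"),
                   vEnd = c(4, 4, 3), dStart = c(-1, 5, -1),
                   dEnd = c(-1, 8, -1), jStart = c(10, 10, 3))
    jf <- junctionFeatures(s)
    i <- match(strrep("A", 15), clonotypes(s)$cdr3nt)
    expect_equal(jf$vGerm[i], 4)
    expect_equal(jf$jGerm[i], 5)
    expect_equal(jf$ndnSize[i], 6)
    expect_true(is.na(jf$vdInsert[i]))
    k <- match(strrep("C", 15), clonotypes(s)$cdr3nt)
    expect_equal(jf$vdInsert[k], 1)
    expect_equal(jf$djInsert[k], 2)
    ## vd + D length + dj = ndn
    expect_equal(jf$vdInsert[k] + (8 - 5) + jf$djInsert[k], jf$ndnSize[k])
    b <- match("TGTGCC", clonotypes(s)$cdr3nt)
    expect_equal(jf$ndnSize[b], 0)  # blunt junction
    ## additivity across a simulated sample
    sim <- simulateSample(syntheticSpec(richness = 100, nMolecules = 500),
                          seed = 4, "jf")
    jfs <- junctionFeatures(sim)
    cl <- clonotypes(sim)
    expect_equal(jfs$vGerm + jfs$ndnSize + jfs$jGerm, nchar(cl$cdr3nt))
})

test_that("undefined markup is excluded from junction aggregates", {
    s <- toySample(c(1, 1), cdr3nt = c("TGTGCCAGC", "TGTGCCACC"),
                   vEnd = c(3, -1), jStart = c(6, -1))
    jf <- junctionFeatures(s)
    expect_equal(sum(is.na(jf$ndnSize)), 1)
    expect_equal(basicStats(s)$meanNdnSize, 3)
})

test_that("group junction summary compares weighted means between groups", {
    mk <- function(id, ndn) {
        k <- length(ndn)
        toySample(rep(1, k), cdr3nt = strrep("A", 6 + ndn),
                  cdr3aa = strrep("X", 2), id = id,
                  vEnd = rep(3, k), jStart = 3 + ndn)
    }
    set.seed(21)
    g1 <- lapply(1:10, function(i) mk(paste0("a", i),
                                      pmax(0, round(rnorm(30, 6, 1)))))
    g2 <- lapply(1:10, function(i) mk(paste0("b", i),
                                      pmax(0, round(rnorm(30, 8, 1)))))
    cc <- toyCollection(c(g1, g2), group = rep(c("ctl", "ms"), each = 10))
    res <- groupJunctionSummary(cc, "group")
    ndn <- res$tests[res$tests$feature == "ndnSize", ]
    expect_lt(ndn$p, 0.05)   # planted +2 nt shift is detected
    expect_lt(ndn$mean1, ndn$mean2)
    ## identical groups: zero difference, p = 1
    res0 <- groupJunctionSummary(
        toyCollection(c(g1, lapply(g1, function(s)
            RepSample(paste0(sampleId(s), "c"), clonotypes(s)))),
            group = rep(c("x", "y"), each = 10)), "group")
    expect_equal(res0$tests$diff[res0$tests$feature == "ndnSize"], 0)
    expect_equal(res0$tests$p[res0$tests$feature == "ndnSize"], 1)
    expect_error(groupJunctionSummary(
        toyCollection(list(g1[[1]], g2[[1]]), group = c("x", "y")), "group"),
        "2 samples")
    ## weighted mean: freqs 0.5/0.5 over ndn 4 and 6
    s <- toySample(c(1, 1), cdr3nt = c(strrep("A", 10), strrep("C", 12)),
                   cdr3aa = c("X", "X"), vEnd = c(3, 3), jStart = c(7, 9))
    expect_equal(basicStats(s)$meanNdnSize, 5)
})

test_that("selected-V subsets are compared within donors by a paired test", {
    mk <- function(id) {
        ndnA <- rep(4, 20); ndnB <- rep(8, 20)
        toySample(rep(1, 40),
                  cdr3nt = strrep("A", 6 + c(ndnA, ndnB)),
                  cdr3aa = "XX",
                  v = rep(c("TRBV9", "TRBV5-1"), each = 20), id = id,
                  vEnd = rep(3, 40), jStart = 3 + c(ndnA, ndnB))
    }
    cc <- toyCollection(lapply(1:4, function(i) mk(paste0("d", i))))
    res <- junctionSubsetPairedTest(cc, "TRBV5-1")
    expect_true(all(res$perSample$subset > res$perSample$all))
    expect_lt(res$p, 0.05)
    expect_error(junctionSubsetPairedTest(
        toyCollection(list(mk("one"))), "TRBV5-1"), "2 samples")
})
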