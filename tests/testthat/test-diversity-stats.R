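test_that("allele frequencies are plain call tallies excluding missing", {
    # 2 individuals: (A,A), (A,B) -> p_A = 0.75, p_B = 0.25
    gt <- mkTable(rbind(c(100L, 100L), c(100L, 102L)), panel = "LocA")
    fr <- alleleFrequencies(gt, "LocA")
    expect_equal(unname(alleleFreqs(fr)), c(0.75, 0.25))
    expect_equal(numAlleles(fr), 2L)
    expect_equal(numTyped(fr), 2L)
    # monomorphic locus
    gtm <- mkTable(rbind(c(100L, 100L)), panel = "LocA")
    expect_equal(unname(alleleFreqs(alleleFrequencies(gtm, "LocA"))), 1)
    expect_error(alleleFrequencies(gtm[integer(0)], "LocA"), "no typed")
})

test_that("frequencies match a brute-force tally on random tables", {
    set.seed(11)
    for (rep in 1:20) {
        gt <- randomTable(n = 30L, nloci = 2L, k = 6L, pMissing = 0.05)
        for (loc in panelLoci(gt)) {
            calls <- alleleCalls(gt, loc)
            expect_equal(unname(alleleFreqs(alleleFrequencies(gt, loc))),
                         bfFreqs(calls))
        }
    }
})

test_that("observed heterozygosity counts differing call pairs", {
    gt <- mkTable(rbind(c(100L, 102L), c(100L, 104L), c(102L, 104L),
                        c(100L, 100L)), panel = "LocA")
    expect_equal(obsHet(gt, "LocA"), 0.75)
    hom <- mkTable(rbind(c(100L, 100L), c(102L, 102L)), panel = "LocA")
    expect_equal(obsHet(hom, "LocA"), 0)
    het <- mkTable(rbind(c(100L, 102L), c(104L, 106L)), panel = "LocA")
    expect_equal(obsHet(het, "LocA"), 1)
})

test_that("expected heterozygosity follows 1 - sum(p^2), with unbiased option", {
    gt <- mkTable(rbind(c(100L, 100L), c(102L, 102L)), panel = "LocA")
    fr <- alleleFrequencies(gt, "LocA")   # p = (0.5, 0.5)
    expect_equal(expHet(fr), 0.5)
    expect_equal(expHet(fr, "unbiased"), 0.5 * 4 / 3)
    # k equifrequent alleles -> 1 - 1/k
    for (k in 2:30) {
        al <- cbind(seq(100L, by = 2L, length.out = k),
                    seq(100L, by = 2L, length.out = k))
        frk <- alleleFrequencies(mkTable(al, panel = "LocA"), "LocA")
        expect_equal(expHet(frk), 1 - 1 / k)
    }
    mono <- alleleFrequencies(mkTable(rbind(c(100L, 100L)), panel = "LocA"), "LocA")
    expect_equal(expHet(mono), 0)
})

test_that("PIC matches its expansion and the ordered-pair brute force", {
    gt <- mkTable(rbind(c(100L, 100L), c(102L, 102L)), panel = "LocA")
    fr <- alleleFrequencies(gt, "LocA")
    expect_equal(picContent(fr), 0.375)   # 1 - 0.5 - 2*0.25*0.25
    mono <- alleleFrequencies(mkTable(rbind(c(100L, 100L)), panel = "LocA"), "LocA")
    expect_equal(picContent(mono), 0)
    set.seed(21)
    for (rep in 1:50) {
        p <- randomFreqs(sample(2:10, 1))
        fr2 <- new("LocusFrequencies", locus = "x", n = 10L, nCalls = 20L,
                   freqs = setNames(p, seq_along(p)))
        expect_equal(picContent(fr2), bfPic(p), tolerance = 1e-12)
        expect_equal(expHet(fr2), bfHexp(p), tolerance = 1e-12)
        # pic below gene diversity at every polymorphic locus
        expect_lt(picContent(fr2), expHet(fr2))
    }
})

test_that("simple F_IS is (HExp - HObs)/HExp with NA at monomorphic loci", {
    expect_equal(fisSimple(0.5, 0.5), 0)
    expect_equal(fisSimple(0.5, 0), 1)
    expect_equal(fisSimple(0.8, 0.9), -0.125)
    expect_true(is.na(fisSimple(0, 0)))
})

test_that("diversity summary has panel-ordered rows and an unweighted mean row", {
    al <- cbind(rep(c(100L, 102L), 5L), rep(c(100L, 104L), 5L),
                rep(200L, 10L), rep(c(200L, 202L), c(4L, 6L)))
    gt <- mkTable(al, panel = c("LocA", "LocB"))
    s <- diversitySummary(gt)
    expect_equal(s$locus, c("LocA", "LocB", "Mean"))
    expect_equal(s$hObs[3], mean(s$hObs[1:2]))
    expect_equal(s$k[3], mean(s$k[1:2]))
    # mean row reconstruction is plain column means of the per-locus rows
    expect_equal(s$fis[3], mean(s$fis[1:2]))
})

test_that("HWE simulation recovers h_exp, h_obs and the inbreeding parameter", {
    panel6 <- data.frame(locus = paste0("L", 1:6), k = 8L,
                         minAllele = 100L, step = 2L)
    sim <- simulateGenotypes(simulationConfig(
        seed = 101L, panel = panel6, fIs = 0, minFreq = 0.06,
        cohortSizes = c("2010" = 10000L)))
    s <- diversitySummary(sim$table)
    for (i in 1:6) {
        p <- sim$ledger$cohortFreqs[["2010"]][[paste0("L", i)]]
        he <- 1 - sum(p^2)
        se <- sqrt(he * (1 - he) / 10000)   # conservative MC scale
        expect_lt(abs(s$hExp[i] - he), 3 * se + 0.003)
        expect_lt(abs(s$hObs[i] - he), 3 * sqrt(he * (1 - he) / 10000))
    }
    # inbreeding recovery across a grid spanning excess to strong inbreeding
    for (f in c(-0.05, 0.05, 0.2)) {
        simf <- simulateGenotypes(simulationConfig(
            seed = 300L + round(1000 * abs(f)) + (f < 0), panel = panel6,
            fIs = f, minFreq = 0.06, cohortSizes = c("2010" = 10000L)))
        sf <- diversitySummary(simf$table)
        fhat <- sf$fis[sf$locus == "Mean"]
        expect_lt(abs(fhat - f), 3 * 1.5 / sqrt(2 * 10000 * 6))
    }
})
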