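test_that("variance components match the hand-worked two-population toy", {
    # 2 pops x 2 alleles, 5 individuals each; components worked out
    # independently from the per-allele formulas (frozen values)
    al <- rbind(c(100L, 100L), c(100L, 102L), c(102L, 102L), c(100L, 100L),
                c(100L, 102L),
                c(100L, 102L), c(102L, 102L), c(102L, 102L), c(100L, 102L),
                c(102L, 102L))
    gt <- mkTable(al, panel = "LocA", year = rep(c(2001L, 2002L), each = 5L))
    comp <- wcComponents(gt, "LocA", birthYears(gt))
    expect_equal(unname(comp), c(0.11, 0.05, 0.40), tolerance = 1e-12)
    expect_equal(unname(comp["a"] / sum(comp)), 11 / 56, tolerance = 1e-12)
    # against the loop-transcription oracle on random data
    set.seed(31)
    for (rep in 1:10) {
        gtr <- randomTable(n = 40L, nloci = 1L, k = 5L, years = 2001:2003)
        ref <- wc84oracle(split.data.frame(alleleCalls(gtr, "L1"),
                                           birthYears(gtr)))
        expect_equal(unname(wcComponents(gtr, "L1", birthYears(gtr))),
                     unname(ref), tolerance = 1e-12)
    }
})

test_that("theta hits the no-differentiation and fixation limits", {
    set.seed(5)
    # identical frequencies -> theta near 0
    sim <- simulateGenotypes(simulationConfig(
        seed = 7L, fDrift = 0, cohortSizes = c("2001" = 5000L, "2002" = 5000L)))
    th <- pairwiseFst(sim$table)@theta[1, 2]
    expect_lt(abs(th), 0.002)
    # fixed alternative alleles -> theta 1
    al <- rbind(matrix(100L, 5L, 2L), matrix(102L, 5L, 2L))
    gt <- mkTable(al, panel = "LocA", year = rep(c(2001L, 2002L), each = 5L))
    comp <- wcComponents(gt, "LocA", birthYears(gt))
    expect_equal(unname(comp["a"] / sum(comp)), 1)
})

test_that("multilocus theta is the ratio of sums, not the mean of ratios", {
    one <- c(a = 0.02, b = 0.1, c = 0.5)
    expect_equal(multilocusTheta(list(one)), 0.02 / 0.62)
    same <- list(one, one, one)
    expect_equal(multilocusTheta(same), 0.02 / 0.62)
    two <- list(c(a = 0.02, b = 0.1, c = 0.5), c(a = 0.001, b = 0.05, c = 0.9))
    rs <- (0.02 + 0.001) / (0.62 + 0.951)
    mr <- mean(c(0.02 / 0.62, 0.001 / 0.951))
    expect_equal(multilocusTheta(two), rs)
    expect_false(isTRUE(all.equal(rs, mr)))
})

test_that("within-population f recovers equilibrium, excess and inbreeding", {
    panel4 <- data.frame(locus = paste0("L", 1:4), k = 8L,
                         minAllele = 100L, step = 2L)
    sim <- simulateGenotypes(simulationConfig(
        seed = 13L, panel = panel4, fIs = 0, minFreq = 0.06,
        cohortSizes = c("2001" = 5000L, "2002" = 5000L)))
    f0 <- wcFisWithin(sim$table, "L1", birthYears(sim$table),
                      loci = paste0("L", 1:4))
    expect_lt(abs(f0), 0.015)
    sim2 <- simulateGenotypes(simulationConfig(
        seed = 17L, panel = panel4, fIs = 0.2, minFreq = 0.06,
        cohortSizes = c("2001" = 5000L, "2002" = 5000L)))
    f2 <- wcFisWithin(sim2$table, "L1", birthYears(sim2$table),
                      loci = paste0("L", 1:4))
    expect_lt(abs(f2 - 0.2), 0.02)
    # all-heterozygote toy -> negative f
    al <- rbind(matrix(c(100L, 102L), 4L, 2L, byrow = TRUE),
                matrix(c(100L, 102L), 4L, 2L, byrow = TRUE))
    gt <- mkTable(al, panel = "LocA", year = rep(c(2001L, 2002L), each = 4L))
    expect_lt(wcFisWithin(gt, "LocA", birthYears(gt)), 0)
})

test_that("pairwise matrix is symmetric, relabeling-invariant and complete", {
    set.seed(19)
    sim <- simulateGenotypes(simulationConfig(
        seed = 23L, fDrift = 0.01,
        cohortSizes = c("2001" = 300L, "2002" = 300L, "2003" = 300L)))
    fm <- pairwiseFst(sim$table)
    th <- thetaMatrix(fm)
    expect_equal(dim(th), c(3L, 3L))
    expect_true(all(is.na(diag(th))))
    expect_equal(th[lower.tri(th)], t(th)[lower.tri(th)])
    expect_equal(sum(!is.na(th)) / 2, 3)
    # permuting individuals leaves theta unchanged
    perm <- sample(nIndividuals(sim$table))
    fm2 <- pairwiseFst(sim$table[perm])
    expect_equal(fm2@theta, th)
    # flooring only affects negative entries
    expect_true(all(thetaMatrix(fm, floorNegative = TRUE) >= 0, na.rm = TRUE))
})

test_that("a cohort split at random shows no differentiation", {
    set.seed(29)
    sim <- simulateGenotypes(simulationConfig(
        seed = 31L, cohortSizes = c("2010" = 4000L)))
    gt <- sim$table
    halves <- sample(rep(c("a", "b"), length.out = nIndividuals(gt)))
    comp <- lapply(panelLoci(gt), function(l) wcComponents(gt, l, halves))
    expect_lt(abs(multilocusTheta(comp)), 0.001)
})

test_that("the HT/HS statistic tracks theta across a drift grid", {
    set.seed(37)
    grid <- c(0.001, 0.005, 0.02, 0.1)
    thetas <- hths <- numeric(0)
    for (F in grid) {
        for (rep in 1:5) {
            sim <- simulateGenotypes(simulationConfig(
                seed = round(1e6 * F) + rep, fDrift = F,
                cohortSizes = c("2001" = 1000L, "2002" = 1000L)))
            thetas <- c(thetas, pairwiseFst(sim$table)@theta[1, 2])
            hths <- c(hths, htHsFst(sim$table, birthYears(sim$table)))
        }
    }
    expect_gt(cor(thetas, hths), 0.99)
    # monotone mean differentiation along the grid
    m <- tapply(thetas, rep(grid, each = 5L), mean)
    expect_true(all(diff(m) > 0))
})

test_that("populations too small to use are excluded with a warning", {
    al <- rbind(c(100L, 102L), c(100L, 100L), c(102L, 102L), c(100L, 102L),
                c(100L, 102L))
    gt <- mkTable(al, panel = "LocA", year = c(2001L, 2001L, 2002L, 2002L, 2003L))
    expect_warning(comp <- wcComponents(gt, "LocA", birthYears(gt)),
                   "< 2 typed")
    gt2 <- gt[1:3]
    expect_warning(expect_error(
        wcComponents(gt2[c(1, 2, 3)], "LocA", c(2001L, 2001L, 2003L)),
        "at least 2 usable"), "< 2 typed")
})
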