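test_that("missing-call filter removes exactly the incompletely typed records", {
    al <- matrix(100L, nrow = 10L, ncol = 4L)
    al[1, 2] <- NA; al[2, 3] <- NA; al[3, 1] <- NA; al[3, 2] <- NA
    gt <- mkTable(al)
    res <- filterMissing(gt)
    expect_equal(res$nRemoved, 3L)
    expect_equal(nIndividuals(res$table), 7L)
    expect_false(anyNA(alleleMatrix(res$table)))
    # no missing -> identity
    res2 <- filterMissing(res$table)
    expect_equal(res2$nRemoved, 0L)
    expect_identical(alleleMatrix(res2$table), alleleMatrix(res$table))
})

test_that("allele-range filter uses inclusive bounds and demands full coverage", {
    al <- rbind(c(100L, 250L), c(100L, 200L), c(100L, 100L), c(150L, NA))
    gt <- mkTable(al, panel = "LocA")
    res <- filterAlleleRange(gt, list(LocA = c(100, 200)))
    expect_equal(res$nRemoved, 1L)          # only the 250 offender
    expect_equal(nIndividuals(res$table), 3L)  # boundary values retained
    expect_error(filterAlleleRange(gt, list(Other = c(1, 2))), "LocA")
})

test_that("sex-marker screen applies its three reasons disjointly in priority order", {
    al <- matrix(100L, nrow = 5L, ncol = 2L)
    gt <- mkTable(al, panel = "LocA",
                  sex = c("F", "M", "F", "F", "M"),
                  mk1 = c("X", "X", "Z", "X", "X"),
                  mk2 = c("Y", "Y", "Y", NA, "Y"))
    # rec1: F with {X,Y} -> mismatch; rec2: M with {X,Y} -> keep;
    # rec3: contains Z -> other (even though also odd for an F);
    # rec4: {X, missing} -> missing regardless of registered sex; rec5: keep
    res <- filterSexMarkers(gt)
    expect_equal(res$nRemoved, 3L)
    expect_equal(unname(res$subcounts),
                 c(1L, 1L, 1L))
    expect_equal(names(res$subcounts),
                 c("otherValue", "missingMarker", "mismatch"))
    expect_equal(nIndividuals(res$table), 2L)
    expect_equal(registeredSex(res$table), c("M", "M"))
})

test_that("unknown registered sex counts as mismatch (no rule to satisfy)", {
    gt <- mkTable(matrix(100L, 1L, 2L), panel = "LocA", sex = "U",
                  mk1 = "X", mk2 = "Y")
    res <- filterSexMarkers(gt)
    expect_equal(unname(res$subcounts["mismatch"]), 1L)
})

test_that("duplicate merging keeps concordant groups once and drops discordant ones", {
    al <- rbind(c(100L, 102L), c(100L, 102L),          # concordant pair
                c(104L, 104L), c(104L, 106L),          # discordant pair
                c(108L, 110L), c(108L, 110L), c(108L, 110L),  # 3-fold
                c(112L, 112L))                          # singleton
    gt <- mkTable(al, panel = "LocA",
                  barcode = c("d1", "d1", "d2", "d2", "d3", "d3", "d3", "s1"))
    res <- mergeDuplicates(gt)
    expect_equal(res$found, c(`2` = 2L, `3` = 1L))
    expect_equal(res$nRecords, 7L)
    expect_equal(res$nRecovered, 2L)       # d1 and d3; d2 dropped entirely
    expect_setequal(barcodes(res$table), c("s1", "d1", "d3"))
})

test_that("duplicate merging fills missing calls from concordant members", {
    al <- rbind(c(100L, NA), c(100L, 102L))
    gt <- mkTable(al, panel = "LocA", barcode = c("d1", "d1"))
    res <- mergeDuplicates(gt)
    expect_equal(res$nRecovered, 1L)
    expect_equal(unname(alleleCalls(res$table, "LocA")[1, ]), c(100L, 102L))
})

test_that("min-cohort filter is a strict-less-than boundary", {
    gt99 <- mkTable(matrix(100L, 99L, 2L), panel = "LocA", year = 2005L)
    gt100 <- mkTable(matrix(100L, 100L, 2L), panel = "LocA", year = 2006L)
    res <- filterMinCohort(rbind2(gt99, gt100), 100L)
    expect_equal(res$nRemoved, 99L)
    expect_equal(unique(birthYears(res$table)), 2006L)
    # minSize = 1 is the identity
    res1 <- filterMinCohort(gt99, 1L)
    expect_equal(res1$nRemoved, 0L)
})

test_that("runQc on a clean table is the identity with an all-zero report", {
    gt <- mkTable(matrix(150L, 120L, 2L), panel = "LocA", year = 2010L)
    cfg <- qcConfig(list(LocA = c(100, 200)))
    res <- runQc(gt, cfg)
    expect_equal(res$report@raw, 120L)
    expect_equal(res$report@final, 120L)
    expect_equal(res$report@missingRemoved +
                 res$report@rangeRemoved + res$report@sexRemoved +
                 res$report@dupRecords + res$report@smallCohortRemoved, 0L)
})

test_that("runQc is idempotent and satisfies the count identity on random tables", {
    set.seed(42)
    cfg <- qcConfig(list(L1 = c(100, 120), L2 = c(100, 120), L3 = c(100, 120)),
                    minCohortSize = 5L)
    for (rep in 1:25) {
        gt <- randomTable(n = 60L, nloci = 3L, k = 11L, pMissing = 0.02,
                          years = 2010:2012)
        res <- runQc(gt, cfg)
        r <- res$report
        expect_equal(r@final,
                     r@raw - r@missingRemoved - r@rangeRemoved - r@sexRemoved -
                     r@dupRecords + r@dupRecovered - r@smallCohortRemoved)
        res2 <- runQc(res$table, cfg)
        expect_equal(res2$report@final, res2$report@raw)
        expect_identical(alleleMatrix(res2$table), alleleMatrix(res$table))
    }
})

test_that("QC config can be read from JSON and YAML", {
    js <- withr::local_tempfile(fileext = ".json")
    writeLines('{"allele_ranges": {"LocA": [100, 200]}, "min_cohort_size": 7}', js)
    cfg <- readQcConfig(js)
    expect_equal(cfg$minCohortSize, 7L)
    expect_equal(cfg$alleleRanges$LocA, c(100, 200))
    yml <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("allele_ranges:", "  LocA: [100, 200]",
                 "min_cohort_size: 3"), yml)
    cfg2 <- readQcConfig(yml)
    expect_equal(cfg2$minCohortSize, 3L)
    bad <- withr::local_tempfile(fileext = ".json")
    writeLines('{"min_cohort_size": 3}', bad)
    expect_error(readQcConfig(bad), "allele_ranges")
})
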