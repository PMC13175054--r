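## Per-birth-year diversity trends and cohort census tables. Each (year,
## locus) cell is computed from that year's cohort alone via the diversity
## module; concatenating all cohorts and recomputing reproduces the pooled
## summary exactly (consistency invariant, tested).

#' Per-year per-locus diversity trend table
#'
#' Long-format table indexed by `(birthYear, locus)` with `n` (typed
#' individuals), `hObs`, `hExp`, `pic`, the simple F_IS and the unbiased
#' within-cohort F_IS ([fisUnbiased()]). Which inbreeding estimator a given
#' downstream plot uses is a display choice, so both are carried.
#'
#' @param table a QC'd [GenotypeTable-class].
#' @param years birth years to include; default all present.
#' @param correction passed to [expHet()].
#' @return a data.frame, years ascending, loci in panel order within year.
#' @export
trendStatistics <- function(table, years = sort(unique(birthYears(table))),
                            correction = "none") {
    if (nIndividuals(table) == 0L)
        stop("empty table")
    out <- list()
    for (y in years) {
        sub <- table[birthYears(table) == y]
        if (nIndividuals(sub) == 0L)
            next
        for (loc in panelLoci(table)) {
            fr <- alleleFrequencies(sub, loc)
            ho <- obsHet(sub, loc)
            he <- expHet(fr, correction)
            out[[length(out) + 1L]] <- data.frame(
                birthYear = y, locus = loc, n = numTyped(fr),
                hObs = ho, hExp = he, pic = picContent(fr),
                fisSimple = fisSimple(he, ho),
                fisUnbiased = fisUnbiased(sub, loc),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Cohort census by birth year and registered sex
#'
#' Counts per birth year split by registered sex, with column percentages
#' (1 decimal) and a `Total` row. Years absent from the table are absent from
#' the output.
#'
#' @param table a QC'd [GenotypeTable-class].
#' @return a data.frame with columns `birthYear`, one count column per sex
#'   present, `total`, `pct`.
#' @export
cohortCensus <- function(table) {
    yrs <- birthYears(table)
    sx <- registeredSex(table)
    years <- sort(unique(yrs))
    sexes <- sort(unique(sx))
    counts <- vapply(sexes, function(s)
        vapply(years, function(y) sum(yrs == y & sx == s), integer(1L)),
        integer(length(years)))
    counts <- matrix(counts, nrow = length(years),
                     dimnames = list(NULL, sexes))
    total <- rowSums(counts)
    out <- data.frame(birthYear = as.character(years), counts,
                      total = total,
                      pct = round(100 * total / sum(total), 1L),
                      check.names = FALSE, stringsAsFactors = FALSE)
    totRow <- data.frame(birthYear = "Total",
                         t(colSums(counts)), total = sum(total),
                         pct = round(sum(100 * total / sum(total)), 1L),
                         check.names = FALSE, stringsAsFactors = FALSE)
    out <- rbind(out, totRow)
    rownames(out) <- NULL
    out
}
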