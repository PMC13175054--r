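## Per-locus allele frequencies and the classical diversity statistics:
## observed heterozygosity, gene diversity (expected heterozygosity), Botstein
## polymorphic information content, and the simple inbreeding coefficient
## F_IS = (HExp - HObs)/HExp.

#' Estimate allele frequencies at one locus
#'
#' Frequencies are simple counts over the non-missing calls: `p_i` is the
#' number of copies of allele `i` divided by the number of non-missing calls.
#' Missing calls are excluded from numerator and denominator alike.
#'
#' @param table a [GenotypeTable-class].
#' @param locus a panel locus name.
#' @return a [LocusFrequencies-class].
#' @export
alleleFrequencies <- function(table, locus) {
    calls <- alleleCalls(table, locus)
    typed <- sum(stats::complete.cases(calls))
    flat <- calls[!is.na(calls)]
    if (!length(flat))
        stop("no typed individuals at locus ", locus)
    counts <- table(flat)
    f <- as.numeric(counts) / length(flat)
    names(f) <- names(counts)
    new("LocusFrequencies", locus = locus, n = as.integer(typed),
        nCalls = length(flat), freqs = f)
}

#' Observed heterozygosity at one locus
#'
#' The fraction of fully typed individuals whose two calls differ.
#'
#' @param table a [GenotypeTable-class].
#' @param locus a panel locus name.
#' @return a proportion in `[0, 1]`.
#' @export
obsHet <- function(table, locus) {
    calls <- alleleCalls(table, locus)
    ok <- stats::complete.cases(calls)
    if (!any(ok))
        stop("no typed individuals at locus ", locus)
    mean(calls[ok, 1L] != calls[ok, 2L])
}

#' Expected heterozygosity (gene diversity)
#'
#' `1 - sum(p_i^2)` under Hardy-Weinberg equilibrium. The `"unbiased"` option
#' applies the small-sample factor `2N/(2N - 1)`; at the panel sizes this
#' package targets the two differ by well under 1e-5, so the exact form is the
#' default.
#'
#' @param freqs a [LocusFrequencies-class].
#' @param correction `"none"` (default) or `"unbiased"`.
#' @return a proportion in `[0, 1]`.
#' @export
expHet <- function(freqs, correction = c("none", "unbiased")) {
    correction <- match.arg(correction)
    p <- alleleFreqs(freqs)
    h <- 1 - sum(p^2)
    if (correction == "unbiased") {
        n <- numTyped(freqs)
        h <- h * 2 * n / (2 * n - 1)
    }
    h
}

#' Polymorphic information content (Botstein)
#'
#' `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, computed via the power sums
#' `S2 = sum(p^2)`, `S4 = sum(p^4)` as `1 - S2 - S2^2 + S4`. PIC never
#' exceeds the gene diversity; equality holds only for a monomorphic locus.
#'
#' @param freqs a [LocusFrequencies-class].
#' @return a proportion in `[0, 1]`.
#' @export
picContent <- function(freqs) {
    p <- alleleFreqs(freqs)
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    1 - s2 - s2^2 + s4
}

#' Simple inbreeding coefficient from the two heterozygosities
#'
#' `(HExp - HObs)/HExp`: positive for homozygote excess, negative for
#' heterozygote excess, zero at Hardy-Weinberg equilibrium. Undefined for a
#' monomorphic locus (`HExp = 0`), returned as `NA`.
#'
#' @param hExp expected heterozygosity.
#' @param hObs observed heterozygosity.
#' @return the coefficient, or `NA` when `hExp` is 0.
#' @export
fisSimple <- function(hExp, hObs) {
    ifelse(hExp > 0, (hExp - hObs) / hExp, NA_real_)
}

#' Unbiased within-cohort inbreeding coefficient
#'
#' The basic-statistics estimator `f = 1 - HObs/Hs` with Nei's unbiased
#' within-sample gene diversity `Hs = n/(n-1) * (1 - sum(p^2) - HObs/(2n))`.
#' This is the estimator population tools compute per population, and it is
#' the second F_IS column of the trend tables.
#'
#' @param table a [GenotypeTable-class] (one cohort).
#' @param locus a panel locus name.
#' @return the coefficient, or `NA` when `Hs` is 0.
#' @export
fisUnbiased <- function(table, locus) {
    fr <- alleleFrequencies(table, locus)
    n <- numTyped(fr)
    ho <- obsHet(table, locus)
    hs <- n / (n - 1) * (1 - sum(alleleFreqs(fr)^2) - ho / (2 * n))
    if (hs <= 0) NA_real_ else 1 - ho / hs
}

#' Per-locus diversity summary with a mean row
#'
#' One row per panel locus with `k` (allele count), `N` (typed individuals),
#' `hObs`, `hExp`, `pic` and the simple F_IS, followed by an unweighted mean
#' row. When `pop` supplies at least two cohort labels, a Weir-Cockerham
#' within-population `f` column (variance-component estimator) is added as an
#' alternative F_IS.
#'
#' @param table a QC'd [GenotypeTable-class].
#' @param correction passed to [expHet()].
#' @param pop optional per-record population labels for the alternative
#'   variance-component F_IS column.
#' @return a data.frame; the last row is labelled `"Mean"`.
#' @export
diversitySummary <- function(table, correction = "none", pop = NULL) {
    rows <- lapply(panelLoci(table), function(loc) {
        fr <- alleleFrequencies(table, loc)
        ho <- obsHet(table, loc)
        he <- expHet(fr, correction)
        data.frame(locus = loc, k = numAlleles(fr), N = numTyped(fr),
                   hObs = ho, hExp = he, pic = picContent(fr),
                   fis = fisSimple(he, ho), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(pop) && length(unique(pop)) >= 2L) {
        out$fisWc <- vapply(panelLoci(table), function(loc)
            wcFisWithin(table, loc, pop), numeric(1L))
    }
    summaryMeanRow(out)
}

#' Append the unweighted mean row to a per-locus summary
#'
#' Column means are unweighted over loci, which is how a multi-locus panel's
#' mean diversity line is conventionally reported.
#'
#' @param perLocus data.frame with a `locus` column and numeric statistic
#'   columns.
#' @return the data.frame with a final `"Mean"` row.
#' @export
summaryMeanRow <- function(perLocus) {
    stopifnot(is.data.frame(perLocus), "locus" %in% names(perLocus))
    body <- perLocus[perLocus$locus != "Mean", , drop = FALSE]
    mean_row <- body[1L, , drop = FALSE]
    mean_row$locus <- "Mean"
    for (cc in setdiff(names(body), "locus")) {
        mean_row[[cc]] <- if (is.numeric(body[[cc]]))
            mean(body[[cc]], na.rm = TRUE) else NA
    }
    out <- rbind(body, mean_row)
    rownames(out) <- NULL
    out
}

#' Format a diversity summary as a fixed-width text table
#'
#' @param summary output of [diversitySummary()].
#' @return a character vector of lines.
#' @export
formatDiversitySummary <- function(summary) {
    num <- function(x, d) ifelse(is.na(x), "NA", formatC(x, digits = d, format = "f"))
    header <- sprintf("%-10s %6s %9s %7s %7s %7s %8s", "Locus", "k", "N",
                      "HObs", "HExp", "PIC", "FIS")
    lines <- vapply(seq_len(nrow(summary)), function(i) {
        r <- summary[i, ]
        sprintf("%-10s %6s %9d %7s %7s %7s %8s", r$locus,
                num(r$k, if (r$locus == "Mean") 3L else 0L), as.integer(r$N),
                num(r$hObs, 3L), num(r$hExp, 3L), num(r$pic, 3L),
                num(r$fis, 4L))
    }, character(1L))
    c(header, lines)
}
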