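#' @import methods
#' @importFrom stats rbinom rgamma runif setNames var sd cor complete.cases
#'   aggregate lm coef
#' @importFrom utils read.csv write.csv read.table head tail
NULL

## Missing allele calls are stored as NA_integer_; missing sex-marker calls as
## NA_character_. Allele pairs are kept sorted ascending (unordered genotype
## convention), with a lone non-missing call in the first position.

#' GenotypeTable: multi-locus microsatellite genotypes with cohort metadata
#'
#' The central container of the package: one row per individual, two integer
#' allele-size calls (base pairs) per autosomal locus, plus the metadata the
#' QC cascade needs (barcode ID, birth year, registered sex and the two
#' sex-determination marker calls). Sex markers are deliberately stored
#' outside the autosomal panel and never enter any diversity or
#' differentiation statistic.
#'
#' @slot panel character vector of locus names, in fixed panel order.
#' @slot alleles integer matrix with `2 * length(panel)` columns named
#'   `<locus>_1`, `<locus>_2`; `NA` encodes a missing call; each pair is
#'   sorted ascending (missing last).
#' @slot meta data.frame with columns `barcode` (character), `birthYear`
#'   (integer), `sex` (one of `"F"`, `"M"`, `"U"`), `sexMarker1`,
#'   `sexMarker2` (character; `"X"`/`"Y"`, `NA` for missing, anything else
#'   is an anomalous call).
#'
#' @seealso [GenotypeTable()] for construction, [readGenotypeCsv()],
#'   [readGenepop()], [runQc()].
#' @export
setClass("GenotypeTable",
         representation(panel = "character",
                        alleles = "matrix",
                        meta = "data.frame"))

.metaCols <- c("barcode", "birthYear", "sex", "sexMarker1", "sexMarker2")

setValidity("GenotypeTable", function(object) {
    msgs <- character(0)
    p <- object@panel
    al <- object@alleles
    if (length(p) < 1L || anyDuplicated(p))
        msgs <- c(msgs, "panel must be a non-empty set of unique locus names")
    wanted <- paste0(rep(p, each = 2L), c("_1", "_2"))
    if (!identical(colnames(al), wanted))
        msgs <- c(msgs, "allele columns must be <locus>_1, <locus>_2 in panel order")
    if (!is.integer(al))
        msgs <- c(msgs, "alleles must be an integer matrix")
    if (nrow(object@meta) != nrow(al))
        msgs <- c(msgs, "meta and alleles must have the same number of rows")
    if (!all(.metaCols %in% names(object@meta)))
        msgs <- c(msgs, paste("meta must contain columns:",
                              paste(.metaCols, collapse = ", ")))
    if (any(al[!is.na(al)] <= 0L))
        msgs <- c(msgs, "allele sizes must be positive")
    if (nrow(al) > 0L) {
        for (i in seq_along(p)) {
            a1 <- al[, 2L * i - 1L]
            a2 <- al[, 2L * i]
            bad <- (!is.na(a1) & !is.na(a2) & a1 > a2) | (is.na(a1) & !is.na(a2))
            if (any(bad)) {
                msgs <- c(msgs, sprintf("allele pair not sorted ascending at locus %s", p[i]))
                break
            }
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeTable
#'
#' Allele pairs are sorted ascending per locus (a single non-missing call is
#' moved to the first slot), so genotypes are stored unordered.
#'
#' @param panel character vector of locus names (panel order).
#' @param alleles integer matrix (or coercible) with columns `<locus>_1`,
#'   `<locus>_2` in panel order; `NA` = missing call.
#' @param meta data.frame with columns `barcode`, `birthYear`, `sex`,
#'   `sexMarker1`, `sexMarker2`.
#' @return A [GenotypeTable-class] object.
#' @examples
#' gt <- GenotypeTable(
#'   panel = "BM1824",
#'   alleles = cbind(BM1824_1 = c(190L, 182L), BM1824_2 = c(182L, 182L)),
#'   meta = data.frame(barcode = c("a", "b"), birthYear = c(2010L, 2010L),
#'                     sex = c("F", "M"), sexMarker1 = "X",
#'                     sexMarker2 = c("X", "Y")))
#' alleleCalls(gt, "BM1824")
#' @export
GenotypeTable <- function(panel, alleles, meta) {
    panel <- as.character(panel)
    alleles <- as.matrix(alleles)
    storage.mode(alleles) <- "integer"
    colnames(alleles) <- paste0(rep(panel, each = 2L), c("_1", "_2"))
    alleles <- .sortAllelePairs(alleles, length(panel))
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    meta$barcode <- as.character(meta$barcode)
    meta$birthYear <- as.integer(meta$birthYear)
    meta$sex <- as.character(meta$sex)
    meta$sexMarker1 <- as.character(meta$sexMarker1)
    meta$sexMarker2 <- as.character(meta$sexMarker2)
    rownames(meta) <- NULL
    rownames(alleles) <- NULL
    new("GenotypeTable", panel = panel, alleles = alleles,
        meta = meta[, .metaCols, drop = FALSE])
}

.sortAllelePairs <- function(al, nloci) {
    for (i in seq_len(nloci)) {
        c1 <- 2L * i - 1L
        c2 <- 2L * i
        a1 <- al[, c1]
        a2 <- al[, c2]
        lo <- pmin(a1, a2)
        hi <- pmax(a1, a2)
        oneNA <- xor(is.na(a1), is.na(a2))
        if (any(oneNA)) {
            lo[oneNA] <- ifelse(is.na(a1[oneNA]), a2[oneNA], a1[oneNA])
            hi[oneNA] <- NA_integer_
        }
        al[, c1] <- lo
        al[, c2] <- hi
    }
    al
}

#' Per-locus allele frequency vector
#'
#' Holds the estimated allele frequencies `p_i` at one locus together with the
#' number of fully typed individuals (`N` of the summary tables) and the
#' allele count `k`.
#'
#' @slot locus locus name.
#' @slot n integer, individuals fully typed at the locus.
#' @slot nCalls integer, non-missing allele calls used in the denominator.
#' @slot freqs named numeric, frequencies by allele size; all positive,
#'   summing to 1.
#' @export
setClass("LocusFrequencies",
         representation(locus = "character", n = "integer",
                        nCalls = "integer", freqs = "numeric"))

setValidity("LocusFrequencies", function(object) {
    msgs <- character(0)
    if (length(object@freqs) < 1L || is.null(names(object@freqs)))
        msgs <- c(msgs, "freqs must be a named, non-empty numeric vector")
    if (any(object@freqs <= 0))
        msgs <- c(msgs, "all frequencies must be positive")
    if (abs(sum(object@freqs) - 1) > 1e-9)
        msgs <- c(msgs, "frequencies must sum to 1")
    if (length(msgs)) msgs else TRUE
})

#' Staged quality-control report
#'
#' Per-stage counted drops of the QC cascade, satisfying the exact identity
#' `final = raw - missing - range - sex - duplicateRecords + duplicatesRecovered
#' - smallCohort`. `duplicateRecords` counts every record that belongs to a
#' multi-record barcode group (all are set aside at the duplicate stage);
#' `duplicatesRecovered` counts the merged representatives added back for
#' concordant groups.
#'
#' @slot raw records read in.
#' @slot missingRemoved records with at least one missing autosomal call.
#' @slot rangeRemoved records with an out-of-range allele.
#' @slot sexRemoved records failing the sex-marker screen.
#' @slot sexSubcounts named integer: `otherValue`, `missingMarker`,
#'   `mismatch` (disjoint, in that priority order).
#' @slot dupGroups named integer: duplicate barcode groups by multiplicity.
#' @slot dupRecords records belonging to multi-record barcode groups.
#' @slot dupRecovered merged records retained from concordant groups.
#' @slot smallCohortRemoved records in cohorts below the size threshold.
#' @slot final records surviving the cascade.
#' @export
setClass("QcReport",
         representation(raw = "integer", missingRemoved = "integer",
                        rangeRemoved = "integer", sexRemoved = "integer",
                        sexSubcounts = "integer", dupGroups = "integer",
                        dupRecords = "integer", dupRecovered = "integer",
                        smallCohortRemoved = "integer", final = "integer"))

setValidity("QcReport", function(object) {
    expect <- object@raw - object@missingRemoved - object@rangeRemoved -
        object@sexRemoved - object@dupRecords + object@dupRecovered -
        object@smallCohortRemoved
    msgs <- character(0)
    if (object@final != expect)
        msgs <- c(msgs, "stage counts do not satisfy the report identity")
    if (object@sexRemoved != sum(object@sexSubcounts))
        msgs <- c(msgs, "sex subcounts must sum to sexRemoved")
    counts <- c(object@raw, object@missingRemoved, object@rangeRemoved,
                object@sexRemoved, object@sexSubcounts, object@dupRecords,
                object@dupRecovered, object@smallCohortRemoved, object@final)
    if (any(counts < 0L))
        msgs <- c(msgs, "all stage counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Pairwise cohort differentiation matrix
#'
#' Symmetric matrix of multilocus Weir-Cockerham theta between cohorts
#' (typically birth years), with the loci-summed variance components kept so
#' raw (possibly negative) estimates are never lost to display flooring.
#'
#' @slot cohorts cohort labels, in order.
#' @slot theta symmetric numeric matrix of raw multilocus theta; diagonal NA.
#' @slot numer loci-summed between-population components (a) per pair.
#' @slot denom loci-summed total components (a + b + c) per pair.
#' @export
setClass("FstMatrix",
         representation(cohorts = "character", theta = "matrix",
                        numer = "matrix", denom = "matrix"))

setValidity("FstMatrix", function(object) {
    k <- length(object@cohorts)
    msgs <- character(0)
    for (s in c("theta", "numer", "denom")) {
        m <- slot(object, s)
        if (!all(dim(m) == c(k, k)))
            msgs <- c(msgs, sprintf("%s must be %d x %d", s, k, k))
    }
    off <- !diag(TRUE, k)
    th <- object@theta
    if (k > 1L && any(abs(th[off] - t(th)[off]) > 1e-12, na.rm = TRUE))
        msgs <- c(msgs, "theta must be symmetric")
    if (any(th[off] > 1 + 1e-12 | th[off] <= -1, na.rm = TRUE))
        msgs <- c(msgs, "theta must lie in (-1, 1]")
    if (length(msgs)) msgs else TRUE
})
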