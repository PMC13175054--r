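## Staged QC cascade. Stage order is fixed (missing -> allele range -> sex
## markers -> duplicate barcodes -> minimum cohort size); permuting stages can
## change the counts, so the canonical order is part of the contract.

#' QC configuration
#'
#' @param alleleRanges named list (or 2-column matrix rows) giving the
#'   inclusive `(min, max)` allele-size window per locus, in base pairs.
#'   Ranges are configuration, not constants: fragment-size windows are
#'   chemistry- and binning-specific.
#' @param minCohortSize cohorts (birth years) with strictly fewer survivors
#'   are dropped entirely; default 100.
#' @param sexRule mapping from registered sex to the required sex-marker
#'   multiset; default `F = {X,X}`, `M = {X,Y}` (amelogenin-type
#'   interpretation). A registered sex with no rule (e.g. unknown) always
#'   counts as a mismatch.
#' @return a list of class `QcConfig`.
#' @export
qcConfig <- function(alleleRanges, minCohortSize = 100L,
                     sexRule = list(F = c("X", "X"), M = c("X", "Y"))) {
    stopifnot(minCohortSize >= 1L)
    ranges <- lapply(alleleRanges, function(r) {
        r <- as.numeric(r)
        stopifnot(length(r) == 2L, r[1L] <= r[2L])
        r
    })
    sexRule <- lapply(sexRule, function(r) sort(as.character(r)))
    structure(list(alleleRanges = ranges,
                   minCohortSize = as.integer(minCohortSize),
                   sexRule = sexRule),
              class = "QcConfig")
}

#' Load a QC configuration from a YAML or JSON file
#'
#' The file holds the same fields as [qcConfig()]: `allele_ranges` (map locus
#' to `[min, max]`), `min_cohort_size`, `sex_rule` (map sex to marker list).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `QcConfig`.
#' @export
readQcConfig <- function(path) {
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("the yaml package is required to read YAML configs")
        yaml::read_yaml(path)
    } else {
        jsonlite::read_json(path, simplifyVector = TRUE)
    }
    if (is.null(raw$allele_ranges))
        stop("config error: missing key 'allele_ranges'")
    qcConfig(alleleRanges = raw$allele_ranges,
             minCohortSize = raw$min_cohort_size %||% 100L,
             sexRule = raw$sex_rule %||% list(F = c("X", "X"), M = c("X", "Y")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove records with missing autosomal allele calls
#'
#' A record is removed (and counted once) if any of its autosomal calls is
#' missing; survivors are fully typed at every panel locus.
#'
#' @param table a [GenotypeTable-class].
#' @return `list(table, nRemoved)`.
#' @export
filterMissing <- function(table) {
    drop <- rowSums(is.na(table@alleles)) > 0L
    list(table = table[!drop], nRemoved = sum(drop))
}

#' Remove records with out-of-range allele sizes
#'
#' Bounds are inclusive: a call exactly at the window edge is retained.
#' Missing calls are never out of range.
#'
#' @param table a [GenotypeTable-class].
#' @param ranges named list of `(min, max)` per locus; must cover the panel.
#' @return `list(table, nRemoved)`.
#' @export
filterAlleleRange <- function(table, ranges) {
    absent <- setdiff(table@panel, names(ranges))
    if (length(absent))
        stop("no allele range configured for locus: ",
             paste(absent, collapse = ", "))
    bad <- rep(FALSE, nIndividuals(table))
    for (i in seq_along(table@panel)) {
        r <- ranges[[table@panel[i]]]
        for (cc in c(2L * i - 1L, 2L * i)) {
            a <- table@alleles[, cc]
            bad <- bad | (!is.na(a) & (a < r[1L] | a > r[2L]))
        }
    }
    list(table = table[!bad], nRemoved = sum(bad))
}

#' Screen sex-determination markers against registered sex
#'
#' A record is removed when its marker pair (a) contains a value other than
#' X or Y, (b) contains a missing call, or (c) as a multiset differs from the
#' rule for its registered sex. The three reasons are disjoint, assigned in
#' that priority order.
#'
#' @param table a [GenotypeTable-class].
#' @param sexRule named list mapping registered sex to its marker multiset.
#' @return `list(table, nRemoved, subcounts)` with `subcounts` named
#'   `otherValue`, `missingMarker`, `mismatch`.
#' @export
filterSexMarkers <- function(table,
                             sexRule = list(F = c("X", "X"), M = c("X", "Y"))) {
    mk <- sexMarkers(table)
    other <- (!is.na(mk[, 1L]) & !(mk[, 1L] %in% c("X", "Y"))) |
             (!is.na(mk[, 2L]) & !(mk[, 2L] %in% c("X", "Y")))
    missing <- !other & (is.na(mk[, 1L]) | is.na(mk[, 2L]))
    key <- paste(pmin(mk[, 1L], mk[, 2L]), pmax(mk[, 1L], mk[, 2L]))
    want <- vapply(registeredSex(table), function(s) {
        r <- sexRule[[s]]
        if (is.null(r)) "" else paste(r[1L], r[2L])
    }, character(1L))
    mismatch <- !other & !missing & key != want
    drop <- other | missing | mismatch
    list(table = table[!drop], nRemoved = sum(drop),
         subcounts = c(otherValue = sum(other), missingMarker = sum(missing),
                       mismatch = sum(mismatch)))
}

#' Collapse duplicated barcode IDs
#'
#' Records are grouped by barcode. Singleton groups pass through. A
#' multi-record group collapses to one merged record iff every member shares
#' `birthYear` and registered sex and agrees at every non-missing call
#' (genotypes and sex markers); the merged record fills each missing call from
#' any member that has it. Discordant groups are dropped entirely.
#'
#' @param table a [GenotypeTable-class].
#' @return `list(table, found, nRecovered, nRecords)`: `found` is a named
#'   integer vector counting duplicate groups by multiplicity, `nRecords` the
#'   records belonging to multi-record groups (all set aside at this stage),
#'   `nRecovered` the merged representatives added back.
#' @export
mergeDuplicates <- function(table) {
    bc <- barcodes(table)
    tab <- table(bc)
    multi <- names(tab)[tab > 1L]
    if (!length(multi)) {
        return(list(table = table, found = integer(0), nRecovered = 0L,
                    nRecords = 0L))
    }
    found <- table(as.integer(tab[multi]))
    found <- stats::setNames(as.integer(found), names(found))
    keepSingle <- which(!(bc %in% multi))
    al <- table@alleles
    meta <- table@meta
    mergedAl <- list(); mergedMeta <- list()
    nRecords <- 0L
    for (b in multi) {
        idx <- which(bc == b)
        nRecords <- nRecords + length(idx)
        g <- al[idx, , drop = FALSE]
        mm <- meta[idx, , drop = FALSE]
        same <- length(unique(mm$birthYear)) == 1L &&
            length(unique(mm$sex)) == 1L
        if (same) {
            for (cc in seq_len(ncol(g))) {
                v <- unique(g[, cc][!is.na(g[, cc])])
                if (length(v) > 1L) { same <- FALSE; break }
            }
        }
        if (same) {
            for (cc in c("sexMarker1", "sexMarker2")) {
                v <- unique(mm[[cc]][!is.na(mm[[cc]])])
                if (length(v) > 1L) { same <- FALSE; break }
            }
        }
        if (same) {
            consensus <- vapply(seq_len(ncol(g)), function(cc) {
                v <- g[, cc][!is.na(g[, cc])]
                if (length(v)) v[1L] else NA_integer_
            }, integer(1L))
            row <- mm[1L, , drop = FALSE]
            for (cc in c("sexMarker1", "sexMarker2")) {
                v <- mm[[cc]][!is.na(mm[[cc]])]
                row[[cc]] <- if (length(v)) v[1L] else NA_character_
            }
            mergedAl[[length(mergedAl) + 1L]] <- consensus
            mergedMeta[[length(mergedMeta) + 1L]] <- row
        }
    }
    nRecovered <- length(mergedAl)
    outAl <- al[keepSingle, , drop = FALSE]
    outMeta <- meta[keepSingle, , drop = FALSE]
    if (nRecovered) {
        outAl <- rbind(outAl, do.call(rbind, mergedAl))
        outMeta <- rbind(outMeta, do.call(rbind, mergedMeta))
    }
    colnames(outAl) <- colnames(al)
    list(table = GenotypeTable(table@panel, outAl, outMeta),
         found = found, nRecovered = nRecovered, nRecords = nRecords)
}

#' Drop undersized birth-year cohorts
#'
#' Removes every record whose birth-year cohort has strictly fewer than
#' `minSize` members (counted after all prior stages).
#'
#' @param table a [GenotypeTable-class].
#' @param minSize minimum cohort size; a cohort of exactly `minSize` is kept.
#' @return `list(table, nRemoved)`.
#' @export
filterMinCohort <- function(table, minSize = 100L) {
    stopifnot(minSize >= 1L)
    yrs <- birthYears(table)
    sizes <- table(yrs)
    small <- names(sizes)[sizes < minSize]
    drop <- as.character(yrs) %in% small
    list(table = table[!drop], nRemoved = sum(drop))
}

#' Run the full QC cascade
#'
#' Applies, in order: missing-call removal, allele-range screen, sex-marker
#' screen, duplicate-barcode merging, minimum-cohort-size filter. The returned
#' [QcReport-class] satisfies its count identity exactly; re-running QC on the
#' output is the identity (all removals zero).
#'
#' @param table a [GenotypeTable-class].
#' @param config a [qcConfig()] list.
#' @return `list(table, report)`.
#' @export
runQc <- function(table, config) {
    stopifnot(inherits(config, "QcConfig"))
    raw <- nIndividuals(table)
    s1 <- filterMissing(table)
    s2 <- filterAlleleRange(s1$table, config$alleleRanges)
    s3 <- filterSexMarkers(s2$table, config$sexRule)
    s4 <- mergeDuplicates(s3$table)
    s5 <- filterMinCohort(s4$table, config$minCohortSize)
    report <- new("QcReport",
                  raw = as.integer(raw),
                  missingRemoved = as.integer(s1$nRemoved),
                  rangeRemoved = as.integer(s2$nRemoved),
                  sexRemoved = as.integer(s3$nRemoved),
                  sexSubcounts = as.integer(s3$subcounts) |>
                      stats::setNames(names(s3$subcounts)),
                  dupGroups = s4$found,
                  dupRecords = as.integer(s4$nRecords),
                  dupRecovered = as.integer(s4$nRecovered),
                  smallCohortRemoved = as.integer(s5$nRemoved),
                  final = nIndividuals(s5$table))
    list(table = s5$table, report = report)
}

#' @rdname QcReport-class
#' @param object a `QcReport`
#' @export
setMethod("show", "QcReport", function(object) {
    fmt <- function(n) formatC(n, big.mark = ",", format = "d")
    g <- object@dupGroups
    cat("QC cascade report\n")
    cat(sprintf("  %-38s %12s\n", "Raw data (i)", fmt(object@raw)))
    cat(sprintf("  %-38s %12s\n", "Missing allele value (ii)", fmt(object@missingRemoved)))
    cat(sprintf("  %-38s %12s\n", "Allele value outlier (iii)", fmt(object@rangeRemoved)))
    cat(sprintf("  %-38s %12s\n", "Sex marker outlier (iv)", fmt(object@sexRemoved)))
    cat(sprintf("    %-36s %12s\n", "no X/Y value", fmt(object@sexSubcounts[["otherValue"]])))
    cat(sprintf("    %-36s %12s\n", "no sex marker", fmt(object@sexSubcounts[["missingMarker"]])))
    cat(sprintf("    %-36s %12s\n", "mismatch with registered sex", fmt(object@sexSubcounts[["mismatch"]])))
    cat(sprintf("  %-38s %12s\n", "Duplicate barcode records", fmt(object@dupRecords)))
    for (m in names(g))
        cat(sprintf("    %-36s %12s\n", paste0(m, "-fold duplicate groups"), fmt(g[[m]])))
    cat(sprintf("  %-38s %12s\n", "Recovered by merging (v)", fmt(object@dupRecovered)))
    cat(sprintf("  %-38s %12s\n", "Below minimum cohort size (vi)", fmt(object@smallCohortRemoved)))
    cat(sprintf("  %-38s %12s\n", "Analysis data", fmt(object@final)))
    invisible(NULL)
})

#' Convert a QcReport to a plain list (for JSON serialisation)
#'
#' @param report a [QcReport-class].
#' @return a named list of the stage counts.
#' @export
qcReportAsList <- function(report) {
    list(raw = report@raw,
         missing_removed = report@missingRemoved,
         range_removed = report@rangeRemoved,
         sex_removed = report@sexRemoved,
         sex_subcounts = as.list(report@sexSubcounts),
         duplicate_groups = if (length(report@dupGroups))
             as.list(report@dupGroups) else list(),
         duplicate_records = report@dupRecords,
         duplicates_recovered = report@dupRecovered,
         small_cohort_removed = report@smallCohortRemoved,
         final = report@final)
}
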