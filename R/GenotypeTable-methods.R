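#' @describeIn GenotypeTable-class number of individual records
#' @param x,object a `GenotypeTable`
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeTable-class
#' @export
setMethod("nIndividuals", "GenotypeTable", function(x) nrow(x@alleles))

#' @describeIn GenotypeTable-class locus names in panel order
#' @export
setGeneric("panelLoci", function(x) standardGeneric("panelLoci"))

#' @rdname GenotypeTable-class
#' @export
setMethod("panelLoci", "GenotypeTable", function(x) x@panel)

#' @describeIn GenotypeTable-class barcode IDs (not necessarily unique pre-QC)
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname GenotypeTable-class
#' @export
setMethod("barcodes", "GenotypeTable", function(x) x@meta$barcode)

#' @describeIn GenotypeTable-class integer birth years
#' @export
setGeneric("birthYears", function(x) standardGeneric("birthYears"))

#' @rdname GenotypeTable-class
#' @export
setMethod("birthYears", "GenotypeTable", function(x) x@meta$birthYear)

#' @describeIn GenotypeTable-class registered sex codes ("F", "M" or "U")
#' @export
setGeneric("registeredSex", function(x) standardGeneric("registeredSex"))

#' @rdname GenotypeTable-class
#' @export
setMethod("registeredSex", "GenotypeTable", function(x) x@meta$sex)

#' @describeIn GenotypeTable-class two-column character matrix of
#'   sex-determination marker calls (NA = missing)
#' @export
setGeneric("sexMarkers", function(x) standardGeneric("sexMarkers"))

#' @rdname GenotypeTable-class
#' @export
setMethod("sexMarkers", "GenotypeTable", function(x)
    cbind(x@meta$sexMarker1, x@meta$sexMarker2))

#' @describeIn GenotypeTable-class the full metadata data.frame
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeTable-class
#' @export
setMethod("sampleInfo", "GenotypeTable", function(x) x@meta)

#' @describeIn GenotypeTable-class the raw allele matrix (2 columns per locus)
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname GenotypeTable-class
#' @export
setMethod("alleleMatrix", "GenotypeTable", function(x) x@alleles)

#' @describeIn GenotypeTable-class n x 2 integer matrix of calls at one locus
#' @param locus a locus name from the panel
#' @export
setGeneric("alleleCalls", function(x, locus) standardGeneric("alleleCalls"))

#' @rdname GenotypeTable-class
#' @export
setMethod("alleleCalls", "GenotypeTable", function(x, locus) {
    i <- match(locus, x@panel)
    if (is.na(i))
        stop("unknown locus: ", locus)
    m <- x@alleles[, c(2L * i - 1L, 2L * i), drop = FALSE]
    colnames(m) <- c("allele1", "allele2")
    m
})

#' @rdname GenotypeTable-class
#' @param i integer or logical index of records to keep
#' @param j,drop,... ignored (records-only subsetting)
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
    new("GenotypeTable", panel = x@panel,
        alleles = x@alleles[i, , drop = FALSE],
        meta = x@meta[i, , drop = FALSE])
})

#' @rdname GenotypeTable-class
#' @export
setMethod("show", "GenotypeTable", function(object) {
    yrs <- object@meta$birthYear
    cat(sprintf("GenotypeTable: %d individuals x %d loci\n",
                nrow(object@alleles), length(object@panel)))
    cat("  loci:", paste(object@panel, collapse = ", "), "\n")
    if (nrow(object@alleles) > 0L) {
        cat(sprintf("  birth years: %s-%s (%d cohorts)\n",
                    min(yrs, na.rm = TRUE), max(yrs, na.rm = TRUE),
                    length(unique(yrs))))
        nmiss <- sum(is.na(object@alleles))
        cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
                    100 * nmiss / length(object@alleles)))
    }
    invisible(NULL)
})

#' Combine genotype tables sharing a panel
#'
#' @param x,... `GenotypeTable` objects with identical panels.
#' @return the row-concatenated `GenotypeTable`.
#' @export
setMethod("rbind2", signature("GenotypeTable", "GenotypeTable"), function(x, y) {
    if (!identical(x@panel, y@panel))
        stop("cannot combine tables with different panels")
    new("GenotypeTable", panel = x@panel,
        alleles = rbind(x@alleles, y@alleles),
        meta = rbind(x@meta, y@meta))
})

#' @rdname LocusFrequencies-class
#' @param object a `LocusFrequencies`
#' @export
setMethod("show", "LocusFrequencies", function(object) {
    cat(sprintf("LocusFrequencies: %s (k = %d alleles, N = %d individuals)\n",
                object@locus, length(object@freqs), object@n))
    print(round(object@freqs, 4))
    invisible(NULL)
})

#' @describeIn LocusFrequencies-class named frequency vector
#' @param x a `LocusFrequencies`
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname LocusFrequencies-class
#' @export
setMethod("alleleFreqs", "LocusFrequencies", function(x) x@freqs)

#' @describeIn LocusFrequencies-class number of distinct alleles
#' @export
setGeneric("numAlleles", function(x) standardGeneric("numAlleles"))

#' @rdname LocusFrequencies-class
#' @export
setMethod("numAlleles", "LocusFrequencies", function(x) length(x@freqs))

#' @describeIn LocusFrequencies-class fully typed individuals behind the estimate
#' @export
setGeneric("numTyped", function(x) standardGeneric("numTyped"))

#' @rdname LocusFrequencies-class
#' @export
setMethod("numTyped", "LocusFrequencies", function(x) x@n)
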