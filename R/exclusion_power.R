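## Non-exclusion probabilities under a shared probability model: genotypes
## drawn under Hardy-Weinberg equilibrium from the locus frequencies,
## candidates unrelated, zero genotyping error, exclusion judged on genotype
## compatibility only. The normative computation enumerates genotype
## configurations exactly (k alleles -> k(k+1)/2 genotypes; the candidate
## dimension is summed in closed form inside the enumeration, which is exact);
## where an independent closed form exists (identity, sib identity) both are
## computed and must agree to numerical precision.

## unordered genotype list with HWE probabilities
.genotypes <- function(p) {
    k <- length(p)
    idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
    a <- as.vector(idx[, 1L])
    b <- as.vector(idx[, 2L])
    prob <- ifelse(a == b, p[a]^2, 2 * p[a] * p[b])
    list(a = a, b = b, prob = prob, k = k)
}

.checkAgreement <- function(enumValue, closedValue, what) {
    if (abs(enumValue - closedValue) > 1e-9)
        stop(sprintf("internal disagreement between enumeration and closed form for %s: %.15g vs %.15g",
                     what, enumValue, closedValue))
    enumValue
}

.freqVector <- function(freqs) {
    if (is(freqs, "LocusFrequencies")) alleleFreqs(freqs) else as.numeric(freqs)
}

#' Non-exclusion probability of identity (NE-I)
#'
#' Probability that two unrelated HWE individuals share a genotype:
#' `sum over genotypes g of P(g)^2`, cross-checked against the closed form
#' `2*(sum p^2)^2 - sum p^4`.
#'
#' @param freqs a [LocusFrequencies-class] or bare frequency vector.
#' @return a probability in `(0, 1]`; 1 iff the locus is monomorphic.
#' @export
neIdentity <- function(freqs) {
    p <- .freqVector(freqs)
    g <- .genotypes(p)
    s2 <- sum(p^2)
    .checkAgreement(sum(g$prob^2), 2 * s2^2 - sum(p^4), "NE-I")
}

#' Non-exclusion probability of sib identity (NE-SI)
#'
#' Probability that two full sibs share a genotype: enumeration over HWE
#' parent pairs and two independent Mendelian offspring, cross-checked
#' against the closed form
#' `1/4 + S2/2 + S2^2/2 - S4/4` with `S2 = sum p^2`, `S4 = sum p^4`.
#'
#' @inheritParams neIdentity
#' @return a probability in `(0, 1]`; always at least [neIdentity()].
#' @export
neSibIdentity <- function(freqs) {
    p <- .freqVector(freqs)
    g <- .genotypes(p)
    m <- length(g$prob)
    i1 <- rep(seq_len(m), each = m)
    i2 <- rep(seq_len(m), times = m)
    ## the four equally likely transmitted-allele combinations, as unordered
    ## genotype ids lo*1000 + hi (allele indices < 1000 always)
    gid <- function(x, y) pmin(x, y) * 1000L + pmax(x, y)
    o <- cbind(gid(g$a[i1], g$a[i2]), gid(g$a[i1], g$b[i2]),
               gid(g$b[i1], g$a[i2]), gid(g$b[i1], g$b[i2]))
    match16 <- rowSums(o[, rep(1:4, times = 4), drop = FALSE] ==
                       o[, rep(1:4, each = 4), drop = FALSE])
    enum <- sum(g$prob[i1] * g$prob[i2] * match16 / 16)
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    .checkAgreement(enum, 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4, "NE-SI")
}

#' Non-exclusion probability, first parent (NE-1P)
#'
#' Probability that a random unrelated individual is NOT excluded as a parent
#' of a random HWE offspring when the other parent is unknown; exclusion iff
#' candidate and offspring share no allele. Exact enumeration over
#' (offspring, candidate) genotype pairs.
#'
#' @inheritParams neIdentity
#' @return a probability in `(0, 1]`.
#' @export
neFirstParent <- function(freqs) {
    p <- .freqVector(freqs)
    g <- .genotypes(p)
    m <- length(g$prob)
    io <- rep(seq_len(m), each = m)
    ic <- rep(seq_len(m), times = m)
    share <- g$a[ic] == g$a[io] | g$a[ic] == g$b[io] |
             g$b[ic] == g$a[io] | g$b[ic] == g$b[io]
    sum(g$prob[io] * g$prob[ic] * share)
}

#' Non-exclusion probability, second parent (NE-2P)
#'
#' Probability that a random unrelated individual is NOT excluded as the
#' second parent given the offspring and one true parent. Enumeration over
#' the true parent's genotype and both transmitted alleles; the admissible
#' alleles the candidate must carry are the offspring alleles not explainable
#' by the known parent (both offspring alleles admissible when the known
#' parent could have contributed either). A candidate is excluded iff it
#' carries no admissible allele.
#'
#' @inheritParams neIdentity
#' @return a probability in `(0, 1]`; never larger than [neFirstParent()].
#' @export
neSecondParent <- function(freqs) {
    p <- .freqVector(freqs)
    g <- .genotypes(p)
    k <- length(p)
    total <- 0
    for (i in seq_along(g$prob)) {       # known parent genotype
        par <- c(g$a[i], g$b[i])
        for (t1 in unique(par)) {        # allele transmitted by known parent
            wt1 <- sum(par == t1) / 2
            for (t2 in seq_len(k)) {     # allele from the unknown parent
                off <- c(min(t1, t2), max(t1, t2))
                if (off[1L] == off[2L]) {
                    adm <- off[1L]
                } else if (all(off %in% par)) {
                    adm <- off
                } else {
                    adm <- off[!(off %in% par)]
                }
                pAdm <- sum(p[adm])
                notExcl <- 1 - (1 - pAdm)^2
                total <- total + g$prob[i] * wt1 * p[t2] * notExcl
            }
        }
    }
    total
}

#' Non-exclusion probability, parent pair (NE-PP)
#'
#' Probability that a random unrelated PAIR is not excluded as the parent
#' pair of a random HWE offspring. The pair is excluded iff no choice of one
#' allele from each candidate reproduces the offspring genotype. Enumeration
#' over offspring genotypes; for offspring `(x, y)` the candidate-pair
#' compatibility probability is `q_x^2` for a homozygote and
#' `2 q_x q_y - (2 p_x p_y)^2` for a heterozygote, with
#' `q_x = 1 - (1 - p_x)^2` the probability a genotype carries `x` (the
#' inclusion-exclusion sum over the two parent-role assignments).
#'
#' @inheritParams neIdentity
#' @return a probability in `(0, 1]`; never larger than [neSecondParent()].
#' @export
neParentPair <- function(freqs) {
    p <- .freqVector(freqs)
    g <- .genotypes(p)
    q <- 1 - (1 - p)^2
    hom <- g$a == g$b
    compat <- ifelse(hom, q[g$a]^2,
                     2 * q[g$a] * q[g$b] - (2 * p[g$a] * p[g$b])^2)
    sum(g$prob * compat)
}

#' Per-locus and combined exclusion report
#'
#' One row per locus with the five non-exclusion probabilities, a `Combined`
#' row (per-column product over loci, valid for unlinked loci) and an
#' `Accuracy` row (`1 - combined`). Frequencies are computed from the entire
#' table, the convention for panel-wide discriminatory power.
#'
#' @param table a QC'd [GenotypeTable-class], or a named list of
#'   [LocusFrequencies-class]/frequency vectors.
#' @return a data.frame with columns `locus`, `ne1p`, `ne2p`, `nePp`, `neI`,
#'   `neSi`.
#' @export
exclusionReport <- function(table) {
    freqsList <- if (is(table, "GenotypeTable")) {
        stats::setNames(lapply(panelLoci(table), function(l)
            alleleFrequencies(table, l)), panelLoci(table))
    } else {
        table
    }
    rows <- lapply(names(freqsList), function(nm) {
        f <- freqsList[[nm]]
        data.frame(locus = nm,
                   ne1p = neFirstParent(f), ne2p = neSecondParent(f),
                   nePp = neParentPair(f), neI = neIdentity(f),
                   neSi = neSibIdentity(f), stringsAsFactors = FALSE)
    })
    perLocus <- do.call(rbind, rows)
    comb <- combineExclusion(perLocus)
    out <- rbind(perLocus,
                 data.frame(locus = "Combined", t(comb$combined)),
                 data.frame(locus = "Accuracy", t(comb$accuracy)))
    rownames(out) <- NULL
    out
}

#' Combine per-locus non-exclusion probabilities across a panel
#'
#' Loci are assumed unlinked, so panel-wide non-exclusion is the per-column
#' product; identification accuracy is `1 -` that product.
#'
#' @param perLocus data.frame of per-locus NE columns (`ne1p`, `ne2p`,
#'   `nePp`, `neI`, `neSi`), e.g. the locus rows of [exclusionReport()].
#' @return `list(combined, accuracy)`, each a named numeric vector.
#' @export
combineExclusion <- function(perLocus) {
    cols <- intersect(c("ne1p", "ne2p", "nePp", "neI", "neSi"),
                      names(perLocus))
    body <- perLocus[!(perLocus$locus %in% c("Combined", "Accuracy")), ]
    combined <- vapply(cols, function(cc) prod(body[[cc]]), numeric(1L))
    list(combined = combined, accuracy = 1 - combined)
}

#' Format an exclusion report as text
#'
#' Per-locus rows at 3 decimals; combined and accuracy rows in scientific
#' notation.
#'
#' @param report output of [exclusionReport()].
#' @return a character vector of lines.
#' @export
formatExclusionReport <- function(report) {
    cols <- c("ne1p", "ne2p", "nePp", "neI", "neSi")
    header <- sprintf("%-10s %10s %10s %10s %10s %10s", "Locus",
                      "NE-1P", "NE-2P", "NE-PP", "NE-I", "NE-SI")
    lines <- vapply(seq_len(nrow(report)), function(i) {
        r <- report[i, ]
        sci <- r$locus %in% c("Combined", "Accuracy")
        vals <- vapply(cols, function(cc)
            if (sci) formatC(r[[cc]], digits = 2L, format = "E")
            else formatC(r[[cc]], digits = 3L, format = "f"), character(1L))
        sprintf("%-10s %10s %10s %10s %10s %10s", r$locus,
                vals[1L], vals[2L], vals[3L], vals[4L], vals[5L])
    }, character(1L))
    c(header, lines)
}
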