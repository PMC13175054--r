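## Weir-Cockerham (1984) variance-component estimators. Per allele, with r
## populations of n_i typed individuals, allele frequency p_i and observed
## frequency h_i of heterozygotes carrying the allele:
##   nbar = sum(n_i)/r,  n_c = (r*nbar - sum(n_i^2)/(r*nbar))/(r-1)
##   pbar = sum(n_i p_i)/(r nbar),  s2 = sum(n_i (p_i-pbar)^2)/((r-1) nbar)
##   hbar = sum(n_i h_i)/(r nbar)
##   a = nbar/n_c * (s2 - (pbar(1-pbar) - (r-1)/r*s2 - hbar/4)/(nbar-1))
##   b = nbar/(nbar-1) * (pbar(1-pbar) - (r-1)/r*s2 - (2nbar-1)/(4nbar)*hbar)
##   c = hbar/2
## summed over alleles; theta = a/(a+b+c), f = 1 - c/(b+c).

## per-population sufficient statistics at one locus
.wcStats <- function(table, locus, pop) {
    calls <- alleleCalls(table, locus)
    ok <- stats::complete.cases(calls)
    calls <- calls[ok, , drop = FALSE]
    pop <- factor(pop[ok])
    n <- as.integer(table(pop))
    alleles <- sort(unique(as.vector(calls)))
    P <- matrix(0, nrow = nlevels(pop), ncol = length(alleles),
                dimnames = list(levels(pop), alleles))
    H <- P
    for (j in seq_along(alleles)) {
        a <- alleles[j]
        copies <- (calls[, 1L] == a) + (calls[, 2L] == a)
        P[, j] <- tapply(copies, pop, sum) / (2 * n)
        H[, j] <- tapply(copies == 1L, pop, sum) / n
    }
    list(n = n, p = P, h = H)
}

.wcFromStats <- function(n, p, h) {
    r <- length(n)
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    w <- n / (r * nbar)
    a <- b <- cc <- 0
    for (j in seq_len(ncol(p))) {
        pbar <- sum(w * p[, j])
        s2 <- sum(n * (p[, j] - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(w * h[, j])
        aA <- nbar / nc *
            (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
        bA <- nbar / (nbar - 1) *
            (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        a <- a + aA
        b <- b + bA
        cc <- cc + hbar / 2
    }
    c(a = a, b = b, c = cc)
}

#' Weir-Cockerham variance components at one locus
#'
#' Returns the per-allele components summed over alleles: `a` (between
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals). `a` and `b` are unbiased estimators and may be negative;
#' `c` never is. Populations with fewer than 2 typed individuals at the locus
#' are excluded with a warning.
#'
#' @param table a [GenotypeTable-class].
#' @param locus a panel locus name.
#' @param pop per-record population labels (e.g. birth years).
#' @return named numeric `c(a, b, c)`.
#' @export
wcComponents <- function(table, locus, pop) {
    stopifnot(length(pop) == nIndividuals(table))
    st <- .wcStats(table, locus, pop)
    usable <- st$n >= 2L
    if (!all(usable)) {
        warning(sprintf("locus %s: dropping %d population(s) with < 2 typed individuals",
                        locus, sum(!usable)))
        st$n <- st$n[usable]
        st$p <- st$p[usable, , drop = FALSE]
        st$h <- st$h[usable, , drop = FALSE]
    }
    if (length(st$n) < 2L)
        stop("need at least 2 usable populations at locus ", locus)
    .wcFromStats(st$n, st$p, st$h)
}

#' Multilocus theta from per-locus variance components
#'
#' Weir & Cockerham's combining convention: the ratio of sums
#' `sum(a) / sum(a + b + c)` over loci, not the mean of per-locus ratios.
#'
#' @param components a list of `c(a, b, c)` vectors (one per locus), or a
#'   matrix/data.frame with columns `a`, `b`, `c`.
#' @return the multilocus theta, or `NA` if the denominator is zero.
#' @export
multilocusTheta <- function(components) {
    if (is.list(components) && !is.data.frame(components))
        components <- do.call(rbind, components)
    components <- as.matrix(components)
    num <- sum(components[, "a"])
    den <- sum(components)
    if (den == 0) NA_real_ else num / den
}

#' Weir-Cockerham within-population inbreeding coefficient
#'
#' `f = 1 - sum(c)/sum(b + c)` over the requested loci; the variance-component
#' analogue of F_IS.
#'
#' @inheritParams wcComponents
#' @param loci panel loci to combine (default: the single `locus`).
#' @return the coefficient, or `NA` when `b + c` sums to zero.
#' @export
wcFisWithin <- function(table, locus, pop, loci = locus) {
    comp <- vapply(loci, function(l) wcComponents(table, l, pop), numeric(3L))
    bc <- sum(comp["b", ]) + sum(comp["c", ])
    if (bc == 0) NA_real_ else 1 - sum(comp["c", ]) / bc
}

#' Pairwise multilocus theta between cohorts
#'
#' For every pair of cohorts, the multilocus Weir-Cockerham theta over the
#' panel loci (ratio of loci-summed components). Unequal cohort sizes are
#' handled by the built-in `n_c` weighting -- no subsampling. Raw estimates
#' (which can be slightly negative near zero differentiation) are always
#' retained; flooring at zero is a display option of [thetaMatrix()].
#'
#' @param table a QC'd [GenotypeTable-class].
#' @param pop per-record cohort labels; default the birth years.
#' @param loci panel loci to use; default the full panel.
#' @return an [FstMatrix-class].
#' @export
pairwiseFst <- function(table, pop = birthYears(table), loci = panelLoci(table)) {
    pop <- as.character(pop)
    cohorts <- sort(unique(pop))
    k <- length(cohorts)
    if (k < 2L)
        stop("need >= 2 cohorts for pairwise differentiation")
    stats <- lapply(loci, function(l) .wcStats(table, l, pop))
    names(stats) <- loci
    theta <- numer <- denom <- matrix(NA_real_, k, k,
                                      dimnames = list(cohorts, cohorts))
    for (i in seq_len(k - 1L)) {
        for (j in seq((i + 1L), k)) {
            aSum <- dSum <- 0
            for (l in loci) {
                st <- stats[[l]]
                sel <- match(c(cohorts[i], cohorts[j]), rownames(st$p))
                n2 <- st$n[sel]
                if (any(is.na(sel)) || any(n2 < 2L))
                    next
                comp <- .wcFromStats(n2, st$p[sel, , drop = FALSE],
                                     st$h[sel, , drop = FALSE])
                aSum <- aSum + comp[["a"]]
                dSum <- dSum + sum(comp)
            }
            numer[i, j] <- numer[j, i] <- aSum
            denom[i, j] <- denom[j, i] <- dSum
            theta[i, j] <- theta[j, i] <- if (dSum == 0) NA_real_ else aSum / dSum
        }
    }
    new("FstMatrix", cohorts = cohorts, theta = theta,
        numer = numer, denom = denom)
}

#' @describeIn FstMatrix-class the pairwise theta matrix, optionally with
#'   negative estimates floored at zero for display
#' @param x an `FstMatrix`
#' @param floorNegative replace negative estimates by 0 (display convention)
#' @export
setGeneric("thetaMatrix", function(x, floorNegative = FALSE)
    standardGeneric("thetaMatrix"))

#' @rdname FstMatrix-class
#' @export
setMethod("thetaMatrix", "FstMatrix", function(x, floorNegative = FALSE) {
    th <- x@theta
    if (floorNegative)
        th[!is.na(th) & th < 0] <- 0
    th
})

#' @rdname FstMatrix-class
#' @param object an `FstMatrix`
#' @export
setMethod("show", "FstMatrix", function(object) {
    cat(sprintf("FstMatrix: %d cohorts (%s ... %s)\n",
                length(object@cohorts), object@cohorts[1L],
                object@cohorts[length(object@cohorts)]))
    rng <- range(object@theta[upper.tri(object@theta)], na.rm = TRUE)
    cat(sprintf("  pairwise theta range: %.4f to %.4f\n", rng[1L], rng[2L]))
    invisible(NULL)
})

#' Write an FstMatrix as an upper-triangle CSV
#'
#' Years on both axes, blank diagonal and lower triangle, 4 decimal places.
#'
#' @param x an [FstMatrix-class].
#' @param path output path.
#' @param floorNegative floor negative estimates at 0 (default TRUE, the
#'   display convention for near-zero differentiation).
#' @return `path`, invisibly.
#' @export
writeFstCsv <- function(x, path, floorNegative = TRUE) {
    th <- thetaMatrix(x, floorNegative)
    out <- matrix("", nrow(th), ncol(th), dimnames = dimnames(th))
    ut <- upper.tri(th)
    out[ut] <- ifelse(is.na(th[ut]), "", formatC(th[ut], digits = 4L, format = "f"))
    df <- data.frame(birth_year = rownames(out), out, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Simple heterozygosity-based differentiation between two populations
#'
#' The textbook `(H_T - H_S)/H_T` form: `H_S` is the unweighted mean within-
#' population gene diversity, `H_T` the gene diversity of the pooled (mean)
#' frequencies, both averaged over loci before the ratio. On large balanced
#' samples it tracks the Weir-Cockerham theta closely but is a different
#' estimator; the variance-component theta is this package's normative one.
#'
#' @param table a [GenotypeTable-class].
#' @param pop per-record population labels (exactly 2 distinct values used).
#' @param loci panel loci to average over.
#' @return the multilocus `(H_T - H_S)/H_T` value.
#' @export
htHsFst <- function(table, pop, loci = panelLoci(table)) {
    pop <- as.character(pop)
    lv <- sort(unique(pop))
    if (length(lv) != 2L)
        stop("htHsFst compares exactly 2 populations")
    hts <- hss <- numeric(0)
    for (l in loci) {
        calls <- alleleCalls(table, l)
        ok <- stats::complete.cases(calls)
        he <- vapply(lv, function(g) {
            flat <- as.vector(calls[ok & pop == g, , drop = FALSE])
            1 - sum((table(flat) / length(flat))^2)
        }, numeric(1L))
        alleles <- sort(unique(as.vector(calls[ok, ])))
        pmat <- vapply(lv, function(g) {
            flat <- as.vector(calls[ok & pop == g, , drop = FALSE])
            as.numeric(table(factor(flat, levels = alleles))) / length(flat)
        }, numeric(length(alleles)))
        pbar <- rowMeans(pmat)
        hts <- c(hts, 1 - sum(pbar^2))
        hss <- c(hss, mean(he))
    }
    (mean(hts) - mean(hss)) / mean(hts)
}
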