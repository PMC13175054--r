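## Synthetic cohort generator. Ancestral allele frequencies are Dirichlet;
## cohorts drift from them under the Balding-Nichols model (frequencies
## Dirichlet-distributed around the ancestral vector with concentration
## (1-F)/F, so F is the expected differentiation); genotypes are drawn with
## P(ii) = p_i^2 + f*p_i*(1-p_i), P(ij) = 2*p_i*p_j*(1-f) for an inbreeding
## coefficient f (negative f = heterozygote excess, bounded below by
## -p_min/(1-p_min) per locus). QC defects are injected last, on disjoint
## record sets, and written to a ground-truth ledger.

#' Default simulated STR panel
#'
#' The 11 autosomal dinucleotide loci of the Korean cattle parentage panel
#' with their published allele counts and plausible even base-pair ladders.
#' The panel mimics the shape (locus names, allele counts, size ranges) of
#' the real marker set, not its allele frequencies.
#'
#' @return data.frame with columns `locus`, `k`, `minAllele`, `step`.
#' @export
defaultPanel <- function() {
    data.frame(
        locus = c("BM1824", "BM2113", "ETH10", "ETH225", "ETH3", "INRA023",
                  "SPS115", "TGLA122", "TGLA126", "TGLA227", "TGLA53"),
        k = c(11L, 17L, 12L, 11L, 15L, 16L, 15L, 28L, 9L, 19L, 19L),
        minAllele = c(178L, 122L, 206L, 140L, 114L, 196L, 240L, 136L, 110L,
                      76L, 152L),
        step = 2L, stringsAsFactors = FALSE)
}

#' Inclusive allele-size windows for a simulated panel
#'
#' @param panel a panel data.frame as from [defaultPanel()].
#' @return named list of `c(min, max)` per locus, usable as the
#'   `alleleRanges` of [qcConfig()].
#' @export
panelAlleleRanges <- function(panel = defaultPanel()) {
    stats::setNames(lapply(seq_len(nrow(panel)), function(i)
        c(panel$minAllele[i],
          panel$minAllele[i] + panel$step[i] * (panel$k[i] - 1L))),
        panel$locus)
}

#' Simulation configuration
#'
#' @param seed integer seed; the generator draws everything from one RNG
#'   stream in a fixed order, so the same seed reproduces the table bitwise.
#' @param panel panel data.frame ([defaultPanel()] layout).
#' @param dirichletAlpha symmetric Dirichlet concentration for the ancestral
#'   frequencies (default 0.5, giving realistically uneven STR spectra with
#'   gene diversity around 0.75-0.85 at these allele counts).
#' @param fDrift Balding-Nichols F per cohort step, in `[0, 1)`.
#' @param driftMode `"star"` (default): every cohort is an independent
#'   Balding-Nichols draw from the ancestral pool at `fDrift`, so `fDrift`
#'   IS the expected pairwise differentiation. `"serial"`: a year-on-year
#'   random walk, under which differentiation accumulates with the birth-year
#'   gap.
#' @param fIs within-cohort inbreeding coefficient; may be negative
#'   (heterozygote excess) down to `-p_min/(1-p_min)` per locus.
#' @param cohortSizes named integer vector, year -> clean cohort size.
#' @param sexRatio probability a simulated individual is a cow (registered
#'   sex F).
#' @param defectRates list of per-record injection rates: `missing`,
#'   `range`, `sexOther`, `sexMissing`, `sexMismatch`, `dup2`, `dup3`.
#' @param minFreq optional floor on simulated allele frequencies: rare
#'   alleles are lifted to the floor and the rest renormalised, so
#'   `min(p) >= minFreq` exactly while the spectrum's shape is preserved.
#'   Default 0 (pure Dirichlet / Balding-Nichols draws, which keeps `fDrift`
#'   an unbiased differentiation target). A positive floor is needed when
#'   `fIs < 0`, whose feasibility bound is `-p_min/(1-p_min)`.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = NULL, panel = defaultPanel(),
                             dirichletAlpha = 0.5, fDrift = 0,
                             driftMode = c("star", "serial"), fIs = 0,
                             cohortSizes = c("2020" = 200L, "2021" = 200L),
                             sexRatio = 0.68,
                             defectRates = list(), minFreq = 0) {
    driftMode <- match.arg(driftMode)
    rates <- list(missing = 0, range = 0, sexOther = 0, sexMissing = 0,
                  sexMismatch = 0, dup2 = 0, dup3 = 0)
    unknown <- setdiff(names(defectRates), names(rates))
    if (length(unknown))
        stop("unknown defect rate(s): ", paste(unknown, collapse = ", "))
    rates[names(defectRates)] <- defectRates
    stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1),
              fDrift >= 0, fDrift < 1, all(cohortSizes >= 0),
              !is.null(names(cohortSizes)), sexRatio >= 0, sexRatio <= 1,
              dirichletAlpha > 0, minFreq >= 0, minFreq < 1)
    structure(list(seed = seed, panel = panel,
                   dirichletAlpha = dirichletAlpha, fDrift = fDrift,
                   driftMode = driftMode, fIs = fIs,
                   cohortSizes = cohortSizes, sexRatio = sexRatio,
                   defectRates = rates, minFreq = minFreq),
              class = "SimulationConfig")
}

.rdirichlet <- function(alpha, minFreq = 0) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) == 0) g <- rep(1, length(alpha))
    p <- g / sum(g)
    if (minFreq > 0) {
        ## lift the tail to the floor and renormalise the rest; touches only
        ## rare alleles, so the shape of the spectrum is preserved
        k <- length(p)
        if (k * minFreq >= 1)
            stop("minFreq too large for ", k, " alleles")
        repeat {
            low <- p <= minFreq + 1e-15
            if (all(low)) { p[] <- 1 / k; break }
            p[!low] <- p[!low] * (1 - sum(low) * minFreq) / sum(p[!low])
            p[low] <- minFreq
            if (min(p) >= minFreq - 1e-15) break
        }
    }
    p
}

.drawGenotypes <- function(p, f, n) {
    k <- length(p)
    P <- outer(p, p) * (1 - f)
    diag(P) <- diag(P) + f * p
    if (any(P < -1e-12))
        stop("negative genotype probability (f below its feasibility bound)")
    P[P < 0] <- 0
    idx <- sample.int(k * k, n, replace = TRUE, prob = as.vector(P))
    cbind((idx - 1L) %% k + 1L, (idx - 1L) %/% k + 1L)
}

#' Simulate a genotype table with a ground-truth ledger
#'
#' Draws ancestral and per-cohort allele frequencies, genotypes, sexes and
#' sex markers, then injects QC defects (missing calls, out-of-range alleles,
#' three kinds of sex-marker anomaly, concordant 2- and 3-fold barcode
#' duplicates) on disjoint record sets. The ledger records the true
#' frequencies, the true inbreeding coefficient, and every injected defect
#' with per-cohort counts, so QC output can be checked against it exactly.
#'
#' @param config a [simulationConfig()].
#' @return `list(table, ledger)`; the ledger has elements `ancestralFreqs`,
#'   `cohortFreqs`, `fIs`, `defects` (per-type barcode vectors), `counts`
#'   (per-type totals), `cohortClean` (clean sizes) and `cohortDefects`
#'   (records per cohort carrying a removing defect).
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (!is.null(config$seed))
        set.seed(config$seed)
    panel <- config$panel
    years <- as.integer(names(config$cohortSizes))
    ord <- order(years)
    years <- years[ord]
    sizes <- as.integer(config$cohortSizes)[ord]
    F <- config$fDrift
    f <- config$fIs

    anc <- lapply(seq_len(nrow(panel)), function(i)
        .rdirichlet(rep(config$dirichletAlpha, panel$k[i]), config$minFreq))
    names(anc) <- panel$locus

    cohortFreqs <- vector("list", length(years))
    names(cohortFreqs) <- as.character(years)
    prev <- anc
    for (t in seq_along(years)) {
        cur <- lapply(panel$locus, function(loc) {
            base <- if (config$driftMode == "star") anc[[loc]] else prev[[loc]]
            if (F > 0) .rdirichlet(base * (1 - F) / F, config$minFreq) else base
        })
        names(cur) <- panel$locus
        cohortFreqs[[t]] <- cur
        prev <- cur
    }

    for (t in seq_along(years)) {
        for (loc in panel$locus) {
            pmin_ <- min(cohortFreqs[[t]][[loc]])
            if (f < -pmin_ / (1 - pmin_))
                stop(sprintf("fIs = %g below the feasibility bound %.4g at locus %s (cohort %d)",
                             f, -pmin_ / (1 - pmin_), loc, years[t]))
        }
    }

    nTot <- sum(sizes)
    al <- matrix(NA_integer_, nrow = nTot, ncol = 2L * nrow(panel))
    yr <- rep(years, sizes)
    offset <- 0L
    for (t in seq_along(years)) {
        n <- sizes[t]
        if (n == 0L) next
        rows <- offset + seq_len(n)
        for (i in seq_len(nrow(panel))) {
            sizesBp <- panel$minAllele[i] + panel$step[i] * (0:(panel$k[i] - 1L))
            gidx <- .drawGenotypes(cohortFreqs[[t]][[panel$locus[i]]], f, n)
            al[rows, 2L * i - 1L] <- sizesBp[gidx[, 1L]]
            al[rows, 2L * i] <- sizesBp[gidx[, 2L]]
        }
        offset <- offset + n
    }
    sex <- ifelse(stats::runif(nTot) < config$sexRatio, "F", "M")
    mk1 <- rep("X", nTot)
    mk2 <- ifelse(sex == "F", "X", "Y")
    barcode <- sprintf("SIM%07d", seq_len(nTot))

    ## ---- defect injection on disjoint record sets ----
    rates <- config$defectRates
    nOf <- function(r) stats::rbinom(1L, nTot, r)
    counts <- c(missing = nOf(rates$missing), range = nOf(rates$range),
                sexOther = nOf(rates$sexOther),
                sexMissing = nOf(rates$sexMissing),
                sexMismatch = nOf(rates$sexMismatch),
                dup2 = nOf(rates$dup2), dup3 = nOf(rates$dup3))
    if (sum(counts) > nTot)
        stop("defect rates too high: more defects than records")
    pick <- sample.int(nTot, sum(counts))
    splitIdx <- split(pick, rep(names(counts), counts))
    idx <- lapply(stats::setNames(names(counts), names(counts)),
                  function(nm) sort(splitIdx[[nm]] %||% integer(0)))

    for (r in idx$missing) {
        l <- sample.int(nrow(panel), 1L)
        al[r, 2L * l - sample(0:1, 1L)] <- NA_integer_
    }
    maxBp <- panel$minAllele + panel$step * (panel$k - 1L)
    for (r in idx$range) {
        l <- sample.int(nrow(panel), 1L)
        al[r, 2L * l] <- maxBp[l] + 11L
    }
    mk1[idx$sexOther] <- "Z"
    mk1[idx$sexMissing] <- NA_character_
    swap <- idx$sexMismatch
    mk2[swap] <- ifelse(sex[swap] == "F", "Y", "X")

    dupRows <- c(idx$dup2, rep(idx$dup3, each = 2L))
    if (length(dupRows)) {
        al <- rbind(al, al[dupRows, , drop = FALSE])
        yr <- c(yr, yr[dupRows])
        sex <- c(sex, sex[dupRows])
        mk1 <- c(mk1, mk1[dupRows])
        mk2 <- c(mk2, mk2[dupRows])
        barcode <- c(barcode, barcode[dupRows])
    }

    table <- GenotypeTable(panel$locus, al,
                           data.frame(barcode = barcode, birthYear = yr,
                                      sex = sex, sexMarker1 = mk1,
                                      sexMarker2 = mk2,
                                      stringsAsFactors = FALSE))
    removing <- c("missing", "range", "sexOther", "sexMissing", "sexMismatch")
    perCohort <- vapply(as.character(years), function(y) {
        sum(vapply(removing, function(nm)
            sum(yr[idx[[nm]]] == as.integer(y)), integer(1L)))
    }, integer(1L))
    ledger <- list(ancestralFreqs = anc, cohortFreqs = cohortFreqs, fIs = f,
                   fDrift = F, driftMode = config$driftMode,
                   defects = lapply(idx, function(i) barcode[i]),
                   counts = counts,
                   cohortClean = stats::setNames(sizes, as.character(years)),
                   cohortDefects = perCohort)
    list(table = table, ledger = ledger)
}

#' Expected QC stage counts from a simulation ledger
#'
#' The exact counts [runQc()] must report on the simulated table, derived
#' from the injection ledger alone.
#'
#' @param ledger the ledger from [simulateGenotypes()].
#' @param minCohortSize the threshold that will be used in QC.
#' @return a named list mirroring [qcReportAsList()].
#' @export
expectedQcCounts <- function(ledger, minCohortSize = 100L) {
    ct <- ledger$counts
    raw <- sum(ledger$cohortClean) + ct[["dup2"]] + 2L * ct[["dup3"]]
    survivors <- ledger$cohortClean - ledger$cohortDefects
    small <- sum(survivors[survivors < minCohortSize])
    dupGroups <- c(`2` = ct[["dup2"]], `3` = ct[["dup3"]])
    dupGroups <- dupGroups[dupGroups > 0L]
    list(raw = raw,
         missing_removed = ct[["missing"]],
         range_removed = ct[["range"]],
         sex_removed = ct[["sexOther"]] + ct[["sexMissing"]] + ct[["sexMismatch"]],
         sex_subcounts = list(otherValue = ct[["sexOther"]],
                              missingMarker = ct[["sexMissing"]],
                              mismatch = ct[["sexMismatch"]]),
         duplicate_groups = if (length(dupGroups)) as.list(dupGroups)
             else list(),
         duplicate_records = 2L * ct[["dup2"]] + 3L * ct[["dup3"]],
         duplicates_recovered = ct[["dup2"]] + ct[["dup3"]],
         small_cohort_removed = small,
         final = sum(survivors[survivors >= minCohortSize]))
}

#' Hanwoo-like preset simulation configuration
#'
#' A scaled-down configuration mimicking the SHAPE of the national cattle
#' parentage dataset -- the 11-locus panel with its published allele counts
#' (TGLA122 the richest at 28 alleles, TGLA126 the poorest at 9), 23 birth-year
#' cohorts (2001-2023) with the published highly unequal sizes divided by 100
#' (floor 50), a cow-biased sex ratio, defect rates in the published
#' proportions, weak serial drift (pairwise theta within the published
#' 0.0003-0.0081 span over 22 years) and a slight heterozygote excess, with
#' the Dirichlet concentration set so mean gene diversity lands near the
#' published 0.77. It mimics the dataset's shape; the real population's
#' allele frequencies are not public and are not imitated.
#'
#' @param seed integer seed.
#' @return a [simulationConfig()].
#' @export
hanwooLikeConfig <- function(seed = 1L) {
    totals <- c(107, 198, 342, 547, 1001, 1672, 2652, 4229, 6679, 11719,
                16543, 25588, 31267, 38457, 47925, 61112, 77225, 91083,
                87444, 105384, 93300, 71733, 2337)
    sizes <- pmax(50L, as.integer(round(totals / 100)))
    names(sizes) <- as.character(2001:2023)
    simulationConfig(
        seed = seed, panel = defaultPanel(), dirichletAlpha = 0.35,
        fDrift = 0.0007, driftMode = "serial", fIs = -0.003,
        cohortSizes = sizes, sexRatio = 0.68,
        defectRates = list(missing = 0.041, range = 0.0004,
                           sexOther = 0.00003, sexMissing = 0.094,
                           sexMismatch = 0.024, dup2 = 0.002, dup3 = 0.0001),
        minFreq = 0.0035)
}
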