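# Fixture builders and independent brute-force oracles. The oracles are
# deliberate plain-loop transcriptions, sharing no code with the package.

mkTable <- function(alleles, panel = NULL, barcode = NULL, year = 2010L,
                    sex = "F", mk1 = NULL, mk2 = NULL) {
    alleles <- as.matrix(alleles)
    n <- nrow(alleles)
    if (is.null(panel))
        panel <- paste0("L", seq_len(ncol(alleles) / 2L))
    if (is.null(barcode))
        barcode <- sprintf("B%03d", seq_len(n))
    sex <- rep_len(sex, n)
    if (is.null(mk1)) mk1 <- rep("X", n)
    if (is.null(mk2)) mk2 <- ifelse(sex == "F", "X", "Y")
    GenotypeTable(panel, alleles,
                  data.frame(barcode = barcode,
                             birthYear = rep_len(year, n), sex = sex,
                             sexMarker1 = rep_len(mk1, n),
                             sexMarker2 = rep_len(mk2, n),
                             stringsAsFactors = FALSE))
}

# random table with optional missing calls, for property tests
randomTable <- function(n = 20L, nloci = 3L, k = 4L, pMissing = 0,
                        years = 2010L) {
    al <- matrix(sample(seq(100L, by = 2L, length.out = k), 2L * nloci * n,
                        replace = TRUE), nrow = n)
    if (pMissing > 0) {
        hit <- runif(length(al)) < pMissing
        al[hit] <- NA_integer_
    }
    mkTable(al, year = sample(years, n, replace = TRUE))
}

# ---- diversity oracles ----

bfFreqs <- function(calls) {  # calls: n x 2, NA allowed
    flat <- c(calls[, 1], calls[, 2])
    flat <- flat[!is.na(flat)]
    tab <- table(flat)
    as.numeric(tab) / sum(tab)
}

bfHexp <- function(p) {
    s <- 0
    for (i in seq_along(p)) s <- s + p[i]^2
    1 - s
}

bfPic <- function(p) {  # loops over all ordered allele pairs
    s1 <- 0
    for (i in seq_along(p)) s1 <- s1 + p[i]^2
    s2 <- 0
    for (i in seq_along(p)) for (j in seq_along(p))
        if (i < j) s2 <- s2 + 2 * p[i]^2 * p[j]^2
    1 - s1 - s2
}

# ---- WC84 oracle: plain transcription of the per-allele formulas ----

wc84oracle <- function(pops) {  # pops: list of n x 2 allele matrices
    alleles <- sort(unique(unlist(pops)))
    r <- length(pops)
    n <- sapply(pops, nrow)
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    A <- B <- C <- 0
    for (al in alleles) {
        p <- sapply(pops, function(m) mean(m == al))
        h <- sapply(pops, function(m) mean((m[, 1] == al) != (m[, 2] == al)))
        pbar <- sum(n * p) / (r * nbar)
        hbar <- sum(n * h) / (r * nbar)
        s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
        A <- A + nbar / nc *
            (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
        B <- B + nbar / (nbar - 1) *
            (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        C <- C + hbar / 2
    }
    c(a = A, b = B, c = C)
}

# ---- exclusion-power oracles: naive nested-loop enumerations ----

bfGenoList <- function(p) {
    out <- list()
    for (i in seq_along(p)) for (j in i:length(p))
        out[[length(out) + 1L]] <- list(a = i, b = j,
            pr = if (i == j) p[i]^2 else 2 * p[i] * p[j])
    out
}

bfNeIdentity <- function(p) {
    g <- bfGenoList(p)
    s <- 0
    for (x in g) s <- s + x$pr^2
    s
}

bfNe1p <- function(p) {
    g <- bfGenoList(p)
    s <- 0
    for (o in g) for (cand in g) {
        share <- cand$a %in% c(o$a, o$b) || cand$b %in% c(o$a, o$b)
        if (share) s <- s + o$pr * cand$pr
    }
    s
}

bfNePp <- function(p) {
    g <- bfGenoList(p)
    s <- 0
    for (o in g) for (c1 in g) for (c2 in g) {
        ok <- FALSE
        for (x in c(c1$a, c1$b)) for (y in c(c2$a, c2$b))
            if (identical(sort(c(x, y)), sort(c(o$a, o$b)))) ok <- TRUE
        if (ok) s <- s + o$pr * c1$pr * c2$pr
    }
    s
}

bfNe2p <- function(p) {
    g <- bfGenoList(p)
    s <- 0
    for (g1 in g) for (g2 in g) for (t1 in c(g1$a, g1$b)) for (t2 in c(g2$a, g2$b)) {
        off <- sort(c(t1, t2))
        par1 <- c(g1$a, g1$b)
        if (off[1] == off[2]) {
            adm <- off[1]
        } else if (all(off %in% par1)) {
            adm <- off
        } else {
            adm <- off[!(off %in% par1)]
        }
        pNot <- 0
        for (cand in g)
            if (!(cand$a %in% adm) && !(cand$b %in% adm)) pNot <- pNot + cand$pr
        s <- s + g1$pr * g2$pr * 0.25 * (1 - pNot)
    }
    s
}

bfNeSib <- function(p) {
    g <- bfGenoList(p)
    s <- 0
    for (g1 in g) for (g2 in g) {
        offs <- list()
        for (t1 in c(g1$a, g1$b)) for (t2 in c(g2$a, g2$b))
            offs[[length(offs) + 1L]] <- sort(c(t1, t2))
        same <- 0
        for (i in 1:4) for (j in 1:4)
            if (identical(offs[[i]], offs[[j]])) same <- same + 1
        s <- s + g1$pr * g2$pr * same / 16
    }
    s
}

randomFreqs <- function(k) {
    p <- rgamma(k, 1)
    p / sum(p)
}
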