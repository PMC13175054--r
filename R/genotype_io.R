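## Project CSV dialect
## --------------------
## header: barcode, birth_year, sex, sexmk_1, sexmk_2, <locus>_1, <locus>_2, ...
## one individual per row; empty cells and the configured sentinel (default "0")
## are missing calls. Reading never drops a record: every removal happens in the
## QC cascade with a counted reason.

#' Read a genotype table from the project CSV dialect
#'
#' @param path path to a CSV file with columns `barcode`, `birth_year`, `sex`,
#'   `sexmk_1`, `sexmk_2` and one `<locus>_1`/`<locus>_2` column pair per
#'   panel locus.
#' @param panel optional character vector of expected locus names; when given,
#'   the file must contain exactly these locus columns (a locus column outside
#'   the panel is a hard error). When `NULL` the panel is taken from the
#'   header, in column order.
#' @param missing values (besides the empty cell) read as a missing allele
#'   call; default `"0"`.
#' @return a [GenotypeTable-class].
#' @seealso [writeGenotypeCsv()]
#' @export
readGenotypeCsv <- function(path, panel = NULL, missing = "0") {
    if (!file.exists(path))
        stop("file not found: ", path)
    fields <- utils::count.fields(path, sep = ",", quote = "\"")
    if (length(fields) < 1L)
        stop("empty file: ", path)
    bad <- which(fields != fields[1L])
    if (length(bad))
        stop(sprintf("malformed row at line %d: expected %d fields, found %d",
                     bad[1L] + 0L, fields[1L], fields[bad[1L]]))
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    fixed <- c("barcode", "birth_year", "sex", "sexmk_1", "sexmk_2")
    if (!all(fixed %in% names(df)))
        stop("CSV header must contain: ", paste(fixed, collapse = ", "))
    locusCols <- setdiff(names(df), fixed)
    stems <- unique(sub("_[12]$", "", locusCols))
    okPairs <- all(paste0(rep(stems, each = 2L), c("_1", "_2")) %in% locusCols) &&
        length(locusCols) == 2L * length(stems)
    if (!okPairs)
        stop("locus columns must come in <locus>_1/<locus>_2 pairs")
    if (is.null(panel)) {
        panel <- stems
    } else {
        unknown <- setdiff(stems, panel)
        if (length(unknown))
            stop("unknown locus column(s): ", paste(unknown, collapse = ", "))
        absent <- setdiff(panel, stems)
        if (length(absent))
            stop("panel locus missing from file: ", paste(absent, collapse = ", "))
    }
    cols <- paste0(rep(panel, each = 2L), c("_1", "_2"))
    al <- as.matrix(df[, cols, drop = FALSE])
    al[al %in% c("", missing)] <- NA
    suppressWarnings(storage.mode(al) <- "integer")
    sx <- toupper(trimws(df$sex))
    sx[!(sx %in% c("F", "M"))] <- "U"
    mk1 <- trimws(df$sexmk_1); mk1[mk1 == ""] <- NA
    mk2 <- trimws(df$sexmk_2); mk2[mk2 == ""] <- NA
    GenotypeTable(panel, al,
                  data.frame(barcode = df$barcode,
                             birthYear = suppressWarnings(as.integer(df$birth_year)),
                             sex = sx, sexMarker1 = mk1, sexMarker2 = mk2,
                             stringsAsFactors = FALSE))
}

#' Write a genotype table in the project CSV dialect
#'
#' Missing allele calls are written as empty cells; [readGenotypeCsv()] on the
#' result restores the identical data values.
#'
#' @param table a [GenotypeTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeCsv <- function(table, path) {
    stopifnot(is(table, "GenotypeTable"))
    al <- table@alleles
    alc <- matrix(as.character(al), nrow = nrow(al), dimnames = dimnames(al))
    alc[is.na(alc)] <- ""
    m <- table@meta
    mk1 <- m$sexMarker1; mk1[is.na(mk1)] <- ""
    mk2 <- m$sexMarker2; mk2[is.na(mk2)] <- ""
    out <- data.frame(barcode = m$barcode, birth_year = m$birthYear,
                      sex = m$sex, sexmk_1 = mk1, sexmk_2 = mk2,
                      stringsAsFactors = FALSE, check.names = FALSE)
    out <- cbind(out, as.data.frame(alc, stringsAsFactors = FALSE))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

## Genepop 4.x dialect
## -------------------
## title line; one locus name per line (or a single comma-separated line);
## "Pop" separators (any text after the word is kept as the cohort label and is
## ignored by Genepop itself); individuals as "id , 123456 123456 ..." with
## 3-digit (or 2-digit) per-allele codes, "000"/"00" = missing.

#' Read a Genepop-format genotype file
#'
#' POP blocks become cohorts. A label following the `Pop` keyword (or, failing
#' that, a 4-digit year embedded in the block's first individual ID) that
#' parses as a year is stored as `birthYear`; otherwise cohorts get the
#' 1-based POP-block index as their `birthYear` key. Genepop carries no sex
#' information, so registered sex is `"U"` and sex markers are missing.
#'
#' @param path path to a Genepop text file.
#' @return a [GenotypeTable-class].
#' @export
readGenepop <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*$", lines)]
    if (length(lines) < 3L)
        stop("not a Genepop file (need title, loci and at least one POP): ", path)
    body <- lines[-1L]
    isPop <- grepl("^\\s*pop\\b", body, ignore.case = TRUE)
    firstPop <- which(isPop)[1L]
    if (is.na(firstPop))
        stop("no POP line found")
    locusLines <- body[seq_len(firstPop - 1L)]
    panel <- trimws(unlist(strsplit(locusLines, ",")))
    panel <- panel[panel != ""]
    if (length(panel) < 1L)
        stop("no locus names before first POP")
    popIdx <- cumsum(isPop)
    labels <- sub("^\\s*pop\\s*", "", body[isPop], ignore.case = TRUE)
    labels <- trimws(labels)
    recs <- which(!isPop & popIdx > 0L)
    n <- length(recs)
    al <- matrix(NA_integer_, nrow = n, ncol = 2L * length(panel))
    ids <- character(n)
    years <- integer(n)
    for (r in seq_len(n)) {
        line <- body[recs[r]]
        parts <- strsplit(line, ",")[[1L]]
        if (length(parts) < 2L)
            stop("individual line without ',' separator: ", line)
        ids[r] <- trimws(parts[1L])
        toks <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
        if (length(toks) != length(panel))
            stop(sprintf("individual '%s' has %d genotypes for %d loci",
                         ids[r], length(toks), length(panel)))
        for (l in seq_along(toks)) {
            tok <- toks[l]
            if (!grepl("^[0-9]+$", tok) || !(nchar(tok) %in% c(4L, 6L)))
                stop(sprintf("genotype token '%s' is not 4 or 6 digits (individual '%s', locus %s)",
                             tok, ids[r], panel[l]))
            w <- nchar(tok) / 2L
            a1 <- as.integer(substr(tok, 1L, w))
            a2 <- as.integer(substr(tok, w + 1L, 2L * w))
            al[r, 2L * l - 1L] <- if (a1 == 0L) NA_integer_ else a1
            al[r, 2L * l] <- if (a2 == 0L) NA_integer_ else a2
        }
        years[r] <- popIdx[recs[r]]
    }
    nPops <- max(popIdx)
    popYear <- integer(nPops)
    for (p in seq_len(nPops)) {
        lab <- labels[p]
        if (grepl("^[0-9]{4}$", lab)) {
            popYear[p] <- as.integer(lab)
        } else {
            first <- ids[years == p][1L]
            m <- regmatches(first, regexpr("[0-9]{4}", first))
            popYear[p] <- if (length(m) && !is.na(first)) as.integer(m) else p
        }
    }
    GenotypeTable(panel, al,
                  data.frame(barcode = ids, birthYear = popYear[years],
                             sex = "U", sexMarker1 = NA_character_,
                             sexMarker2 = NA_character_,
                             stringsAsFactors = FALSE))
}

#' Write a genotype table in Genepop format
#'
#' One POP block per cohort (ascending), individuals ordered by barcode within
#' each block, 3-digit per-allele coding with `000` for missing. The cohort
#' label is written after the `Pop` keyword, which Genepop itself ignores but
#' [readGenepop()] uses to restore the cohort assignment.
#'
#' @param table a [GenotypeTable-class]; all allele sizes must be at most 999.
#' @param path output file path.
#' @param title title line for the file.
#' @return `path`, invisibly.
#' @export
writeGenepop <- function(table, path, title = "msatpop export") {
    stopifnot(is(table, "GenotypeTable"))
    if (nIndividuals(table) == 0L)
        stop("refusing to write an empty table")
    al <- table@alleles
    if (any(al > 999L, na.rm = TRUE))
        stop("allele size over 999 cannot use 3-digit Genepop coding; re-code alleles first")
    out <- c(title, table@panel)
    yrs <- table@meta$birthYear
    for (y in sort(unique(yrs))) {
        out <- c(out, paste("Pop", y))
        idx <- which(yrs == y)
        idx <- idx[order(table@meta$barcode[idx])]
        for (r in idx) {
            codes <- sprintf("%03d", ifelse(is.na(al[r, ]), 0L, al[r, ]))
            g <- paste0(codes[seq(1L, ncol(al), 2L)], codes[seq(2L, ncol(al), 2L)])
            out <- c(out, paste0(table@meta$barcode[r], " ,  ",
                                 paste(g, collapse = " ")))
        }
    }
    writeLines(out, path)
    invisible(path)
}
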