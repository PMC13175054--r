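#' Published reference summaries for the Hanwoo parentage panel
#'
#' Per-locus summary statistics published for the 11-marker Korean cattle
#' (Hanwoo) parentage-verification panel, shipped as plain-text reference
#' data: `"summary"` gives `k`, `N`, `hObs`, `hExp`, `pic`, `fis` per locus
#' (3-4 printed decimals); `"exclusion"` gives the five per-locus
#' non-exclusion probabilities (3 printed decimals). The underlying
#' individual-level genotypes are not public, so these rows serve as worked
#' inputs: the panel's mean diversity line and the combined non-exclusion
#' products are reconstructed from them by [summaryMeanRow()] and
#' [combineExclusion()].
#'
#' @param which `"summary"` or `"exclusion"`.
#' @return a data.frame with one row per panel locus.
#' @examples
#' ref <- hanwooReferenceTable("summary")
#' tail(summaryMeanRow(ref), 1)   # panel mean line
#' @export
hanwooReferenceTable <- function(which = c("summary", "exclusion")) {
    which <- match.arg(which)
    f <- system.file("extdata",
                     paste0("hanwoo_panel_", which, ".csv"),
                     package = "msatpop", mustWork = TRUE)
    utils::read.csv(f, stringsAsFactors = FALSE)
}
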