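#' KIR locus names
#'
#' The 17 copy-number KIR loci typed in the reference data, plus the two
#' extended haplotype classifications: the fine-grained gene-content haplotype
#' (`KIRhaplotype`) and the broad A/B haplotype group (`AvsB`).  Copy numbers
#' are small non-negative integers per haplotype; the two haplotype
#' classifications are categorical labels and are only defined at the
#' haplotype level (per-individual tables never carry them).
#'
#' @param which `"all"` (19 loci), `"copy"` (the 17 copy-number loci) or
#'   `"haplotype"` (the two haplotype-class loci).
#' @return Character vector of locus names.
#' @export
#' @examples
#' kir_loci("copy")
kir_loci <- function(which = c("all", "copy", "haplotype")) {
  which <- match.arg(which)
  copy <- c("KIR2DS2", "KIR2DL2", "KIR2DL3", "KIR2DP1", "KIR2DL1",
            "KIR3DP1", "KIR2DL4", "KIR3DL1ex4", "KIR3DL1ex9", "KIR3DS1",
            "KIR2DL5", "KIR2DS3", "KIR2DS5", "KIR2DS1", "KIR2DS4TOTAL",
            "KIR2DS4WT", "KIR2DS4DEL")
  hap <- c("KIRhaplotype", "AvsB")
  switch(which, all = c(copy, hap), copy = copy, haplotype = hap)
}

.kir_hap_loci <- function() kir_loci("haplotype")
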