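#' Align query panel allele coding to a reference panel
#'
#' Before imputation, the 0/1 allele coding of a query panel must agree with
#' the panel the model was trained on.  SNPs are matched across panels by
#' GRCh37 position (IDs differ between array naming schemes).  For each shared
#' position the query coding is reconciled with the reference by comparison of
#' nucleotide type (purine or pyrimidine) and allele frequencies:
#'
#' * identical allele pair, same order: kept as is;
#' * identical pair, opposite order: 0/1 bits inverted (`swapped_coding`);
#' * pair matching after purine/pyrimidine strand complement: recoded to the
#'   reference strand (`strand_flipped`), with bit inversion when needed;
#' * strand-ambiguous pairs (A/T, C/G), where the complement is
#'   indistinguishable from a coding swap: orientation resolved by matching
#'   the allele-1 frequency within `freq_tol`; dropped when the frequencies
#'   cannot decide (`dropped_ambiguous`);
#' * positions absent from the reference, or with an irreconcilable allele
#'   pair, are dropped (`dropped_absent`).
#'
#' @param reference,query [haplotype_panel()] objects.
#' @param freq_tol Maximum allele-1 frequency difference accepted when
#'   resolving strand-ambiguous SNPs (default 0.1).
#' @return A list with the aligned `panel` (query restricted to kept SNPs,
#'   recoded and carrying the reference allele labels) and a `report` data
#'   frame (one row per query SNP: `snp_id`, `position`, `action`,
#'   `freq_diff` after alignment).
#' @export
align_alleles <- function(reference, query, freq_tol = 0.1) {
  stopifnot(inherits(reference, "haplotype_panel"),
            inherits(query, "haplotype_panel"))
  shared <- intersect(reference$snps$position, query$snps$position)
  if (length(shared) == 0L) stop("panels share no SNP positions")

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_freq <- allele1_freq(reference)
  qry_freq <- allele1_freq(query)

  nq <- nrow(query$snps)
  action <- character(nq)
  invert <- logical(nq)
  new_a1 <- query$snps$allele1
  new_a2 <- query$snps$allele2

  for (j in seq_len(nq)) {
    pos <- query$snps$position[j]
    r <- match(pos, reference$snps$position)
    if (is.na(r)) { action[j] <- "dropped_absent"; next }
    ra1 <- reference$snps$allele1[r]; ra2 <- reference$snps$allele2[r]
    qa1 <- query$snps$allele1[j]; qa2 <- query$snps$allele2[j]
    ambiguous <- qa1 == comp[[qa2]]  # A/T or C/G pair

    if (ambiguous) {
      if (!setequal(c(qa1, qa2), c(ra1, ra2)) &&
          !setequal(comp[c(qa1, qa2)], c(ra1, ra2))) {
        action[j] <- "dropped_absent"; next
      }
      f_ref <- ref_freq[r]
      f_as_is <- if (qa1 == ra1) qry_freq[j] else 1 - qry_freq[j]
      ok_as_is <- is.finite(f_as_is) && abs(f_as_is - f_ref) <= freq_tol
      ok_inv <- is.finite(f_as_is) && abs((1 - f_as_is) - f_ref) <= freq_tol
      if (ok_as_is == ok_inv) { action[j] <- "dropped_ambiguous"; next }
      # under the strand-flip reading each nucleotide maps to its complement,
      # which for an ambiguous pair is the other allele of the same pair
      invert[j] <- ok_inv == (qa1 == ra1)
      action[j] <- if (!invert[j] && qa1 == ra1) "kept_as_is"
                   else if (invert[j] && qa1 != ra1) "swapped_coding"
                   else "strand_flipped"
    } else if (setequal(c(qa1, qa2), c(ra1, ra2))) {
      if (qa1 == ra1) action[j] <- "kept_as_is"
      else { action[j] <- "swapped_coding"; invert[j] <- TRUE }
    } else if (setequal(comp[c(qa1, qa2)], c(ra1, ra2))) {
      action[j] <- "strand_flipped"
      invert[j] <- comp[[qa1]] != ra1
    } else {
      action[j] <- "dropped_absent"; next
    }
    new_a1[j] <- ra1; new_a2[j] <- ra2
  }

  keep <- !startsWith(action, "dropped")
  alleles <- query$alleles
  for (j in which(keep & invert)) alleles[, j] <- 1L - alleles[, j]

  snps <- query$snps
  snps$allele1 <- new_a1; snps$allele2 <- new_a2
  panel <- haplotype_panel(snps[keep, , drop = FALSE],
                           alleles[, keep, drop = FALSE],
                           query$haplotype_ids)

  freq_diff <- rep(NA_real_, nq)
  if (any(keep)) {
    # query arrives position-sorted, so subsetting preserves SNP order
    new_freq <- allele1_freq(panel)
    rpos <- match(panel$snps$position, reference$snps$position)
    freq_diff[which(keep)] <- abs(new_freq - ref_freq[rpos])
  }
  report <- data.frame(snp_id = query$snps$snp_id,
                       position = query$snps$position,
                       action = action, freq_diff = freq_diff,
                       stringsAsFactors = FALSE)
  list(panel = panel, report = report)
}

#' Restrict a panel to a genomic window
#'
#' Keeps SNPs with `start_bp <= position <= end_bp` (closed interval, 1-based
#' GRCh37 coordinates).  An empty result is allowed and reported via a
#' message.
#'
#' @param panel A [haplotype_panel()].
#' @param start_bp,end_bp Window bounds in base pairs, `start_bp < end_bp`.
#' @return The restricted panel.
#' @export
filter_by_region <- function(panel, start_bp, end_bp) {
  stopifnot(inherits(panel, "haplotype_panel"), start_bp < end_bp)
  keep <- panel$snps$position >= start_bp & panel$snps$position <= end_bp
  if (!any(keep))
    message("filter_by_region: no SNPs in [", start_bp, ", ", end_bp, "]")
  panel[, keep]
}

#' Drop monomorphic SNPs
#'
#' Removes SNPs whose non-missing alleles are all 0 or all 1; only
#' polymorphic SNPs carry information for model fitting.
#'
#' @param panel A [haplotype_panel()].
#' @return The panel restricted to polymorphic SNPs.
#' @export
drop_monomorphic <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  poly <- apply(panel$alleles, 2L, function(a) {
    a <- a[!is.na(a)]
    length(a) > 0L && any(a == 0L) && any(a == 1L)
  })
  if (!any(poly)) stop("all SNPs are monomorphic")
  panel[, poly]
}
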