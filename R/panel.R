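#' Construct a phased haplotype panel
#'
#' A haplotype panel holds phased binary SNP alleles (one row per haplotype,
#' one column per SNP, entries 0 = allele 1, 1 = allele 2, `NA` = missing)
#' together with SNP metadata.  SNPs are stored sorted by GRCh37 position
#' (1-based); duplicate positions are not allowed because panels are matched
#' across genotyping platforms by position.
#'
#' @param snps Data frame with columns `snp_id`, `position`, `allele1`,
#'   `allele2`, and optionally `rsid`, `gene`, `poor_clustering`.
#' @param alleles Integer matrix, haplotypes x SNPs, entries in `{0, 1, NA}`.
#' @param haplotype_ids Character vector of haplotype identifiers.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(snps, alleles, haplotype_ids) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "position", "allele1", "allele2")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols))
    stop("snps is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"rsid" %in% names(snps)) snps$rsid <- NA_character_
  if (!"gene" %in% names(snps)) snps$gene <- NA_character_
  if (!"poor_clustering" %in% names(snps)) snps$poor_clustering <- FALSE
  snps$position <- as.integer(snps$position)

  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  haplotype_ids <- as.character(haplotype_ids)

  if (ncol(alleles) != nrow(snps))
    stop("allele matrix has ", ncol(alleles), " columns but ", nrow(snps),
         " SNPs are defined")
  if (nrow(alleles) != length(haplotype_ids))
    stop("allele matrix has ", nrow(alleles), " rows but ",
         length(haplotype_ids), " haplotype ids")
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("allele entries must be 0, 1 or NA")
  if (any(snps$position <= 0L, na.rm = TRUE)) stop("SNP positions must be > 0")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP ID: ", snps$snp_id[duplicated(snps$snp_id)][1L])
  if (anyDuplicated(snps$position))
    stop("duplicate SNP position: ",
         snps$position[duplicated(snps$position)][1L])
  valid_nt <- c("A", "C", "G", "T")
  if (!all(snps$allele1 %in% valid_nt) || !all(snps$allele2 %in% valid_nt))
    stop("alleles must be one of A, C, G, T")
  if (any(snps$allele1 == snps$allele2))
    stop("allele1 and allele2 must differ (SNP ",
         snps$snp_id[snps$allele1 == snps$allele2][1L], ")")

  # stable sort: input column order is preserved among equal positions
  ord <- order(snps$position)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  alleles <- alleles[, ord, drop = FALSE]
  dimnames(alleles) <- list(haplotype_ids, snps$snp_id)

  structure(list(snps = snps, alleles = alleles,
                 haplotype_ids = haplotype_ids),
            class = "haplotype_panel")
}

#' @export
#' @method print haplotype_panel
print.haplotype_panel <- function(x, ...) {
  cat("Phased haplotype panel: ", length(x$haplotype_ids), " haplotypes x ",
      nrow(x$snps), " SNPs\n", sep = "")
  if (nrow(x$snps)) {
    cat("  positions ", min(x$snps$position), "-", max(x$snps$position),
        " (GRCh37)\n", sep = "")
    nmiss <- sum(is.na(x$alleles))
    if (nmiss) cat("  ", nmiss, " missing allele calls\n", sep = "")
  }
  invisible(x)
}

#' Subset a haplotype panel
#'
#' @param x A `haplotype_panel`.
#' @param i Haplotype index (integer, logical, or haplotype id).
#' @param j SNP index (integer, logical, or SNP id).
#' @param ... Unused.
#' @return A `haplotype_panel`.
#' @export
`[.haplotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$haplotype_ids)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  if (is.character(i)) i <- match(i, x$haplotype_ids)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  haplotype_panel(x$snps[j, , drop = FALSE],
                  x$alleles[i, j, drop = FALSE],
                  x$haplotype_ids[i])
}

#' Allele-1 frequencies of a panel
#'
#' Frequency of allele 1 (coded 0) at every SNP, computed over non-missing
#' calls.
#'
#' @param panel A `haplotype_panel`.
#' @return Named numeric vector, one entry per SNP.
#' @export
allele1_freq <- function(panel) {
  f <- apply(panel$alleles, 2L, function(a) mean(a == 0L, na.rm = TRUE))
  setNames(as.numeric(f), panel$snps$snp_id)
}

#' Combine a haplotype panel with KIR types into a reference panel
#'
#' A reference panel is the training set for imputation: phased SNP alleles
#' joined to per-haplotype KIR type labels.  Rows of the type table are
#' matched to panel haplotypes by unit id.
#'
#' @param panel A `haplotype_panel`.
#' @param kir_types A per-haplotype KIR type table (see [read_kir_types()]);
#'   a data frame whose rownames (or `unit_id` column) are haplotype ids.
#' @return An object of class `reference_panel` (also a `haplotype_panel`)
#'   with a `kir` data frame aligned to the haplotypes.
#' @export
reference_panel <- function(panel, kir_types) {
  stopifnot(inherits(panel, "haplotype_panel"))
  kir <- as.data.frame(kir_types, stringsAsFactors = FALSE)
  if ("unit_id" %in% names(kir)) {
    rownames(kir) <- kir$unit_id
    kir$unit_id <- NULL
  }
  idx <- match(panel$haplotype_ids, rownames(kir))
  if (anyNA(idx))
    stop("KIR types missing for haplotype(s): ",
         paste(head(panel$haplotype_ids[is.na(idx)], 3L), collapse = ", "))
  out <- panel
  out$kir <- kir[idx, , drop = FALSE]
  rownames(out$kir) <- panel$haplotype_ids
  class(out) <- c("reference_panel", "haplotype_panel")
  out
}

#' @export
#' @method print reference_panel
print.reference_panel <- function(x, ...) {
  NextMethod()
  cat("  KIR types for ", ncol(x$kir), " loci: ",
      paste(head(names(x$kir), 5L), collapse = ", "),
      if (ncol(x$kir) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.reference_panel` <- function(x, i, j, ...) {
  kir <- x$kir
  out <- NextMethod()
  if (missing(i)) i <- seq_len(nrow(kir))
  if (is.character(i)) i <- match(i, rownames(kir))
  out$kir <- kir[i, , drop = FALSE]
  class(out) <- c("reference_panel", "haplotype_panel")
  out
}
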