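#' Read SHAPEIT-style .haps/.sample files
#'
#' Parses the de facto SHAPEIT phased-output layout: each `.haps` row has five
#' leading columns (chromosome, SNP id, position, allele 1, allele 2) followed
#' by 2N allele columns of 0/1 (missing coded `?`), two per sample.  The
#' `.sample` file supplies sample ids, either in the standard two-header-line
#' dialect (`ID_1 ID_2 missing` / `0 0 0`) or as one id per line.
#'
#' @param haps_path Path to the `.haps` file.
#' @param sample_path Path to the `.sample` file.
#' @return A [haplotype_panel()] with two haplotypes per sample, identified as
#'   `<sample>_1` and `<sample>_2`.
#' @export
read_haps <- function(haps_path, sample_path) {
  if (!file.exists(haps_path)) stop("haps file not found: ", haps_path)
  if (!file.exists(sample_path)) stop("sample file not found: ", sample_path)

  slines <- readLines(sample_path)
  slines <- slines[nzchar(trimws(slines))]
  if (length(slines) >= 2L && grepl("^ID_1\\b", slines[1L]))
    slines <- slines[-(1:2)]
  samples <- vapply(strsplit(trimws(slines), "[ \t]+"), `[[`, "", 1L)
  n_samp <- length(samples)
  if (n_samp == 0L) stop("sample file contains no samples")

  lines <- readLines(haps_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("haps file contains no records")
  toks <- strsplit(trimws(lines), "[ \t]+")
  width <- 5L + 2L * n_samp
  widths <- lengths(toks)
  if (any(widths != width))
    stop("haps line ", which(widths != width)[1L], " has ",
         widths[widths != width][1L], " fields; expected ", width)

  meta <- t(vapply(toks, function(x) x[1:5], character(5L)))
  snp_id <- meta[, 2L]
  if (anyDuplicated(snp_id))
    stop("duplicate SNP ID: ", snp_id[duplicated(snp_id)][1L])

  allele_tok <- lapply(toks, function(x) x[-(1:5)])
  flat <- unlist(allele_tok, use.names = FALSE)
  ok <- flat %in% c("0", "1", "?")
  if (!all(ok)) {
    bad_line <- ceiling(which(!ok)[1L] / (2L * n_samp))
    stop("haps line ", bad_line, ": allele token '",
         flat[!ok][1L], "' is not 0, 1 or ?")
  }
  # flat runs SNP by SNP, so filling 2N rows column-major puts haplotypes
  # in rows and SNPs in columns directly
  alleles <- matrix(suppressWarnings(as.integer(flat)), nrow = 2L * n_samp)
  hap_ids <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))

  snps <- data.frame(snp_id = snp_id, rsid = NA_character_,
                     position = as.integer(meta[, 3L]),
                     allele1 = meta[, 4L], allele2 = meta[, 5L],
                     stringsAsFactors = FALSE)
  haplotype_panel(snps, alleles, hap_ids)
}

#' Write a panel as SHAPEIT-style .haps/.sample files
#'
#' @param panel A [haplotype_panel()].  Haplotype ids must come in pairs
#'   `<sample>_1`, `<sample>_2`.
#' @param haps_path,sample_path Output paths.
#' @param chrom Chromosome label for column 1 (default `"19"`).
#' @return Invisibly, the haps path.
#' @export
write_haps <- function(panel, haps_path, sample_path, chrom = "19") {
  n <- length(panel$haplotype_ids)
  if (n %% 2L != 0L) stop("panel must contain an even number of haplotypes")
  samples <- sub("_1$", "", panel$haplotype_ids[seq(1L, n, 2L)])

  allele_chr <- matrix(as.character(panel$alleles), nrow = n)
  allele_chr[is.na(panel$alleles)] <- "?"
  rows <- vapply(seq_len(nrow(panel$snps)), function(j) {
    paste(c(chrom, panel$snps$snp_id[j], panel$snps$position[j],
            panel$snps$allele1[j], panel$snps$allele2[j], allele_chr[, j]),
          collapse = " ")
  }, character(1L))
  writeLines(rows, haps_path)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(samples, samples, "0")), sample_path)
  invisible(haps_path)
}

#' Read phased biallelic SNPs from a VCF
#'
#' Loads a VCF (4.x) and converts phased biallelic SNP records to a haplotype
#' panel with REF coded 0 and ALT coded 1.  Multi-allelic, non-SNP, or
#' unphased records are skipped; the number skipped is reported via a message
#' and as the `n_skipped` attribute.
#'
#' @param vcf_path Path to a VCF file.
#' @return A [haplotype_panel()] with two haplotypes per sample.
#' @export
read_vcf_phased <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(NULL, colnames(gt)))

  nt <- c("A", "C", "G", "T")
  biallelic_snp <- fix[, "REF"] %in% nt & fix[, "ALT"] %in% nt
  phased <- apply(gt, 1L, function(g) all(grepl("^[01]\\|[01]$", g)))
  keep <- biallelic_snp & phased
  n_skipped <- sum(!keep)
  if (!any(keep))
    stop("no phased biallelic SNP records in ", vcf_path)
  if (n_skipped > 0L)
    message("read_vcf_phased: skipped ", n_skipped,
            " record(s) (multi-allelic, non-SNP or unphased)")

  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  alleles <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(gt))
  alleles[seq(1L, nrow(alleles), 2L), ] <- t(a1)
  alleles[seq(2L, nrow(alleles), 2L), ] <- t(a2)
  hap_ids <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0("snp", fix[no_id, "POS"])
  snps <- data.frame(snp_id = ids, rsid = ifelse(no_id, NA_character_, ids),
                     position = as.integer(fix[, "POS"]),
                     allele1 = fix[, "REF"], allele2 = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  out <- haplotype_panel(snps, alleles, hap_ids)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a KIR type table
#'
#' Reads a delimited table of KIR types, one row per unit (haplotype or
#' individual), with a header of locus names and unit ids in the first
#' column.  Copy-number loci must hold small non-negative integers; `AvsB`
#' must be `A` or `B`.  The haplotype-level classifications `KIRhaplotype`
#' and `AvsB` are rejected in per-individual tables, where they are
#' undefined.  Empty cells become missing labels.
#'
#' @param path Path to a TSV (default) or CSV file; the delimiter is taken
#'   from the extension.
#' @param unit `"haplotype"` or `"individual"`.
#' @param allow_extra Allow locus names outside [kir_loci()]; needed for
#'   synthetic panels with custom haplotype vocabularies.
#' @return A data frame of character labels with unit ids as rownames and a
#'   `unit` attribute.
#' @export
read_kir_types <- function(path, unit = c("haplotype", "individual"),
                           allow_extra = FALSE) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("KIR type file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("", "NA"))
  if (ncol(tab) < 2L) stop("KIR type table needs a unit-id column plus loci")
  ids <- tab[[1L]]
  tab <- tab[, -1L, drop = FALSE]
  rownames(tab) <- ids
  kir_type_table(tab, unit = unit, allow_extra = allow_extra)
}

#' Validate a KIR type table held in a data frame
#'
#' @param values Data frame of labels, units as rows, loci as columns.
#' @param unit `"haplotype"` or `"individual"`.
#' @param allow_extra Allow locus names outside [kir_loci()].
#' @return The validated data frame (character columns) with a `unit`
#'   attribute.
#' @export
kir_type_table <- function(values, unit = c("haplotype", "individual"),
                           allow_extra = FALSE) {
  unit <- match.arg(unit)
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  values[] <- lapply(values, as.character)

  unknown <- setdiff(names(values), kir_loci("all"))
  if (length(unknown) && !allow_extra)
    stop("unknown KIR locus name(s): ", paste(unknown, collapse = ", "),
         " (set allow_extra = TRUE to accept)")
  if (unit == "individual") {
    bad <- intersect(names(values), .kir_hap_loci())
    if (length(bad))
      stop("per-individual tables cannot carry ", paste(bad, collapse = ", "),
           ": these types are only defined on a haplotype level")
  }
  copy_cols <- intersect(names(values), kir_loci("copy"))
  for (lc in copy_cols) {
    v <- suppressWarnings(as.numeric(values[[lc]]))
    bad <- !is.na(values[[lc]]) & (is.na(v) | v < 0 | v != round(v))
    if (any(bad))
      stop("locus ", lc, ": copy numbers must be non-negative integers (got '",
           values[[lc]][bad][1L], "')")
  }
  if ("AvsB" %in% names(values)) {
    ab <- values[["AvsB"]]
    if (any(!is.na(ab) & !ab %in% c("A", "B")))
      stop("AvsB values must be A or B")
  }
  attr(values, "unit") <- unit
  values
}

#' Write a KIR type table
#'
#' @param values KIR type data frame (rownames are unit ids).
#' @param path Output path; `.csv` selects comma separation, otherwise TSV.
#' @return Invisibly, `path`.
#' @export
write_kir_types <- function(values, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- cbind(unit_id = rownames(values),
               as.data.frame(values, stringsAsFactors = FALSE))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP metadata table
#'
#' Reads a delimited table of SNP definitions in the style of a published
#' selected-SNP report: `snp_id`, `rsid`, `position`, `allele1`, `allele2`,
#' and optional annotation columns; yes/no columns (`in_ng_panel`,
#' `poor_clustering`) are converted to logical.
#'
#' @param path Path to a TSV (or CSV) file.
#' @return Data frame of SNP metadata.
#' @export
read_snp_metadata <- function(path) {
  if (!file.exists(path)) stop("SNP table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  for (col in intersect(c("in_ng_panel", "poor_clustering"), names(tab)))
    tab[[col]] <- tolower(as.character(tab[[col]])) %in% c("yes", "true", "1")
  tab$position <- as.integer(tab$position)
  tab
}
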