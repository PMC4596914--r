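# Shared fixture builders and independent oracles.  Everything here is
# deliberately written in a different style from the package internals so the
# oracles stay independent of the code paths they check.

# small hand-built panel: n haplotypes x p SNPs with given allele matrix
make_panel <- function(alleles, positions = NULL, allele1 = NULL,
                       allele2 = NULL, ids = NULL) {
  alleles <- as.matrix(alleles)
  p <- ncol(alleles)
  if (is.null(positions)) positions <- seq(55200000L, by = 1000L, length.out = p)
  if (is.null(allele1)) allele1 <- rep_len(c("A", "C"), p)
  if (is.null(allele2)) allele2 <- rep_len(c("G", "T"), p)
  if (is.null(ids)) ids <- paste0("h", seq_len(nrow(alleles)))
  haplotype_panel(
    data.frame(snp_id = paste0("s", seq_len(p)), position = positions,
               allele1 = allele1, allele2 = allele2,
               stringsAsFactors = FALSE),
    alleles, ids)
}

# a panel whose target is perfectly tagged by SNP 1, with noise SNPs after it
make_tagged_reference <- function(n = 60, p_noise = 5, seed = 42,
                                  locus = "KIR2DS2") {
  set.seed(seed)
  y <- rep(c("0", "1"), length.out = n)
  tag <- as.integer(y)
  noise <- matrix(rbinom(n * p_noise, 1L, 0.5), nrow = n)
  panel <- make_panel(cbind(tag, noise))
  kir <- data.frame(row.names = panel$haplotype_ids)
  kir[[locus]] <- y
  reference_panel(panel, kir)
}

# exhaustive CART oracle: recursively picks the split maximising the exact
# same child-purity score as the implementation, scanning ALL SNPs in
# ascending index order with strict improvement over the parent score
oracle_best_split <- function(X, y) {
  n <- nrow(X)
  classes <- sort(unique(y))
  cnt <- sapply(classes, function(c) sum(y == c))
  parent <- sum(cnt^2) / n
  best_v <- NA_integer_
  best_s <- -Inf
  for (v in seq_len(ncol(X))) {
    left <- X[, v] == 0L
    nl <- sum(left); nr <- n - nl
    if (nl == 0L || nr == 0L) next
    ssl <- sum(sapply(classes, function(c) sum(y[left] == c))^2)
    ssr <- sum(sapply(classes, function(c) sum(y[!left] == c))^2)
    s <- ssl / nl + ssr / nr
    if (s > parent + 1e-12 && s > best_s) { best_v <- v; best_s <- s }
  }
  best_v
}

oracle_tree_predict <- function(X, y, Xnew) {
  classes <- sort(unique(y))
  maj <- classes[which.max(sapply(classes, function(c) sum(y == c)))]
  if (length(unique(y)) == 1L || nrow(X) < 2L)
    return(rep(maj, nrow(Xnew)))
  v <- oracle_best_split(X, y)
  if (is.na(v)) return(rep(maj, nrow(Xnew)))
  left <- X[, v] == 0L
  out <- character(nrow(Xnew))
  go_left <- Xnew[, v] == 0L
  if (any(go_left))
    out[go_left] <- oracle_tree_predict(X[left, , drop = FALSE], y[left],
                                        Xnew[go_left, , drop = FALSE])
  if (any(!go_left))
    out[!go_left] <- oracle_tree_predict(X[!left, , drop = FALSE], y[!left],
                                         Xnew[!go_left, , drop = FALSE])
  out
}

# all 2^p binary input rows
all_binary_rows <- function(p) {
  as.matrix(expand.grid(rep(list(0:1), p)))
}

# write a tiny VCF with phased genotypes; gts is a list of per-record
# genotype strings, one per sample
write_tiny_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}
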