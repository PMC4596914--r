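# Synthetic KIR-region generator.
#
# Haplotypes are built the way the region is organised in European data: one
# centromeric and one telomeric gene-content motif joined at the central
# recombination hotspot between KIR3DP1 and KIR2DL4.  Copy numbers at every
# locus are deterministic given the motif pair; SNPs on each side tag that
# side's motif with configurable strength.

.default_cen_copy <- function() {
  loci <- kir_loci("copy")
  m <- matrix(0L, nrow = 3L, ncol = length(loci),
              dimnames = list(c("cA01", "cB01", "cB02"), loci))
  m["cA01", c("KIR2DL3", "KIR2DP1", "KIR2DL1", "KIR3DP1")] <- 1L
  m["cB01", c("KIR2DS2", "KIR2DL2", "KIR2DL5", "KIR2DS3", "KIR2DP1",
              "KIR2DL1", "KIR3DP1")] <- 1L
  m["cB02", c("KIR2DS2", "KIR2DL2", "KIR3DP1")] <- 1L
  m
}

.default_tel_copy <- function() {
  loci <- kir_loci("copy")
  m <- matrix(0L, nrow = 3L, ncol = length(loci),
              dimnames = list(c("tA01del", "tA01wt", "tB01"), loci))
  m["tA01del", c("KIR2DL4", "KIR3DL1ex4", "KIR3DL1ex9", "KIR2DS4TOTAL",
                 "KIR2DS4DEL")] <- 1L
  m["tA01wt", c("KIR2DL4", "KIR3DL1ex4", "KIR3DL1ex9", "KIR2DS4TOTAL",
                "KIR2DS4WT")] <- 1L
  m["tB01", c("KIR2DL4", "KIR3DS1", "KIR2DL5", "KIR2DS5", "KIR2DS1")] <- 1L
  m
}

.recycle_copy <- function(default, motifs) {
  rows <- default[rep_len(seq_len(nrow(default)), length(motifs)), ,
                  drop = FALSE]
  rownames(rows) <- motifs
  rows
}

#' Long-tail motif frequency spectrum
#'
#' Geometric-tail frequencies for simulating panels where type-allele
#' training counts span rare (<10 copies) to common (>100 copies), as real
#' haplotype-class distributions do.
#'
#' @param n Number of motifs.
#' @param p Geometric decay parameter in (0, 1).
#' @param prefix Label prefix for the motif names.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
long_tail_freqs <- function(n, p = 0.4, prefix = "m") {
  stopifnot(n >= 1L, p > 0, p < 1)
  f <- p * (1 - p)^(seq_len(n) - 1L)
  setNames(f / sum(f), paste0(prefix, sprintf("%02d", seq_len(n))))
}

#' Specify a synthetic KIR-region simulation
#'
#' Defines the generative model: centromeric and telomeric motif labels and
#' frequencies, the motif-to-copy-number map, per-SNP tagging strength (the
#' probability that a SNP allele reflects its side's motif; 1 = perfect
#' tag), a genotyping error rate, SNP counts per side, and the sample size.
#' The default motifs are the common European gene-content blocks (cA01,
#' cB01, cB02 centromeric; tA01 with and without the KIR2DS4 deletion, and
#' tB01 telomeric), with frequencies in the range reported for European
#' cohorts.  Group A haplotypes are those composed only of the designated A
#' motifs on both sides.
#'
#' @param n_haplotypes Number of haplotypes (default 500, the scale of a
#'   family-derived reference panel).
#' @param n_snps Integer vector `c(centromeric, telomeric)` SNP counts
#'   (default 150 each, giving a ~300-SNP panel).
#' @param cen_freqs,tel_freqs Named motif frequency vectors, each summing
#'   to 1.
#' @param tagging Scalar or per-SNP vector in \[0.5, 1\]: probability that a
#'   SNP allele reflects its motif (default 0.99).
#' @param error_rate Independent allele-flip genotyping error (default
#'   0.005).
#' @param cen_copy,tel_copy Motif x copy-locus contribution matrices;
#'   defaults cover the standard motifs and are recycled for custom motif
#'   names.
#' @param a_motifs List with `cen` and `tel`: the motif labels counted as
#'   group A.
#' @param region,hotspot GRCh37 bounds of the simulated window and the
#'   hotspot coordinate splitting centromeric from telomeric SNPs.
#' @param linkage Probability in \[0, 1) that the telomeric motif is drawn
#'   coupled to the centromeric one instead of independently (0 = free
#'   recombination at the hotspot).
#' @param seed Integer seed.
#' @return An object of class `kir_sim_spec`.
#' @export
kir_sim_spec <- function(n_haplotypes = 500L,
                         n_snps = c(150L, 150L),
                         cen_freqs = c(cA01 = 0.55, cB01 = 0.25, cB02 = 0.20),
                         tel_freqs = c(tA01del = 0.40, tA01wt = 0.20,
                                       tB01 = 0.40),
                         tagging = 0.99,
                         error_rate = 0.005,
                         cen_copy = NULL, tel_copy = NULL,
                         a_motifs = NULL,
                         region = c(55.1e6, 55.5e6), hotspot = 55.31e6,
                         linkage = 0,
                         seed = 1L) {
  stopifnot(n_haplotypes >= 1L, length(n_snps) == 2L, all(n_snps >= 1L),
            abs(sum(cen_freqs) - 1) < 1e-8, abs(sum(tel_freqs) - 1) < 1e-8,
            all(cen_freqs > 0), all(tel_freqs > 0),
            all(tagging >= 0.5), all(tagging <= 1),
            error_rate >= 0, error_rate < 0.5,
            region[1L] < hotspot, hotspot < region[2L],
            linkage >= 0, linkage < 1)
  if (is.null(names(cen_freqs)) || is.null(names(tel_freqs)))
    stop("motif frequency vectors must be named")
  n_snps <- as.integer(n_snps)
  p <- sum(n_snps)
  if (!length(tagging) %in% c(1L, p))
    stop("tagging must be a scalar or one value per SNP")
  tagging <- rep_len(tagging, p)
  if (is.null(cen_copy))
    cen_copy <- .recycle_copy(.default_cen_copy(), names(cen_freqs))
  if (is.null(tel_copy))
    tel_copy <- .recycle_copy(.default_tel_copy(), names(tel_freqs))
  stopifnot(identical(rownames(cen_copy), names(cen_freqs)),
            identical(rownames(tel_copy), names(tel_freqs)))
  if (is.null(a_motifs)) {
    a_motifs <- list(
      cen = intersect("cA01", names(cen_freqs)),
      tel = intersect(c("tA01del", "tA01wt"), names(tel_freqs)))
    if (!length(a_motifs$cen)) a_motifs$cen <- names(cen_freqs)[1L]
    if (!length(a_motifs$tel)) a_motifs$tel <- names(tel_freqs)[1L]
  }
  structure(list(n_haplotypes = as.integer(n_haplotypes), n_snps = n_snps,
                 cen_freqs = cen_freqs, tel_freqs = tel_freqs,
                 tagging = tagging, error_rate = error_rate,
                 cen_copy = cen_copy, tel_copy = tel_copy,
                 a_motifs = a_motifs, region = region, hotspot = hotspot,
                 linkage = linkage, seed = as.integer(seed)),
            class = "kir_sim_spec")
}

#' @export
#' @method print kir_sim_spec
print.kir_sim_spec <- function(x, ...) {
  cat("Synthetic KIR-region spec: ", x$n_haplotypes, " haplotypes, ",
      x$n_snps[1L], "+", x$n_snps[2L], " SNPs\n", sep = "")
  cat("  centromeric motifs: ",
      paste(names(x$cen_freqs), round(x$cen_freqs, 3L), collapse = ", "),
      "\n  telomeric motifs:   ",
      paste(names(x$tel_freqs), round(x$tel_freqs, 3L), collapse = ", "),
      "\n", sep = "")
  cat("  tagging ", round(mean(x$tagging), 3L), " (mean), error rate ",
      x$error_rate, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# SNP metadata and motif base alleles are a deterministic function of the
# spec's seed, so panels, families and cohorts from one spec share a platform
.sim_platform <- function(spec) {
  .with_seed(spec$seed, {
    p <- sum(spec$n_snps)
    side <- rep(c("cen", "tel"), spec$n_snps)
    pos <- sort(c(sample(seq(spec$region[1L], spec$hotspot - 1L),
                         spec$n_snps[1L]),
                  sample(seq(spec$hotspot + 1L, spec$region[2L]),
                         spec$n_snps[2L])))
    nt <- c("A", "C", "G", "T")
    pair <- t(vapply(seq_len(p), function(i) sample(nt, 2L), character(2L)))
    base_cen <- matrix(sample(0:1, length(spec$cen_freqs) * spec$n_snps[1L],
                              replace = TRUE),
                       nrow = length(spec$cen_freqs),
                       dimnames = list(names(spec$cen_freqs), NULL))
    base_tel <- matrix(sample(0:1, length(spec$tel_freqs) * spec$n_snps[2L],
                              replace = TRUE),
                       nrow = length(spec$tel_freqs),
                       dimnames = list(names(spec$tel_freqs), NULL))
    snps <- data.frame(snp_id = paste0("snp", sprintf("%04d", seq_len(p))),
                       rsid = NA_character_, position = pos,
                       allele1 = pair[, 1L], allele2 = pair[, 2L],
                       stringsAsFactors = FALSE)
    list(snps = snps, side = side, base_cen = base_cen, base_tel = base_tel)
  })
}

# draw n haplotypes (motifs + alleles) on an existing platform; assumes the
# caller has set the RNG state
.sim_haps <- function(spec, platform, n, hap_ids) {
  cen <- sample(names(spec$cen_freqs), n, replace = TRUE,
                prob = spec$cen_freqs)
  tel <- sample(names(spec$tel_freqs), n, replace = TRUE,
                prob = spec$tel_freqs)
  if (spec$linkage > 0) {
    couple <- stats::runif(n) < spec$linkage
    idx <- match(cen, names(spec$cen_freqs))
    tel[couple] <- names(spec$tel_freqs)[
      ((idx[couple] - 1L) %% length(spec$tel_freqs)) + 1L]
  }
  p <- sum(spec$n_snps)
  n_cen <- spec$n_snps[1L]
  base <- cbind(platform$base_cen[cen, , drop = FALSE],
                platform$base_tel[tel, , drop = FALSE])
  flip_tag <- matrix(stats::runif(n * p) > rep(spec$tagging, each = n),
                     nrow = n)
  flip_err <- matrix(stats::runif(n * p) < spec$error_rate, nrow = n)
  alleles <- (base + flip_tag + flip_err) %% 2L
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- hap_ids

  truth <- data.frame(hap_id = hap_ids, cen_motif = cen, tel_motif = tel,
                      KIRhaplotype = paste(cen, tel, sep = "-"),
                      AvsB = ifelse(cen %in% spec$a_motifs$cen &
                                    tel %in% spec$a_motifs$tel, "A", "B"),
                      stringsAsFactors = FALSE)
  copies <- spec$cen_copy[cen, , drop = FALSE] +
            spec$tel_copy[tel, , drop = FALSE]
  truth <- cbind(truth, as.data.frame(copies, row.names = hap_ids))
  list(alleles = alleles, truth = truth)
}

# order of SNP columns produced by .sim_haps matches platform$snps rows
# (positions are drawn sorted within each side, cen before tel, and the two
# position blocks cannot interleave because they straddle the hotspot)

.truth_kir_table <- function(truth) {
  tab <- truth[, c(kir_loci("copy"), "KIRhaplotype", "AvsB"), drop = FALSE]
  tab[] <- lapply(tab, as.character)
  rownames(tab) <- truth$hap_id
  tab
}

#' Full copy-number map of a simulation spec
#'
#' Enumerates every centromeric x telomeric motif pair and its per-locus
#' copy-number vector; this is the label-to-copy-number map used by
#' [coarsen()].
#'
#' @param spec A [kir_sim_spec()].
#' @return Data frame: rownames are haplotype labels, columns the 17
#'   copy-number loci.
#' @export
sim_copy_map <- function(spec) {
  stopifnot(inherits(spec, "kir_sim_spec"))
  combos <- expand.grid(cen = rownames(spec$cen_copy),
                        tel = rownames(spec$tel_copy),
                        stringsAsFactors = FALSE)
  m <- spec$cen_copy[combos$cen, , drop = FALSE] +
       spec$tel_copy[combos$tel, , drop = FALSE]
  rownames(m) <- paste(combos$cen, combos$tel, sep = "-")
  as.data.frame(m)
}

#' Simulate a KIR reference panel with known truth
#'
#' Draws haplotypes as independent (centromeric, telomeric) motif pairs
#' (unless `linkage` couples them), generates SNP alleles tagging each
#' side's motif at the spec's tagging strength with independent flip noise
#' at the genotyping error rate, and emits the reference panel together
#' with the generating truth and the copy-number map.
#'
#' @param spec A [kir_sim_spec()].
#' @return List with `panel` (a [reference_panel()] carrying all 19 KIR
#'   types), `truth` (per-haplotype motifs and types), `copy_map` (label to
#'   per-locus copy numbers) and `spec`.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "kir_sim_spec"))
  platform <- .sim_platform(spec)
  sim <- .with_seed(spec$seed + 1L, {
    .sim_haps(spec, platform, spec$n_haplotypes,
              paste0("hap", sprintf("%04d", seq_len(spec$n_haplotypes))))
  })
  panel <- haplotype_panel(platform$snps, sim$alleles, sim$truth$hap_id)
  panel <- reference_panel(panel, .truth_kir_table(sim$truth))
  list(panel = panel, truth = sim$truth, copy_map = sim_copy_map(spec),
       spec = spec)
}

#' Simulate family data for panel construction
#'
#' Generates families with founder parents drawn from the spec's motif
#' model; each child inherits one haplotype per parent uniformly at random
#' with no recombination inside the region (inherited copies are re-exposed
#' to the genotyping error rate).  Per-member missingness of KIR or SNP
#' data emulates cohorts where typing sets only partially overlap.
#'
#' @param spec A [kir_sim_spec()].
#' @param n_families Number of families.
#' @param n_children Children per family (default 2).
#' @param missing_kir,missing_snp Probability that a member lacks KIR or SNP
#'   data.
#' @return List with `pedigree`, `snp_panel` (haplotypes of members with SNP
#'   data), `kir_table` (rows for members with KIR data), `founder_truth`
#'   (per founder haplotype) and `truth` (all haplotypes).
#' @export
simulate_families <- function(spec, n_families, n_children = 2L,
                              missing_kir = 0, missing_snp = 0) {
  stopifnot(inherits(spec, "kir_sim_spec"), n_families >= 1L,
            n_children >= 1L)
  platform <- .sim_platform(spec)
  .with_seed(spec$seed + 2L, {
    fam_ids <- paste0("fam", sprintf("%03d", seq_len(n_families)))
    fathers <- paste0(fam_ids, "_F")
    mothers <- paste0(fam_ids, "_M")
    founder_ids <- as.vector(rbind(paste0(fathers, "_1"), paste0(fathers, "_2"),
                                   paste0(mothers, "_1"), paste0(mothers, "_2")))
    founders <- .sim_haps(spec, platform, length(founder_ids), founder_ids)

    ped <- data.frame(family_id = rep(fam_ids, each = 2L + n_children),
                      person_id = as.vector(vapply(seq_len(n_families),
                        function(i) c(fathers[i], mothers[i],
                                      paste0(fam_ids[i], "_C",
                                             seq_len(n_children))),
                        character(2L + n_children))),
                      father_id = NA_character_, mother_id = NA_character_,
                      stringsAsFactors = FALSE)
    is_child <- grepl("_C[0-9]+$", ped$person_id)
    ped$father_id[is_child] <- fathers[match(ped$family_id[is_child], fam_ids)]
    ped$mother_id[is_child] <- mothers[match(ped$family_id[is_child], fam_ids)]

    p <- sum(spec$n_snps)
    child_rows <- list(); child_truth <- list(); child_ids <- character(0)
    for (i in seq_len(n_families)) {
      for (ch in seq_len(n_children)) {
        person <- paste0(fam_ids[i], "_C", ch)
        from_f <- paste0(fathers[i], "_", sample(1:2, 1L))
        from_m <- paste0(mothers[i], "_", sample(1:2, 1L))
        for (k in 1:2) {
          src <- c(from_f, from_m)[k]
          hid <- paste0(person, "_", k)
          a <- founders$alleles[src, ]
          err <- stats::runif(p) < spec$error_rate
          a[err] <- 1L - a[err]
          child_rows[[hid]] <- a
          tr <- founders$truth[founders$truth$hap_id == src, ]
          tr$hap_id <- hid
          child_truth[[hid]] <- tr
          child_ids <- c(child_ids, hid)
        }
      }
    }
    alleles <- rbind(founders$alleles, do.call(rbind, child_rows))
    truth <- rbind(founders$truth, do.call(rbind, child_truth))
    rownames(truth) <- truth$hap_id

    persons <- ped$person_id
    kir_miss <- setNames(stats::runif(length(persons)) < missing_kir, persons)
    snp_miss <- setNames(stats::runif(length(persons)) < missing_snp, persons)
    hap_person <- sub("_[12]$", "", rownames(alleles))
    snp_keep <- !snp_miss[hap_person]
    kir_keep <- !kir_miss[hap_person]

    snp_panel <- haplotype_panel(platform$snps,
                                 alleles[snp_keep, , drop = FALSE],
                                 rownames(alleles)[snp_keep])
    kir_table <- .truth_kir_table(truth[kir_keep, , drop = FALSE])
    list(pedigree = ped, snp_panel = snp_panel, kir_table = kir_table,
         founder_truth = founders$truth, truth = truth)
  })
}

#' Simulate an unphased validation cohort
#'
#' Emulates an independent validation panel: phased SNP haplotypes are
#' available, but KIR types are only measured as per-individual total copy
#' numbers (no haplotype-level labels).
#'
#' @param spec A [kir_sim_spec()].
#' @param n_individuals Number of diploid individuals.
#' @return List with `panel` (a [haplotype_panel()] of `2 * n_individuals`
#'   haplotypes named `<ind>_1`/`<ind>_2`), `kir_individuals` (per-individual
#'   totals over the 17 copy loci, unit `"individual"`), and `truth`
#'   (hidden per-haplotype truth).
#' @export
simulate_validation_cohort <- function(spec, n_individuals) {
  stopifnot(inherits(spec, "kir_sim_spec"), n_individuals >= 1L)
  platform <- .sim_platform(spec)
  .with_seed(spec$seed + 3L, {
    ind <- paste0("ind", sprintf("%05d", seq_len(n_individuals)))
    hap_ids <- as.vector(rbind(paste0(ind, "_1"), paste0(ind, "_2")))
    sim <- .sim_haps(spec, platform, length(hap_ids), hap_ids)
    panel <- haplotype_panel(platform$snps, sim$alleles, hap_ids)
    loci <- kir_loci("copy")
    tot <- sim$truth[seq(1L, length(hap_ids), 2L), loci, drop = FALSE] +
           sim$truth[seq(2L, length(hap_ids), 2L), loci, drop = FALSE]
    tot[] <- lapply(tot, as.character)
    rownames(tot) <- ind
    kir_individuals <- kir_type_table(tot, unit = "individual")
    list(panel = panel, kir_individuals = kir_individuals, truth = sim$truth)
  })
}
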