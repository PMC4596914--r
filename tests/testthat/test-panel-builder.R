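test_that("KIR-based parent-of-origin assignment requires an exact match", {
  loci <- c("KIR2DS2", "KIR2DL2", "KIR2DL3")
  child <- setNames(c("1", "1", "0"), loci)
  fa <- rbind(setNames(c("1", "1", "0"), loci),
              setNames(c("0", "0", "1"), loci))
  mo <- rbind(setNames(c("0", "0", "1"), loci),
              setNames(c("0", "1", "1"), loci))
  expect_equal(match_by_kir(child, fa, mo)$origin, "paternal")
  # matching one haplotype of each parent is ambiguous
  mo2 <- rbind(setNames(c("1", "1", "0"), loci), mo[1L, , drop = TRUE])
  expect_equal(match_by_kir(child, fa, mo2)$origin, "ambiguous")
  # a single-locus mismatch everywhere leaves the haplotype unassigned
  child2 <- setNames(c("1", "1", "1"), loci)
  expect_equal(match_by_kir(child2, fa, mo)$origin, "unassigned")
  bad <- rbind(setNames(c("1", "1"), loci[1:2]))
  expect_error(match_by_kir(child, bad, NULL), "locus sets differ")
})

test_that("SNP-based matching uses a strict fewer-than-20-mismatch rule", {
  p <- 60L
  base <- rep(0L, p)
  flip <- function(h, k) { h[seq_len(k)] <- 1L - h[seq_len(k)]; h }
  fa <- rbind(flip(base, 19L), flip(base, 40L))
  mo <- rbind(flip(base, 30L), flip(base, 50L))
  expect_equal(match_by_snp(base, fa, mo)$origin, "paternal")     # 19 < 20
  fa20 <- rbind(flip(base, 20L), flip(base, 40L))
  expect_equal(match_by_snp(base, fa20, mo)$origin, "unassigned") # 20 is out
  expect_equal(match_by_snp(base, rbind(base), NULL)$origin, "paternal")
  # both haplotypes of one parent within range: assigned to that side,
  # flagged as within-parent ambiguous
  fa2 <- rbind(flip(base, 3L), flip(base, 5L))
  m <- match_by_snp(base, fa2, mo)
  expect_equal(m$origin, "paternal")
  expect_true(m$within_parent_ambiguous)
  expect_error(match_by_snp(base[1:10], fa, mo), "lengths differ")
})

test_that("merging evidence keeps agreement and excludes conflict", {
  expect_equal(merge_assignments("paternal", "paternal"),
               list(origin = "paternal", evidence = "both"))
  expect_equal(merge_assignments("paternal", "maternal"),
               list(origin = "ambiguous", evidence = "conflict"))
  expect_equal(merge_assignments("paternal", "unassigned"),
               list(origin = "paternal", evidence = "kir"))
  expect_equal(merge_assignments("unassigned", "maternal"),
               list(origin = "maternal", evidence = "snp"))
  expect_equal(merge_assignments("ambiguous", "paternal")$evidence,
               "conflict")
  expect_equal(merge_assignments("unassigned", "unassigned")$evidence,
               "none")
})

test_that("within-family pruning keeps parents and deduplicated novel offspring haplotypes", {
  # both parents typed: only the four parental haplotypes survive
  fam <- list(father_haps = c("F_1", "F_2"), mother_haps = c("M_1", "M_2"),
              offspring = data.frame(haplotype_id = c("C1_1", "C1_2"),
                                     origin = c("paternal", "maternal"),
                                     evidence = "both"),
              hap_key = c(C1_1 = "x", C1_2 = "y"))
  expect_setequal(select_unrelated(fam), c("F_1", "F_2", "M_1", "M_2"))

  # one parent typed; two children carry the same unobserved paternal
  # haplotype, which is kept exactly once
  fam2 <- list(father_haps = NULL, mother_haps = c("M_1", "M_2"),
               offspring = data.frame(
                 haplotype_id = c("C1_1", "C1_2", "C2_1", "C2_2"),
                 origin = c("maternal", "unassigned", "maternal",
                            "unassigned"),
                 evidence = c("both", "none", "both", "none")),
               hap_key = c(C1_1 = "m1", C1_2 = "pat", C2_1 = "m2",
                           C2_2 = "pat"))
  kept <- select_unrelated(fam2)
  expect_equal(length(kept), 3L)
  expect_true(sum(kept %in% c("C1_2", "C2_2")) == 1L)

  # no typed members at all
  expect_equal(length(select_unrelated(list(father_haps = NULL,
                                            mother_haps = NULL,
                                            offspring = NULL))), 0L)
})

test_that("fully typed trios contribute exactly their parental haplotypes", {
  spec <- kir_sim_spec(n_haplotypes = 10L, n_snps = c(12L, 12L), tagging = 1,
                       error_rate = 0, seed = 33)
  fam <- simulate_families(spec, n_families = 2L, n_children = 1L)
  built <- build_reference_panel(fam$pedigree, fam$snp_panel, fam$kir_table)
  expect_equal(length(built$kept), 8L)
  expect_setequal(built$kept, fam$founder_truth$hap_id)
})

test_that("panel construction recovers the founder haplotype multiset", {
  spec <- kir_sim_spec(n_haplotypes = 10L, n_snps = c(15L, 15L), tagging = 1,
                       error_rate = 0, seed = 44)
  fam <- simulate_families(spec, n_families = 12L, n_children = 3L)
  built <- build_reference_panel(fam$pedigree, fam$snp_panel, fam$kir_table)
  key <- function(panel, ids) {
    apply(panel$alleles[ids, , drop = FALSE], 1L, paste, collapse = "")
  }
  founder_keys <- sort(key(fam$snp_panel, fam$founder_truth$hap_id))
  built_keys <- sort(key(built$panel, built$kept))
  expect_identical(built_keys, founder_keys)
})

test_that("haplotypes with partial data are used for matching but excluded from the panel", {
  spec <- kir_sim_spec(n_haplotypes = 10L, n_snps = c(10L, 10L), tagging = 1,
                       error_rate = 0, seed = 55)
  fam <- simulate_families(spec, n_families = 4L, n_children = 2L,
                           missing_snp = 0.4)
  built <- build_reference_panel(fam$pedigree, fam$snp_panel, fam$kir_table)
  expect_true(all(built$kept %in% fam$snp_panel$haplotype_ids))
  dropped <- built$log[built$log$detail == "incomplete_data", ]
  missing_snp_haps <- setdiff(rownames(fam$kir_table),
                              fam$snp_panel$haplotype_ids)
  if (length(missing_snp_haps))
    expect_true(any(dropped$haplotype_id %in% missing_snp_haps))
})

test_that("pseudo-individual pairing is disjoint, exhaustive and seeded", {
  ids <- paste0("h", 1:479)
  pairs <- pair_pseudo_individuals(ids, seed = 3)
  expect_equal(nrow(pairs), 239L)
  used <- c(pairs)
  expect_equal(anyDuplicated(used), 0L)
  expect_equal(length(setdiff(ids, used)), 1L)

  four <- pair_pseudo_individuals(paste0("h", 1:4), seed = 1)
  expect_setequal(c(four), paste0("h", 1:4))

  expect_identical(pair_pseudo_individuals(ids, seed = 9),
                   pair_pseudo_individuals(ids, seed = 9))
  expect_error(pair_pseudo_individuals("h1"), "at least 2")
})
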