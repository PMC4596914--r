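test_that("haps/sample files parse and round-trip byte-identically", {
  haps <- tempfile(fileext = ".haps")
  samp <- tempfile(fileext = ".sample")
  writeLines(c("19 rsA 55200000 A G 0 1 1 0",
               "19 rsB 55200500 C T 1 1 0 ?"), haps)
  writeLines(c("ID_1 ID_2 missing", "0 0 0", "S1 S1 0", "S2 S2 0"), samp)

  panel <- read_haps(haps, samp)
  expect_equal(length(panel$haplotype_ids), 4L)
  expect_equal(nrow(panel$snps), 2L)
  expect_equal(panel$haplotype_ids, c("S1_1", "S1_2", "S2_1", "S2_2"))
  expect_equal(unname(panel$alleles[, 1L]), c(0L, 1L, 1L, 0L))
  expect_true(is.na(panel$alleles[4L, 2L]))

  haps2 <- tempfile(); samp2 <- tempfile()
  write_haps(panel, haps2, samp2)
  panel2 <- read_haps(haps2, samp2)
  expect_identical(panel2$alleles, panel$alleles)
  expect_identical(panel2$snps$position, panel$snps$position)
  expect_identical(readLines(haps2), readLines(haps))
})

test_that("malformed haps input fails with an informative error", {
  samp <- tempfile(); writeLines(c("S1", "S2"), samp)
  bad_width <- tempfile()
  writeLines(c("19 rsA 55200000 A G 0 1 1 0",
               "19 rsB 55200500 C T 1 1 0"), bad_width)
  expect_error(read_haps(bad_width, samp), "line 2")

  bad_tok <- tempfile()
  writeLines("19 rsA 55200000 A G 0 2 1 0", bad_tok)
  expect_error(read_haps(bad_tok, samp), "'2'")

  dup_id <- tempfile()
  writeLines(c("19 rsA 55200000 A G 0 1 1 0",
               "19 rsA 55200500 C T 1 1 0 0"), dup_id)
  expect_error(read_haps(dup_id, samp), "rsA")
})

test_that("phased VCF reading matches the haps reader on the same data", {
  vcf <- tempfile(fileext = ".vcf")
  write_tiny_vcf(vcf, c(
    "19\t55200000\trsA\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|0",
    "19\t55200500\trsB\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0",
    "19\t55200700\trsC\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|0",
    "19\t55200900\trsD\tA\tG\t.\tPASS\t.\tGT\t0|0\t1|1"),
    c("S1", "S2"))
  expect_message(panel <- read_vcf_phased(vcf), "skipped 1")
  expect_equal(attr(panel, "n_skipped"), 1L)
  expect_equal(nrow(panel$snps), 3L)
  expect_equal(length(panel$haplotype_ids), 4L)

  haps <- tempfile(); samp <- tempfile()
  writeLines(c("19 rsA 55200000 A G 0 1 1 0",
               "19 rsB 55200500 C T 1 1 0 0",
               "19 rsD 55200900 A G 0 0 1 1"), haps)
  writeLines(c("S1", "S2"), samp)
  ref <- read_haps(haps, samp)
  expect_equal(unname(panel$alleles), unname(ref$alleles))
  expect_equal(panel$snps$position, ref$snps$position)

  empty <- tempfile(fileext = ".vcf")
  write_tiny_vcf(empty, "19\t1\tx\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/1",
                 c("S1", "S2"))
  expect_error(suppressMessages(read_vcf_phased(empty)), "no phased")
})

test_that("KIR type tables validate content and unit semantics", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tKIR2DS2\tKIR2DL2\tKIR2DS4DEL",
               "h1\t0\t1\t2", "h2\t1\t\t0"), f)
  tab <- read_kir_types(f, unit = "haplotype")
  expect_equal(attr(tab, "unit"), "haplotype")
  expect_true(is.na(tab["h2", "KIR2DL2"]))
  expect_equal(tab["h1", "KIR2DS4DEL"], "2")

  g <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tKIR2DS2\tKIRhaplotype", "i1\t2\tcA01-tA01"), g)
  expect_error(read_kir_types(g, unit = "individual"),
               "haplotype level")
  expect_silent(read_kir_types(g, unit = "haplotype"))

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tKIR2DS2", "h1\t-1"), neg)
  expect_error(read_kir_types(neg, unit = "haplotype"), "non-negative")

  ab <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tAvsB", "h1\tC"), ab)
  expect_error(read_kir_types(ab, unit = "haplotype"), "A or B")

  extra <- tempfile(fileext = ".tsv")
  writeLines(c("unit_id\tNOTALOCUS", "h1\tx"), extra)
  expect_error(read_kir_types(extra, unit = "haplotype"), "NOTALOCUS")
  expect_silent(read_kir_types(extra, unit = "haplotype", allow_extra = TRUE))
})

test_that("allele alignment recodes swapped, flipped and ambiguous SNPs", {
  ref <- make_panel(rbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L),
                          c(0L, 1L, 0L), c(0L, 1L, 0L), c(0L, 0L, 0L),
                          c(1L, 1L, 0L), c(0L, 1L, 0L), c(0L, 1L, 1L),
                          c(1L, 1L, 0L)),
                    positions = c(100L, 200L, 300L),
                    allele1 = c("A", "A", "A"), allele2 = c("G", "G", "T"))
  # query SNP1: same pair, swapped order (bits inverted); SNP2: complementary
  # strand (T/C vs A/G), coding already matched; SNP3: ambiguous A/T pair
  # whose frequencies resolve to the inverted orientation
  qry <- make_panel(rbind(c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L),
                          c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 0L, 1L),
                          c(0L, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 0L),
                          c(0L, 1L, 1L)),
                    positions = c(100L, 200L, 300L),
                    allele1 = c("G", "T", "A"), allele2 = c("A", "C", "T"))
  al <- align_alleles(ref, qry, freq_tol = 0.2)
  expect_equal(al$report$action,
               c("swapped_coding", "strand_flipped", "strand_flipped"))
  # after alignment every SNP's bits agree with the reference coding
  expect_identical(unname(al$panel$alleles), unname(ref$alleles))
  expect_identical(al$panel$snps$allele1, ref$snps$allele1)
  expect_true(all(al$report$freq_diff < 1e-9))
})

test_that("ambiguous-pair SNPs with undecidable frequencies are dropped", {
  ref <- make_panel(matrix(rep(c(0L, 1L), 5L), ncol = 1L),
                    positions = 100L, allele1 = "A", allele2 = "T")
  qry <- make_panel(matrix(rep(c(0L, 1L), 5L), ncol = 1L),
                    positions = 100L, allele1 = "A", allele2 = "T")
  # both orientations match a 0.5/0.5 frequency -> cannot decide
  al <- align_alleles(ref, qry, freq_tol = 0.1)
  expect_equal(al$report$action, "dropped_ambiguous")
  expect_equal(nrow(al$panel$snps), 0L)
})

test_that("alignment drops absent positions, errors on no overlap, and is idempotent", {
  set.seed(1)
  ref <- make_panel(matrix(rbinom(40L, 1L, 0.4), ncol = 4L),
                    positions = c(100L, 200L, 300L, 400L),
                    allele1 = c("A", "C", "A", "A"),
                    allele2 = c("G", "T", "C", "G"))
  qry <- ref
  qry$snps$snp_id <- paste0("q", 1:4)
  qry <- haplotype_panel(qry$snps[c(1L, 2L, 4L), ],
                         qry$alleles[, c(1L, 2L, 4L)], qry$haplotype_ids)
  extra <- make_panel(matrix(rbinom(10L, 1L, 0.5), ncol = 1L),
                      positions = 999L, allele1 = "A", allele2 = "G")
  qry2 <- haplotype_panel(rbind(qry$snps, extra$snps),
                          cbind(qry$alleles, extra$alleles),
                          qry$haplotype_ids)
  al <- align_alleles(ref, qry2)
  expect_equal(al$report$action[al$report$position == 999L], "dropped_absent")
  expect_equal(sum(al$report$action == "kept_as_is"), 3L)

  # idempotence: aligning the aligned panel keeps everything as is
  al2 <- align_alleles(ref, al$panel)
  expect_true(all(al2$report$action == "kept_as_is"))
  expect_identical(al2$panel$alleles, al$panel$alleles)

  off <- make_panel(matrix(0:1, ncol = 1L), positions = 555L)
  expect_error(align_alleles(ref, off), "no SNP positions")
})

test_that("region filtering is a closed-interval, idempotent restriction", {
  panel <- make_panel(matrix(rep(0:1, 3L), ncol = 3L),
                      positions = c(53000000L, 55245738L, 55600000L))
  win <- filter_by_region(panel, 55.1e6, 55.5e6)
  expect_equal(win$snps$position, 55245738L)
  ext <- filter_by_region(panel, 53.6e6, 60e6)
  expect_false(53000000L %in% ext$snps$position)
  all_in <- filter_by_region(panel, 1, 60e6)
  expect_identical(all_in$alleles, panel$alleles)
  expect_identical(filter_by_region(win, 55.1e6, 55.5e6)$alleles, win$alleles)
})

test_that("monomorphic SNPs are removed, mirroring extended-region counts", {
  panel <- make_panel(cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L),
                            c(1L, 1L, 1L, 1L)))
  kept <- drop_monomorphic(panel)
  expect_equal(kept$snps$snp_id, "s2")

  # 1,118 extended-region SNPs of which exactly 40 are monomorphic -> 1,078
  set.seed(7)
  n <- 24L
  poly <- matrix(rbinom(n * 1078L, 1L, 0.5), nrow = n)
  poly[1L, ] <- 0L; poly[2L, ] <- 1L   # guarantee polymorphism
  mono <- matrix(rep(rep(0:1, length.out = 40L), each = n), nrow = n)
  big <- make_panel(cbind(poly, mono)[, sample(1118L)])
  expect_equal(nrow(drop_monomorphic(big)$snps), 1078L)

  allmono <- make_panel(matrix(0L, nrow = 4L, ncol = 2L))
  expect_error(drop_monomorphic(allmono), "monomorphic")
})

test_that("panel construction enforces its invariants", {
  expect_error(make_panel(matrix(2L, 2L, 1L)), "0, 1 or NA")
  expect_error(haplotype_panel(
    data.frame(snp_id = c("a", "b"), position = c(1L, 1L),
               allele1 = c("A", "A"), allele2 = c("G", "G")),
    matrix(0L, 2L, 2L), c("h1", "h2")), "duplicate SNP position")
  expect_error(make_panel(matrix(0L, 2L, 1L), allele1 = "A", allele2 = "A"),
               "must differ")
  # SNPs arrive unsorted and come back position-sorted
  p <- haplotype_panel(
    data.frame(snp_id = c("b", "a"), position = c(200L, 100L),
               allele1 = "A", allele2 = "G"),
    cbind(c(1L, 1L), c(0L, 0L)), c("h1", "h2"))
  expect_equal(p$snps$snp_id, c("a", "b"))
  expect_equal(unname(p$alleles[1L, ]), c(0L, 1L))
})
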