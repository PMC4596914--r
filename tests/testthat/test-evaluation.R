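test_that("credible intervals match the closed-form Beta posterior", {
  # 0/10 correct: posterior Beta(1, 11), CDF 1 - (1 - p)^11
  ci <- credible_interval(0, 10)
  expect_equal(ci[1L], 1 - 0.975^(1 / 11), tolerance = 1e-12)
  expect_equal(ci[2L], 1 - 0.025^(1 / 11), tolerance = 1e-12)
  expect_equal(round(ci, 4L), c(0.0023, 0.2849))

  # 10/10: mirror image under p -> 1 - p
  ci10 <- credible_interval(10, 10)
  expect_equal(ci10, 1 - rev(ci), tolerance = 1e-12)

  # 5/10: Beta(6, 6) is symmetric about one half
  ci5 <- credible_interval(5, 10)
  expect_equal(ci5[1L] + ci5[2L], 1, tolerance = 1e-12)

  expect_error(credible_interval(0, 0), "at least 1")
  expect_error(credible_interval(5, 4))
})

test_that("per-allele sensitivity and PPV follow the confusion-matrix definitions", {
  calls <- c(rep("a", 9L), rep("b", 3L))
  truth <- c(rep("a", 8L), "b", rep("a", 2L), "b")
  # allele a: TP = 8, FN = 2, FP = 1
  m <- per_allele_metrics(calls, truth)
  a <- m[m$allele == "a", ]
  expect_equal(a$sensitivity, 0.8)
  expect_equal(a$ppv, 8 / 9)
  expect_equal(a$count_in_panel, 10L)

  perfect <- per_allele_metrics(truth, truth)
  expect_true(all(perfect$sensitivity == 1))
  expect_true(all(perfect$ppv == 1))

  # allele never imputed: sensitivity 0, PPV undefined
  m2 <- per_allele_metrics(rep("a", 4L), c("a", "a", "a", "c"))
  cc <- m2[m2$allele == "c", ]
  expect_equal(cc$sensitivity, 0)
  expect_false(cc$ppv_defined)
  expect_true(is.na(cc$ppv))

  # tally identities: both weighted sums recover the total correct count
  set.seed(2)
  calls3 <- sample(letters[1:4], 200L, replace = TRUE)
  truth3 <- ifelse(runif(200L) < 0.7, calls3,
                   sample(letters[1:4], 200L, replace = TRUE))
  m3 <- per_allele_metrics(calls3, truth3)
  total_correct <- sum(calls3 == truth3)
  expect_equal(sum(m3$count_in_panel * m3$sensitivity, na.rm = TRUE),
               total_correct)
  expect_equal(sum(m3$count_called * m3$ppv, na.rm = TRUE), total_correct)
})

test_that("cross-validation pools fold predictions and tallies accuracy exactly", {
  spec <- kir_sim_spec(n_haplotypes = 90L, n_snps = c(10L, 10L), tagging = 1,
                       error_rate = 0, seed = 61)
  sim <- simulate_panel(spec)
  cv <- cross_validate(sim$panel, loci = c("KIR2DS2", "AvsB"), k = 5L,
                       ntree = 60L, seed = 9)
  # perfect tagging: every locus imputes perfectly
  expect_true(all(cv$accuracy$accuracy == 1))

  # tally oracle: recompute accuracy from the pooled per-haplotype calls
  for (lc in c("KIR2DS2", "AvsB")) {
    acc <- mean(cv$results[[lc]]$map_call == as.character(cv$truth[[lc]]))
    expect_equal(cv$accuracy$accuracy[cv$accuracy$locus == lc], acc)
  }
  expect_true(all(table(cv$folds) %in% c(18L)))

  cv2 <- cross_validate(sim$panel, loci = c("KIR2DS2", "AvsB"), k = 5L,
                        ntree = 60L, seed = 9)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$results$AvsB$prob, cv2$results$AvsB$prob)
})

test_that("each fold's predictions equal a manually refitted model's predictions", {
  spec <- kir_sim_spec(n_haplotypes = 45L, n_snps = c(8L, 8L),
                       tagging = 0.95, seed = 71)
  sim <- simulate_panel(spec)
  loci <- c("KIR2DS2", "KIR2DL3")
  cv <- cross_validate(sim$panel, loci = loci, k = 3L, ntree = 40L, seed = 5)
  test1 <- cv$folds == 1L
  refit <- suppressWarnings(
    kir_imputer(sim$panel[!test1, ], loci = loci, ntree = 40L,
                seed = 5L + 1L * length(loci)))
  manual <- predict(refit, sim$panel[test1, ])
  expect_identical(unname(cv$results$KIR2DS2$prob[test1,
                     colnames(manual$KIR2DS2$prob), drop = FALSE]),
                   unname(manual$KIR2DS2$prob))
})

test_that("calibration bins partition the observed MAP range", {
  # degenerate range: one bin, accuracy 1
  cal <- calibration(rep(1, 20L), rep(TRUE, 20L))
  expect_equal(nrow(cal), 1L)
  expect_equal(cal$observed_accuracy, 1)
  expect_equal(cal$n, 20L)

  set.seed(4)
  mp <- runif(300L, 0.3, 1)
  ok <- runif(300L) < mp
  cal2 <- calibration(mp, ok, n_bins = 10L)
  expect_equal(nrow(cal2), 10L)
  expect_equal(sum(cal2$n), 300L)
  expect_equal(cal2$bin_low[1L], min(mp))
  expect_equal(cal2$bin_high[10L], max(mp))
  # bins of a well-calibrated source mostly cover their mean MAP
  expect_gte(mean(cal2$calibrated[cal2$n > 0L]), 0.7)
})

test_that("accuracy against call rate composes thresholding with tallying", {
  spec <- kir_sim_spec(n_haplotypes = 100L, n_snps = c(8L, 8L),
                       tagging = 0.9, error_rate = 0.01, seed = 81)
  sim <- simulate_panel(spec)
  fit <- kir_imputer(sim$panel, loci = "KIR2DS2", ntree = 80L, seed = 2)
  res <- predict(fit, sim$panel)$KIR2DS2
  truth <- as.character(sim$panel$kir$KIR2DS2)
  thresholds <- seq(0, 1, by = 0.1)
  curve <- accuracy_vs_callrate(res, truth, thresholds)

  expect_equal(curve$call_rate[1L], 1)
  expect_equal(curve$accuracy[1L], mean(res$map_call == truth))
  expect_true(all(diff(curve$call_rate) <= 0))

  # composition oracle
  for (i in c(3L, 6L, 9L)) {
    thr <- apply_threshold(res, thresholds[i])
    expect_equal(curve$call_rate[i], thr$call_rate)
    if (any(thr$called))
      expect_equal(curve$accuracy[i],
                   mean(thr$calls[thr$called] == truth[thr$called]))
  }
})

test_that("expected per-individual accuracy matches exhaustive pairing enumeration", {
  expect_equal(expected_individual_accuracy(c(1L, 0L, 2L, 1L),
                                            c(1L, 0L, 2L, 1L)), 1)
  # one haplotype off by +1: the single pair always sums wrong
  expect_equal(expected_individual_accuracy(c(1L, 1L), c(1L, 0L)), 0)

  # N = 4 with errors (+1, -1, 0, 0): enumerate the 3 perfect matchings:
  # {12|34}: pair1 ok (+1-1), pair2 ok -> 1; {13|24}: 0.0; {14|23}: 0.0
  calls <- c(2L, 0L, 1L, 1L); truth <- c(1L, 1L, 1L, 1L)
  exact <- mean(c(1, 0, 0))
  est <- expected_individual_accuracy(calls, truth, n_pairings = 4000L,
                                      seed = 2)
  expect_lt(abs(est - exact), 0.03)
  expect_error(expected_individual_accuracy(1L, 1L), "at least 2")
})

test_that("leave-one-out cross-validation equals a brute-force loop on a tiny panel", {
  spec <- kir_sim_spec(n_haplotypes = 12L, n_snps = c(5L, 5L), tagging = 1,
                       error_rate = 0, seed = 91)
  sim <- simulate_panel(spec)
  cv <- cross_validate(sim$panel, loci = "AvsB", k = 12L, ntree = 25L,
                       seed = 3)
  # brute force: for each haplotype, train on the others and impute it
  for (i in c(1L, 5L, 12L)) {
    fold <- cv$folds[i]
    fit <- suppressWarnings(
      kir_imputer(sim$panel[cv$folds != fold, ], loci = "AvsB", ntree = 25L,
                  seed = 3L + fold * 1L))
    pr <- predict(fit, sim$panel[cv$folds == fold, ])$AvsB
    expect_equal(unname(cv$results$AvsB$map_call[i]),
                 unname(pr$map_call[which(which(cv$folds == fold) == i)]))
  }
  # at leave-one-out scale a held-out haplotype can carry a class absent
  # from its training fold, so perfect accuracy is not asserted here
  expect_equal(cv$accuracy$n, 12L)
})

test_that("the 95% interval covers the true proportion at the nominal rate", {
  set.seed(12)
  draws <- rbinom(1000L, 100L, 0.9)
  covered <- vapply(draws, function(k) {
    ci <- credible_interval(k, 100L)
    ci[1L] <= 0.9 && 0.9 <= ci[2L]
  }, logical(1L))
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
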