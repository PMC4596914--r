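#' Beta-posterior credible interval for an accuracy proportion
#'
#' Equal-tailed 95% (by default) credible interval under a binomial model
#' with a uniform prior, i.e. quantiles of the Beta(`n_correct` + 1,
#' `n` - `n_correct` + 1) posterior.  The binomial independence assumption is
#' only approximate under cross-validation (training folds overlap), so
#' cross-validation intervals should be read as approximate.
#'
#' @param n_correct Number of correct imputations, `0 <= n_correct <= n`.
#' @param n Number of imputations, `n >= 1`.
#' @param level Credibility level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
#' @examples
#' credible_interval(95, 100)
credible_interval <- function(n_correct, n, level = 0.95) {
  if (n < 1L) stop("n must be at least 1")
  stopifnot(n_correct >= 0, n_correct <= n, level > 0, level < 1)
  alpha <- (1 - level) / 2
  c(qbeta(alpha, n_correct + 1, n - n_correct + 1),
    qbeta(1 - alpha, n_correct + 1, n - n_correct + 1))
}

#' k-fold cross-validated imputation accuracy
#'
#' Haplotypes are partitioned into `k` near-equal folds by a seeded shuffle;
#' each fold is imputed with a model trained on the remaining folds, and
#' accuracy per locus is the fraction of haplotypes whose MAP call matches
#' the truth, pooled over folds.  A fold losing every instance of a rare
#' class is tolerated (that class is simply absent from the training fold).
#'
#' @param panel A [reference_panel()].
#' @param loci Loci to assess (default all in the panel).
#' @param k Number of folds (default 5).
#' @param ntree,mtry,max_nodes Forest parameters, as in [kir_imputer()].
#' @param seed Seed controlling both fold assignment and model fits.
#' @return List of class `kir_cv` with `accuracy` (per-locus data frame with
#'   credible intervals), `results` (per-locus pooled `kir_imputation` over
#'   all haplotypes, in panel order), `truth`, and `folds`.
#' @export
cross_validate <- function(panel, loci = NULL, k = 5L, ntree = 1000L,
                           mtry = NULL, max_nodes = NULL, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"), k >= 2L)
  if (is.null(loci)) loci <- names(panel$kir)
  n <- length(panel$haplotype_ids)
  if (k > n) stop("k exceeds the number of haplotypes")

  folds <- local({
    r <- .seeded_sample(seq_len(n), n, seed)
    f <- integer(n)
    f[r] <- rep_len(seq_len(k), n)
    f
  })

  prob_acc <- setNames(vector("list", length(loci)), loci)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- suppressWarnings(
      kir_imputer(panel[!test, ], loci = loci, ntree = ntree, mtry = mtry,
                  max_nodes = max_nodes,
                  seed = as.integer(seed) + fold * length(loci)))
    res <- predict(fit, panel[test, ])
    for (lc in loci) prob_acc[[lc]][[fold]] <- res[[lc]]$prob
  }

  results <- lapply(loci, function(lc) {
    classes <- sort(unique(unlist(lapply(prob_acc[[lc]], colnames))))
    prob <- matrix(0, nrow = n, ncol = length(classes),
                   dimnames = list(panel$haplotype_ids, classes))
    for (fold in seq_len(k)) {
      p <- prob_acc[[lc]][[fold]]
      prob[folds == fold, colnames(p)] <- p
    }
    .imputation_result(prob, lc)
  })
  names(results) <- loci

  truth <- panel$kir[, loci, drop = FALSE]
  accuracy <- do.call(rbind, lapply(loci, function(lc) {
    correct <- results[[lc]]$map_call == as.character(truth[[lc]])
    ci <- credible_interval(sum(correct), n)
    data.frame(locus = lc, unit = "haplotype", n = n,
               n_correct = sum(correct), accuracy = mean(correct),
               ci_low = ci[1L], ci_high = ci[2L], stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = accuracy, results = results, truth = truth,
                 folds = folds, k = k, seed = seed),
            class = "kir_cv")
}

#' @export
#' @method print kir_cv
print.kir_cv <- function(x, digits = 3L, ...) {
  cat(x$k, "-fold cross-validation over ", nrow(x$truth), " haplotypes\n",
      sep = "")
  y <- x$accuracy
  y$accuracy <- round(y$accuracy, digits)
  y$ci_low <- round(y$ci_low, digits)
  y$ci_high <- round(y$ci_high, digits)
  print(y[, c("locus", "n", "accuracy", "ci_low", "ci_high")],
        row.names = FALSE)
  invisible(x)
}

#' Per-allele sensitivity and positive predictive value
#'
#' For every type allele at a locus: sensitivity is the proportion of
#' correctly imputed types among all haplotypes truly carrying that allele;
#' PPV is the proportion correct among all haplotypes imputed with that
#' allele.  An allele never imputed has undefined PPV (`NA` with
#' `ppv_defined = FALSE`); an allele absent from the truth has undefined
#' sensitivity.
#'
#' @param calls Character vector of imputed types (`NA` allowed; such units
#'   are excluded).
#' @param truth Character vector of true types, same length.
#' @return Data frame with `allele`, `count_in_panel`, `count_called`,
#'   `sensitivity`, `ppv` and the corresponding `*_defined` flags.
#' @export
per_allele_metrics <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  keep <- !is.na(calls) & !is.na(truth)
  calls <- as.character(calls)[keep]
  truth <- as.character(truth)[keep]
  alleles <- sort(unique(c(calls, truth)))
  out <- lapply(alleles, function(a) {
    n_true <- sum(truth == a)
    n_call <- sum(calls == a)
    tp <- sum(calls == a & truth == a)
    data.frame(allele = a, count_in_panel = n_true, count_called = n_call,
               sensitivity = if (n_true > 0) tp / n_true else NA_real_,
               sens_defined = n_true > 0,
               ppv = if (n_call > 0) tp / n_call else NA_real_,
               ppv_defined = n_call > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Calibration of imputation probabilities
#'
#' Groups imputations by their MAP probability into `n_bins` equal-width bins
#' spanning the observed MAP range, and compares each bin's observed accuracy
#' (with a Beta-posterior credible interval) against its mean MAP.  Perfectly
#' calibrated probabilities put the mean MAP inside the interval.
#'
#' @param map_prob Numeric vector of MAP probabilities.
#' @param correct Logical vector: was the MAP call correct?
#' @param n_bins Number of bins (default 10).
#' @param level Credible level for the per-bin intervals.
#' @return Data frame of class `kir_calibration`: per bin, `bin`, `bin_low`,
#'   `bin_high`, `n`, `mean_map`, `observed_accuracy`, `ci_low`, `ci_high`,
#'   `calibrated` (mean MAP within the interval).  Empty bins keep `n = 0`.
#' @export
calibration <- function(map_prob, correct, n_bins = 10L, level = 0.95) {
  stopifnot(length(map_prob) == length(correct), length(map_prob) >= 1L)
  rng <- range(map_prob)
  if (rng[1L] == rng[2L]) {
    edges <- c(rng[1L], rng[2L])
    n_bins <- 1L
  } else edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- pmin(findInterval(map_prob, edges, rightmost.closed = TRUE), n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(bin = b, bin_low = edges[b], bin_high = edges[b + 1L],
                        n = 0L, mean_map = NA_real_,
                        observed_accuracy = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, calibrated = NA))
    ci <- credible_interval(sum(correct[sel]), n, level)
    mm <- mean(map_prob[sel])
    data.frame(bin = b, bin_low = edges[b], bin_high = edges[b + 1L], n = n,
               mean_map = mm, observed_accuracy = mean(correct[sel]),
               ci_low = ci[1L], ci_high = ci[2L],
               calibrated = mm >= ci[1L] && mm <= ci[2L])
  })
  out <- do.call(rbind, out)
  class(out) <- c("kir_calibration", "data.frame")
  out
}

#' @export
#' @method plot kir_calibration
plot.kir_calibration <- function(x, ...) {
  occ <- x[x$n > 0L, ]
  plot(occ$mean_map, occ$observed_accuracy, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Mean MAP probability", ylab = "Observed accuracy",
       pch = 19, ...)
  graphics::segments(occ$mean_map, occ$ci_low, occ$mean_map, occ$ci_high)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Accuracy against call rate over probability thresholds
#'
#' For each threshold, calls are restricted to imputations whose MAP
#' probability meets it; the call rate and the accuracy over called units are
#' reported.  Call rate is non-increasing in the threshold.
#'
#' @param result A `kir_imputation` for one locus.
#' @param truth True labels aligned with the result's units.
#' @param thresholds Numeric thresholds in \[0, 1\].
#' @return Data frame: `threshold`, `call_rate`, `n_called`, `accuracy`.
#' @export
accuracy_vs_callrate <- function(result, truth,
                                 thresholds = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(result, "kir_imputation"),
            all(thresholds >= 0 & thresholds <= 1))
  truth <- as.character(truth)
  out <- lapply(thresholds, function(t) {
    thr <- apply_threshold(result, t)
    called <- thr$called
    data.frame(threshold = t, call_rate = thr$call_rate,
               n_called = sum(called),
               accuracy = if (any(called))
                 mean(thr$calls[called] == truth[called]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Expected per-individual accuracy under random haplotype pairing
#'
#' Estimates the per-individual copy-number accuracy implied by per-haplotype
#' results: haplotypes are paired at random (without replacement, the odd one
#' discarded), a pair is correct when its summed calls equal its summed
#' truths, and the proportion correct is averaged over `n_pairings` seeded
#' random pairings.
#'
#' @param calls Integer (or coercible) per-haplotype copy-number calls.
#' @param truth Integer per-haplotype true copy numbers.
#' @param n_pairings Number of random pairings to average over (default 100).
#' @param seed Integer seed.
#' @return Single numeric estimate.
#' @export
expected_individual_accuracy <- function(calls, truth, n_pairings = 100L,
                                         seed = 1L) {
  stopifnot(length(calls) == length(truth))
  n <- length(calls)
  if (n < 2L) stop("need at least 2 haplotypes")
  calls <- as.integer(as.character(calls))
  truth <- as.integer(as.character(truth))
  err <- calls - truth
  n_even <- n - n %% 2L
  mean(vapply(seq_len(n_pairings), function(r) {
    ord <- .seeded_sample(seq_len(n), n, as.integer(seed) + r - 1L)
    a <- ord[seq(1L, n_even, by = 2L)]
    b <- ord[seq(2L, n_even, by = 2L)]
    mean(err[a] + err[b] == 0L)
  }, numeric(1L)))
}

# draw `size` elements from x without replacement, deterministically from an
# integer seed and independent of the caller's RNG state
.seeded_sample <- function(x, size, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample(x, size)
}
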