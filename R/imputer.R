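#' Fit a KIR imputation model
#'
#' The central fitting function: trains one classification-tree ensemble
#' ([kir_forest()]) per KIR locus on a reference panel of phased SNP
#' haplotypes with known KIR types.  Loci observed with a single class in the
#' panel (e.g. framework genes where nearly every haplotype carries one copy)
#' produce degenerate always-that-class models, with a warning.
#'
#' @param panel A [reference_panel()] with complete SNP alleles and KIR types.
#' @param loci Loci to fit (default: every column of the panel's KIR table).
#' @param ntree Trees per locus (default 1000).
#' @param mtry Attribute-subspace size; default per [default_mtry()].
#' @param max_nodes Optional per-tree node limit.
#' @param seed Integer seed; locus fits use `seed`, `seed + 1`, ... in locus
#'   order, so refits are identical.
#' @return An object of class `kir_imputer` holding the per-locus forests,
#'   the shared SNP definitions, and training metadata.
#' @export
#' @examples
#' spec <- kir_sim_spec(n_haplotypes = 80, n_snps = c(20, 20), seed = 7)
#' sim <- simulate_panel(spec)
#' fit <- kir_imputer(sim$panel, loci = c("KIR2DS2", "AvsB"), ntree = 50)
#' fit
kir_imputer <- function(panel, loci = NULL, ntree = 1000L, mtry = NULL,
                        max_nodes = NULL, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  if (is.null(loci)) loci <- names(panel$kir)
  absent <- setdiff(loci, names(panel$kir))
  if (length(absent))
    stop("locus absent from panel: ", paste(absent, collapse = ", "))
  X <- .check_X(panel$alleles)
  if (is.null(mtry)) mtry <- default_mtry(ncol(X))

  forests <- vector("list", length(loci))
  names(forests) <- loci
  for (k in seq_along(loci)) {
    y <- as.character(panel$kir[[loci[k]]])
    if (anyNA(y))
      stop("locus ", loci[k], " has missing KIR types; panel must be complete")
    if (length(unique(y)) == 1L)
      warning("locus ", loci[k], " has a single observed class ('", y[1L],
              "'); fitting a degenerate always-", y[1L], " model")
    forests[[k]] <- kir_forest(X, y, ntree = ntree, mtry = mtry,
                               max_nodes = max_nodes,
                               seed = as.integer(seed) + k - 1L)
  }
  structure(list(forests = forests, snps = panel$snps,
                 loci = loci,
                 training = list(n_haplotypes = nrow(X), n_snps = ncol(X),
                                 ntree = as.integer(ntree),
                                 mtry = as.integer(mtry),
                                 max_nodes = max_nodes,
                                 seed = as.integer(seed),
                                 date = format(Sys.Date()))),
            class = "kir_imputer")
}

#' @export
#' @method print kir_imputer
print.kir_imputer <- function(x, ...) {
  cat("KIR imputation model\n")
  cat("  ", length(x$loci), " loci: ", paste(head(x$loci, 6L), collapse = ", "),
      if (length(x$loci) > 6L) ", ..." else "", "\n", sep = "")
  cat("  trained on ", x$training$n_haplotypes, " haplotypes x ",
      x$training$n_snps, " SNPs (", x$training$ntree, " trees, mtry ",
      x$training$mtry, ", seed ", x$training$seed, ")\n", sep = "")
  invisible(x)
}

#' Summarise a KIR imputation model by out-of-bag accuracy
#'
#' @param object A [kir_imputer()].
#' @param panel The training [reference_panel()] (needed to recompute
#'   out-of-bag predictions).
#' @param ... Unused.
#' @return Data frame with per-locus OOB accuracy and Beta-posterior 95%
#'   credible intervals, of class `summary.kir_imputer`.
#' @export
summary.kir_imputer <- function(object, panel, ...) {
  stopifnot(inherits(panel, "reference_panel"))
  rows <- lapply(object$loci, function(lc) {
    fr <- object$forests[[lc]]
    ob <- oob_predict(fr, panel$alleles, panel$kir[[lc]])
    n <- sum(ob$covered)
    ncor <- round(ob$oob_accuracy * n)
    ci <- if (n > 0) credible_interval(ncor, n) else c(NA_real_, NA_real_)
    data.frame(locus = lc, n = n, oob_accuracy = ob$oob_accuracy,
               ci_low = ci[1L], ci_high = ci[2L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.kir_imputer", "data.frame")
  out
}

#' @export
#' @method print summary.kir_imputer
print.summary.kir_imputer <- function(x, digits = 3L, ...) {
  cat("Out-of-bag imputation accuracy by locus\n")
  y <- x
  class(y) <- "data.frame"
  y$oob_accuracy <- round(y$oob_accuracy, digits)
  y$ci_low <- round(y$ci_low, digits)
  y$ci_high <- round(y$ci_high, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

.imputation_result <- function(prob, locus) {
  map_idx <- max.col(prob, ties.method = "first")
  map_call <- colnames(prob)[map_idx]
  map_prob <- prob[cbind(seq_len(nrow(prob)), map_idx)]
  names(map_call) <- names(map_prob) <- rownames(prob)
  structure(list(locus = locus,
                 unit_ids = rownames(prob),
                 prob = prob,
                 map_call = map_call,
                 map_prob = map_prob),
            class = "kir_imputation")
}

#' @export
#' @method print kir_imputation
print.kir_imputation <- function(x, ...) {
  cat("KIR imputation for locus ", x$locus, ": ", length(x$map_call),
      " haplotypes, ", ncol(x$prob), " type alleles\n", sep = "")
  if (length(x$map_call))
    cat("  mean MAP probability ", round(mean(x$map_prob), 3L), "\n", sep = "")
  invisible(x)
}

#' Impute KIR types for new haplotypes
#'
#' Applies every per-locus ensemble to a panel of phased haplotypes, giving a
#' vote-fraction probability distribution over type alleles plus the MAP call
#' for each haplotype.  The panel must already be on the model's allele
#' coding: its SNP set must cover the model's SNPs with matching allele
#' labels (run [align_alleles()] against the training panel first when the
#' data come from another platform).
#'
#' @param object A [kir_imputer()].
#' @param panel A [haplotype_panel()] (or bare 0/1 matrix with SNP columns).
#' @param loci Subset of the model's loci (default all).
#' @param ... Unused.
#' @return Named list of `kir_imputation` objects, one per locus, each with
#'   `prob` (haplotype x allele), `map_call` and `map_prob`.
#' @export
predict.kir_imputer <- function(object, panel, loci = NULL, ...) {
  if (is.null(loci)) loci <- object$loci
  absent <- setdiff(loci, object$loci)
  if (length(absent))
    stop("model has no forest for locus: ", paste(absent, collapse = ", "))
  if (inherits(panel, "haplotype_panel")) {
    shared <- intersect(object$snps$snp_id, panel$snps$snp_id)
    if (length(shared) == length(object$snps$snp_id)) {
      idx <- match(shared, panel$snps$snp_id)
      mism <- panel$snps$allele1[idx] != object$snps$allele1[
               match(shared, object$snps$snp_id)]
      if (any(mism))
        stop("allele coding differs from the training panel for ",
             sum(mism), " SNP(s); run align_alleles() first")
    }
    X <- panel$alleles
  } else X <- panel
  out <- lapply(loci, function(lc) {
    prob <- predict(object$forests[[lc]], X, type = "prob")
    .imputation_result(prob, lc)
  })
  names(out) <- loci
  out
}

#' Threshold imputation calls
#'
#' Converts MAP imputations into thresholded calls: a call is retained iff
#' its MAP probability is at least `threshold`; the rest become missing.
#' Accuracy downstream is computed over retained calls only.
#'
#' @param result A `kir_imputation` (one locus) from [predict.kir_imputer()].
#' @param threshold Calling threshold in \[0, 1\].
#' @return List with `calls` (`NA` where not called), `called` (logical) and
#'   `call_rate`.
#' @export
apply_threshold <- function(result, threshold) {
  stopifnot(inherits(result, "kir_imputation"),
            threshold >= 0, threshold <= 1)
  called <- result$map_prob >= threshold
  calls <- ifelse(called, result$map_call, NA_character_)
  list(calls = calls, called = called,
       call_rate = if (length(called)) mean(called) else NA_real_)
}

#' Coarsen whole-haplotype imputations to per-locus copy numbers
#'
#' Converts a fine-grained `KIRhaplotype` imputation into locus-specific
#' copy-number imputations by pushing the probability distribution over
#' haplotype labels through the label-to-copy-number map: the probability of
#' copy number c at a locus is the summed probability of all haplotype
#' labels mapping to c.  MAP calls are recomputed on the coarsened
#' distributions.
#'
#' @param result A `kir_imputation` for the `KIRhaplotype` locus.
#' @param copy_map Data frame mapping haplotype labels (rownames) to
#'   per-locus copy numbers (columns).
#' @return Named list of `kir_imputation` objects, one per copy-number locus.
#' @export
coarsen <- function(result, copy_map) {
  stopifnot(inherits(result, "kir_imputation"))
  copy_map <- as.data.frame(copy_map)
  labels <- colnames(result$prob)
  unmapped <- setdiff(labels, rownames(copy_map))
  if (length(unmapped))
    stop("haplotype label not in copy map: ", paste(unmapped, collapse = ", "))
  out <- lapply(names(copy_map), function(lc) {
    copies <- copy_map[labels, lc]
    levels_c <- sort(unique(copies))
    agg <- vapply(levels_c, function(cv) {
      rowSums(result$prob[, copies == cv, drop = FALSE])
    }, numeric(nrow(result$prob)))
    if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1L)
    dimnames(agg) <- list(result$unit_ids, as.character(levels_c))
    .imputation_result(agg, lc)
  })
  names(out) <- names(copy_map)
  out
}

#' Impute per-individual copy numbers from haplotype pairs
#'
#' For unphased validation data, individuals are imputed as the sum of the
#' MAP copy-number calls of their two phased haplotypes; an individual is
#' judged correct when this sum equals the measured total copy number.
#'
#' @param object A [kir_imputer()].
#' @param panel A [haplotype_panel()] whose haplotypes form the individuals.
#' @param pairs Two-column matrix (or data frame) of haplotype ids or row
#'   indices; each row is one individual.
#' @param loci Copy-number loci to impute (default: the model's copy loci).
#' @return Data frame: individual index, locus, imputed total copy number.
#' @export
impute_individuals <- function(object, panel, pairs, loci = NULL) {
  stopifnot(inherits(object, "kir_imputer"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (is.null(loci)) loci <- intersect(object$loci, kir_loci("copy"))
  res <- predict(object, panel, loci = loci)
  ids <- if (inherits(panel, "haplotype_panel")) panel$haplotype_ids
         else rownames(panel)
  idx <- if (is.character(pairs)) matrix(match(pairs, ids), ncol = 2L)
         else matrix(as.integer(pairs), ncol = 2L)
  if (anyNA(idx)) stop("pair refers to unknown haplotype")
  out <- lapply(loci, function(lc) {
    h <- as.integer(res[[lc]]$map_call)
    data.frame(individual = seq_len(nrow(idx)), locus = lc,
               copy_number = h[idx[, 1L]] + h[idx[, 2L]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Save / load a fitted imputation model
#'
#' Models are written as a versioned, self-describing RDS payload embedding
#' the SNP definitions, class labels, parameters and seed, so training and
#' imputation can run as separate invocations.
#'
#' @param object A [kir_imputer()].
#' @param path File path (conventionally `.kimp`).
#' @return `write_kir_model` returns `path` invisibly; `read_kir_model`
#'   returns the `kir_imputer`.
#' @export
write_kir_model <- function(object, path) {
  stopifnot(inherits(object, "kir_imputer"))
  saveRDS(list(format = "kirimp-model", version = 1L, model = object), path)
  invisible(path)
}

#' @rdname write_kir_model
#' @export
read_kir_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "kirimp-model"))
    stop(path, " is not a kirimp model file")
  payload$model
}
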