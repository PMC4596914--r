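#' Rank SNPs by permutation variable importance
#'
#' Fits a forest for the locus and ranks SNPs by permutation importance,
#' descending; exact ties are broken by genomic position.
#'
#' @param panel A [reference_panel()].
#' @param locus Locus name.
#' @param ntree,mtry Forest parameters (see [kir_forest()]).
#' @param seed Integer seed for fit and permutations.
#' @return Data frame `snp_id`, `position`, `importance`, ordered by
#'   decreasing importance.
#' @export
rank_snps <- function(panel, locus, ntree = 1000L, mtry = NULL, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  y <- as.character(panel$kir[[locus]])
  fr <- kir_forest(panel$alleles, y, ntree = ntree, mtry = mtry, seed = seed)
  imp <- permutation_importance(fr, panel$alleles, y, seed = seed)
  out <- data.frame(snp_id = panel$snps$snp_id, position = panel$snps$position,
                    importance = imp$importance, stringsAsFactors = FALSE)
  out[order(-out$importance, out$position), , drop = FALSE]
}

#' Iterative SNP removal experiment
#'
#' Starting from the full SNP set, iteratively removes the SNP with the
#' highest variable-importance score.  After each removal, one model is
#' fitted to the remaining SNPs (reporting its out-of-bag accuracy and
#' supplying the ranking for the next step) and one to the removed set,
#' the latter with the attribute-subspace size set to the full removed-set
#' size.  The accuracy trajectories show how concentrated the locus's
#' information is in its top SNPs.
#'
#' @param panel A [reference_panel()].
#' @param locus Locus name.
#' @param max_steps Number of removal steps (default: all but one SNP).
#' @param ntree Trees per fitted model.
#' @param seed Integer seed.
#' @param rerank Recompute importance on the remaining set after each
#'   removal (default); `FALSE` follows the initial full-model ranking
#'   throughout.
#' @return Data frame, one row per step: `step`, `removed_snp_id`,
#'   `n_remaining`, `accuracy_remaining`, `accuracy_removed`.
#' @export
removal_experiment <- function(panel, locus, max_steps = NULL,
                               ntree = 1000L, seed = 1L, rerank = TRUE) {
  stopifnot(inherits(panel, "reference_panel"))
  p <- nrow(panel$snps)
  if (p < 2L) stop("removal experiment needs at least 2 SNPs")
  if (is.null(max_steps)) max_steps <- p - 1L
  max_steps <- min(max_steps, p - 1L)
  y <- as.character(panel$kir[[locus]])

  oob_acc <- function(ids, mtry = NULL, sd) {
    X <- panel$alleles[, ids, drop = FALSE]
    fr <- kir_forest(X, y, ntree = ntree, mtry = mtry, seed = sd)
    oob_predict(fr, X, y)$oob_accuracy
  }
  imp_rank <- function(ids, sd) {
    X <- panel$alleles[, ids, drop = FALSE]
    fr <- kir_forest(X, y, ntree = ntree, seed = sd)
    imp <- permutation_importance(fr, X, y, seed = sd)
    pos <- panel$snps$position[match(ids, panel$snps$snp_id)]
    ids[order(-imp$importance, pos)]
  }

  remaining <- panel$snps$snp_id
  ranking <- imp_rank(remaining, seed)
  removed <- character(0)
  rows <- vector("list", max_steps)
  for (k in seq_len(max_steps)) {
    top <- ranking[ranking %in% remaining][1L]
    remaining <- setdiff(remaining, top)
    removed <- c(removed, top)
    sd_k <- as.integer(seed) + k
    acc_rem <- oob_acc(remaining, sd = sd_k)
    acc_out <- oob_acc(removed, mtry = length(removed), sd = sd_k + 10000L)
    if (rerank && k < max_steps && length(remaining) > 1L)
      ranking <- imp_rank(remaining, sd_k + 20000L)
    rows[[k]] <- data.frame(step = k, removed_snp_id = top,
                            n_remaining = length(remaining),
                            accuracy_remaining = acc_rem,
                            accuracy_removed = acc_out,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Construct the selected informative SNP set
#'
#' Takes the top-ranked SNPs per locus (the per-locus count being the
#' minimal number judged necessary for high accuracy), unions them across
#' loci, and excludes SNPs flagged for poor genotype-intensity clustering.
#' Alternatively, a prepared candidate table (e.g. a published
#' selected-SNP list) can be filtered directly by passing `snps` alone.
#'
#' @param snps Data frame of SNP metadata with at least `snp_id` and
#'   `poor_clustering`; when `rankings` is `NULL` its rows are the candidate
#'   set.
#' @param rankings Optional named list of per-locus rankings from
#'   [rank_snps()].
#' @param per_locus_counts Named integer vector: how many top SNPs to take
#'   from each locus in `rankings`.
#' @return List with `snp_ids` (kept), `excluded` (poor-clustering ids), and
#'   `per_locus` (data frame of locus, snp_id contributions; `NULL` without
#'   rankings).
#' @export
build_selected_set <- function(snps, rankings = NULL,
                               per_locus_counts = NULL) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "poor_clustering") %in% names(snps)))
  per_locus <- NULL
  if (!is.null(rankings)) {
    stopifnot(!is.null(per_locus_counts),
              all(names(rankings) %in% names(per_locus_counts)) ||
              all(names(per_locus_counts) %in% names(rankings)))
    loci <- intersect(names(rankings), names(per_locus_counts))
    per_locus <- do.call(rbind, lapply(loci, function(lc) {
      cnt <- per_locus_counts[[lc]]
      avail <- nrow(rankings[[lc]])
      if (cnt > avail)
        stop("locus ", lc, ": requested ", cnt, " SNPs but only ", avail,
             " available")
      if (cnt == 0L) return(NULL)
      data.frame(locus = lc, snp_id = rankings[[lc]]$snp_id[seq_len(cnt)],
                 stringsAsFactors = FALSE)
    }))
    union_ids <- unique(per_locus$snp_id)
  } else {
    union_ids <- unique(snps$snp_id)
  }
  if (!length(union_ids)) stop("selected SNP set is empty")
  flag <- snps$poor_clustering[match(union_ids, snps$snp_id)]
  flag[is.na(flag)] <- FALSE
  flag <- as.logical(flag)
  list(snp_ids = union_ids[!flag], excluded = union_ids[flag],
       per_locus = per_locus)
}

#' Best single tag SNP for a locus
#'
#' The tag-SNP baseline: every SNP is scored as a one-marker classifier
#' whose rule maps each allele to the majority class among training
#' haplotypes carrying it; the SNP with the highest training accuracy wins
#' (ties broken by smallest genomic position).  This maximises prediction
#' accuracy directly rather than Pearson correlation.
#'
#' @param panel A [reference_panel()].
#' @param locus Locus name.
#' @return List of class `kir_tag_snp`: `locus`, `snp_id`, `position`,
#'   `rule` (named map allele -> class), `accuracy`.
#' @export
best_tag_snp <- function(panel, locus) {
  stopifnot(inherits(panel, "reference_panel"))
  y <- as.character(panel$kir[[locus]])
  classes <- sort(unique(y))
  best <- NULL
  for (j in seq_len(nrow(panel$snps))) {
    a <- panel$alleles[, j]
    rule <- vapply(c(0L, 1L), function(al) {
      yy <- y[!is.na(a) & a == al]
      if (!length(yy)) return(classes[1L])
      tab <- table(factor(yy, levels = classes))
      classes[which.max(tab)]  # ties to first in canonical order
    }, character(1L))
    names(rule) <- c("0", "1")
    pred <- rule[as.character(a)]
    acc <- mean(pred == y, na.rm = TRUE)
    if (is.null(best) || acc > best$accuracy ||
        (acc == best$accuracy && panel$snps$position[j] < best$position)) {
      best <- list(locus = locus, snp_id = panel$snps$snp_id[j],
                   position = panel$snps$position[j], rule = rule,
                   accuracy = acc)
    }
  }
  structure(best, class = "kir_tag_snp")
}

#' @export
#' @method print kir_tag_snp
print.kir_tag_snp <- function(x, ...) {
  cat("Best tag SNP for ", x$locus, ": ", x$snp_id, " (position ",
      x$position, "), training accuracy ", round(x$accuracy, 4L),
      "\n  rule: allele1 -> ", x$rule[["0"]], ", allele2 -> ", x$rule[["1"]],
      "\n", sep = "")
  invisible(x)
}

#' Assess imputation accuracy restricted to an array's SNPs
#'
#' Emulates training on another genotyping array: the panel is restricted to
#' SNPs whose GRCh37 coordinates intersect the array manifest, a model is
#' fitted per locus, and out-of-bag accuracy is reported.  This is the
#' best-case scenario where every intersecting SNP is perfectly typed.
#'
#' @param panel A [reference_panel()].
#' @param manifest_positions Integer vector of GRCh37 positions on the
#'   array.
#' @param loci Loci to assess (default all in the panel).
#' @param ntree,mtry,seed Forest parameters.
#' @return Data frame `locus`, `oob_accuracy`, with attribute
#'   `n_intersection` (number of shared SNPs).
#' @export
assess_array <- function(panel, manifest_positions, loci = NULL,
                         ntree = 1000L, mtry = NULL, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  keep <- panel$snps$position %in% as.integer(manifest_positions)
  if (!any(keep)) stop("array manifest shares no positions with the panel")
  sub <- panel[, keep]
  if (is.null(loci)) loci <- names(sub$kir)
  fit <- suppressWarnings(kir_imputer(sub, loci = loci, ntree = ntree,
                                      mtry = mtry, seed = seed))
  out <- do.call(rbind, lapply(loci, function(lc) {
    ob <- oob_predict(fit$forests[[lc]], sub$alleles, sub$kir[[lc]])
    data.frame(locus = lc, oob_accuracy = ob$oob_accuracy,
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_intersection") <- sum(keep)
  out
}
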