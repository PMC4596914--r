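#' Default attribute-subspace size
#'
#' The number of candidate SNPs drawn at each tree node.  For panels of a few
#' hundred SNPs a deliberately large subspace of 100 improves accuracy at loci
#' tagged by only a handful of SNPs (too small an `m` leaves many trees with
#' no informative SNP at all); for small selected sets around a dozen SNPs,
#' 10 is used; in between, the conventional square-root rule applies.
#'
#' @param n_snps Number of SNPs available to the model.
#' @return Integer subspace size, between 1 and `n_snps`.
#' @seealso [mtry_sqrt()] for the plain square-root fallback.
#' @export
#' @examples
#' default_mtry(301) # 100
#' default_mtry(12)  # 10
default_mtry <- function(n_snps) {
  stopifnot(n_snps >= 1L)
  if (n_snps >= 200L) return(100L)
  if (n_snps <= 15L) return(as.integer(min(n_snps, 10L)))
  mtry_sqrt(n_snps)
}

#' Square-root attribute-subspace fallback
#'
#' The conventional random-forest default, `floor(sqrt(n_snps))`; with ~300
#' SNPs this gives 17.
#'
#' @param n_snps Number of SNPs.
#' @return Integer, at least 1.
#' @export
mtry_sqrt <- function(n_snps) {
  stopifnot(n_snps >= 1L)
  max(1L, as.integer(floor(sqrt(n_snps))))
}

.check_X <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (anyNA(X))
    stop("allele matrix contains missing values; impute or drop missing ",
         "alleles upstream before model fitting")
  if (!all(X %in% c(0L, 1L)))
    stop("allele matrix entries must be 0 or 1")
  X
}

#' Fit a classification-tree ensemble for one KIR locus
#'
#' Grows `ntree` CART-style classification trees over binary phased-allele
#' predictors.  Each tree is trained on an independent bootstrap resample of
#' the haplotypes (bagging, resample size equal to the panel size), and each
#' node split considers only a random subset of `mtry` SNPs (attribute
#' bagging), choosing the split that maximises the Gini impurity decrease.
#' Trees are grown to purity unless `max_nodes` limits them.  The fit is
#' deterministic given `seed`.
#'
#' @param X Haplotype x SNP matrix of 0/1 alleles (no missing values).
#' @param y Vector of target labels (copy numbers or haplotype classes).
#' @param ntree Number of trees (default 1000).
#' @param mtry Attribute-subspace size; default via [default_mtry()].
#' @param max_nodes Optional limit on nodes per tree (`NULL` = unlimited).
#' @param seed Integer seed for the ensemble's private RNG.
#' @return An object of class `kir_forest`: trees, bootstrap in-bag counts,
#'   class labels (canonical sorted order), SNP ids, and parameters.
#' @export
kir_forest <- function(X, y, ntree = 1000L, mtry = NULL, max_nodes = NULL,
                       seed = 1L) {
  X <- .check_X(X)
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(y)) stop("target labels contain missing values")
  if (is.null(mtry)) mtry <- default_mtry(ncol(X))
  mtry <- as.integer(mtry)
  if (mtry < 1L || mtry > ncol(X)) stop("mtry must be in [1, n_snps]")
  classes <- sort(unique(y))
  yi <- match(y, classes) - 1L
  fit <- cpp_rf_fit(X, yi, length(classes), as.integer(ntree), mtry,
                    if (is.null(max_nodes)) 0L else as.integer(max_nodes),
                    as.integer(seed), TRUE)
  structure(list(trees = fit$trees, inbag = fit$inbag, classes = classes,
                 snp_ids = colnames(X), n_train = nrow(X),
                 params = list(ntree = as.integer(ntree), mtry = mtry,
                               max_nodes = max_nodes,
                               seed = as.integer(seed))),
            class = "kir_forest")
}

#' Grow a single classification tree (no bagging)
#'
#' Fits one tree on the data as given, without bootstrap resampling.  Mainly
#' useful for studying the split behaviour; ensembles should be fitted with
#' [kir_forest()].
#'
#' @inheritParams kir_forest
#' @return A `kir_forest` with a single tree trained on all rows.
#' @export
grow_tree <- function(X, y, mtry = NULL, max_nodes = NULL, seed = 1L) {
  X <- .check_X(X)
  y <- as.character(y)
  if (is.null(mtry)) mtry <- ncol(X)
  classes <- sort(unique(y))
  yi <- match(y, classes) - 1L
  fit <- cpp_rf_fit(X, yi, length(classes), 1L, as.integer(mtry),
                    if (is.null(max_nodes)) 0L else as.integer(max_nodes),
                    as.integer(seed), FALSE)
  structure(list(trees = fit$trees, inbag = fit$inbag, classes = classes,
                 snp_ids = colnames(X), n_train = nrow(X),
                 params = list(ntree = 1L, mtry = as.integer(mtry),
                               max_nodes = max_nodes,
                               seed = as.integer(seed))),
            class = "kir_forest")
}

.forest_newdata <- function(object, X) {
  X <- .check_X(X)
  if (!is.null(object$snp_ids)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != length(object$snp_ids))
        stop("newdata has ", ncol(X), " SNPs; model expects ",
             length(object$snp_ids))
    } else {
      missing_snps <- setdiff(object$snp_ids, colnames(X))
      if (length(missing_snps))
        stop("newdata is missing model SNP(s): ",
             paste(head(missing_snps, 5L), collapse = ", "))
      X <- X[, object$snp_ids, drop = FALSE]
    }
  }
  X
}

#' Predict from a `kir_forest`
#'
#' Each tree casts one hard vote; the class probability is the fraction of
#' trees voting for that class, so rows sum to exactly 1.
#'
#' @param object A [kir_forest()].
#' @param newdata Haplotype x SNP 0/1 matrix covering the model's SNPs.
#' @param type `"prob"` for the vote-fraction matrix, `"class"` for the MAP
#'   call (ties broken towards the first class in canonical label order).
#' @param ... Unused.
#' @return Probability matrix (rows = haplotypes, columns = classes) or a
#'   character vector of calls.
#' @export
predict.kir_forest <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  X <- .forest_newdata(object, newdata)
  votes <- cpp_rf_votes(object$trees, X, length(object$classes))
  prob <- votes / length(object$trees)
  dimnames(prob) <- list(rownames(X), object$classes)
  if (type == "prob") return(prob)
  object$classes[max.col(prob, ties.method = "first")]
}

#' Out-of-bag predictions
#'
#' For each training haplotype, aggregates votes only from trees whose
#' bootstrap resample excluded it, mimicking cross-validation at no extra
#' cost.  Rows excluded from no tree get `NA` probabilities and are dropped
#' from the accuracy.
#'
#' @param object A [kir_forest()].
#' @param X The training allele matrix the forest was fitted to.
#' @param y The training labels (optional; enables `oob_accuracy`).
#' @return List with `prob` (rows with no covering tree are `NA`),
#'   `covered` (logical), and `oob_accuracy` (MAP accuracy over covered rows;
#'   `NA` when `y` is missing).
#' @export
oob_predict <- function(object, X, y = NULL) {
  stopifnot(inherits(object, "kir_forest"))
  X <- .forest_newdata(object, X)
  if (nrow(X) != nrow(object$inbag))
    stop("X must be the training data (row count mismatch)")
  votes <- cpp_rf_oob_votes(object$trees, object$inbag, X,
                            length(object$classes))
  tot <- rowSums(votes)
  covered <- tot > 0L
  prob <- votes / ifelse(tot > 0L, tot, 1L)
  prob[!covered, ] <- NA_real_
  dimnames(prob) <- list(rownames(X), object$classes)
  acc <- NA_real_
  calls <- rep(NA_character_, nrow(X))
  calls[covered] <- object$classes[max.col(prob[covered, , drop = FALSE],
                                           ties.method = "first")]
  if (!is.null(y)) {
    y <- as.character(y)
    acc <- mean(calls[covered] == y[covered])
  }
  list(prob = prob, calls = calls, covered = covered, oob_accuracy = acc)
}

#' Permutation variable importance
#'
#' Breiman's scheme: for every tree, the out-of-bag accuracy on the actual
#' data is compared with the accuracy after permuting one SNP's alleles
#' within that tree's out-of-bag set (one fresh permutation per tree and
#' SNP).  The per-SNP score is the mean accuracy drop across trees divided by
#' the standard deviation of the drops; SNPs never selected by any tree score
#' exactly 0.
#'
#' @param object A [kir_forest()].
#' @param X,y The training data.
#' @param seed Seed for the permutation stream.
#' @return Data frame with `snp_id`, `mean_drop`, `sd_drop`, `importance`.
#' @export
permutation_importance <- function(object, X, y, seed = 1L) {
  stopifnot(inherits(object, "kir_forest"))
  X <- .forest_newdata(object, X)
  y <- as.character(y)
  yi <- match(y, object$classes) - 1L
  if (anyNA(yi)) stop("y contains labels unknown to the forest")
  imp <- cpp_rf_importance(object$trees, object$inbag, X, yi,
                           as.integer(seed))
  data.frame(snp_id = if (is.null(colnames(X))) paste0("snp", seq_len(ncol(X)))
                      else colnames(X),
             mean_drop = imp$mean_drop, sd_drop = imp$sd_drop,
             importance = imp$score, stringsAsFactors = FALSE)
}

#' @export
#' @method print kir_forest
print.kir_forest <- function(x, ...) {
  cat("KIR classification forest: ", length(x$trees), " trees, mtry ",
      x$params$mtry, ", ", length(x$classes), " classes (",
      paste(head(x$classes, 6L), collapse = ", "),
      if (length(x$classes) > 6L) ", ..." else "", ")\n", sep = "")
  cat("  trained on ", x$n_train, " haplotypes x ", length(x$snp_ids),
      " SNPs, seed ", x$params$seed, "\n", sep = "")
  invisible(x)
}
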