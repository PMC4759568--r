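#' Sequential-gene SVM accuracy curve
#'
#' For k = 1, ..., N_max an SVM (default RBF kernel, default
#' regularization) is trained on the training cohort restricted to the
#' top-k genes of a ranking, and plain accuracy (fraction of correctly
#' classified samples) is evaluated on each test cohort; the mean across
#' test cohorts gives the curve. All cohorts must contain the listed
#' genes and the training cohort must have both classes.
#'
#' @param train A [cohort()] used for fitting.
#' @param tests List of [cohort()] used for evaluation.
#' @param genes A [ranked_genes()] data frame (or character vector, best
#'   first).
#' @param N_max Curve length (default 100; shortened to the ranking
#'   length).
#' @param kernel SVM kernel (default "radial").
#' @param seed Seed fixed before fitting for reproducibility.
#' @return An object of class `accuracy_curve`: data frame with columns
#'   `k`, one accuracy column per test cohort, and `mean_accuracy`.
#' @export
sequential_svm_curve <- function(train, tests, genes, N_max = 100,
                                 kernel = "radial", seed = 1) {
  gene_vec <- if (is.character(genes)) genes else as.data.frame(genes)$gene
  gene_vec <- head(gene_vec, N_max)
  if (length(unique(train$labels)) < 2)
    stop("training cohort has a single class")
  for (co in c(list(train), tests)) {
    miss <- setdiff(gene_vec, genes_of(co))
    if (length(miss) > 0)
      stop("gene(s) absent from cohort '", co$cohort_id, "': ",
           paste(head(miss, 3), collapse = ", "))
  }
  test_names <- vapply(tests, function(co) co$cohort_id, character(1))
  acc <- matrix(NA_real_, length(gene_vec), length(tests),
                dimnames = list(NULL, test_names))
  set.seed(seed)
  for (k in seq_along(gene_vec)) {
    gk <- gene_vec[seq_len(k)]
    xtr <- t(train$values[gk, , drop = FALSE])
    fit <- e1071::svm(xtr, train$labels, kernel = kernel, scale = FALSE)
    for (ti in seq_along(tests)) {
      xte <- t(tests[[ti]]$values[gk, , drop = FALSE])
      pred <- predict(fit, xte)
      acc[k, ti] <- mean(pred == tests[[ti]]$labels)
    }
  }
  out <- data.frame(k = seq_along(gene_vec), acc, check.names = FALSE,
                    mean_accuracy = rowMeans(acc))
  class(out) <- c("accuracy_curve", "data.frame")
  out
}

#' Score a ranking from its accuracy curve
#'
#' The score of a ranking is its maximum mean accuracy, discounted by
#' two multiplicative weights: `w_n = 1 - (n* - 1) / N_max` penalizes
#' needing many genes to reach the maximum (n* = smallest k achieving
#' it), and `w_cv = max(0, 1 - CV)` penalizes an unstable curve (CV =
#' sd/mean of the mean-accuracy curve). Both weight functions can be
#' replaced via `weights_config`.
#'
#' @param curve An `accuracy_curve` (or numeric vector of mean
#'   accuracies).
#' @param weights_config Optional list with functions `w_n(n_star,
#'   N_max)` and `w_cv(cv)` overriding the defaults.
#' @return A list (class `method_score`) with `max_mean_acc`, `n_star`,
#'   `cv`, `w_n`, `w_cv` and `score = max_mean_acc * w_n * w_cv`.
#' @export
score_ranking <- function(curve, weights_config = list()) {
  m <- if (is.numeric(curve)) curve else curve$mean_accuracy
  if (length(m) == 0) stop("empty accuracy curve")
  N_max <- length(m)
  if (mean(m) == 0) {
    warning("zero-mean accuracy curve; score set to 0")
    return(structure(list(max_mean_acc = 0, n_star = 1, cv = NA_real_,
                          w_n = NA_real_, w_cv = NA_real_, score = 0),
                     class = "method_score"))
  }
  max_acc <- max(m)
  n_star <- which(m == max_acc)[1]
  cv <- if (N_max > 1) sd(m) / mean(m) else 0
  fw_n <- weights_config$w_n %||% function(n_star, N_max)
    1 - (n_star - 1) / N_max
  fw_cv <- weights_config$w_cv %||% function(cv) max(0, 1 - cv)
  w_n <- fw_n(n_star, N_max)
  w_cv <- fw_cv(cv)
  structure(list(max_mean_acc = max_acc, n_star = n_star, cv = cv,
                 w_n = w_n, w_cv = w_cv, score = max_acc * w_n * w_cv),
            class = "method_score")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.method_score <- function(x, ...) {
  cat(sprintf(
    "<method_score> score %.3f (max acc %.3f at n* = %d, w_n %.3f, w_cv %.3f)\n",
    x$score, x$max_mean_acc, x$n_star, x$w_n, x$w_cv))
  invisible(x)
}

#' Rank methods by mean score across conditions
#'
#' @param scores Named list (method -> named numeric vector or list of
#'   `method_score` per condition); all methods must cover >= 1
#'   condition.
#' @return Data frame with one row per method, one column per condition,
#'   a `MEAN` column, ordered by decreasing mean (ties by method name).
#' @export
rank_methods <- function(scores) {
  rows <- lapply(names(scores), function(mname) {
    sc <- scores[[mname]]
    if (is.list(sc))
      sc <- vapply(sc, function(s) if (inherits(s, "method_score"))
        s$score else as.numeric(s), numeric(1))
    sc
  })
  conds <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) r[conds]))
  colnames(tab) <- conds
  df <- data.frame(method = names(scores), tab, check.names = FALSE,
                   row.names = NULL)
  df$MEAN <- rowMeans(tab, na.rm = TRUE)
  df <- df[order(-df$MEAN, df$method), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a method score table as TSV
#' @param tab Output of [rank_methods()].
#' @param path TSV path.
#' @export
write_scores_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
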