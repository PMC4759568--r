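#' Pairwise mutual-information matrix
#'
#' Mutual information MI(X, Y) = H(X) + H(Y) - H(X, Y) quantifies the
#' (possibly non-linear) statistical dependence between two genes'
#' expression profiles. Two estimators are provided:
#'
#' * `"knn"` — the Kraskov-Stoegbauer-Grassberger nearest-neighbour
#'   estimator (first variant) for continuous data:
#'   `MI = psi(k) + psi(N) - < psi(nx + 1) + psi(ny + 1) >`, with
#'   neighbourhoods defined by the Chebyshev metric in the (x, y) plane.
#'   Estimates are clamped at 0 (the estimator is unbiased around 0 under
#'   independence and can go slightly negative).
#' * `"plugin"` — the empirical plug-in estimator over joint frequencies
#'   for integer-coded data, in bits (base-2 logs).
#'
#' @param co A [cohort()] (or plain numeric matrix, genes x samples) with
#'   no missing values and at least 4 samples.
#' @param estimator `"knn"` (default) or `"plugin"`.
#' @param k Neighbour count for the knn estimator (default 3).
#' @return A symmetric non-negative matrix with zero diagonal, gene ids
#'   as dimnames, and attributes `estimator` and `estimator_k`.
#' @export
mi_matrix <- function(co, estimator = c("knn", "plugin"), k = 3) {
  estimator <- match.arg(estimator)
  x <- if (inherits(co, "cohort")) co$values else co
  if (anyNA(x)) stop("missing values present; run knn_impute first")
  if (ncol(x) < 4) stop("at least 4 samples required")
  G <- nrow(x)
  M <- matrix(0, G, G, dimnames = list(rownames(x), rownames(x)))
  if (G >= 2) {
    pairs <- combn(G, 2)
    vals <- if (estimator == "knn") {
      apply(pairs, 2, function(ij) mi_ksg(x[ij[1], ], x[ij[2], ], k))
    } else {
      apply(pairs, 2, function(ij) mi_plugin(x[ij[1], ], x[ij[2], ]))
    }
    M[t(pairs)] <- vals
    M[t(pairs)[, 2:1, drop = FALSE]] <- vals
  }
  attr(M, "estimator") <- estimator
  attr(M, "estimator_k") <- if (estimator == "knn") k else NA_integer_
  M
}

# KSG estimator (variant 1), natural logs, clamped at 0.
mi_ksg <- function(x, y, k = 3) {
  n <- length(x)
  if (k >= n) stop("k must be smaller than the sample size")
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1, function(row) sort(row, partial = k)[k])
  nx <- rowSums(dx < eps) - 1  # strictly closer in x, excluding self
  ny <- rowSums(dy < eps) - 1
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(mi, 0)
}

# Plug-in estimator for integer-coded data, base-2 logs.
mi_plugin <- function(x, y) {
  n <- length(x)
  tab <- table(x, y) / n
  px <- rowSums(tab)
  py <- colSums(tab)
  ratio <- tab / outer(px, py)
  mi <- sum(tab[tab > 0] * log2(ratio[tab > 0]))
  max(mi, 0)
}
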