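#' Per-gene min-max normalization
#'
#' Rescales every gene to [0, 1] across the samples of a cohort:
#' `(v - min) / (max - min)` over the gene's non-missing values. Genes
#' that are constant map to 0 everywhere (a fixed convention so that
#' downstream distances stay defined); missing entries stay missing. The
#' operation is idempotent.
#'
#' @param co A [cohort()] with at least one observed value per gene.
#' @return The normalized [cohort()].
#' @export
minmax_normalize <- function(co) {
  stopifnot(inherits(co, "cohort"))
  x <- co$values
  nobs <- rowSums(!is.na(x))
  if (any(nobs == 0))
    stop("gene(s) with all values missing: ",
         paste(head(rownames(x)[nobs == 0], 3), collapse = ", "))
  lo <- apply(x, 1, min, na.rm = TRUE)
  hi <- apply(x, 1, max, na.rm = TRUE)
  rng <- hi - lo
  out <- (x - lo) / ifelse(rng > 0, rng, 1)
  out[rng == 0, ] <- 0
  out[is.na(x)] <- NA_real_
  co$values <- out
  co
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Each missing entry (gene g, sample s) is replaced by the mean of the
#' values at sample s of the k genes nearest to g. Distances are
#' Euclidean over the samples where both genes are observed (scaled to a
#' common length so genes with different missingness are comparable);
#' only genes observed at sample s are candidate neighbours. If fewer
#' than `k` usable neighbours exist for a missing entry, the gene's row
#' mean is used instead, with a warning.
#'
#' @param co A [cohort()]; every gene needs at least one observed value.
#' @param k Number of neighbouring genes (default 10).
#' @return The imputed [cohort()] with no missing entries.
#' @export
knn_impute <- function(co, k = 10) {
  stopifnot(inherits(co, "cohort"), k >= 1)
  x <- co$values
  if (!anyNA(x)) return(co)
  nobs <- rowSums(!is.na(x))
  if (any(nobs == 0))
    stop("gene(s) with all values missing: ",
         paste(head(rownames(x)[nobs == 0], 3), collapse = ", "))
  miss_genes <- which(rowSums(is.na(x)) > 0)
  out <- x
  fallback <- FALSE
  for (g in miss_genes) {
    obs_g <- !is.na(x[g, ])
    # mean squared difference over jointly observed samples, per candidate
    diff2 <- sweep(x, 2, x[g, ])^2
    joint <- sweep(!is.na(x), 2, obs_g, "&")
    njoint <- rowSums(joint)
    d2 <- rowSums(diff2 * joint, na.rm = TRUE) / pmax(njoint, 1)
    d2[njoint == 0] <- Inf
    d2[g] <- Inf
    for (s in which(is.na(x[g, ]))) {
      cand <- which(!is.na(x[, s]) & is.finite(d2))
      if (length(cand) >= k) {
        ord <- cand[order(d2[cand], rownames(x)[cand])]
        out[g, s] <- mean(x[head(ord, k), s])
      } else {
        fallback <- TRUE
        out[g, s] <- mean(x[g, ], na.rm = TRUE)
      }
    }
  }
  if (fallback)
    warning("fewer than k usable neighbours for some entries; ",
            "row means used where needed")
  co$values <- out
  co
}

#' Differential-expression ranking of genes
#'
#' Per-gene Welch two-sample t-test of tumor versus normal samples with
#' Benjamini-Hochberg adjustment across all genes. Genes significant at
#' both thresholds are sorted by absolute log fold change (here: the
#' tumor minus normal mean difference of the, typically normalized,
#' expression values) in decreasing order; ties are broken by smaller
#' p-value, then gene id. At most `top_k` genes are returned.
#'
#' @param co A [cohort()] without missing values; both groups need >= 2
#'   samples.
#' @param top_k Maximum number of ranked genes to return (default 1000).
#' @param p_thresh,q_thresh Significance thresholds (default 0.01 each).
#' @return A list with `ranking` (a `ranked_genes` data frame: rank, gene,
#'   score = |logFC|) and `de` (per-gene data frame: gene, logFC, p_value,
#'   q_value, rank with NA for unselected genes).
#' @export
de_rank <- function(co, top_k = 1000, p_thresh = 0.01, q_thresh = 0.01) {
  stopifnot(inherits(co, "cohort"))
  if (anyNA(co$values)) stop("missing values present; run knn_impute first")
  tum <- co$values[, co$labels == "tumor", drop = FALSE]
  nor <- co$values[, co$labels == "normal", drop = FALSE]
  if (ncol(tum) < 2 || ncol(nor) < 2)
    stop("both groups need at least 2 samples")
  n1 <- ncol(tum); n2 <- ncol(nor)
  m1 <- rowMeans(tum); m2 <- rowMeans(nor)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1)
  v2 <- rowSums((nor - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # constant in both groups: no evidence
  q <- p.adjust(p, method = "BH")
  logfc <- m1 - m2
  genes <- rownames(co$values)
  sel <- which(p < p_thresh & q < q_thresh)
  ord <- sel[order(-abs(logfc[sel]), p[sel], genes[sel])]
  ord <- head(ord, top_k)
  rank_col <- rep(NA_integer_, length(genes))
  rank_col[ord] <- seq_along(ord)
  de <- data.frame(gene = genes, logFC = logfc, p_value = p, q_value = q,
                   rank = rank_col, row.names = NULL)
  ranking <- ranked_genes(genes[ord], abs(logfc[ord]), provenance = "initial")
  list(ranking = ranking, de = de)
}

#' Ranked gene list container
#'
#' @param gene Character vector of gene ids, best first.
#' @param score Numeric scores (non-increasing is not enforced; the order
#'   of `gene` is authoritative).
#' @param provenance Tag: `"initial"`, an inference method name, or
#'   `"voting"`.
#' @return A data frame (class `ranked_genes`) with columns rank, gene,
#'   score.
#' @export
ranked_genes <- function(gene, score, provenance = "initial") {
  if (anyDuplicated(gene)) stop("duplicate genes in ranking")
  structure(data.frame(rank = seq_along(gene), gene = as.character(gene),
                       score = as.numeric(score)),
            provenance = provenance,
            class = c("ranked_genes", "data.frame"))
}

#' Write a ranked gene list as TSV
#' @param rg A [ranked_genes()] data frame.
#' @param path TSV path.
#' @export
write_ranking_tsv <- function(rg, path) {
  write.table(as.data.frame(rg), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a differential-expression table as TSV
#' @param de The `de` element of [de_rank()].
#' @param path TSV path.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
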