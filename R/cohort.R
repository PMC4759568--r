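#' Expression cohort container
#'
#' A cohort bundles a genes-by-samples expression matrix with per-sample
#' tumor/normal labels and a cohort identifier. Rows are genes (unique row
#' names), columns are samples. Missing values are allowed and are handled
#' by [knn_impute()].
#'
#' @param values Numeric matrix, genes in rows (row names = gene ids),
#'   samples in columns (column names = sample ids).
#' @param labels Character or factor vector, one of `"tumor"`/`"normal"`
#'   per sample.
#' @param cohort_id Single string naming the cohort.
#' @return An object of class `cohort`: a list with elements `values`,
#'   `labels` (factor with levels normal, tumor) and `cohort_id`.
#' @examples
#' x <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' co <- cohort(x, c("tumor", "tumor", "tumor", "normal", "normal"), "demo")
#' co
#' @export
cohort <- function(values, labels, cohort_id = "cohort1") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique row names (gene ids)")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("`labels` must have one entry per sample (column)")
  if (!all(labels %in% c("tumor", "normal")))
    stop("labels must be 'tumor' or 'normal'")
  structure(
    list(values = values,
         labels = factor(labels, levels = c("normal", "tumor")),
         cohort_id = as.character(cohort_id)[1]),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d genes x %d samples (%d tumor / %d normal)",
              x$cohort_id, nrow(x$values), ncol(x$values),
              sum(x$labels == "tumor"), sum(x$labels == "normal")),
      sprintf("| missing: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$values)

genes_of <- function(co) rownames(co$values)

#' Write / read a cohort as TSV
#'
#' The expression matrix is written as a TSV whose first column (`gene`)
#' holds gene ids and whose remaining columns are samples; a sidecar file
#' (`<path>.labels.tsv`) records `sample_id`, `label` and `cohort_id`.
#'
#' @param co A [cohort()].
#' @param path Output TSV path for the expression matrix.
#' @return `write_cohort_tsv` returns `path` invisibly; `read_cohort_tsv`
#'   returns a [cohort()].
#' @export
write_cohort_tsv <- function(co, path) {
  stopifnot(inherits(co, "cohort"))
  df <- data.frame(gene = rownames(co$values), co$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(sample_id = colnames(co$values),
                     label = as.character(co$labels),
                     cohort_id = co$cohort_id)
  write.table(side, paste0(path, ".labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  side <- read.delim(paste0(path, ".labels.tsv"), stringsAsFactors = FALSE)
  if (!identical(side$sample_id, colnames(m)))
    stop("labels sidecar does not match sample columns of ", path)
  cohort(m, side$label, side$cohort_id[1])
}
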