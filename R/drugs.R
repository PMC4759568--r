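#' Drug-by-condition presence table
#'
#' Indicator table of which drugs were proposed for which condition
#' (disease stage or molecular subtype). Drug names are kept as exact
#' strings; matching between tables is by exact string equality.
#'
#' @param df Data frame whose first column (`drug`) holds unique drug
#'   names and whose remaining columns are 0/1 (or `"X"`/`""`) condition
#'   indicators.
#' @return An object of class `drug_table`: data frame with a `drug`
#'   column and integer 0/1 condition columns; every drug is present in
#'   at least one condition.
#' @export
drug_table <- function(df) {
  stopifnot(is.data.frame(df), ncol(df) >= 2)
  names(df)[1] <- "drug"
  if (anyDuplicated(df$drug)) stop("duplicate drug names")
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    if (is.character(v)) v <- as.integer(trimws(v) != "")
    if (!all(v %in% c(0, 1))) stop("indicators must be 0/1 or 'X'/''")
    df[[j]] <- as.integer(v)
  }
  if (any(rowSums(df[, -1, drop = FALSE]) == 0))
    stop("every drug must be present in at least one condition")
  structure(df, class = c("drug_table", "data.frame"))
}

#' Read a drug table from TSV
#'
#' Accepts either 0/1 indicators or the `"X"`-mark convention of printed
#' drug lists (any non-empty cell counts as presence).
#'
#' @param path TSV path (first column drug names, one column per
#'   condition).
#' @return A [drug_table()].
#' @export
read_drug_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL,
                   fileEncoding = "UTF-8")
  drug_table(df)
}

conditions_of <- function(t) names(t)[-1]

#' Drug-table summaries
#'
#' `count_unique` counts distinct drug names; `exclusive_drugs` lists the
#' drugs present in one condition and no other; `common_in_all` lists
#' the drugs present in every condition.
#'
#' @param t A [drug_table()].
#' @param condition Condition (column) name for `exclusive_drugs`.
#' @return A count, or a character vector of drug names.
#' @export
count_unique <- function(t) length(unique(t$drug))

#' @rdname count_unique
#' @export
exclusive_drugs <- function(t, condition) {
  conds <- conditions_of(t)
  if (!condition %in% conds)
    stop("unknown condition '", condition, "'; available: ",
         paste(conds, collapse = ", "))
  others <- setdiff(conds, condition)
  m <- as.matrix(t[, others, drop = FALSE])
  t$drug[t[[condition]] == 1 & rowSums(m) == 0]
}

#' @rdname count_unique
#' @export
common_in_all <- function(t) {
  m <- as.matrix(t[, conditions_of(t), drop = FALSE])
  t$drug[rowSums(m) == length(conditions_of(t))]
}

#' Exact hypergeometric probability
#'
#' Probability of observing exactly `k` successes when drawing `n` items
#' without replacement from a population of `N` containing `K`
#' successes: `C(K, k) C(N-K, n-k) / C(N, n)`, evaluated in log space
#' for numerical stability. `hypergeom_tail` gives the upper tail
#' P(X >= k).
#'
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Draws.
#' @param k Observed successes.
#' @return A probability.
#' @examples
#' hypergeom_pmf(N = 5, K = 2, n = 2, k = 1)  # 0.6
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  for (v in c(N, K, n, k))
    if (!is.numeric(v) || v < 0 || v != round(v))
      stop("parameters must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  if (k < max(0, n + K - N)) stop("k below the feasible minimum")
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

#' @rdname hypergeom_pmf
#' @export
hypergeom_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(vapply(ks, function(kk) hypergeom_pmf(N, K, n, kk), numeric(1)))
}

#' Tanimoto similarity and Soergel distance of bit vectors
#'
#' `tanimoto(a, b) = |a AND b| / |a OR b|`, defined as 1 when both
#' vectors are all-zero; `soergel = 1 - tanimoto`.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return A similarity (distance) in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' @rdname tanimoto
#' @export
soergel <- function(a, b) 1 - tanimoto(a, b)

#' Average-linkage hierarchical clustering of fingerprints
#'
#' Agglomerative clustering on Soergel (= 1 - Tanimoto) distances with
#' average linkage. The merge order is deterministic: among equally
#' close pairs the one with the smallest member indices merges first.
#' The result mirrors [stats::hclust()] (`merge`, `height`, `labels`)
#' and can be plotted via `as.hclust`-compatible consumers.
#'
#' @param fps A `fingerprints` list (>= 2 items).
#' @return A list of class `hclust` with `merge`, `height`, `labels`,
#'   `order`, `method = "average"`, `dist.method = "soergel"`.
#' @export
cluster_drugs <- function(fps) {
  n <- length(fps)
  if (n < 2) stop("need at least two fingerprints")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- soergel(fps[[i]], fps[[j]])
  active <- seq_len(n)             # current cluster ids
  id <- -seq_len(n)                # hclust convention: negatives = leaves
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      d <- D[active[ii], active[jj]]
      if (d < bd - 1e-15) { bd <- d; best <- c(ii, jj) }
    }
    i <- best[1]; j <- best[2]
    a <- active[i]; b <- active[j]
    pair <- c(id[a], id[b])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]  # hclust convention
    height[step] <- bd
    # average linkage update into slot a
    others <- setdiff(active, c(a, b))
    D[a, others] <- D[others, a] <-
      (size[a] * D[a, others] + size[b] * D[b, others]) /
      (size[a] + size[b])
    size[a] <- size[a] + size[b]
    id[a] <- step
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge, n),
                 labels = names(fps), method = "average",
                 dist.method = "soergel", call = match.call()),
            class = "hclust")
}

# leaf order by recursive traversal of the merge tree
hclust_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1)
}

#' Cross-set fingerprint pairs above a similarity threshold
#'
#' All pairs (a in setA, b in setB) with Tanimoto similarity strictly
#' greater than `threshold`.
#'
#' @param setA,setB `fingerprints` lists.
#' @param threshold Similarity cut in [0, 1] (default 0.5).
#' @return Data frame with columns `a`, `b`, `similarity`.
#' @export
similar_pairs <- function(setA, setB, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- list()
  for (i in seq_along(setA)) for (j in seq_along(setB)) {
    s <- tanimoto(setA[[i]], setB[[j]])
    if (s > threshold)
      out[[length(out) + 1]] <- data.frame(a = names(setA)[i],
                                           b = names(setB)[j],
                                           similarity = s)
  }
  if (length(out) == 0)
    return(data.frame(a = character(), b = character(),
                      similarity = numeric()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Assemble the typed drug/target/pattern super-network
#'
#' Combines four sub-networks into one typed graph: drug-drug structural
#' similarity edges (weighted), drug-target edges, target-gene physical
#' interactions with pattern genes, and the co-expression edges of the
#' pattern itself. Node types are `lincs_drug`, `fda_drug`,
#' `target_gene`, `pattern_gene`; edge types `similarity`, `targets`,
#' `physical_interaction`, `coexpression`.
#'
#' @param nodes Data frame with columns `name`, `type` declaring every
#'   node.
#' @param drug_drug Data frame `a`, `b`, `similarity` (e.g. from
#'   [similar_pairs()]).
#' @param drug_target Data frame `drug`, `target`.
#' @param target_pattern Data frame `target`, `gene`.
#' @param pattern Optional pattern graph whose edges become
#'   `coexpression` edges.
#' @return An [igraph][igraph::igraph-package] graph with `type` vertex
#'   and edge attributes.
#' @export
assemble_supernetwork <- function(nodes, drug_drug = NULL,
                                  drug_target = NULL,
                                  target_pattern = NULL, pattern = NULL) {
  stopifnot(all(c("name", "type") %in% names(nodes)))
  types <- c("lincs_drug", "fda_drug", "target_gene", "pattern_gene")
  if (!all(nodes$type %in% types))
    stop("node types must be one of: ", paste(types, collapse = ", "))
  if (anyDuplicated(nodes$name)) stop("duplicate node names")
  ed <- list()
  add <- function(a, b, type, weight = NA_real_) {
    miss <- setdiff(c(a, b), nodes$name)
    if (length(miss) > 0)
      stop("edge references undeclared node(s): ",
           paste(head(miss, 3), collapse = ", "))
    data.frame(from = a, to = b, type = type, weight = weight)
  }
  if (!is.null(drug_drug) && nrow(drug_drug) > 0)
    ed <- c(ed, list(add(drug_drug$a, drug_drug$b, "similarity",
                         drug_drug$similarity)))
  if (!is.null(drug_target) && nrow(drug_target) > 0)
    ed <- c(ed, list(add(drug_target$drug, drug_target$target, "targets")))
  if (!is.null(target_pattern) && nrow(target_pattern) > 0)
    ed <- c(ed, list(add(target_pattern$target, target_pattern$gene,
                         "physical_interaction")))
  if (!is.null(pattern) && nrow(pattern) > 0)
    ed <- c(ed, list(add(pattern$gene_a, pattern$gene_b, "coexpression",
                         pattern$weight)))
  edges <- if (length(ed) > 0) do.call(rbind, ed)
           else data.frame(from = character(), to = character(),
                           type = character(), weight = numeric())
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
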