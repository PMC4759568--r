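#' PageRank reconciliation of perturbation scores with a network
#'
#' Blends per-gene differential-expression scores with network topology
#' by iterating the restart recursion
#' `p <- q * S~ + (1 - q) * P p`, where `S~` is the score vector S
#' normalized to sum 1 and `P(v, u) = w(u, v) / d_u` spreads each node's
#' mass over its neighbours proportionally to edge weight (`d_u` = total
#' weight of u's edges). The iteration starts at `p = S~` and is a
#' contraction with factor at most `1 - q`, so the fixed point is unique
#' and `p` stays in [0, 1] with total mass at most 1. A gene that is
#' isolated in the network converges to `q * S~(v)`: its score is kept,
#' only discounted for having no topological support.
#'
#' @param net A [gene_network()]; every scored gene must be in its gene
#'   universe (isolated genes allowed).
#' @param scores Named non-negative numeric vector S(v) (typically
#'   |logFC|), not all zero.
#' @param q Restart weight in (0, 1], default 0.5: 1 keeps the input
#'   scores, smaller values trust the topology more.
#' @param tolerance L1 convergence tolerance (default 1e-9).
#' @param max_iter Iteration cap (default 10000).
#' @return Named vector p over the gene universe, with the iteration
#'   count in attribute `iterations`.
#' @export
pagerank_reconcile <- function(net, scores, q = 0.5, tolerance = 1e-9,
                               max_iter = 10000) {
  stopifnot(q > 0, q <= 1, tolerance > 0)
  genes <- network_genes(net)
  if (!all(names(scores) %in% genes))
    stop("scored genes missing from the network's gene universe: ",
         paste(head(setdiff(names(scores), genes), 3), collapse = ", "))
  if (any(scores < 0)) stop("scores must be non-negative")
  S <- setNames(numeric(length(genes)), genes)
  S[names(scores)] <- scores
  tot <- sum(S)
  if (tot == 0) stop("scores sum to zero; nothing to reconcile")
  S <- S / tot
  W <- network_to_matrix(net)
  d <- colSums(W)
  Pmat <- sweep(W, 2, ifelse(d > 0, d, 1), "/")
  Pmat[, d == 0] <- 0
  p <- S
  for (it in seq_len(max_iter)) {
    p_new <- q * S + (1 - q) * as.numeric(Pmat %*% p)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tolerance) {
      names(p) <- genes
      attr(p, "iterations") <- it
      return(p)
    }
  }
  stop("no convergence within ", max_iter, " iterations (residual ",
       format(delta), ")")
}

#' Re-rank a differential-expression gene list with a network
#'
#' Uses `S(v) = |logFC(v)|` as perturbation scores, reconciles them with
#' the network via [pagerank_reconcile()], and orders genes by the
#' reconciled score (descending), breaking ties by |logFC| (descending)
#' then gene id. Genes of the DE list absent from the network are
#' treated as isolated nodes, so the whole list stays rankable.
#'
#' @param net A [gene_network()].
#' @param de Either the list returned by [de_rank()] or its `de` data
#'   frame (columns gene, logFC); only genes with a DE `rank` (i.e. the
#'   selected list) are ranked if present, otherwise all rows.
#' @param q,tolerance,max_iter Passed to [pagerank_reconcile()].
#' @param provenance Tag stored on the result (default "pagerank").
#' @return A [ranked_genes()] data frame with the reconciled score.
#' @export
rerank_genes <- function(net, de, q = 0.5, tolerance = 1e-9,
                         max_iter = 10000, provenance = "pagerank") {
  if (is.list(de) && !is.data.frame(de) && !is.null(de$de)) de <- de$de
  stopifnot(all(c("gene", "logFC") %in% names(de)))
  if ("rank" %in% names(de) && any(!is.na(de$rank)))
    de <- de[!is.na(de$rank), , drop = FALSE]
  S <- setNames(abs(de$logFC), de$gene)
  genes <- union(network_genes(net), de$gene)
  net_full <- gene_network(as.data.frame(net), genes)
  p <- pagerank_reconcile(net_full, S, q = q, tolerance = tolerance,
                          max_iter = max_iter)
  p <- p[de$gene]
  ord <- order(-p, -abs(de$logFC), de$gene)
  ranked_genes(de$gene[ord], unname(p[ord]), provenance = provenance)
}

#' Voting ensemble over ranked gene lists
#'
#' Combines several rankings by, in lexicographic priority: highest
#' frequency of appearance in the lists' top-K prefixes, minimum mean
#' rank over the lists containing the gene, minimum coefficient of
#' variation of those ranks, then gene id. Returns the first K genes of
#' that ordering (all pool genes if fewer).
#'
#' @param lists List of >= 2 [ranked_genes()] (or data frames with a
#'   `gene` column in rank order).
#' @param K Prefix size (default 100).
#' @return A [ranked_genes()] whose score column is the appearance
#'   frequency.
#' @export
voting_select <- function(lists, K = 100) {
  if (K <= 0) stop("`K` must be positive")
  if (length(lists) < 2) stop("at least two ranked lists required")
  tops <- lapply(lists, function(l) head(as.data.frame(l)$gene, K))
  pool <- sort(unique(unlist(tops)))
  stats <- lapply(pool, function(g) {
    pos <- unlist(lapply(tops, function(tk) which(tk == g)))
    cv <- if (length(pos) > 1 && mean(pos) > 0) sd(pos) / mean(pos) else 0
    c(freq = length(pos), mean_rank = mean(pos), cv = cv)
  })
  stats <- do.call(rbind, stats)
  ord <- order(-stats[, "freq"], stats[, "mean_rank"], stats[, "cv"], pool)
  sel <- head(ord, K)
  ranked_genes(pool[sel], stats[sel, "freq"], provenance = "voting")
}
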