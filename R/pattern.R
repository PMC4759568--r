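#' Edge intersection across cohort networks
#'
#' Keeps the edges present in *every* input network. The consensus
#' weight of a surviving edge is the chosen summary (default: arithmetic
#' mean) of its per-network weights; `support` records the number of
#' networks (constant, = number of inputs). Nodes are the endpoints of
#' surviving edges; the node count of this unfiltered common graph is
#' stored as `n0` for the dynamic filter.
#'
#' @param networks List of >= 2 [gene_network()] over a shared gene
#'   universe.
#' @param consensus `"mean"` (default), `"min"` or `"median"` summary of
#'   per-network weights.
#' @return A pattern graph: a [gene_network()] with a `support` column
#'   and attributes `n0` and `support`.
#' @export
common_edges <- function(networks, consensus = c("mean", "min", "median")) {
  consensus <- match.arg(consensus)
  if (length(networks) < 2) stop("at least two networks required")
  keys <- lapply(networks, edge_key)
  shared <- Reduce(intersect, keys)
  genes <- Reduce(union, lapply(networks, network_genes))
  if (length(shared) == 0) {
    pat <- empty_network(character())
    pat$support <- integer()
    attr(pat, "n0") <- 0L
    attr(pat, "support") <- length(networks)
    return(pat)
  }
  wmat <- vapply(networks, function(nw) {
    nw$weight[match(shared, edge_key(nw))]
  }, numeric(length(shared)))
  wmat <- matrix(wmat, nrow = length(shared))
  w <- switch(consensus,
              mean = rowMeans(wmat),
              min = apply(wmat, 1, min),
              median = apply(wmat, 1, median))
  parts <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
  nodes <- sort(unique(as.vector(parts)))
  pat <- gene_network(data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                                 weight = w,
                                 support = length(networks)), nodes)
  attr(pat, "n0") <- length(nodes)
  attr(pat, "support") <- length(networks)
  pat
}

#' Dynamic weakest-edge filtering of a common network
#'
#' Deletes edges in increasing weight order (ties by edge id) and tracks
#' the largest connected component after every deletion (ties: more
#' edges, then lexicographically smallest node set). A component is a
#' valid candidate when it (i) differs from the initial common graph and
#' (ii) has more than `filter_fraction * n0` nodes, `n0` being the node
#' count of the unfiltered common graph. The component of the *last*
#' deletion step at which (ii) still holds — the most filtered valid
#' state — is returned, with isolated nodes dropped.
#'
#' Component sizes only shrink as deletions proceed, so the scan is
#' implemented as a reverse union-find sweep (edges re-added in
#' decreasing order), which keeps the filter near-linear in the edge
#' count.
#'
#' @param common Pattern graph from [common_edges()] (non-empty).
#' @param filter_fraction Node-count criterion as a fraction of `n0`
#'   (default 0.10).
#' @return The filtered pattern graph (attributes `n0`, `support`,
#'   `filter_fraction` set).
#' @export
dynamic_filter <- function(common, filter_fraction = 0.10) {
  if (nrow(common) == 0) stop("common network is empty")
  n0 <- attr(common, "n0") %||% length(network_genes(common))
  threshold <- filter_fraction * n0
  edges <- as.data.frame(common)
  del_ord <- order(edges$weight, edges$gene_a, edges$gene_b)
  edges <- edges[del_ord, , drop = FALSE]   # deletion order
  nodes <- network_genes(common)
  nid <- setNames(seq_along(nodes), nodes)
  E <- nrow(edges)
  # reverse sweep: add edges from strongest to weakest, union-find
  parent <- seq_along(nodes)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  csize <- rep(1L, length(nodes))
  cur_max <- 1L
  best_m <- NA_integer_
  ia <- nid[edges$gene_a]; ib <- nid[edges$gene_b]
  for (m in seq_len(E)) {
    e <- E - m + 1   # m strongest edges present
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) {
      if (csize[ra] < csize[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      parent[rb] <- ra
      csize[ra] <- csize[ra] + csize[rb]
      if (csize[ra] > cur_max) cur_max <- csize[ra]
    }
    if (cur_max > threshold) {
      best_m <- m
      break
    }
  }
  if (is.na(best_m))
    stop("no component ever exceeds ", filter_fraction,
         " * n0 nodes; relax filter_fraction")
  kept <- edges[seq.int(E - best_m + 1, E), , drop = FALSE]
  # identify the largest component among kept edges (ties: edges, node ids)
  g <- igraph::graph_from_data_frame(
    kept[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = sort(unique(c(kept$gene_a, kept$gene_b))))
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    ecount <- vapply(cand, function(ci) {
      vs <- names(comp$membership)[comp$membership == ci]
      sum(kept$gene_a %in% vs & kept$gene_b %in% vs)
    }, numeric(1))
    cand <- cand[ecount == max(ecount)]
    if (length(cand) > 1) {
      first_node <- vapply(cand, function(ci)
        min(names(comp$membership)[comp$membership == ci]), character(1))
      cand <- cand[order(first_node)][1]
    }
  }
  vs <- names(comp$membership)[comp$membership == cand[1]]
  sub <- kept[kept$gene_a %in% vs & kept$gene_b %in% vs, , drop = FALSE]
  if (identical(sort(edge_key(sub)), sort(edge_key(common))))
    stop("the only valid component is the initial network; ",
         "relax filter_fraction")
  pat <- gene_network(sub, sort(vs))
  attr(pat, "n0") <- n0
  attr(pat, "support") <- attr(common, "support")
  attr(pat, "filter_fraction") <- filter_fraction
  pat
}

#' Top interactions of a pattern
#'
#' Edges sorted by consensus weight (descending, ties by edge id); the
#' first `m` are returned (all if fewer).
#'
#' @param pattern A pattern graph.
#' @param m Number of interactions (default 100).
#' @return A data frame of edges.
#' @export
top_interactions <- function(pattern, m = 100) {
  stopifnot(m >= 1)
  df <- as.data.frame(pattern)
  df <- df[order(-df$weight, df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  head(df, m)
}

#' Common edges of two patterns
#'
#' Plain edge-set intersection (weights reported from the first
#' pattern); intersection is associative, so chaining over successive
#' condition pairs equals the global intersection.
#'
#' @param p1,p2 Pattern graphs (or any [gene_network()]).
#' @return A data frame of shared edges.
#' @export
pairwise_common <- function(p1, p2) {
  shared <- intersect(edge_key(p1), edge_key(p2))
  df <- as.data.frame(p1)[match(shared, edge_key(p1)), , drop = FALSE]
  rownames(df) <- NULL
  df
}
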