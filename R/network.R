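#' Weighted undirected gene network
#'
#' Networks are stored as canonical edge lists: a data frame with columns
#' `gene_a`, `gene_b` (with `gene_a < gene_b` lexicographically) and a
#' positive finite `weight`, plus the full gene universe as an attribute so
#' isolated genes are representable.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`
#'   (extra columns are kept). Zero-row data frames are allowed.
#' @param genes Character vector: the gene universe the network lives on.
#' @return An object of class `gene_network` (a data frame).
#' @export
gene_network <- function(edges, genes) {
  if (nrow(edges) > 0) {
    stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
    swap <- edges$gene_a > edges$gene_b
    if (any(swap)) {
      tmp <- edges$gene_a[swap]
      edges$gene_a[swap] <- edges$gene_b[swap]
      edges$gene_b[swap] <- tmp
    }
    if (any(edges$gene_a == edges$gene_b)) stop("self-edges are not allowed")
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be finite and > 0")
    key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges")
    miss <- setdiff(c(edges$gene_a, edges$gene_b), genes)
    if (length(miss) > 0)
      stop("edge endpoints outside the gene universe: ",
           paste(head(miss, 3), collapse = ", "))
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(as.data.frame(edges), genes = as.character(genes),
            class = c("gene_network", "data.frame"))
}

empty_network <- function(genes) {
  gene_network(data.frame(gene_a = character(), gene_b = character(),
                          weight = numeric()), genes)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d edges\n",
              length(network_genes(x)), nrow(x)))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Gene universe, neighbour counts and weighted degrees
#'
#' `network_genes` returns the gene universe; `node_degree` the per-gene
#' neighbour count N_v and total neighbour weight d_v = sum of w(u, v).
#'
#' @param net A [gene_network()].
#' @return `node_degree` returns a data frame with columns `gene`,
#'   `n_neighbors`, `weighted_degree` covering the whole gene universe.
#' @export
network_genes <- function(net) attr(net, "genes")

#' @rdname network_genes
#' @export
node_degree <- function(net) {
  genes <- network_genes(net)
  nv <- setNames(numeric(length(genes)), genes)
  dv <- nv
  if (nrow(net) > 0) {
    cnt <- table(c(net$gene_a, net$gene_b))
    nv[names(cnt)] <- as.numeric(cnt)
    wsum <- tapply(c(net$weight, net$weight), c(net$gene_a, net$gene_b), sum)
    dv[names(wsum)] <- as.numeric(wsum)
  }
  data.frame(gene = genes, n_neighbors = unname(nv),
             weighted_degree = unname(dv))
}

edge_key <- function(net) paste(net$gene_a, net$gene_b, sep = "\r")

#' Convert a symmetric weight matrix to a gene network
#'
#' Upper-triangle entries > 0 become edges. Used internally by all
#' inference methods.
#' @noRd
matrix_to_network <- function(W, genes = rownames(W)) {
  stopifnot(nrow(W) == ncol(W))
  iu <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(iu) == 0) return(empty_network(genes))
  gene_network(data.frame(gene_a = genes[iu[, 1]], gene_b = genes[iu[, 2]],
                          weight = W[iu]), genes)
}

network_to_matrix <- function(net) {
  genes <- network_genes(net)
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (nrow(net) > 0) {
    W[cbind(net$gene_a, net$gene_b)] <- net$weight
    W[cbind(net$gene_b, net$gene_a)] <- net$weight
  }
  W
}

#' Write / read a network edge list as TSV
#'
#' Three canonical columns (`gene_a`, `gene_b`, `weight`, with
#' `gene_a < gene_b`); any extra columns (e.g. pattern `support`) are kept.
#'
#' @param net A [gene_network()].
#' @param path TSV path.
#' @return `read_network_tsv` returns a [gene_network()]; the gene universe
#'   is taken from the edge endpoints unless `genes` is given.
#' @param genes Optional gene universe for `read_network_tsv`.
#' @export
write_network_tsv <- function(net, path) {
  write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path, genes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- sort(unique(c(df$gene_a, df$gene_b)))
  gene_network(df, genes)
}

#' Export a network to GraphML
#'
#' @param net A [gene_network()] (or pattern graph).
#' @param path Output `.graphml` path.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(as.data.frame(net), directed = FALSE,
                                     vertices = network_genes(net))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
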