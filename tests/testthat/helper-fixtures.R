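# Shared fixtures and independent oracles used across the suite.

# internal helpers used throughout the assertions
edge_key <- coexrank:::edge_key
network_to_matrix <- coexrank:::network_to_matrix

# small cohort with hand-set values
tiny_cohort <- function(values, labels = NULL, id = "tiny") {
  if (is.null(labels))
    labels <- rep(c("tumor", "normal"), length.out = ncol(values))
  cohort(values, labels, id)
}

rand_cohort <- function(n_genes = 20, n_tumor = 10, n_normal = 10,
                        seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_tumor + n_normal), sd = sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_tumor + n_normal))))
  cohort(m, c(rep("tumor", n_tumor), rep("normal", n_normal)), "rand")
}

# symmetric MI-like matrix with distinct positive values
rand_mi <- function(G, seed) {
  set.seed(seed)
  M <- matrix(0, G, G, dimnames = list(letters[1:G], letters[1:G]))
  vals <- sample(seq(0.01, 1, length.out = choose(G, 2)))
  M[upper.tri(M)] <- vals
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

net_from_edges <- function(..., genes = NULL) {
  e <- data.frame(...)
  if (is.null(genes)) genes <- sort(unique(c(e$gene_a, e$gene_b)))
  gene_network(e, genes)
}

# ---- independent oracles -------------------------------------------------

# forward-selection oracle for MRNET: plain loops, explicit sums
oracle_mrnet <- function(M) {
  G <- nrow(M)
  sc <- matrix(NA_real_, G, G)
  for (y in seq_len(G)) {
    S <- c()
    repeat {
      cand <- setdiff(seq_len(G), c(y, S))
      if (length(cand) == 0) break
      u <- sapply(cand, function(k) {
        red <- if (length(S) == 0) 0 else sum(sapply(S, function(j) M[k, j])) / length(S)
        M[k, y] - red
      })
      if (max(u) < 0) break
      pick <- cand[which.max(u)]
      sc[pick, y] <- max(u)
      S <- c(S, pick)
    }
  }
  W <- pmax(sc, t(sc), na.rm = TRUE)
  W[is.na(W)] <- 0
  W[W <= 0] <- 0
  diag(W) <- 0
  dimnames(W) <- dimnames(M)
  W
}

# brute-force triplet rule for ARACNE
oracle_aracne <- function(M, mode, epsilon = 0.05, tau = 0.15) {
  G <- nrow(M)
  W <- M
  diag(W) <- 0
  for (i in 1:G) for (j in 1:G) for (k in 1:G) {
    if (length(unique(c(i, j, k))) < 3) next
    lo <- min(M[i, k], M[j, k])
    drop <- if (mode == "additive") M[i, j] < lo - epsilon
            else M[i, j] < lo * (1 - tau)
    if (drop) W[i, j] <- W[j, i] <- 0
  }
  W[M <= 0] <- 0
  W
}

# exhaustive hypergeometric pmf by enumerating all draws (small N)
oracle_hypergeom <- function(N, K, n, k) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- combn(N, n)
  mean(apply(draws, 2, function(idx) sum(pop[idx]) == k))
}

# J objective used by MRNETB, written independently
oracle_J <- function(M, y, S) {
  if (length(S) == 0) return(0)
  tot <- 0
  for (k in S) {
    rest <- setdiff(S, k)
    red <- if (length(rest) == 0) 0 else mean(sapply(rest, function(j) M[k, j]))
    tot <- tot + M[k, y] - red
  }
  tot
}

# pure backward elimination (no swaps) final J, per target
oracle_backward_J <- function(M, y) {
  S <- setdiff(seq_len(nrow(M)), y)
  J <- oracle_J(M, y, S)
  repeat {
    if (length(S) == 0) break
    Js <- sapply(seq_along(S), function(i) oracle_J(M, y, S[-i]))
    if (max(Js) > J) { J <- max(Js); S <- S[-which.max(Js)] } else break
  }
  J
}

edge_weight <- function(net, a, b) {
  i <- which(net$gene_a == min(a, b) & net$gene_b == max(a, b))
  if (length(i) == 0) return(0)
  net$weight[i]
}
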