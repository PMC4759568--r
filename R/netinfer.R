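#' ARACNE: data-processing-inequality pruning of an MI matrix
#'
#' Starts from all gene pairs with positive mutual information and
#' removes edge (i, j) whenever a third gene k makes it the weakest edge
#' of the triplet, with a tolerance: in additive mode the edge is removed
#' iff `MI(i,j) < min(MI(i,k), MI(j,k)) - epsilon`; in multiplicative
#' mode iff `MI(i,j) < min(MI(i,k), MI(j,k)) * (1 - tau)`. All triplets
#' are evaluated against the original MI matrix, so removals are
#' order-independent. Surviving edges are weighted by MI.
#'
#' @param M Symmetric MI matrix (see [mi_matrix()]).
#' @param mode `"additive"` or `"multiplicative"`.
#' @param epsilon Additive tolerance (default 0.05).
#' @param tau Multiplicative tolerance in [0, 1] (default 0.15).
#' @return A [gene_network()].
#' @export
aracne <- function(M, mode = c("additive", "multiplicative"),
                   epsilon = 0.05, tau = 0.15) {
  mode <- match.arg(mode)
  stopifnot(epsilon >= 0, tau >= 0, tau <= 1)
  G <- nrow(M)
  keep <- M > 0
  diag(keep) <- FALSE
  out <- M
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      if (j <= i || !keep[i, j]) next
      bottleneck <- pmin(M[i, ], M[j, ])
      bottleneck[c(i, j)] <- -Inf
      mx <- max(bottleneck)
      removed <- if (mode == "additive") M[i, j] < mx - epsilon
                 else M[i, j] < mx * (1 - tau)
      if (removed) out[i, j] <- out[j, i] <- 0
    }
  }
  out[!keep] <- 0
  matrix_to_network(out)
}

#' CLR: context likelihood of relatedness
#'
#' Background-corrects each MI value against the empirical distribution
#' of its two rows: `z_i(j) = max(0, (MI(i,j) - mu_i) / sigma_i)` with
#' `mu_i`, `sigma_i` the mean and (sample) standard deviation of row i's
#' off-diagonal MI values, and edge weight
#' `sqrt(z_i(j)^2 + z_j(i)^2)`. Rows with zero spread contribute z = 0.
#' Zero-weight pairs are omitted.
#'
#' @param M Symmetric MI matrix over >= 3 genes.
#' @return A [gene_network()].
#' @export
clr <- function(M) {
  G <- nrow(M)
  if (G < 3) stop("at least 3 genes required")
  off <- M
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sg <- apply(off, 1, sd, na.rm = TRUE)
  z <- (M - mu) / ifelse(sg > 0, sg, 1)
  z[sg == 0, ] <- 0
  z[z < 0] <- 0
  W <- sqrt(z^2 + t(z)^2)
  diag(W) <- 0
  matrix_to_network(W, rownames(M))
}

#' MRNET: maximum relevance / minimum redundancy forward selection
#'
#' For every target gene Y the predictor set S is grown greedily: the
#' first pick maximizes MI(X, Y); each subsequent pick maximizes
#' `u = MI(X, Y) - mean over S of MI(X, X_s)`, the selected gene's u
#' being recorded as the directed pair score. Selection stops when the
#' best u becomes negative. The undirected weight of a pair is the
#' maximum of its two directed scores; pairs with weight <= 0 are
#' omitted. Ties are broken by gene id.
#'
#' @param M Symmetric MI matrix.
#' @return A [gene_network()].
#' @export
mrnet <- function(M) {
  G <- nrow(M)
  score <- matrix(-Inf, G, G)
  for (y in seq_len(G)) {
    cand <- setdiff(seq_len(G), y)
    S <- integer()
    while (length(cand) > 0) {
      u <- if (length(S) == 0) M[cand, y]
           else M[cand, y] - rowMeans(M[cand, S, drop = FALSE])
      best <- which(u == max(u))[1]  # candidates are id-ordered
      if (u[best] < 0) break
      score[cand[best], y] <- u[best]
      S <- c(S, cand[best])
      cand <- cand[-best]
    }
  }
  W <- pmax(score, t(score))
  W[W <= 0 | !is.finite(W)] <- 0
  dimnames(W) <- dimnames(M)
  matrix_to_network(W)
}

# Summed relevance-minus-redundancy objective for a predictor set S of
# target y: J(S) = sum_k [ MI(k, y) - mean_{j in S, j != k} MI(k, j) ].
mrnetb_objective <- function(M, y, S) {
  if (length(S) == 0) return(0)
  if (length(S) == 1) return(M[S, y])
  red <- (rowSums(M[S, S, drop = FALSE])) / (length(S) - 1)
  sum(M[S, y] - red)
}

#' MRNETB: backward elimination with sequential replacement
#'
#' Starts, for each target, from the full predictor set and removes the
#' member whose removal most improves the summed relevance-minus-
#' redundancy objective, while it improves; then tries single-element
#' swaps until none improves. Retained pairs are scored like in
#' [mrnet()] (`u = MI(X, Y) - mean MI(X, rest of S)`), the undirected
#' weight being the maximum of the two directions; non-positive weights
#' are omitted.
#'
#' @param M Symmetric MI matrix.
#' @return A [gene_network()].
#' @export
mrnetb <- function(M) {
  G <- nrow(M)
  score <- matrix(-Inf, G, G)
  for (y in seq_len(G)) {
    S <- setdiff(seq_len(G), y)
    J <- mrnetb_objective(M, y, S)
    # backward elimination
    repeat {
      if (length(S) == 0) break
      Js <- vapply(seq_along(S),
                   function(i) mrnetb_objective(M, y, S[-i]), numeric(1))
      best <- which.max(Js)
      if (Js[best] > J) { S <- S[-best]; J <- Js[best] } else break
    }
    # sequential replacement
    repeat {
      out <- setdiff(seq_len(G), c(y, S))
      improved <- FALSE
      if (length(S) > 0 && length(out) > 0) {
        best_J <- J; best_swap <- NULL
        for (i in seq_along(S)) for (o in out) {
          Js <- mrnetb_objective(M, y, c(S[-i], o))
          if (Js > best_J) { best_J <- Js; best_swap <- c(i, o) }
        }
        if (!is.null(best_swap)) {
          S <- c(S[-best_swap[1]], best_swap[2]); J <- best_J
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    for (kk in S) {
      rest <- setdiff(S, kk)
      score[kk, y] <- if (length(rest) == 0) M[kk, y]
                      else M[kk, y] - mean(M[kk, rest])
    }
  }
  W <- pmax(score, t(score))
  W[W <= 0 | !is.finite(W)] <- 0
  dimnames(W) <- dimnames(M)
  matrix_to_network(W)
}

#' C3NET: maximum mutual information partner per gene
#'
#' Zeroes all MI values at or below `mi_threshold`, then marks for each
#' gene the single remaining partner with maximal MI (ties broken by the
#' lexicographically smallest partner id). The edge set is the union of
#' marked pairs, weighted by MI; hence at most one edge per gene is
#' contributed and the edge count never exceeds the gene count.
#'
#' @param M Symmetric MI matrix.
#' @param mi_threshold Significance threshold (>= 0); see
#'   [c3net_threshold()] for the default permutation-based choice.
#' @return A [gene_network()].
#' @export
c3net <- function(M, mi_threshold) {
  stopifnot(mi_threshold >= 0)
  W <- M
  W[W <= mi_threshold] <- 0
  diag(W) <- 0
  genes <- rownames(M)
  keep <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  for (i in seq_len(nrow(W))) {
    row <- W[i, ]
    if (all(row == 0)) next
    j <- which(row == max(row))
    j <- j[order(genes[j])][1]
    keep[i, j] <- keep[j, i] <- W[i, j]
  }
  matrix_to_network(keep)
}

#' Permutation threshold for C3NET
#'
#' Estimates the null distribution of MI by permuting each gene's sample
#' order independently (destroying all pairwise dependence) and returns
#' the `prob` quantile of the pooled off-diagonal null MI values.
#'
#' @param co A [cohort()] (or matrix) without missing values.
#' @param estimator,k Passed to [mi_matrix()].
#' @param n_perm Number of permutations (default 30).
#' @param prob Quantile (default 0.95).
#' @param seed Seed for the permutations.
#' @return A single threshold value.
#' @export
c3net_threshold <- function(co, estimator = "knn", k = 3, n_perm = 30,
                            prob = 0.95, seed = 1) {
  x <- if (inherits(co, "cohort")) co$values else co
  set.seed(seed)
  null_vals <- replicate(n_perm, {
    xp <- t(apply(x, 1, sample))
    rownames(xp) <- rownames(x)
    Mp <- mi_matrix(xp, estimator = estimator, k = k)
    Mp[upper.tri(Mp)]
  })
  as.numeric(quantile(null_vals, probs = prob, type = 7))
}

#' Spearman adjacency network
#'
#' Soft-threshold adjacency `|spearman rho|^beta` over all gene pairs;
#' invariant to strictly increasing transforms of any gene. Constant
#' genes get zero correlation with a warning. Zero-weight pairs are
#' omitted.
#'
#' @param co A [cohort()] (or matrix) with >= 3 samples, no missing
#'   values.
#' @param beta Soft-threshold power (default 1).
#' @return A [gene_network()].
#' @export
spearman_adjacency <- function(co, beta = 1) {
  x <- if (inherits(co, "cohort")) co$values else co
  if (anyNA(x)) stop("missing values present; run knn_impute first")
  if (ncol(x) < 3) stop("at least 3 samples required")
  const <- apply(x, 1, function(v) max(v) == min(v))
  if (any(const))
    warning("constant gene(s); their correlations are set to 0: ",
            paste(head(rownames(x)[const], 3), collapse = ", "))
  R <- suppressWarnings(cor(t(x), method = "spearman"))
  R[const, ] <- 0
  R[, const] <- 0
  W <- abs(R)^beta
  diag(W) <- 0
  matrix_to_network(W, rownames(x))
}

#' Shrinkage partial-correlation network (Gaussian graphical model)
#'
#' Estimates the gene-gene correlation matrix with Schaefer-Strimmer
#' shrinkage towards the identity (the analytic optimal intensity
#' `lambda = sum Var(r_ij) / sum r_ij^2` over off-diagonal entries,
#' clamped to [0, 1]), inverts it, and converts the precision matrix to
#' partial correlations `pcor(i,j) = -Omega_ij / sqrt(Omega_ii
#' Omega_jj)`. Edge weight is `|pcor|`; exact zeros are omitted. The
#' shrunk correlation matrix is positive definite whenever `lambda > 0`,
#' so the estimator is usable with more genes than samples.
#'
#' @param co A [cohort()] (or matrix) with >= 3 samples, no missing
#'   values.
#' @param lambda Optional shrinkage intensity override in [0, 1]
#'   (`NULL` = analytic estimate).
#' @return A [gene_network()] with the used intensity in attribute
#'   `lambda`.
#' @export
shrinkage_pcor <- function(co, lambda = NULL) {
  x <- if (inherits(co, "cohort")) co$values else co
  if (anyNA(x)) stop("missing values present; run knn_impute first")
  n <- ncol(x)
  if (n < 3) stop("at least 3 samples required")
  xs <- t(scale(t(x)))       # standardize genes
  xs[is.na(xs)] <- 0         # constant genes: zero contribution
  R <- tcrossprod(xs) / (n - 1)
  diag(R) <- 1
  if (is.null(lambda)) {
    # Var(r_ij) estimated from the products w_k = x_ki * x_kj:
    # Var-hat = n / (n-1)^3 * sum_k (w_k - w_bar)^2, w_bar = (n-1)/n r_ij
    sum_r2 <- 0; sum_var <- 0
    for (i in seq_len(nrow(xs) - 1)) {
      jj <- (i + 1):nrow(xs)
      w2sum <- (xs[rep(i, length(jj)), , drop = FALSE] *
                  xs[jj, , drop = FALSE])^2
      w2sum <- rowSums(w2sum)
      w_bar <- (n - 1) / n * R[i, jj]
      var_r <- n / (n - 1)^3 * (w2sum - n * w_bar^2)
      sum_var <- sum_var + sum(var_r)
      sum_r2 <- sum_r2 + sum(R[i, jj]^2)
    }
    lambda <- if (sum_r2 > 0) min(1, max(0, sum_var / sum_r2)) else 1
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  Om <- tryCatch(solve(Rs), error = function(e)
    stop("shrunk correlation matrix is singular (lambda = ", lambda, ")"))
  d <- sqrt(diag(Om))
  P <- -Om / outer(d, d)
  diag(P) <- 0
  W <- abs(P)
  W[W < 1e-12] <- 0   # numerical zeros are zeros
  dimnames(W) <- list(rownames(x), rownames(x))
  net <- matrix_to_network(W, rownames(x))
  attr(net, "lambda") <- lambda
  net
}

#' Neighbourhood-lasso network
#'
#' Regresses every gene on all others with an L1 penalty (via glmnet's
#' coordinate descent at a fixed penalty); in adaptive mode penalties
#' are reweighted by the reciprocal absolute coefficients of an initial
#' ridge fit. An edge is kept when either direction's coefficient is
#' non-zero (OR rule; AND available), weighted by the maximum absolute
#' coefficient.
#'
#' @param co A [cohort()] (or matrix), no missing values.
#' @param penalty Non-negative lasso penalty on the glmnet scale.
#' @param adaptive Use adaptive reweighting (default FALSE).
#' @param rule `"or"` (default) or `"and"` edge combination.
#' @return A [gene_network()].
#' @export
neighborhood_lasso <- function(co, penalty = 0.1, adaptive = FALSE,
                               rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(penalty >= 0)
  x <- if (inherits(co, "cohort")) co$values else co
  if (anyNA(x)) stop("missing values present; run knn_impute first")
  G <- nrow(x)
  B <- matrix(0, G, G, dimnames = list(rownames(x), rownames(x)))
  for (g in seq_len(G)) {
    yv <- x[g, ]
    Xp <- t(x[-g, , drop = FALSE])
    pf <- rep(1, ncol(Xp))
    if (adaptive) {
      init <- glmnet::glmnet(Xp, yv, alpha = 0, lambda = 1e-3,
                             standardize = FALSE)
      b0 <- abs(as.numeric(init$beta))
      pf <- 1 / pmax(b0, 1e-6)
      pf <- pf / mean(pf)   # glmnet rescales penalty.factor to sum p
    }
    fit <- glmnet::glmnet(Xp, yv, alpha = 1, lambda = penalty,
                          standardize = FALSE, penalty.factor = pf)
    B[g, -g] <- as.numeric(fit$beta)
  }
  W <- pmax(abs(B), t(abs(B)))
  if (rule == "and") W[!(B != 0 & t(B) != 0)] <- 0
  diag(W) <- 0
  matrix_to_network(W)
}

#' Tree-ensemble importance network
#'
#' Fits, per target gene, a random regression forest on all other genes
#' and uses the mean impurity-reduction importance as directed edge
#' scores, symmetrized by the maximum. Reproducible from `seed`.
#'
#' @param co A [cohort()] (or matrix), no missing values.
#' @param n_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return A [gene_network()].
#' @export
tree_importance_network <- function(co, n_trees = 100, seed = 1) {
  stopifnot(n_trees >= 1)
  x <- if (inherits(co, "cohort")) co$values else co
  if (anyNA(x)) stop("missing values present; run knn_impute first")
  G <- nrow(x)
  ids <- rownames(x)
  B <- matrix(0, G, G, dimnames = list(ids, ids))
  for (g in seq_len(G)) {
    df <- as.data.frame(t(x))
    colnames(df) <- make.names(ids)
    target <- make.names(ids[g])
    fit <- ranger::ranger(
      formula = stats::as.formula(paste(target, "~ .")), data = df,
      num.trees = n_trees, importance = "impurity",
      mtry = max(1, floor(sqrt(G - 1))), seed = seed + g,
      num.threads = 1)
    imp <- fit$variable.importance
    B[g, match(names(imp), make.names(ids))] <- pmax(imp, 0)
  }
  diag(B) <- 0
  W <- pmax(B, t(B))
  matrix_to_network(W)
}

#' Uniform dispatch over the network-inference methods
#'
#' Runs one of the co-expression inference methods end to end on a
#' cohort, computing the MI matrix first where needed.
#'
#' @param co A [cohort()] without missing values.
#' @param method One of `"aracne.a"`, `"aracne.m"`, `"clr"`, `"mrnet"`,
#'   `"mrnetb"`, `"c3net"`, `"wgcna"`, `"genenet"`, `"lasso"`,
#'   `"adlasso"`, `"genie3"`. `"wgcna"` denotes the Spearman adjacency
#'   and `"genenet"` the shrinkage partial-correlation network.
#' @param config Optional named list of method arguments (e.g. `epsilon`,
#'   `tau`, `k`, `estimator`, `mi_threshold`, `beta`, `penalty`,
#'   `n_trees`, `seed`).
#' @return A [gene_network()].
#' @export
infer <- function(co, method, config = list()) {
  methods <- c("aracne.a", "aracne.m", "clr", "mrnet", "mrnetb", "c3net",
               "wgcna", "genenet", "lasso", "adlasso", "genie3")
  if (!method %in% methods)
    stop("unknown method '", method, "'; valid: ",
         paste(methods, collapse = ", "))
  cfg <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  if (method %in% c("aracne.a", "aracne.m", "clr", "mrnet", "mrnetb",
                    "c3net")) {
    M <- mi_matrix(co, estimator = cfg("estimator", "knn"), k = cfg("k", 3))
    return(switch(method,
      aracne.a = aracne(M, "additive", epsilon = cfg("epsilon", 0.05)),
      aracne.m = aracne(M, "multiplicative", tau = cfg("tau", 0.15)),
      clr = clr(M),
      mrnet = mrnet(M),
      mrnetb = mrnetb(M),
      c3net = {
        thr <- cfg("mi_threshold",
                   c3net_threshold(co, estimator = cfg("estimator", "knn"),
                                   k = cfg("k", 3),
                                   n_perm = cfg("n_perm", 30),
                                   seed = cfg("seed", 1)))
        c3net(M, thr)
      }))
  }
  switch(method,
    wgcna = spearman_adjacency(co, beta = cfg("beta", 1)),
    genenet = shrinkage_pcor(co, lambda = cfg("lambda", NULL)),
    lasso = neighborhood_lasso(co, penalty = cfg("penalty", 0.1),
                               adaptive = FALSE),
    adlasso = neighborhood_lasso(co, penalty = cfg("penalty", 0.1),
                                 adaptive = TRUE),
    genie3 = tree_importance_network(co, n_trees = cfg("n_trees", 100),
                                     seed = cfg("seed", 1)))
}
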