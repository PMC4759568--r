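triangle_mi <- function(ab, ac, bc) {
  M <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  M["a", "b"] <- M["b", "a"] <- ab
  M["a", "c"] <- M["c", "a"] <- ac
  M["b", "c"] <- M["c", "b"] <- bc
  M
}

test_that("ARACNE applies the DPI rule with additive and multiplicative tolerance", {
  M <- triangle_mi(ab = 0.5, ac = 0.3, bc = 0.4)
  add <- aracne(M, "additive", epsilon = 0.05)
  expect_equal(nrow(add), 2)
  expect_equal(edge_weight(add, "a", "c"), 0)   # 0.3 < 0.4 - 0.05
  expect_equal(edge_weight(add, "a", "b"), 0.5)
  expect_equal(edge_weight(add, "b", "c"), 0.4)
  lax <- aracne(M, "additive", epsilon = 0.15)
  expect_equal(nrow(lax), 3)                    # 0.3 >= 0.4 - 0.15
  mult <- aracne(M, "multiplicative", tau = 0.15)
  expect_equal(nrow(mult), 2)                   # 0.3 < 0.4 * 0.85
  expect_equal(edge_weight(mult, "a", "c"), 0)
})

test_that("ARACNE agrees with the brute-force triplet oracle and prunes monotonically", {
  for (s in 1:5) {
    M <- rand_mi(6, seed = s)
    for (mode in c("additive", "multiplicative")) {
      got <- network_to_matrix(aracne(M, mode))
      want <- oracle_aracne(M, mode)
      expect_equal(got, want, tolerance = 1e-12)
    }
    # edge set shrinks within the MI support; larger tolerance only removes
    e_small <- edge_key(aracne(M, "additive", epsilon = 0.02))
    e_big <- edge_key(aracne(M, "additive", epsilon = 0.2))
    support <- edge_key(coexrank:::matrix_to_network(M))
    expect_true(all(e_small %in% support))
    expect_true(all(e_small %in% e_big))
  }
})

test_that("CLR matches hand computation and handles flat rows", {
  M <- triangle_mi(ab = 0.6, ac = 0.2, bc = 0.2)
  net <- clr(M)
  # row a: mu 0.4, sd 0.2828...; z_a(b) = z_b(a) = sqrt(0.5); others clamp to 0
  expect_equal(nrow(net), 1)
  expect_equal(edge_weight(net, "a", "b"),
               sqrt(2 * ((0.6 - 0.4) / sd(c(0.6, 0.2)))^2), tolerance = 1e-12)
  # all off-diagonal equal: every z is 0, empty network
  expect_equal(nrow(clr(triangle_mi(0.3, 0.3, 0.3))), 0)
  # symmetric output for any symmetric input
  M2 <- rand_mi(5, seed = 4)
  W <- network_to_matrix(clr(M2))
  expect_equal(W, t(W))
})

test_that("MRNET equals the forward-selection oracle", {
  # two genes: single edge with weight MI
  M2 <- triangle_mi(0.4, 0, 0)[1:2, 1:2]
  net2 <- mrnet(M2)
  expect_equal(nrow(net2), 1)
  expect_equal(edge_weight(net2, "a", "b"), 0.4)
  # all-zero MI: empty
  expect_equal(nrow(mrnet(matrix(0, 3, 3,
                                 dimnames = list(letters[1:3],
                                                 letters[1:3])))), 0)
  # oracle equivalence on distinct-valued matrices up to 5 genes
  for (G in 2:5) for (s in 1:6) {
    M <- rand_mi(G, seed = 100 * G + s)
    expect_equal(network_to_matrix(mrnet(M)), oracle_mrnet(M),
                 tolerance = 1e-12)
  }
})

test_that("MRNETB reduces to MRNET on two genes and swaps never hurt", {
  M2 <- triangle_mi(0.4, 0, 0)[1:2, 1:2]
  expect_equal(as.data.frame(mrnetb(M2)), as.data.frame(mrnet(M2)))
  expect_equal(nrow(mrnetb(matrix(0, 3, 3,
                                  dimnames = list(letters[1:3],
                                                  letters[1:3])))), 0)
  # final J (with replacement phase) >= pure backward elimination J
  for (s in 1:6) {
    M <- rand_mi(4, seed = 200 + s)
    for (y in 1:4) {
      # recompute the package's final set by reusing its objective
      netJ <- local({
        S <- setdiff(1:4, y)
        J <- coexrank:::mrnetb_objective(M, y, S)
        repeat {
          if (length(S) == 0) break
          Js <- vapply(seq_along(S), function(i)
            coexrank:::mrnetb_objective(M, y, S[-i]), numeric(1))
          if (max(Js) > J) { J <- max(Js); S <- S[-which.max(Js)] } else break
        }
        repeat {
          out <- setdiff(1:4, c(y, S)); better <- FALSE
          for (i in seq_along(S)) for (o in out) {
            Js <- coexrank:::mrnetb_objective(M, y, c(S[-i], o))
            if (Js > J) { J <- Js; S <- c(S[-i], o); better <- TRUE; break }
          }
          if (!better) break
        }
        J
      })
      expect_gte(netJ, oracle_backward_J(M, y) - 1e-12)
    }
  }
})

test_that("C3NET keeps each gene's maximum-MI partner above threshold", {
  M <- triangle_mi(ab = 0.5, ac = 0.2, bc = 0.4)
  net <- c3net(M, 0.1)
  expect_setequal(edge_key(net), c("a\rb", "b\rc"))
  net2 <- c3net(M, 0.45)
  expect_equal(edge_key(net2), "a\rb")
  expect_equal(nrow(c3net(M, 0.6)), 0)
  # edge count is bounded by the gene count
  for (s in 1:4) {
    M <- rand_mi(7, seed = 300 + s)
    expect_lte(nrow(c3net(M, 0.2)), 7)
  }
})

test_that("Spearman adjacency is a rank statistic", {
  x <- seq(-2, 2, length.out = 9)
  m <- rbind(g1 = x, g2 = exp(x), g3 = rnorm(9))
  colnames(m) <- paste0("s", 1:9)
  net <- spearman_adjacency(tiny_cohort(m))
  expect_equal(edge_weight(net, "g1", "g2"), 1)   # monotone pair
  m2 <- rbind(g1 = c(1, 2, 3), g2 = c(3, 1, 2))
  colnames(m2) <- paste0("s", 1:3)
  net2 <- spearman_adjacency(tiny_cohort(m2, labels = c("tumor", "tumor", "normal")))
  expect_equal(edge_weight(net2, "g1", "g2"), 0.5)  # rho = -0.5
  # invariance under strictly increasing transforms
  m3 <- m; m3["g3", ] <- m3["g3", ]^3 + 10
  net3 <- spearman_adjacency(tiny_cohort(m3))
  expect_equal(as.data.frame(net3), as.data.frame(net))
  mc <- rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3))
  colnames(mc) <- paste0("s", 1:3)
  expect_warning(netc <- spearman_adjacency(
    tiny_cohort(mc, labels = c("tumor", "tumor", "normal"))), "constant")
  expect_equal(nrow(netc), 0)
})

test_that("shrinkage partial correlation recovers conditional structure", {
  # full shrinkage: empty network regardless of data
  co <- rand_cohort(n_genes = 6, seed = 5)
  expect_equal(nrow(shrinkage_pcor(co, lambda = 1)), 0)
  # data with an exactly diagonal sample correlation: empty at lambda 0
  set.seed(8)
  z <- qr.Q(qr(scale(matrix(rnorm(40 * 3), 40, 3), scale = FALSE)))
  m <- t(z); rownames(m) <- paste0("g", 1:3); colnames(m) <- paste0("s", 1:40)
  expect_equal(nrow(shrinkage_pcor(
    cohort(m, rep(c("tumor", "normal"), each = 20), "o"), lambda = 0)), 0)
  # Markov chain X -> Y -> Z with the sample correlation forced to the
  # population matrix: pcor must match the analytic 3x3 inverse
  rho_xy <- 0.8; rho_yz <- 0.7
  R <- matrix(c(1, rho_xy, rho_xy * rho_yz,
                rho_xy, 1, rho_yz,
                rho_xy * rho_yz, rho_yz, 1), 3, 3)
  L <- chol(R)
  n <- 50
  z <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  x <- z * sqrt(n - 1)        # exact identity sample covariance
  dat <- t(x %*% L)
  rownames(dat) <- c("X", "Y", "Z"); colnames(dat) <- paste0("s", 1:n)
  net <- shrinkage_pcor(cohort(dat, rep(c("tumor", "normal"), length.out = n),
                               "mc"), lambda = 0)
  pcor_xy <- (rho_xy - rho_xy * rho_yz * rho_yz) /
    sqrt((1 - (rho_xy * rho_yz)^2) * (1 - rho_yz^2))
  pcor_yz <- (rho_yz - rho_xy * rho_xy * rho_yz) /
    sqrt((1 - rho_xy^2) * (1 - (rho_xy * rho_yz)^2))
  expect_equal(edge_weight(net, "X", "Y"), pcor_xy, tolerance = 1e-8)
  expect_equal(edge_weight(net, "Y", "Z"), pcor_yz, tolerance = 1e-8)
  expect_equal(edge_weight(net, "X", "Z"), 0, tolerance = 1e-8)
  # analytic lambda is inside [0, 1] and shrinks noise on real-ish data
  net2 <- shrinkage_pcor(rand_cohort(n_genes = 30, seed = 6))
  expect_gte(attr(net2, "lambda"), 0)
  expect_lte(attr(net2, "lambda"), 1)
})

test_that("neighbourhood lasso shrinks to empty and soft-thresholds", {
  co <- rand_cohort(n_genes = 5, seed = 9)
  expect_equal(nrow(neighborhood_lasso(co, penalty = 100)), 0)
  # orthonormal predictors: lasso coefficient = soft-thresholded OLS
  set.seed(10)
  n <- 32
  q <- qr.Q(qr(scale(matrix(rnorm(n * 2), n, 2), scale = FALSE))) * sqrt(n)
  # columns are zero-mean with X'X / n = I
  beta <- c(1.5, 0.3)
  y <- q %*% beta
  m <- rbind(t = as.numeric(y), p1 = q[, 1], p2 = q[, 2])
  colnames(m) <- paste0("s", 1:n)
  pen <- 0.5
  net <- neighborhood_lasso(tiny_cohort(m), penalty = pen)
  ols <- beta  # predictors orthonormal in the 1/n inner product
  soft <- pmax(abs(ols) - pen, 0)
  expect_equal(edge_weight(net, "t", "p1"), soft[1], tolerance = 0.05)
  expect_equal(edge_weight(net, "t", "p2"), soft[2], tolerance = 0.05)
})

test_that("tree-importance network is seeded and finds duplicated genes", {
  set.seed(11)
  m <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:30)))
  m["g02", ] <- m["g01", ] + rnorm(30, sd = 0.01)
  co <- tiny_cohort(m)
  a <- tree_importance_network(co, n_trees = 50, seed = 3)
  b <- tree_importance_network(co, n_trees = 50, seed = 3)
  expect_equal(as.data.frame(a), as.data.frame(b))
  top <- a[order(-a$weight), ][1, ]
  expect_setequal(c(top$gene_a, top$gene_b), c("g01", "g02"))
})

test_that("the dispatcher runs every core method end to end", {
  sim <- generate_cohort_set(cohort_spec(n_genes = 40, n_tumor = 20,
                                         n_normal = 20, n_cohorts = 1,
                                         de_genes = 5, module_genes = 8,
                                         nuisance_blocks = 0, seed = 12))
  co <- sim$cohorts[[1]]
  expect_error(infer(co, "nope"), "valid")
  # dispatch contract: aracne.a == aracne(mi_matrix(.), additive)
  M <- mi_matrix(co)
  expect_equal(as.data.frame(infer(co, "aracne.a")),
               as.data.frame(aracne(M, "additive", epsilon = 0.05)))
  for (m in c("aracne.a", "aracne.m", "clr", "mrnet", "mrnetb", "c3net",
              "wgcna", "genenet", "genie3")) {
    net <- infer(co, m, config = list(n_perm = 5, n_trees = 30))
    expect_s3_class(net, "gene_network")
    W <- network_to_matrix(net)
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(is.finite(net$weight)) && all(net$weight > 0))
  }
  # 2-gene data: at most one edge for any MI method
  co2 <- co; co2$values <- co$values[1:2, , drop = FALSE]
  expect_lte(nrow(infer(co2, "mrnet")), 1)
})

test_that("every core method ranks planted module edges above background", {
  sim <- generate_cohort_set(cohort_spec(n_genes = 40, n_tumor = 30,
                                         n_normal = 10, n_cohorts = 1,
                                         de_genes = 0, module_genes = 10,
                                         latent_loading = 1, noise_sd = 0.5,
                                         nuisance_blocks = 0, seed = 17))
  co <- sim$cohorts[[1]]
  mkey <- paste(sim$truth$module_edges$gene_a,
                sim$truth$module_edges$gene_b, sep = "\r")
  all_pairs <- combn(sort(rownames(co$values)), 2)
  akey <- paste(all_pairs[1, ], all_pairs[2, ], sep = "\r")
  truth <- akey %in% mkey
  for (m in c("aracne.a", "aracne.m", "clr", "mrnet", "mrnetb", "c3net",
              "wgcna", "genenet", "genie3")) {
    net <- infer(co, m, config = list(n_perm = 5, n_trees = 50))
    w <- setNames(numeric(length(akey)), akey)
    w[edge_key(net)] <- net$weight
    auc <- mean(outer(w[truth], w[!truth], ">") + 0.5 * outer(w[truth], w[!truth], "=="))
    expect_gt(auc, 0.5)
  }
})
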