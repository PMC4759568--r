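stage_tab <- read_drug_table(system.file("extdata", "table_stages.tsv",
                                         package = "coexrank"))
subtype_tab <- read_drug_table(system.file("extdata", "table_subtypes.tsv",
                                           package = "coexrank"))

test_that("drug table summaries reproduce the published counts", {
  expect_equal(count_unique(stage_tab), 63)
  expect_equal(count_unique(subtype_tab), 58)
  expect_length(exclusive_drugs(stage_tab, "Stage I"), 12)
  expect_length(exclusive_drugs(stage_tab, "Stage III"), 13)
  expect_length(exclusive_drugs(stage_tab, "Stage IV"), 11)
  expect_length(exclusive_drugs(subtype_tab, "LuminalA"), 7)
  expect_length(exclusive_drugs(subtype_tab, "LuminalB"), 12)
  expect_length(exclusive_drugs(subtype_tab, "TripleNegative"), 12)
  expect_equal(common_in_all(stage_tab), "idarubicin")
  expect_setequal(common_in_all(subtype_tab), c("etoposide", "wortmannin"))
  expect_error(exclusive_drugs(stage_tab, "Stage V"), "unknown condition")
})

test_that("exclusive and shared drugs partition each table", {
  for (tab in list(stage_tab, subtype_tab)) {
    excl <- unlist(lapply(names(tab)[-1],
                          function(cc) exclusive_drugs(tab, cc)))
    expect_false(anyDuplicated(excl) > 0)
    shared <- tab$drug[rowSums(tab[, -1]) >= 2]
    expect_setequal(c(excl, shared), tab$drug)
    # a drug present everywhere is exclusive nowhere
    expect_length(intersect(common_in_all(tab), excl), 0)
  }
  one_cond <- drug_table(data.frame(drug = c("x", "y"), A = c(1, 1)))
  expect_setequal(common_in_all(one_cond), c("x", "y"))
  expect_equal(count_unique(one_cond), 2)
})

test_that("hypergeometric pmf is exact, stable and normalized", {
  # published overlap probability of the repurposed-drug analysis
  expect_equal(hypergeom_pmf(N = 20413, K = 22, n = 105, k = 2),
               0.005471157, tolerance = 1e-9 / 0.005471157)
  expect_equal(hypergeom_pmf(N = 100, K = 0, n = 10, k = 0), 1)
  expect_equal(hypergeom_pmf(N = 5, K = 2, n = 2, k = 1), 0.6)
  # matches exhaustive enumeration for all feasible k at small N
  for (prm in list(c(8, 3, 4), c(10, 5, 4), c(12, 6, 6))) {
    N <- prm[1]; K <- prm[2]; n <- prm[3]
    for (k in max(0, n + K - N):min(n, K))
      expect_equal(hypergeom_pmf(N, K, n, k), oracle_hypergeom(N, K, n, k),
                   tolerance = 1e-12)
  }
  # pmf sums to one over the feasible range
  set.seed(14)
  for (i in 1:5) {
    N <- sample(5:40, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    expect_equal(sum(vapply(ks, function(k) hypergeom_pmf(N, K, n, k),
                            numeric(1))), 1, tolerance = 1e-12)
  }
  expect_equal(hypergeom_tail(20, 5, 8, 0), 1, tolerance = 1e-12)
  expect_error(hypergeom_pmf(10, 12, 3, 1), "exceed")
})

test_that("tanimoto and soergel behave on the edge cases", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)   # all-zero convention
  expect_equal(soergel(c(1, 1, 0, 0), c(1, 0, 1, 0)), 2 / 3)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("soergel distance satisfies the triangle inequality on 4-bit vectors", {
  vecs <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  for (i in seq_len(16)) for (j in seq_len(16)) for (k in seq_len(16)) {
    dij <- soergel(unlist(vecs[i, ]), unlist(vecs[j, ]))
    dik <- soergel(unlist(vecs[i, ]), unlist(vecs[k, ]))
    dkj <- soergel(unlist(vecs[k, ]), unlist(vecs[j, ]))
    expect_lte(dij, dik + dkj + 1e-12)
  }
})

test_that("average-linkage clustering is deterministic and monotone", {
  fps <- structure(list(a = c(TRUE, TRUE, FALSE, FALSE),
                        b = c(TRUE, TRUE, FALSE, FALSE),
                        c = c(FALSE, FALSE, TRUE, TRUE)),
                   class = "fingerprints")
  hc <- cluster_drugs(fps)
  expect_equal(hc$height[1], 0)               # identical pair joins first
  expect_setequal(hc$merge[1, ], c(-1, -2))
  expect_equal(nrow(hc$merge), 2)             # n - 1 merges
  # monotone heights, agreement with stats::hclust on distinct distances
  set.seed(18)
  fps2 <- generate_fingerprints(6, n_bits = 64, density = 0.3, seed = 18)
  hc2 <- cluster_drugs(fps2)
  expect_true(all(diff(hc2$height) >= -1e-12))
  D <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    D[i, j] <- D[j, i] <- soergel(fps2[[i]], fps2[[j]])
  ref <- hclust(as.dist(D), method = "average")
  expect_equal(hc2$height, ref$height, tolerance = 1e-12)
  expect_equal(abs(hc2$merge), abs(ref$merge))
})

test_that("similar pairs respects the strict threshold and symmetry", {
  A <- structure(list(x = c(TRUE, TRUE, FALSE, FALSE),
                      y = c(TRUE, FALSE, TRUE, FALSE)),
                 class = "fingerprints")
  B <- structure(list(u = c(TRUE, TRUE, FALSE, FALSE),
                      v = c(FALSE, FALSE, FALSE, TRUE)),
                 class = "fingerprints")
  sp <- similar_pairs(A, B, threshold = 0.5)
  expect_equal(nrow(sp), 1)                   # only x-u (similarity 1)
  expect_equal(sp$similarity, 1)
  # threshold 1 is strict: identical pairs do not pass
  expect_equal(nrow(similar_pairs(A, B, threshold = 1)), 0)
  # symmetric up to column naming
  sp_ab <- similar_pairs(A, B, threshold = 0)
  sp_ba <- similar_pairs(B, A, threshold = 0)
  expect_setequal(paste(sp_ab$a, sp_ab$b), paste(sp_ba$b, sp_ba$a))
})

test_that("the super-network is typed and rejects dangling edges", {
  nodes <- data.frame(name = c("drugA", "fdaB", "T1", "P1", "P2"),
                      type = c("lincs_drug", "fda_drug", "target_gene",
                               "pattern_gene", "pattern_gene"))
  pat <- gene_network(data.frame(gene_a = "P1", gene_b = "P2",
                                 weight = 0.7), c("P1", "P2"))
  g <- assemble_supernetwork(
    nodes,
    drug_drug = data.frame(a = "drugA", b = "fdaB", similarity = 0.8),
    drug_target = data.frame(drug = "fdaB", target = "T1"),
    target_pattern = data.frame(target = "T1", gene = "P1"),
    pattern = pat)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  expect_setequal(igraph::E(g)$type,
                  c("similarity", "targets", "physical_interaction",
                    "coexpression"))
  empty <- assemble_supernetwork(nodes[0, ])
  expect_equal(igraph::vcount(empty), 0)
  expect_error(assemble_supernetwork(
    nodes, drug_target = data.frame(drug = "ghost", target = "T1")),
    "undeclared")
})
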