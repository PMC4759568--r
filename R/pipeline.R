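#' End-to-end multi-cohort analysis
#'
#' Orchestrates the full pipeline on a cohort set: per-gene min-max
#' normalization and kNN imputation; differential-expression ranking on
#' the reference cohort (the first); per-method network inference on the
#' reference and PageRank re-ranking; hold-out SVM scoring of every
#' re-ranked list (reference as training set, remaining cohorts as test
#' sets) and method ranking; inference with the best-scoring method on
#' every cohort; edge intersection and dynamic filtering into the
#' conserved pattern; and a drug-table summary of the bundled stage and
#' subtype fixtures. Intermediates are written as TSV under `out_dir`
#' plus a JSON run report.
#'
#' @param cohorts List of [cohort()] (e.g. from [generate_cohort_set()]);
#'   the first is the reference set.
#' @param methods Character vector of [infer()] method names to compare.
#' @param q Reconciliation restart weight (default 0.5).
#' @param N_max Sequential SVM curve length (default 100).
#' @param top_k DE list size (default 1000).
#' @param filter_fraction Dynamic-filter node criterion (default 0.10).
#' @param seed Integer seed for the SVM and any method randomness.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param infer_config Optional named list of per-method [infer()]
#'   configs.
#' @return A list (the run report): DE ranking, per-method scores, the
#'   score table, best method, pattern graph, top interactions and drug
#'   summaries.
#' @export
run_all <- function(cohorts, methods = c("genenet", "wgcna", "clr"),
                    q = 0.5, N_max = 100, top_k = 1000,
                    filter_fraction = 0.10, seed = 1, out_dir = NULL,
                    infer_config = list()) {
  stopifnot(length(cohorts) >= 2)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, name, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    obj
  }
  cohorts <- lapply(cohorts, function(co) knn_impute(minmax_normalize(co)))
  ref <- cohorts[[1]]
  tests <- cohorts[-1]
  de <- de_rank(ref, top_k = top_k)
  emit(de$de, "de_table.tsv", write_de_tsv)
  emit(de$ranking, "ranking_initial.tsv", write_ranking_tsv)
  deg <- de$ranking$gene
  ref_deg <- ref; ref_deg$values <- ref$values[deg, , drop = FALSE]

  rankings <- list(initial = de$ranking)
  for (m in methods) {
    net <- infer(ref_deg, m, config = c(infer_config[[m]],
                                        list(seed = seed)))
    rankings[[m]] <- rerank_genes(net, de, q = q, provenance = m)
    emit(rankings[[m]], paste0("ranking_", m, ".tsv"), write_ranking_tsv)
  }
  scores <- lapply(rankings, function(rg) {
    curve <- sequential_svm_curve(ref, tests, rg, N_max = N_max,
                                  seed = seed)
    score_ranking(curve)
  })
  score_tab <- rank_methods(lapply(scores, function(s)
    c(condition1 = s$score)))
  emit(score_tab, "method_scores.tsv", write_scores_tsv)
  best <- setdiff(score_tab$method, "initial")[1]

  nets <- lapply(cohorts, function(co) {
    cod <- co; cod$values <- co$values[deg, , drop = FALSE]
    infer(cod, best, config = c(infer_config[[best]], list(seed = seed)))
  })
  common <- common_edges(nets)
  pattern <- dynamic_filter(common, filter_fraction = filter_fraction)
  emit(pattern, "pattern.tsv", write_network_tsv)
  top <- top_interactions(pattern, 100)

  stage_tab <- read_drug_table(system.file("extdata", "table_stages.tsv",
                                           package = "coexrank"))
  subtype_tab <- read_drug_table(system.file("extdata",
                                             "table_subtypes.tsv",
                                             package = "coexrank"))
  drugs <- list(
    stage_unique = count_unique(stage_tab),
    subtype_unique = count_unique(subtype_tab),
    stage_exclusive = lapply(setNames(nm = conditions_of(stage_tab)),
                             function(cc) exclusive_drugs(stage_tab, cc)),
    subtype_exclusive = lapply(setNames(nm = conditions_of(subtype_tab)),
                               function(cc) exclusive_drugs(subtype_tab, cc)),
    stage_common = common_in_all(stage_tab),
    subtype_common = common_in_all(subtype_tab))

  report <- list(n_cohorts = length(cohorts), n_deg = length(deg),
                 methods = methods, best_method = best,
                 scores = lapply(scores, function(s) s$score),
                 pattern_nodes = length(network_genes(pattern)),
                 pattern_edges = nrow(pattern),
                 seed = seed, drug_summary = drugs)
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  c(report,
    list(de = de, rankings = rankings, pattern = pattern,
         top_interactions = top))
}
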