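#' Specification for a synthetic multi-cohort study
#'
#' Defines the generative model for a set of tumor/normal expression
#' cohorts with (i) planted differentially expressed (DE) genes, (ii) a
#' planted co-expression module that is conserved across cohorts, and
#' (iii) cohort-specific nuisance blocks that are *not* conserved. The
#' module follows a single-factor model: for tumor sample s, a module gene
#' takes the value `baseline + latent_loading * f_s + noise`, with
#' `f_s ~ N(0, 1)` drawn per sample and per cohort. The expected pairwise
#' correlation among module genes within tumor samples is therefore
#' `latent_loading^2 / (latent_loading^2 + noise_sd^2)` in every cohort.
#' Nuisance blocks use the same factor construction (over all samples) but
#' their gene membership and factor values are re-drawn per cohort, so
#' intersecting networks across cohorts prunes them.
#'
#' Defaults emulate a small multi-cohort microarray compendium: a few
#' hundred genes after DE pre-selection, cohorts of a few dozen samples
#' with roughly 2:1 tumor:normal ratio, an effect size of two residual
#' standard deviations for planted DE genes, and a 15-gene conserved
#' module.
#'
#' @param n_genes Total number of genes.
#' @param n_tumor,n_normal Samples per group in every cohort.
#' @param n_cohorts Number of cohorts to generate.
#' @param de_genes Number of planted DE genes (tumor mean shifted by
#'   `effect_size`, alternating sign).
#' @param effect_size Mean shift (expression units) for planted DE genes.
#' @param module_genes Number of genes in the planted conserved module.
#' @param latent_loading Loading of module (and nuisance) genes on their
#'   latent factor.
#' @param noise_sd Residual standard deviation.
#' @param nuisance_blocks Number of cohort-specific correlated blocks.
#' @param block_size Genes per nuisance block.
#' @param module_delta Optional tumor mean shift applied to module genes
#'   (0 keeps DE and module gene sets disjoint in effect; set it positive
#'   to make the module genes differentially expressed as well).
#' @param missing_rate Fraction of entries set missing, in [0, 1).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_genes = 300, n_tumor = 40, n_normal = 20,
                        n_cohorts = 5, de_genes = 30, effect_size = 1,
                        module_genes = 15, latent_loading = 1,
                        noise_sd = 0.5, nuisance_blocks = 3,
                        block_size = 15, module_delta = 0,
                        missing_rate = 0, seed = 1) {
  spec <- list(n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
               n_cohorts = n_cohorts, de_genes = de_genes,
               effect_size = effect_size, module_genes = module_genes,
               latent_loading = latent_loading, noise_sd = noise_sd,
               nuisance_blocks = nuisance_blocks, block_size = block_size,
               module_delta = module_delta, missing_rate = missing_rate,
               seed = seed)
  counts <- c("n_genes", "n_tumor", "n_normal", "n_cohorts")
  for (f in counts)
    if (!is.numeric(spec[[f]]) || spec[[f]] < 1 || spec[[f]] != round(spec[[f]]))
      stop("`", f, "` must be a positive integer")
  if (de_genes < 0 || module_genes < 0 || nuisance_blocks < 0)
    stop("gene counts must be non-negative")
  if (de_genes + module_genes > n_genes)
    stop("de_genes + module_genes must not exceed n_genes")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (nuisance_blocks * block_size > n_genes - de_genes - module_genes)
    stop("nuisance blocks do not fit among the background genes")
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic multi-cohort expression study
#'
#' Draws `n_cohorts` tumor/normal cohorts over a shared gene universe
#' according to a [cohort_spec()], together with the planted ground truth.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `cohorts` (list of [cohort()]) and `truth`, a list
#'   holding `de_gene_ids`, `module_gene_ids`, `module_edges` (all
#'   unordered module gene pairs), per-cohort latent factor values and
#'   per-cohort nuisance block membership.
#' @examples
#' sim <- generate_cohort_set(cohort_spec(n_genes = 60, n_cohorts = 2,
#'                                        seed = 7))
#' sim$cohorts[[1]]
#' @export
generate_cohort_set <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  de_ids <- sort(sample(genes, spec$de_genes))
  module_ids <- sort(sample(setdiff(genes, de_ids), spec$module_genes))
  background <- setdiff(genes, c(de_ids, module_ids))
  baseline <- setNames(rnorm(spec$n_genes, mean = 7, sd = 1), genes)
  de_sign <- setNames(rep_len(c(1, -1), spec$de_genes), de_ids)

  n <- spec$n_tumor + spec$n_normal
  labels <- c(rep("tumor", spec$n_tumor), rep("normal", spec$n_normal))
  tumor_idx <- seq_len(spec$n_tumor)

  module_edges <- if (spec$module_genes >= 2) {
    cmb <- combn(module_ids, 2)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ])
  } else data.frame(gene_a = character(), gene_b = character())

  cohorts <- vector("list", spec$n_cohorts)
  factors <- vector("list", spec$n_cohorts)
  blocks <- vector("list", spec$n_cohorts)
  for (ci in seq_len(spec$n_cohorts)) {
    id <- sprintf("cohort%02d", ci)
    x <- matrix(rnorm(spec$n_genes * n, sd = spec$noise_sd), spec$n_genes, n,
                dimnames = list(genes, sprintf("%s_s%03d", id, seq_len(n))))
    x <- x + baseline
    if (spec$de_genes > 0)
      x[de_ids, tumor_idx] <- x[de_ids, tumor_idx] +
        de_sign * spec$effect_size
    f <- rnorm(spec$n_tumor)
    if (spec$module_genes > 0) {
      x[module_ids, tumor_idx] <- x[module_ids, tumor_idx] +
        rep(spec$latent_loading * f, each = spec$module_genes)
      if (spec$module_delta != 0)
        x[module_ids, tumor_idx] <- x[module_ids, tumor_idx] +
          spec$module_delta
    }
    blk <- list()
    if (spec$nuisance_blocks > 0) {
      pool <- sample(background)
      for (b in seq_len(spec$nuisance_blocks)) {
        members <- sort(pool[seq.int((b - 1) * spec$block_size + 1,
                                     b * spec$block_size)])
        g <- rnorm(n)
        x[members, ] <- x[members, ] +
          rep(spec$latent_loading * g, each = spec$block_size)
        blk[[b]] <- members
      }
    }
    if (spec$missing_rate > 0) {
      nmiss <- rbinom(1, length(x), spec$missing_rate)
      x[sample(length(x), nmiss)] <- NA_real_
    }
    cohorts[[ci]] <- cohort(x, labels, id)
    factors[[ci]] <- f
    blocks[[ci]] <- blk
  }
  list(cohorts = cohorts,
       truth = list(de_gene_ids = de_ids, module_gene_ids = module_ids,
                    module_edges = module_edges, tumor_factors = factors,
                    nuisance_blocks = blocks))
}

#' Write planted truth as JSON
#'
#' @param truth The `truth` element of [generate_cohort_set()].
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Generate a synthetic drug-by-condition indicator table
#'
#' Each drug is present in a condition independently with probability
#' `1 - sparsity`; rows that would be empty are given one random
#' condition, so every drug appears at least once.
#'
#' @param n_drugs Number of drugs.
#' @param conditions Character vector of condition names (non-empty).
#' @param sparsity Fraction in [0, 1): probability a given drug/condition
#'   cell is absent.
#' @param seed Integer seed.
#' @return A [drug_table()].
#' @export
generate_drug_table <- function(n_drugs, conditions, sparsity = 0.5,
                                seed = 1) {
  if (length(conditions) < 1) stop("`conditions` must be non-empty")
  if (n_drugs < 1) stop("`n_drugs` must be >= 1")
  if (sparsity < 0 || sparsity >= 1) stop("`sparsity` must be in [0, 1)")
  set.seed(seed)
  m <- matrix(rbinom(n_drugs * length(conditions), 1, 1 - sparsity),
              n_drugs, length(conditions),
              dimnames = list(NULL, conditions))
  empty <- rowSums(m) == 0
  if (any(empty))
    m[cbind(which(empty), sample(length(conditions), sum(empty),
                                 replace = TRUE))] <- 1
  df <- data.frame(drug = sprintf("drug%03d", seq_len(n_drugs)), m,
                   check.names = FALSE)
  drug_table(df)
}

#' Generate random bit-vector fingerprints with planted similar pairs
#'
#' Bits are independent Bernoulli(`density`). For each planted pair
#' `(i, j)`, item j is rebuilt to share enough of item i's set bits that
#' the *expected* Tanimoto similarity of the pair is at least
#' `similarity_target` (with `similarity_target = 1` the pair is
#' identical).
#'
#' @param n_items Number of fingerprints (0 allowed).
#' @param n_bits Bits per fingerprint (>= 8).
#' @param planted_pairs List of integer pairs (indices into the item set).
#' @param similarity_target Fraction in [0, 1].
#' @param density Bernoulli bit density.
#' @param seed Integer seed.
#' @return A named list of logical vectors (class `fingerprints`).
#' @export
generate_fingerprints <- function(n_items, n_bits = 1024,
                                  planted_pairs = list(),
                                  similarity_target = 0.8, density = 0.1,
                                  seed = 1) {
  if (n_bits < 8) stop("`n_bits` must be >= 8")
  for (p in planted_pairs)
    if (length(p) != 2 || any(p < 1) || any(p > n_items))
      stop("planted pair index out of range")
  set.seed(seed)
  fps <- vector("list", n_items)
  names(fps) <- if (n_items > 0) sprintf("item%03d", seq_len(n_items))
  for (i in seq_len(n_items))
    fps[[i]] <- runif(n_bits) < density
  for (p in planted_pairs) {
    i <- p[1]; j <- p[2]
    if (similarity_target >= 1) { fps[[j]] <- fps[[i]]; next }
    on_i <- which(fps[[i]])
    m <- length(on_i)
    if (m == 0) { fps[[j]] <- fps[[i]]; next }
    # shared bits s so that s / (2m - s) >= target
    s <- min(m, ceiling(2 * m * similarity_target / (1 + similarity_target)))
    keep <- sample(on_i, s)
    fresh <- sample(setdiff(seq_len(n_bits), on_i), m - s)
    v <- rep(FALSE, n_bits)
    v[c(keep, fresh)] <- TRUE
    fps[[j]] <- v
  }
  structure(fps, class = "fingerprints")
}

#' Write / read fingerprints as a name + hex-string TSV
#'
#' Bit vectors are hex-encoded 4 bits per character (most significant bit
#' first); the true bit length is stored in an `n_bits` column.
#'
#' @param fps A `fingerprints` list (logical vectors).
#' @param path TSV path.
#' @return `read_fingerprints_tsv` returns a `fingerprints` list.
#' @export
write_fingerprints_tsv <- function(fps, path) {
  hexchars <- strsplit("0123456789abcdef", "")[[1]]
  enc <- vapply(fps, function(bits) {
    pad <- (-length(bits)) %% 4
    b <- matrix(as.integer(c(bits, rep(FALSE, pad))), nrow = 4)
    paste(hexchars[colSums(b * c(8, 4, 2, 1)) + 1], collapse = "")
  }, character(1))
  df <- data.frame(name = names(fps), n_bits = lengths(fps), hex = enc)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints_tsv
#' @export
read_fingerprints_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character"))
  fps <- lapply(seq_len(nrow(df)), function(i) {
    nib <- strtoi(strsplit(df$hex[i], "")[[1]], base = 16L)
    bits <- as.vector(vapply(nib, function(v) bitwAnd(v, c(8, 4, 2, 1)) > 0,
                             logical(4)))
    bits[seq_len(df$n_bits[i])]
  })
  names(fps) <- df$name
  structure(fps, class = "fingerprints")
}
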