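#' Tissue-specificity vectors from a gene x tissue expression matrix
#'
#' Within each tissue, genes are ranked by mean expression (ascending,
#' midranks for ties) and ranks are scaled to `[0, 1]` by
#' `(rank - 1)/(n_genes - 1)`; each gene's cross-tissue vector of scaled
#' ranks is then divided by its Euclidean norm. The result reflects
#' whether a gene is expressed in a given tissue but not in others, and
#' is invariant to any monotone transformation of within-tissue
#' expression. Genes ranked bottom in every tissue (all-zero vectors)
#' are given the uniform vector `1/sqrt(T)` and flagged.
#'
#' @param expr numeric matrix, genes in rows (rownames), tissues in
#'   columns (colnames); per-tissue mean expression (RPKM-like units).
#' @return class `pln_tissue_spec`: `tissues`, `vectors` (gene x tissue
#'   matrix, unit row norms), `mean_expr`, `flagged_zero` (gene ids).
#' @export
specificity_vectors <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("at least 2 tissues are required")
  if (nrow(expr) < 2) stop("at least 2 genes are required")
  n <- nrow(expr)
  scaled <- apply(expr, 2, function(v) (rank(v, ties.method = "average") - 1) / (n - 1))
  rownames(scaled) <- rownames(expr)
  norms <- sqrt(rowSums(scaled^2))
  flagged <- rownames(scaled)[norms == 0]
  vectors <- scaled / ifelse(norms > 0, norms, 1)
  vectors[norms == 0, ] <- 1 / sqrt(ncol(expr))
  structure(list(tissues = colnames(expr), vectors = vectors,
                 mean_expr = expr, flagged_zero = flagged),
            class = "pln_tissue_spec")
}

#' Tissue-specific expression enrichment of a gene set
#'
#' Per tissue, the observed statistic is the summed specificity-vector
#' component of the set's genes; the null recomputes it for
#' CDS-length-matched random gene sets (one shared batch of draws for
#' all tissues). Per-tissue one-sided empirical p-values are
#' BH-adjusted across tissues.
#'
#' @param gene_set query genes (rows of the specificity matrix).
#' @param spec a `pln_tissue_spec`.
#' @param universe gene pool for matched draws.
#' @param stats a `pln_gene_stats`.
#' @param n_perm permutations (default 999).
#' @param covariates matching covariates (default CDS length).
#' @param rng_seed integer seed.
#' @return data.table: `tissue`, `observed`, `p`, `q`.
#' @export
tissue_enrichment <- function(gene_set, spec, universe, stats,
                              n_perm = 999L, covariates = "cds_length",
                              rng_seed = 1L) {
  stopifnot(inherits(spec, "pln_tissue_spec"))
  if (length(gene_set) == 0) stop("empty gene set")
  universe <- intersect(universe, rownames(spec$vectors))
  if (!all(gene_set %in% universe))
    stop("gene_set must lie in the universe and specificity matrix")
  obs <- colSums(spec$vectors[gene_set, , drop = FALSE])
  set.seed(rng_seed)
  draw <- matched_sampler(universe, gene_set, stats, covariates)
  null <- matrix(0, n_perm, length(spec$tissues))
  for (b in seq_len(n_perm))
    null[b, ] <- colSums(spec$vectors[draw(), , drop = FALSE])
  p <- vapply(seq_along(spec$tissues), function(k)
    empirical_p(obs[k], null[, k], "greater"), numeric(1))
  data.table(tissue = spec$tissues, observed = unname(obs), p = p,
             q = adjust_pvalues(p, "BH"))
}
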