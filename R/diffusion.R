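#' Column-stochastic transition matrix of a network
#'
#' `U[i, j] = w(i, j) / weighted_degree(j)`: each nonzero column sums
#' to 1, the random-walk convention that guarantees convergence of the
#' restart iteration for any back probability above 0. Isolated genes
#' (zero weighted degree) keep zero columns and are recorded.
#'
#' @param net a `pln_network`.
#' @param genes optional node ordering (default: `net$genes`); extra
#'   names add isolated nodes.
#' @return class `pln_transition`: `U` (sparse dgCMatrix), `genes`,
#'   `isolated_genes`.
#' @export
normalize_adjacency <- function(net, genes = NULL) {
  stopifnot(inherits(net, "pln_network"))
  if (nrow(net$links) == 0) stop("empty network")
  genes <- genes %||% net$genes
  stopifnot(all(net$genes %in% genes))
  n <- length(genes)
  i <- match(c(net$links$gene_a, net$links$gene_b), genes)
  j <- match(c(net$links$gene_b, net$links$gene_a), genes)
  w <- rep(net$links$weight, 2L)
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n),
                            dimnames = list(genes, genes))
  colsum <- Matrix::colSums(A)
  isolated <- genes[colsum == 0]
  scale <- ifelse(colsum > 0, 1 / colsum, 0)
  U <- A %*% Matrix::Diagonal(n, scale)
  dimnames(U) <- list(genes, genes)
  structure(list(U = U, genes = genes, isolated_genes = isolated),
            class = "pln_transition")
}

#' Diffusion configuration
#'
#' @param alpha back probability in `(0, 1]`: restart mass returned to
#'   the seed genes at each iteration (default 0.5).
#' @param iterations number of update iterations (default 100).
#' @param n_null_draws random seed-set draws for empirical significance.
#' @return a list of class `pln_diffusion_config`.
#' @export
diffusion_config <- function(alpha = 0.5, iterations = 100L, n_null_draws = 999L) {
  stopifnot(alpha > 0, alpha <= 1, iterations >= 1)
  structure(list(alpha = alpha, iterations = as.integer(iterations),
                 n_null_draws = as.integer(n_null_draws)),
            class = "pln_diffusion_config")
}

seed_vector <- function(trans, seeds) {
  if (length(seeds) == 0) stop("empty seed set")
  missing <- setdiff(seeds, trans$genes)
  if (length(missing))
    stop("seed gene(s) not in network: ", paste(head(missing, 5), collapse = ", "))
  f0 <- setNames(numeric(length(trans$genes)), trans$genes)
  f0[seeds] <- 1 / length(seeds)
  f0
}

#' Propagate seed signal by iterative ranking
#'
#' Iterates `f_{t+1} = alpha * f0 + (1 - alpha) * U f_t` exactly
#' `iterations` times from `f0` uniform over the seed set, spreading the
#' seeds' signal to directly and indirectly connected genes.
#'
#' @param trans a `pln_transition`.
#' @param seeds character vector of seed genes (all in the network).
#' @param cfg a `pln_diffusion_config`.
#' @return class `pln_diffusion`: `scores` (named, non-negative),
#'   `seed_set`, `alpha`, `iterations`.
#' @export
propagate <- function(trans, seeds, cfg = diffusion_config()) {
  stopifnot(inherits(trans, "pln_transition"))
  f0 <- seed_vector(trans, seeds)
  f <- f0
  for (t in seq_len(cfg$iterations))
    f <- cfg$alpha * f0 + (1 - cfg$alpha) * as.numeric(trans$U %*% f)
  structure(list(scores = setNames(as.numeric(f), trans$genes),
                 seed_set = seeds, alpha = cfg$alpha,
                 iterations = cfg$iterations),
            class = "pln_diffusion")
}

#' Stationary diffusion scores by direct linear solve
#'
#' Exact fixed point `f* = alpha * (I - (1 - alpha) U)^{-1} f0` of the
#' iterative update; used to bound the error of the finite iteration.
#'
#' @inheritParams propagate
#' @param alpha back probability (> 0).
#' @return named numeric score vector.
#' @export
closed_form_scores <- function(trans, seeds, alpha = 0.5) {
  stopifnot(alpha > 0)
  f0 <- seed_vector(trans, seeds)
  n <- length(f0)
  M <- Matrix::Diagonal(n) - (1 - alpha) * trans$U
  f <- alpha * Matrix::solve(M, f0)
  setNames(as.numeric(f), trans$genes)
}

#' Empirical significance of diffusion scores
#'
#' Reruns the propagation from `n_null_draws` uniformly sampled random
#' seed sets of the same size and computes, per gene, the add-one
#' empirical p-value of its observed score against the null score
#' distribution.
#'
#' @param trans a `pln_transition`.
#' @param seeds observed seed genes.
#' @param cfg a `pln_diffusion_config` (`n_null_draws >= 99`).
#' @param rng_seed integer seed for the null draws.
#' @return a `pln_diffusion` with additional fields `p_mono` (named,
#'   in `(0, 1]`), `n_null_draws`, `rng_seed`. Isolated genes get
#'   score 0 and `p_mono` 1.
#' @export
seed_significance <- function(trans, seeds, cfg = diffusion_config(),
                              rng_seed = 1L) {
  stopifnot(cfg$n_null_draws >= 99)
  if (length(seeds) > length(trans$genes))
    stop("network smaller than the seed set")
  obs <- propagate(trans, seeds, cfg)
  exceed <- setNames(integer(length(trans$genes)), trans$genes)
  set.seed(rng_seed)
  for (b in seq_len(cfg$n_null_draws)) {
    null_seeds <- sample(trans$genes, length(seeds))
    fb <- propagate(trans, null_seeds, cfg)$scores
    exceed <- exceed + (fb >= obs$scores)
  }
  p <- (1 + exceed) / (1 + cfg$n_null_draws)
  p[trans$genes %in% trans$isolated_genes] <- 1
  obs$p_mono <- p
  obs$n_null_draws <- cfg$n_null_draws
  obs$rng_seed <- rng_seed
  obs
}

#' Do significantly linked genes concentrate in genomic intervals?
#'
#' Counts genes with `p_mono < p_cut` lying in any interval and compares
#' that count with the same statistic under circular gene-rank shifts of
#' the intervals, which preserve interval gene counts and genomic
#' clustering.
#'
#' @param result a `pln_diffusion` carrying `p_mono`.
#' @param intervals a `pln_intervals` (see [genomic_intervals()]).
#' @param p_cut significance cut on `p_mono` (default 0.05).
#' @param n_shifts number of random shifts (default 1000).
#' @param rng_seed integer seed.
#' @return class `pln_enrichment` (observed count, null draws, p).
#' @export
interval_linkage_test <- function(result, intervals, p_cut = 0.05,
                                  n_shifts = 1000L, rng_seed = 1L) {
  stopifnot(inherits(result, "pln_diffusion"), !is.null(result$p_mono))
  member_genes <- unique(unlist(intervals$gene_members, use.names = FALSE))
  if (!any(member_genes %in% names(result$p_mono)))
    stop("intervals cover no network genes")
  sig <- names(result$p_mono)[result$p_mono < p_cut]
  tabs <- interval_offset_tables(intervals, sig, "genes_in")
  set.seed(rng_seed)
  res <- shift_null_from_tables(tabs, n_shifts)
  enrichment_result(res$observed, res$null, alternative = "greater",
                    method = "none", rng_seed = rng_seed)
}
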