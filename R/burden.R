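#' Case/control variant-count data
#'
#' @param counts named non-negative integer vector: per-individual
#'   protein-truncating-variant count within the gene set of interest.
#' @param labels named character vector (`"case"`/`"control"`), same
#'   individuals. Individuals missing a count are excluded listwise
#'   (reported via message).
#' @return class `pln_case_control`: `counts`, `labels`, `n_cases`,
#'   `n_controls`.
#' @export
case_control_counts <- function(counts, labels) {
  stopifnot(!is.null(names(counts)), !is.null(names(labels)))
  common <- intersect(names(counts), names(labels))
  dropped <- length(union(names(counts), names(labels))) - length(common)
  if (dropped > 0)
    message(dropped, " individual(s) without both count and label excluded")
  counts <- counts[common]
  labels <- labels[common]
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  structure(list(counts = counts, labels = labels,
                 n_cases = sum(labels == "case"),
                 n_controls = sum(labels == "control")),
            class = "pln_case_control")
}

#' Case/control rate-difference burden test
#'
#' `d_obs = x_cases/n_cases - x_controls/n_controls`, the difference in
#' per-individual variant rates; its two-sided empirical p-value comes
#' from permuting case/control status across individuals while holding
#' group sizes fixed.
#'
#' @param data a `pln_case_control` (both groups nonempty).
#' @param n_perm permutations (default 999).
#' @param rng_seed integer seed.
#' @return class `pln_burden`: `d_obs`, `perm_p`, `n_perm`,
#'   `direction`, `rng_seed`.
#' @export
dobs_test <- function(data, n_perm = 999L, rng_seed = 1L) {
  stopifnot(inherits(data, "pln_case_control"))
  if (data$n_cases == 0 || data$n_controls == 0)
    stop("both groups must be nonempty")
  x <- data$counts
  is_case <- data$labels == "case"
  d_obs <- sum(x[is_case]) / data$n_cases - sum(x[!is_case]) / data$n_controls
  total <- sum(x)
  n <- length(x)
  set.seed(rng_seed)
  null <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, data$n_cases)
    xc <- sum(x[idx])
    xc / data$n_cases - (total - xc) / data$n_controls
  }, numeric(1))
  structure(list(d_obs = d_obs,
                 perm_p = empirical_p(d_obs, null, "two.sided"),
                 n_perm = n_perm, direction = sign(d_obs),
                 rng_seed = rng_seed, null = null),
            class = "pln_burden")
}

#' Logistic-regression burden: per-variant odds ratio
#'
#' Maximum-likelihood fit of `logit P(case) = beta0 + beta1 * count`;
#' the per-variant odds ratio is `exp(beta1)` with a Wald 95% interval
#' `exp(beta1 +/- 1.96 se)`. Complete separation is flagged
#' (`converged = FALSE`) rather than reported as an estimate.
#'
#' @param data a `pln_case_control` with at least two distinct counts.
#' @return class `pln_logistic_burden`: `beta0`, `beta1`, `or`, `ci95`,
#'   `converged`.
#' @export
logistic_burden <- function(data) {
  stopifnot(inherits(data, "pln_case_control"))
  if (length(unique(data$counts)) < 2)
    stop("constant variant count: odds ratio is undefined")
  y <- as.integer(data$labels == "case")
  x <- as.numeric(data$counts)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[2]
  converged <- fit$converged && !sep_warn && abs(b[2]) < 15
  structure(list(beta0 = unname(b[1]), beta1 = unname(b[2]),
                 or = unname(exp(b[2])),
                 ci95 = unname(exp(b[2] + c(-1.96, 1.96) * se)),
                 converged = converged),
            class = "pln_logistic_burden")
}

#' @export
print.pln_logistic_burden <- function(x, ...) {
  cat("Logistic burden: OR =", format(x$or, digits = 3),
      "[", format(x$ci95[1], digits = 3), "-",
      format(x$ci95[2], digits = 3), "]",
      if (!x$converged) "(NOT converged / separated)" else "", "\n")
  invisible(x)
}

#' Gene-set burden from per-gene association p-values
#'
#' Observed statistic: `sum(-log10 p)` over the gene set (p-values from
#' an upstream per-gene association test, consumed as input). The null
#' recomputes the sum for CDS-length-matched random gene sets.
#'
#' @param gene_p named numeric vector of per-gene p-values in `(0, 1]`.
#' @param gene_set genes to test (subset of `names(gene_p)`).
#' @param universe gene pool for matched draws.
#' @param stats a `pln_gene_stats`.
#' @param n_perm permutations (default 999).
#' @param covariates matching covariates (default CDS length).
#' @param rng_seed integer seed.
#' @return a `pln_enrichment`.
#' @export
pval_set_burden <- function(gene_p, gene_set, universe, stats,
                            n_perm = 999L, covariates = "cds_length",
                            rng_seed = 1L) {
  stopifnot(all(gene_set %in% names(gene_p)), all(universe %in% names(gene_p)))
  if (any(gene_p <= 0 | gene_p > 1)) stop("p-values must lie in (0, 1]")
  stat <- function(g) sum(-log10(gene_p[g]))
  observed <- stat(gene_set)
  set.seed(rng_seed)
  draw <- matched_sampler(universe, gene_set, stats, covariates)
  null <- vapply(seq_len(n_perm), function(b) stat(draw()), numeric(1))
  enrichment_result(observed, null, "greater", "none", rng_seed)
}

#' Top-k most strongly associated genes
#'
#' @param gene_p named numeric per-gene p-values.
#' @param k number of genes (default 300).
#' @return character vector of the `k` smallest-p genes, ties broken by
#'   gene id.
#' @export
select_top_genes <- function(gene_p, k = 300L) {
  if (k > length(gene_p)) stop("k exceeds the number of genes")
  ord <- order(gene_p, names(gene_p))
  names(gene_p)[ord][seq_len(k)]
}
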