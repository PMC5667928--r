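#' @import data.table
#' @importFrom stats median lm anova glm binomial coef vcov residuals
#'   p.adjust quantile rnorm runif rpois cor setNames
#' @importFrom utils head tail packageVersion
NULL

# canonical pair key: gene_a < gene_b lexicographically
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(gene_a = a, gene_b = b)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' A single master seed fans out to per-component seeds so that each
#' randomized stage is reproducible in isolation. The rule is
#' `(master * 7919 + sum(utf8(tag)) * 104729) mod (2^31 - 1)`.
#'
#' @param seed integer master seed.
#' @param tag character label of the component.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag))
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 7919 + h * 104729) %% 2147483647)
}

#' Add-one empirical p-value
#'
#' `(1 + exceedances) / (1 + n_null)`: never zero, bounded in
#' `[1/(n+1), 1]`.
#'
#' @param observed observed statistic (scalar).
#' @param null numeric vector of null draws.
#' @param alternative `"greater"` (enrichment), `"less"`, or
#'   `"two.sided"` (on absolute values).
#' @return empirical p-value.
#' @export
empirical_p <- function(observed, null, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  exc <- switch(alternative,
    greater   = sum(null >= observed),
    less      = sum(null <= observed),
    two.sided = sum(abs(null) >= abs(observed)))
  (1 + exc) / (1 + length(null))
}

# validate a pair data.table (gene_a, gene_b, value column)
assert_pair_table <- function(dt, value_col = "score") {
  stopifnot(is.data.table(dt), all(c("gene_a", "gene_b", value_col) %in% names(dt)))
  if (any(dt$gene_a == dt$gene_b)) stop("self-pairs are not allowed")
  if (any(dt$gene_a > dt$gene_b)) stop("pairs must be canonical (gene_a < gene_b)")
  invisible(dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
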