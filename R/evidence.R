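#' Construct an evidence dataset from a pair-score table
#'
#' @param pairs data.frame/data.table with columns `gene_a`, `gene_b`,
#'   `score` (higher = stronger evidence). Pairs are canonicalized to
#'   `gene_a < gene_b`; self-pairs are rejected; duplicate pairs with
#'   conflicting scores are an error.
#' @param name dataset label.
#' @return object of class `pln_evidence` (`name`, `pairs`, `coverage`).
#' @export
evidence_dataset <- function(pairs, name = "evidence") {
  dt <- as.data.table(pairs)[, c("gene_a", "gene_b", "score")]
  cp <- canonical_pairs(dt$gene_a, dt$gene_b)
  dt[, `:=`(gene_a = cp$gene_a, gene_b = cp$gene_b)]
  if (any(dt$gene_a == dt$gene_b)) stop("self-pairs are not allowed in evidence")
  dup <- dt[, .N, by = .(gene_a, gene_b)][N > 1L]
  if (nrow(dup)) {
    conf <- dt[dup, on = c("gene_a", "gene_b")][, .(k = uniqueN(score)), by = .(gene_a, gene_b)]
    if (any(conf$k > 1L))
      stop("duplicate pairs with conflicting scores, e.g. ",
           conf[k > 1L][1L, paste(gene_a, gene_b)])
    dt <- unique(dt, by = c("gene_a", "gene_b"))
  }
  setkey(dt, gene_a, gene_b)
  structure(list(name = name, pairs = dt, coverage = nrow(dt)),
            class = "pln_evidence")
}

#' @export
print.pln_evidence <- function(x, ...) {
  cat("Evidence dataset '", x$name, "': ", x$coverage, " gene pairs\n", sep = "")
  invisible(x)
}

#' Co-expression evidence from an expression matrix
#'
#' Scores every gene pair by the Pearson correlation of their expression
#' profiles. Genes with zero variance across samples cannot be
#' correlated and are excluded (reported via the `dropped` attribute).
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns; at least 3 samples.
#' @param name dataset label.
#' @return a `pln_evidence` of correlation scores.
#' @export
coexpression_scores <- function(expr, name = "coexpression") {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  v <- apply(expr, 1, stats::var)
  dropped <- rownames(expr)[v == 0]
  expr <- expr[v > 0, , drop = FALSE]
  if (nrow(expr) < 2) stop("fewer than 2 genes with nonzero variance")
  C <- cor(t(expr))
  ut <- upper.tri(C)
  idx <- which(ut, arr.ind = TRUE)
  ds <- evidence_dataset(data.table(gene_a = rownames(C)[idx[, 1]],
                                    gene_b = rownames(C)[idx[, 2]],
                                    score = C[ut]), name = name)
  attr(ds, "dropped") <- dropped
  ds
}

# deterministic descending-score order with lexicographic pair tie-break
order_pairs_desc <- function(dt, score_col = "score") {
  dt[order(-get(score_col), gene_a, gene_b)]
}

#' Bin an evidence dataset against a phenotypic benchmark
#'
#' Pairs covered by the benchmark are sorted by descending raw score
#' (ties broken lexicographically by pair id) and cut into consecutive
#' bins of `bin_size` pairs; the per-bin medians of raw score and
#' benchmark similarity form the dataset's evaluation curve.
#'
#' @param ds a `pln_evidence`.
#' @param bench a `pln_benchmark`.
#' @param bin_size pairs per bin (default 500).
#' @return class `pln_bin_profile`: `bins` (data.table `bin_index`,
#'   `median_score`, `median_similarity`, `n_pairs`), `bin_size`,
#'   `overall_median` (of the whole benchmark), `binned_pairs` (the
#'   sorted pair table with its bin assignment), `name`.
#' @export
bin_profile <- function(ds, bench, bin_size = 500) {
  stopifnot(inherits(ds, "pln_evidence"), inherits(bench, "pln_benchmark"),
            bin_size >= 1)
  dt <- copy(ds$pairs)
  dt[, similarity := benchmark_lookup(bench, gene_a, gene_b)]
  dt <- dt[!is.na(similarity)]
  if (nrow(dt) == 0) stop("dataset '", ds$name, "' has no overlap with the benchmark")
  dt <- order_pairs_desc(dt)
  dt[, bin_index := ((seq_len(.N) - 1L) %/% as.integer(bin_size)) + 1L]
  bins <- dt[, .(median_score = median(score),
                 median_similarity = median(similarity),
                 n_pairs = .N), by = bin_index]
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 overall_median = bench$overall_median,
                 binned_pairs = dt, name = ds$name),
            class = "pln_bin_profile")
}

# leading contiguous run of bins whose median similarity strictly
# exceeds the benchmark overall median
informative_bin_count <- function(profile) {
  above <- profile$bins$median_similarity > profile$overall_median
  if (!length(above) || !above[1]) return(0L)
  r <- rle(above)
  r$lengths[1]
}

#' Informativeness threshold of an evidence dataset
#'
#' Bins whose median benchmark similarity exceeds the similarity
#' expected for random pairs (the benchmark overall median) are
#' informative. The threshold is the median raw score of the last bin in
#' the leading informative run; below it the dataset carries no
#' phenotype signal and its pairs are discarded.
#'
#' Because each bin's median fluctuates symmetrically around the overall
#' median when scores carry no signal, a dataset whose scores are pure
#' noise still opens with a short spurious run about half the time. A
#' dataset is therefore only called informative when its leading run
#' spans at least `min_run` bins; under the no-signal null a run of 5
#' bins has probability about `2^-5` (~3%), and a rescoring curve could
#' not be fitted from fewer points anyway.
#'
#' @param profile a `pln_bin_profile`.
#' @param min_run minimum leading-run length (bins) for a dataset to
#'   count as informative (default 5).
#' @return the threshold raw score, or `NA` (the "uninformative
#'   dataset" sentinel) when the leading run is shorter than `min_run`.
#' @export
informative_cutoff <- function(profile, min_run = 5L) {
  stopifnot(inherits(profile, "pln_bin_profile"))
  k <- informative_bin_count(profile)
  if (k < min_run) return(NA_real_)
  profile$bins$median_score[k]
}

#' Fit the polynomial rescoring curve of an evidence dataset
#'
#' Least-squares polynomial of bin median similarity on bin median raw
#' score over the informative bins. The order starts at 1 and grows
#' while the nested-model ANOVA F-test prefers the richer fit at
#' `p < signif_level`, up to `max_degree`. Predictions are clamped to
#' `[0, max informative-bin median similarity]` so no rescored value can
#' leave the range the benchmark supports.
#'
#' @param profile a `pln_bin_profile`.
#' @param max_degree maximum polynomial order considered (default 6).
#' @param signif_level nested-F acceptance level (default 0.01).
#' @return class `pln_rescoring`: `degree`, `coefficients` (ascending
#'   powers), `threshold_score`, `clamp_range`, `name`.
#' @export
fit_rescoring <- function(profile, max_degree = 6, signif_level = 0.01,
                          min_run = 5L) {
  stopifnot(inherits(profile, "pln_bin_profile"), max_degree >= 1)
  k <- informative_bin_count(profile)
  if (k < max(3L, min_run))
    stop("dataset '", profile$name, "': too few informative bins (", k,
         ") to fit a rescoring curve")
  inf_bins <- profile$bins[seq_len(k)]
  x <- inf_bins$median_score
  y <- inf_bins$median_similarity
  max_degree <- min(max_degree, k - 2L, length(unique(x)) - 1L)
  if (max_degree < 1L)
    stop("dataset '", profile$name, "': degenerate informative bins")
  fit <- lm(y ~ poly(x, 1, raw = TRUE))
  degree <- 1L
  while (degree + 1L <= max_degree) {
    fit_next <- lm(y ~ poly(x, degree + 1L, raw = TRUE))
    if (sum(residuals(fit)^2) < 1e-12) break
    p <- anova(fit, fit_next)[["Pr(>F)"]][2]
    if (is.na(p) || p >= signif_level) break
    fit <- fit_next
    degree <- degree + 1L
  }
  structure(list(degree = degree,
                 coefficients = unname(coef(fit)),
                 threshold_score = informative_cutoff(profile, min_run),
                 clamp_range = c(0, max(y)),
                 name = profile$name),
            class = "pln_rescoring")
}

# evaluate polynomial with coefficients in ascending powers
polyval_asc <- function(coefs, x) {
  acc <- rep(0, length(x))
  for (j in rev(seq_along(coefs))) acc <- acc * x + coefs[j]
  acc
}

#' Replace raw evidence scores with predicted phenotype similarity
#'
#' Pairs at or above the informativeness threshold are mapped through
#' the fitted polynomial and clamped into the model's range; pairs below
#' the threshold are dropped. The mapping applies to every dataset pair,
#' including genes absent from the benchmark — this is what lets the
#' final network extend beyond phenotype-annotated genes.
#'
#' @param ds a `pln_evidence` (raw scores).
#' @param model a `pln_rescoring`, or `NA` (the uninformative sentinel).
#' @return a rescored `pln_evidence`, or `NULL` (with a warning) when
#'   the model is the uninformative sentinel.
#' @export
rescore <- function(ds, model) {
  if (length(model) == 1L && is.na(model)) {
    warning("dataset '", ds$name, "' is uninformative; dropped from integration")
    return(NULL)
  }
  stopifnot(inherits(ds, "pln_evidence"), inherits(model, "pln_rescoring"))
  dt <- ds$pairs[score >= model$threshold_score]
  if (nrow(dt) == 0) {
    warning("dataset '", ds$name, "' has no pairs above its threshold")
    return(NULL)
  }
  val <- polyval_asc(model$coefficients, dt$score)
  dt[, score := pmin(pmax(val, model$clamp_range[1]), model$clamp_range[2])]
  out <- evidence_dataset(dt, name = ds$name)
  attr(out, "rescored") <- TRUE
  out
}
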