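#' Rank-penalized weighted sum of corroborating evidence
#'
#' For one gene pair with rescored values from several datasets,
#' `WS = L0 + sum_i Li / (D * i)` where `L0` is the largest value and
#' the remaining values, sorted descending, are indexed `i = 1..n`.
#' Larger `D` down-weights corroborating evidence more strongly.
#'
#' @param values numeric vector of rescored link values for one pair.
#' @param D positive penalty divisor.
#' @return the WS weight (scalar).
#' @export
weighted_sum <- function(values, D) {
  if (length(values) == 0) stop("weighted_sum needs at least one value")
  stopifnot(D >= 1)
  v <- sort(values, decreasing = TRUE)
  if (length(v) == 1L) return(v)
  v[1] + sum(v[-1] / (D * seq_len(length(v) - 1L)))
}

# WS for many pairs at once: dt has columns gene_a, gene_b, score
# (one row per dataset contribution); returns pair table with ws
ws_table <- function(dt, D) {
  dt <- dt[order(gene_a, gene_b, -score)]
  dt[, rank0 := seq_len(.N) - 1L, by = .(gene_a, gene_b)]
  out <- dt[, .(ws = score[1] + sum(score[-1] / (D * rank0[-1]))),
            by = .(gene_a, gene_b)]
  out
}

#' Integration configuration
#'
#' @param D penalty divisor of the weighted sum (default: the first
#'   value of `D_range`; normally set from [select_D()]).
#' @param D_range candidate values searched by [select_D()].
#' @param top_links number of highest-weighted links retained.
#' @param bin_size bin size used when selecting `D`.
#' @return a list of class `pln_integration_config`.
#' @export
integration_config <- function(D = NULL, D_range = 1:20, top_links = 1e6,
                               bin_size = 500) {
  D <- D %||% D_range[1]
  stopifnot(D %in% D_range, top_links >= 1, bin_size >= 1)
  structure(list(D = as.integer(D), D_range = as.integer(D_range),
                 top_links = top_links, bin_size = as.integer(bin_size)),
            class = "pln_integration_config")
}

# stack rescored datasets into one long pair/score table
stack_datasets <- function(datasets) {
  datasets <- Filter(Negate(is.null), datasets)
  if (length(datasets) == 0) stop("no (informative) datasets to integrate")
  rbindlist(lapply(datasets, function(d) d$pairs[, .(gene_a, gene_b, score)]))
}

#' Select the weighted-sum penalty D against the benchmark
#'
#' For each candidate `D`, WS weights are computed for all
#' benchmark-covered pairs, sorted descending, binned, and the per-bin
#' median benchmark similarity is regressed on bin rank; the `D` whose
#' regression attains the smallest F-test p-value (ties to the smallest
#' `D`) best orders pairs by phenotype similarity.
#'
#' @param datasets list of rescored `pln_evidence` objects.
#' @param bench a `pln_benchmark`.
#' @param cfg a `pln_integration_config`.
#' @return list: `D` (selected), `table` (data.table `D`, `p_value`,
#'   `slope`, `n_bins`).
#' @export
select_D <- function(datasets, bench, cfg = integration_config()) {
  long <- stack_datasets(datasets)
  long[, similarity := benchmark_lookup(bench, gene_a, gene_b)]
  long <- long[!is.na(similarity)]
  if (nrow(long) == 0) stop("no dataset pair overlaps the benchmark")
  res <- rbindlist(lapply(cfg$D_range, function(D) {
    ws <- ws_table(long[, .(gene_a, gene_b, score)], D)
    ws[, similarity := benchmark_lookup(bench, gene_a, gene_b)]
    ws <- ws[order(-ws, gene_a, gene_b)]
    ws[, bin_index := ((seq_len(.N) - 1L) %/% cfg$bin_size) + 1L]
    bins <- ws[, .(med_sim = median(similarity)), by = bin_index]
    if (nrow(bins) < 3)
      return(data.table(D = D, p_value = NA_real_, slope = NA_real_,
                        n_bins = nrow(bins)))
    fit <- lm(med_sim ~ bin_index, data = bins)
    a <- anova(fit)
    data.table(D = D, p_value = a[["Pr(>F)"]][1],
               slope = unname(coef(fit)[2]), n_bins = nrow(bins))
  }))
  ok <- res[!is.na(p_value)]
  if (nrow(ok) == 0) stop("too few binned pairs to select D")
  best <- ok[p_value == min(p_value)][which.min(D)]
  list(D = best$D, table = res)
}

#' Integrate rescored evidence into a phenotypic-linkage network
#'
#' Computes the WS weight of every pair scored by at least one dataset,
#' sorts links by descending weight (lexicographic pair tie-break) and
#' keeps the `top_links` strongest.
#'
#' @param datasets list of rescored `pln_evidence` objects (`NULL`
#'   entries from dropped uninformative datasets are ignored).
#' @param cfg a `pln_integration_config`; `cfg$D` is the penalty used.
#' @return class `pln_network`: `links` (data.table `gene_a`, `gene_b`,
#'   `weight`, descending), `genes`, `degree`, `weighted_degree`, `D`.
#' @export
integrate_network <- function(datasets, cfg = integration_config()) {
  long <- stack_datasets(datasets)
  ws <- ws_table(long, cfg$D)
  setnames(ws, "ws", "weight")
  ws <- ws[weight > 0]
  ws <- ws[order(-weight, gene_a, gene_b)]
  if (nrow(ws) > cfg$top_links) ws <- ws[seq_len(cfg$top_links)]
  pln_network(ws, D = cfg$D)
}

#' Construct a PLN object from a weighted edge list
#'
#' @param links data.frame/data.table `gene_a`, `gene_b`, `weight`
#'   (strictly positive; pairs canonicalized; no self-links).
#' @param D penalty parameter recorded for provenance (optional).
#' @return a `pln_network`.
#' @export
pln_network <- function(links, D = NA_integer_) {
  dt <- as.data.table(links)[, c("gene_a", "gene_b", "weight")]
  cp <- canonical_pairs(dt$gene_a, dt$gene_b)
  dt[, `:=`(gene_a = cp$gene_a, gene_b = cp$gene_b)]
  if (any(dt$gene_a == dt$gene_b)) stop("self-links are not allowed")
  if (any(dt$weight <= 0)) stop("link weights must be strictly positive")
  if (anyDuplicated(dt, by = c("gene_a", "gene_b")))
    stop("duplicate links")
  dt <- dt[order(-weight, gene_a, gene_b)]
  genes <- sort(unique(c(dt$gene_a, dt$gene_b)))
  deg_tab <- table(factor(c(dt$gene_a, dt$gene_b), levels = genes))
  wdeg <- vapply(split(c(dt$weight, dt$weight),
                       factor(c(dt$gene_a, dt$gene_b), levels = genes)),
                 sum, numeric(1))
  structure(list(links = dt, genes = genes,
                 degree = setNames(as.integer(deg_tab), genes),
                 weighted_degree = wdeg, D = D),
            class = "pln_network")
}

#' @export
print.pln_network <- function(x, ...) {
  cat("Phenotypic-linkage network:", length(x$genes), "genes,",
      nrow(x$links), "links\n")
  invisible(x)
}

# igraph view of a pln_network (weighted, undirected)
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$links[, .(from = gene_a, to = gene_b, weight = weight)],
    directed = FALSE, vertices = net$genes)
}
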