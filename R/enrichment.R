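#' Per-gene covariates used to match permutation nulls
#'
#' Coding-sequence length and network degree both bias functional
#' association statistics, so random gene draws are matched on them.
#'
#' @param cds_length named numeric vector, gene -> CDS length (bp, > 0).
#' @param degree named numeric vector, gene -> network link count
#'   (optional; required only by degree-matched tests).
#' @return class `pln_gene_stats`.
#' @export
gene_stats <- function(cds_length, degree = NULL) {
  stopifnot(is.numeric(cds_length), !is.null(names(cds_length)))
  if (any(cds_length <= 0)) stop("cds_length must be positive")
  structure(list(cds_length = cds_length, degree = degree),
            class = "pln_gene_stats")
}

# reusable covariate-matched sampler: returns a zero-argument function
# drawing one matched gene set (uses the current RNG stream)
matched_sampler <- function(universe, target, stats, covariates, n_bins = 10L) {
  stopifnot(inherits(stats, "pln_gene_stats"), length(covariates) >= 1,
            all(covariates %in% c("cds_length", "degree")))
  if (!all(target %in% universe)) stop("target genes must lie in the universe")
  bin_idx <- sapply(covariates, function(cv) {
    vals <- stats[[cv]]
    if (is.null(vals)) stop("covariate '", cv, "' not available")
    miss <- setdiff(universe, names(vals))
    if (length(miss))
      stop("covariate '", cv, "' missing for gene(s): ",
           paste(head(miss, 5), collapse = ", "))
    v <- vals[universe]
    brk <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1L)))
    findInterval(v, brk, all.inside = TRUE)
  })
  bin_idx <- matrix(as.integer(bin_idx), nrow = length(universe),
                    dimnames = list(universe, covariates))
  key <- apply(bin_idx, 1, paste, collapse = "_")
  groups <- split(universe, key)
  group_bins <- do.call(rbind, lapply(strsplit(names(groups), "_"), as.integer))
  t_key <- key[match(target, universe)]
  need <- table(t_key)
  # per needed key: ordered fallback keys by Manhattan bin distance
  plans <- lapply(names(need), function(k) {
    kb <- as.integer(strsplit(k, "_")[[1]])
    d <- rowSums(abs(sweep(group_bins, 2, kb)))
    names(groups)[order(d, names(groups))]
  })
  names(plans) <- names(need)
  function() {
    out <- character(0)
    for (k in names(need)) {
      m <- need[[k]]
      for (gk in plans[[k]]) {
        pool <- setdiff(groups[[gk]], out)
        if (length(pool) == 0) next
        take <- min(m, length(pool))
        out <- c(out, pool[sample.int(length(pool), take)])
        m <- m - take
        if (m == 0) break
      }
      if (m > 0) stop("universe exhausted while matching")
    }
    out
  }
}

#' Draw a covariate-matched random gene set
#'
#' For each target gene, a random universe gene is drawn (without
#' replacement within the draw) from the same joint decile bin of the
#' matching covariates; empty joint bins fall back to the nearest
#' nonempty bin by bin-index distance.
#'
#' @param universe candidate gene pool.
#' @param target genes to match (subset of universe).
#' @param stats a `pln_gene_stats`.
#' @param covariates subset of `c("cds_length", "degree")`.
#' @param rng_seed optional integer seed (`NULL`: current RNG stream).
#' @return character vector, same length as `target`.
#' @export
matched_sample <- function(universe, target, stats,
                           covariates = c("cds_length", "degree"),
                           rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  matched_sampler(universe, target, stats, covariates)()
}

#' Permutation enrichment result
#'
#' @param observed observed statistic.
#' @param null numeric vector of null draws.
#' @param alternative test direction (see [empirical_p()]).
#' @param method multiple-testing method tag (`"bonferroni"`, `"BH"`,
#'   `"none"`).
#' @param rng_seed seed used for the null draws.
#' @return class `pln_enrichment`: `observed_stat`, `null_draws`,
#'   `empirical_p`, `adjusted_p` (NA until adjusted), `method`,
#'   `rng_seed`, `null` (the draws).
#' @export
enrichment_result <- function(observed, null, alternative = "greater",
                              method = "none", rng_seed = NA_integer_) {
  structure(list(observed_stat = observed, null_draws = length(null),
                 empirical_p = empirical_p(observed, null, alternative),
                 adjusted_p = NA_real_, method = method,
                 rng_seed = rng_seed, null = null),
            class = "pln_enrichment")
}

#' @export
print.pln_enrichment <- function(x, ...) {
  cat("Permutation enrichment: observed =", format(x$observed_stat, digits = 4),
      "| p =", format(x$empirical_p, digits = 4),
      "(", x$null_draws, "null draws )\n")
  invisible(x)
}

#' Is a community enriched in a gene set?
#'
#' Compares the number of set genes inside the community with the same
#' count for covariate-matched random gene sets of equal size.
#'
#' @param community gene ids of one community.
#' @param gene_set query gene set (subset of universe).
#' @param universe gene universe to draw matched nulls from.
#' @param stats a `pln_gene_stats`.
#' @param n_perm permutations (default 999).
#' @param covariates matching covariates (default CDS length only, as
#'   for community membership tests).
#' @param rng_seed integer seed.
#' @return a `pln_enrichment`.
#' @export
community_set_enrichment <- function(community, gene_set, universe, stats,
                                     n_perm = 999L,
                                     covariates = "cds_length",
                                     rng_seed = 1L) {
  if (length(gene_set) == 0) stop("empty gene set")
  if (!all(gene_set %in% universe)) stop("gene_set must lie in the universe")
  observed <- sum(gene_set %in% community)
  set.seed(rng_seed)
  draw <- matched_sampler(universe, gene_set, stats, covariates)
  null <- vapply(seq_len(n_perm), function(b) sum(draw() %in% community),
                 numeric(1))
  enrichment_result(observed, null, "greater", "none", rng_seed)
}

#' Genomic interval set with gene memberships
#'
#' @param intervals data.frame `chrom`, `start`, `end` (0-based
#'   half-open, `start < end`).
#' @param gene_order data.frame `gene`, `chrom`, `rank` and, when
#'   `gene_members` must be computed, `start`, `end` gene spans.
#'   `rank` is the 1-based gene order along each chromosome.
#' @param gene_members optional list (one entry per interval row) of
#'   member gene ids; when `NULL`, membership is any overlap of the
#'   gene span with the interval.
#' @return class `pln_intervals`: `intervals` (with `interval_id`),
#'   `gene_members`, `gene_order`, `chrom_genes` (per-chromosome gene
#'   vectors in rank order).
#' @export
genomic_intervals <- function(intervals, gene_order, gene_members = NULL) {
  intervals <- as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(c("gene", "chrom", "rank") %in% names(gene_order)))
  if (any(intervals$start >= intervals$end))
    stop("interval start must be < end")
  gene_order <- as.data.table(gene_order)
  if (anyDuplicated(gene_order$gene)) stop("duplicate genes in gene_order")
  intervals[, interval_id := seq_len(.N)]
  if (is.null(gene_members)) {
    stopifnot(all(c("start", "end") %in% names(gene_order)))
    iv <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start + 1L, intervals$end))
    gn <- GenomicRanges::GRanges(gene_order$chrom,
                                 IRanges::IRanges(gene_order$start + 1L, gene_order$end))
    hits <- GenomicRanges::findOverlaps(iv, gn)
    gene_members <- split(gene_order$gene[S4Vectors_subjectHits(hits)],
                          factor(S4Vectors_queryHits(hits),
                                 levels = seq_len(nrow(intervals))))
    gene_members <- lapply(gene_members, as.character)
  }
  stopifnot(length(gene_members) == nrow(intervals))
  names(gene_members) <- as.character(intervals$interval_id)
  unknown <- setdiff(unlist(gene_members, use.names = FALSE), gene_order$gene)
  if (length(unknown))
    stop("interval member gene(s) absent from gene_order: ",
         paste(head(unknown, 5), collapse = ", "))
  chrom_genes <- lapply(split(gene_order, gene_order$chrom),
                        function(d) d$gene[order(d$rank)])
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    if (length(gene_members[[i]]) > length(chrom_genes[[ch]] %||% character(0)))
      stop("chromosome ", ch, " has fewer genes than interval ", i, " members")
  }
  structure(list(intervals = intervals, gene_members = gene_members,
                 gene_order = gene_order, chrom_genes = chrom_genes),
            class = "pln_intervals")
}

# helpers avoiding a hard S4Vectors import surface
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' Circularly shift intervals in gene-rank space
#'
#' Each chromosome's intervals are moved by one shared random offset in
#' gene-rank coordinates with wrap-around, so every shifted interval
#' keeps exactly its original gene count and intervals on a chromosome
#' keep their relative spacing — the null preserves genomic clustering.
#'
#' @param intervals a `pln_intervals`.
#' @param rng_seed optional integer seed (`NULL`: current RNG stream).
#' @param offsets optional named integer vector (chromosome -> offset)
#'   overriding the random draw (used for exhaustive enumeration).
#' @return list of shifted member-gene vectors, same names as
#'   `intervals$gene_members`.
#' @export
shift_intervals <- function(intervals, rng_seed = NULL, offsets = NULL) {
  stopifnot(inherits(intervals, "pln_intervals"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  chroms <- names(intervals$chrom_genes)
  if (is.null(offsets)) {
    n <- vapply(intervals$chrom_genes, length, 1L)
    offsets <- setNames(vapply(n, function(k) sample.int(k, 1L) - 1L, 1L), chroms)
  }
  rank_of <- lapply(intervals$chrom_genes, function(g) setNames(seq_along(g), g))
  out <- intervals$gene_members
  for (i in seq_along(out)) {
    ch <- intervals$intervals$chrom[i]
    genes_ch <- intervals$chrom_genes[[ch]]
    r <- rank_of[[ch]][out[[i]]]
    r2 <- ((r - 1L + offsets[[ch]]) %% length(genes_ch)) + 1L
    out[[i]] <- unname(genes_ch[r2])
  }
  out
}

# Per-chromosome statistic tables over every circular offset, so shift
# nulls cost one lookup per chromosome per replicate instead of an
# explicit re-shift. tab[[ch]][o + 1] is, at offset o:
#   mode "intervals_hit": #intervals on ch containing >= 1 flagged gene
#   mode "genes_in":      #flagged genes in the union of ch's intervals
# Offset 0 reproduces the observed configuration exactly.
interval_offset_tables <- function(intervals, flagged,
                                   mode = c("intervals_hit", "genes_in")) {
  mode <- match.arg(mode)
  iv_chrom <- intervals$intervals$chrom
  tabs <- list()
  for (ch in names(intervals$chrom_genes)) {
    genes_ch <- intervals$chrom_genes[[ch]]
    n <- length(genes_ch)
    ind <- as.integer(genes_ch %in% flagged)
    rank_of <- setNames(seq_len(n), genes_ch)
    iv_idx <- which(iv_chrom == ch)
    if (length(iv_idx) == 0) {
      tabs[[ch]] <- numeric(n)
      next
    }
    window_counts <- function(ranks) {
      idx <- (outer(ranks - 1L, 0:(n - 1L), "+") %% n) + 1L
      colSums(matrix(ind[idx], nrow = length(ranks)))
    }
    if (mode == "genes_in") {
      u <- sort(unique(unlist(lapply(intervals$gene_members[iv_idx],
                                     function(m) rank_of[m]), use.names = FALSE)))
      tabs[[ch]] <- window_counts(u)
    } else {
      acc <- numeric(n)
      for (i in iv_idx)
        acc <- acc + (window_counts(unname(rank_of[intervals$gene_members[[i]]])) > 0)
      tabs[[ch]] <- acc
    }
  }
  tabs
}

# observed value (offset 0) and n_shifts random-offset null draws from
# precomputed offset tables; offsets are uniform per chromosome
shift_null_from_tables <- function(tabs, n_shifts) {
  observed <- sum(vapply(tabs, function(tb) tb[1], numeric(1)))
  null <- numeric(n_shifts)
  for (tb in tabs)
    null <- null + tb[sample.int(length(tb), n_shifts, replace = TRUE)]
  list(observed = observed, null = null)
}

#' Do intervals preferentially harbour a community's genes?
#'
#' Observed statistic: how many intervals contain at least one community
#' gene; the null recomputes the count under circular gene-rank shifts
#' of the intervals (one shared random offset per chromosome and
#' replicate, evaluated through precomputed per-offset tables).
#'
#' @param intervals a `pln_intervals`.
#' @param community gene ids.
#' @param n_shifts number of random shifts (default 10000).
#' @param rng_seed integer seed.
#' @return a `pln_enrichment`.
#' @export
interval_community_enrichment <- function(intervals, community,
                                          n_shifts = 10000L, rng_seed = 1L) {
  tabs <- interval_offset_tables(intervals, community, "intervals_hit")
  set.seed(rng_seed)
  res <- shift_null_from_tables(tabs, n_shifts)
  enrichment_result(res$observed, res$null, "greater", "none", rng_seed)
}

# sum of link weights with both endpoints in `set`
internal_link_weight <- function(net, set) {
  sum(net$links$weight[net$links$gene_a %in% set & net$links$gene_b %in% set])
}

#' Functional clustering of a gene set in the network
#'
#' Compares the summed weight of links joining set genes with the same
#' statistic for equal-sized random gene sets matched in CDS length and
#' degree, asking whether the set is unusually interlinked.
#'
#' @param net a `pln_network`.
#' @param gene_set query genes (subset of universe).
#' @param universe gene pool for matched nulls.
#' @param stats a `pln_gene_stats` (needs both covariates).
#' @param n_perm permutations (default 999).
#' @param covariates matching covariates.
#' @param rng_seed integer seed.
#' @return a `pln_enrichment`.
#' @export
clustering_test <- function(net, gene_set, universe, stats, n_perm = 999L,
                            covariates = c("cds_length", "degree"),
                            rng_seed = 1L) {
  if (!all(gene_set %in% universe)) stop("gene_set must lie in the universe")
  observed <- internal_link_weight(net, gene_set)
  set.seed(rng_seed)
  draw <- matched_sampler(universe, gene_set, stats, covariates)
  null <- vapply(seq_len(n_perm), function(b)
    internal_link_weight(net, draw()), numeric(1))
  enrichment_result(observed, null, "greater", "none", rng_seed)
}

#' Joint functional clustering of two gene sets
#'
#' Observed statistic: summed weight of all links internal to the
#' combined set `A` union `B`. Nulls resample both sets independently,
#' matched in size, CDS length and degree, from the universe (which may
#' itself be a single community). With `set_b` empty this reduces
#' exactly to [clustering_test()] of `set_a`.
#'
#' @param net a `pln_network`.
#' @param set_a,set_b gene sets (subsets of universe; `set_a` nonempty).
#' @inheritParams clustering_test
#' @return a `pln_enrichment`.
#' @export
between_set_clustering <- function(net, set_a, set_b, universe, stats,
                                   n_perm = 999L,
                                   covariates = c("cds_length", "degree"),
                                   rng_seed = 1L) {
  if (length(set_a) == 0) stop("set_a must be nonempty")
  if (!all(c(set_a, set_b) %in% universe)) stop("sets must lie in the universe")
  observed <- internal_link_weight(net, union(set_a, set_b))
  set.seed(rng_seed)
  draw_a <- matched_sampler(universe, set_a, stats, covariates)
  draw_b <- if (length(set_b)) matched_sampler(universe, set_b, stats, covariates)
            else function() character(0)
  null <- vapply(seq_len(n_perm), function(b)
    internal_link_weight(net, union(draw_a(), draw_b())), numeric(1))
  enrichment_result(observed, null, "greater", "none", rng_seed)
}

#' Annotation-term enrichment of a gene set
#'
#' Per term, the observed overlap of the gene set with the term's genes
#' is compared against covariate-matched random gene sets (one shared
#' batch of matched draws serves every term); p-values are BH-adjusted
#' across terms. A classical hypergeometric test is available as an
#' alternative.
#'
#' @param gene_set query genes.
#' @param annotation named list, term -> gene ids.
#' @param universe gene pool.
#' @param stats a `pln_gene_stats`.
#' @param n_perm permutations (default 999).
#' @param covariates matching covariates (default CDS length).
#' @param method `"permutation"` (default) or `"hypergeometric"`.
#' @param rng_seed integer seed.
#' @return data.table: `term`, `observed`, `p`, `q` (BH).
#' @export
annotation_enrichment <- function(gene_set, annotation, universe, stats,
                                  n_perm = 999L, covariates = "cds_length",
                                  method = c("permutation", "hypergeometric"),
                                  rng_seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(annotation) >= 1, !is.null(names(annotation)))
  annotation <- lapply(annotation, intersect, y = universe)
  if (all(vapply(annotation, length, 1L) == 0))
    stop("annotation terms cover no universe gene")
  obs <- vapply(annotation, function(g) sum(gene_set %in% g), numeric(1))
  if (method == "hypergeometric") {
    p <- vapply(seq_along(annotation), function(k)
      stats::phyper(obs[k] - 1, length(annotation[[k]]),
                    length(universe) - length(annotation[[k]]),
                    length(gene_set), lower.tail = FALSE), numeric(1))
  } else {
    set.seed(rng_seed)
    draw <- matched_sampler(universe, gene_set, stats, covariates)
    null <- matrix(0, n_perm, length(annotation))
    for (b in seq_len(n_perm)) {
      s <- draw()
      null[b, ] <- vapply(annotation, function(g) sum(s %in% g), numeric(1))
    }
    p <- vapply(seq_along(annotation), function(k)
      empirical_p(obs[k], null[, k], "greater"), numeric(1))
  }
  data.table(term = names(annotation), observed = obs, p = p,
             q = adjust_pvalues(p, "BH"))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"BH"`.
#' @return adjusted p-values, same length.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}
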