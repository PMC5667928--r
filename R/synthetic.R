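#' Specification of the synthetic study conditions
#'
#' One declarative object holds every generator's parameters, with
#' defaults chosen as a desk-scale emulation of a phenotype-annotation
#' corpus, heterogeneous evidence compendium, modular gene network,
#' rare-variant case/control panel and multi-tissue expression atlas:
#' a depth-4, branching-3 ontology with 3 designated branch roots;
#' 120 annotated genes in 6 planted 12-gene modules; 4 evidence
#' datasets spanning informativeness 1 down to pure noise; a 4-block
#' stochastic-block-model network; a 4,000-individual case/control
#' panel with planted per-variant odds ratio 1.5; and a 10-tissue
#' expression matrix with one planted tissue-specific set.
#'
#' @param rng_seed master seed; per-generator seeds derive from it via
#'   [derive_seed()].
#' @param ontology list(depth, branching, n_branch_roots).
#' @param genes list(n_genes, n_modules, module_size, terms_per_gene).
#' @param evidence list(informativeness (vector, one per dataset; 0 =
#'   pure noise), noise_sd, coverage_fraction).
#' @param network list(block_sizes, p_in, p_out, weights: "unit" or
#'   "lognormal").
#' @param case_control list(n_cases, n_controls, n_risk_genes,
#'   true_or, lambda: mean variant count per risk gene).
#' @param expression list(n_tissues, set_size, fold).
#' @param intervals list(n_intervals, genes_per_interval, n_chrom).
#' @return a list of class `pln_synthetic_spec`.
#' @export
synthetic_spec <- function(rng_seed = 1L,
                           ontology = list(depth = 4L, branching = 3L, n_branch_roots = 3L),
                           genes = list(n_genes = 120L, n_modules = 6L,
                                        module_size = 12L, terms_per_gene = 3L),
                           evidence = list(informativeness = c(1, 0.8, 0.6, 0),
                                           noise_sd = 0.1, coverage_fraction = 0.6),
                           network = list(block_sizes = c(50L, 50L, 50L, 50L),
                                          p_in = 0.3, p_out = 0.01,
                                          weights = "unit"),
                           case_control = list(n_cases = 2000L, n_controls = 2000L,
                                               n_risk_genes = 10L, true_or = 1.5,
                                               lambda = 0.02),
                           expression = list(n_tissues = 10L, set_size = 20L,
                                             fold = 5),
                           intervals = list(n_intervals = 12L,
                                            genes_per_interval = 5L,
                                            n_chrom = 4L)) {
  stopifnot(ontology$depth >= 2, ontology$branching >= 2,
            genes$n_modules * genes$module_size <= genes$n_genes,
            all(evidence$informativeness >= 0 & evidence$informativeness <= 1),
            evidence$coverage_fraction > 0, evidence$coverage_fraction <= 1,
            network$p_in > network$p_out, case_control$true_or > 0,
            expression$n_tissues >= 2)
  structure(list(rng_seed = as.integer(rng_seed), ontology = ontology,
                 genes = genes, evidence = evidence, network = network,
                 case_control = case_control, expression = expression,
                 intervals = intervals),
            class = "pln_synthetic_spec")
}

# balanced is_a tree: root "T:0"; level l has branching^l terms
balanced_ontology <- function(depth, branching) {
  terms <- "T:0"
  parents <- list("T:0" = character(0))
  prev <- "T:0"
  counter <- 0L
  for (l in seq_len(depth)) {
    cur <- character(0)
    for (p in prev) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("T:%04d", counter)
        parents[[id]] <- p
        cur <- c(cur, id)
      }
    }
    terms <- c(terms, cur)
    prev <- cur
  }
  ont <- structure(list(terms = terms, parents = parents,
                        alt_map = character(0), branch_roots = character(0)),
                   class = "pln_ontology")
  ont$roots <- "T:0"
  ont$ancestors <- compute_ancestors(terms, parents)
  ont
}

#' Generate a synthetic ontology with planted functional modules
#'
#' Builds a balanced is_a tree, designates the first
#' `n_branch_roots` children of the root as branch roots, and annotates
#' genes to leaf terms: genes of the same planted module draw their
#' terms from one small shared leaf cluster (inside one branch), so
#' within-module phenotypic similarity is high; the remaining genes
#' draw leaves independently from the whole tree.
#'
#' @param spec a `pln_synthetic_spec`.
#' @return list: `ontology` (`pln_ontology` with `branch_roots` set),
#'   `annotations` (`pln_annotations`), `modules` (named integer vector,
#'   gene -> module id, 0 = background), `direct` (the raw gene->terms
#'   list).
#' @export
make_ontology_and_annotations <- function(spec) {
  o <- spec$ontology; g <- spec$genes
  set.seed(derive_seed(spec$rng_seed, "ontology"))
  ont <- balanced_ontology(o$depth, o$branching)
  children_of_root <- names(ont$parents)[vapply(ont$parents, function(p)
    identical(p, "T:0"), logical(1))]
  ont$branch_roots <- children_of_root[seq_len(o$n_branch_roots)]
  leaves <- setdiff(ont$terms, unique(unlist(ont$parents, use.names = FALSE)))
  gene_ids <- sprintf("g%04d", seq_len(g$n_genes))
  modules <- setNames(integer(g$n_genes), gene_ids)
  direct <- vector("list", g$n_genes)
  names(direct) <- gene_ids
  pool_size <- max(2L * g$terms_per_gene, 6L)
  k <- 0L
  for (m in seq_len(g$n_modules)) {
    br <- sample(ont$branch_roots, 1L)
    branch_leaves <- intersect(leaves, term_descendants(ont, br))
    pool <- sample(branch_leaves, min(pool_size, length(branch_leaves)))
    for (j in seq_len(g$module_size)) {
      k <- k + 1L
      modules[k] <- m
      direct[[k]] <- sample(pool, min(g$terms_per_gene, length(pool)))
    }
  }
  for (i in seq(k + 1L, g$n_genes))
    direct[[i]] <- sample(leaves, g$terms_per_gene)
  list(ontology = ont,
       annotations = propagate_annotations(ont, direct),
       modules = modules, direct = direct)
}

#' Generate evidence datasets as noisy monotone transforms of the benchmark
#'
#' Each dataset's raw score for a pair is
#' `informativeness * z + noise`, where `z` is the standardized true
#' benchmark similarity and the noise is Gaussian with sd `noise_sd`;
#' informativeness 0 yields a pure-noise dataset. Each dataset covers a
#' random `coverage_fraction` of the benchmark pairs.
#'
#' @param bench a `pln_benchmark`.
#' @param spec a `pln_synthetic_spec`.
#' @return list of `pln_evidence` (named `ev1`, `ev2`, ...).
#' @export
make_evidence <- function(bench, spec) {
  e <- spec$evidence
  if (e$coverage_fraction <= 0) stop("coverage_fraction must be positive")
  set.seed(derive_seed(spec$rng_seed, "evidence"))
  sim <- bench$pairs$similarity
  z <- (sim - mean(sim)) / stats::sd(sim)
  total <- nrow(bench$pairs)
  n_keep <- max(1L, round(e$coverage_fraction * total))
  lapply(seq_along(e$informativeness), function(d) {
    q <- e$informativeness[d]
    idx <- sort(sample.int(total, n_keep))
    score <- q * z[idx] + rnorm(n_keep, sd = if (q > 0) e$noise_sd else 1)
    evidence_dataset(data.table(gene_a = bench$pairs$gene_a[idx],
                                gene_b = bench$pairs$gene_b[idx],
                                score = score),
                     name = paste0("ev", d))
  })
}

#' Generate a stochastic-block-model weighted network
#'
#' Blocks of the stated sizes; within-block edges appear with `p_in`,
#' between-block edges with `p_out`; weights are 1 ("unit") or
#' log-normal draws.
#'
#' @param spec a `pln_synthetic_spec`.
#' @param rng_seed optional override of the derived seed.
#' @return list: `network` (`pln_network`), `blocks` (named integer,
#'   gene -> planted block).
#' @export
make_block_network <- function(spec, rng_seed = NULL) {
  nw <- spec$network
  set.seed(rng_seed %||% derive_seed(spec$rng_seed, "network"))
  sizes <- nw$block_sizes
  n <- sum(sizes)
  genes <- sprintf("n%04d", seq_len(n))
  block <- setNames(rep(seq_along(sizes), sizes), genes)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(block[ij[, 1]] == block[ij[, 2]], nw$p_in, nw$p_out)
  keep <- runif(nrow(ij)) < p
  ij <- ij[keep, , drop = FALSE]
  w <- if (identical(nw$weights, "lognormal")) stats::rlnorm(nrow(ij), 0, 0.5)
       else rep(1, nrow(ij))
  list(network = pln_network(data.table(gene_a = genes[ij[, 1]],
                                        gene_b = genes[ij[, 2]],
                                        weight = w)),
       blocks = block)
}

#' Generate case/control variant counts with a planted odds ratio
#'
#' Per-individual, per-gene variant counts are Poisson(`lambda`) in the
#' risk-gene set; case status is drawn from
#' `logit P(case) = beta0 + ln(true_or) * total_count`, with `beta0`
#' solved so the expected case fraction matches
#' `n_cases/(n_cases + n_controls)`.
#'
#' @param spec a `pln_synthetic_spec`.
#' @param rng_seed optional override of the derived seed.
#' @return list: `data` (`pln_case_control`, counts = per-individual
#'   totals in the risk set), `gene_counts` (individual x gene matrix),
#'   `risk_genes`, `beta0`.
#' @export
make_case_control <- function(spec, rng_seed = NULL) {
  cc <- spec$case_control
  stopifnot(cc$true_or > 0)
  set.seed(rng_seed %||% derive_seed(spec$rng_seed, "case_control"))
  n <- cc$n_cases + cc$n_controls
  target <- cc$n_cases / n
  genes <- sprintf("r%03d", seq_len(cc$n_risk_genes))
  ids <- sprintf("ind%05d", seq_len(n))
  gc <- matrix(rpois(n * cc$n_risk_genes, cc$lambda), n, cc$n_risk_genes,
               dimnames = list(ids, genes))
  x <- rowSums(gc)
  f <- function(b0) mean(stats::plogis(b0 + log(cc$true_or) * x)) - target
  sol <- tryCatch(stats::uniroot(f, c(-30, 30)), error = function(e)
    stop("target case fraction unattainable: ", conditionMessage(e)))
  p <- stats::plogis(sol$root + log(cc$true_or) * x)
  status <- ifelse(runif(n) < p, "case", "control")
  list(data = case_control_counts(setNames(x, ids), setNames(status, ids)),
       gene_counts = gc, risk_genes = genes, beta0 = sol$root)
}

#' Generate a gene x tissue expression matrix with a planted set
#'
#' Log-normal baseline expression; genes of the planted set are
#' multiplied by `fold` in one designated tissue, making them
#' tissue-specific there.
#'
#' @param genes gene ids (rows).
#' @param spec a `pln_synthetic_spec`.
#' @param rng_seed optional override of the derived seed.
#' @return list: `expr` (matrix), `planted_genes`, `planted_tissue`.
#' @export
make_expression <- function(genes, spec, rng_seed = NULL) {
  ex <- spec$expression
  set.seed(rng_seed %||% derive_seed(spec$rng_seed, "expression"))
  tissues <- sprintf("tissue%02d", seq_len(ex$n_tissues))
  expr <- matrix(stats::rlnorm(length(genes) * ex$n_tissues, 1, 1),
                 length(genes), ex$n_tissues,
                 dimnames = list(genes, tissues))
  planted <- sample(genes, min(ex$set_size, length(genes)))
  planted_tissue <- tissues[1]
  expr[planted, planted_tissue] <- expr[planted, planted_tissue] * ex$fold
  list(expr = expr, planted_genes = planted, planted_tissue = planted_tissue)
}

#' Generate a synthetic gene order and genomic intervals
#'
#' Genes are laid out on `n_chrom` chromosomes in rank order with
#' non-overlapping spans; intervals of exactly `genes_per_interval`
#' consecutive genes are placed at random positions, optionally seeded
#' with genes from an enrichment target set.
#'
#' @param genes gene ids.
#' @param spec a `pln_synthetic_spec`.
#' @param enrich_genes optional gene set; when given, half the
#'   intervals are centred on its members.
#' @param rng_seed optional override of the derived seed.
#' @return list: `intervals` (`pln_intervals`), `gene_order`
#'   (data.table `gene`, `chrom`, `rank`, `start`, `end`).
#' @export
make_intervals <- function(genes, spec, enrich_genes = NULL, rng_seed = NULL) {
  iv <- spec$intervals
  set.seed(rng_seed %||% derive_seed(spec$rng_seed, "intervals"))
  n <- length(genes)
  chrom <- sort(rep_len(sprintf("chr%d", seq_len(iv$n_chrom)), n))
  perm <- sample.int(n)
  go <- data.table(gene = genes[perm], chrom = chrom)
  go[, rank := seq_len(.N), by = chrom]
  gene_len <- 10000L
  go[, start := (rank - 1L) * 2L * gene_len]
  go[, end := start + gene_len]
  k <- iv$genes_per_interval
  pick_start <- function(ch) {
    nch <- sum(go$chrom == ch)
    if (nch < k) stop("chromosome ", ch, " has fewer genes than an interval needs")
    sample.int(nch - k + 1L, 1L)
  }
  rows <- lapply(seq_len(iv$n_intervals), function(i) {
    if (!is.null(enrich_genes) && i <= ceiling(iv$n_intervals / 2)) {
      g0 <- sample(enrich_genes, 1L)
      ch <- go$chrom[go$gene == g0]
      r0 <- go$rank[go$gene == g0]
      nch <- sum(go$chrom == ch)
      s <- min(max(1L, r0 - sample.int(k, 1L) + 1L), nch - k + 1L)
    } else {
      ch <- sample(unique(go$chrom), 1L)
      s <- pick_start(ch)
    }
    members <- go[chrom == ch & rank >= s & rank < s + k][order(rank)]
    list(chrom = ch, start = members$start[1], end = members$end[k],
         members = members$gene)
  })
  ints <- data.table(chrom = vapply(rows, `[[`, "", "chrom"),
                     start = vapply(rows, `[[`, 0, "start"),
                     end = vapply(rows, `[[`, 0, "end"))
  list(intervals = genomic_intervals(ints, go,
                                     gene_members = lapply(rows, `[[`, "members")),
       gene_order = go)
}

#' Synthetic per-gene covariates
#'
#' Log-normal CDS lengths; degree taken from a network when provided.
#'
#' @param genes gene ids.
#' @param net optional `pln_network` supplying degrees.
#' @param rng_seed integer seed.
#' @return a `pln_gene_stats`.
#' @export
make_gene_stats <- function(genes, net = NULL, rng_seed = 1L) {
  set.seed(rng_seed)
  cds <- setNames(round(stats::rlnorm(length(genes), log(1500), 0.6)) + 100,
                  genes)
  deg <- NULL
  if (!is.null(net)) {
    deg <- setNames(numeric(length(genes)), genes)
    deg[names(net$degree)] <- net$degree
  }
  gene_stats(cds, deg)
}
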