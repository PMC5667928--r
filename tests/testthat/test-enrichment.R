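w_enr <- make_test_world(seed = 17)

test_that("matched sampling: closed universe, uniformity and matching quality", {
  stats <- w_enr$stats
  universe <- w_enr$net$genes
  target <- universe[1:12]
  # universe == target: every draw is a permutation of the target
  s <- matched_sample(target, target, stats, "cds_length", rng_seed = 1)
  expect_setequal(s, target)
  # one covariate, all genes forced into one bin -> uniform draws
  flat <- gene_stats(setNames(rep(1000, 60), universe[1:60]))
  draws <- replicate(10000, matched_sample(universe[1:60], universe[1], flat,
                                           "cds_length"))
  tab <- table(factor(draws, levels = universe[1:60]))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
  # matched draws track the target's CDS-length distribution
  set.seed(5)
  heavy <- names(sort(stats$cds_length[universe], decreasing = TRUE))[1:15]
  env <- quantile(stats$cds_length[universe], c(0.4, 1))
  ok <- 0
  for (r in 1:200) {
    m <- matched_sample(universe, heavy, stats, "cds_length")
    if (median(stats$cds_length[m]) >= env[1]) ok <- ok + 1
  }
  expect_gte(ok / 200, 0.95)
  expect_error(matched_sample(universe, "nope", stats, "cds_length"), "universe")
})

test_that("community/set enrichment: planted bound, saturation and calibration", {
  universe <- w_enr$net$genes
  stats <- w_enr$stats
  community <- names(w_enr$blocks)[w_enr$blocks == 1]
  # gene set entirely inside a small community -> minimal attainable p
  gene_set <- community[1:12]
  e <- community_set_enrichment(community, gene_set, universe, stats,
                                n_perm = 199, rng_seed = 5)
  expect_equal(e$observed_stat, 12)
  expect_equal(e$empirical_p, 1 / 200)
  # community == universe: saturated, p = 1
  sat <- community_set_enrichment(universe, gene_set, universe, stats,
                                  n_perm = 99, rng_seed = 5)
  expect_equal(sat$observed_stat, length(gene_set))
  expect_equal(sat$empirical_p, 1)
  expect_error(community_set_enrichment(community, character(0), universe,
                                        stats, 99), "empty")
})

test_that("interval shifting conserves counts, spacing and cycles uniformly", {
  mi <- make_intervals(w_enr$net$genes, w_enr$spec)
  iv <- mi$intervals
  # offset 0 on every chromosome reproduces the input
  zero <- setNames(rep(0L, length(iv$chrom_genes)), names(iv$chrom_genes))
  expect_equal(shift_intervals(iv, offsets = zero), iv$gene_members)
  # counts conserved in every replicate
  for (s in 1:25) {
    sh <- shift_intervals(iv, rng_seed = s)
    expect_equal(lengths(sh), lengths(iv$gene_members))
  }
  # full-cycle enumeration on a 30-gene toy chromosome covers genes equally
  genes30 <- sprintf("t%02d", 1:30)
  toy <- genomic_intervals(
    data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 160)),
    data.frame(gene = genes30, chrom = "chr1", rank = 1:30,
               start = seq(0, by = 20, length.out = 30),
               end = seq(10, by = 20, length.out = 30)))
  k <- sum(lengths(toy$gene_members))
  hits <- setNames(integer(30), genes30)
  for (off in 0:29) {
    sh <- shift_intervals(toy, offsets = c(chr1 = off))
    for (g in unlist(sh)) hits[g] <- hits[g] + 1L
  }
  expect_true(all(hits == k))
})

test_that("interval/community enrichment: saturation, empty and planted overlap", {
  mi <- make_intervals(w_enr$net$genes, w_enr$spec)
  # community containing every gene: observed = #intervals, p = 1
  sat <- interval_community_enrichment(mi$intervals, w_enr$net$genes,
                                       n_shifts = 99, rng_seed = 2)
  expect_equal(sat$observed_stat, nrow(mi$intervals$intervals))
  expect_equal(sat$empirical_p, 1)
  # empty community
  emp <- interval_community_enrichment(mi$intervals, character(0),
                                       n_shifts = 99, rng_seed = 2)
  expect_equal(emp$observed_stat, 0)
  expect_equal(emp$empirical_p, 1)
  # planted overlap: half the intervals seeded with community genes
  comm <- names(w_enr$blocks)[w_enr$blocks == 2][1:10]
  spec2 <- w_enr$spec
  spec2$intervals$n_intervals <- 24L
  mi2 <- make_intervals(w_enr$net$genes, spec2, enrich_genes = comm)
  r <- interval_community_enrichment(mi2$intervals, comm, n_shifts = 1000,
                                     rng_seed = 3)
  expect_lt(r$empirical_p, 0.01)
})

test_that("clustering statistics match a naive double loop and find planted modules", {
  net <- w_enr$net
  stats <- w_enr$stats
  universe <- net$genes
  gene_set <- names(w_enr$blocks)[w_enr$blocks == 3][1:20]
  # observed sum vs naive loop over the edge list
  naive <- 0
  for (r in seq_len(nrow(net$links)))
    if (net$links$gene_a[r] %in% gene_set && net$links$gene_b[r] %in% gene_set)
      naive <- naive + net$links$weight[r]
  expect_equal(plnet:::internal_link_weight(net, gene_set), naive,
               tolerance = 1e-12)
  # no internal links -> observed 0, p = 1
  sparse_set <- c(names(w_enr$blocks)[w_enr$blocks == 1][1],
                  names(w_enr$blocks)[w_enr$blocks == 2][1])
  e0 <- clustering_test(net, sparse_set, universe, stats, n_perm = 99,
                        rng_seed = 1)
  if (e0$observed_stat == 0) expect_equal(e0$empirical_p, 1)
  # planted dense module reaches the minimal attainable p
  e1 <- clustering_test(net, gene_set, universe, stats, n_perm = 999,
                        rng_seed = 4)
  expect_equal(e1$empirical_p, 1 / 1000)
})

test_that("between-set clustering: degenerate, symmetric and planted cases", {
  net <- w_enr$net
  stats <- w_enr$stats
  universe <- net$genes
  A <- names(w_enr$blocks)[w_enr$blocks == 1][1:8]
  B <- names(w_enr$blocks)[w_enr$blocks == 1][9:16]
  # empty B reduces exactly to the one-set clustering test
  e_ab0 <- between_set_clustering(net, A, character(0), universe, stats,
                                  n_perm = 199, rng_seed = 9)
  e_a <- clustering_test(net, A, universe, stats, n_perm = 199, rng_seed = 9)
  expect_equal(e_ab0$observed_stat, e_a$observed_stat)
  expect_equal(e_ab0$empirical_p, e_a$empirical_p)
  # statistic symmetric in A and B
  expect_equal(between_set_clustering(net, A, B, universe, stats, 49, rng_seed = 1)$observed_stat,
               between_set_clustering(net, B, A, universe, stats, 49, rng_seed = 1)$observed_stat)
  # two sets in the same planted block cluster jointly
  e_ab <- between_set_clustering(net, A, B, universe, stats, n_perm = 999,
                                 rng_seed = 2)
  expect_lt(e_ab$empirical_p, 0.01)
  expect_error(between_set_clustering(net, character(0), B, universe, stats, 9),
               "nonempty")
})

test_that("annotation enrichment flags the planted term with BH control", {
  universe <- w_enr$net$genes
  stats <- w_enr$stats
  set.seed(31)
  annotation <- c(list(planted = names(w_enr$blocks)[w_enr$blocks == 4][1:30],
                       everything = universe),
                  lapply(setNames(1:6, paste0("rand", 1:6)), function(i)
                    sample(universe, 25)))
  gene_set <- annotation$planted[1:10]
  res <- annotation_enrichment(gene_set, annotation, universe, stats,
                               n_perm = 499, rng_seed = 12)
  expect_lt(res[term == "planted", q], 0.05)
  expect_equal(res[term == "everything", p], 1)
  # q-values equal a textbook BH recomputation
  expect_equal(res$q, textbook_bh(res$p), tolerance = 1e-12)
  # hypergeometric alternative agrees on the planted call
  hyp <- annotation_enrichment(gene_set, annotation, universe, stats,
                               method = "hypergeometric")
  expect_lt(hyp[term == "planted", q], 0.05)
})

test_that("p-value adjustment matches closed forms and validates input", {
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_pvalues(0.2, "BH"), 0.2)
  set.seed(3)
  for (r in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_pvalues(p, "BH"), textbook_bh(p), tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "bonferroni"), pmin(1, length(p) * p))
    # BH monotone in p
    q <- adjust_pvalues(p, "BH")
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
})

test_that("matched permutation draws are bit-reproducible given a seed", {
  universe <- w_enr$net$genes
  stats <- w_enr$stats
  gene_set <- universe[5:16]
  a <- matched_sample(universe, gene_set, stats, "cds_length", rng_seed = 7)
  b <- matched_sample(universe, gene_set, stats, "cds_length", rng_seed = 7)
  expect_identical(a, b)
  mi <- make_intervals(universe, w_enr$spec)
  expect_identical(shift_intervals(mi$intervals, rng_seed = 3),
                   shift_intervals(mi$intervals, rng_seed = 3))
  e1 <- clustering_test(w_enr$net, gene_set, universe, stats, 49, rng_seed = 2)
  e2 <- clustering_test(w_enr$net, gene_set, universe, stats, 49, rng_seed = 2)
  expect_identical(e1$null, e2$null)
})
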