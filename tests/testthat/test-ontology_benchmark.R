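test_that("parse_obo reads chains, multi-parent terms and drops obsolete stanzas", {
  # simple chain A <- B <- C
  path <- write_obo_fixture(chain_obo_lines(c("A", "B", "C")))
  ont <- parse_obo(path)
  expect_setequal(ont$terms, c("A", "B", "C"))
  expect_equal(ont$parents[["C"]], "B")
  expect_equal(ont$parents[["B"]], "A")
  expect_equal(ont$roots, "A")

  # two is_a parents are both recorded
  lines <- c("format-version: 1.2",
             "", "[Term]", "id: A",
             "", "[Term]", "id: B",
             "", "[Term]", "id: C", "is_a: A ! a name", "is_a: B")
  ont2 <- parse_obo(write_obo_fixture(lines))
  expect_setequal(ont2$parents[["C"]], c("A", "B"))
  expect_setequal(ont2$roots, c("A", "B"))

  # obsolete stanza absent; its alt_id does not leak in
  lines <- c("format-version: 1.2",
             "", "[Term]", "id: A",
             "", "[Term]", "id: B", "is_a: A", "is_obsolete: true",
             "", "[Term]", "id: C", "alt_id: C2", "is_a: A")
  ont3 <- parse_obo(write_obo_fixture(lines))
  expect_setequal(ont3$terms, c("A", "C"))
  expect_equal(unname(ont3$alt_map["C2"]), "C")
})

test_that("parse_obo rejects malformed stanzas and cyclic is_a", {
  bad <- c("format-version: 1.2", "", "[Term]", "is_a: A")
  expect_error(parse_obo(write_obo_fixture(bad)), "stanza")
  cyc <- c("format-version: 1.2",
           "", "[Term]", "id: A", "is_a: B",
           "", "[Term]", "id: B", "is_a: A")
  expect_error(parse_obo(write_obo_fixture(cyc)), "cycl")
})

test_that("annotation propagation is the ancestor closure", {
  path <- write_obo_fixture(chain_obo_lines(c("A", "B", "C")))
  ont <- parse_obo(path)
  ann <- propagate_annotations(ont, list(g1 = "C", g2 = "A"))
  expect_setequal(ann$propagated$g1, c("A", "B", "C"))
  expect_equal(ann$propagated$g2, "A")
  expect_error(propagate_annotations(ont, list(g1 = "ZZZ")), "ZZZ")
})

test_that("propagation matches brute-force transitive closure on random DAGs", {
  for (seed in 1:5) {
    dag <- random_dag_obo(20, seed)
    ont <- parse_obo(write_obo_fixture(dag$lines))
    set.seed(seed + 100)
    direct <- list(gA = sample(dag$ids, 4), gB = sample(dag$ids, 3))
    ann <- propagate_annotations(ont, direct)
    for (g in names(direct)) {
      expected <- unique(unlist(lapply(direct[[g]], function(t)
        closure_ancestors(ont$parents, t))))
      expect_setequal(ann$propagated[[g]], expected)
    }
    # direct subset of propagated
    expect_true(all(direct$gA %in% ann$propagated$gA))
  }
})

test_that("information content follows -ln(annotation frequency)", {
  path <- write_obo_fixture(chain_obo_lines(c("A", "B", "C")))
  ont <- parse_obo(path)
  # 4 genes: all reach A, two carry B, one carries C
  ann <- propagate_annotations(ont, list(g1 = "C", g2 = "B", g3 = "A", g4 = "A"))
  ic <- information_content(ann)
  expect_equal(unname(ic["A"]), 0)
  expect_equal(unname(ic["B"]), log(2))          # 2 of 4 genes
  expect_equal(unname(ic["C"]), -log(1 / 4))
})

test_that("IC is monotone non-increasing from child to parent on a random DAG", {
  dag <- random_dag_obo(25, 7)
  ont <- parse_obo(write_obo_fixture(dag$lines))
  set.seed(77)
  direct <- lapply(setNames(1:15, sprintf("g%02d", 1:15)), function(i)
    sample(dag$ids, 3))
  ann <- propagate_annotations(ont, direct)
  ic <- information_content(ann)
  # oracle: recount per-term gene counts directly
  for (t in names(ic)) {
    n_t <- sum(vapply(ann$propagated, function(p) t %in% p, logical(1)))
    expect_equal(unname(ic[t]), -log(n_t / ann$universe_size))
  }
  for (t in names(ic))
    for (p in intersect(ont$parents[[t]], names(ic)))
      expect_lte(ic[[p]], ic[[t]] + 1e-12)
})

test_that("pair similarity: identity, root-only overlap, and symmetry", {
  lines <- c("format-version: 1.2",
             "", "[Term]", "id: R",
             "", "[Term]", "id: X", "is_a: R",
             "", "[Term]", "id: Y", "is_a: R")
  ont <- parse_obo(write_obo_fixture(lines))
  ann <- propagate_annotations(ont, list(g1 = "X", g2 = "Y", g3 = "X", g4 = "R"))
  ic <- information_content(ann)
  # identical single-leaf profiles: similarity = summed IC of the profile
  s <- gene_pair_similarity("g1", "g3", ann, ic, ont)
  # g1/g3 profiles {X, R}: best-match sum = ic(X) + ic(R) = ic(X)
  expect_equal(s, ic[["X"]] + 0)
  # identical single-term root profile: similarity ic(root) = 0
  expect_equal(gene_pair_similarity("g4", "g4", ann, ic, ont), 0)
  # only the root in common -> 0
  expect_equal(gene_pair_similarity("g1", "g2", ann, ic, ont), 0)
  expect_equal(gene_pair_similarity("g2", "g1", ann, ic, ont),
               gene_pair_similarity("g1", "g2", ann, ic, ont))
  expect_error(gene_pair_similarity("g1", "nope", ann, ic, ont), "annotation")
})

test_that("pair similarity equals exhaustive common-ancestor enumeration", {
  for (seed in 1:5) {
    dag <- random_dag_obo(18, seed + 50)
    ont <- parse_obo(write_obo_fixture(dag$lines))
    set.seed(seed)
    direct <- lapply(setNames(1:8, sprintf("g%d", 1:8)), function(i)
      sample(dag$ids, 5))
    ann <- propagate_annotations(ont, direct)
    ic <- information_content(ann)
    for (pair in list(c("g1", "g2"), c("g3", "g7"), c("g5", "g5"))) {
      got <- gene_pair_similarity(pair[1], pair[2], ann, ic, ont)
      want <- bms_bruteforce(ann$propagated[[pair[1]]],
                             ann$propagated[[pair[2]]], ont$parents, ic)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("benchmark stores all unordered pairs and a consistent median", {
  dag <- random_dag_obo(20, 11)
  ont <- parse_obo(write_obo_fixture(dag$lines))
  set.seed(11)
  direct <- lapply(setNames(1:6, sprintf("g%d", 1:6)), function(i)
    sample(dag$ids, 3))
  ann <- propagate_annotations(ont, direct)
  ic <- information_content(ann)
  bench <- build_benchmark(ann, ic, ont)
  expect_equal(nrow(bench$pairs), 6 * 5 / 2)
  expect_true(all(bench$pairs$gene_a < bench$pairs$gene_b))
  expect_equal(bench$overall_median, median(bench$pairs$similarity))
  # every stored value matches the pairwise operation
  for (r in sample(nrow(bench$pairs), 5)) {
    row <- bench$pairs[r]
    expect_equal(row$similarity,
                 gene_pair_similarity(row$gene_a, row$gene_b, ann, ic, ont),
                 tolerance = 1e-12)
  }
})

test_that("branch restriction shrinks the universe and never raises similarity", {
  lines <- c("format-version: 1.2",
             "", "[Term]", "id: R",
             "", "[Term]", "id: B1", "is_a: R",
             "", "[Term]", "id: B2", "is_a: R",
             "", "[Term]", "id: L1", "is_a: B1",
             "", "[Term]", "id: L2", "is_a: B1",
             "", "[Term]", "id: L3", "is_a: B2")
  ont <- parse_obo(write_obo_fixture(lines))
  direct <- list(g1 = c("L1", "L3"), g2 = c("L2", "L3"), g3 = "L3", g4 = "L1")
  ann <- propagate_annotations(ont, direct)
  ic <- information_content(ann)
  full <- build_benchmark(ann, ic, ont)
  restricted <- build_benchmark(ann, ic, ont, branch_roots = "B1")
  # g3 is annotated only under B2 and must drop out
  expect_setequal(restricted$gene_universe, c("g1", "g2", "g4"))
  merged <- merge(restricted$pairs, full$pairs, by = c("gene_a", "gene_b"),
                  suffixes = c("_res", "_full"))
  expect_true(all(merged$similarity_res <= merged$similarity_full + 1e-12))
  expect_error(build_benchmark(ann, ic, ont, branch_roots = "L2"), "fewer than 2")
  expect_error(build_benchmark(ann, ic, ont, branch_roots = "NOPE"), "NOPE")
})

test_that("planted modules score higher within than between (many seeds)", {
  ok <- 0
  for (seed in 1:20) {
    sspec <- synthetic_spec(rng_seed = seed,
                            genes = list(n_genes = 40L, n_modules = 4L,
                                         module_size = 8L, terms_per_gene = 3L))
    oa <- make_ontology_and_annotations(sspec)
    ic <- information_content(oa$annotations)
    bench <- build_benchmark(oa$annotations, ic, oa$ontology)
    mods <- oa$modules
    bp <- bench$pairs
    within <- bp[mods[gene_a] == mods[gene_b] & mods[gene_a] > 0, median(similarity)]
    between <- bp[mods[gene_a] != mods[gene_b], median(similarity)]
    if (within > between) ok <- ok + 1
  }
  expect_equal(ok, 20)
})
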