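# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive reimplementation (brute force,
# enumeration, closed form) kept separate from the package code paths
# it checks.

library(data.table)

# ---- ontology fixtures ---------------------------------------------------

# chain ontology A <- B <- C ... (first element is the root)
chain_obo_lines <- function(ids) {
  out <- "format-version: 1.2"
  for (i in seq_along(ids)) {
    out <- c(out, "", "[Term]", paste0("id: ", ids[i]))
    if (i > 1) out <- c(out, paste0("is_a: ", ids[i - 1]))
  }
  out
}

write_obo_fixture <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

# random DAG: term i may take parents among terms 1..i-1
random_dag_obo <- function(n_terms, seed, p_edge = 0.4) {
  set.seed(seed)
  ids <- sprintf("D:%03d", seq_len(n_terms))
  out <- c("format-version: 1.2", "", "[Term]", paste0("id: ", ids[1]))
  for (i in 2:n_terms) {
    out <- c(out, "", "[Term]", paste0("id: ", ids[i]))
    parents <- ids[seq_len(i - 1)][runif(i - 1) < p_edge]
    if (length(parents) == 0) parents <- ids[sample.int(i - 1, 1)]
    out <- c(out, paste0("is_a: ", parents))
  }
  list(lines = out, ids = ids)
}

# brute-force transitive closure of the parent relation (incl. self)
closure_ancestors <- function(parents, term) {
  res <- term
  repeat {
    nxt <- unique(c(res, unlist(parents[res], use.names = FALSE)))
    if (length(nxt) == length(res)) return(res)
    res <- nxt
  }
}

# exhaustive Resnik best-match sum: enumerate all common ancestors per
# term pair, then sum each profile's best matches
bms_bruteforce <- function(p1, p2, parents, ic) {
  term_sim <- function(a, b) {
    common <- intersect(closure_ancestors(parents, a),
                        closure_ancestors(parents, b))
    common <- common[common %in% names(ic)]
    if (!length(common)) 0 else max(ic[common])
  }
  S <- outer(p1, p2, Vectorize(term_sim))
  (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / 2
}

# ---- graph / partition oracles -------------------------------------------

# all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(i, maxv, rgs) {
    if (i > n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <- v
      rec(i + 1L, max(maxv, v), rgs)
    }
  }
  rec(1L, 0L, integer(n))
  out
}

# exhaustive maximum modularity over every partition (<= 8 nodes)
brute_max_modularity <- function(net, resolution = 1) {
  genes <- net$genes
  max(vapply(all_partitions(length(genes)), function(p)
    modularity_score(net, setNames(p, genes), resolution), numeric(1)))
}

# naive O(n^2) modularity: double loop over ordered node pairs
naive_modularity <- function(net, assignment, resolution = 1) {
  gamma <- 1 / resolution
  genes <- names(assignment)
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  for (r in seq_len(nrow(net$links))) {
    a <- net$links$gene_a[r]; b <- net$links$gene_b[r]; w <- net$links$weight[r]
    A[a, b] <- A[a, b] + w
    A[b, a] <- A[b, a] + w
  }
  k <- rowSums(A)
  W <- sum(A) / 2
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (assignment[i] == assignment[j])
      q <- q + A[i, j] / (2 * W) - gamma * k[i] * k[j] / (4 * W^2)
  unname(q)
}

# random connected unweighted graph as a pln_network
random_connected_net <- function(n, p = 0.45) {
  repeat {
    m <- matrix(runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(m + t(m), mode = "undirected")
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  el <- igraph::as_edgelist(g)
  genes <- sprintf("v%02d", seq_len(n))
  pln_network(data.table(gene_a = genes[el[, 1]], gene_b = genes[el[, 2]],
                         weight = 1))
}

# random weighted graph (possibly disconnected)
random_weighted_net <- function(n, p = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(idx)) < p
    if (sum(keep) > 0) break
  }
  idx <- idx[keep, , drop = FALSE]
  genes <- sprintf("v%03d", seq_len(n))
  pln_network(data.table(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                         weight = runif(nrow(idx), 0.2, 2)))
}

# adjusted Rand index between two labelings (closed form)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ij <- si * sj / n2
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}

# ---- misc oracles --------------------------------------------------------

# direct-summation weighted sum
naive_ws <- function(values, D) {
  v <- sort(values, decreasing = TRUE)
  s <- v[1]
  if (length(v) > 1)
    for (i in seq_len(length(v) - 1L)) s <- s + v[i + 1L] / (D * i)
  s
}

# textbook Benjamini-Hochberg step-up with monotonicity enforcement
textbook_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# small synthetic world reused by several enrichment tests
make_test_world <- function(seed = 3) {
  sspec <- synthetic_spec(rng_seed = seed,
                          network = list(block_sizes = c(50L, 50L, 50L, 50L),
                                         p_in = 0.3, p_out = 0.01,
                                         weights = "unit"))
  bn <- make_block_network(sspec)
  stats <- make_gene_stats(bn$network$genes, bn$network,
                           derive_seed(seed, "stats"))
  list(spec = sspec, net = bn$network, blocks = bn$blocks, stats = stats)
}
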