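#' Parse an OBO 1.2 phenotype ontology
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `is_a` and `alt_id`
#' lines. Obsolete terms are dropped; alternative identifiers are
#' recorded so annotations using them can be mapped to the primary id.
#' The `is_a` relation must be acyclic.
#'
#' @param path path to an OBO v1.2 file.
#' @return an object of class `pln_ontology` with elements `terms`
#'   (character vector), `parents` (named list, term -> parent terms),
#'   `roots`, `alt_map` (named character, alt id -> primary id),
#'   `ancestors` (named list, term -> ancestors including the term
#'   itself) and `branch_roots` (empty until set).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) stop("no [Term] stanzas found in ", path)
  # stanza ends at the next bracketed header or EOF
  headers <- grep("^\\[", lines)
  terms <- character(0)
  parents <- list()
  alt_map <- character(0)
  for (s in stanza_starts) {
    nxt <- headers[headers > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):e]
    block <- block[nzchar(block)]
    ids <- sub("^id:\\s*", "", grep("^id:", block, value = TRUE))
    if (length(ids) != 1L)
      stop("malformed [Term] stanza at line ", s, ": expected exactly one id line")
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    id <- ids[[1]]
    isa <- grep("^is_a:", block, value = TRUE)
    # "is_a: MP:0000001 ! name" -> parent id before any comment
    pids <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "", isa))
    pids <- trimws(pids)
    alts <- sub("\\s*!.*$", "", sub("^alt_id:\\s*", "", grep("^alt_id:", block, value = TRUE)))
    terms <- c(terms, id)
    parents[[id]] <- unique(pids)
    if (length(alts)) alt_map[trimws(alts)] <- id
  }
  if (anyDuplicated(terms)) stop("duplicate term ids in ", path)
  # drop is_a edges pointing at obsolete/unknown terms
  parents <- lapply(parents, function(p) p[p %in% terms])
  ont <- structure(list(terms = terms, parents = parents,
                        alt_map = alt_map, branch_roots = character(0)),
                   class = "pln_ontology")
  ont$roots <- terms[vapply(parents, length, 1L) == 0L]
  ont$ancestors <- compute_ancestors(terms, parents)
  ont
}

# ancestors (including self) by memoized DFS; detects is_a cycles
compute_ancestors <- function(terms, parents) {
  anc <- vector("list", length(terms))
  names(anc) <- terms
  state <- setNames(integer(length(terms)), terms) # 0 unvisited, 1 in-stack, 2 done
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("cyclic is_a relation involving term ", t)
    state[[t]] <<- 1L
    res <- t
    for (p in parents[[t]]) res <- union(res, visit(p))
    state[[t]] <<- 2L
    anc[[t]] <<- res
    res
  }
  for (t in terms) visit(t)
  anc
}

#' @export
print.pln_ontology <- function(x, ...) {
  cat("Phenotype ontology:", length(x$terms), "terms,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

# descendants of a set of terms (including the terms themselves)
term_descendants <- function(ont, roots) {
  stopifnot(all(roots %in% ont$terms))
  hit <- vapply(ont$ancestors, function(a) any(roots %in% a), logical(1))
  names(hit)[hit]
}

#' Propagate gene annotations up the ontology
#'
#' Each gene's propagated profile is the ancestor closure of its direct
#' annotations (a gene annotated to a specific term is implicitly
#' annotated to every more general parent).
#'
#' @param ont a `pln_ontology`.
#' @param direct named list, gene id -> character vector of term ids
#'   (alternative ids are mapped to their primary term).
#' @return an object of class `pln_annotations` with `direct`,
#'   `propagated` and `universe_size`.
#' @export
propagate_annotations <- function(ont, direct) {
  stopifnot(is.list(direct), length(direct) > 0, !is.null(names(direct)))
  direct <- lapply(direct, function(ts) {
    hit <- ts %in% names(ont$alt_map)
    ts[hit] <- ont$alt_map[ts[hit]]
    unique(ts)
  })
  bad <- lapply(direct, function(ts) ts[!ts %in% ont$terms])
  nbad <- vapply(bad, length, 1L)
  if (any(nbad > 0)) {
    off <- unlist(lapply(names(bad)[nbad > 0], function(g)
      paste0("(", g, ", ", bad[[g]], ")")))
    stop("unknown term id(s): ", paste(head(off, 10), collapse = " "))
  }
  propagated <- lapply(direct, function(ts)
    unique(unlist(ont$ancestors[ts], use.names = FALSE)))
  structure(list(direct = direct, propagated = propagated,
                 universe_size = sum(vapply(propagated, length, 1L) > 0L)),
            class = "pln_annotations")
}

#' Information content of ontology terms
#'
#' `ic(t) = -ln(n_t / N)` where `n_t` is the number of annotated genes
#' whose propagated profile contains `t` and `N` the annotated-gene
#' universe size. The root of an ontology that annotates every gene has
#' IC 0; rarer terms are more informative. Terms annotating no gene are
#' absent from the result.
#'
#' @param ann a `pln_annotations`.
#' @return named numeric vector of information contents (nats).
#' @export
information_content <- function(ann) {
  stopifnot(inherits(ann, "pln_annotations"))
  if (ann$universe_size < 1) stop("empty annotation map")
  tab <- table(unlist(ann$propagated, use.names = FALSE))
  ic <- -log(as.numeric(tab) / ann$universe_size)
  setNames(ic, names(tab))
}

# Resnik MICA matrix over a term set: M[i, j] = IC of the
# most-informative common ancestor. Filled in decreasing-IC order so
# each cell is set by its MICA first.
mica_matrix <- function(ont, ic) {
  terms <- names(ic)
  A <- ont$ancestors[terms]
  n <- length(terms)
  M <- matrix(NA_real_, n, n, dimnames = list(terms, terms))
  ord <- order(ic, decreasing = TRUE)
  # desc_idx[[k]]: indices of terms having term k among their ancestors
  idx <- setNames(seq_len(n), terms)
  desc <- vector("list", n)
  for (i in seq_len(n)) {
    js <- idx[match(A[[i]], names(idx))]
    js <- js[!is.na(js)]
    for (j in js) desc[[j]] <- c(desc[[j]], i)
  }
  for (k in ord) {
    d <- desc[[k]]
    if (length(d) == 0) next
    sub <- M[d, d, drop = FALSE]
    sub[is.na(sub)] <- ic[[k]]
    M[d, d] <- sub
  }
  M[is.na(M)] <- 0 # no common ancestor with positive IC
  M
}

# symmetric best-match sum over a pairwise term-similarity submatrix:
# each term contributes its best match on the other profile, so the
# statistic is cumulative in annotation depth and can only decrease
# when a profile is restricted to fewer terms
best_match_sum <- function(M, p1, p2) {
  S <- M[p1, p2, drop = FALSE]
  rmax <- S[cbind(seq_along(p1), max.col(S, ties.method = "first"))]
  cmax <- t(S)[cbind(seq_along(p2), max.col(t(S), ties.method = "first"))]
  (sum(rmax) + sum(cmax)) / 2
}

#' Semantic similarity between two genes' annotation profiles
#'
#' Resnik term similarity (IC of the most-informative common ancestor)
#' aggregated by the symmetric best-match sum over the two propagated
#' profiles: every term contributes the IC of its best counterpart, so
#' the measure is cumulative in annotation depth. Symmetric and
#' non-negative; two profiles sharing only an IC-0 root score 0;
#' identical single-term profiles `{t}` score `ic(t)`.
#'
#' @param gene_a,gene_b gene ids, both annotated.
#' @param ann a `pln_annotations`.
#' @param ic named IC vector from [information_content()].
#' @param ont the `pln_ontology` (for ancestor lookups).
#' @return similarity score (non-negative scalar).
#' @export
gene_pair_similarity <- function(gene_a, gene_b, ann, ic, ont) {
  for (g in c(gene_a, gene_b))
    if (is.null(ann$propagated[[g]]) || length(ann$propagated[[g]]) == 0)
      stop("gene ", g, " has no annotations")
  p1 <- ann$propagated[[gene_a]]
  p2 <- ann$propagated[[gene_b]]
  best <- function(t1, t2) {
    common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
    common <- common[common %in% names(ic)]
    if (length(common) == 0) 0 else max(ic[common])
  }
  S <- outer(p1, p2, Vectorize(best))
  (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / 2
}

#' Build a phenotypic benchmark of gene-pair similarities
#'
#' Computes the semantic similarity for every unordered pair of genes in
#' the universe. With `branch_roots` set, the universe is restricted to
#' genes annotated under at least one branch (the branch root or any
#' descendant) and profiles are restricted to branch terms, giving a
#' phenotype-domain-specific benchmark.
#'
#' @param ann a `pln_annotations`.
#' @param ic named IC vector.
#' @param ont the `pln_ontology`.
#' @param branch_roots character vector of branch root terms, or `NULL`
#'   for the general benchmark.
#' @return an object of class `pln_benchmark`: `gene_universe` (sorted),
#'   `pairs` (data.table `gene_a`, `gene_b`, `similarity`; `gene_a <
#'   gene_b`), `overall_median`, `restricted_branch_roots`.
#' @export
build_benchmark <- function(ann, ic, ont, branch_roots = NULL) {
  stopifnot(inherits(ann, "pln_annotations"))
  profiles <- ann$propagated
  if (!is.null(branch_roots) && length(branch_roots)) {
    if (!all(branch_roots %in% ont$terms))
      stop("branch root(s) not in ontology: ",
           paste(setdiff(branch_roots, ont$terms), collapse = ", "))
    branch_terms <- term_descendants(ont, branch_roots)
    profiles <- lapply(profiles, function(p) intersect(p, branch_terms))
  }
  keep <- vapply(profiles, length, 1L) > 0L
  universe <- sort(names(profiles)[keep])
  if (length(universe) < 2)
    stop("fewer than 2 genes remain after branch restriction")
  M <- mica_matrix(ont, ic)
  prof_idx <- lapply(profiles[universe], function(p) intersect(p, rownames(M)))
  n <- length(universe)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  sim <- numeric(length(ii))
  for (k in seq_along(ii))
    sim[k] <- best_match_sum(M, prof_idx[[ii[k]]], prof_idx[[jj[k]]])
  pairs <- data.table(gene_a = universe[ii], gene_b = universe[jj],
                      similarity = sim)
  setkey(pairs, gene_a, gene_b)
  structure(list(gene_universe = universe, pairs = pairs,
                 overall_median = median(sim),
                 restricted_branch_roots = branch_roots %||% character(0)),
            class = "pln_benchmark")
}

#' @export
print.pln_benchmark <- function(x, ...) {
  cat("Phenotypic benchmark:", length(x$gene_universe), "genes,",
      nrow(x$pairs), "pairs, overall median",
      format(x$overall_median, digits = 4), "\n")
  if (length(x$restricted_branch_roots))
    cat("  restricted to branches:",
        paste(x$restricted_branch_roots, collapse = ", "), "\n")
  invisible(x)
}

# fast lookup of benchmark similarity for canonical pair keys;
# NA where the pair is not in the benchmark
benchmark_lookup <- function(bench, gene_a, gene_b) {
  qry <- data.table(gene_a = gene_a, gene_b = gene_b)
  bench$pairs[qry, on = c("gene_a", "gene_b")]$similarity
}
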