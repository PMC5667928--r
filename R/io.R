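# ---- readers -------------------------------------------------------------

# read a TSV body, skipping '#' comment lines and (optionally) a header
# row that repeats the expected column names
fread_body <- function(path, col_names, header_names = col_names) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) && identical(strsplit(lines[1], "\t")[[1]], header_names))
    lines <- lines[-1]
  if (!length(lines)) stop("no data rows in ", path)
  dt <- fread(text = lines, header = FALSE, sep = "\t")
  if (ncol(dt) != length(col_names))
    stop("expected ", length(col_names), " columns in ", path,
         " but found ", ncol(dt))
  setnames(dt, col_names)
  dt
}

#' Read a gene->term annotation table
#'
#' TSV with two columns `gene_id<TAB>term_id`, one pair per line;
#' `#` lines are comments.
#'
#' @param path file path.
#' @return named list, gene -> character vector of terms.
#' @export
read_annotations_tsv <- function(path) {
  dt <- fread_body(path, c("gene", "term"))
  lapply(split(dt$term, dt$gene), unique)
}

#' Read a 1:1 orthology map
#'
#' TSV `human_id<TAB>mouse_id`. Genes involved in many-to-many
#' orthology are excluded (only unique orthologues are kept).
#'
#' @param path file path.
#' @return named character vector, human id -> mouse id.
#' @export
read_orthology <- function(path) {
  dt <- fread_body(path, c("human", "mouse"))
  dt <- dt[!human %in% dt[duplicated(human), human]]
  dt <- dt[!mouse %in% dt[duplicated(mouse), mouse]]
  setNames(dt$mouse, dt$human)
}

#' Map annotation genes through a 1:1 orthology table
#'
#' Re-keys a direct-annotation list (e.g. mouse genes) to the other
#' species' identifiers; genes without a unique orthologue are dropped,
#' with a message reporting how many.
#'
#' @param direct named list, gene -> terms (keys in the map's values).
#' @param orthology named character vector from [read_orthology()]
#'   (human id -> mouse id).
#' @return named list keyed by human id.
#' @export
apply_orthology <- function(direct, orthology) {
  rev_map <- setNames(names(orthology), orthology)
  hit <- names(direct) %in% names(rev_map)
  if (any(!hit))
    message(sum(!hit), " gene(s) without a unique orthologue dropped")
  out <- direct[hit]
  names(out) <- unname(rev_map[names(out)])
  out
}

#' Read a gene set (one id per line; '#' comments)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x[!grepl("^#", x) & nzchar(trimws(x))])
  unique(x)
}

#' Read a gene-pair evidence table (`gene_a<TAB>gene_b<TAB>score`)
#' @param path file path.
#' @param name dataset label (default: file base name).
#' @return a `pln_evidence`.
#' @export
read_evidence_tsv <- function(path, name = NULL) {
  dt <- fread_body(path, c("gene_a", "gene_b", "score"))
  evidence_dataset(dt, name = name %||% basename(path))
}

#' Read an expression matrix (gene id column + numeric columns, header)
#' @param path file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a weighted edge list (`gene_a<TAB>gene_b<TAB>weight`)
#' @param path file path.
#' @return a `pln_network`.
#' @export
read_edge_list <- function(path) {
  dt <- fread_body(path, c("gene_a", "gene_b", "weight"))
  cp <- canonical_pairs(dt$gene_a, dt$gene_b)
  dt[, `:=`(gene_a = cp$gene_a, gene_b = cp$gene_b)]
  dup <- dt[, .(k = uniqueN(weight), .N), by = .(gene_a, gene_b)][N > 1L]
  if (nrow(dup[k > 1L]))
    stop("duplicate edges with conflicting weights, e.g. ",
         dup[k > 1L][1L, paste(gene_a, gene_b)], " in ", path)
  pln_network(unique(dt, by = c("gene_a", "gene_b")))
}

#' Read a BED interval file plus a gene-order table
#'
#' BED: 3+ columns, 0-based half-open. Gene order:
#' `gene<TAB>chrom<TAB>rank<TAB>start<TAB>end[<TAB>cds_length]` with
#' header. Interval gene membership is any overlap with the gene span.
#'
#' @param bed_path BED file.
#' @param gene_order_path gene-order TSV.
#' @return a `pln_intervals` (gene_order keeps `cds_length` if given).
#' @export
read_intervals_bed <- function(bed_path, gene_order_path) {
  bed <- fread(bed_path, header = FALSE, sep = "\t")
  if (ncol(bed) < 3) stop("BED needs at least 3 columns: ", bed_path)
  setnames(bed, 1:3, c("chrom", "start", "end"))
  go <- fread(gene_order_path, header = TRUE, sep = "\t")
  genomic_intervals(bed[, .(chrom, start, end)], go)
}

#' Read per-gene p-values (`gene<TAB>p`, header optional)
#' @param path file path.
#' @return named numeric vector.
#' @export
read_gene_pvalues <- function(path) {
  dt <- fread(path, header = "auto", sep = "\t")
  setnames(dt, 1:2, c("gene", "p"))
  setNames(as.numeric(dt$p), dt$gene)
}

#' Read per-individual case/control variant counts
#'
#' TSV with header `individual<TAB>label<TAB>count` (aggregate count)
#' or `individual<TAB>label<TAB><gene1>...` (per-gene columns, summed).
#'
#' @param path file path.
#' @return a `pln_case_control`.
#' @export
read_case_control_tsv <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  if (ncol(dt) < 3) stop("need individual, label and count column(s): ", path)
  counts <- if (ncol(dt) == 3) as.numeric(dt[[3]])
            else rowSums(as.matrix(dt[, -(1:2)]))
  case_control_counts(setNames(counts, dt[[1]]),
                      setNames(as.character(dt[[2]]), dt[[1]]))
}

# ---- writers (sorted, fixed precision, provenance headers) ---------------

provenance_header <- function(seed = NA, extra = character(0)) {
  c(paste0("# plnet v", as.character(packageVersion("plnet"))),
    paste0("# seed: ", seed), extra)
}

write_tsv_with_header <- function(dt, path, header_lines, num_cols = character(0)) {
  dt <- copy(as.data.table(dt))
  for (cl in intersect(num_cols, names(dt)))
    dt[[cl]] <- sprintf("%.6f", dt[[cl]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste(names(dt), collapse = "\t"), con)
  if (nrow(dt))
    writeLines(do.call(paste, c(unname(as.list(dt)), sep = "\t")), con)
  invisible(path)
}

#' Export a benchmark as TSV (`gene_a`, `gene_b`, `similarity`)
#' @param bench a `pln_benchmark`.
#' @param path output file.
#' @param seed provenance seed.
#' @return the path, invisibly.
#' @export
write_benchmark <- function(bench, path, seed = NA) {
  dt <- bench$pairs[order(gene_a, gene_b)]
  write_tsv_with_header(dt, path, provenance_header(seed,
    paste0("# overall_median: ", sprintf("%.6f", bench$overall_median))),
    num_cols = "similarity")
}

#' Export a network edge list (descending weight, 6 decimals)
#' @param net a `pln_network`.
#' @param path output file.
#' @param seed provenance seed.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(net, path, seed = NA) {
  write_tsv_with_header(net$links, path, provenance_header(seed),
                        num_cols = "weight")
}

#' Export a bin profile for plotting
#' @param profile a `pln_bin_profile`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bin_profile <- function(profile, path) {
  write_tsv_with_header(
    profile$bins[, .(bin_index, median_score, median_similarity, n_pairs)],
    path, provenance_header(extra = paste0("# dataset: ", profile$name)),
    num_cols = c("median_score", "median_similarity"))
}

#' Write an ontology in OBO 1.2 format
#' @param ont a `pln_ontology`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ont$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    for (p in ont$parents[[t]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param intervals a `pln_intervals`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  dt <- intervals$intervals[order(chrom, start)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d", dt$chrom, as.integer(dt$start),
                     as.integer(dt$end)), con)
  invisible(path)
}

# ---- pipeline ------------------------------------------------------------

# polynomial rolling hash of a string, 8 hex digits (config provenance)
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_defaults <- function() {
  list(seed = 1L, out_dir = "pln_out", bin_size = 100L,
       d_range = 1:10, top_links = 5000L, alpha = 0.5, iterations = 50L,
       n_null_draws = 99L, resolution = 1, min_size = 10L, n_perm = 199L,
       synthetic = list())
}

#' Run the full analysis pipeline on synthetic study data
#'
#' Executes the stage chain benchmark -> evaluate -> integrate ->
#' communities/diffuse -> enrich on inputs from the synthetic
#' generators, writing each artifact with a provenance header (tool
#' version, seed, config hash). Re-running with an identical
#' configuration reproduces every artifact byte-identically.
#'
#' @param config configuration list, or path to a YAML file with the
#'   same keys: `seed`, `out_dir`, `bin_size`, `d_range`, `top_links`,
#'   `alpha`, `iterations`, `n_null_draws`, `resolution`, `min_size`,
#'   `n_perm`, `synthetic` (overrides for [synthetic_spec()]). Unknown
#'   keys are rejected.
#' @return invisibly, a list of the written artifact paths plus the key
#'   in-memory results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  # hash analysis parameters only; the output location is not provenance
  hcfg <- cfg[sort(setdiff(names(cfg), "out_dir"))]
  cfg_hash <- config_hash(paste(deparse(hcfg), collapse = ""))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- function(extra = character(0))
    provenance_header(cfg$seed, c(paste0("# config: ", cfg_hash), extra))
  paths <- list()

  sspec <- do.call(synthetic_spec, c(list(rng_seed = cfg$seed), cfg$synthetic))
  oa <- make_ontology_and_annotations(sspec)
  ic <- information_content(oa$annotations)
  bench <- build_benchmark(oa$annotations, ic, oa$ontology)
  paths$benchmark <- file.path(cfg$out_dir, "benchmark.tsv")
  write_tsv_with_header(bench$pairs[order(gene_a, gene_b)], paths$benchmark,
                        hdr(), num_cols = "similarity")

  datasets <- make_evidence(bench, sspec)
  rescored <- list()
  eval_rows <- list()
  for (ds in datasets) {
    prof <- bin_profile(ds, bench, cfg$bin_size)
    paths[[paste0("profile_", ds$name)]] <-
      file.path(cfg$out_dir, paste0("profile_", ds$name, ".tsv"))
    write_bin_profile(prof, paths[[paste0("profile_", ds$name)]])
    thr <- informative_cutoff(prof)
    if (is.na(thr)) {
      eval_rows[[ds$name]] <- data.table(dataset = ds$name, informative = FALSE,
                                         degree = NA_integer_, threshold = NA_real_)
      next
    }
    model <- fit_rescoring(prof)
    rescored[[ds$name]] <- suppressWarnings(rescore(ds, model))
    eval_rows[[ds$name]] <- data.table(dataset = ds$name, informative = TRUE,
                                       degree = model$degree,
                                       threshold = model$threshold_score)
  }
  paths$evaluation <- file.path(cfg$out_dir, "evaluation.tsv")
  write_tsv_with_header(rbindlist(eval_rows), paths$evaluation, hdr(),
                        num_cols = "threshold")

  icfg <- integration_config(D = min(cfg$d_range), D_range = cfg$d_range,
                             top_links = cfg$top_links, bin_size = cfg$bin_size)
  sel <- select_D(rescored, bench, icfg)
  icfg$D <- sel$D
  net <- integrate_network(rescored, icfg)
  paths$network <- file.path(cfg$out_dir, "network.tsv")
  write_edge_list(net, paths$network, cfg$seed)

  part <- louvain(net, cfg$resolution, derive_seed(cfg$seed, "louvain"))
  paths$communities <- file.path(cfg$out_dir, "communities.tsv")
  pt <- data.table(gene = names(part$assignment),
                   community = unname(part$assignment))[order(gene)]
  write_tsv_with_header(pt, paths$communities,
                        hdr(sprintf("# modularity: %.6f", part$modularity)))

  trans <- normalize_adjacency(net)
  dcfg <- diffusion_config(cfg$alpha, cfg$iterations, cfg$n_null_draws)
  seeds_genes <- head(sort(net$genes), 8L)
  diff <- seed_significance(trans, seeds_genes, dcfg,
                            derive_seed(cfg$seed, "diffusion"))
  paths$diffusion <- file.path(cfg$out_dir, "diffusion.tsv")
  dt <- data.table(gene = names(diff$scores), score = unname(diff$scores),
                   p_mono = unname(diff$p_mono))[order(gene)]
  write_tsv_with_header(dt, paths$diffusion, hdr(),
                        num_cols = c("score", "p_mono"))

  stats <- make_gene_stats(net$genes, net, derive_seed(cfg$seed, "stats"))
  comms <- filter_communities(part, cfg$min_size)
  enr_rows <- list()
  if (length(comms)) {
    gene_set <- head(comms[[1]], 10L)
    e <- community_set_enrichment(comms[[1]], gene_set, net$genes, stats,
                                  n_perm = cfg$n_perm,
                                  rng_seed = derive_seed(cfg$seed, "enrich"))
    enr_rows$community_set <- data.table(test = "community_set",
                                         observed = e$observed_stat,
                                         n_perm = e$null_draws, p = e$empirical_p)
    ct <- clustering_test(net, gene_set, net$genes, stats, n_perm = cfg$n_perm,
                          rng_seed = derive_seed(cfg$seed, "cluster"))
    enr_rows$clustering <- data.table(test = "clustering",
                                      observed = ct$observed_stat,
                                      n_perm = ct$null_draws, p = ct$empirical_p)
  }
  paths$enrichment <- file.path(cfg$out_dir, "enrichment.tsv")
  write_tsv_with_header(rbindlist(enr_rows), paths$enrichment, hdr(),
                        num_cols = c("observed", "p"))

  invisible(list(paths = paths, config = cfg, benchmark = bench,
                 selected_D = sel$D, network = net, partition = part,
                 diffusion = diff))
}
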