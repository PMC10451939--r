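# End-to-end orchestration: a validated run configuration, a benchmark
# simulation wiring the generator to the downstream statistics, and
# run_pipeline() producing the count matrix, contingency tests and
# fraction reports from either real input files or a simulation.

#' Build a run configuration
#'
#' Exactly one of `input` and `simulation` must be supplied. `input` is a
#' list of paths: either `count_matrix` (a wide-layout count table, see
#' [read_count_matrix]) or `hits` + `query_genes` + `subject_genes`
#' (+ optional `protein_map`). `simulation` is a list of parameters for
#' [simulate_chromosome_benchmark] (`n_genes`, `retention`, optional
#' `noise_sd`).
#'
#' @param input list of input paths, or `NULL`.
#' @param simulation list of simulation parameters, or `NULL`.
#' @param significance_threshold e-value cutoff for hit classification.
#' @param groups a [chromosome_groups] object (ignored for simulations,
#'   which define their own groups).
#' @param query_pairs list of length-2 character vectors of query
#'   chromosomes to test.
#' @param columns count columns to test.
#' @param seed integer seed covering every stochastic stage.
#' @param output_dir directory for report files, or `NULL` to skip
#'   writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       significance_threshold = 1e-5,
                       groups = chromosome_groups(),
                       query_pairs = list(c("8", "41"), c("8", "22")),
                       columns = c("top", "total", "solo"),
                       seed = 1L, output_dir = NULL) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of input and simulation must be given")
  stopifnot(all(columns %in% c("top", "total", "solo")))
  for (p in query_pairs)
    if (length(p) != 2L) stop("each query pair must name two chromosomes")
  structure(list(input = input, simulation = simulation,
                 significance_threshold = significance_threshold,
                 groups = groups, query_pairs = query_pairs,
                 columns = columns, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML form round-trips: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a [run_config].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns a [run_config].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$groups <- unclass(x$groups)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  groups <- if (is.null(x$groups)) chromosome_groups()
            else chromosome_groups(x$groups$group_a, x$groups$group_b,
                                   x$groups$ancestral_label %||% "")
  run_config(input = x$input, simulation = x$simulation,
             significance_threshold = x$significance_threshold %||% 1e-5,
             groups = groups,
             query_pairs = lapply(x$query_pairs, as.character),
             columns = unlist(x$columns),
             seed = x$seed %||% 1L,
             output_dir = x$output_dir)
}

#' Benchmark simulation: one ancestral chromosome through two WGD rounds
#'
#' Emulates the study design at small scale: a single ancestral
#' chromosome is duplicated by the shared WGD1; lineage A (the query
#' genome) keeps the two resulting chromosomes, so each descends from one
#' WGD1 copy; lineage B undergoes a second WGD, yielding two sister
#' groups of two chromosomes each — the analogue of the human {4,5} vs
#' {2,8,10} chromosome groups, which descend from the two WGD1 copies.
#' Independent per-copy losses at retention `r` act in both lineages.
#' The return value wires directly into the downstream statistics: the
#' correct test compares the two A chromosomes against the two B groups.
#'
#' @param n_genes ancestral gene count (default 500).
#' @param retention per-copy retention probability (default 0.6).
#' @param noise_sd bit-score noise standard deviation (default 2).
#' @param seed integer seed.
#' @return list: `history`, `hits`, `query_locations`,
#'   `subject_locations`, `groups` ([chromosome_groups] over the B
#'   chromosomes by WGD1-copy ancestry), `query_chromosomes` (the two A
#'   chromosomes).
#' @export
simulate_chromosome_benchmark <- function(n_genes = 500L, retention = 0.6,
                                          noise_sd = 2, seed = 1L) {
  seeds <- spawn_seeds(seed, 2L)
  ancestral <- ancestral_genome(n_genes, chromosome_ids = "q")
  schedule <- event_schedule(
    shared = list(ev_wgd(2L)),
    lineage_a = list(ev_loss(retention)),
    lineage_b = list(ev_wgd(2L), ev_loss(retention)),
    seed = seeds[1]
  )
  history <- simulate_history(ancestral, schedule)
  hits <- emit_hit_table(history,
                         similarity_model(noise_sd = noise_sd),
                         seed = seeds[2])
  list(history = history,
       hits = hits,
       query_locations = history$genome_a,
       subject_locations = history$genome_b,
       groups = chromosome_groups(group_a = c("q.1.1", "q.1.2"),
                                  group_b = c("q.2.1", "q.2.2"),
                                  ancestral_label = "q"),
       query_chromosomes = c("q.1", "q.2"))
}

#' Run the full chromosome-association pipeline
#'
#' Produces the count matrix (from a packaged/previous count table, from
#' hit and gene-location files, or from a benchmark simulation), then for
#' every configured query-chromosome pair and count column the pooled 2x2
#' contingency table and its Pearson chi-square, plus per-chromosome
#' group fractions and group sums. When `output_dir` is set, writes
#' `count_matrix.tsv`, `association_tests.tsv` and `group_fractions.tsv`,
#' each headed by comment lines recording the configuration hash, seed
#' and significance threshold.
#'
#' @param config a [run_config].
#' @return list of class `pipeline_result`: `count_matrix`, `tests`
#'   (data.frame: comparison, column, a, b, c, d, statistic, df,
#'   p_value), `fractions` (data.frame: query_chromosome, column,
#'   group_count, denominator, percent), `config`, `paths` (written
#'   files, if any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  groups <- config$groups
  query_pairs <- config$query_pairs

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    bench <- simulate_chromosome_benchmark(
      n_genes = sim$n_genes %||% 500L,
      retention = sim$retention %||% 0.6,
      noise_sd = sim$noise_sd %||% 2,
      seed = config$seed)
    summaries <- summarize_hits(bench$hits, config$significance_threshold)
    cm <- build_count_matrix(summaries, bench$query_locations,
                             bench$subject_locations)
    groups <- bench$groups
    query_pairs <- list(bench$query_chromosomes)
  } else if (!is.null(config$input$count_matrix)) {
    path <- config$input$count_matrix
    if (!file.exists(path))
      stop_stage("input", "count matrix file not found: ", path)
    cm <- read_count_matrix(path)
  } else {
    inp <- config$input
    for (key in c("hits", "query_genes", "subject_genes"))
      if (is.null(inp[[key]]) || !file.exists(inp[[key]]))
        stop_stage("input", key, " file missing or not found: ",
                   inp[[key]] %||% "<unset>")
    pmap <- if (!is.null(inp$protein_map))
      read_protein_gene_map(inp$protein_map) else NULL
    hits <- read_outfmt6(inp$hits, pmap, strict = !is.null(pmap))
    summaries <- summarize_hits(hits, config$significance_threshold)
    cm <- build_count_matrix(summaries,
                             read_gene_table(inp$query_genes),
                             read_gene_table(inp$subject_genes))
  }

  tests <- do.call(rbind, lapply(query_pairs, function(pair) {
    do.call(rbind, lapply(config$columns, function(col) {
      tab <- pool_counts(cm, pair, groups, col)
      if (isTRUE(attr(tab, "untestable")))
        return(data.frame(comparison = paste(pair, collapse = " vs "),
                          column = col, a = tab[1, 1], b = tab[1, 2],
                          c = tab[2, 1], d = tab[2, 2],
                          statistic = NA_real_, df = 1L,
                          p_value = NA_real_))
      res <- pearson_chi_square(tab)
      data.frame(comparison = paste(pair, collapse = " vs "),
                 column = col, a = tab[1, 1], b = tab[1, 2],
                 c = tab[2, 1], d = tab[2, 2],
                 statistic = res$statistic, df = res$df,
                 p_value = res$p_value)
    }))
  }))
  rownames(tests) <- NULL

  group_set <- c(groups$group_a, groups$group_b)
  qchroms <- unique(unlist(query_pairs))
  fractions <- do.call(rbind, lapply(qchroms, function(q) {
    do.call(rbind, lapply(config$columns, function(col) {
      data.frame(query_chromosome = q, column = col,
                 group_count = count_group_sum(cm, q, group_set, col),
                 denominator = sum(cm_column(cm, q, col)),
                 percent = fraction_on_group(cm, q, group_set, col))
    }))
  }))
  rownames(fractions) <- NULL

  paths <- character(0)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    hashed <- unclass(config)
    hashed$output_dir <- NULL   # hash the analysis, not where it lands
    hdr <- c(paste0("# config_hash: ", config_hash(hashed)),
             paste0("# seed: ", config$seed),
             paste0("# significance_threshold: ",
                    format(config$significance_threshold)))
    paths <- vapply(
      list(list("count_matrix.tsv", function(p) write_count_matrix(cm, p)),
           list("association_tests.tsv",
                function(p) write_report_tsv(tests, p, hdr)),
           list("group_fractions.tsv",
                function(p) write_report_tsv(fractions, p, hdr))),
      function(spec) {
        p <- file.path(config$output_dir, spec[[1]])
        spec[[2]](p)
        p
      }, "")
  }

  structure(list(count_matrix = cm, tests = tests, fractions = fractions,
                 config = config, paths = paths),
            class = "pipeline_result")
}

write_report_tsv <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  t <- x$tests
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %s [%s]: chi-square = %.2f, df = %d, p = %.3f\n",
                t$comparison[i], t$column[i], t$statistic[i], t$df[i],
                t$p_value[i]))
  invisible(x)
}

#' Packaged lamprey-vs-human chromosome count table
#'
#' Per-chromosome best-hit counts comparing the protein-coding genes of
#' *Petromyzon marinus* chromosomes 8, 41 and 22 with the human proteome:
#' for each query chromosome, the number of query genes whose best hit
#' ("top"), any of whose three best hits ("total"), or whose single
#' significant hit ("solo") lies on each human chromosome.
#'
#' @return a `count_matrix`.
#' @export
lamprey_human_counts <- function() {
  read_count_matrix(system.file("extdata",
                                "petromyzon_human_chromosome_counts.tsv",
                                package = "paralogon", mustWork = TRUE))
}
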