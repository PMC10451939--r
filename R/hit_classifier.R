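# Best-hit classification: reduce raw protein-level hits to per-query-gene
# summaries (up to three highest-scoring distinct subject genes, plus a
# "solo" flag for queries with a single significant subject), and aggregate
# summaries into the per-chromosome top/total/solo count matrix.

# Shared ranking rule: bit score descending, then e-value ascending, then
# subject id ascending. Deterministic under any input order.
rank_subjects <- function(df) {
  df[order(-df$bit_score, df$e_value, df$subject_gene), , drop = FALSE]
}

# Collapse protein-level hits to one row per distinct subject gene,
# keeping the best-scoring record (isoform collapse).
collapse_subjects <- function(df) {
  df <- rank_subjects(df)
  df[!duplicated(df$subject_gene), , drop = FALSE]
}

#' Summarize the hits of one query gene
#'
#' Applies the significance filter, collapses isoform-level hits to one
#' record per distinct subject gene (keeping the highest bit score), ranks
#' subjects by (bit score desc, e-value asc, subject id asc), and truncates
#' to the `max_subjects` highest-scoring distinct subjects. The `is_solo`
#' flag records whether exactly one distinct significant subject gene
#' existed, evaluated before truncation: a query with four weak distinct
#' subjects is not solo.
#'
#' @param hits data.frame of hits sharing one `query_gene` (columns
#'   `query_gene`, `subject_gene`, `bit_score`, `e_value`).
#' @param significance_threshold keep hits with e-value at or below this
#'   (default `1e-5`).
#' @param max_subjects number of distinct subjects to retain (default 3).
#' @return list of class `query_hit_summary`: `query_gene`,
#'   `best_subjects` (data.frame `subject_gene`, `bit_score`, `e_value`,
#'   ranked), `n_distinct_subjects` (pre-truncation), `is_solo`.
#' @export
summarize_query <- function(hits, significance_threshold = 1e-5,
                            max_subjects = 3L) {
  qg <- unique(hits$query_gene)
  if (length(qg) > 1L)
    stop("summarize_query expects hits for a single query gene, got: ",
         paste(qg, collapse = ", "))
  keep <- hits$e_value <= significance_threshold
  df <- hits[keep, c("subject_gene", "bit_score", "e_value"), drop = FALSE]
  df <- collapse_subjects(df)
  n_distinct <- nrow(df)
  out <- list(
    query_gene = if (length(qg)) qg else NA_character_,
    best_subjects = utils::head(df, max_subjects),
    n_distinct_subjects = n_distinct,
    is_solo = n_distinct == 1L
  )
  rownames(out$best_subjects) <- NULL
  class(out) <- "query_hit_summary"
  out
}

#' Summarize every query gene in a hit table
#'
#' @inheritParams summarize_query
#' @param hits data.frame of hits (any number of query genes).
#' @return named list of [summarize_query] results, one per query gene
#'   appearing in `hits`.
#' @export
summarize_hits <- function(hits, significance_threshold = 1e-5,
                           max_subjects = 3L) {
  parts <- split(hits, hits$query_gene)
  out <- lapply(parts, summarize_query,
                significance_threshold = significance_threshold,
                max_subjects = max_subjects)
  out[order(names(out))]
}

#' Build the per-chromosome top/total/solo count matrix
#'
#' For each query gene with at least one significant subject: the
#' chromosome of its rank-1 subject gains one "top" count; every
#' chromosome appearing among its retained subjects gains one "total"
#' count (at most once per query per chromosome); if the query is solo,
#' the single subject's chromosome gains one "solo" count. Per query
#' chromosome the matrix also records the denominators
#' `n_queries_with_hits` and `n_solo_queries`.
#'
#' @param summaries list from [summarize_hits].
#' @param query_locations,subject_locations [gene_locations] tables for
#'   the query and subject genomes.
#' @return object of class `count_matrix`: list with `counts` (data.frame
#'   `query_chromosome`, `subject_chromosome`, `top`, `total`, `solo`) and
#'   `denominators` (data.frame `query_chromosome`,
#'   `n_queries_with_hits`, `n_solo_queries`).
#' @export
build_count_matrix <- function(summaries, query_locations, subject_locations) {
  summaries <- Filter(function(s) nrow(s$best_subjects) > 0L, summaries)
  qmap <- stats::setNames(query_locations$chromosome, query_locations$gene_id)
  smap <- stats::setNames(subject_locations$chromosome, subject_locations$gene_id)

  all_subj <- unique(unlist(lapply(summaries,
                                   function(s) s$best_subjects$subject_gene)))
  bad <- setdiff(all_subj, names(smap))
  if (length(bad))
    stop("subject genes not locatable: ", paste(bad, collapse = ", "))
  bad_q <- setdiff(vapply(summaries, `[[`, "", "query_gene"), names(qmap))
  if (length(bad_q))
    stop("query genes not locatable: ", paste(bad_q, collapse = ", "))

  rows <- lapply(summaries, function(s) {
    qc <- unname(qmap[s$query_gene])
    sc <- unname(smap[s$best_subjects$subject_gene])
    top_chrom <- sc[1]
    data.frame(
      query_chromosome = qc,
      subject_chromosome = unique(sc),
      top = as.integer(unique(sc) == top_chrom),
      total = 1L,
      solo = as.integer(s$is_solo & unique(sc) == top_chrom)
    )
  })
  long <- do.call(rbind, rows)
  counts <- stats::aggregate(cbind(top, total, solo) ~
                               query_chromosome + subject_chromosome,
                             data = long, FUN = sum)
  counts <- counts[order(counts$query_chromosome, counts$subject_chromosome), ]
  rownames(counts) <- NULL

  qc_all <- vapply(summaries, function(s) unname(qmap[s$query_gene]), "")
  solo_all <- vapply(summaries, `[[`, TRUE, "is_solo")
  denom <- data.frame(
    query_chromosome = sort(unique(qc_all)),
    n_queries_with_hits = as.integer(table(qc_all)[sort(unique(qc_all))]),
    n_solo_queries = vapply(sort(unique(qc_all)),
                            function(ch) sum(solo_all[qc_all == ch]), 0L)
  )
  rownames(denom) <- NULL
  new_count_matrix(counts, denom)
}

new_count_matrix <- function(counts, denominators) {
  out <- list(counts = counts, denominators = denominators)
  class(out) <- "count_matrix"
  validate_count_matrix(out)
  out
}

#' Validate count-matrix invariants
#'
#' Checks: all counts non-negative; per cell `solo <= top <= total`; per
#' query chromosome the "top" counts sum to the number of queries with
#' hits, the "solo" counts sum to the number of solo queries, and the
#' "total" counts sum to at most three times the number of queries.
#'
#' @param x a `count_matrix`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_count_matrix <- function(x) {
  cc <- x$counts
  if (any(cc$top < 0 | cc$total < 0 | cc$solo < 0))
    stop("negative count in count matrix")
  if (any(cc$solo > cc$top) || any(cc$top > cc$total))
    stop("count matrix violates solo <= top <= total")
  for (i in seq_len(nrow(x$denominators))) {
    d <- x$denominators[i, ]
    sub <- cc[cc$query_chromosome == d$query_chromosome, ]
    if (sum(sub$top) != d$n_queries_with_hits)
      stop("top counts do not sum to query denominator for chromosome ",
           d$query_chromosome)
    if (sum(sub$solo) != d$n_solo_queries)
      stop("solo counts do not sum to solo denominator for chromosome ",
           d$query_chromosome)
    if (sum(sub$total) > 3L * d$n_queries_with_hits)
      stop("total counts exceed 3x query denominator for chromosome ",
           d$query_chromosome)
  }
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(unique(x$counts$query_chromosome)),
      "query chromosome(s),", length(unique(x$counts$subject_chromosome)),
      "subject chromosome(s)\n")
  print(x$denominators, row.names = FALSE)
  invisible(x)
}

# Extract one column (top/total/solo) for one query chromosome as a named
# vector over subject chromosomes.
cm_column <- function(x, query_chromosome, column = c("top", "total", "solo")) {
  column <- match.arg(column)
  sub <- x$counts[x$counts$query_chromosome == query_chromosome, ]
  if (!nrow(sub))
    stop("query chromosome not in count matrix: ", query_chromosome)
  stats::setNames(sub[[column]], sub$subject_chromosome)
}

#' Write a count matrix in the wide report layout
#'
#' Rows are subject chromosomes; for each query chromosome there is a
#' triple of columns `top:<q>`, `total:<q>`, `solo:<q>`. Denominators are
#' recoverable as the column sums of the top and solo columns.
#'
#' @param x a `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  qs <- unique(x$counts$query_chromosome)
  subj <- sort(unique(x$counts$subject_chromosome))
  wide <- data.frame(subject_chromosome = subj, check.names = FALSE)
  for (q in qs) {
    for (col in c("top", "total", "solo")) {
      v <- cm_column(x, q, col)
      wide[[paste0(col, ":", q)]] <- as.integer(v[subj]) |>
        (\(z) ifelse(is.na(z), 0L, z))()
    }
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from the wide report layout
#'
#' Inverse of [write_count_matrix]. Denominators are reconstructed from
#' the column sums (every query with hits contributes exactly one "top"
#' count, every solo query exactly one "solo" count).
#'
#' @param path file path.
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path) {
  wide <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                            colClasses = "character")
  if (names(wide)[1] != "subject_chromosome")
    stop("count matrix file must start with a subject_chromosome column")
  trip <- names(wide)[-1]
  parts <- strsplit(trip, ":", fixed = TRUE)
  qs <- unique(vapply(parts, `[`, "", 2))
  counts <- do.call(rbind, lapply(qs, function(q) {
    data.frame(query_chromosome = q,
               subject_chromosome = wide$subject_chromosome,
               top = as.integer(wide[[paste0("top:", q)]]),
               total = as.integer(wide[[paste0("total:", q)]]),
               solo = as.integer(wide[[paste0("solo:", q)]]))
  }))
  counts <- counts[counts$total > 0 | counts$top > 0 | counts$solo > 0, ]
  counts <- counts[order(counts$query_chromosome, counts$subject_chromosome), ]
  rownames(counts) <- NULL
  denom <- data.frame(
    query_chromosome = qs,
    n_queries_with_hits = vapply(qs, function(q)
      sum(counts$top[counts$query_chromosome == q]), 0L),
    n_solo_queries = vapply(qs, function(q)
      sum(counts$solo[counts$query_chromosome == q]), 0L)
  )
  rownames(denom) <- NULL
  new_count_matrix(counts, denom)
}

#' Tabulate closest within-genome paralogs by chromosome
#'
#' For each gene of a region, finds its best significant non-self hit
#' within the same genome (same ranking rules as [summarize_query]) and
#' attributes the gene to the chromosome of that closest paralog. Genes of
#' the region with no significant non-self hit are counted as having no
#' detected paralog.
#'
#' @param hits within-genome hit table (`query_gene`, `subject_gene`,
#'   `bit_score`, `e_value`).
#' @param locations [gene_locations] for the genome.
#' @param region a chromosome id (genes are taken from `locations`) or a
#'   character vector of gene ids.
#' @param significance_threshold e-value cutoff (default `1e-5`).
#' @return list: `counts` (named integer vector, chromosome of closest
#'   paralog -> number of genes), `n_with_paralog`, `n_no_paralog`.
#' @export
closest_paralog_counts <- function(hits, locations, region,
                                   significance_threshold = 1e-5) {
  if (length(region) == 1L && region %in% locations$chromosome) {
    region_genes <- locations$gene_id[locations$chromosome == region]
  } else {
    region_genes <- region
    bad <- setdiff(region_genes, locations$gene_id)
    if (length(bad))
      stop("region genes not locatable: ", paste(bad, collapse = ", "))
  }
  smap <- stats::setNames(locations$chromosome, locations$gene_id)
  keep <- hits$query_gene %in% region_genes &
    hits$query_gene != hits$subject_gene &
    hits$e_value <= significance_threshold
  df <- hits[keep, , drop = FALSE]
  bad <- setdiff(unique(df$subject_gene), names(smap))
  if (length(bad))
    stop("subject genes not locatable: ", paste(bad, collapse = ", "))
  best <- lapply(split(df, df$query_gene), function(d) {
    rank_subjects(d)[1, "subject_gene"]
  })
  chroms <- unname(smap[unlist(best)])
  counts <- table(chroms)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n_with_paralog = length(best),
       n_no_paralog = length(region_genes) - length(best))
}
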