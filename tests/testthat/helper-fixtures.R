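# Shared fixture builders; everything is generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_hit <- function(query_gene, subject_gene, bit_score, e_value = 1e-30,
                     query_protein = paste0(query_gene, ".p1"),
                     subject_protein = paste0(subject_gene, ".p1")) {
  data.frame(query_protein = query_protein,
             subject_protein = subject_protein,
             pident = 90, length = 100, mismatch = 5, gapopen = 1,
             qstart = 1, qend = 100, sstart = 1, send = 100,
             e_value = e_value, bit_score = bit_score,
             query_gene = query_gene, subject_gene = subject_gene)
}

make_hits <- function(...) do.call(rbind, list(...))

# n genes laid out on one chromosome, 1 kb apart
make_locations <- function(gene_ids, chromosome = "chr1",
                           strand = rep("+", length(gene_ids))) {
  n <- length(gene_ids)
  gene_locations(data.frame(gene_id = gene_ids, chromosome = chromosome,
                            start = (seq_len(n) - 1L) * 1000L + 1L,
                            end = (seq_len(n) - 1L) * 1000L + 500L,
                            strand = strand))
}

# random hit table: queries on chromosomes qA/qB, subjects spread over
# subject chromosomes, random scores; used for oracle-equivalence tests
random_hit_fixture <- function(n_queries = 20L, n_subjects = 12L,
                               n_subject_chroms = 4L, seed = 1L) {
  set.seed(seed)
  queries <- sprintf("q%02d", seq_len(n_queries))
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  qloc <- gene_locations(data.frame(
    gene_id = queries,
    chromosome = sample(c("qA", "qB"), n_queries, replace = TRUE),
    start = seq_len(n_queries) * 100L, end = seq_len(n_queries) * 100L + 50L,
    strand = "+"))
  sloc <- gene_locations(data.frame(
    gene_id = subjects,
    chromosome = sample(paste0("s", seq_len(n_subject_chroms)), n_subjects,
                        replace = TRUE),
    start = seq_len(n_subjects) * 100L, end = seq_len(n_subjects) * 100L + 50L,
    strand = sample(c("+", "-"), n_subjects, replace = TRUE)))
  rows <- lapply(queries, function(q) {
    k <- sample.int(6L, 1L)
    do.call(rbind, lapply(sample(subjects, k), function(s)
      make_hit(q, s, bit_score = round(stats::runif(1, 40, 120), 1),
               e_value = 10^-stats::runif(1, 3, 40))))
  })
  list(hits = do.call(rbind, rows), query_locations = qloc,
       subject_locations = sloc)
}

# Independent naive recount of the top/total/solo matrix, straight from
# the definitions; serves as the oracle for build_count_matrix.
naive_count_matrix <- function(hits, qloc, sloc, threshold = 1e-5) {
  qmap <- setNames(qloc$chromosome, qloc$gene_id)
  smap <- setNames(sloc$chromosome, sloc$gene_id)
  acc <- list()
  bump <- function(qc, sc, col) {
    key <- paste(qc, sc)
    if (is.null(acc[[key]]))
      acc[[key]] <<- list(qc = qc, sc = sc, top = 0L, total = 0L, solo = 0L)
    acc[[key]][[col]] <<- acc[[key]][[col]] + 1L
  }
  for (q in unique(hits$query_gene)) {
    h <- hits[hits$query_gene == q & hits$e_value <= threshold, ]
    if (!nrow(h)) next
    per_subject <- lapply(split(h, h$subject_gene), function(d)
      d[order(-d$bit_score, d$e_value)[1], ])
    tab <- do.call(rbind, per_subject)
    tab <- tab[order(-tab$bit_score, tab$e_value, tab$subject_gene), ]
    solo <- nrow(tab) == 1L
    kept <- head(tab, 3L)
    bump(qmap[q], smap[kept$subject_gene[1]], "top")
    for (sc in unique(smap[kept$subject_gene])) bump(qmap[q], sc, "total")
    if (solo) bump(qmap[q], smap[kept$subject_gene[1]], "solo")
  }
  df <- do.call(rbind, lapply(acc, function(x)
    data.frame(query_chromosome = unname(x$qc),
               subject_chromosome = unname(x$sc),
               top = x$top, total = x$total, solo = x$solo)))
  df <- df[order(df$query_chromosome, df$subject_chromosome), ]
  rownames(df) <- NULL
  df
}
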