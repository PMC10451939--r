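test_that("isoform hits collapse to one subject and mark the query solo", {
  hits <- make_hits(
    make_hit("q1", "G", 80, 1e-30, subject_protein = "G.p1"),
    make_hit("q1", "G", 75, 1e-28, subject_protein = "G.p2"))
  s <- summarize_query(hits)
  expect_equal(nrow(s$best_subjects), 1L)
  expect_equal(s$best_subjects$subject_gene, "G")
  expect_equal(s$best_subjects$bit_score, 80)
  expect_true(s$is_solo)
})

test_that("summaries truncate to three subjects but judge solo before truncation", {
  hits <- do.call(rbind, lapply(1:5, function(i)
    make_hit("q1", paste0("s", i), 95 - 5 * i)))
  s <- summarize_query(hits)
  expect_equal(s$best_subjects$subject_gene, c("s1", "s2", "s3"))
  expect_equal(s$n_distinct_subjects, 5L)
  expect_false(s$is_solo)
  # four weak distinct subjects: still not solo
  weak <- do.call(rbind, lapply(1:4, function(i)
    make_hit("q2", paste0("w", i), 50, 1e-6)))
  expect_false(summarize_query(weak)$is_solo)
})

test_that("score ties break by e-value then id, under any input order", {
  rows <- list(make_hit("q1", "sB", 80, 1e-20),
               make_hit("q1", "sA", 80, 1e-30),
               make_hit("q1", "sC", 80, 1e-30))
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1),
                c(1, 3, 2), c(3, 1, 2))
  for (p in perms) {
    s <- summarize_query(do.call(rbind, rows[p]))
    expect_equal(s$best_subjects$subject_gene, c("sA", "sC", "sB"))
  }
})

test_that("the significance threshold removes hits before ranking", {
  hits <- make_hits(make_hit("q1", "far", 90, e_value = 1e-3),
                    make_hit("q1", "near", 60, e_value = 1e-10))
  s <- summarize_query(hits, significance_threshold = 1e-5)
  expect_equal(s$best_subjects$subject_gene, "near")
  expect_true(s$is_solo)
  empty <- summarize_query(hits[hits$e_value < 1e-20, ])
  expect_equal(nrow(empty$best_subjects), 0L)
  expect_false(empty$is_solo)
})

test_that("count matrix attributes queries to chromosomes per definition", {
  qloc <- make_locations("q1", chromosome = "qc")
  sloc <- gene_locations(data.frame(
    gene_id = c("s1", "s2", "s3"), chromosome = c("10", "10", "4"),
    start = c(1L, 100L, 1L), end = c(50L, 150L, 50L), strand = "+"))
  hits <- make_hits(make_hit("q1", "s1", 90), make_hit("q1", "s2", 85),
                    make_hit("q1", "s3", 80))
  cm <- build_count_matrix(summarize_hits(hits), qloc, sloc)
  expect_equal(cm_col <- cm$counts[cm$counts$subject_chromosome == "10", ],
               data.frame(query_chromosome = "qc", subject_chromosome = "10",
                          top = 1, total = 1, solo = 0),
               ignore_attr = TRUE)
  expect_equal(cm$counts$total[cm$counts$subject_chromosome == "4"], 1)
  expect_equal(cm$counts$top[cm$counts$subject_chromosome == "4"], 0)

  solo_cm <- build_count_matrix(
    summarize_hits(make_hit("q1", "s3", 80)), qloc, sloc)
  row <- solo_cm$counts
  expect_equal(c(row$top, row$total, row$solo), c(1, 1, 1))
  expect_equal(row$subject_chromosome, "4")
})

test_that("unlocatable subject genes are reported by id", {
  qloc <- make_locations("q1")
  sloc <- make_locations("s1", chromosome = "sc")
  hits <- make_hits(make_hit("q1", "s1", 90), make_hit("q1", "ghost", 85))
  expect_error(build_count_matrix(summarize_hits(hits), qloc, sloc), "ghost")
})

test_that("count matrix equals a naive recount on random fixtures", {
  for (seed in 1:5) {
    fx <- random_hit_fixture(n_queries = 20L, seed = seed)
    cm <- build_count_matrix(summarize_hits(fx$hits),
                             fx$query_locations, fx$subject_locations)
    oracle <- naive_count_matrix(fx$hits, fx$query_locations,
                                 fx$subject_locations)
    got <- cm$counts
    got$top <- as.integer(got$top); got$total <- as.integer(got$total)
    got$solo <- as.integer(got$solo)
    expect_equal(got, oracle, ignore_attr = TRUE)
  }
})

test_that("count-matrix invariants hold across random simulations", {
  for (seed in 1:20) {
    h <- simulate_history(
      ancestral_genome(c(30, 30)),
      event_schedule(shared = list(ev_wgd(2L), ev_loss(0.8)),
                     lineage_a = list(ev_loss(0.9), ev_transposition(0.05)),
                     lineage_b = list(ev_wgd(2L), ev_loss(0.7)),
                     seed = seed))
    hits <- emit_hit_table(h, similarity_model(noise_sd = 5), seed + 100L)
    if (!nrow(hits)) next
    cm <- build_count_matrix(summarize_hits(hits), h$genome_a, h$genome_b)
    expect_no_error(validate_count_matrix(cm))
  }
})

test_that("noise-free top attribution recovers the ortholog chromosome", {
  h <- simulate_history(
    ancestral_genome(40),
    event_schedule(shared = list(ev_wgd(2L), ev_loss(0.7)),
                   lineage_b = list(ev_wgd(2L), ev_loss(0.7)), seed = 8L))
  hits <- emit_hit_table(h, similarity_model(noise_sd = 0), 1L)
  summaries <- summarize_hits(hits)
  smap <- setNames(h$genome_b$chromosome, h$genome_b$gene_id)
  truth <- h$truth[h$truth$relation == "ortholog", ]
  for (s in summaries) {
    ortho <- truth$gene_b[truth$gene_a == s$query_gene]
    if (!length(ortho)) next
    expect_true(unname(smap[s$best_subjects$subject_gene[1]]) %in%
                  unname(smap[ortho]))
  }
})

test_that("tightening the significance threshold only removes evidence", {
  # per-cell counts can shift between chromosomes when a query's best
  # subject is filtered away; what is monotone is the evidence itself:
  # the significant-hit set, the per-query distinct-subject counts and
  # the number of queries with hits all shrink or stay equal
  fx <- random_hit_fixture(n_queries = 25L, seed = 7L)
  thresholds <- 10^c(-3, -5, -10, -20)
  prev <- NULL
  for (th in thresholds) {
    summaries <- summarize_hits(fx$hits, significance_threshold = th)
    n_subjects <- vapply(summaries, `[[`, 0L, "n_distinct_subjects")
    n_with_hits <- sum(n_subjects > 0L)
    if (!is.null(prev)) {
      expect_lte(n_with_hits, prev$n_with_hits)
      expect_true(all(n_subjects[names(prev$n_subjects)] <=
                        prev$n_subjects))
    }
    prev <- list(n_with_hits = n_with_hits, n_subjects = n_subjects)
  }
})

test_that("closest-paralog tabulation matches its definition", {
  loc <- gene_locations(data.frame(
    gene_id = c("g1", "g2", "p1", "p2"),
    chromosome = c("22", "22", "8", "41"),
    start = c(1L, 100L, 1L, 1L), end = c(50L, 150L, 50L, 50L),
    strand = "+"))
  hits <- make_hits(
    make_hit("g1", "g1", 200),           # self hit only: no paralog
    make_hit("g2", "p1", 90), make_hit("g2", "p2", 80))
  res <- closest_paralog_counts(hits, loc, region = "22")
  expect_equal(res$counts, c("8" = 1L))
  expect_equal(res$n_with_paralog, 1L)
  expect_equal(res$n_no_paralog, 1L)
})

test_that("an engineered 31-gene region recovers the expected paralog split", {
  # 31 genes with detected paralogs: 11 closest on chrA, 5 on chrB, 15
  # elsewhere; 6 further region genes have no paralog at all
  region_genes <- sprintf("r%02d", 1:37)
  targets <- c(rep("chrA", 11), rep("chrB", 5), rep("chrC", 15))
  subj <- sprintf("t%02d", seq_along(targets))
  loc <- gene_locations(data.frame(
    gene_id = c(region_genes, subj),
    chromosome = c(rep("22", 37), targets),
    start = c(seq_len(37) * 10L, seq_along(subj) * 10L),
    end = c(seq_len(37) * 10L + 5L, seq_along(subj) * 10L + 5L),
    strand = "+"))
  hits <- do.call(rbind, lapply(seq_along(targets), function(i)
    make_hit(region_genes[i], subj[i], 100)))
  res <- closest_paralog_counts(hits, loc, region = "22")
  expect_equal(res$counts[c("chrA", "chrB", "chrC")],
               c(chrA = 11L, chrB = 5L, chrC = 15L))
  expect_equal(res$n_with_paralog, 31L)
  expect_equal(res$n_no_paralog, 6L)
})
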