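test_that("neighborhood extraction truncates at chromosome ends", {
  loc <- make_locations(sprintf("g%d", 1:6))
  nb <- extract_neighborhood(loc, "g3", half_width = 5L)
  expect_equal(nb$flank$gene_id, sprintf("g%d", 1:6))
  expect_true(nb$truncated_left)
  expect_true(nb$truncated_right)

  lone <- make_locations("solo1", chromosome = "chrS")
  nb1 <- extract_neighborhood(lone, "solo1")
  expect_equal(nb1$flank$gene_id, "solo1")
  expect_error(extract_neighborhood(loc, "nope"), "unknown anchor")
})

test_that("neighborhood windows equal a naive rank-window oracle", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:30)
  loc <- make_locations(genes, strand = sample(c("+", "-"), 30, TRUE))
  for (anchor in sample(genes, 8)) {
    nb <- extract_neighborhood(loc, anchor, half_width = 5L)
    r <- loc$rank[loc$gene_id == anchor]
    naive <- loc$gene_id[loc$rank >= r - 5 & loc$rank <= r + 5]
    expect_equal(nb$flank$gene_id, naive[order(loc$rank[match(naive, loc$gene_id)])])
  }
})

test_that("mapping marks genes without significant hits as no hit", {
  qloc <- make_locations(c("q1", "q2", "q3"))
  sloc <- make_locations(c("s1", "s2"), chromosome = "hs4",
                         strand = c("+", "-"))
  hits <- make_hits(make_hit("q1", "s1", 90),
                    make_hit("q3", "s2", 70, e_value = 1e-2))
  nb <- extract_neighborhood(qloc, "q2")
  m <- map_neighborhood(nb, hits, sloc)
  expect_equal(m$status, c("hit", "no hit", "no hit"))
  expect_equal(m$subject_chromosome[1], "hs4")
  expect_equal(m$orientation[1], "same")
})

test_that("on a clean WGD simulation the mapping recovers truth orthologs", {
  h <- simulate_history(
    ancestral_genome(11),
    event_schedule(shared = list(ev_wgd(2L)),
                   lineage_b = list(ev_loss(0.99)), seed = 13L))
  hits <- emit_hit_table(h, similarity_model(noise_sd = 0), 1L)
  anchor <- h$genome_a$gene_id[6]
  nb <- extract_neighborhood(h$genome_a, anchor, genome = "A")
  m <- map_neighborhood(nb, hits, h$genome_b)
  truth <- h$truth[h$truth$relation == "ortholog", ]
  for (i in which(m$status == "hit")) {
    expected <- truth$gene_b[truth$gene_a == m$gene_id[i]]
    expect_true(m$subject_gene[i] %in% expected)
  }
})

test_that("congruence is perfect for identical and for reversed orderings", {
  qloc1 <- make_locations(sprintf("a%d", 1:7), chromosome = "c1")
  qloc2 <- make_locations(sprintf("b%d", 1:7), chromosome = "c2")
  sloc <- make_locations(sprintf("s%d", 1:7), chromosome = "hs")
  hits1 <- do.call(rbind, lapply(1:7, function(i)
    make_hit(paste0("a", i), paste0("s", i), 90)))
  hits2 <- do.call(rbind, lapply(1:7, function(i)
    make_hit(paste0("b", i), paste0("s", i), 90)))
  n1 <- extract_neighborhood(qloc1, "a4")
  n2 <- extract_neighborhood(qloc2, "b4")
  m1 <- map_neighborhood(n1, hits1, sloc)
  m2 <- map_neighborhood(n2, hits2, sloc)
  sc <- congruence_scores(m1, m2)
  expect_equal(sc$shared, 7L)
  expect_equal(sc$order_score, 1)
  expect_equal(sc$orientation_score, 1)

  # reversed gene order in the second region: an inversion, still syntenic
  hits2r <- do.call(rbind, lapply(1:7, function(i)
    make_hit(paste0("b", i), paste0("s", 8 - i), 90)))
  m2r <- map_neighborhood(n2, hits2r, sloc)
  expect_equal(congruence_scores(m1, m2r)$order_score, 1)

  # symmetry
  swapped <- congruence_scores(m2, m1)
  expect_equal(swapped$order_score, sc$order_score)
  expect_equal(swapped$shared, sc$shared)
})

test_that("order scores match a brute-force Kendall computation", {
  qloc1 <- make_locations(sprintf("a%d", 1:6), chromosome = "c1")
  qloc2 <- make_locations(sprintf("b%d", 1:6), chromosome = "c2")
  sloc <- make_locations(sprintf("s%d", 1:6), chromosome = "hs")
  m1 <- map_neighborhood(
    extract_neighborhood(qloc1, "a3"),
    do.call(rbind, lapply(1:6, function(i)
      make_hit(paste0("a", i), paste0("s", i), 90))), sloc)
  kendall_abs <- function(x, y) {
    con <- 0; dis <- 0
    for (i in 1:(length(x) - 1)) for (j in (i + 1):length(x)) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) con <- con + 1 else if (s < 0) dis <- dis + 1
    }
    abs((con - dis) / choose(length(x), 2))
  }
  set.seed(9)
  for (rep in 1:25) {
    perm <- sample(6)
    m2 <- map_neighborhood(
      extract_neighborhood(qloc2, "b3"),
      do.call(rbind, lapply(1:6, function(i)
        make_hit(paste0("b", i), paste0("s", perm[i]), 90))), sloc)
    sc <- congruence_scores(m1, m2)
    expect_equal(sc$order_score, kendall_abs(1:6, order(perm)),
                 tolerance = 1e-12)
  }
})

test_that("too few shared families leaves the order score undefined", {
  qloc <- make_locations(c("a1", "a2"), chromosome = "c1")
  sloc <- make_locations(c("s1", "s2"), chromosome = "hs")
  m1 <- map_neighborhood(extract_neighborhood(qloc, "a1"),
                         make_hit("a1", "s1", 90), sloc)
  m2 <- map_neighborhood(extract_neighborhood(qloc, "a2"),
                         make_hit("a2", "s1", 90), sloc)
  sc <- congruence_scores(m1, m2)
  expect_equal(sc$shared, 1L)
  expect_true(is.na(sc$order_score))
})

test_that("a fully conserved seven-gene block is reported at length seven", {
  # lamprey-like neighborhood carries the full GRID-CCSER-MMRN-SNC-GLUD-
  # SHLD-GPRIN run; the two human-like neighborhoods carry partial runs
  block7 <- c("GRID", "CCSER", "MMRN", "SNC", "GLUD", "SHLD", "GPRIN")
  fams <- list(
    lamprey_chr8 = block7,
    human_snca = c("GRID", "CCSER", "MMRN", "SNC", NA, "X1"),
    human_sncg = c("X2", NA, "SNC", "GLUD", "SHLD")
  )
  blocks <- find_conserved_blocks(fams, min_members = 1L, min_length = 2L)
  lengths7 <- Filter(function(b) b$length == 7L, blocks)
  expect_equal(length(lengths7), 1L)
  expect_equal(lengths7[[1]]$families, block7)
  expect_true("lamprey_chr8" %in% lengths7[[1]]$members)
  # the partial runs are sub-blocks shared with the human neighborhoods
  sub <- Filter(function(b) "human_snca" %in% b$members, blocks)
  expect_true(any(vapply(sub, function(b)
    identical(b$families, c("GRID", "CCSER", "MMRN", "SNC")), TRUE)))
})

test_that("neighborhoods sharing no family yield no blocks", {
  fams <- list(n1 = c("A", "B", "C"), n2 = c("D", "E", "F"))
  expect_equal(find_conserved_blocks(fams, min_members = 2L), list())
})

test_that("reversed occurrences and gap budgets are honored", {
  fams <- list(n1 = c("A", "B", "C"),
               n2 = c("C", "B", "A"),                 # reversed: counts
               n3 = c("A", NA, NA, "B", "C"),          # 2 gaps: within budget
               n4 = c("A", NA, NA, NA, "B", "C"))      # 3 gaps: over budget
  blocks <- find_conserved_blocks(fams, min_members = 2L, min_length = 3L,
                                  gap_budget = 2L)
  abc <- Filter(function(b) identical(sort(b$families), c("A", "B", "C")),
                blocks)
  expect_equal(length(abc), 1L)
  expect_setequal(abc[[1]]$members, c("n1", "n2", "n3"))
  # an intervening gene from another family breaks the run
  fams2 <- list(n1 = c("A", "B", "C"), n2 = c("A", "Z", "B", "C"))
  blocks2 <- find_conserved_blocks(fams2, min_members = 2L, min_length = 3L)
  expect_false(any(vapply(blocks2, function(b)
    identical(b$families, c("A", "B", "C")) && "n2" %in% b$members, TRUE)))
})

test_that("reported blocks equal exhaustive enumeration on small instances", {
  # independent oracle: enumerate every contiguous family window of every
  # neighborhood, test membership by regular-expression matching over an
  # encoded gene string, then apply the same maximality rule
  oracle_blocks <- function(fams, min_members, min_length, gap_budget) {
    occurs <- function(labels, block) {
      s <- paste(ifelse(is.na(labels), ".", labels), collapse = "")
      hit <- function(b) grepl(
        paste(b, collapse = sprintf("\\.{0,%d}", gap_budget)), s)
      hit(block) || hit(rev(block))
    }
    cands <- list()
    for (labels in fams) {
      idx <- which(!is.na(labels)); f <- labels[idx]; gaps <- diff(idx) - 1
      for (i in seq_along(f)) for (j in seq_along(f)) {
        if (j < i || j - i + 1 < min_length) next
        if (j > i && any(gaps[i:(j - 1)] > gap_budget)) next
        b <- f[i:j]
        if (anyDuplicated(b)) next
        cands[[paste(c(min(paste(b, collapse = ""),
                          paste(rev(b), collapse = ""))), collapse = "")]] <- b
      }
    }
    out <- list()
    for (b in cands) {
      mem <- names(fams)[vapply(fams, occurs, TRUE, block = b)]
      if (length(mem) >= min_members)
        out[[length(out) + 1]] <- list(families = b, length = length(b),
                                       members = mem)
    }
    out
  }
  set.seed(21)
  alphabet <- LETTERS[1:5]
  for (rep in 1:15) {
    fams <- lapply(1:3, function(i) {
      n <- sample(4:8, 1)
      v <- rep(NA_character_, n)
      k <- sample(2:min(5L, n), 1)
      v[sample(n, k)] <- sample(alphabet, k)
      v
    })
    names(fams) <- paste0("n", 1:3)
    got <- find_conserved_blocks(fams, min_members = 2L, min_length = 2L,
                                 gap_budget = 1L)
    exp <- oracle_blocks(fams, 2L, 2L, 1L)
    key <- function(b) paste(min(paste(b$families, collapse = "|"),
                                 paste(rev(b$families), collapse = "|")),
                             paste(sort(b$members), collapse = ","))
    got_keys <- vapply(got, key, "")
    exp_keys <- vapply(exp, key, "")
    # every reported block must be present in the oracle's candidate set
    expect_true(all(got_keys %in% exp_keys))
    # every maximal oracle block must be reported
    exp_max <- Filter(function(b) {
      !any(vapply(exp, function(B)
        B$length > b$length && all(b$members %in% B$members) &&
          grepl(paste(b$families, collapse = " "),
                paste(c(B$families, "#", rev(B$families)), collapse = " "),
                fixed = TRUE), TRUE))
    }, exp)
    expect_true(all(vapply(exp_max, key, "") %in% got_keys))
  }
})

test_that("no reported block is a sub-block of another over the same members", {
  set.seed(33)
  for (rep in 1:10) {
    fams <- lapply(1:3, function(i) sample(c(LETTERS[1:6], NA, NA), 8))
    names(fams) <- paste0("n", 1:3)
    blocks <- find_conserved_blocks(fams, min_members = 2L, min_length = 2L)
    for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
      if (i == j) next
      bi <- blocks[[i]]; bj <- blocks[[j]]
      if (bi$length >= bj$length) next
      if (!all(bi$members %in% bj$members)) next
      fwd <- paste(bj$families, collapse = " ")
      rev_ <- paste(rev(bj$families), collapse = " ")
      needle <- paste(bi$families, collapse = " ")
      expect_false(grepl(needle, fwd, fixed = TRUE) ||
                     grepl(needle, rev_, fixed = TRUE))
    }
  }
})
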