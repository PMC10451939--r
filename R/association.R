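# Chromosome-association testing: pool count-matrix columns into
# WGD-derived chromosome groups, test 2x2 contingency tables with the
# Pearson chi-square (df = 1, no continuity correction), and compute the
# derived group fractions and ohnolog-pair tallies.

#' Define WGD-derived subject-chromosome groups
#'
#' The defaults encode the human chromosome groups descending from the two
#' post-WGD1 copies of the proto-vertebrate chromosome carrying the
#' synuclein region: chromosomes 4 and 5 on one side, 2, 8 and 10 on the
#' other.
#'
#' @param group_a,group_b disjoint, non-empty character vectors of subject
#'   chromosome ids.
#' @param ancestral_label free-text label for the ancestral chromosome.
#' @return list of class `chromosome_groups`.
#' @export
chromosome_groups <- function(group_a = c("4", "5"),
                              group_b = c("2", "8", "10"),
                              ancestral_label = "CLGQ/Pvc8") {
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b))
    stop("both chromosome groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("chromosome groups must be disjoint")
  structure(list(group_a = group_a, group_b = group_b,
                 ancestral_label = ancestral_label),
            class = "chromosome_groups")
}

#' Pool count-matrix columns into a 2x2 contingency table
#'
#' Rows are the two chromosome groups, columns the two query chromosomes;
#' each cell sums the chosen count column over the group's subject
#' chromosomes. Subject chromosomes outside both groups are ignored.
#'
#' @param matrix a `count_matrix`.
#' @param query_chromosomes character vector of length 2.
#' @param groups a [chromosome_groups] object.
#' @param column `"top"`, `"total"` or `"solo"`.
#' @return 2x2 integer matrix of class `contingency_2x2`, with an
#'   `untestable` attribute set when the grand total is zero.
#' @export
pool_counts <- function(matrix, query_chromosomes,
                        groups = chromosome_groups(),
                        column = c("top", "total", "solo")) {
  column <- match.arg(column)
  if (length(query_chromosomes) != 2L)
    stop("exactly two query chromosomes required")
  cell <- function(q, grp) {
    v <- cm_column(matrix, q, column)
    sum(v[names(v) %in% grp])
  }
  tab <- rbind(
    c(cell(query_chromosomes[1], groups$group_a),
      cell(query_chromosomes[2], groups$group_a)),
    c(cell(query_chromosomes[1], groups$group_b),
      cell(query_chromosomes[2], groups$group_b))
  )
  dimnames(tab) <- list(
    group = c(paste(groups$group_a, collapse = "+"),
              paste(groups$group_b, collapse = "+")),
    query = query_chromosomes
  )
  structure(tab, class = c("contingency_2x2", class(tab)),
            untestable = sum(tab) == 0)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Computes the closed-form Pearson statistic
#' \deqn{X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' with one degree of freedom and no continuity correction, and the
#' upper-tail p-value from the chi-square distribution.
#'
#' @param table 2x2 numeric matrix (e.g. from [pool_counts]).
#' @return list of class `chi_square_result`: `statistic`, `df` (always
#'   1), `p_value`, and the input `table`.
#' @export
pearson_chi_square <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0)) stop("negative cell count")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero marginal")
  storage.mode(table) <- "double"   # avoid integer overflow in products
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 table = table),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.2f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Monte-Carlo conditional permutation p-value for a 2x2 table
#'
#' Draws tables from the null distribution conditional on both margins
#' (all tables with the observed margins, hypergeometric weights) and
#' reports the fraction with a Pearson statistic at least as large as the
#' observed one (`p_value`), together with the mid-p variant (`mid_p`,
#' counting half the probability of ties). The conditional null is
#' discrete; the mid-p is the standard comparator when checking a
#' discrete test against the continuous asymptotic chi-square reference,
#' and agreement is only expected for tables with all expected cells in
#' the asymptotic regime.
#'
#' @param table 2x2 numeric matrix.
#' @param n_draws number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @return list: `p_value`, `mid_p`, `std_error` (of `p_value`),
#'   `mid_p_std_error`, `n_draws`.
#' @export
permutation_chi_square_p <- function(table, n_draws = 1e5, seed = 1L) {
  obs <- pearson_chi_square(table)$statistic
  stat_of <- function(m) {
    n <- sum(m)
    n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m), colSums(m))
  }
  draws <- with_seed(seed,
                     stats::r2dtable(n_draws, rowSums(table), colSums(table)))
  stats_null <- vapply(draws, stat_of, 0)
  tie <- abs(stats_null - obs) <= 1e-9
  p <- mean(stats_null >= obs - 1e-9)
  mid <- mean(stats_null > obs + 1e-9) + 0.5 * mean(tie)
  list(p_value = p, std_error = sqrt(p * (1 - p) / n_draws),
       mid_p = mid, mid_p_std_error = sqrt(mid * (1 - mid) / n_draws),
       n_draws = n_draws)
}

#' Fraction of a query chromosome's counts on a chromosome set
#'
#' The percentage of the chosen column's counts (over all subject
#' chromosomes) that fall on the named subject chromosomes — e.g. the
#' share of a query chromosome's best hits landing on the WGD-related
#' human chromosomes.
#'
#' @param matrix a `count_matrix`.
#' @param query_chromosome query chromosome id.
#' @param chromosomes character vector of subject chromosome ids.
#' @param column `"top"`, `"total"` or `"solo"`.
#' @return percentage in `[0, 100]` (unrounded; reports print it at 1
#'   decimal place and nearest integer).
#' @export
fraction_on_group <- function(matrix, query_chromosome, chromosomes,
                              column = c("top", "total", "solo")) {
  column <- match.arg(column)
  v <- cm_column(matrix, query_chromosome, column)
  denom <- sum(v)
  if (denom == 0) stop("zero denominator for query chromosome ",
                       query_chromosome)
  100 * sum(v[names(v) %in% chromosomes]) / denom
}

#' Count of a query chromosome's genes attributed to a chromosome set
#'
#' The numerator of [fraction_on_group] as an integer count: the number of
#' query genes whose chosen-column attribution falls on the named subject
#' chromosomes.
#'
#' @inheritParams fraction_on_group
#' @return integer count.
#' @export
count_group_sum <- function(matrix, query_chromosome, chromosomes,
                            column = c("top", "total", "solo")) {
  column <- match.arg(column)
  v <- cm_column(matrix, query_chromosome, column)
  as.integer(sum(v[names(v) %in% chromosomes]))
}

#' Count ohnolog pairs per unordered chromosome pair
#'
#' Each ohnolog pair whose two members are both locatable increments
#' exactly one unordered chromosome-pair bucket (same-chromosome buckets
#' included); pairs with an unlocatable member are tallied separately.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (see
#'   [read_ohnolog_pairs]).
#' @param locations [gene_locations] table.
#' @return data.frame `chrom_a`, `chrom_b` (`chrom_a <= chrom_b`),
#'   `n_pairs`, sorted by decreasing count; attribute `n_unplaced` gives
#'   the number of pairs with an unlocatable member.
#' @export
count_ohnolog_pairs <- function(pairs, locations) {
  cmap <- stats::setNames(locations$chromosome, locations$gene_id)
  ca <- unname(cmap[pairs$gene_a])
  cb <- unname(cmap[pairs$gene_b])
  placed <- !is.na(ca) & !is.na(cb)
  lo <- pmin(ca[placed], cb[placed])
  hi <- pmax(ca[placed], cb[placed])
  if (!length(lo)) {
    out <- data.frame(chrom_a = character(0), chrom_b = character(0),
                      n_pairs = integer(0))
  } else {
    tab <- table(paste(lo, hi, sep = "\r"))
    keys <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(chrom_a = vapply(keys, `[`, "", 1),
                      chrom_b = vapply(keys, `[`, "", 2),
                      n_pairs = as.integer(tab))
    out <- out[order(-out$n_pairs, out$chrom_a, out$chrom_b), ]
    rownames(out) <- NULL
  }
  attr(out, "n_unplaced") <- sum(!placed)
  out
}
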