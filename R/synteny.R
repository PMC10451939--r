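# Anchor-centered local synteny: extract the genes flanking an anchor,
# map each to its best cross-genome subject, score order/orientation
# congruence between neighborhoods, and detect maximal conserved blocks
# shared across neighborhoods.

#' Extract the neighborhood around an anchor gene
#'
#' Returns up to `half_width` genes on each side of the anchor, in rank
#' order along the chromosome; fewer are returned (and flagged) near
#' chromosome ends.
#'
#' @param locations a [gene_locations] table.
#' @param anchor anchor gene id.
#' @param half_width genes per side (default 5, i.e. an 11-gene window).
#' @param genome free-text genome label carried through to reports.
#' @return list of class `neighborhood`: `anchor`, `genome`, `flank`
#'   (ordered [gene_locations] rows including the anchor),
#'   `truncated_left`, `truncated_right`.
#' @export
extract_neighborhood <- function(locations, anchor, half_width = 5L,
                                 genome = "") {
  i <- match(anchor, locations$gene_id)
  if (is.na(i)) stop("unknown anchor gene: ", anchor)
  chrom <- locations$chromosome[i]
  r <- locations$rank[i]
  on_chrom <- locations[locations$chromosome == chrom, , drop = FALSE]
  keep <- on_chrom$rank >= r - half_width & on_chrom$rank <= r + half_width
  flank <- on_chrom[keep, , drop = FALSE]
  flank <- flank[order(flank$rank), , drop = FALSE]
  rownames(flank) <- NULL
  structure(list(anchor = anchor, genome = genome, flank = flank,
                 truncated_left = r - half_width < min(on_chrom$rank),
                 truncated_right = r + half_width > max(on_chrom$rank)),
            class = "neighborhood")
}

#' Map a neighborhood's genes to their best cross-genome subjects
#'
#' Each flank gene is assigned the rank-1 subject of its significant hits
#' under the same ranking rules as [summarize_query]; genes without a
#' significant hit are marked `"no hit"` and excluded from congruence
#' denominators. Relative orientation records whether query and subject
#' strands agree.
#'
#' @param nbhd a [extract_neighborhood] result.
#' @param hits cross-genome hit table covering the query genome.
#' @param subject_locations [gene_locations] for the subject genome.
#' @param significance_threshold e-value cutoff (default `1e-5`).
#' @return data.frame of class `neighborhood_mapping`: one row per flank
#'   gene with `gene_id`, `query_strand`, `status` (`"hit"`/`"no hit"`),
#'   `subject_gene`, `subject_chromosome`, `orientation`
#'   (`"same"`/`"opposite"`); anchor and genome kept as attributes.
#' @export
map_neighborhood <- function(nbhd, hits, subject_locations,
                             significance_threshold = 1e-5) {
  stopifnot(inherits(nbhd, "neighborhood"))
  smap <- stats::setNames(subject_locations$chromosome,
                          subject_locations$gene_id)
  sstrand <- stats::setNames(subject_locations$strand,
                             subject_locations$gene_id)
  rows <- lapply(seq_len(nrow(nbhd$flank)), function(i) {
    g <- nbhd$flank$gene_id[i]
    qs <- nbhd$flank$strand[i]
    h <- hits[hits$query_gene == g &
                hits$e_value <= significance_threshold, , drop = FALSE]
    if (!nrow(h))
      return(data.frame(gene_id = g, query_strand = qs, status = "no hit",
                        subject_gene = NA_character_,
                        subject_chromosome = NA_character_,
                        orientation = NA_character_))
    best <- rank_subjects(collapse_subjects(
      h[, c("subject_gene", "bit_score", "e_value")]))[1, ]
    sg <- best$subject_gene
    if (!sg %in% names(smap))
      stop("subject gene not locatable: ", sg)
    data.frame(gene_id = g, query_strand = qs, status = "hit",
               subject_gene = sg,
               subject_chromosome = unname(smap[sg]),
               orientation = if (qs == unname(sstrand[sg])) "same"
                             else "opposite")
  })
  out <- do.call(rbind, rows)
  attr(out, "anchor") <- nbhd$anchor
  attr(out, "genome") <- nbhd$genome
  class(out) <- c("neighborhood_mapping", "data.frame")
  out
}

#' Assign homology-family labels across neighborhoods
#'
#' A family is a connected component of best-hit links restricted to the
#' compared neighborhoods: flank genes (from any neighborhood) sharing a
#' best subject gene — or linked through a chain of shared subjects —
#' receive the same family label, named after the lexicographically
#' smallest subject gene of the component. Genes with no hit get `NA`.
#'
#' @param mappings list of [map_neighborhood] results.
#' @return list of character vectors, one per mapping, aligned with its
#'   rows.
#' @export
assign_families <- function(mappings) {
  subjects <- unique(unlist(lapply(mappings, function(m)
    m$subject_gene[m$status == "hit"])))
  if (!length(subjects))
    return(lapply(mappings, function(m) rep(NA_character_, nrow(m))))
  # union-find over subject genes; here each flank gene links to exactly
  # one subject, so components are just subjects shared across genes --
  # but keep the general structure so multi-link extensions stay correct
  parent <- stats::setNames(seq_along(subjects), subjects)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  roots <- vapply(seq_along(subjects), find, 0L)
  label <- stats::setNames(subjects[roots], subjects)
  lapply(mappings, function(m)
    ifelse(m$status == "hit", unname(label[m$subject_gene]),
           NA_character_))
}

#' Order and orientation congruence of two neighborhood mappings
#'
#' Shared families are the subject genes hit by both neighborhoods. The
#' order score is the absolute normalized Kendall rank correlation
#' between the two orderings of shared families (1 for identical or
#' exactly reversed order — an inversion preserves synteny); the
#' orientation score is the fraction of shared families whose relative
#' orientation (query vs subject strand) agrees between the two
#' neighborhoods.
#'
#' @param m1,m2 [map_neighborhood] results referencing a common subject
#'   genome.
#' @return list: `shared` (family count), `order_score` (in `[0, 1]`,
#'   `NA` when fewer than 2 shared families), `orientation_score`.
#' @export
congruence_scores <- function(m1, m2) {
  fam <- assign_families(list(m1, m2))
  f1 <- fam[[1]]; f2 <- fam[[2]]
  # first occurrence of each family along each neighborhood
  pos1 <- tapply(seq_along(f1)[!is.na(f1)], f1[!is.na(f1)], min)
  pos2 <- tapply(seq_along(f2)[!is.na(f2)], f2[!is.na(f2)], min)
  shared <- intersect(names(pos1), names(pos2))
  n <- length(shared)
  if (n < 2L) {
    order_score <- NA_real_
  } else {
    tau <- stats::cor(rank(pos1[shared]), rank(pos2[shared]),
                      method = "kendall")
    order_score <- abs(tau)
  }
  o1 <- m1$orientation[vapply(shared, function(s) which(f1 == s)[1], 0L)]
  o2 <- m2$orientation[vapply(shared, function(s) which(f2 == s)[1], 0L)]
  orientation_score <- if (n) mean(o1 == o2) else NA_real_
  list(shared = n, order_score = order_score,
       orientation_score = orientation_score)
}

# Does `block` (vector of family labels) occur in the labeled gene
# sequence `labels` in the given direction? Consecutive block members may
# be separated by at most `gap_budget` unlabeled (NA) genes; any
# intervening gene carrying a family label breaks the run.
block_occurs_directed <- function(labels, block, gap_budget) {
  starts <- which(!is.na(labels) & labels == block[1])
  for (s in starts) {
    pos <- s
    ok <- TRUE
    for (k in seq_along(block)[-1]) {
      j <- pos + 1L
      gaps <- 0L
      found <- FALSE
      while (j <= length(labels)) {
        if (is.na(labels[j])) {
          gaps <- gaps + 1L
          if (gaps > gap_budget) break
          j <- j + 1L
        } else if (labels[j] == block[k]) {
          found <- TRUE
          break
        } else break
      }
      if (!found) { ok <- FALSE; break }
      pos <- j
    }
    if (ok) return(TRUE)
  }
  FALSE
}

block_occurs <- function(labels, block, gap_budget) {
  block_occurs_directed(labels, block, gap_budget) ||
    block_occurs_directed(labels, rev(block), gap_budget)
}

#' Detect maximal conserved blocks across neighborhoods
#'
#' A block is an ordered run of homology families present — as an
#' order-preserving, gap-free-in-family-space subsequence, forward or
#' reversed — in at least `min_members` neighborhoods. Between
#' consecutive block families up to `gap_budget` unlabeled genes may
#' intervene in a neighborhood; a gene carrying a different family label
#' breaks the run. Reported blocks are maximal: no block is dropped-in
#' favor of an extension unless the extension retains every member.
#'
#' @param neighborhood_families named list of family-label vectors (one
#'   per neighborhood, genes in order, `NA` for unlabeled genes), e.g.
#'   from [assign_families].
#' @param min_members minimum member neighborhoods (default 2).
#' @param min_length minimum block length in families (default 2).
#' @param gap_budget allowed unlabeled genes between consecutive
#'   families per neighborhood (default 2).
#' @return list of blocks, each a list with `families` (ordered labels),
#'   `length` and `members` (neighborhood names); sorted by decreasing
#'   length.
#' @export
find_conserved_blocks <- function(neighborhood_families, min_members = 2L,
                                  min_length = 2L, gap_budget = 2L) {
  stopifnot(length(neighborhood_families) >= 1L)
  if (is.null(names(neighborhood_families)))
    names(neighborhood_families) <-
      paste0("nbhd", seq_along(neighborhood_families))

  # candidate blocks: every contiguous family-space window of every
  # neighborhood whose internal gaps respect the budget
  candidates <- list()
  for (labels in neighborhood_families) {
    idx <- which(!is.na(labels))
    if (length(idx) < min_length) next
    fams <- labels[idx]
    gaps <- diff(idx) - 1L
    for (i in seq_along(fams)) {
      for (j in i:length(fams)) {
        if (j - i + 1L < min_length) next
        if (j > i && any(gaps[i:(j - 1L)] > gap_budget)) break
        block <- fams[i:j]
        if (anyDuplicated(block)) next
        key <- canonical_block_key(block)
        if (is.null(candidates[[key]])) candidates[[key]] <- block
      }
    }
  }
  if (!length(candidates)) return(list())

  blocks <- lapply(candidates, function(block) {
    members <- names(neighborhood_families)[vapply(
      neighborhood_families, block_occurs, TRUE,
      block = block, gap_budget = gap_budget)]
    list(families = block, length = length(block), members = members)
  })
  blocks <- Filter(function(b) length(b$members) >= min_members, blocks)
  if (!length(blocks)) return(list())

  # maximality: drop a block contained (forward or reversed, contiguously
  # in family space) in a longer block whose member set covers it
  contained_in <- function(small, big) {
    k <- length(small$families)
    if (k >= length(big$families)) return(FALSE)
    seqs <- list(big$families, rev(big$families))
    for (s in seqs)
      for (off in 0:(length(s) - k))
        if (identical(s[(off + 1):(off + k)], small$families)) return(TRUE)
    FALSE
  }
  keep <- rep(TRUE, length(blocks))
  for (i in seq_along(blocks))
    for (j in seq_along(blocks))
      if (i != j && keep[j] && contained_in(blocks[[i]], blocks[[j]]) &&
          all(blocks[[i]]$members %in% blocks[[j]]$members))
        keep[i] <- FALSE
  blocks <- blocks[keep]
  blocks[order(-vapply(blocks, `[[`, 0L, "length"))]
}

canonical_block_key <- function(block) {
  fwd <- paste(block, collapse = "\r")
  rev_ <- paste(rev(block), collapse = "\r")
  min(fwd, rev_)
}
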