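# Ground-truthed simulator of genome evolution through whole-genome
# duplications, chromosome fusions, stochastic gene loss and
# transposition. Two lineages (A and B) descend from a common ancestor
# through a shared event list, split, and then evolve independently; the
# simulator records the full copy lineage of every extant gene so that
# ortholog/paralog truth labels and divergence depths are exact.

#' Construct an ancestral genome
#'
#' @param genes_per_chromosome integer vector; one entry per ancestral
#'   chromosome giving its gene count.
#' @param chromosome_ids optional chromosome names (default
#'   `"chr1"`, `"chr2"`, ...).
#' @return list of class `ancestral_genome`: `chromosomes` (ids), `genes`
#'   (named list, chromosome -> ordered gene ids), `strands` (named
#'   vector; orientations alternate along each chromosome).
#' @export
ancestral_genome <- function(genes_per_chromosome,
                             chromosome_ids = NULL) {
  genes_per_chromosome <- as.integer(genes_per_chromosome)
  if (!length(genes_per_chromosome) || any(genes_per_chromosome < 1L))
    stop("every ancestral chromosome must carry at least one gene")
  n_chrom <- length(genes_per_chromosome)
  chromosome_ids <- chromosome_ids %||% paste0("chr", seq_len(n_chrom))
  if (length(chromosome_ids) != n_chrom || anyDuplicated(chromosome_ids))
    stop("chromosome_ids must be unique, one per chromosome")
  genes <- lapply(seq_len(n_chrom), function(i)
    sprintf("%s_g%03d", chromosome_ids[i], seq_len(genes_per_chromosome[i])))
  names(genes) <- chromosome_ids
  strands <- stats::setNames(
    unlist(lapply(genes_per_chromosome,
                  function(n) rep_len(c("+", "-"), n)), use.names = FALSE),
    unlist(genes, use.names = FALSE))
  structure(list(chromosomes = chromosome_ids, genes = genes,
                 strands = strands),
            class = "ancestral_genome")
}

#' Genome-evolution events
#'
#' Constructors for the four event kinds of an [event_schedule]:
#' `ev_wgd(m)` duplicates every chromosome (and its gene order) `m` times
#' (`m = 3` models a hexaploidization); `ev_fusion(a, b)` concatenates the
#' gene orders of chromosomes `a` and `b` into one chromosome;
#' `ev_loss(retention)` removes each gene copy independently with
#' probability `1 - retention` (optionally overridden per chromosome);
#' `ev_transposition(q)` moves each gene with probability `q` to a
#' uniformly chosen position on a uniformly chosen chromosome, preserving
#' strand with probability 1/2.
#'
#' @param m integer ploidy multiplier, at least 2.
#' @param a,b chromosome ids as they exist when the event fires.
#' @param retention per-gene-copy retention probability in `[0, 1]`.
#' @param per_chromosome optional named vector of retention overrides
#'   keyed by chromosome id (models preferential retention).
#' @param q per-gene move probability in `[0, 1]`.
#' @return an event object for [event_schedule].
#' @name events
NULL

#' @rdname events
#' @export
ev_wgd <- function(m = 2L) {
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("WGD multiplier must be an integer >= 2")
  list(kind = "WGD", m = m)
}

#' @rdname events
#' @export
ev_fusion <- function(a, b) list(kind = "FUSION", a = as.character(a),
                                 b = as.character(b))

#' @rdname events
#' @export
ev_loss <- function(retention, per_chromosome = NULL) {
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]")
  if (!is.null(per_chromosome) &&
      (any(per_chromosome < 0) || any(per_chromosome > 1)))
    stop("per-chromosome retention must be in [0, 1]")
  list(kind = "LOSS_EPOCH", retention = retention,
       per_chromosome = per_chromosome)
}

#' @rdname events
#' @export
ev_transposition <- function(q) {
  if (q < 0 || q > 1) stop("move probability must be in [0, 1]")
  list(kind = "TRANSPOSITION_EPOCH", q = q)
}

#' Construct an event schedule
#'
#' @param shared ordered list of events applied before the lineage split.
#' @param lineage_a,lineage_b ordered event lists applied after the split
#'   in each lineage.
#' @param seed integer RNG seed; identical schedules with identical seeds
#'   give byte-identical histories.
#' @return list of class `event_schedule`.
#' @export
event_schedule <- function(shared = list(), lineage_a = list(),
                           lineage_b = list(), seed = 1L) {
  chk <- function(evs, where) {
    for (e in evs)
      if (!is.list(e) || !e$kind %in%
          c("WGD", "FUSION", "LOSS_EPOCH", "TRANSPOSITION_EPOCH"))
        stop("invalid event in ", where)
  }
  chk(shared, "shared"); chk(lineage_a, "lineage_a"); chk(lineage_b, "lineage_b")
  structure(list(shared = shared, lineage_a = lineage_a,
                 lineage_b = lineage_b, seed = as.integer(seed)),
            class = "event_schedule")
}

# Internal genome state: data.frame(gene_id, chromosome, strand,
# ancestral_gene, shared_path). Row order within a chromosome is gene
# order. shared_path holds the copy index chosen at each shared WGD.
init_state <- function(ancestral) {
  chrom <- rep(names(ancestral$genes), lengths(ancestral$genes))
  genes <- unlist(ancestral$genes, use.names = FALSE)
  data.frame(gene_id = genes, chromosome = chrom,
             strand = unname(ancestral$strands[genes]),
             ancestral_gene = genes, shared_path = "",
             stringsAsFactors = FALSE)
}

apply_wgd <- function(state, m, shared) {
  parts <- lapply(seq_len(m), function(k) {
    s <- state
    s$chromosome <- paste0(s$chromosome, ".", k)
    s$gene_id <- paste0(s$gene_id, ".", k)
    if (shared)
      s$shared_path <- ifelse(nzchar(s$shared_path),
                              paste0(s$shared_path, ".", k), as.character(k))
    s
  })
  do.call(rbind, parts)
}

apply_fusion <- function(state, a, b, epoch) {
  missing <- setdiff(c(a, b), unique(state$chromosome))
  if (length(missing))
    stop("fusion at epoch ", epoch, " names missing chromosome(s): ",
         paste(missing, collapse = ", "))
  new_id <- paste0(a, "+", b)
  ia <- which(state$chromosome == a)
  ib <- which(state$chromosome == b)
  rest <- setdiff(seq_len(nrow(state)), c(ia, ib))
  fused <- state[c(ia, ib), , drop = FALSE]
  fused$chromosome <- new_id
  rbind(state[rest, , drop = FALSE], fused)
}

apply_loss <- function(state, retention, per_chromosome, epoch) {
  r <- rep(retention, nrow(state))
  if (!is.null(per_chromosome)) {
    idx <- match(state$chromosome, names(per_chromosome))
    r[!is.na(idx)] <- per_chromosome[idx[!is.na(idx)]]
  }
  keep <- stats::runif(nrow(state)) < r
  out <- state[keep, , drop = FALSE]
  if (!nrow(out))
    stop("genome empty after loss epoch ", epoch)
  out
}

apply_transposition <- function(state, q) {
  move_ids <- state$gene_id[stats::runif(nrow(state)) < q]
  chroms <- unique(state$chromosome)
  for (id in move_ids) {
    i <- match(id, state$gene_id)
    dest <- sample(chroms, 1L)
    flip <- stats::runif(1) < 0.5
    row <- state[i, , drop = FALSE]
    if (flip) row$strand <- if (row$strand == "+") "-" else "+"
    state <- state[-i, , drop = FALSE]
    members <- which(state$chromosome == dest)
    pos <- sample.int(length(members) + 1L, 1L)
    if (length(members) == 0L || pos > length(members)) {
      insert_after <- if (length(members)) members[length(members)] else nrow(state)
    } else {
      insert_after <- if (pos == 1L) members[1L] - 1L else members[pos - 1L]
    }
    top <- if (insert_after >= 1L) state[seq_len(insert_after), , drop = FALSE]
           else state[0, , drop = FALSE]
    bottom <- if (insert_after < nrow(state))
      state[(insert_after + 1L):nrow(state), , drop = FALSE]
      else state[0, , drop = FALSE]
    row$chromosome <- dest
    state <- rbind(top, row, bottom)
  }
  state
}

run_events <- function(state, events, shared, epoch0, lineage, log_env) {
  epoch <- epoch0
  for (e in events) {
    epoch <- epoch + 1L
    n_before <- nrow(state)
    state <- switch(e$kind,
      WGD = apply_wgd(state, e$m, shared),
      FUSION = apply_fusion(state, e$a, e$b, epoch),
      LOSS_EPOCH = apply_loss(state, e$retention, e$per_chromosome, epoch),
      TRANSPOSITION_EPOCH = apply_transposition(state, e$q)
    )
    log_env$log[[length(log_env$log) + 1L]] <-
      data.frame(lineage = lineage, epoch = epoch, kind = e$kind,
                 n_before = n_before, n_after = nrow(state))
  }
  list(state = state, epoch = epoch)
}

state_to_locations <- function(state, gene_length = 500L, spacing = 1000L) {
  parts <- split(seq_len(nrow(state)), state$chromosome)
  rows <- lapply(parts, function(idx) {
    n <- length(idx)
    data.frame(gene_id = state$gene_id[idx],
               chromosome = state$chromosome[idx],
               start = (seq_len(n) - 1L) * spacing + 1L,
               end = (seq_len(n) - 1L) * spacing + gene_length,
               strand = state$strand[idx])
  })
  gene_locations(do.call(rbind, rows))
}

#' Simulate a two-lineage genome history
#'
#' Evolves the ancestral genome through the shared event list, splits into
#' lineages A and B (gene ids gain an `A_`/`B_` prefix), applies each
#' lineage's events, and returns the extant genomes together with exact
#' truth labels for every cross-genome gene pair sharing an ancestral
#' gene: the pair is an ortholog if the two genes descend from the same
#' copy at every shared (pre-split) WGD, a paralog otherwise. Divergence
#' depth counts the epochs separating the pair from its most recent common
#' copy, summed over both lineages, so paralog pairs are always deeper
#' than ortholog pairs of the same ancestral gene.
#'
#' @param ancestral an [ancestral_genome].
#' @param schedule an [event_schedule].
#' @return list of class `simulated_history`: `genome_a`, `genome_b`
#'   ([gene_locations]), `lineage` (per-gene ancestry table with
#'   `genome`, `gene_id`, `ancestral_gene`, `shared_path`), `truth`
#'   (data.frame `gene_a`, `gene_b`, `relation`, `depth`), `event_log`,
#'   and `epochs` (split epoch and per-lineage final epochs).
#' @export
simulate_history <- function(ancestral, schedule) {
  stopifnot(inherits(ancestral, "ancestral_genome"),
            inherits(schedule, "event_schedule"))
  with_seed(schedule$seed, {
    log_env <- new.env()
    log_env$log <- list()

    shared <- run_events(init_state(ancestral), schedule$shared,
                         shared = TRUE, epoch0 = 0L, lineage = "shared",
                         log_env = log_env)
    split_epoch <- shared$epoch + 1L
    # epochs of shared WGD events, aligned with shared_path entries
    wgd_epochs <- which(vapply(schedule$shared, `[[`, "", "kind") == "WGD")

    start_a <- shared$state
    start_a$gene_id <- paste0("A_", start_a$gene_id)
    start_b <- shared$state
    start_b$gene_id <- paste0("B_", start_b$gene_id)

    res_a <- run_events(start_a, schedule$lineage_a, shared = FALSE,
                        epoch0 = split_epoch, lineage = "A", log_env = log_env)
    res_b <- run_events(start_b, schedule$lineage_b, shared = FALSE,
                        epoch0 = split_epoch, lineage = "B", log_env = log_env)

    truth <- truth_labels(res_a$state, res_b$state, wgd_epochs,
                          split_epoch, res_a$epoch, res_b$epoch)
    lineage_tab <- rbind(
      data.frame(genome = "A", gene_id = res_a$state$gene_id,
                 ancestral_gene = res_a$state$ancestral_gene,
                 shared_path = res_a$state$shared_path),
      data.frame(genome = "B", gene_id = res_b$state$gene_id,
                 ancestral_gene = res_b$state$ancestral_gene,
                 shared_path = res_b$state$shared_path))
    structure(list(
      genome_a = state_to_locations(res_a$state),
      genome_b = state_to_locations(res_b$state),
      lineage = lineage_tab,
      truth = truth,
      event_log = if (length(log_env$log)) do.call(rbind, log_env$log)
                  else data.frame(),
      epochs = list(split = split_epoch, final_a = res_a$epoch,
                    final_b = res_b$epoch)
    ), class = "simulated_history")
  })
}

truth_labels <- function(state_a, state_b, wgd_epochs, split_epoch,
                         final_a, final_b) {
  common <- intersect(state_a$ancestral_gene, state_b$ancestral_gene)
  if (!length(common))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      relation = character(0), depth = integer(0)))
  a_by <- split(seq_len(nrow(state_a)), state_a$ancestral_gene)
  b_by <- split(seq_len(nrow(state_b)), state_b$ancestral_gene)
  out <- vector("list", length(common))
  for (i in seq_along(common)) {
    ia <- a_by[[common[i]]]
    ib <- b_by[[common[i]]]
    grid <- expand.grid(ia = ia, ib = ib)
    pa <- state_a$shared_path[grid$ia]
    pb <- state_b$shared_path[grid$ib]
    div <- mapply(divergence_epoch, pa, pb,
                  MoreArgs = list(wgd_epochs = wgd_epochs,
                                  split_epoch = split_epoch))
    out[[i]] <- data.frame(
      gene_a = state_a$gene_id[grid$ia],
      gene_b = state_b$gene_id[grid$ib],
      relation = ifelse(pa == pb, "ortholog", "paralog"),
      depth = (final_a - div) + (final_b - div)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Epoch at which two shared copy paths diverged: the epoch of the first
# shared WGD where they took different copies, or the split epoch if the
# paths agree throughout.
divergence_epoch <- function(pa, pb, wgd_epochs, split_epoch) {
  if (pa == pb) return(split_epoch)
  va <- strsplit(pa, ".", fixed = TRUE)[[1]]
  vb <- strsplit(pb, ".", fixed = TRUE)[[1]]
  first_diff <- which(va != vb)[1]
  wgd_epochs[first_diff]
}

#' Construct a similarity model for hit emission
#'
#' Similarity is modeled directly in bit-score space: a pair at
#' divergence depth `d` scores `base_score - decay * d` plus Gaussian
#' noise; pairs falling below the significance floor emit no hit. The
#' e-value is a fixed strictly decreasing function of the bit score
#' (`1e3 * 2^-bits`, the standard Karlin-Altschul shape with an arbitrary
#' search-space constant).
#'
#' @param base_score bit score of a zero-depth pair.
#' @param decay bit-score loss per divergence epoch.
#' @param noise_sd standard deviation of the Gaussian score noise.
#' @param floor significance floor in bit-score units; lower-scoring
#'   pairs are dropped.
#' @return list of class `similarity_model`.
#' @export
similarity_model <- function(base_score = 200, decay = 10, noise_sd = 0,
                             floor = 50) {
  if (floor < 0 || base_score <= 0 || decay < 0 || noise_sd < 0)
    stop("invalid similarity model parameters")
  structure(list(base_score = base_score, decay = decay,
                 noise_sd = noise_sd, floor = floor),
            class = "similarity_model")
}

#' Emit a BLAST-like hit table from a simulated history
#'
#' One candidate hit per cross-genome pair sharing an ancestral gene
#' (genome A genes as queries, genome B genes as subjects); bit score is
#' drawn from the similarity model and pairs below the significance floor
#' are dropped. The result carries the 12 standard outfmt-6 columns
#' (alignment columns filled with sentinel 0, percent identity a monotone
#' transform of the bit score) and is serializable with [write_outfmt6].
#'
#' @param history a [simulate_history] result.
#' @param model a [similarity_model].
#' @param seed RNG seed for the score noise, independent of the history
#'   seed so noise can be varied on a fixed history.
#' @return hit data.frame as from [read_outfmt6]; zero rows if every pair
#'   falls below the floor.
#' @export
emit_hit_table <- function(history, model = similarity_model(), seed = 1L) {
  stopifnot(inherits(history, "simulated_history"),
            inherits(model, "similarity_model"))
  tr <- history$truth
  if (!nrow(tr)) return(empty_hits())
  score <- with_seed(seed,
    model$base_score - model$decay * tr$depth +
      stats::rnorm(nrow(tr), sd = model$noise_sd))
  keep <- score >= model$floor
  if (!any(keep)) return(empty_hits())
  tr <- tr[keep, , drop = FALSE]
  score <- score[keep]
  data.frame(
    query_protein = paste0(tr$gene_a, ".p1"),
    subject_protein = paste0(tr$gene_b, ".p1"),
    pident = round(pmin(100, 100 * score / model$base_score), 2),
    length = 0, mismatch = 0, gapopen = 0,
    qstart = 0, qend = 0, sstart = 0, send = 0,
    e_value = 1e3 * 2^(-score),
    bit_score = score,
    query_gene = tr$gene_a,
    subject_gene = tr$gene_b,
    row.names = NULL
  )
}

empty_hits <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(.OUTFMT6_COLS)), .OUTFMT6_COLS))
  df$query_protein <- character(0)
  df$subject_protein <- character(0)
  df$query_gene <- character(0)
  df$subject_gene <- character(0)
  df[c(.OUTFMT6_COLS, "query_gene", "subject_gene")]
}

#' Protein-to-gene map for a simulated history
#'
#' The simulator emits one protein (`<gene>.p1`) per gene; this returns
#' the corresponding isoform-collapse map covering both genomes.
#'
#' @param history a [simulate_history] result.
#' @return data.frame with columns `protein_id`, `gene_id`.
#' @export
history_protein_map <- function(history) {
  genes <- c(history$genome_a$gene_id, history$genome_b$gene_id)
  data.frame(protein_id = paste0(genes, ".p1"), gene_id = genes)
}
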