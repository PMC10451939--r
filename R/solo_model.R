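# Gene-loss scenario model for "solo" genes: an agnathan query gene with
# exactly one significant gnathostome match. Three loss histories can
# leave a single human gene; they differ in whether the surviving human
# gene is forced to be the agnathan gene's ortholog. Scenario (a) — one
# loss after WGD1 but before the agnathan/gnathostome split, one more
# after WGD2 — forces orthology. Scenarios (b) (two gnathostome losses,
# one before and one after WGD2) and (c) (three gnathostome losses after
# WGD2) leave a 50% ortholog probability. The asymmetry biases solo genes
# toward true orthologs, which is what makes them usable as
# chromosome-correspondence markers.

#' Construct a loss scenario
#'
#' @param id `"a"`, `"b"` or `"c"`.
#' @return list of class `loss_scenario` with the scenario's ordered loss
#'   events (lineage, timing) and required loss count.
#' @export
loss_scenario <- function(id = c("a", "b", "c")) {
  id <- match.arg(id)
  losses <- switch(id,
    a = list(list(lineage = "shared", timing = "post-WGD1"),
             list(lineage = "gnathostome", timing = "post-WGD2")),
    b = list(list(lineage = "gnathostome", timing = "pre-WGD2"),
             list(lineage = "gnathostome", timing = "post-WGD2")),
    c = list(list(lineage = "gnathostome", timing = "post-WGD2"),
             list(lineage = "gnathostome", timing = "post-WGD2"),
             list(lineage = "gnathostome", timing = "post-WGD2")))
  structure(list(id = id, losses = losses, n_losses = length(losses)),
            class = "loss_scenario")
}

# Enumerate every equally likely copy-loss assignment of a scenario and
# return one row per assignment: which WGD1 copy the surviving human gene
# descends from, and which copy the agnathan query gene is. All
# assignments leave exactly one human survivor by construction of the
# scenario definitions; the uniform choice of struck copies formalizes
# the symmetry assumption the 50% figures rest on.
enumerate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "loss_scenario"))
  rows <- switch(scenario$id,
    a = {
      # shared loss strikes copy s in {1,2}; survivor copy inherited by
      # both lineages; WGD2 doubles it; final loss strikes one duplicate.
      g <- expand.grid(shared_struck = 1:2, wgd2_struck = 1:2)
      surv <- 3L - g$shared_struck
      data.frame(human_copy = surv, agnathan_copy = surv)
    },
    b = {
      # agnathan query is one WGD1 copy (uniform); gnathostome pre-WGD2
      # loss strikes copy s; the survivor doubles at WGD2; one duplicate
      # is then lost.
      g <- expand.grid(agnathan_copy = 1:2, pre_struck = 1:2,
                       wgd2_struck = 1:2)
      data.frame(human_copy = 3L - g$pre_struck,
                 agnathan_copy = g$agnathan_copy)
    },
    c = {
      # both copies double at WGD2 -> duplicates 1a 1b 2a 2b; three
      # sequential losses each strike a surviving duplicate uniformly.
      copies <- c(1L, 1L, 2L, 2L)
      perms <- expand.grid(l1 = 1:4, l2 = 1:3, l3 = 1:2)
      human <- integer(nrow(perms))
      for (i in seq_len(nrow(perms))) {
        alive <- 1:4
        alive <- alive[-perms$l1[i]]
        alive <- alive[-perms$l2[i]]
        alive <- alive[-perms$l3[i]]
        human[i] <- copies[alive]
      }
      g <- expand.grid(row = seq_len(nrow(perms)), agnathan_copy = 1:2)
      data.frame(human_copy = human[g$row], agnathan_copy = g$agnathan_copy)
    })
  rows
}

#' Exact ortholog probability of a loss scenario
#'
#' Exhaustively enumerates every copy-loss assignment (uniform over which
#' copy each unspecified loss strikes), conditions on exactly one
#' surviving human gene and one agnathan query gene, and returns the
#' fraction of assignments in which the human survivor descends from the
#' same WGD1 copy as the agnathan gene.
#'
#' @param scenario a [loss_scenario] or a scenario id (`"a"`, `"b"`,
#'   `"c"`).
#' @return list of class `scenario_outcome`: `probability` (exact, from
#'   enumeration), `n_losses`, `n_assignments`.
#' @export
ortholog_probability <- function(scenario) {
  if (is.character(scenario)) scenario <- loss_scenario(scenario)
  rows <- enumerate_scenario(scenario)
  structure(list(probability = mean(rows$human_copy == rows$agnathan_copy),
                 n_losses = scenario$n_losses,
                 n_assignments = nrow(rows)),
            class = "scenario_outcome")
}

#' Scenario weight under a per-loss probability
#'
#' When each independent gene loss has probability `p`, a scenario
#' requiring `k` losses has relative weight `p^k`; the three-loss
#' scenario is therefore rarer than either two-loss scenario by a factor
#' of `p`.
#'
#' @param scenario a [loss_scenario] or scenario id.
#' @param p per-loss probability in `(0, 1)`.
#' @return numeric weight `p^n_losses`.
#' @export
scenario_weight <- function(scenario, p) {
  if (is.character(scenario)) scenario <- loss_scenario(scenario)
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  p^scenario$n_losses
}

#' Monte-Carlo estimate of a scenario's ortholog probability
#'
#' Samples random copy-loss assignments from the same generative process
#' [ortholog_probability] enumerates; the estimate converges to the exact
#' enumeration value, providing an independent stochastic check.
#'
#' @param scenario a [loss_scenario] or scenario id.
#' @param n_replicates number of sampled histories.
#' @param seed RNG seed.
#' @return list: `fraction_ortholog`, `std_error`, `n_replicates`.
#' @export
simulate_scenario <- function(scenario, n_replicates = 1e4, seed = 1L) {
  if (is.character(scenario)) scenario <- loss_scenario(scenario)
  rows <- enumerate_scenario(scenario)
  hits <- with_seed(seed, {
    idx <- sample.int(nrow(rows), n_replicates, replace = TRUE)
    rows$human_copy[idx] == rows$agnathan_copy[idx]
  })
  f <- mean(hits)
  list(fraction_ortholog = f,
       std_error = sqrt(f * (1 - f) / n_replicates),
       n_replicates = n_replicates)
}

#' Simulated ortholog enrichment of solo genes
#'
#' Runs the genome simulator through WGD1, the lineage split and a
#' gnathostome-side WGD2 with independent per-copy losses (retention `r`
#' at each loss epoch: once before the split, once in each lineage, once
#' after WGD2), classifies every genome-A query on noise-free hits, and
#' measures two ortholog fractions: for solo queries, whether the single
#' match is a true ortholog; for non-solo queries, the fraction of all
#' their distinct significant matches (pre-truncation) that are true
#' orthologs — the relevant contrast, since a multi-match query's matches
#' cannot be told apart without score information. The pre-split loss
#' epoch is what creates the asymmetry: a loss before the split forces
#' the surviving cross-lineage pair to be orthologs, so solo matches are
#' systematically enriched for true orthologs relative to both chance
#' (1/2) and the non-solo match pool.
#'
#' @param retention per-copy retention probability in `(0, 1)`.
#' @param n_genes ancestral gene count.
#' @param seed RNG seed (history and classification are deterministic
#'   given it).
#' @return list: `solo` (`fraction_ortholog`, `n` solo queries,
#'   `std_error`) and `non_solo` (`fraction_ortholog`, `n` matches of
#'   non-solo queries, `std_error`); plus `n_queries`. Fractions are
#'   `NaN` when no query of that kind exists (e.g. no solo genes at
#'   `retention = 1`).
#' @export
simulate_solo_bias <- function(retention, n_genes = 2000L, seed = 1L) {
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  seeds <- spawn_seeds(seed, 2L)
  ancestral <- ancestral_genome(n_genes)
  schedule <- event_schedule(
    shared = list(ev_wgd(2L), ev_loss(retention)),
    lineage_a = list(ev_loss(retention)),
    lineage_b = list(ev_loss(retention), ev_wgd(2L), ev_loss(retention)),
    seed = seeds[1]
  )
  history <- simulate_history(ancestral, schedule)
  hits <- emit_hit_table(history, similarity_model(noise_sd = 0), seeds[2])
  if (!nrow(hits))
    return(list(solo = list(fraction_ortholog = NaN, n = 0L, std_error = NaN),
                non_solo = list(fraction_ortholog = NaN, n = 0L,
                                std_error = NaN),
                n_queries = 0L))
  rel <- stats::setNames(history$truth$relation,
                         paste(history$truth$gene_a, history$truth$gene_b))
  # distinct significant subjects per query, before truncation to three
  pairs <- unique(hits[hits$e_value <= 1e-5,
                       c("query_gene", "subject_gene")])
  pairs$ortholog <- rel[paste(pairs$query_gene, pairs$subject_gene)] ==
    "ortholog"
  n_subjects <- table(pairs$query_gene)
  solo_queries <- names(n_subjects)[n_subjects == 1L]
  solo_hits <- pairs$ortholog[pairs$query_gene %in% solo_queries]
  nonsolo_hits <- pairs$ortholog[!pairs$query_gene %in% solo_queries]
  frac <- function(x) {
    n <- length(x)
    f <- if (n) mean(x) else NaN
    list(fraction_ortholog = f, n = n,
         std_error = if (n) sqrt(f * (1 - f) / n) else NaN)
  }
  list(solo = frac(solo_hits), non_solo = frac(nonsolo_hits),
       n_queries = length(n_subjects))
}
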