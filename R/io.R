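#' Construct a validated gene-location table
#'
#' Gene locations are the shared positional backbone of every analysis in
#' the package: each gene has a chromosome, 1-based inclusive coordinates,
#' a strand, and a `rank` giving its 0-based order along its chromosome by
#' start coordinate (ties broken by end, then gene id).
#'
#' @param df data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`). Any `rank` column is recomputed.
#' @return data.frame of class `gene_locations` with an added `rank`
#'   column, ordered by chromosome then rank.
#' @export
gene_locations <- function(df) {
  req <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("gene table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$gene_id <- as.character(df$gene_id)
  df$chromosome <- as.character(df$chromosome)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(df$start > df$end)
  if (length(bad))
    stop("start > end for gene(s): ", paste(df$gene_id[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ord <- order(df$chromosome, df$start, df$end, df$gene_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(df$start, df$chromosome, FUN = seq_along) - 1L
  rownames(df) <- NULL
  class(df) <- c("gene_locations", "data.frame")
  df
}

#' Read a gene-location table (TSV or BED6)
#'
#' The dialect is auto-detected: a header line containing `gene_id` selects
#' the native TSV layout (`gene_id chromosome start end strand`, 1-based
#' inclusive coordinates); six headerless columns select BED6 (0-based
#' half-open), converted to 1-based inclusive on read. Order ranks are
#' recomputed from coordinates, so row order in the file is immaterial.
#'
#' @param path file path.
#' @return a [gene_locations] table.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first, fixed = TRUE)) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(df) != 6L)
      stop("headerless gene table must be BED6 (6 columns), got ", ncol(df))
    df <- data.frame(gene_id = df[[4]], chromosome = df[[1]],
                     start = as.integer(df[[2]]) + 1L,
                     end = as.integer(df[[3]]), strand = df[[6]])
  }
  gene_locations(df)
}

#' Write a gene-location table
#'
#' @param locations a [gene_locations] table.
#' @param path output path.
#' @param format `"tsv"` (1-based inclusive, with header) or `"bed6"`
#'   (0-based half-open, no header).
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(locations, path, format = c("tsv", "bed6")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- locations[c("gene_id", "chromosome", "start", "end", "strand")]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(locations$chromosome, locations$start - 1L,
                      locations$end, locations$gene_id, 0L, locations$strand)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

.OUTFMT6_COLS <- c("query_protein", "subject_protein", "pident", "length",
                   "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                   "e_value", "bit_score")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Optionally resolves protein ids to gene ids through a
#' protein-to-gene map (isoform collapse itself — keeping one record per
#' distinct subject gene — is deferred to [summarize_query] so raw
#' protein-level hits stay inspectable).
#'
#' @param path file path.
#' @param protein_to_gene optional two-column data.frame
#'   (`protein_id`, `gene_id`) or named character vector mapping protein
#'   ids to gene ids. When `NULL`, gene ids equal protein ids.
#' @param strict if `TRUE` (default) any protein absent from the map is an
#'   error listing the offenders; if `FALSE` unmapped proteins keep their
#'   protein id as gene id.
#' @return data.frame of hits with the 12 standard columns plus
#'   `query_gene` and `subject_gene`.
#' @export
read_outfmt6 <- function(path, protein_to_gene = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.OUTFMT6_COLS)), .OUTFMT6_COLS))
    df$query_gene <- character(0)
    df$subject_gene <- character(0)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("malformed outfmt6 at line ", which(nf != 12L)[1],
         ": expected 12 columns, got ", nf[nf != 12L][1])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- .OUTFMT6_COLS
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "e_value", "bit_score")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric ", col, " at line ", which(is.na(v))[1])
    df[[col]] <- v
  }
  if (any(df$bit_score < 0)) stop("negative bit score")
  if (any(df$e_value < 0)) stop("negative e-value")
  df$query_gene <- map_protein_to_gene(df$query_protein, protein_to_gene, strict)
  df$subject_gene <- map_protein_to_gene(df$subject_protein, protein_to_gene, strict)
  df
}

map_protein_to_gene <- function(proteins, map, strict) {
  if (is.null(map)) return(proteins)
  if (is.data.frame(map)) map <- stats::setNames(as.character(map[[2]]),
                                                 as.character(map[[1]]))
  genes <- unname(map[proteins])
  unmapped <- unique(proteins[is.na(genes)])
  if (length(unmapped)) {
    if (strict)
      stop("proteins missing from protein-to-gene map: ",
           paste(unmapped, collapse = ", "))
    genes[is.na(genes)] <- proteins[is.na(genes)]
  }
  genes
}

#' Write hits as BLAST tabular (outfmt 6)
#'
#' @param hits data.frame as returned by [read_outfmt6] or
#'   [emit_hit_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outfmt6 <- function(hits, path) {
  out <- hits[.OUTFMT6_COLS]
  out$e_value <- formatC(out$e_value, format = "g", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein-to-gene (isoform) map
#'
#' Two-column TSV, `protein_id` then `gene_id`, with or without header.
#'
#' @param path file path.
#' @return data.frame with columns `protein_id`, `gene_id`.
#' @export
read_protein_gene_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) != 2L) stop("protein-to-gene map must have 2 columns")
  if (identical(tolower(df[1, 1]), "protein_id")) df <- df[-1, , drop = FALSE]
  stats::setNames(df, c("protein_id", "gene_id"))
}

#' Read an ohnolog-pair list
#'
#' Two gene ids per row (TSV). Pairs are stored canonically sorted within
#' the row and de-duplicated; a self pair is an error.
#'
#' @param path file path.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ohnolog_pairs <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("ohnolog pair list must have 2 columns")
  if (identical(tolower(df[1, 1]), "gene_a")) df <- df[-1, , drop = FALSE]
  a <- pmin(df[[1]], df[[2]])
  b <- pmax(df[[1]], df[[2]])
  if (any(a == b))
    stop("self pair in ohnolog list: ", a[a == b][1])
  out <- unique(data.frame(gene_a = a, gene_b = b))
  rownames(out) <- NULL
  out
}
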