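# BLAST outfmt-6 column order; the contract every hit file must honour.
OUTFMT6_COLS <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Screening configuration
#'
#' Parameters of the HGT candidate screen. The "best hits" set over which the
#' outside-majority condition is evaluated can be the top `top_n` hits by
#' bitscore (`top_set_mode = "top_n"`, the default) or all hits within
#' `bitscore_fraction` of the maximum bitscore.
#'
#' @param boundary_rank Rank at which inside/outside is decided.
#' @param outside_majority_threshold Fraction of the top set that must be
#'   outside the recipient lineage (strict `>`; default 0.90).
#' @param top_set_mode `"top_n"` or `"bitscore_fraction"`.
#' @param top_n Size of the top set in `"top_n"` mode.
#' @param bitscore_fraction Fraction of the maximum bitscore in
#'   `"bitscore_fraction"` mode.
#' @param evalue_ceiling Hits with larger E-value are discarded.
#' @param self_exclusion_rank Rank at which hits from the recipient's own
#'   taxon are dropped (`"species"` by default; `NA` disables).
#' @param unknown_is_outside Policy for subjects unannotated at
#'   `boundary_rank`; see [is_outside()].
#' @return An object of class `hgt_screen_config`.
#' @export
screen_config <- function(boundary_rank = "phylum",
                          outside_majority_threshold = 0.90,
                          top_set_mode = c("top_n", "bitscore_fraction"),
                          top_n = 50L,
                          bitscore_fraction = 0.95,
                          evalue_ceiling = 1e-5,
                          self_exclusion_rank = "species",
                          unknown_is_outside = FALSE) {
  top_set_mode <- match.arg(top_set_mode)
  stopifnot(outside_majority_threshold > 0, outside_majority_threshold < 1,
            top_n >= 1, bitscore_fraction > 0, bitscore_fraction <= 1,
            evalue_ceiling >= 0)
  if (!boundary_rank %in% rank_ladder())
    stop("screen_config(): boundary_rank not on the ladder")
  if (!is.na(self_exclusion_rank) && !self_exclusion_rank %in% rank_ladder())
    stop("screen_config(): self_exclusion_rank not on the ladder")
  structure(list(boundary_rank = boundary_rank,
                 outside_majority_threshold = outside_majority_threshold,
                 top_set_mode = top_set_mode,
                 top_n = as.integer(top_n),
                 bitscore_fraction = bitscore_fraction,
                 evalue_ceiling = evalue_ceiling,
                 self_exclusion_rank = self_exclusion_rank,
                 unknown_is_outside = unknown_is_outside),
            class = "hgt_screen_config")
}

# canonical hit order: descending bitscore, then ascending evalue, then
# lexicographic subject id -- makes every downstream verdict independent of
# input row order.
sort_hits <- function(hits) {
  hits[order(-hits$bitscore, hits$evalue, hits$subject_id,
             method = "radix"), , drop = FALSE]
}

#' Build a hit table for one query gene
#'
#' @param hits data.frame with at least `subject_id`, `percent_identity`,
#'   `alignment_length`, `evalue`, `bitscore` columns.
#' @param query_id Query gene identifier.
#' @param lineages List of [lineage()] objects, one per hit row.
#' @return Object of class `hgt_hit_table`: the sorted data.frame with the
#'   subject lineages in a `subject_lineage` list column and the query id as
#'   an attribute.
#' @export
hit_table <- function(hits, query_id, lineages) {
  stopifnot(is.data.frame(hits), length(lineages) == nrow(hits))
  need <- c("subject_id", "percent_identity", "alignment_length",
            "evalue", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit_table(): missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(hits)) {
    if (any(hits$evalue < 0)) stop("hit_table(): negative evalue")
    if (any(hits$percent_identity < 0 | hits$percent_identity > 100))
      stop("hit_table(): percent_identity outside [0, 100]")
    if (any(hits$alignment_length < 1))
      stop("hit_table(): alignment_length < 1")
  }
  hits$subject_lineage <- lineages
  hits <- sort_hits(hits)
  rownames(hits) <- NULL
  structure(hits, query_id = query_id,
            class = c("hgt_hit_table", "data.frame"))
}

#' @export
print.hgt_hit_table <- function(x, ...) {
  cat("<hit table> query ", attr(x, "query_id"), ": ", nrow(x), " hits\n",
      sep = "")
  invisible(x)
}

#' Read BLAST outfmt-6 hit tables
#'
#' Reads a 12-column tab-separated BLAST tabular file (columns `qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`),
#' annotates every subject with its lineage and returns one sorted
#' [hit_table()] per distinct query.
#'
#' @param path TSV file path; `#` comment lines are ignored.
#' @param lineage_map A [read_lineage_map()] result resolving every subject.
#' @param lenient If `TRUE`, rows whose subject is missing from the map are
#'   dropped with a warning instead of raising an error.
#' @return Named list of `hgt_hit_table` objects, keyed by query id.
#' @export
read_hit_tables <- function(path, lineage_map, lenient = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop("read_hit_tables(): line ", lineno[i], " has ", nf[i],
         " columns, expected 12 (BLAST outfmt 6)")
  }
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   percent_identity = as.numeric(m[, 3L]),
                   alignment_length = as.integer(m[, 4L]),
                   mismatch = as.integer(m[, 5L]),
                   gapopen = as.integer(m[, 6L]),
                   qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
                   sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
                   evalue = as.numeric(m[, 11L]),
                   bitscore = as.numeric(m[, 12L]),
                   stringsAsFactors = FALSE)
  unresolved <- setdiff(unique(df$subject_id), names(lineage_map))
  if (length(unresolved)) {
    if (!lenient)
      stop("read_hit_tables(): subject id(s) missing from lineage map: ",
           paste(unresolved, collapse = ", "))
    warning("read_hit_tables(): dropping ",
            sum(df$subject_id %in% unresolved),
            " row(s) with unmapped subjects: ",
            paste(unresolved, collapse = ", "))
    df <- df[!df$subject_id %in% unresolved, , drop = FALSE]
  }
  split_df <- split(df, factor(df$query_id, levels = unique(df$query_id)))
  lapply(split_df, function(d) {
    hit_table(d[setdiff(names(d), "query_id")], query_id = d$query_id[1L],
              lineages = unname(lineage_map[d$subject_id]))
  })
}

#' Filter a hit table for screening
#'
#' Drops hits whose E-value exceeds the configured ceiling and hits that
#' share the recipient's name at the self-exclusion rank (removing the
#' query's own genome/species from its evidence). Canonical order is
#' preserved.
#'
#' @param table A [hit_table()].
#' @param recipient Recipient [lineage()].
#' @param config A [screen_config()].
#' @return Filtered `hgt_hit_table` (possibly empty).
#' @export
apply_filters <- function(table, recipient, config = screen_config()) {
  stopifnot(inherits(table, "hgt_hit_table"))
  if (nrow(table) == 0L) return(table)
  keep <- table$evalue <= config$evalue_ceiling
  if (!is.na(config$self_exclusion_rank)) {
    self_hit <- vapply(table$subject_lineage, shares_rank, logical(1),
                       b = recipient, rank = config$self_exclusion_rank)
    keep <- keep & !self_hit
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query_id") <- attr(table, "query_id")
  class(out) <- class(table)
  out
}

#' Select the "best hits" set of a filtered table
#'
#' @param table A filtered, canonically sorted [hit_table()].
#' @param config A [screen_config()]; see its `top_set_mode`.
#' @return The selected rows (same class), deterministic under the tie rule.
#' @export
top_set <- function(table, config = screen_config()) {
  stopifnot(inherits(table, "hgt_hit_table"))
  if (nrow(table) == 0L) return(table)
  idx <- if (config$top_set_mode == "top_n") {
    seq_len(min(config$top_n, nrow(table)))
  } else {
    which(table$bitscore >= config$bitscore_fraction * max(table$bitscore))
  }
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query_id") <- attr(table, "query_id")
  class(out) <- class(table)
  out
}
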