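#' Screen one gene's hit table for horizontal transfer
#'
#' Implements the best-hit / outside-majority screening rule for microbial
#' HGT candidates. With `T` the best-hits set of the filtered table:
#' \itemize{
#'   \item `cond_best` — the highest-bitscore hit of `T` lies outside the
#'     recipient lineage at the boundary rank;
#'   \item `cond_major` — the outside fraction of `T` strictly exceeds the
#'     majority threshold (default \eqn{>} 0.90);
#'   \item `cond_dominance` — no inside hit anywhere in the full filtered
#'     table has a bitscore \eqn{\ge} the best outside bitscore ("lower
#'     scoring hits or no hits within the lineage", read globally).
#' }
#' A gene is a candidate iff `(cond_best | cond_major) & cond_dominance`.
#' The donor is the subject of the best outside hit. Degenerate inputs
#' (empty tables, no outside hits) yield non-candidate calls, never errors.
#'
#' @param table A [hit_table()].
#' @param recipient Recipient [lineage()].
#' @param config A [screen_config()].
#' @param prefiltered Set `FALSE` to run [apply_filters()] internally.
#' @return Object of class `hgt_call` with fields `query_id`, `is_candidate`,
#'   `best_hit_outside`, `outside_fraction`, `best_inside_bitscore`,
#'   `best_outside_bitscore`, `donor_subject_id`, `donor_lineage`,
#'   `alien_index`, `n_hits_used`.
#' @export
screen_gene <- function(table, recipient, config = screen_config(),
                        prefiltered = TRUE) {
  stopifnot(inherits(table, "hgt_hit_table"))
  if (!prefiltered) table <- apply_filters(table, recipient, config)
  qid <- attr(table, "query_id")
  empty_call <- function() {
    structure(list(query_id = qid, is_candidate = FALSE,
                   best_hit_outside = FALSE, outside_fraction = 0,
                   best_inside_bitscore = NA_real_,
                   best_outside_bitscore = NA_real_,
                   donor_subject_id = NA_character_, donor_lineage = NULL,
                   alien_index = 0, n_hits_used = 0L),
              class = "hgt_call")
  }
  if (nrow(table) == 0L) return(empty_call())

  outside <- vapply(table$subject_lineage, is_outside, logical(1),
                    recipient = recipient,
                    boundary_rank = config$boundary_rank,
                    unknown_is_outside = config$unknown_is_outside)
  ts <- top_set(table, config)
  ts_outside <- outside[seq_len(nrow(ts))]
  if (config$top_set_mode == "bitscore_fraction")
    ts_outside <- outside[table$bitscore >= config$bitscore_fraction *
                            max(table$bitscore)]

  outside_fraction <- mean(ts_outside)
  cond_best <- ts_outside[1L]
  cond_major <- outside_fraction > config$outside_majority_threshold

  best_outside_bit <- if (any(outside)) max(table$bitscore[outside]) else NA_real_
  best_inside_bit <- if (any(!outside)) max(table$bitscore[!outside]) else NA_real_
  cond_dominance <- !is.na(best_outside_bit) &&
    (is.na(best_inside_bit) || best_inside_bit < best_outside_bit)

  is_candidate <- (cond_best || cond_major) && cond_dominance
  donor_row <- if (any(outside)) which(outside)[1L] else NA_integer_

  structure(list(
    query_id = qid,
    is_candidate = is_candidate,
    best_hit_outside = cond_best,
    outside_fraction = outside_fraction,
    best_inside_bitscore = best_inside_bit,
    best_outside_bitscore = best_outside_bit,
    donor_subject_id = if (is.na(donor_row)) NA_character_
                       else table$subject_id[donor_row],
    donor_lineage = if (is.na(donor_row)) NULL
                    else table$subject_lineage[[donor_row]],
    alien_index = alien_index(table, recipient, config),
    n_hits_used = nrow(table)
  ), class = "hgt_call")
}

#' @export
print.hgt_call <- function(x, ...) {
  cat("<hgt call> ", x$query_id, ": ",
      if (x$is_candidate) "CANDIDATE" else "not a candidate",
      " (outside fraction ", sprintf("%.2f", x$outside_fraction),
      ", AI ", sprintf("%.1f", x$alien_index), ")\n", sep = "")
  invisible(x)
}

#' Alien index of a hit table
#'
#' Corroborating log E-value contrast
#' \eqn{AI = \ln(e_{inside} + \epsilon) - \ln(e_{outside} + \epsilon)}
#' with \eqn{\epsilon = 10^{-200}}, where \eqn{e} are the best (smallest)
#' E-values on either side of the lineage boundary; a side with no hits
#' contributes \eqn{e = 1}. Positive values favour foreign origin.
#'
#' @inheritParams screen_gene
#' @return Numeric scalar; 0 for an empty table.
#' @export
alien_index <- function(table, recipient, config = screen_config()) {
  stopifnot(inherits(table, "hgt_hit_table"))
  if (nrow(table) == 0L) return(0)
  eps <- 1e-200
  outside <- vapply(table$subject_lineage, is_outside, logical(1),
                    recipient = recipient,
                    boundary_rank = config$boundary_rank,
                    unknown_is_outside = config$unknown_is_outside)
  e_in <- if (any(!outside)) min(table$evalue[!outside]) else 1
  e_out <- if (any(outside)) min(table$evalue[outside]) else 1
  log(e_in + eps) - log(e_out + eps)
}

# fixed category order; first match in this order wins
STRESS_CATEGORIES <- c("metal", "osmotic_drought", "heat_cold", "oxidative",
                       "acid_pH", "dna_damage_uv", "organic_pollutant")

#' The bundled stress-category keyword lexicon
#'
#' Keyword/phrase patterns mapping gene product descriptions onto the seven
#' abiotic stress resistance categories (metal, osmotic/drought, heat/cold,
#' oxidative, acid/pH, DNA damage/UV, organic pollutant). Seeded from
#' curated product names of microbe-derived stress-resistance genes reported
#' in plant genomes; editable by passing your own TSV to [read_lexicon()].
#'
#' @return Named list `category -> character vector of patterns`, in fixed
#'   category order (class `hgt_lexicon`).
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "stress_lexicon.tsv", package = "planthgt",
                      mustWork = TRUE)
  read_lexicon(path)
}

#' Read a category lexicon TSV
#'
#' Two columns: `category<TAB>pattern`. Categories must be among the seven
#' fixed stress categories; every category present needs at least one
#' non-empty pattern.
#'
#' @param path TSV path; `#` comments allowed.
#' @return `hgt_lexicon` object.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("read_lexicon(): expected 2 tab-separated columns")
  cat_ <- vapply(parts, `[[`, "", 1L)
  pat <- vapply(parts, `[[`, "", 2L)
  bad <- setdiff(unique(cat_), STRESS_CATEGORIES)
  if (length(bad))
    stop("read_lexicon(): unknown categor(ies): ", paste(bad, collapse = ", "))
  if (any(!nzchar(trimws(pat)))) stop("read_lexicon(): empty pattern")
  lex <- lapply(STRESS_CATEGORIES, function(k) pat[cat_ == k])
  names(lex) <- STRESS_CATEGORIES
  lex <- lex[lengths(lex) > 0L]
  structure(lex, class = "hgt_lexicon")
}

#' Assign a stress category to a gene product description
#'
#' Returns the first category (in the fixed category order metal,
#' osmotic_drought, heat_cold, oxidative, acid_pH, dna_damage_uv,
#' organic_pollutant) with any lexicon pattern matching the description
#' case-insensitively as a substring, or `"uncategorized"`.
#'
#' @param product_description Non-empty character scalar (vectorized over
#'   several descriptions).
#' @param lexicon A lexicon from [default_lexicon()] or [read_lexicon()].
#' @return Character vector of categories.
#' @export
categorize_function <- function(product_description,
                                lexicon = default_lexicon()) {
  if (any(is.na(product_description) | !nzchar(product_description)))
    stop("categorize_function(): empty product description")
  desc <- tolower(product_description)
  vapply(desc, function(d) {
    for (k in names(lexicon)) {
      if (any(vapply(tolower(lexicon[[k]]), grepl, logical(1),
                     x = d, fixed = TRUE)))
        return(k)
    }
    "uncategorized"
  }, character(1), USE.NAMES = FALSE)
}

#' Tabulate donor taxa across candidate calls
#'
#' @param calls List of [screen_gene()] results.
#' @param rank Ladder rank at which donors are tabulated (default phylum).
#' @return data.frame `(taxon, count)` sorted by descending count, ties
#'   broken alphabetically; only `is_candidate` calls are counted.
#' @export
summarize_donors <- function(calls, rank = "phylum") {
  if (!rank %in% rank_ladder())
    stop("summarize_donors(): rank not on the ladder")
  cand <- Filter(function(x) isTRUE(x$is_candidate), calls)
  if (length(cand) == 0L)
    return(data.frame(taxon = character(0), count = integer(0)))
  taxa <- vapply(cand, function(x) {
    nm <- x$donor_lineage$ranks[[rank]]
    if (is.na(nm)) "unclassified" else nm
  }, character(1))
  tab <- table(taxa)
  out <- data.frame(taxon = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$taxon, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flatten screen calls to a data.frame
#'
#' @param calls List of `hgt_call` objects.
#' @param lexicon Optional lexicon plus `products` named vector mapping
#'   query ids to product descriptions, used to fill the `category` column.
#' @param products Named character vector `query_id -> product description`.
#' @return data.frame, one row per call.
#' @export
calls_to_frame <- function(calls, products = NULL, lexicon = NULL) {
  df <- data.frame(
    query_id = vapply(calls, `[[`, "", "query_id"),
    is_candidate = vapply(calls, `[[`, logical(1), "is_candidate"),
    outside_fraction = vapply(calls, `[[`, numeric(1), "outside_fraction"),
    best_inside_bitscore = vapply(calls, `[[`, numeric(1), "best_inside_bitscore"),
    best_outside_bitscore = vapply(calls, `[[`, numeric(1), "best_outside_bitscore"),
    donor_subject_id = vapply(calls, `[[`, "", "donor_subject_id"),
    donor_lineage = vapply(calls, function(x)
      if (is.null(x$donor_lineage)) NA_character_
      else format_lineage(x$donor_lineage), character(1)),
    alien_index = vapply(calls, `[[`, numeric(1), "alien_index"),
    n_hits_used = vapply(calls, `[[`, integer(1), "n_hits_used"),
    stringsAsFactors = FALSE)
  if (!is.null(products)) {
    if (is.null(lexicon)) lexicon <- default_lexicon()
    prod <- products[df$query_id]
    df$category <- ifelse(is.na(prod), NA_character_,
                          categorize_function(ifelse(is.na(prod), "x", prod),
                                              lexicon))
  }
  rownames(df) <- NULL
  df
}
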