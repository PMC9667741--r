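#' Taxonomic rank ladder
#'
#' The fixed eight-level NCBI-style rank vocabulary used throughout the
#' package, ordered from the most inclusive rank down to species.
#'
#' @return Character vector of rank labels.
#' @export
#' @examples
#' rank_ladder()
rank_ladder <- function() {
  c("domain", "kingdom", "phylum", "class", "order", "family",
    "genus", "species")
}

# Default ladder used when parsing delimiter-separated lineage strings.
# Donor-taxon strings in published HGT tables run domain;phylum;class;...
# and never carry a kingdom field, so kingdom is skipped positionally.
parse_ladder_default <- function() setdiff(rank_ladder(), "kingdom")

#' Construct a taxonomic lineage
#'
#' A `hgt_lineage` holds one taxon name per rank of the fixed ladder
#' (see [rank_ladder()]); ranks without information are `NA`.
#'
#' @param ... Named taxon names, e.g. `domain = "Bacteria",
#'   phylum = "Proteobacteria"`. Names must be ladder ranks.
#' @param source_id Free-text identifier for the organism the lineage
#'   describes (a taxid, genome name, ...).
#' @return An object of class `hgt_lineage`.
#' @export
#' @examples
#' lineage(domain = "Bacteria", phylum = "Proteobacteria")
lineage <- function(..., source_id = NA_character_) {
  given <- c(...)
  ladder <- rank_ladder()
  if (length(given) == 0L || is.null(names(given)) || any(names(given) == ""))
    stop("lineage(): supply at least one named rank, e.g. domain = \"Bacteria\"")
  bad <- setdiff(names(given), ladder)
  if (length(bad))
    stop("lineage(): unknown rank(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(given)))
    stop("lineage(): duplicated rank(s)")
  ranks <- stats::setNames(rep(NA_character_, length(ladder)), ladder)
  ranks[names(given)] <- as.character(given)
  if (all(is.na(ranks) | !nzchar(ranks)))
    stop("lineage(): at least one rank must be non-empty")
  structure(list(ranks = ranks, source_id = source_id),
            class = "hgt_lineage")
}

#' @export
print.hgt_lineage <- function(x, ...) {
  present <- x$ranks[!is.na(x$ranks)]
  cat("<lineage", if (!is.na(x$source_id)) paste0("[", x$source_id, "]") else "",
      "> ", paste(present, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Parse a delimiter-separated lineage string
#'
#' Fields are assigned positionally: the first field is the domain and the
#' remaining fields descend the ladder phylum, class, order, family, genus,
#' species (the kingdom rank never appears in the donor-taxon notation this
#' parser targets, e.g. `"Bacteria; Proteobacteria; Gammaproteobacteria"`).
#' Nonstandard grouping fields such as `"FCB group"` or
#' `"Terrabacteria group"` are accepted at their position and flagged via the
#' `nonstandard` attribute rather than rejected.
#'
#' @param text Lineage string, e.g. `"Eukaryota; Ascomycota; Eurotiomycetes"`.
#' @param delim Field delimiter (default `";"`).
#' @param ladder Ordered rank labels fields are mapped onto; defaults to the
#'   full ladder minus kingdom.
#' @param source_id Identifier stored on the result.
#' @return A [lineage()] object.
#' @export
#' @examples
#' parse_lineage("Bacteria; Proteobacteria; Gammaproteobacteria")
parse_lineage <- function(text, delim = ";", ladder = parse_ladder_default(),
                          source_id = NA_character_) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("parse_lineage(): empty lineage string")
  bad <- setdiff(ladder, rank_ladder())
  if (length(bad))
    stop("parse_lineage(): ladder contains unknown rank(s): ",
         paste(bad, collapse = ", "))
  fields <- trimws(strsplit(text, delim, fixed = TRUE)[[1]])
  if (!any(nzchar(fields)))
    stop("parse_lineage(): empty lineage string")
  if (length(fields) > length(ladder))
    stop("parse_lineage(): more fields than ladder ranks; offending field: \"",
         fields[length(ladder) + 1L], "\"")
  # empty fields keep their position (unannotated intermediate ranks)
  present <- nzchar(fields)
  args <- stats::setNames(as.list(fields[present]),
                          ladder[seq_along(fields)][present])
  out <- do.call(lineage, c(args, list(source_id = source_id)))
  fields <- fields[present]
  flagged <- fields[grepl("\\bgroup\\b|,", fields, ignore.case = TRUE)]
  attr(out, "nonstandard") <- flagged
  out
}

#' Do two lineages share a name at a rank?
#'
#' @param a,b [lineage()] objects.
#' @param rank A ladder rank label.
#' @return `TRUE` iff both lineages carry a name at `rank` and the names are
#'   equal case-insensitively.
#' @export
shares_rank <- function(a, b, rank) {
  stopifnot(inherits(a, "hgt_lineage"), inherits(b, "hgt_lineage"))
  if (length(rank) != 1L || !rank %in% rank_ladder())
    stop("shares_rank(): rank \"", rank, "\" is not on the ladder")
  na <- a$ranks[[rank]]; nb <- b$ranks[[rank]]
  if (is.na(na) || is.na(nb)) return(FALSE)
  tolower(trimws(na)) == tolower(trimws(nb))
}

#' Is a subject lineage outside a recipient's lineage at a boundary rank?
#'
#' The primitive on which the HGT screen rests: a hit subject is "outside"
#' the recipient when the two lineages do not share a name at the boundary
#' rank. Subjects with no name at the boundary rank are treated as inside
#' (not screen-eligible) by default, which avoids false HGT calls from
#' unannotated taxa; set `unknown_is_outside = TRUE` to invert that policy.
#'
#' @param subject,recipient [lineage()] objects.
#' @param boundary_rank Ladder rank at which the inside/outside decision is
#'   made (default `"phylum"`).
#' @param unknown_is_outside Policy for subjects lacking a name at
#'   `boundary_rank`.
#' @return Logical.
#' @export
is_outside <- function(subject, recipient, boundary_rank = "phylum",
                       unknown_is_outside = FALSE) {
  if (length(boundary_rank) != 1L || !boundary_rank %in% rank_ladder())
    stop("is_outside(): rank \"", boundary_rank, "\" is not on the ladder")
  if (is.na(subject$ranks[[boundary_rank]]))
    return(isTRUE(unknown_is_outside))
  !shares_rank(subject, recipient, boundary_rank)
}

#' Read a subject-to-lineage map
#'
#' Two-column tab-separated file `subject_id<TAB>lineage_string`; `#`
#' comment lines allowed.
#'
#' @param path File path.
#' @param delim Delimiter inside the lineage strings (default `";"`).
#' @return A named list of [lineage()] objects (class `hgt_lineage_map`).
#' @export
read_lineage_map <- function(path, delim = ";") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(structure(list(), class = "hgt_lineage_map"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("read_lineage_map(): expected 2 tab-separated columns; line ",
         which(nf != 2L)[1L], " has ", nf[nf != 2L][1L])
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  if (any(!nzchar(ids))) stop("read_lineage_map(): empty subject id")
  if (anyDuplicated(ids))
    stop("read_lineage_map(): duplicated subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(seq_along(ids), function(i)
    parse_lineage(parts[[i]][2L], delim = delim, source_id = ids[i]))
  names(out) <- ids
  structure(out, class = "hgt_lineage_map")
}

#' Serialize a lineage back to its delimited string form
#'
#' @param x A [lineage()] object.
#' @param delim Delimiter.
#' @return Character scalar.
#' @export
format_lineage <- function(x, delim = ";") {
  paste(x$ranks[!is.na(x$ranks)], collapse = delim)
}
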