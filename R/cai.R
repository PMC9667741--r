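# codon table machinery -------------------------------------------------

.codon_env <- new.env(parent = emptyenv())

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))  # 64 DNA codons
}

# codon -> one-letter amino acid (stops "*"), for a genetic code table id
codon_aa_map <- function(numcode = 1) {
  key <- as.character(numcode)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  codons <- all_codons()
  aa <- vapply(codons, function(cd)
    seqinr::translate(seqinr::s2c(cd), numcode = numcode), character(1))
  map <- stats::setNames(aa, codons)
  .codon_env[[key]] <- map
  map
}

# codons scored by CAI: synonymous-family members, excluding ATG, TGG and
# stops (the standard convention; single-codon families carry no bias signal)
informative_codons <- function(numcode = 1) {
  map <- codon_aa_map(numcode)
  fam_size <- table(map)
  keep <- map != "*" & fam_size[map] > 1L
  names(map)[keep]
}

#' Count codons in a coding sequence
#'
#' Reads consecutive non-overlapping triplets from position 1. Triplets
#' containing non-ACGT symbols are skipped (and tallied); a trailing partial
#' triplet is ignored with a warning.
#'
#' @param cds Nucleotide sequence (character scalar, case-insensitive;
#'   `U` accepted as `T`).
#' @param numcode Genetic code table id (default 1, standard).
#' @return Object of class `hgt_codon_counts`: list with `counts` (named
#'   64-entry integer vector), `skipped` and `numcode`.
#' @export
count_codons <- function(cds, numcode = 1) {
  stopifnot(length(cds) == 1L, is.character(cds))
  s <- chartr("u", "t", tolower(cds))
  n <- nchar(s)
  if (n < 3L) stop("count_codons(): sequence shorter than one codon")
  if (n %% 3L != 0L)
    warning("count_codons(): trailing partial codon (", n %% 3L,
            " nt) ignored")
  starts <- seq.int(1L, n - n %% 3L, by = 3L)
  triplets <- toupper(substring(s, starts, starts + 2L))
  ok <- grepl("^[ACGT]{3}$", triplets)
  counts <- stats::setNames(integer(64L), all_codons())
  tab <- table(triplets[ok])
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, skipped = sum(!ok), numcode = numcode),
            class = "hgt_codon_counts")
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{j} of a synonymous family \eqn{i} of size \eqn{n_i},
#' \eqn{RSCU_{ij} = x_{ij} n_i / \sum_j x_{ij}}: the observed count divided
#' by its expectation under uniform synonymous usage. Families with zero
#' total count carry no information and get RSCU = 1 for all members.
#'
#' @param counts A [count_codons()] result (or a named 64-entry count
#'   vector).
#' @return Named numeric vector over the 64 codons.
#' @export
rscu <- function(counts) {
  if (inherits(counts, "hgt_codon_counts")) {
    numcode <- counts$numcode
    x <- counts$counts
  } else {
    numcode <- 1
    x <- counts
  }
  stopifnot(length(x) == 64L, !is.null(names(x)))
  map <- codon_aa_map(numcode)
  x <- x[names(map)]
  out <- stats::setNames(numeric(64L), names(map))
  for (aa in unique(map)) {
    fam <- names(map)[map == aa]
    tot <- sum(x[fam])
    out[fam] <- if (tot == 0) 1 else x[fam] * length(fam) / tot
  }
  out
}

#' Relative-adaptiveness weights from a highly expressed reference set
#'
#' Pools codon counts across the reference sequences and, within each
#' synonymous family, sets \eqn{w_{ij} = x_{ij} / \max_j x_{ij}}. Codons
#' unobserved in the reference are assigned a count of 0.5 before division
#' (the classic repair that keeps every weight positive, so logs stay
#' finite). ATG, TGG and stop codons are excluded: the table covers the 59
#' informative codons of the standard code.
#'
#' @param reference_cds Character vector of CDS sequences (or a named list),
#'   e.g. EF-Tu/elongation-factor genes, the conventional highly expressed
#'   reference.
#' @param numcode Genetic code table id.
#' @param description Free-text provenance note stored on the table.
#' @return Object of class `hgt_weight_table`: list with `w` (named numeric
#'   over informative codons, all in (0, 1]), `numcode`,
#'   `reference_description`.
#' @export
reference_weights <- function(reference_cds, numcode = 1,
                              description = "user reference set") {
  reference_cds <- unlist(reference_cds, use.names = FALSE)
  if (length(reference_cds) == 0L)
    stop("reference_weights(): empty reference set")
  pooled <- stats::setNames(integer(64L), all_codons())
  for (s in reference_cds) {
    cc <- count_codons(s, numcode = numcode)
    pooled <- pooled + cc$counts
  }
  map <- codon_aa_map(numcode)
  inf <- informative_codons(numcode)
  x <- as.numeric(pooled[inf])
  x[x == 0] <- 0.5
  names(x) <- inf
  w <- stats::setNames(numeric(length(inf)), inf)
  for (aa in unique(map[inf])) {
    fam <- inf[map[inf] == aa]
    w[fam] <- x[fam] / max(x[fam])
  }
  structure(list(w = w, numcode = numcode,
                 reference_description = description),
            class = "hgt_weight_table")
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the relative-adaptiveness weights over the gene's
#' scorable codons: \eqn{CAI = \exp(\frac{1}{L}\sum_k \ln w_k)}. Codons
#' outside the weight table (ATG, TGG, stops, ambiguous triplets) are
#' skipped and tallied.
#'
#' @param gene_cds CDS sequence (character scalar).
#' @param weights A [reference_weights()] table.
#' @param gene_id Identifier stored on the result.
#' @return Object of class `hgt_cai`: list with `gene_id`, `cai` in
#'   \[0, 1\], `codons_scored`, `codons_skipped`.
#' @export
cai <- function(gene_cds, weights, gene_id = NA_character_) {
  stopifnot(inherits(weights, "hgt_weight_table"))
  cc <- count_codons(gene_cds, numcode = weights$numcode)
  x <- cc$counts[names(weights$w)]
  L <- sum(x)
  if (L < 1L)
    stop("cai(): no scorable codons in gene ", gene_id)
  value <- exp(sum(x * log(weights$w)) / L)
  skipped <- sum(cc$counts) - L + cc$skipped
  structure(list(gene_id = gene_id, cai = value,
                 codons_scored = as.integer(L),
                 codons_skipped = as.integer(skipped)),
            class = "hgt_cai")
}

#' @export
print.hgt_cai <- function(x, ...) {
  cat("<cai> ", x$gene_id, ": ", sprintf("%.4f", x$cai), " over ",
      x$codons_scored, " codons (", x$codons_skipped, " skipped)\n", sep = "")
  invisible(x)
}

#' Summarize CAI by stress category
#'
#' @param results List of [cai()] results.
#' @param categories Character vector of categories, parallel to `results`.
#' @return data.frame `(category, n, mean, min, max)`, one row per category
#'   present, in fixed category order (then alphabetical for categories
#'   outside the fixed set).
#' @export
summarize_cai_by_category <- function(results, categories) {
  stopifnot(length(results) == length(categories))
  if (length(results) == 0L)
    return(data.frame(category = character(0), n = integer(0),
                      mean = numeric(0), min = numeric(0), max = numeric(0)))
  vals <- vapply(results, `[[`, numeric(1), "cai")
  lev <- c(STRESS_CATEGORIES, "uncategorized")
  lev <- c(lev, sort(setdiff(unique(categories), lev)))
  f <- factor(categories, levels = lev)
  agg <- lapply(split(vals, f, drop = TRUE), function(v)
    c(n = length(v), mean = mean(v), min = min(v), max = max(v)))
  out <- data.frame(category = names(agg),
                    n = vapply(agg, `[[`, numeric(1), "n"),
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    min = vapply(agg, `[[`, numeric(1), "min"),
                    max = vapply(agg, `[[`, numeric(1), "max"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read CDS sequences from a FASTA file
#'
#' Thin wrapper returning plain uppercase character strings named by
#' sequence id.
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_cds_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(seqs, `[[`, "", 1L)), names(seqs))
}

#' Write CDS sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 60)
  invisible(path)
}
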