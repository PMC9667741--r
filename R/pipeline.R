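#' Pipeline configuration
#'
#' Bundles the stage parameters of the full workflow (screen, tree
#' verification, CAI, structure comparison, report).
#'
#' @param screen A [screen_config()].
#' @param m,theta,s_min [nesting_test()] parameters.
#' @param lexicon_path Optional category lexicon TSV (default: bundled).
#' @param out_dir Output directory for stage TSVs.
#' @param seed Integer seed recorded in every output header.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return Object of class `hgt_pipeline_config`.
#' @export
pipeline_config <- function(screen = screen_config(), m = 5L, theta = 0.8,
                            s_min = 70, lexicon_path = NULL,
                            out_dir = tempfile("hgt_run_"), seed = 1L,
                            log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  structure(list(screen = screen, m = as.integer(m), theta = theta,
                 s_min = s_min, lexicon_path = lexicon_path,
                 out_dir = out_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "hgt_pipeline_config")
}

plog <- function(config, level, ...) {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[config$log_level]] >= lv[[level]])
    message("[planthgt] ", ...)
}

# tiny polynomial hash over the serialized config, for output provenance
# headers (stays within double-exact integer range)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)),
                           collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

output_header <- function(config) {
  # the hash covers the scientific parameters, not where output lands
  hashed <- config[setdiff(names(config), c("out_dir", "log_level"))]
  c(paste0("# planthgt ", as.character(utils::packageVersion("planthgt"))),
    paste0("# config_hash: ", config_hash(hashed)),
    paste0("# seed: ", config$seed))
}

write_stage_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# family|taxon query ids: the tree file key is the family, the focal leaf
# the taxon; plain query ids map to themselves
query_tree_key <- function(qid) sub("\\|.*$", "", qid)
query_focal_leaf <- function(qid) {
  ifelse(grepl("|", qid, fixed = TRUE), sub("^[^|]*\\|", "", qid), qid)
}

#' Run the full HGT detection and assessment workflow
#'
#' Stages, in fixed order: screen the hit tables (mandatory), assign stress
#' categories from product descriptions (optional), verify candidates by
#' the gene-tree nesting test (optional, needs trees + labels), score CAI
#' against the highly expressed reference (optional, needs CDS + reference
#' FASTA), compare structure pairs (optional), and join everything into a
#' report. Optional stages skip gracefully, leaving their columns `NA`.
#' Every stage's table is materialized under `config$out_dir` before the
#' join so stages can be re-run in isolation.
#'
#' @param inputs Named list of inputs: `hits` (outfmt-6 TSV path),
#'   `lineages` (lineage map TSV path), `recipient_lineage` (lineage
#'   string, e.g. `"Eukaryota;Streptophyta"`); optional `products` (named
#'   vector or 2-column TSV path `gene<TAB>product`), `trees_dir`
#'   (directory of `<family>.nwk` files), `labels` (leaf-group TSV path),
#'   `cds_fasta`, `reference_fasta`, `structure_pairs` (list of
#'   `list(A =, B =)` traces or a 2-column TSV of trace file pairs).
#' @param config A [pipeline_config()].
#' @return Object of class `hgt_report`: `detail` data.frame (one row per
#'   query), `donor_summary`, `category_counts`, `cai_summary`,
#'   `structure_table`, `paths` of the stage TSVs.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  if (is.null(inputs$hits) || is.null(inputs$lineages) ||
      is.null(inputs$recipient_lineage))
    stop("run_pipeline(): 'hits', 'lineages' and 'recipient_lineage' are mandatory")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lexicon <- if (is.null(config$lexicon_path)) default_lexicon()
             else read_lexicon(config$lexicon_path)

  # stage 1: screen -------------------------------------------------------
  plog(config, "info", "screen: reading hit tables")
  lmap <- read_lineage_map(inputs$lineages)
  tables <- read_hit_tables(inputs$hits, lmap)
  recipient <- parse_lineage(inputs$recipient_lineage)
  calls <- lapply(tables, function(tb)
    screen_gene(apply_filters(tb, recipient, config$screen), recipient,
                config$screen))
  names(calls) <- vapply(calls, `[[`, "", "query_id")

  products <- inputs$products
  if (is.character(products) && length(products) == 1L &&
      file.exists(products)) {
    pr <- utils::read.table(products, sep = "\t", comment.char = "#",
                            quote = "", stringsAsFactors = FALSE)
    products <- stats::setNames(pr[[2L]], pr[[1L]])
  }
  detail <- calls_to_frame(calls, products = products, lexicon = lexicon)
  if (is.null(detail$category)) detail$category <- NA_character_
  write_stage_tsv(detail, file.path(config$out_dir, "screen_calls.tsv"),
                  config)

  # stage 2: gene-tree verification ---------------------------------------
  nest_cols <- data.frame(query_id = detail$query_id,
                          nesting_verdict = NA_character_,
                          foreign_fraction = NA_real_,
                          donor_consistency = NA_real_,
                          min_support_on_path = NA_real_,
                          stringsAsFactors = FALSE)
  if (!is.null(inputs$trees_dir) && !is.null(inputs$labels)) {
    plog(config, "info", "verify-tree: nesting tests")
    labels <- read_group_labels(inputs$labels)
    for (i in seq_len(nrow(detail))) {
      qid <- detail$query_id[i]
      tp <- file.path(inputs$trees_dir, paste0(query_tree_key(qid), ".nwk"))
      if (!file.exists(tp)) next
      gt <- read_gene_tree(tp)
      res <- nesting_test(gt, labels, focal = query_focal_leaf(qid),
                          m = config$m, s_min = config$s_min,
                          theta = config$theta)
      nest_cols$nesting_verdict[i] <- res$verdict
      nest_cols$foreign_fraction[i] <- res$foreign_fraction
      nest_cols$donor_consistency[i] <- res$donor_consistency
      nest_cols$min_support_on_path[i] <- res$min_support_on_path
    }
    write_stage_tsv(nest_cols, file.path(config$out_dir, "nesting.tsv"),
                    config)
  }

  # stage 3: CAI ----------------------------------------------------------
  cai_cols <- data.frame(query_id = detail$query_id, cai = NA_real_,
                         codons_scored = NA_integer_,
                         codons_skipped = NA_integer_,
                         stringsAsFactors = FALSE)
  if (!is.null(inputs$cds_fasta) && !is.null(inputs$reference_fasta)) {
    plog(config, "info", "cai: scoring expressivity")
    genes <- read_cds_fasta(inputs$cds_fasta)
    ref <- read_cds_fasta(inputs$reference_fasta)
    wt <- reference_weights(ref, description = inputs$reference_fasta)
    hit <- intersect(detail$query_id, names(genes))
    for (qid in hit) {
      r <- cai(genes[[qid]], wt, gene_id = qid)
      i <- match(qid, cai_cols$query_id)
      cai_cols$cai[i] <- r$cai
      cai_cols$codons_scored[i] <- r$codons_scored
      cai_cols$codons_skipped[i] <- r$codons_skipped
    }
    write_stage_tsv(cai_cols, file.path(config$out_dir, "cai.tsv"), config)
  }

  # stage 4: structures ---------------------------------------------------
  structure_table <- NULL
  if (!is.null(inputs$structure_pairs)) {
    plog(config, "info", "structcomp: pairwise TM-scores")
    sp <- inputs$structure_pairs
    if (is.character(sp) && length(sp) == 1L && file.exists(sp)) {
      m <- utils::read.table(sp, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
      sp <- lapply(seq_len(nrow(m)), function(i)
        list(A = read_ca_trace(m[i, 1L]), B = read_ca_trace(m[i, 2L])))
    }
    structure_table <- pairwise_tm_table(sp)
    write_stage_tsv(structure_table,
                    file.path(config$out_dir, "structcomp.tsv"), config)
  }

  # stage 5: join + summaries ---------------------------------------------
  detail <- merge(detail, nest_cols, by = "query_id", sort = FALSE)
  detail <- merge(detail, cai_cols, by = "query_id", sort = FALSE)
  detail <- detail[order(detail$query_id, method = "radix"), , drop = FALSE]
  rownames(detail) <- NULL

  donor_summary <- summarize_donors(calls, rank = config$screen$boundary_rank)
  cand <- detail[detail$is_candidate, , drop = FALSE]
  cat_tab <- table(factor(cand$category,
                          levels = c(STRESS_CATEGORIES, "uncategorized")))
  category_counts <- data.frame(category = names(cat_tab),
                                n_candidates = as.integer(cat_tab),
                                stringsAsFactors = FALSE)
  cai_summary <- NULL
  if (any(!is.na(detail$cai)) && any(!is.na(detail$category))) {
    ok <- !is.na(detail$cai) & !is.na(detail$category)
    cai_summary <- summarize_cai_by_category(
      lapply(which(ok), function(i)
        structure(list(gene_id = detail$query_id[i], cai = detail$cai[i],
                       codons_scored = detail$codons_scored[i],
                       codons_skipped = detail$codons_skipped[i]),
                  class = "hgt_cai")),
      detail$category[ok])
  }

  report <- structure(list(detail = detail, donor_summary = donor_summary,
                           category_counts = category_counts,
                           cai_summary = cai_summary,
                           structure_table = structure_table,
                           config = config),
                      class = "hgt_report")
  stopifnot(report_self_consistent(report))
  write_stage_tsv(detail, file.path(config$out_dir, "report.tsv"), config)
  write_stage_tsv(donor_summary,
                  file.path(config$out_dir, "donor_summary.tsv"), config)
  report
}

# summary tallies must equal recounts of the detail rows
report_self_consistent <- function(report) {
  d <- report$detail
  n_cand <- sum(d$is_candidate)
  ok_cat <- sum(report$category_counts$n_candidates) ==
    sum(d$is_candidate & !is.na(d$category))
  ok_donor <- sum(report$donor_summary$count) == n_cand
  ok_cat && ok_donor
}

#' @export
print.hgt_report <- function(x, ...) {
  cat("<hgt report> ", nrow(x$detail), " genes screened, ",
      sum(x$detail$is_candidate), " HGT candidates\n", sep = "")
  if (nrow(x$donor_summary))
    cat("  top donor: ", x$donor_summary$taxon[1L], " (n=",
        x$donor_summary$count[1L], ")\n", sep = "")
  invisible(x)
}

#' Benchmark the pipeline over an amelioration grid
#'
#' For each amelioration level `a`, simulates a fresh world (same seed,
#' everything else equal), screens every recipient gene, scores calls
#' against the planted truth, measures the nesting test's power on the
#' event trees, and the CAI separation between planted and native genes
#' (both scored against the recipient-clade reference).
#'
#' @param base_config A [world_config()]; its `amelioration` is swept.
#' @param a_grid Numeric vector of amelioration levels (non-empty).
#' @param screen A [screen_config()].
#' @param m,theta,s_min [nesting_test()] parameters.
#' @return data.frame with one row per `a`: sensitivity, specificity,
#'   donor_accuracy, nesting_power, cai_native_mean, cai_planted_mean,
#'   cai_separation.
#' @export
run_benchmark <- function(base_config = world_config(),
                          a_grid = c(0, 0.25, 0.5, 0.75, 1),
                          screen = screen_config(), m = 5L, theta = 0.8,
                          s_min = 70) {
  if (length(a_grid) == 0L) stop("run_benchmark(): empty amelioration grid")
  rows <- lapply(a_grid, function(a) {
    cfg <- base_config
    cfg$amelioration <- a
    world <- simulate_world(cfg)
    met <- world_metrics(world, screen = screen, m = m, theta = theta,
                         s_min = s_min)
    data.frame(a = a, sensitivity = met$score$sensitivity,
               specificity = met$score$specificity,
               donor_accuracy = met$score$donor_accuracy,
               nesting_power = met$nesting_power,
               cai_native_mean = met$cai_native_mean,
               cai_planted_mean = met$cai_planted_mean,
               cai_separation = met$cai_native_mean - met$cai_planted_mean)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# screen + verify + CAI metrics for one world (shared by run_benchmark and
# the acceptance script)
world_metrics <- function(world, screen = screen_config(), m = 5L,
                          theta = 0.8, s_min = 70) {
  emitted <- emit_hit_tables(world)
  # each query is screened against its own taxon's lineage (its "genome")
  calls <- lapply(emitted$tables, function(tb) {
    recipient <- world$lineage_map[[query_focal_leaf(attr(tb, "query_id"))]]
    screen_gene(apply_filters(tb, recipient, screen), recipient, screen)
  })
  score <- score_calls(calls, world)

  nesting_power <- NA_real_
  if (length(world$truth)) {
    gt <- emit_gene_trees(world)
    verdicts <- vapply(world$truth, function(ev) {
      res <- nesting_test(gt$trees[[ev$family]], gt$labels,
                          focal = ev$recipient_taxon, m = m,
                          s_min = s_min, theta = theta)
      res$verdict == "nested"
    }, logical(1))
    nesting_power <- mean(verdicts)
  }

  ref <- emit_reference_cds(world)
  wt <- reference_weights(ref, description = "recipient EF-Tu-like set")
  planted_ids <- vapply(world$truth, function(ev)
    paste0(ev$family, "|", ev$recipient_taxon), character(1))
  qids <- world_query_ids(world)
  native_ids <- setdiff(qids, planted_ids)
  cai_of <- function(qid) {
    f <- query_tree_key(qid); tx <- query_focal_leaf(qid)
    cai(world_gene_cds(world, f, tx), wt, gene_id = qid)$cai
  }
  # subsample native genes for the mean; planted genes all scored
  native_sub <- native_ids[seq_len(min(100L, length(native_ids)))]
  cai_native <- vapply(native_sub, cai_of, numeric(1))
  cai_planted <- if (length(planted_ids))
    vapply(planted_ids, cai_of, numeric(1)) else numeric(0)

  list(score = score, calls = calls, nesting_power = nesting_power,
       weights = wt,
       cai_native_mean = mean(cai_native),
       cai_planted_mean = if (length(cai_planted)) mean(cai_planted)
                          else NA_real_,
       cai_native = cai_native, cai_planted = cai_planted)
}
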