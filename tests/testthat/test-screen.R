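# crafted single-purpose tables -------------------------------------------

mk_table <- function(bitscores, outside, evalues = NULL, qid = "q") {
  n <- length(bitscores)
  if (n == 0L)
    return(hit_table(data.frame(subject_id = character(0),
                                percent_identity = numeric(0),
                                alignment_length = integer(0),
                                evalue = numeric(0), bitscore = numeric(0)),
                     query_id = qid, lineages = list()))
  if (is.null(evalues)) evalues <- 2^(-bitscores)
  lins <- lapply(seq_len(n), function(i)
    if (outside[i]) lin_out(paste0("m", i)) else lin_in(paste0("p", i)))
  hit_table(data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                       percent_identity = 50, alignment_length = 100L,
                       evalue = evalues, bitscore = bitscores),
            query_id = qid, lineages = lins)
}

test_that("screen_gene verdicts on forced configurations", {
  recipient <- lin_in()
  cfg <- screen_config()

  all_in <- mk_table(c(90, 80, 70), outside = c(FALSE, FALSE, FALSE))
  call <- screen_gene(all_in, recipient, cfg)
  expect_false(call$is_candidate)
  expect_equal(call$outside_fraction, 0)

  single_out <- mk_table(75, outside = TRUE)
  call <- screen_gene(single_out, recipient, cfg)
  expect_true(call$is_candidate)
  expect_equal(call$outside_fraction, 1)
  expect_equal(call$donor_subject_id, "s01")
  expect_true(is.na(call$best_inside_bitscore))

  # an inside hit tops the table: dominance (and the best-hit rule) veto
  cfg3 <- screen_config(top_n = 3)
  dom <- mk_table(c(90, 85, 80, 95), outside = c(TRUE, TRUE, TRUE, FALSE))
  call <- screen_gene(dom, recipient, cfg3)
  expect_false(call$is_candidate)
  expect_equal(call$best_inside_bitscore, 95)
  expect_equal(call$best_outside_bitscore, 90)

  # tie case: top set all outside by tie-break, but an equal-bitscore
  # inside hit below the top set still vetoes via dominance
  cfg2 <- screen_config(top_n = 2)
  tie <- mk_table(c(90, 90, 90), outside = c(TRUE, TRUE, FALSE),
                  evalues = c(1e-20, 1e-20, 1e-19))
  call_tie <- screen_gene(tie, recipient, cfg2)
  expect_true(call_tie$best_hit_outside)
  expect_equal(call_tie$outside_fraction, 1)
  expect_false(call_tie$is_candidate)

  empty <- mk_table(numeric(0), logical(0))
  call <- screen_gene(empty, recipient, cfg)
  expect_false(call$is_candidate)
  expect_equal(call$n_hits_used, 0L)
})

test_that("the outside-majority threshold is strict at exactly 90%", {
  recipient <- lin_in()
  cfg <- screen_config(top_n = 10)
  # 9/10 outside = 0.90 exactly, best hit inside and dominating
  tb <- mk_table(c(100, 99, 98, 97, 96, 95, 94, 93, 92, 91),
                 outside = c(FALSE, rep(TRUE, 9)))
  call <- screen_gene(tb, recipient, cfg)
  expect_equal(call$outside_fraction, 0.9)
  expect_false(call$is_candidate)
  # one more outside hit tips the fraction over the threshold, but the
  # dominating inside best still vetoes
  tb2 <- mk_table(c(100, 99, 98, 97, 96, 95, 94, 93, 92, 91, 90),
                  outside = c(FALSE, rep(TRUE, 10)))
  call2 <- screen_gene(tb2, recipient, screen_config(top_n = 11))
  expect_gt(call2$outside_fraction, 0.9)
  expect_false(call2$is_candidate)
})

test_that("screen_gene agrees with the brute-force oracle on random tables", {
  recipient <- lin_in()
  cfg <- screen_config(top_n = 4)
  set.seed(1001)
  seen <- character(0)
  for (i in 1:500) {
    tb <- random_hit_table(8)
    outside <- if (nrow(tb)) table_outside_flags(tb, recipient) else logical(0)
    orc <- oracle_screen(as.data.frame(tb)[, c("subject_id", "evalue",
                                               "bitscore"), drop = FALSE],
                         outside, top_n = 4, threshold = 0.90)
    call <- screen_gene(tb, recipient, cfg)
    expect_identical(call$is_candidate, orc$is_candidate)
    expect_equal(call$outside_fraction, orc$outside_fraction)
    orc_combo <- paste0(as.integer(orc$cond_best),
                        as.integer(orc$cond_major),
                        as.integer(orc$cond_dominance))
    if (nrow(tb)) expect_identical(call_combo(call), orc_combo)
    seen <- union(seen, orc_combo)
  }
  # no random table ever realizes dominance with an inside best hit: a
  # dominating outside hit always tops the sorted table
  expect_true(all(seen %in% FEASIBLE_COMBOS))
})

test_that("every feasible corner of the condition truth table behaves as crafted", {
  recipient <- lin_in()
  for (case in corner_cases()) {
    cfg <- screen_config(top_n = case$top_n)
    call <- screen_gene(case$table, recipient, cfg)
    outside <- table_outside_flags(case$table, recipient)
    orc <- oracle_screen(as.data.frame(case$table)[, c("subject_id",
                                                       "evalue", "bitscore"),
                                                   drop = FALSE],
                         outside, top_n = case$top_n, threshold = 0.90)
    expect_identical(call_combo(call), case$combo, label = case$combo)
    expect_identical(paste0(as.integer(orc$cond_best),
                            as.integer(orc$cond_major),
                            as.integer(orc$cond_dominance)), case$combo)
    expect_identical(call$is_candidate, case$candidate, label = case$combo)
    expect_identical(orc$is_candidate, case$candidate)
  }
})

test_that("hits outside the top set and off both optima are irrelevant", {
  recipient <- lin_in()
  cfg <- screen_config(top_n = 3)
  set.seed(77)
  for (i in 1:50) {
    tb <- random_hit_table(8)
    if (nrow(tb) < 5) next
    outside <- table_outside_flags(tb, recipient)
    base <- screen_gene(tb, recipient, cfg)
    # candidates for removal: rows below the top set that are not the best
    # hit of either side
    best_out <- if (any(outside)) which(outside)[1L] else 0L
    best_in <- if (any(!outside)) which(!outside)[1L] else 0L
    removable <- setdiff(5:nrow(tb), c(best_out, best_in))
    for (r in removable) {
      tb_r <- hit_table(as.data.frame(tb)[-r, names(tb) != "subject_lineage"],
                        "q", tb$subject_lineage[-r])
      expect_identical(screen_gene(tb_r, recipient, cfg)$is_candidate,
                       base$is_candidate)
    }
  }
})

test_that("hgt call invariants hold on random screens", {
  recipient <- lin_in()
  cfg <- screen_config(top_n = 5)
  set.seed(2002)
  for (i in 1:200) {
    call <- screen_gene(random_hit_table(8), recipient, cfg)
    expect_gte(call$outside_fraction, 0)
    expect_lte(call$outside_fraction, 1)
    if (call$is_candidate) {
      expect_false(is.null(call$donor_lineage))
      expect_true(is.na(call$best_inside_bitscore) ||
                    call$best_inside_bitscore < call$best_outside_bitscore)
    }
  }
})

test_that("alien index follows the log E-value contrast", {
  recipient <- lin_in()
  tb <- mk_table(c(50, 90), outside = c(FALSE, TRUE),
                 evalues = c(1e-5, 1e-50))
  expect_equal(alien_index(tb, recipient), log(1e-5) - log(1e-50),
               tolerance = 1e-9)
  expect_equal(alien_index(tb, recipient), 103.6, tolerance = 1e-3)

  sym <- mk_table(c(50, 60), outside = c(FALSE, TRUE),
                  evalues = c(1e-8, 1e-8))
  expect_equal(alien_index(sym, recipient), 0)

  only_out <- mk_table(60, outside = TRUE, evalues = 1e-10)
  expect_equal(alien_index(only_out, recipient), log(1) - log(1e-10),
               tolerance = 1e-9)
  expect_equal(alien_index(only_out, recipient), 23.0, tolerance = 1e-2)

  expect_equal(alien_index(mk_table(numeric(0), logical(0)), recipient), 0)
})

test_that("product descriptions map to stress categories", {
  lex <- default_lexicon()
  expect_equal(categorize_function("Chromate transporter ChrA", lex), "metal")
  expect_equal(categorize_function("Cold-shock DNA-binding protein CspA", lex),
               "heat_cold")
  expect_equal(categorize_function("Arginine deiminase ArcA (EC 3.5.3.6)", lex),
               "acid_pH")
  expect_equal(categorize_function("hypothetical protein", lex),
               "uncategorized")
  expect_error(categorize_function("", lex), "empty")
})

test_that("the bundled lexicon reproduces the curated product categories", {
  fixture <- system.file("extdata", "stress_gene_products.tsv",
                         package = "planthgt")
  tab <- utils::read.table(fixture, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("product", "category"))
  got <- categorize_function(tab$product)
  expect_identical(got, tab$category)
})

test_that("donor summaries count candidates with deterministic ties", {
  expect_equal(nrow(summarize_donors(list())), 0)
  mk_call <- function(cand, phylum) {
    structure(list(query_id = "q", is_candidate = cand,
                   donor_lineage = if (cand)
                     lineage(domain = "Bacteria", phylum = phylum)),
              class = "hgt_call")
  }
  calls <- list(mk_call(TRUE, "Proteobacteria"),
                mk_call(TRUE, "Proteobacteria"),
                mk_call(TRUE, "Ascomycota"),
                mk_call(FALSE, "Ignored"))
  out <- summarize_donors(calls)
  expect_equal(out$taxon, c("Proteobacteria", "Ascomycota"))
  expect_equal(out$count, c(2L, 1L))
  # alphabetical tie order
  calls2 <- list(mk_call(TRUE, "Zeta"), mk_call(TRUE, "Alpha"))
  expect_equal(summarize_donors(calls2)$taxon, c("Alpha", "Zeta"))
})
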