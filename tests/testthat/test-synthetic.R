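small_cfg <- function(n_hgt_events = 4, ...) {
  world_config(n_recipient_taxa = 4, n_donor_taxa = 5, n_other_taxa = 5,
               n_families = 12, protein_length = 120,
               n_hgt_events = n_hgt_events, seed = 7, ...)
}

test_that("identical seeds give identical worlds; zero events give empty truth", {
  w1 <- simulate_world(small_cfg())
  w2 <- simulate_world(small_cfg())
  expect_identical(w1$families, w2$families)
  expect_identical(w1$truth, w2$truth)
  expect_identical(ape::write.tree(w1$species_tree$tree),
                   ape::write.tree(w2$species_tree$tree))

  w0 <- simulate_world(small_cfg(n_hgt_events = 0))
  expect_length(w0$truth, 0)

  expect_error(world_config(n_families = 3, n_hgt_events = 5), "exceeds")
})

test_that("sequence divergence tracks patristic distance", {
  w <- cached_world()
  dmat <- ape::cophenetic.phylo(w$species_tree$tree)
  taxa <- rownames(dmat)
  set.seed(3)
  pick <- t(combn(taxa, 2))
  pick <- pick[sample.int(nrow(pick), 60), , drop = FALSE]
  # average identity across families, excluding planted genes
  ev_fams <- vapply(w$truth, `[[`, "", "family")
  fams <- setdiff(names(w$families), ev_fams)[1:30]
  ident <- apply(pick, 1, function(pr) {
    mean(vapply(fams, function(f)
      mean(w$families[[f]]$aa[pr[1], ] == w$families[[f]]$aa[pr[2], ]),
      numeric(1)))
  })
  dist <- apply(pick, 1, function(pr) dmat[pr[1], pr[2]])
  rho <- stats::cor(ident, dist, method = "spearman")
  expect_lte(rho, -0.8)
})

test_that("emitted hit evidence is self-maximal and monotone in identity", {
  w <- simulate_world(small_cfg())
  e <- emit_hit_tables(w)
  for (qid in names(e$tables)[1:8]) {
    tb <- e$tables[[qid]]
    self <- tb[tb$subject_id == qid, ]
    expect_equal(self$bitscore, max(tb$bitscore))
    ord <- order(tb$percent_identity, decreasing = TRUE)
    expect_true(all(diff(tb$bitscore[ord]) <= 0))
  }
})

test_that("unameliorated planted genes hit the donor clade first", {
  w <- cached_world()   # default world: a = 0, 10 events
  e <- emit_hit_tables(w)
  for (ev in w$truth) {
    qid <- paste0(ev$family, "|", ev$recipient_taxon)
    tb <- e$tables[[qid]]
    nonself <- tb[tb$subject_id != qid, ]
    # the best non-self hit is a donor-clade gene (ties between identical
    # donor-clade sequences are broken lexicographically) and the true
    # donor scores maximally
    best_taxon <- sub("^[^|]*\\|", "", nonself$subject_id[1L])
    expect_true(best_taxon %in% w$taxa$donor)
    donor_row <- nonself[nonself$subject_id ==
                           paste0(ev$family, "|", ev$donor_taxon), ]
    expect_equal(donor_row$bitscore, max(nonself$bitscore))
  }
})

test_that("gene trees equal the species tree except grafted events", {
  w <- simulate_world(small_cfg())
  gt <- emit_gene_trees(w)
  ev_fams <- vapply(w$truth, `[[`, "", "family")
  quiet <- setdiff(names(w$families), ev_fams)[1]
  expect_equal(ape::dist.topo(gt$trees[[quiet]]$tree,
                              w$species_tree$tree), 0, ignore_attr = TRUE)
  for (ev in w$truth) {
    tr <- gt$trees[[ev$family]]$tree
    # the grafted recipient leaf's sister is the donor leaf
    tip <- which(tr$tip.label == ev$recipient_taxon)
    parent <- tr$edge[tr$edge[, 2] == tip, 1]
    sibs <- tr$edge[tr$edge[, 1] == parent, 2]
    sibs <- setdiff(sibs, tip)
    expect_true(any(tr$tip.label[sibs] == ev$donor_taxon))
  }
})

test_that("structure pairs are exact at zero noise and reproducible", {
  p0 <- emit_structures(3, length = 30, noise_sigma = 0, seed = 11)
  for (p in p0) {
    r <- tm_score(p$A, p$B)
    expect_equal(r$tm_score, 1, tolerance = 1e-9)
    expect_lt(r$rmsd, 1e-9)
  }
  p1 <- emit_structures(3, length = 30, noise_sigma = 0.5, seed = 11)
  p2 <- emit_structures(3, length = 30, noise_sigma = 0.5, seed = 11)
  expect_identical(p1, p2)
  # mean rmsd grows with noise
  mean_rmsd <- function(sigma) {
    ps <- emit_structures(10, length = 30, noise_sigma = sigma, seed = 13)
    mean(vapply(ps, function(p) kabsch(p$A, p$B)$rmsd, numeric(1)))
  }
  sweep_rmsd <- vapply(c(0, 0.5, 1, 2), mean_rmsd, numeric(1))
  expect_true(all(diff(sweep_rmsd) > 0))
})

test_that("score_calls reproduces a hand-built confusion matrix", {
  w <- simulate_world(small_cfg())
  e <- emit_hit_tables(w)
  calls <- lapply(e$tables, function(tb) {
    rec <- w$lineage_map[[sub("^[^|]*\\|", "", attr(tb, "query_id"))]]
    screen_gene(apply_filters(tb, rec, screen_config()), rec)
  })
  s <- score_calls(calls, w)

  planted <- vapply(w$truth, function(ev)
    paste0(ev$family, "|", ev$recipient_taxon), character(1))
  cand <- names(Filter(function(x) x$is_candidate, calls))
  tp <- length(intersect(cand, planted))
  fp <- length(setdiff(cand, planted))
  expect_equal(s$sensitivity, tp / length(planted))
  expect_equal(s$specificity,
               1 - fp / (length(calls) - length(planted)))

  # degenerate cases
  no_cand <- lapply(calls, function(x) { x$is_candidate <- FALSE; x })
  expect_equal(score_calls(no_cand, w)$sensitivity, 0)
  expect_error(score_calls(calls[-1], w), "cover")
})

test_that("planted gene reconstruction recodes nested position sets", {
  w <- cached_world()
  ev <- w$truth[[1]]
  g0 <- planted_gene_at(ev, 0)
  g1 <- planted_gene_at(ev, 1)
  expect_equal(g0, paste(ev$donor_codons, collapse = ""))
  expect_equal(g1, paste(ev$recipient_draw, collapse = ""))
  split3 <- function(s) substring(s, seq(1, nchar(s)-2, 3),
                                  seq(3, nchar(s), 3))
  prev <- rep(FALSE, length(ev$u))
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    recoded <- split3(planted_gene_at(ev, a)) != ev$donor_codons
    expect_true(all(recoded | !prev))  # once recoded, stays recoded
    prev <- recoded | prev
  }
})
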