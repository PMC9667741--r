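test_that("newick parsing reads supports and roots degenerate inputs", {
  gt <- read_gene_tree(text = "((A:1,B:1)90:1,(C:1,D:1)80:1);")
  expect_equal(sort(gt$tree$tip.label), c("A", "B", "C", "D"))
  expect_setequal(gt$supports[!is.na(gt$supports)], c(90, 80))
  expect_equal(gt$support_scale, "percent")

  tri <- read_gene_tree(text = "(A,B,C);")
  expect_equal(tri$tree$Nnode, 1)
  expect_true(all(is.na(tri$supports)))

  frac <- read_gene_tree(text = "((A:1,B:1)0.9:1,C:1);")
  expect_equal(frac$support_scale, "fraction")

  expect_error(read_gene_tree(text = "((A,B,(C,D);"), "unbalanced")
  expect_error(read_gene_tree(text = "((A:1,B:1):1,(A:1,C:1):1);"),
               "duplicate")
})

test_that("labels files validate their groups", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\trecipient_group", "B\tdonor_group", "C\tother"), tmp)
  lab <- read_group_labels(tmp)
  expect_equal(unname(lab["B"]), "donor_group")
  writeLines("A\tplants", tmp)
  expect_error(read_group_labels(tmp), "unknown group")
})

caterpillar_labels <- c(X = "recipient_group", D1 = "donor_group",
                        D2 = "donor_group", D3 = "donor_group",
                        D4 = "donor_group", R1 = "recipient_group",
                        R2 = "recipient_group", O1 = "other")

test_that("nesting verdicts on forced topologies", {
  # focal leaf buried inside a donor caterpillar, all supports 95
  gt <- read_gene_tree(
    text = "((((X:1,D1:1)95:1,D2:1)95:1,D3:1)95:1,((R1:1,R2:1)95:1,O1:1)95:1)95;")
  res <- nesting_test(gt, caterpillar_labels, focal = "X", m = 3)
  expect_equal(res$verdict, "nested")
  expect_equal(res$foreign_fraction, 1.0)
  expect_equal(res$donor_consistency, 1.0)
  expect_equal(res$min_support_on_path, 95)

  # focal sister to recipient leaves only
  gt2 <- read_gene_tree(
    text = "(((X:1,R1:1)95:1,(R2:1,R3:1)95:1)95:1,(D1:1,D2:1)95:1)95;")
  lab2 <- c(X = "recipient_group", R1 = "recipient_group",
            R2 = "recipient_group", R3 = "recipient_group",
            D1 = "donor_group", D2 = "donor_group")
  res2 <- nesting_test(gt2, lab2, focal = "X", m = 3)
  expect_equal(res2$foreign_fraction, 0)
  expect_equal(res2$verdict, "not_nested")

  # too few non-focal leaves before the root -> indeterminate
  gt3 <- read_gene_tree(text = "((X:1,R1:1)95:1,R2:1)95;")
  lab3 <- c(X = "recipient_group", R1 = "recipient_group",
            R2 = "recipient_group")
  expect_equal(nesting_test(gt3, lab3, focal = "X", m = 5)$verdict,
               "indeterminate")

  expect_error(nesting_test(gt3, lab3, focal = "ZZ"), "ZZ")
})

test_that("low support and foreign-fraction thresholds gate the verdict", {
  gt <- read_gene_tree(
    text = "((((X:1,D1:1)40:1,D2:1)95:1,D3:1)95:1,(R1:1,R2:1)95:1)95;")
  lab <- caterpillar_labels
  res <- nesting_test(gt, lab, focal = "X", m = 3, s_min = 70)
  expect_equal(res$verdict, "not_nested")  # weak node on the path
  expect_equal(res$min_support_on_path, 40)
  expect_equal(nesting_test(gt, lab, focal = "X", m = 3,
                            s_min = 30)$verdict, "nested")
})

test_that("raising theta or s_min never converts not_nested into nested", {
  set.seed(55)
  w <- cached_world(n_families = 20, n_hgt_events = 10)
  gt <- emit_gene_trees(w, support_jitter_sd = 20, seed = 9)
  for (ev in w$truth) {
    tr <- gt$trees[[ev$family]]
    verdicts <- sapply(c(0.5, 0.8, 0.95), function(th)
      sapply(c(50, 70, 90), function(sm)
        nesting_test(tr, gt$labels, focal = ev$recipient_taxon,
                     m = 5, s_min = sm, theta = th)$verdict))
    nested_flag <- verdicts == "nested"
    # monotone in both axes: once lost, never regained
    expect_true(all(diff(colSums(nested_flag)) <= 0))  # theta increasing
    expect_true(all(apply(nested_flag, 2, function(col) all(diff(col) <= 0))))
  }
})

test_that("nesting agrees with an independent leaf-walk oracle", {
  w <- cached_world(n_families = 60, n_hgt_events = 30)
  gt <- emit_gene_trees(w)
  for (ev in w$truth) {
    tr <- gt$trees[[ev$family]]
    mine <- nesting_test(tr, gt$labels, focal = ev$recipient_taxon)
    orc <- oracle_nesting(tr, gt$labels, focal = ev$recipient_taxon)
    expect_identical(mine$verdict, orc$verdict)
    expect_equal(mine$foreign_fraction, orc$foreign_fraction)
    expect_equal(mine$min_support_on_path, orc$min_support_on_path)
  }
})

test_that("verdicts are invariant under re-serialization and rotation", {
  gt <- read_gene_tree(
    text = "((((X:1,D1:1)95:1,D2:1)95:1,D3:1)95:1,((R1:1,R2:1)95:1,O1:1)95:1)95;")
  base <- nesting_test(gt, caterpillar_labels, focal = "X", m = 3)
  rot <- ape::rotateConstr(gt$tree, rev(gt$tree$tip.label))
  gt_rot <- read_gene_tree(text = ape::write.tree(rot))
  res_rot <- nesting_test(gt_rot, caterpillar_labels, focal = "X", m = 3)
  expect_identical(res_rot$verdict, base$verdict)
  expect_equal(res_rot$foreign_fraction, base$foreign_fraction)
})

test_that("monophyly matches brute-force clade enumeration", {
  gt <- read_gene_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(monophyly_check(gt, c("A", "B")))
  gt2 <- read_gene_tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_false(monophyly_check(gt2, c("A", "B")))
  expect_error(monophyly_check(gt2, c("A", "Z")), "Z")

  set.seed(66)
  for (i in 1:10) {
    phy <- ape::rtree(64)
    gt_r <- structure(list(tree = phy, supports = rep(NA_real_, phy$Nnode),
                           support_scale = "percent"),
                      class = "hgt_gene_tree")
    grp <- sample(phy$tip.label, sample(2:10, 1))
    expect_identical(monophyly_check(gt_r, grp),
                     oracle_monophyletic(phy, grp))
    clade_tips <- ape::extract.clade(phy, sample((66):(64 + phy$Nnode), 1))$tip.label
    expect_true(monophyly_check(gt_r, clade_tips))
  }
})
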