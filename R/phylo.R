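#' Read a gene tree from a Newick file
#'
#' Internal node labels are interpreted as clade supports; the support scale
#' (percentage 0-100 vs fractional 0-1) is auto-detected (any value > 1
#' implies percentages). Unrooted trees with branch lengths are
#' midpoint-rooted; without branch lengths the basal multifurcation is kept
#' as the root.
#'
#' @param path Newick file (or a Newick string via `text`).
#' @param text Optional Newick string instead of a file.
#' @return Object of class `hgt_gene_tree`: a list with `tree` (an
#'   [ape::read.tree()] phylo), `supports` (numeric per internal node, NA
#'   where absent) and `support_scale` (`"percent"` or `"fraction"`).
#' @export
read_gene_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) {
    raw <- paste(readLines(path, warn = FALSE), collapse = "")
    parse_newick_checked(raw)
  } else parse_newick_checked(text)
  if (anyDuplicated(tr$tip.label))
    stop("read_gene_tree(): duplicate leaf name(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(tr) && !is.null(tr$edge.length))
    tr <- phangorn::midpoint(tr)
  supports <- rep(NA_real_, tr$Nnode)
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    supports[seq_along(sup)] <- sup
  }
  scale <- if (any(supports > 1, na.rm = TRUE)) "percent" else "fraction"
  structure(list(tree = tr, supports = supports, support_scale = scale),
            class = "hgt_gene_tree")
}

parse_newick_checked <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("read_gene_tree(): unbalanced parentheses (", n_open, " '(' vs ",
         n_close, " ')') near character ", nchar(text))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("read_gene_tree(): parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("read_gene_tree(): parse error: no tree in input")
  tr
}

#' Read a leaf-group labeling
#'
#' Two-column TSV `leaf<TAB>group` with groups among `recipient_group`,
#' `donor_group`, `other`.
#'
#' @param path TSV path.
#' @return Named character vector `leaf -> group`.
#' @export
read_group_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("read_group_labels(): expected 2 tab-separated columns")
  groups <- vapply(parts, `[[`, "", 2L)
  bad <- setdiff(unique(groups), c("recipient_group", "donor_group", "other"))
  if (length(bad))
    stop("read_group_labels(): unknown group(s): ", paste(bad, collapse = ", "))
  stats::setNames(groups, vapply(parts, `[[`, "", 1L))
}

# children-of-node lookup from the edge matrix
tree_children <- function(tr) split(tr$edge[, 2L], tr$edge[, 1L])

# tip indices descending from each node (tips map to themselves)
node_tips <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(node)
  kids <- tree_children(tr)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  out
}

#' Support-aware nesting test for phylogenetic incongruence
#'
#' Quantifies the classic HGT signature — a recipient sequence "nested
#' within" a foreign clade of its gene tree. Starting from the smallest
#' clade containing the focal leaves, the test ascends towards the root
#' until the current clade holds at least `m` non-focal leaves, recording
#' the minimum support among the clades traversed. The foreign fraction of
#' those non-focal neighbour leaves (and the fraction from the putative
#' donor group) is then measured, and the verdict is `"nested"` iff the
#' foreign fraction reaches `theta` and the minimum support on the path
#' reaches `s_min`. If the root is reached with fewer than `m` non-focal
#' leaves the verdict is `"indeterminate"`.
#'
#' @param gene_tree A [read_gene_tree()] result.
#' @param labels Named `leaf -> group` vector covering every leaf
#'   (groups `recipient_group`, `donor_group`, `other`).
#' @param focal Character vector of focal leaf names (must be labeled
#'   `recipient_group`).
#' @param m Minimum number of non-focal neighbour leaves (default 5).
#' @param s_min Minimum clade support on the traversed path (default 70,
#'   interpreted on the tree's detected support scale; if the tree uses
#'   fractional supports and `s_min > 1`, it is divided by 100).
#' @param theta Minimum foreign fraction for a nested verdict (default 0.8).
#' @return Object of class `hgt_nesting`: `focal_leaves`,
#'   `evaluated_clade_size`, `foreign_fraction`, `donor_consistency`,
#'   `min_support_on_path`, `verdict`.
#' @export
nesting_test <- function(gene_tree, labels, focal, m = 5L, s_min = 70,
                         theta = 0.8) {
  stopifnot(inherits(gene_tree, "hgt_gene_tree"), m >= 1)
  tr <- gene_tree$tree
  ntip <- length(tr$tip.label)
  missing_leaf <- setdiff(focal, tr$tip.label)
  if (length(missing_leaf))
    stop("nesting_test(): focal leaf absent from tree: ",
         paste(missing_leaf, collapse = ", "))
  unlabeled <- setdiff(tr$tip.label, names(labels))
  if (length(unlabeled))
    stop("nesting_test(): unlabeled leaf/leaves: ",
         paste(unlabeled, collapse = ", "))
  if (gene_tree$support_scale == "fraction" && s_min > 1) s_min <- s_min / 100

  focal_idx <- match(focal, tr$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tr$edge))
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]

  node <- if (length(focal_idx) == 1L) focal_idx else
    ape::getMRCA(tr, focal_idx)
  sup_of <- function(v) {
    if (v <= ntip) NA_real_ else gene_tree$supports[v - ntip]
  }
  path_supports <- numeric(0)
  repeat {
    path_supports <- c(path_supports, sup_of(node))
    tips <- node_tips(tr, node)
    nonfocal <- setdiff(tips, focal_idx)
    if (length(nonfocal) >= m) break
    if (node == root) {
      return(structure(list(focal_leaves = focal,
                            evaluated_clade_size = length(tips),
                            foreign_fraction = NA_real_,
                            donor_consistency = NA_real_,
                            min_support_on_path = NA_real_,
                            verdict = "indeterminate"),
                       class = "hgt_nesting"))
    }
    node <- parent[node]
  }
  grp <- labels[tr$tip.label[nonfocal]]
  foreign_fraction <- mean(grp != "recipient_group")
  donor_consistency <- mean(grp == "donor_group")
  min_sup <- if (all(is.na(path_supports))) NA_real_
             else min(path_supports, na.rm = TRUE)
  sup_ok <- !is.na(min_sup) && min_sup >= s_min
  verdict <- if (foreign_fraction >= theta && sup_ok) "nested" else "not_nested"
  structure(list(focal_leaves = focal,
                 evaluated_clade_size = length(node_tips(tr, node)),
                 foreign_fraction = foreign_fraction,
                 donor_consistency = donor_consistency,
                 min_support_on_path = min_sup,
                 verdict = verdict),
            class = "hgt_nesting")
}

#' @export
print.hgt_nesting <- function(x, ...) {
  cat("<nesting test> ", paste(x$focal_leaves, collapse = ","), ": ",
      x$verdict, " (foreign ", sprintf("%.2f", x$foreign_fraction),
      ", donor ", sprintf("%.2f", x$donor_consistency),
      ", min support ", x$min_support_on_path, ")\n", sep = "")
  invisible(x)
}

#' Is a leaf set monophyletic?
#'
#' `TRUE` iff the smallest clade containing the group contains no other
#' leaves.
#'
#' @param gene_tree A [read_gene_tree()] result.
#' @param group Character vector of leaf names (non-empty, all present).
#' @return Logical scalar.
#' @export
monophyly_check <- function(gene_tree, group) {
  stopifnot(inherits(gene_tree, "hgt_gene_tree"), length(group) >= 1)
  tr <- gene_tree$tree
  missing_leaf <- setdiff(group, tr$tip.label)
  if (length(missing_leaf))
    stop("monophyly_check(): leaf absent from tree: ",
         paste(missing_leaf, collapse = ", "))
  ape::is.monophyletic(tr, group)
}
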