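# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately coded from first principles, not by
# calling the package internals it checks.

# --- lineages ---------------------------------------------------------------

lin_in <- function(sp = "Planta vulgaris") {
  lineage(domain = "Eukaryota", phylum = "Streptophyta", species = sp)
}
lin_out <- function(sp = "Microbe sp.") {
  lineage(domain = "Bacteria", phylum = "Proteobacteria", species = sp)
}

# --- random hit tables ------------------------------------------------------

# random already-filtered table with <= max_hits hits; small bitscore
# alphabet so ties are frequent
random_hit_table <- function(max_hits = 8L, qid = "q") {
  n <- sample(0:max_hits, 1L)
  if (n == 0L) {
    return(hit_table(data.frame(subject_id = character(0),
                                percent_identity = numeric(0),
                                alignment_length = integer(0),
                                evalue = numeric(0), bitscore = numeric(0)),
                     query_id = qid, lineages = list()))
  }
  outside <- sample(c(TRUE, FALSE), n, replace = TRUE)
  lins <- lapply(seq_len(n), function(i)
    if (outside[i]) lin_out(paste0("m", i)) else lin_in(paste0("p", i)))
  df <- data.frame(
    subject_id = sprintf("s%02d", sample.int(99L, n)),
    percent_identity = round(stats::runif(n, 20, 100), 1),
    alignment_length = sample(50:500, n, replace = TRUE),
    evalue = 10^(-sample(6:50, n, replace = TRUE)),
    bitscore = sample(c(50, 60, 70, 80, 90, 100), n, replace = TRUE),
    stringsAsFactors = FALSE)
  hit_table(df, query_id = qid, lineages = lins)
}

# --- screen rule oracle -----------------------------------------------------

# brute-force evaluator of (cond_best, cond_major, cond_dominance) from a
# plain data.frame; its own sort, its own set logic
oracle_screen <- function(df, outside, top_n = 50L, threshold = 0.90) {
  if (nrow(df) == 0L)
    return(list(cond_best = FALSE, cond_major = FALSE,
                cond_dominance = FALSE, is_candidate = FALSE,
                outside_fraction = 0))
  ord <- order(-df$bitscore, df$evalue, df$subject_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  outside <- outside[ord]
  k <- min(top_n, nrow(df))
  top_out <- outside[1:k]
  cond_best <- top_out[1L]
  frac <- sum(top_out) / k
  cond_major <- frac > threshold
  best_out <- if (any(outside)) max(df$bitscore[outside]) else -Inf
  insides <- df$bitscore[!outside]
  cond_dominance <- is.finite(best_out) &&
    !any(insides >= best_out)
  list(cond_best = cond_best, cond_major = cond_major,
       cond_dominance = cond_dominance,
       is_candidate = (cond_best || cond_major) && cond_dominance,
       outside_fraction = frac)
}

table_outside_flags <- function(tb, recipient, rank = "phylum") {
  vapply(tb$subject_lineage, function(l) {
    nm <- l$ranks[[rank]]
    if (is.na(nm)) FALSE
    else tolower(nm) != tolower(recipient$ranks[[rank]])
  }, logical(1))
}

# condition combo string from an hgt_call's diagnostic fields
call_combo <- function(call, threshold = 0.90) {
  dominance <- !is.na(call$best_outside_bitscore) &&
    (is.na(call$best_inside_bitscore) ||
       call$best_inside_bitscore < call$best_outside_bitscore)
  paste0(as.integer(call$best_hit_outside),
         as.integer(call$outside_fraction > threshold),
         as.integer(dominance))
}

# crafted hit tables realizing each structurally feasible corner of the
# (cond_best, cond_major, cond_dominance) truth table; the two corners
# "001"/"011" (dominance with an inside best hit) are impossible because a
# dominating outside hit always tops the sorted table
corner_cases <- function() {
  tb <- function(bits, outside, evalues = 2^(-bits)) {
    lins <- lapply(seq_along(bits), function(i)
      if (outside[i]) lin_out(paste0("m", i)) else lin_in(paste0("p", i)))
    hit_table(data.frame(subject_id = sprintf("s%02d", seq_along(bits)),
                         percent_identity = 50, alignment_length = 100L,
                         evalue = evalues, bitscore = bits),
              query_id = "q", lineages = lins)
  }
  list(
    list(combo = "000", candidate = FALSE, top_n = 4,
         table = tb(c(90, 80), c(FALSE, FALSE))),
    list(combo = "010", candidate = FALSE, top_n = 21,
         table = tb(c(100, 99:79), c(FALSE, rep(TRUE, 21)))),
    list(combo = "100", candidate = FALSE, top_n = 4,
         table = tb(c(90, 90), c(TRUE, FALSE), evalues = c(1e-9, 1e-9))),
    list(combo = "101", candidate = TRUE, top_n = 4,
         table = tb(c(100, 50, 40), c(TRUE, FALSE, FALSE))),
    list(combo = "110", candidate = FALSE, top_n = 2,
         table = tb(c(90, 90, 90), c(TRUE, TRUE, FALSE),
                    evalues = rep(1e-9, 3))),
    list(combo = "111", candidate = TRUE, top_n = 4,
         table = tb(c(90, 80), c(TRUE, TRUE))))
}

FEASIBLE_COMBOS <- c("000", "010", "100", "101", "110", "111")

# --- CAI oracle -------------------------------------------------------------

# direct product form (prod w_k)^(1/L) over the gene's scorable codons
oracle_cai <- function(cds, w) {
  cods <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  cods <- toupper(cods)
  scored <- cods[cods %in% names(w)]
  prod(w[scored])^(1 / length(scored))
}

random_cds <- function(n_codons = 50L) {
  bases <- c("A", "C", "G", "T")
  paste(replicate(n_codons,
                  paste(sample(bases, 3L, replace = TRUE), collapse = "")),
        collapse = "")
}

# --- Kabsch oracle (Horn quaternion method) ---------------------------------

oracle_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz,  Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,      Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,      Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,      Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  ss <- sum(Pc^2) + sum(Qc^2) - 2 * lam
  sqrt(max(ss, 0) / nrow(P))
}

random_rigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3,
              byrow = TRUE)
  list(R = R, t = stats::runif(3, -20, 20))
}

# --- nesting oracle (phangorn-based leaf walk) ------------------------------

oracle_nesting <- function(gt, labels, focal, m = 5L, s_min = 70,
                           theta = 0.8) {
  tr <- gt$tree
  ntip <- length(tr$tip.label)
  focal_idx <- match(focal, tr$tip.label)
  start <- if (length(focal_idx) == 1L) focal_idx else {
    anc <- lapply(focal_idx, function(i)
      c(i, phangorn::Ancestors(tr, i, "all")))
    common <- Reduce(intersect, anc)
    common[1L]  # deepest common ancestor first in Ancestors order
  }
  chain <- c(start, phangorn::Ancestors(tr, start, "all"))
  sups <- numeric(0)
  for (nd in chain) {
    if (nd > ntip) sups <- c(sups, gt$supports[nd - ntip])
    tips <- unlist(phangorn::Descendants(tr, nd, "tips"))
    nf <- setdiff(tips, focal_idx)
    if (length(nf) >= m) {
      grp <- labels[tr$tip.label[nf]]
      ff <- mean(grp != "recipient_group")
      ms <- if (all(is.na(sups))) NA_real_ else min(sups, na.rm = TRUE)
      v <- if (!is.na(ms) && ms >= s_min && ff >= theta) "nested"
           else "not_nested"
      return(list(verdict = v, foreign_fraction = ff,
                  min_support_on_path = ms))
    }
  }
  list(verdict = "indeterminate", foreign_fraction = NA_real_,
       min_support_on_path = NA_real_)
}

oracle_monophyletic <- function(phy, group) {
  ntip <- length(phy$tip.label)
  g <- sort(match(group, phy$tip.label))
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    tips <- sort(unlist(phangorn::Descendants(phy, nd, "tips")))
    if (identical(tips, g)) return(TRUE)
  }
  length(g) == 1L
}

# --- cached synthetic worlds ------------------------------------------------

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(...) {
  cfg <- world_config(...)
  key <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- simulate_world(cfg)
  .world_cache[[key]]
}

cached_metrics <- function(world) {
  key <- paste0("metrics_", world$config$seed, "_",
                world$config$amelioration, "_", world$config$n_families,
                "_", world$config$n_hgt_events)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- planthgt:::world_metrics(world)
  .world_cache[[key]]
}
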