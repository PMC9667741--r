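AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Karlin-Altschul-style constants used to turn raw identity scores into
# bitscores; chosen fixed so emitted hit evidence is deterministic and
# monotone in identity, which is all the screen consumes.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Configuration of a synthetic planted-HGT world
#'
#' Defines the study conditions the simulator emulates: a species tree with
#' three marked top-level clades (recipient plants, microbial donors, an
#' outgroup of other taxa), per-clade codon-bias profiles, homolog families
#' diverging along the tree, and a set of planted cross-clade HGT events
#' with tunable amelioration of codon usage toward the recipient's bias.
#'
#' @param n_recipient_taxa,n_donor_taxa,n_other_taxa Taxa per clade.
#' @param n_families Number of homolog families (one gene per taxon each).
#' @param protein_length Protein length in residues (default 200).
#' @param bias_strength Codon bias `b` in \[0, 1\]: each clade prefers one
#'   codon per synonymous family with probability `b + (1 - b)/n_i`
#'   (default 0.8).
#' @param divergence_scale Substitutions per site per unit branch length
#'   (default 0.3).
#' @param n_hgt_events Number of planted HGT events (distinct families).
#' @param amelioration Fraction `a` in \[0, 1\] of a transferred gene's
#'   codon positions re-sampled under the recipient clade's profile.
#' @param seed Integer seed; the whole world is a pure function of it.
#' @param clade_height Height each clade subtree is scaled to.
#' @param root_branch Branch length joining each clade to the root.
#' @param support_value Bootstrap-style support written on emitted gene-tree
#'   nodes (default 95).
#' @return Object of class `hgt_world_config`.
#' @export
world_config <- function(n_recipient_taxa = 6L, n_donor_taxa = 8L,
                         n_other_taxa = 8L, n_families = 100L,
                         protein_length = 200L, bias_strength = 0.8,
                         divergence_scale = 0.3, n_hgt_events = 10L,
                         amelioration = 0, seed = 42L,
                         clade_height = 0.5, root_branch = 1.0,
                         support_value = 95) {
  stopifnot(n_recipient_taxa >= 1, n_donor_taxa >= 1, n_other_taxa >= 1,
            n_families >= 1, protein_length >= 1,
            bias_strength >= 0, bias_strength <= 1,
            divergence_scale >= 0, n_hgt_events >= 0,
            amelioration >= 0, amelioration <= 1)
  if (n_hgt_events > n_families)
    stop("world_config(): n_hgt_events exceeds n_families")
  structure(as.list(environment()), class = "hgt_world_config")
}

clade_lineage_strings <- function() {
  c(recipient = "Eukaryota;Streptophyta;Embryophyceae;Embryophytales;Plantaceae;Planta",
    donor = "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Donoria",
    other = "Eukaryota;Ascomycota;Eurotiomycetes;Eurotiales;Aspergillaceae;Altera")
}

# Yule subtree over n taxa, rescaled to the requested height
yule_subtree <- function(n, labels, height) {
  if (n == 1L) return(NULL)  # handled by caller as a bare tip
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- labels
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * height / max(depths)
  tr
}

subtree_newick <- function(n, labels, height, root_branch) {
  if (n == 1L) return(paste0(labels, ":", height + root_branch))
  tr <- yule_subtree(n, labels, height)
  s <- ape::write.tree(tr)
  s <- sub(";$", "", s)
  paste0(s, ":", root_branch)
}

# one preferred codon per amino-acid family per clade; returns
# aa -> named probability vector over that family's codons
clade_codon_profile <- function(b, numcode = 1) {
  map <- codon_aa_map(numcode)
  aas <- setdiff(unique(map), "*")
  prof <- lapply(aas, function(aa) {
    cods <- names(map)[map == aa]
    n <- length(cods)
    p <- rep((1 - b) / n, n)
    pref <- if (n == 1L) 1L else sample.int(n, 1L)
    p[pref] <- b + (1 - b) / n
    stats::setNames(p, cods)
  })
  stats::setNames(prof, aas)
}

mutate_protein <- function(aa, n_sub) {
  if (n_sub == 0L) return(aa)
  L <- length(aa)
  pos <- sample.int(L, n_sub, replace = TRUE)
  for (p in pos) aa[p] <- sample(AA20[AA20 != aa[p]], 1L)
  aa
}

codons_from_profile <- function(aa, profile) {
  out <- character(length(aa))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    p <- profile[[a]]
    out[idx] <- if (length(p) == 1L) rep(names(p), length(idx))
                else sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  out
}

#' Simulate a truth-labeled planted-HGT world
#'
#' Builds the species tree (three marked clades joined at the root, Yule
#' topology within each clade), draws one codon-bias profile per clade,
#' evolves every homolog family's protein along the tree (Poisson
#' substitutions at `divergence_scale` per site per unit length) and
#' re-samples codons from the taxon's clade profile, then plants
#' `n_hgt_events` HGT events: the recipient taxon's gene is replaced by the
#' donor taxon's current gene and a fraction `amelioration` of its codon
#' positions is re-sampled under the recipient profile. Per-position
#' amelioration uses one uniform draw per position so worlds at different
#' `a` (same seed) recode nested position sets.
#'
#' @param config A [world_config()].
#' @return Object of class `hgt_world`: `config`, `taxa` (with clade
#'   membership), `species_tree` ([read_gene_tree()]-style object),
#'   `lineage_map`, `profiles`, `families` (per family: `aa` and `codons`
#'   taxon-by-position character matrices), `truth` (list of planted
#'   events).
#' @export
simulate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "hgt_world_config"))
  set.seed(config$seed)
  cfg <- config

  taxa <- list(
    recipient = sprintf("R%02d", seq_len(cfg$n_recipient_taxa)),
    donor = sprintf("D%02d", seq_len(cfg$n_donor_taxa)),
    other = sprintf("O%02d", seq_len(cfg$n_other_taxa)))
  clade_of <- stats::setNames(rep(names(taxa), lengths(taxa)),
                              unlist(taxa, use.names = FALSE))

  nwk <- paste0("(",
                subtree_newick(cfg$n_recipient_taxa, taxa$recipient,
                               cfg$clade_height, cfg$root_branch), ",",
                subtree_newick(cfg$n_donor_taxa, taxa$donor,
                               cfg$clade_height, cfg$root_branch), ",",
                subtree_newick(cfg$n_other_taxa, taxa$other,
                               cfg$clade_height, cfg$root_branch), ");")
  sp_tree <- ape::read.tree(text = nwk)
  sp_tree$node.label <- rep(as.character(cfg$support_value), sp_tree$Nnode)

  lin_str <- clade_lineage_strings()
  all_taxa <- unlist(taxa, use.names = FALSE)
  lmap <- lapply(all_taxa, function(tx)
    parse_lineage(paste0(lin_str[[clade_of[[tx]]]], ";", tx),
                  source_id = tx))
  names(lmap) <- all_taxa
  lmap <- structure(lmap, class = "hgt_lineage_map")

  profiles <- lapply(stats::setNames(nm = names(taxa)), function(cl)
    clade_codon_profile(cfg$bias_strength))

  fam_ids <- sprintf("F%03d", seq_len(cfg$n_families))
  event_fams <- if (cfg$n_hgt_events > 0)
    sort(sample(fam_ids, cfg$n_hgt_events)) else character(0)

  # preorder edge traversal of the species tree for protein evolution
  tr <- stats::reorder(sp_tree, "cladewise")
  ntip <- length(tr$tip.label)
  L <- cfg$protein_length

  families <- vector("list", cfg$n_families)
  names(families) <- fam_ids
  truth <- list()

  for (f in fam_ids) {
    node_aa <- vector("list", ntip + tr$Nnode)
    node_aa[[ntip + 1L]] <- sample(AA20, L, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; chi <- tr$edge[e, 2L]
      n_sub <- stats::rpois(1L, cfg$divergence_scale * tr$edge.length[e] * L)
      node_aa[[chi]] <- mutate_protein(node_aa[[par]], n_sub)
    }
    aa_mat <- do.call(rbind, node_aa[seq_len(ntip)])
    rownames(aa_mat) <- tr$tip.label
    aa_mat <- aa_mat[all_taxa, , drop = FALSE]

    cod_mat <- matrix("", nrow = length(all_taxa), ncol = L,
                      dimnames = list(all_taxa, NULL))
    for (tx in all_taxa)
      cod_mat[tx, ] <- codons_from_profile(aa_mat[tx, ],
                                           profiles[[clade_of[[tx]]]])

    if (f %in% event_fams) {
      recip <- sample(taxa$recipient, 1L)
      donor <- sample(taxa$donor, 1L)
      u <- stats::runif(L)
      aa_mat[recip, ] <- aa_mat[donor, ]
      recip_draw <- codons_from_profile(aa_mat[donor, ],
                                        profiles[["recipient"]])
      donor_codons <- cod_mat[donor, ]
      cod_mat[recip, ] <- ifelse(u < cfg$amelioration, recip_draw,
                                 donor_codons)
      truth[[length(truth) + 1L]] <- list(
        family = f, recipient_taxon = recip, donor_taxon = donor,
        amelioration = cfg$amelioration, u = u,
        donor_codons = donor_codons, recipient_draw = recip_draw)
    }
    families[[f]] <- list(aa = aa_mat, codons = cod_mat)
  }

  structure(list(config = cfg, taxa = taxa, clade_of = clade_of,
                 species_tree = structure(
                   list(tree = sp_tree,
                        supports = rep(cfg$support_value, sp_tree$Nnode),
                        support_scale = "percent"),
                   class = "hgt_gene_tree"),
                 lineage_map = lmap, profiles = profiles,
                 families = families, truth = truth),
            class = "hgt_world")
}

#' @export
print.hgt_world <- function(x, ...) {
  cat("<synthetic HGT world> ", length(unlist(x$taxa)), " taxa, ",
      length(x$families), " families, ", length(x$truth),
      " planted events (a = ", x$config$amelioration, ", seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Reconstruct a planted gene's CDS at a chosen amelioration level
#'
#' Uses the per-position uniforms stored with the event, so position sets
#' recoded at increasing `a` are nested (exact monotone coupling across an
#' amelioration grid).
#'
#' @param event One element of `world$truth`.
#' @param a Amelioration level in \[0, 1\].
#' @return CDS character string.
#' @export
planted_gene_at <- function(event, a) {
  paste(ifelse(event$u < a, event$recipient_draw, event$donor_codons),
        collapse = "")
}

world_gene_cds <- function(world, family, taxon) {
  paste(world$families[[family]]$codons[taxon, ], collapse = "")
}

world_query_ids <- function(world) {
  unlist(lapply(names(world$families), function(f)
    paste0(f, "|", world$taxa$recipient)), use.names = FALSE)
}

# identity -> outfmt-6 row fields for one family
family_hit_frame <- function(world, fam_id) {
  fam <- world$families[[fam_id]]
  L <- ncol(fam$aa)
  all_taxa <- rownames(fam$aa)
  n_fam <- length(all_taxa)
  rows <- lapply(world$taxa$recipient, function(q) {
    qaa <- matrix(fam$aa[q, ], nrow = n_fam, ncol = L, byrow = TRUE)
    matches <- rowSums(fam$aa == qaa)
    S <- 3 * matches - L
    bit <- (KA_LAMBDA * S - log(KA_K)) / log(2)
    evalue <- pmax(L * n_fam * L * 2^(-bit), 1e-180)
    data.frame(query_id = paste0(fam_id, "|", q),
               subject_id = paste0(fam_id, "|", all_taxa),
               percent_identity = round(100 * matches / L, 2),
               alignment_length = L, mismatch = L - matches, gapopen = 0L,
               qstart = 1L, qend = L, sstart = 1L, send = L,
               evalue = evalue, bitscore = round(bit, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Emit BLAST-style hit tables (and the lineage map) from a world
#'
#' One row per homolog of each recipient gene's family: percent identity is
#' the observed amino-acid identity, the raw score is the ungapped
#' `2*matches - mismatches`, bitscores follow fixed Karlin-Altschul-style
#' constants and E-values are `L * |family| * L * 2^-bitscore`, floored at
#' 1e-180. Subject ids carry the family so lineages resolve per gene.
#'
#' @param world A [simulate_world()] result.
#' @param dir Optional output directory; writes `hits.tsv` (outfmt 6) and
#'   `lineages.tsv`.
#' @return List with `tables` (named list of [hit_table()] per recipient
#'   query), `lineage_map` (subject-id keyed), and file `paths` when `dir`
#'   is given.
#' @export
emit_hit_tables <- function(world, dir = NULL) {
  stopifnot(inherits(world, "hgt_world"))
  frames <- lapply(names(world$families), family_hit_frame, world = world)
  df <- do.call(rbind, frames)

  # subject-id level lineage map (gene ids share their taxon's lineage)
  subj_ids <- unique(df$subject_id)
  taxon_of <- sub("^[^|]+\\|", "", subj_ids)
  smap <- lapply(seq_along(subj_ids), function(i) {
    l <- world$lineage_map[[taxon_of[i]]]
    l$source_id <- subj_ids[i]
    l
  })
  names(smap) <- subj_ids
  smap <- structure(smap, class = "hgt_lineage_map")

  split_df <- split(df, factor(df$query_id, levels = unique(df$query_id)))
  tables <- lapply(split_df, function(d)
    hit_table(d[setdiff(names(d), "query_id")], query_id = d$query_id[1L],
              lineages = unname(smap[d$subject_id])))

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    hits_path <- file.path(dir, "hits.tsv")
    write_outfmt6(df, hits_path)
    lin_path <- file.path(dir, "lineages.tsv")
    writeLines(c("# subject_id<TAB>lineage",
                 paste0(names(smap), "\t",
                        vapply(smap, format_lineage, character(1)))),
               lin_path)
    paths <- c(hits = hits_path, lineages = lin_path)
  }
  list(tables = tables, lineage_map = smap, paths = paths)
}

write_outfmt6 <- function(df, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   df$query_id, df$subject_id, df$percent_identity,
                   df$alignment_length, df$mismatch, df$gapopen,
                   df$qstart, df$qend, df$sstart, df$send,
                   format(df$evalue, digits = 3, scientific = TRUE,
                          trim = TRUE),
                   format(df$bitscore, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Emit per-family gene trees and group labels from a world
#'
#' Families without planted events get the species tree verbatim; a planted
#' event grafts the recipient leaf inside the donor clade as sister to the
#' donor taxon's leaf (halfway along its branch). All internal nodes carry
#' the configured support value.
#'
#' @param world A [simulate_world()] result.
#' @param dir Optional output directory; writes `<family>.nwk` per family
#'   plus one shared `labels.tsv`.
#' @param support_jitter_sd Optional Gaussian jitter (sd, support units)
#'   applied to node supports, truncated to the valid scale; default 0
#'   (fixed supports).
#' @param seed Seed for the jitter draws.
#' @return List with `trees` (named list of [read_gene_tree()]-style
#'   objects), `labels` (named leaf -> group vector), `focal` (named list:
#'   planted recipient leaf per event family), and `paths` when `dir` is
#'   given.
#' @export
emit_gene_trees <- function(world, dir = NULL, support_jitter_sd = 0,
                            seed = world$config$seed) {
  stopifnot(inherits(world, "hgt_world"))
  sp <- world$species_tree$tree
  sup <- world$config$support_value
  events <- stats::setNames(world$truth,
                            vapply(world$truth, `[[`, "", "family"))
  if (support_jitter_sd > 0) set.seed(seed)

  labels <- stats::setNames(
    c("recipient_group", "donor_group", "other")[
      match(world$clade_of, c("recipient", "donor", "other"))],
    names(world$clade_of))

  make_tree <- function(f) {
    tr <- sp
    if (f %in% names(events)) {
      ev <- events[[f]]
      tr <- ape::drop.tip(tr, ev$recipient_taxon)
      donor_tip <- which(tr$tip.label == ev$donor_taxon)
      donor_edge <- which(tr$edge[, 2L] == donor_tip)
      pos <- tr$edge.length[donor_edge] / 2
      tr <- phytools::bind.tip(tr, ev$recipient_taxon,
                               edge.length = pos, where = donor_tip,
                               position = pos)
    }
    s <- rep(sup, tr$Nnode)
    if (support_jitter_sd > 0)
      s <- pmin(100, pmax(0, s + stats::rnorm(tr$Nnode, 0,
                                              support_jitter_sd)))
    tr$node.label <- as.character(round(s, 1))
    structure(list(tree = tr, supports = round(s, 1),
                   support_scale = "percent"),
              class = "hgt_gene_tree")
  }
  trees <- lapply(stats::setNames(nm = names(world$families)), make_tree)
  focal <- lapply(events, `[[`, "recipient_taxon")

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tree_paths <- vapply(names(trees), function(f) {
      p <- file.path(dir, paste0(f, ".nwk"))
      ape::write.tree(trees[[f]]$tree, file = p)
      p
    }, character(1))
    lab_path <- file.path(dir, "labels.tsv")
    writeLines(paste0(names(labels), "\t", labels), lab_path)
    paths <- list(trees = tree_paths, labels = lab_path)
  }
  list(trees = trees, labels = labels, focal = focal, paths = paths)
}

#' Emit synthetic CA-trace pairs (ideal helix + noisy rigid copy)
#'
#' Generates an ideal alpha-helix CA trace (rise 1.5 A, turn 100 degrees,
#' radius 2.3 A) and, per pair, a partner obtained by a random proper rigid
#' transform plus isotropic Gaussian coordinate noise.
#'
#' @param n_pairs Number of pairs.
#' @param length Residues per trace (>= 10).
#' @param noise_sigma Noise standard deviation in Angstrom.
#' @param seed Integer seed.
#' @param dir Optional output directory (`pair<k>_{a,b}.xyz`).
#' @return List of `list(A =, B =)` [ca_trace()] pairs (positional
#'   correspondence), plus `paths` attribute when `dir` is given.
#' @export
emit_structures <- function(n_pairs, length = 60L, noise_sigma = 0,
                            seed = 1L, dir = NULL) {
  stopifnot(length >= 10L, n_pairs >= 1L)
  set.seed(seed)
  helix <- ideal_helix(length)
  pairs <- lapply(seq_len(n_pairs), function(k) {
    R <- random_rotation()
    t_vec <- stats::runif(3, -10, 10)
    noise <- matrix(stats::rnorm(3 * length, 0, noise_sigma),
                    ncol = 3L)
    B <- sweep(helix %*% t(R), 2L, t_vec, `+`) + noise
    list(A = ca_trace(helix, id = sprintf("pair%03d_a", k)),
         B = ca_trace(B, id = sprintf("pair%03d_b", k)))
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(seq_along(pairs), function(k) {
      pa <- file.path(dir, sprintf("pair%03d_a.xyz", k))
      pb <- file.path(dir, sprintf("pair%03d_b.xyz", k))
      write_ca_trace(pairs[[k]]$A, pa)
      write_ca_trace(pairs[[k]]$B, pb)
      c(pa, pb)
    })
    attr(pairs, "paths") <- paths
  }
  pairs
}

ideal_helix <- function(n) {
  i <- seq_len(n) - 1L
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

# uniform random proper rotation via quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

#' Emit a highly-expressed reference CDS set for a clade
#'
#' Draws elongation-factor-like reference genes directly from a clade's
#' codon profile: random proteins whose codons follow the clade bias, the
#' role the EF-Tu convention plays for CAI references.
#'
#' @param world A [simulate_world()] result.
#' @param clade `"recipient"` (default), `"donor"` or `"other"`.
#' @param n_genes Number of reference genes.
#' @param length Protein length per gene (defaults to the world's).
#' @param seed Seed (defaults to the world seed + 1).
#' @return Named character vector of CDS strings.
#' @export
emit_reference_cds <- function(world, clade = "recipient", n_genes = 30L,
                               length = NULL,
                               seed = world$config$seed + 1L) {
  stopifnot(inherits(world, "hgt_world"), clade %in% names(world$profiles))
  if (is.null(length)) length <- world$config$protein_length
  set.seed(seed)
  prof <- world$profiles[[clade]]
  seqs <- vapply(seq_len(n_genes), function(k) {
    aa <- sample(AA20, length, replace = TRUE)
    paste(codons_from_profile(aa, prof), collapse = "")
  }, character(1))
  stats::setNames(seqs, sprintf("%s_ref%02d", clade, seq_len(n_genes)))
}

#' Score screen calls against a world's planted truth
#'
#' @param calls List of [screen_gene()] results covering every recipient
#'   gene of the world (query ids `family|taxon`).
#' @param world The [simulate_world()] result that produced the inputs.
#' @return List with `sensitivity` (detected planted / planted),
#'   `specificity` (1 - false calls / non-planted), `donor_accuracy`
#'   (fraction of detected events whose reported donor matches the true
#'   donor clade at phylum), and the underlying counts.
#' @export
score_calls <- function(calls, world) {
  stopifnot(inherits(world, "hgt_world"))
  ids <- vapply(calls, `[[`, "", "query_id")
  expected <- world_query_ids(world)
  missing_q <- setdiff(expected, ids)
  if (length(missing_q))
    stop("score_calls(): calls do not cover recipient gene(s): ",
         paste(utils::head(missing_q, 5L), collapse = ", "))
  unknown <- setdiff(ids, expected)
  if (length(unknown))
    stop("score_calls(): truth references unknown gene(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  is_cand <- stats::setNames(vapply(calls, `[[`, logical(1), "is_candidate"),
                             ids)
  planted_ids <- vapply(world$truth, function(ev)
    paste0(ev$family, "|", ev$recipient_taxon), character(1))
  truth_by_id <- stats::setNames(world$truth, planted_ids)

  n_planted <- length(planted_ids)
  detected <- planted_ids[is_cand[planted_ids]]
  n_nonplanted <- length(expected) - n_planted
  false_calls <- sum(is_cand[setdiff(expected, planted_ids)])

  donor_phylum <- function(call) {
    if (is.null(call$donor_lineage)) return(NA_character_)
    call$donor_lineage$ranks[["phylum"]]
  }
  calls_by_id <- stats::setNames(calls, ids)
  donor_ok <- vapply(detected, function(qid) {
    true_donor <- truth_by_id[[qid]]$donor_taxon
    true_phylum <- world$lineage_map[[true_donor]]$ranks[["phylum"]]
    identical(donor_phylum(calls_by_id[[qid]]), true_phylum)
  }, logical(1))

  list(sensitivity = if (n_planted == 0) NA_real_
                     else length(detected) / n_planted,
       specificity = if (n_nonplanted == 0) NA_real_
                     else 1 - false_calls / n_nonplanted,
       donor_accuracy = if (length(detected) == 0) NA_real_
                        else mean(donor_ok),
       n_planted = n_planted, n_detected = length(detected),
       n_false = as.integer(false_calls), n_nonplanted = n_nonplanted)
}
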