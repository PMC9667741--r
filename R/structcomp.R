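#' Construct a CA trace
#'
#' @param coords Numeric matrix, one row per residue, columns x/y/z in
#'   Angstrom.
#' @param id Identifier.
#' @return Object of class `hgt_ca_trace` (the matrix with an `id`
#'   attribute).
#' @export
ca_trace <- function(coords, id = NA_character_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("ca_trace(): coordinates must be n x 3")
  if (nrow(coords) < 3L) stop("ca_trace(): need at least 3 residues")
  if (!all(is.finite(coords))) stop("ca_trace(): non-finite coordinate")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(coords, id = id, class = c("hgt_ca_trace", "matrix", "array"))
}

#' Read a CA trace from disk
#'
#' Accepts a plain whitespace-separated 3-column XYZ text file (one residue
#' per line, `#` comments allowed) or a CA-only PDB file (requires the
#' `bio3d` package; only `CA` atoms are taken, in file order).
#'
#' @param path File path; format chosen by extension (`.pdb` vs anything
#'   else).
#' @param id Identifier (defaults to the file base name).
#' @return A [ca_trace()].
#' @export
read_ca_trace <- function(path, id = NULL) {
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("read_ca_trace(): reading PDB files requires the bio3d package")
    pdb <- bio3d::read.pdb(path)
    sel <- bio3d::atom.select(pdb, elety = "CA")
    xyz <- matrix(pdb$xyz[sel$xyz], ncol = 3L, byrow = TRUE)
    return(ca_trace(xyz, id = id))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 3L))
    stop("read_ca_trace(): expected 3 whitespace-separated columns")
  xyz <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  ca_trace(xyz, id = id)
}

#' Write a CA trace as 3-column XYZ text
#'
#' @param trace A [ca_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.6f %.6f %.6f", trace[, 1L], trace[, 2L],
                     trace[, 3L]), con)
  invisible(path)
}

#' Residue correspondence between two traces
#'
#' @param pairs_a,pairs_b Parallel 1-based index vectors into traces A and
#'   B; both must be strictly increasing with at least 3 pairs.
#' @return Object of class `hgt_correspondence` (2-column integer matrix).
#' @export
correspondence <- function(pairs_a, pairs_b) {
  a <- as.integer(pairs_a); b <- as.integer(pairs_b)
  if (length(a) != length(b)) stop("correspondence(): unequal lengths")
  if (length(a) < 3L) stop("correspondence(): need at least 3 pairs")
  if (any(diff(a) <= 0L) || any(diff(b) <= 0L))
    stop("correspondence(): indices must be strictly increasing")
  if (any(a < 1L) || any(b < 1L)) stop("correspondence(): indices must be >= 1")
  structure(cbind(a = a, b = b), class = c("hgt_correspondence", "matrix",
                                           "array"))
}

# positional 1:1 correspondence for equal-length traces
positional_correspondence <- function(A, B) {
  if (nrow(A) != nrow(B))
    stop("positional correspondence requires equal-length traces")
  correspondence(seq_len(nrow(A)), seq_len(nrow(B)))
}

#' Read a correspondence from a 2-column index TSV
#'
#' @param path TSV path (1-based indices, `#` comments allowed).
#' @return A [correspondence()].
#' @export
read_correspondence <- function(path) {
  m <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("a", "b"))
  correspondence(m$a, m$b)
}

# Kabsch rotation for centered coordinate sets (rows = points); SVD with
# determinant sign correction so reflections are never returned.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)                      # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$v %*% D %*% t(s$u)                      # rotation mapping P onto Q
}

#' Optimal rigid-body superposition of corresponded CA traces
#'
#' Least-squares (Kabsch) superposition of the corresponded residues of A
#' onto B; reflections are excluded by the SVD determinant correction, which
#' also keeps degenerate (collinear/planar) point sets well-defined.
#'
#' @param A,B [ca_trace()] objects.
#' @param corr A [correspondence()]; defaults to the positional 1:1 mapping
#'   for equal-length traces.
#' @return Object of class `hgt_superposition`: `rotation` (3x3, det +1),
#'   `translation` (length-3, applied as `x %*% t(rotation) + translation`
#'   to A's coordinates), `rmsd` (Angstrom) and the per-pair distances
#'   `distances`.
#' @export
kabsch <- function(A, B, corr = NULL) {
  if (is.null(corr)) corr <- positional_correspondence(A, B)
  if (max(corr[, 1L]) > nrow(A) || max(corr[, 2L]) > nrow(B))
    stop("kabsch(): correspondence index out of range")
  P <- A[corr[, 1L], , drop = FALSE]
  Q <- B[corr[, 2L], , drop = FALSE]
  fit <- kabsch_fit(P, Q)
  structure(list(rotation = fit$R, translation = fit$t, rmsd = fit$rmsd,
                 distances = fit$d, n_pairs = nrow(corr)),
            class = "hgt_superposition")
}

# core fit on already-extracted paired coordinates
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  R <- kabsch_rotation(Pc, Qc)
  Pr <- Pc %*% t(R)
  resid <- Pr - Qc
  d <- sqrt(rowSums(resid^2))
  list(R = R, t = as.numeric(cq - cp %*% t(R)),
       rmsd = sqrt(mean(d^2)), d = d)
}

#' TM-score of corresponded CA traces
#'
#' Computes the length-normalized template-modeling score
#' \deqn{TM = \max \frac{1}{L_{norm}} \sum_i \frac{1}{1 + (d_i/d_0)^2}}
#' with \eqn{d_0 = \max(1.24 (L_{norm}-15)^{1/3} - 1.8,\ 0.5)} Angstrom,
#' on a *given* correspondence with iterative-trim refinement: superpose on
#' all pairs, then repeatedly keep the pairs closer than
#' \eqn{\max(d_0, 4.5)} Angstrom, re-superpose on them and re-score all
#' pairs, until the kept set converges (at most 20 iterations); the maximum
#' score encountered is reported. The full dynamic-programming alignment
#' search of TM-align is deliberately not performed — alignments are
#' consumed, not inferred.
#'
#' @inheritParams kabsch
#' @param L_norm Normalizing chain length (by convention the second/target
#'   trace; default `nrow(B)`).
#' @return Object of class `hgt_superposition` with `tm_score`, `d0`,
#'   `L_norm` in addition to the rotation/translation/rmsd of the final
#'   all-pair superposition stage that achieved the reported score.
#' @export
tm_score <- function(A, B, corr = NULL, L_norm = NULL) {
  if (is.null(corr)) corr <- positional_correspondence(A, B)
  if (is.null(L_norm)) L_norm <- nrow(B)
  if (L_norm < 3L) stop("tm_score(): L_norm must be >= 3")
  P <- A[corr[, 1L], , drop = FALSE]
  Q <- B[corr[, 2L], , drop = FALSE]
  d0 <- max(1.24 * (L_norm - 15)^(1/3) - 1.8, 0.5)
  if (!is.finite(d0)) d0 <- 0.5   # L_norm < 15: cube-root of negative
  cutoff <- max(d0, 4.5)

  score_of <- function(d) sum(1 / (1 + (d / d0)^2)) / L_norm

  keep <- seq_len(nrow(P))
  best <- -Inf; best_fit <- NULL
  for (it in seq_len(20L)) {
    fit <- kabsch_fit(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    # score over ALL corresponded pairs under this superposition
    Pr <- sweep(P %*% t(fit$R), 2L, fit$t, `+`)
    d_all <- sqrt(rowSums((Pr - Q)^2))
    tm <- score_of(d_all)
    if (tm > best) { best <- tm; best_fit <- fit }
    new_keep <- which(d_all < cutoff)
    if (length(new_keep) < 3L) break
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  all_fit <- kabsch_fit(P, Q)
  structure(list(rotation = best_fit$R, translation = best_fit$t,
                 rmsd = all_fit$rmsd, tm_score = min(best, 1),
                 L_norm = as.integer(L_norm), d0 = d0,
                 n_pairs = nrow(corr)),
            class = "hgt_superposition")
}

#' @export
print.hgt_superposition <- function(x, ...) {
  cat("<superposition> ", x$n_pairs, " pairs: rmsd ",
      sprintf("%.3f", x$rmsd), " A",
      if (!is.null(x$tm_score)) sprintf(", TM %.3f (d0 %.2f, L %d)",
                                        x$tm_score, x$d0, x$L_norm),
      "\n", sep = "")
  invisible(x)
}

#' Pairwise TM-score / RMSD table
#'
#' @param pairs List of `list(A =, B =, corr =)` triples (corr optional).
#' @param L_norm_mode `"target"` (normalize by B's length, the default) or
#'   `"query"` (by A's length).
#' @return data.frame with one row per pair (`id_a`, `id_b`, `tm_score`,
#'   `rmsd`) in input order, carrying the arithmetic `mean_tm` as an
#'   attribute.
#' @export
pairwise_tm_table <- function(pairs, L_norm_mode = c("target", "query")) {
  L_norm_mode <- match.arg(L_norm_mode)
  if (length(pairs) == 0L) stop("pairwise_tm_table(): empty pair list")
  rows <- lapply(pairs, function(p) {
    L <- if (L_norm_mode == "target") nrow(p$B) else nrow(p$A)
    r <- tm_score(p$A, p$B, corr = p$corr, L_norm = L)
    data.frame(id_a = attr(p$A, "id"), id_b = attr(p$B, "id"),
               tm_score = r$tm_score, rmsd = r$rmsd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_tm") <- mean(out$tm_score)
  out
}
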