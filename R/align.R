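# Pairwise structural alignment: fragment-seeded, TM-score-optimizing, run
# bidirectionally. The TM-score is normalized by the length of the stationary
# structure, so each ordered pair has its own score.

#' TM-score distance scale d0
#'
#' `d0 = max(0.5, 1.24 * (L_ref - 15)^(1/3) - 1.8)`; the 0.5 A floor covers
#' reference lengths of 15 residues or fewer.
#'
#' @param L_ref stationary (reference) length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L_ref) {
  stopifnot(L_ref >= 1)
  max(0.5, 1.24 * max(L_ref - 15, 0)^(1 / 3) - 1.8)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `P` onto `Q`
#' (`q ~ R p + t`). Degenerate reflection cases take the proper-rotation
#' branch (det +1).
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3.
#' @return list with `rotation` (3x3, det +1), `translation`, `rmsd`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3, ncol(P) == 3)
  out <- cpp_kabsch(P, Q)
  out$translation <- as.numeric(out$translation)
  out
}

#' TM-score of a residue mapping
#'
#' Computes `(1/L_ref) * sum 1/(1 + (d_i/d0)^2)` over mapped CA pairs after
#' the TM-score-optimal superposition of the mapped pairs (iterative subset
#' refinement), with `d0` from [tm_d0()] of the stationary length.
#'
#' @param mapping 2-column integer matrix (mobile index, stationary index),
#'   strictly increasing in both columns.
#' @param coords_mobile,coords_stationary CA coordinate matrices.
#' @param L_ref normalization length; defaults to `nrow(coords_stationary)`.
#' @return unitless TM-score in (0, 1].
#' @export
tm_score <- function(mapping, coords_mobile, coords_stationary,
                     L_ref = nrow(coords_stationary)) {
  mapping <- as.matrix(mapping)
  stopifnot(ncol(mapping) == 2, L_ref >= 1)
  if (any(diff(mapping[, 1]) <= 0) || any(diff(mapping[, 2]) <= 0))
    stop("mapping must be strictly increasing in both coordinates")
  d0 <- tm_d0(L_ref)
  r <- cpp_tm_refine(coords_mobile[mapping[, 1], , drop = FALSE],
                     coords_stationary[mapping[, 2], , drop = FALSE], d0)
  r$tm_sum / L_ref
}

# secondary-structure segment seeds for the fragment aligner: CA-geometry
# helix detection (i to i+4 distance ~6.2 A in alpha helices), no backbone
# needed. Returns 0-based (i, j, len) triples pairing segments of both models.
.sse_seeds <- function(xm, xs) {
  seg_of <- function(x) {
    n <- nrow(x)
    if (n < 7) return(data.frame(start = integer(), end = integer()))
    d14 <- sqrt(rowSums((x[-(1:4), , drop = FALSE] - x[seq_len(n - 4), , drop = FALSE])^2))
    helical <- d14 > 4.5 & d14 < 7.5
    r <- rle(helical)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    ok <- r$values & r$lengths >= 6
    data.frame(start = starts[ok], end = pmin(ends[ok] + 4, n))
  }
  sm <- seg_of(xm); ss <- seg_of(xs)
  if (!nrow(sm) || !nrow(ss)) return(matrix(integer(), 0, 3))
  out <- list()
  for (a in seq_len(nrow(sm))) for (b in seq_len(nrow(ss))) {
    L <- min(sm$end[a] - sm$start[a], ss$end[b] - ss$start[b]) + 1
    out[[length(out) + 1]] <- c(sm$start[a] - 1L, ss$start[b] - 1L, L)
  }
  do.call(rbind, out)
}

#' Fragment-seeded pairwise structural alignment
#'
#' Seeds candidate superpositions from gapless alignment of all fragment
#' pairs (length `fragment_len`, stride `stride`) plus a secondary-structure
#' segment seeding pass, then for each promising seed iterates
#' superposition -> distance score matrix `1/(1+(d_ij/d0)^2)` -> global
#' dynamic programming (gap penalty `gap`, free end gaps) until the mapping
#' is fixed. Returns the seed whose final stationary-normalized TM-score is
#' highest. Deterministic.
#'
#' @param mobile,stationary StructureModel, domain-extracted, with CA atoms
#'   for all residues.
#' @param fragment_len fragment length (default 8).
#' @param stride fragment stride (default 4).
#' @param gap DP gap penalty in score-matrix units (default 0.6).
#' @param max_iter iteration cap per seed (default 20).
#' @param top_k seeds carried into full iteration (default 20).
#' @return object of class `AlignmentResult`: `mobile_id`, `stationary_id`,
#'   `mapping` (2-column index matrix), `mobile_keys`, `stationary_keys`,
#'   `rotation`, `translation`, `tm_score`, `rmsd`, `n_aligned`,
#'   `seq_identity`.
#' @export
fragment_align <- function(mobile, stationary, fragment_len = 8L, stride = 4L,
                           gap = 0.6, max_iter = 20L, top_k = 20L) {
  xm <- ca_coords(mobile); xs <- ca_coords(stationary)
  if (nrow(xm) < 3 || nrow(xs) < 3) stop("need at least 3 residues with CA")
  rt_m <- residue_table(mobile); rt_s <- residue_table(stationary)
  no_ca_m <- setdiff(rt_m$key, rownames(xm))
  no_ca_s <- setdiff(rt_s$key, rownames(xs))
  if (length(c(no_ca_m, no_ca_s)))
    stop("residues lack CA atoms: ",
         paste(head(c(no_ca_m, no_ca_s), 10), collapse = ", "))
  d0 <- tm_d0(nrow(xs))
  seeds <- .sse_seeds(xm, xs)
  if (!is.matrix(seeds) || !nrow(seeds)) seeds <- matrix(0L, 0, 3)
  res <- cpp_fragment_align(xm, xs, as.integer(fragment_len),
                            as.integer(stride), gap, as.integer(max_iter),
                            d0, as.integer(top_k), seeds)
  mapping <- cbind(mobile = res$mi, stationary = res$mj)
  seq_m <- model_sequence(mobile); seq_s <- model_sequence(stationary)
  ident <- mean(seq_m[res$mi] == seq_s[res$mj])
  structure(list(mobile_id = mobile$pdb_id, stationary_id = stationary$pdb_id,
                 mapping = mapping,
                 mobile_keys = rownames(xm), stationary_keys = rownames(xs),
                 rotation = res$rotation,
                 translation = as.numeric(res$translation),
                 tm_score = res$tm_sum / nrow(xs), rmsd = res$rmsd,
                 n_aligned = nrow(mapping), seq_identity = ident),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult %s (mobile) -> %s (stationary)\n",
              x$mobile_id, x$stationary_id))
  cat(sprintf("  TM-score %.4f  rmsd %.2f A  aligned %d  identity %.1f%%\n",
              x$tm_score, x$rmsd, x$n_aligned, 100 * x$seq_identity))
  invisible(x)
}

#' Bidirectional pairwise alignment
#'
#' Runs [fragment_align()] twice, exchanging mobile and stationary; the two
#' TM-scores are generally unequal because each is normalized by its own
#' stationary length.
#'
#' @param a,b StructureModel.
#' @param ... passed to [fragment_align()].
#' @return list with elements `ab` (a mobile, b stationary) and `ba`.
#' @export
align_pair_bidirectional <- function(a, b, ...) {
  list(ab = fragment_align(a, b, ...), ba = fragment_align(b, a, ...))
}

#' All-vs-all TM-score matrix
#'
#' @param models named list of StructureModel (domain-extracted).
#' @param ... passed to [fragment_align()].
#' @return `ScoreMatrix`: list with `values` (rows = mobile, columns =
#'   stationary), `row_ids`, `col_ids`.
#' @export
score_matrix_all <- function(models, ...) {
  ids <- unname(vapply(models, function(m) m$pdb_id, character(1)))
  n <- length(models)
  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v[i, j] <- if (i == j) 1
    else fragment_align(models[[i]], models[[j]], ...)$tm_score
  }
  structure(list(values = v, row_ids = ids, col_ids = ids),
            class = "ScoreMatrix")
}
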