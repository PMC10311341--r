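#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum ||R p_i + t - q_i||^2` for two equal-length point sets, via SVD of
#' the covariance matrix with the usual reflection correction.
#'
#' @param P,Q numeric matrices (n x 3) of corresponding points.
#' @return an object of class `superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length-3), and `rmsd` of the
#'   superposed sets.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) abort("point sets must have equal length")
  if (nrow(P) < 3L) abort("degenerate geometry: need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  dp <- svd(Pc)$d; dq <- svd(Qc)$d
  if (dp[2] < 1e-9 * max(dp[1], 1) || dq[2] < 1e-9 * max(dq[1], 1)) {
    abort("degenerate geometry: points are rank-deficient (collinear)")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  Pf <- sweep(P %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((Pf - Q)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to a point set
#' @param sup a `superposition`.
#' @param P numeric matrix (n x 3).
#' @return transformed matrix.
#' @export
apply_superposition <- function(sup, P) {
  sweep(as.matrix(P) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' TM-score of a matched correspondence
#'
#' Computes `(1/L_target) * sum_i 1 / (1 + (d_i/d0)^2)` over the matched
#' positions, where `d_i` is the distance between representative atoms
#' after the given superposition.  The score is length-normalized and lies
#' in (0, 1].
#'
#' @param matches two-column matrix or tibble (`u`, `v`) of matched
#'   position indices.
#' @param coordsA,coordsB representative-atom coordinate matrices (n x 3).
#' @param superposition a `superposition` applied to `coordsA`.
#' @param L_target normalization length (>= 1).
#' @param d0 distance scale in Angstrom (> 0).
#' @return unitless score.
#' @export
tm_score <- function(matches, coordsA, coordsB, superposition, L_target, d0) {
  stopifnot(d0 > 0, L_target >= 1)
  m <- as.matrix(matches)
  if (nrow(m) == 0L) return(0)
  PA <- apply_superposition(superposition, coordsA[m[, 1], , drop = FALSE])
  d <- sqrt(rowSums((PA - coordsB[m[, 2], , drop = FALSE])^2))
  sum(1 / (1 + (d / d0)^2)) / L_target
}

#' Global coordinate-based alignment of two motifs
#'
#' Sequence-order-preserving 3D alignment under a TM-score objective.
#' From each seed (gapless threadings at every offset plus short fragment
#' seeds) the algorithm alternates: superpose on the current matched set,
#' fill the TM-score affinity matrix, run the dynamic-programming step
#' with a gap penalty, and update the matched set, until the match set is
#' stable or the iteration cap is reached.  The best-TM-score alignment
#' over all seeds is returned.  Every position competes for matching; the
#' only penalty for unmatched positions is the `L_target` normalization.
#' There is no randomness and the iteration order is fixed, so the result
#' is deterministic.
#'
#' @param A,B `rna_motif` objects (>= 3 nucleotides each, with a
#'   representative atom present for every nucleotide).
#' @param params a [coordinate_params()] object.
#' @param l_target normalization length; defaults to the length of the
#'   shorter motif, which makes inter-family comparisons symmetric.
#' @return an object of class `coordinate_alignment`: list with `matches`
#'   (tibble `u`, `v`, monotone in both), `tm_score`, `aligned_length`,
#'   `superposition`, `L_target`, `d0`.
#' @export
align_coordinates <- function(A, B, params = coordinate_params(),
                              l_target = NULL) {
  PA <- motif_rep_coords(A, params$rep_atoms)
  PB <- motif_rep_coords(B, params$rep_atoms)
  n <- nrow(PA); m <- nrow(PB)
  if (n < 3L || m < 3L) abort("motif too short for coordinate alignment (< 3 nt)")
  L <- l_target %||% min(n, m)
  d0 <- tm_d0(L, params$d0_floor)

  seeds <- alignment_seeds(n, m, params$fragment_length)
  best <- NULL
  for (seed in seeds) {
    res <- refine_alignment(seed, PA, PB, L, d0, params)
    if (is.null(best) || res$tm > best$tm + 1e-12 ||
        (abs(res$tm - best$tm) <= 1e-12 &&
         nrow(res$matches) > nrow(best$matches))) {
      best <- res
    }
  }
  structure(list(matches = tibble(u = best$matches[, 1], v = best$matches[, 2]),
                 tm_score = best$tm,
                 aligned_length = nrow(best$matches),
                 superposition = best$sup, L_target = L, d0 = d0),
            class = "coordinate_alignment")
}

# Seed matchings: gapless threadings at every offset with overlap >= 3,
# plus fragment seeds on a coarse grid.
alignment_seeds <- function(n, m, frag = 4L) {
  seeds <- list()
  for (off in (-(m - 3L)):(n - 3L)) {
    i <- max(1L, 1L + off):min(n, m + off)
    j <- i - off
    if (length(i) >= 3L) seeds[[length(seeds) + 1L]] <- cbind(i, j)
  }
  if (n >= frag && m >= frag) {
    for (i0 in seq(1L, n - frag + 1L, by = frag)) {
      for (j0 in seq(1L, m - frag + 1L, by = frag)) {
        seeds[[length(seeds) + 1L]] <- cbind(i0:(i0 + frag - 1L),
                                             j0:(j0 + frag - 1L))
      }
    }
  }
  seeds
}

refine_alignment <- function(matches, PA, PB, L, d0, params) {
  best <- NULL
  cur <- matches
  for (it in seq_len(params$max_iter)) {
    if (nrow(cur) < 3L) break
    sup <- kabsch(PA[cur[, 1], , drop = FALSE], PB[cur[, 2], , drop = FALSE])
    PAs <- apply_superposition(sup, PA)
    D2 <- outer(rowSums(PAs^2), rowSums(PB^2), "+") - 2 * PAs %*% t(PB)
    S <- 1 / (1 + pmax(D2, 0) / d0^2)
    dp <- .cpp_dp_align(S, params$gap_penalty)
    nxt <- dp$matches
    tm <- tm_score(nxt, PA, PB, sup, L, d0)
    if (is.null(best) || tm > best$tm) {
      best <- list(tm = tm, matches = nxt, sup = sup)
    }
    if (nrow(nxt) == nrow(cur) && all(nxt == cur)) break
    cur <- nxt
  }
  if (is.null(best)) {
    # degenerate seed; fall back to the seed itself
    sup <- kabsch(PA[matches[, 1], , drop = FALSE],
                  PB[matches[, 2], , drop = FALSE])
    best <- list(tm = tm_score(matches, PA, PB, sup, L, d0),
                 matches = matches, sup = sup)
  }
  best
}

#' @export
print.coordinate_alignment <- function(x, ...) {
  cat(sprintf("<coordinate_alignment> %d nt matched, TM-score %.4f (L=%d, d0=%.2f A)\n",
              x$aligned_length, x$tm_score, x$L_target, x$d0))
  invisible(x)
}
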