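#' Build a base-interaction graph for a motif
#'
#' Converts a motif plus its (motif-restricted) annotations into the graph
#' the interaction aligner consumes: nodes are the motif's nucleotides in
#' segment order, edges are base pairs and stackings over node indices.
#'
#' @param motif an `rna_motif`.
#' @param ann an `annotation_set` (it is restricted to the motif
#'   internally).
#' @return an object of class `interaction_graph` with elements
#'   `nucleotides` (tibble: `idx`, `segment`, `rid`, `base`), `pairs`
#'   (tibble: `i`, `j`, `edge_i`, `edge_j`, `orientation`) and `stacks`
#'   (tibble: `i`, `j`, `kind`), plus the originating `motif_id`.
#' @export
interaction_graph <- function(motif, ann) {
  ann <- motif_interactions(ann, motif)
  nts <- motif$nucleotides
  idx <- setNames(seq_len(nrow(nts)), nts$rid)
  pairs <- if (nrow(ann$pairs) > 0L) {
    tibble(i = unname(idx[ann$pairs$rid_i]), j = unname(idx[ann$pairs$rid_j]),
           edge_i = ann$pairs$edge_i, edge_j = ann$pairs$edge_j,
           orientation = ann$pairs$orientation)
  } else {
    tibble(i = integer(), j = integer(), edge_i = character(),
           edge_j = character(), orientation = character())
  }
  stacks <- if (nrow(ann$stacks) > 0L) {
    tibble(i = unname(idx[ann$stacks$rid_i]), j = unname(idx[ann$stacks$rid_j]),
           kind = ann$stacks$kind)
  } else {
    tibble(i = integer(), j = integer(), kind = character())
  }
  structure(
    list(motif_id = motif$motif_id,
         nucleotides = tibble(idx = seq_len(nrow(nts)), segment = nts$segment,
                              rid = nts$rid, base = nts$base),
         pairs = pairs, stacks = stacks),
    class = "interaction_graph"
  )
}

#' Score the match of two interactions
#'
#' Compares two interactions of the same kind under a given endpoint
#' correspondence-free convention: a base pair matches fully when the two
#' Leontis-Westhof classes agree, allowing the symmetric endpoint flip
#' (`tHS` equals `tSH` with swapped endpoints); it matches partially when
#' only the orientation or only one edge agrees.  Two stackings match at
#' the stacking score; a pair against a stacking scores 0.
#'
#' @param e_a,e_b single-row tibbles from an `interaction_graph` (`pairs`
#'   or `stacks` rows).
#' @param params an [interaction_params()] object.
#' @return score in score units.
#' @export
interaction_match_score <- function(e_a, e_b, params = interaction_params()) {
  a_pair <- "orientation" %in% names(e_a)
  b_pair <- "orientation" %in% names(e_b)
  if (a_pair != b_pair) return(0)
  if (!a_pair) return(params$stack)
  score_pair_match(e_a$edge_i, e_a$edge_j, e_a$orientation,
                   e_b$edge_i, e_b$edge_j, e_b$orientation,
                   params, allow_flip = TRUE)
}

# Endpoint-respecting pair-class comparison.  When allow_flip is TRUE the
# symmetric flip (swap both endpoints) is also accepted as a full match.
score_pair_match <- function(ea1, ea2, oa, eb1, eb2, ob, params,
                             allow_flip = FALSE) {
  full <- (oa == ob) && (ea1 == eb1) && (ea2 == eb2)
  if (!full && allow_flip) full <- (oa == ob) && (ea1 == eb2) && (ea2 == eb1)
  if (full) return(params$pair_full)
  partial <- (oa == ob) || (ea1 == eb1) || (ea2 == eb2)
  if (partial) return(params$pair_partial)
  0
}

# Enumerate the segment correspondences to try: with equal segment counts,
# all cyclic rotations of B's segments; otherwise all order-preserving
# injections of the smaller motif's segments into the larger's.
segment_mappings <- function(nseg_a, nseg_b) {
  if (nseg_a == nseg_b) {
    lapply(seq_len(nseg_a) - 1L, function(r) {
      ((seq_len(nseg_a) - 1L + r) %% nseg_a) + 1L
    })
  } else if (nseg_a < nseg_b) {
    combn(nseg_b, nseg_a, simplify = FALSE)
  } else {
    # map every segment of A somewhere is impossible; align the A segments
    # that fit, leaving the rest unmatched: choose which A segments map.
    sel <- combn(nseg_a, nseg_b, simplify = FALSE)
    lapply(sel, function(s) {
      m <- rep(NA_integer_, nseg_a)
      m[s] <- seq_len(nseg_b)
      m
    })
  }
}

#' Build the match-compatibility graph for two interaction graphs
#'
#' Vertices are candidate nucleotide matches `(u, v)`; two candidates are
#' compatible (connected) when they use distinct nucleotides on both sides
#' and preserve the within-segment order.  Vertex weights carry the
#' sequence bonus, auxiliary edge weights carry the interaction-match
#' score of the interactions the two candidates would superpose.
#'
#' @param A,B `interaction_graph` objects.
#' @param params an [interaction_params()] object.
#' @param seg_map integer vector mapping segments of `A` to segments of
#'   `B` (NA = segment unmatched); defaults to the identity.
#' @return list with `vertices` (tibble `u`, `v`, `weight`), `adj`
#'   (logical matrix) and `ew` (numeric matrix of edge weights).
#' @export
build_compatibility_graph <- function(A, B, params = interaction_params(),
                                      seg_map = NULL) {
  na <- nrow(A$nucleotides); nb <- nrow(B$nucleotides)
  if (na == 0L || nb == 0L) abort("empty interaction graph")
  nseg_a <- max(A$nucleotides$segment)
  seg_map <- seg_map %||% seq_len(nseg_a)
  seg_a <- A$nucleotides$segment
  seg_b <- B$nucleotides$segment

  inter_a <- unique(c(A$pairs$i, A$pairs$j, A$stacks$i, A$stacks$j))
  inter_b <- unique(c(B$pairs$i, B$pairs$j, B$stacks$i, B$stacks$j))

  cand <- list()
  for (u in seq_len(na)) {
    sv <- seg_map[seg_a[u]]
    if (is.na(sv)) next
    for (v in which(seg_b == sv)) {
      wgt <- if (A$nucleotides$base[u] == B$nucleotides$base[v])
        params$seq_match else params$seq_mismatch
      # candidates that can never contribute positively are dropped
      if (wgt < 0 && !(u %in% inter_a && v %in% inter_b)) next
      cand[[length(cand) + 1L]] <- c(u, v, wgt)
    }
  }
  if (length(cand) == 0L) {
    return(list(vertices = tibble(u = integer(), v = integer(),
                                  weight = numeric()),
                adj = matrix(FALSE, 0, 0), ew = matrix(0, 0, 0)))
  }
  cm <- do.call(rbind, cand)
  verts <- tibble(u = as.integer(cm[, 1]), v = as.integer(cm[, 2]),
                  weight = cm[, 3])
  nv <- nrow(verts)

  # compatibility: distinct nucleotides on both sides; within a segment
  # pair the matching must not cross (B segments are tied to A segments by
  # seg_map, so same-segment on one side implies same-segment on the other)
  du <- outer(verts$u, verts$u, "-")
  dv <- outer(verts$v, verts$v, "-")
  same_seg <- outer(seg_a[verts$u], seg_a[verts$u], "==")
  adj <- du != 0L & dv != 0L & !(same_seg & (sign(du) != sign(dv)))

  # auxiliary edge weights: only vertex pairs whose underlying nucleotide
  # pairs both carry an interaction can score, so iterate interactions
  ew <- matrix(0, nv, nv)
  vidx <- matrix(0L, na, nb)
  vidx[cbind(verts$u, verts$v)] <- seq_len(nv)
  ints_a <- gather_interactions(A)
  ints_b <- gather_interactions(B)
  if (nrow(ints_a) > 0L && nrow(ints_b) > 0L) {
    for (r in seq_len(nrow(ints_a))) {
      for (s in seq_len(nrow(ints_b))) {
        if (ints_a$kind[r] != ints_b$kind[s]) next
        for (flip in c(FALSE, TRUE)) {
          k <- if (flip) ints_b$j[s] else ints_b$i[s]
          l <- if (flip) ints_b$i[s] else ints_b$j[s]
          p <- vidx[ints_a$i[r], k]; q <- vidx[ints_a$j[r], l]
          if (p == 0L || q == 0L || !adj[p, q]) next
          sc <- if (ints_a$kind[r] == "stack") params$stack else
            score_pair_match(ints_a$edge_i[r], ints_a$edge_j[r],
                             ints_a$orientation[r],
                             if (flip) ints_b$edge_j[s] else ints_b$edge_i[s],
                             if (flip) ints_b$edge_i[s] else ints_b$edge_j[s],
                             ints_b$orientation[s], params)
          if (sc > ew[p, q]) { ew[p, q] <- sc; ew[q, p] <- sc }
        }
      }
    }
  }
  list(vertices = verts, adj = adj, ew = ew)
}

# Flat table of a graph's interactions (pairs and stacks together).
gather_interactions <- function(G) {
  bind_rows(
    if (nrow(G$pairs) > 0L)
      tibble(i = G$pairs$i, j = G$pairs$j, kind = "pair",
             edge_i = G$pairs$edge_i, edge_j = G$pairs$edge_j,
             orientation = G$pairs$orientation),
    if (nrow(G$stacks) > 0L)
      tibble(i = G$stacks$i, j = G$stacks$j, kind = "stack",
             edge_i = NA_character_, edge_j = NA_character_,
             orientation = NA_character_)
  ) %||% tibble(i = integer(), j = integer(), kind = character(),
                edge_i = character(), edge_j = character(),
                orientation = character())
}

#' Align two base-interaction graphs
#'
#' Local, order-aware alignment of two motifs' interaction graphs: the
#' match-compatibility graph is built for every admissible segment
#' correspondence and the maximum-weight clique (vertex weights = sequence
#' bonuses, edge weights = interaction-match scores) gives the optimal set
#' of nucleotide matches.  The search is exact branch-and-bound for the
#' motif sizes in scope; `params$greedy = TRUE` switches to a heuristic.
#' Ties are broken toward larger aligned length, then toward the
#' lexicographically smallest match set, so results are deterministic.
#'
#' @param A,B `interaction_graph` objects.
#' @param params an [interaction_params()] object.
#' @return an object of class `interaction_alignment`: list with `matches`
#'   (tibble `u`, `v`), `score`, `aligned_length`, `matched_pairs`,
#'   `matched_stacks`.
#' @export
align_interactions <- function(A, B, params = interaction_params()) {
  empty <- structure(list(matches = tibble(u = integer(), v = integer()),
                          score = 0, aligned_length = 0L,
                          matched_pairs = 0L, matched_stacks = 0L),
                     class = "interaction_alignment")
  if (nrow(A$nucleotides) == 0L || nrow(B$nucleotides) == 0L) return(empty)
  nseg_a <- max(A$nucleotides$segment)
  nseg_b <- max(B$nucleotides$segment)
  maps <- segment_mappings(nseg_a, nseg_b)
  best <- NULL
  for (m in maps) {
    g <- build_compatibility_graph(A, B, params, seg_map = m)
    if (nrow(g$vertices) == 0L) next
    res <- .cpp_max_weight_clique(g$vertices$weight,
                                  matrix(as.integer(g$adj), nrow(g$adj)),
                                  g$ew, g$vertices$u, g$vertices$v,
                                  greedy = params$greedy)
    matches <- g$vertices[res$vertices, c("u", "v")]
    matches <- arrange(matches, .data$u)
    cand <- list(matches = matches, score = res$score)
    if (is.null(best) || alignment_better(cand, best)) best <- cand
  }
  if (is.null(best) || nrow(best$matches) == 0L) return(empty)
  counts <- count_matched_interactions(A, B, best$matches, params)
  structure(list(matches = best$matches, score = best$score,
                 aligned_length = nrow(best$matches),
                 matched_pairs = counts$pairs,
                 matched_stacks = counts$stacks),
            class = "interaction_alignment")
}

alignment_better <- function(a, b, eps = 1e-9) {
  if (a$score > b$score + eps) return(TRUE)
  if (a$score < b$score - eps) return(FALSE)
  if (nrow(a$matches) != nrow(b$matches)) {
    return(nrow(a$matches) > nrow(b$matches))
  }
  # lexicographic on the (u, v) sequence
  av <- as.vector(t(as.matrix(a$matches)))
  bv <- as.vector(t(as.matrix(b$matches)))
  d <- which(av != bv)
  length(d) > 0L && av[d[1]] < bv[d[1]]
}

# Count matched base pairs (class-compatible only) and stackings carried
# by a match set.
count_matched_interactions <- function(A, B, matches,
                                       params = interaction_params()) {
  if (nrow(matches) < 2L) return(list(pairs = 0L, stacks = 0L))
  v_of_u <- setNames(matches$v, matches$u)
  npair <- 0L; nstk <- 0L
  if (nrow(A$pairs) > 0L && nrow(B$pairs) > 0L) {
    bkey <- paste(pmin(B$pairs$i, B$pairs$j), pmax(B$pairs$i, B$pairs$j))
    for (r in seq_len(nrow(A$pairs))) {
      ui <- A$pairs$i[r]; uj <- A$pairs$j[r]
      if (!(as.character(ui) %in% names(v_of_u)) ||
          !(as.character(uj) %in% names(v_of_u))) next
      vi <- v_of_u[[as.character(ui)]]; vj <- v_of_u[[as.character(uj)]]
      s <- which(bkey == paste(min(vi, vj), max(vi, vj)))
      if (length(s) == 0L) next
      s <- s[1]
      # orient the B pair along the mapping (ui -> vi, uj -> vj)
      eb1 <- if (B$pairs$i[s] == vi) B$pairs$edge_i[s] else B$pairs$edge_j[s]
      eb2 <- if (B$pairs$i[s] == vi) B$pairs$edge_j[s] else B$pairs$edge_i[s]
      sc <- score_pair_match(A$pairs$edge_i[r], A$pairs$edge_j[r],
                             A$pairs$orientation[r], eb1, eb2,
                             B$pairs$orientation[s], params)
      if (sc > 0) npair <- npair + 1L
    }
  }
  if (nrow(A$stacks) > 0L && nrow(B$stacks) > 0L) {
    bkey <- paste(pmin(B$stacks$i, B$stacks$j), pmax(B$stacks$i, B$stacks$j))
    for (r in seq_len(nrow(A$stacks))) {
      ui <- A$stacks$i[r]; uj <- A$stacks$j[r]
      if (!(as.character(ui) %in% names(v_of_u)) ||
          !(as.character(uj) %in% names(v_of_u))) next
      vi <- v_of_u[[as.character(ui)]]; vj <- v_of_u[[as.character(uj)]]
      if (paste(min(vi, vj), max(vi, vj)) %in% bkey) nstk <- nstk + 1L
    }
  }
  list(pairs = npair, stacks = nstk)
}

#' @export
print.interaction_alignment <- function(x, ...) {
  cat(sprintf("<interaction_alignment> %d nt matched, score %.3f, %d pairs, %d stacks\n",
              x$aligned_length, x$score, x$matched_pairs, x$matched_stacks))
  invisible(x)
}
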