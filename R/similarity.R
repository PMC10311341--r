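#' RMSD over aligned nucleotides
#'
#' For every matched nucleotide pair, collects the heavy atoms of the
#' backbone and the ribose sugar, reduces each nucleotide to the centroid
#' of those atoms, superposes the two centroid sets by least squares, and
#' returns `sqrt(mean(delta_i^2))` over the matched centroid pairs.
#' Nucleotides without any in-scope atom are skipped pairwise with a
#' warning.  With a single usable centroid pair the RMSD is 0 (a point can
#' always be superposed exactly); with two pairs it is the residual of the
#' optimal superposition of two segments, `|d_A - d_B| / 2`.
#'
#' @param matches tibble or matrix with matched nucleotide indices
#'   (`u` into `motifA`, `v` into `motifB`).
#' @param motifA,motifB `rna_motif` objects.
#' @param atom_scope atom names defining the centroid scope.
#' @return RMSD in Angstrom.
#' @export
aligned_rmsd <- function(matches, motifA, motifB,
                         atom_scope = BACKBONE_RIBOSE_ATOMS) {
  m <- as.matrix(matches)
  if (nrow(m) < 1L) abort("undefined RMSD: no matched nucleotides")
  ca <- motif_centroids(motifA, atom_scope, quiet = TRUE)
  cb <- motif_centroids(motifB, atom_scope, quiet = TRUE)
  ok <- is.finite(ca[m[, 1], 1]) & is.finite(cb[m[, 2], 1])
  if (!all(ok)) {
    warn(sprintf("aligned_rmsd: %d matched nucleotide(s) without usable atoms skipped",
                 sum(!ok)))
  }
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0L) abort("undefined RMSD: zero usable atoms")
  P <- ca[m[, 1], , drop = FALSE]
  Q <- cb[m[, 2], , drop = FALSE]
  if (nrow(m) == 1L) return(0)
  if (nrow(m) == 2L) {
    dA <- sqrt(sum((P[1, ] - P[2, ])^2))
    dB <- sqrt(sum((Q[1, ] - Q[2, ])^2))
    return(abs(dA - dB) / 2)
  }
  kabsch(P, Q)$rmsd
}

#' All-pairs alignment records for a motif set
#'
#' Runs pairwise alignments (one mode) over every unordered motif pair and
#' returns one record per pair: the unit of all downstream similarity
#' statistics.
#'
#' @param motifs named list of `rna_motif` objects.
#' @param annotations named list of `annotation_set` objects keyed by
#'   structure id (`pdb_id`); required for interaction mode.
#' @param mode `"interaction"` or `"coordinate"`.
#' @param iparams,cparams scoring parameter objects.
#' @param progress emit a progress message every few hundred pairs.
#' @return a tibble of pair records: `motif_a`, `motif_b`, `family_a`,
#'   `family_b`, `mode`, `aligned_length`, `rmsd`, `score_or_tm`,
#'   `matched_pairs`, `matched_stacks`.
#' @export
align_motif_pairs <- function(motifs, annotations = NULL,
                              mode = c("interaction", "coordinate"),
                              iparams = interaction_params(),
                              cparams = coordinate_params(),
                              progress = FALSE) {
  mode <- match.arg(mode)
  ids <- names(motifs)
  stopifnot(!is.null(ids), anyDuplicated(ids) == 0L)
  graphs <- NULL
  if (mode == "interaction") {
    graphs <- map(motifs, function(m) {
      ann <- annotations[[m$pdb_id]]
      if (is.null(ann)) ann <- annotation_set(m$pdb_id)
      interaction_graph(m, ann)
    })
  }
  cmb <- combn(length(motifs), 2L)
  rows <- vector("list", ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    rows[[k]] <- align_pair_record(motifs[[i]], motifs[[j]], mode,
                                   graphs[[i]], graphs[[j]],
                                   iparams, cparams)
    if (progress && k %% 250L == 0L) {
      inform(sprintf("aligned %d / %d pairs (%s mode)", k, ncol(cmb), mode))
    }
  }
  bind_rows(rows)
}

align_pair_record <- function(ma, mb, mode, ga = NULL, gb = NULL,
                              iparams = interaction_params(),
                              cparams = coordinate_params()) {
  if (mode == "interaction") {
    al <- align_interactions(ga, gb, iparams)
    rmsd <- if (al$aligned_length >= 1L)
      aligned_rmsd(al$matches, ma, mb) else NA_real_
    tibble(motif_a = ma$motif_id, motif_b = mb$motif_id,
           family_a = ma$family, family_b = mb$family, mode = mode,
           aligned_length = al$aligned_length, rmsd = rmsd,
           score_or_tm = al$score,
           matched_pairs = al$matched_pairs,
           matched_stacks = al$matched_stacks)
  } else {
    al <- align_coordinates(ma, mb, cparams)
    rmsd <- if (al$aligned_length >= 1L)
      aligned_rmsd(al$matches, ma, mb) else NA_real_
    tibble(motif_a = ma$motif_id, motif_b = mb$motif_id,
           family_a = ma$family, family_b = mb$family, mode = mode,
           aligned_length = al$aligned_length, rmsd = rmsd,
           score_or_tm = al$tm_score,
           matched_pairs = NA_integer_, matched_stacks = NA_integer_)
  }
}

intra_records <- function(records, family = NULL) {
  out <- filter(records, .data$family_a == .data$family_b)
  if (!is.null(family)) out <- filter(out, .data$family_a == family)
  out
}

#' Z-score outlier filter within families
#'
#' For each instance of a family, summarises how well it aligns with its
#' same-family partners (mean alignment score in interaction mode, mean
#' TM-score in coordinate mode, i.e. the `score_or_tm` column), converts
#' the summaries to z-scores within the family, and flags instances with
#' `z < cutoff` as removed.  Families with fewer than 3 instances are
#' skipped; zero-variance families produce no removals (with a warning).
#'
#' @param records pair-record tibble (intra-family rows are used).
#' @param cutoff z-score cutoff (default -2).
#' @return a tibble with `motif_id`, `family`, `summary`, `zscore`,
#'   `removed`.
#' @export
zscore_filter <- function(records, cutoff = -2) {
  intra <- intra_records(records)
  fams <- unique(c(intra$family_a))
  out <- map(fams, function(f) {
    rec <- filter(intra, .data$family_a == f)
    ids <- sort(unique(c(rec$motif_a, rec$motif_b)))
    if (length(ids) < 3L) {
      return(tibble(motif_id = ids, family = f, summary = NA_real_,
                    zscore = NA_real_, removed = FALSE))
    }
    summ <- map_dbl(ids, function(id) {
      mean(rec$score_or_tm[rec$motif_a == id | rec$motif_b == id])
    })
    sdv <- sd(summ)
    if (!is.finite(sdv) || sdv < 1e-12) {
      warn(sprintf("family %s: zero variance in alignment summaries; no outliers removed", f))
      z <- rep(0, length(ids))
    } else {
      z <- (summ - mean(summ)) / sdv
    }
    tibble(motif_id = ids, family = f, summary = summ, zscore = z,
           removed = is.finite(z) & z < cutoff & sdv >= 1e-12)
  })
  bind_rows(out)
}

#' Family-specific alignment-length thresholds
#'
#' The threshold of a family is the arithmetic mean of `aligned_length`
#' over all unordered intra-family pairs (after outlier filtering).  An
#' inter-family pair later qualifies only if its aligned length meets the
#' thresholds of both families.  Singleton families have no intra pair and
#' hence an undefined threshold; pairs involving them never qualify.
#'
#' @param records pair-record tibble (intra-family rows are used).
#' @return tibble with `family`, `length_threshold`, `n_pairs`,
#'   `n_instances`.
#' @export
family_length_threshold <- function(records) {
  intra <- intra_records(records)
  if (nrow(intra) == 0L) {
    return(tibble(family = character(), length_threshold = numeric(),
                  n_pairs = integer(), n_instances = integer()))
  }
  intra %>%
    group_by(family = .data$family_a) %>%
    summarise(length_threshold = mean(.data$aligned_length),
              n_pairs = n(),
              n_instances = length(unique(c(.data$motif_a, .data$motif_b))),
              .groups = "drop")
}

#' Select the best-aligned inter-family pairs
#'
#' Keeps the records whose aligned length is at least both families'
#' length thresholds and whose RMSD is at or below the cutoff.
#'
#' @param records inter-family pair records for one family pair and mode.
#' @param thresholds output of [family_length_threshold()].
#' @param rmsd_cutoff RMSD cutoff in Angstrom.
#' @return the qualifying subset of `records`.
#' @export
select_best_pairs <- function(records, thresholds, rmsd_cutoff) {
  if (nrow(records) == 0L) return(records)
  thr <- setNames(thresholds$length_threshold, thresholds$family)
  ta <- unname(thr[records$family_a])
  tb <- unname(thr[records$family_b])
  keep <- !is.na(ta) & !is.na(tb) &
    records$aligned_length >= pmax(ta, tb) &
    !is.na(records$rmsd) & records$rmsd <= rmsd_cutoff
  records[keep, , drop = FALSE]
}

#' Participation percentages of a family pair
#'
#' The participation of a family is the percentage of its instances that
#' appear in at least one qualifying best-aligned pair; the edge label is
#' the minimum of the two percentages.
#'
#' @param best_pairs qualifying records for one family pair.
#' @param size_a,size_b family sizes (post-filter instance counts).
#' @return tibble with `pct_a`, `pct_b`, `label_pct`, `n_a`, `n_b`.
#' @export
participation <- function(best_pairs, size_a, size_b) {
  stopifnot(size_a >= 1, size_b >= 1)
  if (nrow(best_pairs) == 0L) {
    return(tibble(pct_a = 0, pct_b = 0, label_pct = 0, n_a = 0L, n_b = 0L))
  }
  fa <- best_pairs$family_a[1]
  ids_a <- unique(c(best_pairs$motif_a[best_pairs$family_a == fa],
                    best_pairs$motif_b[best_pairs$family_b == fa]))
  fb <- setdiff(unique(c(best_pairs$family_a, best_pairs$family_b)), fa)
  fb <- if (length(fb) == 0L) fa else fb[1]
  ids_b <- unique(c(best_pairs$motif_a[best_pairs$family_a == fb],
                    best_pairs$motif_b[best_pairs$family_b == fb]))
  pct_a <- 100 * length(ids_a) / size_a
  pct_b <- 100 * length(ids_b) / size_b
  tibble(pct_a = pct_a, pct_b = pct_b, label_pct = min(pct_a, pct_b),
         n_a = length(ids_a), n_b = length(ids_b))
}

#' Build the family similarity graph
#'
#' For every unordered family pair, selects the best-aligned pairs
#' (length thresholds and RMSD cutoff), computes participation
#' percentages, and derives the edge: solid when the minimum participation
#' is at least `pct_threshold`, dotted when it is positive but below the
#' threshold, absent when no pair qualifies.  Edges carry the unweighted
#' mean RMSD and mean aligned length over the selected pairs.
#'
#' @param records pair-record tibble for one mode (post outlier filter).
#' @param family_sizes named integer vector of post-filter family sizes.
#' @param mode `"interaction"` or `"coordinate"`.
#' @param rmsd_cutoff RMSD cutoff in Angstrom (defaults: 1.0 for
#'   interaction mode, 1.5 for coordinate mode).
#' @param pct_threshold participation percentage required for a solid
#'   edge (default 20).
#' @param thresholds optionally precomputed [family_length_threshold()]
#'   output.
#' @return an object of class `similarity_graph`: list with `nodes`
#'   (tibble `family`, `n_instances`), `edges` (tibble `family_a`,
#'   `family_b`, `n_pairs`, `avg_rmsd`, `avg_length`, `pct_a`, `pct_b`,
#'   `label_pct`, `status`), `mode`, `parameters`.
#' @export
build_similarity_graph <- function(records, family_sizes,
                                   mode = c("interaction", "coordinate"),
                                   rmsd_cutoff = NULL, pct_threshold = 20,
                                   thresholds = NULL) {
  mode <- match.arg(mode)
  rmsd_cutoff <- rmsd_cutoff %||% if (mode == "interaction") 1.0 else 1.5
  fams <- sort(names(family_sizes))
  if (length(fams) < 2L) abort("need at least 2 families to build a graph")
  thresholds <- thresholds %||% family_length_threshold(records)
  edges <- list()
  cmb <- combn(fams, 2L)
  for (k in seq_len(ncol(cmb))) {
    fa <- cmb[1, k]; fb <- cmb[2, k]
    rec <- filter(records,
                  (.data$family_a == fa & .data$family_b == fb) |
                    (.data$family_a == fb & .data$family_b == fa))
    sel <- select_best_pairs(rec, thresholds, rmsd_cutoff)
    if (nrow(sel) == 0L) next
    # participation with family_a := fa
    part <- participation_named(sel, fa, fb,
                                family_sizes[[fa]], family_sizes[[fb]])
    status <- if (part$label_pct >= pct_threshold) "solid" else "dotted"
    edges[[length(edges) + 1L]] <- tibble(
      family_a = fa, family_b = fb, n_pairs = nrow(sel),
      avg_rmsd = mean(sel$rmsd), avg_length = mean(sel$aligned_length),
      pct_a = part$pct_a, pct_b = part$pct_b, label_pct = part$label_pct,
      status = status
    )
  }
  edges <- if (length(edges) > 0L) bind_rows(edges) else
    tibble(family_a = character(), family_b = character(),
           n_pairs = integer(), avg_rmsd = numeric(), avg_length = numeric(),
           pct_a = numeric(), pct_b = numeric(), label_pct = numeric(),
           status = character())
  structure(
    list(nodes = tibble(family = fams,
                        n_instances = as.integer(family_sizes[fams])),
         edges = edges, mode = mode,
         parameters = list(rmsd_cutoff = rmsd_cutoff,
                           pct_threshold = pct_threshold)),
    class = "similarity_graph"
  )
}

participation_named <- function(best_pairs, fa, fb, size_a, size_b) {
  ids_a <- unique(c(best_pairs$motif_a[best_pairs$family_a == fa],
                    best_pairs$motif_b[best_pairs$family_b == fa]))
  ids_b <- unique(c(best_pairs$motif_a[best_pairs$family_a == fb],
                    best_pairs$motif_b[best_pairs$family_b == fb]))
  pct_a <- 100 * length(ids_a) / size_a
  pct_b <- 100 * length(ids_b) / size_b
  list(pct_a = pct_a, pct_b = pct_b, label_pct = min(pct_a, pct_b))
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %s mode: %d families, %d edge(s) (%d solid)\n",
              x$mode, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$status == "solid")))
  if (nrow(x$edges) > 0L) {
    e <- x$edges
    cat(sprintf("  %s -- %s  [%s]  %.2f A / %.1f nt / %.1f%%\n",
                e$family_a, e$family_b, e$status, e$avg_rmsd, e$avg_length,
                e$label_pct), sep = "")
  }
  invisible(x)
}

#' Solid edges of a similarity graph
#' @param g a `similarity_graph`.
#' @return tibble of solid edges.
#' @export
solid_edges <- function(g) filter(g$edges, .data$status == "solid")
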