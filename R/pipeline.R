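#' Compare motif families end to end
#'
#' The full similarity analysis for one viewpoint: align every motif pair,
#' filter family outliers by z-score, derive the family-specific
#' alignment-length thresholds, select the best-aligned inter-family
#' pairs under the RMSD cutoff, and build the labeled similarity graph.
#'
#' @param corpus a list with `motifs` (named list of `rna_motif`) and
#'   `annotations` (named list of `annotation_set`), e.g. from
#'   [read_motif_corpus()].
#' @param mode `"interaction"` or `"coordinate"`.
#' @param rmsd_cutoff RMSD cutoff in Angstrom; defaults to 1.0
#'   (interaction) or 1.5 (coordinate) -- the coordinate cutoff is looser
#'   because the global alignment includes weakly superposable positions
#'   that a local alignment would leave out.
#' @param pct_threshold participation percentage for a solid edge.
#' @param zscore_cutoff z-score below which a family instance is removed
#'   as an outlier.
#' @param iparams,cparams alignment parameter objects.
#' @param records optionally precomputed pair records (skips alignment).
#' @param progress print stage messages.
#' @return an object of class `motif_comparison`: list with `records`
#'   (all pair records), `outliers`, `kept_records`, `thresholds`,
#'   `family_sizes`, `graph` (a `similarity_graph`), `mode`, `parameters`.
#' @export
compare_motif_families <- function(corpus,
                                   mode = c("interaction", "coordinate"),
                                   rmsd_cutoff = NULL, pct_threshold = 20,
                                   zscore_cutoff = -2,
                                   iparams = interaction_params(),
                                   cparams = coordinate_params(),
                                   records = NULL, progress = FALSE) {
  mode <- match.arg(mode)
  rmsd_cutoff <- rmsd_cutoff %||% if (mode == "interaction") 1.0 else 1.5
  motifs <- corpus$motifs
  if (length(motifs) < 2L) abort("need at least 2 motifs")
  if (is.null(records)) {
    if (progress) inform(sprintf("aligning all pairs (%s mode)...", mode))
    records <- align_motif_pairs(motifs, corpus$annotations, mode,
                                 iparams, cparams, progress = progress)
  }
  outliers <- zscore_filter(records, cutoff = zscore_cutoff)
  removed <- outliers$motif_id[outliers$removed]
  kept <- filter(records, !(.data$motif_a %in% removed) &
                   !(.data$motif_b %in% removed))
  fam_tab <- tibble(motif_id = names(motifs),
                    family = map_chr(motifs, "family")) %>%
    filter(!(.data$motif_id %in% removed))
  family_sizes <- table(fam_tab$family)
  family_sizes <- setNames(as.integer(family_sizes), names(family_sizes))
  thresholds <- family_length_threshold(kept)
  graph <- build_similarity_graph(kept, family_sizes, mode,
                                  rmsd_cutoff, pct_threshold, thresholds)
  structure(
    list(records = records, outliers = outliers, kept_records = kept,
         thresholds = thresholds, family_sizes = family_sizes,
         graph = graph, mode = mode,
         parameters = list(rmsd_cutoff = rmsd_cutoff,
                           pct_threshold = pct_threshold,
                           zscore_cutoff = zscore_cutoff)),
    class = "motif_comparison"
  )
}

#' @export
print.motif_comparison <- function(x, ...) {
  cat(sprintf("<motif_comparison> %s mode: %d families, %d pair records, %d outlier(s) removed\n",
              x$mode, length(x$family_sizes), nrow(x$records),
              sum(x$outliers$removed)))
  print(x$graph)
  invisible(x)
}

#' Tidy a motif comparison
#' @param x a `motif_comparison`.
#' @param ... unused.
#' @return the similarity-graph edge tibble, one row per family pair.
#' @export
tidy.motif_comparison <- function(x, ...) {
  mutate(x$graph$edges, mode = x$mode)
}

#' One-row summary of a motif comparison
#' @param x a `motif_comparison`.
#' @param ... unused.
#' @return tibble with counts and parameters.
#' @export
glance.motif_comparison <- function(x, ...) {
  tibble(mode = x$mode, n_families = length(x$family_sizes),
         n_records = nrow(x$records),
         n_outliers_removed = sum(x$outliers$removed),
         n_edges = nrow(x$graph$edges),
         n_solid = sum(x$graph$edges$status == "solid"),
         rmsd_cutoff = x$parameters$rmsd_cutoff,
         pct_threshold = x$parameters$pct_threshold)
}

#' Tidy a similarity graph
#' @param x a `similarity_graph`.
#' @param ... unused.
#' @return the edge tibble.
#' @export
tidy.similarity_graph <- function(x, ...) x$edges

#' Write all comparison outputs to a directory
#'
#' Emits the similarity graph in all three formats, one similar-instance
#' TSV per family pair with qualifying pairs, and a JSON run report
#' (parameters, outliers, thresholds).
#'
#' @param comparison a `motif_comparison`.
#' @param dir output directory.
#' @return (invisibly) the directory.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- comparison$graph
  base <- file.path(dir, paste0("similarity_", comparison$mode))
  export_graph(g, paste0(base, ".dot"), "DOT")
  export_graph(g, paste0(base, ".graphml"), "GraphML")
  export_graph(g, paste0(base, ".json"), "JSON")
  thr <- comparison$thresholds
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k, ]
    rec <- filter(comparison$kept_records,
                  (.data$family_a == e$family_a & .data$family_b == e$family_b) |
                    (.data$family_a == e$family_b & .data$family_b == e$family_a))
    sel <- select_best_pairs(rec, thr, comparison$parameters$rmsd_cutoff)
    write_similar_instances(
      sel, file.path(dir, sprintf("similar_%s_%s_%s.tsv", comparison$mode,
                                  e$family_a, e$family_b)))
  }
  report <- list(
    mode = comparison$mode,
    parameters = comparison$parameters,
    family_sizes = as.list(comparison$family_sizes),
    thresholds = comparison$thresholds,
    outliers_removed = comparison$outliers$motif_id[comparison$outliers$removed],
    n_records = nrow(comparison$records)
  )
  jsonlite::write_json(report, file.path(dir, paste0("report_",
                                                     comparison$mode, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
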