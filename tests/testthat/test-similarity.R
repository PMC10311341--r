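# Crafted pair-record tables: the unit the similarity statistics consume.
mk_records <- function(...) {
  dplyr::bind_rows(...)
}

rec <- function(a, b, fa, fb, len, rmsd, score = 1, mode = "interaction") {
  tibble::tibble(motif_a = a, motif_b = b, family_a = fa, family_b = fb,
                 mode = mode, aligned_length = len, rmsd = rmsd,
                 score_or_tm = score, matched_pairs = NA_integer_,
                 matched_stacks = NA_integer_)
}

test_that("aligned RMSD is zero on self, rigid-motion invariant, and oracle-exact", {
  set.seed(501)
  A <- motif_from_centers("a", "F", random_centers(6, 5))
  m <- tibble::tibble(u = 1:6, v = 1:6)
  expect_equal(aligned_rmsd(m, A, A), 0, tolerance = 1e-12)

  B <- rigid_transform_motif(A, random_rotation_matrix(), c(4, -2, 9))
  expect_equal(aligned_rmsd(m, A, B), 0, tolerance = 1e-9)

  # noisy partner: equals the independent numeric minimization over the
  # per-nucleotide backbone+ribose centroids
  C <- perturb(A, 0.5, seed = 2)
  got <- aligned_rmsd(m, A, C)
  P <- rnamotifsim:::motif_centroids(A)
  Q <- rnamotifsim:::motif_centroids(C)
  expect_lt(abs(got - oracle_min_rmsd(P, Q)), 1e-6)

  # 3-nt controlled case, verified against the same oracle
  D <- perturb(A, 1.0, seed = 3)
  m3 <- tibble::tibble(u = 1:3, v = 1:3)
  expect_lt(abs(aligned_rmsd(m3, A, D) -
                  oracle_min_rmsd(P[1:3, ], rnamotifsim:::motif_centroids(D)[1:3, ])),
            1e-6)

  expect_error(aligned_rmsd(m[0, ], A, A), "no matched nucleotides")
})

test_that("degenerate match counts have well-defined RMSD", {
  A <- motif_from_centers("a", "F", rbind(c(0, 0, 0), c(2, 0, 0), c(9, 4, 1)))
  B <- motif_from_centers("b", "F", rbind(c(5, 5, 5), c(5, 9, 5), c(0, 1, 2)))
  expect_equal(aligned_rmsd(tibble::tibble(u = 1L, v = 1L), A, B), 0)
  # two matches: residual of superposing two segments of lengths 2 and 4
  expect_equal(aligned_rmsd(tibble::tibble(u = 1:2, v = 1:2), A, B), 1)
})

test_that("z-score filtering removes exactly the planted low scorers", {
  ids <- sprintf("m%02d", 1:10)
  rows <- list()
  for (i in 1:9) for (j in (i + 1):10) {
    s <- if (i == 10 || j == 10) 0.3 else 0.9 + 0.001 * (i + j)
    rows[[length(rows) + 1L]] <- rec(ids[i], ids[j], "F", "F", 10, 0.2, s)
  }
  out <- zscore_filter(mk_records(!!!rows), cutoff = -2)
  expect_equal(out$motif_id[out$removed], "m10")
  expect_equal(sum(out$removed), 1L)
  expect_lt(out$zscore[out$motif_id == "m10"], -2)

  # identical instances: zero variance, warning, nothing removed
  same <- mk_records(!!!lapply(1:3, function(i)
    rec(ids[i], ids[i + 3], "G", "G", 10, 0.2, 1)))
  expect_warning(out2 <- zscore_filter(same), "zero variance")
  expect_false(any(out2$removed))

  # families of fewer than 3 instances are skipped
  two <- rec("a", "b", "H", "H", 10, 0.2, 1)
  out3 <- zscore_filter(two)
  expect_false(any(out3$removed))
  expect_true(all(is.na(out3$zscore)))
})

test_that("family length thresholds are intra-family means", {
  r <- mk_records(
    rec("a", "b", "F", "F", 8, 0.1), rec("a", "c", "F", "F", 10, 0.1),
    rec("b", "c", "F", "F", 12, 0.1),
    rec("x", "y", "G", "G", 7, 0.1),
    rec("a", "x", "F", "G", 9, 0.1)  # inter pair ignored
  )
  thr <- family_length_threshold(r)
  expect_equal(thr$length_threshold[thr$family == "F"], 10)
  expect_equal(thr$length_threshold[thr$family == "G"], 7)
  expect_equal(thr$n_instances[thr$family == "F"], 3L)
})

test_that("best-pair selection enforces both thresholds and the RMSD cutoff", {
  thr <- tibble::tibble(family = c("F", "G"), length_threshold = c(10, 11),
                        n_pairs = c(1L, 1L), n_instances = c(3L, 3L))
  r <- mk_records(
    rec("a", "x", "F", "G", 12, 0.8),
    rec("b", "y", "F", "G", 12, 1.2),
    rec("c", "z", "F", "G", 10.5, 0.5)
  )
  sel <- select_best_pairs(r, thr, rmsd_cutoff = 1.0)
  expect_equal(sel$motif_a, "a")  # len>=max(10,11) & rmsd<=1.0

  # raising the cutoff can only grow the selection
  sel15 <- select_best_pairs(r, thr, rmsd_cutoff = 1.5)
  expect_true(all(sel$motif_a %in% sel15$motif_a))
})

test_that("participation percentages match the published worked examples", {
  f <- system.file("extdata", "il_participation_counts.tsv",
                   package = "rnamotifsim")
  counts <- utils::read.delim(f, comment.char = "#")
  sizes <- utils::read.delim(system.file("extdata", "il_family_counts.tsv",
                                         package = "rnamotifsim"),
                             comment.char = "#")
  sz <- stats::setNames(sizes$n_instances, sizes$abbrev)

  mk_best <- function(na, nb, fa, fb) {
    dplyr::bind_rows(lapply(seq_len(max(na, nb)), function(k) {
      rec(sprintf("%s_%02d", fa, min(k, na)), sprintf("%s_%02d", fb, min(k, nb)),
          fa, fb, 10, 0.5)
    }))
  }
  # 13 of 49 E-loop vs 25 of 45 Tandem-shear -> label 26.5%
  p1 <- participation(mk_best(13, 25, "EL", "TS"), sz[["EL"]], sz[["TS"]])
  expect_equal(round(p1$label_pct, 1), 26.5)
  expect_equal(p1$label_pct, p1$pct_a)
  # 31 of 49 vs 10 of 45 -> label 22.2%
  p2 <- participation(mk_best(31, 10, "EL", "TS"), sz[["EL"]], sz[["TS"]])
  expect_equal(round(p2$label_pct, 1), 22.2)
  # 42 of 49 vs 25 of 34 -> label 73.5%
  p3 <- participation(mk_best(42, 25, "EL", "HT"), sz[["EL"]], sz[["HT"]])
  expect_equal(round(p3$label_pct, 1), 73.5)

  p0 <- participation(rec("a", "b", "F", "G", 1, 1)[0, ], 5, 5)
  expect_equal(c(p0$pct_a, p0$pct_b, p0$label_pct), c(0, 0, 0))
})

test_that("similarity graphs classify edges by participation threshold", {
  intra <- mk_records(
    !!!lapply(1:3, function(i) rec(sprintf("f%d", i), sprintf("f%d", i + 1),
                                   "F", "F", 10, 0.1)),
    !!!lapply(1:3, function(i) rec(sprintf("g%d", i), sprintf("g%d", i + 1),
                                   "G", "G", 10, 0.1))
  )
  inter <- mk_records(
    rec("f1", "g1", "F", "G", 10, 0.3), rec("f2", "g2", "F", "G", 10, 0.4),
    rec("f3", "g3", "F", "G", 10, 0.5), rec("f4", "g4", "F", "G", 10, 0.6)
  )
  sizes <- c(F = 4L, G = 4L)
  g <- build_similarity_graph(dplyr::bind_rows(intra, inter), sizes,
                              "interaction", rmsd_cutoff = 1.0)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$status, "solid")
  expect_equal(g$edges$label_pct, 100)
  expect_equal(g$edges$avg_rmsd, mean(c(0.3, 0.4, 0.5, 0.6)))

  # an unreachable participation threshold demotes every edge
  g2 <- build_similarity_graph(dplyr::bind_rows(intra, inter), sizes,
                               "interaction", rmsd_cutoff = 1.0,
                               pct_threshold = 101)
  expect_true(all(g2$edges$status == "dotted"))

  # input family order does not matter
  g3 <- build_similarity_graph(dplyr::bind_rows(inter, intra),
                               sizes[c("G", "F")], "interaction",
                               rmsd_cutoff = 1.0)
  expect_equal(g3$edges, g$edges)
})

test_that("graph exports are deterministic and round-trip through JSON", {
  intra <- mk_records(
    rec("f1", "f2", "F", "F", 10, 0.1), rec("g1", "g2", "G", "G", 10, 0.1),
    rec("h1", "h2", "H", "H", 10, 0.1))
  inter <- mk_records(rec("f1", "g1", "F", "G", 10, 0.3))
  g <- build_similarity_graph(dplyr::bind_rows(intra, inter),
                              c(F = 2L, G = 2L, H = 2L), "interaction", 1.0)

  dot1 <- tempfile(fileext = ".dot"); dot2 <- tempfile(fileext = ".dot")
  export_graph(g, dot1, "DOT"); export_graph(g, dot2, "DOT")
  expect_identical(readLines(dot1), readLines(dot2))
  txt <- readLines(dot1)
  expect_true(any(grepl("style=solid", txt)))
  expect_equal(sum(grepl("--", txt, fixed = TRUE)), 1L)

  gml <- tempfile(fileext = ".graphml")
  export_graph(g, gml, "GraphML")
  expect_true(any(grepl("edgedefault=\"undirected\"", readLines(gml))))

  js <- tempfile(fileext = ".json")
  export_graph(g, js, "JSON")
  back <- read_graph_json(js)
  expect_equal(back$edges, g$edges)
  expect_equal(back$nodes, g$nodes)
  expect_equal(back$mode, g$mode)

  expect_error(export_graph(g, tempfile(), "XML"), "unknown graph format")
})
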