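ann_file <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("both annotation dialects parse to canonical interaction tables", {
  d <- read_annotations(ann_file(c("# hdr",
                                   "pair A.10 A.25 tHS",
                                   "pair A.30 A.12 cWW",
                                   "stack A.10 A.11 upward")),
                        "DSSR", structure_id = "S1")
  expect_equal(nrow(d$pairs), 2L)
  expect_equal(nrow(d$stacks), 1L)
  # canonical order: residues swapped, edges follow
  swapped <- d$pairs[d$pairs$rid_i == "A.12", ]
  expect_equal(swapped$rid_j, "A.30")
  expect_equal(swapped$edge_i, "W")

  f <- read_annotations(ann_file(c("A.10 A.25 tHS", "A.10 A.11 s35")),
                        "FR3D", structure_id = "S1")
  expect_equal(f$pairs$orientation, "trans")
  expect_equal(f$stacks$kind, "upward")
  expect_equal(f$pairs$source, "FR3D")

  expect_error(read_annotations(ann_file("pair A.10 A.10 tHS"), "DSSR"),
               "itself")
  expect_error(read_annotations(ann_file("pair A.10 A.12 qXX"), "DSSR"),
               "malformed pair class")
})

test_that("merging agrees, unions, and resolves class conflicts by chain frequency", {
  mk <- function(lines, src) read_annotations(ann_file(lines), src, "S1")
  base <- c(sprintf("pair A.%d A.%d cWW", 1:5, 21:25))

  # identical inputs: idempotent union with joint source
  a <- mk(base, "DSSR"); b <- mk(sub("^pair ", "", base), "FR3D")
  m <- merge_annotations(a, b)
  expect_equal(nrow(m$pairs), 5L)
  expect_true(all(m$pairs$source == "DSSR+FR3D"))
  expect_equal(nrow(m$conflicts), 0L)

  # union: pair only in one source is kept
  a2 <- mk(c(base, "pair A.10 A.30 tHS"), "DSSR")
  m2 <- merge_annotations(a2, b)
  expect_equal(nrow(m2$pairs), 6L)
  expect_equal(m2$pairs$source[m2$pairs$rid_i == "A.10"], "DSSR")

  # conflict at one pair: the chain-wide more frequent class wins
  a3 <- mk(c(base, "pair A.10 A.30 cWW"), "DSSR")
  b3 <- mk(c(sub("^pair ", "", base), "A.10 A.30 tHS"), "FR3D")
  m3 <- merge_annotations(a3, b3)
  won <- m3$pairs[m3$pairs$rid_i == "A.10", ]
  expect_equal(paste0(substr(won$orientation, 1, 1), won$edge_i, won$edge_j),
               "cWW")
  expect_equal(m3$conflicts$kind, "pair_class")
  expect_equal(m3$conflicts$chosen, "cWW")

  # merging is deterministic
  m3b <- merge_annotations(a3, b3)
  expect_identical(m3$pairs, m3b$pairs)

  expect_error(merge_annotations(a, annotation_set("OTHER")),
               "different structures")
})

test_that("conflict resolution tie-breaks: joint source, then class label", {
  counts <- tibble::tibble(chain = "A", class = c("cWW", "tHS"), n = c(3L, 3L))
  grp <- dplyr::bind_rows(
    tibble::tibble(rid_i = "A.1", rid_j = "A.9", chain_i = "A", chain_j = "A",
                   edge_i = "H", edge_j = "S", orientation = "trans",
                   source = "DSSR"),
    tibble::tibble(rid_i = "A.1", rid_j = "A.9", chain_i = "A", chain_j = "A",
                   edge_i = "W", edge_j = "W", orientation = "cis",
                   source = "DSSR+FR3D")
  )
  win <- resolve_conflicts(list(grp), counts)[[1]]
  expect_equal(win$orientation, "cis")  # joint assertion beats single source

  grp$source <- c("DSSR", "FR3D")
  win2 <- resolve_conflicts(list(grp), counts)[[1]]
  # still tied: lexicographically smaller class label (cWW < tHS)
  expect_equal(win2$orientation, "cis")

  expect_error(resolve_conflicts(list(grp[1, ]), counts), "at least 2")
})

test_that("one nucleotide edge keeps a single partner after merging", {
  mk <- function(lines, src) read_annotations(ann_file(lines), src, "S1")
  base <- sprintf("pair A.%d A.%d cWW", 1:6, 21:26)
  # sugar edge of A.10 claimed for two different partners by the sources
  a <- mk(c(base, "pair A.10 A.40 tSS"), "DSSR")
  b <- mk(c(sub("^pair ", "", base), "A.10 A.50 cSW"), "FR3D")
  m <- merge_annotations(a, b)
  ep <- dplyr::bind_rows(
    tibble::tibble(rid = m$pairs$rid_i, edge = m$pairs$edge_i),
    tibble::tibble(rid = m$pairs$rid_j, edge = m$pairs$edge_j)
  )
  expect_equal(max(table(paste(ep$rid, ep$edge))), 1L)
  expect_true("edge_partner" %in% m$conflicts$kind)
})

test_that("stack kind conflicts resolve by the same frequency rule", {
  mk <- function(lines, src) read_annotations(ann_file(lines), src, "S1")
  a <- mk(c("stack A.1 A.2 upward", "stack A.2 A.3 upward",
            "stack A.3 A.4 upward"), "DSSR")
  b <- mk(c("A.1 A.2 s35", "A.2 A.3 s35", "A.3 A.4 s53"), "FR3D")
  m <- merge_annotations(a, b)
  expect_equal(nrow(m$stacks), 3L)
  k <- m$stacks$kind[m$stacks$rid_i == "A.3"]
  expect_equal(k, "upward")  # upward is the frequent kind chain-wide
  expect_true("stack_kind" %in% m$conflicts$kind)
})

test_that("per-motif interaction files carry the sequence and interaction lines", {
  ann <- read_annotations(ann_file(c("pair A.1 A.4 tHS", "stack A.1 A.2 upward")),
                          "DSSR", "S1")
  motif <- motif_from_centers("m", "F", random_centers(4),
                              bases = c("A", "G", "C", "U"),
                              segments = c(1L, 1L, 2L, 2L))
  f <- tempfile(fileext = ".txt")
  write_motif_interactions(motif, motif_interactions(ann, motif), f)
  lines <- readLines(f)
  expect_true(any(grepl("^>m F AG&CU$", lines)))
  expect_true(any(grepl("^pair A.1 A.4 tHS$", lines)))
  expect_true(any(grepl("^stack A.1 A.2 upward$", lines)))
})

test_that("motif restriction keeps only fully internal interactions", {
  ann <- read_annotations(ann_file(c("pair A.10 A.25 tHS",
                                     "pair A.10 A.99 cWW",
                                     "stack A.10 A.11 upward",
                                     "stack A.25 A.99 s35")),
                          "DSSR", "S1")
  motif <- motif_from_centers("m", "F", random_centers(4),
                              bases = c("A", "G", "C", "U"))
  motif$nucleotides$seq_num <- c(10L, 11L, 25L, 26L)
  motif$nucleotides$rid <- sprintf("A.%d", motif$nucleotides$seq_num)
  sub <- motif_interactions(ann, motif)
  expect_equal(nrow(sub$pairs), 1L)
  expect_equal(sub$pairs$rid_j, "A.25")
  expect_equal(nrow(sub$stacks), 1L)

  empty_motif <- motif_from_centers("m2", "F", random_centers(3))
  empty_motif$nucleotides$seq_num <- c(70L, 71L, 72L)
  empty_motif$nucleotides$rid <- sprintf("A.%d", 70:72)
  sub2 <- motif_interactions(ann, empty_motif)
  expect_equal(nrow(sub2$pairs), 0L)
  expect_equal(nrow(sub2$stacks), 0L)
})
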