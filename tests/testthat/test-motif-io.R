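test_that("motif location parsing filters, splits ranges, and validates", {
  f <- withr::local_tempfile(fileext = ".in")
  writeLines(c("# comment",
               "EL 1ABC A 10-14,30-33",
               "SR 2XYZ B 5-9"), f)
  stubs <- parse_motif_locations(f)
  expect_equal(nrow(stubs), 2L)
  expect_equal(stubs$family, c("EL", "SR"))
  rng <- stubs$ranges[[1]]
  expect_equal(nrow(rng), 2L)
  expect_equal(rng$end - rng$start + 1L, c(5L, 4L))

  only_el <- parse_motif_locations(f, family_filter = "EL")
  expect_equal(only_el$family, "EL")

  # idempotent and order-stable
  expect_identical(parse_motif_locations(f)[, 1:4], stubs[, 1:4])

  dup <- withr::local_tempfile(fileext = ".in")
  writeLines(c("m1 EL 1ABC A 10-14", "m1 EL 1ABC A 10-14"), dup)
  expect_error(parse_motif_locations(dup), "duplicated motif_id.*m1")

  bad <- withr::local_tempfile(fileext = ".in")
  writeLines("EL 1ABC A 10-14,x-9", bad)
  expect_error(parse_motif_locations(bad), "malformed residue range")

  empty <- withr::local_tempfile(fileext = ".in")
  writeLines("# nothing", empty)
  expect_warning(res <- parse_motif_locations(empty), "empty")
  expect_equal(nrow(res), 0L)
})

test_that("structures load identically from PDB and mmCIF, with HETATM flags", {
  set.seed(11)
  n <- 6L
  offs <- rnamotifsim:::ATOM_OFFSETS
  centers <- random_centers(n, 4)
  st <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    xyz <- round(sweep(offs, 2, centers[i, ], "+"), 3)
    tibble::tibble(chain = "A", seq_num = i, icode = "",
                   resid = sample(c("A", "C", "G", "U"), 1),
                   is_het = i == 4L, atom = rownames(offs),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  pdb_f <- withr::local_tempfile(fileext = ".pdb")
  cif_f <- withr::local_tempfile(fileext = ".cif")
  write_structure_pdb(st, pdb_f, "TST")
  write_structure_cif(st, cif_f, "TST")

  from_pdb <- load_structure(pdb_f)
  from_cif <- load_structure(cif_f)
  cols <- c("chain", "seq_num", "icode", "base", "atom", "x", "y", "z",
            "is_het")
  a <- as.data.frame(from_pdb[, cols]); b <- as.data.frame(from_cif[, cols])
  attr(a, "structure_id") <- NULL; attr(b, "structure_id") <- NULL
  expect_equal(a, b)
  expect_equal(length(unique(from_pdb$rid)), 6L)
  expect_true(all(from_pdb$is_het[from_pdb$seq_num == 4L]))
  expect_false(any(from_pdb$is_het[from_pdb$seq_num != 4L]))
})

test_that("water residues are dropped and nucleotide-free files error", {
  rows <- tibble::tibble(
    chain = "A", seq_num = c(1L, 1L, 90L), icode = "",
    resid = c("A", "A", "HOH"), is_het = c(FALSE, FALSE, TRUE),
    atom = c("C3'", "P", "O"),
    x = c(1, 2, 9), y = c(2, 2.5, 9), z = c(3, 3.5, 9)
  )
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(rows, f1, "TST")
  st <- load_structure(f1)
  expect_false(any(st$resid == "HOH"))
  expect_equal(nrow(st), 2L)

  prot <- tibble::tibble(chain = "A", seq_num = 1L, icode = "",
                         resid = "GLY", is_het = FALSE, atom = "CA",
                         x = 1, y = 2, z = 3)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(prot, f2, "TST")
  expect_error(load_structure(f2), "no nucleic-acid residues")
})

test_that("materialize_motif preserves order, flags HETATM motifs, and reports missing residues", {
  set.seed(12)
  offs <- rnamotifsim:::ATOM_OFFSETS
  st <- dplyr::bind_rows(lapply(1:10, function(i) {
    xyz <- round(sweep(offs, 2, random_centers(1, 3)[1, ], "+"), 3)
    tibble::tibble(chain = "A", seq_num = i, icode = "",
                   rid = sprintf("A.%d", i), resid = "G", base = "G",
                   is_nt = TRUE, is_het = i == 9L, modified = FALSE,
                   atom = rownames(offs),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  stub <- tibble::tibble(motif_id = "m", family = "F", pdb_id = "P",
                         chain = "A",
                         ranges = list(tibble::tibble(start = 10L, end = 14L)))
  expect_error(materialize_motif(stub, st), "missing residue A.11")

  stub$ranges <- list(tibble::tibble(start = 2L, end = 6L))
  m <- materialize_motif(stub, st)
  expect_s3_class(m, "rna_motif")
  expect_equal(m$nucleotides$seq_num, 2:6)
  expect_false(m$excluded)

  stub$ranges <- list(tibble::tibble(start = 7L, end = 10L))
  m2 <- materialize_motif(stub, st)
  expect_true(m2$excluded)
})

test_that("partial PDB writing round-trips coordinates and re-homes chains", {
  set.seed(13)
  centers <- round(random_centers(9, 4), 3)
  motif <- motif_from_centers("m9", "F", centers,
                              bases = rep(c("A", "G", "C"), 3),
                              segments = rep(c(1L, 2L), c(5L, 4L)))
  # two-chain motif: re-home second segment to another chain id
  motif$nucleotides$chain[motif$nucleotides$segment == 2L] <- "B"
  f <- withr::local_tempfile(fileext = ".pdb")
  remap <- write_partial_pdb(motif, f)

  expect_equal(nrow(remap), 9L)
  expect_equal(sort(remap$new_seq), 1:9)         # bijection onto 1..9
  expect_equal(anyDuplicated(remap$rid), 0L)

  st <- load_structure(f)
  expect_equal(unique(st$chain), "A")            # single first chain
  expect_equal(length(unique(st$rid)), 9L)
  # coordinates survive the round trip exactly (3-decimal inputs)
  orig <- motif$atoms[order(motif$atoms$rid, motif$atoms$atom), ]
  back <- dplyr::left_join(st, remap, by = c(seq_num = "new_seq"))
  back <- back[order(back$rid.y, back$atom), ]
  expect_equal(unname(back$x), unname(orig$x))
  expect_equal(unname(back$y), unname(orig$y))
  expect_equal(unname(back$z), unname(orig$z))
})

test_that("similar-instance lists are sorted, tie-broken, and typed", {
  pairs <- tibble::tibble(
    motif_a = c("m3", "m1", "m2"), motif_b = c("x3", "x1", "x2"),
    family_a = "F1", family_b = "F2", mode = "interaction",
    aligned_length = c(8, 9, 10), rmsd = c(0.9, 0.5, 0.5)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similar_instances(pairs, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")][-1]
  got <- vapply(strsplit(body, "\t"), `[`, "", 1)
  expect_equal(got, c("m1", "m2", "m3"))   # rmsd asc, then lexicographic

  empty <- pairs[0, ]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_similar_instances(empty, f2)
  expect_equal(sum(!startsWith(readLines(f2), "#")), 1L)  # header only

  mixed <- pairs
  mixed$family_a[1] <- "other"
  expect_error(write_similar_instances(mixed, f2), "multiple family pairs")
})
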