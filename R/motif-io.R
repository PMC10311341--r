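#' Parse a motif-location list
#'
#' Reads a whitespace-separated motif-location file.  Each non-comment line
#' names one motif instance:
#'
#' ```
#' [motif_id] family pdb_id chain range1,range2,...
#' ```
#'
#' where each range is a 1-based closed interval `start-end` (or a single
#' residue number) in author numbering, one range per loop strand.  The
#' leading `motif_id` token is optional; when absent an identifier is
#' derived from the remaining fields.  Lines starting with `#` are ignored.
#'
#' @param path path to the location file.
#' @param family_filter optional character vector; records whose family is
#'   not in this set are dropped.
#' @return a tibble of motif stubs with columns `motif_id`, `family`,
#'   `pdb_id`, `chain` and a list-column `ranges` (tibbles with `start`,
#'   `end`), in file order.
#' @export
parse_motif_locations <- function(path, family_filter = NULL) {
  if (!file.exists(path)) abort(paste0("location file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) {
    warn("empty motif-location file")
    return(tibble(motif_id = character(), family = character(),
                  pdb_id = character(), chain = character(),
                  ranges = list(), source_file = character()))
  }
  recs <- map(keep, function(ln) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) == 5L) {
      id <- toks[1]; toks <- toks[-1]
    } else if (length(toks) == 4L) {
      id <- NA_character_
    } else {
      abort(sprintf("line %d: expected 4 or 5 fields, got %d", ln, length(toks)))
    }
    rng <- parse_ranges(toks[4], line = ln)
    if (is.na(id)) {
      id <- paste(toks[1], toks[2], toks[3], gsub(",", "+", toks[4]), sep = "_")
    }
    tibble(motif_id = id, family = toks[1], pdb_id = toks[2],
           chain = toks[3], ranges = list(rng))
  })
  out <- bind_rows(recs)
  dup <- out$motif_id[duplicated(out$motif_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicated motif_id in location file: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(family_filter)) out <- filter(out, .data$family %in% family_filter)
  out$source_file <- path
  out
}

parse_ranges <- function(txt, line = NA) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  rows <- map(parts, function(p) {
    m <- regmatches(p, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
    if (length(m) == 0L || !nzchar(m[1])) {
      abort(sprintf("line %s: malformed residue range '%s'", line, p))
    }
    s <- as.integer(m[2])
    e <- if (nzchar(m[3])) as.integer(m[3]) else s
    if (e < s) abort(sprintf("line %s: range end before start in '%s'", line, p))
    tibble(start = s, end = e)
  })
  bind_rows(rows)
}

#' Load nucleotide residues from a PDB or mmCIF file
#'
#' Reads a coordinate file (format chosen by extension: `.cif`/`.mmcif` use
#' the mmCIF reader, everything else the PDB reader), keeps model 1, drops
#' waters, and returns one row per atom for every residue.  Residues
#' originating from HETATM records are flagged; modified nucleotides with a
#' known parent base keep the parent base code and a `modified` flag.
#' Non-nucleotide hetero residues (ligands) are retained and flagged so
#' that motifs overlapping them can be excluded downstream.
#'
#' @param path path to the structure file.
#' @return a tibble with columns `chain`, `seq_num`, `icode`, `rid`,
#'   `resid` (original residue code), `base` (parent base or residue code),
#'   `is_nt`, `is_het`, `modified`, `atom`, `x`, `y`, `z`; attribute
#'   `structure_id` carries the file stem.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path, multi = FALSE, verbose = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    ),
    error = function(e) abort(paste0("failed to read structure: ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[!(at$resid %in% WATER_RESIDUES), , drop = FALSE]
  if (nrow(at) == 0L) abort("empty structure: no non-water residues")
  icode <- at$insert
  icode[is.na(icode)] <- ""
  resid <- trimws(at$resid)
  base <- ifelse(resid %in% STANDARD_BASES, resid,
                 unname(MODIFIED_BASE_MAP[resid]))
  is_nt <- !is.na(base)
  base[is.na(base)] <- resid[is.na(base)]
  tab <- tibble(
    chain = as.character(at$chain),
    seq_num = as.integer(at$resno),
    icode = as.character(icode),
    rid = rid_str(as.character(at$chain), as.integer(at$resno),
                  as.character(icode)),
    resid = resid,
    base = base,
    is_nt = is_nt,
    is_het = at$type == "HETATM",
    modified = is_nt & !(resid %in% STANDARD_BASES),
    atom = gsub("^\"|\"$", "", trimws(at$elety)),
    x = at$x, y = at$y, z = at$z
  )
  if (!any(tab$is_nt)) abort("empty structure: no nucleic-acid residues found")
  if (any(!is.finite(c(tab$x, tab$y, tab$z)))) {
    abort("non-finite coordinates in structure file")
  }
  tab <- tab[residue_order(tab$chain, tab$seq_num, tab$icode), ]
  attr(tab, "structure_id") <- sub("\\.(pdb|ent|cif|mmcif)$", "",
                                   basename(path), ignore.case = TRUE)
  tab
}

#' Fill a motif stub with nucleotides from a structure table
#'
#' Extracts the residues addressed by the stub's ranges (1-based closed
#' intervals in author numbering) from a structure table in chain order,
#' one segment per range.  A motif containing any HETATM-origin residue is
#' marked `excluded` (conservative reading of the curation rule: HETATM
#' records inside the motif region make the instance unusable, whether the
#' residue is a modified base or a ligand).
#'
#' @param stub a single-row tibble as produced by [parse_motif_locations()].
#' @param structure a structure table from [load_structure()].
#' @return an object of class `rna_motif`: a list with `motif_id`,
#'   `family`, `pdb_id`, `excluded`, a `nucleotides` tibble (`segment`,
#'   `chain`, `seq_num`, `icode`, `rid`, `base`, `is_het`, `modified`) and
#'   an `atoms` tibble (`rid`, `atom`, `x`, `y`, `z`).
#' @export
materialize_motif <- function(stub, structure) {
  stopifnot(nrow(stub) == 1L)
  rngs <- stub$ranges[[1]]
  segs <- map(seq_len(nrow(rngs)), function(k) {
    res <- filter(structure,
                  .data$chain == stub$chain,
                  .data$seq_num >= rngs$start[k],
                  .data$seq_num <= rngs$end[k])
    want <- setdiff(rngs$start[k]:rngs$end[k], unique(res$seq_num))
    if (length(want) > 0L) {
      abort(sprintf("motif %s: missing residue %s in structure",
                    stub$motif_id,
                    rid_str(stub$chain, want[1])))
    }
    res
  })
  nts <- bind_rows(imap(segs, function(s, k) {
    u <- distinct(s, .data$rid, .keep_all = TRUE)
    tibble(segment = as.integer(k), chain = u$chain, seq_num = u$seq_num,
           icode = u$icode, rid = u$rid, base = u$base,
           is_het = map_lgl_rid(s, u$rid), modified = u$modified)
  }))
  atoms <- bind_rows(segs) %>%
    select("rid", "atom", "x", "y", "z")
  structure(
    list(motif_id = stub$motif_id, family = stub$family,
         pdb_id = stub$pdb_id,
         excluded = any(nts$is_het),
         nucleotides = nts, atoms = atoms,
         source_file = if ("source_file" %in% names(stub))
           stub$source_file else NA_character_),
    class = "rna_motif"
  )
}

# TRUE per residue if any of its atoms came from a HETATM record.
map_lgl_rid <- function(atom_rows, rids) {
  vapply(rids, function(r) any(atom_rows$is_het[atom_rows$rid == r]),
         logical(1), USE.NAMES = FALSE)
}

#' @export
print.rna_motif <- function(x, ...) {
  cat(sprintf("<rna_motif> %s  family=%s  pdb=%s  %d nt in %d segment(s)%s\n",
              x$motif_id, x$family, x$pdb_id, nrow(x$nucleotides),
              max(x$nucleotides$segment),
              if (isTRUE(x$excluded)) "  [excluded: HETATM]" else ""))
  invisible(x)
}

#' Number of nucleotides in a motif
#' @param motif an `rna_motif`.
#' @return integer count.
#' @export
motif_length <- function(motif) nrow(motif$nucleotides)

# n x 3 matrix of representative-atom coordinates, one row per nucleotide.
motif_rep_coords <- function(motif, rep_atoms = REP_ATOMS) {
  at <- motif$atoms
  out <- matrix(NA_real_, nrow(motif$nucleotides), 3)
  for (i in seq_len(nrow(motif$nucleotides))) {
    rows <- at[at$rid == motif$nucleotides$rid[i], ]
    for (nm in rep_atoms) {
      hit <- which(rows$atom == nm)
      if (length(hit) > 0L) {
        out[i, ] <- c(rows$x[hit[1]], rows$y[hit[1]], rows$z[hit[1]])
        break
      }
    }
  }
  if (any(!is.finite(out))) {
    abort(sprintf("motif %s: no representative atom (%s) for some nucleotide",
                  motif$motif_id, paste(rep_atoms, collapse = "/")))
  }
  out
}

# n x 3 matrix of backbone+ribose heavy-atom centroids per nucleotide.
motif_centroids <- function(motif, atom_scope = BACKBONE_RIBOSE_ATOMS,
                            quiet = FALSE) {
  at <- motif$atoms[motif$atoms$atom %in% atom_scope, ]
  out <- matrix(NA_real_, nrow(motif$nucleotides), 3)
  for (i in seq_len(nrow(motif$nucleotides))) {
    rows <- at[at$rid == motif$nucleotides$rid[i], ]
    if (nrow(rows) == 0L) next
    out[i, ] <- c(mean(rows$x), mean(rows$y), mean(rows$z))
  }
  if (!quiet && any(!is.finite(out[, 1]))) {
    warn(sprintf("motif %s: %d nucleotide(s) without backbone/ribose atoms skipped",
                 motif$motif_id, sum(!is.finite(out[, 1]))))
  }
  out
}

#' Write a motif as a single-chain partial PDB file
#'
#' Serializes a materialized motif as a one-model PDB file in which all of
#' the motif's nucleotides form the first (and only) chain `A`, residues
#' renumbered consecutively from 1 and atom serials from 1.  Coordinate
#' aligners that consume only the first chain of a file therefore see
#' exactly the motif.  A comment header records the tool version and the
#' residue renumbering map, which is returned invisibly as a bijection
#' between original residue ids and new residue numbers.
#'
#' @param motif an `rna_motif`.
#' @param path output path.
#' @return (invisibly) a tibble with `rid` and `new_seq`.
#' @export
write_partial_pdb <- function(motif, path) {
  nts <- motif$nucleotides
  remap <- tibble(rid = nts$rid, new_seq = seq_len(nrow(nts)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  writeLines(c(
    sprintf("REMARK   3 generated by rnamotifsim %s",
            as.character(utils::packageVersion("rnamotifsim"))),
    sprintf("REMARK   3 motif %s family %s source %s", motif$motif_id,
            motif$family, motif$pdb_id),
    sprintf("REMARK   3 map %s -> %d", remap$rid, remap$new_seq)
  ), con)
  serial <- 0L
  for (i in seq_len(nrow(nts))) {
    rows <- motif$atoms[motif$atoms$rid == nts$rid[i], ]
    base <- nts$base[i]
    for (a in seq_len(nrow(rows))) {
      serial <- serial + 1L
      nm <- rows$atom[a]
      nm_fmt <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      writeLines(sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         serial, nm_fmt, base, "A", remap$new_seq[i],
                         rows$x[a], rows$y[a], rows$z[a], 1.0, 0.0), con)
    }
  }
  writeLines(c("TER", "END"), con)
  invisible(remap)
}

#' Write a similar-instance list
#'
#' Writes the qualifying motif pairs of one family pair (one mode) as a
#' tab-separated file: motif ids, aligned length, RMSD; sorted by RMSD
#' ascending with ties broken lexicographically by the motif ids.
#'
#' @param pairs a tibble of pair records sharing one `(family_a, family_b,
#'   mode)` combination.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_similar_instances <- function(pairs, path) {
  if (nrow(pairs) > 0L) {
    key <- unique(pairs[, c("family_a", "family_b", "mode")])
    if (nrow(key) != 1L) {
      abort("write_similar_instances: pairs span multiple family pairs or modes")
    }
  }
  hdr <- c(
    sprintf("# rnamotifsim %s similar-instance list",
            as.character(utils::packageVersion("rnamotifsim"))),
    "motif_a\tmotif_b\taligned_length\trmsd"
  )
  if (nrow(pairs) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  pairs <- arrange(pairs, .data$rmsd, .data$motif_a, .data$motif_b)
  body <- sprintf("%s\t%s\t%g\t%.6g", pairs$motif_a, pairs$motif_b,
                  pairs$aligned_length, pairs$rmsd)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a structure table as a minimal mmCIF file
#'
#' Emits an `atom_site` loop equivalent to the given structure table.  Used
#' by the synthetic corpus generator and the cross-format fixtures; it is a
#' writer for this package's own tables, not a general mmCIF tool.
#'
#' @param structure a structure table (or the atom tibble of a motif with
#'   the same columns).
#' @param path output path.
#' @param structure_id entry id to record.
#' @return (invisibly) the path.
#' @export
write_structure_cif <- function(structure, path, structure_id = "SYNTH") {
  # standard wwPDB atom_site column layout
  lines <- c(
    paste0("data_", structure_id),
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  grp <- ifelse(structure$is_het, "HETATM", "ATOM")
  ic <- ifelse(structure$icode == "", "?", structure$icode)
  elem <- substr(structure$atom, 1, 1)
  body <- sprintf(
    "%s %d %s \"%s\" . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 ? %d %s %s \"%s\" 1",
    grp, seq_len(nrow(structure)), elem, structure$atom, structure$resid,
    structure$chain, structure$seq_num, ic,
    structure$x, structure$y, structure$z,
    structure$seq_num, structure$resid, structure$chain, structure$atom
  )
  writeLines(c(lines, body, "#"), path)
  invisible(path)
}

#' Write a structure table as a PDB file
#'
#' Companion writer to [write_structure_cif()] used by the synthetic corpus
#' generator.
#'
#' @inheritParams write_structure_cif
#' @return (invisibly) the path.
#' @export
write_structure_pdb <- function(structure, path, structure_id = "SYNTH") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   3 synthetic structure %s (rnamotifsim %s)",
                     structure_id,
                     as.character(utils::packageVersion("rnamotifsim"))), con)
  rec <- ifelse(structure$is_het, "HETATM", "ATOM  ")
  nm <- structure$atom
  nm_fmt <- ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  lines <- sprintf("%s%5d %s %3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                   rec, seq_len(nrow(structure)), nm_fmt, structure$resid,
                   structure$chain, structure$seq_num,
                   ifelse(structure$icode == "", " ", structure$icode),
                   structure$x, structure$y, structure$z, 1.0, 0.0)
  writeLines(lines, con)
  writeLines(c("TER", "END"), con)
  invisible(path)
}
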