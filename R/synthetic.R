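# Synthetic motif corpora with controlled structure.  Instances are built
# from parameterized helical backbones: only backbone and ribose atoms are
# generated (the RMSD atom scope), so the fixtures are deliberately not
# physically realistic RNA -- they exist to give every pipeline stage a
# ground truth.

# Local atom offsets (Angstrom) from the nucleotide center; backbone and
# ribose heavy atoms only.
ATOM_OFFSETS <- rbind(
  "P"   = c(-1.2,  1.5,  0.0),
  "O5'" = c(-0.8,  0.9,  0.4),
  "C5'" = c(-0.4,  0.5,  0.8),
  "C4'" = c( 0.0,  0.0,  0.9),
  "C3'" = c( 0.3, -0.4,  0.6),
  "O3'" = c( 0.7, -1.0,  0.6),
  "C1'" = c( 0.9,  0.6, -0.3),
  "C2'" = c( 0.8, -0.1,  0.1),
  "O2'" = c( 1.2, -0.6, -0.2),
  "O4'" = c( 0.5,  1.1,  0.2)
)

LW_CLASSES <- as.vector(outer(c("c", "t"),
                              as.vector(outer(c("W", "H", "S"), c("W", "H", "S"),
                                              paste0)), paste0))

# Run expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed)
  for (k in ks) s <- (s * 7919 + as.double(k) * 104729 + 17) %% 2147483629
  as.integer(s)
}

#' Describe a synthetic motif family
#'
#' A family is a two-strand internal-loop template: nucleotide centers on
#' a perturbed helical curve (per-family smooth random displacement on top
#' of the helix), a fixed template sequence drawn from `alphabet`, and
#' cross-strand signature base pairs covering the core positions.
#' Instances are noisy, rigidly displaced copies of the template with
#' optional per-instance sequence mutations.
#'
#' @param name family name.
#' @param n_instances number of instances to generate.
#' @param strand_lengths lengths of the two loop strands.
#' @param helix_radius,helix_rise,helix_twist backbone helix parameters
#'   (Angstrom, Angstrom, degrees).
#' @param wiggle_sd scale of the family-specific smooth shape displacement
#'   in Angstrom; this is what makes different families geometrically
#'   distinct.
#' @param alphabet base letters the template sequence is drawn from.
#' @param pair_classes Leontis-Westhof class labels (e.g. `"tHS"`) used for
#'   the signature pairs; recycled over the cross-strand pairs.
#' @param coordinate_noise_sd per-axis isotropic Gaussian coordinate noise
#'   added to every instance, in Angstrom.
#' @param mutation_rate per-position probability that an instance mutates
#'   the template base (within `alphabet`).
#' @param n_outliers number of trailing instances given an independent
#'   random geometry (planted structural outliers).
#' @param seed family seed.
#' @return a list of class `synthetic_family_spec`.
#' @export
synthetic_family_spec <- function(name, n_instances = 10,
                                  strand_lengths = c(3, 3),
                                  helix_radius = 9, helix_rise = 2.8,
                                  helix_twist = 32, wiggle_sd = 2.5,
                                  alphabet = c("A", "C", "G", "U"),
                                  pair_classes = "cWW",
                                  coordinate_noise_sd = 0.15,
                                  mutation_rate = 0.05,
                                  n_outliers = 0, seed = 1) {
  stopifnot(n_instances >= 1, coordinate_noise_sd >= 0,
            length(strand_lengths) == 2L, all(strand_lengths >= 1))
  structure(list(name = name, n_instances = as.integer(n_instances),
                 strand_lengths = as.integer(strand_lengths),
                 helix_radius = helix_radius, helix_rise = helix_rise,
                 helix_twist = helix_twist, wiggle_sd = wiggle_sd,
                 alphabet = alphabet, pair_classes = pair_classes,
                 coordinate_noise_sd = coordinate_noise_sd,
                 mutation_rate = mutation_rate,
                 n_outliers = as.integer(n_outliers),
                 seed = as.integer(seed)),
            class = "synthetic_family_spec")
}

#' Describe a planted cross-family similarity
#'
#' Defines a ground-truth similarity to inject into the corpus.  In
#' `"interaction"` mode the participating instances of both families gain
#' a shared block: extra nucleotides appended to the loop strands that
#' carry identical base pairs, sequence and internal geometry (each family
#' places the block rigidly in its own way, so only the interaction
#' viewpoint, plus the local geometry of the block itself, is shared).  In
#' `"coordinate"` mode the participating instances keep their family's
#' sequence and base pairs but their whole-motif geometry is replaced by a
#' shared donor shape.  `"both"` replaces geometry, sequence and pairs.
#'
#' @param family_a,family_b family names.
#' @param shared_mode `"interaction"`, `"coordinate"` or `"both"`.
#' @param participation_a,participation_b fractions (0..1) of each
#'   family's instances that carry the planted similarity.
#' @param block_lengths for interaction mode: nucleotides appended per
#'   strand.
#' @param block_alphabet base letters of the shared block sequence.
#' @param pair_classes classes of the shared pairs.
#' @param seed seed of the donor template.
#' @return a list of class `planted_similarity`.
#' @export
planted_similarity <- function(family_a, family_b,
                               shared_mode = c("interaction", "coordinate", "both"),
                               participation_a = 0.3, participation_b = 0.3,
                               block_lengths = c(5, 5),
                               block_alphabet = c("C", "U"),
                               pair_classes = "tHS", seed = 99) {
  shared_mode <- match.arg(shared_mode)
  if (participation_a > 1 || participation_b > 1 ||
      participation_a < 0 || participation_b < 0) {
    abort("participation fractions must lie in [0, 1]")
  }
  structure(list(family_a = family_a, family_b = family_b,
                 shared_mode = shared_mode,
                 participation_a = participation_a,
                 participation_b = participation_b,
                 block_lengths = as.integer(block_lengths),
                 block_alphabet = block_alphabet,
                 pair_classes = pair_classes, seed = as.integer(seed)),
            class = "planted_similarity")
}

# Nucleotide centers for a two-strand internal loop on a helix, plus a
# smooth seeded displacement field.
template_centers <- function(n1, n2, radius, rise, twist_deg, wiggle_sd, seed) {
  n <- n1 + n2
  tw <- twist_deg * pi / 180
  idx1 <- seq_len(n1) - 1L
  c1 <- cbind(radius * cos(tw * idx1), radius * sin(tw * idx1), rise * idx1)
  idx2 <- seq_len(n2) - 1L
  c2 <- cbind(-radius * cos(tw * idx2), -radius * sin(tw * idx2),
              rise * (n1 - 1 - idx2))
  centers <- rbind(c1, c2)
  with_seed(seed, {
    steps <- matrix(rnorm(n * 3, 0, wiggle_sd / 2), n, 3)
    centers + apply(steps, 2, cumsum)
  })
}

# Full family template: centers, sequence, pairs, stacks.
family_template <- function(spec) {
  n1 <- spec$strand_lengths[1]; n2 <- spec$strand_lengths[2]
  centers <- template_centers(n1, n2, spec$helix_radius, spec$helix_rise,
                              spec$helix_twist, spec$wiggle_sd,
                              derive_seed(spec$seed, 1))
  seqs <- with_seed(derive_seed(spec$seed, 2), {
    sample(spec$alphabet, n1 + n2, replace = TRUE)
  })
  npairs <- min(n1, n2)
  cls <- rep(spec$pair_classes, length.out = npairs)
  # cross-strand pairs: strand-1 position k pairs strand-2 position n2+1-k
  pairs <- tibble(pos_i = seq_len(npairs),
                  pos_j = n1 + n2 + 1L - seq_len(npairs),
                  class = cls)
  stacks <- bind_rows(
    if (n1 >= 2L) tibble(pos_i = seq_len(n1 - 1L), pos_j = seq_len(n1 - 1L) + 1L),
    if (n2 >= 2L) tibble(pos_i = n1 + seq_len(n2 - 1L),
                         pos_j = n1 + seq_len(n2 - 1L) + 1L)
  )
  list(centers = centers, seq = seqs, pairs = pairs,
       stacks = stacks %||% tibble(pos_i = integer(), pos_j = integer()),
       strand_lengths = c(n1, n2))
}

# Donor template for a planted similarity.
donor_template <- function(plant, strand_lengths) {
  spec <- synthetic_family_spec(
    name = paste0("donor_", plant$family_a, "_", plant$family_b),
    strand_lengths = strand_lengths,
    alphabet = plant$block_alphabet,
    pair_classes = plant$pair_classes,
    wiggle_sd = 2.0,
    seed = plant$seed
  )
  family_template(spec)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic motif corpus on disk
#'
#' Writes, deterministically for a seed, one structure file per instance
#' (PDB, plus mmCIF if requested), two annotation files per structure (the
#' DSSR-style dialect with the true interactions and the FR3D-style
#' dialect with orientation flips injected at `disagreement_rate` to
#' exercise conflict merging), a motif-location file, and a ground-truth
#' manifest JSON.
#'
#' @param specs list of [synthetic_family_spec()] objects (unique names).
#' @param planted list of [planted_similarity()] objects.
#' @param seed corpus seed; all randomness derives from it.
#' @param dir output directory (created if needed).
#' @param disagreement_rate fraction of true pairs whose orientation is
#'   flipped in the FR3D-style annotation file.
#' @param write_cif also emit mmCIF copies of every structure.
#' @return (invisibly) the manifest as a list (`locations`, `families`,
#'   `planted`, `dir`).
#' @export
generate_corpus <- function(specs, planted = list(), seed = 1, dir,
                            disagreement_rate = 0.1, write_cif = FALSE) {
  nm <- map_chr(specs, "name")
  if (anyDuplicated(nm) > 0L) abort("family names must be unique")
  names(specs) <- nm
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  templates <- map(specs, family_template)

  # choose participants per planted similarity (deterministic for a seed)
  plant_info <- imap(planted, function(pl, k) {
    for (f in c(pl$family_a, pl$family_b)) {
      if (!f %in% nm) abort(paste0("planted similarity names unknown family: ", f))
    }
    donor_sl <- if (pl$shared_mode == "interaction") pl$block_lengths
      else specs[[pl$family_a]]$strand_lengths
    donor <- donor_template(pl, donor_sl)
    pick <- function(frac, n, which) {
      k_n <- round(frac * n)
      if (k_n == 0L) integer(0) else
        with_seed(derive_seed(seed, 500 + k, which), sort(sample(n, k_n)))
    }
    list(plant = pl, donor = donor,
         participants_a = pick(pl$participation_a,
                               specs[[pl$family_a]]$n_instances, 1),
         participants_b = pick(pl$participation_b,
                               specs[[pl$family_b]]$n_instances, 2))
  })

  loc_lines <- character(0)
  manifest_fams <- list()
  for (fi in seq_along(specs)) {
    spec <- specs[[fi]]; tpl <- templates[[fi]]
    for (ii in seq_len(spec$n_instances)) {
      inst <- build_instance(spec, tpl, fi, ii, plant_info, seed)
      pdb_id <- sprintf("%s%d%02d",
                        toupper(substr(gsub("[^A-Za-z0-9]", "", spec$name), 1, 3)),
                        fi, ii)
      write_instance(inst, pdb_id, dir, disagreement_rate,
                     derive_seed(seed, 900, fi, ii), write_cif)
      n1 <- inst$strand_lengths[1]; n2 <- inst$strand_lengths[2]
      rng <- sprintf("1-%d,101-%d", n1, 100 + n2)
      loc_lines <- c(loc_lines,
                     sprintf("%s_%02d %s %s A %s", spec$name, ii, spec$name,
                             pdb_id, rng))
    }
    manifest_fams[[spec$name]] <- list(
      n_instances = spec$n_instances,
      outliers = if (spec$n_outliers > 0L)
        seq.int(spec$n_instances - spec$n_outliers + 1L, spec$n_instances)
      else integer(0)
    )
  }
  loc_path <- file.path(dir, "motifs.in")
  writeLines(c("# motif_id family pdb_id chain ranges", loc_lines), loc_path)

  manifest <- list(
    locations = loc_path,
    families = manifest_fams,
    planted = map(plant_info, function(pi) {
      list(family_a = pi$plant$family_a, family_b = pi$plant$family_b,
           shared_mode = pi$plant$shared_mode,
           participants_a = pi$participants_a,
           participants_b = pi$participants_b)
    }),
    seed = seed, disagreement_rate = disagreement_rate, dir = dir
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Assemble one instance: centers, sequence, pairs/stacks (template
# positions), after planted modifications, noise and rigid motion.
build_instance <- function(spec, tpl, fi, ii, plant_info, corpus_seed) {
  centers <- tpl$centers
  seqs <- tpl$seq
  pairs <- tpl$pairs
  stacks <- tpl$stacks
  sl <- tpl$strand_lengths

  for (pi in plant_info) {
    pl <- pi$plant
    role <- if (pl$family_a == spec$name && ii %in% pi$participants_a) "a"
      else if (pl$family_b == spec$name && ii %in% pi$participants_b) "b"
      else NA_character_
    if (is.na(role)) next
    if (pl$shared_mode == "interaction") {
      # append the shared block: b1 nts after strand 1, b2 nts before
      # strand 2's core, placing the donor geometry rigidly at a
      # family-specific offset and orientation
      b1 <- pi$donor$strand_lengths[1]; b2 <- pi$donor$strand_lengths[2]
      ori <- with_seed(derive_seed(pl$seed, fi, 7), random_rotation())
      offset <- with_seed(derive_seed(pl$seed, fi, 8),
                          runif(3, -4, 4)) + centers[sl[1], ] + c(6, 0, 6)
      bc <- pi$donor$centers %*% t(ori)
      bc <- sweep(bc, 2, colMeans(bc)) ; bc <- sweep(bc, 2, offset, "+")
      n1 <- sl[1]; n2 <- sl[2]
      new_centers <- rbind(centers[seq_len(n1), , drop = FALSE],
                           bc[seq_len(b1), , drop = FALSE],
                           bc[b1 + seq_len(b2), , drop = FALSE],
                           centers[n1 + seq_len(n2), , drop = FALSE])
      shift_core2 <- function(p) ifelse(p > n1, p + b1 + b2, p)
      remap_block <- function(p) ifelse(p <= b1, n1 + p, n1 + p)
      pairs <- bind_rows(
        tibble(pos_i = shift_core2(pairs$pos_i),
               pos_j = shift_core2(pairs$pos_j), class = pairs$class),
        tibble(pos_i = remap_block(pi$donor$pairs$pos_i),
               pos_j = remap_block(pi$donor$pairs$pos_j),
               class = pi$donor$pairs$class)
      )
      stacks <- bind_rows(
        tibble(pos_i = shift_core2(stacks$pos_i),
               pos_j = shift_core2(stacks$pos_j)),
        tibble(pos_i = remap_block(pi$donor$stacks$pos_i),
               pos_j = remap_block(pi$donor$stacks$pos_j))
      )
      seqs <- c(seqs[seq_len(n1)], pi$donor$seq, seqs[n1 + seq_len(n2)])
      centers <- new_centers
      sl <- c(n1 + b1, n2 + b2)
    } else if (pl$shared_mode == "coordinate") {
      if (!all(dim(pi$donor$centers) == dim(centers))) {
        abort("coordinate-mode donor must match the family's strand lengths")
      }
      centers <- pi$donor$centers
    } else { # both
      centers <- pi$donor$centers
      seqs <- pi$donor$seq
      pairs <- pi$donor$pairs
      stacks <- pi$donor$stacks
      sl <- pi$donor$strand_lengths
    }
  }

  # planted geometric outliers: independent random shape
  if (spec$n_outliers > 0L &&
      ii > spec$n_instances - spec$n_outliers) {
    centers <- template_centers(sl[1], sl[2], spec$helix_radius,
                                spec$helix_rise, spec$helix_twist,
                                spec$wiggle_sd * 2,
                                derive_seed(corpus_seed, 777, fi, ii))
  }

  # per-instance mutations, noise and rigid motion
  inst_seed <- derive_seed(corpus_seed, fi, ii)
  with_seed(inst_seed, {
    mut <- runif(length(seqs)) < spec$mutation_rate
    if (any(mut)) {
      seqs[mut] <- vapply(seqs[mut], function(b) {
        alt <- setdiff(spec$alphabet, b)
        if (length(alt) == 0L) b else sample(alt, 1L)
      }, character(1))
    }
    n <- nrow(centers)
    atoms_per_nt <- nrow(ATOM_OFFSETS)
    coords <- matrix(NA_real_, n * atoms_per_nt, 3)
    for (i in seq_len(n)) {
      coords[(i - 1L) * atoms_per_nt + seq_len(atoms_per_nt), ] <-
        sweep(ATOM_OFFSETS, 2, centers[i, ], "+")
    }
    coords <- coords + matrix(rnorm(length(coords), 0, spec$coordinate_noise_sd),
                              nrow(coords), 3)
    R <- random_rotation()
    tr <- runif(3, -20, 20)
    coords <- sweep(coords %*% t(R), 2, tr, "+")
    list(seq = seqs, coords = round(coords, 3), pairs = pairs,
         stacks = stacks, strand_lengths = sl,
         atom_names = rownames(ATOM_OFFSETS))
  })
}

# Serialize one instance: PDB (+ optional CIF) and the two annotation
# dialect files.
write_instance <- function(inst, pdb_id, dir, disagreement_rate, flip_seed,
                           write_cif) {
  n1 <- inst$strand_lengths[1]; n2 <- inst$strand_lengths[2]
  n <- n1 + n2
  seq_nums <- c(seq_len(n1), 100L + seq_len(n2))
  atoms_per_nt <- length(inst$atom_names)
  st <- tibble(
    chain = "A",
    seq_num = rep(seq_nums, each = atoms_per_nt),
    icode = "",
    resid = rep(inst$seq, each = atoms_per_nt),
    is_het = FALSE,
    atom = rep(inst$atom_names, n),
    x = inst$coords[, 1], y = inst$coords[, 2], z = inst$coords[, 3]
  )
  write_structure_pdb(st, file.path(dir, paste0(pdb_id, ".pdb")), pdb_id)
  if (write_cif) {
    write_structure_cif(st, file.path(dir, paste0(pdb_id, ".cif")), pdb_id)
  }

  rid_of <- function(pos) rid_str("A", seq_nums[pos])
  p <- inst$pairs
  true_lines <- sprintf("pair %s %s %s", rid_of(p$pos_i), rid_of(p$pos_j),
                        p$class)
  s <- inst$stacks
  stack_lines <- sprintf("stack %s %s %s", rid_of(s$pos_i), rid_of(s$pos_j),
                         "upward")
  writeLines(c(sprintf("# DSSR-style annotations for %s", pdb_id),
               true_lines, stack_lines),
             file.path(dir, paste0(pdb_id, ".dssr")))

  flipped <- with_seed(flip_seed, runif(nrow(p)) < disagreement_rate)
  cls2 <- p$class
  cls2[flipped] <- paste0(ifelse(substr(cls2[flipped], 1, 1) == "c", "t", "c"),
                          substr(cls2[flipped], 2, 3))
  fr3d_pairs <- sprintf("%s %s %s", rid_of(p$pos_i), rid_of(p$pos_j), cls2)
  fr3d_stacks <- sprintf("%s %s s35", rid_of(s$pos_i), rid_of(s$pos_j))
  writeLines(c(sprintf("# FR3D-style annotations for %s", pdb_id),
               fr3d_pairs, fr3d_stacks),
             file.path(dir, paste0(pdb_id, ".fr3d")))
  invisible(pdb_id)
}

#' Add isotropic Gaussian coordinate noise to a motif
#'
#' Returns a copy of the motif whose atom coordinates are displaced by
#' independent Gaussian noise on each axis, so the expected squared
#' per-atom displacement is `3 * noise_sd^2`.  Base identities and
#' topology are unchanged.
#'
#' @param motif an `rna_motif`.
#' @param noise_sd per-axis standard deviation in Angstrom (>= 0).
#' @param seed RNG seed.
#' @return the perturbed `rna_motif`.
#' @export
perturb <- function(motif, noise_sd, seed = 1) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(motif)
  n <- nrow(motif$atoms)
  noise <- with_seed(seed, matrix(rnorm(3 * n, 0, noise_sd), n, 3))
  motif$atoms$x <- motif$atoms$x + noise[, 1]
  motif$atoms$y <- motif$atoms$y + noise[, 2]
  motif$atoms$z <- motif$atoms$z + noise[, 3]
  motif
}

#' Load a generated (or equivalently formatted) corpus from disk
#'
#' Reads the motif-location file, loads every referenced structure,
#' merges the two annotation files per structure, and materializes all
#' motifs.  Motifs flagged as excluded (HETATM content) are dropped with a
#' message.
#'
#' @param locations path to the motif-location file.
#' @param dir directory holding `<pdb_id>.pdb` (or `.cif`) and
#'   `<pdb_id>.dssr` / `<pdb_id>.fr3d` annotation files; defaults to the
#'   location file's directory.
#' @param family_filter optional family subset.
#' @return list with `motifs` (named list of `rna_motif`), `annotations`
#'   (named list of merged `annotation_set`), `stubs`, `excluded`
#'   (character vector of excluded motif ids).
#' @export
read_motif_corpus <- function(locations, dir = dirname(locations),
                              family_filter = NULL) {
  stubs <- parse_motif_locations(locations, family_filter)
  motifs <- list(); anns <- list(); excluded <- character(0)
  for (pdb in unique(stubs$pdb_id)) {
    pdb_path <- file.path(dir, paste0(pdb, ".pdb"))
    if (!file.exists(pdb_path)) pdb_path <- file.path(dir, paste0(pdb, ".cif"))
    st <- load_structure(pdb_path)
    d_path <- file.path(dir, paste0(pdb, ".dssr"))
    f_path <- file.path(dir, paste0(pdb, ".fr3d"))
    ann <- if (file.exists(d_path) && file.exists(f_path)) {
      merge_annotations(read_annotations(d_path, "DSSR", pdb),
                        read_annotations(f_path, "FR3D", pdb))
    } else if (file.exists(d_path)) {
      read_annotations(d_path, "DSSR", pdb)
    } else if (file.exists(f_path)) {
      read_annotations(f_path, "FR3D", pdb)
    } else {
      annotation_set(pdb)
    }
    anns[[pdb]] <- ann
    for (r in which(stubs$pdb_id == pdb)) {
      m <- materialize_motif(stubs[r, ], st)
      if (isTRUE(m$excluded)) {
        excluded <- c(excluded, m$motif_id)
      } else {
        motifs[[m$motif_id]] <- m
      }
    }
  }
  if (length(excluded) > 0L) {
    inform(sprintf("excluded %d motif(s) containing HETATM residues: %s",
                   length(excluded), paste(excluded, collapse = ", ")))
  }
  list(motifs = motifs, annotations = anns, stubs = stubs,
       excluded = excluded)
}

#' Family specifications of the reference synthetic corpus
#'
#' Seven internal-loop families with three planted similarities:
#' an interaction-only pair at participation 0.3, a coordinate-only pair
#' at participation 0.3, a both-viewpoints pair at participation 0.5, and
#' one family with no planted similarity.  Base alphabets and pair classes
#' are chosen so that planted structure, not chance sequence identity,
#' drives the recovered similarities; geometry differs between families
#' through independent shape displacement fields.
#'
#' @param n_instances instances per family.
#' @return list with `specs` and `planted`, ready for [generate_corpus()].
#' @export
reference_corpus_design <- function(n_instances = 10) {
  specs <- list(
    synthetic_family_spec("famA", n_instances, strand_lengths = c(3, 3),
                          alphabet = c("A", "G"), pair_classes = "tHS",
                          helix_twist = 30, seed = 101),
    synthetic_family_spec("famB", n_instances, strand_lengths = c(3, 3),
                          alphabet = c("C", "U"), pair_classes = "cWW",
                          helix_twist = 40, seed = 202),
    synthetic_family_spec("famC", n_instances, strand_lengths = c(6, 6),
                          alphabet = c("A", "G"), pair_classes = "cWW",
                          helix_twist = 28, seed = 303),
    synthetic_family_spec("famD", n_instances, strand_lengths = c(6, 6),
                          alphabet = c("C", "U"), pair_classes = "tHS",
                          helix_twist = 36, seed = 404),
    synthetic_family_spec("famE", n_instances, strand_lengths = c(6, 6),
                          alphabet = c("A", "G"), pair_classes = "cWH",
                          helix_twist = 26, seed = 505),
    synthetic_family_spec("famF", n_instances, strand_lengths = c(6, 6),
                          alphabet = c("C", "U"), pair_classes = "tWS",
                          helix_twist = 44, seed = 606),
    synthetic_family_spec("famG", n_instances, strand_lengths = c(5, 5),
                          alphabet = c("A", "C", "G", "U"),
                          pair_classes = c("cWW", "tHS"),
                          helix_twist = 34, seed = 707)
  )
  planted <- list(
    planted_similarity("famA", "famB", "interaction",
                       participation_a = 0.3, participation_b = 0.3,
                       block_lengths = c(5, 5), block_alphabet = c("C", "U"),
                       pair_classes = "tSH", seed = 1001),
    planted_similarity("famC", "famD", "coordinate",
                       participation_a = 0.3, participation_b = 0.3,
                       seed = 2002),
    planted_similarity("famE", "famF", "both",
                       participation_a = 0.5, participation_b = 0.5,
                       block_alphabet = c("A", "G"), pair_classes = "tSS",
                       seed = 3003)
  )
  list(specs = specs, planted = planted)
}
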