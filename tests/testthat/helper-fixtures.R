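# Builders for small in-code fixtures and independent oracles.

# ---- motif builders ------------------------------------------------------

# Build an rna_motif directly from nucleotide centers (one atom set per
# nucleotide at fixed offsets, like the synthetic generator).
motif_from_centers <- function(id, family, centers, bases = NULL,
                               segments = NULL, pdb_id = "TEST") {
  n <- nrow(centers)
  bases <- bases %||% rep("A", n)
  segments <- segments %||% rep(1L, n)
  offs <- rnamotifsim:::ATOM_OFFSETS
  seq_nums <- seq_len(n)
  rid <- sprintf("A.%d", seq_nums)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- sweep(offs, 2, centers[i, ], "+")
    tibble::tibble(rid = rid[i], atom = rownames(offs),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  structure(list(
    motif_id = id, family = family, pdb_id = pdb_id, excluded = FALSE,
    nucleotides = tibble::tibble(segment = segments, chain = "A",
                                 seq_num = seq_nums, icode = "",
                                 rid = rid, base = bases,
                                 is_het = FALSE, modified = FALSE),
    atoms = atoms, source_file = NA_character_
  ), class = "rna_motif")
}

random_centers <- function(n, scale = 5) {
  matrix(stats::rnorm(n * 3, 0, scale), n, 3)
}

# Random rigid motion applied to a motif's atoms.
rigid_transform_motif <- function(motif, R, t) {
  xyz <- as.matrix(motif$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  motif$atoms$x <- xyz[, 1]; motif$atoms$y <- xyz[, 2]; motif$atoms$z <- xyz[, 3]
  motif
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# ---- interaction-graph builders -----------------------------------------

toy_graph <- function(bases, segments = NULL, pairs = NULL, stacks = NULL) {
  n <- length(bases)
  segments <- segments %||% rep(1L, n)
  pairs <- pairs %||% tibble::tibble(i = integer(), j = integer(),
                                     edge_i = character(), edge_j = character(),
                                     orientation = character())
  stacks <- stacks %||% tibble::tibble(i = integer(), j = integer(),
                                       kind = character())
  structure(list(motif_id = "toy",
                 nucleotides = tibble::tibble(idx = seq_len(n),
                                              segment = segments,
                                              rid = sprintf("A.%d", seq_len(n)),
                                              base = bases),
                 pairs = pairs, stacks = stacks),
            class = "interaction_graph")
}

tp <- function(i, j, cls) {
  tibble::tibble(i = i, j = j, edge_i = substr(cls, 2, 2),
                 edge_j = substr(cls, 3, 3),
                 orientation = ifelse(substr(cls, 1, 1) == "c", "cis", "trans"))
}

ts <- function(i, j, kind = "upward") tibble::tibble(i = i, j = j, kind = kind)

# Random small interaction graph over `n` nucleotides.
random_graph <- function(n, n_pairs = 2, n_segments = 1) {
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  segments <- sort(sample(seq_len(n_segments), n, replace = TRUE))
  segments <- as.integer(factor(segments))  # ensure 1..k contiguous
  pairs <- NULL
  if (n_pairs > 0 && n >= 2) {
    got <- list()
    for (k in seq_len(n_pairs)) {
      ij <- sort(sample(n, 2))
      cls <- sample(rnamotifsim:::LW_CLASSES, 1)
      got[[k]] <- tp(ij[1], ij[2], cls)
    }
    pairs <- dplyr::distinct(dplyr::bind_rows(got), i, j, .keep_all = TRUE)
  }
  stacks <- NULL
  if (n >= 2 && stats::runif(1) < 0.7) {
    i <- sample(n - 1, 1)
    if (segments[i] == segments[i + 1]) stacks <- ts(i, i + 1)
  }
  toy_graph(bases, segments, pairs, stacks)
}

# ---- independent oracles -------------------------------------------------

# Score one complete match set the way the scoring rules define it:
# sequence bonuses per matched nucleotide plus interaction-match scores for
# every superposed interaction.  Used by the exhaustive-enumeration oracle.
score_matching <- function(A, B, matches, params) {
  if (nrow(matches) == 0L) return(0)
  sc <- 0
  ab <- A$nucleotides$base[matches$u]
  bb <- B$nucleotides$base[matches$v]
  sc <- sc + sum(ifelse(ab == bb, params$seq_match, params$seq_mismatch))
  v_of_u <- stats::setNames(matches$v, matches$u)
  gi <- function(G) dplyr::bind_rows(
    if (nrow(G$pairs) > 0) dplyr::mutate(G$pairs, kind = "pair"),
    if (nrow(G$stacks) > 0) tibble::tibble(i = G$stacks$i, j = G$stacks$j,
                                           edge_i = NA, edge_j = NA,
                                           orientation = NA, kind = "stack"))
  ia <- gi(A); ib <- gi(B)
  if (!is.null(ia) && !is.null(ib) && nrow(ia) > 0 && nrow(ib) > 0) {
    for (r in seq_len(nrow(ia))) {
      ui <- ia$i[r]; uj <- ia$j[r]
      if (!(as.character(ui) %in% names(v_of_u)) ||
          !(as.character(uj) %in% names(v_of_u))) next
      vi <- v_of_u[[as.character(ui)]]; vj <- v_of_u[[as.character(uj)]]
      hit <- which((ib$i == pmin(vi, vj)) & (ib$j == pmax(vi, vj)))
      if (length(hit) == 0L) next
      s <- hit[1]
      if (ia$kind[r] != ib$kind[s]) next
      if (ia$kind[r] == "stack") { sc <- sc + params$stack; next }
      eb1 <- if (ib$i[s] == vi) ib$edge_i[s] else ib$edge_j[s]
      eb2 <- if (ib$i[s] == vi) ib$edge_j[s] else ib$edge_i[s]
      sc <- sc + rnamotifsim:::score_pair_match(
        ia$edge_i[r], ia$edge_j[r], ia$orientation[r],
        eb1, eb2, ib$orientation[s], params)
    }
  }
  sc
}

# Exhaustive enumeration of order-consistent one-to-one matchings (within
# each admissible segment correspondence); returns the best score.
brute_force_align_score <- function(A, B, params) {
  seg_a <- A$nucleotides$segment
  seg_b <- B$nucleotides$segment
  maps <- rnamotifsim:::segment_mappings(max(seg_a), max(seg_b))
  best <- 0
  for (m in maps) {
    # enumerate monotone matchings segment by segment
    seg_sets <- lapply(seq_len(max(seg_a)), function(sa) {
      sb <- m[sa]
      if (is.na(sb)) return(list(tibble::tibble(u = integer(), v = integer())))
      us <- which(seg_a == sa); vs <- which(seg_b == sb)
      enumerate_monotone(us, vs)
    })
    combos <- expand.grid(lapply(seg_sets, seq_along))
    for (r in seq_len(nrow(combos))) {
      matches <- dplyr::bind_rows(lapply(seq_along(seg_sets), function(k) {
        seg_sets[[k]][[combos[r, k]]]
      }))
      sc <- score_matching(A, B, matches, params)
      if (sc > best) best <- sc
    }
  }
  best
}

# All monotone partial matchings between two ordered index vectors.
enumerate_monotone <- function(us, vs) {
  out <- list()
  rec <- function(ui, vi, acc) {
    out[[length(out) + 1L]] <<- acc
    if (ui > length(us) || vi > length(vs)) return()
    for (a in ui:length(us)) {
      for (b in vi:length(vs)) {
        rec(a + 1L, b + 1L, rbind(acc, data.frame(u = us[a], v = vs[b])))
      }
    }
  }
  rec(1L, 1L, data.frame(u = integer(), v = integer()))
  lapply(out, tibble::as_tibble)
}

# Numeric oracle for the optimal superposition RMSD: minimize over Euler
# angles (translation eliminated by centering), multi-start Nelder-Mead.
oracle_min_rmsd <- function(P, Q, n_starts = 8) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  starts <- rbind(c(0, 0, 0),
                  as.matrix(expand.grid(c(0, pi), c(0, pi / 2), c(0, pi)))[1:(n_starts - 1), , drop = FALSE])
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    r <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    if (r$value < best) best <- r$value
  }
  best
}

# Independent reference for the monotone-alignment DP score (free end
# gaps, linear internal gap penalty): plain memoized recursion.
reference_dp_score <- function(S, gap) {
  n <- nrow(S); m <- ncol(S)
  H <- matrix(0, n + 1, m + 1)
  for (i in 1:(n + 1)) for (j in 1:(m + 1)) {
    if (i == 1L || j == 1L) { H[i, j] <- 0; next }
    up <- H[i - 1, j] + if (j == m + 1) 0 else gap
    left <- H[i, j - 1] + if (i == n + 1) 0 else gap
    H[i, j] <- max(H[i - 1, j - 1] + S[i - 1, j - 1], up, left)
  }
  H[n + 1, m + 1]
}

# Gaussian-blob feature tables for the classifier harness.
blob_features <- function(n_per, centers, seed = 1, sd = 0.3) {
  fams <- names(centers)
  rnamotifsim:::with_seed(seed, {
    dplyr::bind_rows(lapply(fams, function(f) {
      mu <- centers[[f]]
      X <- matrix(stats::rnorm(n_per * length(mu), mean = rep(mu, each = n_per),
                               sd = sd), n_per, length(mu))
      out <- tibble::as_tibble(as.data.frame(X))
      names(out) <- paste0("f", seq_along(mu))
      dplyr::bind_cols(tibble::tibble(motif_id = sprintf("%s_%02d", f, 1:n_per),
                                      family = f), out)
    }))
  })
}

# ---- corpus cache --------------------------------------------------------

.corpus_cache <- new.env(parent = emptyenv())

# Reference corpus (seed 42) with both comparisons, generated once per
# test run and reused across test files.
get_test_corpus <- function() {
  if (!exists("bundle", envir = .corpus_cache)) {
    dir <- file.path(tempdir(), "rnamotifsim-test-corpus")
    des <- reference_corpus_design(10)
    manifest <- generate_corpus(des$specs, des$planted, seed = 42, dir = dir)
    corpus <- read_motif_corpus(file.path(dir, "motifs.in"))
    ci <- compare_motif_families(corpus, "interaction")
    cc <- compare_motif_families(corpus, "coordinate")
    assign("bundle", list(dir = dir, design = des, manifest = manifest,
                          corpus = corpus, interaction = ci,
                          coordinate = cc),
           envir = .corpus_cache)
  }
  get("bundle", envir = .corpus_cache)
}
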