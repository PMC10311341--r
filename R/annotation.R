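#' Create an annotation set
#'
#' Container for the base-pair and base-stacking annotations of one
#' structure.  Base pairs are Leontis-Westhof classified: each base
#' interacts through one of its three edges (Watson-Crick `W`, Hoogsteen
#' `H`, Sugar `S`) and the pair has a cis or trans glycosidic-bond
#' orientation.  Pairs and stacks are stored in canonical residue order
#' (`i < j` by chain, residue number, insertion code).
#'
#' @param structure_id identifier of the annotated structure.
#' @param pairs tibble with columns `rid_i`, `rid_j`, `chain_i`, `chain_j`,
#'   `edge_i`, `edge_j` (each one of `"W"`, `"H"`, `"S"`), `orientation`
#'   (`"cis"`/`"trans"`), `source`.
#' @param stacks tibble with columns `rid_i`, `rid_j`, `chain_i`,
#'   `chain_j`, `kind` (`"upward"`, `"downward"`, `"outward"`, `"inward"`
#'   or `"unspecified"`), `source`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(structure_id,
                           pairs = empty_pairs(),
                           stacks = empty_stacks()) {
  structure(list(structure_id = structure_id, pairs = pairs, stacks = stacks,
                 conflicts = NULL),
            class = "annotation_set")
}

empty_pairs <- function() {
  tibble(rid_i = character(), rid_j = character(),
         chain_i = character(), chain_j = character(),
         edge_i = character(), edge_j = character(),
         orientation = character(), source = character())
}

empty_stacks <- function() {
  tibble(rid_i = character(), rid_j = character(),
         chain_i = character(), chain_j = character(),
         kind = character(), source = character())
}

pair_class <- function(edge_i, edge_j, orientation) {
  paste0(substr(orientation, 1, 1), edge_i, edge_j)
}

STACK_KIND_MAP <- c(
  "s35" = "upward", "s53" = "downward", "s55" = "outward", "s33" = "inward",
  "upward" = "upward", "downward" = "downward", "outward" = "outward",
  "inward" = "inward", "stack" = "unspecified"
)

# Parse a residue token "CHAIN.SEQ" or "CHAIN.SEQ.ICODE".
parse_res_token <- function(tok) {
  parts <- strsplit(tok, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2L) abort(paste0("malformed residue token: ", tok))
  list(chain = parts[1], seq_num = as.integer(parts[2]),
       icode = if (length(parts) >= 3L) parts[3] else "")
}

#' Read base-pair and stacking annotations
#'
#' Reads an annotation listing in either of the two minimal dialects the
#' package understands.  The DSSR-style dialect carries an explicit record
#' type:
#'
#' ```
#' pair  A.10 A.25 tHS
#' stack A.10 A.11 upward
#' ```
#'
#' while the FR3D-style dialect is bare triples, with stackings encoded as
#' `s35`/`s53`/`s55`/`s33`:
#'
#' ```
#' A.10 A.25 tHS
#' A.10 A.11 s35
#' ```
#'
#' Pair classes are a cis/trans prefix (`c`/`t`) followed by the two edge
#' letters.  Residue tokens are `chain.seq` or `chain.seq.icode`.
#'
#' @param path path to the annotation file.
#' @param source annotation source label (`"DSSR"` or `"FR3D"`).
#' @param structure_id structure the annotations describe; defaults to the
#'   file stem.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(path, source = c("DSSR", "FR3D"),
                             structure_id = NULL) {
  source <- match.arg(source)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  structure_id <- structure_id %||%
    sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  prow <- list(); srow <- list()
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (toks[1] %in% c("pair", "stack")) {
      kind_tok <- toks[1]; toks <- toks[-1]
    } else {
      kind_tok <- NA_character_
    }
    if (length(toks) != 3L) abort(paste0("malformed annotation line: ", ln))
    ri <- parse_res_token(toks[1]); rj <- parse_res_token(toks[2])
    cls <- toks[3]
    is_stack <- identical(kind_tok, "stack") ||
      (is.na(kind_tok) && cls %in% names(STACK_KIND_MAP))
    if (is_stack) {
      srow[[length(srow) + 1L]] <- c(toks[1], toks[2], ri$chain, rj$chain,
                                     unname(STACK_KIND_MAP[cls]))
    } else {
      if (!grepl("^[ct][WHS][WHS]$", cls)) {
        abort(paste0("malformed pair class '", cls, "' in line: ", ln))
      }
      prow[[length(prow) + 1L]] <- c(toks[1], toks[2], ri$chain, rj$chain,
                                     substr(cls, 2, 2), substr(cls, 3, 3),
                                     if (substr(cls, 1, 1) == "c") "cis" else "trans")
    }
  }
  pairs <- if (length(prow) > 0L) {
    m <- do.call(rbind, prow)
    tibble(rid_i = m[, 1], rid_j = m[, 2], chain_i = m[, 3], chain_j = m[, 4],
           edge_i = m[, 5], edge_j = m[, 6], orientation = m[, 7],
           source = source)
  } else empty_pairs()
  stacks <- if (length(srow) > 0L) {
    m <- do.call(rbind, srow)
    tibble(rid_i = m[, 1], rid_j = m[, 2], chain_i = m[, 3], chain_j = m[, 4],
           kind = m[, 5], source = source)
  } else empty_stacks()
  canonicalize_annotations(annotation_set(structure_id, pairs, stacks))
}

# Order residues within each interaction so rid_i < rid_j by
# (chain, seq_num, icode); swap the edges along with the residues.
canonicalize_annotations <- function(ann) {
  ann$pairs <- canonicalize_pairs(ann$pairs)
  ann$stacks <- canonicalize_stacks(ann$stacks)
  ann
}

res_key <- function(rid) {
  p <- map(rid, parse_res_token)
  sprintf("%s|%09d|%s", map_chr(p, "chain"),
          map_int(p, "seq_num") + 500000000L, map_chr(p, "icode"))
}

canonicalize_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  ki <- res_key(pairs$rid_i); kj <- res_key(pairs$rid_j)
  if (any(ki == kj)) abort("base pair between a residue and itself")
  swap <- ki > kj
  out <- pairs
  out$rid_i[swap] <- pairs$rid_j[swap]; out$rid_j[swap] <- pairs$rid_i[swap]
  out$chain_i[swap] <- pairs$chain_j[swap]; out$chain_j[swap] <- pairs$chain_i[swap]
  out$edge_i[swap] <- pairs$edge_j[swap]; out$edge_j[swap] <- pairs$edge_i[swap]
  out[order(res_key(out$rid_i), res_key(out$rid_j)), ]
}

canonicalize_stacks <- function(stacks) {
  if (nrow(stacks) == 0L) return(stacks)
  ki <- res_key(stacks$rid_i); kj <- res_key(stacks$rid_j)
  if (any(ki == kj)) abort("stacking between a residue and itself")
  swap <- ki > kj
  out <- stacks
  out$rid_i[swap] <- stacks$rid_j[swap]; out$rid_j[swap] <- stacks$rid_i[swap]
  out$chain_i[swap] <- stacks$chain_j[swap]; out$chain_j[swap] <- stacks$chain_i[swap]
  flip <- c(upward = "downward", downward = "upward",
            outward = "outward", inward = "inward",
            unspecified = "unspecified")
  out$kind[swap] <- unname(flip[stacks$kind[swap]])
  out[order(res_key(out$rid_i), res_key(out$rid_j)), ]
}

#' Merge two annotation sets with frequency-based conflict resolution
#'
#' Forms the union of two annotation sets for the same structure.
#' Interactions asserted identically by both sources are kept with a joint
#' source label.  When the sources disagree -- a different pair class at
#' the same residue pair, or one base edge claimed by two different
#' partners -- the conflict is resolved by [resolve_conflicts()]: the
#' interaction whose class is most frequent among the chain's agreeing
#' interactions wins.  The returned set records every conflict it resolved
#' in its `conflicts` element.
#'
#' @param a,b `annotation_set` objects describing the same structure.
#' @param class_counts optional precomputed class-frequency table (tibble
#'   with `chain`, `class`, `n`) to use instead of counts derived from the
#'   agreeing interactions of this structure.
#' @return a merged `annotation_set` with a `conflicts` tibble.
#' @export
merge_annotations <- function(a, b, class_counts = NULL) {
  if (!identical(a$structure_id, b$structure_id)) {
    abort(sprintf("annotation sets describe different structures: %s vs %s",
                  a$structure_id, b$structure_id))
  }
  pk <- function(p) paste(p$rid_i, p$rid_j, sep = "~")
  pa <- a$pairs; pb <- b$pairs
  ka <- pk(pa); kb <- pk(pb)
  cls_a <- pair_class(pa$edge_i, pa$edge_j, pa$orientation)
  cls_b <- pair_class(pb$edge_i, pb$edge_j, pb$orientation)

  agree_idx <- which(ka %in% kb & paste(ka, cls_a) %in% paste(kb, cls_b))
  agree <- pa[agree_idx, ]
  if (nrow(agree) > 0L) agree$source <- "DSSR+FR3D"

  only_a <- pa[!(ka %in% kb), ]
  only_b <- pb[!(kb %in% ka), ]

  conf_keys <- intersect(ka, kb)
  conf_keys <- conf_keys[vapply(conf_keys, function(k) {
    !identical(sort(cls_a[ka == k]), sort(cls_b[kb == k]))
  }, logical(1))]

  counts <- class_counts %||% class_frequencies(agree)

  resolved <- list(); conf_log <- list()
  for (k in conf_keys) {
    grp <- bind_rows(pa[ka == k, ], pb[kb == k, ])
    win <- resolve_conflicts(list(grp), counts)[[1]]
    resolved[[length(resolved) + 1L]] <- win
    conf_log[[length(conf_log) + 1L]] <- tibble(
      kind = "pair_class", key = k,
      candidates = paste(pair_class(grp$edge_i, grp$edge_j, grp$orientation),
                         collapse = "|"),
      chosen = pair_class(win$edge_i, win$edge_j, win$orientation)
    )
  }
  pairs <- bind_rows(agree, only_a, only_b, bind_rows(resolved))

  # One partner per nucleotide edge: drop the chain-wise rarer class when a
  # residue edge participates in two merged pairs with different partners.
  if (nrow(pairs) > 0L) {
    repeat {
      ep <- bind_rows(
        tibble(rid = pairs$rid_i, edge = pairs$edge_i, row = seq_len(nrow(pairs))),
        tibble(rid = pairs$rid_j, edge = pairs$edge_j, row = seq_len(nrow(pairs)))
      )
      dup <- ep %>% group_by(.data$rid, .data$edge) %>%
        filter(n() > 1L) %>% ungroup()
      if (nrow(dup) == 0L) break
      key1 <- paste(dup$rid[1], dup$edge[1])
      rows <- dup$row[paste(dup$rid, dup$edge) == key1]
      grp <- pairs[rows, ]
      win <- resolve_conflicts(list(grp), counts)[[1]]
      keep_row <- rows[which(pair_class(grp$edge_i, grp$edge_j, grp$orientation) ==
                               pair_class(win$edge_i, win$edge_j, win$orientation) &
                               grp$rid_i == win$rid_i & grp$rid_j == win$rid_j)][1]
      conf_log[[length(conf_log) + 1L]] <- tibble(
        kind = "edge_partner", key = key1,
        candidates = paste(grp$rid_i, grp$rid_j, sep = "-", collapse = "|"),
        chosen = paste(win$rid_i, win$rid_j, sep = "-")
      )
      pairs <- pairs[-setdiff(rows, keep_row), ]
    }
  }

  # Stackings: same frequency rule for kind mismatches at the same pair.
  sk <- function(s) paste(s$rid_i, s$rid_j, sep = "~")
  sa <- a$stacks; sb <- b$stacks
  ska <- sk(sa); skb <- sk(sb)
  s_agree_idx <- which(ska %in% skb &
                         paste(ska, sa$kind) %in% paste(skb, sb$kind))
  s_agree <- sa[s_agree_idx, ]
  if (nrow(s_agree) > 0L) s_agree$source <- "DSSR+FR3D"
  s_only_a <- sa[!(ska %in% skb), ]
  s_only_b <- sb[!(skb %in% ska), ]
  s_conf <- setdiff(intersect(ska, skb), ska[s_agree_idx])
  s_counts <- s_agree %>% group_by(chain = .data$chain_i, class = .data$kind) %>%
    summarise(n = n(), .groups = "drop")
  s_res <- list()
  for (k in s_conf) {
    grp <- bind_rows(sa[ska == k, ], sb[skb == k, ])
    cnt <- vapply(grp$kind, function(cl) {
      hit <- s_counts$n[s_counts$chain == grp$chain_i[1] & s_counts$class == cl]
      if (length(hit) == 0L) 0L else as.integer(hit[1])
    }, integer(1))
    win <- grp[order(-cnt, grp$kind), ][1, ]
    win$source <- "merged"
    s_res[[length(s_res) + 1L]] <- win
    conf_log[[length(conf_log) + 1L]] <- tibble(
      kind = "stack_kind", key = k,
      candidates = paste(grp$kind, collapse = "|"), chosen = win$kind
    )
  }
  stacks <- bind_rows(s_agree, s_only_a, s_only_b, bind_rows(s_res))

  out <- annotation_set(a$structure_id,
                        canonicalize_pairs(pairs),
                        canonicalize_stacks(stacks))
  out$conflicts <- if (length(conf_log) > 0L) bind_rows(conf_log) else
    tibble(kind = character(), key = character(),
           candidates = character(), chosen = character())
  out
}

#' Class frequencies over agreeing interactions
#'
#' Counts Leontis-Westhof class occurrences per chain over a set of base
#' pairs (normally the interactions both annotation sources agree on).
#' These counts drive conflict resolution.
#'
#' @param pairs a pairs tibble.
#' @return tibble with `chain`, `class`, `n`.
#' @export
class_frequencies <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble(chain = character(), class = character(), n = integer()))
  }
  tibble(chain = pairs$chain_i,
         class = pair_class(pairs$edge_i, pairs$edge_j, pairs$orientation)) %>%
    group_by(.data$chain, .data$class) %>%
    summarise(n = n(), .groups = "drop")
}

#' Resolve conflicting base-pair groups by chain-wide class frequency
#'
#' For each group of mutually conflicting base pairs (same residue pair
#' with different classes, or one residue edge claimed by several
#' partners), keeps the pair whose class occurs most often among the
#' chain's agreeing interactions.  Ties are broken in favour of a pair
#' asserted jointly by both sources, then by the lexicographically smaller
#' class label; the outcome is fully deterministic.
#'
#' @param groups list of pairs tibbles, each with >= 2 rows.
#' @param class_counts tibble with `chain`, `class`, `n` (see
#'   [class_frequencies()]); may also be an `annotation_set`, in which case
#'   frequencies are computed from its pairs.
#' @return list of single-row tibbles, one chosen pair per group.
#' @export
resolve_conflicts <- function(groups, class_counts) {
  if (inherits(class_counts, "annotation_set")) {
    class_counts <- class_frequencies(class_counts$pairs)
  }
  map(groups, function(grp) {
    if (nrow(grp) < 2L) abort("conflict group must contain at least 2 pairs")
    cls <- pair_class(grp$edge_i, grp$edge_j, grp$orientation)
    cnt <- vapply(seq_len(nrow(grp)), function(r) {
      hit <- class_counts$n[class_counts$chain == grp$chain_i[r] &
                              class_counts$class == cls[r]]
      if (length(hit) == 0L) 0L else as.integer(sum(hit))
    }, integer(1))
    joint <- as.integer(grp$source == "DSSR+FR3D")
    win <- grp[order(-cnt, -joint, cls), ][1, , drop = FALSE]
    if (!identical(win$source, "DSSR+FR3D")) win$source <- "merged"
    win
  })
}

#' Restrict an annotation set to a motif
#'
#' Keeps only the interactions whose two endpoints both lie inside the
#' motif (closure rule); interactions reaching outside the motif region are
#' dropped.  An empty result is valid -- the interaction aligner then sees
#' a sequence-only graph.
#'
#' @param ann an `annotation_set`.
#' @param motif an `rna_motif`.
#' @return an `annotation_set` restricted to the motif's residues.
#' @export
motif_interactions <- function(ann, motif) {
  rids <- motif$nucleotides$rid
  out <- annotation_set(
    ann$structure_id,
    filter(ann$pairs, .data$rid_i %in% rids & .data$rid_j %in% rids),
    filter(ann$stacks, .data$rid_i %in% rids & .data$rid_j %in% rids)
  )
  out
}

#' Write a per-motif interaction file
#'
#' Emits the sequence line and interaction lines for one motif, the format
#' consumed by the interaction aligner's file-based interface.
#'
#' @param motif an `rna_motif`.
#' @param ann an `annotation_set` already restricted to the motif.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_motif_interactions <- function(motif, ann, path) {
  seq_line <- paste0(">", motif$motif_id, " ", motif$family, " ",
                     paste(tapply(motif$nucleotides$base,
                                  motif$nucleotides$segment, paste0,
                                  collapse = ""), collapse = "&"))
  p <- ann$pairs
  s <- ann$stacks
  lines <- c(
    sprintf("# rnamotifsim %s", as.character(utils::packageVersion("rnamotifsim"))),
    seq_line,
    if (nrow(p) > 0L) sprintf("pair %s %s %s", p$rid_i, p$rid_j,
                              pair_class(p$edge_i, p$edge_j, p$orientation)),
    if (nrow(s) > 0L) sprintf("stack %s %s %s", s$rid_i, s$rid_j, s$kind)
  )
  writeLines(lines, path)
  invisible(path)
}
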