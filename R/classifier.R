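# Evaluation harness: alignment-derived features against family
# representatives, balanced Gaussian naive Bayes binary classifiers with
# repeated stratified cross-validation, and a multiclass variant.

#' Select a family's representative motif
#'
#' The representative is the instance that best aligns with all other
#' instances of its family: it maximizes the mean alignment score (or
#' TM-score) over its same-family partners; ties are broken by the lowest
#' mean RMSD, then by the lexicographically smallest motif id.
#'
#' @param records pair-record tibble containing the family's intra pairs.
#' @param family family name.
#' @return tibble with `family`, `motif_id`, `criterion_score`,
#'   `mean_rmsd`.
#' @export
select_representative <- function(records, family) {
  rec <- intra_records(records, family)
  ids <- sort(unique(c(rec$motif_a, rec$motif_b)))
  if (length(ids) < 2L) {
    abort(sprintf("family %s has fewer than 2 instances; no representative", family))
  }
  stats <- map(ids, function(id) {
    r <- rec[rec$motif_a == id | rec$motif_b == id, ]
    tibble(motif_id = id,
           criterion_score = mean(r$score_or_tm),
           mean_rmsd = mean(r$rmsd, na.rm = TRUE))
  }) %>% bind_rows()
  stats <- arrange(stats, dplyr::desc(.data$criterion_score),
                   .data$mean_rmsd, .data$motif_id)
  tibble(family = family, motif_id = stats$motif_id[1],
         criterion_score = stats$criterion_score[1],
         mean_rmsd = stats$mean_rmsd[1])
}

#' Alignment-derived feature vectors against family representatives
#'
#' Aligns every motif against each family representative and assembles one
#' feature row per motif.  In interaction mode each representative
#' contributes five features (alignment score, aligned length, RMSD,
#' matching base pairs, matching stackings); in coordinate mode three
#' (aligned length, RMSD, TM-score).  Blocks are ordered by representative
#' family name, so the column layout is deterministic.
#'
#' @param motifs named list of `rna_motif` objects.
#' @param representatives tibble with `family`, `motif_id` (e.g. bound
#'   rows of [select_representative()] outputs).
#' @param mode `"interaction"` or `"coordinate"`.
#' @param annotations named list of `annotation_set`s (interaction mode).
#' @param iparams,cparams parameter objects.
#' @return tibble: `motif_id`, `family`, then numeric feature columns
#'   named `<rep_family>_<feature>`.  Motifs whose alignment against any
#'   representative fails are dropped with a warning.
#' @export
build_features <- function(motifs, representatives,
                           mode = c("interaction", "coordinate"),
                           annotations = NULL,
                           iparams = interaction_params(),
                           cparams = coordinate_params()) {
  mode <- match.arg(mode)
  representatives <- arrange(representatives, .data$family)
  rep_motifs <- map(representatives$motif_id, function(id) motifs[[id]])
  graphs <- NULL
  rep_graphs <- NULL
  if (mode == "interaction") {
    gr <- function(m) {
      ann <- annotations[[m$pdb_id]] %||% annotation_set(m$pdb_id)
      interaction_graph(m, ann)
    }
    graphs <- map(motifs, gr)
    rep_graphs <- map(rep_motifs, gr)
  }
  rows <- list()
  for (id in names(motifs)) {
    vals <- list(motif_id = id, family = motifs[[id]]$family)
    ok <- TRUE
    for (r in seq_len(nrow(representatives))) {
      rf <- representatives$family[r]
      rec <- tryCatch(
        align_pair_record(motifs[[id]], rep_motifs[[r]], mode,
                          graphs[[id]], rep_graphs[[r]], iparams, cparams),
        error = function(e) NULL
      )
      if (is.null(rec)) { ok <- FALSE; break }
      if (mode == "interaction") {
        vals[[paste0(rf, "_score")]] <- rec$score_or_tm
        vals[[paste0(rf, "_length")]] <- as.numeric(rec$aligned_length)
        vals[[paste0(rf, "_rmsd")]] <- ifelse(is.na(rec$rmsd), 0, rec$rmsd)
        vals[[paste0(rf, "_pairs")]] <- as.numeric(rec$matched_pairs)
        vals[[paste0(rf, "_stacks")]] <- as.numeric(rec$matched_stacks)
      } else {
        vals[[paste0(rf, "_length")]] <- as.numeric(rec$aligned_length)
        vals[[paste0(rf, "_rmsd")]] <- ifelse(is.na(rec$rmsd), 0, rec$rmsd)
        vals[[paste0(rf, "_tm")]] <- rec$score_or_tm
      }
    }
    if (!ok) {
      warn(sprintf("motif %s: alignment against a representative failed; row dropped", id))
      next
    }
    rows[[length(rows) + 1L]] <- as_tibble(vals)
  }
  bind_rows(rows)
}

# ---- Gaussian naive Bayes ------------------------------------------------
# Authored here because the evaluation protocol pins the variance
# smoothing semantics: the per-class, per-feature variances are inflated
# by var_smoothing times the largest feature variance of the training set.

gnb_fit <- function(X, y, var_smoothing = 1e-9) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  eps <- var_smoothing * max(apply(X, 2, function(c) mean((c - mean(c))^2)))
  mods <- map(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(class = cl,
         prior = nrow(Xi) / nrow(X),
         mu = colMeans(Xi),
         var = apply(Xi, 2, function(c) mean((c - mean(c))^2)) + eps)
  })
  structure(list(classes = classes, models = mods, eps = eps), class = "gnb")
}

gnb_predict <- function(fit, X) {
  X <- as.matrix(X)
  ll <- vapply(fit$models, function(m) {
    v <- pmax(m$var, 1e-300)
    rowSums(sweep(sweep(X, 2, m$mu)^2, 2, 2 * v, "/") * -1 -
              matrix(0.5 * log(2 * pi * v), nrow(X), ncol(X), byrow = TRUE)) +
      log(m$prior)
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) ll <- matrix(ll, nrow = 1L)
  fit$classes[max.col(ll, ties.method = "first")]
}

# Stratified k-fold assignment: within each class, instances are shuffled
# and dealt round-robin, keeping the class ratio in every fold.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

feature_columns <- function(features) {
  setdiff(names(features), c("motif_id", "family"))
}

#' Evaluate a balanced binary Gaussian naive Bayes classifier
#'
#' Labels the positive family as Class 1 and everything else Class 0,
#' undersamples Class 0 to the size of Class 1 (one seeded draw per
#' report), and runs stratified 3-fold cross-validation repeated 5 times
#' (15 runs) with a Gaussian naive Bayes classifier (variance smoothing
#' 1e-9).  Reports per-run and mean accuracy, sensitivity (Class 1
#' recall) and specificity (Class 0 recall), as percentages.
#'
#' @param features a feature table from [build_features()].
#' @param positive_family name of the Class-1 family.
#' @param seed RNG seed for undersampling and fold assignment.
#' @param n_splits folds per repeat.
#' @param n_repeats repeats.
#' @param var_smoothing Gaussian naive Bayes variance smoothing.
#' @param resample_per_repeat redraw the undersample every repeat instead
#'   of once per report.
#' @return an object of class `cv_report`.
#' @export
evaluate_binary <- function(features, positive_family, seed = 1,
                            n_splits = 3, n_repeats = 5,
                            var_smoothing = 1e-9,
                            resample_per_repeat = FALSE) {
  cols <- feature_columns(features)
  pos <- features$family == positive_family
  if (sum(pos) < 2 * n_splits) {
    abort(sprintf("positive class too small: %d instances (need >= %d)",
                  sum(pos), 2 * n_splits))
  }
  runs <- with_seed(seed, {
    draw <- function() {
      neg_idx <- which(!pos)
      sel <- sample(neg_idx, sum(pos))
      sort(c(which(pos), sel))
    }
    idx <- draw()
    out <- list()
    for (rep_i in seq_len(n_repeats)) {
      if (resample_per_repeat && rep_i > 1L) idx <- draw()
      X <- as.matrix(features[idx, cols])
      y <- ifelse(features$family[idx] == positive_family, 1L, 0L)
      fold <- stratified_folds(y, n_splits)
      for (f in seq_len(n_splits)) {
        tr <- fold != f; te <- fold == f
        fit <- gnb_fit(X[tr, , drop = FALSE], y[tr], var_smoothing)
        pred <- gnb_predict(fit, X[te, , drop = FALSE])
        truth <- y[te]
        out[[length(out) + 1L]] <- tibble(
          run = length(out) + 1L, repeat_i = rep_i, fold = f,
          n_class1 = sum(y == 1L), n_class0 = sum(y == 0L),
          accuracy = 100 * mean(pred == truth),
          sensitivity = 100 * mean(pred[truth == 1L] == 1L),
          specificity = 100 * mean(pred[truth == 0L] == 0L)
        )
      }
    }
    bind_rows(out)
  })
  new_cv_report(model = positive_family, kind = "binary", runs = runs)
}

#' Evaluate a multiclass Gaussian naive Bayes classifier
#'
#' Same cross-validation protocol as [evaluate_binary()] but over all
#' families jointly, without undersampling (the stratified folds keep the
#' class ratios).  Reports mean accuracy.
#'
#' @inheritParams evaluate_binary
#' @param families optional subset of families to include.
#' @return an object of class `cv_report`.
#' @export
evaluate_multiclass <- function(features, families = NULL, seed = 1,
                                n_splits = 3, n_repeats = 5,
                                var_smoothing = 1e-9) {
  if (!is.null(families)) {
    features <- filter(features, .data$family %in% families)
  }
  tab <- table(features$family)
  if (length(tab) < 2L) abort("need at least 2 families")
  if (any(tab < 2 * n_splits)) {
    abort(sprintf("family too small for %d-fold CV: %s (need >= %d)",
                  n_splits, names(tab)[which.min(tab)], 2 * n_splits))
  }
  cols <- feature_columns(features)
  runs <- with_seed(seed, {
    X <- as.matrix(features[, cols])
    y <- features$family
    out <- list()
    for (rep_i in seq_len(n_repeats)) {
      fold <- stratified_folds(y, n_splits)
      for (f in seq_len(n_splits)) {
        tr <- fold != f; te <- fold == f
        fit <- gnb_fit(X[tr, , drop = FALSE], y[tr], var_smoothing)
        pred <- gnb_predict(fit, X[te, , drop = FALSE])
        out[[length(out) + 1L]] <- tibble(
          run = length(out) + 1L, repeat_i = rep_i, fold = f,
          n_class1 = NA_integer_, n_class0 = NA_integer_,
          accuracy = 100 * mean(pred == y[te]),
          sensitivity = NA_real_, specificity = NA_real_
        )
      }
    }
    bind_rows(out)
  })
  new_cv_report(model = "multiclass", kind = "multiclass", runs = runs)
}

new_cv_report <- function(model, kind, runs) {
  structure(list(model = model, kind = kind, runs = runs,
                 means = list(accuracy = mean(runs$accuracy),
                              sensitivity = mean(runs$sensitivity),
                              specificity = mean(runs$specificity))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s (%s): %d runs\n", x$model, x$kind, nrow(x$runs)))
  cat(sprintf("  mean accuracy    %.1f%%\n", x$means$accuracy))
  if (is.finite(x$means$sensitivity)) {
    cat(sprintf("  mean sensitivity %.1f%%\n  mean specificity %.1f%%\n",
                x$means$sensitivity, x$means$specificity))
  }
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation report
#' @param x a `cv_report`.
#' @param ... unused.
#' @return the per-run metric tibble.
#' @export
tidy.cv_report <- function(x, ...) {
  mutate(x$runs, model = x$model, kind = x$kind)
}

#' One-row summary of a cross-validation report
#' @param x a `cv_report`.
#' @param ... unused.
#' @return tibble with mean metrics.
#' @export
glance.cv_report <- function(x, ...) {
  tibble(model = x$model, kind = x$kind, n_runs = nrow(x$runs),
         accuracy = x$means$accuracy,
         sensitivity = x$means$sensitivity,
         specificity = x$means$specificity)
}

#' 2D principal-component projection of a feature table
#'
#' Standardizes the feature columns (constant columns are dropped with a
#' warning), runs PCA, and returns the first two principal components per
#' motif -- a plotting utility for eyeballing family separation.
#'
#' @param features a feature table from [build_features()].
#' @return tibble: `motif_id`, `family`, `PC1`, `PC2`; attribute
#'   `variance` holds the component variances.
#' @export
pca_projection <- function(features) {
  cols <- feature_columns(features)
  if (nrow(features) < 3L || length(cols) < 2L) {
    abort("need at least 3 motifs and 2 features for a projection")
  }
  X <- as.matrix(features[, cols])
  const <- apply(X, 2, function(c) sd(c) < 1e-12)
  if (any(const)) {
    warn(sprintf("dropping %d constant feature(s): %s", sum(const),
                 paste(cols[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2L) abort("fewer than 2 non-constant features")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  out <- tibble(motif_id = features$motif_id, family = features$family,
                PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  attr(out, "variance") <- pc$sdev^2
  out
}
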