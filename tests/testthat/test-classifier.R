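rec_c <- function(a, b, fam, score, rmsd = 0.5) {
  tibble::tibble(motif_a = a, motif_b = b, family_a = fam, family_b = fam,
                 mode = "interaction", aligned_length = 10, rmsd = rmsd,
                 score_or_tm = score, matched_pairs = NA_integer_,
                 matched_stacks = NA_integer_)
}

test_that("representative selection maximizes mean score with stated tie-breaks", {
  # identical clones: lexicographically first id wins
  r <- dplyr::bind_rows(rec_c("m2", "m1", "F", 1), rec_c("m1", "m3", "F", 1),
                        rec_c("m2", "m3", "F", 1))
  expect_equal(select_representative(r, "F")$motif_id, "m1")

  # strictly higher mean score wins
  r2 <- dplyr::bind_rows(rec_c("a", "b", "F", 2), rec_c("a", "c", "F", 2),
                         rec_c("b", "c", "F", 1))
  expect_equal(select_representative(r2, "F")$motif_id, "a")

  # planted star center: high score to everyone else
  set.seed(601)
  ids <- sprintf("s%d", 1:6)
  rows <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    s <- if (i == 3 || j == 3) 3 else runif(1, 0.5, 1.5)
    rows[[length(rows) + 1L]] <- rec_c(ids[i], ids[j], "F", s)
  }
  expect_equal(select_representative(dplyr::bind_rows(rows), "F")$motif_id, "s3")

  expect_error(select_representative(rec_c("a", "b", "F", 1)[0, ], "F"),
               "fewer than 2")
})

test_that("feature tables have the documented per-representative block layout", {
  b <- get_test_corpus()
  motifs <- b$corpus$motifs
  fams <- c("famE", "famF", "famG")
  reps <- dplyr::bind_rows(lapply(fams, function(f)
    select_representative(b$interaction$kept_records, f)))
  in_fams <- names(motifs)[vapply(motifs, function(m) m$family %in% fams,
                                  logical(1))]
  sub <- motifs[unique(c(reps$motif_id, head(in_fams, 4)))]

  fi <- build_features(sub, reps, "interaction", b$corpus$annotations)
  expect_equal(ncol(fi), 2 + 3 * 5)  # id, family + 3 reps x 5 features
  expect_true(all(sprintf("fam%s_score", c("E", "F", "G")) %in% names(fi)))

  fc <- build_features(sub, reps, "coordinate")
  expect_equal(ncol(fc), 2 + 3 * 3)  # 3 reps x 3 features

  # a representative's own row has RMSD 0 against itself
  rep1 <- reps$motif_id[1]
  own <- build_features(motifs[rep1], reps[1, ], "coordinate")
  expect_equal(own[[paste0(reps$family[1], "_rmsd")]], 0, tolerance = 1e-9)
})

test_that("the in-package Gaussian naive Bayes agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(602)
  X <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 2.5), 20, 3))
  y <- rep(c("a", "b"), each = 20)
  fit <- rnamotifsim:::gnb_fit(X, y, var_smoothing = 0)
  ref <- e1071::naiveBayes(data.frame(X), y)
  Xt <- rbind(matrix(rnorm(30, 0), 10, 3), matrix(rnorm(30, 2.5), 10, 3))
  got <- rnamotifsim:::gnb_predict(fit, Xt)
  want <- as.character(predict(ref, data.frame(Xt)))
  expect_equal(got, want)
  # class-conditional means agree with the independent fit
  expect_equal(unname(fit$models[[1]]$mu[1]), unname(ref$tables$X1["a", 1]),
               tolerance = 1e-9)
  expect_equal(unname(fit$models[[1]]$mu), unname(colMeans(X[1:20, ])),
               tolerance = 1e-9)
})

test_that("binary evaluation balances classes and separates blobs", {
  feats <- blob_features(12, list(pos = c(0, 0, 0), neg1 = c(6, 6, 6),
                                  neg2 = c(-6, 6, -6)), seed = 603)
  rep1 <- evaluate_binary(feats, "pos", seed = 9)
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$runs), 15L)  # 3 splits x 5 repeats
  expect_true(all(rep1$runs$n_class1 == rep1$runs$n_class0))
  expect_gt(rep1$means$accuracy, 95)

  # determinism under a seed
  rep2 <- evaluate_binary(feats, "pos", seed = 9)
  expect_equal(tidy(rep1), tidy(rep2))

  g <- glance(rep1)
  expect_equal(g$n_runs, 15L)
  expect_equal(g$model, "pos")

  expect_error(evaluate_binary(feats[feats$family != "pos", ], "pos"),
               "positive class too small")
})

test_that("shuffled labels drive binary accuracy to chance", {
  feats <- blob_features(15, list(pos = c(0, 0), neg = c(5, 5)), seed = 604)
  shuffled <- feats
  shuffled$family <- rnamotifsim:::with_seed(99, sample(shuffled$family))
  rep <- evaluate_binary(shuffled, "pos", seed = 9)
  expect_lt(abs(rep$means$accuracy - 50), 18)
})

test_that("multiclass evaluation hits the separated and chance baselines", {
  feats <- blob_features(10, list(a = c(0, 0, 0), b = c(7, 0, 7),
                                  c = c(0, 7, -7)), seed = 605)
  rep <- evaluate_multiclass(feats, seed = 4)
  expect_gt(rep$means$accuracy, 95)
  expect_true(is.na(rep$means$sensitivity))

  same <- blob_features(12, list(a = c(0, 0), b = c(0, 0), c = c(0, 0)),
                        seed = 606)
  rep2 <- evaluate_multiclass(same, seed = 4)
  expect_lt(abs(rep2$means$accuracy - 100 / 3), 18)

  expect_identical(tidy(evaluate_multiclass(feats, seed = 4)), tidy(rep))
})

test_that("stratified folds are non-overlapping, exhaustive, and ratio-preserving", {
  y <- rep(c("a", "b"), c(12, 6))
  rnamotifsim:::with_seed(607, {
    for (r in 1:5) {
      fold <- rnamotifsim:::stratified_folds(y, 3)
      expect_setequal(fold, 1:3)
      expect_equal(length(fold), 18L)
      for (f in 1:3) {
        expect_equal(sum(fold == f & y == "a"), 4L)
        expect_equal(sum(fold == f & y == "b"), 2L)
      }
    }
  })
})

test_that("PCA projection separates blobs and handles degeneracies", {
  feats <- blob_features(10, list(a = c(0, 0, 0), b = c(8, 8, 8)), seed = 608)
  pr <- pca_projection(feats)
  expect_equal(names(pr), c("motif_id", "family", "PC1", "PC2"))
  expect_gt(abs(mean(pr$PC1[pr$family == "a"]) -
                  mean(pr$PC1[pr$family == "b"])), 2)
  v <- attr(pr, "variance")
  expect_gte(v[1], v[2])

  dup <- feats[c(1, 1, 2:10), ]
  prd <- pca_projection(dup)
  expect_equal(prd[1, c("PC1", "PC2")], prd[2, c("PC1", "PC2")])

  feats$const <- 1
  expect_warning(pca_projection(feats), "constant feature")
})
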