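test_that("common arm scores scale onto the unit range as specified", {
  expect_equal(common_arm_score(bars_arm = 1.32, group = "ataxia"), 0.33)
  expect_equal(common_arm_score(bars_arm = 1.15, group = "ataxia"), 0.2875)
  expect_equal(common_arm_score(bars_arm = 0, group = "ataxia"), 0)
  expect_equal(common_arm_score(group = "control"), 0)
  expect_equal(common_arm_score(updrs_arm_sum = 3.68,
                                group = "parkinsonism"),
               3.68 / 12, tolerance = 1e-12)
  expect_equal(common_arm_score(updrs_arm_sum = 3.68,
                                group = "parkinsonism",
                                updrs_divisor = 24),
               3.68 / 24, tolerance = 1e-12)
  expect_error(common_arm_score(bars_arm = 5, group = "ataxia"),
               class = "tapkin_validation_error")
  expect_error(common_arm_score(updrs_arm_sum = -1, group = "parkinsonism"),
               class = "tapkin_validation_error")
  expect_warning(common_arm_score(updrs_arm_sum = 16,
                                  group = "parkinsonism"), "clipped")
})

test_that("per-family PCA yields 10 orthonormal components over 5 families", {
  cf <- small_cohort_features()
  res <- fit_family_pca(cf$features)
  expect_equal(ncol(res$scores), 10)
  expect_equal(sort(colnames(res$scores)),
               sort(paste0(rep(c("TS", "Pk", "Th", "PkTh", "ThTh"),
                               each = 2), ".PC", 1:2)))
  for (b in res$transform$blocks) {
    gram <- t(b$loadings) %*% b$loadings
    expect_equal(gram, diag(2), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_gte(b$var_explained[1], b$var_explained[2])
  }
})

test_that("a rank-1 family loads everything on its first component", {
  withr::with_seed(5, {
    x <- matrix(rnorm(60), ncol = 2)
    x <- cbind(x[, 1], 2 * x[, 1] + 3, rnorm(30), rnorm(30))
    colnames(x) <- c("d.ts.a", "d.ts.b", "d.pk.a", "d.pk.b")
    res <- fit_family_pca(x)
    b <- res$transform$blocks[["TS"]]
    expect_equal(b$var_explained[1], 1, tolerance = 1e-12)
    expect_lt(sd(res$scores[, "TS.PC2"]), 1e-8)
  })
})

test_that("PCA scores match an independent eigendecomposition", {
  cf <- small_cohort_features()
  # one (non-degenerate) family is enough for the oracle
  x <- cf$features[, grep("^d\\.pk\\.", colnames(cf$features))]
  fam <- feature_family_of(colnames(x))
  res <- fit_family_pca(x, families = fam)
  z <- scale(x)
  eig <- eigen(cov(z))
  for (c_i in 1:2) {
    want <- as.numeric(z %*% eig$vectors[, c_i])
    got <- res$scores[, c_i]
    expect_lt(min(max(abs(got - want)), max(abs(got + want))), 1e-8)
  }
})

test_that("grouped folds never split a subject and balance sizes", {
  subjects <- c(rep(sprintf("S%02d", 1:15), 1),
                rep(sprintf("S%02d", 1:5), 1))   # 5 subjects twice
  folds <- grouped_folds(subjects, k = 10, seed = 1)
  expect_length(folds, 20)
  split_check <- tapply(folds, subjects, function(f) length(unique(f)))
  expect_true(all(split_check == 1))
  # leave-one-subject-out when k equals the number of subjects
  folds2 <- grouped_folds(subjects, k = 15, seed = 1)
  expect_equal(sort(unique(folds2)), 1:15)
  expect_error(grouped_folds(subjects, k = 16),
               class = "tapkin_parameter_error")
  # a 191-subject / 301-recording roster balances within +/- 3
  withr::with_seed(2, {
    reps <- sample(191, 110)
    roster <- c(sprintf("P%03d", 1:191), sprintf("P%03d", reps))
  })
  f3 <- grouped_folds(roster, k = 10, seed = 3)
  expect_equal(length(f3), 301)
  expect_true(all(abs(table(f3) - 30.1) <= 3))
})

test_that("classification reports are deterministic and well-formed", {
  cf <- small_cohort_features()
  cs <- contrast_subset(cf$sessions, "ataxia_vs_control")
  args <- list(cf$features[cs$idx, ], cs$labels,
               cf$sessions$subject_id[cs$idx], positive = cs$positive,
               k = 5, seed = 7, n_boot = 50)
  r1 <- do.call(classify_groups, args)
  r2 <- do.call(classify_groups, args)
  expect_identical(r1, r2)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  expect_equal(sort(unique(r1$predictions$fold)), 1:5)
  # every recording in exactly one test fold, subjects not split
  by_subj <- tapply(r1$predictions$fold, r1$predictions$subject_id,
                    function(f) length(unique(f)))
  expect_true(all(by_subj == 1))
})

test_that("pooled AUC is invariant to monotone probability transforms", {
  cf <- small_cohort_features()
  cs <- contrast_subset(cf$sessions, "ataxia_vs_control")
  r <- classify_groups(cf$features[cs$idx, ], cs$labels,
                       cf$sessions$subject_id[cs$idx],
                       positive = cs$positive, k = 5, seed = 7, n_boot = 0)
  p <- r$predictions$prob
  y <- r$predictions$y
  a1 <- as.numeric(pROC::roc(y, p, levels = c(0, 1), direction = "<",
                             quiet = TRUE)$auc)
  a2 <- as.numeric(pROC::roc(y, qlogis(pmin(1 - 1e-9, pmax(1e-9, p))),
                             levels = c(0, 1), direction = "<",
                             quiet = TRUE)$auc)
  expect_equal(r$auc, a1)
  expect_equal(a1, a2)
})

test_that("per-fold PCA uses only training rows (no test leakage)", {
  cf <- small_cohort_features()
  cs <- contrast_subset(cf$sessions, "ataxia_vs_control")
  x <- cf$features[cs$idx, ]
  subj <- cf$sessions$subject_id[cs$idx]
  r1 <- classify_groups(x, cs$labels, subj, positive = cs$positive,
                        k = 5, seed = 7, n_boot = 0)
  # perturb one row; rows sharing its fold are tested under a transform
  # fitted without it, so their predictions must not move
  j <- which(r1$predictions$fold == 1)[1]
  x2 <- x
  x2[j, ] <- x2[j, ] * 3 + 1
  r2 <- classify_groups(x2, cs$labels, subj, positive = cs$positive,
                        k = 5, seed = 7, n_boot = 0)
  same_fold_others <- setdiff(which(r1$predictions$fold == 1), j)
  expect_equal(r1$predictions$prob[same_fold_others],
               r2$predictions$prob[same_fold_others], tolerance = 1e-12)
})

test_that("hopelessly imbalanced splits are refused with a typed error", {
  cf <- small_cohort_features()
  # keep all ataxia subjects but only one control subject: some outer
  # training split must end up with < 2 recordings of one class
  keep <- cf$sessions$group == "ataxia" |
    cf$sessions$subject_id == cf$sessions$subject_id[
      cf$sessions$group == "control"][1]
  expect_error(
    classify_groups(cf$features[keep, ],
                    factor(cf$sessions$group[keep]),
                    cf$sessions$subject_id[keep], k = 5, seed = 1,
                    n_boot = 0),
    class = "tapkin_single_class_fold")
})

test_that("regression reports r and r2 = r^2 and refuses degenerate targets", {
  cf <- small_cohort_features()
  r <- regress_severity(cf$features, cf$sessions,
                        cf$sessions$subject_id,
                        target = "severity_dominant", k = 5, seed = 3,
                        n_boot = 50)
  expect_equal(r$r2, r$r^2)
  expect_gt(r$r, 0.5)
  expect_true(all(c("true", "fit", "lo", "hi") %in% names(r$fit_line)))
  expect_error(
    regress_severity(cf$features, rep(1, nrow(cf$features)),
                     cf$sessions$subject_id, k = 5),
    class = "tapkin_validation_error")
  expect_error(
    regress_severity(cf$features, cf$sessions, cf$sessions$subject_id,
                     target = "no_such_column", k = 5),
    class = "tapkin_validation_error")
})

test_that("feature contributions expand the PC model exactly", {
  cf <- small_cohort_features()
  res <- fit_family_pca(cf$features)
  pcs <- colnames(res$scores)
  withr::with_seed(8, w <- setNames(rnorm(length(pcs)), pcs))
  contrib <- feature_contributions(w, res$transform, top_fraction = 0.02)
  # oracle: the PC-space linear model must equal the expanded model on
  # standardised features, row by row
  z <- scale(cf$features[, contrib$feature[order(contrib$feature)]])
  beta <- contrib$contribution[order(contrib$feature)]
  expect_lt(max(abs(as.numeric(res$scores %*% w) -
                      as.numeric(z %*% beta))), 1e-10)
  # zero coefficients give zero contributions
  z0 <- feature_contributions(setNames(numeric(length(pcs)), pcs),
                              res$transform)
  expect_true(all(z0$contribution == 0))
  # top flag covers 2% of features
  expect_equal(sum(contrib$top), ceiling(0.02 * nrow(contrib)))
  expect_equal(contrib$rank, seq_len(nrow(contrib)))
})

test_that("identity loadings return the coefficients themselves", {
  loadings <- diag(2)
  colnames(loadings) <- c("TS.PC1", "TS.PC2")
  tr <- structure(list(
    blocks = list(TS = list(features = c("d.ts.a", "d.ts.b"),
                            mean = c(0, 0), sd = c(1, 1),
                            loadings = loadings)),
    families = "TS"), class = "family_pca")
  w <- c(TS.PC1 = 0.7, TS.PC2 = -0.2)
  contrib <- feature_contributions(w, tr)
  expect_equal(contrib$contribution[match(c("d.ts.a", "d.ts.b"),
                                          contrib$feature)],
               c(0.7, -0.2))
  # mismatched transform and coefficients are refused
  expect_error(feature_contributions(c(Pk.PC1 = 1, Pk.PC2 = 0), tr),
               class = "tapkin_validation_error")
})

test_that("diagnostics report correlations and flag degenerate inputs", {
  cf <- small_cohort_features()
  cs <- contrast_subset(cf$sessions, "ataxia_vs_control")
  r <- classify_groups(cf$features[cs$idx, ], cs$labels,
                       cf$sessions$subject_id[cs$idx],
                       positive = cs$positive, k = 5, seed = 7, n_boot = 0)
  d <- model_diagnostics(r, cf$sessions$age[cs$idx],
                         cf$sessions$severity_dominant[cs$idx])
  expect_equal(d$covariate, c("age", "severity"))
  expect_true(all(is.finite(d$r) | nzchar(d$note)))
  # constant probabilities: undefined, not zero
  r0 <- r
  r0$predictions$prob <- rep(0.5, nrow(r0$predictions))
  r0$predictions$y <- rep(1L, nrow(r0$predictions))
  d0 <- model_diagnostics(r0, cf$sessions$age[cs$idx])
  expect_true(is.na(d0$r))
  expect_match(d0$note, "undefined")
  expect_error(model_diagnostics(r, c(1, 2, 3)),
               class = "tapkin_validation_error")
})

test_that("vectorised Welch t matches the textbook formula via t.test", {
  withr::with_seed(14, {
    x <- matrix(rnorm(200), ncol = 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    x[1:25, 1] <- x[1:25, 1] + 2
    g <- rep(c("a", "b"), each = 25)
    got <- group_tscores(x, g)
    for (i in seq_len(nrow(got))) {
      tt <- t.test(x[g == "a", got$feature[i]], x[g == "b", got$feature[i]])
      expect_equal(got$t[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(got$p_value[i], tt$p.value, tolerance = 1e-10)
    }
    expect_equal(got$feature[1], "f1")   # ranked by |t|
    expect_true(all(diff(abs(got$t)) <= 0))
  })
})
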