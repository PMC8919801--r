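#' Harmonised common arm severity score
#'
#' Maps group-specific clinical arm scores onto one unit-range scale so
#' ataxia and parkinsonism severities are comparable: the ataxia arm
#' score (0-4 scale, 0.5 steps) is divided by its single-arm maximum of
#' 4; the parkinsonism arm composite (sum of the configured arm
#' bradykinesia items) is divided by its composite maximum, 12 by
#' default; controls are assigned exactly 0.
#'
#' @param bars_arm Ataxia arm score(s) on the 0-4 scale.
#' @param updrs_arm_sum Parkinsonism arm composite (sum of arm items).
#' @param group `"ataxia"`, `"parkinsonism"` or `"control"`.
#' @param updrs_divisor Composite maximum used for scaling (default 12;
#'   some arm-item selections make 24 the appropriate value).
#' @return Common arm score(s) in `[0, 1]`.
#' @export
#' @examples
#' common_arm_score(bars_arm = 1.32, group = "ataxia") # 0.33
common_arm_score <- function(bars_arm = NULL, updrs_arm_sum = NULL,
                             group, updrs_divisor = 12) {
  if (identical(group, "control")) return(0)
  if (identical(group, "ataxia")) {
    if (is.null(bars_arm) || any(!is.finite(bars_arm)) ||
        any(bars_arm < 0 | bars_arm > 4)) {
      tapkin_error("ataxia arm score must lie in [0, 4]",
                   "tapkin_validation_error")
    }
    return(bars_arm / 4)
  }
  if (identical(group, "parkinsonism")) {
    if (is.null(updrs_arm_sum) || any(!is.finite(updrs_arm_sum)) ||
        any(updrs_arm_sum < 0)) {
      tapkin_error("parkinsonism arm composite must be non-negative",
                   "tapkin_validation_error")
    }
    if (any(updrs_arm_sum > updrs_divisor)) {
      warning("arm composite exceeds the divisor; score clipped to 1")
    }
    return(clip01(updrs_arm_sum / updrs_divisor))
  }
  tapkin_error(sprintf("unknown group '%s'", group), "tapkin_validation_error")
}

#' Per-family PCA reduction of the feature table
#'
#' Standardises each feature (training mean and SD) and decomposes each
#' feature family independently, retaining the first `n_components`
#' principal components per family. The sign of each component is fixed
#' by making its largest-magnitude loading positive. Constant feature
#' columns are dropped with a warning before decomposition.
#'
#' @param x Numeric matrix or data frame, one row per recording,
#'   columns named as produced by [extract_features()].
#' @param families Family tag per column; derived from column names if
#'   `NULL`.
#' @param n_components Components retained per family (default 2).
#' @return A list with `transform` (a `family_pca` holding per-family
#'   standardisation parameters and loadings) and `scores` (matrix with
#'   `n_components * n_families` columns, e.g. `TS.PC1`).
#' @export
fit_family_pca <- function(x, families = NULL, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 3) {
    tapkin_error("need at least 3 recordings for PCA",
                 "tapkin_insufficient_data")
  }
  if (is.null(families)) families <- feature_family_of(colnames(x))
  fams <- unique(families)
  blocks <- list()
  for (fam in fams) {
    cols <- which(families == fam)
    if (length(cols) < 2) {
      tapkin_error(sprintf("family %s has fewer than 2 features", fam),
                   "tapkin_insufficient_data")
    }
    xf <- x[, cols, drop = FALSE]
    mu <- colMeans(xf)
    sdv <- apply(xf, 2, sd)
    # numerically constant columns (e.g. the identically-zero mean of a
    # z-scored amplitude) cannot be standardised; exact constants warn
    keep <- sdv > 1e-10 * pmax(1, abs(mu))
    if (any(sdv == 0)) {
      warning(sprintf("dropping %d constant feature(s) in family %s",
                      sum(sdv == 0), fam))
    }
    xf <- xf[, keep, drop = FALSE]
    mu <- mu[keep]; sdv <- sdv[keep]
    z <- sweep(sweep(xf, 2, mu), 2, sdv, "/")
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    ncomp <- min(n_components, ncol(pc$rotation))
    load <- pc$rotation[, seq_len(ncomp), drop = FALSE]
    for (c_i in seq_len(ncol(load))) {
      j <- which.max(abs(load[, c_i]))
      if (load[j, c_i] < 0) load[, c_i] <- -load[, c_i]
    }
    colnames(load) <- paste0(fam, ".PC", seq_len(ncol(load)))
    blocks[[fam]] <- list(features = colnames(xf), mean = mu, sd = sdv,
                          loadings = load,
                          var_explained = pc$sdev[seq_len(ncomp)]^2 /
                            sum(pc$sdev^2))
  }
  transform <- structure(list(blocks = blocks, families = fams),
                         class = "family_pca")
  list(transform = transform, scores = predict(transform, x))
}

#' Project a feature table onto a fitted per-family PCA
#'
#' @param object A `family_pca` transform from [fit_family_pca()].
#' @param newdata Feature matrix/data frame with the training columns.
#' @param ... Unused.
#' @return Matrix of per-family PC scores.
#' @export
predict.family_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- lapply(object$blocks, function(b) {
    z <- sweep(sweep(newdata[, b$features, drop = FALSE], 2, b$mean),
               2, b$sd, "/")
    z %*% b$loadings
  })
  do.call(cbind, out)
}

#' Subject-grouped fold assignment
#'
#' Partitions subjects (not recordings) into `k` folds of near-equal
#' recording counts, so all sessions of a subject share one fold and
#' repeat visits can never straddle train and test. Greedy balancing:
#' subjects in seeded random order, largest recording counts first,
#' each assigned to the currently smallest fold. When `strata` is
#' given (class labels in classification), balancing additionally runs
#' within each stratum so every fold carries a near-equal class mix;
#' without stratification the fold-to-fold prevalence drift biases
#' pooled cross-validated AUC below 0.5 under the null.
#'
#' @param subject_ids Subject identifier per recording.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param strata Optional per-recording stratum (e.g. class label);
#'   must be constant within subject.
#' @return Integer fold assignment per recording (1..k).
#' @export
grouped_folds <- function(subject_ids, k = 10, seed = 1, strata = NULL) {
  subjects <- unique(subject_ids)
  if (length(subjects) < k) {
    tapkin_error(sprintf(
      "only %d distinct subjects for %d folds; use a smaller k",
      length(subjects), k), "tapkin_parameter_error")
  }
  counts <- table(subject_ids)
  subj_stratum <- if (is.null(strata)) {
    rep("all", length(subjects))
  } else {
    as.character(strata)[match(subjects, subject_ids)]
  }
  with_seed(seed, {
    fold_of <- setNames(integer(length(subjects)), subjects)
    load_tot <- numeric(k)
    for (cl in unique(subj_stratum)) {
      sc <- sample(subjects[subj_stratum == cl])
      sc <- sc[order(-as.integer(counts[sc]))]
      load_cl <- numeric(k)
      for (s in sc) {
        f <- order(load_cl, load_tot)[1]
        fold_of[s] <- f
        load_cl[f] <- load_cl[f] + counts[[s]]
        load_tot[f] <- load_tot[f] + counts[[s]]
      }
    }
    as.integer(fold_of[as.character(subject_ids)])
  })
}

# glmnet's small-sample caution is expected at smoke-test scale;
# everything else propagates
quiet_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# binomial log-loss with probability clamping
log_loss <- function(y, p) {
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# choose lambda by grouped inner CV on (x, y); metric: log-loss or MSE
tune_lambda <- function(x, y, subjects, family, alpha, lambda_grid,
                        inner_k, seed, strata = NULL) {
  inner_k <- min(inner_k, length(unique(subjects)))
  folds <- grouped_folds(subjects, inner_k, seed, strata)
  loss <- matrix(NA_real_, inner_k, length(lambda_grid))
  for (f in seq_len(inner_k)) {
    tr <- folds != f; te <- !tr
    # degenerate tuning splits (a class with < 2 training rows) carry no
    # information about lambda; skip them
    if (family == "binomial" && min(table(y[tr])) < 2) next
    fit <- quiet_small_class(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = family,
                     alpha = alpha, lambda = lambda_grid,
                     standardize = FALSE))
    p <- predict(fit, x[te, , drop = FALSE],
                 type = if (family == "binomial") "response" else "link",
                 s = lambda_grid, exact = FALSE)
    for (l in seq_len(ncol(p))) {
      loss[f, l] <- if (family == "binomial") log_loss(y[te], p[, l]) else
        mean((y[te] - p[, l])^2)
    }
  }
  m <- colMeans(loss, na.rm = TRUE)
  if (all(!is.finite(m))) {
    tapkin_error(
      "every tuning split was single-class; try another seed or smaller k",
      "tapkin_single_class_fold")
  }
  lambda_grid[which.min(m)]
}

# shared outer cross-validation engine for classification and regression
cv_penalized <- function(x, y, subjects, family, alpha, k, seed,
                         lambda_grid, inner_k, families, pca_scope,
                         n_components) {
  x <- as.matrix(x)
  strata <- if (family == "binomial") y else NULL
  folds <- grouped_folds(subjects, k, seed, strata)
  global_pc <- NULL
  if (pca_scope == "global") {
    global_pc <- fit_family_pca(x, families, n_components)$transform
  }
  pred <- rep(NA_real_, length(y))
  lambda_hat <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (pca_scope == "fold") {
      pc <- fit_family_pca(x[tr, , drop = FALSE], families,
                           n_components)$transform
      xtr <- predict(pc, x[tr, , drop = FALSE])
      xte <- predict(pc, x[te, , drop = FALSE])
    } else if (pca_scope == "global") {
      xtr <- predict(global_pc, x[tr, , drop = FALSE])
      xte <- predict(global_pc, x[te, , drop = FALSE])
    } else {
      xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    }
    if (family == "binomial" && min(table(y[tr])) < 2) {
      tapkin_error(
        "an outer training split has fewer than 2 recordings of one class; try another seed or smaller k",
        "tapkin_single_class_fold")
    }
    lam <- tune_lambda(xtr, y[tr], subjects[tr], family, alpha,
                       lambda_grid, inner_k, child_seed(seed, f),
                       strata = if (is.null(strata)) NULL else strata[tr])
    fit <- quiet_small_class(
      glmnet::glmnet(xtr, y[tr], family = family, alpha = alpha,
                     lambda = lambda_grid, standardize = FALSE))
    pred[te] <- as.numeric(predict(
      fit, xte, s = lam,
      type = if (family == "binomial") "response" else "link"))
    lambda_hat[f] <- lam
  }
  # full-data model (global transform) for interpretation
  if (pca_scope == "none") {
    full_x <- x; full_pc <- NULL
  } else {
    full_pc <- if (is.null(global_pc)) {
      fit_family_pca(x, families, n_components)$transform
    } else global_pc
    full_x <- predict(full_pc, x)
  }
  full_lam <- tune_lambda(full_x, y, subjects, family, alpha, lambda_grid,
                          min(inner_k, k), child_seed(seed, 1000L),
                          strata = strata)
  full_fit <- quiet_small_class(
    glmnet::glmnet(full_x, y, family = family, alpha = alpha,
                   lambda = lambda_grid, standardize = FALSE))
  cf <- as.matrix(coef(full_fit, s = full_lam))
  list(pred = pred, folds = folds, lambda = lambda_hat,
       full_model = list(
         coef = setNames(cf[-1, 1], rownames(cf)[-1]),
         intercept = cf[1, 1], lambda = full_lam, transform = full_pc))
}

# subject-level percentile bootstrap of a metric over pooled predictions
boot_metric <- function(stat, subjects, n_boot, seed) {
  if (n_boot <= 0) return(c(NA_real_, NA_real_))
  subj <- unique(subjects)
  idx_of <- split(seq_along(subjects), subjects)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(idx_of[sample(length(subj), replace = TRUE)],
                     use.names = FALSE)
      stat(take)
    }, numeric(1))
  })
  as.numeric(quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
}

auc_of <- function(y01, p) {
  if (length(unique(y01)) < 2) return(NA_real_)
  as.numeric(pROC::roc(y01, p, levels = c(0, 1), direction = "<",
                       quiet = TRUE)$auc)
}

#' Cross-validated group classification
#'
#' Penalised logistic regression (L1 by default, the choice that yields
#' sparse, interpretable weights; L2 available) on per-family principal
#' component scores, evaluated by subject-grouped k-fold cross
#' validation. The regularisation strength is chosen per outer fold by
#' a grouped inner 10-fold cross validation over a log-spaced grid.
#' AUC, sensitivity and specificity are computed on the pooled
#' out-of-fold probabilities at the 0.5 operating point, with
#' subject-level percentile-bootstrap 95% intervals. By default the
#' standardisation and PCA are refit inside every training fold
#' (leakage-safe); `pca_scope = "global"` fits them once on all data.
#'
#' @param x Feature table (rows = recordings) or, with
#'   `pca_scope = "none"`, an already-reduced score table.
#' @param labels Factor (or coercible) with two levels.
#' @param subject_ids Subject identifier per row.
#' @param positive Label of the positive (case) class; default the
#'   second factor level.
#' @param penalty `"l1"` or `"l2"`.
#' @param k Outer folds.
#' @param seed Integer seed for folds and bootstrap.
#' @param families Family tag per column (derived from names if `NULL`).
#' @param pca_scope `"fold"`, `"global"` or `"none"`.
#' @param n_components PCs per family.
#' @param lambda_grid Regularisation grid (13 log-spaced points,
#'   1e-3 to 1e3, by default).
#' @param inner_k Inner tuning folds.
#' @param threshold Probability operating point for sens/spec.
#' @param n_boot Bootstrap resamples for the 95% intervals (0 skips).
#' @return A `model_report` with out-of-fold `predictions`, `auc`,
#'   `sensitivity`, `specificity` (each with `*_ci`), per-fold `lambda`,
#'   and `full_model` (coefficients + transform) for
#'   [feature_contributions()].
#' @export
classify_groups <- function(x, labels, subject_ids, positive = NULL,
                            penalty = c("l1", "l2"), k = 10, seed = 1,
                            families = NULL,
                            pca_scope = c("fold", "global", "none"),
                            n_components = 2,
                            lambda_grid = 10^seq(3, -3, length.out = 13),
                            inner_k = 10, threshold = 0.5, n_boot = 1000) {
  penalty <- match.arg(penalty)
  pca_scope <- match.arg(pca_scope)
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    tapkin_error("classification needs exactly two classes",
                 "tapkin_validation_error")
  }
  if (is.null(positive)) positive <- levels(labels)[2]
  y <- as.integer(labels == positive)
  cv <- cv_penalized(x, y, subject_ids, "binomial",
                     alpha = if (penalty == "l1") 1 else 0,
                     k = k, seed = seed, lambda_grid = sort(lambda_grid,
                                                            decreasing = TRUE),
                     inner_k = inner_k, families = families,
                     pca_scope = pca_scope, n_components = n_components)
  p <- cv$pred
  auc <- auc_of(y, p)
  sens <- mean(p[y == 1] > threshold)
  spec <- mean(p[y == 0] <= threshold)
  ci <- list(
    auc = boot_metric(function(i) auc_of(y[i], p[i]), subject_ids, n_boot,
                      child_seed(seed, 2001L)),
    sens = boot_metric(function(i) mean(p[i][y[i] == 1] > threshold),
                       subject_ids, n_boot, child_seed(seed, 2002L)),
    spec = boot_metric(function(i) mean(p[i][y[i] == 0] <= threshold),
                       subject_ids, n_boot, child_seed(seed, 2003L)))
  structure(list(
    kind = "classification", positive = positive, penalty = penalty,
    predictions = data.frame(subject_id = subject_ids, label = labels,
                             y = y, prob = p, fold = cv$folds,
                             stringsAsFactors = FALSE),
    auc = auc, auc_ci = ci$auc,
    sensitivity = sens, sensitivity_ci = ci$sens,
    specificity = spec, specificity_ci = ci$spec,
    threshold = threshold, lambda = cv$lambda,
    full_model = cv$full_model
  ), class = "model_report")
}

#' Cross-validated severity regression
#'
#' Ridge regression of a clinical severity score on the per-family
#' principal component scores, with the same subject-grouped cross
#' validation and inner-loop regularisation tuning as
#' [classify_groups()]. Performance is the Pearson correlation `r`
#' between pooled out-of-fold predictions and the true scores, with
#' `r2 = r^2` (explained variance in the correlation sense). Also
#' returns the data for a fitted-line plot with a subject-level
#' bootstrap 95% band.
#'
#' @param x Feature table (rows = recordings).
#' @param scores Numeric target vector, or a data frame from which
#'   `target` selects a column.
#' @param subject_ids Subject identifier per row.
#' @param target Column of `scores` to predict when `scores` is a data
#'   frame.
#' @inheritParams classify_groups
#' @return A `model_report` with `predictions`, `r`, `r2`, bootstrap
#'   `r_ci`, `fit_line` (true-score grid with fitted value and 95%
#'   band), per-fold `lambda` and `full_model`.
#' @export
regress_severity <- function(x, scores, subject_ids, target = NULL,
                             k = 10, seed = 1, families = NULL,
                             pca_scope = c("fold", "global", "none"),
                             n_components = 2,
                             lambda_grid = 10^seq(3, -3, length.out = 13),
                             inner_k = 10, n_boot = 1000) {
  pca_scope <- match.arg(pca_scope)
  y <- if (is.data.frame(scores)) {
    if (is.null(target) || !target %in% names(scores)) {
      tapkin_error("target must name a column of scores",
                   "tapkin_validation_error")
    }
    scores[[target]]
  } else as.numeric(scores)
  if (sd(y) == 0) {
    tapkin_error("target score has zero variance", "tapkin_validation_error")
  }
  cv <- cv_penalized(x, y, subject_ids, "gaussian", alpha = 0,
                     k = k, seed = seed,
                     lambda_grid = sort(lambda_grid, decreasing = TRUE),
                     inner_k = inner_k, families = families,
                     pca_scope = pca_scope, n_components = n_components)
  p <- cv$pred
  r <- if (sd(p) == 0) NA_real_ else cor(p, y)
  r_ci <- boot_metric(function(i) {
    if (sd(p[i]) == 0 || sd(y[i]) == 0) NA_real_ else cor(p[i], y[i])
  }, subject_ids, n_boot, child_seed(seed, 2004L))

  # fitted line of predicted vs true score with bootstrap band
  grid <- seq(min(y), max(y), length.out = 50)
  line_of <- function(i) {
    if (sd(y[i]) == 0) return(rep(NA_real_, length(grid)))
    b <- cov(y[i], p[i]) / var(y[i])
    a <- mean(p[i]) - b * mean(y[i])
    a + b * grid
  }
  fit <- line_of(seq_along(y))
  band <- if (n_boot > 0) {
    subj <- unique(subject_ids)
    idx_of <- split(seq_along(subject_ids), subject_ids)
    lines <- with_seed(child_seed(seed, 2005L), {
      vapply(seq_len(n_boot), function(b) {
        take <- unlist(idx_of[sample(length(subj), replace = TRUE)],
                       use.names = FALSE)
        line_of(take)
      }, numeric(length(grid)))
    })
    t(apply(lines, 1, quantile, c(0.025, 0.975), na.rm = TRUE))
  } else matrix(NA_real_, length(grid), 2)
  structure(list(
    kind = "regression", target = target,
    predictions = data.frame(subject_id = subject_ids, true = y, pred = p,
                             fold = cv$folds, stringsAsFactors = FALSE),
    r = r, r2 = r^2, r_ci = r_ci,
    fit_line = data.frame(true = grid, fit = fit,
                          lo = band[, 1], hi = band[, 2]),
    lambda = cv$lambda, full_model = cv$full_model
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  if (x$kind == "classification") {
    cat(sprintf(
      "<model_report> classification (positive = %s, %s penalty)\n",
      x$positive, toupper(x$penalty)))
    cat(sprintf("  AUC %.3f (%.3f-%.3f)  sens %.3f  spec %.3f  [n = %d]\n",
                x$auc, x$auc_ci[1], x$auc_ci[2], x$sensitivity,
                x$specificity, nrow(x$predictions)))
  } else {
    cat(sprintf("<model_report> regression (target = %s)\n",
                x$target %||% "score"))
    cat(sprintf("  r %.3f  r2 %.3f  [n = %d]\n", x$r, x$r2,
                nrow(x$predictions)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-feature contributions of a PC-space linear model
#'
#' Expands a linear model fitted on per-family principal component
#' scores back onto the original standardised features: the
#' contribution of a feature is the sum over its family's retained
#' components of (model coefficient for the component) x (the feature's
#' loading on that component). Contributions are signed and ranked by
#' magnitude; the top `top_fraction` are flagged for plotting.
#' Components given zero weight by an L1 penalty contribute nothing.
#'
#' @param model A `model_report` (its full-data model is used) or a
#'   named coefficient vector over PC columns.
#' @param transform The `family_pca` transform behind the coefficients;
#'   taken from the report when `model` is a `model_report`.
#' @param top_fraction Fraction of features flagged as top contributors.
#' @return Data frame with `feature`, `family`, `contribution`, `rank`
#'   and `top`, ordered by decreasing `|contribution|`.
#' @export
feature_contributions <- function(model, transform = NULL,
                                  top_fraction = 0.02) {
  if (inherits(model, "model_report")) {
    transform <- transform %||% model$full_model$transform
    coefs <- model$full_model$coef
  } else {
    coefs <- model
  }
  if (is.null(transform)) {
    tapkin_error("a family_pca transform is required",
                 "tapkin_validation_error")
  }
  rows <- list()
  for (fam in names(transform$blocks)) {
    b <- transform$blocks[[fam]]
    pcs <- colnames(b$loadings)
    if (!all(pcs %in% names(coefs))) {
      tapkin_error(sprintf(
        "model coefficients are missing components of family %s", fam),
        "tapkin_validation_error")
    }
    contrib <- as.numeric(b$loadings %*% coefs[pcs])
    rows[[fam]] <- data.frame(feature = b$features, family = fam,
                              contribution = contrib,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$contribution)), ]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= max(1L, ceiling(top_fraction * nrow(out)))
  rownames(out) <- NULL
  out
}

#' Probability-age and probability-severity diagnostics
#'
#' Pearson correlations (with p-values) between the out-of-fold
#' true-class probability and age, and optionally severity. A constant
#' probability vector makes the correlation undefined; it is reported
#' as `NA` with a note rather than as 0.
#'
#' @param report A classification `model_report`.
#' @param ages Age per recording (same order as the report rows).
#' @param severities Optional severity per recording.
#' @return Data frame with one row per covariate: `r`, `p_value`, `n`,
#'   `note`.
#' @export
model_diagnostics <- function(report, ages, severities = NULL) {
  p <- report$predictions$prob
  # probability assigned to the recording's true class
  p_true <- ifelse(report$predictions$y == 1, p, 1 - p)
  one <- function(v, name) {
    if (length(v) != length(p_true)) {
      tapkin_error(sprintf("%s has length %d, expected %d", name,
                           length(v), length(p_true)),
                   "tapkin_validation_error")
    }
    if (sd(p_true) == 0 || sd(v) == 0) {
      return(data.frame(covariate = name, r = NA_real_, p_value = NA_real_,
                        n = length(v), note = "undefined: constant input",
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(p_true, v)
    data.frame(covariate = name, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(v), note = "",
               stringsAsFactors = FALSE)
  }
  out <- one(ages, "age")
  if (!is.null(severities)) out <- rbind(out, one(severities, "severity"))
  out
}

#' Welch two-sample t statistics per feature
#'
#' For a two-group feature table: Welch's t (unequal variances) per
#' column, two-sided p-values on the Welch-Satterthwaite degrees of
#' freedom, and Benjamini-Hochberg adjusted q-values, ranked by `|t|`.
#'
#' @param x Feature matrix or data frame.
#' @param labels Two-group factor.
#' @return Data frame with `feature`, `t`, `df`, `p_value`, `q_value`.
#' @export
group_tscores <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    tapkin_error("t-scores need exactly two groups",
                 "tapkin_validation_error")
  }
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2, var)
  v2 <- apply(x[!g1, , drop = FALSE], 2, var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t_stat), df)
  out <- data.frame(feature = colnames(x), t = t_stat, df = df,
                    p_value = p, q_value = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$t)), ]
  rownames(out) <- NULL
  out
}
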