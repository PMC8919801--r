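#' Preprocess a cohort and extract its feature table
#'
#' Runs [preprocess_recording()] and [extract_features()] for every
#' session of a cohort. Per-recording failures (for example an
#' unrecoverable tracking gap) are collected, not fatal: the affected
#' session is dropped and logged.
#'
#' @param cohort A `cohort_dataset`.
#' @param profile A [feature_profile()] or its name.
#' @param config A [preprocess_config()].
#' @param hands Hands to use; sessions must have all requested hands.
#'   `NULL` (default) uses every hand present in the cohort manifest.
#' @return List with `features` (matrix, one row per surviving session,
#'   `manifest` attribute from the first assessment), `sessions` (the
#'   matching rows of `cohort$sessions`), `failures` (data frame) and
#'   `qc` (aggregate counters).
#' @export
cohort_features <- function(cohort, profile = feature_profile("canonical"),
                            config = preprocess_config(), hands = NULL) {
  if (is.character(profile)) profile <- feature_profile(profile)
  if (is.null(hands)) {
    hands <- intersect(c("dominant", "nondominant"),
                       unique(cohort$manifest$hand))
  }
  sess <- cohort$sessions
  rows <- list(); kept <- logical(nrow(sess))
  failures <- list()
  qc_out <- 0L; qc_interp <- 0L
  manifest <- NULL
  for (i in seq_len(nrow(sess))) {
    key <- sess$session_key[i]
    res <- tryCatch({
      sigs <- lapply(hands, function(h) {
        rec <- cohort$recordings[[sprintf("%s_%s", key, h)]]
        if (is.null(rec)) {
          tapkin_error(sprintf("session %s lacks %s-hand recording", key, h),
                       "tapkin_io_error")
        }
        preprocess_recording(rec, config)
      })
      f <- extract_features(sigs[[1]],
                            if (length(sigs) > 1) sigs[[2]] else NULL,
                            profile)
      list(f = f, sigs = sigs)
    }, tapkin_error = function(e) e)
    if (inherits(res, "tapkin_error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        session_key = key, message = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    kept[i] <- TRUE
    rows[[key]] <- res$f
    if (is.null(manifest)) manifest <- attr(res$f, "manifest")
    for (s in res$sigs) {
      qc_out <- qc_out + s$qc$outlier_count
      qc_interp <- qc_interp + s$qc$interpolated_count
    }
  }
  if (!length(rows)) {
    tapkin_error("no session survived preprocessing", "tapkin_empty_dataset")
  }
  features <- do.call(rbind, rows)
  attr(features, "manifest") <- manifest
  attr(features, "family") <- feature_family_of(colnames(features))
  list(features = features, sessions = sess[kept, , drop = FALSE],
       failures = if (length(failures)) do.call(rbind, failures) else
         data.frame(session_key = character(0), message = character(0)),
       qc = list(outliers_removed = qc_out, samples_interpolated = qc_interp,
                 sessions_failed = length(failures)))
}

#' Select the rows, labels and positive class of a named contrast
#'
#' Subsets a session table for one of the named classification
#' contrasts (see [run_pipeline()] for the list, including the
#' mild-ataxia and age-restricted variants).
#'
#' @param sessions Session table as produced by [generate_cohort()].
#' @param name Contrast name.
#' @return List with `idx` (row indices), `labels` (two-level factor)
#'   and `positive` (the case class).
#' @export
contrast_subset <- function(sessions, name) {
  pick <- function(keep, positive) {
    idx <- which(keep)
    list(idx = idx,
         labels = factor(sessions$group[idx],
                         levels = c(setdiff(unique(sessions$group[idx]),
                                            positive), positive)),
         positive = positive)
  }
  g <- sessions$group
  switch(name,
    "ataxia_vs_control" = pick(g %in% c("ataxia", "control"), "ataxia"),
    "ataxia_vs_parkinsonism" =
      pick(g %in% c("ataxia", "parkinsonism"), "ataxia"),
    "parkinsonism_vs_control" =
      pick(g %in% c("parkinsonism", "control"), "parkinsonism"),
    "mild_ataxia_vs_control" = pick(
      (g == "ataxia" & sessions$common_arm_dominant <= 0.5 / 4) |
        g == "control", "ataxia"),
    "ataxia_vs_control_under45" = pick(
      g %in% c("ataxia", "control") & sessions$age < 45, "ataxia"),
    "ataxia_vs_parkinsonism_over45" = pick(
      g %in% c("ataxia", "parkinsonism") & sessions$age > 45, "ataxia"),
    tapkin_error(sprintf("unknown contrast '%s'", name),
                 "tapkin_parameter_error")
  )
}

#' Assemble a pipeline run configuration
#'
#' @param cohort A [cohort_spec()] (or a list of its arguments).
#' @param profile Feature profile name.
#' @param contrasts Character vector of contrast names (see
#'   [run_pipeline()]).
#' @param regression_targets Session-table columns to regress.
#' @param penalty,k,pca_scope,n_boot Model settings.
#' @param preprocess A [preprocess_config()].
#' @param hands Hands used for feature extraction (`NULL`: all present).
#' @param seed Master seed.
#' @param out_dir Optional output directory for all artefacts.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(n_ataxia = 30,
                                            n_parkinsonism = 30,
                                            n_control = 30),
                       profile = "canonical",
                       contrasts = c("ataxia_vs_control",
                                     "ataxia_vs_parkinsonism",
                                     "parkinsonism_vs_control"),
                       regression_targets = c("common_arm_dominant",
                                              "score_total"),
                       penalty = "l1", k = 10, pca_scope = "fold",
                       n_boot = 200, preprocess = preprocess_config(),
                       hands = NULL, seed = 1L, out_dir = NULL) {
  if (!profile %in% c("canonical", "paper-total")) {
    tapkin_error(sprintf("unknown feature profile '%s'", profile),
                 "tapkin_parameter_error")
  }
  structure(list(cohort = cohort, profile = profile, contrasts = contrasts,
                 regression_targets = regression_targets, penalty = penalty,
                 k = k, pca_scope = pca_scope, n_boot = n_boot,
                 preprocess = preprocess, hands = hands, seed = seed,
                 out_dir = out_dir), class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    list(profile = config$profile, contrasts = config$contrasts,
         targets = config$regression_targets, penalty = config$penalty,
         k = config$k, pca_scope = config$pca_scope, seed = config$seed,
         counts = as.list(config$cohort$counts)),
    tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort generation, preprocessing, feature extraction,
#' per-family PCA, the requested classification contrasts and severity
#' regressions, and consolidates everything into one report.
#' Per-recording failures are logged and skipped; a contrast that
#' cannot be fitted is recorded as a failure rather than aborting the
#' run. All randomness derives from the config seed, so a re-run with
#' an identical config reproduces every number.
#'
#' Available contrasts: `ataxia_vs_control`, `ataxia_vs_parkinsonism`,
#' `parkinsonism_vs_control`, `mild_ataxia_vs_control` (dominant-arm
#' common score at most 0.5 on the 0-4 arm scale),
#' `ataxia_vs_control_under45`, `ataxia_vs_parkinsonism_over45`.
#'
#' @param config A [run_config()].
#' @return A `run_report`: stage timings, QC summary, feature manifest,
#'   one `model_report` (or recorded failure) per contrast and
#'   regression target, package version and config hash.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  timing <- list()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  cohort <- generate_cohort(if (inherits(config$cohort, "cohort_spec"))
    config$cohort else do.call(cohort_spec, config$cohort))
  timing$synth <- tic() - t0

  t0 <- tic()
  cf <- cohort_features(cohort, config$profile, config$preprocess,
                        config$hands)
  timing$features <- tic() - t0

  t0 <- tic()
  classification <- list()
  for (ct in config$contrasts) {
    classification[[ct]] <- tryCatch({
      cs <- contrast_subset(cf$sessions, ct)
      classify_groups(cf$features[cs$idx, , drop = FALSE], cs$labels,
                      cf$sessions$subject_id[cs$idx],
                      positive = cs$positive, penalty = config$penalty,
                      k = config$k, seed = config$seed,
                      pca_scope = config$pca_scope, n_boot = config$n_boot)
    }, tapkin_error = function(e) {
      list(failed = TRUE, message = conditionMessage(e))
    })
  }
  regression <- list()
  for (tg in config$regression_targets) {
    regression[[tg]] <- tryCatch({
      regress_severity(cf$features, cf$sessions, cf$sessions$subject_id,
                       target = tg, k = config$k, seed = config$seed,
                       pca_scope = config$pca_scope, n_boot = config$n_boot)
    }, tapkin_error = function(e) {
      list(failed = TRUE, message = conditionMessage(e))
    })
  }
  timing$models <- tic() - t0

  report <- structure(list(
    config = config, config_hash = config_hash(config),
    version = as.character(packageVersion("tapkin")),
    qc = cf$qc, failures = cf$failures,
    feature_manifest = attr(cf$features, "manifest"),
    classification = classification, regression = regression,
    timing = timing
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    write_features_csv(cf$features,
                       file.path(config$out_dir, "features.csv"))
    jsonlite::write_json(report_payload(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

# JSON-friendly numeric payload of a run report
report_payload <- function(report) {
  strip <- function(m) {
    if (isTRUE(m$failed)) return(list(failed = TRUE, message = m$message))
    if (m$kind == "classification") {
      list(auc = m$auc, auc_ci = m$auc_ci, sensitivity = m$sensitivity,
           specificity = m$specificity, n = nrow(m$predictions),
           lambda = m$lambda)
    } else {
      list(r = m$r, r2 = m$r2, r_ci = m$r_ci, n = nrow(m$predictions),
           lambda = m$lambda)
    }
  }
  list(version = report$version, config_hash = report$config_hash,
       qc = report$qc, feature_manifest = report$feature_manifest,
       classification = lapply(report$classification, strip),
       regression = lapply(report$regression, strip))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> tapkin ", x$version, " | config ", x$config_hash, "\n",
      sep = "")
  cat("  features:", x$feature_manifest$total, "per assessment (profile",
      x$feature_manifest$profile, ")\n")
  for (ct in names(x$classification)) {
    m <- x$classification[[ct]]
    if (isTRUE(m$failed)) {
      cat(sprintf("  %-32s FAILED: %s\n", ct, m$message))
    } else {
      cat(sprintf("  %-32s AUC %.3f sens %.3f spec %.3f\n", ct, m$auc,
                  m$sensitivity, m$specificity))
    }
  }
  for (tg in names(x$regression)) {
    m <- x$regression[[tg]]
    if (isTRUE(m$failed)) {
      cat(sprintf("  %-32s FAILED: %s\n", tg, m$message))
    } else {
      cat(sprintf("  %-32s r %.3f r2 %.3f\n", tg, m$r, m$r2))
    }
  }
  invisible(x)
}

#' Validate a cohort directory
#'
#' Schema and consistency checks on a directory written by
#' [write_cohort()] (or any conforming source): required manifest
#' columns, sampling rates in {30, 60}, recording files present and
#' readable, required CSV columns, strictly increasing frames per
#' landmark, confidence in [0, 1]. Never modifies data.
#'
#' @param dir Cohort directory.
#' @return Data frame of violations (`file`, `field`, `message`);
#'   zero rows means the directory is clean.
#' @export
validate_inputs <- function(dir) {
  if (!dir.exists(dir)) {
    tapkin_error(sprintf("directory not found: %s", dir), "tapkin_io_error")
  }
  v <- list()
  note <- function(file, field, message) {
    v[[length(v) + 1L]] <<- data.frame(file = file, field = field,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    note("manifest.csv", "", "manifest missing")
    return(do.call(rbind, v))
  }
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  need <- c("recording_id", "subject_id", "hand", "group", "fs", "file")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    note("manifest.csv", paste(miss, collapse = ","), "missing column(s)")
    return(do.call(rbind, v))
  }
  for (i in seq_len(nrow(man))) {
    f <- man$file[i]
    path <- file.path(dir, f)
    if (!man$fs[i] %in% c(30, 60)) {
      note(f, "fs", sprintf("sampling rate %s not in {30, 60}", man$fs[i]))
    }
    if (!file.exists(path)) {
      note(f, "file", "recording referenced by manifest is missing")
      next
    }
    lm <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(lm)) { note(f, "file", "unreadable CSV"); next }
    needc <- c("frame", "landmark", "x", "y", "confidence")
    missc <- setdiff(needc, names(lm))
    if (length(missc)) {
      note(f, paste(missc, collapse = ","), "missing column(s)")
      next
    }
    for (l in unique(lm$landmark)) {
      fr <- lm$frame[lm$landmark == l]
      if (any(diff(fr) <= 0)) {
        note(f, "frame", sprintf("frames not strictly increasing (%s)", l))
      }
    }
    conf <- lm$confidence[!is.na(lm$confidence)]
    if (length(conf) && (min(conf) < 0 || max(conf) > 1)) {
      note(f, "confidence", "confidence outside [0, 1]")
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(file = character(0), field = character(0),
               message = character(0), stringsAsFactors = FALSE)
}
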