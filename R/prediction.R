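#' Cross-validation configuration
#'
#' Defaults follow the study protocol: tenfold cross-validation repeated
#' ten times (100 prediction models per target), 100-tree random-forest
#' regressors, a p < 0.01 screen for highly predictable targets, and
#' sex, age and education as confounds regressed out of the features
#' within cross-validation.
#'
#' @param n_folds Number of folds (>= 2).
#' @param n_repetitions Number of repeated partitions.
#' @param n_trees Trees per random forest.
#' @param alpha Significance screen on the per-target p value.
#' @param seed Integer seed driving fold partitions and forest fitting.
#' @param confounds Demographic columns regressed out of the features.
#' @param p_method `"parametric"`: two-sided t-test treating the mean
#'   fold correlation as a correlation at n = number of participants
#'   (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`); `"permutation"`: re-run the
#'   full procedure on permuted targets.
#' @param n_permutations Permutations when `p_method = "permutation"`.
#' @param standardize_target Z-score the target as well as the features
#'   (Pearson r is scale-invariant, so the default leaves targets raw).
#' @param compute_importance Record out-of-bag permutation importance on
#'   every model (default). Skipping it speeds up large calibration
#'   sweeps where only `mean_r` matters.
#' @param return_details Keep per-fold preprocessing parameters on the
#'   result (used by leakage audits).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10, n_repetitions = 10, n_trees = 100,
                      alpha = 0.01, seed = 1,
                      confounds = c("sex", "age", "education"),
                      p_method = c("parametric", "permutation"),
                      n_permutations = 100,
                      standardize_target = FALSE,
                      compute_importance = TRUE,
                      return_details = FALSE) {
  stopifnot(n_folds >= 2, n_repetitions >= 1, n_trees >= 1)
  structure(list(
    n_folds = as.integer(n_folds), n_repetitions = as.integer(n_repetitions),
    n_trees = as.integer(n_trees), alpha = alpha, seed = as.integer(seed),
    confounds = confounds, p_method = match.arg(p_method),
    n_permutations = as.integer(n_permutations),
    standardize_target = isTRUE(standardize_target),
    compute_importance = isTRUE(compute_importance),
    return_details = isTRUE(return_details)
  ), class = "cv_config")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
.sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

# Fit fold-local preprocessing on training rows only: median imputation,
# z-scoring, and OLS confound coefficients for [1, confounds].
fit_fold_preprocess <- function(train_x, train_confounds) {
  train_x <- as.matrix(train_x)
  medians <- apply(train_x, 2, stats::median, na.rm = TRUE)
  medians[is.na(medians)] <- 0  # feature missing for every training row
  for (j in seq_len(ncol(train_x))) {
    train_x[is.na(train_x[, j]), j] <- medians[j]
  }
  means <- colMeans(train_x)
  sds <- apply(train_x, 2, stats::sd)
  zero_var <- sds == 0 | is.na(sds)
  if (any(zero_var)) {
    warning("zero-variance feature(s) on training rows passed through as zeros: ",
            paste(colnames(train_x)[zero_var], collapse = ", "), call. = FALSE)
    sds[zero_var] <- 1
  }
  z <- sweep(sweep(train_x, 2, means), 2, sds, "/")
  cmat <- cbind(intercept = 1, as.matrix(train_confounds))
  q <- qr(cmat)
  if (q$rank < ncol(cmat)) {
    stop("confound matrix is rank deficient on training rows", call. = FALSE)
  }
  coefs <- qr.coef(q, z)  # one OLS fit per feature column
  list(medians = medians, means = means, sds = sds, coefs = coefs)
}

apply_fold_preprocess <- function(prep, x, confounds) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- prep$medians[j]
  }
  z <- sweep(sweep(x, 2, prep$means), 2, prep$sds, "/")
  cmat <- cbind(intercept = 1, as.matrix(confounds))
  z - cmat %*% prep$coefs
}

#' Residualize demographic confounds out of features
#'
#' Implements the within-cross-validation confound correction: each
#' feature is z-scored with training-row mean and standard deviation,
#' regressed on `[intercept, sex, age, education]` by ordinary least
#' squares fitted on training rows only, and the fitted values are
#' subtracted from training and test rows using the training
#' coefficients. Missing feature values are imputed with training-row
#' medians first. Test rows never influence any fitted parameter.
#'
#' @param train_x,test_x Feature data frames / matrices (numeric).
#' @param train_confounds,test_confounds Confound data frames aligned
#'   row-wise with the feature tables.
#' @return A list with elements `train`, `test` (adjusted feature
#'   matrices) and `prep` (the training-derived parameters).
#' @export
residualize_confounds <- function(train_x, train_confounds, test_x, test_confounds) {
  prep <- fit_fold_preprocess(train_x, train_confounds)
  list(
    train = apply_fold_preprocess(prep, train_x, train_confounds),
    test = apply_fold_preprocess(prep, test_x, test_confounds),
    prep = prep
  )
}

# two-sided t-test p value for a correlation r at sample size n
.cor_p_value <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

# core repeated-CV loop; returns fold r's, averaged importance and
# optional per-fold preprocessing details
.repeated_cv_core <- function(x, y, confounds, config,
                              with_importance = config$compute_importance %||% TRUE) {
  n <- nrow(x)
  fold_rows <- list(); details <- list()
  rs <- numeric(0); imp_sum <- NULL; n_imp <- 0L
  for (rep_i in seq_len(config$n_repetitions)) {
    fold_of <- withr::with_seed(
      .sub_seed(config$seed, 7001, rep_i),
      sample(rep(seq_len(config$n_folds), length.out = n))
    )
    for (fold_i in seq_len(config$n_folds)) {
      test_idx <- which(fold_of == fold_i)
      train_idx <- which(fold_of != fold_i)
      prep <- fit_fold_preprocess(x[train_idx, , drop = FALSE],
                                  confounds[train_idx, , drop = FALSE])
      xtr <- apply_fold_preprocess(prep, x[train_idx, , drop = FALSE],
                                   confounds[train_idx, , drop = FALSE])
      xte <- apply_fold_preprocess(prep, x[test_idx, , drop = FALSE],
                                   confounds[test_idx, , drop = FALSE])
      ytr <- y[train_idx]
      if (config$standardize_target) {
        mu <- mean(ytr); sdy <- stats::sd(ytr)
        if (sdy == 0) sdy <- 1
        ytr <- (ytr - mu) / sdy
      }
      fit <- ranger::ranger(
        x = as.data.frame(xtr), y = ytr,
        num.trees = config$n_trees,
        importance = if (with_importance) "permutation" else "none",
        seed = .sub_seed(config$seed, 7919, rep_i, fold_i),
        num.threads = 1L, verbose = FALSE
      )
      pred <- stats::predict(fit, data = as.data.frame(xte))$predictions
      r <- suppressWarnings(stats::cor(y[test_idx], pred))
      rs <- c(rs, r)
      fold_rows[[length(fold_rows) + 1L]] <-
        tibble(repetition = rep_i, fold = fold_i, r = r, n_test = length(test_idx))
      if (with_importance) {
        vi <- fit$variable.importance
        imp_sum <- if (is.null(imp_sum)) vi else imp_sum + vi
        n_imp <- n_imp + 1L
      }
      if (config$return_details) {
        details[[length(details) + 1L]] <-
          c(prep, list(repetition = rep_i, fold = fold_i,
                       train_idx = train_idx, test_idx = test_idx))
      }
    }
  }
  list(
    fold_r = bind_rows(fold_rows),
    mean_r = mean(rs, na.rm = TRUE),
    importance = if (with_importance) imp_sum / n_imp else NULL,
    details = details
  )
}

#' Repeated cross-validated random-forest prediction of one EF target
#'
#' For each of `n_repetitions` random partitions into `n_folds` folds:
#' impute missing features with training-fold medians, z-score with
#' training parameters, regress sex, age and education out of the
#' features using training coefficients, fit a random-forest regressor
#' on the training rows and predict the held-out fold, recording the
#' Pearson correlation of true and predicted scores. Prediction
#' performance is the mean fold correlation over all
#' `n_folds * n_repetitions` models; out-of-bag permutation importance
#' is averaged over the same models.
#'
#' @param features Feature table (`participant_id` + numeric features)
#'   from [build_feature_table()] or [classical_features()].
#' @param ef_scores EF score tibble (`participant_id` + targets) or a
#'   named numeric vector aligned to `features$participant_id`.
#' @param target Name of the target column in `ef_scores`.
#' @param demographics Demographics tibble (`participant_id` + the
#'   configured confound columns).
#' @param config A [cv_config()].
#' @return An object of class `fluency_cv` with elements `target`,
#'   `fold_r` (per-model correlations), `mean_r`, `p_value`,
#'   `significant`, `importance`, `n`, `n_models`.
#' @export
run_repeated_cv <- function(features, ef_scores, target, demographics,
                            config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  data <- features |>
    left_join(select(ef_scores, all_of(c("participant_id", target))),
              by = "participant_id") |>
    left_join(select(demographics, all_of(c("participant_id", config$confounds))),
              by = "participant_id") |>
    filter(!is.na(.data[[target]]))
  if (anyNA(data[config$confounds])) {
    stop("missing confound values for participants with target '", target, "'")
  }
  n <- nrow(data)
  if (n < 20) stop("fewer than 20 participants with non-missing target '", target, "'")
  y <- data[[target]]
  if (stats::sd(y) == 0) {
    stop("constant target '", target, "': correlation undefined", call. = FALSE)
  }
  feat_cols <- setdiff(names(features), "participant_id")
  x <- data[feat_cols]
  confounds <- data[config$confounds]

  # zero-variance warnings repeat across folds; surface each message once
  seen_warnings <- character(0)
  core <- withCallingHandlers(
    .repeated_cv_core(x, y, confounds, config),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("zero-variance", msg)) {
        if (!msg %in% seen_warnings) {
          seen_warnings <<- c(seen_warnings, msg)
          warning(w)
        }
        invokeRestart("muffleWarning")
      }
    })
  p <- switch(config$p_method,
    parametric = .cor_p_value(core$mean_r, n),
    permutation = {
      perm_means <- vapply(seq_len(config$n_permutations), function(b) {
        yb <- withr::with_seed(.sub_seed(config$seed, 555, b), sample(y))
        cfg_b <- config; cfg_b$return_details <- FALSE
        .repeated_cv_core(x, yb, confounds, cfg_b, with_importance = FALSE)$mean_r
      }, numeric(1))
      (1 + sum(abs(perm_means) >= abs(core$mean_r))) / (config$n_permutations + 1)
    })
  structure(list(
    target = target,
    fold_r = core$fold_r,
    mean_r = core$mean_r,
    p_value = p,
    significant = !is.na(p) && p < config$alpha,
    importance = if (is.null(core$importance)) NULL else
      tibble(feature = feat_cols,
             importance = unname(core$importance[feat_cols])),
    n = n,
    n_models = nrow(core$fold_r),
    config = config,
    fold_details = if (config$return_details) core$details else NULL
  ), class = "fluency_cv")
}

#' @export
print.fluency_cv <- function(x, ...) {
  cat("<fluency_cv> target ", x$target, ": mean r = ", signif(x$mean_r, 3),
      ", p = ", signif(x$p_value, 3), " (", x$n_models, " models, n = ",
      x$n, ")\n", sep = "")
  invisible(x)
}

#' Predict every battery target from the fluency features
#'
#' Runs [run_repeated_cv()] per EF variable. Targets with fewer than 20
#' scored participants or zero variance are skipped with a report entry.
#'
#' @inheritParams run_repeated_cv
#' @param schema Battery registry (to annotate test and domain); defaults
#'   to the schema attached to `ef_scores` or the bundled registry.
#' @param feature_set Label recorded on the result (`"full"` or
#'   `"classical"`).
#' @return An object of class `fluency_battery`: per-target results
#'   tibble plus the per-target importance tables.
#' @export
predict_battery <- function(features, ef_scores, demographics,
                            config = cv_config(), schema = NULL,
                            feature_set = "full") {
  schema <- schema %||% attr(ef_scores, "schema") %||% ef_schema()
  targets <- setdiff(names(ef_scores), "participant_id")
  runs <- list(); skipped <- character(0); seen_warnings <- character(0)
  for (tg in targets) {
    res <- withCallingHandlers(
      tryCatch(run_repeated_cv(features, ef_scores, tg, demographics, config),
               error = function(e) e),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("zero-variance", msg)) {
          if (!msg %in% seen_warnings) {
            seen_warnings <<- c(seen_warnings, msg)
            warning(w)
          }
          invokeRestart("muffleWarning")
        }
      })
    if (inherits(res, "error")) {
      skipped <- c(skipped, stats::setNames(conditionMessage(res), tg))
    } else {
      runs[[tg]] <- res
    }
  }
  results <- purrr::map_dfr(runs, function(r) tibble(
    target = r$target, mean_r = r$mean_r, p_value = r$p_value,
    significant = r$significant, n = r$n, n_models = r$n_models)) |>
    left_join(select(schema, all_of(c("variable", "test", "domain"))),
              by = c(target = "variable")) |>
    select(all_of(c("target", "test", "domain", "mean_r", "p_value",
                    "significant", "n", "n_models")))
  structure(list(
    results = results,
    importance = purrr::map(runs, "importance"),
    fold_r = purrr::map(runs, "fold_r"),
    skipped = skipped,
    config = config,
    feature_set = feature_set,
    schema = schema,
    participants = sort(unique(features$participant_id))
  ), class = "fluency_battery")
}

#' @export
print.fluency_battery <- function(x, ...) {
  cat("<fluency_battery> ", x$feature_set, " feature set: ",
      nrow(x$results), " targets scored, ",
      sum(x$results$significant), " significant at p < ",
      x$config$alpha, "\n", sep = "")
  invisible(x)
}

#' Screen for highly predictable targets
#'
#' @param battery A `fluency_battery`.
#' @param alpha Significance level (default: the config's).
#' @return Tibble of targets with `p < alpha`, sorted by `mean_r`
#'   descending (the report layout).
#' @export
screen_targets <- function(battery, alpha = NULL) {
  alpha <- alpha %||% battery$config$alpha
  battery$results |>
    filter(!is.na(.data$p_value), .data$p_value < alpha) |>
    arrange(dplyr::desc(.data$mean_r))
}

#' Averaged permutation importance and top-k features
#'
#' Importance is the out-of-bag permutation importance (mean increase in
#' prediction error when one feature's out-of-bag values are permuted),
#' averaged across all fitted models for the target. Ties are broken by
#' canonical feature-name order.
#'
#' @param x A `fluency_cv`, or a `fluency_battery` with `target` given.
#' @param target Target name (battery case).
#' @return A tibble `feature`, `importance`, sorted descending.
#' @export
feature_importance <- function(x, target = NULL) {
  imp <- if (inherits(x, "fluency_cv")) x$importance
         else if (inherits(x, "fluency_battery")) x$importance[[target]]
         else stop("x must be a fluency_cv or fluency_battery")
  if (is.null(imp)) stop("no importance recorded for target ", target)
  canon <- c(feature_names("full"), imp$feature)
  imp |>
    arrange(dplyr::desc(.data$importance), match(.data$feature, canon))
}

#' @rdname feature_importance
#' @param k Number of features to return.
#' @export
top_features <- function(x, target = NULL, k = 5) {
  utils::head(feature_importance(x, target)$feature, k)
}

#' Spearman follow-up of top features against a raw target
#'
#' Rank correlations of the most important fluency features with the raw
#' (non-residualized) EF score over complete pairs, with the report's
#' flagging convention: `p < 0.05` starred as significant, `p < 0.1`
#' marked as a trend.
#'
#' @param features Feature table.
#' @param ef_scores EF score tibble.
#' @param target Target column name.
#' @param top Character vector of feature names (e.g. from
#'   [top_features()]).
#' @return A tibble `feature`, `rho`, `p_value`, `n`, `significant`,
#'   `trend`.
#' @export
followup_spearman <- function(features, ef_scores, target, top) {
  data <- left_join(features,
                    select(ef_scores, all_of(c("participant_id", target))),
                    by = "participant_id")
  purrr::map_dfr(top, function(f) {
    ok <- stats::complete.cases(data[[f]], data[[target]])
    if (sum(ok) < 3) {
      return(tibble(feature = f, rho = NA_real_, p_value = NA_real_,
                    n = sum(ok), significant = NA, trend = NA))
    }
    ct <- suppressWarnings(
      stats::cor.test(data[[f]][ok], data[[target]][ok],
                      method = "spearman", exact = FALSE))
    tibble(feature = f, rho = unname(ct$estimate), p_value = ct$p.value,
           n = sum(ok), significant = ct$p.value < 0.05,
           trend = ct$p.value < 0.1)
  })
}

#' Compare the full and classical feature sets
#'
#' Per-target difference in mean fold correlation, significance counts
#' per set, and a domain-level summary. Both arms must have been run
#' with the same seed (identical fold partitions) on the same
#' participants.
#'
#' @param full,classical `fluency_battery` objects for the two arms.
#' @return An object of class `fluency_comparison` with elements
#'   `by_target`, `counts`, `by_domain`.
#' @export
compare_feature_sets <- function(full, classical) {
  stopifnot(inherits(full, "fluency_battery"), inherits(classical, "fluency_battery"))
  if (!identical(full$participants, classical$participants)) {
    stop("the two arms were run on different participant sets")
  }
  if (!identical(full$config$seed, classical$config$seed)) {
    stop("the two arms used different seeds; fold partitions differ")
  }
  by_target <- full$results |>
    select(all_of(c("target", "test", "domain")),
           mean_r_full = "mean_r", p_full = "p_value", sig_full = "significant") |>
    dplyr::inner_join(
      select(classical$results, all_of(c("target")),
             mean_r_classical = "mean_r", p_classical = "p_value",
             sig_classical = "significant"),
      by = "target") |>
    mutate(delta_mean_r = .data$mean_r_full - .data$mean_r_classical)
  counts <- tibble(
    feature_set = c("full", "classical"),
    n_significant = c(sum(by_target$sig_full), sum(by_target$sig_classical)),
    n_targets = nrow(by_target)
  )
  by_domain <- by_target |>
    group_by(.data$domain) |>
    summarise(n_sig_full = sum(.data$sig_full),
              n_sig_classical = sum(.data$sig_classical),
              mean_delta = mean(.data$delta_mean_r), .groups = "drop")
  structure(list(by_target = by_target, counts = counts, by_domain = by_domain),
            class = "fluency_comparison")
}

#' @export
print.fluency_comparison <- function(x, ...) {
  cat("<fluency_comparison> significant targets: full = ",
      x$counts$n_significant[1], ", classical = ", x$counts$n_significant[2],
      " of ", x$counts$n_targets[1], "\n", sep = "")
  invisible(x)
}
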