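# small feature/confound matrices for residualization checks
make_confound_data <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    sex = stats::rbinom(n, 1, 0.4),
    age = stats::runif(n, 20, 55),
    education = sample(1:4, n, replace = TRUE)))
}

test_that("a perfectly confounded feature residualizes to zero on train and test", {
  conf <- make_confound_data(100)
  x <- tibble::tibble(f = 2 * conf$age)
  idx <- 1:80
  out <- residualize_confounds(x[idx, ], conf[idx, ], x[-idx, ], conf[-idx, ])
  expect_lt(max(abs(out$train)), 1e-10)
  expect_lt(max(abs(out$test)), 1e-10)
})

test_that("train residuals are orthogonal to every confound column", {
  conf <- make_confound_data(120, seed = 2)
  x <- withr::with_seed(3, tibble::tibble(
    f1 = rnorm(120) + 0.05 * conf$age, f2 = rnorm(120)))
  out <- residualize_confounds(x, conf, x[1:5, ], conf[1:5, ])
  for (cc in names(conf)) {
    expect_lt(abs(stats::cor(out$train[, "f1"], conf[[cc]])), 1e-10)
    expect_lt(abs(stats::cor(out$train[, "f2"], conf[[cc]])), 1e-10)
  }
})

test_that("residualization barely distorts features independent of confounds", {
  conf <- make_confound_data(500, seed = 4)
  x <- withr::with_seed(5, tibble::tibble(f = rnorm(500)))
  out <- residualize_confounds(x, conf, x[1:5, ], conf[1:5, ])
  expect_gt(stats::cor(out$train[, "f"], x$f), 0.95)
})

test_that("zero-variance features pass through as zeros with a warning", {
  conf <- make_confound_data(50, seed = 6)
  x <- tibble::tibble(flat = rep(3, 50), ok = rnorm(50))
  expect_warning(out <- residualize_confounds(x, conf, x[1:5, ], conf[1:5, ]),
                 "zero-variance.*flat")
  expect_true(all(out$train[, "flat"] == 0))
})

test_that("self-prediction of a copied feature scores near-perfectly", {
  coh <- small_cohort(n = 200, seed = 31)
  ft <- coh$features
  ef <- tibble::tibble(participant_id = ft$participant_id,
                       echo = ft$sum_total)
  cfg <- cv_config(seed = 9, n_repetitions = 1, compute_importance = FALSE)
  cv <- run_repeated_cv(ft, ef, "echo", coh$demographics, cfg)
  expect_gte(cv$mean_r, 0.95)
  expect_equal(cv$n_models, 10)
})

test_that("default configuration fits 100 models per target", {
  coh <- small_cohort(n = 40, seed = 32)
  ef <- tibble::tibble(participant_id = coh$features$participant_id,
                       y = withr::with_seed(1, rnorm(40)))
  cv <- run_repeated_cv(coh$features, ef, "y", coh$demographics,
                        cv_config(seed = 2, n_trees = 25,
                                  compute_importance = FALSE))
  expect_equal(cv$n_models, 100)
  expect_equal(nrow(cv$fold_r), 100)
  expect_equal(dplyr::n_distinct(cv$fold_r$repetition), 10)
})

test_that("identical seeds reproduce mean_r to machine precision", {
  coh <- small_cohort(n = 40, seed = 32)
  ef <- tibble::tibble(participant_id = coh$features$participant_id,
                       y = withr::with_seed(4, rnorm(40)))
  cfg <- cv_config(seed = 11, n_repetitions = 2, n_trees = 25)
  a <- run_repeated_cv(coh$features, ef, "y", coh$demographics, cfg)
  b <- run_repeated_cv(coh$features, ef, "y", coh$demographics, cfg)
  expect_identical(a$mean_r, b$mean_r)
  expect_identical(a$fold_r, b$fold_r)
  expect_identical(a$importance, b$importance)
})

test_that("guards reject degenerate targets", {
  coh <- small_cohort(n = 40, seed = 32)
  ids <- coh$features$participant_id
  expect_error(
    run_repeated_cv(coh$features,
                    tibble::tibble(participant_id = ids, y = 1), "y",
                    coh$demographics, cv_config()),
    "constant target")
  sparse <- tibble::tibble(participant_id = ids,
                           y = c(rnorm(15), rep(NA, 25)))
  expect_error(
    run_repeated_cv(coh$features, sparse, "y", coh$demographics, cv_config()),
    "fewer than 20")
})

test_that("screening respects alpha and orders by mean_r", {
  coh <- small_cohort(n = 60, seed = 33)
  ft <- coh$features
  ef <- tibble::tibble(
    participant_id = ft$participant_id,
    strong = ft$sum_total + withr::with_seed(5, rnorm(60, sd = 3)),
    noise = withr::with_seed(6, rnorm(60)))
  cfg <- cv_config(seed = 3, n_repetitions = 2, n_trees = 50,
                   compute_importance = FALSE)
  bat <- predict_battery(classical_features(ft), ef, coh$demographics, cfg,
                         schema = tibble::tibble(
                           variable = c("strong", "noise"),
                           test = "SIM", domain = "simulated",
                           polarity = "higher_better"))
  sig <- screen_targets(bat)
  expect_true("strong" %in% sig$target)
  all_flagged <- screen_targets(bat, alpha = 1.0)
  expect_equal(nrow(all_flagged), 2)
  expect_true(!is.unsorted(rev(all_flagged$mean_r)))
})

test_that("top_k returns exactly k canonical names with deterministic ties", {
  imp <- tibble::tibble(feature = feature_names("full"),
                        importance = c(rep(1, 6), rep(0, 37)))
  cv <- structure(list(importance = imp), class = "fluency_cv")
  top <- top_features(cv, k = 5)
  expect_length(top, 5)
  expect_identical(top, feature_names("full")[order(
    -imp$importance, match(imp$feature, feature_names("full")))][1:5])
})

test_that("Spearman follow-up is rank-invariant and flags the conventions", {
  ft <- tibble::tibble(participant_id = paste0("p", 1:30),
                       mono = 1:30, rev = 30:1,
                       tiny = c(1, 2, rep(NA, 28)))
  ef <- tibble::tibble(participant_id = ft$participant_id, y = exp(seq(0.1, 3, length.out = 30)))
  out <- followup_spearman(ft, ef, "y", c("mono", "rev", "tiny"))
  expect_equal(out$rho[out$feature == "mono"], 1.0)
  expect_equal(out$rho[out$feature == "rev"], -1.0)
  expect_true(is.na(out$rho[out$feature == "tiny"]))  # < 3 complete pairs
  expect_true(out$significant[out$feature == "mono"])
})

test_that("Spearman recovery of a planted rank correlation", {
  hits <- 0L
  for (s in 1:10) {
    n <- 230
    dat <- withr::with_seed(100 + s, {
      x <- rnorm(n); y <- -0.2 * x + sqrt(1 - 0.04) * rnorm(n); list(x = x, y = y)
    })
    ft <- tibble::tibble(participant_id = paste0("p", 1:n), f = dat$x)
    ef <- tibble::tibble(participant_id = ft$participant_id, y = dat$y)
    rho <- followup_spearman(ft, ef, "y", "f")$rho
    if (abs(rho - (-0.2)) <= 0.12) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("comparing identical feature sets yields zero deltas", {
  coh <- small_cohort(n = 40, seed = 32)
  ef <- tibble::tibble(participant_id = coh$features$participant_id,
                       y1 = withr::with_seed(7, rnorm(40)),
                       y2 = withr::with_seed(8, rnorm(40)))
  schema <- tibble::tibble(variable = c("y1", "y2"), test = "SIM",
                           domain = "simulated", polarity = "higher_better")
  cfg <- cv_config(seed = 5, n_repetitions = 1, n_trees = 25,
                   compute_importance = FALSE)
  a <- predict_battery(classical_features(coh$features), ef, coh$demographics,
                       cfg, schema = schema, feature_set = "full")
  b <- predict_battery(classical_features(coh$features), ef, coh$demographics,
                       cfg, schema = schema, feature_set = "classical")
  cmp <- compare_feature_sets(a, b)
  expect_equal(cmp$by_target$delta_mean_r, c(0, 0))
  expect_error(compare_feature_sets(a, structure(
    modifyList(unclass(b), list(participants = "p9")),
    class = "fluency_battery")), "different participant sets")
})

test_that("permutation p-values agree in direction with parametric ones", {
  coh <- small_cohort(n = 60, seed = 33)
  ft <- classical_features(coh$features)
  ef <- tibble::tibble(participant_id = ft$participant_id,
                       strong = coh$features$sum_total +
                         withr::with_seed(9, rnorm(60, sd = 2)))
  cfg <- cv_config(seed = 4, n_repetitions = 1, n_trees = 25,
                   p_method = "permutation", n_permutations = 19,
                   compute_importance = FALSE)
  cv <- run_repeated_cv(ft, ef, "strong", coh$demographics, cfg)
  expect_lt(cv$p_value, 0.1)  # 1/(19+1) attainable minimum
})
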