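#' Run the full fluency-to-EF pipeline
#'
#' Orchestrates simulate (optional) -> feature extraction -> prediction
#' with the full and the classical feature set -> comparison -> report
#' files. The configuration is a YAML file or an equivalent nested list
#' with blocks `seed`, either `simulate` (passed to [cohort_config()])
#' or `inputs` (paths to `sessions`, `ef_scores`, `demographics`),
#' optional `resources` (paths for `taxonomy` files and `embeddings`;
#' defaults to the bundled toy resource) and `cv` (passed to
#' [cv_config()]). Each stage fails atomically with its name in the
#' error; a missing embedding resource degrades gracefully (the `_emb`
#' features stay missing, with a warning).
#'
#' @param config YAML path or list.
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, a list with the in-memory stage results; on disk:
#'   `features.tsv`, `results.tsv` (both arms), `importance.tsv`,
#'   `top5_spearman.tsv`, `comparison.tsv` and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message("stage '", name, "' done (", timings[[name]], "s)")
    res
  }
  seed <- config$seed %||% 1L
  digests <- list()

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      cohort <- do.call(cohort_config, sim_args)
      generate_cohort(cohort)
    } else {
      paths <- config$inputs
      for (p in unlist(paths)) digests[[p]] <- unname(tools::md5sum(p))
      list(sessions = read_sessions(paths$sessions),
           ef_scores = read_ef_scores(paths$ef_scores),
           demographics = read_demographics(paths$demographics))
    }
  })

  resources <- stage("resources", {
    rs <- config$resources
    tax <- if (is.null(rs$taxonomy)) toy_taxonomy() else
      do.call(load_taxonomy, as.list(rs$taxonomy))
    emb <- if (is.null(rs$embeddings)) toy_embeddings() else if
      (identical(rs$embeddings, "none")) NULL else load_embeddings(rs$embeddings)
    if (is.null(emb)) warning("no embedding resource configured; ",
                              "'_emb' features will be missing", call. = FALSE)
    list(taxonomy = tax, embeddings = emb)
  })

  features <- stage("features", {
    ft <- build_feature_table(inputs$sessions, resources$taxonomy,
                              resources$embeddings)
    readr::write_tsv(ft, file.path(out_dir, "features.tsv"), na = "NA")
    ft
  })

  cv_args <- config$cv %||% list()
  cv_args$seed <- cv_args$seed %||% seed
  cfg <- do.call(cv_config, cv_args)

  full <- stage("predict_full", predict_battery(
    features, inputs$ef_scores, inputs$demographics, cfg, feature_set = "full"))
  classical <- stage("predict_classical", predict_battery(
    classical_features(features), inputs$ef_scores, inputs$demographics, cfg,
    feature_set = "classical"))

  comparison <- stage("compare", compare_feature_sets(full, classical))

  stage("reports", {
    results <- bind_rows(
      mutate(full$results, feature_set = "full"),
      mutate(classical$results, feature_set = "classical"))
    readr::write_tsv(results, file.path(out_dir, "results.tsv"), na = "NA")
    imp <- purrr::imap_dfr(full$importance,
                           ~ mutate(.x, target = .y, .before = 1))
    readr::write_tsv(imp, file.path(out_dir, "importance.tsv"), na = "NA")
    sig <- screen_targets(full)
    top5 <- purrr::map_dfr(sig$target, function(tg) {
      mutate(followup_spearman(features, inputs$ef_scores, tg,
                               top_features(full, tg, k = 5)),
             target = tg, rank = dplyr::row_number(), .before = 1)
    })
    readr::write_tsv(top5, file.path(out_dir, "top5_spearman.tsv"), na = "NA")
    readr::write_tsv(comparison$by_target, file.path(out_dir, "comparison.tsv"),
                     na = "NA")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fluencyEF")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    cv = unclass(cfg)[c("n_folds", "n_repetitions", "n_trees", "alpha",
                        "confounds", "p_method")],
    input_digests = digests,
    timings = timings,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = features, full = full, classical = classical,
                 comparison = comparison, manifest = manifest))
}

#' Render publication-style reports from a results directory
#'
#' Reads the pipeline's result files (no recomputation) and writes a bar
#' chart of significantly predicted targets' mean correlations grouped
#' by EF domain, plus a flagged top-5 Spearman table (trend `p < 0.1`
#' bolded, significant `p < 0.05` starred, matching the report
#' convention).
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param feature_set Which arm to plot.
#' @return Invisibly, a list with the `ggplot` figure and the flagged
#'   table; on disk: `figure_predictions.png` and `table_top5.tsv`.
#' @export
render_reports <- function(results_dir, feature_set = "full") {
  results <- readr::read_tsv(file.path(results_dir, "results.tsv"),
                             show_col_types = FALSE)
  results <- filter(results, .data$feature_set == !!feature_set)
  sig <- filter(results, .data$significant) |>
    arrange(.data$domain, dplyr::desc(.data$mean_r))
  fig <- plot_prediction_bars(sig)
  ggplot2::ggsave(file.path(results_dir, "figure_predictions.png"), fig,
                  width = 8, height = 4.5, dpi = 150)
  top5_path <- file.path(results_dir, "top5_spearman.tsv")
  tab <- NULL
  if (file.exists(top5_path)) {
    top5 <- readr::read_tsv(top5_path, show_col_types = FALSE)
    if (nrow(top5) > 0) {
      tab <- mutate(top5, display = paste0(
        dplyr::if_else(.data$trend %in% TRUE, "**", ""),
        "rho = ", sprintf("%.2f", .data$rho),
        dplyr::if_else(.data$trend %in% TRUE, "**", ""),
        dplyr::if_else(.data$significant %in% TRUE, " *", "")))
    } else tab <- top5
    readr::write_tsv(tab, file.path(results_dir, "table_top5.tsv"), na = "NA")
  }
  invisible(list(figure = fig, table = tab))
}

# bar chart in the style of the study's prediction figures
plot_prediction_bars <- function(sig) {
  if (nrow(sig) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no significantly predicted targets") +
             ggplot2::theme_void() +
             ggplot2::labs(title = "Prediction of EF variables from fluency features"))
  }
  sig$target <- factor(sig$target, levels = rev(sig$target))
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$mean_r, y = .data$target,
                                    fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean correlation of true and predicted scores",
                  y = NULL, fill = "EF domain",
                  title = "Significantly predicted EF variables") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-model fold correlations of a repeated-CV run
#' @param x A `fluency_cv`.
#' @param ... Unused.
#' @return A tibble with one row per fitted model.
#' @export
tidy.fluency_cv <- function(x, ...) {
  mutate(x$fold_r, target = x$target, .before = 1)
}

#' @rdname tidy.fluency_cv
#' @export
glance.fluency_cv <- function(x, ...) {
  tibble(target = x$target, mean_r = x$mean_r, p_value = x$p_value,
         significant = x$significant, n = x$n, n_models = x$n_models)
}

#' Tidy per-target results of a battery prediction run
#' @param x A `fluency_battery`.
#' @param ... Unused.
#' @return The per-target results tibble.
#' @export
tidy.fluency_battery <- function(x, ...) {
  mutate(x$results, feature_set = x$feature_set)
}

#' @rdname tidy.fluency_battery
#' @export
glance.fluency_battery <- function(x, ...) {
  tibble(feature_set = x$feature_set,
         n_targets = nrow(x$results),
         n_significant = sum(x$results$significant),
         n_skipped = length(x$skipped),
         mean_mean_r = mean(x$results$mean_r),
         alpha = x$config$alpha,
         n_models = x$config$n_folds * x$config$n_repetitions)
}

#' @export
tidy.fluency_comparison <- function(x, ...) x$by_target

#' @export
glance.fluency_comparison <- function(x, ...) {
  tibble(n_targets = x$counts$n_targets[1],
         n_sig_full = x$counts$n_significant[x$counts$feature_set == "full"],
         n_sig_classical = x$counts$n_significant[x$counts$feature_set == "classical"],
         mean_delta = mean(x$by_target$delta_mean_r))
}

#' Bar chart of significantly predicted targets
#' @param object A `fluency_battery`.
#' @param ... Unused.
#' @return A `ggplot`.
#' @export
autoplot.fluency_battery <- function(object, ...) {
  plot_prediction_bars(screen_targets(object))
}

#' Per-target comparison of the two feature sets
#' @param object A `fluency_comparison`.
#' @param ... Unused.
#' @return A `ggplot` of full vs classical mean correlations.
#' @export
autoplot.fluency_comparison <- function(object, ...) {
  ggplot2::ggplot(object$by_target,
                  ggplot2::aes(x = .data$mean_r_classical, y = .data$mean_r_full,
                               colour = .data$domain)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean r (classical sum scores)",
                  y = "mean r (comprehensive features)",
                  colour = "EF domain") +
    ggplot2::theme_minimal()
}
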