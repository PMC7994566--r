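#' Canonical fluency feature names
#'
#' The full comprehensive set has 43 features: 5 sum-score features
#' (per-task sums, total, switch coefficient), 4 error counts, 18 latency
#' features (per-task overall mean, four 30-second interval means, and the
#' interval difference i4 - i1), and 16 semantic relatedness features
#' (sequential and cumulative means per task plus per-category sequential
#' means in the switching task, computed once on the taxonomy backend and
#' once on the embedding backend). The classical set is the 4 sum scores
#' used in standard clinical evaluation.
#'
#' @param set `"full"` (43 features) or `"classical"` (4 sum scores).
#' @return Character vector of feature names.
#' @export
feature_names <- function(set = c("full", "classical")) {
  set <- match.arg(set)
  classical <- c("sum_t1", "sum_t2", "sum_t3", "sum_total")
  if (set == "classical") return(classical)
  tasks <- c("t1", "t2", "t3")
  sem <- function(tag) c(paste0("sem_seq_", tag, "_", tasks),
                         paste0("sem_cum_", tag, "_", tasks),
                         paste0("sem_seq_", tag, "_cat1_t3"),
                         paste0("sem_seq_", tag, "_cat2_t3"))
  c(classical, "switch_coef",
    paste0("err_rep_", tasks), "err_cat_t3",
    paste0("lat_mean_", tasks),
    paste0("lat_q", rep(1:4, each = 3), "_", tasks),
    paste0("lat_diff_", tasks),
    sem("tax"), sem("emb"))
}

# participants x tasks scaffold so missing tasks yield NA features
.task_grid <- function(sessions) {
  tidyr::expand_grid(participant_id = unique(sessions$participant_id),
                     task = c("t1", "t2", "t3"))
}

#' Sum scores and switch coefficient
#'
#' Per-task sums count only correct-coded tokens; the total is their sum
#' over the three tasks. The switch coefficient relates switching-task
#' output to simple-task output: `sum_t3 / ((sum_t1 + sum_t2) / 2)`,
#' undefined when `sum_t1 + sum_t2 = 0`. Features involving a missing
#' task are `NA`.
#'
#' @param sessions A validated session tibble.
#' @return A tibble: `participant_id`, `sum_t1`..`sum_t3`, `sum_total`,
#'   `switch_coef`.
#' @export
extract_sum_scores <- function(sessions) {
  sums <- sessions |>
    group_by(.data$participant_id, .data$task) |>
    summarise(n_correct = sum(.data$code == "correct"), .groups = "drop") |>
    dplyr::right_join(.task_grid(sessions), by = c("participant_id", "task")) |>
    tidyr::pivot_wider(names_from = "task", values_from = "n_correct",
                       names_prefix = "sum_")
  for (col in c("sum_t1", "sum_t2", "sum_t3")) {
    if (!col %in% names(sums)) sums[[col]] <- NA_integer_
  }
  sums |>
    mutate(
      sum_total = .data$sum_t1 + .data$sum_t2 + .data$sum_t3,
      switch_coef = dplyr::if_else(
        (.data$sum_t1 + .data$sum_t2) > 0,
        .data$sum_t3 / ((.data$sum_t1 + .data$sum_t2) / 2),
        NA_real_)
    ) |>
    select(all_of(c("participant_id", "sum_t1", "sum_t2", "sum_t3",
                    "sum_total", "switch_coef")))
}

#' Error counts
#'
#' Repetition-error counts per task and the category-error count in the
#' switching task. Counts for a missing task are `NA`.
#'
#' @param sessions A validated session tibble.
#' @return A tibble: `participant_id`, `err_rep_t1`..`err_rep_t3`,
#'   `err_cat_t3`.
#' @export
extract_error_counts <- function(sessions) {
  errs <- sessions |>
    group_by(.data$participant_id, .data$task) |>
    summarise(rep = sum(.data$code == "repetition_error"),
              cat = sum(.data$code == "category_error"), .groups = "drop") |>
    dplyr::right_join(.task_grid(sessions), by = c("participant_id", "task"))
  wide <- errs |>
    tidyr::pivot_wider(names_from = "task", values_from = c("rep", "cat"))
  tibble(
    participant_id = wide$participant_id,
    err_rep_t1 = wide$rep_t1, err_rep_t2 = wide$rep_t2,
    err_rep_t3 = wide$rep_t3, err_cat_t3 = wide$cat_t3
  )
}

#' Speech-latency profile
#'
#' A latency (speech break) is the gap from one token's offset to the next
#' token's onset, computed over all tokens regardless of code (errors
#' occupy speaking time). Each task is divided into four 30-second
#' intervals; a pause is assigned to the interval containing its start
#' (the preceding token's offset). Features per task: overall mean
#' latency, the four interval means (`NA` when no pause starts in the
#' interval), and the difference i4 - i1 tracking slowing over the task
#' (`NA` when either interval mean is undefined). The gap before the
#' first word is not a latency.
#'
#' @param sessions A validated session tibble.
#' @param duration Task duration in seconds (default 120); interval width
#'   is `duration / 4`.
#' @return A tibble: `participant_id`, `lat_mean_t*`, `lat_q1_t*` ..
#'   `lat_q4_t*`, `lat_diff_t*`.
#' @export
extract_latencies <- function(sessions, duration = 120) {
  breaks <- duration / 4 * (0:3)
  per_task <- sessions |>
    group_by(.data$participant_id, .data$task) |>
    summarise(
      pause = list(diff_gap(.data$onset, .data$offset)),
      start = list(.data$offset[-dplyr::n()][seq_along(diff_gap(.data$onset, .data$offset))]),
      .groups = "drop") |>
    mutate(
      lat_mean = purrr::map_dbl(.data$pause, ~ if (length(.x)) mean(.x) else NA_real_),
      qmeans = purrr::map2(.data$pause, .data$start, function(p, s) {
        q <- findInterval(s, breaks)
        vapply(1:4, function(k) if (any(q == k)) mean(p[q == k]) else NA_real_,
               numeric(1))
      }),
      lat_q1 = purrr::map_dbl(.data$qmeans, 1), lat_q2 = purrr::map_dbl(.data$qmeans, 2),
      lat_q3 = purrr::map_dbl(.data$qmeans, 3), lat_q4 = purrr::map_dbl(.data$qmeans, 4),
      lat_diff = .data$lat_q4 - .data$lat_q1
    ) |>
    select(all_of(c("participant_id", "task", "lat_mean",
                    "lat_q1", "lat_q2", "lat_q3", "lat_q4", "lat_diff"))) |>
    dplyr::right_join(.task_grid(sessions), by = c("participant_id", "task"))
  per_task |>
    tidyr::pivot_wider(names_from = "task",
                       values_from = c("lat_mean", "lat_q1", "lat_q2",
                                       "lat_q3", "lat_q4", "lat_diff"),
                       names_sep = "_") |>
    select(all_of(c("participant_id",
                    paste0(rep(c("lat_mean", paste0("lat_q", 1:4), "lat_diff"),
                               each = 3), "_", c("t1", "t2", "t3")))))
}

# mean that treats "no surviving pair" as undefined rather than NaN
.pair_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' Semantic relatedness means
#'
#' For each task, over correct-coded tokens in production order:
#' the *sequential* mean averages the similarity of consecutive word
#' pairs; the *cumulative* mean averages over all unordered word pairs.
#' Word pairs with undefined similarity (a word missing from the lexical
#' resource, or an unreachable synset pair) are deleted before averaging;
#' after a deletion the two neighbours of the missing word are not
#' treated as consecutive. For the switching task, per-category
#' sequential means average consecutive (adjacent-in-production) pairs
#' that share the same category label (cat1 = sports, cat2 = fruits).
#' A mean with no surviving pair is `NA`.
#'
#' @param sessions A validated session tibble.
#' @param resource A `fluency_taxonomy` or `fluency_embeddings` backend.
#' @param tag Column-name tag for the backend (`"tax"` or `"emb"`).
#' @return A tibble: `participant_id`, `sem_seq_<tag>_t*`,
#'   `sem_cum_<tag>_t*`, `sem_seq_<tag>_cat1_t3`, `sem_seq_<tag>_cat2_t3`.
#' @export
extract_semantic_means <- function(sessions, resource, tag = "tax") {
  correct <- filter(sessions, .data$code == "correct")
  S <- similarity_matrix(resource, unique(correct$word))
  per_task <- correct |>
    group_by(.data$participant_id, .data$task) |>
    summarise(
      seq_mean = semantic_seq_mean(.data$word, S),
      cum_mean = semantic_cum_mean(.data$word, S),
      cat1 = semantic_seq_mean(.data$word[.data$category %in% "sports"], S,
                               adjacency = which(.data$category %in% "sports")),
      cat2 = semantic_seq_mean(.data$word[.data$category %in% "fruits"], S,
                               adjacency = which(.data$category %in% "fruits")),
      .groups = "drop") |>
    dplyr::right_join(.task_grid(sessions), by = c("participant_id", "task"))
  wide <- per_task |>
    tidyr::pivot_wider(names_from = "task",
                       values_from = c("seq_mean", "cum_mean", "cat1", "cat2"))
  out <- tibble(participant_id = wide$participant_id)
  for (tk in c("t1", "t2", "t3")) {
    out[[paste0("sem_seq_", tag, "_", tk)]] <- wide[[paste0("seq_mean_", tk)]]
    out[[paste0("sem_cum_", tag, "_", tk)]] <- wide[[paste0("cum_mean_", tk)]]
  }
  out[[paste0("sem_seq_", tag, "_cat1_t3")]] <- wide$cat1_t3
  out[[paste0("sem_seq_", tag, "_cat2_t3")]] <- wide$cat2_t3
  out
}

# mean similarity over consecutive pairs; when `adjacency` (original token
# positions) is given, only pairs adjacent in the *full* production order
# count as consecutive — used for within-category means in the switching
# task, where strict alternation leaves no consecutive same-category pair.
semantic_seq_mean <- function(words, S, adjacency = NULL) {
  m <- length(words)
  if (m < 2) return(NA_real_)
  i <- seq_len(m - 1L)
  if (!is.null(adjacency)) i <- i[diff(adjacency) == 1L]
  if (length(i) == 0) return(NA_real_)
  .pair_mean(S[cbind(words[i], words[i + 1L])])
}

semantic_cum_mean <- function(words, S) {
  m <- length(words)
  if (m < 2) return(NA_real_)
  sub <- S[words, words, drop = FALSE]
  .pair_mean(sub[upper.tri(sub)])
}

#' Build the comprehensive fluency feature table
#'
#' Assembles all 43 features per participant: sum scores, error counts,
#' latency profiles, and semantic relatedness means on both backends.
#' Features whose ingredients are missing (absent task, undefined mean,
#' missing backend) are `NA`; the prediction engine imputes within
#' cross-validation folds.
#'
#' @param sessions A validated session tibble.
#' @param taxonomy A `fluency_taxonomy`, or `NULL` to leave the `_tax`
#'   features missing.
#' @param embeddings A `fluency_embeddings`, or `NULL` to leave the
#'   `_emb` features missing.
#' @param duration Task duration in seconds.
#' @return A tibble `participant_id` + exactly 43 feature columns in
#'   canonical order.
#' @export
build_feature_table <- function(sessions, taxonomy = NULL, embeddings = NULL,
                                duration = 120) {
  sessions <- validate_sessions(sessions, duration = duration)
  parts <- list(
    extract_sum_scores(sessions),
    extract_error_counts(sessions),
    extract_latencies(sessions, duration = duration)
  )
  sem_na <- function(tag) {
    out <- tibble(participant_id = unique(sessions$participant_id))
    for (nm in grep(paste0("^sem_.*_", tag, "_"),
                    feature_names("full"), value = TRUE)) {
      out[[nm]] <- NA_real_
    }
    out
  }
  parts <- c(parts, list(
    if (is.null(taxonomy)) sem_na("tax") else
      extract_semantic_means(sessions, taxonomy, tag = "tax"),
    if (is.null(embeddings)) sem_na("emb") else
      extract_semantic_means(sessions, embeddings, tag = "emb")
  ))
  out <- purrr::reduce(parts, left_join, by = "participant_id")
  out <- select(out, all_of(c("participant_id", feature_names("full"))))
  stopifnot(ncol(out) == 44L)
  out
}

#' Classical sum-score feature subset
#'
#' @param features A feature table from [build_feature_table()].
#' @return `participant_id` plus the four sum-score columns.
#' @export
classical_features <- function(features) {
  select(features, all_of(c("participant_id", feature_names("classical"))))
}
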