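test_that("feature name sets have the canonical sizes and nesting", {
  full <- feature_names("full")
  classical <- feature_names("classical")
  expect_length(full, 43)
  expect_length(classical, 4)
  expect_true(all(classical %in% full))
  expect_equal(anyDuplicated(full), 0)
})

# sessions where p1 has correct counts 20/10/15 and some error tokens
sum_fixture <- function() {
  mk <- function(task, n_correct, n_rep = 0, category = NA) {
    k <- n_correct + n_rep
    tibble::tibble(
      participant_id = "p1", task = task,
      word = paste0(task, "w", seq_len(k)),
      onset = seq_len(k) * 2, offset = seq_len(k) * 2 + 0.5,
      code = rep(c("correct", "repetition_error"), c(n_correct, n_rep)),
      category = as.character(category))
  }
  dplyr::bind_rows(mk("t1", 20, n_rep = 2), mk("t2", 10),
                   mk("t3", 15, category = "sports"))
}

test_that("sum scores count correct tokens only and form the switch coefficient", {
  sums <- extract_sum_scores(validate_sessions(sum_fixture()))
  expect_equal(sums$sum_t1, 20)  # the 2 repetition errors do not count
  expect_equal(sums$sum_t2, 10)
  expect_equal(sums$sum_t3, 15)
  expect_equal(sums$sum_total, 45)
  expect_equal(sums$switch_coef, 15 / ((20 + 10) / 2))  # = 1.0
})

test_that("switch coefficient is undefined when both simple tasks are empty", {
  s <- dplyr::bind_rows(
    tok("p1", "t1", "dog", 1, 2, code = "repetition_error"),
    tok("p1", "t2", "baker", 1, 2, code = "repetition_error"),
    tok("p1", "t3", "golf", 1, 2, category = "sports"),
    tok("p1", "t3", "plum", 3, 4, category = "fruits"),
    tok("p1", "t3", "judo", 5, 6, category = "sports"),
    tok("p1", "t3", "kiwi", 7, 8, category = "fruits"))
  sums <- extract_sum_scores(validate_sessions(s))
  expect_equal(sums$sum_t1 + sums$sum_t2, 0)
  expect_true(is.na(sums$switch_coef))
  expect_equal(sums$sum_t3, 4)
})

test_that("error counts split by code and task; absent tasks give NA", {
  s <- dplyr::bind_rows(
    tok("p1", "t1", "dog", 1, 2),
    tok("p1", "t3", "golf", 1, 2, category = "sports"),
    tok("p1", "t3", "golf", 3, 4, code = "repetition_error", category = "sports"),
    tok("p1", "t3", "dog", 5, 6, code = "category_error", category = "fruits"),
    tok("p1", "t3", "plum", 7, 8, category = "fruits"))
  errs <- extract_error_counts(validate_sessions(s))
  expect_equal(errs$err_rep_t1, 0)
  expect_true(is.na(errs$err_rep_t2))  # no t2 session
  expect_equal(errs$err_rep_t3, 1)
  expect_equal(errs$err_cat_t3, 1)
})

test_that("latency intervals follow the pause-start rule", {
  # one pause of 2.0 s starting at offset 1.5 (first 30 s interval)
  s1 <- dplyr::bind_rows(tok("p1", "t1", "dog", 1.0, 1.5),
                         tok("p1", "t1", "cat", 3.5, 4.0))
  lat <- extract_latencies(validate_sessions(s1))
  expect_equal(lat$lat_mean_t1, 2.0)
  expect_equal(lat$lat_q1_t1, 2.0)
  expect_true(all(is.na(c(lat$lat_q2_t1, lat$lat_q3_t1, lat$lat_q4_t1,
                          lat$lat_diff_t1))))

  # pauses 1.0 s starting at 10 s and 3.0 s starting at 100 s
  s2 <- dplyr::bind_rows(tok("p1", "t1", "dog", 9.0, 10.0),
                         tok("p1", "t1", "cat", 11.0, 100.0),
                         tok("p1", "t1", "fox", 103.0, 104.0))
  lat2 <- extract_latencies(validate_sessions(s2))
  expect_equal(lat2$lat_q1_t1, 1.0)
  expect_equal(lat2$lat_q4_t1, 3.0)
  expect_equal(lat2$lat_diff_t1, 2.0)
  expect_equal(lat2$lat_mean_t1, 2.0)

  # single token: no pause at all
  lat3 <- extract_latencies(validate_sessions(tok("p1", "t1", "dog", 1, 2)))
  expect_true(all(is.na(dplyr::select(lat3, -participant_id))))
})

test_that("latencies include error tokens (they occupy speaking time)", {
  s <- dplyr::bind_rows(tok("p1", "t1", "dog", 1.0, 1.5),
                        tok("p1", "t1", "dog", 2.5, 3.0, code = "repetition_error"),
                        tok("p1", "t1", "cat", 5.0, 5.5))
  lat <- extract_latencies(validate_sessions(s))
  expect_equal(lat$lat_mean_t1, mean(c(1.0, 2.0)))
})

test_that("sequential and cumulative semantic means follow the fixture arithmetic", {
  gram <- matrix(c(1, .9, .7,
                   .9, 1, .8,
                   .7, .8, 1), 3, 3, dimnames = list(NULL, NULL))
  emb <- embeddings_with_gram(c("w1", "w2", "w3"), gram)
  s <- dplyr::bind_rows(tok("p1", "t1", "w1", 1, 2), tok("p1", "t1", "w2", 3, 4),
                        tok("p1", "t1", "w3", 5, 6))
  sem <- extract_semantic_means(validate_sessions(s), emb, tag = "emb")
  expect_equal(sem$sem_seq_emb_t1, (0.9 + 0.8) / 2, tolerance = 1e-10)
  expect_equal(sem$sem_cum_emb_t1, (0.9 + 0.8 + 0.7) / 3, tolerance = 1e-10)
})

test_that("pairs with a missing word are deleted without splicing neighbours", {
  gram <- matrix(c(1, .9, .7,
                   .9, 1, .8,
                   .7, .8, 1), 3, 3)
  emb <- embeddings_with_gram(c("w1", "w2", "w3"), gram)
  emb_missing <- structure(unclass(emb)[c("w1", "w3"), ],
                           class = class(emb))  # w2 has no vector
  s <- dplyr::bind_rows(tok("p1", "t1", "w1", 1, 2), tok("p1", "t1", "w2", 3, 4),
                        tok("p1", "t1", "w3", 5, 6))
  sem <- extract_semantic_means(validate_sessions(s), emb_missing, tag = "emb")
  # both consecutive pairs involve w2 and are deleted; w1-w3 is NOT consecutive
  expect_true(is.na(sem$sem_seq_emb_t1))
  expect_equal(sem$sem_cum_emb_t1, 0.7, tolerance = 1e-10)
})

test_that("strict alternation leaves per-category sequential means undefined", {
  s <- dplyr::bind_rows(
    tok("p1", "t3", "golf", 1, 2, category = "sports"),
    tok("p1", "t3", "plum", 3, 4, category = "fruits"),
    tok("p1", "t3", "judo", 5, 6, category = "sports"))
  sem <- extract_semantic_means(validate_sessions(s), toy_taxonomy(), tag = "tax")
  expect_true(is.na(sem$sem_seq_tax_cat1_t3))
  expect_true(is.na(sem$sem_seq_tax_cat2_t3))
  expect_false(is.na(sem$sem_seq_tax_t3))  # task-level mean still defined
})

test_that("per-category sequential means use adjacent same-category pairs", {
  s <- dplyr::bind_rows(
    tok("p1", "t3", "golf", 1, 2, category = "sports"),
    tok("p1", "t3", "judo", 3, 4, category = "sports"),
    tok("p1", "t3", "plum", 5, 6, category = "fruits"),
    tok("p1", "t3", "tennis", 7, 8, category = "sports"))
  tax <- toy_taxonomy()
  sem <- extract_semantic_means(validate_sessions(s), tax, tag = "tax")
  expect_equal(sem$sem_seq_tax_cat1_t3, word_similarity(tax, "golf", "judo"))
  expect_true(is.na(sem$sem_seq_tax_cat2_t3))  # only one fruit token
})

test_that("cumulative means are permutation invariant, sequential means are not", {
  set.seed(7)
  tax <- toy_taxonomy()
  pool <- c("dog", "cow", "lion", "eagle", "salmon", "cat", "wolf", "hawk")
  for (rep_i in 1:5) {
    words <- sample(pool, 6)
    mk <- function(w) validate_sessions(tibble::tibble(
      participant_id = "p1", task = "t1", word = w,
      onset = seq_along(w) * 2, offset = seq_along(w) * 2 + 0.5,
      code = "correct", category = NA_character_))
    perm <- sample(words)
    a <- extract_semantic_means(mk(words), tax, tag = "tax")
    b <- extract_semantic_means(mk(perm), tax, tag = "tax")
    expect_equal(a$sem_cum_tax_t1, b$sem_cum_tax_t1, tolerance = 1e-12)
  }
  # a swap of two non-consecutive tokens that changes adjacent similarities
  words <- c("dog", "cat", "cow", "eagle", "salmon")
  swapped <- c("salmon", "cat", "cow", "eagle", "dog")
  mk <- function(w) validate_sessions(tibble::tibble(
    participant_id = "p1", task = "t1", word = w,
    onset = seq_along(w) * 2, offset = seq_along(w) * 2 + 0.5,
    code = "correct", category = NA_character_))
  a <- extract_semantic_means(mk(words), tax, tag = "tax")
  b <- extract_semantic_means(mk(swapped), tax, tag = "tax")
  expect_equal(a$sem_cum_tax_t1, b$sem_cum_tax_t1, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$sem_seq_tax_t1, b$sem_seq_tax_t1)))
})

test_that("semantic means use correct-coded tokens only", {
  tax <- toy_taxonomy()
  s_clean <- dplyr::bind_rows(tok("p1", "t1", "dog", 1, 2),
                              tok("p1", "t1", "cat", 3, 4))
  s_err <- dplyr::bind_rows(tok("p1", "t1", "dog", 1, 2),
                            tok("p1", "t1", "salmon", 2.2, 2.8,
                                code = "repetition_error"),
                            tok("p1", "t1", "cat", 3, 4))
  a <- extract_semantic_means(validate_sessions(s_clean), tax, tag = "tax")
  b <- extract_semantic_means(validate_sessions(s_err), tax, tag = "tax")
  expect_equal(a$sem_seq_tax_t1, b$sem_seq_tax_t1)
  expect_equal(a$sem_cum_tax_t1, b$sem_cum_tax_t1)
})

test_that("the assembled table has 43 features and propagates missingness", {
  tbl <- make_sessions_tbl()
  ft <- build_feature_table(tbl, toy_taxonomy(), toy_embeddings())
  expect_equal(ncol(ft), 44)  # participant_id + 43
  expect_identical(setdiff(names(ft), "participant_id"), feature_names("full"))
  expect_equal(ncol(classical_features(ft)), 5)

  only_t1 <- tok("p9", "t1", "dog", 1, 1.5)
  ft2 <- build_feature_table(dplyr::bind_rows(tbl, only_t1),
                             toy_taxonomy(), toy_embeddings())
  row <- ft2[ft2$participant_id == "p9", ]
  expect_equal(row$sum_t1, 1)
  expect_true(is.na(row$sum_t2) && is.na(row$sum_t3))
  expect_true(is.na(row$sum_total) && is.na(row$switch_coef))
  expect_true(is.na(row$err_rep_t3) && is.na(row$err_cat_t3))

  # sum conservation where defined
  ok <- !is.na(ft$sum_total)
  expect_equal(ft$sum_total[ok], ft$sum_t1[ok] + ft$sum_t2[ok] + ft$sum_t3[ok])
})

test_that("missing backends leave their feature block NA but keep the shape", {
  ft <- build_feature_table(make_sessions_tbl(), toy_taxonomy(), NULL)
  expect_equal(ncol(ft), 44)
  emb_cols <- grep("_emb_", names(ft), value = TRUE)
  expect_true(all(is.na(as.matrix(ft[emb_cols]))))
  expect_false(all(is.na(ft$sem_seq_tax_t1)))
})
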