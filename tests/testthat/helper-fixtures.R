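# Shared fixtures built in code.

# one hand-coded token row
tok <- function(pid, task, word, onset, offset, code = "correct", category = NA) {
  tibble::tibble(participant_id = pid, task = task, word = word,
                 onset = onset, offset = offset, code = code,
                 category = as.character(category))
}

# two participants x three tasks, a few tokens each
make_sessions_tbl <- function() {
  dplyr::bind_rows(
    tok("p1", "t1", "dog", 1.0, 1.5), tok("p1", "t1", "cat", 3.5, 4.0),
    tok("p1", "t2", "baker", 2.0, 2.6), tok("p1", "t2", "nurse", 5.0, 5.5),
    tok("p1", "t3", "soccer", 1.0, 1.6, category = "sports"),
    tok("p1", "t3", "apple", 4.0, 4.5, category = "fruits"),
    tok("p2", "t1", "wolf", 0.5, 1.0),
    tok("p2", "t2", "judge", 1.0, 1.4),
    tok("p2", "t3", "tennis", 2.0, 2.5, category = "sports")
  )
}

# write a taxonomy from vectors and load it
make_taxonomy <- function(synsets, edges, lexicon) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  readr::write_tsv(tibble::tibble(id = synsets), file.path(d, "synsets.tsv"))
  readr::write_tsv(tibble::tibble(id1 = edges[[1]], id2 = edges[[2]]),
                   file.path(d, "edges.tsv"))
  readr::write_tsv(tibble::tibble(word = lexicon[[1]], synset_id = lexicon[[2]]),
                   file.path(d, "lexicon.tsv"))
  load_taxonomy(file.path(d, "synsets.tsv"), file.path(d, "edges.tsv"),
                file.path(d, "lexicon.tsv"))
}

# a--b--c chain, one word per synset
chain_taxonomy <- function() {
  make_taxonomy(c("a", "b", "c"),
                list(c("a", "b"), c("b", "c")),
                list(c("wa", "wb", "wc"), c("a", "b", "c")))
}

# embeddings object with prescribed pairwise cosine similarities
embeddings_with_gram <- function(words, gram) {
  v <- t(chol(gram))  # rows are unit vectors with the requested inner products
  rownames(v) <- words
  structure(v, class = c("fluency_embeddings", class(v)))
}

# independent dense all-pairs shortest-path oracle (Floyd-Warshall)
fw_distances <- function(n_nodes, edges) {
  d <- matrix(Inf, n_nodes, n_nodes)
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n_nodes)) {
    for (i in seq_len(n_nodes)) {
      dk <- d[i, k] + d[k, ]
      lower <- dk < d[i, ]
      d[i, lower] <- dk[lower]
    }
  }
  d
}

# oracle path similarity from a Floyd-Warshall distance matrix
fw_similarity <- function(d) {
  msp <- max(d[is.finite(d)])
  s <- (msp - d) / msp
  s[!is.finite(d)] <- NA_real_
  if (msp == 0) { s <- ifelse(d == 0, 1, NA_real_) }
  s
}

# random connected-ish undirected graph as an edge matrix
random_edges <- function(n_nodes, p_edge) {
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  pairs[keep, , drop = FALSE]
}

# small cohort + features, cached per test file via memoised env
small_cohort <- local({
  cache <- new.env()
  function(n = 40, seed = 1, scenario = "realistic") {
    key <- paste(n, seed, scenario, sep = "_")
    if (is.null(cache[[key]])) {
      coh <- generate_cohort(cohort_config(n_participants = n, seed = seed,
                                           scenario = scenario))
      coh$features <- build_feature_table(coh$sessions, toy_taxonomy(),
                                          toy_embeddings())
      cache[[key]] <- coh
    }
    cache[[key]]
  }
})
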