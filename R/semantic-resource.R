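#' Load a taxonomy backend
#'
#' Builds the taxonomy-graph relatedness backend from three TSV files:
#' `synsets.tsv` (`id`, optional `gloss`), `edges.tsv` (`id1`, `id2`;
#' undirected, unweighted semantic relations) and `lexicon.tsv` (`word`,
#' `synset_id`; one row per word sense). The longest finite shortest path
#' between any two synsets (`max_shortest_path`) is computed at load by
#' all-pairs breadth-first search and cached together with the full synset
#' distance matrix, so word-pair queries are O(senses^2) lookups.
#'
#' @param synsets,edges,lexicon Paths to the three TSV files.
#' @return An object of class `fluency_taxonomy`.
#' @export
load_taxonomy <- function(synsets, edges, lexicon) {
  syn <- readr::read_tsv(synsets, col_types = readr::cols(.default = readr::col_character()))
  edg <- readr::read_tsv(edges, col_types = readr::cols(.default = readr::col_character()))
  lex <- readr::read_tsv(lexicon, col_types = readr::cols(.default = readr::col_character()))
  dangling <- setdiff(c(edg$id1, edg$id2), syn$id)
  if (length(dangling) > 0) {
    stop("edge endpoints not in synset list: ", paste(dangling, collapse = ", "))
  }
  orphan <- setdiff(lex$synset_id, syn$id)
  if (length(orphan) > 0) {
    stop("lexicon synsets not in synset list: ", paste(orphan, collapse = ", "))
  }
  lex <- mutate(lex, word = normalize_word(.data$word))
  g <- igraph::graph_from_data_frame(edg, directed = FALSE,
                                     vertices = data.frame(name = syn$id))
  dist <- igraph::distances(g)      # hop counts; Inf across components
  finite <- dist[is.finite(dist)]
  structure(list(
    graph = g,
    synsets = syn$id,
    lexicon = lex,
    dist = dist,
    max_shortest_path = if (length(finite) > 0) max(finite) else 0
  ), class = "fluency_taxonomy")
}

#' @export
print.fluency_taxonomy <- function(x, ...) {
  cat("<fluency_taxonomy> ", length(x$synsets), " synsets, ",
      igraph::ecount(x$graph), " edges, ", length(unique(x$lexicon$word)),
      " words; max_shortest_path = ", x$max_shortest_path, "\n", sep = "")
  invisible(x)
}

#' Path-based synset similarity
#'
#' Relatedness of two synsets on the taxonomy graph:
#' `(max_shortest_path - length(s1, s2)) / max_shortest_path`, where
#' `length` is the shortest-path hop count and `max_shortest_path` the
#' longest finite shortest path in the whole taxonomy. Identical synsets
#' score 1; a pair realizing the taxonomy diameter scores 0; pairs in
#' different components are undefined (`NA`) and are dropped by callers.
#'
#' @param taxonomy A `fluency_taxonomy`.
#' @param s1,s2 Synset identifiers (vectorized, recycled).
#' @return Numeric similarity in `[0, 1]`, `NA` where undefined.
#' @export
path_similarity <- function(taxonomy, s1, s2) {
  stopifnot(inherits(taxonomy, "fluency_taxonomy"))
  bad <- setdiff(c(s1, s2), taxonomy$synsets)
  if (length(bad) > 0) stop("unknown synset(s): ", paste(bad, collapse = ", "))
  len <- taxonomy$dist[cbind(s1, s2)]
  msp <- taxonomy$max_shortest_path
  if (msp == 0) return(ifelse(len == 0, 1, NA_real_))
  ifelse(is.finite(len), (msp - len) / msp, NA_real_)
}

#' Word similarity through the taxonomy
#'
#' Words may map to several synsets; the synset pair with the closest
#' relatedness is selected, i.e. the similarity is maximized over all
#' sense pairs. A word absent from the lexicon (or a cross-component
#' pair) yields `NA`; downstream the corresponding word pair is deleted
#' before averaging.
#'
#' @param taxonomy A `fluency_taxonomy`.
#' @param w1,w2 Single words (normalized or raw).
#' @return Similarity in `[0, 1]` or `NA`.
#' @export
word_similarity <- function(taxonomy, w1, w2) {
  s1 <- taxonomy$lexicon$synset_id[taxonomy$lexicon$word == normalize_word(w1)]
  s2 <- taxonomy$lexicon$synset_id[taxonomy$lexicon$word == normalize_word(w2)]
  if (length(s1) == 0 || length(s2) == 0) return(NA_real_)
  len <- min(taxonomy$dist[s1, s2, drop = FALSE])
  msp <- taxonomy$max_shortest_path
  if (!is.finite(len)) return(NA_real_)
  if (msp == 0) return(if (len == 0) 1 else NA_real_)
  (msp - len) / msp
}

#' Load word vectors in word2vec text format
#'
#' First line `N d`, then `N` lines `word v1 ... vd`. Zero vectors are
#' dropped at load (they have no direction, so cosine similarity is
#' undefined for them).
#'
#' @param path Path to the vector file.
#' @return An object of class `fluency_embeddings`: a numeric matrix with
#'   one row per word, words as rownames.
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2) stop("malformed word2vec header: ", lines[1])
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("word2vec header announces ", n, " vectors but file has ", length(body))
  }
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad) > 0) {
    stop("malformed vector line(s) (dimension != ", d, "): line ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  words <- normalize_word(vapply(parts, `[[`, "", 1L))
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(mat) <- words
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) mat <- mat[norms > 0, , drop = FALSE]
  structure(mat, class = c("fluency_embeddings", class(mat)))
}

#' @export
print.fluency_embeddings <- function(x, ...) {
  cat("<fluency_embeddings> ", nrow(x), " words x ", ncol(x), " dims\n", sep = "")
  invisible(x)
}

#' Cosine similarity of two word vectors
#'
#' Undefined (`NA`) when either word has no vector; the caller deletes
#' the word pair. Cosine can be negative for arbitrary embeddings; values
#' are used as-is downstream since only relative ordering matters.
#'
#' @param embeddings A `fluency_embeddings`.
#' @param w1,w2 Single words.
#' @return Similarity in `[-1, 1]` or `NA`.
#' @export
embedding_similarity <- function(embeddings, w1, w2) {
  w1 <- normalize_word(w1); w2 <- normalize_word(w2)
  if (!w1 %in% rownames(embeddings) || !w2 %in% rownames(embeddings)) {
    return(NA_real_)
  }
  v1 <- embeddings[w1, ]; v2 <- embeddings[w2, ]
  sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

#' Pairwise word similarity matrix
#'
#' Computes the full word-by-word similarity matrix for a set of words
#' under either backend, so that per-session semantic means reduce to
#' indexing. `NA` marks undefined pairs (missing lexical entries or
#' cross-component synsets).
#'
#' @param resource A `fluency_taxonomy` or `fluency_embeddings`.
#' @param words Character vector of words (deduplicated, normalized).
#' @return A symmetric numeric matrix with `words` as dimnames.
#' @export
similarity_matrix <- function(resource, words) {
  words <- unique(normalize_word(words))
  n <- length(words)
  out <- matrix(NA_real_, n, n, dimnames = list(words, words))
  if (inherits(resource, "fluency_taxonomy")) {
    lex <- resource$lexicon
    senses <- split(lex$synset_id, lex$word)[words]
    msp <- resource$max_shortest_path
    for (i in seq_len(n)) {
      si <- senses[[i]]
      if (is.null(si)) next
      for (j in i:n) {
        sj <- senses[[j]]
        if (is.null(sj)) next
        len <- min(resource$dist[si, sj, drop = FALSE])
        if (!is.finite(len)) next
        out[i, j] <- out[j, i] <-
          if (msp == 0) (if (len == 0) 1 else NA_real_) else (msp - len) / msp
      }
    }
  } else if (inherits(resource, "fluency_embeddings")) {
    present <- words[words %in% rownames(resource)]
    if (length(present) > 0) {
      v <- unclass(resource)[present, , drop = FALSE]
      v <- v / sqrt(rowSums(v^2))
      out[present, present] <- tcrossprod(v)
    }
  } else {
    stop("unknown semantic backend of class ", paste(class(resource), collapse = "/"))
  }
  out
}

#' Bundled toy lexical resource
#'
#' A small two-level taxonomy covering the four task categories (animals,
#' jobs, sports, fruits) in domain subtrees, with matched 16-dimensional
#' word vectors. Shipped as demo data and as the word pool the synthetic
#' cohort generator draws from; it is a synthetic stand-in, not a real
#' lexical-semantic net.
#'
#' @return `toy_taxonomy()`: a `fluency_taxonomy`; `toy_embeddings()`: a
#'   `fluency_embeddings`.
#' @export
toy_taxonomy <- function() {
  d <- system.file("extdata", package = "fluencyEF")
  load_taxonomy(file.path(d, "toy_synsets.tsv"),
                file.path(d, "toy_edges.tsv"),
                file.path(d, "toy_lexicon.tsv"))
}

#' @rdname toy_taxonomy
#' @export
toy_embeddings <- function() {
  load_embeddings(system.file("extdata", "toy_embeddings.vec", package = "fluencyEF"))
}
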