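#' Tokenize an SMS text into a set of stemmed tokens
#'
#' Lowercases the text and splits it into word tokens (runs of unicode word
#' characters, with internal apostrophes kept), standalone punctuation
#' tokens (every other non-space character is its own token), and bracketed
#' placeholder slots such as `[person_name]`, which are kept as single
#' tokens. Duplicate tokens collapse: the result is a set.
#'
#' @param text Character vector of texts.
#' @param stemmer `"lancaster"` to stem word tokens with [stem_lancaster()],
#'   `"none"` to leave them unstemmed.
#' @return A list of character vectors, one set of distinct tokens per text.
#' @export
#' @examples
#' tokenize_message("Hi [person_name], did you exercise today?",
#'                  stemmer = "none")
tokenize_message <- function(text, stemmer = c("lancaster", "none")) {
  stemmer <- match.arg(stemmer)
  text <- tolower(as.character(text))
  pattern <- "\\[[^][]*\\]|[[:alnum:]_]+(?:'[[:alnum:]_]+)*|[^[:alnum:]_[:space:]]"
  toks <- regmatches(text, gregexpr(pattern, text, perl = TRUE))
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (stemmer == "lancaster") tk <- stem_lancaster(tk)
    unique(tk)
  })
}

#' Jaccard similarity of two token sets
#'
#' Size of the intersection over the size of the union. Two empty sets are
#' identical content, so their similarity is 1; an empty set against a
#' non-empty one scores 0.
#'
#' @param a,b Character vectors (token sets; duplicates are ignored).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Clustering configuration
#'
#' @param threshold Similarity threshold in `(0, 1]`; pairs with Jaccard
#'   similarity strictly greater than it are joined. Default 0.5.
#' @param stemmer `"lancaster"` or `"none"`.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(threshold = 0.5, stemmer = c("lancaster", "none")) {
  stemmer <- match.arg(stemmer)
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1)
  structure(list(threshold = threshold, stemmer = stemmer),
            class = "cluster_config")
}

#' Group near-duplicate messages by stemmed-token Jaccard similarity
#'
#' Builds the graph whose vertices are messages and whose edges join every
#' pair with Jaccard similarity strictly above `config$threshold` (computed
#' on stemmed token sets), and returns its connected components: any two
#' messages similar above the threshold land in the same cluster, and
#' similarity propagates transitively. Byte-identical texts always
#' co-cluster. Cluster ids are integers `0..C-1`, numbered by each
#' cluster's smallest input position, so the labeling is invariant to
#' input order.
#'
#' @param messages A character vector of texts, or the `messages` tibble of
#'   a [communication_log()] (column `text`, ids from `message_id`).
#' @param config A [cluster_config()].
#' @return A tibble with columns `message_id` and `cluster_id`.
#' @export
cluster_messages <- function(messages, config = cluster_config()) {
  if (is.data.frame(messages)) {
    ids <- messages$message_id
    texts <- messages$text
  } else {
    texts <- as.character(messages)
    ids <- if (!is.null(names(texts))) names(texts) else
      sprintf("m%d", seq_along(texts))
  }
  n <- length(texts)
  if (n == 0) stop("cluster_messages requires at least one message")

  token_sets <- tokenize_message(texts, stemmer = config$stemmer)

  # identical token sets are merged up front; similarity is computed once
  # per distinct set via a sparse token-incidence crossproduct
  keys <- vapply(token_sets, function(s) paste(sort(s), collapse = "\r"),
                 character(1))
  uk <- unique(keys)
  grp <- match(keys, uk)
  usets <- token_sets[match(uk, keys)]
  m <- length(usets)

  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }

  sizes <- lengths(usets)
  nonempty <- which(sizes > 0)
  if (length(nonempty) > 1) {
    vocab <- unique(unlist(usets[nonempty], use.names = FALSE))
    ii <- rep.int(nonempty, sizes[nonempty])
    jj <- match(unlist(usets[nonempty], use.names = FALSE), vocab)
    inc <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                dims = c(m, length(vocab)))
    inter <- Matrix::tcrossprod(inc)
    pairs <- Matrix::summary(inter)
    pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    if (nrow(pairs) > 0) {
      un <- sizes[pairs$i] + sizes[pairs$j] - pairs$x
      sim <- pairs$x / un
      hit <- which(sim > config$threshold)
      for (k in hit) union_(pairs$i[k], pairs$j[k])
    }
  }
  # all-empty token sets are mutually identical (similarity 1)
  empties <- which(sizes == 0)
  if (length(empties) > 1 && config$threshold < 1) {
    for (k in empties[-1]) union_(empties[1], k)
  }

  roots <- vapply(seq_len(m), find, integer(1))
  root_of_msg <- roots[grp]
  first_pos <- tapply(seq_len(n), root_of_msg, min)
  cluster_of_root <- rank(first_pos, ties.method = "first") - 1L
  cluster_id <- as.integer(cluster_of_root[as.character(root_of_msg)])

  tibble::tibble(message_id = as.character(ids), cluster_id = cluster_id)
}
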