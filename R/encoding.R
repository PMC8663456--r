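# 32-bit FNV-1a over UTF-8 bytes, in pure R. Multiplication by the FNV
# prime is split into 16-bit halves so every intermediate stays below 2^53
# and the arithmetic is exact in doubles on every platform.
fnv1a32 <- function(strings) {
  prime_lo <- 403         # 16777619 = 256 * 65536 + 403
  prime_hi <- 256
  vapply(strings, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 2166136261
    for (b in bytes) {
      h <- xor32(h, b)
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (lo * prime_lo + ((hi * prime_lo + lo * prime_hi) %% 65536) * 65536) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# xor of two non-negative doubles < 2^32, via 16-bit halves (bitwXor is
# limited to 32-bit signed integers)
xor32 <- function(a, b) {
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(a_lo, b_lo) + bitwXor(a_hi, b_hi) * 65536
}

#' Encoder configuration
#'
#' The default encoder is a deterministic hashed n-gram text vectorizer:
#' stemmed token n-grams are bucketed by a signed 32-bit hash, counts are
#' log-scaled and the vector is L2-normalised. A pretrained sentence
#' embedding satisfying the same contract (fixed width, deterministic,
#' finite) can be plugged in via `provider`.
#'
#' @param encoder `"hashed_ngram"` or `"pretrained_embedding"`.
#' @param dim Vector width; default 768.
#' @param ngram_orders Token n-gram orders to hash; default `c(1, 2)`.
#' @param hash_seed Integer mixed into the hash so independent feature
#'   spaces can be drawn.
#' @param stemmer Passed to [tokenize_message()].
#' @param provider For `"pretrained_embedding"`: a function
#'   `function(texts, dim)` returning a numeric matrix with one row per
#'   text. No provider is bundled; omitting it is a capability error at
#'   encoding time, never a silent fallback.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(encoder = c("hashed_ngram", "pretrained_embedding"),
                           dim = 768, ngram_orders = c(1, 2), hash_seed = 0,
                           stemmer = "lancaster", provider = NULL) {
  encoder <- match.arg(encoder)
  stopifnot(is.numeric(dim), length(dim) == 1, dim >= 1, dim == round(dim),
            length(ngram_orders) >= 1, all(ngram_orders >= 1))
  structure(list(encoder = encoder, dim = as.integer(dim),
                 ngram_orders = as.integer(sort(unique(ngram_orders))),
                 hash_seed = as.integer(hash_seed), stemmer = stemmer,
                 provider = provider),
            class = "encoder_config")
}

text_ngrams <- function(text, config) {
  # order matters for n-grams, so re-tokenize without the set collapse
  text <- tolower(as.character(text))
  pattern <- "\\[[^][]*\\]|[[:alnum:]_]+(?:'[[:alnum:]_]+)*|[^[:alnum:]_[:space:]]"
  toks <- regmatches(text, gregexpr(pattern, text, perl = TRUE))[[1]]
  if (config$stemmer == "lancaster") toks <- stem_lancaster(toks)
  out <- character(0)
  for (k in config$ngram_orders) {
    if (length(toks) >= k) {
      if (k == 1) {
        out <- c(out, toks)
      } else {
        idx <- seq_len(length(toks) - k + 1)
        grams <- toks[idx]
        for (j in seq_len(k - 1)) grams <- paste(grams, toks[idx + j])
        out <- c(out, grams)
      }
    }
  }
  out
}

hash_bucket <- function(grams, config) {
  h <- fnv1a32(paste0(config$hash_seed, "\x1f", grams))
  sign_h <- fnv1a32(paste0(config$hash_seed, "\x1e", grams))
  list(bucket = (h %% config$dim) + 1,
       sign = ifelse(sign_h %% 2 == 0, 1, -1))
}

#' Encode texts as fixed-length feature vectors
#'
#' @param text Character vector.
#' @param config An [encoder_config()].
#' @return A numeric matrix, one row per text, `config$dim` columns. With
#'   the hashed n-gram encoder each non-empty text row has unit L2 norm;
#'   the all-zero vector encodes empty/whitespace text.
#' @export
encode_text <- function(text, config = encoder_config()) {
  text <- as.character(text)
  if (config$encoder == "pretrained_embedding") {
    if (is.null(config$provider)) {
      stop("capability error: no pretrained embedding provider configured; ",
           "supply encoder_config(provider = ...) or use the hashed_ngram ",
           "encoder", call. = FALSE)
    }
    m <- config$provider(text, config$dim)
    if (!is.matrix(m) || nrow(m) != length(text) || ncol(m) != config$dim ||
        any(!is.finite(m))) {
      stop("embedding provider violated its contract (shape or finiteness)",
           call. = FALSE)
    }
    return(m)
  }
  uniq <- unique(text)
  out <- matrix(0, nrow = length(uniq), ncol = config$dim)
  for (i in seq_along(uniq)) {
    grams <- text_ngrams(uniq[i], config)
    if (length(grams) == 0) next
    hb <- hash_bucket(grams, config)
    counts <- tapply(hb$sign, hb$bucket, sum)
    v <- numeric(config$dim)
    idx <- as.integer(names(counts))
    v[idx] <- sign(counts) * log1p(abs(counts))
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    out[i, ] <- v
  }
  out[match(text, uniq), , drop = FALSE]
}

#' Contextualised reply features
#'
#' Concatenates the reply-text encoding with the one-hot intent of the
#' eliciting outgoing message, giving `config$dim + 5` columns.
#'
#' @param reply_text Character vector of reply texts.
#' @param eliciting_intent Character vector of intents of the messages the
#'   replies answer; must be fully labeled (or predicted upstream).
#' @param config An [encoder_config()].
#' @return Numeric matrix `length(reply_text)` x `(config$dim + 5)`.
#' @export
reply_features <- function(reply_text, eliciting_intent,
                           config = encoder_config()) {
  stopifnot(length(reply_text) == length(eliciting_intent))
  if (anyNA(eliciting_intent)) {
    stop("eliciting intent unknown for ", sum(is.na(eliciting_intent)),
         " replies; label or predict intents first", call. = FALSE)
  }
  cbind(encode_text(reply_text, config), one_hot_intent(eliciting_intent))
}
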