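test_that("tokenizer lowercases, splits punctuation, keeps placeholders whole", {
  expect_equal(tokenize_message("", stemmer = "none")[[1]], character(0))
  expect_equal(tokenize_message("STOP", stemmer = "none")[[1]], "stop")
  expect_setequal(
    tokenize_message("Hi [person_name], did you exercise today?",
                     stemmer = "none")[[1]],
    c("hi", "[person_name]", ",", "did", "you", "exercise", "today", "?"))
  # duplicates collapse: result is a set
  expect_equal(tokenize_message("go go go", stemmer = "none")[[1]], "go")
})

test_that("stemmer reproduces published reference stems and passes tokens through", {
  # reference pairs for the default Paice/Husk rule table
  expect_equal(
    stem_lancaster(c("maximum", "presumably", "multiply", "provision",
                     "owed", "ear", "saying", "crying", "string", "meant",
                     "cement")),
    c("maxim", "presum", "multiply", "provid", "ow", "ear", "say", "cry",
      "string", "meant", "cem"))
  expect_equal(stem_lancaster(c("walking", "running", "questions")),
               c("walk", "run", "quest"))
  # too short to strip; punctuation and placeholders untouched
  expect_equal(stem_lancaster(c("go", "?", "[person_name]", "123")),
               c("go", "?", "[person_name]", "123"))
})

test_that("stemming is deterministic and never lengthens a token", {
  bank <- unlist(c(smsengage:::message_template_bank(),
                   smsengage:::reply_template_bank()))
  vocab <- unique(unlist(tokenize_message(bank, stemmer = "none")))
  once <- stem_lancaster(vocab)
  expect_identical(stem_lancaster(vocab), once)
  expect_true(all(nchar(once) <= nchar(vocab)))
  # non-alphabetic tokens are untouched
  keep <- !grepl("^[a-z]+$", vocab)
  expect_identical(once[keep], vocab[keep])
})

test_that("jaccard matches enumeration and its boundary conventions", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(character(0), c("a")), 0)
})

test_that("jaccard is symmetric, bounded, and 1 iff sets are equal", {
  set.seed(42)
  for (i in 1:50) {
    a <- sample(letters, sample(0:8, 1))
    b <- sample(letters, sample(0:8, 1))
    s <- jaccard(a, b)
    expect_equal(s, jaccard(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s == 1, setequal(a, b))
  }
})

test_that("identical texts co-cluster and sub-threshold pairs stay apart", {
  cl <- cluster_messages(c(a = "Take your pill", b = "take your PILL",
                           c = "completely different words here"))
  expect_equal(cl$cluster_id[1], cl$cluster_id[2])
  expect_false(cl$cluster_id[3] == cl$cluster_id[1])
})

test_that("similarity chains merge transitively even when endpoints are dissimilar", {
  # A~B and B~C exceed 0.5 while A~C is far below: one component
  a <- "alpha beta gamma delta"
  b <- "alpha beta gamma epsilon"
  c_ <- "alpha epsilon zeta eta"
  ts <- tokenize_message(c(a, b, c_), stemmer = "none")
  expect_gt(jaccard(ts[[1]], ts[[2]]), 0.5)
  expect_gt(jaccard(ts[[2]], ts[[3]]), 0.33)
  cl <- cluster_messages(c(a, b, c_),
                         cluster_config(threshold = 0.33, stemmer = "none"))
  expect_equal(length(unique(cl$cluster_id)), 1)
})

test_that("clustering equals the brute-force union-find oracle", {
  set.seed(11)
  for (n in c(15, 60, 200)) {
    vocab <- sprintf("w%02d", 1:40)
    texts <- vapply(seq_len(n), function(i) {
      paste(sample(vocab, sample(3:10, 1)), collapse = " ")
    }, character(1))
    for (thr in c(0.3, 0.5, 0.7)) {
      got <- cluster_messages(texts, cluster_config(threshold = thr,
                                                    stemmer = "none"))
      want <- brute_force_clusters(tokenize_message(texts, stemmer = "none"),
                                   thr)
      expect_equal(canonical_partition(got$cluster_id),
                   canonical_partition(want),
                   info = sprintf("n=%d thr=%.1f", n, thr))
    }
  }
})

test_that("raising the threshold refines the partition and order does not matter", {
  set.seed(12)
  texts <- vapply(1:80, function(i) {
    paste(sample(sprintf("w%d", 1:25), sample(4:9, 1)), collapse = " ")
  }, character(1))
  cl_lo <- cluster_messages(texts, cluster_config(threshold = 0.4,
                                                  stemmer = "none"))
  cl_hi <- cluster_messages(texts, cluster_config(threshold = 0.7,
                                                  stemmer = "none"))
  # refinement: messages together at the high threshold are together at the low
  for (cid in unique(cl_hi$cluster_id)) {
    members <- which(cl_hi$cluster_id == cid)
    expect_equal(length(unique(cl_lo$cluster_id[members])), 1)
  }
  perm <- sample(seq_along(texts))
  cl_perm <- cluster_messages(texts[perm],
                              cluster_config(threshold = 0.4, stemmer = "none"))
  back <- integer(length(texts)); back[perm] <- cl_perm$cluster_id
  expect_equal(canonical_partition(back), canonical_partition(cl_lo$cluster_id))
})

test_that("empty input errors and ties at the threshold do not merge", {
  expect_error(cluster_messages(character(0)), "at least one")
  # jaccard exactly 0.5: {a,b,c} vs {b,c,d}
  cl <- cluster_messages(c("a b c", "b c d"),
                         cluster_config(threshold = 0.5, stemmer = "none"))
  expect_equal(length(unique(cl$cluster_id)), 2)
})
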