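test_that("generation is reproducible from the seed", {
  cfg <- synthetic_config(n_participants = c(ONE_WAY = 30, TWO_WAY = 30),
                          messages_per_participant = 6, seed = 31L)
  g1 <- generate_log(cfg)
  g2 <- generate_log(cfg)
  for (part in c("messages", "replies", "participants")) {
    expect_identical(as.data.frame(g1$log[[part]]),
                     as.data.frame(g2$log[[part]]))
  }
  g3 <- generate_log(synthetic_config(n_participants = c(ONE_WAY = 30,
                                                         TWO_WAY = 30),
                                      messages_per_participant = 6,
                                      seed = 32L))
  expect_false(identical(g1$log$messages$text, g3$log$messages$text))
})

test_that("generator output always passes log validation", {
  for (name in c("tiny", "easy", "hard", "null_effect")) {
    fx <- make_fixture(name)
    expect_equal(nrow(validate_log(fx$log)), 0, info = name)
  }
})

test_that("realized intent frequencies concentrate around the configured simplex", {
  cfg <- synthetic_config(n_participants = c(ONE_WAY = 500, TWO_WAY = 500),
                          messages_per_participant = 10,
                          intervention_fraction = 1, with_text = FALSE,
                          seed = 33L)
  gen <- generate_log(cfg)
  for (pr in program_levels()) {
    msgs <- gen$log$messages[gen$log$messages$program == pr, ]
    n <- nrow(msgs)
    expect_equal(n, 5000)
    p <- cfg$intent_distribution[, pr]
    freq <- table(factor(msgs$intent, intent_levels())) / n
    expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / n)), info = pr)
  }
})

test_that("noise-free texts are verbatim templates; noisy copies stay similar", {
  bank <- smsengage:::message_template_bank()
  set.seed(34)
  txt <- generate_message_text("INFORMATIVE", bank, noise = 0, template_id = 1)
  got <- strsplit(txt, " ", fixed = TRUE)[[1]]
  want <- strsplit(bank$INFORMATIVE[1], " ", fixed = TRUE)[[1]]
  expect_equal(length(got), length(want))
  slot <- want == "[person_name]"
  expect_equal(got[!slot], want[!slot])  # verbatim outside the name slot
  expect_true(all(got[slot] %in% smsengage:::person_names))
  # two draws from one template at noise 0.1: stemmed Jaccard > 0.5 almost always
  hits <- replicate(400, {
    a <- generate_message_text("MOTIVATIONAL", bank, noise = 0.1,
                               template_id = 2)
    b <- generate_message_text("MOTIVATIONAL", bank, noise = 0.1,
                               template_id = 2)
    ts <- tokenize_message(c(a, b))
    jaccard(ts[[1]], ts[[2]]) > 0.5
  })
  expect_gt(mean(hits), 0.95)
  expect_error(generate_message_text("INFORMATIVE", list(), noise = 0),
               "empty template bank")
})

test_that("intent template banks share little cross-intent vocabulary", {
  bank <- smsengage:::message_template_bank()
  vocab <- lapply(bank, function(tt) unique(unlist(tokenize_message(tt))))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(jaccard(vocab[[i]], vocab[[j]]), 0.2)
  }
})

test_that("the realized stop odds ratio tracks the configured truth", {
  or <- matrix(1, 5, 2, dimnames = list(intent_levels(), program_levels()))
  or["INFORMATIVE", ] <- 2
  cfg <- synthetic_config(
    n_participants = c(ONE_WAY = 900, TWO_WAY = 900),
    messages_per_participant = 20, intervention_fraction = 1,
    reply_propensity = c(INFORMATIVE = 0.55, INSTRUCTIONAL = 0.55,
                         MOTIVATIONAL = 0.55, SUPPORTIVE = 0.55,
                         NOTIFICATION = 0.55),
    true_stop_OR = or, withdrawal_rate = 0, with_text = FALSE, seed = 35L)
  gen <- generate_log(cfg)
  ev <- build_event_table(gen$log)
  expect_gt(nrow(ev), 10000)
  fit <- fit_univariate_logistic(ev$is_stop, ev$intent == "INFORMATIVE")
  expect_gt(fit$or, 1.8)
  expect_lt(fit$or, 2.2)
})

test_that("infeasible stop configurations fail fast with the offending cell", {
  dist <- smsengage:::default_reply_category_distribution()
  dist["STOP", "NOTIFICATION"] <- 0
  dist["GENERAL_COMMENT", "NOTIFICATION"] <-
    dist["GENERAL_COMMENT", "NOTIFICATION"] + 0.05
  or <- matrix(1, 5, 2, dimnames = list(intent_levels(), program_levels()))
  or["NOTIFICATION", "ONE_WAY"] <- 3
  expect_error(synthetic_config(reply_category_distribution = dist,
                                true_stop_OR = or),
               "NOTIFICATION")
})

test_that("fixtures honour their contracts", {
  tiny <- make_fixture("tiny")
  expect_lte(nrow(tiny$log$participants), 30)
  null_fx <- make_fixture("null_effect")
  expect_true(all(null_fx$truth$config$true_stop_OR == 1))
  easy <- make_fixture("easy")
  expect_true(any(easy$truth$config$true_stop_OR != 1))
  expect_error(make_fixture("bogus"))
})

test_that("a stop reply ends the participant's reply stream", {
  fx <- make_fixture("easy")
  reps <- fx$log$replies
  msgs <- fx$log$messages
  day_of <- msgs$sent_day[match(reps$in_reply_to, msgs$message_id)]
  for (pid in unique(reps$participant_id[reps$category == "STOP"])) {
    mine <- reps$participant_id == pid
    stop_day <- day_of[mine & reps$category == "STOP"]
    expect_equal(length(stop_day), 1)
    expect_true(all(day_of[mine] <= stop_day))
  }
})
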