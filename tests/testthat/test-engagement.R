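test_that("engagement boundaries follow the at-least-3-and-did-not-stop rule", {
  three <- derive_outcomes(make_outcome_log(rep("THANKS", 3)))
  expect_true(three$engaged); expect_false(three$stopped)

  two <- derive_outcomes(make_outcome_log(rep("THANKS", 2)))
  expect_false(two$engaged)

  with_stop <- derive_outcomes(make_outcome_log(
    c("THANKS", "THANKS", "QUESTION", "STOP", "THANKS")))
  expect_true(with_stop$stopped); expect_false(with_stop$engaged)

  withdrawn <- derive_outcomes(make_outcome_log(rep("THANKS", 4),
                                                withdrew = TRUE))
  expect_true(withdrawn$stopped); expect_false(withdrawn$engaged)

  silent <- derive_outcomes(make_outcome_log(character(0)))
  expect_equal(silent$n_replies, 0L)
  expect_false(silent$engaged); expect_false(silent$stopped)
})

test_that("outcome derivation is monotone in added replies", {
  base <- c("THANKS", "THANKS")
  # adding a non-STOP reply can only promote toward engagement
  more <- derive_outcomes(make_outcome_log(c(base, "QUESTION")))
  expect_true(more$engaged)
  # adding a STOP reply can never create engagement
  stopd <- derive_outcomes(make_outcome_log(c(base, "QUESTION", "STOP")))
  expect_false(stopd$engaged)
  expect_true(stopd$stopped)
})

test_that("missing categories are reported with reply ids", {
  log <- make_outcome_log(c("THANKS", "THANKS"))
  log$replies$category[2] <- NA_character_
  expect_error(derive_outcomes(log), "r2")
})

test_that("the event table joins intents correctly and matches generator tallies", {
  gen <- generate_log(synthetic_config(
    n_participants = c(ONE_WAY = 60, TWO_WAY = 60),
    messages_per_participant = 10, intervention_fraction = 1,
    with_text = FALSE, seed = 21L))
  ev <- build_event_table(gen$log)
  expect_equal(nrow(ev), nrow(gen$log$replies))
  mi <- match(gen$log$replies$in_reply_to, gen$log$messages$message_id)
  expect_equal(ev$intent, gen$log$messages$intent[mi])
  # marginals agree with the generator's own cell bookkeeping
  got <- as.data.frame(table(intent = factor(ev$intent, intent_levels()),
                             program = factor(ev$program, program_levels()),
                             is_stop = ev$is_stop),
                       stringsAsFactors = FALSE)
  truth <- gen$truth$stop_cells
  expect_equal(got$Freq[order(got$intent, got$program, got$is_stop)],
               truth$count[order(truth$intent, truth$program, truth$is_stop)])
})

test_that("control-arm replies are excluded unless requested", {
  log <- make_mini_log()
  log$participants$arm[1] <- "CONTROL"
  default <- build_event_table(log)
  expect_equal(nrow(default), 0)
  kept <- build_event_table(log, include_control_arm = TRUE)
  expect_equal(nrow(kept), 1)
})

test_that("the univariate logistic OR equals the 2x2 cross-product ratio", {
  # a=20 exposed cases, b=80 exposed non-cases, c=10, d=90
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  fit <- fit_univariate_logistic(y, x)
  expect_equal(fit$or, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_equal(fit$or, exp(fit$beta))
  expect_true(fit$ci_low <= fit$or && fit$or <= fit$ci_high)

  # equal rates in both groups: a null association
  y0 <- rep(c(1, 0, 1, 0), times = c(10, 40, 10, 40))
  x0 <- rep(c(1, 0), each = 50)
  null_fit <- fit_univariate_logistic(y0, x0)
  expect_equal(null_fit$or, 1, tolerance = 1e-6)
  expect_gt(null_fit$p, 0.9)

  # perfect separation is a diagnostic error, not a silent estimate
  expect_error(
    suppressWarnings(fit_univariate_logistic(c(1, 1, 1, 0, 0, 0),
                                             c(1, 1, 1, 0, 0, 0))),
    "separation")
})

test_that("the interaction coefficient equals the log ratio of stratum ORs", {
  # stratum ORs 2.0 (g=0) and 8.0 (g=1) from exact counts
  cells <- function(a, b, c_, d, g) {
    data.frame(y = rep(c(1, 0, 1, 0), times = c(a, b, c_, d)),
               x = rep(c(1, 1, 0, 0), times = c(a, b, c_, d)), g = g)
  }
  # g=0: (40*100)/(80*25) = 2 ; g=1: (80*120)/(60*20) = 8
  dat <- rbind(cells(40, 80, 25, 100, 0), cells(80, 60, 20, 120, 1))
  res <- fit_interaction_model(dat$y, dat$x, dat$g)
  expect_equal(res$beta_interaction, log(8 / 2), tolerance = 1e-6)
  expect_equal(res$strata$or, c(2, 8), tolerance = 1e-6)

  # identical stratum ORs: interaction vanishes
  dat0 <- rbind(cells(40, 80, 25, 100, 0), cells(40, 80, 25, 100, 1))
  res0 <- fit_interaction_model(dat0$y, dat0$x, dat0$g)
  expect_equal(res0$beta_interaction, 0, tolerance = 1e-6)
  expect_gt(res0$p_interaction, 0.9)

  expect_error(fit_interaction_model(c(1, 0, 1, 0), c(1, 1, 0, 0),
                                     c(0, 0, 0, 0)), "empty")
})

test_that("chi-square independence matches hand computation", {
  flat <- chi_square_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  t22 <- chi_square_independence(rbind(c(20, 10), c(10, 20)))
  expect_equal(t22$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(t22$dof, 1)
  expect_equal(t22$p, stats::pchisq(20 / 3, 1, lower.tail = FALSE))

  five_by_two <- chi_square_independence(matrix(5, 5, 2))
  expect_equal(five_by_two$dof, 4)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 1))), "expected")
})

test_that("the association table covers outcome x intent x stratum", {
  gen <- make_fixture("easy")
  assoc <- intent_associations(build_event_table(gen$log))
  expect_equal(nrow(assoc), 2 * 5 * 3)
  expect_setequal(unique(assoc$stratum), c("ALL", "ONE_WAY", "TWO_WAY"))
  ok <- !is.na(assoc$or)
  expect_true(all(assoc$or[ok] == exp(assoc$beta[ok])))
  expect_true(all(assoc$ci_low[ok] <= assoc$or[ok] &
                    assoc$or[ok] <= assoc$ci_high[ok]))
})
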