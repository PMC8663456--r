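#' Derive premature-stop and engagement outcomes per participant
#'
#' A participant *stopped* if any of their replies is of category `STOP` or
#' if they withdrew from the study. A participant is *engaged* if they
#' replied at least `min_replies` times (default 3) and did not stop.
#' Participants with no replies are included (engaged = `FALSE`).
#'
#' @param log A [communication_log()].
#' @param reply_categories Optional named vector mapping `reply_id` to a
#'   reply category (gold or predicted); defaults to the log's own
#'   `category` column. Every reply must be covered.
#' @param min_replies Reply-count threshold for engagement.
#' @return A tibble with `participant_id`, `program`, `arm`, `n_replies`,
#'   `stopped`, `engaged`.
#' @export
derive_outcomes <- function(log, reply_categories = NULL, min_replies = 3) {
  stopifnot(inherits(log, "communication_log"))
  reps <- log$replies
  if (is.null(reply_categories)) {
    reply_categories <- stats::setNames(reps$category, reps$reply_id)
  }
  cat_of <- reply_categories[reps$reply_id]
  if (anyNA(cat_of)) {
    missing_ids <- reps$reply_id[is.na(cat_of)]
    stop("replies without a category: ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) sprintf(" (and %d more)",
                                               length(missing_ids) - 10),
         call. = FALSE)
  }
  assert_enum(cat_of, reply_levels(), "reply category")

  parts <- log$participants
  n_replies <- as.integer(table(factor(reps$participant_id,
                                       levels = parts$participant_id)))
  sent_stop <- parts$participant_id %in%
    unique(reps$participant_id[cat_of == "STOP"])
  stopped <- sent_stop | parts$withdrew
  tibble::tibble(
    participant_id = parts$participant_id,
    program = parts$program,
    arm = parts$arm,
    n_replies = n_replies,
    stopped = stopped,
    engaged = n_replies >= min_replies & !stopped
  )
}

#' Build the reply-level event table
#'
#' One row per analyzable reply, carrying the intent of the eliciting
#' outgoing message (the exposure), whether the reply itself is a `STOP`,
#' and whether its sender met the engagement definition. Control-arm
#' replies are excluded by default because intervention messages define
#' the exposure.
#'
#' @param log A [communication_log()].
#' @param intents Optional named vector `message_id -> intent` (gold or
#'   predicted); defaults to the log's `intent` column. Must cover every
#'   eliciting message.
#' @param outcomes Output of [derive_outcomes()]; computed from the log's
#'   own categories when omitted.
#' @param reply_categories As in [derive_outcomes()].
#' @param include_control_arm Keep replies from control-arm participants.
#' @return A tibble with `reply_id`, `participant_id`, `program`, `intent`,
#'   `is_stop`, `from_engaged`.
#' @export
build_event_table <- function(log, intents = NULL, outcomes = NULL,
                              reply_categories = NULL,
                              include_control_arm = FALSE) {
  stopifnot(inherits(log, "communication_log"))
  reps <- log$replies
  if (is.null(intents)) {
    intents <- stats::setNames(log$messages$intent, log$messages$message_id)
  }
  if (is.null(reply_categories)) {
    reply_categories <- stats::setNames(reps$category, reps$reply_id)
  }
  if (is.null(outcomes)) {
    outcomes <- derive_outcomes(log, reply_categories = reply_categories)
  }
  intent_of <- intents[reps$in_reply_to]
  if (anyNA(intent_of)) {
    stop("unresolved intent for eliciting message(s): ",
         paste(utils::head(unique(reps$in_reply_to[is.na(intent_of)]), 10),
               collapse = ", "), call. = FALSE)
  }
  assert_enum(intent_of, intent_levels(), "intent")
  cat_of <- reply_categories[reps$reply_id]
  if (anyNA(cat_of)) stop("replies without a category", call. = FALSE)

  oi <- match(reps$participant_id, outcomes$participant_id)
  tab <- tibble::tibble(
    reply_id = reps$reply_id,
    participant_id = reps$participant_id,
    program = reps$program,
    intent = unname(intent_of),
    is_stop = unname(cat_of) == "STOP",
    from_engaged = outcomes$engaged[oi]
  )
  if (!include_control_arm) {
    arm <- log$participants$arm[match(tab$participant_id,
                                      log$participants$participant_id)]
    tab <- tab[arm != "CONTROL", , drop = FALSE]
  }
  tab
}

check_separation <- function(fit, context) {
  sm <- summary(fit)$coefficients
  if (!fit$converged || any(abs(stats::coef(fit)) > 15) ||
      any(sm[, "Std. Error"] > 100)) {
    stop("logistic fit failed (separation or non-convergence) in ", context,
         call. = FALSE)
  }
}

#' Univariate logistic regression of a binary outcome on a binary exposure
#'
#' Maximum-likelihood fit of `logit P(y = 1) = alpha + beta * x` via
#' `stats::glm`, reported as an odds ratio with a Wald 95% confidence
#' interval `exp(beta +/- 1.96 SE)` and a two-sided Wald p-value. For a
#' binary exposure this is saturated, so the fitted OR equals the
#' cross-product ratio `ad/bc` of the 2x2 table.
#'
#' @param y Logical/0-1 outcome vector.
#' @param x Logical/0-1 exposure vector.
#' @return A tibble with `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
fit_univariate_logistic <- function(y, x) {
  y <- as.integer(y); x <- as.integer(x)
  stopifnot(length(y) == length(x), all(y %in% 0:1), all(x %in% 0:1))
  if (length(unique(y)) < 2) stop("outcome has a single level", call. = FALSE)
  if (length(unique(x)) < 2) stop("exposure has a single level", call. = FALSE)
  fit <- stats::glm(y ~ x, family = stats::binomial())
  check_separation(fit, "fit_univariate_logistic")
  beta <- stats::coef(fit)[["x"]]
  se <- summary(fit)$coefficients["x", "Std. Error"]
  z <- beta / se
  tibble::tibble(
    beta = beta, se = se, or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)), n = length(y)
  )
}

#' Logistic model with a program-type interaction
#'
#' Fits `logit P(y=1) = a + b1 x + b2 g + b3 (x*g)` where `x` is the
#' exposure (an intent indicator) and `g` the program-type indicator, and
#' reports the interaction coefficient `b3` with its Wald two-sided
#' p-value, plus per-stratum univariate odds ratios. In the saturated
#' binary-by-binary case `b3` equals the log of the ratio of the two
#' stratum odds ratios.
#'
#' @param y Binary outcome.
#' @param x Binary exposure.
#' @param g Binary stratum indicator (e.g. `program == "TWO_WAY"`).
#' @return A list with `beta_interaction`, `se_interaction`,
#'   `p_interaction`, and `strata` (a two-row tibble of univariate fits
#'   for `g == 0` and `g == 1`).
#' @export
fit_interaction_model <- function(y, x, g) {
  y <- as.integer(y); x <- as.integer(x); g <- as.integer(g)
  stopifnot(length(y) == length(x), length(y) == length(g),
            all(y %in% 0:1), all(x %in% 0:1), all(g %in% 0:1))
  cells <- table(factor(x, levels = 0:1), factor(g, levels = 0:1))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty exposure-by-stratum cell (x=%d, g=%d)",
                 empty[1] - 1, empty[2] - 1), call. = FALSE)
  }
  fit <- stats::glm(y ~ x * g, family = stats::binomial())
  check_separation(fit, "fit_interaction_model")
  sm <- summary(fit)$coefficients
  beta3 <- stats::coef(fit)[["x:g"]]
  se3 <- sm["x:g", "Std. Error"]
  strata <- do.call(rbind, lapply(0:1, function(gv) {
    res <- fit_univariate_logistic(y[g == gv], x[g == gv])
    res$stratum <- gv
    res
  }))
  list(beta_interaction = beta3, se_interaction = se3,
       p_interaction = 2 * stats::pnorm(-abs(beta3 / se3)),
       strata = strata)
}

#' Pearson chi-square test of independence
#'
#' @param counts An r x c matrix of observed counts.
#' @return A list with `statistic`, `dof`, `p`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("zero expected count; test undefined", call. = FALSE)
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), dof = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Intent-outcome association table
#'
#' For each message intent and each outcome (reply type `stop`;
#' engagement), fits the univariate logistic model of the outcome on the
#' intent indicator overall and within each program type, plus the
#' program-type interaction model. Rows mirror the layout
#' outcome x intent x stratum.
#'
#' @param events An event table from [build_event_table()].
#' @return A tibble with columns `outcome`, `intent`, `stratum`, `or`,
#'   `ci_low`, `ci_high`, `beta`, `p`, `n`, `p_interaction` (the
#'   interaction p is repeated on each of the intent's rows).
#' @export
intent_associations <- function(events) {
  outcomes <- c(STOP = "is_stop", ENGAGEMENT = "from_engaged")
  rows <- list()
  for (oc in names(outcomes)) {
    yv <- as.integer(events[[outcomes[[oc]]]])
    for (intent in intent_levels()) {
      xv <- as.integer(events$intent == intent)
      gv <- as.integer(events$program == "TWO_WAY")
      fits <- list(
        ALL = try(fit_univariate_logistic(yv, xv), silent = TRUE),
        ONE_WAY = try(fit_univariate_logistic(yv[gv == 0], xv[gv == 0]),
                      silent = TRUE),
        TWO_WAY = try(fit_univariate_logistic(yv[gv == 1], xv[gv == 1]),
                      silent = TRUE)
      )
      pint <- tryCatch(fit_interaction_model(yv, xv, gv)$p_interaction,
                       error = function(e) NA_real_)
      for (st in names(fits)) {
        f <- fits[[st]]
        if (inherits(f, "try-error")) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            outcome = oc, intent = intent, stratum = st, or = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_, beta = NA_real_,
            p = NA_real_, n = NA_integer_, p_interaction = pint)
        } else {
          rows[[length(rows) + 1]] <- tibble::tibble(
            outcome = oc, intent = intent, stratum = st, or = f$or,
            ci_low = f$ci_low, ci_high = f$ci_high, beta = f$beta,
            p = f$p, n = f$n, p_interaction = pint)
        }
      }
    }
  }
  do.call(rbind, rows)
}
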