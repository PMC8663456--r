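# Shared helpers: tiny hand-built logs, brute-force oracles, canonical
# partition labels.

make_mini_log <- function() {
  messages <- data.frame(
    message_id = c("m1", "m2"),
    program = c("ONE_WAY", "TWO_WAY"),
    sent_day = c(0L, 3L),
    text = c("hello world", "take your tablets"),
    intent = c("NOTIFICATION", "INSTRUCTIONAL")
  )
  replies <- data.frame(
    reply_id = "r1", participant_id = "p1", program = "ONE_WAY",
    reply_day = 2L, text = "thanks", in_reply_to = "m1",
    category = "THANKS"
  )
  participants <- data.frame(
    participant_id = c("p1", "p2"),
    program = c("ONE_WAY", "TWO_WAY"),
    arm = c("INTERVENTION", "INTERVENTION"),
    withdrew = c(FALSE, FALSE),
    withdrawal_day = c(NA_integer_, NA_integer_)
  )
  communication_log(messages, replies, participants)
}

# single-participant log with a prescribed reply-category history
make_outcome_log <- function(reply_cats, withdrew = FALSE) {
  n <- length(reply_cats)
  messages <- data.frame(
    message_id = sprintf("m%d", seq_len(max(n, 1))), program = "ONE_WAY",
    sent_day = seq_len(max(n, 1)), text = "hello", intent = "INFORMATIVE")
  replies <- if (n > 0) data.frame(
    reply_id = sprintf("r%d", seq_len(n)), participant_id = "p1",
    program = "ONE_WAY", reply_day = seq_len(n) + 1, text = "ok",
    in_reply_to = sprintf("m%d", seq_len(n)), category = reply_cats)
  else data.frame(reply_id = character(0), participant_id = character(0),
                  program = character(0), reply_day = integer(0),
                  text = character(0), in_reply_to = character(0),
                  category = character(0))
  participants <- data.frame(
    participant_id = "p1", program = "ONE_WAY", arm = "INTERVENTION",
    withdrew = withdrew,
    withdrawal_day = if (withdrew) 100L else NA_integer_)
  communication_log(messages, replies, participants)
}

# generator configuration for odds-ratio recovery studies: one exposed
# intent with the given true stop OR, everything else at the null
or_recovery_config <- function(seed, true_or = 2) {
  or <- matrix(1, 5, 2, dimnames = list(intent_levels(), program_levels()))
  or["INFORMATIVE", ] <- true_or
  synthetic_config(
    n_participants = c(ONE_WAY = 900, TWO_WAY = 900),
    messages_per_participant = 20, intervention_fraction = 1,
    reply_propensity = c(INFORMATIVE = 0.55, INSTRUCTIONAL = 0.55,
                         MOTIVATIONAL = 0.55, SUPPORTIVE = 0.55,
                         NOTIFICATION = 0.55),
    true_stop_OR = or, withdrawal_rate = 0, with_text = FALSE,
    seed = seed)
}

# independent O(n^2) union-find clustering over token sets
brute_force_clusters <- function(token_sets, threshold) {
  n <- length(token_sets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (jaccard(token_sets[[i]], token_sets[[j]]) > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# relabel a partition by each block's smallest member position
canonical_partition <- function(labels) {
  first <- tapply(seq_along(labels), labels, min)
  rank_of <- rank(first, ties.method = "first")
  unname(rank_of[as.character(labels)])
}

# direct one-vs-rest counting of confusion metrics
brute_force_class_metrics <- function(y_true, y_pred, cl) {
  tp <- sum(y_true == cl & y_pred == cl)
  fn <- sum(y_true == cl & y_pred != cl)
  fp <- sum(y_true != cl & y_pred == cl)
  tn <- sum(y_true != cl & y_pred != cl)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn))
}

# pairwise-concordance AUC (ties count one half)
concordance_auc <- function(y_pos, scores) {
  pos <- scores[y_pos]; neg <- scores[!y_pos]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}
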