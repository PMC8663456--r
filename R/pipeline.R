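#' Pipeline configuration
#'
#' Bundles the stage configurations for a full run: clustering, encoding,
#' cross-validation, and engagement options.
#'
#' @param cluster A [cluster_config()].
#' @param encoder An [encoder_config()].
#' @param cv A [cv_config()].
#' @param min_replies Engagement reply threshold.
#' @param include_control_arm Keep control-arm replies in the association
#'   analysis.
#' @param use_gold_intents Use labeled intents for reply features and the
#'   event table when present (predicted intents otherwise).
#' @param seed Master seed recorded in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cluster = cluster_config(),
                            encoder = encoder_config(),
                            cv = cv_config(),
                            min_replies = 3,
                            include_control_arm = FALSE,
                            use_gold_intents = TRUE,
                            seed = 1L) {
  structure(list(cluster = cluster, encoder = encoder, cv = cv,
                 min_replies = min_replies,
                 include_control_arm = include_control_arm,
                 use_gold_intents = use_gold_intents,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full content-analysis pipeline on a communication log
#'
#' Stages: validate the log; cluster near-duplicate outgoing messages
#' (cluster ids become the anti-leakage groups of the intent model);
#' encode message texts and run group-constrained nested CV for the
#' intent model; build contextualised reply features (text encoding plus
#' one-hot eliciting intent) and run nested CV for the reply model with
#' participants as groups; derive premature-stop and engagement outcomes;
#' estimate intent-outcome associations with program-type interactions
#' and chi-square tests. Deterministic for a fixed log and config.
#'
#' @param log A labeled [communication_log()].
#' @param config A [pipeline_config()].
#' @return A `run_report` list: `config`, `n` (record counts),
#'   `clustering` (assignment tibble plus summary), `intent_eval` and
#'   `reply_eval` ([evaluation_report()]s), `intent_cv`/`reply_cv` fold
#'   summaries, `outcomes`, `associations`, `chi_square`, `warnings`.
#' @export
run_pipeline <- function(log, config = pipeline_config()) {
  stopifnot(inherits(log, "communication_log"))
  set.seed(config$seed)
  warnings <- character(0)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  stage("validate", {
    v <- validate_log(log)
    if (nrow(v) > 0) {
      stop("log fails validation: ", paste(utils::head(v$message, 5),
                                           collapse = "; "))
    }
  })

  clustering <- stage("cluster", cluster_messages(log$messages, config$cluster))
  cluster_sizes <- table(clustering$cluster_id)

  msgs <- log$messages
  labeled <- !is.na(msgs$intent)
  intent_cv <- intent_eval <- NULL
  if (sum(labeled) > 0) {
    X <- stage("encode", encode_text(msgs$text[labeled], config$encoder))
    groups <- clustering$cluster_id[match(msgs$message_id[labeled],
                                          clustering$message_id)]
    intent_cv <- stage("intent_cv",
      nested_cv(X, msgs$intent[labeled], groups, config$cv,
                classes = intent_levels()[intent_levels() %in%
                                            msgs$intent[labeled]]))
    intent_eval <- stage("intent_eval", evaluation_report(intent_cv))
  }

  reps <- log$replies
  rlabeled <- !is.na(reps$category)
  reply_cv <- reply_eval <- NULL
  intents_for_replies <- stats::setNames(msgs$intent, msgs$message_id)
  if (!config$use_gold_intents && !is.null(intent_cv)) {
    pred <- stats::setNames(
      unlist(lapply(intent_cv$folds, `[[`, "y_pred")),
      msgs$message_id[labeled][unlist(lapply(intent_cv$folds, `[[`,
                                             "test_idx"))])
    intents_for_replies[names(pred)] <- pred
  }
  if (sum(rlabeled) > 0) {
    elic <- intents_for_replies[reps$in_reply_to[rlabeled]]
    Xr <- stage("reply_features",
                reply_features(reps$text[rlabeled], unname(elic),
                               config$encoder))
    reply_cv <- stage("reply_cv",
      nested_cv(Xr, reps$category[rlabeled], reps$participant_id[rlabeled],
                config$cv,
                classes = reply_levels()[reply_levels() %in%
                                           reps$category[rlabeled]]))
    reply_eval <- stage("reply_eval", evaluation_report(reply_cv))
  }

  outcomes <- stage("outcomes",
                    derive_outcomes(log, min_replies = config$min_replies))
  events <- stage("event_table",
                  build_event_table(
                    log, intents = intents_for_replies, outcomes = outcomes,
                    include_control_arm = config$include_control_arm))
  associations <- stage("associations", intent_associations(events))

  chi <- stage("chi_square", {
    lapply(c(STOP = "is_stop", ENGAGEMENT = "from_engaged"), function(col) {
      tab <- table(events$intent, events[[col]])
      if (ncol(tab) < 2 || any(rowSums(tab) == 0)) NULL else
        chi_square_independence(tab)
    })
  })

  structure(list(
    config = config,
    n = c(messages = nrow(msgs), replies = nrow(reps),
          participants = nrow(log$participants)),
    clustering = list(
      assignment = clustering,
      n_clusters = length(cluster_sizes),
      size_distribution = as.integer(table(factor(
        pmin(as.integer(cluster_sizes), 10), levels = 1:10)))),
    intent_cv = cv_summary(intent_cv),
    intent_eval = intent_eval,
    reply_cv = cv_summary(reply_cv),
    reply_eval = reply_eval,
    leakage_violations =
      (if (is.null(intent_cv)) 0L else leakage_violations(intent_cv)) +
      (if (is.null(reply_cv)) 0L else leakage_violations(reply_cv)),
    outcomes = outcomes,
    associations = associations,
    chi_square = chi,
    warnings = warnings
  ), class = "run_report")
}

cv_summary <- function(cv) {
  if (is.null(cv)) return(NULL)
  tibble::tibble(
    fold = vapply(cv$folds, `[[`, integer(1), "fold"),
    best_C = vapply(cv$folds, `[[`, numeric(1), "best_C"),
    n_test = vapply(cv$folds, function(f) length(f$test_idx), integer(1)),
    converged = vapply(cv$folds, `[[`, logical(1), "converged")
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d messages / %d replies / %d participants, %d clusters\n",
              x$n["messages"], x$n["replies"], x$n["participants"],
              x$clustering$n_clusters))
  if (!is.null(x$intent_eval)) {
    cat(sprintf("  intent model balanced accuracy: %.3f\n",
                x$intent_eval$balanced_accuracy$mean))
  }
  if (!is.null(x$reply_eval)) {
    cat(sprintf("  reply model balanced accuracy: %.3f\n",
                x$reply_eval$balanced_accuracy$mean))
  }
  invisible(x)
}

#' Render a run report
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param format `"json"` or `"markdown"`.
#' @return A single string (JSON document or markdown).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "run_report"))
  required <- c("config", "n", "clustering", "outcomes", "associations")
  missing <- required[vapply(report[required], is.null, logical(1))]
  if (length(missing) > 0) {
    stop("incomplete report; missing sections: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (format == "json") {
    payload <- list(
      seed = report$config$seed,
      n = as.list(report$n),
      clustering = list(n_clusters = report$clustering$n_clusters,
                        size_distribution = report$clustering$size_distribution),
      intent = eval_payload(report$intent_eval),
      reply = eval_payload(report$reply_eval),
      outcomes = list(
        n_engaged = sum(report$outcomes$engaged),
        n_stopped = sum(report$outcomes$stopped),
        n_participants = nrow(report$outcomes)),
      associations = report$associations
    )
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         na = "null", digits = 10)))
  }
  md <- c(sprintf("# Pipeline run (seed %d)", report$config$seed),
          "",
          sprintf("%d messages, %d replies, %d participants; %d message clusters.",
                  report$n["messages"], report$n["replies"],
                  report$n["participants"], report$clustering$n_clusters),
          "")
  for (model in c("intent", "reply")) {
    ev <- report[[paste0(model, "_eval")]]
    if (is.null(ev)) next
    md <- c(md, sprintf("## %s model", model), "",
            sprintf("Balanced accuracy %.3f (95%% CI %.3f-%.3f); macro AUC %.3f.",
                    ev$balanced_accuracy$mean, ev$balanced_accuracy$ci_low,
                    ev$balanced_accuracy$ci_high, ev$auc_macro),
            "", metrics_markdown(ev), "")
  }
  md <- c(md, "## Associations", "", associations_markdown(report$associations))
  paste(md, collapse = "\n")
}

eval_payload <- function(ev) {
  if (is.null(ev)) return(NULL)
  list(per_class = ev$per_class, macro = ev$macro,
       balanced_accuracy = ev$balanced_accuracy,
       auc = as.list(ev$auc), auc_macro = ev$auc_macro)
}

metrics_markdown <- function(ev) {
  cols <- c("sensitivity", "specificity", "ppv", "npv", "fpr", "fnr", "f1")
  hdr <- paste0("| class | ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols) + 1), collapse = "|"), "|")
  fmt <- function(m, s) {
    ifelse(is.na(m), "--", sprintf("%.3f (%.3f)", m, ifelse(is.na(s), 0, s)))
  }
  body <- vapply(seq_len(nrow(ev$per_class)), function(i) {
    vals <- vapply(cols, function(cn) {
      fmt(ev$per_class[[paste0(cn, "_mean")]][i],
          ev$per_class[[paste0(cn, "_sd")]][i])
    }, character(1))
    paste0("| ", ev$per_class$class[i], " | ",
           paste(vals, collapse = " | "), " |")
  }, character(1))
  macro <- paste0("| MACRO | ",
                  paste(sprintf("%.3f", ev$macro$mean), collapse = " | "),
                  " |")
  paste(c(hdr, sep, body, macro), collapse = "\n")
}

associations_markdown <- function(assoc) {
  hdr <- "| outcome | intent | stratum | OR (95% CI) | beta | p | p interaction |"
  sep <- "|---|---|---|---|---|---|---|"
  body <- vapply(seq_len(nrow(assoc)), function(i) {
    r <- assoc[i, ]
    or_txt <- if (is.na(r$or)) "--" else
      sprintf("%.2f (%.2f-%.2f)", r$or, r$ci_low, r$ci_high)
    sprintf("| %s | %s | %s | %s | %s | %s | %s |",
            r$outcome, r$intent, r$stratum, or_txt,
            ifelse(is.na(r$beta), "--", sprintf("%.2f", r$beta)),
            ifelse(is.na(r$p), "--", format.pval(r$p, digits = 2)),
            ifelse(is.na(r$p_interaction), "--",
                   format.pval(r$p_interaction, digits = 2)))
  }, character(1))
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Write the standard pipeline artifacts to a directory
#'
#' Writes `clusters.csv`, `folds.csv` (per model), `metrics.csv` (per
#' model), `roc_points.csv`, `outcomes.csv`, `associations.csv` and
#' `report.json`. Every file carries a header comment with the seed.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_artifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stamp <- sprintf("# seed=%d", report$config$seed)
  put <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    close(con)
    written <<- c(written, path)
  }
  put(report$clustering$assignment, "clusters.csv")
  if (!is.null(report$intent_eval)) {
    put(report$intent_eval$per_class, "intent_metrics.csv")
    put(report$intent_eval$roc, "intent_roc_points.csv")
  }
  if (!is.null(report$reply_eval)) {
    put(report$reply_eval$per_class, "reply_metrics.csv")
    put(report$reply_eval$roc, "reply_roc_points.csv")
  }
  put(report$outcomes, "outcomes.csv")
  put(report$associations, "associations.csv")
  json_path <- file.path(dir, "report.json")
  writeLines(render_report(report, "json"), json_path, useBytes = TRUE)
  invisible(c(written, json_path))
}
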