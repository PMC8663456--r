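#' Construct a communication log
#'
#' A communication log is the universal input of the pipeline: the outgoing
#' program messages, the participant replies (each linked to the message it
#' answers), and the participant roster with withdrawal status.
#'
#' @param messages Data frame with columns `message_id`, `program`,
#'   `sent_day`, `text`, `intent` (`NA` when unlabeled) and optionally
#'   `cluster_id`.
#' @param replies Data frame with columns `reply_id`, `participant_id`,
#'   `program`, `reply_day`, `text`, `in_reply_to`, `category` (`NA` when
#'   unlabeled).
#' @param participants Data frame with columns `participant_id`, `program`,
#'   `arm`, `withdrew` (logical), `withdrawal_day` (`NA` unless withdrew).
#' @param validate Check invariants and fail on the first violation set.
#' @return An object of class `communication_log`: a list of three tibbles.
#' @seealso [validate_log()], [read_log()], [generate_log()]
#' @export
communication_log <- function(messages, replies, participants, validate = TRUE) {
  log <- structure(
    list(
      messages = as_log_tibble(messages, message_cols()),
      replies = as_log_tibble(replies, reply_cols()),
      participants = as_log_tibble(participants, participant_cols())
    ),
    class = "communication_log"
  )
  if (validate) {
    v <- validate_log(log)
    if (nrow(v) > 0) {
      stop("invalid communication log:\n",
           paste(utils::head(v$message, 10), collapse = "\n"), call. = FALSE)
    }
  }
  log
}

message_cols <- function() {
  list(message_id = "character", program = "character", sent_day = "integer",
       text = "character", intent = "character", cluster_id = "integer")
}
reply_cols <- function() {
  list(reply_id = "character", participant_id = "character",
       program = "character", reply_day = "integer", text = "character",
       in_reply_to = "character", category = "character")
}
participant_cols <- function() {
  list(participant_id = "character", program = "character", arm = "character",
       withdrew = "logical", withdrawal_day = "integer")
}

as_log_tibble <- function(df, spec) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in names(spec)) {
    if (!col %in% names(df)) {
      # cluster_id / withdrawal_day are optional on input
      if (col %in% c("cluster_id", "withdrawal_day", "intent", "category")) {
        df[[col]] <- NA
      } else {
        stop(sprintf("schema error: missing column '%s'", col), call. = FALSE)
      }
    }
    # blank strings mean missing everywhere except in message text,
    # where the empty string is legitimate content
    if (is.character(df[[col]]) && col != "text") {
      df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA
    }
    df[[col]] <- switch(spec[[col]],
      character = as.character(df[[col]]),
      integer = as.integer(df[[col]]),
      logical = as.logical(df[[col]])
    )
  }
  tibble::as_tibble(df[names(spec)])
}

#' @export
print.communication_log <- function(x, ...) {
  cat(sprintf(
    "<communication_log> %d messages, %d replies, %d participants\n",
    nrow(x$messages), nrow(x$replies), nrow(x$participants)))
  invisible(x)
}

#' Validate a communication log
#'
#' Checks identifier uniqueness, enum values, referential integrity of
#' `in_reply_to` and `participant_id`, program consistency across linked
#' records, reply timing, and the withdrawal-day contract. Violations are
#' returned, never raised.
#'
#' @param log A `communication_log`.
#' @return A tibble with columns `record_id`, `rule`, `message`; zero rows
#'   when every invariant holds.
#' @export
validate_log <- function(log) {
  stopifnot(inherits(log, "communication_log"))
  msgs <- log$messages; reps <- log$replies; parts <- log$participants
  out <- list()
  add <- function(ids, rule, fmt) {
    if (length(ids) > 0) {
      out[[length(out) + 1]] <<- tibble::tibble(
        record_id = as.character(ids), rule = rule,
        message = sprintf(fmt, ids))
    }
  }

  add(msgs$message_id[duplicated(msgs$message_id)], "unique_message_id",
      "duplicate message_id '%s'")
  add(reps$reply_id[duplicated(reps$reply_id)], "unique_reply_id",
      "duplicate reply_id '%s'")
  add(parts$participant_id[duplicated(parts$participant_id)],
      "unique_participant_id", "duplicate participant_id '%s'")

  bad_enum <- function(x, lev) !is.na(x) & !(x %in% lev)
  add(msgs$message_id[bad_enum(msgs$program, program_levels())],
      "program_enum", "message '%s' has invalid program")
  add(msgs$message_id[bad_enum(msgs$intent, intent_levels())],
      "intent_enum", "message '%s' has invalid intent")
  add(reps$reply_id[bad_enum(reps$category, reply_levels())],
      "category_enum", "reply '%s' has invalid category")
  add(parts$participant_id[bad_enum(parts$arm, arm_levels())],
      "arm_enum", "participant '%s' has invalid arm")

  add(msgs$message_id[is.na(msgs$text)], "text_non_null",
      "message '%s' has null text")
  add(msgs$message_id[!is.na(msgs$sent_day) & msgs$sent_day < 0],
      "sent_day_nonnegative", "message '%s' has negative sent_day")

  dangling_msg <- !(reps$in_reply_to %in% msgs$message_id)
  add(reps$reply_id[dangling_msg], "in_reply_to_resolves",
      "reply '%s' references an absent message_id")
  dangling_part <- !(reps$participant_id %in% parts$participant_id)
  add(reps$reply_id[dangling_part], "participant_resolves",
      "reply '%s' references an absent participant_id")

  mi <- match(reps$in_reply_to, msgs$message_id)
  ok <- !is.na(mi)
  add(reps$reply_id[ok & reps$reply_day < msgs$sent_day[mi]],
      "reply_after_sent", "reply '%s' predates its eliciting message")
  add(reps$reply_id[ok & reps$program != msgs$program[mi]],
      "program_consistent_message", "reply '%s' program differs from its message")
  pi <- match(reps$participant_id, parts$participant_id)
  ok <- !is.na(pi)
  add(reps$reply_id[ok & reps$program != parts$program[pi]],
      "program_consistent_participant",
      "reply '%s' program differs from its participant")

  add(parts$participant_id[parts$withdrew & is.na(parts$withdrawal_day)],
      "withdrawal_day_present", "participant '%s' withdrew without a day")
  add(parts$participant_id[!parts$withdrew & !is.na(parts$withdrawal_day)],
      "withdrawal_day_absent", "participant '%s' has a day but did not withdraw")

  if (length(out) == 0) {
    tibble::tibble(record_id = character(), rule = character(),
                   message = character())
  } else {
    do.call(rbind, out)
  }
}

#' Read a communication log from disk
#'
#' Reads the three-file on-disk representation (messages, replies,
#' participants) in either CSV or JSONL dialect. Blank label fields are
#' read as unlabeled (`NA`).
#'
#' @param messages,replies,participants File paths.
#' @param dialect `"csv"` or `"jsonl"`.
#' @param validate Run [validate_log()] and raise an integrity error on
#'   violations.
#' @return A `communication_log`.
#' @export
read_log <- function(messages, replies, participants,
                     dialect = c("csv", "jsonl"), validate = TRUE) {
  dialect <- match.arg(dialect)
  for (p in c(messages, replies, participants)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  reader <- if (dialect == "csv") read_table_csv else read_table_jsonl
  m <- reader(messages, message_cols())
  r <- reader(replies, reply_cols())
  p <- reader(participants, participant_cols())
  log <- communication_log(m, r, p, validate = FALSE)
  if (validate) {
    v <- validate_log(log)
    dang <- v[v$rule == "in_reply_to_resolves", , drop = FALSE]
    if (nrow(dang) > 0) {
      bad <- log$replies$in_reply_to[match(dang$record_id, log$replies$reply_id)]
      stop(sprintf(
        "integrity error: replies [%s] reference absent message_id(s) [%s]",
        paste(dang$record_id, collapse = ", "),
        paste(unique(bad), collapse = ", ")), call. = FALSE)
    }
    if (nrow(v) > 0) {
      stop("integrity error:\n", paste(v$message, collapse = "\n"),
           call. = FALSE)
    }
  }
  log
}

read_table_csv <- function(path, spec) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0), fileEncoding = "UTF-8")
  required <- setdiff(names(spec), c("cluster_id", "withdrawal_day"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error in '%s': missing column '%s'", path,
                 missing[1]), call. = FALSE)
  }
  df
}

read_table_jsonl <- function(path, spec) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    df <- as.data.frame(lapply(spec, function(t) character(0)))
    names(df) <- names(spec)
    return(df)
  }
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  cols <- unique(unlist(lapply(recs, names)))
  required <- setdiff(names(spec), c("cluster_id", "withdrawal_day"))
  missing <- setdiff(required, cols)
  if (length(missing) > 0) {
    stop(sprintf("schema error in '%s': missing column '%s'", path,
                 missing[1]), call. = FALSE)
  }
  df <- lapply(cols, function(cn) {
    sapply(recs, function(r) {
      v <- r[[cn]]
      if (is.null(v) || length(v) == 0 || is.na(v)) NA else v
    })
  })
  names(df) <- cols
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Write a communication log to disk
#'
#' Inverse of [read_log()]: `read_log()` after `write_log()` recovers a
#' logically identical log. Unlabeled fields are written blank (CSV) or
#' `null` (JSONL); files are UTF-8.
#'
#' @inheritParams read_log
#' @param log A valid `communication_log`.
#' @return Invisibly, the three paths written.
#' @export
write_log <- function(log, messages, replies, participants,
                      dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(log, "communication_log"))
  writer <- if (dialect == "csv") write_table_csv else write_table_jsonl
  writer(log$messages, messages)
  writer(log$replies, replies)
  writer(log$participants, participants)
  invisible(c(messages, replies, participants))
}

write_table_csv <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

write_table_jsonl <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
    }
  }
}
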