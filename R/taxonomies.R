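#' Label taxonomies for SMS program content analysis
#'
#' Outgoing program messages carry one of five functional intents and
#' participant replies one of seven reply categories. The orders returned
#' here are canonical: one-hot encodings, confusion matrices and report
#' tables all use them.
#'
#' @return A character vector of labels in canonical order.
#' @name taxonomies
NULL

#' @rdname taxonomies
#' @export
intent_levels <- function() {
  c("INFORMATIVE", "INSTRUCTIONAL", "MOTIVATIONAL", "SUPPORTIVE", "NOTIFICATION")
}

#' @rdname taxonomies
#' @export
reply_levels <- function() {
  c("STOP", "THANKS", "QUESTION", "REPORTING_HEALTHY", "REPORTING_STRUGGLE",
    "GENERAL_COMMENT", "OTHER")
}

#' @rdname taxonomies
#' @export
program_levels <- function() {
  c("ONE_WAY", "TWO_WAY")
}

#' @rdname taxonomies
#' @export
arm_levels <- function() {
  c("INTERVENTION", "CONTROL")
}

#' One-hot encode a message intent
#'
#' @param intent Character vector of intent labels.
#' @return A numeric matrix with one row per input and five columns in
#'   canonical intent order; each row has exactly one 1.
#' @export
#' @examples
#' one_hot_intent("SUPPORTIVE")
one_hot_intent <- function(intent) {
  lev <- intent_levels()
  idx <- match(intent, lev)
  if (anyNA(idx)) {
    stop("unknown intent label(s): ",
         paste(unique(intent[is.na(idx)]), collapse = ", "))
  }
  m <- matrix(0, nrow = length(intent), ncol = length(lev),
              dimnames = list(NULL, lev))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

assert_enum <- function(x, levels, what, id = NULL) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
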