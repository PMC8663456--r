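# Paice/Husk "Lancaster" stemmer.
#
# Rules are the published default table. Each rule string is
# <reversed ending><'*'?><remove count><append><'.' stop | '>' continue>:
# the ending is matched against the reversed tail of the word, '*' restricts
# the rule to intact (not yet stemmed) words, <remove count> characters are
# stripped, <append> is appended, and '.' terminates while '>' re-enters the
# rule loop on the new tail.
lancaster_rules_raw <- c(
  "ai*2.", "a*1.",
  "bb1.",
  "city3s.", "ci2>", "cn1t>",
  "dd1.", "dei3y>", "deec2ss.", "dee1.", "de2>", "dooh4>",
  "e1>",
  "feil1v.", "fi2>",
  "gni3>", "gai3y.", "ga2>", "gg1.",
  "ht*2.", "hsiug5ct.", "hsi3>",
  "i*1.", "i1y>",
  "ji1d.", "juf1s.", "ju1d.", "jo1d.", "jeh1r.", "jrev1t.", "jsim2t.",
  "jn1d.", "j1s.",
  "lbaifi6.", "lbai4y.", "lba3>", "lbi3.", "lib2l>", "lc1.", "lufi4y.",
  "luf3>", "lu2.", "lai3>", "lau3>", "la2>", "ll1.",
  "mui3.", "mu*2.", "msi3>", "mm1.",
  "nois4j>", "noix4ct.", "noi3>", "nai3>", "na2>", "nee0.", "ne2>", "nn1.",
  "pihs4>", "pp1.",
  "re2>", "rae0.", "ra2.", "ro2>", "ru2>", "rr1.", "rt1>", "rei3y>",
  "sei3y>", "sis2.", "si2>", "ssen4>", "ss0.", "suo3>", "su*2.", "s*1>",
  "s0.",
  "tacilp4c.", "ta2>", "tnem4>", "tne3>", "tna3>", "tpir2b.", "tpro2b.",
  "tcud1.", "tpmus2.", "tpec2iv.", "tulo2v.", "tsis0.", "tsi3>", "tt1.",
  "uqi3.", "ugo1.",
  "vis3j>", "vie0.", "vi2>",
  "ylb1>", "yli3y>", "ylp0.", "yl2>", "ygo1.", "yhp1.", "ymo1.", "ypo1.",
  "yti3>", "yte3>", "ytl2.", "yrtsi5.", "yra3>", "yro3>", "yfi3.", "yln2>",
  "yc1>",
  "zi2>", "zy1s."
)

parse_lancaster_rules <- function(raw = lancaster_rules_raw) {
  m <- regmatches(raw, regexec("^([a-z]+)(\\*?)([0-9])([a-z]*)([.>])$", raw))
  bad <- vapply(m, length, integer(1)) != 6
  if (any(bad)) stop("malformed stemmer rule: ", raw[bad][1])
  rules <- lapply(m, function(g) {
    rev_end <- g[2]
    list(
      ending = paste(rev(strsplit(rev_end, "")[[1]]), collapse = ""),
      intact = g[3] == "*",
      remove = as.integer(g[4]),
      append = g[5],
      cont = g[6] == ">"
    )
  })
  # index by the word's final letter == first char of the reversed ending
  split(rules, vapply(m, function(g) substr(g[2], 1, 1), character(1)))
}

lancaster_rule_index <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) idx <<- parse_lancaster_rules()
    idx
  }
})

is_acceptable_stem <- function(stem) {
  n <- nchar(stem)
  if (n == 0) return(FALSE)
  first <- substr(stem, 1, 1)
  if (first %in% c("a", "e", "i", "o", "u")) {
    n >= 2
  } else {
    n >= 3 && grepl("[aeiouy]", stem)
  }
}

stem_word <- function(word) {
  idx <- lancaster_rule_index()
  intact <- TRUE
  repeat {
    n <- nchar(word)
    if (n == 0) return(word)
    rules <- idx[[substr(word, n, n)]]
    if (is.null(rules)) return(word)
    applied <- FALSE
    for (r in rules) {
      ne <- nchar(r$ending)
      if (ne > n) next
      if (substr(word, n - ne + 1, n) != r$ending) next
      if (r$intact && !intact) next
      candidate <- paste0(substr(word, 1, n - r$remove), r$append)
      if (!is_acceptable_stem(candidate)) next
      word <- candidate
      intact <- FALSE
      applied <- TRUE
      if (!r$cont) return(word)
      break
    }
    if (!applied) return(word)
  }
}

#' Stem a token with the Lancaster (Paice/Husk) algorithm
#'
#' Aggressive iterative suffix stripping using the published default rule
#' table. Only lowercase alphabetic tokens are stemmed; punctuation,
#' digits, and bracketed placeholder tokens such as `[person_name]` pass
#' through unchanged. Deterministic; note that re-feeding a stem as a
#' fresh word can occasionally strip further, because intact-only rules
#' (marked `*` in the table) apply again to unmodified input.
#'
#' @param tokens Character vector of tokens (lowercase).
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' stem_lancaster(c("walking", "maximum", "?", "[person_name]"))
stem_lancaster <- function(tokens) {
  out <- tokens
  stemmable <- grepl("^[a-z]+$", tokens)
  if (any(stemmable)) {
    uniq <- unique(tokens[stemmable])
    stems <- vapply(uniq, stem_word, character(1), USE.NAMES = FALSE)
    out[stemmable] <- stems[match(tokens[stemmable], uniq)]
  }
  out
}
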