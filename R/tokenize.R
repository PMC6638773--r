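# Tokenisation: lower-cased, lightly lemmatised word tokens with emojis,
# emoticons and the <URL> placeholder preserved as standalone tokens.

# unicode pictograph ranges (emoji blocks, misc symbols, dingbats, flags,
# variation selector)
emoji_pattern <- paste0(
  "[\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{26FF}\\x{2700}-\\x{27BF}",
  "\\x{2B00}-\\x{2BFF}\\x{2190}-\\x{21FF}\\x{1F1E6}-\\x{1F1FF}\\x{FE0F}]"
)

# Western emoticons plus a small kaomoji set; longest first so that e.g.
# ":'-(" wins over ":-(" and ":("
emoticon_inventory <- c(
  ":'-(", ":'-)", "(T_T)", ":'(", ":')", ":-)", ":-(", ":-D", ":-P", ":-/",
  ":-|", ";-)", "D-:", "T_T", ";_;", "-_-", "._.", "=D", ":)", ":(", ":D",
  ":P", ":/", ":|", ";)", "xD", "XD", "D:", ":o", ":O"
)

emoticon_pattern <- local({
  esc <- gsub("([^A-Za-z0-9])", "\\\\\\1",
              emoticon_inventory[order(-nchar(emoticon_inventory))])
  paste0("(?:", paste(esc, collapse = "|"), ")")
})

.SENT_URL <- "\x02URL\x02"

#' Tokenise a post
#'
#' Splits cleaned text into lower-cased word tokens, applying a light
#' rule-based lemmatiser (plural/verb suffix stripping plus an
#' irregular-form table). Emojis and emoticons are emitted as standalone
#' tokens and are never lemmatised; a literal `<URL>` placeholder (as
#' produced by [replace_urls()]) survives as a single token; remaining
#' punctuation is dropped.
#'
#' @param text a single character string (cleaned, i.e. URLs tokenised).
#' @return character vector of tokens, in order of appearance.
#' @examples
#' tokenize("My asthma attacks are worse :'( \U0001F637")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  # any raw URL still present is tokenised first, so its punctuation can
  # never masquerade as an emoticon
  s <- replace_urls(enc2utf8(text))
  s <- gsub("<URL>", paste0(" ", .SENT_URL, " "), s, fixed = TRUE)

  # pull emoticons and emojis out before any case-folding or
  # punctuation stripping; each becomes a numbered sentinel
  kept <- character(0)
  for (pat in c(emoticon_pattern, paste0("(*UTF)", emoji_pattern))) {
    m <- gregexpr(pat, s, perl = TRUE)
    found <- regmatches(s, m)[[1]]
    if (length(found) > 0) {
      regmatches(s, m) <- list(
        paste0(" \x01", length(kept) + seq_along(found), "\x01 "))
      kept <- c(kept, found)
    }
  }
  s <- tolower(s)
  s <- gsub("\u2019", "'", s, fixed = TRUE)
  # keep word chars, digits, apostrophes and the sentinels
  s <- gsub("[^a-z0-9'\x01\x02[:space:]]|_", " ", s, perl = TRUE)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(character(0))
  toks <- gsub("^'+|'+$", "", toks)
  toks <- toks[nzchar(toks)]

  # restore sentinels
  is_em <- grepl("^\x01[0-9]+\x01$", toks)
  if (any(is_em)) {
    idx <- as.integer(gsub("\x01", "", toks[is_em]))
    toks[is_em] <- kept[idx]
  }
  toks[toks == tolower(.SENT_URL)] <- "<URL>"

  word <- grepl("^[a-z][a-z']*$", toks)
  toks[word] <- lemmatise(toks[word])
  toks
}

irregular_lemmas <- c(
  am = "be", is = "be", are = "be", was = "be", were = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", goes = "go", went = "go", gone = "go",
  worse = "bad", worst = "bad", better = "good", best = "good",
  felt = "feel", children = "child", feet = "foot", men = "man",
  women = "woman", got = "get", gotten = "get", made = "make",
  said = "say", took = "take", taken = "take"
)

#' Light rule-based lemmatiser
#'
#' Collapses common English inflections: an irregular-form lookup followed
#' by suffix rules for plural `-s`/`-es`/`-ies`, progressive `-ing` and
#' past `-ed` (with doubled-consonant collapsing and a heuristic final-`e`
#' restore). The goal is not linguistic perfection but stable,
#' inflection-collapsing normalisation: lexicon entries are passed through
#' the same function, so both sides of every dictionary match live in the
#' same lemma space.
#'
#' @param tokens character vector of lower-case word tokens.
#' @return character vector of the same length.
#' @examples
#' lemmatise(c("attacks", "wheezing", "worried", "has"))
#' @export
lemmatise <- function(tokens) {
  if (length(tokens) == 0) return(tokens)
  out <- tokens
  hit <- !is.na(match(out, names(irregular_lemmas)))
  out[hit] <- irregular_lemmas[out[hit]]

  stem1 <- function(w) {
    n <- nchar(w)
    if (n >= 5 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n >= 5 && endsWith(w, "sses")) return(substr(w, 1, n - 2))
    if (n >= 5 && grepl("(x|ch|sh|zz)es$", w)) return(substr(w, 1, n - 2))
    if (n >= 4 && endsWith(w, "s") && !grepl("(ss|us|is|'s)$", w))
      return(substr(w, 1, n - 1))
    if (n >= 6 && endsWith(w, "ing")) return(fix_stem(substr(w, 1, n - 3)))
    if (n >= 5 && endsWith(w, "ed") && !endsWith(w, "eed")) {
      st <- fix_stem(substr(w, 1, n - 2))
      if (endsWith(st, "i")) st <- paste0(substr(st, 1, nchar(st) - 1), "y")
      return(st)
    }
    w
  }
  fix_stem <- function(st) {
    n <- nchar(st)
    if (n >= 3) {
      last2 <- substr(st, n - 1, n)
      # collapse doubled final consonant (running -> run), keep ll/ss
      if (substr(last2, 1, 1) == substr(last2, 2, 2) &&
          grepl("[bdfgkmnprt]", substr(last2, 2, 2)))
        return(substr(st, 1, n - 1))
    }
    # heuristic e-restore: wheez -> wheeze, hav -> have, liv -> live
    if (grepl("[zv]$", st)) return(paste0(st, "e"))
    st
  }
  reg <- !hit
  out[reg] <- vapply(out[reg], stem1, character(1), USE.NAMES = FALSE)
  out
}

is_emoji_token <- function(tokens) {
  grepl(paste0("(*UTF)", emoji_pattern), tokens, perl = TRUE)
}

is_emoticon_token <- function(tokens) {
  tokens %in% emoticon_inventory
}

# word tokens eligible for n-gram vocabulary construction
word_tokens <- function(tokens) {
  tokens[!is_emoji_token(tokens) & !is_emoticon_token(tokens)]
}
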