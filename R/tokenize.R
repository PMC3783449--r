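## Emoticon-aware tokenizer in the style of Potts' "happyfuntokenizer":
## a prioritized regex battery where emoticons outrank punctuation splitting.

# Western emoticons, both orientations: optional hat/brow, eyes, optional
# nose, one or more mouths; e.g. :-) :( ;D =P >:[ and reversed (: D:
.western  <- "[<>]?[:;=8][-o^*']?[()\\[\\]dDpP/\\\\:{}@|]+"
.westrev  <- "[()\\[\\]dDpP/\\\\{}@|]+[-o^*']?[:;=8][<>]?"
# Eastern / kaomoji-style: ^_^ ^__^ T_T o_O -_- x_x @_@ >_< and variants
.eastern  <- "[>]?[\\^oOtTxX@;-][_.]+[\\^oOtTxX@;-][<;]?"
.eastern2 <- ">[_.]+<"
# Hearts
.heart    <- "<+/?3+"

.emoticonPatterns <- c(.heart, .western, .westrev, .eastern, .eastern2)

# Non-emoticon token classes, in priority order: URLs, @-mentions and
# hashtags kept whole (open-vocabulary: nothing is deleted a priori),
# words with internal apostrophes/hyphens, numbers, any other single glyph.
.wordPatterns <- c(
    "(?:https?://|www\\.)[^\\s]+",
    "@[A-Za-z0-9_]+",
    "#[A-Za-z0-9_]+",
    # words may embed digits (net speak: 2day, b4, w00t) but need a letter
    "[0-9]*[A-Za-zÀ-ɏ][A-Za-zÀ-ɏ0-9]*(?:['’-][A-Za-zÀ-ɏ0-9]+)*",
    "[0-9]+(?:[.,][0-9]+)*",
    "[^\\s]"
)

.tokenRegex <- function(extra = NULL) {
    pats <- c(extra, .emoticonPatterns, .wordPatterns)
    paste0("(", paste(pats, collapse = ")|("), ")")
}

.emoticonRegex <- function(extra = NULL) {
    pats <- c(extra, .emoticonPatterns)
    paste0("^(?:(?:", paste(pats, collapse = ")|(?:"), "))$")
}

#' Emoticon-aware tokenization
#'
#' Splits social-media text into tokens the way an emoticon-aware
#' tokenizer must: emoticons such as `:-)`, `;)`, `<3`, `^_^` or `D:`
#' survive as single tokens instead of being shredded into punctuation;
#' URLs, @-mentions and hashtags are kept whole; remaining punctuation is
#' split from words; alphabetic tokens are lowercased (emoticons are left
#' untouched, since `:D` and `:d` are different glyphs only in appearance).
#' Elongations ("soooo") are kept as written.
#'
#' @param text character vector of messages.
#' @param extraEmoticons optional character vector of additional emoticon
#'   regular expressions (matched before the built-in battery), e.g. read
#'   from a supplement file with one pattern per line.
#' @return a list with one character vector of tokens per input message
#'   (empty messages give `character(0)`).
#' @examples
#' tokenize("good day :-)")
#' tokenize("LOVE you!!")
#' @export
tokenize <- function(text, extraEmoticons = NULL) {
    stopifnot(is.character(text))
    rx <- .tokenRegex(extraEmoticons)
    emo <- .emoticonRegex(extraEmoticons)
    m <- gregexpr(rx, text, perl = TRUE)
    toks <- regmatches(text, m)
    lapply(toks, function(tt) {
        if (!length(tt) || (length(tt) == 1L && is.na(tt))) return(character(0))
        isEmo <- grepl(emo, tt, perl = TRUE)
        tt[!isEmo] <- tolower(tt[!isEmo])
        tt
    })
}

#' Read an emoticon supplement file
#'
#' One regular-expression pattern per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return character vector of patterns.
#' @export
readEmoticonFile <- function(path) {
    ln <- trimws(readLines(path, warn = FALSE))
    ln[nzchar(ln) & !startsWith(ln, "#")]
}
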