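# NRC-style emotion lexicon: word -> emotions, emotion -> polarity.

POSITIVE_EMOTIONS <- c("anticipation", "trust", "surprise", "joy")
NEGATIVE_EMOTIONS <- c("fear", "anger", "sadness", "disgust")

#' The eight emotion categories
#'
#' Canonical ordering used throughout the package: the four negative
#' emotions (fear, anger, sadness, disgust) followed by the four positive
#' ones (anticipation, trust, surprise, joy).
#'
#' @return Character vector of length 8.
#' @export
emotions <- function() {
  c(NEGATIVE_EMOTIONS, POSITIVE_EMOTIONS)
}

#' Polarity of an emotion category
#'
#' Anticipation, trust, surprise and joy are positive; fear, anger,
#' sadness and disgust are negative.
#'
#' @param emotion One of the 8 emotion labels.
#' @return `"positive"` or `"negative"`.
#' @export
#' @examples
#' polarity_of("anticipation")
#' polarity_of("disgust")
polarity_of <- function(emotion) {
  if (length(emotion) != 1 || !emotion %in% emotions()) {
    stop_domain("unknown emotion label: '", paste(emotion, collapse = ","),
                "' (expected one of: ", paste(emotions(), collapse = ", "), ")")
  }
  if (emotion %in% POSITIVE_EMOTIONS) "positive" else "negative"
}

new_emotion_lexicon <- function(associations) {
  if (!length(associations)) stop_domain("emotion lexicon is empty")
  structure(list(associations = associations,
                 words = names(associations)),
            class = "emotion_lexicon")
}

#' Build an emotion lexicon from word/emotion pairs
#'
#' @param word Character vector of (lowercase) words.
#' @param emotion Parallel character vector of emotion labels; labels
#'   outside the 8 categories are ignored.
#' @return An `emotion_lexicon`.
#' @export
emotion_lexicon <- function(word, emotion) {
  keep <- emotion %in% emotions()
  word <- tolower(word[keep])
  emotion <- emotion[keep]
  if (!length(word)) stop_domain("no associations among the 8 emotion categories")
  assoc <- lapply(split(emotion, word), function(e) {
    emotions()[emotions() %in% e]
  })
  new_emotion_lexicon(assoc)
}

#' Load an NRC-style emotion lexicon
#'
#' Reads an association table in the NRC TSV format
#' (`word<TAB>emotion<TAB>flag`, flag 0 or 1, optional header). Rows with
#' emotions outside the 8 target categories (e.g. the `positive` /
#' `negative` meta-rows of the full NRC file) are ignored. A word is in
#' the lexicon iff it has at least one flag-1 association.
#'
#' @param path Path to the TSV file.
#' @return An `emotion_lexicon`.
#' @export
load_emotion_lexicon <- function(path) {
  if (!file.exists(path)) stop("cannot read lexicon: no such file '", path, "'")
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("word", "emotion", "flag"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (nrow(df) && identical(tolower(unlist(df[1, ])),
                            c("word", "emotion", "flag"))) {
    df <- df[-1, , drop = FALSE]
  }
  if (!nrow(df)) stop_domain("emotion lexicon file '", path, "' is empty")
  if (!all(df$flag %in% c("0", "1"))) {
    bad <- which(!df$flag %in% c("0", "1"))[[1L]]
    stop_format("unknown flag value '", df$flag[[bad]], "' on row ", bad,
                " of '", path, "' (expected 0 or 1)")
  }
  df <- df[df$flag == "1" & df$emotion %in% emotions(), , drop = FALSE]
  if (!nrow(df)) stop_domain("lexicon '", path, "' has no flag-1 associations ",
                             "among the 8 emotion categories")
  emotion_lexicon(df$word, df$emotion)
}

#' Write an emotion lexicon in NRC TSV format
#'
#' @param lexicon An `emotion_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emotion_lexicon <- function(lexicon, path) {
  rows <- unlist(lapply(lexicon$words, function(w) {
    paste(w, lexicon$associations[[w]], "1", sep = "\t")
  }))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Emotions associated with a token
#'
#' @param lexicon An `emotion_lexicon`.
#' @param token A lowercase token.
#' @return Character vector of emotions (empty for non-lexicon words).
#' @export
#' @examples
#' lex <- emotion_lexicon(c("sick", "sick", "tomorrow"),
#'                        c("disgust", "sadness", "anticipation"))
#' emotions_of(lex, "sick")
#' emotions_of(lex, "xxx")
emotions_of <- function(lexicon, token) {
  lexicon$associations[[token]] %||% character(0)
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  cat("<emotion_lexicon> ", length(x$words), " words, ",
      sum(lengths(x$associations)), " associations over ",
      length(emotions()), " emotions\n", sep = "")
  invisible(x)
}

# words x 8 logical membership matrix; the workhorse of all counting.
emotion_membership <- function(lexicon) {
  m <- vapply(emotions(), function(e) {
    vapply(lexicon$associations, function(a) e %in% a, logical(1))
  }, logical(length(lexicon$words)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(lexicon$words, emotions()))
  rownames(m) <- lexicon$words
  m
}
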