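# Reading, writing, tokenizing and splitting labeled forum-post collections.

#' Construct a post collection
#'
#' A post collection is a data frame with columns `post_id`, `group` and
#' `text`, one row per forum post. Post ids must be unique and group labels
#' non-empty; text may be empty.
#'
#' @param post_id Character vector of unique post identifiers.
#' @param group Character vector of group labels (non-empty strings).
#' @param text Character vector of post texts.
#' @return A `post_collection` (a data frame).
#' @export
#' @examples
#' pc <- post_collection(c("p1", "p2"), c("A", "B"), c("hello", "world"))
#' post_groups(pc)
post_collection <- function(post_id, group, text) {
  post_id <- as.character(post_id)
  group <- as.character(group)
  text <- as.character(text)
  n <- length(post_id)
  if (length(group) != n || length(text) != n) {
    stop_domain("post_id, group and text must have equal length")
  }
  if (anyDuplicated(post_id)) {
    stop_domain("post ids must be unique within a collection")
  }
  if (n > 0 && any(is.na(group) | !nzchar(group))) {
    stop_domain("group labels must be non-empty")
  }
  text[is.na(text)] <- ""
  out <- data.frame(post_id = post_id, group = group, text = text,
                    stringsAsFactors = FALSE)
  class(out) <- c("post_collection", "data.frame")
  out
}

#' Distinct group labels of a collection
#'
#' @param posts A `post_collection`.
#' @return Character vector of group labels in order of first appearance.
#' @export
post_groups <- function(posts) {
  unique(posts$group)
}

as_post_collection <- function(df) {
  post_collection(df$post_id, df$group, df$text)
}

check_post_fields <- function(nms, where) {
  required <- c("post_id", "group", "text")
  missing <- setdiff(required, nms)
  if (length(missing)) {
    stop_format("missing required field '", missing[[1L]], "' in ", where)
  }
}

#' Read a labeled post collection from disk
#'
#' Supports CSV (header `post_id,group,text`, RFC-4180 quoting) and JSON
#' Lines (one object per line with keys `post_id`, `group`, `text`).
#'
#' @param path Path to the input file.
#' @param format `"csv"` or `"jsonl"`.
#' @return A [post_collection()].
#' @export
read_posts <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read posts: no such file '", path, "'")
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE)
    check_post_fields(names(df), paste0("csv file '", path, "'"))
    as_post_collection(df)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(post_collection(character(), character(), character()))
    }
    recs <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        stop_format("malformed JSON on line ", i, " of '",
                                    path, "': ", conditionMessage(e))
                      })
      check_post_fields(names(obj), paste0("jsonl line ", i))
      obj
    })
    post_collection(
      vapply(recs, function(r) as.character(r$post_id), character(1)),
      vapply(recs, function(r) as.character(r$group), character(1)),
      vapply(recs, function(r) as.character(r$text), character(1))
    )
  }
}

#' Write a post collection to disk
#'
#' @param posts A [post_collection()].
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(posts)[, c("post_id", "group", "text")],
                     path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(posts))) {
      writeLines(jsonlite::toJSON(list(post_id = posts$post_id[[i]],
                                       group = posts$group[[i]],
                                       text = posts$text[[i]]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Tokenizer configuration
#'
#' Tokens are maximal runs of Unicode letters; punctuation, digits and
#' (optionally) apostrophes act as separators, so "don't" tokenizes to
#' `don`, `t`. Stopwords are carried along but *not* removed at
#' tokenization time: removal happens at feature selection, so that total
#' word counts (the denominators of relative frequencies) include them.
#'
#' @param lowercase Lowercase the text before tokenizing.
#' @param keep_alphabetic_only Restrict tokens to letter runs (otherwise
#'   digits are allowed inside tokens).
#' @param split_on_apostrophe Treat apostrophes as separators.
#' @param stopwords Character vector of stopwords (lowercase).
#' @return A `tokenizer_config` list.
#' @export
tokenizer_config <- function(lowercase = TRUE, keep_alphabetic_only = TRUE,
                             split_on_apostrophe = TRUE,
                             stopwords = character()) {
  if (lowercase && length(stopwords) && any(stopwords != tolower(stopwords))) {
    stop_domain("stopwords must be lowercase when the lowercase flag is on")
  }
  structure(list(lowercase = isTRUE(lowercase),
                 keep_alphabetic_only = isTRUE(keep_alphabetic_only),
                 split_on_apostrophe = isTRUE(split_on_apostrophe),
                 stopwords = as.character(stopwords)),
            class = "tokenizer_config")
}

token_pattern <- function(config) {
  cls <- if (config$keep_alphabetic_only) "\\p{L}" else "[\\p{L}\\p{N}]"
  if (config$split_on_apostrophe) {
    paste0(cls, "+")
  } else {
    paste0(cls, "+(?:'", cls, "+)*")
  }
}

#' Tokenize text
#'
#' @param text A character string (or vector; see value).
#' @param config A [tokenizer_config()].
#' @return For a single string, a character vector of tokens; for a vector
#'   of strings, a list of token vectors.
#' @export
#' @examples
#' tokenize("Thanks xxx I hope you feel better soon")
#' tokenize("don't")
tokenize <- function(text, config = tokenizer_config()) {
  out <- tokenize_many(text, config)
  if (length(text) == 1L) out[[1L]] else out
}

# Vectorized tokenizer; always returns a list of token vectors.
tokenize_many <- function(text, config = tokenizer_config()) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  if (config$lowercase) text <- tolower(text)
  regmatches(text, gregexpr(token_pattern(config), text, perl = TRUE))
}

#' Read a plain-text word list
#'
#' One lowercase token per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list.
#' @return Character vector of tokens.
#' @export
read_wordlist <- function(path) {
  if (!file.exists(path)) stop("cannot read word list: no such file '", path, "'")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  tolower(lines[nzchar(lines)])
}

#' Packaged English stopword list
#'
#' A compact general-purpose English stopword list (~175 function words)
#' shipped with the package so feature selection is reproducible across
#' environments.
#'
#' @return Character vector of stopwords.
#' @export
stopwords_en <- function() {
  read_wordlist(system.file("extdata", "stopwords_en.txt",
                            package = "forumstylo", mustWork = TRUE))
}

#' Packaged English pronoun list
#'
#' Personal, possessive and reflexive pronouns used for the
#' `token_pron` / `emotion_pron` feature types.
#'
#' @return Character vector of pronouns.
#' @export
pronouns_en <- function() {
  read_wordlist(system.file("extdata", "pronouns_en.txt",
                            package = "forumstylo", mustWork = TRUE))
}

#' Stratified train/test split
#'
#' Splits a collection into train and test partitions, stratified by group:
#' within each group of m posts, `max(1, floor(train_fraction * m))` posts go
#' to train and the rest to test. Deterministic given `seed`.
#'
#' @param posts A [post_collection()].
#' @param train_fraction Proportion in (0, 1] of each group assigned to train.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both post collections.
#' @export
split_train_test <- function(posts, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      is.na(train_fraction) || train_fraction <= 0 || train_fraction > 1) {
    stop_domain("train_fraction must lie in (0, 1]")
  }
  groups <- post_groups(posts)
  if (!length(groups)) stop_domain("cannot split an empty collection")
  train_idx <- with_seed(seed, {
    unlist(lapply(groups, function(g) {
      idx <- which(posts$group == g)
      m <- length(idx)
      n_train <- max(1L, floor(train_fraction * m))
      sort(idx[sample.int(m, n_train)])
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = as_post_collection(posts[train_idx, , drop = FALSE]),
       test = as_post_collection(posts[setdiff(seq_len(nrow(posts)), train_idx),
                                       , drop = FALSE]))
}

#' Summarize post-length distributions by group
#'
#' Computes per-group post counts and word-count statistics (word count =
#' number of tokens, stopwords included), plus two-sided Mann-Whitney U
#' tests on word counts for every pair of groups (normal approximation with
#' tie correction).
#'
#' @param posts A [post_collection()] with at least one post per group.
#' @param config A [tokenizer_config()].
#' @return List with `summary` (data frame: group, n_posts, mean_words,
#'   sd_words, median_words) and `pairwise` (data frame: group_a, group_b,
#'   statistic, p_value); `pairwise` has zero rows for a single group.
#' @export
summarize_groups <- function(posts, config = tokenizer_config()) {
  groups <- post_groups(posts)
  if (!length(groups)) stop_domain("collection has no posts")
  wc <- lengths(tokenize_many(posts$text, config))
  by_group <- split(wc, factor(posts$group, levels = groups))
  summary <- data.frame(
    group = groups,
    n_posts = vapply(by_group, length, integer(1)),
    mean_words = vapply(by_group, mean, numeric(1)),
    sd_words = vapply(by_group, function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
                      numeric(1)),
    median_words = vapply(by_group, stats::median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  pairwise <- if (length(groups) < 2) {
    data.frame(group_a = character(), group_b = character(),
               statistic = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  } else {
    pairs <- utils::combn(groups, 2)
    res <- apply(pairs, 2, function(p) {
      wt <- suppressWarnings(stats::wilcox.test(by_group[[p[1]]], by_group[[p[2]]],
                                                exact = FALSE, correct = FALSE))
      c(statistic = unname(wt$statistic), p_value = wt$p.value)
    })
    data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
               statistic = res["statistic", ], p_value = res["p_value", ],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(summary = summary, pairwise = pairwise)
}
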