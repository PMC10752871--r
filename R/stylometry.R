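# Burrows' Delta: subcorpora, feature selection, z-score profiles, delta
# scores and group attribution.

#' Merge posts into per-group subcorpora
#'
#' Concatenates the tokenized posts of each group, preserving post order,
#' into one token stream per group (the group's subcorpus). The union of
#' all subcorpora is the corpus.
#'
#' @param posts A [post_collection()].
#' @param config A [tokenizer_config()].
#' @return A named list of token vectors, one per group, in order of first
#'   appearance; class `subcorpora`.
#' @export
build_subcorpora <- function(posts, config = tokenizer_config()) {
  if (!nrow(posts)) stop_domain("cannot build subcorpora from an empty collection")
  groups <- post_groups(posts)
  toks <- tokenize_many(posts$text, config)
  out <- lapply(groups, function(g) {
    unlist(toks[posts$group == g], use.names = FALSE) %||% character(0)
  })
  names(out) <- groups
  structure(out, class = c("subcorpora", "list"))
}

#' Merged corpus of a set of subcorpora
#'
#' @param subcorpora A named list of token vectors (see [build_subcorpora()]).
#' @return A single token vector.
#' @export
merged_corpus <- function(subcorpora) {
  unlist(unname(subcorpora), use.names = FALSE) %||% character(0)
}

FEATURE_TYPES <- c("token", "emotion", "token_pron", "emotion_pron")

# Candidate feature pool for one feature type. Stopword removal applies to
# the token pool only; emotion pools are defined by lexicon membership; in
# the +pronoun types pronoun tokens are added explicitly, exempt from
# stopword removal (pronouns are stopwords, so they could otherwise never
# enter).
candidate_pool <- function(vocab, feature_type, stopwords, lexicon, pronouns) {
  base <- switch(sub("_pron$", "", feature_type),
    token = setdiff(vocab, stopwords),
    emotion = {
      if (is.null(lexicon)) {
        stop_domain("an emotion lexicon is required for the '", feature_type,
                    "' feature type")
      }
      intersect(vocab, lexicon$words)
    }
  )
  if (grepl("_pron$", feature_type)) {
    base <- union(base, intersect(vocab, pronouns))
  }
  base
}

#' Select stylometric features and corpus norms
#'
#' Picks the k most frequent candidate words in the merged corpus (ties
#' broken by descending count, then lexicographically ascending) and
#' computes, for each feature, the mean and standard deviation of its
#' relative frequency across the n group subcorpora. Relative frequency
#' denominators are each group's total token count, stopwords included.
#' Features whose standard deviation is zero carry no discriminating
#' signal and are dropped with a warning.
#'
#' @param subcorpora Named list of per-group token vectors.
#' @param feature_type One of `"token"`, `"emotion"`, `"token_pron"`,
#'   `"emotion_pron"`.
#' @param k Number of features requested (all candidates if fewer exist).
#' @param stopwords Stopword vector (see [stopwords_en()]).
#' @param lexicon An `emotion_lexicon` (required for emotion types).
#' @param pronouns Pronoun vector (required for the `_pron` types).
#' @param sd_type `"population"` (divide by n; the default, standardizing
#'   over the comparison set) or `"sample"` (divide by n - 1).
#' @return A `feature_set`: list with `feature_type`, `k` (retained count),
#'   `features`, `mu`, `sigma`, `group_freq` (group x feature relative
#'   frequencies), `dropped` (zero-variance features removed).
#' @export
select_features <- function(subcorpora,
                            feature_type = FEATURE_TYPES,
                            k = 100L,
                            stopwords = character(),
                            lexicon = NULL,
                            pronouns = character(),
                            sd_type = c("population", "sample")) {
  feature_type <- match.arg(feature_type)
  sd_type <- match.arg(sd_type)
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop_domain("k must be >= 1")
  corpus <- merged_corpus(subcorpora)
  counts <- table(corpus)
  pool <- candidate_pool(names(counts), feature_type, stopwords, lexicon, pronouns)
  if (!length(pool)) {
    stop_domain("empty candidate pool for feature type '", feature_type, "'")
  }
  pool_counts <- as.integer(counts[pool])
  ord <- order(-pool_counts, pool)
  features <- pool[ord][seq_len(min(k, length(pool)))]

  totals <- lengths(subcorpora)
  if (any(totals == 0)) {
    stop_domain("every group subcorpus must contain at least one token")
  }
  freq <- freq_matrix(subcorpora, features)

  mu <- colMeans(freq)
  n <- nrow(freq)
  sigma <- if (sd_type == "population") {
    sqrt(colMeans(sweep(freq, 2, mu)^2))
  } else {
    if (n < 2) stop_domain("sample sd needs at least 2 groups")
    apply(freq, 2, stats::sd)
  }

  dropped <- features[sigma == 0]
  if (length(dropped)) {
    warning(length(dropped), " feature(s) with zero variance across groups ",
            "dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
    keep <- sigma > 0
    features <- features[keep]
    mu <- mu[keep]
    sigma <- sigma[keep]
    freq <- freq[, keep, drop = FALSE]
  }
  if (!length(features)) stop_domain("no features retained (all zero variance)")

  structure(list(feature_type = feature_type, k = length(features),
                 k_requested = as.integer(k), features = features,
                 mu = mu, sigma = sigma, group_freq = freq,
                 dropped = dropped, sd_type = sd_type),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> type=", x$feature_type, ", k=", x$k,
      if (length(x$dropped)) paste0(" (", length(x$dropped), " dropped)"),
      "; top: ", paste(utils::head(x$features, 8), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Profile a token stream against a feature set
#'
#' Computes relative feature frequencies `C_i = count(f_i) / total tokens`
#' and z-scores `z_i = (C_i - mu_i) / sigma_i` using the feature set's
#' training-corpus norms.
#'
#' @param tokens Non-empty token vector.
#' @param fs A `feature_set`.
#' @param label Optional text label.
#' @return A `subcorpus_profile`: list with `label`, `total_tokens`,
#'   `freq`, `z` and the generating `features`.
#' @export
profile <- function(tokens, fs, label = NULL) {
  if (!length(tokens)) stop_domain("cannot profile an empty token list")
  freq <- tabulate(match(tokens, fs$features), nbins = length(fs$features)) /
    length(tokens)
  names(freq) <- fs$features
  z <- (freq - fs$mu) / fs$sigma
  structure(list(label = label, total_tokens = length(tokens),
                 freq = freq, z = z, features = fs$features),
            class = "subcorpus_profile")
}

# texts x features relative-frequency matrix (robust to a single feature,
# where vapply would collapse to a vector).
freq_matrix <- function(token_lists, features) {
  nf <- length(features)
  raw <- vapply(token_lists, function(toks) {
    tabulate(match(toks, features), nbins = nf) / max(1L, length(toks))
  }, numeric(nf))
  freq <- if (is.matrix(raw)) t(raw) else matrix(raw, ncol = 1L)
  dimnames(freq) <- list(names(token_lists), features)
  freq
}

# Fast path: z matrix (texts x features) for a list of token vectors.
profile_z_matrix <- function(token_lists, fs) {
  freq <- freq_matrix(token_lists, fs$features)
  sweep(sweep(freq, 2, fs$mu), 2, fs$sigma, "/")
}

check_same_features <- function(a, b) {
  if (!identical(a$features, b$features)) {
    stop_domain("profiles were built from different feature sets")
  }
}

#' Burrows' Delta between two profiles
#'
#' The mean absolute difference of z-scores over the retained features:
#' `Delta = sum_i |z_a,i - z_b,i| / k`.
#'
#' @param a,b `subcorpus_profile` objects built from the same feature set.
#' @return A non-negative number.
#' @export
delta_score <- function(a, b) {
  check_same_features(a, b)
  mean(abs(a$z - b$z))
}

#' Delta matrix between training groups and test texts
#'
#' @param train Named list of `subcorpus_profile`s (training groups; rows).
#' @param test Named list of `subcorpus_profile`s (test texts; columns).
#' @return A `delta_matrix`: numeric matrix of delta scores with group /
#'   text dimnames.
#' @export
delta_matrix <- function(train, test) {
  m <- vapply(test, function(p_test) {
    vapply(train, delta_score, numeric(1), b = p_test)
  }, numeric(length(train)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(train))
  dimnames(m) <- list(names(train), names(test))
  structure(m, class = c("delta_matrix", class(matrix())))
}

#' Attribute an unknown text to a group
#'
#' Ranks candidate groups by ascending delta score; the most likely group
#' comes first. Exact ties are broken by group label order and flagged.
#'
#' @param test_profile A `subcorpus_profile` of the unknown text.
#' @param train Named list of training-group `subcorpus_profile`s.
#' @return Data frame with columns `group`, `delta`, `tied`, ordered by
#'   ascending delta.
#' @export
attribute <- function(test_profile, train) {
  if (!length(train)) stop_domain("at least one training group is required")
  deltas <- vapply(train, delta_score, numeric(1), b = test_profile)
  ord <- order(deltas, names(train))
  d <- deltas[ord]
  data.frame(group = names(train)[ord], delta = unname(d),
             tied = duplicated(d) | duplicated(d, fromLast = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split a token stream into fixed-size chunks
#'
#' Produces `floor(n / chunk_size)` chunks (at least one); the short tail
#' is merged into the last chunk, so every chunk has at least
#' `chunk_size` tokens except when the stream itself is shorter.
#'
#' @param tokens Token vector.
#' @param chunk_size Target tokens per chunk.
#' @return List of token vectors.
#' @export
chunk_tokens <- function(tokens, chunk_size = 500L) {
  if (chunk_size < 1) stop_domain("chunk_size must be >= 1")
  n <- length(tokens)
  if (!n) return(list())
  n_chunks <- max(1L, n %/% chunk_size)
  starts <- (seq_len(n_chunks) - 1L) * chunk_size + 1L
  ends <- c(starts[-1L] - 1L, n)
  lapply(seq_len(n_chunks), function(i) tokens[starts[i]:ends[i]])
}

#' Write a feature set to TSV
#'
#' One row per feature: feature, corpus mean, corpus sd, then the relative
#' frequency in each group.
#'
#' @param fs A `feature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(fs, path) {
  df <- data.frame(feature = fs$features, mu = fs$mu, sigma = fs$sigma,
                   t(fs$group_freq), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a delta (or probability) matrix to CSV
#'
#' Adds a `best` column naming, for each training-group row, the test
#' column with the minimal delta (or maximal probability).
#'
#' @param m A matrix with dimnames.
#' @param path Output path.
#' @param best `"min"` or `"max"`.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, best = c("min", "max")) {
  best <- match.arg(best)
  pick <- apply(unclass(m), 1, function(r) {
    colnames(m)[if (best == "min") which.min(r) else which.max(r)]
  })
  df <- data.frame(group = rownames(m), unclass(m), best = pick,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
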