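# Shared fixtures built in code.

# Tiny lexicon using word -> emotion associations observed in real forum
# posts (hope/good carry all four positive emotions; sick is
# disgust+sadness; struggle's "negative" meta-tag exercises the
# ignore-unknown-category rule at load time).
fixture_lexicon_rows <- function() {
  data.frame(
    word = c(rep("hope", 4), "infection", "sick", "sick", "tomorrow",
             rep("painful", 4), "hot", rep("good", 4), "start",
             "heal", "heal", "struggle", "struggle", "struggle", "struggle",
             "daily", "time"),
    emotion = c("anticipation", "joy", "surprise", "trust",
                "fear",
                "disgust", "sadness",
                "anticipation",
                "anger", "disgust", "fear", "sadness",
                "anger",
                "anticipation", "joy", "surprise", "trust",
                "anticipation",
                "joy", "trust",
                "anger", "fear", "negative", "sadness",
                "anticipation",
                "anticipation"),
    flag = 1L,
    stringsAsFactors = FALSE
  )
}

fixture_lexicon <- function() {
  rows <- fixture_lexicon_rows()
  rows <- rows[rows$emotion %in% emotions(), ]
  emotion_lexicon(rows$word, rows$emotion)
}

write_fixture_lexicon <- function(path = tempfile(fileext = ".tsv"),
                                  extra_rows = NULL) {
  rows <- rbind(fixture_lexicon_rows(), extra_rows)
  writeLines(paste(rows$word, rows$emotion, rows$flag, sep = "\t"), path)
  path
}

# A small labeled corpus with deterministic, distinguishable groups.
fixture_posts <- function() {
  post_collection(
    paste0("p", 1:6),
    c("A", "A", "B", "B", "C", "C"),
    c("I hope you feel better soon",
      "good morning and good hope to you",
      "the infection was painful and I felt sick",
      "sick again with a painful struggle",
      "tomorrow we start the daily plan",
      "time to start again tomorrow")
  )
}

# Independent brute-force Burrows' Delta: recounts everything from the raw
# token lists without touching the package's profiling code paths.
oracle_delta <- function(subcorpora, features, text_a, text_b) {
  rel <- function(tokens, f) sum(tokens == f) / length(tokens)
  mu <- sapply(features, function(f) mean(sapply(subcorpora, rel, f = f)))
  sigma <- sapply(features, function(f) {
    v <- sapply(subcorpora, rel, f = f)
    sqrt(mean((v - mean(v))^2))
  })
  za <- (sapply(features, rel, tokens = text_a) - mu) / sigma
  zb <- (sapply(features, rel, tokens = text_b) - mu) / sigma
  mean(abs(za - zb))
}

# Independent AUC oracle: explicit loop over all positive/negative pairs,
# ties counted 1/2.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Independent Pearson chi-square from first principles.
oracle_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}
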