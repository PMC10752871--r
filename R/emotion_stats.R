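# Group x emotion count tables, polarity aggregation, pairwise chi-square
# with BH correction, odds ratios with Woolf CIs, and radar scores.

#' Construct a group x emotion count table
#'
#' @param counts Integer matrix, groups in rows, the 8 emotions in
#'   columns (any column order containing all of [emotions()]).
#' @param totals Per-group total token counts (the proportion
#'   denominator), same length/order as the rows.
#' @return An `emotion_count_table`: list with `groups`, `counts`,
#'   `totals` and `proportions` (percent of total tokens).
#' @export
emotion_count_table <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (!setequal(colnames(counts), emotions())) {
    stop_domain("counts must have exactly the 8 emotion columns")
  }
  counts <- counts[, emotions(), drop = FALSE]
  if (is.null(rownames(counts))) stop_domain("counts must have group rownames")
  if (length(totals) != nrow(counts)) {
    stop_domain("totals must have one entry per group")
  }
  if (any(counts < 0) || any(totals <= 0)) {
    stop_domain("counts must be non-negative and totals positive")
  }
  totals <- stats::setNames(as.numeric(totals), rownames(counts))
  structure(list(groups = rownames(counts), counts = counts, totals = totals,
                 proportions = sweep(counts, 1, totals, "/") * 100),
            class = "emotion_count_table")
}

#' @export
print.emotion_count_table <- function(x, ...) {
  cat("<emotion_count_table> ", length(x$groups), " groups x 8 emotions\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Count emotion-word occurrences per group
#'
#' Every token occurrence increments each emotion it is associated with
#' (a word carrying four emotions adds 1 to four cells). The proportion
#' denominator is each group's total token count, stopwords included.
#'
#' @param subcorpora Named list of per-group token vectors
#'   (see [build_subcorpora()]).
#' @param lexicon An `emotion_lexicon`.
#' @return An [emotion_count_table()].
#' @export
count_emotions <- function(subcorpora, lexicon) {
  if (!length(subcorpora) || any(lengths(subcorpora) == 0)) {
    stop_domain("every group subcorpus must be non-empty")
  }
  M <- emotion_membership(lexicon)
  counts <- t(vapply(subcorpora, function(toks) {
    hits <- tabulate(match(toks, lexicon$words), nbins = length(lexicon$words))
    as.numeric(crossprod(M, hits))
  }, numeric(8L)))
  colnames(counts) <- emotions()
  rownames(counts) <- names(subcorpora)
  emotion_count_table(counts, lengths(subcorpora))
}

#' Most frequent emotion-related words in a corpus
#'
#' Lexicon-member words ranked by total corpus count, ties broken by
#' descending count then lexicographically.
#'
#' @param subcorpora Named list of per-group token vectors.
#' @param lexicon An `emotion_lexicon`.
#' @param n Number of words to return (all if fewer exist).
#' @return Data frame with columns `rank`, `word`, `count`.
#' @export
top_emotion_words <- function(subcorpora, lexicon, n = 100L) {
  if (n < 1) stop_domain("n must be >= 1")
  corpus <- merged_corpus(subcorpora)
  corpus <- corpus[corpus %in% lexicon$words]
  if (!length(corpus)) {
    return(data.frame(rank = integer(), word = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(corpus)
  ord <- order(-as.integer(tab), names(tab))
  top <- utils::head(ord, n)
  data.frame(rank = seq_along(top), word = names(tab)[top],
             count = as.integer(tab)[top], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Aggregate emotion counts by polarity
#'
#' Sums the four positive (anticipation, trust, surprise, joy) and four
#' negative (fear, anger, sadness, disgust) emotion columns per group,
#' with proportions against the same per-group token totals, plus a
#' cross-group average row (mean of the group counts and of the group
#' proportions).
#'
#' @param ect An [emotion_count_table()].
#' @return Data frame (class `polarity_table`) with columns `group`,
#'   `positive`, `negative`, `positive_prop`, `negative_prop`; the last
#'   row is the average.
#' @export
polarity_table <- function(ect) {
  pos <- rowSums(ect$counts[, POSITIVE_EMOTIONS, drop = FALSE])
  neg <- rowSums(ect$counts[, NEGATIVE_EMOTIONS, drop = FALSE])
  pos_p <- pos / ect$totals * 100
  neg_p <- neg / ect$totals * 100
  out <- data.frame(
    group = c(ect$groups, "average"),
    positive = c(pos, mean(pos)),
    negative = c(neg, mean(neg)),
    positive_prop = c(pos_p, mean(pos_p)),
    negative_prop = c(neg_p, mean(neg_p)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("polarity_table", "data.frame")
  out
}

#' Positive-to-negative emotion ratio of a group
#'
#' @param pt A [polarity_table()].
#' @param group Group label.
#' @return The ratio positive/negative rounded (half-even) to 2 decimals.
#' @export
polarity_ratio <- function(pt, group) {
  row <- pt[pt$group == group, , drop = FALSE]
  if (nrow(row) != 1) stop_domain("unknown group '", group, "'")
  if (row$negative <= 0) {
    stop_domain("polarity ratio undefined: group '", group,
                "' has zero negative count")
  }
  round(row$positive / row$negative, 2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value family; order-preserving with the
#' input and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise chi-square tests of emotion distributions
#'
#' For every pair of groups, a Pearson chi-square test (no continuity
#' correction) on the 2 x 8 table of emotion counts (`eight_emotions`,
#' df 7) or the 2 x 2 table of polarity counts (`binary_polarity`, df 1),
#' with Benjamini-Hochberg adjustment across the pair family. Categories
#' that are zero in both groups of a pair are dropped (df reduced) with a
#' warning.
#'
#' @param ect An [emotion_count_table()].
#' @param mode `"eight_emotions"` or `"binary_polarity"`.
#' @return Data frame with columns `group_a`, `group_b`, `chi_square`,
#'   `df`, `p_raw`, `p_adjusted`.
#' @export
pairwise_chi_square <- function(ect, mode = c("eight_emotions",
                                              "binary_polarity")) {
  mode <- match.arg(mode)
  mat <- if (mode == "eight_emotions") {
    ect$counts
  } else {
    cbind(positive = rowSums(ect$counts[, POSITIVE_EMOTIONS, drop = FALSE]),
          negative = rowSums(ect$counts[, NEGATIVE_EMOTIONS, drop = FALSE]))
  }
  if (length(ect$groups) < 2) stop_domain("need at least 2 groups")
  pairs <- utils::combn(ect$groups, 2)
  res <- apply(pairs, 2, function(p) {
    tab <- mat[p, , drop = FALSE]
    empty <- colSums(tab) == 0
    if (any(empty)) {
      warning("pair (", p[1], ", ", p[2], "): dropping all-zero categories ",
              paste(colnames(tab)[empty], collapse = ", "))
      tab <- tab[, !empty, drop = FALSE]
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    c(chi_square = unname(ct$statistic), df = unname(ct$parameter),
      p_raw = ct$p.value)
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    chi_square = res["chi_square", ],
                    df = as.integer(res["df", ]),
                    p_raw = res["p_raw", ],
                    p_adjusted = bh_adjust(res["p_raw", ]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Odds ratio of emotion use between two groups
#'
#' Builds the 2 x 2 table (`a` = tokens counted for the emotion, `b` =
#' remaining tokens) for a reference and a comparison group and reports
#' the odds ratio `(a_ref/b_ref) / (a_cmp/b_cmp)`, its 95% Woolf
#' (log-normal) confidence interval, and the Pearson chi-square test of
#' OR = 1.
#'
#' @param ect An [emotion_count_table()].
#' @param emotion One of the 8 emotion labels.
#' @param group_ref,group_cmp Group labels.
#' @param continuity Add 0.5 to every cell of the 2 x 2 table before
#'   computing the OR and CI (off by default; required when a cell is 0).
#' @return One-row data frame with columns `emotion`, `group_ref`,
#'   `group_cmp`, `odds_ratio`, `ci_low`, `ci_high`, `chi_square`, `p`.
#' @export
odds_ratio <- function(ect, emotion, group_ref, group_cmp,
                       continuity = FALSE) {
  if (!emotion %in% emotions()) stop_domain("unknown emotion '", emotion, "'")
  for (g in c(group_ref, group_cmp)) {
    if (!g %in% ect$groups) stop_domain("unknown group '", g, "'")
  }
  a <- ect$counts[group_ref, emotion]
  b <- ect$totals[[group_ref]] - a
  c_ <- ect$counts[group_cmp, emotion]
  d <- ect$totals[[group_cmp]] - c_
  cells <- c(a, b, c_, d)
  if (any(cells == 0) && !continuity) {
    stop_domain("zero cell in the 2x2 table; use continuity = TRUE ",
                "for a continuity-corrected estimate")
  }
  adj <- if (continuity) cells + 0.5 else cells
  or <- (adj[1] / adj[2]) / (adj[3] / adj[4])
  se <- sqrt(sum(1 / adj))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  ct <- suppressWarnings(stats::chisq.test(matrix(cells, nrow = 2,
                                                  byrow = TRUE),
                                           correct = FALSE))
  data.frame(emotion = emotion, group_ref = group_ref, group_cmp = group_cmp,
             odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
             chi_square = unname(ct$statistic), p = ct$p.value,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Odds-ratio table of one group against all others
#'
#' All 8 emotions crossed with every comparison group, with
#' Benjamini-Hochberg adjustment across the whole family of tests.
#'
#' @param ect An [emotion_count_table()].
#' @param group_ref Reference group label.
#' @param groups_cmp Comparison groups (default: all other groups).
#' @param continuity Passed to [odds_ratio()].
#' @return Data frame: one row per emotion x comparison group, columns as
#'   in [odds_ratio()] plus `p_adjusted`.
#' @export
odds_ratio_table <- function(ect, group_ref,
                             groups_cmp = setdiff(ect$groups, group_ref),
                             continuity = FALSE) {
  rows <- do.call(rbind, lapply(emotions(), function(e) {
    do.call(rbind, lapply(groups_cmp, function(g) {
      odds_ratio(ect, e, group_ref, g, continuity = continuity)
    }))
  }))
  rows$p_adjusted <- bh_adjust(rows$p)
  rows
}

#' Per-post mean emotion-word counts (radar scores)
#'
#' For each group and emotion, the mean over the group's posts of the
#' number of tokens in the post associated with that emotion
#' (multi-emotion words count once per emotion).
#'
#' @param posts A [post_collection()].
#' @param lexicon An `emotion_lexicon`.
#' @param config A [tokenizer_config()].
#' @return Numeric matrix, groups x 8 emotions.
#' @export
radar_scores <- function(posts, lexicon, config = tokenizer_config()) {
  groups <- post_groups(posts)
  if (!length(groups)) stop_domain("collection has no posts")
  toks <- tokenize_many(posts$text, config)
  M <- emotion_membership(lexicon)
  post_idx <- rep(seq_along(toks), lengths(toks))
  flat <- unlist(toks, use.names = FALSE)
  hit <- match(flat, lexicon$words)
  keep <- !is.na(hit)
  per_post <- matrix(0, nrow = nrow(posts), ncol = 8L,
                     dimnames = list(NULL, emotions()))
  if (any(keep)) {
    agg <- rowsum(M[hit[keep], , drop = FALSE] + 0, post_idx[keep])
    per_post[as.integer(rownames(agg)), ] <- agg
  }
  out <- rowsum(per_post, group = factor(posts$group, levels = groups)) /
    as.vector(table(factor(posts$group, levels = groups)))
  rownames(out) <- groups
  out
}

#' Radar scores in long format
#'
#' @param scores Matrix from [radar_scores()].
#' @return Data frame with columns `group`, `emotion`, `score`.
#' @export
radar_long <- function(scores) {
  data.frame(group = rep(rownames(scores), times = ncol(scores)),
             emotion = rep(colnames(scores), each = nrow(scores)),
             score = as.vector(scores),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published emotion counts for the five SANE forum user groups
#'
#' Group x emotion counts of emotion-lexicon words in the posts of the
#' five most active peer-support user groups of the SANE Australia
#' forums, as published in summary form (the underlying corpus is not
#' public). The per-group total word counts are approximate: they are
#' back-computed from the published polarity percentages, which are
#' printed to one decimal place.
#'
#' @return An [emotion_count_table()] for the five user groups.
#' @export
sane_emotion_counts <- function() {
  path <- system.file("extdata", "sane_group_emotion_counts.csv",
                      package = "forumstylo", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, emotions()])
  rownames(counts) <- df$group
  emotion_count_table(counts, df$total_words)
}
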