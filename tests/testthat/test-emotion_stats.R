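test_that("emotion counting increments every associated emotion per occurrence", {
  lex <- fixture_lexicon()
  toks <- c("thanks", "xxx", "i", "hope", "you", "feel", "better", "soon",
            "infection", "sick", "tomorrow")
  sub <- structure(list(G = toks), class = c("subcorpora", "list"))
  ect <- count_emotions(sub, lex)
  want <- c(fear = 1, anger = 0, sadness = 1, disgust = 1,
            anticipation = 2, trust = 1, surprise = 1, joy = 1)
  expect_equal(ect$counts["G", names(want)], want)
  expect_equal(unname(ect$totals["G"]), length(toks))

  # no lexicon words -> zero row
  sub0 <- structure(list(G = c("purely", "neutral", "words")),
                    class = c("subcorpora", "list"))
  expect_equal(unname(count_emotions(sub0, lex)$counts["G", ]), rep(0, 8))
})

test_that("emotion counts match a per-token brute-force recount and are additive", {
  spec <- default_profiles(n_posts = 25, seed = 31)
  posts <- generate_posts(spec)
  lex <- spec$emotion_vocab
  sub <- build_subcorpora(posts)
  ect <- count_emotions(sub, lex)
  for (g in names(sub)[1:2]) {
    recount <- sapply(emotions(), function(e) {
      sum(vapply(sub[[g]], function(tok) e %in% emotions_of(lex, tok),
                 logical(1)))
    })
    expect_equal(ect$counts[g, ], recount)
  }
  # additivity over subcorpus concatenation
  joined <- structure(list(AB = c(sub[[1]], sub[[2]])),
                      class = c("subcorpora", "list"))
  expect_equal(unname(count_emotions(joined, lex)$counts["AB", ]),
               unname(ect$counts[1, ] + ect$counts[2, ]))
})

test_that("top emotion words rank by count with lexicographic tie-break", {
  lex <- fixture_lexicon()
  sub <- structure(list(G = c("hope", "hope", "good", "xxx")),
                   class = c("subcorpora", "list"))
  tw <- top_emotion_words(sub, lex, 2)
  expect_equal(tw$word, c("hope", "good"))
  expect_equal(tw$count, c(2L, 1L))
  expect_equal(nrow(top_emotion_words(sub, lex, 50)), 2L)  # saturation
  sub0 <- structure(list(G = "xxx"), class = c("subcorpora", "list"))
  expect_equal(nrow(top_emotion_words(sub0, lex, 5)), 0L)
})

test_that("polarity aggregation reproduces the published per-group counts", {
  pt <- polarity_table(sane_emotion_counts())
  get <- function(g, col) pt[[col]][pt$group == g]
  expect_equal(get("senior contributor", "positive"), 425086)
  expect_equal(get("senior contributor", "negative"), 256474)
  expect_equal(get("community guide", "positive"), 129080)
  expect_equal(get("community guide", "negative"), 59126)
  expect_equal(get("community elder", "positive"), 50346)
  expect_equal(get("community elder", "negative"), 28922)
  expect_equal(get("casual contributor", "positive"), 49134)
  expect_equal(get("casual contributor", "negative"), 46628)
  expect_equal(get("contributor", "positive"), 39532)
  expect_equal(get("contributor", "negative"), 31060)
  expect_equal(get("average", "negative"), 84442)

  # consistency: positive + negative = total of the 8 emotion columns
  ect <- sane_emotion_counts()
  expect_equal(pt$positive[1:5] + pt$negative[1:5],
               unname(rowSums(ect$counts)))
})

test_that("polarity ratios round half-even to two decimals", {
  pt <- polarity_table(sane_emotion_counts())
  expect_equal(polarity_ratio(pt, "senior contributor"), 1.66)
  expect_equal(polarity_ratio(pt, "community guide"), 2.18)
  expect_equal(polarity_ratio(pt, "community elder"), 1.74)
  expect_equal(polarity_ratio(pt, "casual contributor"), 1.05)
  expect_equal(polarity_ratio(pt, "contributor"), 1.27)

  eq <- emotion_count_table(
    matrix(10, 1, 8, dimnames = list("G", emotions())), 1000)
  expect_equal(polarity_ratio(polarity_table(eq), "G"), 1.00)

  zero <- emotion_count_table(
    matrix(c(0, 0, 0, 0, 5, 5, 5, 5), 1, 8,
           dimnames = list("G", emotions())), 100)
  expect_error(polarity_ratio(polarity_table(zero), "G"),
               class = "forumstylo_domain_error")
})

test_that("pairwise chi-square matches the brute-force expected-count oracle", {
  set.seed(17)
  for (i in 1:10) {
    counts <- matrix(rpois(16, 200) + 1, 2, 8,
                     dimnames = list(c("A", "B"), emotions()))
    ect <- emotion_count_table(counts, rowSums(counts) + 500)
    res <- pairwise_chi_square(ect)
    expect_equal(res$chi_square, oracle_chisq(counts), tolerance = 1e-9)
    expect_equal(res$df, 7L)
  }
  # proportional rows are independent: statistic exactly 0
  prop <- matrix(c(1:8, 2 * (1:8)), 2, 8, byrow = TRUE,
                 dimnames = list(c("A", "B"), emotions()))
  ect0 <- emotion_count_table(prop, c(100, 200))
  expect_equal(pairwise_chi_square(ect0)$chi_square, 0)

  # binary polarity mode collapses to a 2x2 with df 1
  resb <- pairwise_chi_square(ect0, "binary_polarity")
  expect_equal(resb$df, 1L)
  expect_equal(resb$chi_square, 0)

  # adjusted p-values never fall below raw ones
  ect5 <- sane_emotion_counts()
  res5 <- pairwise_chi_square(ect5)
  expect_equal(nrow(res5), 10L)
  expect_true(all(res5$p_adjusted >= res5$p_raw))
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "forumstylo_domain_error")

  set.seed(29)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone non-decreasing in raw-p rank order
    expect_false(is.unsorted(adj[order(p)]))
  }
  # idempotent on an already-adjusted uniform family
  expect_equal(bh_adjust(bh_adjust(rep(0.3, 6))), rep(0.3, 6))
})

test_that("odds ratios follow the Woolf formulation with anti-symmetry", {
  counts <- matrix(c(20, rep(1, 7), 10, rep(1, 7)), 2, 8, byrow = TRUE,
                   dimnames = list(c("ref", "cmp"), emotions()))
  ect <- emotion_count_table(counts, c(100, 100))
  or <- odds_ratio(ect, "fear", "ref", "cmp")
  expect_equal(or$odds_ratio, 2.25)
  # frozen from the Woolf formula: exp(log(2.25) +- 1.96 * 0.41667)
  expect_equal(or$ci_low, exp(log(2.25) - qnorm(0.975) *
                                sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)))
  expect_equal(round(or$ci_low, 2), 0.99)
  expect_equal(round(or$ci_high, 2), 5.09)
  expect_true(or$ci_low <= or$odds_ratio & or$odds_ratio <= or$ci_high)

  # anti-symmetry: OR flips to its reciprocal, CI endpoints swap and invert
  rev <- odds_ratio(ect, "fear", "cmp", "ref")
  expect_equal(rev$odds_ratio, 1 / or$odds_ratio)
  expect_equal(rev$ci_low, 1 / or$ci_high)
  expect_equal(rev$ci_high, 1 / or$ci_low)
  expect_equal(rev$chi_square, or$chi_square)

  # identical proportions: OR 1, chi-square 0
  same <- emotion_count_table(
    matrix(c(10, rep(2, 7), 20, rep(4, 7)), 2, 8, byrow = TRUE,
           dimnames = list(c("ref", "cmp"), emotions())), c(100, 200))
  orn <- odds_ratio(same, "fear", "ref", "cmp")
  expect_equal(orn$odds_ratio, 1.0)
  expect_equal(orn$chi_square, 0)

  # zero cells need the continuity-corrected variant
  zc <- emotion_count_table(
    matrix(c(0, rep(2, 7), 5, rep(2, 7)), 2, 8, byrow = TRUE,
           dimnames = list(c("ref", "cmp"), emotions())), c(50, 50))
  expect_error(odds_ratio(zc, "fear", "ref", "cmp"), "continuity",
               class = "forumstylo_domain_error")
  cc <- odds_ratio(zc, "fear", "ref", "cmp", continuity = TRUE)
  expect_true(is.finite(cc$odds_ratio) && cc$odds_ratio > 0)
})

test_that("odds ratios on the published counts reproduce the reported directions", {
  ect <- sane_emotion_counts()
  tab <- odds_ratio_table(ect, "senior contributor")
  fear_guide <- tab[tab$emotion == "fear" &
                      tab$group_cmp == "community guide", ]
  fear_casual <- tab[tab$emotion == "fear" &
                       tab$group_cmp == "casual contributor", ]
  expect_gt(fear_guide$odds_ratio, 1)
  expect_lt(fear_casual$odds_ratio, 1)
  expect_equal(nrow(tab), 32L)  # 8 emotions x 4 comparison groups
  expect_true(all(tab$p_adjusted >= tab$p))
})

test_that("radar scores average per-post emotion counts and ignore post order", {
  lex <- fixture_lexicon()
  pc <- post_collection(
    c("1", "2", "3"), c("A", "A", "B"),
    c("hope is good",            # joy: hope + good = 2... per word
      "sick but sick words",     # joy 0
      "tomorrow")
  )
  rs <- radar_scores(pc, lex)
  # post 1: hope, good each carry joy -> 2; post 2: 0 -> group mean 1
  expect_equal(unname(rs["A", "joy"]), 1.0)
  expect_equal(unname(rs["A", "sadness"]), 1.0)  # sick twice in post 2
  expect_equal(unname(rs["B", "anticipation"]), 1.0)
  expect_equal(unname(rs["B", "fear"]), 0)

  perm <- post_collection(c("3", "2", "1"), c("B", "A", "A"),
                          c("tomorrow", "sick but sick words",
                            "hope is good"))
  expect_equal(radar_scores(perm, lex)[rownames(rs), ], rs)

  long <- radar_long(rs)
  expect_equal(nrow(long), 16L)
  expect_equal(long$score[long$group == "A" & long$emotion == "joy"], 1.0)
})
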