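# Logistic calibration of delta scores into same-group probabilities, and
# ROC/AUC evaluation including the feature-type x k sweep.

# Chunk every group's training stream and return the chunk z-matrix plus
# the chunk group labels.
chunk_group_z <- function(posts, fs, config, chunk_size) {
  sub <- build_subcorpora(posts, config)
  chunk_lists <- lapply(sub, chunk_tokens, chunk_size = chunk_size)
  few <- names(chunk_lists)[vapply(chunk_lists, length, integer(1)) < 2]
  if (length(few)) {
    warning("group(s) with fewer than 2 chunks contribute only cross-group ",
            "pairs: ", paste(few, collapse = ", "))
  }
  chunks <- unlist(chunk_lists, recursive = FALSE, use.names = FALSE)
  group <- rep(names(chunk_lists), vapply(chunk_lists, length, integer(1)))
  list(z = profile_z_matrix(chunks, fs), group = group)
}

# All unordered chunk pairs with Manhattan/k deltas, labeled same/different
# group, subsampled per class. dist() stores pairs in combn(n, 2) order.
pairs_from_z <- function(z, group, max_pairs_per_class, seed) {
  n <- nrow(z)
  if (n < 2) stop_domain("need at least 2 chunks to form pairs")
  delta <- as.vector(stats::dist(z, method = "manhattan")) / ncol(z)
  idx <- utils::combn(n, 2L)
  same <- group[idx[1L, ]] == group[idx[2L, ]]
  keep <- with_seed(seed, {
    pick <- function(w) if (length(w) > max_pairs_per_class) {
      sort(sample(w, max_pairs_per_class))
    } else w
    sort(c(pick(which(same)), pick(which(!same))))
  })
  data.frame(delta = delta[keep], same_group = as.integer(same[keep]),
             group_a = group[idx[1L, keep]], group_b = group[idx[2L, keep]],
             stringsAsFactors = FALSE)
}

#' Build labeled same/different-group delta pairs
#'
#' Chunks each group's merged token stream into fixed-size windows
#' (default 500 tokens; short tails merged into the last chunk), profiles
#' every chunk against the feature set, and computes the delta score for
#' unordered chunk pairs, labeled 1 when both chunks come from the same
#' group. Each class is subsampled (seeded) to at most
#' `max_pairs_per_class` pairs.
#'
#' @param train A [post_collection()] (training posts).
#' @param fs A `feature_set` fitted on the training subcorpora.
#' @param config A [tokenizer_config()].
#' @param chunk_size Tokens per chunk.
#' @param max_pairs_per_class Cap on pairs per class.
#' @param seed Integer seed for the subsampling.
#' @return Data frame with columns `delta`, `same_group` (0/1), `group_a`,
#'   `group_b`.
#' @export
make_pairs <- function(train, fs, config = tokenizer_config(),
                       chunk_size = 500L, max_pairs_per_class = 10000L,
                       seed = 1L) {
  cz <- chunk_group_z(train, fs, config, chunk_size)
  pairs_from_z(cz$z, cz$group, max_pairs_per_class, seed)
}

#' Fit the logistic delta-to-probability calibration
#'
#' Maximum-likelihood logistic regression of the same-group label on the
#' delta score. With `class_weighting` on, observation weights are
#' inversely proportional to class frequencies so both classes carry
#' equal total weight. On data where lower delta means same group, the
#' fitted slope is negative.
#'
#' @param samples Data frame with numeric `delta` and 0/1 `same_group`
#'   (see [make_pairs()]).
#' @param class_weighting Balance the two classes.
#' @return A `delta_calibration`: list with `intercept`, `slope`,
#'   `class_weighting`.
#' @export
fit_calibration <- function(samples, class_weighting = TRUE) {
  y <- samples$same_group
  x <- samples$delta
  if (!all(is.finite(x))) stop_domain("deltas must be finite")
  if (length(unique(y)) < 2) {
    stop_domain("calibration needs both same-group and different-group pairs")
  }
  w <- if (isTRUE(class_weighting)) {
    tab <- table(y)
    unname(length(y) / (2 * tab[as.character(y)]))
  } else {
    rep(1, length(y))
  }
  # quasibinomial gives the same IRLS coefficients as binomial while
  # accepting the fractional balancing weights without complaint;
  # separable data drives the MLE to the boundary, which is fine for
  # calibration use, so the convergence chatter is muffled
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::quasibinomial(), weights = w),
    warning = function(w_) {
      if (grepl("did not converge|numerically 0 or 1",
                conditionMessage(w_))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  co[is.na(co)] <- 0  # constant deltas: no slope estimable, treat as flat
  structure(list(intercept = unname(co[1L]),
                 slope = unname(co[2L]),
                 class_weighting = isTRUE(class_weighting)),
            class = "delta_calibration")
}

#' Same-group probability for delta scores
#'
#' @param object A `delta_calibration`.
#' @param delta Numeric vector (or matrix) of delta scores.
#' @param ... Unused.
#' @return Probabilities `1 / (1 + exp(-(intercept + slope * delta)))`,
#'   same shape as `delta`.
#' @export
predict.delta_calibration <- function(object, delta, ...) {
  stats::plogis(object$intercept + object$slope * delta)
}

#' @export
print.delta_calibration <- function(x, ...) {
  cat("<delta_calibration> p(same | delta) = plogis(",
      format(x$intercept, digits = 4), " + ", format(x$slope, digits = 4),
      " * delta), class_weighting=", x$class_weighting, "\n", sep = "")
  invisible(x)
}

#' Write a calibration model to a JSON sidecar
#'
#' @param model A `delta_calibration`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON (e.g. seed, k).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path, extra = list()) {
  jsonlite::write_json(c(list(intercept = model$intercept,
                              slope = model$slope,
                              class_weighting = model$class_weighting),
                         extra),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Calibrated probability matrix
#'
#' Applies the calibration elementwise to a delta matrix, giving the
#' probability that each test text (column) was written by each training
#' group (row).
#'
#' @param model A `delta_calibration`.
#' @param dm A `delta_matrix`.
#' @return Numeric matrix of probabilities with the same dimnames.
#' @export
probability_matrix <- function(model, dm) {
  p <- predict(model, unclass(dm))
  structure(p, class = c("probability_matrix", class(matrix())))
}

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney rank form: the probability that a random
#' positive scores above a random negative, ties counted 1/2 (equivalent
#' to trapezoidal integration of the ROC curve).
#'
#' @param labels 0/1 (or logical) vector; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))  # 0.75
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stop_domain("labels and scores must have equal length")
  }
  if (!all(labels %in% c(0L, 1L))) stop_domain("labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_domain("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Feature-type x k AUC sweep
#'
#' For each combination of feature type and feature count k: split the
#' corpus 80/20 by group (one split per sweep, seeded), select features
#' and fit the logistic calibration on training chunk pairs, then score
#' test chunk pairs and report the ROC AUC of the calibrated same-group
#' probability. Cells that cannot be computed are recorded with an `NA`
#' AUC and an explanatory note rather than dropped.
#'
#' @param posts A [post_collection()].
#' @param feature_types Subset of
#'   `c("token", "emotion", "token_pron", "emotion_pron")`.
#' @param k_values Integer vector of feature counts (default 50 to 500 by
#'   50).
#' @param train_fraction Train share of the split.
#' @param seed Integer seed driving the split and pair subsampling.
#' @param config A [tokenizer_config()].
#' @param stopwords,lexicon,pronouns Feature-pool inputs (see
#'   [select_features()]).
#' @param chunk_size,max_pairs_per_class Pair construction settings (see
#'   [make_pairs()]).
#' @param class_weighting Passed to [fit_calibration()].
#' @return Data frame (class `sweep_result`) with columns `feature_type`,
#'   `k`, `k_used`, `auc`, `n_pairs_train`, `n_pairs_test`, `note`.
#' @export
sweep_feature_grid <- function(posts,
                               feature_types = FEATURE_TYPES,
                               k_values = seq(50L, 500L, by = 50L),
                               train_fraction = 0.8,
                               seed = 1L,
                               config = tokenizer_config(),
                               stopwords = stopwords_en(),
                               lexicon = NULL,
                               pronouns = pronouns_en(),
                               chunk_size = 500L,
                               max_pairs_per_class = 10000L,
                               class_weighting = TRUE) {
  if (!length(k_values)) stop_domain("k_values must be non-empty")
  feature_types <- match.arg(feature_types, FEATURE_TYPES, several.ok = TRUE)
  sp <- split_train_test(posts, train_fraction, seed)
  train_sub <- build_subcorpora(sp$train, config)
  test_sub <- build_subcorpora(sp$test, config)

  split_chunks <- function(sub) {
    cl <- lapply(sub, chunk_tokens, chunk_size = chunk_size)
    list(chunks = unlist(cl, recursive = FALSE, use.names = FALSE),
         group = rep(names(cl), vapply(cl, length, integer(1))))
  }
  tr <- split_chunks(train_sub)
  te <- split_chunks(test_sub)

  rows <- list()
  cell <- 0L
  for (ft in feature_types) {
    fs_full <- tryCatch(
      suppressWarnings(select_features(train_sub, ft, k = max(k_values),
                                       stopwords = stopwords, lexicon = lexicon,
                                       pronouns = pronouns)),
      error = function(e) e)
    for (k in sort(k_values)) {
      cell <- cell + 1L
      row <- data.frame(feature_type = ft, k = as.integer(k),
                        k_used = NA_integer_, auc = NA_real_,
                        n_pairs_train = NA_integer_, n_pairs_test = NA_integer_,
                        note = "", stringsAsFactors = FALSE)
      if (inherits(fs_full, "error")) {
        row$note <- conditionMessage(fs_full)
        rows[[cell]] <- row
        next
      }
      kk <- min(k, fs_full$k)
      fs_k <- fs_full
      fs_k$features <- fs_full$features[seq_len(kk)]
      fs_k$mu <- fs_full$mu[seq_len(kk)]
      fs_k$sigma <- fs_full$sigma[seq_len(kk)]
      fs_k$k <- kk
      res <- tryCatch({
        z_tr <- profile_z_matrix(tr$chunks, fs_k)
        z_te <- profile_z_matrix(te$chunks, fs_k)
        ptr <- pairs_from_z(z_tr, tr$group, max_pairs_per_class, seed + cell)
        pte <- pairs_from_z(z_te, te$group, max_pairs_per_class,
                            seed + cell + 104729L)
        model <- fit_calibration(ptr, class_weighting = class_weighting)
        auc <- roc_auc(pte$same_group, predict(model, pte$delta))
        list(auc = auc, n_tr = nrow(ptr), n_te = nrow(pte))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$k_used <- kk
        row$note <- conditionMessage(res)
      } else {
        row$k_used <- kk
        row$auc <- res$auc
        row$n_pairs_train <- res$n_tr
        row$n_pairs_test <- res$n_te
        if (kk < k) row$note <- sprintf("saturated: only %d candidates", kk)
      }
      rows[[cell]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}
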