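# Overproduce-and-select ensemble machinery: a pool of CART base classifiers
# trained on bootstrap sub-samples, the correctness (vote) matrix on the
# pruning set, per-sample voting margins, and majority-vote prediction.

check_feature_frame <- function(data, require_label = TRUE) {
  if (!is.data.frame(data) || (require_label && !"label" %in% names(data))) {
    abort("`data` must be a data frame with a `label` column.",
          class = "msep_dimension_error")
  }
  labels <- if ("label" %in% names(data)) as.integer(data$label) else NULL
  if (!is.null(labels) && !all(labels %in% c(0L, 1L))) {
    abort("`label` must be binary 0/1.", class = "msep_config_error")
  }
  feats <- dplyr::select(data, -dplyr::any_of(c("label", "sample_id")))
  if (ncol(feats) < 1 || !all(purrr::map_lgl(feats, is.numeric))) {
    abort("`data` must contain at least one numeric feature column.",
          class = "msep_dimension_error")
  }
  list(features = as.data.frame(feats), labels = labels)
}

round_half_up <- function(x) floor(x + 0.5)

#' Train an overproduced pool of CART base classifiers
#'
#' Trains `M` decision trees (CART: Gini impurity, unpruned, minimum leaf
#' size 1), each on an independent bootstrap drawn with replacement of size
#' `round(sample_fraction * N)` from the training data. Per-tree seeds are
#' derived deterministically from the master seed, so the pool is fully
#' reproducible. A bootstrap that happens to contain a single class is
#' redrawn (up to 10 attempts).
#'
#' @param data Data frame with a binary `label` column (1 = positive) and
#'   numeric feature columns; an optional `sample_id` column is ignored.
#' @param M Odd number of base classifiers (default 101).
#' @param sample_fraction Bootstrap size as a fraction of the training set
#'   (default 0.3).
#' @param seed Master integer seed.
#' @return An object of class `ensemble_pool`.
#' @export
train_pool <- function(data, M = 101, sample_fraction = 0.3, seed = 1L) {
  if (M %% 2 == 0) {
    abort("`M` must be odd (avoids voting ties).", class = "msep_config_error")
  }
  if (sample_fraction <= 0 || sample_fraction > 1) {
    abort("`sample_fraction` must lie in (0, 1].", class = "msep_config_error")
  }
  parsed <- check_feature_frame(data)
  n <- length(parsed$labels)
  if (n < 2 || length(unique(parsed$labels)) < 2) {
    abort("Training data must contain both classes.",
          class = "msep_degenerate_data_error")
  }
  n_boot <- max(2L, as.integer(round_half_up(sample_fraction * n)))
  df <- parsed$features
  df$.label <- factor(parsed$labels, levels = c(0, 1))
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, M)
  ctrl <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                               maxdepth = 30, xval = 0)
  trees <- purrr::map(seq_len(M), function(j) {
    set.seed(tree_seeds[j])
    boot <- NULL
    for (attempt in seq_len(10)) {
      idx <- sample.int(n, n_boot, replace = TRUE)
      if (length(unique(parsed$labels[idx])) == 2) {
        boot <- df[idx, , drop = FALSE]
        break
      }
    }
    if (is.null(boot)) {
      abort("Could not draw a two-class bootstrap in 10 attempts.",
            class = "msep_degenerate_data_error")
    }
    rpart::rpart(.label ~ ., data = boot, method = "class",
                 parms = list(split = "gini"), control = ctrl)
  })
  structure(
    list(trees = trees, M = M, n_boot = n_boot,
         feature_names = names(parsed$features),
         tree_seeds = tree_seeds, seed = seed),
    class = "ensemble_pool"
  )
}

#' @export
print.ensemble_pool <- function(x, ...) {
  cat(sprintf("<ensemble_pool: %d CART learners, bootstrap size %d>\n",
              x$M, x$n_boot))
  invisible(x)
}

# Integer matrix (samples x learners) of 0/1 class predictions.
pool_predictions <- function(pool, data) {
  parsed <- check_feature_frame(data, require_label = FALSE)
  missing <- setdiff(pool$feature_names, names(parsed$features))
  if (length(missing) > 0) {
    abort(paste0("Feature columns missing from `data`: ",
                 paste(missing, collapse = ", ")),
          class = "msep_dimension_error")
  }
  newdf <- parsed$features[pool$feature_names]
  preds <- purrr::map(pool$trees, function(tr) {
    as.integer(as.character(predict(tr, newdata = newdf, type = "class")))
  })
  do.call(cbind, preds)
}

#' Compute the correctness (vote) matrix of a pool on a pruning set
#'
#' Entry (i, j) is 1 exactly when learner j's prediction equals the true
#' label of sample i.
#'
#' @param pool A trained [train_pool()] object.
#' @param data Pruning-set data frame (same layout as for [train_pool()]).
#' @return A [vote_matrix()] object.
#' @export
compute_vote_matrix <- function(pool, data) {
  parsed <- check_feature_frame(data)
  preds <- pool_predictions(pool, data)
  correct <- 1L * (preds == matrix(parsed$labels, nrow(preds), ncol(preds)))
  vote_matrix(correct, parsed$labels)
}

#' Per-sample voting margins of the full pool
#'
#' The margin of a sample is the fraction of correct votes minus the
#' fraction of incorrect votes over all M learners, a number in \[-1, 1\]
#' (never exactly 0 when M is odd). Also returns the pool-wide incorrect
#' fraction NF used by the MSM bonus term.
#'
#' @param votes A [vote_matrix()].
#' @return A tibble with columns `sample`, `margin` and `nf_pool`.
#' @export
compute_margins <- function(votes) {
  if (!inherits(votes, "vote_matrix") || nrow(votes$correct) == 0) {
    abort("`votes` must be a non-empty vote_matrix.",
          class = "msep_dimension_error")
  }
  frac_correct <- rowMeans(votes$correct)
  tibble(
    sample = seq_len(nrow(votes$correct)),
    margin = 2 * frac_correct - 1,
    nf_pool = 1 - frac_correct
  )
}

check_subset <- function(subset, M) {
  if (length(subset) == 0 || anyDuplicated(subset) ||
      any(subset < 1 | subset > M)) {
    abort("`subset` must be a non-empty set of distinct learner indices.",
          class = "msep_config_error")
  }
  if (length(subset) %% 2 == 0) {
    abort("`subset` must have odd size (avoids voting ties).",
          class = "msep_config_error")
  }
}

#' Predict by majority voting
#'
#' Majority vote of the pool's learners (or an odd-sized subset of them).
#' The score is the fraction of voting learners that predict class 1, used
#' as the AUC score.
#'
#' @param object A trained `ensemble_pool`.
#' @param data Data frame of features (a `label` column, if present, is
#'   ignored for prediction).
#' @param subset Optional vector of learner indices; defaults to all M.
#' @param ... Unused.
#' @return A tibble with columns `.pred_class` (integer 0/1) and
#'   `.pred_score` (fraction of votes for class 1).
#' @export
predict.ensemble_pool <- function(object, data, subset = NULL, ...) {
  if (is.null(subset)) subset <- seq_len(object$M)
  check_subset(subset, object$M)
  preds <- pool_predictions(object, data)[, subset, drop = FALSE]
  score <- rowMeans(preds)
  tibble(
    .pred_class = as.integer(score > 0.5),
    .pred_score = score
  )
}

#' Construct a pruned ensemble
#'
#' Binds a pool to an ordered selection of learner indices produced by a
#' pruning measure.
#'
#' @param pool A trained `ensemble_pool`.
#' @param selected Ordered vector of distinct learner indices (odd length).
#' @param measure Name of the measure that produced the selection.
#' @param marks Marks of the selected learners, in selection order.
#' @return An object of class `pruned_ensemble`.
#' @export
pruned_ensemble <- function(pool, selected, measure = "msm", marks = NULL) {
  check_subset(selected, pool$M)
  structure(
    list(pool = pool, selected = as.integer(selected),
         measure = measure, marks = marks),
    class = "pruned_ensemble"
  )
}

#' @export
print.pruned_ensemble <- function(x, ...) {
  cat(sprintf("<pruned_ensemble: %d of %d learners, measure %s>\n",
              length(x$selected), x$pool$M, x$measure))
  invisible(x)
}

#' @rdname predict.ensemble_pool
#' @export
predict.pruned_ensemble <- function(object, data, ...) {
  predict(object$pool, data, subset = object$selected)
}
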