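# Evaluation harness: the full overproduce-prune-vote pipeline on a single
# stratified train/prune/test split, repeated Monte-Carlo validation, the
# standard confusion metrics, rank-based AUC, and the rank-scoring rule for
# comparing models across metrics.

#' Confusion counts and accuracy / sensitivity / specificity
#'
#' Positive class is 1 throughout. Sensitivity is TP / (TP + FN) (the
#' complement of the missed-diagnosis rate), specificity TN / (FP + TN).
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' coerced to 0.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return A one-row tibble `tp`, `fp`, `tn`, `fn`, `acc`, `sen`, `spe`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must be non-empty and of equal length.",
          class = "msep_dimension_error")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    abort("Labels and predictions must be binary 0/1.",
          class = "msep_config_error")
  }
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = (tp + tn) / (tp + fp + tn + fn),
    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (fp + tn > 0) tn / (fp + tn) else NA_real_
  )
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from the rank statistic, with tied
#' scores counted half. Scores are typically the positive-vote fractions
#' from [predict.ensemble_pool()].
#'
#' @param y_true Binary (0/1) vector.
#' @param scores Numeric scores, higher meaning more positive.
#' @return The AUC, or `NA` (with a warning) if only one class is present.
#' @export
auc_score <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    abort("`y_true` and `scores` must have equal length.",
          class = "msep_dimension_error")
  }
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0 || n_neg == 0) {
    warn("AUC undefined: only one class present.")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified train/prune/test split
#'
#' Allocates each class across the three parts by largest-remainder rounding
#' of the ratio (preserving class proportions per part), then assigns
#' shuffled sample indices. The per-part class counts are deterministic
#' given the class sizes and ratio; if any part would receive zero samples
#' of some class, the split is degenerate and errors.
#'
#' @param labels Binary (0/1) label vector.
#' @param ratio Positive weights for train : prune : test (default 7:2:1).
#' @param seed Optional integer seed for the shuffle.
#' @return A list of integer index vectors `train`, `prune`, `test`.
#' @export
split_dataset <- function(labels, ratio = c(7, 2, 1), seed = NULL) {
  if (length(ratio) != 3 || any(ratio <= 0)) {
    abort("`ratio` must be three positive weights.", class = "msep_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- as.integer(labels)
  parts <- list(train = integer(0), prune = integer(0), test = integer(0))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    n_c <- length(idx)
    q <- n_c * ratio / sum(ratio)
    counts <- floor(q)
    rem <- n_c - sum(counts)
    if (rem > 0) {
      # round the fractional parts so float noise cannot decide exact ties
      frac <- round(q - counts, 9)
      give <- order(-frac, seq_along(q))[seq_len(rem)]
      counts[give] <- counts[give] + 1
    }
    if (any(counts == 0)) {
      abort(sprintf("Class %d too small for a three-way split.", cls),
            class = "msep_degenerate_data_error")
    }
    idx <- sample(idx)
    bounds <- cumsum(counts)
    parts$train <- c(parts$train, idx[seq_len(bounds[1])])
    parts$prune <- c(parts$prune, idx[(bounds[1] + 1):bounds[2]])
    parts$test <- c(parts$test, idx[(bounds[2] + 1):bounds[3]])
  }
  lapply(parts, sort)
}

#' Run the overproduce-prune-vote pipeline on one split
#'
#' Splits the data into stratified train/prune/test parts, trains the pool
#' of `M` bagged CARTs on the training part, computes the vote matrix and
#' margins on the pruning part, ranks (or greedily selects) classifiers
#' under the chosen measure, keeps the top `T`, and evaluates the pruned
#' ensemble by majority voting on the test part.
#'
#' @param data Data frame with a binary `label` column and numeric feature
#'   columns.
#' @param M Odd pool size (default 101).
#' @param T Odd pruned-ensemble size (default 11, about 10% of the pool).
#' @param measure One of `"msm"`, `"mep"`, `"umep"`, `"mdm"`, `"sdacc"`.
#' @param theta MSM margin threshold in \[-1, 0\].
#' @param alpha MDM margin/diversity trade-off in \[0, 1\].
#' @param sample_fraction Bootstrap size fraction for [train_pool()].
#' @param ratio Train : prune : test weights (default 7:2:1).
#' @param seed Integer seed controlling the split and the pool.
#' @return An object of class `msep_result`: list with `pruned` (a
#'   [pruned_ensemble()]), `metrics` (one-row tibble with acc/sen/spe/auc),
#'   `ranking` (the measure ranking, `NULL` for sdacc) and `split`.
#' @export
run_msep <- function(data, M = 101, T = 11, measure = "msm", theta = -0.8,
                     alpha = 0.5, sample_fraction = 0.3, ratio = c(7, 2, 1),
                     seed = 1L) {
  measure <- match.arg(measure, measure_names)
  if (T > M) abort("`T` cannot exceed `M`.", class = "msep_config_error")
  parsed <- check_feature_frame(data)
  set.seed(seed)
  split <- split_dataset(parsed$labels, ratio)
  pool_seed <- sample.int(.Machine$integer.max - 1L, 1)
  pool <- train_pool(data[split$train, , drop = FALSE], M = M,
                     sample_fraction = sample_fraction, seed = pool_seed)
  votes <- compute_vote_matrix(pool, data[split$prune, , drop = FALSE])
  sel <- select_classifiers(votes, T, measure = measure, theta = theta,
                            alpha = alpha)
  pruned <- pruned_ensemble(pool, sel$selected, measure = sel$measure,
                            marks = sel$marks)
  test_data <- data[split$test, , drop = FALSE]
  pred <- predict(pruned, test_data)
  y_te <- parsed$labels[split$test]
  metrics <- dplyr::bind_cols(
    confusion_metrics(y_te, pred$.pred_class),
    tibble(auc = auc_score(y_te, pred$.pred_score))
  )
  structure(
    list(pruned = pruned, metrics = metrics, ranking = sel$ranking,
         votes = votes, split = split, measure = measure, seed = seed),
    class = "msep_result"
  )
}

#' @export
print.msep_result <- function(x, ...) {
  cat(sprintf("<msep_result: measure %s, %d of %d learners>\n",
              x$measure, length(x$pruned$selected), x$pruned$pool$M))
  print(x$metrics)
  invisible(x)
}

#' Repeated stratified-split validation
#'
#' Runs [run_msep()] on `repetitions` independent stratified random
#' train/prune/test splits (Monte-Carlo validation) and aggregates the mean
#' and standard deviation of each metric. Undefined metrics (empty
#' denominators) are excluded from the aggregation rather than coerced to 0.
#'
#' @inheritParams run_msep
#' @param repetitions Number of independent splits (default 50).
#' @return An object of class `metrics_report`: list with `per_rep` (tibble
#'   of per-repetition metrics) and `summary` (tibble `metric`, `mean`,
#'   `sd`).
#' @export
cross_validate <- function(data, repetitions = 50, M = 101, T = 11,
                           measure = "msm", theta = -0.8, alpha = 0.5,
                           sample_fraction = 0.3, ratio = c(7, 2, 1),
                           seed = 1L) {
  if (repetitions < 1) {
    abort("`repetitions` must be >= 1.", class = "msep_config_error")
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  per_rep <- purrr::map_dfr(seq_len(repetitions), function(r) {
    res <- run_msep(data, M = M, T = T, measure = measure, theta = theta,
                    alpha = alpha, sample_fraction = sample_fraction,
                    ratio = ratio, seed = rep_seeds[r])
    dplyr::bind_cols(tibble(rep = r), res$metrics)
  })
  structure(
    list(per_rep = per_rep, summary = summarize_metrics(per_rep),
         measure = measure, repetitions = repetitions, seed = seed),
    class = "metrics_report"
  )
}

summarize_metrics <- function(per_rep) {
  per_rep |>
    dplyr::select(dplyr::any_of(c("acc", "sen", "spe", "auc"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n_defined = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$metric, c("acc", "sen", "spe", "auc")))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: measure %s, %d repetitions>\n",
              x$measure, x$repetitions))
  print(x$summary)
  invisible(x)
}

#' Compare pruning measures on shared pools
#'
#' For each repetition, draws one stratified split and trains one pool, then
#' evaluates every requested measure's pruned ensemble (and optionally the
#' complete unpruned ensemble, `"full"`) on the same test part — the
#' protocol for ablation studies such as MSM versus its margin-only MEP
#' variant.
#'
#' @inheritParams cross_validate
#' @param measures Character vector drawn from `"msm"`, `"mep"`, `"umep"`,
#'   `"mdm"`, `"sdacc"`, `"full"`.
#' @return An object of class `measure_comparison`: list with `per_rep`
#'   (tibble `rep`, `measure`, metrics) and `summary` (per-measure means and
#'   sds).
#' @export
compare_measures <- function(data, measures = c("msm", "mep"),
                             repetitions = 50, M = 101, T = 11, theta = -0.8,
                             alpha = 0.5, sample_fraction = 0.3,
                             ratio = c(7, 2, 1), seed = 1L) {
  ok <- c(measure_names, "full")
  if (!all(measures %in% ok)) {
    abort(paste0("`measures` must be drawn from: ", paste(ok, collapse = ", ")),
          class = "msep_config_error")
  }
  parsed <- check_feature_frame(data)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  per_rep <- purrr::map_dfr(seq_len(repetitions), function(r) {
    set.seed(rep_seeds[r])
    split <- split_dataset(parsed$labels, ratio)
    pool_seed <- sample.int(.Machine$integer.max - 1L, 1)
    pool <- train_pool(data[split$train, , drop = FALSE], M = M,
                       sample_fraction = sample_fraction, seed = pool_seed)
    votes <- compute_vote_matrix(pool, data[split$prune, , drop = FALSE])
    test_data <- data[split$test, , drop = FALSE]
    y_te <- parsed$labels[split$test]
    purrr::map_dfr(measures, function(ms) {
      subset <- if (ms == "full") {
        seq_len(M)
      } else {
        select_classifiers(votes, T, measure = ms, theta = theta,
                           alpha = alpha)$selected
      }
      pred <- predict(pool, test_data, subset = subset)
      dplyr::bind_cols(
        tibble(rep = r, measure = ms),
        confusion_metrics(y_te, pred$.pred_class),
        tibble(auc = auc_score(y_te, pred$.pred_score))
      )
    })
  })
  summary <- per_rep |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("acc", "sen", "spe", "auc")),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop"
    )
  structure(
    list(per_rep = per_rep, summary = summary, repetitions = repetitions,
         seed = seed),
    class = "measure_comparison"
  )
}

#' @export
print.measure_comparison <- function(x, ...) {
  cat(sprintf("<measure_comparison: %d repetitions>\n", x$repetitions))
  print(x$summary)
  invisible(x)
}

#' Rank-scoring comparison of models across metrics
#'
#' For each metric column, the model with the highest value receives as many
#' points as there are models, the next one fewer, and so on; tied models
#' share the mean of the points they would jointly occupy. The average of a
#' model's points across metrics summarises its overall standing.
#'
#' @param metric_table Data frame with a `model` column and one numeric
#'   column per metric (higher is better).
#' @return A tibble with `model`, one `<metric>_points` column per metric,
#'   and `average` (mean of the points over metrics, missing values excluded
#'   pairwise with a warning).
#' @export
rank_scores <- function(metric_table) {
  if (!is.data.frame(metric_table) || !"model" %in% names(metric_table) ||
      nrow(metric_table) < 2) {
    abort("`metric_table` must be a data frame with a `model` column and >= 2 rows.",
          class = "msep_config_error")
  }
  metrics <- dplyr::select(metric_table, -dplyr::all_of("model"))
  if (ncol(metrics) < 1 || !all(purrr::map_lgl(metrics, is.numeric))) {
    abort("All metric columns must be numeric.", class = "msep_config_error")
  }
  n <- nrow(metric_table)
  if (anyNA(metrics)) {
    warn("Missing metric values excluded pairwise from rank scoring.")
  }
  pts <- purrr::map(metrics, function(x) {
    out <- rep(NA_real_, n)
    ok <- !is.na(x)
    # best defined model gets n points; ties share the mean of their slots
    r <- rank(-x[ok], ties.method = "average")
    out[ok] <- n + 1 - r
    out
  })
  names(pts) <- paste0(names(metrics), "_points")
  out <- dplyr::bind_cols(tibble(model = metric_table$model), as_tibble(pts))
  out$average <- rowMeans(as.matrix(as_tibble(pts)), na.rm = TRUE)
  out
}
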