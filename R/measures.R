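# Pruning measures: per-classifier marks over the pruning-set vote matrix.
#
# All ordering measures share the same shape: a classifier's mark is a sum
# over pruning samples it classifies correctly, weighted by a per-sample
# importance derived from the voting margin. Rankings are descending by
# mark with ties broken by ascending classifier index (stable, deterministic).

new_measure_ranking <- function(marks, measure, config = list()) {
  M <- length(marks)
  ord <- order(-marks, seq_len(M))
  rank <- integer(M)
  rank[ord] <- seq_len(M)
  out <- tibble(classifier = seq_len(M), mark = as.numeric(marks), rank = rank)
  attr(out, "measure") <- measure
  attr(out, "config") <- config
  class(out) <- c("measure_ranking", class(out))
  out
}

#' Top-T classifiers of a ranking
#'
#' @param ranking A `measure_ranking` from one of the `*_scores()` functions.
#' @param T Odd number of classifiers to keep.
#' @return Integer vector of the selected classifier indices, best first.
#' @export
top_classifiers <- function(ranking, T) {
  M <- nrow(ranking)
  if (T > M) abort("`T` cannot exceed the pool size.", class = "msep_config_error")
  if (T %% 2 == 0) abort("`T` must be odd.", class = "msep_config_error")
  ranking$classifier[order(ranking$rank)][seq_len(T)]
}

check_votes_margins <- function(votes, margins) {
  if (!inherits(votes, "vote_matrix")) {
    abort("`votes` must be a vote_matrix.", class = "msep_dimension_error")
  }
  if (nrow(margins) != nrow(votes$correct)) {
    abort("`margins` must have one row per pruning sample.",
          class = "msep_dimension_error")
  }
}

#' Margin and sensitivity based measure (MSM)
#'
#' Scores classifier j as the average, over pruning samples it classifies
#' correctly whose margin exceeds the threshold `theta`, of
#' `exp(y_i * NF_i) * exp(-margin_i)`: samples with many incorrect votes
#' (small margin) contribute more, and correct decisions on positive
#' (disease) samples earn an extra exponential bonus that grows with the
#' fraction of the pool that got the sample wrong. With `bonus = FALSE` the
#' bonus factor is 1, giving the margin-only ablation (MEP).
#'
#' @param votes A [vote_matrix()].
#' @param theta Margin threshold in \[-1, 0\]; samples with margin <= theta
#'   are treated as outliers and excluded (strict inequality retains
#'   margin > theta).
#' @param bonus Include the sensitivity bonus term (`FALSE` gives MEP).
#' @param margins Optional precomputed [compute_margins()] table.
#' @return A `measure_ranking` tibble (`classifier`, `mark`, `rank`).
#' @export
msm_scores <- function(votes, theta = -0.8, bonus = TRUE,
                       margins = compute_margins(votes)) {
  if (theta < -1 || theta > 0) {
    abort("`theta` must lie in [-1, 0].", class = "msep_config_error")
  }
  check_votes_margins(votes, margins)
  m <- margins$margin
  nf <- margins$nf_pool
  y <- votes$labels
  bonus_term <- if (bonus) exp(y * nf) else rep(1, length(y))
  w <- (m > theta) * bonus_term * exp(-m)
  marks <- as.numeric(crossprod(votes$correct, w)) / nrow(votes$correct)
  new_measure_ranking(marks, if (bonus) "msm" else "mep",
                      list(theta = theta, bonus = bonus))
}

#' Unsupervised margin based measure (UMEP)
#'
#' Scores classifier j by summing `-log(margin_i)` over pruning samples it
#' classifies correctly that have a strictly positive margin, normalised by
#' the pruning-set size; samples with non-positive margin are neglected
#' entirely.
#'
#' @inheritParams msm_scores
#' @return A `measure_ranking` tibble.
#' @export
umep_scores <- function(votes, margins = compute_margins(votes)) {
  check_votes_margins(votes, margins)
  m <- margins$margin
  w <- ifelse(m > 0, -log(pmax(m, .Machine$double.eps)), 0)
  marks <- as.numeric(crossprod(votes$correct, w)) / nrow(votes$correct)
  new_measure_ranking(marks, "umep", list())
}

#' Margin and diversity based measure (MDM)
#'
#' Scores classifier j by summing, over samples it classifies correctly,
#' a convex combination `alpha * f_m + (1 - alpha) * f_d` of a margin term
#' `f_m = -log(max(|margin_i|, epsilon))` and a diversity term
#' `f_d = -log(fraction of the pool correct on i)`.
#'
#' @inheritParams msm_scores
#' @param alpha Trade-off between margin and diversity terms, in \[0, 1\].
#' @param epsilon Clamp for `|margin|` inside the log (defaults to 1/M).
#' @return A `measure_ranking` tibble.
#' @export
mdm_scores <- function(votes, alpha = 0.5, epsilon = NULL,
                       margins = compute_margins(votes)) {
  if (alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1].", class = "msep_config_error")
  }
  check_votes_margins(votes, margins)
  M <- ncol(votes$correct)
  if (is.null(epsilon)) epsilon <- 1 / M
  m <- margins$margin
  f_m <- -log(pmax(abs(m), epsilon))
  f_d <- -log(pmax(1 - margins$nf_pool, 1 / M))
  w <- alpha * f_m + (1 - alpha) * f_d
  marks <- as.numeric(crossprod(votes$correct, w))
  new_measure_ranking(marks, "mdm", list(alpha = alpha, epsilon = epsilon))
}

#' Per-sample SDAcc mark for one event
#'
#' The simultaneous diversity and accuracy measure assigns, per pruning
#' sample, a mark to a candidate classifier according to which of four
#' events holds (classifier correct? current sub-ensemble correct?): correct
#' classifiers earn `+NF` (the sub-ensemble's incorrect fraction) in both
#' e10 and e11; an incorrect classifier loses `NF` when the sub-ensemble is
#' right (e01) and loses `NT` (the correct fraction) when both are wrong
#' (e00).
#'
#' @param event One of `"e00"`, `"e01"`, `"e10"`, `"e11"`; the first digit
#'   is the classifier's correctness, the second the sub-ensemble's.
#' @param nt_sub,nf_sub Correct and incorrect vote fractions of the current
#'   sub-ensemble on the sample; must sum to 1.
#' @return The numeric mark (vectorised over `nt_sub`/`nf_sub`).
#' @examples
#' sdacc_mark("e01", nt_sub = 0.8, nf_sub = 0.2) # -0.2
#' @export
sdacc_mark <- function(event, nt_sub, nf_sub) {
  event <- match.arg(event, c("e00", "e01", "e10", "e11"))
  if (any(nt_sub < 0 | nt_sub > 1 | nf_sub < 0 | nf_sub > 1) ||
      any(abs(nt_sub + nf_sub - 1) > 1e-8)) {
    abort("`nt_sub` and `nf_sub` must lie in [0, 1] and sum to 1.",
          class = "msep_consistency_error")
  }
  switch(event,
    e10 = nf_sub,
    e11 = nf_sub,
    e01 = -nf_sub,
    e00 = -nt_sub
  )
}

#' Greedy forward selection under the SDAcc measure
#'
#' Seeds the sub-ensemble with the individually most accurate classifier on
#' the pruning set (ties broken by lowest index), then repeatedly adds the
#' candidate maximising the summed [sdacc_mark()] over all pruning samples,
#' with events evaluated against the current sub-ensemble's majority vote
#' (an exactly split sub-ensemble counts as incorrect), until `T` learners
#' are selected.
#'
#' @param votes A [vote_matrix()].
#' @param T Odd target sub-ensemble size, at most the pool size.
#' @return A list with `selected` (ordered indices), `measure` ("sdacc")
#'   and `marks` (each learner's objective value when it was added).
#' @export
sdacc_greedy_select <- function(votes, T) {
  if (!inherits(votes, "vote_matrix")) {
    abort("`votes` must be a vote_matrix.", class = "msep_dimension_error")
  }
  C <- votes$correct
  M <- ncol(C)
  if (T > M) abort("`T` cannot exceed the pool size.", class = "msep_config_error")
  if (T %% 2 == 0) abort("`T` must be odd.", class = "msep_config_error")
  acc <- colMeans(C)
  sel <- which.max(acc) # ties -> lowest index
  marks <- acc[sel]
  while (length(sel) < T) {
    nt <- rowMeans(C[, sel, drop = FALSE])
    nf <- 1 - nt
    s_correct <- nt > 0.5
    # correct candidate earns +nf in both e10/e11; wrong one loses nf (e01)
    # or nt (e00) depending on the sub-ensemble's own correctness
    wrong_penalty <- ifelse(s_correct, nf, nt)
    cand <- setdiff(seq_len(M), sel)
    Cc <- C[, cand, drop = FALSE]
    scores <- as.numeric(crossprod(Cc, nf) - crossprod(1 - Cc, wrong_penalty))
    best <- which.max(scores)
    sel <- c(sel, cand[best])
    marks <- c(marks, scores[best])
  }
  list(selected = as.integer(sel), measure = "sdacc", marks = as.numeric(marks))
}

measure_names <- c("msm", "mep", "umep", "mdm", "sdacc")

# Dispatch helper: selection of T learners from a vote matrix under any
# supported measure.
select_classifiers <- function(votes, T, measure = "msm", theta = -0.8,
                               alpha = 0.5) {
  measure <- match.arg(measure, measure_names)
  if (measure == "sdacc") {
    g <- sdacc_greedy_select(votes, T)
    return(list(selected = g$selected, marks = g$marks, measure = measure,
                ranking = NULL))
  }
  ranking <- switch(measure,
    msm = msm_scores(votes, theta = theta, bonus = TRUE),
    mep = msm_scores(votes, theta = theta, bonus = FALSE),
    umep = umep_scores(votes),
    mdm = mdm_scores(votes, alpha = alpha)
  )
  sel <- top_classifiers(ranking, T)
  list(selected = sel, marks = ranking$mark[sel], measure = measure,
       ranking = ranking)
}
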