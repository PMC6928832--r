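# Independent brute-force oracles used across the suite. These deliberately
# use naive loops and stay independent of the package's vectorised code
# paths.

# Nearest-centroid rule trained and evaluated on the same flattened signals.
centroid_train_acc <- function(X, y) {
  c0 <- colMeans(X[y == 0, , drop = FALSE])
  c1 <- colMeans(X[y == 1, , drop = FALSE])
  pred <- as.integer(rowSums(sweep(X, 2, c1)^2) < rowSums(sweep(X, 2, c0)^2))
  mean(pred == y)
}

# Same rule with odd/even split so accuracy reflects generalisation.
centroid_holdout_acc <- function(X, y) {
  n <- nrow(X)
  tr <- seq(1, n, by = 2)
  te <- setdiff(seq_len(n), tr)
  c0 <- colMeans(X[tr, , drop = FALSE][y[tr] == 0, , drop = FALSE])
  c1 <- colMeans(X[tr, , drop = FALSE][y[tr] == 1, , drop = FALSE])
  pred <- as.integer(rowSums(sweep(X[te, , drop = FALSE], 2, c1)^2) <
                       rowSums(sweep(X[te, , drop = FALSE], 2, c0)^2))
  mean(pred == y[te])
}

# Per-learner correctness recount by explicit loops.
naive_vote_matrix <- function(pool, data) {
  labels <- as.integer(data$label)
  out <- matrix(NA_integer_, nrow(data), pool$M)
  newdf <- as.data.frame(data[, pool$feature_names, drop = FALSE])
  for (j in seq_len(pool$M)) {
    pj <- as.integer(as.character(
      predict(pool$trees[[j]], newdata = newdf, type = "class")
    ))
    for (i in seq_len(nrow(data))) out[i, j] <- as.integer(pj[i] == labels[i])
  }
  out
}

# Naive greedy forward selection under the SDAcc marking scheme.
naive_sdacc_greedy <- function(C, T) {
  M <- ncol(C)
  acc <- colMeans(C)
  sel <- which(acc == max(acc))[1]
  while (length(sel) < T) {
    nt <- rowMeans(C[, sel, drop = FALSE])
    nf <- 1 - nt
    s_ok <- nt > 0.5
    best <- NA
    best_score <- -Inf
    for (j in setdiff(seq_len(M), sel)) {
      score <- 0
      for (i in seq_len(nrow(C))) {
        if (C[i, j] == 1) {
          score <- score + nf[i] # e10 and e11 both reward NF
        } else if (s_ok[i]) {
          score <- score - nf[i] # e01
        } else {
          score <- score - nt[i] # e00
        }
      }
      if (score > best_score) {
        best_score <- score
        best <- j
      }
    }
    sel <- c(sel, best)
  }
  sel
}

# Step-by-step re-execution of the ordering-pruning loop: per classifier,
# accumulate the margin/sensitivity mark sample by sample, then rank.
naive_msep_select <- function(C, y, T, theta = -0.8, bonus = TRUE) {
  M <- ncol(C)
  N <- nrow(C)
  marks <- numeric(M)
  for (j in seq_len(M)) {
    acc <- 0
    for (i in seq_len(N)) {
      margin_i <- (sum(C[i, ]) - sum(1 - C[i, ])) / M
      if (C[i, j] == 1 && margin_i > theta) {
        nf_i <- sum(1 - C[i, ]) / M
        b <- if (bonus) exp(y[i] * nf_i) else 1
        acc <- acc + b * exp(-margin_i)
      }
    }
    marks[j] <- acc / N
  }
  ord <- order(-marks, seq_len(M))
  ord[seq_len(T)]
}

# AUC by brute force over all positive-negative pairs, ties counted half.
pair_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small two-class feature set for ensemble tests: noisy Gaussian clusters.
gaussian_features <- function(n_per_class = 40, p = 6, shift = 1.5, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n_per_class)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  X[y == 1, ] <- X[y == 1, ] + shift
  colnames(X) <- paste0("x", seq_len(p))
  dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(X))
}

# Perfectly separable noiseless features (one informative column).
separable_features <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n_per_class)
  tibble::tibble(
    label = y,
    x1 = ifelse(y == 1, 2, -2) + runif(2 * n_per_class, -0.1, 0.1),
    x2 = rnorm(2 * n_per_class)
  )
}
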