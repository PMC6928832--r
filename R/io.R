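# Readers and writers for the package's tabular interchange formats:
# long-format CSV for sensor samples, headerless 0/1 CSV plus a sidecar
# labels file for vote matrices, CSV for feature tables and rankings, and a
# serialised container for sample sets and pools.

#' Write / read sensor samples as long-format CSV
#'
#' One row per (sample, channel, time) observation with columns
#' `sample_id`, `label`, `channel`, `t`, `value`.
#'
#' @param samples Sample tibble from [simulate_breath_samples()].
#' @param path CSV file path.
#' @return `write_samples_csv()` returns `path` invisibly;
#'   `read_samples_csv()` returns the reconstructed sample tibble.
#' @export
write_samples_csv <- function(samples, path) {
  long <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    sig <- samples$signal[[i]]
    tibble(
      sample_id = samples$sample_id[i],
      label = samples$label[i],
      channel = rep(seq_len(nrow(sig)), times = ncol(sig)),
      t = rep(seq_len(ncol(sig)), each = nrow(sig)),
      value = as.vector(sig)
    )
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    label = readr::col_integer(),
    channel = readr::col_integer(),
    t = readr::col_integer(),
    value = readr::col_double()
  ))
  ids <- unique(long$sample_id)
  rows <- purrr::map(ids, function(id) {
    sub <- long[long$sample_id == id, ]
    n_channels <- max(sub$channel)
    n_timesteps <- max(sub$t)
    sig <- matrix(NA_real_, n_channels, n_timesteps)
    sig[cbind(sub$channel, sub$t)] <- sub$value
    list(label = sub$label[1], signal = sig)
  })
  tibble(
    sample_id = ids,
    label = purrr::map_int(rows, "label"),
    signal = purrr::map(rows, "signal")
  )
}

#' Write / read sensor samples as a serialised container
#'
#' Compact single-file alternative to the long CSV for large sample sets.
#'
#' @inheritParams write_samples_csv
#' @param path File path (`.rds`).
#' @export
write_samples_rds <- function(samples, path) {
  saveRDS(samples, path)
  invisible(path)
}

#' @rdname write_samples_rds
#' @export
read_samples_rds <- function(path) {
  readRDS(path)
}

#' Write / read a vote matrix as headerless CSV
#'
#' The correctness matrix is written as a headerless CSV of 0/1 values; the
#' pruning-set labels go to a sidecar single-column file (default
#' `<path>.labels`).
#'
#' @param votes A [vote_matrix()].
#' @param path CSV file path for the 0/1 matrix.
#' @param labels_path Sidecar file path for the labels column.
#' @export
write_vote_csv <- function(votes, path, labels_path = paste0(path, ".labels")) {
  utils::write.table(votes$correct, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(votes$labels, labels_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_vote_csv
#' @export
read_vote_csv <- function(path, labels_path = paste0(path, ".labels")) {
  correct <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(correct) <- NULL
  labels <- utils::read.table(labels_path, header = FALSE)[[1]]
  vote_matrix(correct, labels)
}

#' Write a measure ranking as CSV
#'
#' Columns `rank`, `classifier`, `mark`, `measure`.
#'
#' @param ranking A `measure_ranking`.
#' @param path CSV file path.
#' @export
write_ranking_csv <- function(ranking, path) {
  out <- ranking |>
    dplyr::arrange(.data$rank) |>
    dplyr::mutate(measure = attr(ranking, "measure")) |>
    dplyr::select(dplyr::all_of(c("rank", "classifier", "mark", "measure")))
  readr::write_csv(out, path)
  invisible(path)
}

#' Save or load a trained ensemble pool
#'
#' @param pool A trained [train_pool()] object.
#' @param path File path (`.rds`).
#' @export
save_pool <- function(pool, path) {
  if (!inherits(pool, "ensemble_pool")) {
    abort("`pool` must be an ensemble_pool.", class = "msep_config_error")
  }
  saveRDS(pool, path)
  invisible(path)
}

#' @rdname save_pool
#' @export
load_pool <- function(path) {
  pool <- readRDS(path)
  if (!inherits(pool, "ensemble_pool")) {
    abort("File does not contain an ensemble_pool.", class = "msep_config_error")
  }
  pool
}
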