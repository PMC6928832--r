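# Broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a measure ranking
#'
#' @param x A `measure_ranking`.
#' @param ... Unused.
#' @return A tibble `classifier`, `mark`, `rank`, `measure`, ordered by rank.
#' @export
tidy.measure_ranking <- function(x, ...) {
  as_tibble(x) |>
    dplyr::mutate(measure = attr(x, "measure")) |>
    dplyr::arrange(.data$rank)
}

#' Tidy / summarise an autoencoder fit
#'
#' `tidy()` returns the per-epoch training curve; `glance()` a one-row
#' summary.
#'
#' @param x A fitted `gru_autoencoder`.
#' @param ... Unused.
#' @export
tidy.gru_autoencoder <- function(x, ...) {
  tibble(epoch = seq_along(x$training_history), mse = x$training_history)
}

#' @rdname tidy.gru_autoencoder
#' @export
glance.gru_autoencoder <- function(x, ...) {
  tibble(
    latent_dim = x$latent_dim,
    n_channels = x$input_dims[["n_channels"]],
    n_timesteps = x$input_dims[["n_timesteps"]],
    epochs = length(x$training_history),
    final_mse = x$training_history[length(x$training_history)]
  )
}

#' Tidy / summarise a repeated-validation report
#'
#' `tidy()` returns per-repetition metrics in long form; `glance()` the
#' mean/sd summary in wide form.
#'
#' @param x A `metrics_report` from [cross_validate()].
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_rep |>
    tidyr::pivot_longer(dplyr::all_of(c("acc", "sen", "spe", "auc")),
                        names_to = "metric")
}

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"),
                       id_cols = character(0))
  dplyr::bind_cols(tibble(measure = x$measure, repetitions = x$repetitions),
                   wide)
}

#' Tidy an end-to-end pipeline result
#'
#' @param x An `msep_result` from [run_msep()].
#' @param ... Unused.
#' @return One row per selected learner with its mark and selection order.
#' @export
tidy.msep_result <- function(x, ...) {
  tibble(
    order = seq_along(x$pruned$selected),
    classifier = x$pruned$selected,
    mark = if (is.null(x$pruned$marks)) NA_real_ else x$pruned$marks,
    measure = x$measure
  )
}

#' @rdname tidy.msep_result
#' @export
glance.msep_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(measure = x$measure, M = x$pruned$pool$M,
           T = length(x$pruned$selected)),
    x$metrics
  )
}

#' Plot a sample set's response curves
#'
#' Draws the per-channel transients, faceted by channel and coloured by
#' class label.
#'
#' @param samples Sample tibble from [simulate_breath_samples()].
#' @param max_samples Cap on the number of samples drawn per class.
#' @return A ggplot object.
#' @export
plot_samples <- function(samples, max_samples = 5) {
  keep <- samples |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = max_samples) |>
    dplyr::ungroup()
  long <- purrr::map_dfr(seq_len(nrow(keep)), function(i) {
    sig <- keep$signal[[i]]
    tibble(
      sample_id = keep$sample_id[i],
      label = factor(keep$label[i]),
      channel = rep(seq_len(nrow(sig)), times = ncol(sig)),
      t = rep(seq_len(ncol(sig)), each = nrow(sig)),
      value = as.vector(sig)
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     group = .data$sample_id,
                                     colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time step", y = "sensor response", colour = "class")
}

#' @export
autoplot.gru_autoencoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean reconstruction error")
}

#' @export
autoplot.measure_ranking <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$rank, y = .data$mark)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "rank", y = "mark",
                  title = paste("measure:", attr(object, "measure")))
}

#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "value per repetition")
}

#' @export
autoplot.measure_comparison <- function(object, ...) {
  long <- object$per_rep |>
    tidyr::pivot_longer(dplyr::all_of(c("acc", "sen", "spe", "auc")),
                        names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "value per repetition")
}
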