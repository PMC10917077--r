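#' Tidy a contrastive-embedding fit
#'
#' One row per training epoch with the mean balanced InfoNCE loss.
#' @param x A `po2vec_fit`.
#' @param ... Unused.
#' @return A tibble `epoch`, `mean_loss`.
#' @export
tidy.po2vec_fit <- function(x, ...) x$history

#' @rdname tidy.po2vec_fit
#' @export
glance.po2vec_fit <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$embedding),
    d_prime = ncol(x$embedding),
    epochs = nrow(x$history),
    initial_loss = x$history$mean_loss[[1]],
    final_loss = x$history$mean_loss[[nrow(x$history)]],
    tau = x$config$tau,
    k = x$sampler_config$k,
    u = x$sampler_config$u
  )
}

#' Tidy a joint-predictor fit
#' @param x A `po2go_model`.
#' @param ... Unused.
#' @return A tibble `epoch`, `mean_loss`.
#' @export
tidy.po2go_model <- function(x, ...) x$history

#' @rdname tidy.po2go_model
#' @export
glance.po2go_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$term_ids),
    protein_dim = x$d,
    hidden = x$config$hidden,
    h = x$config$h,
    epochs = nrow(x$history),
    frozen_terms = x$config$freeze_terms,
    final_loss = x$history$mean_loss[[nrow(x$history)]]
  )
}

#' Generic tidy/glance (exported so the package works without broom)
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Training-history plot
#' @param object A `po2vec_fit` or `po2go_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.po2vec_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean balanced InfoNCE loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.po2vec_fit
#' @export
autoplot.po2go_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean BCE loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Similarity-distribution plot
#'
#' Overlaid densities of two labelled similarity samples (e.g. ancestor vs
#' non-ancestor) with their 1-Wasserstein distance in the subtitle.
#'
#' @param a,b `similarity_sample` objects.
#' @return A ggplot.
#' @export
plot_similarity_samples <- function(a, b) {
  df <- rbind(
    data.frame(value = a$values, label = a$label),
    data.frame(value = b$values, label = b$label)
  )
  w <- wasserstein_1(a, b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "cosine similarity",
                  subtitle = sprintf("1-Wasserstein distance = %.3f", w)) +
    ggplot2::theme_minimal()
}
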