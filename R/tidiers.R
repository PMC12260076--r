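# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the iteration history of a fitted run
#'
#' @param x A `genaug_fit`.
#' @param ... Unused.
#' @return Tibble with one row per iteration: recorded losses and the
#'   segmenter learning rate.
#' @exportS3Method generics::tidy
tidy.genaug_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted run
#'
#' @param x A `genaug_fit`.
#' @param ... Unused.
#' @return Tibble with the method, iteration count, checkpoint metric and
#'   iteration, and final architecture entropy (mean over cells).
#' @exportS3Method generics::glance
glance.genaug_fit <- function(x, ...) {
  a <- alphas_of(x$arch)
  ent <- mean(apply(a, 2L, function(p) -sum(p * log(pmax(p, 1e-12)))))
  tibble::tibble(method = x$method,
                 iterations = max(x$history$iteration),
                 metric = x$config$metric,
                 best_val = x$best$metric,
                 best_iteration = x$best$iteration,
                 arch_entropy = ent)
}

#' @exportS3Method generics::tidy
tidy.seg_evaluation <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.seg_evaluation <- function(x, ...) {
  tibble::tibble(metric = x$metric, mean = x$mean, n = nrow(x$scores))
}

#' Plot training and validation trajectories
#'
#' @param object A `genaug_fit`.
#' @param ... Unused.
#' @return A ggplot: recorded losses over iterations with the validation
#'   metric overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.genaug_fit <- function(object, ...) {
  h <- object$history
  keep <- intersect(c("l_gan", "l_d", "l_g", "l_seg_gen", "l_seg_real",
                      "l_val", "l_seg"), names(h))
  long <- tidyr::pivot_longer(h[, c("iteration", keep)], -"iteration",
                              names_to = "loss", values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                          colour = .data$loss)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "iteration", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$val_history)) {
    p <- p + ggplot2::geom_line(
      data = object$val_history,
      ggplot2::aes(.data$iteration, .data$metric),
      inherit.aes = FALSE, linetype = 2)
  }
  p
}

#' Montage of pairs in a dataset
#'
#' @param object A [seg_dataset()].
#' @param n Number of pairs to show.
#' @param ... Unused.
#' @return A ggplot raster montage of images with mask contours.
#' @exportS3Method ggplot2::autoplot
autoplot.seg_dataset <- function(object, n = 6L, ...) {
  n <- min(n, length(object))
  dfs <- purrr::map(seq_len(n), function(i) {
    p <- object$pairs[[i]]
    H <- nrow(p$mask)
    tibble::tibble(
      id = p$id,
      row = rep(seq_len(H), times = ncol(p$mask)),
      col = rep(seq_len(ncol(p$mask)), each = H),
      intensity = as.vector(if (length(dim(p$image)) == 2L) p$image
                            else p$image[, , 1L]),
      fg = as.vector(p$mask) > 0)
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$fg),
                        colour = "red", size = 0.1, alpha = 0.25) +
    ggplot2::facet_wrap(~id) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
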