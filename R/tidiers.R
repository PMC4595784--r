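#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a modulation analysis: one row per (unit, family) comparison
#'
#' @param x a `nap_modulation` object.
#' @param ... unused.
#' @return the records tibble (`unit_id`, `family_id`, `r_base`,
#'   `delta_nap`, `delta_mp1`..`delta_mp4`).
#' @method tidy nap_modulation
#' @export
tidy.nap_modulation <- function(x, ...) x$records

#' One-row summary of a modulation analysis
#'
#' @param x a `nap_modulation` object.
#' @param ... unused.
#' @return one-row tibble: mean NAP and headline-MP modulation (percent),
#'   number of comparisons, Wilcoxon p, percentage of comparisons with
#'   NAP > MP modulation.
#' @method glance nap_modulation
#' @export
glance.nap_modulation <- function(x, ...) x$summary

#' Scatter of NAP versus MP modulation per comparison
#'
#' One point per (unit, family) comparison; points below the diagonal are
#' more strongly modulated by the metric change, points above by the
#' non-accidental change.
#'
#' @param object a `nap_modulation` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot nap_modulation
#' @export
autoplot.nap_modulation <- function(object, ...) {
  mp_col <- paste0("delta_mp", object$headline_mp_level)
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data[[mp_col]], y = .data$delta_nap)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = sprintf("%% modulation base → MP%d",
                  object$headline_mp_level),
      y = "% modulation base → NAP",
      title = sprintf("%s model", object$summary$model)) +
    ggplot2::theme_minimal()
}

#' Tidy an SVM benchmark: one row per (split, model)
#'
#' @param x an `svm_benchmark` object.
#' @param ... unused.
#' @return tibble with `split`, `model`, chosen `cost` and test `accuracy`
#'   (percent).
#' @method tidy svm_benchmark
#' @export
tidy.svm_benchmark <- function(x, ...) x$per_split

#' Per-model summary of an SVM benchmark
#'
#' @param x an `svm_benchmark` object.
#' @param ... unused.
#' @return tibble with mean/sd accuracy, number of splits, chance level,
#'   and the paired p-value comparing the two models.
#' @method glance svm_benchmark
#' @export
glance.svm_benchmark <- function(x, ...) {
  dplyr::mutate(x$summary, paired_p = x$paired_p)
}

#' Per-split accuracy of the two model variants
#'
#' @param object an `svm_benchmark` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot svm_benchmark
#' @export
autoplot.svm_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$per_split,
                  ggplot2::aes(x = .data$model, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$chance_level, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "held-out accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Display the six images of a stimulus family
#'
#' @param object a `stim_family`.
#' @param ... unused.
#' @return a ggplot object (raster facets base, MP1-MP4, NAP).
#' @method autoplot stim_family
#' @export
autoplot.stim_family <- function(object, ...) {
  imgs <- c(list(base = object$base),
            stats::setNames(object$mp, paste0("MP", 1:4)),
            list(NAP = object$nap))
  df <- purrr::imap_dfr(imgs, function(img, nm) {
    tibble::tibble(
      name = nm,
      row = rep(seq_len(nrow(img)), times = ncol(img)),
      col = rep(seq_len(ncol(img)), each = nrow(img)),
      value = as.vector(img))
  })
  df$name <- factor(df$name, levels = names(imgs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::facet_wrap(~name, nrow = 1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$family_id)
}
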