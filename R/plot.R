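# ggplot2 views of calibration results.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   labs scale_y_log10
NULL

#' Plot a naive calibration: log ccdf with the fitted tail line
#'
#' @param object a `naive_calibration` from [naive_calibrate()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.naive_calibration <- function(object, ...) {
  scores <- object$scores
  s <- sort(unique(scores))
  p <- vapply(s, function(v) sum(scores >= v), 1L) / length(scores)
  df <- tibble(score = s, p = p,
               in_fit = s %in% object$fit$score)
  line <- tibble(score = s,
                 p = exp(object$params$C - object$params$lam * s))
  ggplot(df, aes(x = score, y = p)) +
    geom_point(aes(colour = in_fit)) +
    geom_line(data = line, linetype = "dashed") +
    scale_y_log10() +
    labs(y = "P[S >= s] (ccdf)", x = "top alignment score s",
         colour = "in tail fit",
         title = sprintf("naive calibration (%s): lambda = %.3f, C = %.2f",
                         object$params$regime, object$params$lam,
                         object$params$C))
}

#' Plot an importance-sampling calibration: anchored tail vs naive ccdf
#'
#' @param object an `is_calibration` from [calibrate_importance()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.is_calibration <- function(object, ...) {
  tail <- is_tail_ccdf(object)
  df <- rbind(
    tibble(score = tail$score, p = tail$p_is, method = "importance"),
    tibble(score = tail$score, p = tail$p_naive, method = "naive")
  )
  df <- df[!is.na(df$p), ]
  ggplot(df, aes(x = score, y = p, colour = method)) +
    geom_point() +
    scale_y_log10() +
    labs(y = "P[S >= s] (ccdf)", x = "top alignment score s",
         title = sprintf(
           "importance-sampling calibration (%s): lambda = %.3f, C = %.2f",
           object$params$regime, object$params$lam, object$params$C))
}

#' Histogram of importance-sampling score counts
#'
#' With a well-chosen bias rate the histogram is nearly flat over a broad
#' score interval, showing that the chain samples deep into the tail.
#'
#' @param samples an `mh_samples` object
#' @return a ggplot
#' @export
plot_sample_counts <- function(samples) {
  df <- tibble(score = as.integer(names(samples$counts)),
               count = as.integer(samples$counts))
  ggplot(df, aes(x = score, y = count)) +
    geom_col() +
    labs(title = sprintf("importance samples per score (lambda0 = %.3f)",
                         samples$lambda0))
}
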