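#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_step geom_rect
#'   geom_line geom_point geom_errorbar scale_fill_viridis_c labs
#'   scale_y_log10 theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a hypnogram as a state ribbon
#'
#' @param object a [hypnogram].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  ep <- object$epochs
  ep$state <- factor(ep$state, levels = c("wake", "REM", "NREM", "artifact"))
  ggplot(ep, aes(x = .data$start_s / 3600,
                 y = as.numeric(.data$state))) +
    geom_step() +
    ggplot2::scale_y_continuous(breaks = 1:4,
                                labels = levels(ep$state)) +
    labs(x = "time (h)", y = NULL, title = "Hypnogram") +
    theme_minimal()
}

#' Plot a multitaper spectral estimate
#'
#' @param object a `spectral_estimate`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot spectral_estimate
#' @export
autoplot.spectral_estimate <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df[df$psd > 0, ], aes(.data$freq_hz, .data$psd)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (mV^2 / Hz))) +
    theme_minimal()
}

#' Plot a multitaper spectrogram
#'
#' @param object a `spectrogram`.
#' @param max_freq_hz upper frequency shown (default 30 Hz).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot spectrogram
#' @export
autoplot.spectrogram <- function(object, max_freq_hz = 30, ...) {
  df <- as_tibble(object)
  df <- df[df$freq_hz <= max_freq_hz, ]
  ggplot(df, aes(.data$time_s / 3600, .data$freq_hz,
                 fill = log10(.data$psd + 1e-12))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10 PSD") +
    labs(x = "time (h)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot group means with SEM bars from a cohort result
#'
#' @param object a `cohort_result` (see [cohort_report()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cohort_result
#' @export
autoplot.cohort_result <- function(object, ...) {
  df <- as_tibble(object)
  long <- list()
  for (i in seq_len(nrow(df))) {
    labs_i <- strsplit(df$groups[i], "/", fixed = TRUE)[[1]]
    means_i <- as.numeric(strsplit(df$means[i], "/", fixed = TRUE)[[1]])
    sems_i <- as.numeric(strsplit(df$sems[i], "/", fixed = TRUE)[[1]])
    long[[i]] <- tibble(metric = df$metric[i], comparison = df$comparison[i],
                        group = labs_i, mean = means_i, sem = sems_i,
                        significant = df$significant[i])
  }
  long <- bind_rows(long)
  ggplot(long, aes(.data$group, .data$mean)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    facet_wrap(~ metric + comparison, scales = "free") +
    labs(x = NULL, y = "mean +/- SEM") +
    theme_minimal()
}
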