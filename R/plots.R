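#' Plot an in situ ploidy map
#'
#' Nuclei in root coordinates (arclength vs signed radial position by
#' azimuth half), coloured by relative DNA content.
#'
#' @param object A [ploidy_map()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ploidy_map <- function(object, ...) {
  d <- dplyr::mutate(object,
                     r_signed = ifelse(.data$phi < pi, .data$r, -.data$r))
  ggplot2::ggplot(d, ggplot2::aes(.data$z_root, .data$r_signed,
                                  colour = .data$C)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "C") +
    ggplot2::labs(x = "distance from QC (µm)",
                  y = "radial position (µm)",
                  title = "In situ relative ploidy map") +
    ggplot2::theme_minimal()
}

#' Plot configuration-code frequencies
#'
#' Bar chart of joint-code proportions with the uniform-null expectation as
#' a dashed reference line.
#'
#' @param object A [configuration_frequencies()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.configuration_freq <- function(object, ...) {
  ggplot2::ggplot(object$per_code,
                  ggplot2::aes(.data$config, .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1 / object$k, linetype = "dashed") +
    ggplot2::labs(x = "configuration (euchromatin_heterochromatin)",
                  y = "frequency",
                  title = "Chromatin configuration frequencies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a run-length cluster distribution
#'
#' @param object A [file_run_lengths()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(factor(.data$length), .data$count,
                               fill = .data$state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cluster size (nuclei)", y = "clusters",
                  title = "Clustering of nuclei along cell files") +
    ggplot2::theme_minimal()
}

#' Plot S0/S1/S2 proportions over incubation time
#'
#' @param object A [pattern_timecourse()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pattern_timecourse <- function(object, ...) {
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(factor(.data$time), .data$proportion,
                               fill = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "EdU incubation (min)", y = "proportion of nuclei",
                  title = "EdU pattern composition over incubation time") +
    ggplot2::theme_minimal()
}

#' Plot DNA-volume trends by layer
#'
#' @param object A [dna_volume_trend()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dna_trend <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$z_root, .data$volume_um3,
                               colour = .data$layer)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.8) +
    ggplot2::labs(x = "distance from QC (µm)",
                  y = "DNA volume (µm³)",
                  title = "Axial DNA-volume trend by tissue layer") +
    ggplot2::theme_minimal()
}
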