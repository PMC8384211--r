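#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a GA fitness trajectory
#'
#' Best and population-mean assembly yield per generation.
#'
#' @param object a `ga_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ga_result <- function(object, ...) {
  tr <- object$trajectory
  df <- tidyr_longer(tr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$yield,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = "assembly yield (%)",
                  colour = NULL,
                  title = paste0("PS-affinity optimisation, move set {",
                                 paste(unclass(object$move_set),
                                       collapse = ","), "}")) +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr dependency for one pivot)
tidyr_longer <- function(tr) {
  dplyr::bind_rows(
    tibble::tibble(generation = tr$generation, yield = tr$best,
                   series = "best"),
    tibble::tibble(generation = tr$generation, yield = tr$mean_top,
                   series = "mean of top"),
    tibble::tibble(generation = tr$generation, yield = tr$mean,
                   series = "population mean"))
}

#' Plot a fitness-landscape histogram
#'
#' @param object a [landscape_histogram()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.landscape_histogram <- function(object, ...) {
  ms <- attr(object, "move_set")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = "assembly yield (%)", y = "RNA variants",
                  title = paste0("Assembly fitness landscape, move set {",
                                 paste(unclass(ms), collapse = ","), "}")) +
    ggplot2::theme_minimal()
}

#' Plot an RNA variant's affinity profile
#'
#' Bars of the 30 PS binding free energies coloured by affinity band,
#' with the detected nucleation site outlined.
#'
#' @param variant length-30 affinity vector.
#' @param bands an [affinity_bands()].
#' @return A ggplot.
#' @export
plot_variant <- function(variant, bands = affinity_bands()) {
  site <- nucleation_site(variant, bands)
  df <- tibble::tibble(ps = seq_along(variant), dg = variant,
                       band = band_of(variant, bands),
                       site = seq_along(variant) %in% site)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ps, y = .data$dg,
                                   fill = .data$band)) +
    ggplot2::geom_col(ggplot2::aes(colour = .data$site), linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(weak = "#69b368",
                                          medium = "#8e6bb3",
                                          strong = "#c23b3b")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = NA),
                                 guide = "none") +
    ggplot2::labs(x = "packaging signal (5' to 3')",
                  y = expression(Delta * G[ps] ~ "(kcal/mol)"),
                  fill = "band") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
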