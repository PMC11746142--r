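#' Plot a radial intensity profile
#'
#' Normalized intensity versus radius with the diameter cutoff marked.
#'
#' @param profile A [as_radial_profile()] tibble.
#' @param cutoff Intensity cutoff drawn as a horizontal line (default 0.3);
#'   `NULL` suppresses it.
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(profile, cutoff = 0.3) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$radius_A,
                                    y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (Å)", y = "normalized intensity")
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' @rdname plot_radial_profile
#' @param object,... For `autoplot`, the profile and ignored arguments.
#' @export
autoplot.radial_profile <- function(object, ...) {
  plot_radial_profile(object)
}

#' Histogram of vesicle perimeters
#'
#' @param vesicles A per-vesicle tibble from [measure_vesicles()].
#' @param binwidth_nm Histogram bin width in nm.
#' @return A ggplot object.
#' @export
plot_perimeters <- function(vesicles, binwidth_nm = 10) {
  ggplot2::ggplot(vesicles, ggplot2::aes(x = .data$perimeter_nm)) +
    ggplot2::geom_histogram(binwidth = binwidth_nm, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "vesicle perimeter (nm)", y = "count")
}

#' Mass-per-length versus rod diameter
#'
#' Visualizes the linear mass-per-length increase across the symmetry
#' classes of [pspa_symmetry_table()].
#'
#' @param sym_table A tibble with `diameter_A` and `mass_per_length_kDa_A`.
#' @return A ggplot object.
#' @export
plot_mass_per_length <- function(sym_table = pspa_symmetry_table()) {
  ggplot2::ggplot(sym_table,
                  ggplot2::aes(x = .data$diameter_A,
                               y = .data$mass_per_length_kDa_A)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rod diameter (Å)",
                  y = "mass per length (kDa/Å)")
}

#' Contact flexibility per residue pair
#'
#' Standard deviation of the inter-subunit distance changes per pair, with
#' the fixed/switching threshold marked.
#'
#' @param contacts A tibble from [contact_series()].
#' @param threshold Threshold line in Angstrom (default 1).
#' @return A ggplot object.
#' @export
plot_contact_series <- function(contacts, threshold = 1) {
  contacts <- dplyr::mutate(
    contacts,
    pair = sprintf("%d/%+d:%d", .data$residue_i, .data$chain_offset,
                   .data$residue_j))
  ggplot2::ggplot(contacts,
                  ggplot2::aes(x = .data$pair, y = .data$sd_A,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue pair (i / chain offset : j)",
                  y = "s.d. of distance change (Å)", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Group activity plot in the mean/SEM boxplot convention
#'
#' Boxes span mean +/- s.e.m., whiskers the 10th-90th percentiles, and
#' values outside the whiskers are drawn as diamonds.
#'
#' @param data A data frame with a grouping column and a value column.
#' @param group,value Column names (strings) of group labels and values.
#' @return A ggplot object.
#' @export
plot_activity_groups <- function(data, group = "sample",
                                 value = "activity_per_h") {
  data <- dplyr::rename(as_tibble(data), .group = !!rlang::sym(group),
                        .value = !!rlang::sym(value))
  summ <- data |>
    dplyr::group_by(.data$.group) |>
    dplyr::reframe(group_summary(.data$.value))
  outl <- summ |>
    dplyr::select(".group", "outliers") |>
    tidyr::unnest("outliers")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$.group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                           width = 0.2) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.numeric(factor(.data$.group)) - 0.3,
      xmax = as.numeric(factor(.data$.group)) + 0.3,
      ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      fill = "grey80", colour = "grey20") +
    ggplot2::geom_segment(ggplot2::aes(
      x = as.numeric(factor(.data$.group)) - 0.3,
      xend = as.numeric(factor(.data$.group)) + 0.3,
      y = .data$mean, yend = .data$mean)) +
    (if (nrow(outl) > 0) {
      ggplot2::geom_point(data = outl,
                          ggplot2::aes(x = .data$.group,
                                       y = .data$outliers),
                          shape = 23, fill = "white")
    } else NULL) +
    ggplot2::labs(x = NULL, y = "ATPase activity (h⁻¹)")
}
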