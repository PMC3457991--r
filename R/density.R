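#' Summarize per-unit densities by region label
#'
#' Densities are computed per unit (one miRNA or one footprint) and then
#' averaged, so the standard error of the mean describes between-unit
#' spread — the quantity the error bars of a density profile show.
#'
#' @param densities Output of [region_density()].
#' @return Tibble of class `density_summary`: `label`, `n_units`,
#'   `mean_density`, `sem`.
#' @export
density_summary <- function(densities) {
  out <- densities %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(
      n_units = dplyr::n(),
      mean_density = mean(.data$density),
      sem = stats::sd(.data$density) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  class(out) <- c("density_summary", class(out))
  out
}

#' Pool flanking regions into a per-unit average density
#'
#' Appends, for each unit, one row whose density is the mean of that unit's
#' densities over the given flank labels (the "average across all four
#' flanking regions" used when contrasting a core region with its flanks).
#'
#' @param densities Output of [region_density()].
#' @param flank_labels Labels to pool (default: the four miRNA flanks).
#' @param label Name of the pooled label (default `"flank_avg"`).
#' @return `densities` with the pooled rows appended.
#' @export
add_flank_average <- function(densities,
                              flank_labels = c("flank2_5p", "flank1_5p",
                                               "flank1_3p", "flank2_3p"),
                              label = "flank_avg") {
  new_label <- label
  pooled <- densities %>%
    dplyr::filter(.data$label %in% flank_labels) %>%
    dplyr::group_by(.data$unit_id) %>%
    dplyr::summarise(
      label = .env$new_label,
      length = sum(.data$length),
      n_variants = sum(.data$n_variants),
      density = mean(.data$density),
      .groups = "drop"
    )
  dplyr::bind_rows(densities, pooled)
}

#' Welch two-sample test between two region labels
#'
#' Compares per-unit densities of two labels with a two-sided Welch
#' (unequal-variance) t-test. When both groups are constant the test is
#' degenerate: equal means give t = 0, p = 1; unequal means t = +/-Inf,
#' p = 0.
#'
#' @param densities Output of [region_density()] (possibly after
#'   [add_flank_average()]).
#' @param label_a,label_b The two region labels to compare.
#' @return An object of class `density_test` with [tidy()] and [glance()]
#'   methods.
#' @export
density_test <- function(densities, label_a, label_b) {
  x <- densities$density[densities$label == label_a]
  y <- densities$density[densities$label == label_b]
  if (length(x) < 2 || length(y) < 2) {
    stop("density_test() needs at least 2 units per group; got ",
         length(x), " for '", label_a, "' and ", length(y),
         "' for '", label_b, "'")
  }
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se <- sqrt(vx + vy)
  if (se == 0) {
    d <- mean(x) - mean(y)
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    df <- length(x) + length(y) - 2
    p <- if (d == 0) 1 else 0
  } else {
    t_stat <- (mean(x) - mean(y)) / se
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(
    list(label_a = label_a, label_b = label_b,
         mean_a = mean(x), mean_b = mean(y),
         n_a = length(x), n_b = length(y),
         t_stat = t_stat, df = df, p_value = p),
    class = "density_test"
  )
}

#' @export
print.density_test <- function(x, ...) {
  cat(sprintf("Welch two-sample density test: %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  mean %s = %.6g (n = %d), mean %s = %.6g (n = %d)\n",
              x$label_a, x$mean_a, x$n_a, x$label_b, x$mean_b, x$n_b))
  cat(sprintf("  t = %.4g, df = %.4g, two-sided p = %.4g\n",
              x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' @rdname density_test
#' @param x A `density_test` object.
#' @param ... Unused.
#' @export
tidy.density_test <- function(x, ...) {
  tibble(label_a = x$label_a, label_b = x$label_b,
         t_stat = x$t_stat, df = x$df, p_value = x$p_value)
}

#' @rdname density_test
#' @export
glance.density_test <- function(x, ...) {
  tibble(mean_a = x$mean_a, mean_b = x$mean_b, n_a = x$n_a, n_b = x$n_b,
         t_stat = x$t_stat, df = x$df, p_value = x$p_value)
}

#' Run several label-pair comparisons at once
#'
#' @param densities Output of [region_density()].
#' @param pairs Two-column data frame (or list of length-2 vectors) of label
#'   pairs.
#' @return Tibble with one tidied comparison row per pair.
#' @export
density_compare <- function(densities, pairs) {
  if (is.data.frame(pairs)) pairs <- purrr::transpose(pairs)
  purrr::map_dfr(pairs, function(p) {
    p <- unlist(p, use.names = FALSE)
    tidy(density_test(densities, p[1], p[2]))
  })
}

#' Bar-chart of a density summary with standard-error bars
#'
#' @param object A `density_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$label, y = .data$mean_density)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_density - .data$sem,
                   ymax = .data$mean_density + .data$sem),
      width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "variants per nt") +
    ggplot2::theme_minimal()
}
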