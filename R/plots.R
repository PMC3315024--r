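# ggplot2 views of the result types. CSVs are the canonical outputs;
# plots are quick-look companions.

#' Plot an equilibrium branch
#'
#' Bifurcation diagram: one species against the continuation parameter,
#' coloured by stability class.
#'
#' @param object a `bifurcation_branch`.
#' @param species state column to display (default nuclear NF-kB when
#'   present).
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot bifurcation_branch
#' @export
autoplot.bifurcation_branch <- function(object, species = NULL, ...) {
  cols <- setdiff(names(object), c("param_value", "max_re_eig",
                                   "freq_im_eig", "stability"))
  species <- species %||% if ("NFkBn" %in% cols) "NFkBn" else cols[1]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$param_value,
                               y = .data[[species]],
                               colour = .data$stability)) +
    ggplot2::geom_path(ggplot2::aes(group = 1)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = attr(object, "par_name") %||% "parameter",
                  y = paste0(species, " (uM)"), colour = "stability") +
    ggplot2::theme_minimal()
}

#' Plot a two-parameter Hopf curve
#'
#' @param object a `hopf_curve`.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot hopf_curve
#' @export
autoplot.hopf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$TR, y = .data$mu,
                                       colour = .data$branch)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_path(ggplot2::aes(group = .data$branch),
                       linewidth = 0.3, alpha = 0.6) +
    ggplot2::labs(x = "TR", y = unique(object$second_param)[1],
                  colour = "branch") +
    ggplot2::theme_minimal()
}

#' Plot a period curve
#'
#' @param object a `period_curve`.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot period_curve
#' @export
autoplot.period_curve <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$oscillatory),
                  ggplot2::aes(x = .data$param_value, y = .data$period)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "par_name") %||% "parameter",
                  y = "period (min)") +
    ggplot2::theme_minimal()
}

#' Plot sensitivity scores
#'
#' Stem plot of the scores against the parameter index, with the
#' published |score| = 0.5 threshold marked.
#'
#' @param object a `sensitivity_table`.
#' @param absolute plot |score| instead of the signed score.
#' @param ... ignored.
#' @return A ggplot.
#' @method autoplot sensitivity_table
#' @export
autoplot.sensitivity_table <- function(object, absolute = FALSE, ...) {
  df <- dplyr::filter(object, !is.na(.data$score))
  df$y <- if (absolute) abs(df$score) else df$score
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$param_num_alt,
                                        y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$param_num_alt,
                                       yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "parameter number",
                  y = if (absolute) "|sensitivity score|" else
                    "sensitivity score") +
    ggplot2::theme_minimal()
  thr <- if (absolute) 0.5 else c(-0.5, 0.5)
  p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                          colour = "grey50")
}

#' Plot a simulated time course
#'
#' @param sim a [simulate()] result.
#' @param species columns to show (default nuclear NF-kB when present).
#' @return A ggplot.
#' @export
plot_timecourse <- function(sim, species = NULL) {
  cols <- setdiff(names(sim), "time")
  species <- species %||% if ("NFkBn" %in% cols) "NFkBn" else cols
  long <- tidyr::pivot_longer(sim[, c("time", species)],
                              cols = dplyr::all_of(species),
                              names_to = "species", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
}
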