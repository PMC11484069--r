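# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted subject
#'
#' One row per estimated parameter with its bound interval.
#'
#' @param x a `burn_fit`; `...` unused.
#' @return tibble `term, estimate, lower, upper`.
#' @export
tidy.burn_fit <- function(x, ...) {
  i <- match(names(x$theta), x$params$name)
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 lower = x$params$lower[i], upper = x$params$upper[i])
}

#' Glance at a fitted subject
#'
#' @param x a `burn_fit`; `...` unused.
#' @return one-row tibble `cost, n_obs, n_par, starts, converged_starts`.
#' @export
glance.burn_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_obs = nrow(x$measurements),
                 n_par = length(x$theta), starts = nrow(x$starts),
                 converged_starts = sum(is.finite(x$starts$cost)))
}

#' Long-format trajectory
#'
#' @param x a `burn_sim`.
#' @param variables trajectory columns to keep (default: the six fitted
#'   observables).
#' @param ... unused.
#' @return tibble `time_h, variable, value`.
#' @export
tidy.burn_sim <- function(x, variables = c("hct", "cvp", "co", "map",
                                           "j_uo", "na_plasma"), ...) {
  x$trajectory |>
    dplyr::select(dplyr::all_of(c("time_h", variables))) |>
    tidyr::pivot_longer(-"time_h", names_to = "variable")
}

#' Plot a simulation
#'
#' Faceted time courses of the main observables with the infusion schedule.
#'
#' @param object a `burn_sim`.
#' @param variables trajectory columns to facet.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.burn_sim <- function(object,
                              variables = c("hct", "cvp", "co", "map",
                                            "j_uo", "na_plasma"), ...) {
  d <- tidy.burn_sim(object, variables)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "hours post-burn", y = NULL)
}

#' Plot a renal pressure sweep
#'
#' Four panels mirroring the verification figure: node sodium
#' concentrations, GFR and urine output (relative to the 85 mmHg baseline),
#' and the relative renin release rate, all against renal arterial pressure.
#'
#' @param object a `burn_sweep` from [pra_sweep()]; `...` unused.
#' @return a ggplot.
#' @export
autoplot.burn_sweep <- function(object, ...) {
  i0 <- which(abs(object$p_ra - 85) < 1e-9)
  d <- dplyr::bind_rows(
    object |>
      dplyr::select(dplyr::all_of(c("p_ra", "na_p", "na_n", "na_k", "na_e"))) |>
      tidyr::pivot_longer(-"p_ra", names_to = "series") |>
      dplyr::mutate(panel = "node sodium (mEq/L)"),
    tibble::tibble(
      p_ra = rep(object$p_ra, 2),
      value = c(object$j_gfr / object$j_gfr[i0], object$j_uo / object$j_uo[i0]),
      series = rep(c("GFR", "UO"), each = nrow(object)),
      panel = "GFR and UO relative to 85 mmHg"),
    tibble::tibble(p_ra = object$p_ra, value = object$s_renin,
                   series = "renin", panel = "relative renin release")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$p_ra, .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "renal arterial pressure (mmHg)", y = NULL)
}
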