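#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-node structural metrics
#' @param x An `fw_metrics` from [structural_metrics()].
#' @param ... Unused.
#' @return Tibble with one row per node.
#' @method tidy fw_metrics
#' @export
tidy.fw_metrics <- function(x, ...) x$nodes

#' One-row summary of structural metrics
#' @param x An `fw_metrics`.
#' @param ... Unused.
#' @return One-row tibble: `S`, `L`, `connectance`, `mean_swtl`.
#' @method glance fw_metrics
#' @export
glance.fw_metrics <- function(x, ...) {
  tibble::tibble(S = x$S, L = x$L, connectance = x$connectance,
                 mean_swtl = x$mean_swtl)
}

#' Tidy a deletion run
#' @param x A `deletion_run`.
#' @param ... Unused.
#' @return Per-step tibble with added fractions of the web extinct.
#' @method tidy deletion_run
#' @export
tidy.deletion_run <- function(x, ...) {
  dplyr::mutate(x$steps,
                frac_removed = .data$n_primary / x$S,
                frac_secondary = .data$n_secondary / x$S)
}

#' One-row summary of a deletion run
#' @param x A `deletion_run`.
#' @param ... Unused.
#' @return One-row tibble: `mode`, `S`, `n_steps`, `total_secondary`, `r50`.
#' @method glance deletion_run
#' @export
glance.deletion_run <- function(x, ...) {
  tibble::tibble(mode = x$mode, S = x$S, n_steps = nrow(x$steps),
                 total_secondary = max(c(0L, x$steps$n_secondary)),
                 r50 = x$r50)
}

#' Tidy a random-sequence ensemble
#' @param x A `deletion_ensemble`.
#' @param ... Unused.
#' @return Per-step tibble with mean and 95% CI of cumulative secondary
#'   extinctions.
#' @method tidy deletion_ensemble
#' @export
tidy.deletion_ensemble <- function(x, ...) x$summary

#' One-row summary of a random-sequence ensemble
#' @param x A `deletion_ensemble`.
#' @param ... Unused.
#' @return One-row tibble with replicate count and the R50 distribution
#'   summary.
#' @method glance deletion_ensemble
#' @export
glance.deletion_ensemble <- function(x, ...) {
  tibble::tibble(mode = x$mode, S = x$S, reps = x$reps,
                 mean_r50 = mean(x$r50, na.rm = TRUE),
                 mean_total_secondary = x$summary$mean_secondary[nrow(x$summary)])
}

#' Tidy a biomass trajectory into long format
#' @param x An `atn_trajectory`.
#' @param ... Unused.
#' @return Long tibble `time`, `species`, `biomass`.
#' @method tidy atn_trajectory
#' @export
tidy.atn_trajectory <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$B)) |>
    dplyr::mutate(time = x$times, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "biomass")
}

#' Tidy a scenario result
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return Per-species tibble of before/after biomasses and percent change.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  dplyr::mutate(x$species, fishing = x$fishing, subsidy = x$subsidy)
}

#' One-row summary of a scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return One-row tibble: perturbation levels, extinction count, median
#'   change of non-harvested species, achieved change of harvested species.
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  sp <- x$species
  tibble::tibble(
    fishing = x$fishing, subsidy = x$subsidy,
    n_extinct = length(x$extinct),
    median_change_nonharvested = stats::median(sp$change_pct[!sp$harvested], na.rm = TRUE),
    total_change_harvested = biomass_change(sum(sp$before[sp$harvested]),
                                            sum(sp$after[sp$harvested]))
  )
}

#' Summaries of every cell of a factorial design
#' @param x A `factorial_result`.
#' @param ... Unused.
#' @return Tibble with one row per (fishing, subsidy) cell.
#' @method tidy factorial_result
#' @export
tidy.factorial_result <- function(x, ...) {
  purrr::map_dfr(x$result, glance)
}

#' Plot a deletion run
#'
#' Fraction of the web secondarily extinct against the fraction primarily
#' removed.
#'
#' @param object A `deletion_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deletion_run
#' @export
autoplot.deletion_run <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$frac_removed, y = .data$frac_secondary)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "fraction of species removed",
                  y = "fraction secondarily extinct",
                  title = paste0(object$mode, " deletion sequence")) +
    ggplot2::theme_minimal()
}

#' Plot a random-sequence ensemble
#' @param object A `deletion_ensemble`.
#' @param ... Unused.
#' @return A ggplot with the mean and 95% CI ribbon per step.
#' @method autoplot deletion_ensemble
#' @export
autoplot.deletion_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$step)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_secondary)) +
    ggplot2::labs(x = "species removed", y = "cumulative secondary extinctions",
                  title = paste0("random deletion sequences (", object$reps,
                                 " replicates)")) +
    ggplot2::theme_minimal()
}

#' Plot a biomass trajectory
#' @param object An `atn_trajectory`.
#' @param ... Unused.
#' @return A ggplot of biomass through time, one line per species.
#' @method autoplot atn_trajectory
#' @export
autoplot.atn_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$biomass,
                               group = .data$species)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (days)", y = "biomass") +
    ggplot2::theme_minimal()
}

#' Plot per-category biomass changes of a scenario
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of percent change per trophic category, split
#'   by harvested status.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  dat <- dplyr::filter(object$category, !is.na(.data$harvested))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$change_pct,
                                    fill = .data$harvested)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% biomass change",
                  title = sprintf("fishing %d%%, subsidy %+d%%",
                                  as.integer(object$fishing),
                                  as.integer(object$subsidy))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
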