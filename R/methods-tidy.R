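#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted mixed model
#'
#' @param x an `mm_fit`.
#' @param ... unused.
#' @return tibble with one row per animal and trait: `animal`, `trait`,
#'   `value` (the predicted genetic value).
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) x$solutions

#' @rdname tidy.mm_fit
#' @return for `glance()`: one-row tibble with `model_tag`, `n_records`,
#'   `n_animals`, `n_traits`, `logLik`.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(model_tag = x$model_tag, n_records = x$n,
                 n_animals = x$mme$q, n_traits = x$mme$t, logLik = x$logLik)
}

#' Tidy estimated variance components
#'
#' @param x a `variance_components` object.
#' @param ... unused.
#' @return tibble with one row per (co)variance parameter: `component`
#'   (`"genetic"` or `"residual"`), `trait_1`, `trait_2`, `estimate`.
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  t <- nrow(x$H)
  ut <- which(upper.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(component = "genetic", trait_1 = ut[, 1], trait_2 = ut[, 2],
                   estimate = x$H[ut]),
    tibble::tibble(component = "residual", trait_1 = ut[, 1], trait_2 = ut[, 2],
                   estimate = x$R[ut])
  )
}

#' @rdname tidy.variance_components
#' @return for `glance()`: one-row tibble with `logLik`, `iterations`,
#'   `converged`, `method` and per-trait heritabilities.
#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  out <- tibble::tibble(logLik = x$logLik, iterations = x$iterations,
                        converged = x$converged, method = x$method)
  for (i in seq_along(x$h2)) out[[paste0("h2_trait", i)]] <- x$h2[i]
  out
}

#' Tidy a study result
#'
#' @param x a `study_result`.
#' @param ... unused.
#' @return `tidy()` returns the aggregated summary tibble; `glance()` a
#'   one-row overview.
#' @method tidy study_result
#' @export
tidy.study_result <- function(x, ...) x$summary

#' @rdname tidy.study_result
#' @method glance study_result
#' @export
glance.study_result <- function(x, ...) {
  tibble::tibble(
    n_replicates = max(x$replicates$replicate),
    n_scenarios = length(unique(x$replicates$scenario[x$replicates$scenario != "pedigree"])),
    n_cells = nrow(x$summary)
  )
}

#' Plot an evaluation report or study result
#'
#' Bar chart of a chosen statistic (default: validation GEBV reliability)
#' by trait, scenario, genomic model and response variable; study results
#' get replicate-SD error bars.
#'
#' @param object an `evaluation_report` (from [run_replicate()]) or
#'   `study_result` (from [run_study()]).
#' @param statistic which statistic to display.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, statistic = "reliability_gebv", ...) {
  d <- object[object$statistic == statistic & !is.na(object$model), ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$trait), y = .data$value,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(response ~ scenario) +
    ggplot2::labs(x = "trait", y = statistic, fill = "model") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.evaluation_report
#' @method autoplot study_result
#' @export
autoplot.study_result <- function(object, statistic = "reliability_gebv", ...) {
  d <- object$summary[object$summary$statistic == statistic &
                        !is.na(object$summary$model), ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$trait), y = .data$mean,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::facet_grid(response ~ scenario) +
    ggplot2::labs(x = "trait", y = statistic, fill = "model") +
    ggplot2::theme_minimal()
}

#' Plot predictions against true breeding values
#'
#' @param fit an `mm_fit`.
#' @param truths tibble (`animal`, `trait`, `value`) or matrix of TBVs
#'   with animal-id rownames.
#' @param animals subset of animal ids (default: all in the fit).
#' @return a ggplot object with the identity line.
#' @export
plot_prediction <- function(fit, truths, animals = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  sols <- fit$solutions
  if (!is.null(animals)) sols <- sols[sols$animal %in% as.character(animals), ]
  if (is.matrix(truths)) {
    sols$tbv <- truths[cbind(sols$animal, sols$trait)]
  } else {
    m <- match(paste(sols$animal, sols$trait),
               paste(truths$animal, truths$trait))
    sols$tbv <- truths$value[m]
  }
  ggplot2::ggplot(sols, ggplot2::aes(x = .data$value, y = .data$tbv)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "predicted genetic value", y = "true breeding value") +
    ggplot2::theme_minimal()
}
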