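#' Reliability of a genetic-value predictor
#'
#' The squared Pearson correlation between predictions (EBV or GEBV) and
#' the true breeding values, the standard validation reliability of
#' genomic prediction. Invariant to affine transforms of either argument.
#'
#' @param estimates,truths numeric vectors of equal length (>= 3), both
#'   non-constant.
#' @return a single value in \[0, 1\].
#' @export
reliability <- function(estimates, truths) {
  if (length(estimates) != length(truths) || length(estimates) < 3) {
    stop("need two equal-length vectors with at least 3 values.", call. = FALSE)
  }
  if (stats::sd(estimates) == 0 || stats::sd(truths) == 0) {
    stop("reliability is undefined for a constant vector.", call. = FALSE)
  }
  stats::cor(estimates, truths)^2
}

#' Bias regression of true on predicted breeding values
#'
#' Ordinary least squares of TBV (response) on GEBV/EBV (predictor). A
#' slope of 1 indicates unbiased dispersion of the predictions; the
#' intercept should be near 0 for centered data.
#'
#' @param truths numeric response vector (TBV).
#' @param estimates numeric predictor vector (GEBV or EBV).
#' @return one-row tibble with `intercept` and `slope`.
#' @export
regression_tbv_on_gebv <- function(truths, estimates) {
  if (length(estimates) != length(truths) || length(estimates) < 3) {
    stop("need two equal-length vectors with at least 3 values.", call. = FALSE)
  }
  if (stats::sd(estimates) == 0) {
    stop("zero-variance predictor.", call. = FALSE)
  }
  slope <- stats::cov(truths, estimates) / stats::var(estimates)
  tibble::tibble(intercept = mean(truths) - slope * mean(estimates),
                 slope = slope)
}

#' Rescale GEBVs by the mean reliability of the response EBVs
#'
#' When regressed (shrunken) EBVs are used as the response variable of
#' GBLUP, the resulting GEBVs are deflated roughly in proportion to the
#' mean reliability of those EBVs; dividing the GEBVs by that mean
#' reliability restores the real scale. Consequently the bias-regression
#' slope transforms as b_c = b * mean_reliability.
#'
#' @param gebv numeric vector of genomic predictions.
#' @param mean_reliability mean reliability of the response EBVs, in (0, 1].
#' @return the rescaled vector `gebv / mean_reliability`.
#' @export
rescale_gebv <- function(gebv, mean_reliability) {
  check_scalar(mean_reliability, "mean_reliability")
  if (mean_reliability <= 0) {
    stop("`mean_reliability` must be > 0.", call. = FALSE)
  }
  gebv / mean_reliability
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests whether two correlations that share a variable differ: here,
#' cor(GEBV from one model, TBV) versus cor(GEBV from another model, TBV),
#' with `r_12` the correlation between the two predictor sets. Uses
#' Williams' modified t with n - 3 degrees of freedom:
#'
#' t = (r_1T - r_2T) * sqrt( (n-1)(1+r_12) /
#'       ( 2 ((n-1)/(n-3)) |R| + rbar^2 (1-r_12)^3 ) ),
#'
#' where |R| = 1 - r_1T^2 - r_2T^2 - r_12^2 + 2 r_1T r_2T r_12 and
#' rbar = (r_1T + r_2T)/2.
#'
#' @param r_1T,r_2T correlations of predictors 1 and 2 with the shared
#'   variable (TBV).
#' @param r_12 correlation between the two predictors.
#' @param n number of observations (>= 4).
#' @return one-row tibble with `t`, `df` (= n - 3) and the two-sided
#'   `p_value`.
#' @export
hotelling_williams_t <- function(r_1T, r_2T, r_12, n) {
  check_scalar(n, "n", integer = TRUE)
  if (n < 4) stop("`n` must be at least 4.", call. = FALSE)
  rr <- c(r_1T, r_2T, r_12)
  if (any(!is.finite(rr)) || any(abs(rr) > 1)) {
    stop("correlations must lie in [-1, 1].", call. = FALSE)
  }
  detR <- 1 - r_1T^2 - r_2T^2 - r_12^2 + 2 * r_1T * r_2T * r_12
  if (detR < -1e-12) {
    stop("inconsistent correlation triple (matrix not positive semi-definite).",
         call. = FALSE)
  }
  detR <- max(detR, 0)
  rbar <- (r_1T + r_2T) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_12)^3
  tval <- if (denom <= 0) {
    if (r_1T == r_2T) 0 else Inf * sign(r_1T - r_2T)
  } else {
    (r_1T - r_2T) * sqrt((n - 1) * (1 + r_12) / denom)
  }
  df <- n - 3
  tibble::tibble(t = tval, df = df,
                 p_value = 2 * stats::pt(-abs(tval), df))
}

#' Aggregate per-replicate evaluation reports
#'
#' Collapses a list of per-replicate reports (long tibbles with a common
#' cell structure) to per-cell means and sample standard deviations
#' (n - 1 denominator). With a single replicate the SD is reported as 0
#' and flagged.
#'
#' @param reports list of evaluation-report tibbles, or one tibble with a
#'   `replicate` column.
#' @return tibble with one row per cell: grouping columns, `mean`, `sd`,
#'   `n_replicates`, `single_replicate`.
#' @export
aggregate_replicates <- function(reports) {
  if (is.data.frame(reports)) {
    combined <- tibble::as_tibble(reports)
    if (!"replicate" %in% names(combined)) combined$replicate <- 1L
  } else {
    if (!length(reports)) stop("no replicates supplied.", call. = FALSE)
    cols <- lapply(reports, function(r) sort(setdiff(names(r), "replicate")))
    if (length(unique(vapply(cols, paste, character(1), collapse = "|"))) != 1) {
      stop("replicate reports have mismatched structure.", call. = FALSE)
    }
    combined <- dplyr::bind_rows(
      purrr::imap(reports, function(r, i) {
        r$replicate <- r$replicate %||% i
        r
      })
    )
  }
  keys <- setdiff(names(combined), c("replicate", "value"))
  out <- combined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_replicate = .data$n_replicates == 1L)
  if (length(unique(out$n_replicates)) > 1) {
    stop("replicate reports have mismatched cell structure.", call. = FALSE)
  }
  out
}
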