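# Evaluation statistics: pooled and per-base Pearson correlations,
# per-base ASA summaries, and the 2-D density table behind the
# predicted-vs-actual plots.

#' Pearson correlation with explicit preconditions
#'
#' Standard product-moment correlation via `stats::cor`, wrapped so that
#' too-short or zero-variance inputs raise a clear error instead of NA.
#'
#' @param x,y Numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Per-base stratified correlations
#'
#' Splits a paired predicted/actual series by base identity and reports the
#' Pearson correlation within each stratum. Empty strata are absent from the
#' output, not reported as zero; strata without variance get `NA`.
#'
#' @param data Data frame with columns `predicted`, `actual`, `base`.
#' @return Tibble `base`, `n`, `r`, one row per base present.
#' @export
per_base_pcc <- function(data) {
  stopifnot(all(c("predicted", "actual", "base") %in% names(data)))
  data |>
    dplyr::filter(.data$base %in% BASES) |>
    dplyr::group_by(base = .data$base) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 2 && stats::sd(.data$actual) > 0 &&
              stats::sd(.data$predicted) > 0) {
        stats::cor(.data$predicted, .data$actual)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Per-base ASA summaries (mean and sample SD)
#'
#' @param data Data frame with columns `asa` and `base`.
#' @return Tibble `base`, `n`, `mean`, `sd` (sample, n-1 denominator; 0 for
#'   a single value).
#' @export
base_asa_summary <- function(data) {
  stopifnot(all(c("asa", "base") %in% names(data)))
  data |>
    dplyr::group_by(base = .data$base) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$asa),
      sd = if (dplyr::n() > 1) stats::sd(.data$asa) else 0,
      .groups = "drop"
    )
}

#' 2-D binned density table of predicted vs actual values
#'
#' Counts pairs on a rectangular grid; bin totals sum to the number of
#' pairs. This is the table behind the density-plot rendering of model
#' evaluations.
#'
#' @param data Data frame with `predicted` and `actual` columns.
#' @param n_bins Bins per axis (default 40).
#' @return Tibble `pred_mid`, `actual_mid`, `count` for occupied bins.
#' @export
density_table <- function(data, n_bins = 40) {
  stopifnot(all(c("predicted", "actual") %in% names(data)), nrow(data) >= 1)
  brk <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n_bins + 1)
  }
  bx <- brk(data$predicted)
  by <- brk(data$actual)
  ix <- findInterval(data$predicted, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(data$actual, by, rightmost.closed = TRUE, all.inside = TRUE)
  mid <- function(b) (b[-1] + b[-length(b)]) / 2
  tibble::tibble(ix = ix, iy = iy) |>
    dplyr::count(.data$ix, .data$iy, name = "count") |>
    dplyr::transmute(
      pred_mid = mid(bx)[.data$ix],
      actual_mid = mid(by)[.data$iy],
      count = .data$count
    )
}

#' Full evaluation report for a prediction set
#'
#' @param data Data frame with `predicted`, `actual`, and optionally `base`
#'   and `chain` columns.
#' @return List: pooled `r`, `per_base` (if base present), `per_chain` (if
#'   chain present), `density` table.
#' @export
evaluate_predictions <- function(data) {
  out <- list(r = pearson_r(data$predicted, data$actual))
  if ("base" %in% names(data)) out$per_base <- per_base_pcc(data)
  if ("chain" %in% names(data)) {
    out$per_chain <- data |>
      dplyr::group_by(chain = .data$chain) |>
      dplyr::summarise(
        n = dplyr::n(),
        r = if (dplyr::n() >= 2 && stats::sd(.data$actual) > 0 &&
                stats::sd(.data$predicted) > 0) {
          stats::cor(.data$predicted, .data$actual)
        } else NA_real_,
        .groups = "drop"
      )
  }
  out$density <- density_table(data)
  out
}
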