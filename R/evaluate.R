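#' Goodness-of-fit statistics for simulated vs observed series
#'
#' The four statistics used to judge agreement between a simulated series
#' `S` and a measured series `m`:
#' \describe{
#'   \item{`d_index()`}{Willmott index of agreement,
#'     `1 - sum((m - S)^2) / sum((abs(S - mbar) + abs(m - mbar))^2)` with
#'     `mbar` the observed mean; lies in `[0, 1]`, 1 means perfect 1:1
#'     agreement.}
#'   \item{`model_efficiency()`}{Nash-Sutcliffe modelling efficiency,
#'     `1 - sum((m - S)^2) / sum((m - mbar)^2)`; 1 is perfect, 0 means the
#'     model is no better than the observed mean, negative means worse.}
#'   \item{`rmse()`}{Root mean square error, in the units of the series; a
#'     value under 10 percent of the observed mean is conventionally
#'     considered good.}
#'   \item{`bias()`}{Signed mean error `mean(S - m)`: positive means
#'     over-prediction.}
#' }
#' Pairs with a missing value in either series are dropped before computing.
#'
#' @param observed,simulated Numeric vectors of equal length.
#' @return A single number.
#' @examples
#' d_index(c(1, 2, 3), c(2, 2, 2))          # 0
#' model_efficiency(c(1, 2, 3), c(3, 2, 1)) # -3
#' rmse(c(1, 2, 3), c(2, 3, 4))             # 1
#' @export
d_index <- function(observed, simulated) {
  p <- paired(observed, simulated)
  mbar <- mean(p$m)
  denom <- sum((abs(p$s - mbar) + abs(p$m - mbar))^2)
  if (denom <= 0) {
    abort("Degenerate series: both series constant at the observed mean.",
          class = "gxemaize_degenerate_series")
  }
  1 - sum((p$m - p$s)^2) / denom
}

#' @rdname d_index
#' @export
model_efficiency <- function(observed, simulated) {
  p <- paired(observed, simulated)
  denom <- sum((p$m - mean(p$m))^2)
  if (denom <= 0) {
    abort("Model efficiency is undefined for a constant observed series.",
          class = "gxemaize_degenerate_series")
  }
  1 - sum((p$m - p$s)^2) / denom
}

#' @rdname d_index
#' @export
rmse <- function(observed, simulated) {
  p <- paired(observed, simulated)
  sqrt(mean((p$m - p$s)^2))
}

#' @rdname d_index
#' @export
bias <- function(observed, simulated) {
  p <- paired(observed, simulated)
  mean(p$s - p$m)
}

paired <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    abort("`observed` and `simulated` must have the same length.")
  }
  keep <- !is.na(observed) & !is.na(simulated)
  m <- observed[keep]
  s <- simulated[keep]
  if (length(m) < 2) abort("Need at least 2 complete observation pairs.")
  list(m = m, s = s)
}

#' Evaluate paired observed/simulated data
#'
#' Data-frame-first wrapper computing all fit statistics at once, optionally
#' per group.
#'
#' @param data A data frame.
#' @param observed,simulated Column names (tidy-eval) holding the measured
#'   and simulated values.
#' @param ... Optional grouping columns (tidy-eval).
#' @return A tibble with one row per group: `n`, `bias`, `rmse`,
#'   `rmse_pct_of_mean`, `d`, `me`.
#' @examples
#' df <- data.frame(obs = c(4.1, 5.2, 3.9), sim = c(4.3, 5.0, 4.1))
#' evaluate_fit(df, obs, sim)
#' @export
evaluate_fit <- function(data, observed, simulated, ...) {
  obs <- rlang::enquo(observed)
  sim <- rlang::enquo(simulated)
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = sum(!is.na(!!obs) & !is.na(!!sim)),
      bias = bias(!!obs, !!sim),
      rmse = rmse(!!obs, !!sim),
      rmse_pct_of_mean = 100 * .data$rmse / mean(!!obs, na.rm = TRUE),
      d = d_index(!!obs, !!sim),
      me = model_efficiency(!!obs, !!sim),
      .groups = "drop"
    )
}
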