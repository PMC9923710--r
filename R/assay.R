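#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression of method B (`y`) on method A (`x`) that is
#' robust to measurement error in both variables: the slope is the shifted
#' median of all pairwise slopes `(y_j - y_i)/(x_j - x_i)`, where slopes
#' equal to -1 are excluded, pairs with identical x are skipped, and the
#' median index is offset by the number of slopes below -1 (the original
#' 1983 procedure, which makes the estimate invariant to swapping the
#' methods). The intercept is `median(y - slope * x)`. Confidence intervals
#' are the distribution-free rank-based intervals of the same paper.
#'
#' @param data A data frame with columns `x` and `y` (paired measurements
#'   of the same samples by two methods), or two numeric vectors via `x`
#'   and `y`.
#' @param x,y Optional numeric vectors (alternative to `data`).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `ecu_method_comparison` with `slope`,
#'   `intercept`, their confidence intervals and the input size.
#' @export
#' @examples
#' pb <- passing_bablok(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
#' tidy(pb)
passing_bablok <- function(data = NULL, x = NULL, y = NULL, conf_level = 0.95) {
  if (!is.null(data)) {
    stopifnot(all(c("x", "y") %in% names(data)))
    x <- data$x; y <- data$y
  }
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  if (any(is.na(x)) || any(is.na(y))) abort("missing pairs are not allowed")
  if (n < 3) abort("Passing-Bablok regression needs at least 3 pairs")
  if (length(unique(x)) == 1) abort("all x values identical: slope undefined")

  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0 | dy != 0
  dx <- dx[keep]; dy <- dy[keep]
  s <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  s <- s[s != -1] # slopes of exactly -1 are discarded
  s <- sort(s)
  nS <- length(s)
  if (nS == 0) abort("degenerate data: no valid pairwise slopes")
  K <- sum(s < -1)
  med_shifted <- function(v, offset) {
    m <- length(v)
    if (m %% 2 == 1) v[(m + 1) / 2 + offset]
    else mean(v[(m / 2 + offset):(m / 2 + 1 + offset)])
  }
  slope <- med_shifted(s, K)
  intercept <- median(y - slope * x)

  z <- qnorm(1 - (1 - conf_level) / 2)
  ci_ok <- FALSE
  slope_ci <- c(NA_real_, NA_real_); int_ci <- c(NA_real_, NA_real_)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nS - w) / 2)
  m2 <- nS - m1 + 1
  if ((m1 + K) >= 1 && (m2 + K) <= nS) {
    lo <- s[m1 + K]; hi <- s[m2 + K]
    if (is.finite(lo) && is.finite(hi)) {
      slope_ci <- c(lo, hi)
      int_ci <- c(median(y - hi * x), median(y - lo * x))
      ci_ok <- TRUE
    }
  }
  structure(list(method = "passing_bablok", n = n, conf_level = conf_level,
                 slope = slope, intercept = intercept,
                 slope_ci = slope_ci, intercept_ci = int_ci, ci_valid = ci_ok),
            class = "ecu_method_comparison")
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference `mean(y - x)`; the 95% limits of agreement
#' are `bias +/- 1.96 * SD(y - x)`.
#'
#' @inheritParams passing_bablok
#' @return An `ecu_method_comparison` object with `bias`, `loa_low`,
#'   `loa_high`.
#' @export
bland_altman <- function(data = NULL, x = NULL, y = NULL) {
  if (!is.null(data)) {
    stopifnot(all(c("x", "y") %in% names(data)))
    x <- data$x; y <- data$y
  }
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (any(is.na(x)) || any(is.na(y))) abort("missing pairs are not allowed")
  if (length(x) < 2) abort("Bland-Altman analysis needs at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  structure(list(method = "bland_altman", n = length(x), bias = bias,
                 sd_diff = s, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s),
            class = "ecu_method_comparison")
}

#' @export
print.ecu_method_comparison <- function(x, ...) {
  if (x$method == "passing_bablok") {
    cat(sprintf("<Passing-Bablok regression, n = %d>\n", x$n))
    cat(sprintf("  slope %.4g (%g%% CI %.4g to %.4g)\n", x$slope,
                100 * x$conf_level, x$slope_ci[1], x$slope_ci[2]))
    cat(sprintf("  intercept %.4g (%g%% CI %.4g to %.4g)\n", x$intercept,
                100 * x$conf_level, x$intercept_ci[1], x$intercept_ci[2]))
  } else {
    cat(sprintf("<Bland-Altman agreement, n = %d>\n", x$n))
    cat(sprintf("  bias %.4g; 95%% limits of agreement %.4g to %.4g\n",
                x$bias, x$loa_low, x$loa_high))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ecu_method_comparison <- function(x, ...) {
  if (x$method == "passing_bablok") {
    tibble(term = c("slope", "intercept"),
           estimate = c(x$slope, x$intercept),
           conf.low = c(x$slope_ci[1], x$intercept_ci[1]),
           conf.high = c(x$slope_ci[2], x$intercept_ci[2]))
  } else {
    tibble(term = c("bias", "loa_low", "loa_high"),
           estimate = c(x$bias, x$loa_low, x$loa_high))
  }
}

#' @exportS3Method generics::glance
glance.ecu_method_comparison <- function(x, ...) {
  tibble(method = x$method, n = x$n)
}

#' Convert in-house CP activity values to the Wieslab ELISA scale
#'
#' The two classical-pathway activity assays are related by
#' `CP_inhouse = 6.33 + 1.05 * CP_Wieslab` (Passing-Bablok cross-
#' validation); in-house values are therefore mapped to the Wieslab scale
#' as `(CP_inhouse - 6.33) / 1.05` before modelling. Negative results are
#' clipped to 0 with a warning.
#'
#' @param cp_inhouse In-house ELISA CP activity, % (vectorised,
#'   nonnegative).
#' @param intercept,slope Cross-validation regression coefficients.
#' @return CP activity on the Wieslab scale, %.
#' @export
#' @examples
#' convert_cp_inhouse_to_wieslab(c(6.33, 58.83, 111.33))
convert_cp_inhouse_to_wieslab <- function(cp_inhouse, intercept = 6.33,
                                          slope = 1.05) {
  if (any(cp_inhouse < 0)) abort("`cp_inhouse` must be nonnegative")
  out <- (cp_inhouse - intercept) / slope
  if (any(out < 0)) {
    warn("converted CP value(s) below 0 were clipped to 0")
    out <- pmax(out, 0)
  }
  out
}
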