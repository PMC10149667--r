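resolve_pair_cols <- function(data, x, y) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  xq <- rlang::enquo(x); yq <- rlang::enquo(y)
  if (rlang::quo_is_null(xq) || rlang::quo_is_null(yq)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    if (length(num) < 2) {
      stop("`data` needs two numeric columns (or name them via x/y)",
           call. = FALSE)
    }
    xv <- data[[num[1]]]; yv <- data[[num[2]]]
  } else {
    xv <- rlang::eval_tidy(xq, data); yv <- rlang::eval_tidy(yq, data)
  }
  if (length(xv) != length(yv)) stop("x and y differ in length",
                                     call. = FALSE)
  if (!all(is.finite(xv)) || !all(is.finite(yv))) {
    stop("paired measurements must be finite", call. = FALSE)
  }
  list(x = as.numeric(xv), y = as.numeric(yv))
}

#' Bland-Altman agreement analysis
#'
#' Bias and limits of agreement between two measurement methods on paired
#' data: mean difference `mean(y - x)`, its sample SD (n - 1 denominator),
#' and limits of agreement at mean +/- 1.96 SD.
#'
#' @param data Data frame of paired measurements.
#' @param x,y Columns holding the reference and test method (tidy-eval;
#'   default: the first two numeric columns).
#' @return An object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `data` (`mean`, `diff`).
#'   Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
#' @examples
#' bland_altman(load_table1_fixture(), goniometer_deg, software_deg)
bland_altman <- function(data, x = NULL, y = NULL) {
  p <- resolve_pair_cols(data, {{ x }}, {{ y }})
  n <- length(p$x)
  if (n < 3) stop("insufficient data: need at least 3 pairs", call. = FALSE)
  d <- p$y - p$x
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    mean_diff = mean_diff, sd_diff = sd_diff,
    loa_low = mean_diff - 1.96 * sd_diff,
    loa_high = mean_diff + 1.96 * sd_diff,
    n = n,
    data = tibble::tibble(mean = (p$x + p$y) / 2, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.2f, SD %.2f, LoA [%.2f, %.2f]\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @rdname bland_altman
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy.bland_altman(x)

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for method comparison. All pairwise slopes
#' `S_ij = (y_j - y_i) / (x_j - x_i)` (i < j, `x_i != x_j`) are formed;
#' slopes exactly equal to -1 are excluded and the estimate is the shifted
#' median of the sorted slopes with offset `K`, the number of slopes below
#' -1 (this makes the estimate invariant to swapping the methods). The
#' intercept is `median(y - slope * x)`; the slope confidence interval uses
#' the rank-based normal approximation with
#' `C = z * sqrt(n (n - 1) (2 n + 5) / 18)` at alpha = 0.05.
#'
#' @inheritParams bland_altman
#' @param alpha Confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `passing_bablok`: `slope`, `intercept`,
#'   `slope_ci_low/high`, `slope_angle_deg` (= atan(slope) in degrees),
#'   `n`, `n_pairwise_slopes`, and the paired `data`. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
#' @examples
#' passing_bablok(load_table1_fixture(), goniometer_deg, software_deg)
passing_bablok <- function(data, x = NULL, y = NULL, alpha = 0.05) {
  p <- resolve_pair_cols(data, {{ x }}, {{ y }})
  n <- length(p$x)
  if (n < 3) stop("insufficient data: need at least 3 pairs", call. = FALSE)
  ij <- utils::combn(n, 2)
  dx <- p$x[ij[2, ]] - p$x[ij[1, ]]
  dy <- p$y[ij[2, ]] - p$y[ij[1, ]]
  keep <- dx != 0
  if (!any(keep)) {
    stop("undefined slope: all x values are identical", call. = FALSE)
  }
  S <- dy[keep] / dx[keep]
  S <- S[S != -1]
  if (length(S) == 0) {
    stop("undefined slope: no admissible pairwise slopes", call. = FALSE)
  }
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  slope <- shifted_median(S, K)
  intercept <- stats::median(p$y - slope * p$x)

  Cq <- stats::qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - Cq) / 2)
  M2 <- N - M1 + 1
  ci <- if (M1 >= 1 && M2 <= N) c(S[M1 + K], S[M2 + K]) else c(NA_real_,
                                                               NA_real_)
  if (any(is.na(ci))) ci <- c(NA_real_, NA_real_)
  structure(list(
    slope = slope, intercept = intercept,
    slope_ci_low = ci[1], slope_ci_high = ci[2],
    slope_angle_deg = atan(slope) / DEG,
    n = n, n_pairwise_slopes = N,
    data = tibble::tibble(x = p$x, y = p$y)
  ), class = "passing_bablok")
}

# Median of sorted values with index offset K (shifted median).
shifted_median <- function(sorted_vals, K) {
  N <- length(sorted_vals)
  idx <- function(i) sorted_vals[min(max(i, 1L), N)]
  if (N %% 2 == 1) {
    idx((N + 1) / 2 + K)
  } else {
    (idx(N / 2 + K) + idx(N / 2 + 1 + K)) / 2
  }
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf(
    "Passing-Bablok (n = %d, %d pairwise slopes):\n  slope %.4f [%.4f, %.4f] (angle %.2f deg), intercept %.4f\n",
    x$n, x$n_pairwise_slopes, x$slope, x$slope_ci_low, x$slope_ci_high,
    x$slope_angle_deg, x$intercept))
  invisible(x)
}

#' @rdname passing_bablok
#' @param ... Unused.
#' @export
tidy.passing_bablok <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, x$slope_ci_low),
    conf.high = c(NA_real_, x$slope_ci_high)
  )
}

#' @rdname passing_bablok
#' @export
glance.passing_bablok <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 slope_angle_deg = x$slope_angle_deg,
                 slope_ci_low = x$slope_ci_low,
                 slope_ci_high = x$slope_ci_high,
                 n = x$n, n_pairwise_slopes = x$n_pairwise_slopes)
}

#' Coefficient of variation for repeated measurements
#'
#' Bland's within-subject CV for repeated (k >= 2) measurements: each
#' subject's within-subject variance `s_i^2` (sample variance across its
#' replicates) is divided by its squared mean `m_i^2`, and the CV is the
#' root of the mean of those ratios, `100 * sqrt(mean(s_i^2 / m_i^2))`
#' (`method = "rms"`). The alternative log-method estimates the
#' within-subject SD of the log values: `100 * (exp(s_w) - 1)` with
#' `s_w^2 = mean(var(log(values)))`.
#'
#' @param data Long data frame of repeated measurements.
#' @param subject,value Columns with the subject identifier and the measured
#'   value (tidy-eval).
#' @param method `"rms"` (Bland's duplicate formula; default) or `"log"`.
#' @return Object of class `cv_result`: `cv_percent`, `n_subjects`, `k`,
#'   `rating` (see [rate_cv()]) and `method`. Supports `tidy()`.
#' @export
#' @examples
#' d <- tibble::tibble(id = rep(1:3, each = 2),
#'                     v = c(10, 11, 20, 19, 30, 33))
#' cv_repeated(d, id, v)
cv_repeated <- function(data, subject, value, method = c("rms", "log")) {
  method <- match.arg(method)
  subj <- rlang::eval_tidy(rlang::enquo(subject), data)
  val <- rlang::eval_tidy(rlang::enquo(value), data)
  if (!all(is.finite(val))) stop("values must be finite", call. = FALSE)
  groups <- split(val, subj)
  k <- unique(vapply(groups, length, integer(1)))
  if (length(k) != 1 || k < 2) {
    stop("every subject needs the same number k >= 2 of replicates",
         call. = FALSE)
  }
  m <- vapply(groups, mean, numeric(1))
  if (any(m <= 0)) {
    stop("nonpositive subject mean: CV is undefined near zero",
         call. = FALSE)
  }
  s2 <- vapply(groups, stats::var, numeric(1))
  cv <- if (method == "rms") {
    100 * sqrt(mean(s2 / m^2))
  } else {
    s2l <- vapply(groups, function(g) stats::var(log(g)), numeric(1))
    100 * (exp(sqrt(mean(s2l))) - 1)
  }
  structure(list(cv_percent = cv, n_subjects = length(groups),
                 k = as.integer(k), rating = rate_cv(cv), method = method),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Within-subject CV (%s method): %.2f%% (%s) over %d subjects x %d replicates\n",
    x$method, x$cv_percent, x$rating, x$n_subjects, x$k))
  invisible(x)
}

#' @rdname cv_repeated
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(cv_percent = x$cv_percent, n_subjects = x$n_subjects,
                 k = x$k, rating = x$rating, method = x$method)
}

#' Rate a coefficient of variation for repeated measurements
#'
#' Standard rating scale: excellent below 3 percent, good at 3 to below 10,
#' moderate/fair at 10 to below 15, poor at 15 and above (boundaries belong
#' to the worse class).
#'
#' @param cv_percent Nonnegative CV value(s), percent.
#' @return Character vector of ratings.
#' @export
#' @examples
#' rate_cv(c(2.9, 8.26, 15))
rate_cv <- function(cv_percent) {
  if (any(!is.finite(cv_percent)) || any(cv_percent < 0)) {
    stop("invalid value: CV must be finite and >= 0", call. = FALSE)
  }
  cut(cv_percent, breaks = c(-Inf, 3, 10, 15, Inf), right = FALSE,
      labels = c("excellent", "good", "moderate/fair", "poor")) |>
    as.character()
}
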