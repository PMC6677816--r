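#' Doubling time from an OD600 growth curve
#'
#' Fits a least-squares line to `ln(OD)` versus time within a window and
#' reports the doubling time `ln(2) / slope`. With `window = "auto"` the
#' contiguous run of at least `min_points` points maximizing the fit R^2
#' (subject to a positive slope) is selected -- published doubling times
#' rarely state their fitting window, so the chosen window and diagnostics
#' are always exposed. An explicit window is a numeric range of times
#' `c(from, to)`. A non-positive slope (or no qualifying window) yields a
#' "no growth" marker rather than a number.
#'
#' @param data A data frame of one growth series.
#' @param time,od Column names (tidy-eval) holding time in hours (strictly
#'   increasing) and OD600 (> 0). Defaults `time_h`, `od600`.
#' @param window `"auto"` or a numeric `c(from, to)` time range.
#' @param min_points Minimum points in an auto-selected window (default 4).
#' @return An object of class `growth_fit`: `doubling_time` (hours, `NA` if
#'   no growth), `slope` (per hour), `r_squared`, `window` (time range used),
#'   `n_points`, `status` (`"ok"` or `"no_growth"`), and the data. `tidy()`
#'   and `glance()` return these as tibbles.
#' @examples
#' d <- tibble::tibble(time_h = 0:6, od600 = 0.01 * 2^(0:6))
#' glance(doubling_time(d))
#' @export
doubling_time <- function(data, time = time_h, od = od600,
                          window = "auto", min_points = 4L) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ od }})
  if (length(t) < 3) abort("Need at least 3 points in a growth series")
  if (any(diff(t) <= 0)) abort("Times must be strictly increasing")
  if (any(y <= 0)) abort("OD values must be positive")
  ly <- log(y)
  fit_window <- function(idx) {
    sl <- stats::cov(t[idx], ly[idx]) / stats::var(t[idx])
    r2 <- if (stats::var(ly[idx]) == 0) NA_real_ else
      stats::cor(t[idx], ly[idx])^2
    list(idx = idx, slope = sl, r2 = r2)
  }
  if (identical(window, "auto")) {
    n <- length(t)
    if (n < min_points) abort("Fewer points than min_points")
    best <- NULL
    for (i in seq_len(n - min_points + 1)) {
      for (j in seq(i + min_points - 1, n)) {
        f <- fit_window(i:j)
        if (is.na(f$r2) || f$slope <= 0) next
        better <- is.null(best) ||
          f$r2 > best$r2 + 1e-12 ||
          (abs(f$r2 - best$r2) <= 1e-12 &&
             (length(f$idx) > length(best$idx) ||
                (length(f$idx) == length(best$idx) &&
                   f$idx[1] < best$idx[1])))
        if (better) best <- f
      }
    }
    f <- best
  } else {
    stopifnot(is.numeric(window), length(window) == 2)
    idx <- which(t >= window[1] & t <= window[2])
    if (length(idx) < 3) abort("Fewer than 3 points in the explicit window")
    f <- fit_window(idx)
    if (is.na(f$r2) || f$slope <= 0) f <- NULL
  }
  if (is.null(f)) {
    out <- list(doubling_time = NA_real_, slope = NA_real_,
                r_squared = NA_real_, window = c(NA_real_, NA_real_),
                n_points = 0L, status = "no_growth",
                data = tibble(time_h = t, od600 = y))
  } else {
    out <- list(doubling_time = log(2) / f$slope, slope = f$slope,
                r_squared = f$r2,
                window = c(t[f$idx[1]], t[f$idx[length(f$idx)]]),
                n_points = length(f$idx), status = "ok",
                data = tibble(time_h = t, od600 = y))
  }
  structure(out, class = "growth_fit")
}

#' Doubling times for several labelled growth series
#'
#' @param data A data frame of stacked growth series.
#' @param time,od,label Tidy-eval column names; `label` distinguishes series.
#' @param ... Passed to [doubling_time()].
#' @return A tibble with one [glance()] row per label.
#' @export
doubling_times <- function(data, time = time_h, od = od600, label = label,
                           ...) {
  data |>
    dplyr::group_by({{ label }}) |>
    dplyr::group_modify(function(d, key) {
      glance(doubling_time(d, {{ time }}, {{ od }}, ...))
    }) |>
    dplyr::ungroup()
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$status == "no_growth") {
    cat("<growth_fit> no growth observed (NA)\n")
  } else {
    cat(sprintf(
      "<growth_fit> doubling time %.3f h (slope %.4f /h, R^2 %.4f, window %g-%g h, %d points)\n",
      x$doubling_time, x$slope, x$r_squared, x$window[1], x$window[2],
      x$n_points))
  }
  invisible(x)
}

#' @rdname doubling_time
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("slope", "doubling_time"),
         estimate = c(x$slope, x$doubling_time),
         unit = c("1/h", "h"))
}

#' @rdname doubling_time
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(doubling_time = x$doubling_time, slope = x$slope,
         r_squared = x$r_squared, window_from = x$window[1],
         window_to = x$window[2], n_points = x$n_points, status = x$status)
}

#' @rdname doubling_time
#' @param object A `growth_fit`.
#' @export
autoplot.growth_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$od600)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "OD600 (log scale)") +
    ggplot2::theme_minimal()
  if (object$status == "ok") {
    w <- object$window
    d <- object$data[object$data$time_h >= w[1] & object$data$time_h <= w[2], ]
    fit <- stats::lm(log(od600) ~ time_h, data = d)
    d$pred <- exp(stats::predict(fit))
    p <- p + ggplot2::geom_line(data = d,
                                ggplot2::aes(y = .data$pred),
                                colour = "red")
  }
  p
}

#' Read growth curves from TSV
#'
#' Expects columns `time_h`, `od600` and optionally `label`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_growth_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("time_h", "od600") %in% names(d))) {
    abort("Growth TSV needs columns time_h and od600")
  }
  d
}
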