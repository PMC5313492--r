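#' Bland-Altman agreement analysis
#'
#' Summarizes the agreement between two paired measurements of the same
#' quantity by the mean difference (bias, `x - y` convention), the SD of
#' the differences, and the 95% limits of agreement
#' `bias +/- 1.96 * sd`. The per-pair means and differences are returned
#' for plotting.
#'
#' @param x,y equal-length paired numeric vectors (n >= 2); pairs with a
#'   missing value are dropped.
#' @return A `bland_altman_result` with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and a `points` data frame (`mean`, `diff`).
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 2, 2))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2)
    stop("Bland-Altman needs at least 2 complete pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n = length(x),
                 points = data.frame(mean = (x + y) / 2, diff = d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %.4g, SD of differences %.4g\n", x$bias, x$sd_diff))
  cat(sprintf("  95%% limits of agreement [%.4g, %.4g]\n", x$loa_low,
              x$loa_high))
  invisible(x)
}
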