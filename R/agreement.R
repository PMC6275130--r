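#' Pair two rate series by window centre
#'
#' Matches each test window to the nearest reference window centre, keeping a
#' pair only when the offset is at most `max_offset_s` (default: half the
#' test series' hop). Each reference window is used at most once; unmatched
#' windows on either side are counted, not silently dropped. Only windows
#' valid in both series are paired.
#'
#' @param reference,test `rate_series` objects (events/min).
#' @param max_offset_s maximum window-centre offset for a match, seconds.
#' @return object of class `paired_rates`: list with numeric vectors
#'   `reference` and `test`, `n_pairs`, `n_unmatched`.
#' @export
pair_rate_series <- function(reference, test, max_offset_s = NULL) {
  stopifnot(inherits(reference, "rate_series"), inherits(test, "rate_series"))
  if (is.null(max_offset_s)) {
    max_offset_s <- attr(test, "hop_s") / 2
  }
  rok <- which(reference$valid & !is.na(reference$rate))
  tok <- which(test$valid & !is.na(test$rate))
  used <- logical(length(rok))
  ref_out <- test_out <- numeric(0)
  for (j in tok) {
    if (!length(rok)) break
    off <- abs(reference$window_center_s[rok] - test$window_center_s[j])
    i <- which.min(ifelse(used, Inf, off))
    if (!used[i] && off[i] <= max_offset_s) {
      used[i] <- TRUE
      ref_out <- c(ref_out, reference$rate[rok[i]])
      test_out <- c(test_out, test$rate[j])
    }
  }
  structure(
    list(reference = ref_out, test = test_out, n_pairs = length(ref_out),
         n_unmatched = (length(tok) - length(test_out)) +
           (length(rok) - sum(used))),
    class = "paired_rates"
  )
}

#' Construct paired rates directly
#'
#' @param reference,test equal-length numeric vectors of rates (events/min).
#' @return a `paired_rates` object.
#' @export
paired_rates <- function(reference, test) {
  if (!is.numeric(reference) || !is.numeric(test) ||
      length(reference) != length(test)) {
    stop_invalid_input("reference and test must be numeric vectors of equal length")
  }
  structure(
    list(reference = as.numeric(reference), test = as.numeric(test),
         n_pairs = length(reference), n_unmatched = 0L),
    class = "paired_rates"
  )
}

#' Bland-Altman agreement statistics
#'
#' For paired differences d = test - reference: the mean error, the sample
#' standard deviation of the differences (n - 1 divisor, standard
#' Bland-Altman practice), the 95% limits of agreement mean +/- 1.96 SD, and
#' the root-mean-square error sqrt(mean(d^2)). Per-pair (average, difference)
#' coordinates are returned for plotting.
#'
#' @param pairs a `paired_rates` object.
#' @return object of class `agreement_stats`: list with `mean_error`,
#'   `sd_error`, `loa_lower`, `loa_upper`, `rmse`, `n_pairs`, and a
#'   data.frame `points` with columns `average`, `difference`.
#' @examples
#' bland_altman(paired_rates(c(60, 62, 64), c(61, 61, 66)))
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_rates"))
  if (pairs$n_pairs < 2L) {
    stop_insufficient_data("Bland-Altman requires at least 2 pairs")
  }
  d <- pairs$test - pairs$reference
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      mean_error = m,
      sd_error = s,
      loa_lower = m - 1.96 * s,
      loa_upper = m + 1.96 * s,
      rmse = sqrt(mean(d^2)),
      n_pairs = pairs$n_pairs,
      points = data.frame(average = (pairs$test + pairs$reference) / 2,
                          difference = d)
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement_stats> n = %d pairs\n",
           "  mean error %.3f, SD %.3f, RMSE %.3f\n",
           "  95%% limits of agreement [%.3f, %.3f]\n"),
    x$n_pairs, x$mean_error, x$sd_error, x$rmse, x$loa_lower, x$loa_upper
  ))
  invisible(x)
}

#' Two-column error table (heartbeat vs respiration)
#'
#' @param stats_hr,stats_rr `agreement_stats` for the heartbeat and
#'   respiration comparisons.
#' @return object of class `agreement_table`: a data.frame with rows RMSE
#'   and SD and columns `heartbeat`, `respiration`.
#' @export
agreement_table <- function(stats_hr, stats_rr) {
  stopifnot(inherits(stats_hr, "agreement_stats"),
            inherits(stats_rr, "agreement_stats"))
  structure(
    data.frame(
      heartbeat = c(stats_hr$rmse, stats_hr$sd_error),
      respiration = c(stats_rr$rmse, stats_rr$sd_error),
      row.names = c("RMSE", "SD")
    ),
    class = c("agreement_table", "data.frame")
  )
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against averages with the mean-error line
#' and the 1.96 SD limit lines.
#'
#' @param stats an `agreement_stats` object.
#' @param xlab,ylab,main plot labels.
#' @param ... further arguments passed to `plot()`.
#' @return `stats`, invisibly.
#' @export
plot_bland_altman <- function(stats, xlab = "average (events/min)",
                              ylab = "difference (events/min)",
                              main = "Bland-Altman", ...) {
  stopifnot(inherits(stats, "agreement_stats"))
  graphics::plot(stats$points$average, stats$points$difference,
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::abline(h = stats$mean_error, lty = 2, col = "grey40")
  graphics::abline(h = c(stats$loa_lower, stats$loa_upper), lty = 3,
                   col = "grey20")
  invisible(stats)
}
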