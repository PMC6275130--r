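#' Distribution shape (length and height) of a rate series
#'
#' The health statistic this package computes is built from two features of
#' the distribution of windowed rate estimates: its *length* L — the span of
#' observed rates — and its *height* h — how many windows fall in the most
#' populated bin. A narrow, tall distribution (small L, large h) indicates a
#' steady rate; a wide, flat one indicates a disordered cardiorespiratory
#' system.
#'
#' Two conventions are provided. `"histogram"` (default) is empirical:
#' L = max(rate) - min(rate), h = the maximal count of a histogram with bins
#' of `bin_width` anchored at multiples of `bin_width`. `"normal"` fits a
#' normal distribution: L = 2 z sd (z defaults to 2, covering ~95% of mass)
#' and h = the expected count in the modal bin,
#' n * bin_width * dnorm(mean; mean, sd). The convention used is recorded in
#' the result.
#'
#' @param series a `rate_series` (or numeric vector of rates).
#' @param bin_width histogram bin width in rate units (default 1).
#' @param method `"histogram"` or `"normal"`.
#' @param z half-width of the normal-fit length in SD units (default 2,
#'   only used by `method = "normal"`).
#' @param min_windows minimum number of valid windows required (default 10).
#' @return object of class `distribution_shape`: list with `length_L`,
#'   `height_h`, `bin_width`, `n_samples`, `kind`, `method`, `degenerate`.
#' @export
estimate_distribution_shape <- function(series, bin_width = 1,
                                        method = c("histogram", "normal"),
                                        z = 2, min_windows = 10L) {
  method <- match.arg(method)
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    stop_invalid_config("'bin_width' must be a positive number")
  }
  if (inherits(series, "rate_series")) {
    r <- series$rate[series$valid & !is.na(series$rate)]
    kind <- attr(series, "kind")
  } else if (is.numeric(series)) {
    r <- series[!is.na(series)]
    kind <- "heartbeat"
  } else {
    stop_invalid_input("'series' must be a rate_series or numeric vector")
  }
  if (length(r) < min_windows) {
    stop_insufficient_data(sprintf(
      "need at least %d valid windows for a distribution shape, got %d",
      min_windows, length(r)
    ))
  }
  degenerate <- max(r) == min(r)
  if (method == "histogram" || degenerate) {
    L <- max(r) - min(r)
    counts <- table(floor(r / bin_width))
    h <- as.integer(max(counts))
  } else {
    mu <- mean(r)
    s <- stats::sd(r)
    L <- 2 * z * s
    h <- length(r) * bin_width * stats::dnorm(mu, mu, s)
  }
  structure(
    list(length_L = L, height_h = h, bin_width = bin_width,
         n_samples = length(r), kind = kind, method = method,
         degenerate = degenerate),
    class = "distribution_shape"
  )
}

#' Construct a distribution shape from known length and height
#'
#' For computing the healthy measure from externally reported distribution
#' features.
#'
#' @param length_L distribution length in rate units, >= 0.
#' @param height_h modal bin count, >= 1.
#' @param kind `"heartbeat"` or `"respiration"`.
#' @param bin_width bin width the height refers to (default 1).
#' @return a `distribution_shape`.
#' @examples
#' healthy_measure(distribution_shape(length_L = 17, height_h = 10))
#' @export
distribution_shape <- function(length_L, height_h,
                               kind = c("heartbeat", "respiration"),
                               bin_width = 1) {
  kind <- match.arg(kind)
  if (!is_scalar_number(length_L) || length_L < 0) {
    stop_invalid_input("'length_L' must be >= 0")
  }
  if (!is_scalar_number(height_h) || height_h < 0) {
    stop_invalid_input("'height_h' must be >= 0")
  }
  structure(
    list(length_L = length_L, height_h = height_h, bin_width = bin_width,
         n_samples = NA_integer_, kind = kind, method = "supplied",
         degenerate = length_L == 0),
    class = "distribution_shape"
  )
}

#' @export
print.distribution_shape <- function(x, ...) {
  cat(sprintf("<distribution_shape> %s: L = %g, h = %g (%s%s)\n",
              x$kind, x$length_L, x$height_h, x$method,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Healthy measure of a rate distribution
#'
#' The ratio length / height of the rate distribution: larger values mean a
#' wider, flatter distribution, i.e. a more disordered heartbeat or
#' respiration pattern. For the printed healthy-subject heartbeat
#' distribution with length 17 and height 10 the measure is 1.7.
#'
#' @param shape a `distribution_shape`.
#' @return object of class `healthy_measure`: list with `value` and `kind`.
#' @examples
#' healthy_measure(distribution_shape(17, 10)) # value 1.7
#' @export
healthy_measure <- function(shape) {
  stopifnot(inherits(shape, "distribution_shape"))
  if (shape$height_h <= 0) {
    scg_stop("degenerate distribution: height is zero",
             "scg_degenerate_distribution")
  }
  structure(
    list(value = shape$length_L / shape$height_h, kind = shape$kind,
         degenerate = isTRUE(shape$degenerate)),
    class = "healthy_measure"
  )
}

#' @export
print.healthy_measure <- function(x, ...) {
  cat(sprintf("<healthy_measure> %s: %.4g\n", x$kind, x$value))
  invisible(x)
}

#' Default class borders for the healthy measure
#'
#' Thresholds separating the three classes (healthy, entering emergency,
#' dangerous). The per-class measures observed in the underlying study are
#' 1.7 / 5.56 / 9.88 for heartbeat and 1.54 / 1.9 / 2.3 for respiration;
#' the default borders are the midpoints between consecutive class values.
#' They carry no claim of clinical validity and are fully configurable.
#'
#' @param kind `"heartbeat"` or `"respiration"`.
#' @return numeric length-2 vector (lower, upper), strictly increasing.
#' @export
default_class_borders <- function(kind = c("heartbeat", "respiration")) {
  kind <- match.arg(kind)
  if (kind == "heartbeat") {
    c((1.7 + 5.56) / 2, (5.56 + 9.88) / 2)
  } else {
    c((1.54 + 1.9) / 2, (1.9 + 2.3) / 2)
  }
}

#' Classify a healthy measure into the three-class scheme
#'
#' A step function of the measure: below the lower border is `healthy`,
#' from the lower border up to (but not including) the upper border is
#' `emergency`, and at or above the upper border is `dangerous`. Boundary
#' values belong to the more severe class.
#'
#' @param measure a `healthy_measure` (or a bare number, with `kind`).
#' @param borders strictly increasing numeric length-2 vector; defaults to
#'   [default_class_borders()] for the measure's kind.
#' @param kind used only when `measure` is a bare number.
#' @return object of class `health_class`: list with `label` (factor level
#'   among healthy/emergency/dangerous), `borders`, `measure`.
#' @examples
#' classify_health(healthy_measure(distribution_shape(17, 10)))
#' @export
classify_health <- function(measure, borders = NULL,
                            kind = c("heartbeat", "respiration")) {
  if (is.numeric(measure)) {
    kind <- match.arg(kind)
    measure <- structure(list(value = measure, kind = kind),
                         class = "healthy_measure")
  }
  stopifnot(inherits(measure, "healthy_measure"))
  if (is.null(borders)) borders <- default_class_borders(measure$kind)
  if (length(borders) != 2L || !is.numeric(borders) ||
      !(borders[1L] < borders[2L])) {
    stop_invalid_config("'borders' must be two strictly increasing numbers")
  }
  label <- if (measure$value < borders[1L]) {
    "healthy"
  } else if (measure$value < borders[2L]) {
    "emergency"
  } else {
    "dangerous"
  }
  structure(
    list(label = label, borders = as.numeric(borders), measure = measure),
    class = "health_class"
  )
}

#' @export
print.health_class <- function(x, ...) {
  cat(sprintf("<health_class> %s: measure %.4g vs borders (%.4g, %.4g) -> %s\n",
              x$measure$kind, x$measure$value, x$borders[1L], x$borders[2L],
              x$label))
  invisible(x)
}
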