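# Internal helpers: classed conditions and rolling statistics.

scg_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "scg_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

stop_invalid_config <- function(msg) scg_stop(msg, "scg_invalid_config")
stop_invalid_trace <- function(msg) scg_stop(msg, "scg_invalid_trace")
stop_invalid_filter <- function(msg) scg_stop(msg, "scg_invalid_filter")
stop_insufficient_data <- function(msg) scg_stop(msg, "scg_insufficient_data")
stop_no_valid_data <- function(msg) scg_stop(msg, "scg_no_valid_data")
stop_invalid_input <- function(msg) scg_stop(msg, "scg_invalid_input")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Rolling mean and standard deviation over a centred window
#'
#' Exact O(n) rolling first and second moments via cumulative sums. Windows
#' are truncated at the edges of the series (the count shrinks, no padding),
#' and the returned standard deviation is the population form, which is what
#' the peak-detection threshold uses.
#'
#' @param x numeric vector.
#' @param half_width integer, samples on each side of the centre.
#' @return list with numeric vectors `mean` and `sd` of `length(x)`.
#' @keywords internal
#' @noRd
rolling_moments <- function(x, half_width) {
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(1L, i - half_width)
  hi <- pmin(n, i + half_width)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  cnt <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  m <- s / cnt
  v <- pmax(0, s2 / cnt - m * m)
  list(mean = m, sd = sqrt(v))
}

# Rolling maximum over a centred window (van Herk two-pass block scheme,
# O(n)); edges use the truncated window.
rolling_max <- function(x, half_width) {
  n <- length(x)
  w <- 2L * half_width + 1L
  if (w >= n) return(rep(max(x), n))
  nblk <- ceiling(n / w)
  pad <- nblk * w
  xp <- c(x, rep(-Inf, pad - n))
  m <- matrix(xp, nrow = w)
  pre <- apply(m, 2, cummax)
  suf <- apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  pre <- as.numeric(pre)
  suf <- as.numeric(suf)
  i <- seq_len(n)
  lo <- pmax(1L, i - half_width)
  hi <- pmin(n, i + half_width)
  pmax(suf[lo], pre[hi])
}

# Deterministic local RNG: evaluates expr with the seed set, restoring the
# caller's RNG state afterwards so simulation calls do not perturb sessions.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
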