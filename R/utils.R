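# Shared numeric helpers: histogramming, Gaussian histogram fits, misc checks.

abort_config <- function(msg) abort(msg, class = "rodfold_config_error")
abort_input <- function(msg) abort(msg, class = "rodfold_input_error")

check_number <- function(x, name, lower = -Inf, strict = FALSE, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort_config(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", lower))
  }
  invisible(x)
}

#' Freedman-Diaconis bin width
#'
#' Bin width `2 * IQR(x) / n^(1/3)`, optionally rounded to the nearest
#' multiple of `round_to` (never below `round_to` itself) as is conventional
#' when presenting distance histograms with round bin edges.
#'
#' @param x Numeric vector of observations.
#' @param round_to Round to the nearest multiple of this value; `NULL` leaves
#'   the raw width.
#' @return A single bin width in the units of `x`.
#' @export
#' @examples
#' fd_bin_width(rnorm(100, 54, 15), round_to = 5)
fd_bin_width <- function(x, round_to = NULL) {
  if (length(x) < 2) abort_input("need at least 2 values for a bin width")
  w <- 2 * IQR(x) / length(x)^(1 / 3)
  if (!is.null(round_to)) {
    w <- max(round_to, round_to * round(w / round_to))
  }
  w
}

# Histogram counts on edges covering all of x; returns centers + counts.
hist_counts <- function(x, bin_width, origin = NULL) {
  if (is.null(origin)) origin <- bin_width * floor(min(x) / bin_width)
  edges <- seq(origin, max(x) + bin_width, by = bin_width)
  if (max(edges) <= max(x)) edges <- c(edges, max(edges) + bin_width)
  idx <- findInterval(x, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  tibble(
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = counts
  )
}

# Least-squares Gaussian A*exp(-(x-mu)^2/(2*sd^2)) fitted to histogram counts.
# Returns list(mean, sd, amplitude, converged, degenerate).
fit_gaussian_histogram <- function(mid, count) {
  keep <- count > 0
  if (sum(keep) < 2) {
    return(list(
      mean = if (any(keep)) mid[which.max(count)] else NA_real_,
      sd = 0, amplitude = max(count), converged = TRUE, degenerate = TRUE
    ))
  }
  w <- count / sum(count)
  mu0 <- sum(mid * w)
  sd0 <- sqrt(max(sum((mid - mu0)^2 * w), (mid[2] - mid[1])^2 / 12))
  a0 <- max(count)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      count ~ A * exp(-(mid - mu)^2 / (2 * s^2)),
      start = list(A = a0, mu = mu0, s = sd0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(mean = mu0, sd = sd0, amplitude = a0, converged = FALSE, degenerate = FALSE))
  }
  p <- coef(fit)
  list(
    mean = unname(p[["mu"]]), sd = abs(unname(p[["s"]])),
    amplitude = unname(p[["A"]]), converged = TRUE, degenerate = FALSE
  )
}

# Draw a fresh integer seed stream: deterministic children of a parent seed.
# Kept below 2^31 and exact in double arithmetic.
child_seeds <- function(seed, n) {
  s <- as.double(seed) %% 2147483647
  ((s * 69069 + 12345 + seq_len(n) * 104729) %% 2147483647)
}
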