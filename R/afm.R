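# Force-extension analysis: sawtooth peak detection, one-parameter
# worm-like-chain contour-length fits, contour-length increments, E/G5 event
# classification, modal statistics and retraction-speed dependence.

#' Worm-like chain interpolation force
#'
#' Marko-Siggia interpolation
#' `F = (kBT/p) * (1/(4 (1 - x/Lc)^2) - 1/4 + x/Lc)`, with kBT = 4.114 pN nm
#' at 298 K. Diverges as `x -> Lc`; `x >= Lc` is a domain error.
#'
#' @param x Extension (nm), `0 <= x < Lc`.
#' @param Lc Contour length (nm).
#' @param p Persistence length (nm), default 0.4.
#' @param temperature_K Temperature (K); 298 by default.
#' @return Force in pN.
#' @export
#' @examples
#' wlc_force(50, Lc = 100, p = 0.4)  # x/Lc = 0.5 -> 12.86 pN
wlc_force <- function(x, Lc, p = 0.4, temperature_K = 298) {
  if (p <= 0 || Lc <= 0) abort_input("`Lc` and `p` must be > 0")
  if (any(x < 0) || any(x >= Lc)) {
    abort_input("extension must satisfy 0 <= x < Lc (force diverges at Lc)")
  }
  kBT <- KBT_PN_NM * temperature_K / 298
  u <- x / Lc
  (kBT / p) * (1 / (4 * (1 - u)^2) - 0.25 + u)
}

#' Detect unfolding peaks in a force-extension trace
#'
#' Finds local maxima of the (lightly smoothed) force that are followed by a
#' drop of at least `min_drop` pN within `drop_window` samples and exceed
#' `min_force` pN. The final peak is labelled the detachment event. An empty
#' result is valid (e.g. a pure-noise trace).
#'
#' @param trace Data frame with columns `extension_nm` and `force_pN`
#'   (extension non-decreasing).
#' @param min_drop Minimum force drop after a peak (pN). Default 30.
#' @param min_force Minimum peak force (pN). Default 50.
#' @param smooth_window Running-mean window (samples) applied before peak
#'   finding. Default 5.
#' @param drop_window Samples after the peak within which the drop must
#'   occur. Default 20.
#' @return Tibble of peaks ordered by extension: `peak_index`,
#'   `extension_nm`, `force_pN` (smoothed force at the peak),
#'   `is_detachment`.
#' @export
detect_events <- function(trace, min_drop = 30, min_force = 50,
                          smooth_window = 5, drop_window = 20) {
  trace <- as_tibble(trace)
  if (!all(c("extension_nm", "force_pN") %in% names(trace))) {
    abort_input("`trace` needs columns `extension_nm` and `force_pN`")
  }
  f <- running_mean(trace$force_pN, smooth_window)
  n <- length(f)
  empty <- tibble(peak_index = integer(0), extension_nm = numeric(0),
                  force_pN = numeric(0), is_detachment = logical(0))
  if (n < 3) return(empty)

  half <- 3L
  is_max <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    f[i] >= max(f[lo:hi]) && f[i] >= min_force
  }, logical(1))
  cand <- which(is_max)
  peaks <- integer(0)
  for (i in cand) {
    hi <- min(n, i + drop_window)
    if (min(f[i:hi]) <= f[i] - min_drop) peaks <- c(peaks, i)
  }
  if (!length(peaks)) return(empty)
  # merge candidates closer than the drop window (same sawtooth: noise maxima
  # on the rising edge within drop_window of the rupture also pass the test)
  grp <- cumsum(c(TRUE, diff(peaks) > drop_window))
  peaks <- vapply(split(peaks, grp), function(ix) ix[which.max(f[ix])], integer(1))
  peaks <- sort(unname(peaks))

  # refine each peak to the sample just before the sharpest raw force drop
  # (the rupture), then average a few rising-edge samples so the reported
  # force is not the extreme of the local noise
  raw <- trace$force_pN
  refined <- vapply(peaks, function(i) {
    lo <- max(1, i - smooth_window); hi <- min(n - 1, i + drop_window)
    (lo:hi)[which.min(raw[(lo:hi) + 1] - raw[lo:hi])]
  }, integer(1))
  refined <- refined[!duplicated(refined)]
  peak_force <- vapply(refined, function(i) {
    mean(raw[max(1, i - 2):i])
  }, numeric(1))

  out <- tibble(
    peak_index = refined,
    extension_nm = trace$extension_nm[refined],
    force_pN = peak_force,
    is_detachment = FALSE
  )
  out$is_detachment[nrow(out)] <- TRUE
  out
}

running_mean <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2)) -> y
  # fill the edges with the raw values
  bad <- is.na(y)
  y[bad] <- x[bad]
  y
}

#' Fit a worm-like chain to the rising edge before a peak
#'
#' One-parameter least-squares fit of [wlc_force()] in the contour length
#' `Lc`, with the persistence length held fixed (400 pm by default). The
#' extension axis is the tip-sample separation corrected for cantilever
#' deflection.
#'
#' @param trace Data frame with `extension_nm`, `force_pN`.
#' @param range Integer indices of the segment (>= 15 points).
#' @param p Persistence length (nm), fixed.
#' @param min_force_fit Only points above this force (pN) enter the fit
#'   (avoids the noise floor). Default 20.
#' @return An object of class `wlc_fit`: `Lc_nm`, `p_nm`, `range`,
#'   `residual_norm`, `converged`, `n_points`.
#' @export
fit_segment <- function(trace, range, p = 0.4, min_force_fit = 20) {
  trace <- as_tibble(trace)
  if (length(range) < 15) abort_input("segment needs >= 15 points")
  x <- trace$extension_nm[range]
  f <- trace$force_pN[range]
  keep <- f > min_force_fit
  if (sum(keep) < 10) {
    return(structure(list(Lc_nm = NA_real_, p_nm = p, range = range,
                          residual_norm = NA_real_, converged = FALSE,
                          n_points = sum(keep)),
                     class = "wlc_fit"))
  }
  x <- x[keep]; f <- f[keep]
  xmax <- max(x)
  sse <- function(Lc) sum((wlc_force(x, Lc, p) - f)^2)
  opt <- optimize(sse, interval = c(xmax * 1.001 + 1e-6, xmax * 20 + 50))
  structure(
    list(Lc_nm = opt$minimum, p_nm = p, range = range,
         residual_norm = sqrt(opt$objective), converged = TRUE,
         n_points = length(x)),
    class = "wlc_fit"
  )
}

#' Contour-length increments between consecutive fitted segments
#'
#' `dLc_i = Lc_{i+1} - Lc_i`: the contour length released by the domain that
#' ruptured at peak i. A non-positive increment is flagged `"other"`.
#'
#' @param Lc Numeric vector of fitted contour lengths (nm), ordered by
#'   extension, length >= 2.
#' @return Tibble with `event`, `Lc_before_nm`, `dLc_nm`.
#' @export
delta_lc <- function(Lc) {
  if (length(Lc) < 2) abort_input("need >= 2 fitted segments")
  tibble(
    event = seq_len(length(Lc) - 1),
    Lc_before_nm = Lc[-length(Lc)],
    dLc_nm = diff(Lc)
  )
}

#' Classify an unfolding event by its contour-length increment
#'
#' Window defaults bracket the measured per-speed ranges: E domains release
#' 145-154 A and G5 domains 216-227 A, so increments in `[12, 18.5)` nm are
#' E, `[18.5, 26]` nm are G5, anything else `"other"`.
#'
#' @param dLc_nm Contour-length increment(s) in nm.
#' @param e_window,g5_window Class windows in nm (half-open / closed).
#' @return Character vector: `"E"`, `"G5"` or `"other"`.
#' @export
#' @examples
#' classify_event(c(14.5, 21.6, 30))
classify_event <- function(dLc_nm, e_window = c(12, 18.5), g5_window = c(18.5, 26)) {
  dplyr::case_when(
    !is.finite(dLc_nm) ~ "other",
    dLc_nm >= e_window[1] & dLc_nm < e_window[2] ~ "E",
    dLc_nm >= g5_window[1] & dLc_nm <= g5_window[2] ~ "G5",
    TRUE ~ "other"
  )
}

#' Modal statistics from a Gaussian fit to a histogram
#'
#' Histograms the values (5 A bins for contour-length increments,
#' Freedman-Diaconis bins for forces, or any explicit width) and fits a
#' Gaussian to the bin counts; the reported mode is the fitted mean and the
#' spread the fitted sigma. Refuses fewer than `min_n` values.
#'
#' @param values Numeric vector (>= `min_n`).
#' @param bin_width Histogram bin width in the units of `values`, or `NULL`
#'   for the Freedman-Diaconis width.
#' @param min_n Minimum number of values for a reported mode. Default 20.
#' @return An object of class `modal_stat`: `mode`, `sd`, `n`, `bin_width`,
#'   `bins`, `degenerate`.
#' @export
modal_stats <- function(values, bin_width = NULL, min_n = 20) {
  values <- values[is.finite(values)]
  if (length(values) < min_n) {
    abort_input(sprintf("need >= %d values for a modal estimate; have %d",
                        min_n, length(values)))
  }
  if (length(unique(values)) == 1L) {
    return(structure(list(mode = values[1], sd = 0, n = length(values),
                          bin_width = bin_width %||% 0, bins = NULL,
                          degenerate = TRUE),
                     class = "modal_stat"))
  }
  if (is.null(bin_width)) bin_width <- fd_bin_width(values)
  bins <- hist_counts(values, bin_width)
  g <- fit_gaussian_histogram(bins$mid, bins$count)
  if (g$degenerate) {
    # essentially a single occupied bin: the sample centre beats the bin mid
    g$mean <- median(values)
    g$sd <- sd(values)
  }
  structure(
    list(mode = g$mean, sd = g$sd, n = length(values), bin_width = bin_width,
         bins = bins, degenerate = g$degenerate),
    class = "modal_stat"
  )
}

#' @export
print.modal_stat <- function(x, ...) {
  cat(sprintf("mode %.2f +/- %.2f (Gaussian fit, n = %d, bin %.3g)%s\n",
              x$mode, x$sd, x$n, x$bin_width,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Speed dependence of the modal unfolding force
#'
#' Weighted linear regression of the modal force on the natural log of the
#' retraction speed. Under the Bell-Evans picture the slope is `kBT / xu`,
#' so the distance to the transition state is estimated as
#' `xu = kBT / slope`.
#'
#' @param data Data frame with columns `speed` (nm/s) and `force_mode` (pN),
#'   optionally `force_sd` and `n` for weights (`n / force_sd^2`).
#' @return Tibble with `slope_pN` (per e-fold of speed), `slope_se`,
#'   `intercept_pN`, `xu_nm`, `n_speeds`.
#' @export
speed_series <- function(data) {
  data <- as_tibble(data)
  if (!all(c("speed", "force_mode") %in% names(data))) {
    abort_input("`data` needs columns `speed` and `force_mode`")
  }
  if (nrow(data) < 3) abort_input("need >= 3 speeds")
  w <- if (all(c("force_sd", "n") %in% names(data))) {
    data$n / data$force_sd^2
  } else {
    rep(1, nrow(data))
  }
  fit <- lm(force_mode ~ log(speed), data = data, weights = w)
  sl <- coef(fit)[["log(speed)"]]
  tibble(
    slope_pN = sl,
    slope_se = summary(fit)$coefficients["log(speed)", "Std. Error"],
    intercept_pN = coef(fit)[["(Intercept)"]],
    xu_nm = KBT_PN_NM / sl,
    n_speeds = nrow(data)
  )
}

#' Accept or reject an analyzed trace
#'
#' A trace is acceptable when it has at least `min_events` classified
#' unfolding events, ends in a detachment peak, and its per-class counts do
#' not exceed the construct composition (at most `max_e` E and `max_g5` G5
#' events for the seven-G5/six-E construct).
#'
#' @param events Analyzed event table with columns `class` and
#'   `is_detachment` (as from [afm_analyze_trace()]).
#' @param min_events Minimum classified unfolding events. Default 3.
#' @param max_e,max_g5 Composition bounds. Defaults 6 and 7.
#' @return List with `accepted` (logical) and `reason` (NA when accepted).
#' @export
accept_trace <- function(events, min_events = 3, max_e = 6, max_g5 = 7) {
  events <- as_tibble(events)
  n_e <- sum(events$class == "E", na.rm = TRUE)
  n_g5 <- sum(events$class == "G5", na.rm = TRUE)
  has_detach <- nrow(events) > 0 && any(events$is_detachment)
  reason <- if (n_e + n_g5 < min_events) {
    "too few events"
  } else if (!has_detach) {
    "no detachment peak"
  } else if (n_e > max_e || n_g5 > max_g5) {
    "exceeds composition"
  } else {
    NA_character_
  }
  list(accepted = is.na(reason), reason = reason)
}

#' Analyze one force-extension trace end to end
#'
#' Peak detection, per-segment worm-like-chain fits on the rising edges,
#' contour-length increments, event classification and trace acceptance.
#'
#' @param trace Data frame with `extension_nm`, `force_pN` (and optionally
#'   `time_s`).
#' @param p Persistence length (nm), fixed in all fits.
#' @param min_drop,min_force Passed to [detect_events()].
#' @param e_window,g5_window Passed to [classify_event()].
#' @param ... Further arguments to [detect_events()].
#' @return A list of class `afm_analysis`: `events` (tibble with peak force,
#'   fitted `Lc_nm`, `dLc_nm`, `class`, `is_detachment`), `accepted`,
#'   `reason`.
#' @export
afm_analyze_trace <- function(trace, p = 0.4, min_drop = 30, min_force = 50,
                              e_window = c(12, 18.5), g5_window = c(18.5, 26),
                              ...) {
  trace <- as_tibble(trace)
  peaks <- detect_events(trace, min_drop = min_drop, min_force = min_force, ...)
  if (!nrow(peaks)) {
    return(structure(list(events = peaks, accepted = FALSE,
                          reason = "no peaks"), class = "afm_analysis"))
  }
  starts <- c(1L, head(peaks$peak_index, -1) + 3L)
  fits <- purrr::map2(starts, peaks$peak_index, function(a, b) {
    if (b - a + 1 < 15) return(NULL)
    fit_segment(trace, a:b, p = p)
  })
  Lc <- vapply(fits, function(f) {
    if (is.null(f) || !f$converged) NA_real_ else f$Lc_nm
  }, numeric(1))
  events <- peaks
  events$Lc_nm <- Lc
  events$dLc_nm <- c(diff(Lc), NA_real_)
  events$class <- ifelse(events$is_detachment, "detachment",
                         classify_event(events$dLc_nm,
                                        e_window = e_window,
                                        g5_window = g5_window))
  acc <- accept_trace(events)
  structure(list(events = events, accepted = acc$accepted, reason = acc$reason),
            class = "afm_analysis")
}

#' Pool analyzed traces and compute per-class modal statistics
#'
#' Runs [afm_analyze_trace()] on each trace, pools classified events from
#' accepted traces (mirroring the pooling of experimental triplicates within
#' a speed), and reports modal force and contour-length increment per class
#' from Gaussian histogram fits (0.5 nm = 5 A bins for increments,
#' Freedman-Diaconis for forces).
#'
#' @param traces List of force-extension data frames.
#' @param ... Passed to [afm_analyze_trace()].
#' @return A list of class `afm_pool`: `events` (pooled tibble with a
#'   `trace_id` column), `summary` (tibble per class: `n`, `force_mode_pN`,
#'   `force_sd_pN`, `dLc_mode_A`, `dLc_sd_A`), `n_accepted`, `n_traces`.
#' @export
afm_pool_traces <- function(traces, ...) {
  analyses <- purrr::imap(traces, function(tr, i) {
    a <- afm_analyze_trace(tr, ...)
    if (!a$accepted || !nrow(a$events)) return(NULL)
    ev <- a$events
    ev$trace_id <- i
    ev
  })
  kept <- analyses[!vapply(analyses, is.null, logical(1))]
  events <- if (length(kept)) list_rbind(kept) else tibble()
  classified <- if (nrow(events)) {
    dplyr::filter(events, .data$class %in% c("E", "G5"))
  } else {
    events
  }
  summary <- if (nrow(classified)) {
    classified |>
      group_by(.data$class) |>
      summarise(
        n = dplyr::n(),
        force_mode_pN = modal_stats(.data$force_pN)$mode,
        force_sd_pN = modal_stats(.data$force_pN)$sd,
        dLc_mode_A = 10 * modal_stats(.data$dLc_nm, bin_width = 0.5)$mode,
        dLc_sd_A = 10 * modal_stats(.data$dLc_nm, bin_width = 0.5)$sd,
        .groups = "drop"
      )
  } else {
    tibble()
  }
  structure(
    list(events = events, summary = summary,
         n_accepted = length(kept), n_traces = length(traces)),
    class = "afm_pool"
  )
}

#' @export
print.afm_pool <- function(x, ...) {
  cat(sprintf("AFM pool: %d/%d traces accepted, %d events\n",
              x$n_accepted, x$n_traces, nrow(x$events)))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}
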