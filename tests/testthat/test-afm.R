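# Force-extension analysis: WLC mechanics, peak detection, contour-length
# fits and increments, classification, modal statistics, speed dependence.

test_that("the Marko-Siggia force follows its closed form", {
  expect_equal(wlc_force(0, Lc = 100), 0)
  # x/Lc = 1/2, p = 0.4 nm: (4.114 / 0.4) * (1 - 1/4 + 1/2) = 12.85625 pN
  expect_equal(wlc_force(50, Lc = 100, p = 0.4), (4.114 / 0.4) * 1.25,
               tolerance = 1e-12)
  x <- seq(0, 99, by = 0.5)
  expect_true(all(diff(wlc_force(x, Lc = 100)) > 0))
  expect_error(wlc_force(100, Lc = 100), "diverges")
  expect_error(wlc_force(-1, Lc = 100))
})

test_that("peak detection finds all thirteen ruptures plus detachment", {
  pull <- simulate_afm_trace(noiseless_afm(seed = 2))
  peaks <- detect_events(pull$trace)
  expect_identical(nrow(peaks), 14L)
  expect_true(peaks$is_detachment[14])
  expect_false(any(peaks$is_detachment[1:13]))
  expect_true(all(diff(peaks$extension_nm) > 0))
})

test_that("pure noise produces no peaks", {
  set.seed(9)
  tr <- tibble::tibble(extension_nm = seq(0, 100, length.out = 2000),
                       force_pN = rnorm(2000, 0, 5))
  expect_identical(nrow(detect_events(tr, min_drop = 30)), 0L)
})

test_that("detected peak positions match generator truth within three samples", {
  ok <- 0; total <- 0
  for (s in 1:100) {
    pull <- simulate_afm_trace(quick_afm(seed = s))
    peaks <- detect_events(pull$trace)
    truth_t <- pull$truth$time_s
    if (nrow(peaks) != nrow(pull$truth)) next
    dt_samp <- 1 / pull$config$sample_rate
    err <- abs(pull$trace$time_s[peaks$peak_index] - truth_t) / dt_samp
    total <- total + 1
    if (all(err <= 3)) ok <- ok + 1
  }
  expect_gte(total, 90)           # nearly every trace yields a full event set
  expect_gte(ok / total, 0.95)
})

test_that("WLC segment fits recover the contour length", {
  x <- seq(20, 78, length.out = 60)
  tr <- tibble::tibble(extension_nm = x, force_pN = wlc_force(x, Lc = 80))
  fit <- fit_segment(tr, seq_len(60))
  expect_true(fit$converged)
  expect_lt(abs(fit$Lc_nm - 80), 0.1)
  expect_error(fit_segment(tr, 1:5), ">= 15")

  errs <- purrr::map_dbl(1:50, function(s) {
    set.seed(s)
    trn <- tibble::tibble(extension_nm = x,
                          force_pN = wlc_force(x, Lc = 80) + rnorm(60, 0, 10))
    fit_segment(trn, seq_len(60))$Lc_nm - 80
  })
  expect_gte(mean(abs(errs) < 1), 0.95)
})

test_that("contour-length increments subtract exactly and classify by window", {
  d <- delta_lc(c(60, 74.5))
  expect_equal(d$dLc_nm, 14.5)
  expect_identical(classify_event(14.5), "E")      # 145 A
  expect_identical(classify_event(21.6), "G5")     # 216 A
  expect_identical(classify_event(30), "other")
  expect_identical(classify_event(0), "other")     # flat increment is flagged
  expect_error(delta_lc(60), ">= 2")
})

test_that("the analysis pipeline recovers generator contour-length truth", {
  evs <- purrr::map(1:30, function(s) {
    pull <- simulate_afm_trace(quick_afm(seed = s))
    an <- afm_analyze_trace(pull$trace)
    if (!an$accepted) return(NULL)
    an$events
  }) |> purrr::list_rbind()
  e_cls <- evs$dLc_nm[evs$class == "E"]
  g_cls <- evs$dLc_nm[evs$class == "G5"]
  expect_gt(length(e_cls), 100)
  expect_lt(abs(mean(e_cls) - 14.5) / 14.5, 0.02)  # < 2% bias
  expect_lt(abs(mean(g_cls) - 21.6) / 21.6, 0.02)
  # misclassification between the two windows is rare
  expect_lt(mean(classify_event(c(e_cls, g_cls)) == "other"), 0.01)
  # increment bookkeeping: classified gains never exceed the fitted Lc span
  sums <- purrr::map_lgl(1:10, function(s) {
    an <- afm_analyze_trace(simulate_afm_trace(quick_afm(seed = s))$trace)
    ev <- an$events
    cls <- ev$class %in% c("E", "G5")
    sum(ev$dLc_nm[cls]) <= diff(range(ev$Lc_nm, na.rm = TRUE)) + 1e-9
  })
  expect_true(all(sums))
})

test_that("modal statistics recover a Gaussian mode and refuse small samples", {
  hits <- purrr::map_lgl(1:20, function(s) {
    set.seed(s)
    m <- modal_stats(rnorm(409, 250, 35))
    abs(m$mode - 250) < 5
  })
  expect_gte(mean(hits), 0.9)
  same <- modal_stats(rep(5, 25))
  expect_true(same$degenerate)
  expect_identical(same$mode, 5)
  expect_identical(same$sd, 0)
  expect_error(modal_stats(rnorm(10)), ">= 20")
})

test_that("speed series recovers the Bell distance to the transition state", {
  cls <- tibble::tibble(class = "G5", n = 7L, dLc_nm = 21.6,
                        force_mean_pN = NA, force_sd_pN = NA,
                        xu_nm = 0.25, k0_s = 0.08)
  # compliant cantilever so the loading rate is ~ speed * k_c (clean Bell)
  per_speed <- purrr::map(c(200, 800, 1500, 3000, 5000), function(v) {
    f <- purrr::map(1:30, function(s) {
      p <- simulate_afm_trace(afm_config(classes = cls, unfold_model = "bell",
                                         cantilever_k = 3,
                                         speed = v, sample_rate = 2000,
                                         seed = s))
      p$truth$force_pN[p$truth$class == "G5"]
    })
    tibble::tibble(speed = v, force_mode = modal_stats(unlist(f))$mode)
  }) |> purrr::list_rbind()
  ss <- speed_series(per_speed)
  expect_lt(abs(ss$xu_nm - 0.25) / 0.25, 0.30)

  # speed-independent forces: slope indistinguishable from zero
  flat <- tibble::tibble(speed = c(200, 800, 1500, 3000, 5000),
                         force_mode = c(301, 299, 300, 300.5, 299.5))
  sf <- speed_series(flat)
  expect_lt(abs(sf$slope_pN), 3 * sf$slope_se)
  expect_error(speed_series(flat[1:2, ]), ">= 3")
})

test_that("trace acceptance enforces composition and event-count rules", {
  pull <- simulate_afm_trace(noiseless_afm(seed = 3))
  an <- afm_analyze_trace(pull$trace)
  expect_true(an$accepted)
  expect_identical(sum(an$events$class == "E"), 6L)
  expect_identical(sum(an$events$class == "G5"), 7L)

  two <- tibble::tibble(class = c("E", "G5", "detachment"),
                        is_detachment = c(FALSE, FALSE, TRUE))
  expect_identical(accept_trace(two)$reason, "too few events")
  eight <- tibble::tibble(class = c(rep("G5", 8), "detachment"),
                          is_detachment = c(rep(FALSE, 8), TRUE))
  expect_identical(accept_trace(eight)$reason, "exceeds composition")
  no_det <- tibble::tibble(class = rep("E", 4), is_detachment = rep(FALSE, 4))
  expect_identical(accept_trace(no_det)$reason, "no detachment peak")
})
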