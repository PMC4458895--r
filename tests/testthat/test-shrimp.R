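# SHRImP pipeline: filtering, step detection, level images, PSF fitting,
# eccentricity QC, distances and histograms.

test_that("Chung-Kennedy filter preserves constants and noiseless steps", {
  expect_equal(chung_kennedy_filter(rep(100, 50)), rep(100, 50))
  step <- c(rep(100, 24), rep(50, 26))
  expect_equal(chung_kennedy_filter(step), step, tolerance = 1e-12)
})

test_that("Chung-Kennedy filtering reduces the MSE of a noisy two-level trace", {
  truth <- c(rep(1000, 30), rep(400, 30))
  worse <- 0
  for (rep_i in 1:200) {
    set.seed(rep_i)
    noisy <- truth + rnorm(60, 0, 10)
    filt <- chung_kennedy_filter(noisy)
    if (mean((filt - truth)^2) >= mean((noisy - truth)^2)) worse <- worse + 1
  }
  expect_identical(worse, 0)
})

test_that("two-step detection recovers generator step positions within one frame", {
  hits <- 0
  for (s in 1:200) {
    tr <- staircase_trace(noise_sd = 15, seed = s)
    sm <- detect_two_steps(chung_kennedy_filter(tr))
    if (sm$accepted && all(abs(sm$step_frames - c(40, 90)) <= 1)) hits <- hits + 1
  }
  expect_gte(hits, 190)
})

test_that("non-staircase traces are rejected with informative reasons", {
  expect_false(detect_two_steps(rep(500, 60))$accepted)
  expect_identical(detect_two_steps(rep(500, 60))$reason, "no steps")
  one <- c(rep(1000, 30), rep(30, 30))
  sm1 <- detect_two_steps(chung_kennedy_filter(one))
  expect_identical(sm1$reason, "one fluorophore")
  # two steps but a plateau shorter than seven frames
  short <- staircase_trace(n = 60, steps = c(20, 26), levels = c(900, 500, 50))
  expect_identical(detect_two_steps(chung_kennedy_filter(short))$reason,
                   "short plateau")
  up <- c(rep(100, 20), rep(900, 20), rep(400, 20))
  expect_identical(detect_two_steps(chung_kennedy_filter(up))$reason,
                   "upward step")
})

test_that("level images average the seven frames either side of the step", {
  P <- matrix(7, 4, 4); Q <- matrix(2, 4, 4)
  stack <- array(NA_real_, c(4, 4, 14))
  for (f in 1:7) stack[, , f] <- P
  for (f in 8:14) stack[, , f] <- Q
  li <- level_images(stack, step1 = 8)
  expect_equal(li$I1, P)
  expect_equal(li$I2, Q)
  # constant stack: both images equal the constant frame
  cst <- array(3, c(4, 4, 20))
  li2 <- level_images(cst, step1 = 10)
  expect_equal(li2$I1, li2$I2)
  expect_error(level_images(stack, step1 = 3), "frames before")
  # averaging noise: per-pixel sd of the level image ~ frame sd / sqrt(7)
  sds <- purrr::map_dbl(1:100, function(s) {
    set.seed(s)
    st <- array(rnorm(4 * 4 * 14, 100, 12), c(4, 4, 14))
    sd(level_images(st, step1 = 8)$I2)
  })
  expect_equal(mean(sds), 12 / sqrt(7), tolerance = 0.2 * 12 / sqrt(7))
})

test_that("PSF fitting recovers a rendered emitter to sub-millipixel accuracy", {
  img <- rodfold:::render_emitter(10, 10, 4.30, 5.70, 0.8, 2e4) + 5
  fit <- fit_psf(img)
  expect_true(fit$converged)
  expect_lt(abs(fit$x0 - 4.30), 1e-3)
  expect_lt(abs(fit$y0 - 5.70), 1e-3)
  expect_equal(fit$sigma_x, 0.8, tolerance = 1e-3)
  expect_lt(eccentricity(fit), 1e-3)
  expect_equal(fit$B, 5, tolerance = 1e-3)
})

test_that("a flat image is reported as a failed fit, not an error", {
  fit <- fit_psf(matrix(5, 10, 10))
  expect_false(fit$converged)
  expect_true(is.na(eccentricity(fit)))
})

test_that("localization precision scales roughly as psf_sigma over sqrt(photons)", {
  prec <- purrr::map_dbl(c(200, 5000), function(N) {
    errs <- purrr::map(1:40, function(s) {
      set.seed(s)
      expected <- rodfold:::render_emitter(10, 10, 5.3, 5.6, 0.7, N) + 3
      im <- matrix(rpois(100, expected), 10, 10)
      ft <- fit_psf(im)
      c(ft$x0 - 5.3, ft$y0 - 5.6)
    })
    sd(unlist(errs))
  })
  theory <- 0.7 / sqrt(c(200, 5000))
  expect_true(all(prec < 2 * theory))
  expect_true(all(prec > theory / 2))
})

test_that("eccentricity follows its closed form", {
  circular <- list(sigma_x = 1.1, sigma_y = 1.1, converged = TRUE)
  expect_equal(eccentricity(circular), 0)
  elong <- list(sigma_x = 0.6, sigma_y = 1.0, converged = TRUE)
  expect_equal(eccentricity(elong), 0.8, tolerance = 1e-12)
  near <- list(sigma_x = 0.999, sigma_y = 1.0, converged = TRUE)
  expect_equal(eccentricity(near), sqrt(1 - 0.999^2), tolerance = 1e-12)
  expect_gt(eccentricity(near), 0.04)  # even 0.1% anisotropy fails the cutoff
})

test_that("noiseless movies localize to the true separation across the rod range", {
  for (sep in c(20, 59, 100)) {
    found <- FALSE
    for (seed in 1:12) {
      mv <- simulate_tirf_movie(tirf_config(separation = sep,
                                            shot_noise = FALSE, seed = seed))
      res <- shrimp_analyze_movie(mv)
      if (nrow(res) == 1 && isTRUE(res$passed_qc[1])) {
        expect_lt(abs(res$distance_nm[1] - sep), 1e-2)
        found <- TRUE
        break
      }
    }
    expect_true(found)
  }
})

test_that("noisy separation recovery lands near truth and QC is monotone", {
  rows <- purrr::map(1:60, function(s) {
    mv <- simulate_tirf_movie(tirf_config(seed = s))
    shrimp_analyze_movie(mv, ecc_max = Inf)
  }) |> purrr::list_rbind()
  fitted <- rows[is.finite(rows$distance_nm), ]
  expect_gt(nrow(fitted), 15)
  expect_lt(abs(mean(fitted$distance_nm) - 59), 5)
  # zero true separation: the recovered distance is positively biased
  d0 <- purrr::map_dbl(1:25, function(s) {
    mv <- simulate_tirf_movie(tirf_config(separation = 0, seed = s))
    r <- shrimp_analyze_movie(mv, ecc_max = Inf)
    if (nrow(r)) r$distance_nm[1] else NA_real_
  })
  expect_gt(mean(d0, na.rm = TRUE), 0)
  # raising the eccentricity threshold never loses accepted pairs
  n_acc <- purrr::map_int(c(0.04, 0.1, 0.3, 0.5, 1),
    function(th) sum(fitted$ecc1 < th & fitted$ecc2 < th, na.rm = TRUE))
  expect_true(all(diff(n_acc) >= 0))
})

test_that("distance histograms follow Freedman-Diaconis and conserve counts", {
  # IQR 34 at n = 100: width 2*34/100^(1/3) = 14.65 -> rounds to 15 nm
  x <- seq(0, 68, length.out = 100)
  expect_equal(IQR(x), 34)
  expect_equal(fd_bin_width(x, round_to = 5), 15)

  set.seed(4)
  d <- rnorm(150, 54, 15)
  h <- distance_histogram(d)
  expect_identical(sum(h$bins$count), 150L)
  expect_lt(abs(h$gauss_mean - 54), 4)
  h25 <- distance_histogram(d, bin_width = 25)
  expect_identical(sum(h25$bins$count), 150L)
  expect_equal(h25$bin_width, 25)

  same <- distance_histogram(rep(42, 20), bin_width = 5)
  expect_true(same$degenerate)
  expect_error(distance_histogram(rnorm(5)), "at least 10")
})
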