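# Generators: TIRF movies, AFM traces, denaturation curves, chevron data.

test_that("TIRF generator obeys closed-form limits", {
  # no light at all -> an all-zero stack
  dark <- simulate_tirf_movie(tirf_config(
    photons_per_frame = 0, background = 0, read_noise_sd = 0,
    n_frames = 20, seed = 1
  ))
  expect_true(all(dark$stack == 0))

  # coincident fluorophores, no noise: early frames carry exactly twice the
  # single-fluorophore signal of the frames between the two bleach events
  seed <- 3
  repeat {
    mv <- simulate_tirf_movie(tirf_config(
      separation = 0, shot_noise = FALSE, background = 0, n_frames = 80,
      seed = seed
    ))
    b <- sort(c(mv$truth$bleach_frame_1, mv$truth$bleach_frame_2))
    if (b[1] > 2 && b[2] - b[1] > 2 && b[2] < 80) break
    seed <- seed + 1
  }
  both_on <- mv$stack[, , 1]
  one_on <- mv$stack[, , b[1]]
  expect_equal(both_on, 2 * one_on, tolerance = 1e-12)
})

test_that("TIRF ground truth has one row per molecule and in-movie bleach frames", {
  mv <- simulate_tirf_movie(tirf_config(
    n_molecules = 50, n_frames = 40, photons_per_frame = 100, seed = 7
  ))
  expect_identical(nrow(mv$truth), 50L)
  expect_true(all(mv$truth$bleach_frame_1 <= 40))
  expect_true(all(mv$truth$bleach_frame_2 <= 40))
  expect_equal(mv$truth$separation_nm, rep(59, 50), tolerance = 1e-9)
})

test_that("noiseless TIRF renders conserve the photon budget per frame", {
  mv <- simulate_tirf_movie(tirf_config(
    n_molecules = 2, shot_noise = FALSE, n_frames = 30, background = 4,
    photons_per_frame = 800, seed = 2
  ))
  npix <- prod(dim(mv$stack)[1:2])
  for (f in c(1, 15, 30)) {
    active <- sum(mv$truth$bleach_frame_1 > f) + sum(mv$truth$bleach_frame_2 > f)
    expect_equal(sum(mv$stack[, , f]), active * 800 + 4 * npix,
                 tolerance = 1e-9)
  }
})

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg_t <- tirf_config(n_frames = 20, seed = 99)
  expect_identical(simulate_tirf_movie(cfg_t)$stack,
                   simulate_tirf_movie(cfg_t)$stack)
  cfg_e <- eq_config(m = 1.4, d50 = 4.4, seed = 99)
  expect_identical(simulate_denaturation(cfg_e), simulate_denaturation(cfg_e))
  cfg_c <- chevron_config(kf0 = 100, m_kf = 1.5, ku0 = 1e-3, m_ku = 0.8, seed = 99)
  expect_identical(simulate_chevron(cfg_c), simulate_chevron(cfg_c))
  cfg_a <- quick_afm(seed = 99)
  expect_identical(simulate_afm_trace(cfg_a)$trace, simulate_afm_trace(cfg_a)$trace)
})

test_that("a saturated noiseless pull unfolds all thirteen domains then detaches", {
  pull <- simulate_afm_trace(noiseless_afm(seed = 5))
  tr <- pull$truth
  expect_identical(nrow(tr), 14L)
  expect_identical(sum(tr$class == "E"), 6L)
  expect_identical(sum(tr$class == "G5"), 7L)
  expect_identical(tr$class[14], "detachment")
  # contour-length bookkeeping is exact
  expect_equal(tr$Lc_after_nm[13], 60 + 6 * 14.5 + 7 * 21.6, tolerance = 1e-12)
  # E (lower threshold) domains all rupture before any G5
  expect_true(max(which(tr$class == "E")) < min(which(tr$class == "G5")))
})

test_that("an empty composition gives a single detachment peak", {
  cfg <- afm_config(classes = afm_domain_classes()[0, ], sample_rate = 4000,
                    seed = 1)
  pull <- simulate_afm_trace(cfg)
  expect_identical(nrow(pull$truth), 1L)
  expect_identical(pull$truth$class, "detachment")
  expect_gt(max(pull$trace$force_true_pN), 0.99 * cfg$detachment_force)
})

test_that("AFM traces satisfy the generator invariants", {
  for (seed in 1:5) {
    pull <- simulate_afm_trace(quick_afm(seed = seed))
    expect_lte(nrow(pull$truth), 13 + 1)
    expect_true(all(diff(pull$trace$extension_nm) > -1e-9))
    unf <- dplyr::filter(pull$truth, class != "detachment")
    expect_equal(max(pull$truth$Lc_after_nm),
                 60 + sum(ifelse(unf$class == "E", 14.5, 21.6)),
                 tolerance = 1e-9)
  }
})

test_that("doubling xu lowers Bell-model unfolding forces", {
  cls <- afm_domain_classes()
  cls <- cls[cls$class == "G5", ]
  mean_force <- function(xu) {
    cls$xu_nm <- xu
    f <- purrr::map_dbl(1:40, function(s) {
      p <- simulate_afm_trace(afm_config(
        classes = cls, unfold_model = "bell", sample_rate = 2000, seed = s
      ))
      mean(p$truth$force_pN[p$truth$class != "detachment"])
    })
    mean(f, na.rm = TRUE)
  }
  expect_gt(mean_force(0.1143), mean_force(2 * 0.1143))
})

test_that("Bell-model unfolding force increases with retraction speed", {
  speeds <- c(200, 800, 1500, 3000, 5000)
  cls <- afm_domain_classes()
  med <- purrr::map_dbl(speeds, function(v) {
    f <- purrr::map(1:30, function(s) {
      p <- simulate_afm_trace(afm_config(
        classes = cls, unfold_model = "bell", speed = v,
        sample_rate = 2000, seed = s
      ))
      p$truth$force_pN[p$truth$class == "G5"]
    })
    median(unlist(f))
  })
  expect_true(all(diff(med) > 0))
})

test_that("denaturation generator inverts the two-state model", {
  cfg0 <- eq_config(m = 1.4, d50 = 4.4, noise_sd = 0, seed = 1)
  curve <- simulate_denaturation(cfg0)
  expect_equal(curve$signal,
               two_state_signal(curve$denaturant_M, 1.4, 4.4,
                                cfg0$alpha_n, cfg0$beta_n, cfg0$alpha_d, cfg0$beta_d),
               tolerance = 1e-12)
  # flat equal-slope-free baselines: midpoint signal is the baseline midpoint
  cfg_flat <- eq_config(m = 1.0, d50 = 3.0, alpha_n = 1, beta_n = 0,
                        alpha_d = 0.2, beta_d = 0, noise_sd = 0,
                        denaturant_grid = c(0:2, 3, 4:8), seed = 1)
  y <- simulate_denaturation(cfg_flat)
  expect_equal(y$signal[y$denaturant_M == 3], (1 + 0.2) / 2, tolerance = 1e-12)
})

test_that("chevron generator matches its closed form", {
  cfg <- chevron_config(kf0 = 400, m_kf = 1.5, ku0 = 2e-3, m_ku = 0.8,
                        log_noise_sd = 0, grid = seq(0, 8, 0.5), seed = 1)
  ch <- simulate_chevron(cfg)
  expect_equal(ch$kobs_s[ch$denaturant_M == 0], 400 + 2e-3, tolerance = 1e-12)
  # minimum of the noiseless log-chevron at the stationary point of the sum
  d_min_theory <- log(400 * 1.5 / (2e-3 * 0.8)) / (1.5 + 0.8)
  fine <- seq(0, 8, 0.001)
  kf <- chevron_rate(fine, 400, 1.5, 2e-3, 0.8)
  expect_equal(fine[which.min(log(kf))], d_min_theory, tolerance = 2e-3)
  # folding limb dominates at low denaturant: natural-log slope ~ -m_kf
  low <- ch$denaturant_M <= 1
  slope <- coef(lm(log(ch$kobs_s[low]) ~ ch$denaturant_M[low]))[[2]]
  expect_equal(slope, -1.5, tolerance = 1e-3)
})
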