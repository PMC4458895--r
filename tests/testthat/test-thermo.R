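# Two-state equilibrium fits, chevron fits and the interface ledger.

test_that("the two-state signal obeys its symmetry identities", {
  # K = 1 at the midpoint: signal is the baseline midpoint
  expect_equal(two_state_signal(3.0, m = 1.2, d50 = 3.0,
                                alpha_n = 1, alpha_d = 0.2),
               0.6, tolerance = 1e-12)
  expect_equal(fraction_unfolded(3.0, m = 1.2, d50 = 3.0), 0.5)
  # the free energy identity at printed parameters: 1.0 * 3.2 = 3.2
  expect_equal(1.0 * 3.2, 3.2)
})

test_that("noiseless curves are recovered exactly and dG = m * d50", {
  cfg <- eq_config(m = 1.4, d50 = 4.4, noise_sd = 0, seed = 1)
  fit <- fit_two_state(simulate_denaturation(cfg))
  expect_equal(fit$m, 1.4, tolerance = 1e-6)
  expect_equal(fit$d50, 4.4, tolerance = 1e-6)
  expect_equal(fit$dG, 1.4 * 4.4, tolerance = 1e-6)  # 6.16 kcal/mol
  expect_identical(fit$dG, fit$m * fit$d50)          # exact identity, always
})

test_that("noisy fits recover the generator parameters on average", {
  fits <- purrr::map(1:40, function(s) {
    glance(fit_two_state(simulate_denaturation(eq_config(m = 1.4, d50 = 4.4,
                                                         seed = s))))
  }) |> purrr::list_rbind()
  expect_lt(abs(mean(fits$m) - 1.4), 0.1)
  expect_lt(abs(mean(fits$d50) - 4.4), 0.1)
  expect_true(all(fits$dG == fits$m * fits$d50))
})

test_that("a transition-free signal is refused", {
  lin <- tibble::tibble(denaturant_M = seq(0, 8, length.out = 30))
  lin$signal <- 1 - 0.01 * lin$denaturant_M
  expect_error(fit_two_state(lin), "transition")
})

test_that("stability differences combine in quadrature", {
  d <- ddg(list(dG = 6.3, dG_se = 0.2), list(dG = 2.8, dG_se = 0.1))
  expect_equal(d$ddG, 3.5)
  expect_equal(d$ddG_se, sqrt(0.2^2 + 0.1^2))
  expect_equal(ddg(list(dG = 7.5, dG_se = 0.2), list(dG = 6.3, dG_se = 0.2))$ddG,
               1.2, tolerance = 1e-12)
  same <- list(dG = 4, dG_se = 0.1)
  expect_equal(ddg(same, same)$ddG, 0)
})

ledger_domains <- tibble::tibble(
  domain = c("G5_1", "E", "G5_2"),
  dG_fold = c(-3.2, 2.5, -2.8),
  bound = c("eq", "ge", "eq"),
  m = c(1.0, NA, 1.0),
  d50 = c(3.2, NA, 2.8)
)
ledger_constructs <- tibble::tibble(
  construct = c("E-G5_2", "G5_1-E-G5_2"),
  dG = c(6.3, 7.5), d50 = c(4.4, 4.9),
  interface = c("E:G5_2", "G5_1:E"),
  rule = c("A", "B"),
  parts = list(c("E", "G5_2"), NULL),
  shift_domain = c(NA, "G5_1")
)

test_that("the interface ledger reproduces both stability bounds", {
  led <- interface_ledger(ledger_domains, ledger_constructs)
  a <- led[led$interface == "E:G5_2", ]
  expect_equal(a$conferred, 6.0, tolerance = 1e-12)  # >= 6 kcal/mol
  expect_identical(a$bound, "ge")
  b <- led[led$interface == "G5_1:E", ]
  expect_equal(b$conferred, 1.7, tolerance = 1e-12)  # >= 1.5 kcal/mol
  expect_identical(b$bound, "ge")
  expect_gte(a$conferred, 6)
  expect_gte(b$conferred, 1.5)
})

test_that("ledger bounds propagate and zero inputs give zero interfaces", {
  dz <- ledger_domains
  dz$dG_fold <- 0
  cz <- ledger_constructs[1, ]
  cz$dG <- 0
  expect_equal(interface_ledger(dz, cz)$conferred, 0)
  # an equality-only partition yields an equality output
  d_eq <- dz
  d_eq$bound <- "eq"
  expect_identical(interface_ledger(d_eq, cz)$bound, "eq")
  # any bounded input forces a bound on the output
  expect_identical(interface_ledger(ledger_domains, ledger_constructs)$bound,
                   c("ge", "ge"))
  # a missing partition names the problem
  bad <- ledger_constructs[1, ]
  bad$parts <- list(c("E", "missing_domain"))
  expect_error(interface_ledger(ledger_domains, bad), "missing_domain")
})

test_that("noiseless chevrons are self-inverse and match equilibrium", {
  m_kf <- 1.6; m_ku <- 0.9
  m_eq <- rodfold_constants()$RT_kcal * (m_kf + m_ku)
  d50 <- 4.0
  kf0 <- 80
  ku0 <- kf0 * exp(-m_eq * d50 / rodfold_constants()$RT_kcal)
  ch <- simulate_chevron(chevron_config(kf0 = kf0, m_kf = m_kf, ku0 = ku0,
                                        m_ku = m_ku, log_noise_sd = 0,
                                        grid = seq(0, 8, length.out = 30),
                                        seed = 1))
  fit <- fit_chevron(ch, model = "two_state")
  expect_equal(fit$kf0, kf0, tolerance = 1e-6)
  expect_equal(fit$m_kf, m_kf, tolerance = 1e-6)
  expect_equal(fit$ku0, ku0, tolerance = 1e-6)
  expect_equal(fit$m_ku, m_ku, tolerance = 1e-6)

  # kinetics/equilibrium consistency on matched synthetics
  eq <- fit_two_state(simulate_denaturation(eq_config(m = m_eq, d50 = d50,
                                                      noise_sd = 0, seed = 1)))
  expect_lt(abs(eq$m - fit$m_kin) / eq$m, 1e-6)
  expect_lt(abs(eq$dG - fit$dG_kin) / eq$dG, 1e-5)
})

test_that("a curved unfolding limb selects the sequential transition-state model", {
  D <- seq(0, 9, length.out = 30)
  k_seq <- chevron_rate(D, 200, 1.6, 1e-4, 1.2, ku2 = 0.05, m_ku2 = 0.15,
                        model = "sequential")
  data <- tibble::tibble(denaturant_M = D, kobs_s = k_seq)
  f2 <- fit_chevron(data, model = "two_state")
  fa <- fit_chevron(data, model = "auto")
  expect_identical(fa$model, "sequential")
  expect_lt(fa$rss, 0.1 * f2$rss)
  # two-state data keep the simpler model
  k2 <- chevron_rate(D, 200, 1.6, 1e-3, 0.8)
  fb <- fit_chevron(tibble::tibble(denaturant_M = D, kobs_s = k2), model = "auto")
  expect_identical(fb$model, "two_state")
})
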