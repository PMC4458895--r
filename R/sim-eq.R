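# Seeded generators for equilibrium denaturation curves and chevron rate data.

#' Configuration for a synthetic denaturation curve
#'
#' Defaults emulate a tyrosine-fluorescence urea titration of a small
#' beta-sheet domain: unit native amplitude, gently sloping baselines and
#' 2% amplitude Gaussian noise.
#'
#' @param m Equilibrium m-value (kcal mol^-1 M^-1), > 0.
#' @param d50 Midpoint (M), > 0.
#' @param alpha_n,beta_n,alpha_d,beta_d Linear baseline parameters.
#' @param denaturant_grid Urea concentrations (M), strictly increasing.
#' @param noise_sd Gaussian noise sd in signal units. The default is 2% of
#'   the native-minus-denatured amplitude.
#' @param temperature_K Temperature (K); thermodynamics use RT at 298 K.
#' @param seed Integer seed.
#' @return A list of class `eq_config`.
#' @export
eq_config <- function(m, d50,
                      alpha_n = 1, beta_n = -0.005,
                      alpha_d = 0.1, beta_d = 0.005,
                      denaturant_grid = seq(0, 8, length.out = 30),
                      noise_sd = 0.02 * abs(alpha_n - alpha_d),
                      temperature_K = 298,
                      seed = 1) {
  check_number(m, "m", 0, strict = TRUE)
  check_number(d50, "d50", 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  if (any(diff(denaturant_grid) <= 0)) {
    abort_config("`denaturant_grid` must be strictly increasing")
  }
  structure(
    list(m = m, d50 = d50, alpha_n = alpha_n, beta_n = beta_n,
         alpha_d = alpha_d, beta_d = beta_d,
         denaturant_grid = denaturant_grid, noise_sd = noise_sd,
         temperature_K = temperature_K, seed = as.integer(seed)),
    class = "eq_config"
  )
}

#' Simulate an equilibrium denaturation curve
#'
#' Draws the two-state signal on the configured denaturant grid and adds
#' Gaussian noise. Bit-reproducible for a given seed.
#'
#' @param cfg An [eq_config()].
#' @return A tibble with columns `denaturant_M`, `signal`, `signal_true`.
#' @export
#' @examples
#' simulate_denaturation(eq_config(m = 1.4, d50 = 4.4, seed = 7))
simulate_denaturation <- function(cfg) {
  stopifnot(inherits(cfg, "eq_config"))
  y0 <- two_state_signal(cfg$denaturant_grid, cfg$m, cfg$d50,
                         cfg$alpha_n, cfg$beta_n, cfg$alpha_d, cfg$beta_d)
  withr::with_seed(cfg$seed, {
    noise <- rnorm(length(y0), 0, cfg$noise_sd)
  })
  tibble(
    denaturant_M = cfg$denaturant_grid,
    signal = y0 + noise,
    signal_true = y0
  )
}

#' Configuration for synthetic chevron data
#'
#' @param kf0,ku0 Folding/unfolding rates in water (s^-1), > 0.
#' @param m_kf,m_ku Kinetic m-values (M^-1), > 0.
#' @param grid Denaturant concentrations (M).
#' @param log_noise_sd Log-normal noise sd on rates (dimensionless).
#' @param seed Integer seed.
#' @return A list of class `chevron_config`.
#' @export
chevron_config <- function(kf0, m_kf, ku0, m_ku,
                           grid = seq(0, 8, length.out = 25),
                           log_noise_sd = 0.05, seed = 1) {
  for (v in c("kf0", "ku0")) check_number(get(v), v, 0, strict = TRUE)
  check_number(m_kf, "m_kf", 0, strict = TRUE)
  check_number(m_ku, "m_ku", 0, strict = TRUE)
  check_number(log_noise_sd, "log_noise_sd", 0)
  structure(
    list(kf0 = kf0, m_kf = m_kf, ku0 = ku0, m_ku = m_ku,
         grid = grid, log_noise_sd = log_noise_sd, seed = as.integer(seed)),
    class = "chevron_config"
  )
}

#' Simulate chevron rate data
#'
#' `kobs(D) = kf0 exp(-m_kf D) + ku0 exp(m_ku D)` with log-normal
#' multiplicative noise.
#'
#' @param cfg A [chevron_config()].
#' @return A tibble with columns `denaturant_M`, `kobs_s`, `kobs_true`.
#' @export
simulate_chevron <- function(cfg) {
  stopifnot(inherits(cfg, "chevron_config"))
  k0 <- chevron_rate(cfg$grid, cfg$kf0, cfg$m_kf, cfg$ku0, cfg$m_ku)
  withr::with_seed(cfg$seed, {
    fac <- exp(rnorm(length(k0), 0, cfg$log_noise_sd))
  })
  tibble(denaturant_M = cfg$grid, kobs_s = k0 * fac, kobs_true = k0)
}
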