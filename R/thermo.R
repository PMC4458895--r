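# Two-state equilibrium denaturation, chevron kinetics and the interface
# free-energy ledger.
#
# Conventions: denaturant (urea) in M; free energies in kcal/mol with
# RT = 0.592 kcal/mol (25 C). Equilibrium fits report the unfolding free
# energy dG = m * d50 (positive = stable); the ledger converts to the folding
# convention (negative = stable) internally and reports both.

#' Two-state equilibrium signal
#'
#' Observed spectroscopic signal of a two-state folder with linear native and
#' denatured baselines:
#' \deqn{Y(D) = \frac{(\alpha_N + \beta_N D) + (\alpha_D + \beta_D D)\,K}{1 + K},
#'   \quad K = e^{m (D - D_{50}) / RT}}
#' so the fraction unfolded is exactly 1/2 at the midpoint `d50` and the
#' unfolding free energy in water is `m * d50`.
#'
#' @param denaturant Denaturant concentrations (M), any numeric vector.
#' @param m Equilibrium m-value (kcal mol^-1 M^-1), > 0.
#' @param d50 Denaturation midpoint (M).
#' @param alpha_n,beta_n Native baseline intercept and slope (signal, signal/M).
#' @param alpha_d,beta_d Denatured baseline intercept and slope.
#' @return Signal values, same length as `denaturant`.
#' @export
#' @examples
#' two_state_signal(seq(0, 8, 0.5), m = 1.4, d50 = 4.4)
two_state_signal <- function(denaturant, m, d50,
                             alpha_n = 1, beta_n = 0,
                             alpha_d = 0, beta_d = 0) {
  K <- exp(m * (denaturant - d50) / RT_KCAL)
  ((alpha_n + beta_n * denaturant) + (alpha_d + beta_d * denaturant) * K) / (1 + K)
}

#' Fraction of molecules unfolded at a denaturant concentration
#'
#' @inheritParams two_state_signal
#' @return `K / (1 + K)` with `K = exp(m (D - d50) / RT)`.
#' @export
fraction_unfolded <- function(denaturant, m, d50) {
  K <- exp(m * (denaturant - d50) / RT_KCAL)
  K / (1 + K)
}

#' Fit a two-state denaturation curve
#'
#' Six-parameter least-squares fit of [two_state_signal()] (m, d50 and the two
#' linear baselines) to a measured curve. The unfolding free energy is the
#' exact identity `dG = m * d50`; its standard error propagates the fit
#' covariance of `m` and `d50`.
#'
#' @param curve Data frame with columns `denaturant_M` and `signal`.
#' @param min_transition Refuse to fit when the signal range is smaller than
#'   this multiple of the residual noise level (no detectable transition).
#' @return An object of class `two_state_fit`: list with `m`, `d50`, `dG`,
#'   baselines, standard errors, covariance and the data. `tidy()` and
#'   `glance()` methods are provided.
#' @export
#' @examples
#' curve <- simulate_denaturation(eq_config(m = 1.4, d50 = 4.4, seed = 1))
#' fit <- fit_two_state(curve)
#' glance(fit)
fit_two_state <- function(curve, min_transition = 3) {
  curve <- as_tibble(curve)
  if (!all(c("denaturant_M", "signal") %in% names(curve))) {
    abort_input("`curve` needs columns `denaturant_M` and `signal`")
  }
  D <- curve$denaturant_M
  y <- curve$signal
  if (length(D) < 10) abort_input("need at least 10 points across the transition")

  # starting values: baselines from curve ends, midpoint from half-signal
  n_end <- max(3L, floor(length(D) / 5))
  ord <- order(D)
  D <- D[ord]; y <- y[ord]
  lo <- seq_len(n_end); hi <- seq(length(D) - n_end + 1, length(D))
  bn <- coef(lm(y[lo] ~ D[lo]))
  bd <- coef(lm(y[hi] ~ D[hi]))
  y_mid <- (mean(y[lo]) + mean(y[hi])) / 2
  d50_0 <- D[which.min(abs(y - y_mid))]
  start <- list(
    m = 1, d50 = max(d50_0, 0.5),
    alpha_n = unname(bn[1]), beta_n = unname(bn[2]),
    alpha_d = unname(bd[1]), beta_d = unname(bd[2])
  )

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ two_state_signal(D, m, d50, alpha_n, beta_n, alpha_d, beta_d),
      start = start,
      lower = c(m = 1e-3, d50 = 1e-3, alpha_n = -Inf, beta_n = -Inf,
                alpha_d = -Inf, beta_d = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) abort_input("two-state fit failed to converge")

  resid_sd <- sd(residuals(fit))
  # no transition: a straight line explains the data as well as the sigmoid,
  # or the sigmoid amplitude is buried in the residual noise
  rss_line <- sum(residuals(lm(y ~ D))^2)
  rss_fit <- sum(residuals(fit)^2)
  amp <- abs((coef(fit)[["alpha_n"]] + coef(fit)[["beta_n"]] * coef(fit)[["d50"]]) -
               (coef(fit)[["alpha_d"]] + coef(fit)[["beta_d"]] * coef(fit)[["d50"]]))
  if (rss_line <= 1.05 * rss_fit || amp < min_transition * resid_sd) {
    abort_input("no detectable transition in the signal")
  }

  p <- coef(fit)
  V <- vcov(fit)
  se <- sqrt(diag(V))
  m <- unname(p[["m"]]); d50 <- unname(p[["d50"]])
  # dG = m * d50; delta-method error including the m-d50 covariance
  dG_var <- (d50 * se[["m"]])^2 + (m * se[["d50"]])^2 +
    2 * d50 * m * V["m", "d50"]
  out <- list(
    m = m, d50 = d50, dG = m * d50,
    alpha_n = unname(p[["alpha_n"]]), beta_n = unname(p[["beta_n"]]),
    alpha_d = unname(p[["alpha_d"]]), beta_d = unname(p[["beta_d"]]),
    se = c(m = unname(se[["m"]]), d50 = unname(se[["d50"]]),
           dG = sqrt(max(dG_var, 0))),
    cov = V, residual_sd = resid_sd,
    data = tibble(denaturant_M = D, signal = y, fitted = predict(fit))
  )
  class(out) <- "two_state_fit"
  out
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state denaturation fit\n")
  cat(sprintf("  m   = %.3f +/- %.3f kcal mol^-1 M^-1\n", x$m, x$se[["m"]]))
  cat(sprintf("  d50 = %.3f +/- %.3f M\n", x$d50, x$se[["d50"]]))
  cat(sprintf("  dG  = %.3f +/- %.3f kcal/mol (m * d50)\n", x$dG, x$se[["dG"]]))
  invisible(x)
}

#' @export
tidy.two_state_fit <- function(x, ...) {
  tibble(
    term = c("m", "d50", "dG", "alpha_n", "beta_n", "alpha_d", "beta_d"),
    estimate = c(x$m, x$d50, x$dG, x$alpha_n, x$beta_n, x$alpha_d, x$beta_d),
    std.error = c(x$se[["m"]], x$se[["d50"]], x$se[["dG"]],
                  sqrt(diag(x$cov))[c("alpha_n", "beta_n", "alpha_d", "beta_d")])
  )
}

#' @export
glance.two_state_fit <- function(x, ...) {
  tibble(
    m = x$m, d50 = x$d50, dG = x$dG,
    m_se = x$se[["m"]], d50_se = x$se[["d50"]], dG_se = x$se[["dG"]],
    residual_sd = x$residual_sd, n = nrow(x$data)
  )
}

#' Stability difference between two constructs
#'
#' `dG_a - dG_b` in kcal/mol with errors combined in quadrature.
#'
#' @param fit_a,fit_b Either `two_state_fit` objects or lists with elements
#'   `dG` and optionally `se["dG"]` / `dG_se`.
#' @return A tibble with `ddG` and `ddG_se`.
#' @export
#' @examples
#' ddg(list(dG = 6.3, dG_se = 0.2), list(dG = 2.8, dG_se = 0.1))
ddg <- function(fit_a, fit_b) {
  get_dg <- function(f) {
    se <- if (!is.null(f$se)) unname(f$se[["dG"]]) else f$dG_se %||% NA_real_
    c(f$dG, se)
  }
  a <- get_dg(fit_a); b <- get_dg(fit_b)
  tibble(ddG = a[1] - b[1], ddG_se = sqrt(a[2]^2 + b[2]^2))
}

#' Interface free-energy ledger
#'
#' Attributes the stability of multi-domain constructs to per-domain folding
#' free energies plus inter-domain interface contributions, with explicit
#' bound propagation: any input known only as a bound yields an output bound,
#' never an equality.
#'
#' Two derivation rules are implemented:
#' \describe{
#'   \item{rule A (partition additivity)}{For a construct partitioned into
#'     independently measured parts,
#'     `dG_int = dG_fold(construct) - sum(dG_fold(parts))`. A part whose
#'     instability is itself a lower bound (e.g. a domain that never folds in
#'     isolation, `dG_fold >= +x`) makes the interface term a lower bound on
#'     the conferred stabilization.}
#'   \item{rule B (midpoint-shift bound)}{A domain `d` folding inside
#'     construct `c` at a higher denaturant midpoint than in isolation must be
#'     stabilized by at least `m_d * (d50_c - d50_d)` kcal/mol; attributing
#'     the shift entirely to the flanking interface gives a lower bound on
#'     that interface.}
#' }
#'
#' @param domains Data frame with columns `domain`, `dG_fold` (kcal/mol,
#'   folding convention: negative = stable), `bound` (`"eq"` or `"ge"`,
#'   meaning `dG_fold` >= the stated value, i.e. at least that unstable), and
#'   optionally `m` and `d50` (the isolated domain's equilibrium parameters,
#'   needed for rule B).
#' @param constructs Data frame with columns `construct`, `dG` (unfolding
#'   convention, positive = stable), `d50`, and `parts` (list-column of
#'   domain/interface partitions for rule A) and/or `shift_domain` (character,
#'   the domain whose midpoint shift bounds the interface, for rule B) plus
#'   `interface` naming the interface each row derives.
#' @return A tibble with one row per derived interface: `interface`, `rule`,
#'   `conferred` (kcal/mol of stabilization), `bound` (`"ge"` or `"eq"`),
#'   `construct`.
#' @export
#' @examples
#' domains <- tibble::tibble(
#'   domain = c("G5_1", "E", "G5_2"),
#'   dG_fold = c(-3.2, 2.5, -2.8),
#'   bound = c("eq", "ge", "eq"),
#'   m = c(1.0, NA, 1.0),
#'   d50 = c(3.2, NA, 2.8)
#' )
#' constructs <- tibble::tibble(
#'   construct = c("E-G5_2", "G5_1-E-G5_2"),
#'   dG = c(6.3, 7.5),
#'   d50 = c(4.4, 4.9),
#'   interface = c("E:G5_2", "G5_1:E"),
#'   rule = c("A", "B"),
#'   parts = list(c("E", "G5_2"), NULL),
#'   shift_domain = c(NA, "G5_1")
#' )
#' interface_ledger(domains, constructs)
interface_ledger <- function(domains, constructs) {
  domains <- as_tibble(domains)
  constructs <- as_tibble(constructs)
  need_d <- c("domain", "dG_fold", "bound")
  if (!all(need_d %in% names(domains))) {
    abort_input("`domains` needs columns domain, dG_fold, bound")
  }
  if (!"rule" %in% names(constructs)) {
    abort_input("`constructs` needs a `rule` column ('A' or 'B') per row")
  }

  rows <- purrr::pmap(constructs, function(...) {
    row <- list(...)
    if (identical(row$rule, "A")) {
      parts <- row$parts
      if (is.null(parts) || !all(parts %in% domains$domain)) {
        missing <- setdiff(parts, domains$domain)
        abort_input(sprintf(
          "rule A partition for %s needs domains: %s",
          row$construct, paste(if (length(missing)) missing else "(none given)",
                               collapse = ", ")
        ))
      }
      d <- domains[match(parts, domains$domain), ]
      dg_fold_construct <- -row$dG        # unfolding -> folding convention
      dg_int <- dg_fold_construct - sum(d$dG_fold)
      bounded <- any(d$bound == "ge")
      tibble(
        interface = row$interface, rule = "A",
        conferred = -dg_int,              # stabilization conferred (positive)
        bound = if (bounded) "ge" else "eq",
        construct = row$construct
      )
    } else if (identical(row$rule, "B")) {
      dom <- row$shift_domain
      if (is.na(dom) || !dom %in% domains$domain) {
        abort_input(sprintf("rule B for %s needs a known `shift_domain`", row$construct))
      }
      d <- domains[domains$domain == dom, ]
      if (!all(c("m", "d50") %in% names(d)) || is.na(d$m) || is.na(d$d50)) {
        abort_input(sprintf("rule B needs m and d50 for domain %s", dom))
      }
      tibble(
        interface = row$interface, rule = "B",
        conferred = d$m * (row$d50 - d$d50),
        bound = "ge",                     # shift attribution is always a bound
        construct = row$construct
      )
    } else {
      abort_input(sprintf("unknown ledger rule '%s'", row$rule))
    }
  })
  out <- list_rbind(rows)
  class(out) <- c("interface_ledger", class(out))
  out
}

#' Observed rate constant of a two-state or sequential-barrier folder
#'
#' Two-state: `kobs = kf0 exp(-m_kf D) + ku0 exp(m_ku D)` (a V-shaped chevron
#' on a log scale). Sequential transition states: the unfolding limb is the
#' harmonic combination `1/ku = 1/(ku0 e^(m_ku D)) + 1/(ku2 e^(m_ku2 D))`, so
#' the slower barrier limits the rate and the limb curves as the rate-limiting
#' barrier switches with denaturant.
#'
#' @param denaturant Denaturant concentrations (M).
#' @param kf0,ku0 Folding/unfolding rate constants in water (s^-1).
#' @param m_kf,m_ku Kinetic m-values (M^-1, natural-log slope magnitudes).
#' @param ku2,m_ku2 Second unfolding barrier (sequential model only).
#' @param model `"two_state"` or `"sequential"`.
#' @return `kobs` in s^-1.
#' @export
#' @examples
#' chevron_rate(seq(0, 8, 0.5), kf0 = 100, m_kf = 1.5, ku0 = 1e-3, m_ku = 0.8)
chevron_rate <- function(denaturant, kf0, m_kf, ku0, m_ku,
                         ku2 = NULL, m_ku2 = NULL, model = "two_state") {
  kf <- kf0 * exp(-m_kf * denaturant)
  ku <- ku0 * exp(m_ku * denaturant)
  if (identical(model, "sequential")) {
    if (is.null(ku2) || is.null(m_ku2)) {
      abort_input("sequential model needs ku2 and m_ku2")
    }
    ku <- 1 / (1 / ku + 1 / (ku2 * exp(m_ku2 * denaturant)))
  }
  kf + ku
}

#' Fit a chevron plot
#'
#' Least squares on the natural log of the observed rate. The two-state model
#' has four parameters; the sequential transition-state model adds a second
#' unfolding barrier (`ku2`, `m_ku2`) whose harmonic combination with the
#' first curves the unfolding limb. With `model = "auto"` both are fitted and
#' the one with the smaller residual sum of squares on log-rates is kept
#' (ties favour the simpler model).
#'
#' @param data Data frame with columns `denaturant_M` and `kobs_s`.
#' @param model `"two_state"`, `"sequential"` or `"auto"`.
#' @return An object of class `chevron_fit`: rate parameters, their standard
#'   errors, the model, `dG_kin = RT*ln(kf0/ku0)` and the kinetic m-value
#'   `RT*(m_kf + m_ku)` in kcal mol^-1 M^-1.
#' @export
fit_chevron <- function(data, model = c("auto", "two_state", "sequential")) {
  model <- arg_match(model)
  data <- as_tibble(data)
  if (!all(c("denaturant_M", "kobs_s") %in% names(data))) {
    abort_input("`data` needs columns `denaturant_M` and `kobs_s`")
  }
  if (nrow(data) < 8) abort_input("need at least 8 denaturant points")
  D <- data$denaturant_M
  ly <- log(data$kobs_s)

  i_min <- which.min(ly)
  fold_side <- D <= D[i_min]
  partial <- sum(fold_side) < 3 || sum(!fold_side) < 2

  # limb-based starting values
  sf <- if (sum(fold_side) >= 2) coef(lm(ly[fold_side] ~ D[fold_side])) else c(max(ly), -1)
  su <- if (sum(!fold_side) >= 2) coef(lm(ly[!fold_side] ~ D[!fold_side])) else c(min(ly), 0.5)
  start2 <- list(
    lkf0 = unname(sf[1]), m_kf = max(-unname(sf[2]), 0.1),
    lku0 = unname(su[1]), m_ku = max(unname(su[2]), 0.05)
  )

  fit_one <- function(mod) {
    if (mod == "two_state") {
      f <- tryCatch(minpack.lm::nlsLM(
        ly ~ log(exp(lkf0 - m_kf * D) + exp(lku0 + m_ku * D)),
        start = start2,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ), error = function(e) NULL)
    } else {
      start4 <- c(start2, list(lku2 = start2$lku0 + 1, m_ku2 = start2$m_ku / 4))
      f <- tryCatch(minpack.lm::nlsLM(
        ly ~ log(exp(lkf0 - m_kf * D) +
                   1 / (exp(-(lku0 + m_ku * D)) + exp(-(lku2 + m_ku2 * D)))),
        start = start4,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ), error = function(e) NULL)
    }
    f
  }

  candidates <- switch(model,
    auto = c("two_state", "sequential"),
    model
  )
  fits <- setNames(lapply(candidates, fit_one), candidates)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) abort_input("chevron fit failed to converge")
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  # require a meaningful improvement before adopting the extra barrier
  chosen <- if (length(fits) == 1) {
    names(fits)
  } else if (rss[["sequential"]] < 0.8 * rss[["two_state"]]) {
    "sequential"
  } else {
    "two_state"
  }
  f <- fits[[chosen]]
  p <- coef(f)
  se_log <- sqrt(diag(vcov(f)))
  out <- list(
    model = chosen,
    kf0 = exp(unname(p[["lkf0"]])), m_kf = unname(p[["m_kf"]]),
    ku0 = exp(unname(p[["lku0"]])), m_ku = unname(p[["m_ku"]]),
    ku2 = if (chosen == "sequential") exp(unname(p[["lku2"]])) else NA_real_,
    m_ku2 = if (chosen == "sequential") unname(p[["m_ku2"]]) else NA_real_,
    se_log = se_log,
    dG_kin = RT_KCAL * (unname(p[["lkf0"]]) - unname(p[["lku0"]])),
    m_kin = RT_KCAL * (unname(p[["m_kf"]]) + unname(p[["m_ku"]])),
    rss = sum(residuals(f)^2),
    partial = partial,
    data = tibble(denaturant_M = D, kobs_s = exp(ly), fitted = exp(predict(f)))
  )
  class(out) <- "chevron_fit"
  out
}

#' @export
print.chevron_fit <- function(x, ...) {
  cat(sprintf("Chevron fit (%s model)%s\n", x$model,
              if (x$partial) " [one limb poorly covered]" else ""))
  cat(sprintf("  kf0 = %.4g s^-1, m_kf = %.3f M^-1\n", x$kf0, x$m_kf))
  cat(sprintf("  ku0 = %.4g s^-1, m_ku = %.3f M^-1\n", x$ku0, x$m_ku))
  if (x$model == "sequential") {
    cat(sprintf("  ku2 = %.4g s^-1, m_ku2 = %.3f M^-1\n", x$ku2, x$m_ku2))
  }
  cat(sprintf("  dG_kin = %.3f kcal/mol, kinetic m = %.3f kcal mol^-1 M^-1\n",
              x$dG_kin, x$m_kin))
  invisible(x)
}

#' @export
tidy.chevron_fit <- function(x, ...) {
  terms <- c("kf0", "m_kf", "ku0", "m_ku")
  est <- c(x$kf0, x$m_kf, x$ku0, x$m_ku)
  if (x$model == "sequential") {
    terms <- c(terms, "ku2", "m_ku2")
    est <- c(est, x$ku2, x$m_ku2)
  }
  tibble(term = terms, estimate = est)
}

#' @export
glance.chevron_fit <- function(x, ...) {
  tibble(model = x$model, dG_kin = x$dG_kin, m_kin = x$m_kin,
         rss = x$rss, n = nrow(x$data))
}
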