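# Seeded generator of AFM force-extension traces of a multi-domain
# polyprotein: serial worm-like-chain elasticity, quasi-static force balance
# against a Hookean cantilever, and stochastic domain unfolding.

# Inverse Marko-Siggia relation: fractional extension u = x/Lc for reduced
# force phi = F p / kBT. Vectorized bisection on w = 1 - u.
wlc_inverse_rel <- function(phi) {
  lo <- rep(1e-9, length(phi))
  hi <- rep(1, length(phi))
  for (i in 1:80) {
    w <- (lo + hi) / 2
    f <- 1 / (4 * w^2) - 0.25 + (1 - w) - phi
    too_stiff <- f > 0  # force too high at this w -> root lies at larger w
    lo[too_stiff] <- w[too_stiff]
    hi[!too_stiff] <- w[!too_stiff]
  }
  1 - (lo + hi) / 2
}

#' Bell-model parameters matched to a rupture-force distribution
#'
#' Inverts the Bell-Evans phenomenology: for a constant loading rate `r`, the
#' rupture-force distribution has width ~ `kBT / xu` and mode
#' `F* = (kBT/xu) ln(r xu / (k0 kBT))`. Given a target modal force and sd at
#' one retraction speed, returns the implied `xu` and `k0`. The loading rate
#' is `speed` times the series stiffness of the cantilever and a
#' representative worm-like chain evaluated at the modal force.
#'
#' @param force_mode,force_sd Target modal rupture force and sd (pN).
#' @param speed Retraction speed (nm/s).
#' @param Lc_ref Representative contour length (nm) for the chain stiffness.
#' @param cantilever_k Cantilever stiffness (pN/nm).
#' @param p Persistence length (nm).
#' @return Named list with `xu_nm`, `k0_s`, `loading_rate_pN_s`.
#' @export
bell_from_force_dist <- function(force_mode, force_sd, speed = 800,
                                 Lc_ref = 150, cantilever_k = 30, p = 0.4) {
  xu <- KBT_PN_NM / force_sd
  u <- wlc_inverse_rel(force_mode * p / KBT_PN_NM)
  k_wlc <- (KBT_PN_NM / p) * (1 / (2 * Lc_ref * (1 - u)^3) + 1 / Lc_ref)
  k_eff <- 1 / (1 / cantilever_k + 1 / k_wlc)
  r <- speed * k_eff
  k0 <- (r * xu / KBT_PN_NM) * exp(-force_mode * xu / KBT_PN_NM)
  list(xu_nm = xu, k0_s = k0, loading_rate_pN_s = r)
}

#' Default per-class domain parameters
#'
#' Thirteen-domain tandem construct: six E domains and seven G5 domains.
#' Contour-length increments and rupture-force distributions default to the
#' values measured at 800 nm/s (E: 145 A, 250 +/- 35 pN; G5: 216 A,
#' 421 +/- 36 pN); Bell parameters are derived from those distributions with
#' [bell_from_force_dist()].
#'
#' @param speed Retraction speed (nm/s) used to derive Bell parameters.
#' @param cantilever_k,p Passed to [bell_from_force_dist()].
#' @return Tibble with one row per class: `class`, `n`, `dLc_nm`,
#'   `force_mean_pN`, `force_sd_pN`, `xu_nm`, `k0_s`.
#' @export
afm_domain_classes <- function(speed = 800, cantilever_k = 30, p = 0.4) {
  base <- tibble(
    class = c("E", "G5"),
    n = c(6L, 7L),
    dLc_nm = c(14.5, 21.6),
    force_mean_pN = c(250, 421),
    force_sd_pN = c(35, 36)
  )
  bell <- purrr::map2(base$force_mean_pN, base$force_sd_pN,
                      ~ bell_from_force_dist(.x, .y, speed = speed,
                                             cantilever_k = cantilever_k, p = p))
  base$xu_nm <- map_dbl(bell, "xu_nm")
  base$k0_s <- map_dbl(bell, "k0_s")
  base
}

#' Configuration for a synthetic AFM pulling trace
#'
#' @param classes Per-class domain table as from [afm_domain_classes()]
#'   (columns `class`, `n`, `dLc_nm`, plus `force_mean_pN`/`force_sd_pN` for
#'   the threshold model or `k0_s`/`xu_nm` for the Bell model). An empty
#'   table (`n = 0` everywhere or zero rows) gives a single detachment peak.
#' @param unfold_model `"threshold"` — each domain ruptures when the force
#'   first reaches a pre-drawn Gaussian threshold (used when the rupture-force
#'   distribution itself is the specified ground truth) — or `"bell"` — each
#'   folded domain unfolds as a Poisson process with rate
#'   `k0 exp(F xu / kBT)` (used for speed-dependence studies).
#' @param Lc0_nm Contour length of the folded construct plus tether (nm).
#' @param persistence_nm Persistence length (nm), fixed at 0.4 by default.
#' @param cantilever_k Cantilever stiffness (pN/nm), default 30.
#' @param speed Retraction speed (nm/s).
#' @param sample_rate Sampling rate (Hz).
#' @param force_noise_sd Gaussian force noise sd (pN).
#' @param detachment_force Force (pN) at which the tether detaches.
#' @param temperature_K Temperature; mechanics use kBT at 298 K.
#' @param seed Integer seed.
#' @return A list of class `afm_config`.
#' @export
afm_config <- function(classes = afm_domain_classes(speed = speed,
                                                    cantilever_k = cantilever_k,
                                                    p = persistence_nm),
                       unfold_model = c("threshold", "bell"),
                       Lc0_nm = 60,
                       persistence_nm = 0.4,
                       cantilever_k = 30,
                       speed = 800,
                       sample_rate = 10000,
                       force_noise_sd = 10,
                       detachment_force = 600,
                       temperature_K = 298,
                       seed = 1) {
  unfold_model <- arg_match(unfold_model)
  check_number(persistence_nm, "persistence_nm", 0, strict = TRUE)
  check_number(cantilever_k, "cantilever_k", 0, strict = TRUE)
  check_number(speed, "speed", 0, strict = TRUE)
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  check_number(force_noise_sd, "force_noise_sd", 0)
  check_number(Lc0_nm, "Lc0_nm", 0, strict = TRUE)
  check_number(detachment_force, "detachment_force", 0, strict = TRUE)
  classes <- as_tibble(classes)
  if (nrow(classes) && any(classes$dLc_nm <= 0)) {
    abort_config("`dLc_nm` must be > 0 for every class")
  }
  structure(
    list(classes = classes, unfold_model = unfold_model, Lc0_nm = Lc0_nm,
         persistence_nm = persistence_nm, cantilever_k = cantilever_k,
         speed = speed, sample_rate = sample_rate,
         force_noise_sd = force_noise_sd,
         detachment_force = detachment_force,
         temperature_K = temperature_K, seed = as.integer(seed)),
    class = "afm_config"
  )
}

#' Simulate an AFM force-extension trace
#'
#' Quasi-static forward model: the cantilever base moves at constant speed,
#' and at every instant the force balance
#' `F = k_c (z - x) = F_WLC(x; Lc, p)` determines the protein extension `x`.
#' Unfolding of a domain adds its contour-length increment to `Lc`, dropping
#' the force; the trace ends with a detachment event when the force reaches
#' `detachment_force`. The force balance is solved exactly by parametrizing
#' the ramp in force (`z(F) = Lc u(F) + F / k_c` is closed-form and monotone),
#' so no per-sample root finding is needed.
#'
#' @param cfg An [afm_config()].
#' @return A list of class `afm_pull`: `trace` (tibble `time_s`,
#'   `extension_nm`, `force_pN`, `force_true_pN`, class `fx_trace`) and
#'   `truth` (tibble of events: `event`, `time_s`, `force_pN`, `class`,
#'   `Lc_before_nm`, `Lc_after_nm`).
#' @export
#' @examples
#' pull <- simulate_afm_trace(afm_config(seed = 42))
#' pull$truth
simulate_afm_trace <- function(cfg) {
  stopifnot(inherits(cfg, "afm_config"))
  p <- cfg$persistence_nm
  kc <- cfg$cantilever_k
  v <- cfg$speed
  dt <- 1 / cfg$sample_rate
  kBT <- KBT_PN_NM

  classes <- cfg$classes
  n_dom <- if (nrow(classes)) sum(classes$n) else 0L
  dom_class <- if (n_dom) rep(classes$class, classes$n) else character(0)
  dom_dlc <- if (n_dom) rep(classes$dLc_nm, classes$n) else numeric(0)

  # force grid shared by all segments; z(F) is exact on it
  F_grid <- seq(0, cfg$detachment_force, length.out = 1500)
  u_grid <- wlc_inverse_rel(F_grid * p / kBT)

  withr::with_seed(cfg$seed, {
    folded <- rep(TRUE, n_dom)
    if (cfg$unfold_model == "threshold" && n_dom) {
      dom_thr <- pmax(
        rnorm(n_dom, rep(classes$force_mean_pN, classes$n),
              rep(classes$force_sd_pN, classes$n)),
        20
      )
    }
    Lc <- cfg$Lc0_nm
    t_cur <- 0; z_cur <- 0
    times <- list(); zs <- list(); forces <- list()
    events <- list()
    ev <- 0L

    repeat {
      z_of_F <- Lc * u_grid + F_grid / kc
      F_of_z <- function(z) approx(z_of_F, F_grid, xout = z, rule = 2)$y

      if (cfg$unfold_model == "threshold" && any(folded)) {
        F_evt <- min(dom_thr[folded])
        which_evt <- which(folded)[which.min(dom_thr[folded])]
        detach <- F_evt >= cfg$detachment_force
        F_end <- min(F_evt, cfg$detachment_force)
        z_end <- approx(F_grid, z_of_F, xout = F_end, rule = 2)$y
        t_end <- z_end / v
        tk <- seq_tick(t_cur, t_end, dt)
        Fk <- F_of_z(tk * v)
      } else if (cfg$unfold_model == "bell" && any(folded)) {
        z_detach <- approx(F_grid, z_of_F, xout = cfg$detachment_force, rule = 2)$y
        t_detach <- z_detach / v
        tk_all <- seq_tick(t_cur, t_detach, dt)
        Fk_all <- F_of_z(tk_all * v)
        lam <- rowSums(vapply(seq_len(nrow(classes)), function(i) {
          nf <- sum(folded & dom_class == classes$class[i])
          nf * classes$k0_s[i] * exp(Fk_all * classes$xu_nm[i] / kBT)
        }, numeric(length(Fk_all))))
        H <- cumsum(c(0, (lam[-1] + lam[-length(lam)]) / 2 *
                        diff(tk_all)))
        E_draw <- rexp(1)
        if (E_draw < H[length(H)]) {
          i_evt <- which(H >= E_draw)[1]
          detach <- FALSE
          tk <- tk_all[seq_len(i_evt)]
          Fk <- Fk_all[seq_len(i_evt)]
          F_end <- Fk_all[i_evt]
          t_end <- tk_all[i_evt]
          z_end <- t_end * v
          # which domain: proportional to per-class hazard at the event force
          w_cls <- vapply(seq_len(nrow(classes)), function(i) {
            nf <- sum(folded & dom_class == classes$class[i])
            nf * classes$k0_s[i] * exp(F_end * classes$xu_nm[i] / kBT)
          }, numeric(1))
          cls_evt <- sample(classes$class, 1, prob = w_cls)
          which_evt <- which(folded & dom_class == cls_evt)[1]
        } else {
          detach <- TRUE
          tk <- tk_all; Fk <- Fk_all
          F_end <- cfg$detachment_force
          t_end <- t_detach; z_end <- z_detach
        }
      } else {
        # nothing left folded (or no domains): pull to detachment
        detach <- TRUE
        F_end <- cfg$detachment_force
        z_end <- approx(F_grid, z_of_F, xout = F_end, rule = 2)$y
        t_end <- z_end / v
        tk <- seq_tick(t_cur, t_end, dt)
        Fk <- F_of_z(tk * v)
      }

      # exact sample at the rupture/detachment point
      tk <- c(tk, t_end)
      Fk <- c(Fk, F_end)
      times[[length(times) + 1L]] <- tk
      zs[[length(zs) + 1L]] <- tk * v
      forces[[length(forces) + 1L]] <- Fk

      ev <- ev + 1L
      if (detach) {
        events[[ev]] <- tibble(
          event = ev, time_s = t_end, force_pN = F_end,
          class = "detachment", Lc_before_nm = Lc, Lc_after_nm = Lc
        )
        # post-detachment baseline so the final peak has a visible drop
        n_tail <- max(20L, ceiling(0.02 * cfg$sample_rate))
        t_tail <- t_end + dt * seq_len(n_tail)
        times[[length(times) + 1L]] <- t_tail
        zs[[length(zs) + 1L]] <- t_tail * v
        forces[[length(forces) + 1L]] <- rep(0, n_tail)
        break
      }
      events[[ev]] <- tibble(
        event = ev, time_s = t_end, force_pN = F_end,
        class = dom_class[which_evt], Lc_before_nm = Lc,
        Lc_after_nm = Lc + dom_dlc[which_evt]
      )
      folded[which_evt] <- FALSE
      Lc <- Lc + dom_dlc[which_evt]
      t_cur <- t_end; z_cur <- z_end
    }

    tt <- unlist(times); zz <- unlist(zs); FF <- unlist(forces)
    x <- zz - FF / kc
    noise <- if (cfg$force_noise_sd > 0) rnorm(length(FF), 0, cfg$force_noise_sd) else 0
    trace <- tibble(
      time_s = tt, extension_nm = x,
      force_pN = FF + noise, force_true_pN = FF
    )
  })
  class(trace) <- c("fx_trace", class(trace))
  attr(trace, "speed") <- cfg$speed
  attr(trace, "seed") <- cfg$seed
  structure(list(trace = trace, truth = list_rbind(events), config = cfg),
            class = "afm_pull")
}

# Regular tick times in (t_from, t_to); may be empty.
seq_tick <- function(t_from, t_to, dt) {
  k0 <- floor(t_from / dt) + 1
  k1 <- floor(t_to / dt)
  if (k1 < k0) return(numeric(0))
  seq(k0, k1) * dt
}
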