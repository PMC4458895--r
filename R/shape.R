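# Coarse rigid/flexed multi-domain bead-chain models and model-level
# scattering observables: P(r), Dmax, cross-section distribution, Debye
# intensity, Guinier and cross-sectional Guinier fits, Porod exponent.

#' Build a collinear bead-chain model of an alternating G5/E tandem array
#'
#' Domains alternate G5-(E-G5)^k along one axis; each domain is a short
#' cylinder of beads on a regular axial/disc lattice. The default domain
#' lengths (G5 6.2 nm, E 4.6 nm) are solved from the two crystallographic
#' end-to-end anchors: 17 nm for the three-domain fragment and 71 nm for the
#' full seven-G5/six-E array.
#'
#' @param n_g5,n_e Number of G5 and E domains; must satisfy
#'   `n_g5 == n_e + 1` (alternating array) unless `n_e == 0`.
#' @param len_g5,len_e Domain lengths along the axis (nm).
#' @param beads_per_nm Axial bead density (stations per nm).
#' @param radius Cylinder radius (nm); 0 gives an ideal thin rod.
#' @return An object of class `bead_chain`: `beads` (tibble `x`, `y`, `z` in
#'   nm, `domain`, `class`), `junctions` (axial positions of the
#'   inter-domain joints), `length_nm` (rigid end-to-end), `radius`.
#' @export
#' @examples
#' build_chain(2, 1)$length_nm   # three-domain fragment, 17 nm
#' build_chain(7, 6)$length_nm   # full array, 71 nm
build_chain <- function(n_g5, n_e, len_g5 = 6.2, len_e = 4.6,
                        beads_per_nm = 3, radius = 1.0) {
  if (len_g5 <= 0 || len_e <= 0) abort_config("domain lengths must be > 0")
  if (n_e > 0 && n_g5 != n_e + 1) {
    abort_config("composition must alternate G5-(E-G5)^k: need n_g5 == n_e + 1")
  }
  if (n_g5 < 1) abort_config("need at least one G5 domain")
  classes <- if (n_e == 0) rep("G5", n_g5) else {
    c("G5", rep(c("E", "G5"), n_e))
  }
  lens <- ifelse(classes == "G5", len_g5, len_e)
  ends <- cumsum(lens)
  starts <- c(0, head(ends, -1))

  dz <- 1 / beads_per_nm
  disc <- disc_points(radius, dz)
  beads <- purrr::imap(seq_along(classes), function(i, ...) {
    z <- seq(starts[i] + dz / 2, ends[i], by = dz)
    tibble(
      x = rep(disc$x, times = length(z)),
      y = rep(disc$y, times = length(z)),
      z = rep(z, each = nrow(disc)),
      domain = i, class = classes[i]
    )
  }) |> list_rbind()

  structure(
    list(beads = beads, junctions = head(ends, -1),
         length_nm = sum(lens), radius = radius,
         classes = classes, lengths = lens),
    class = "bead_chain"
  )
}

# Cross-section lattice: symmetric square grid within the radius (spacing
# scales with the radius so the support always resolves the full diameter);
# the axis bead is always present.
disc_points <- function(radius, spacing) {
  if (radius <= 0) return(tibble(x = 0, y = 0))
  k <- max(3, ceiling(radius / spacing))
  spacing <- radius / k
  g <- seq(-k, k) * spacing
  pts <- expand.grid(x = g, y = g)
  pts <- pts[pts$x^2 + pts$y^2 <= radius^2 + 1e-12, ]
  as_tibble(pts)
}

#' Sample flexed conformations of a bead chain
#'
#' Domains stay rigid; at every inter-domain junction the downstream part is
#' tilted by a random polar angle (Gaussian with sd `bend_sd` degrees) about
#' a uniformly random azimuth, emulating bending confined to the G5-E and
#' E-G5 interfaces.
#'
#' @param chain A [build_chain()] result.
#' @param bend_sd Polar tilt sd per junction (degrees), >= 0.
#' @param n_samples Number of conformations.
#' @param seed Integer seed.
#' @return List of `bead_chain` objects (with `length_nm` the flexed
#'   end-to-end distance of the domain-axis polyline).
#' @export
sample_flexed <- function(chain, bend_sd, n_samples = 1, seed = 1) {
  stopifnot(inherits(chain, "bead_chain"))
  check_number(bend_sd, "bend_sd", 0)
  lens <- chain$lengths
  n_dom <- length(lens)
  withr::with_seed(seed, {
    purrr::map(seq_len(n_samples), function(k) {
      # direction of each domain: successive random tilts
      dirs <- matrix(0, n_dom, 3)
      d <- c(0, 0, 1)
      for (i in seq_len(n_dom)) {
        if (i > 1 && bend_sd > 0) {
          tilt <- rnorm(1, 0, bend_sd) * pi / 180
          azi <- runif(1, 0, 2 * pi)
          d <- tilt_direction(d, tilt, azi)
        }
        dirs[i, ] <- d
      }
      origins <- apply(rbind(c(0, 0, 0), dirs[-n_dom, , drop = FALSE] * lens[-n_dom]),
                       2, cumsum)
      beads <- chain$beads
      new_xyz <- matrix(NA_real_, nrow(beads), 3)
      start_z <- c(0, cumsum(head(lens, -1)))
      for (i in seq_len(n_dom)) {
        sel <- beads$domain == i
        local_z <- beads$z[sel] - start_z[i]
        # orthonormal frame with dirs[i,] as the axis
        fr <- frame_for(dirs[i, ])
        new_xyz[sel, ] <- cbind(beads$x[sel], beads$y[sel], local_z) %*%
          rbind(fr$u, fr$v, dirs[i, ]) +
          matrix(origins[i, ], sum(sel), 3, byrow = TRUE)
      }
      out <- chain
      out$beads$x <- new_xyz[, 1]
      out$beads$y <- new_xyz[, 2]
      out$beads$z <- new_xyz[, 3]
      ends <- origins[n_dom, ] + dirs[n_dom, ] * lens[n_dom]
      out$length_nm <- sqrt(sum(ends^2))
      out
    })
  })
}

# Rotate direction d by polar angle tilt about a random azimuth.
tilt_direction <- function(d, tilt, azi) {
  fr <- frame_for(d)
  axis_perp <- cos(azi) * fr$u + sin(azi) * fr$v
  d * cos(tilt) + axis_perp * sin(tilt)
}

# Any orthonormal pair perpendicular to unit vector d.
frame_for <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(
    d[2] * u[3] - d[3] * u[2],
    d[3] * u[1] - d[1] * u[3],
    d[1] * u[2] - d[2] * u[1]
  )
  list(u = u, v = v)
}

# Pairwise-distance histogram computed in blocks (memory-bounded).
pair_distance_hist <- function(xyz, bin_width, r_max = NULL) {
  n <- nrow(xyz)
  if (is.null(r_max)) {
    rng <- apply(xyz, 2, range)
    r_max <- sqrt(sum((rng[2, ] - rng[1, ])^2)) + bin_width
  }
  edges <- seq(0, r_max + bin_width, by = bin_width)
  counts <- numeric(length(edges) - 1)
  dmax <- 0
  block <- max(1L, floor(2e6 / n))
  i <- 1L
  while (i <= n - 1L) {
    j <- min(n, i + block - 1L)
    rows <- i:j
    d2 <- outer(xyz[rows, 1], xyz[, 1], "-")^2 +
      outer(xyz[rows, 2], xyz[, 2], "-")^2 +
      outer(xyz[rows, 3], xyz[, 3], "-")^2
    # keep strictly upper triangle: pair (a, b) with b > a
    keep <- outer(rows, seq_len(n), "<")
    d <- sqrt(d2[keep])
    if (length(d)) {
      dmax <- max(dmax, max(d))
      idx <- pmin(findInterval(d, edges, rightmost.closed = TRUE), length(counts))
      counts <- counts + tabulate(idx, nbins = length(counts))
    }
    i <- j + 1L
  }
  list(edges = edges, counts = counts, dmax = dmax)
}

#' Pair-distance distribution P(r) of a bead chain
#'
#' Histogram of all pairwise bead distances, normalized so that
#' `sum(P) * bin_width = 1`. `Dmax` is the exact maximum pairwise distance.
#'
#' @param chain A `bead_chain`, or a matrix/data frame of bead coordinates.
#' @param bin_width Histogram bin width (nm).
#' @return An object of class `pair_distribution`: tibble-like list with
#'   `r` (bin mid-points), `p`, `bin_width`, `Dmax`, `n_beads`.
#' @export
pair_distribution <- function(chain, bin_width = 0.5) {
  xyz <- chain_coords(chain)
  if (nrow(xyz) < 2) abort_input("need at least 2 beads")
  h <- pair_distance_hist(xyz, bin_width)
  p <- h$counts / (sum(h$counts) * bin_width)
  keep <- seq_len(max(which(h$counts > 0)))
  structure(
    list(r = (h$edges[keep] + h$edges[keep + 1]) / 2, p = p[keep],
         bin_width = bin_width, Dmax = h$dmax, n_beads = nrow(xyz)),
    class = "pair_distribution"
  )
}

chain_coords <- function(chain) {
  if (inherits(chain, "bead_chain")) {
    as.matrix(chain$beads[, c("x", "y", "z")])
  } else {
    m <- as.matrix(chain)
    stopifnot(ncol(m) == 3)
    m
  }
}

#' Cross-sectional pair-distance distribution Pc(r)
#'
#' Projects the beads onto the plane normal to the principal (longest
#' inertia) axis and histograms the projected pairwise distances, giving the
#' distance distribution of the particle cross-section.
#'
#' @inheritParams pair_distribution
#' @return A `pair_distribution` object of the projected coordinates.
#' @export
cross_section_distribution <- function(chain, bin_width = 0.1) {
  xyz <- chain_coords(chain)
  xyz_c <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xyz_c) / nrow(xyz_c), symmetric = TRUE)
  if (ev$values[1] - ev$values[2] < 1e-9 * max(ev$values[1], 1)) {
    warn("chain has no distinct principal axis; choosing one arbitrarily")
  }
  axis <- ev$vectors[, 1]
  proj <- xyz_c - outer(drop(xyz_c %*% axis), axis)
  out <- pair_distribution(proj, bin_width = bin_width)
  out
}

#' Debye scattering intensity of a bead model
#'
#' `I(s) = sum_ij w_i w_j sin(s r_ij) / (s r_ij)` with unit bead weights,
#' evaluated via a finely binned pair-distance histogram (exact at `s = 0`,
#' where `I = n_beads^2`).
#'
#' @param chain A `bead_chain` or coordinate matrix.
#' @param s Scattering vector grid (nm^-1), `s = 4 pi sin(theta) / lambda`.
#' @param r_bin Internal pair-distance bin (nm) for the Debye sum.
#' @return An object of class `scattering_profile`: `s`, `I`, `n_beads`.
#' @export
debye_intensity <- function(chain, s = seq(0.01, 5, length.out = 200),
                            r_bin = 0.05) {
  if (any(s < 0)) abort_input("s must be >= 0")
  xyz <- chain_coords(chain)
  n <- nrow(xyz)
  if (n == 1) {
    I <- rep(1, length(s))
  } else {
    h <- pair_distance_hist(xyz, r_bin)
    mids <- (h$edges[-length(h$edges)] + h$edges[-1]) / 2
    nz <- h$counts > 0
    mids <- mids[nz]; cnt <- h$counts[nz]
    I <- vapply(s, function(si) {
      if (si == 0) return(n^2)
      sr <- si * mids
      n + 2 * sum(cnt * sin(sr) / sr)
    }, numeric(1))
  }
  structure(list(s = s, I = I, n_beads = n), class = "scattering_profile")
}

#' Guinier fit: radius of gyration and forward scattering
#'
#' Linear regression of `ln I` on `s^2` in the low-angle regime
#' (`s * Rg < ~1.3`): slope `= -Rg^2 / 3`, intercept `= ln I(0)`. A warning
#' flag is set when the residuals show curvature beyond tolerance.
#'
#' @param profile A `scattering_profile` (or list with `s`, `I`).
#' @param s_range Length-2 numeric range of s to use.
#' @return Tibble with `Rg`, `I0`, `n_points`, `warning_nonlinear`.
#' @export
guinier_fit <- function(profile, s_range) {
  sel <- profile$s >= s_range[1] & profile$s <= s_range[2] & profile$I > 0 &
    profile$s > 0
  if (sum(sel) < 3) abort_input("need >= 3 points in the Guinier range")
  s2 <- profile$s[sel]^2
  li <- log(profile$I[sel])
  fit <- lm(li ~ s2)
  slope <- coef(fit)[["s2"]]
  if (slope >= 0) abort_input("Guinier slope is non-negative; range too wide or invalid")
  curv <- curvature_flag(s2, residuals(fit), li)
  tibble(
    Rg = sqrt(-3 * slope),
    I0 = exp(coef(fit)[["(Intercept)"]]),
    n_points = sum(sel),
    warning_nonlinear = curv
  )
}

#' Cross-sectional Guinier fit: radius of gyration of the cross-section
#'
#' Regression of `ln(I s)` on `s^2` at intermediate angles for rod-like
#' particles: slope `= -Rc^2 / 2`.
#'
#' @inheritParams guinier_fit
#' @return Tibble with `Rc`, `n_points`, `warning_nonlinear`.
#' @export
cross_section_guinier <- function(profile, s_range) {
  sel <- profile$s >= s_range[1] & profile$s <= s_range[2] & profile$I > 0 &
    profile$s > 0
  if (sum(sel) < 3) abort_input("need >= 3 points in the cross-section range")
  s2 <- profile$s[sel]^2
  li <- log(profile$I[sel] * profile$s[sel])
  fit <- lm(li ~ s2)
  slope <- coef(fit)[["s2"]]
  if (slope >= 0) abort_input("cross-sectional Guinier slope is non-negative")
  tibble(
    Rc = sqrt(-2 * slope),
    n_points = sum(sel),
    warning_nonlinear = curvature_flag(s2, residuals(fit), li)
  )
}

curvature_flag <- function(x, resid, y) {
  if (length(x) < 4) return(FALSE)
  q <- lm(resid ~ poly(x, 2))
  summary(q)$r.squared > 0.8 && sd(resid) > 0.02 * max(abs(diff(range(y))), 1e-12)
}

#' Porod exponent from the mid-angle power-law decay
#'
#' Negative slope of a linear fit of `log I` versus `log s` over the stated
#' mid-s range: ~1 for thin rods, ~4 for compact globular particles.
#'
#' @inheritParams guinier_fit
#' @return Single numeric exponent.
#' @export
porod_exponent <- function(profile, s_range) {
  sel <- profile$s >= s_range[1] & profile$s <= s_range[2] & profile$I > 0 &
    profile$s > 0
  if (sum(sel) < 5) abort_input("need >= 5 points in the Porod range")
  fit <- lm(log(profile$I[sel]) ~ log(profile$s[sel]))
  -coef(fit)[[2]]
}

#' Radius of gyration directly from bead coordinates
#'
#' Second moment about the centre of mass; the reciprocal-space consistency
#' check for [guinier_fit()].
#'
#' @param chain A `bead_chain` or coordinate matrix.
#' @return Rg in nm.
#' @export
rg_direct <- function(chain) {
  xyz <- chain_coords(chain)
  xyz_c <- sweep(xyz, 2, colMeans(xyz))
  sqrt(mean(rowSums(xyz_c^2)))
}
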