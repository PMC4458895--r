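# Seeded generator of TIRF movies of surface-immobilized molecules carrying
# two fluorophores at a fixed separation, with stochastic single-step
# photobleaching, Poisson shot noise and camera gain/read noise.

#' Configuration for a synthetic two-fluorophore TIRF movie
#'
#' Emulates prism-coupled TIRF imaging of end-labelled molecules sparsely
#' immobilized on a slide: each molecule carries two fluorophores separated by
#' `separation` nm (well below the pixel size), each bleaching in a single
#' irreversible step with a geometric lifetime. No blinking or drift is
#' simulated.
#'
#' @param n_molecules Number of molecules in the movie.
#' @param separation True inter-fluorophore distance (nm), >= 0.
#' @param psf_sigma PSF Gaussian sigma (nm). Default 110 nm, diffraction
#'   limited for ~525 nm emission at NA 1.4.
#' @param pixel_size Camera pixel size in the sample plane (nm). Default 157.
#' @param frame_exposure Exposure per frame (s). Default 0.5 (2 fps).
#' @param n_frames Number of frames.
#' @param photons_per_frame Expected photons per active fluorophore per frame.
#' @param bleach_mean_lifetime Mean active lifetime (frames) of the geometric
#'   bleaching distribution.
#' @param background Expected background photons per pixel per frame.
#' @param camera_gain Camera counts per photon.
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param shot_noise Apply Poisson/read noise (`TRUE`) or return the exact
#'   expected-count render (`FALSE`; useful for oracle tests).
#' @param cell_px Side of the square tile (pixels) reserved per molecule.
#' @param seed Integer seed.
#' @return A list of class `tirf_config`.
#' @export
tirf_config <- function(n_molecules = 1,
                        separation = 59,
                        psf_sigma = 110,
                        pixel_size = 157,
                        frame_exposure = 0.5,
                        n_frames = 150,
                        photons_per_frame = 1500,
                        bleach_mean_lifetime = 40,
                        background = 10,
                        camera_gain = 1,
                        read_noise_sd = 2,
                        shot_noise = TRUE,
                        cell_px = 16,
                        seed = 1) {
  check_number(n_molecules, "n_molecules", 1)
  check_number(separation, "separation", 0)
  check_number(psf_sigma, "psf_sigma", 0, strict = TRUE)
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  check_number(n_frames, "n_frames", 15)
  check_number(photons_per_frame, "photons_per_frame", 0)
  check_number(bleach_mean_lifetime, "bleach_mean_lifetime", 0, strict = TRUE)
  check_number(background, "background", 0)
  check_number(cell_px, "cell_px", 8)
  structure(
    list(n_molecules = as.integer(n_molecules), separation = separation,
         psf_sigma = psf_sigma, pixel_size = pixel_size,
         frame_exposure = frame_exposure, n_frames = as.integer(n_frames),
         photons_per_frame = photons_per_frame,
         bleach_mean_lifetime = bleach_mean_lifetime,
         background = background, camera_gain = camera_gain,
         read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
         cell_px = as.integer(cell_px), seed = as.integer(seed)),
    class = "tirf_config"
  )
}

# Expected photons in each pixel of an ny x nx frame from one emitter at
# (x0, y0) in pixel units (pixel i centred on integer i, covering
# [i - 0.5, i + 0.5)). Pixel-integrated symmetric Gaussian via the normal CDF.
render_emitter <- function(nx, ny, x0, y0, sigma_px, photons) {
  ex <- pnorm((seq_len(nx) + 0.5 - x0) / sigma_px) -
    pnorm((seq_len(nx) - 0.5 - x0) / sigma_px)
  ey <- pnorm((seq_len(ny) + 0.5 - y0) / sigma_px) -
    pnorm((seq_len(ny) - 0.5 - y0) / sigma_px)
  photons * outer(ey, ex)
}

#' Simulate a two-fluorophore TIRF movie
#'
#' Molecules are laid out on a sparse tile grid; each renders as the sum of
#' two pixel-integrated Gaussian PSFs whose amplitudes drop to zero at their
#' independent, geometrically distributed bleaching frames. Poisson photon
#' noise, camera gain and Gaussian read noise are applied when
#' `cfg$shot_noise` is `TRUE`. Lifetimes are truncated to the movie length
#' (a fluorophore still alive in the final frame is recorded as bleaching
#' there; such traces fail step QC downstream, as in a real experiment).
#'
#' @param cfg A [tirf_config()].
#' @return A list of class `tirf_movie` with elements `stack` (array
#'   y-by-x-by-frame, camera counts), `truth` (tibble: one row per molecule
#'   with both fluorophore positions in nm and both bleaching frames, the
#'   first dark frame of each) and `config`.
#' @export
#' @examples
#' mv <- simulate_tirf_movie(tirf_config(n_molecules = 2, n_frames = 60, seed = 3))
#' dim(mv$stack)
#' mv$truth
simulate_tirf_movie <- function(cfg) {
  stopifnot(inherits(cfg, "tirf_config"))
  n <- cfg$n_molecules
  grid_n <- ceiling(sqrt(n))
  nx <- grid_n * cfg$cell_px
  ny <- grid_n * cfg$cell_px
  sigma_px <- cfg$psf_sigma / cfg$pixel_size
  sep_px <- cfg$separation / cfg$pixel_size

  withr::with_seed(cfg$seed, {
    cell <- seq_len(n) - 1L
    cx <- (cell %% grid_n) * cfg$cell_px + cfg$cell_px / 2 + 0.5
    cy <- (cell %/% grid_n) * cfg$cell_px + cfg$cell_px / 2 + 0.5
    jx <- runif(n, -1, 1)
    jy <- runif(n, -1, 1)
    ang <- runif(n, 0, 2 * pi)
    x1 <- cx + jx - sep_px / 2 * cos(ang)
    y1 <- cy + jy - sep_px / 2 * sin(ang)
    x2 <- cx + jx + sep_px / 2 * cos(ang)
    y2 <- cy + jy + sep_px / 2 * sin(ang)
    # active for T >= 1 frames; first dark frame = T + 1, capped at n_frames
    t1 <- pmin(rgeom(n, 1 / cfg$bleach_mean_lifetime) + 1L, cfg$n_frames - 1L)
    t2 <- pmin(rgeom(n, 1 / cfg$bleach_mean_lifetime) + 1L, cfg$n_frames - 1L)

    stack <- array(0, dim = c(ny, nx, cfg$n_frames))
    base <- matrix(cfg$background, ny, nx)
    psf1 <- vector("list", n)
    psf2 <- vector("list", n)
    for (i in seq_len(n)) {
      psf1[[i]] <- render_emitter(nx, ny, x1[i], y1[i], sigma_px, cfg$photons_per_frame)
      psf2[[i]] <- render_emitter(nx, ny, x2[i], y2[i], sigma_px, cfg$photons_per_frame)
    }
    for (f in seq_len(cfg$n_frames)) {
      expected <- base
      for (i in seq_len(n)) {
        if (f < t1[i] + 1L) expected <- expected + psf1[[i]]
        if (f < t2[i] + 1L) expected <- expected + psf2[[i]]
      }
      if (cfg$shot_noise) {
        counts <- cfg$camera_gain * rpois(length(expected), expected) +
          rnorm(length(expected), 0, cfg$read_noise_sd)
        stack[, , f] <- matrix(counts, ny, nx)
      } else {
        stack[, , f] <- cfg$camera_gain * expected
      }
    }

    truth <- tibble(
      molecule = seq_len(n),
      x1_nm = x1 * cfg$pixel_size, y1_nm = y1 * cfg$pixel_size,
      x2_nm = x2 * cfg$pixel_size, y2_nm = y2 * cfg$pixel_size,
      separation_nm = sqrt((x2 - x1)^2 + (y2 - y1)^2) * cfg$pixel_size,
      bleach_frame_1 = t1 + 1L,
      bleach_frame_2 = t2 + 1L
    )
  })

  structure(list(stack = stack, truth = truth, config = cfg),
            class = "tirf_movie")
}
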