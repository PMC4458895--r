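# Shared fixtures: small, fast configurations used across test files.

# Staircase intensity trace with two downward bleach steps.
staircase_trace <- function(n = 130, steps = c(40, 90),
                            levels = c(1000, 520, 30), noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lvl <- c(rep(levels[1], steps[1] - 1),
           rep(levels[2], steps[2] - steps[1]),
           rep(levels[3], n - steps[2] + 1))
  lvl + rnorm(n, 0, noise_sd)
}

# Quick AFM config: fewer samples than the default for unit-test speed.
quick_afm <- function(seed = 1, ...) {
  afm_config(sample_rate = 4000, seed = seed, ...)
}

# Noiseless saturated AFM config: every threshold far below detachment and no
# force noise, so all 13 domains unfold deterministically.
noiseless_afm <- function(seed = 1) {
  cls <- afm_domain_classes()
  cls$force_sd_pN <- c(1e-6, 1e-6)
  afm_config(classes = cls, force_noise_sd = 0, sample_rate = 4000, seed = seed)
}

# Lattice sphere of radius R (bead spacing `by`).
lattice_sphere <- function(R = 5, by = 0.45) {
  g <- seq(-R + by / 2, R, by = by)
  m <- as.matrix(expand.grid(x = g, y = g, z = g))
  m[rowSums(m^2) <= R^2, ]
}
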