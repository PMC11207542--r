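# Independent brute-force oracles: radial Fourier quadrature of the
# scattering amplitude, kept free of the package's analytic formulas.

sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

# A(q, R) as the radial Fourier integral of a unit sphere
amp_oracle <- function(q, R) {
  4 * pi * stats::integrate(function(r) r^2 * sinc(q * r), 0, R,
                            rel.tol = 1e-10, subdivisions = 1000L,
                            stop.on.error = FALSE)$value
}

# F(q) for the piecewise-constant radial density of a core/tri-shell
# particle, integrated region by region
particle_amp_oracle <- function(q, particle,
                                core = particle$core_radius_mean) {
  radii <- core + c(0, cumsum(particle$shell_thicknesses))
  lims <- c(0, radii)
  rho <- particle$region_contrasts
  tot <- 0
  for (i in 1:4) {
    tot <- tot + rho[i] * 4 * pi *
      stats::integrate(function(r) r^2 * sinc(q * r), lims[i], lims[i + 1],
                       rel.tol = 1e-10, subdivisions = 1000L,
                       stop.on.error = FALSE)$value
  }
  tot
}

# random valid particle under a fixed RNG state (caller sets the seed)
random_particle <- function() {
  repeat {
    rc <- stats::runif(4, -1.5, 1.5)
    if (any(abs(rc) > 0.1)) break
  }
  shell_particle(core_radius_mean = stats::runif(1, 10, 60),
                 rel_polydispersity = stats::runif(1, 0, 0.35),
                 shell_thicknesses = stats::runif(3, 1, 3),
                 region_contrasts = rc)
}
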