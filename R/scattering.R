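#' Scattering amplitude of a homogeneous sphere
#'
#' `A(q, R) = 4 pi (sin(qR) - qR cos(qR)) / q^3`, the Fourier transform of a
#' unit-density sphere of radius R. At `q = 0` this equals the sphere volume
#' `V(R) = (4 pi / 3) R^3`; a series expansion is used for small `qR` to
#' avoid catastrophic cancellation.
#'
#' @param q Momentum transfer in 1/nm (>= 0); vectorized.
#' @param R Sphere radius in nm (> 0); vectorized (recycled against `q`).
#' @return Amplitude in a.u. * nm^3.
#' @examples
#' sphere_amplitude(0, 1)      # 4 pi / 3
#' sphere_amplitude(1, 36.4)
#' @export
sphere_amplitude <- function(q, R) {
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be finite and > 0")
  n <- max(length(q), length(R))
  q <- rep_len(q, n); R <- rep_len(R, n)
  x <- q * R
  out <- numeric(n)
  small <- x < 1e-2
  if (any(small)) {
    xs <- x[small]
    # A = V(R) * 3 (sin x - x cos x)/x^3 ; series of the bracket
    out[small] <- (4 * pi / 3) * R[small]^3 *
      (1 - xs^2 / 10 + xs^4 / 280 - xs^6 / 15120)
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- 4 * pi * (sin(xl) - xl * cos(xl)) / q[!small]^3
  }
  out
}

# amplitude as an n_q x n_R matrix (internal, no argument checks)
.amp_matrix <- function(q, R) {
  x <- outer(q, R)
  A <- 4 * pi * (sin(x) - x * cos(x))
  qcube <- q^3
  small <- x < 1e-2
  if (any(small)) {
    Vterm <- outer(rep(4 * pi / 3, length(q)), R^3)
    A_series <- Vterm * (1 - x^2 / 10 + x^4 / 280)
    A <- A / qcube # recycles column-wise over q
    A[small] <- A_series[small]
  } else {
    A <- A / qcube
  }
  A
}

# contrast steps Delta rho_i = rho_i - rho_{i+1}, rho_5 = 0 (solvent)
.contrast_steps <- function(region_contrasts) {
  diff(-c(region_contrasts, 0))
}

#' Scattering amplitude of a core/tri-shell particle
#'
#' The piecewise-constant radial density is a telescoping sum of homogeneous
#' spheres: `F(q) = sum_i Delta rho_i A(R_i, q)` with
#' `Delta rho_i = rho_i - rho_{i+1}` and the solvent level `rho_5 = 0`.
#'
#' @param q Momentum transfer in 1/nm; vectorized.
#' @param particle A [shell_particle()].
#' @param core_radius_override Core radius in nm at which to evaluate (the
#'   polydisperse integration variable); defaults to `core_radius_mean`.
#' @return Amplitude vector, same length as `q`.
#' @export
particle_amplitude <- function(q, particle,
                               core_radius_override = particle$core_radius_mean) {
  if (!is.finite(core_radius_override) || core_radius_override <= 0)
    stop("core_radius_override must be > 0")
  if (all(particle$region_contrasts == 0))
    stop("no scattering contrast: all region contrasts are zero")
  radii <- region_radii(particle, core_radius_override)
  drho <- .contrast_steps(particle$region_contrasts)
  A <- .amp_matrix(q, radii)
  as.vector(A %*% drho)
}

#' Normalized form factor of a single particle
#'
#' `P(q) = F(q)^2 / F(0)^2` with `F(0) = sum_i Delta rho_i V(R_i)` the total
#' excess scattering mass. `P(0) = 1` by construction; `P >= 0` everywhere.
#'
#' @inheritParams particle_amplitude
#' @return Dimensionless form factor, same length as `q`.
#' @export
form_factor <- function(q, particle,
                        core_radius_override = particle$core_radius_mean) {
  radii <- region_radii(particle, core_radius_override)
  drho <- .contrast_steps(particle$region_contrasts)
  F0 <- sum(drho * (4 * pi / 3) * radii^3)
  if (abs(F0) < 1e-12 * sum(abs(drho)) * (4 * pi / 3) * radii[4]^3)
    stop("contrast-matched particle: F(0) = 0, form factor undefined")
  (particle_amplitude(q, particle, core_radius_override) / F0)^2
}

#' Truncated Gaussian core-size distribution
#'
#' Gaussian density in the core radius, truncated at `R <= 0` and
#' renormalized so the integral over `R > 0` is 1.
#'
#' @param R Radius grid in nm; vectorized.
#' @param R_av Mean radius in nm (> 0).
#' @param sigma Standard deviation in nm (> 0).
#' @return Density values in 1/nm (0 for `R <= 0`).
#' @export
size_distribution <- function(R, R_av, sigma) {
  if (!is.finite(R_av) || R_av <= 0) stop("R_av must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  norm <- 1 - stats::pnorm(0, mean = R_av, sd = sigma)
  ifelse(R > 0, stats::dnorm(R, mean = R_av, sd = sigma) / norm, 0)
}

# quadrature rule over the polydisperse core radius: nodes, and weights that
# already include the (renormalized) truncated Gaussian density
.poly_quadrature <- function(particle, n_nodes = 61) {
  R_av <- particle$core_radius_mean
  sigma <- particle$rel_polydispersity * R_av
  if (sigma == 0) return(list(R = R_av, w = 1))
  gl <- .gauss_legendre(n_nodes)
  a <- max(0.1, R_av - 4 * sigma)
  b <- R_av + 4 * sigma
  R <- 0.5 * (b - a) * gl$x + 0.5 * (a + b)
  w <- 0.5 * (b - a) * gl$w * stats::dnorm(R, R_av, sigma)
  # renormalize on the truncated support so <P>(0) = 1 exactly
  list(R = R, w = w / sum(w))
}

#' Polydispersity-averaged form factor
#'
#' `<P>(q) = integral D(R) P(q, R) dR` over the truncated Gaussian core-size
#' distribution; the three shells ride rigidly on the core. Evaluated with a
#' fixed 61-node Gauss-Legendre rule on `[max(0.1, R_av - 4 sigma),
#' R_av + 4 sigma]`, renormalized so `<P>(0) = 1`.
#'
#' @inheritParams particle_amplitude
#' @param n_nodes Number of quadrature nodes (default 61).
#' @return Dimensionless averaged form factor, same length as `q`.
#' @export
average_form_factor <- function(q, particle, n_nodes = 61) {
  if (all(particle$region_contrasts == 0))
    stop("no scattering contrast: all region contrasts are zero")
  quad <- .poly_quadrature(particle, n_nodes)
  if (length(quad$R) == 1)
    return(form_factor(q, particle))
  drho <- .contrast_steps(particle$region_contrasts)
  sh <- c(0, cumsum(particle$shell_thicknesses))
  Fm <- matrix(0, length(q), length(quad$R))
  F0 <- numeric(length(quad$R))
  for (j in 1:4) {
    Rj <- quad$R + sh[j]
    Fm <- Fm + drho[j] * .amp_matrix(q, Rj)
    F0 <- F0 + drho[j] * (4 * pi / 3) * Rj^3
  }
  if (any(abs(F0) < 1e-12 * sum(abs(drho)) * (4 * pi / 3) *
            (max(quad$R) + sh[4])^3))
    stop("contrast-matched particle: F(0) = 0 at a quadrature node")
  P <- sweep(Fm, 2, F0, "/")^2
  as.vector(P %*% quad$w)
}

#' Radial electron-density profile
#'
#' The piecewise-constant excess electron density of the particle: four
#' plateaus (core, inner polar, hydrophobic, outer polar) then the solvent
#' level 0 beyond the outer radius.
#'
#' @param particle A [shell_particle()].
#' @param dr Radial sampling step in nm for the returned grid (default 0.05).
#' @return A data frame with columns `r` (nm) and `rho` (a.u.), of class
#'   `density_profile`; the region boundaries are in `attr(, "breaks")`.
#' @export
electron_density_profile <- function(particle, dr = 0.05) {
  radii <- region_radii(particle)
  rho <- particle$region_contrasts
  r <- seq(0, radii[4] * 1.15, by = dr)
  idx <- findInterval(r, radii) + 1 # 1..4 inside, 5 = solvent (r >= R_4)
  prof <- data.frame(r = r, rho = c(rho, 0)[idx])
  attr(prof, "breaks") <- radii
  attr(prof, "levels") <- rho
  class(prof) <- c("density_profile", "data.frame")
  prof
}

#' Write an electron-density profile as two-column text
#'
#' @param profile A `density_profile` from [electron_density_profile()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_density_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# radial electron-density profile",
               "# columns: r_nm rho_au"), con)
  writeLines(sprintf("%.10g %.10g", profile$r, profile$rho), con)
  invisible(path)
}

#' @export
plot.density_profile <- function(x, ...) {
  plot(x$r, x$rho, type = "s", xlab = "r (nm)",
       ylab = expression(rho ~ "(a.u.)"), ...)
  abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}
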