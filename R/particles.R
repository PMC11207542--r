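#' Core/tri-shell particle geometry and contrasts
#'
#' Describes one LNP as a homogeneous spherical core wrapped in three
#' concentric shells (inner polar headgroup region, hydrophobic tail region,
#' outer polar headgroup region). Each region carries an electron-density
#' contrast relative to the solvent; the shell thicknesses are fixed
#' properties of the lipid bilayer (2 nm each by default) while the core
#' radius is the polydisperse size variable.
#'
#' @param core_radius_mean Mean core radius R_av in nm (> 0).
#' @param rel_polydispersity Relative width sigma/R_av of the Gaussian core
#'   size distribution, in `[0, 0.5]`. Default 0.2.
#' @param shell_thicknesses Numeric vector of 3 shell thicknesses in nm,
#'   all > 0. Default `c(2, 2, 2)`.
#' @param region_contrasts Numeric vector of 4 electron-density contrasts
#'   relative to solvent (a.u.): core, inner polar, hydrophobic, outer polar.
#'
#' @return An object of class `shell_particle`.
#' @examples
#' shell_particle(36.4, region_contrasts = c(0.2, 1, -1, 1))
#' @export
shell_particle <- function(core_radius_mean,
                           rel_polydispersity = 0.2,
                           shell_thicknesses = c(2, 2, 2),
                           region_contrasts = c(0.2, 1, -1, 1)) {
  stopifnot(is.numeric(core_radius_mean), length(core_radius_mean) == 1)
  if (!is.finite(core_radius_mean) || core_radius_mean <= 0)
    stop("core_radius_mean must be a positive length (nm)")
  if (!is.finite(rel_polydispersity) || rel_polydispersity < 0 ||
      rel_polydispersity > 0.5)
    stop("rel_polydispersity must lie in [0, 0.5]")
  if (length(shell_thicknesses) != 3 || any(shell_thicknesses <= 0))
    stop("shell_thicknesses must be 3 positive lengths (nm)")
  if (length(region_contrasts) != 4 || any(!is.finite(region_contrasts)))
    stop("region_contrasts must be 4 finite values (core + 3 shells)")
  structure(
    list(core_radius_mean = core_radius_mean,
         rel_polydispersity = rel_polydispersity,
         shell_thicknesses = as.numeric(shell_thicknesses),
         region_contrasts = as.numeric(region_contrasts)),
    class = "shell_particle")
}

#' @export
print.shell_particle <- function(x, ...) {
  cat("LNP core/tri-shell particle\n")
  cat(sprintf("  core radius R_av : %.3g nm (sigma/R = %.3g)\n",
              x$core_radius_mean, x$rel_polydispersity))
  cat(sprintf("  shells           : %s nm\n",
              paste(format(x$shell_thicknesses), collapse = " / ")))
  cat(sprintf("  contrasts        : %s (core, polar, tail, polar)\n",
              paste(format(x$region_contrasts), collapse = ", ")))
  cat(sprintf("  outer diameter   : %.3g nm\n", outer_diameter(x)))
  invisible(x)
}

# region boundary radii R_1..R_4 for a given core radius (shells ride rigidly)
region_radii <- function(particle, core_radius = particle$core_radius_mean) {
  core_radius + c(0, cumsum(particle$shell_thicknesses)) # R_1 = core .. R_4
}

#' Outer diameter of a particle
#'
#' `2 * (R_av + sum of shell thicknesses)`; the "diameter" that cryo-TEM and
#' DLS comparisons refer to.
#'
#' @param particle A [shell_particle()].
#' @return Outer diameter in nm.
#' @export
outer_diameter <- function(particle) {
  2 * (particle$core_radius_mean + sum(particle$shell_thicknesses))
}

#' Lamellar stacking (multilamellarity) parameters
#'
#' The correlation between concentric bilayers is modelled as a 1D
#' paracrystal: `n_layers` bilayers at repeat distance `repeat_distance`
#' with Gaussian nearest-neighbour spacing disorder.
#'
#' @param repeat_distance Lamellar repeat distance d in nm (> 0).
#' @param n_layers Average number of bilayers N_av (real, >= 1); non-integer
#'   values are handled by interpolation in [normalized_sf()].
#' @param rel_disorder Relative spacing disorder sigma_d/d (>= 0). Default
#'   0.01.
#' @return An object of class `lamellar_stacking`.
#' @examples
#' lamellar_stacking(6.3, n_layers = 2.3)
#' @export
lamellar_stacking <- function(repeat_distance, n_layers,
                              rel_disorder = 0.01) {
  if (!is.finite(repeat_distance) || repeat_distance <= 0)
    stop("repeat_distance must be a positive length (nm)")
  if (!is.finite(n_layers) || n_layers < 1)
    stop("n_layers must be >= 1")
  if (!is.finite(rel_disorder) || rel_disorder < 0)
    stop("rel_disorder must be >= 0")
  structure(
    list(repeat_distance = repeat_distance, n_layers = n_layers,
         rel_disorder = rel_disorder),
    class = "lamellar_stacking")
}

#' @export
print.lamellar_stacking <- function(x, ...) {
  cat(sprintf("Lamellar stacking: d = %.3g nm, N_av = %.3g, disorder = %.3g\n",
              x$repeat_distance, x$n_layers, x$rel_disorder))
  invisible(x)
}

#' Intensity scale, multilamellar fraction and background
#'
#' The measured intensity is
#' `I(q) = scale * ((1 - f) + f * S_hat(q)) * <P>(q) + background`,
#' where `f = multilayer_fraction` is the share of the scattering
#' attributable to multilamellar particles ("Multilayer (%)" = 100 f) and
#' `S_hat` is the per-layer-normalized paracrystal structure factor.
#'
#' @param scale Overall intensity scale (> 0, a.u.).
#' @param multilayer_fraction Multilamellar fraction f in `[0, 1]`.
#' @param background Flat background (>= 0, a.u.).
#' @return An object of class `intensity_params`.
#' @export
intensity_params <- function(scale = 1, multilayer_fraction = 0,
                             background = 0) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  if (!is.finite(multilayer_fraction) || multilayer_fraction < 0 ||
      multilayer_fraction > 1)
    stop("multilayer_fraction must lie in [0, 1]")
  if (!is.finite(background) || background < 0)
    stop("background must be >= 0")
  structure(
    list(scale = scale, multilayer_fraction = multilayer_fraction,
         background = background),
    class = "intensity_params")
}

#' @export
print.intensity_params <- function(x, ...) {
  cat(sprintf("Intensity: scale = %.4g, multilayer = %.1f%%, back = %.4g\n",
              x$scale, 100 * x$multilayer_fraction, x$background))
  invisible(x)
}
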