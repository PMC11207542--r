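#' Paracrystal structure factor of a 1D lamellar stack
#'
#' Ideal 1D paracrystal of `N` layers at repeat distance `d` with cumulative
#' Gaussian nearest-neighbour spacing disorder `Delta = rel_disorder`
#' (sigma_d / d):
#' `S_N(q) = N + 2 sum_{k=1}^{N-1} (N - k) cos(k q d) exp(-k q^2 d^2 Delta^2 / 2)`.
#' `S(0) = N^2`; for `Delta > 0`, `S -> N` at large q; `S_1 == 1`.
#'
#' @param q Momentum transfer in 1/nm; vectorized.
#' @param stacking A [lamellar_stacking()] with integer `n_layers` (use
#'   [normalized_sf()] for fractional layer numbers).
#' @return Dimensionless structure factor, same length as `q`.
#' @examples
#' s <- lamellar_stacking(6.3, 2)
#' paracrystal_sf(0, s)  # N^2 = 4
#' @export
paracrystal_sf <- function(q, stacking) {
  N <- stacking$n_layers
  if (N != round(N))
    stop("paracrystal_sf needs integer n_layers; see normalized_sf()")
  N <- as.integer(round(N))
  d <- stacking$repeat_distance
  Delta <- stacking$rel_disorder
  S <- rep(N, length(q))
  if (N > 1) {
    damp <- q^2 * d^2 * Delta^2 / 2
    for (k in seq_len(N - 1))
      S <- S + 2 * (N - k) * cos(k * q * d) * exp(-k * damp)
  }
  S
}

#' Per-layer-normalized structure factor with fractional layer support
#'
#' `S_hat(q) = S_N(q) / N`, linearly interpolated between the adjacent
#' integer layer counts when `n_layers` is fractional (fitted averages like
#' N_av = 2.3 need a continuous layer number). `S_hat -> 1` at large q and
#' `S_hat(0)` equals the interpolated layer count.
#'
#' @param q Momentum transfer in 1/nm; vectorized.
#' @param stacking A [lamellar_stacking()]; `n_layers` may be fractional.
#' @return Dimensionless normalized structure factor.
#' @export
normalized_sf <- function(q, stacking) {
  N <- stacking$n_layers
  lo <- floor(N)
  if (lo == N) {
    st <- stacking; st$n_layers <- lo
    return(paracrystal_sf(q, st) / lo)
  }
  hi <- lo + 1
  t <- N - lo
  st_lo <- stacking; st_lo$n_layers <- lo
  st_hi <- stacking; st_hi$n_layers <- hi
  (1 - t) * paracrystal_sf(q, st_lo) / lo +
    t * paracrystal_sf(q, st_hi) / hi
}

#' Assembled model intensity
#'
#' `I(q) = scale * ((1 - f) + f * S_hat(q)) * <P>(q) + background`, the
#' incoherent mixture of a unilamellar population (structure factor 1) and a
#' multilamellar population with paracrystal stacking, both sharing the
#' polydisperse core/tri-shell envelope `<P>`.
#'
#' @param q Momentum transfer in 1/nm; vectorized.
#' @param particle A [shell_particle()].
#' @param stacking A [lamellar_stacking()], or `NULL` when
#'   `multilayer_fraction = 0` (purely unilamellar).
#' @param ip An [intensity_params()].
#' @return Intensity in a.u., same length as `q`.
#' @examples
#' p <- shell_particle(36.4)
#' s <- lamellar_stacking(6.3, 2.3)
#' i <- intensity_params(scale = 1, multilayer_fraction = 0.72,
#'                       background = 2e-7)
#' q <- seq(0.05, 2, length.out = 200)
#' plot(q, model_intensity(q, p, s, i), log = "xy", type = "l")
#' @export
model_intensity <- function(q, particle, stacking, ip) {
  f <- ip$multilayer_fraction
  avgP <- average_form_factor(q, particle)
  if (f > 0) {
    if (is.null(stacking))
      stop("multilayer_fraction > 0 requires a lamellar_stacking")
    mix <- (1 - f) + f * normalized_sf(q, stacking)
  } else {
    mix <- 1
  }
  ip$scale * mix * avgP + ip$background
}
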