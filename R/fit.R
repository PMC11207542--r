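# Weighted nonlinear least-squares fitting of the intensity model.
#
# All fittable quantities live in one named vector; the geometry that the
# model treats as fixed material properties (polydispersity, shell
# thicknesses, spacing disorder) is carried separately in the config.

.param_names <- c("core_radius_mean", "rho_core", "rho_polar_in", "rho_tail",
                  "rho_polar_out", "multilayer_fraction", "n_layers",
                  "repeat_distance", "scale", "background")

.default_free <- c("core_radius_mean", "rho_core", "rho_tail",
                   "rho_polar_out", "multilayer_fraction", "n_layers",
                   "repeat_distance", "scale", "background")

#' Configuration of a profile fit
#'
#' Which parameters are free, their bounds and starting values, the q window
#' and the multi-start policy. The inner polar-shell contrast is fixed at 1
#' by default: the normalized form factor is invariant under a common
#' rescaling of all four contrasts, so one contrast must serve as the unit.
#'
#' @param free Character vector of free parameter names, a subset of
#'   `core_radius_mean`, `rho_core`, `rho_polar_in`, `rho_tail`,
#'   `rho_polar_out`, `multilayer_fraction`, `n_layers`, `repeat_distance`,
#'   `scale`, `background`.
#' @param fixed Named list overriding default values for non-free parameters
#'   and the fixed material properties `rel_polydispersity` (default 0.2),
#'   `shell_thicknesses` (default `c(2, 2, 2)` nm) and `rel_disorder`
#'   (default 0.01).
#' @param start Named numeric vector overriding default starting values.
#'   `scale` and `background` starts default to data-driven values.
#' @param bounds Named list of `c(lo, hi)` pairs overriding default bounds.
#' @param q_window Fitted q range in 1/nm (default `c(0.08, 2.0)`, excluding
#'   the beamstop region).
#' @param n_starts Number of optimizer starts (>= 1, default 5); the first
#'   uses the default start, the rest jitter it by up to 20% of each bound
#'   range.
#' @param rng_seed Seed for the start jitter (default 1).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = .default_free, fixed = list(), start = NULL,
                       bounds = list(), q_window = c(0.08, 2.0),
                       n_starts = 5, rng_seed = 1) {
  bad <- setdiff(free, .param_names)
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  fixed_defaults <- list(rel_polydispersity = 0.2,
                         shell_thicknesses = c(2, 2, 2),
                         rel_disorder = 0.01,
                         rho_polar_in = 1)
  fixed <- modifyList(fixed_defaults, as.list(fixed))
  default_start <- c(core_radius_mean = 30, rho_core = 0.5, rho_polar_in = 1,
                     rho_tail = -0.8, rho_polar_out = 1.2,
                     multilayer_fraction = 0.5, n_layers = 2,
                     repeat_distance = 2 * pi / 1.0,
                     scale = NA_real_, background = NA_real_)
  if (!is.null(start)) default_start[names(start)] <- start
  default_bounds <- list(core_radius_mean = c(5, 80),
                         rho_core = c(-2, 2), rho_polar_in = c(0.1, 3),
                         rho_tail = c(-3, 0.5), rho_polar_out = c(0, 3),
                         multilayer_fraction = c(0, 1), n_layers = c(1, 5),
                         repeat_distance = c(4, 10),
                         scale = c(NA, NA), background = c(NA, NA))
  default_bounds[names(bounds)] <- bounds
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (q_window[1] >= q_window[2]) stop("invalid q_window")
  structure(list(free = free, fixed = fixed, start = default_start,
                 bounds = default_bounds, q_window = q_window,
                 n_starts = as.integer(n_starts),
                 rng_seed = as.integer(rng_seed)),
            class = "fit_config")
}

# assemble model components from a full named parameter vector
.build_model <- function(p, fixed) {
  particle <- shell_particle(
    core_radius_mean = p[["core_radius_mean"]],
    rel_polydispersity = fixed$rel_polydispersity,
    shell_thicknesses = fixed$shell_thicknesses,
    region_contrasts = c(p[["rho_core"]], p[["rho_polar_in"]],
                         p[["rho_tail"]], p[["rho_polar_out"]]))
  stacking <- lamellar_stacking(p[["repeat_distance"]],
                                max(1, p[["n_layers"]]),
                                fixed$rel_disorder)
  ip <- intensity_params(scale = p[["scale"]],
                         multilayer_fraction = min(1, max(0,
                           p[["multilayer_fraction"]])),
                         background = max(0, p[["background"]]))
  list(particle = particle, stacking = stacking, ip = ip)
}

# sigma for weighting: the stored uncertainties, or (for data without an
# error column) counting-statistics shaped sigma = c sqrt(I) with c set so
# the median relative error is 2%
.effective_sigma <- function(intensity, sigma = NULL, rel = 0.02) {
  if (!is.null(sigma)) {
    if (any(sigma <= 0)) stop("stored sigma must be > 0 for fitting")
    return(sigma)
  }
  I_floor <- max(intensity) * 1e-12
  s <- sqrt(pmax(intensity, I_floor))
  c0 <- rel / stats::median(s / pmax(intensity, I_floor))
  c0 * s
}

#' Weighted residuals of the intensity model against a profile
#'
#' `r_i = (I_i - I_model(q_i)) / sigma_i` over the points inside the q
#' window. When the profile carries no uncertainties, counting-statistics
#' shaped ones are substituted (see [fit_profile()]).
#'
#' @param profile A [saxs_profile()].
#' @param particle,stacking,ip Model components as in [model_intensity()].
#' @param q_window Fitted q range in 1/nm; `NULL` uses all points.
#' @return Vector of weighted residuals.
#' @export
profile_residuals <- function(profile, particle, stacking, ip,
                              q_window = NULL) {
  keep <- if (is.null(q_window)) rep(TRUE, length(profile$q))
          else profile$q >= q_window[1] & profile$q <= q_window[2]
  if (!any(keep)) stop("empty q window")
  q <- profile$q[keep]
  I <- profile$intensity[keep]
  sig <- .effective_sigma(I, profile$sigma[keep])
  (I - model_intensity(q, particle, stacking, ip)) / sig
}

#' Reduced chi-squared
#'
#' `sum(r^2) / (n - p)` for `n` residuals and `p` free parameters; ~1 for a
#' correctly specified model with well-calibrated uncertainties.
#'
#' @param residuals Vector of weighted residuals.
#' @param n_free Number of free parameters.
#' @return Dimensionless reduced chi-squared.
#' @export
reduced_chi2 <- function(residuals, n_free) {
  n <- length(residuals)
  if (n <= n_free) stop("non-positive degrees of freedom")
  sum(residuals^2) / (n - n_free)
}

# Moore-Penrose pseudo-inverse (the contrast-scale direction can be flat)
.pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit the multi-shell / paracrystal intensity model to a SAXS profile
#'
#' Bounded Levenberg-Marquardt weighted least squares
#' (via [minpack.lm::nls.lm()]) with multi-start: the first start uses the
#' configured defaults (scale and background seeded from the data), the
#' remaining `n_starts - 1` jitter each free parameter by up to +/- 20% of
#' its bound range under the configured seed. The best start by reduced
#' chi-squared wins; ties go to the start closest to the defaults.
#'
#' Reported derived quantities follow the conventions of the multilayer
#' model: outer diameter `2 (R_av + sum of shell thicknesses)`, multilayer
#' percentage `100 f`, and the average layer number N_av (reported as `NA`
#' when the fitted multilamellar fraction is 0, where the stacking is
#' undefined).
#'
#' @param profile A [saxs_profile()].
#' @param config A [fit_config()].
#' @return An object of class `saxs_fit` with `print`, `summary`, `coef`,
#'   `vcov`, `predict`, `fitted`, `residuals`, `plot` and `simulate`
#'   methods.
#' @examples
#' fx <- table1_fixtures()$GV
#' prof <- simulate_profile(fx$particle, fx$stacking, fx$ip,
#'                          beamline_config(rng_seed = 7))
#' fit <- fit_profile(prof, fit_config(n_starts = 2))
#' summary(fit)
#' @export
fit_profile <- function(profile, config = fit_config()) {
  stopifnot(inherits(profile, "saxs_profile"),
            inherits(config, "fit_config"))
  keep <- profile$q >= config$q_window[1] & profile$q <= config$q_window[2]
  if (sum(keep) <= length(config$free))
    stop("q window contains too few points (", sum(keep), ")")
  q <- profile$q[keep]
  I <- profile$intensity[keep]
  sig <- .effective_sigma(I, profile$sigma[keep])

  # full parameter vector: start values with data-driven scale/background
  start <- config$start
  fixed_vals <- config$fixed
  for (nm in .param_names)
    if (!(nm %in% config$free) && !is.null(fixed_vals[[nm]]))
      start[nm] <- fixed_vals[[nm]]
  if (is.na(start[["background"]])) start[["background"]] <- 0.8 * min(I)
  if (is.na(start[["scale"]])) {
    m0 <- .build_model(replace(start, "scale", 1), fixed_vals)
    P1 <- average_form_factor(q[1], m0$particle)
    start[["scale"]] <- max(I[1], .Machine$double.xmin) / P1
  }
  # Data-driven initialization: coarse scan over the core radius. For each
  # candidate radius (and a few canonical bilayer contrast shapes) the
  # model is exactly linear in the nonnegative coefficients of the basis
  # {<P>, <P> S_hat_2 .. S_hat_5, 1} -- the cte1/cte2/back form with the
  # stacking order left open -- so those are profiled out by weighted
  # nonnegative least squares. The local minima of the resulting score
  # curve become multistart positions: the smeared sphere envelope has
  # wrong-radius local minima that can trap a single gradient start, and
  # the profiled score alone cannot always rank the true basin first.
  scan_starts <- list()
  if ("core_radius_mean" %in% config$free) {
    nm_sh <- c("rho_core", "rho_polar_in", "rho_tail", "rho_polar_out")
    contrasts_free <- any(nm_sh %in% config$free)
    n_free_layers <- "n_layers" %in% config$free
    f_free <- "multilayer_fraction" %in% config$free
    use_mix <- f_free || start[["multilayer_fraction"]] > 0
    cr_b <- config$bounds$core_radius_mean
    scan <- seq(cr_b[1], cr_b[2], length.out = 41)
    m_s <- .build_model(start, fixed_vals)
    Smix <- if (!use_mix) NULL
    else if (n_free_layers)
      vapply(2:5, function(N) {
        st <- m_s$stacking; st$n_layers <- N
        normalized_sf(q, st)
      }, numeric(length(q)))
    else matrix(normalized_sf(q, m_s$stacking), ncol = 1)
    shapes <- list(start[nm_sh])
    if (contrasts_free)
      shapes <- c(shapes, lapply(c(0.1, 0.5, 1),
                                 function(cc) c(cc, 1, -1, 1)))
    score <- rep(Inf, length(scan))
    picks <- vector("list", length(scan))
    for (ri in seq_along(scan)) {
      for (sh in shapes) {
        p_try <- start
        p_try[["core_radius_mean"]] <- scan[ri]
        p_try[nm_sh] <- sh
        P <- average_form_factor(q, .build_model(p_try, fixed_vals)$particle)
        X <- if (is.null(Smix)) cbind(P, 1) else cbind(P, P * Smix, 1)
        nn <- tryCatch(pracma::lsqnonneg(X / sig, I / sig),
                       error = function(e) NULL)
        if (is.null(nn)) next
        cf <- nn$x
        if (sum(cf[-length(cf)]) <= 0) next
        ssr <- sum((I - as.vector(X %*% cf))^2 / sig^2)
        if (ssr < score[ri]) {
          score[ri] <- ssr
          picks[[ri]] <- list(sh = sh, cf = cf)
        }
      }
    }
    if (any(is.finite(score))) {
      finite <- is.finite(score)
      is_min <- vapply(seq_along(scan), function(i) {
        finite[i] &&
          (i == 1 || !finite[i - 1] || score[i] <= score[i - 1]) &&
          (i == length(scan) || !finite[i + 1] || score[i] < score[i + 1])
      }, TRUE)
      cand <- which(is_min)[order(score[is_min])]
      cand <- utils::head(cand, max(1, config$n_starts - 1))
      scan_starts <- lapply(cand, function(ri) {
        s <- start
        s[["core_radius_mean"]] <- scan[ri]
        pk <- picks[[ri]]
        if (contrasts_free)
          s[nm_sh[nm_sh %in% config$free]] <- pk$sh[nm_sh %in% config$free]
        cf <- pk$cf
        n_mix <- length(cf) - 2
        c_lam <- if (n_mix > 0) cf[1 + seq_len(n_mix)] else numeric(0)
        tot <- cf[1] + sum(c_lam)
        if ("scale" %in% config$free && tot > 0) s[["scale"]] <- tot
        if (f_free && tot > 0)
          s[["multilayer_fraction"]] <- min(0.99, max(0.01,
                                                      sum(c_lam) / tot))
        if (n_free_layers && sum(c_lam) > 0)
          s[["n_layers"]] <- min(4.9, max(1.1,
            sum((2:5)[seq_len(n_mix)] * c_lam) / sum(c_lam)))
        if ("background" %in% config$free && cf[length(cf)] > 0)
          s[["background"]] <- cf[length(cf)]
        s
      })
      # seed the default start from the overall scan winner
      start <- scan_starts[[1]]
    }
  }
  bounds <- config$bounds
  if (anyNA(bounds$scale))
    bounds$scale <- start[["scale"]] * c(1e-4, 1e4)
  if (anyNA(bounds$background))
    bounds$background <- c(0, max(I))
  free <- config$free
  lo <- vapply(free, function(nm) bounds[[nm]][1], 0)
  hi <- vapply(free, function(nm) bounds[[nm]][2], 0)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("every free parameter needs finite bounds with lo < hi")
  start_free <- pmin(pmax(start[free], lo), hi)

  n_eval <- 0L
  resid_fun <- function(pf) {
    n_eval <<- n_eval + 1L
    p <- start
    p[free] <- pf
    m <- .build_model(p, fixed_vals)
    (I - model_intensity(q, m$particle, m$stacking, m$ip)) / sig
  }

  # start positions: the scan's local minima first, then jittered copies
  # of the best start (+/- 20% of the bound range for shape parameters;
  # scale-like parameters, whose bounds span decades, jitter
  # multiplicatively)
  starts <- c(list(start_free),
              lapply(scan_starts[-1], function(s)
                pmin(pmax(s[free], lo), hi)))
  starts <- utils::head(starts, config$n_starts)
  multiplicative <- free %in% c("scale", "background")
  if (length(starts) < config$n_starts) {
    jit <- .with_seed(config$rng_seed, {
      lapply(seq_len(config$n_starts - length(starts)), function(i) {
        u <- stats::runif(length(free), -0.2, 0.2)
        s <- start_free + u * (hi - lo)
        s[multiplicative] <- start_free[multiplicative] *
          10^(2.5 * u[multiplicative])
        pmin(pmax(s, lo), hi)
      })
    })
    starts <- c(starts, jit)
  }

  runs <- lapply(starts, function(s0) {
    tryCatch(
      minpack.lm::nls.lm(par = s0, lower = lo, upper = hi, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, TRUE)
  if (!any(ok)) stop("all optimizer starts failed")
  runs <- runs[ok]
  dev <- vapply(runs, function(r) r$deviance, 0)
  best_i <- which(dev <= min(dev) * (1 + 1e-9))
  if (length(best_i) > 1) { # tie: closest to the default start
    dist <- vapply(runs[best_i], function(r)
      sum(((unlist(r$par) - start_free) / (hi - lo))^2), 0)
    best_i <- best_i[which.min(dist)]
  } else best_i <- best_i[1]
  best <- runs[[best_i]]
  converged <- best$info %in% c(1, 2, 3)
  if (!converged)
    warning("optimizer did not converge (info = ", best$info, "): ",
            best$message)

  pars <- start
  pars[free] <- unlist(best$par)
  res <- best$fvec
  chi2 <- reduced_chi2(res, length(free))

  at_bound <- free[abs(pars[free] - lo) < 1e-7 * (hi - lo) |
                   abs(pars[free] - hi) < 1e-7 * (hi - lo)]
  if (length(at_bound))
    warning("parameter(s) at bound: ", paste(at_bound, collapse = ", "))

  # scale-normalize JtJ before the pseudo-inverse: parameter units differ
  # by many decades, and an absolute SVD cutoff would truncate legitimate
  # stiff/soft directions rather than only the exactly flat ones
  jtj <- best$hessian
  d <- sqrt(pmax(diag(jtj), 0))
  d[d == 0] <- 1
  corr <- jtj / tcrossprod(d)
  covm <- chi2 * (.pinv(corr) / tcrossprod(d))
  dimnames(covm) <- list(free, free)
  unc <- setNames(rep(NA_real_, length(.param_names)), .param_names)
  unc[free] <- sqrt(pmax(diag(covm), 0))

  f_hat <- pars[["multilayer_fraction"]]
  derived <- list(
    outer_diameter_nm = 2 * (pars[["core_radius_mean"]] +
                               sum(fixed_vals$shell_thicknesses)),
    multilayer_percent = 100 * f_hat,
    n_layers = if (f_hat == 0) NA_real_ else pars[["n_layers"]],
    outer_diameter_unc = 2 * unc[["core_radius_mean"]])

  m <- .build_model(pars, fixed_vals)
  structure(list(
    parameters = pars, free = free, uncertainties = unc,
    vcov = covm, reduced_chi2 = chi2, derived = derived,
    particle = m$particle,
    stacking = if (f_hat > 0) m$stacking else NULL,
    ip = m$ip,
    fixed = fixed_vals, config = config, profile = profile,
    window = keep, sigma_used = sig,
    fitted_intensity = I - res * sig, residuals = res,
    n_function_evals = n_eval, n_starts_run = length(runs),
    start_deviances = dev, converged = converged, at_bound = at_bound,
    rsstrace = best$rsstrace, seed = config$rng_seed),
    class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat("Multi-shell / paracrystal SAXS fit\n")
  d <- x$derived
  cat(sprintf("  outer diameter : %.1f +/- %.1f nm\n",
              d$outer_diameter_nm, d$outer_diameter_unc))
  cat(sprintf("  multilayer     : %.0f %%\n", d$multilayer_percent))
  cat(sprintf("  N_av           : %s\n",
              if (is.na(d$n_layers)) "-" else sprintf("%.1f", d$n_layers)))
  cat(sprintf("  reduced chi^2  : %.3g  (%d points, %d free)\n",
              x$reduced_chi2, sum(x$window), length(x$free)))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.saxs_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = object$parameters,
    std_error = object$uncertainties,
    free = names(object$parameters) %in% object$free)
  structure(list(table = tab, derived = object$derived,
                 reduced_chi2 = object$reduced_chi2,
                 converged = object$converged, at_bound = object$at_bound,
                 n_points = sum(object$window),
                 n_free = length(object$free)),
            class = "summary.saxs_fit")
}

#' @export
print.summary.saxs_fit <- function(x, ...) {
  cat("Multi-shell / paracrystal SAXS fit\n\nParameters:\n")
  print(format(x$table, digits = 4))
  cat(sprintf("\nReduced chi^2: %.4g on %d points, %d free parameters\n",
              x$reduced_chi2, x$n_points, x$n_free))
  d <- x$derived
  cat(sprintf("Outer diameter %.1f nm | multilayer %.0f%% | N_av %s\n",
              d$outer_diameter_nm, d$multilayer_percent,
              if (is.na(d$n_layers)) "-" else sprintf("%.2f", d$n_layers)))
  if (length(x$at_bound))
    cat("At bound:", paste(x$at_bound, collapse = ", "), "\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.saxs_fit <- function(object, ...) object$parameters

#' @export
vcov.saxs_fit <- function(object, ...) object$vcov

#' @export
fitted.saxs_fit <- function(object, ...) object$fitted_intensity

#' @export
residuals.saxs_fit <- function(object, ...) object$residuals

#' @export
predict.saxs_fit <- function(object, q = NULL, ...) {
  if (is.null(q)) q <- object$profile$q
  m <- .build_model(object$parameters, object$fixed)
  model_intensity(q, m$particle, m$stacking, m$ip)
}

#' @export
plot.saxs_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  q <- x$profile$q[x$window]
  I <- x$profile$intensity[x$window]
  plot(q, I, log = "xy", pch = 16, cex = 0.4,
       xlab = expression(q ~ (nm^-1)), ylab = "I(q) (a.u.)", ...)
  lines(q, x$fitted_intensity, col = 2, lwd = 1.5)
  legend("topright", c("data", "fit"), col = c(1, 2),
         pch = c(16, NA), lty = c(NA, 1), bty = "n")
  plot(q, x$residuals, type = "h", xlab = expression(q ~ (nm^-1)),
       ylab = "weighted residual")
  abline(h = 0, col = "grey60")
  invisible(x)
}

#' Simulate replicate profiles from a fitted model
#'
#' Draws `nsim` noisy profiles from the fitted intensity curve on the
#' fitted q grid, using the uncertainties that weighted the fit as the
#' noise scale.
#'
#' @param object A `saxs_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [saxs_profile()] objects.
#' @export
simulate.saxs_fit <- function(object, nsim = 1, seed = 1, ...) {
  q <- object$profile$q[object$window]
  mu <- object$fitted_intensity
  sig <- object$sigma_used
  .with_seed(seed, lapply(seq_len(nsim), function(i) {
    I <- mu + stats::rnorm(length(q), sd = 1) * sig
    floor_I <- 1e-6 * min(mu)
    I[I < floor_I] <- floor_I
    saxs_profile(q, I, sig,
                 metadata = list(sample = "simulated from fit",
                                 replicate = i, seed = seed))
  }))
}

#' Write a fit report as JSON
#'
#' Serializes parameters, uncertainties, fixed settings, fit quality and
#' derived quantities, plus a config echo and the seed.
#'
#' @param fit A `saxs_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    parameters = as.list(fit$parameters),
    uncertainties = as.list(fit$uncertainties),
    fixed = fit$fixed,
    reduced_chi2 = fit$reduced_chi2,
    derived = list(outer_diameter_nm = fit$derived$outer_diameter_nm,
                   multilayer_percent = fit$derived$multilayer_percent,
                   n_layers = fit$derived$n_layers),
    converged = fit$converged,
    at_bound = fit$at_bound,
    n_function_evals = fit$n_function_evals,
    config = list(free = fit$config$free, q_window = fit$config$q_window,
                  n_starts = fit$config$n_starts),
    seed = fit$seed,
    package_version = as.character(utils::packageVersion("lnpsaxs")))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
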