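# Pipeline entry points: simulate -> fit -> recovery summaries. These are
# what the command-line wrapper (inst/cli/lnpsaxs.R) dispatches to.

.get_fixture <- function(name) {
  fx <- table1_fixtures()
  if (!name %in% names(fx))
    stop("unknown fixture '", name, "'; valid names: ",
         paste(names(fx), collapse = ", "))
  fx[[name]]
}

#' Simulate a named fixture to disk
#'
#' Writes the noisy profile as a `.dat` file plus a JSON sidecar with the
#' generating truth (for recovery studies). Deterministic per seed.
#'
#' @param fixture Fixture name (`"GV"`, `"LM1"`..`"LM4"`).
#' @param out Output `.dat` path; the sidecar gets the extension
#'   `.truth.json`.
#' @param seed Integer seed.
#' @param config A [beamline_config()]; its seed is overridden by `seed`.
#' @return The simulated [saxs_profile()], invisibly.
#' @export
run_simulate <- function(fixture, out, seed = 1,
                         config = beamline_config()) {
  fx <- .get_fixture(fixture)
  config$rng_seed <- as.integer(seed)
  prof <- simulate_profile(fx$particle, fx$stacking, fx$ip, config)
  prof$metadata$sample <- paste0(fixture, " (synthetic)")
  write_profile(prof, out)
  truth <- list(
    fixture = fixture, seed = as.integer(seed),
    particle = unclass(fx$particle),
    stacking = if (!is.null(fx$stacking)) unclass(fx$stacking),
    ip = unclass(fx$ip),
    outer_diameter_nm = outer_diameter(fx$particle),
    multilayer_percent = 100 * fx$ip$multilayer_fraction,
    n_layers = if (is.null(fx$stacking)) NA else fx$stacking$n_layers,
    package_version = as.character(utils::packageVersion("lnpsaxs")))
  jsonlite::write_json(truth, paste0(sub("\\.dat$", "", out), ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(prof)
}

#' Fit a profile file and write the report
#'
#' Reads a reduced `.dat` profile, fits the intensity model, and writes the
#' JSON fit report plus a three-column text file (q, fitted intensity,
#' weighted residual).
#'
#' @param input Input `.dat` path.
#' @param out_prefix Output prefix; writes `<prefix>.fit.json` and
#'   `<prefix>.curve.dat`.
#' @param config A [fit_config()].
#' @param q_units Units of the q column in the input file.
#' @return The `saxs_fit`, invisibly.
#' @export
run_fit <- function(input, out_prefix = sub("\\.dat$", "", input),
                    config = fit_config(), q_units = "nm-1") {
  prof <- read_profile(input, q_units = q_units)
  fit <- fit_profile(prof, config)
  write_fit_report(fit, paste0(out_prefix, ".fit.json"))
  con <- file(paste0(out_prefix, ".curve.dat"), "w")
  writeLines(c("# best-fit curve", "# columns: q I_fit residual"), con)
  writeLines(sprintf("%.10g %.10g %.10g", prof$q[fit$window],
                     fit$fitted_intensity, fit$residuals), con)
  close(con)
  invisible(fit)
}

#' Parameter-recovery study on a fixture
#'
#' The simulate-and-refit harness: generates `n_seeds` noisy profiles from
#' a fixture, fits each, and summarizes the recovered geometry against the
#' generating truth. The fixture's unilamellar case (multilayer fraction 0)
#' is fitted without the stacking parameters, mirroring how such a profile
#' would be analysed.
#'
#' @param fixture Fixture name (`"GV"`, `"LM1"`..`"LM4"`).
#' @param n_seeds Number of noise replicates (default 20).
#' @param base_seed Offset added to the replicate index to form each
#'   profile's seed (default 0: seeds `1..n_seeds`).
#' @param config A [beamline_config()] controlling grid and noise.
#' @param fit_cfg A [fit_config()], or `NULL` for the fixture-appropriate
#'   default (stacking parameters fixed for the unilamellar fixture).
#' @param out Optional CSV path for the per-seed table.
#' @return Data frame with one row per seed (recovered outer diameter,
#'   multilayer percent, N_av, repeat distance, reduced chi^2, convergence)
#'   and the truth + medians in `attr(, "summary")`.
#' @export
run_recover <- function(fixture, n_seeds = 20, base_seed = 0,
                        config = beamline_config(), fit_cfg = NULL,
                        out = NULL) {
  fx <- .get_fixture(fixture)
  unilamellar <- is.null(fx$stacking)
  if (is.null(fit_cfg)) {
    fit_cfg <- if (unilamellar)
      fit_config(free = setdiff(.default_free,
                                c("n_layers", "repeat_distance")))
    else fit_config()
  }
  rows <- lapply(seq_len(n_seeds), function(i) {
    seed <- base_seed + i
    config$rng_seed <- as.integer(seed)
    prof <- simulate_profile(fx$particle, fx$stacking, fx$ip, config)
    fit_cfg$rng_seed <- as.integer(seed)
    fit <- fit_profile(prof, fit_cfg)
    data.frame(seed = seed,
               outer_diameter_nm = fit$derived$outer_diameter_nm,
               outer_diameter_unc = fit$derived$outer_diameter_unc,
               multilayer_percent = fit$derived$multilayer_percent,
               n_layers = fit$derived$n_layers,
               repeat_distance = fit$parameters[["repeat_distance"]],
               reduced_chi2 = fit$reduced_chi2,
               converged = fit$converged)
  })
  res <- do.call(rbind, rows)
  truth <- list(outer_diameter_nm = outer_diameter(fx$particle),
                multilayer_percent = 100 * fx$ip$multilayer_fraction,
                n_layers = if (unilamellar) NA_real_
                           else fx$stacking$n_layers)
  attr(res, "summary") <- list(
    fixture = fixture, truth = truth,
    median_outer_diameter_nm = stats::median(res$outer_diameter_nm),
    median_multilayer_percent = stats::median(res$multilayer_percent),
    median_n_layers = stats::median(res$n_layers),
    median_reduced_chi2 = stats::median(res$reduced_chi2),
    n_converged = sum(res$converged))
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
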