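#' A reduced 1D SAXS profile
#'
#' Container for a reduced scattering curve: momentum transfer `q` (1/nm,
#' strictly increasing), intensity `I` (a.u.) and optional per-point
#' uncertainties `sigma`.
#'
#' @param q Momentum transfer vector in 1/nm, strictly increasing, all > 0.
#' @param intensity Intensity vector, same length as `q`.
#' @param sigma Optional uncertainty vector (> 0), same length, or `NULL`.
#' @param metadata Named list of provenance (sample id, source units, seed,
#'   generating truth for synthetic profiles, ...).
#' @param allow_negative Keep negative intensities instead of rejecting them
#'   (background-subtracted data can dip below zero). Default `FALSE`.
#' @return An object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, metadata = list(),
                         allow_negative = FALSE) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity must have the same length")
  if (length(q) == 0) stop("empty profile")
  if (any(!is.finite(q)) || any(!is.finite(intensity)))
    stop("q and intensity must be finite (drop NaN rows on read)")
  if (any(q <= 0)) stop("q must be > 0")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (!allow_negative && any(intensity < 0))
    stop("negative intensities; pass allow_negative = TRUE to keep them")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(!is.finite(sigma)) || any(sigma < 0)) stop("sigma must be >= 0")
    if (all(sigma == 0)) sigma <- NULL # treat as absent
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 metadata = metadata),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile: %d points, q in [%.4g, %.4g] 1/nm%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no sigma" else ""))
  if (!is.null(x$metadata$sample)) cat("  sample:", x$metadata$sample, "\n")
  invisible(x)
}

#' @export
plot.saxs_profile <- function(x, ..., log = "xy") {
  plot(x$q, x$intensity, log = log, xlab = expression(q ~ (nm^-1)),
       ylab = "I(q) (a.u.)", pch = 16, cex = 0.4, ...)
  invisible(x)
}

#' @export
as.data.frame.saxs_profile <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' Read a reduced SAXS profile from a 2-3 column text file
#'
#' Accepts the de-facto reduced `.dat` dialect: whitespace- or
#' comma-delimited numeric columns `q, I[, sigma]`, with `#` comment lines.
#' Rows containing non-finite values are dropped (with a message); `q` is
#' converted to 1/nm when the source is in 1/Angstrom.
#'
#' @param path Input file.
#' @param q_units Units of the q column in the file: `"nm-1"` (default) or
#'   `"A-1"` (converted via q_nm = 10 * q_A).
#' @param allow_negative Keep negative intensities (see [saxs_profile()]).
#' @return A [saxs_profile()] with source units recorded in the metadata.
#' @export
read_profile <- function(path, q_units = c("nm-1", "A-1"),
                         allow_negative = FALSE) {
  q_units <- match.arg(q_units)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no data rows in ", path)
  delim <- if (any(grepl(",", lines))) "," else "[[:space:]]+"
  fields <- strsplit(lines, delim)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1)
    stop("inconsistent column count in ", path)
  if (ncol < 2 || ncol > 3)
    stop("expected 2 or 3 numeric columns (q, I[, sigma]), got ", ncol)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = ncol, byrow = TRUE)
  bad <- rowSums(!is.finite(m)) > 0
  if (any(bad)) {
    message("read_profile: dropped ", sum(bad), " non-finite row(s)")
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no finite data rows in ", path)
  m <- m[order(m[, 1]), , drop = FALSE]
  if (any(diff(m[, 1]) <= 0))
    stop("q values are not strictly increasing after sorting (duplicates?)")
  scale_q <- if (q_units == "A-1") 10 else 1
  saxs_profile(q = m[, 1] * scale_q, intensity = m[, 2],
               sigma = if (ncol == 3) m[, 3] else NULL,
               metadata = list(source = path, source_q_units = q_units),
               allow_negative = allow_negative)
}

#' Write a SAXS profile as delimited text
#'
#' Deterministic full-precision whitespace-delimited output with a `#`
#' header carrying the units and metadata; round-trips exactly through
#' [read_profile()].
#'
#' @param profile A [saxs_profile()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("# reduced SAXS profile", "# q units: nm-1")
  meta <- profile$metadata
  for (key in setdiff(names(meta), "truth"))
    if (is.character(meta[[key]]) || is.numeric(meta[[key]]))
      hdr <- c(hdr, sprintf("# %s: %s", key,
                            paste(format(meta[[key]]), collapse = " ")))
  hdr <- c(hdr, if (is.null(profile$sigma)) "# columns: q I"
           else "# columns: q I sigma")
  writeLines(hdr, con)
  if (is.null(profile$sigma)) {
    writeLines(sprintf("%.17g %.17g", profile$q, profile$intensity), con)
  } else {
    writeLines(sprintf("%.17g %.17g %.17g", profile$q, profile$intensity,
                       profile$sigma), con)
  }
  invisible(path)
}
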