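#' mRNA encapsulation efficiency
#'
#' `EE% = 100 (total - free) / total` from paired RiboGreen readings: total
#' mRNA is measured after detergent lysis of the particles, free
#' (unencapsulated) mRNA without lysis; the difference is the encapsulated
#' share. Inputs are concentrations or background-corrected signals on a
#' common calibration.
#'
#' @param total_mrna Total mRNA reading (> 0); vectorized.
#' @param free_mrna Free mRNA reading, in `[0, total_mrna]`; vectorized.
#' @return Encapsulation efficiency in percent, in `[0, 100]`.
#' @examples
#' encapsulation_efficiency(120, 3) # 97.5
#' @export
encapsulation_efficiency <- function(total_mrna, free_mrna) {
  if (any(!is.finite(total_mrna)) || any(total_mrna <= 0))
    stop("total mRNA must be > 0")
  if (any(!is.finite(free_mrna)) || any(free_mrna < 0))
    stop("free mRNA must be >= 0")
  if (any(free_mrna > total_mrna))
    stop("free mRNA exceeds total mRNA: check calibration")
  100 * (total_mrna - free_mrna) / total_mrna
}

#' Hemolysis percentage
#'
#' `H% = 100 (A_sample - A_neg) / (A_pos - A_neg)` where the positive
#' control (100% lysis) is detergent-treated erythrocytes and the negative
#' control is PBS incubation. Readings below the negative control clip to
#' 0%; values above 100% are kept with a warning.
#'
#' @param sample_abs Sample absorbance; vectorized.
#' @param negative_abs Negative-control absorbance.
#' @param positive_abs Positive-control absorbance (> negative).
#' @return Hemolysis in percent (>= 0).
#' @examples
#' hemolysis_percent(0.07, 0.05, 1.05) # 2
#' @export
hemolysis_percent <- function(sample_abs, negative_abs, positive_abs) {
  if (any(!is.finite(c(sample_abs, negative_abs, positive_abs))))
    stop("absorbances must be finite")
  if (any(positive_abs <= negative_abs))
    stop("degenerate controls: positive must exceed negative")
  h <- 100 * (sample_abs - negative_abs) / (positive_abs - negative_abs)
  h <- pmax(h, 0)
  if (any(h > 100))
    warning("hemolysis above the positive control (> 100%)")
  h
}

#' Summarize replicate assay readings
#'
#' Reads a CSV of replicate rows and writes/returns per-sample mean and SD.
#' For `type = "ee"` the file needs columns `sample, total, free`; for
#' `type = "hemolysis"` columns `sample, absorbance, negative, positive`.
#'
#' @param path Input CSV.
#' @param type `"ee"` or `"hemolysis"`.
#' @param out Optional output CSV path.
#' @return Data frame with columns `sample, mean, sd, n`.
#' @export
summarize_assay <- function(path, type = c("ee", "hemolysis"), out = NULL) {
  type <- match.arg(type)
  d <- utils::read.csv(path)
  val <- if (type == "ee") {
    if (!all(c("sample", "total", "free") %in% names(d)))
      stop("EE input needs columns: sample, total, free")
    encapsulation_efficiency(d$total, d$free)
  } else {
    if (!all(c("sample", "absorbance", "negative", "positive") %in% names(d)))
      stop("hemolysis input needs columns: sample, absorbance, negative, positive")
    hemolysis_percent(d$absorbance, d$negative, d$positive)
  }
  agg <- do.call(rbind, lapply(split(val, d$sample), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  res <- cbind(sample = rownames(agg), agg)
  rownames(res) <- NULL
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
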