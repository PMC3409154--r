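#' Convert qPCR threshold cycles to linear-scale signals
#'
#' Threshold cycles are logarithmic in template amount and must not be
#' averaged directly; they are first converted to signals in arbitrary
#' units by \deqn{signal = 10^{10} E^{-C_t}}{signal = 1e10 * E^-Ct} where
#' \eqn{E} is the per-cycle amplification efficiency (2 = perfect doubling).
#' The \eqn{10^{10}} prefactor only sets a convenient scale; every
#' downstream ratio is invariant to it.
#'
#' @param ct Numeric vector of threshold cycles; \code{NA} = undetermined
#'   well (propagates to \code{NA}).
#' @param efficiency Amplification efficiency \eqn{E}, with
#'   \eqn{1 < E \le 2}; default 2.
#' @return Numeric vector of signals (arbitrary units).
#' @examples
#' ct_to_signal(10)           # 1e10 / 2^10
#' ct_to_signal(20, 1.9)
#' @export
ct_to_signal <- function(ct, efficiency = 2) {
  .check_efficiency(efficiency)
  1e10 * efficiency^(-ct)
}

.check_efficiency <- function(efficiency) {
  if (!is.numeric(efficiency) || anyNA(efficiency) ||
      any(efficiency <= 1) || any(efficiency > 2))
    stop("efficiency must lie in (1, 2]")
  invisible(efficiency)
}

#' Invert the signal equation
#'
#' @param signal Signal in arbitrary units (> 0).
#' @param efficiency Amplification efficiency in (1, 2].
#' @return The threshold cycle producing \code{signal}.
#' @export
signal_to_ct <- function(signal, efficiency = 2) {
  .check_efficiency(efficiency)
  log(1e10 / signal) / log(efficiency)
}

#' Summarize a qPCR technical triplicate on the signal scale
#'
#' Each amplified well's Ct is converted to a signal and the arithmetic
#' mean and sample standard deviation (n - 1 denominator) of the signals
#' are reported. Cts are never averaged directly. A triplicate counts as
#' detected only when at least two of its wells amplified; otherwise it is
#' "nd" (not detected) and the mean is undefined.
#'
#' @param ct Numeric vector of up to 3 threshold cycles; \code{NA} =
#'   undetermined well.
#' @param efficiency Amplification efficiency in (1, 2]; default 2.
#' @return A \code{signal_summary} list with elements \code{mean_signal},
#'   \code{sd_signal}, \code{n}, \code{detected} and the raw per-well
#'   \code{signals}.
#' @examples
#' summarize_triplicate(c(10, 11, 12))
#' summarize_triplicate(c(25.1, NA, NA))   # nd
#' @export
summarize_triplicate <- function(ct, efficiency = 2) {
  if (length(ct) > 3L) stop("a technical triplicate has at most 3 wells")
  if (any(!is.na(ct) & (!is.finite(ct) | ct <= 0)))
    stop("Ct values must be finite and positive where present")
  sig <- ct_to_signal(ct[!is.na(ct)], efficiency)
  n <- length(sig)
  detected <- n >= 2L
  structure(list(
    mean_signal = if (detected) mean(sig) else NA_real_,
    sd_signal = if (detected) stats::sd(sig) else NA_real_,
    n = n, detected = detected, signals = sig,
    efficiency = efficiency), class = "signal_summary")
}

#' @export
print.signal_summary <- function(x, ...) {
  if (x$detected)
    cat(sprintf("signal: %.4g +/- %.4g (n = %d)\n",
                x$mean_signal, x$sd_signal, x$n))
  else cat(sprintf("nd (not detected; %d well(s) amplified)\n", x$n))
  invisible(x)
}

.plate_header <- c("well", "sample", "genotype", "fraction", "antibody",
                   "amplicon", "ct", "efficiency")

#' Read a qPCR plate table
#'
#' Reads the plate CSV dialect with the exact header
#' \code{well,sample,genotype,fraction,antibody,amplicon,ct,efficiency};
#' an empty \code{ct} field denotes an undetermined well.
#'
#' @param file Path to a plate CSV.
#' @return Data frame with \code{ct} numeric (\code{NA} for undetermined
#'   wells) and \code{efficiency} numeric.
#' @export
read_plate_csv <- function(file) {
  plate <- utils::read.csv(file, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(names(plate), .plate_header))
    stop("plate CSV header must be exactly: ",
         paste(.plate_header, collapse = ","))
  plate$ct <- suppressWarnings(as.numeric(plate$ct))
  plate$ct[trimws(plate$ct) == ""] <- NA_real_
  plate$efficiency <- as.numeric(plate$efficiency)
  plate
}

#' Write a qPCR plate table
#'
#' @param plate Data frame in the plate dialect (see
#'   \code{\link{read_plate_csv}}).
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_plate_csv <- function(plate, file) {
  stopifnot(identical(names(plate), .plate_header))
  utils::write.csv(plate, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}
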