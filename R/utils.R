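#' @keywords internal
"_PACKAGE"

## Internal validation + numeric helpers shared across modules.

stop_validation <- function(...) {
  stop(structure(
    class = c("rsnvar_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("rsnvar_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop_validation(what, " contains non-finite values")
  invisible(x)
}

## All randomness flows through withr::with_seed so no global RNG state leaks.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Z-score a vector
#'
#' Standardizes to mean 0, sd 1 using the sample (n-1) standard deviation;
#' idempotent on already-standardized input.
#'
#' @param x numeric vector with positive sd.
#' @return standardized vector.
#' @export
zscore <- function(x) {
  assert_finite(x, "input")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_validation("cannot z-score a constant vector")
  (x - mean(x)) / s
}

#' Sample skewness
#'
#' Bias-uncorrected third standardized moment (population convention,
#' `m3 / m2^1.5`).
#'
#' @param x numeric vector, `n >= 3`, non-constant.
#' @return scalar skewness.
#' @export
sample_skewness <- function(x) {
  if (length(x) < 3L) stop_validation("skewness needs n >= 3")
  assert_finite(x, "input")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) stop_validation("skewness undefined for a constant vector")
  mean((x - m)^3) / s2^1.5
}

## Pearson (non-excess) kurtosis, m4/m2^2; 3 for a normal sample in expectation.
sample_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2
}

## Zero-phase band-pass by masking DFT bins; band edges in Hz, inclusive.
## Removes DC unless flo == 0. Errors when the band lies at/above Nyquist.
fft_bandpass <- function(x, tr, flo, fhi) {
  n <- length(x)
  nyq <- 1 / (2 * tr)
  if (fhi > nyq || flo >= fhi)
    stop_config("band [", flo, ", ", fhi, "] Hz incompatible with TR ", tr,
                " s (Nyquist ", nyq, " Hz)")
  f <- (seq_len(n) - 1L) / (n * tr)
  f <- pmin(f, 1 / tr - f)           # two-sided frequency axis
  keep <- f >= flo & f <= fhi
  if (flo > 0) keep[1L] <- FALSE
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

## Fraction of periodogram power (positive frequencies) inside [flo, fhi].
band_power_fraction <- function(x, tr, flo, fhi) {
  n <- length(x)
  x <- x - mean(x)
  total <- sum(x^2)
  if (total == 0) return(0)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) / (n * tr)
  pos <- f > 0 & f <= 1 / (2 * tr)
  sum(p[pos & f >= flo & f <= fhi]) / sum(p[pos])
}

## Gini concentration of a nonnegative vector, in [0, 1).
gini_concentration <- function(x) {
  x <- sort(abs(x))
  n <- length(x)
  if (sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

## Shannon entropy (nats) of a 32-bin histogram of standardized values.
binned_entropy <- function(x, bins = 32L) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  z <- (x - mean(x)) / s
  h <- tabulate(cut(z, breaks = bins, labels = FALSE), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}

## Short config checksum embedded in every output for provenance.
config_checksum <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)
  bytes <- utf8ToInt(json)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
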