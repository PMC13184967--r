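#' @useDynLib ecoassembly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale cor dist median qnorm rbinom rlnorm rmultinom
#'   rnorm runif sd setNames p.adjust
#' @importFrom utils read.delim write.table packageVersion
NULL

# Deterministic 32-bit-safe child seed so each analysis stage draws from an
# independent, reproducible stream derived from one master seed.
MOD31 <- 2147483647

string_hash <- function(name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% MOD31
  h
}

#' Derive a named child seed from a master seed
#'
#' All randomized stages accept a `seed` argument; pipelines derive one child
#' seed per stage from the master seed and the stage name, so any stage can be
#' re-run in isolation and reproduce its in-pipeline results exactly.
#'
#' @param seed integer master seed.
#' @param name character stage name.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "beta_nti")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  as.integer((abs(seed) %% MOD31 * 69069 + string_hash(name)) %% (MOD31 - 1) + 1)
}

config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  format(string_hash(s), scientific = FALSE)
}

#' Write a result table as TSV with a provenance header
#'
#' The first line is a `#` comment recording the package version, a hash of
#' the generating configuration, and the RNG seed, so every result file is
#' self-describing.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @param seed integer seed used to produce `df` (NA if deterministic).
#' @param config object (list) hashed into the header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ecoassembly %s config=%s seed=%s",
                     as.character(packageVersion("ecoassembly")),
                     config_hash(config), as.character(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Centered rolling mean with truncated edges
#'
#' Smooths a time series of e.g. normalized 16S copy numbers with a centered
#' moving average. At the series boundaries the window is truncated to the
#' available points, so the output has the same length as the input.
#'
#' @param series ordered numeric vector.
#' @param window positive integer window size, at most `length(series)`.
#' @return Numeric vector of the same length as `series`.
#' @export
#' @examples
#' rolling_mean(c(1, 2, 3, 4, 5), window = 5)
rolling_mean <- function(series, window) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0 ||
      window != floor(window))
    stop("`window` must be a positive integer")
  n <- length(series)
  if (window > n) stop("`window` exceeds the series length")
  lo <- floor((window - 1) / 2)
  hi <- window - 1 - lo
  vapply(seq_len(n), function(i) {
    mean(series[max(1, i - lo):min(n, i + hi)])
  }, numeric(1))
}
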