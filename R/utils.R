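#' Derive a stage seed from a global seed
#'
#' Counter-based derivation so that adding a pipeline stage never perturbs
#' the randomness of earlier stages. Kept below 2^31 so the result is a
#' valid R integer seed.
#'
#' @param seed global integer seed.
#' @param stage integer stage counter (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((as.double(seed) * 48271 + as.double(stage) * 16807) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_glom <- function(class, msg, ...) {
  stop(structure(class = c(class, "glomscape_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

assert_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_glom("glomscape_schema_error", "%s is missing required column(s): %s",
              what, paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Otsu threshold of a numeric vector
#'
#' Exhaustive maximization of between-class variance over a histogram of the
#' values; used as the default positivity rule for protein intensities.
#'
#' @param x numeric vector.
#' @param n_bins number of histogram bins.
#' @return the threshold value (upper edge of the background class).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop_glom("glomscape_parameter_error", "no finite values for Otsu threshold")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  breaks[which.max(between) + 1L]
}
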