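#' Mass isotopomer distribution vectors
#'
#' A MID of an n-carbon species is the length-(n+1) vector of fractional
#' abundances M+0 ... M+n: the probability that a molecule carries k heavy
#' (tracer-derived) carbons.  MIDs are the universal currency of this
#' package: simulation results, protein hydrolysate measurements and
#' natural-abundance-corrected spectra are all MIDs.
#'
#' @param fractions numeric vector of fractional abundances, M+0 first.
#' @param metabolite optional metabolite id carried as an attribute.
#' @return a numeric vector of class `mid`.
#' @examples
#' mid(c(0.7, 0.2, 0.1), "accoa")
#' @export
mid <- function(fractions, metabolite = NULL) {
  fractions <- as.numeric(fractions)
  if (length(fractions) < 1L || anyNA(fractions))
    stop("MID fractions must be a non-empty numeric vector without NA")
  if (any(fractions < -1e-9) || any(fractions > 1 + 1e-9))
    stop("MID fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("MID fractions must sum to 1 (got ", format(sum(fractions)), ")")
  structure(fractions, metabolite = metabolite, class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  met <- attr(x, "metabolite")
  cat("MID", if (!is.null(met)) paste0("of ", met), "\n")
  v <- as.numeric(x)
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(round(v, 6))
  invisible(x)
}

is_mid_normalized <- function(x, tol = 1e-6) {
  is.numeric(x) && !anyNA(x) && abs(sum(x) - 1) <= tol && all(x >= -tol)
}

#' Convolve two mass isotopomer distributions
#'
#' The MID of a molecule assembled by condensing two independent carbon
#' units is the Cauchy product (discrete convolution) of the unit MIDs.
#' This is how, for example, the citrate MID arises from the oxaloacetate
#' and acetyl-CoA MIDs at citrate synthase.
#'
#' @param a,b numeric MID vectors (each summing to 1).
#' @return numeric vector of length `length(a) + length(b) - 1`.
#' @examples
#' convolve_mid(c(0.5, 0.5), c(1, 0))
#' @export
convolve_mid <- function(a, b) {
  if (!is_mid_normalized(a) || !is_mid_normalized(b))
    stop("convolve_mid requires normalized MID vectors")
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

## convolution without normalization checks, for solver-internal use
conv_raw <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}
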