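#' Natural isotope abundance correction for GC-MS fragments
#'
#' A raw GC-MS mass isotopomer spectrum of a derivatized amino acid mixes
#' the tracer signal with naturally occurring heavy isotopes (13C, 2H, 15N,
#' 17/18O, 29/30Si ...) of every atom in the fragment.  TBDMS
#' derivatization adds Si- and C-rich groups that dominate this
#' contamination.  The correction matrix gives, per number of tracer
#' carbons, the distribution of observed mass shifts; correcting a raw
#' spectrum solves the resulting linear model under non-negativity.
#' Tracer-able backbone carbons are excluded from the natural-abundance
#' convolution: their labeling is the signal being estimated.
#'
#' @name mid_correction
NULL

#' Default natural-abundance table
#'
#' Representative terrestrial isotope abundances (IUPAC 2013 rounding):
#' 13C 0.0107, 2H 0.000115, 15N 0.00364, 17O 0.00038 / 18O 0.00205,
#' 29Si 0.0468 / 30Si 0.0309, 33S 0.0075 / 34S 0.0425 / 36S 0.0001.
#'
#' @return named list: per element, data.frame of `shift` and `abundance`
#'   (summing to 1).
#' @export
default_abundance_table <- function() {
  tab <- list(
    C  = data.frame(shift = c(0, 1), abundance = c(1 - 0.0107, 0.0107)),
    H  = data.frame(shift = c(0, 1), abundance = c(1 - 0.000115, 0.000115)),
    N  = data.frame(shift = c(0, 1), abundance = c(1 - 0.00364, 0.00364)),
    O  = data.frame(shift = c(0, 1, 2),
                    abundance = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205)),
    Si = data.frame(shift = c(0, 1, 2),
                    abundance = c(1 - 0.0468 - 0.0309, 0.0468, 0.0309)),
    S  = data.frame(shift = c(0, 1, 2, 4),
                    abundance = c(1 - 0.0075 - 0.0425 - 1e-4,
                                  0.0075, 0.0425, 1e-4)))
  for (el in names(tab))
    stopifnot(abs(sum(tab[[el]]$abundance) - 1) < 1e-9)
  tab
}

#' Elemental composition of a GC-MS fragment
#'
#' @param formula formula string such as `"C18H40NO4Si3"`, or a named
#'   numeric vector of element counts.
#' @param n_backbone number of tracer-able analyte backbone carbons
#'   contained in the fragment (1 <= n_backbone <= C count).
#' @param id optional fragment id.
#' @return object of class `fragment_formula`.
#' @examples
#' fragment_formula("C11H26NO2Si2", n_backbone = 3, id = "Ala [M-57]")
#' @export
fragment_formula <- function(formula, n_backbone, id = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  counts <- counts[counts > 0]
  if (any(counts < 0)) stop("element counts must be non-negative")
  n_backbone <- as.integer(n_backbone)
  if (is.na(n_backbone) || n_backbone < 1L)
    stop("n_backbone must be a positive integer")
  nC <- if ("C" %in% names(counts)) counts[["C"]] else 0
  if (n_backbone > nC)
    stop("n_backbone (", n_backbone, ") exceeds the fragment carbon count (",
         nC, ")")
  structure(list(counts = counts, n_backbone = n_backbone, id = id),
            class = "fragment_formula")
}

parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(s))
    stop("cannot parse formula string '", s, "'")
  counts <- numeric()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    prev <- if (el %in% names(counts)) counts[[el]] else 0
    counts[el] <- prev + if (nchar(n)) as.numeric(n) else 1
  }
  counts
}

## n-fold convolution of one element's single-atom shift distribution
element_dist <- function(entry, n) {
  base <- numeric(max(entry$shift) + 1L)
  base[entry$shift + 1L] <- entry$abundance
  out <- 1
  for (i in seq_len(n)) out <- conv_raw(out, base)
  out
}

#' Natural-abundance correction matrix
#'
#' Column `j + 1` is the distribution of observed mass shifts for an
#' analyte carrying exactly `j` tracer carbons: the convolution of the
#' natural isotope distributions of all fragment atoms except the
#' `n_backbone` tracer-able carbons, shifted by `j`, truncated at `K` and
#' column-renormalized.
#'
#' @param f a [fragment_formula()].
#' @param tab abundance table from [default_abundance_table()] (or a
#'   user override of the same shape).
#' @param K largest observed mass shift (`K >= n_backbone`).
#' @return `(K + 1) x (n_backbone + 1)` matrix with probability-vector
#'   columns.
#' @export
correction_matrix <- function(f, tab = default_abundance_table(),
                              K = f$n_backbone) {
  stopifnot(inherits(f, "fragment_formula"))
  if (K < f$n_backbone) stop("K must be at least n_backbone")
  counts <- f$counts
  counts["C"] <- counts["C"] - f$n_backbone
  base <- 1
  for (el in names(counts)) {
    if (counts[[el]] == 0) next
    if (!el %in% names(tab))
      stop("abundance table lacks element '", el, "'")
    base <- conv_raw(base, element_dist(tab[[el]], counts[[el]]))
  }
  M <- matrix(0, nrow = K + 1L, ncol = f$n_backbone + 1L,
              dimnames = list(paste0("m", 0:K), paste0("x", 0:f$n_backbone)))
  for (j in 0:f$n_backbone) {
    col <- numeric(K + 1L)
    top <- min(length(base) - 1L, K - j)
    if (top >= 0) col[j + seq_len(top + 1L)] <- base[seq_len(top + 1L)]
    M[, j + 1L] <- col / sum(col)
  }
  M
}

#' Forward contamination model
#'
#' Predicts the raw (natural-abundance-contaminated) spectrum from a true
#' tracer MID: `M %*% true_mid`, renormalized over shifts `0..K`.  Used to
#' synthesize raw data.
#'
#' @param true_mid normalized tracer MID (length `n_backbone + 1`).
#' @inheritParams correction_matrix
#' @return numeric vector of length `K + 1` summing to 1.
#' @export
contaminate <- function(true_mid, f, tab = default_abundance_table(),
                        K = f$n_backbone + 3L) {
  if (!is_mid_normalized(true_mid))
    stop("true_mid must be a normalized MID")
  if (length(true_mid) != f$n_backbone + 1L)
    stop("true_mid length (", length(true_mid), ") does not match n_backbone + 1 (",
         f$n_backbone + 1L, ")")
  M <- correction_matrix(f, tab, K)
  v <- as.vector(M %*% as.numeric(true_mid))
  v / sum(v)
}

#' Correct a raw spectrum for natural isotope abundance
#'
#' Solves `raw ~ M x` for `x >= 0` by non-negative least squares
#' (Lawson-Hanson, via `pracma::lsqnonneg`) and renormalizes `x` to sum 1.
#' NNLS is used instead of matrix inversion because inversion can yield
#' negative fractions on noisy data.
#'
#' @param raw non-negative intensities at shifts `0..K` (at least
#'   `n_backbone + 1` values; arbitrary scale).
#' @inheritParams correction_matrix
#' @return a `mid` vector with attribute `residual` (relative residual
#'   norm of the NNLS fit).
#' @export
correct_natural_abundance <- function(raw, f, tab = default_abundance_table()) {
  raw <- as.numeric(raw)
  if (length(raw) < f$n_backbone + 1L)
    stop("raw spectrum must cover shifts 0..n_backbone")
  if (any(raw < 0)) stop("raw intensities must be non-negative")
  if (sum(raw) <= 0) stop("raw spectrum is all zero")
  K <- length(raw) - 1L
  M <- correction_matrix(f, tab, K)
  sol <- pracma::lsqnonneg(M, raw / sum(raw))
  x <- sol$x
  if (sum(x) <= 0) stop("correction produced an all-zero MID")
  structure(x / sum(x), metabolite = f$id, class = "mid",
            residual = sqrt(sol$resid.norm) / max(sum(raw / sum(raw)), 1e-12))
}

#' Bundled TBDMS fragment library
#'
#' [M-57] (loss of tert-butyl) fragments of the TBDMS-derivatized amino
#' acids quantified from protein hydrolysates, plus the MOX-TBDMS pyruvate
#' and TBDMS lactate fragments used for free polar metabolites.  These
#' elemental formulas are library defaults from standard GC-MS practice,
#' not values printed in any particular study; override per fragment if
#' your instrument uses different ions.
#'
#' @return named list of [fragment_formula()] objects keyed by metabolite
#'   id (`ala`, `ser`, `asp`, `glu`, `pro`, `pyr`, `lac`).
#' @export
fragment_library <- function() {
  list(
    ala = fragment_formula("C11H26NO2Si2", 3, "ala [M-57]"),
    ser = fragment_formula("C17H40NO3Si3", 3, "ser [M-57]"),
    asp = fragment_formula("C18H40NO4Si3", 4, "asp [M-57]"),
    glu = fragment_formula("C19H42NO4Si3", 5, "glu [M-57]"),
    pro = fragment_formula("C13H28NO2Si2", 5, "pro [M-57]"),
    pyr = fragment_formula("C6H12NO3Si", 3, "pyr MOX [M-57]"),
    lac = fragment_formula("C11H25O3Si2", 3, "lac [M-57]"))
}
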