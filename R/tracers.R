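#' Tracer specifications
#'
#' A tracer specification gives, for one boundary metabolite, a set of
#' positional 13C labeling patterns and the fraction of molecules carrying
#' each; the remainder is all-12C.  Natural 13C abundance is deliberately
#' excluded here: simulation works in tracer-derived label only, and natural
#' isotopes enter through the natural-abundance correction module.
#'
#' @param metabolite_id id of the labeled boundary metabolite.
#' @param components list of `list(pattern =, fraction =)` entries; `pattern`
#'   is a 0/1 vector over carbons (C1 first), `fraction` in \[0, 1\].
#'   Fractions must sum to at most 1.
#' @return object of class `tracer_spec`.
#' @examples
#' tracer_uglc(0.4)       # 40% U-13C-glucose, the plasma plateau of a
#'                        # steady-state glucose infusion
#' tracer_34glc(1)        # 3,4-13C-glucose: labels only pyruvate C1
#' tracer_1pyr(1)         # 1-13C-pyruvate in the medium
#' @export
tracer_spec <- function(metabolite_id, components) {
  stopifnot(is.character(metabolite_id), length(metabolite_id) == 1L)
  total <- 0
  for (cmp in components) {
    if (!all(cmp$pattern %in% c(0, 1)))
      stop("tracer pattern must be a 0/1 vector")
    if (cmp$fraction < 0 || cmp$fraction > 1)
      stop("tracer fraction must lie in [0, 1]")
    total <- total + cmp$fraction
  }
  if (total > 1 + 1e-9)
    stop("tracer fractions sum to ", format(total), " > 1")
  structure(list(metabolite_id = metabolite_id, components = components),
            class = "tracer_spec")
}

#' @rdname tracer_spec
#' @param enrichment fraction of molecules carrying the labeled pattern.
#' @export
tracer_uglc <- function(enrichment = 1) {
  tracer_spec("glc", list(list(pattern = rep(1, 6), fraction = enrichment)))
}

#' @rdname tracer_spec
#' @export
tracer_34glc <- function(enrichment = 1) {
  tracer_spec("glc", list(list(pattern = c(0, 0, 1, 1, 0, 0),
                               fraction = enrichment)))
}

#' @rdname tracer_spec
#' @export
tracer_1pyr <- function(enrichment = 1) {
  tracer_spec("pyr.ext", list(list(pattern = c(1, 0, 0), fraction = enrichment)))
}

## MID of the carbon subset `positions` of a boundary metabolite under the
## given tracers.  Unreferenced boundary pools are unlabeled; the CO2 pool
## may carry a fixed enrichment set on the network.
boundary_emu_mid <- function(net, tracers, met, positions) {
  k <- length(positions)
  out <- numeric(k + 1L)
  spec <- NULL
  for (tr in tracers) if (tr$metabolite_id == met) spec <- tr
  if (is.null(spec)) {
    if (identical(met, net$co2_id) && isTRUE((net$co2_enrichment %||% 0) > 0)) {
      p <- net$co2_enrichment
      return(c(1 - p, p))
    }
    out[1L] <- 1
    return(out)
  }
  total <- 0
  for (cmp in spec$components) {
    if (length(cmp$pattern) != n_carbons_of(net, met))
      stop("tracer pattern length does not match '", met, "' carbon count")
    shift <- sum(cmp$pattern[positions])
    out[shift + 1L] <- out[shift + 1L] + cmp$fraction
    total <- total + cmp$fraction
  }
  out[1L] <- out[1L] + (1 - total)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
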