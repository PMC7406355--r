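#' Cell-type compartments and shared-medium coupling
#'
#' A tumor or organoid co-culture is a mixture of cell types with distinct
#' metabolism; a bulk measurement of such a tissue reflects the
#' weighted average of the labeling of every cell type present.  This
#' module couples per-type network compartments through shared medium pools
#' (pyruvate and lactate by default, since labeled pyruvate and lactate
#' exchange rapidly among cell types) and computes per-type and bulk MIDs.
#'
#' @name population_mixing
NULL

#' Describe one cell-type compartment
#'
#' @param name cell-type name (e.g. `"cancer"`, `"PSC"`).
#' @param fractions a [flux_fractions()] object for this type.
#' @param weight non-negative mixture proportion (relative cell abundance
#'   times per-cell metabolic rate); weights need not sum to 1.
#' @param kinetics a [protein_kinetics()] object (protein-labeling model).
#' @param net core network; default [build_core_network()].
#' @return object of class `cell_type_model` with a balanced `flux_state`.
#' @export
cell_type_model <- function(name, fractions, weight = 1,
                            kinetics = protein_kinetics(), net = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (weight < 0) stop("weight must be non-negative")
  if (is.null(net)) net <- build_core_network()
  flux <- fractions_to_flux(net, fractions)
  structure(list(name = name, fractions = fractions, flux_state = flux,
                 weight = weight, kinetics = kinetics, net = net),
            class = "cell_type_model")
}

#' Specify shared medium pools
#'
#' @param metabolites internal metabolite ids exchanged through the medium;
#'   supported: `"pyr"`, `"lac"`.
#' @param supply named external supply fluxes into each medium pool (fresh
#'   medium or plasma turnover); the supply MID is set by the tracer
#'   specification for the corresponding boundary pool (`pyr.ext`,
#'   `lac.ext`).
#' @return object of class `shared_pool_spec`.
#' @export
shared_pool_spec <- function(metabolites = c("pyr", "lac"),
                             supply = c(pyr = 0.5, lac = 0)) {
  known <- c("pyr", "lac")
  bad <- setdiff(metabolites, known)
  if (length(bad))
    stop("unsupported shared metabolite(s): ", paste(bad, collapse = ", "),
         " (exchange is modeled for ", paste(known, collapse = ", "), ")")
  supply <- supply[metabolites]
  if (anyNA(supply)) stop("supply flux required for every shared metabolite")
  if (any(supply < 0)) stop("supply fluxes must be non-negative")
  structure(list(metabolites = metabolites, supply = supply,
                 ext_id = c(pyr = "pyr.ext", lac = "lac.ext")[metabolites],
                 uptake_rxn = c(pyr = "pyr_in", lac = "lac_in")[metabolites],
                 release_rxn = c(pyr = "pyr_out", lac = "lac_out")[metabolites]),
            class = "shared_pool_spec")
}

## Recover the positional isotopomer distribution of `met` from the solved
## subset-EMU MIDs by Moebius inversion: P(exactly A labeled) =
## sum over B >= A of (-1)^|B \ A| P(all of B labeled).
positional_from_emus <- function(solved, met, n) {
  q <- numeric(2^n)          # q[mask+1] = P(all carbons in mask labeled)
  q[1L] <- 1
  for (mask in seq_len(2^n - 1L)) {
    pos <- which(bitwAnd(mask %/% 2^(seq_len(n) - 1L), 1L) == 1L)
    v <- solved[[emu_key(met, pos)]]
    if (is.null(v) || anyNA(v)) return(NULL)
    q[mask + 1L] <- v[length(pos) + 1L]
  }
  p <- numeric(2^n)
  for (a in 0:(2^n - 1L)) {
    s <- 0
    rest <- bitwAnd(2^n - 1L, bitwNot(a))
    ## iterate supersets of a
    sub <- rest
    repeat {
      b <- bitwOr(a, sub)
      nb <- sum(bitwAnd(sub %/% 2^(0:(n - 1L)), 1L))
      s <- s + (-1)^nb * q[b + 1L]
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, rest)
    }
    p[a + 1L] <- s
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

## pattern distribution (length 2^n) -> tracer components for a boundary pool
pattern_to_tracer <- function(met_ext, p, n) {
  comps <- list()
  for (mask in seq_len(2^n - 1L)) {
    if (p[mask + 1L] <= 0) next
    comps[[length(comps) + 1L]] <-
      list(pattern = as.integer(bitwAnd(mask %/% 2^(seq_len(n) - 1L), 1L) == 1L),
           fraction = p[mask + 1L])
  }
  if (length(comps) == 0L)
    comps <- list(list(pattern = rep(0L, n), fraction = 0))
  tracer_spec(met_ext, comps)
}

## supply pattern distribution of a shared pool under the given tracers
supply_pattern <- function(net, tracers, ext_id, n) {
  p <- numeric(2^n)
  spec <- NULL
  for (tr in tracers) if (tr$metabolite_id == ext_id) spec <- tr
  if (is.null(spec)) { p[1L] <- 1; return(p) }
  total <- 0
  for (cmp in spec$components) {
    idx <- 1L + sum(cmp$pattern * 2^(seq_len(n) - 1L))
    p[idx] <- p[idx] + cmp$fraction
    total <- total + cmp$fraction
  }
  p[1L] <- p[1L] + (1 - total)
  p
}

#' Simulate coupled cell-type compartments sharing medium pools
#'
#' Solves the fixed point of the coupled system: each compartment is solved
#' by [simulate_mids()] with the current medium labeling imposed on its
#' uptake boundary; medium pools are then recomputed as the flux-weighted
#' mixture of fresh supply and weighted cellular release, at isotopic steady
#' state.  Damped fixed-point iteration (damping 0.5) is used because
#' exchange loops can oscillate under plain iteration.
#'
#' @param types list of [cell_type_model()] objects (all on the same
#'   network).
#' @param shared a [shared_pool_spec()].
#' @param tracers list of [tracer_spec()] objects; specs on `pyr.ext` /
#'   `lac.ext` define the supply labeling of the shared pools.
#' @param observables metabolite ids to report per type.
#' @param tol fixed-point tolerance (max absolute change of any medium
#'   pattern fraction); default 1e-10.
#' @param max_iter iteration cap (default 1e4).
#' @param damping damping factor in (0, 1]; 1 is undamped.
#' @return list with elements `per_type` (named list of MID maps),
#'   `medium` (named list of medium pool MIDs), and `iterations`.
#' @export
simulate_coculture <- function(types, shared = shared_pool_spec(), tracers,
                               observables = NULL, tol = 1e-10,
                               max_iter = 1e4, damping = 0.5) {
  if (inherits(tracers, "tracer_spec")) tracers <- list(tracers)
  stopifnot(length(types) >= 1L)
  names(types) <- vapply(types, `[[`, "", "name")
  net <- types[[1L]]$net
  for (ty in types) {
    bal <- validate_flux_balance(net, ty$flux_state)
    if (!isTRUE(attr(bal, "balanced")))
      stop("compartment '", ty$name, "' flux state is not balanced")
  }
  ns <- vapply(shared$metabolites, function(m) n_carbons_of(net, m), integer(1))
  system <- emu_system(net, observables = observables,
                       subset_closure = shared$metabolites)

  ## medium pattern state, initialized at the supply labeling
  medium <- lapply(seq_along(shared$metabolites), function(i)
    supply_pattern(net, tracers, shared$ext_id[[i]], ns[[i]]))
  names(medium) <- shared$metabolites

  base_tracers <- Filter(function(tr)
    !(tr$metabolite_id %in% shared$ext_id), tracers)

  per_type <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    med_tracers <- lapply(seq_along(shared$metabolites), function(i)
      pattern_to_tracer(shared$ext_id[[i]], medium[[i]], ns[[i]]))
    per_type <- lapply(types, function(ty)
      simulate_mids(net, ty$flux_state, c(base_tracers, med_tracers),
                    system = system, check_balance = FALSE))
    delta <- 0
    for (i in seq_along(shared$metabolites)) {
      m <- shared$metabolites[[i]]
      sup_v <- shared$supply[[i]]
      acc <- sup_v * supply_pattern(net, tracers, shared$ext_id[[i]], ns[[i]])
      tot <- sup_v
      for (ty in types) {
        rel <- ty$weight * ty$flux_state[[shared$release_rxn[[i]]]]
        if (rel <= 0) next
        solved <- attr(per_type[[ty$name]], "emu_solutions")
        p <- positional_from_emus(solved, m, ns[[i]])
        if (is.null(p)) next  # undefined pool releases nothing labeled
        acc <- acc + rel * p
        tot <- tot + rel
      }
      if (tot <= 0) next
      newp <- acc / tot
      upd <- (1 - damping) * medium[[i]] + damping * newp
      delta <- max(delta, max(abs(upd - medium[[i]])))
      medium[[i]] <- upd
    }
    if (delta < tol) break
    if (iter >= max_iter)
      stop("co-culture fixed point did not converge in ", max_iter,
           " iterations (last change ", format(delta), ")")
  }

  medium_mids <- lapply(seq_along(shared$metabolites), function(i) {
    n <- ns[[i]]
    mass <- vapply(seq_len(2^n) - 1L, function(pt)
      sum(bitwAnd(pt %/% 2^(seq_len(n) - 1L), 1L)), integer(1))
    v <- vapply(0:n, function(k) sum(medium[[i]][mass == k]), numeric(1))
    structure(v, metabolite = shared$metabolites[[i]], class = "mid")
  })
  names(medium_mids) <- shared$metabolites

  list(per_type = per_type, medium = medium_mids, iterations = iter)
}

#' Weighted-average (bulk) MID across cell types
#'
#' A measurement on unsorted tissue reflects the weighted average of the
#' labeling of all cell types present; this computes that convex
#' combination.
#'
#' @param per_type named list of MID vectors for one metabolite, one per
#'   cell type.
#' @param weights non-negative weights (same order/names); sum must be
#'   positive.  Only relative weights matter.
#' @return a `mid` vector.
#' @examples
#' bulk_average(list(cancer = mid(c(0, 0, 1)), psc = mid(c(1, 0, 0))),
#'              weights = c(cancer = 1, psc = 3))
#' @export
bulk_average <- function(per_type, weights) {
  stopifnot(length(per_type) >= 1L, length(weights) == length(per_type))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must have positive sum")
  if (!is.null(names(weights)) && !is.null(names(per_type)))
    weights <- weights[names(per_type)]
  len <- unique(lengths(per_type))
  if (length(len) != 1L)
    stop("per-type MIDs have differing lengths; same metabolite required")
  w <- weights / sum(weights)
  out <- numeric(len)
  for (i in seq_along(per_type)) out <- out + w[[i]] * as.numeric(per_type[[i]])
  structure(out, metabolite = attr(per_type[[1L]], "metabolite"), class = "mid")
}

#' Flatten a co-culture into one combined network
#'
#' Builds a single network in which each cell type's internal pools are
#' prefixed copies and the shared medium pools are explicit internal pools
#' with supply and outflow, so the coupled system can be solved directly by
#' either solver.  Used to cross-check [simulate_coculture()].
#'
#' @inheritParams simulate_coculture
#' @return list with `net`, `flux`, and `map` (per-type prefix).
#' @export
flatten_coculture <- function(types, shared = shared_pool_spec()) {
  names(types) <- vapply(types, `[[`, "", "name")
  net <- types[[1L]]$net
  carbons <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)

  mets <- list(); rxns <- list(); flux <- numeric()
  ## medium pools
  for (i in seq_along(shared$metabolites)) {
    m <- shared$metabolites[[i]]
    n <- carbons[[m]]
    med <- paste0("med.", m)
    mets[[med]] <- metabolite(med, n)
    letters_n <- paste(letters[seq_len(n)], collapse = "")
    rid <- paste0(med, ".supply")
    rxns[[rid]] <- reaction(rid, paste(shared$ext_id[[i]], "->", med),
                            paste(letters_n, "->", letters_n))
    flux[rid] <- shared$supply[[i]]
    sink <- paste0(med, ".sink")
    mets[[sink]] <- metabolite(sink, n, TRUE)
    rid <- paste0(med, ".outflow")
    rxns[[rid]] <- reaction(rid, paste(med, "->", sink),
                            paste(letters_n, "->", letters_n))
    out_total <- shared$supply[[i]]
    in_total <- 0
    for (ty in types) {
      out_total <- out_total + ty$weight * ty$flux_state[[shared$release_rxn[[i]]]]
      in_total <- in_total + ty$weight * ty$flux_state[[shared$uptake_rxn[[i]]]]
    }
    if (out_total - in_total < -1e-9)
      stop("medium pool '", m, "' has more uptake than supply plus release")
    flux[rid] <- max(out_total - in_total, 0)
  }
  ## shared boundary pools (tracer inputs) declared once
  for (b in net$metabolites$id[net$metabolites$is_boundary])
    mets[[b]] <- metabolite(b, carbons[[b]], TRUE)

  sym <- character()
  for (ty in types) {
    pre <- paste0(ty$name, ".")
    rename <- function(m) {
      if (is_boundary_of(net, m)) m else paste0(pre, m)
    }
    for (m in net$metabolites$id[!net$metabolites$is_boundary])
      mets[[paste0(pre, m)]] <- metabolite(paste0(pre, m), carbons[[m]])
    sym <- c(sym, paste0(pre, net$symmetric_species))
    for (r in net$reactions) {
      subs <- r$substrates; prods <- r$products
      ## uptake reactions draw from the medium pool, release feeds it
      if (r$id %in% shared$uptake_rxn) {
        i <- match(r$id, shared$uptake_rxn)
        subs <- paste0("med.", shared$metabolites[[i]])
        prods <- vapply(prods, function(m) paste0(pre, m), "")
      } else if (r$id %in% shared$release_rxn) {
        i <- match(r$id, shared$release_rxn)
        subs <- vapply(subs, function(m) paste0(pre, m), "")
        prods <- paste0("med.", shared$metabolites[[i]])
      } else {
        subs <- vapply(subs, rename, "")
        prods <- vapply(prods, rename, "")
      }
      rid <- paste0(pre, r$id)
      map <- r$map_string
      rxns[[rid]] <- reaction(rid, paste(paste(subs, collapse = " + "),
                                         "->", paste(prods, collapse = " + ")),
                              map)
      flux[rid] <- ty$weight * ty$flux_state[[r$id]]
    }
  }
  ## internal cell pools of shared metabolites keep their per-type copies
  big <- atom_network(do.call(rbind, mets), rxns, symmetric_species = sym,
                      co2_id = net$co2_id)
  big$co2_enrichment <- net$co2_enrichment
  list(net = big, flux = flux,
       map = stats::setNames(paste0(names(types), "."), names(types)))
}
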