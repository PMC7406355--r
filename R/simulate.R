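#' Steady-state MID simulation by EMU decomposition
#'
#' At isotopic steady state the MID of every metabolite pool is the
#' influx-weighted mixture of the MIDs delivered by its producing reactions,
#' where a reaction that condenses several carbon units delivers the
#' convolution of the source MIDs.  The elementary metabolite unit (EMU)
#' decomposition exploits the fact that the labeling of any subset of a
#' metabolite's carbons can be balanced independently: tracing each
#' observable back through the atom maps yields, per EMU size, a linear
#' system that is solved level-by-level from size 1 upward.  Condensation
#' terms always involve strictly smaller EMUs, so every level is linear.
#'
#' @name emu_simulation
NULL

## ---- symmetric species -----------------------------------------------------
## Replace each reaction producing a rotationally symmetric metabolite by
## variants with the product carbon order reversed, at equal flux shares.
## Equivalent to averaging each EMU MID with its mirror image.  Shared by the
## EMU solver and the isotopomer oracle (it is a network transformation, not
## a solution method).
expand_symmetric <- function(net) {
  if (length(net$symmetric_species) == 0L) {
    for (i in seq_along(net$reactions)) {
      net$reactions[[i]]$orig_id <- net$reactions[[i]]$id
      net$reactions[[i]]$share <- 1
    }
    return(net)
  }
  carbons <- stats::setNames(net$metabolites$n_carbons, net$metabolites$id)
  out <- list()
  for (r in net$reactions) {
    sym_occ <- which(r$products %in% net$symmetric_species)
    variants <- list(r$carbon_map)
    for (j in sym_occ) {
      n <- carbons[[r$products[j]]]
      variants <- unlist(lapply(variants, function(cm) {
        rev_cm <- lapply(cm, function(m) {
          hit <- m[, "occ"] == j
          m[hit, "carbon"] <- n + 1L - m[hit, "carbon"]
          m
        })
        list(cm, rev_cm)
      }), recursive = FALSE)
    }
    share <- 1 / length(variants)
    for (k in seq_along(variants)) {
      rk <- r
      rk$id <- if (k == 1L) r$id else paste0(r$id, "@sym", k - 1L)
      rk$orig_id <- r$id
      rk$share <- share
      rk$carbon_map <- variants[[k]]
      out[[rk$id]] <- rk
    }
  }
  net$reactions <- out
  net
}

## flux vector on the expanded network
expanded_flux <- function(enet, flux) {
  vapply(enet$reactions, function(r) flux[[r$orig_id]] * r$share, numeric(1))
}

## Metabolites with a well-defined steady-state MID: positive influx and
## reachable from a boundary pool through positive-flux reactions.  Under a
## balanced flux state, pools failing this sit in closed exchange loops with
## no external label source and their MID is reported as undefined.
defined_metabolites <- function(enet, eflux) {
  ids <- enet$metabolites$id
  boundary <- stats::setNames(enet$metabolites$is_boundary, ids)
  influx <- stats::setNames(numeric(length(ids)), ids)
  reach <- boundary
  for (r in enet$reactions)
    for (m in r$products) influx[m] <- influx[m] + eflux[[r$id]]
  repeat {
    changed <- FALSE
    for (r in enet$reactions) {
      if (eflux[[r$id]] <= 0) next
      if (any(reach[r$substrates])) {
        for (m in r$products) if (!reach[m]) { reach[m] <- TRUE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  ids[!boundary & reach & influx > 1e-12 * max(eflux, 0)]
}

## ---- EMU decomposition -----------------------------------------------------
emu_key <- function(met, positions) paste0(met, "|", paste(positions, collapse = ","))

## Trace the EMU (met, positions) back through one producing reaction
## occurrence: returns a list of precursor EMUs, one per contributing
## substrate occurrence.
emu_sources <- function(r, prod_occ, positions) {
  by_sub <- list()
  for (p in positions) {
    found <- FALSE
    for (i in seq_along(r$carbon_map)) {
      m <- r$carbon_map[[i]]
      hit <- which(m[, "occ"] == prod_occ & m[, "carbon"] == p)
      if (length(hit) == 1L) {
        key <- as.character(i)
        by_sub[[key]] <- c(by_sub[[key]], hit)
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("reaction '", r$id, "': no source for product carbon C", p)
  }
  lapply(names(by_sub), function(i) {
    list(met = r$substrates[[as.integer(i)]],
         positions = sort(unname(by_sub[[i]])))
  })
}

#' Precompile the EMU system for a network
#'
#' The decomposition depends only on the network topology and the set of
#' observable metabolites, not on fluxes or tracers, so it can be reused
#' across many [simulate_mids()] calls (parameter fitting, co-culture
#' iteration).
#'
#' @param net an `atn` network.
#' @param observables metabolite ids whose full MIDs are wanted; default all
#'   non-boundary metabolites.
#' @param subset_closure metabolite ids for which every carbon-subset EMU is
#'   also solved, so that the full positional isotopomer distribution can be
#'   recovered afterwards (needed for shared-pool coupling).
#' @return opaque `emu_system` object accepted by [simulate_mids()].
#' @export
emu_system <- function(net, observables = NULL, subset_closure = character()) {
  enet <- expand_symmetric(net)
  ids <- enet$metabolites$id
  boundary <- stats::setNames(enet$metabolites$is_boundary, ids)
  carbons <- stats::setNames(enet$metabolites$n_carbons, ids)
  if (is.null(observables)) observables <- ids[!boundary]
  missing <- setdiff(observables, ids)
  if (length(missing))
    stop("unknown observable metabolite(s): ", paste(missing, collapse = ", "))

  ## producer occurrences per metabolite
  producers <- stats::setNames(vector("list", length(ids)), ids)
  for (ri in seq_along(enet$reactions)) {
    r <- enet$reactions[[ri]]
    for (j in seq_along(r$products)) {
      m <- r$products[[j]]
      producers[[m]] <- c(producers[[m]], list(list(ri = ri, occ = j)))
    }
  }

  emus <- list()     # key -> list(met, positions, terms)
  queue <- lapply(sort(observables), function(m)
    list(met = m, positions = seq_len(carbons[[m]])))
  for (m in subset_closure) {
    n <- carbons[[m]]
    for (mask in seq_len(2^n - 1L)) {
      pos <- which(bitwAnd(mask %/% 2^(seq_len(n) - 1L), 1L) == 1L)
      queue <- c(queue, list(list(met = m, positions = pos)))
    }
  }
  while (length(queue)) {
    e <- queue[[1L]]; queue <- queue[-1L]
    key <- emu_key(e$met, e$positions)
    if (!is.null(emus[[key]]) || boundary[[e$met]]) next
    terms <- list()
    for (pr in producers[[e$met]]) {
      r <- enet$reactions[[pr$ri]]
      srcs <- emu_sources(r, pr$occ, e$positions)
      for (s in srcs) {
        if (!boundary[[s$met]])
          queue <- c(queue, list(list(met = s$met, positions = s$positions)))
      }
      terms <- c(terms, list(list(ri = pr$ri, sources = srcs)))
    }
    emus[[key]] <- list(met = e$met, positions = e$positions, terms = terms)
  }
  ## deterministic ordering: by size, then key
  keys <- names(emus)
  sizes <- vapply(emus, function(e) length(e$positions), integer(1))
  ord <- order(sizes, keys)
  emus <- emus[ord]
  sizes <- sizes[ord]
  keys <- names(emus)

  ## precompile integer indices so the solver does no string work
  emu_index <- stats::setNames(seq_along(emus), keys)
  for (i in seq_along(emus)) {
    emus[[i]]$met_i <- match(emus[[i]]$met, ids)
    for (ti in seq_along(emus[[i]]$terms)) {
      term <- emus[[i]]$terms[[ti]]
      term$src_emu <- integer(length(term$sources))
      term$src_boundary <- logical(length(term$sources))
      for (si in seq_along(term$sources)) {
        s <- term$sources[[si]]
        term$src_boundary[si] <- boundary[[s$met]]
        term$src_emu[si] <- if (boundary[[s$met]]) NA_integer_
                            else emu_index[[emu_key(s$met, s$positions)]]
      }
      emus[[i]]$terms[[ti]] <- term
    }
  }
  ## production incidence: influx = prod_counts %*% expanded flux
  prod_counts <- matrix(0, nrow = length(ids), ncol = length(enet$reactions),
                        dimnames = list(ids, names(enet$reactions)))
  for (ri in seq_along(enet$reactions))
    for (m in enet$reactions[[ri]]$products)
      prod_counts[m, ri] <- prod_counts[m, ri] + 1
  levels <- lapply(sort(unique(sizes)), function(k) which(sizes == k))
  names(levels) <- sort(unique(sizes))

  structure(list(net = net, enet = enet, emus = emus, keys = keys,
                 sizes = sizes, boundary = boundary, met_ids = ids,
                 carbons = carbons, observables = observables,
                 prod_counts = prod_counts, levels = levels,
                 defined_cache = new.env(parent = emptyenv())),
            class = "emu_system")
}

## ---- solver ----------------------------------------------------------------

#' Simulate steady-state mass isotopomer distributions
#'
#' Solves the isotopic steady state of the network under the given balanced
#' flux vector and tracer specification, by EMU decomposition (see
#' [emu_system()]).  Pools with no positive influx, or connected to no
#' labeled/unlabeled external source (closed exchange loops), have no
#' defined steady-state MID and are returned as `NA` vectors.
#'
#' @param net an `atn` network (ignored if `system` is given).
#' @param flux named balanced flux vector (see [validate_flux_balance()]).
#' @param tracers list of [tracer_spec()] objects on boundary metabolites.
#' @param observables metabolite ids to report; default all non-boundary.
#' @param system optional precompiled [emu_system()] for repeated solves.
#' @param check_balance verify flux balance first (default `TRUE`).
#' @return named list of MID vectors (class `mid`), `NA` where undefined.
#' @examples
#' net <- build_core_network()
#' flux <- fractions_to_flux(net, flux_fractions())
#' mids <- simulate_mids(net, flux, list(tracer_uglc(0.4)))
#' mids$asp
#' @export
simulate_mids <- function(net, flux, tracers, observables = NULL,
                          system = NULL, check_balance = TRUE) {
  if (inherits(tracers, "tracer_spec")) tracers <- list(tracers)
  if (is.null(system)) system <- emu_system(net, observables)
  else if (!is.null(observables) &&
           !all(observables %in% system$observables))
    stop("precompiled system lacks requested observables")
  net <- system$net
  if (check_balance && !is_balanced(net, flux))
    stop("flux state is not balanced; simulate_mids requires steady state")
  for (tr in tracers) {
    if (!is_boundary_of(net, tr$metabolite_id))
      stop("tracer metabolite '", tr$metabolite_id, "' is not a boundary pool")
  }
  enet <- system$enet
  eflux <- expanded_flux(enet, flux)
  ## definedness depends only on which fluxes are positive: cache it
  zkey <- rawToChar(as.raw(44L + (eflux > 0)))
  defined <- system$defined_cache[[zkey]]
  if (is.null(defined)) {
    defined <- defined_metabolites(enet, eflux)
    system$defined_cache[[zkey]] <- defined
  }
  def_i <- system$met_ids %in% defined
  influx <- as.vector(system$prod_counts %*% eflux)

  bcache <- new.env(parent = emptyenv())
  bmid <- function(met, positions) {
    key <- emu_key(met, positions)
    v <- bcache[[key]]
    if (is.null(v)) {
      v <- boundary_emu_mid(net, tracers, met, positions)
      bcache[[key]] <- v
    }
    v
  }

  nemu <- length(system$emus)
  solved <- vector("list", nemu)
  for (lev in seq_along(system$levels)) {
    k <- as.integer(names(system$levels)[lev])
    idx <- system$levels[[lev]]
    idx <- idx[def_i[vapply(system$emus[idx], `[[`, 0L, "met_i")]]
    if (length(idx) == 0L) next
    n <- length(idx)
    A <- matrix(0, n, n)
    B <- matrix(0, n, k + 1L)
    pos_of <- integer(nemu); pos_of[idx] <- seq_len(n)
    for (row in seq_len(n)) {
      e <- system$emus[[idx[row]]]
      A[row, row] <- influx[e$met_i]
      for (term in e$terms) {
        v <- eflux[[term$ri]]
        if (v <= 0) next
        ## single same-size internal precursor -> coupling; otherwise the
        ## term is fully known (boundary, lower level, or condensation)
        if (length(term$src_emu) == 1L && !term$src_boundary[1L] &&
            length(term$sources[[1L]]$positions) == k) {
          col <- pos_of[term$src_emu[1L]]
          if (col == 0L) {              # inflow from an undefined pool:
            A[row, row] <- A[row, row] - v   # drop the term and its share
            next                             # of the denominator
          }
          A[row, col] <- A[row, col] - v
          next
        }
        vec <- 1
        known <- TRUE
        for (si in seq_along(term$src_emu)) {
          smid <- if (term$src_boundary[si]) {
            s <- term$sources[[si]]
            bmid(s$met, s$positions)
          } else solved[[term$src_emu[si]]]
          if (is.null(smid) || anyNA(smid)) { known <- FALSE; break }
          vec <- conv_raw(vec, smid)
        }
        if (known) B[row, ] <- B[row, ] + v * vec
        else A[row, row] <- A[row, row] - v
      }
    }
    ## equilibrate rows by pool influx so well-separated flux scales do not
    ## make the level system appear singular
    sc <- influx[vapply(system$emus[idx], `[[`, 0L, "met_i")]
    X <- solve(A / sc, B / sc)
    for (row in seq_len(n)) solved[[idx[row]]] <- X[row, ]
  }
  names(solved) <- system$keys

  out <- list()
  attr(out, "emu_solutions") <- solved
  attr(out, "defined") <- defined
  for (m in sort(system$observables)) {
    nc <- system$carbons[[m]]
    v <- solved[[emu_key(m, seq_len(nc))]]
    if (is.null(v) || !(m %in% defined)) {
      out[[m]] <- structure(rep(NA_real_, nc + 1L), metabolite = m,
                            class = "mid")
    } else {
      v <- pmin(pmax(v, 0), 1)
      out[[m]] <- structure(v / sum(v), metabolite = m, class = "mid")
    }
  }
  out
}
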