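#' Brute-force isotopomer oracle
#'
#' Independent verification route for [simulate_mids()]: represents every
#' metabolite by its full distribution over the 2^n positional isotopomer
#' patterns and iterates the steady-state balance (each pool equals the
#' influx-weighted mixture of the pattern distributions its producing
#' reactions deliver) to a fixed point.  MIDs are then obtained by summing
#' pattern probabilities per mass.  Exponential in carbon count, so guarded
#' by a state-space cap; intended for verification, not production use.
#'
#' @param net an `atn` network.
#' @param flux named balanced flux vector.
#' @param tracers list of [tracer_spec()] objects.
#' @param observables metabolite ids to report; default all non-boundary.
#' @param tol fixed-point tolerance on the max absolute change per sweep.
#' @param max_iter iteration cap.
#' @param max_states cap on the total number of isotopomer states.
#' @return named list of MID vectors, `NA` where undefined.
#' @export
simulate_mids_oracle <- function(net, flux, tracers, observables = NULL,
                                 tol = 1e-12, max_iter = 1e5,
                                 max_states = 1e6) {
  if (inherits(tracers, "tracer_spec")) tracers <- list(tracers)
  if (!is_balanced(net, flux))
    stop("flux state is not balanced")
  enet <- expand_symmetric(net)
  eflux <- expanded_flux(enet, flux)
  ids <- enet$metabolites$id
  carbons <- stats::setNames(enet$metabolites$n_carbons, ids)
  boundary <- stats::setNames(enet$metabolites$is_boundary, ids)
  internal <- ids[!boundary]
  if (is.null(observables)) observables <- internal
  if (sum(2^carbons[internal]) > max_states)
    stop("isotopomer state space exceeds max_states")

  defined <- defined_metabolites(enet, eflux)
  influx <- stats::setNames(numeric(length(ids)), ids)
  for (r in enet$reactions)
    for (m in r$products) influx[m] <- influx[m] + eflux[[r$id]]

  ## boundary pattern distributions from the tracer specification
  pattern_dist <- function(met) {
    n <- carbons[[met]]
    out <- numeric(2^n)
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
      idx <- 1L + sum(cmp$pattern * 2^(seq_len(n) - 1L))
      out[idx] <- out[idx] + cmp$fraction
      total <- total + cmp$fraction
    }
    out[1L] <- out[1L] + (1 - total)
    out
  }

  ## per (reaction, internal product occurrence): 0/1 scatter matrix from
  ## the joint substrate pattern index to the product pattern index
  ops <- list()
  for (ri in seq_along(enet$reactions)) {
    r <- enet$reactions[[ri]]
    if (eflux[[ri]] <= 0) next
    ns <- carbons[r$substrates]
    N <- sum(ns)
    joint_bits <- 2^(seq_len(N) - 1L)
    offsets <- cumsum(c(0L, ns))[seq_along(ns)]
    for (j in seq_along(r$products)) {
      pm <- r$products[[j]]
      if (boundary[[pm]]) next
      np <- carbons[[pm]]
      ## product bit weight for each joint carbon (0 if carbon goes elsewhere)
      w <- numeric(N)
      for (i in seq_along(r$carbon_map)) {
        mm <- r$carbon_map[[i]]
        for (c in seq_len(nrow(mm)))
          if (mm[c, "occ"] == j)
            w[offsets[i] + c] <- 2^(mm[c, "carbon"] - 1L)
      }
      joint_idx <- seq_len(2^N) - 1L
      prod_idx <- integer(2^N)
      for (b in seq_len(N)) {
        bit <- bitwAnd(joint_idx %/% joint_bits[b], 1L)
        prod_idx <- prod_idx + bit * w[b]
      }
      P <- matrix(0, nrow = 2^np, ncol = 2^N)
      P[cbind(prod_idx + 1L, seq_len(2^N))] <- 1
      ops[[length(ops) + 1L]] <- list(ri = ri, subs = r$substrates,
                                      product = pm, P = P)
    }
  }

  x <- lapply(stats::setNames(internal, internal), function(m) {
    v <- numeric(2^carbons[[m]]); v[1L] <- 1; v
  })
  get_dist <- function(m) if (boundary[[m]]) pattern_dist(m) else x[[m]]

  solve_set <- intersect(internal, defined)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    acc <- lapply(stats::setNames(solve_set, solve_set), function(m)
      numeric(2^carbons[[m]]))
    for (op in ops) {
      if (!(op$product %in% solve_set)) next
      joint <- 1
      for (s in op$subs) joint <- as.vector(outer(joint, get_dist(s)))
      acc[[op$product]] <- acc[[op$product]] +
        eflux[[op$ri]] * as.vector(op$P %*% joint)
    }
    delta <- 0
    for (m in solve_set) {
      newv <- acc[[m]] / influx[[m]]
      delta <- max(delta, max(abs(newv - x[[m]])))
      x[[m]] <- newv
    }
    if (delta < tol) break
    if (iter >= max_iter)
      stop("isotopomer fixed point did not converge in ", max_iter,
           " iterations (last change ", format(delta), ")")
  }

  out <- list()
  for (m in sort(intersect(observables, internal))) {
    nc <- carbons[[m]]
    if (!(m %in% defined)) {
      out[[m]] <- structure(rep(NA_real_, nc + 1L), metabolite = m,
                            class = "mid")
      next
    }
    mass <- vapply(seq_len(2^nc) - 1L, function(p) {
      s <- 0L
      for (b in seq_len(nc)) s <- s + bitwAnd(p %/% 2^(b - 1L), 1L)
      s
    }, integer(1))
    v <- vapply(0:nc, function(k) sum(x[[m]][mass == k]), numeric(1))
    v <- pmin(pmax(v, 0), 1)
    out[[m]] <- structure(v / sum(v), metabolite = m, class = "mid")
  }
  out
}
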