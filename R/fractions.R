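#' Pyruvate-fate flux fractions
#'
#' The model is parameterized by the fractional fate of pyruvate: of each
#' unit of pyruvate consumed, `phi_pdh` goes through pyruvate dehydrogenase,
#' `phi_pc` through pyruvate carboxylase, `phi_me1c` through carboxylating
#' malic enzyme, `phi_lac` to lactate, `phi_ala` to alanine and `phi_rel`
#' is released to the medium; these six sum to 1.  `phi_me1d` is the
#' fraction of pyruvate production supplied by decarboxylating malic enzyme
#' (pyruvate cycling), and `phi_ana` the minimum unlabeled anaplerotic OAA
#' influx, both on the same scale (total pyruvate consumption = 1).
#'
#' Secondary parameters shape the rest of the network: `f_pyr_uptake` is
#' the fraction of (non-recycled) pyruvate influx taken up from the medium
#' rather than made by glycolysis; `rho_ldh` the fraction of lactate
#' returned to pyruvate; `lac_uptake` a medium-lactate uptake flux;
#' `d_ser`, `d_asp`, `d_glu`, `d_pro` biosynthetic demands; and
#' `cit_efflux_frac` the fraction of citrate leaving the cycle
#' (cataplerosis, e.g. lipogenesis).
#'
#' @param phi_pdh,phi_pc,phi_me1c,phi_lac,phi_ala,phi_rel pyruvate-fate
#'   fractions; if `phi_lac` is `NULL` it absorbs the remainder so the six
#'   sum to 1.
#' @param phi_me1d,phi_ana see above.
#' @param f_pyr_uptake,rho_ldh,lac_uptake,d_ser,d_asp,d_glu,d_pro,cit_efflux_frac
#'   secondary parameters, see above.
#' @return object of class `flux_fractions`.
#' @seealso [fractions_to_flux()]
#' @export
flux_fractions <- function(phi_pdh = 0.40, phi_pc = 0.10, phi_me1c = 0.05,
                           phi_lac = NULL, phi_ala = 0.05, phi_rel = 0.05,
                           phi_me1d = 0, phi_ana = 0.05,
                           f_pyr_uptake = 0.1, rho_ldh = 0.25, lac_uptake = 0,
                           d_ser = 0.05, d_asp = 0.06, d_glu = 0.05,
                           d_pro = 0.02, cit_efflux_frac = 0.05) {
  if (is.null(phi_lac)) {
    phi_lac <- 1 - (phi_pdh + phi_pc + phi_me1c + phi_ala + phi_rel)
    if (phi_lac < -1e-9)
      stop("pyruvate-fate fractions exceed 1; no room left for phi_lac")
    phi_lac <- max(phi_lac, 0)
  }
  fr <- list(phi_pdh = phi_pdh, phi_pc = phi_pc, phi_me1c = phi_me1c,
             phi_lac = phi_lac, phi_ala = phi_ala, phi_rel = phi_rel,
             phi_me1d = phi_me1d, phi_ana = phi_ana,
             f_pyr_uptake = f_pyr_uptake, rho_ldh = rho_ldh,
             lac_uptake = lac_uptake, d_ser = d_ser, d_asp = d_asp,
             d_glu = d_glu, d_pro = d_pro, cit_efflux_frac = cit_efflux_frac)
  fate <- c(phi_pdh, phi_pc, phi_me1c, fr$phi_lac, phi_ala, phi_rel)
  if (any(unlist(fr) < -1e-9)) stop("flux fractions must be non-negative")
  if (any(fate > 1 + 1e-9)) stop("each pyruvate-fate fraction must be <= 1")
  if (abs(sum(fate) - 1) > 1e-6)
    stop("pyruvate-fate fractions must sum to 1 (got ", format(sum(fate)), ")")
  structure(fr, class = "flux_fractions")
}

#' Map flux fractions to a balanced flux state
#'
#' Every valid set of fractions yields a balanced steady-state flux vector
#' on the core network (total pyruvate consumption normalized to 1).
#' Infeasible secondary demands are clamped rather than rejected — the
#' decarboxylating malic-enzyme flux is capped by malate influx, TCA
#' biosynthetic demands by the flux entering the cycle, and the unlabeled
#' anaplerotic influx rises as needed to cover OAA consumption — so the
#' mapping is total on the fraction simplex.
#'
#' @param net core network from [build_core_network()].
#' @param fr a [flux_fractions()] object.
#' @return named non-negative flux vector over all reactions of `net`,
#'   passing [validate_flux_balance()].
#' @export
fractions_to_flux <- function(net, fr) {
  stopifnot(inherits(fr, "flux_fractions"))
  rids <- names(net$reactions)
  v <- stats::setNames(numeric(length(rids)), rids)
  need <- function(id, phi) {
    if (!(id %in% rids) && phi > 1e-12)
      stop("fraction requires reaction '", id, "' absent from this network")
    id %in% rids
  }
  ## pyruvate consumption (total = 1)
  v["pdh"] <- fr$phi_pdh
  if (need("pc", fr$phi_pc)) v["pc"] <- fr$phi_pc
  if (need("me1c", fr$phi_me1c)) v["me1c"] <- fr$phi_me1c
  v["ldh_f"] <- fr$phi_lac
  v["ala_syn"] <- fr$phi_ala
  v["ala_out"] <- fr$phi_ala
  v["pyr_out"] <- fr$phi_rel
  ## lactate pool
  v["lac_in"] <- fr$lac_uptake
  v["ldh_r"] <- fr$rho_ldh * (v[["ldh_f"]] + v[["lac_in"]])
  v["lac_out"] <- (1 - fr$rho_ldh) * (v[["ldh_f"]] + v[["lac_in"]])
  ## TCA chain (independent of pyruvate production split)
  v["cs"] <- v[["pdh"]]
  v["cit_out"] <- fr$cit_efflux_frac * v[["cs"]]
  v["idh"] <- v[["cs"]] - v[["cit_out"]]
  tca_demand <- fr$d_glu + fr$d_pro
  scale_gp <- if (tca_demand > v[["idh"]] && tca_demand > 0)
    v[["idh"]] / tca_demand else 1
  d_glu <- fr$d_glu * scale_gp; d_pro <- fr$d_pro * scale_gp
  v["glu_syn"] <- d_glu + d_pro
  v["glu_out"] <- d_glu
  v["pro_syn"] <- d_pro; v["pro_out"] <- d_pro
  v["akgdh"] <- v[["idh"]] - v[["glu_syn"]]
  v["sdh"] <- v[["akgdh"]]; v["fum_h"] <- v[["sdh"]]
  ## malate pool; cap pyruvate cycling by malate influx
  mal_in <- v[["fum_h"]] + (if ("me1c" %in% rids) v[["me1c"]] else 0)
  me1d <- 0
  if (need("me1d", fr$phi_me1d)) {
    me1d <- min(fr$phi_me1d, mal_in)
    v["me1d"] <- me1d
  }
  v["mdh"] <- mal_in - me1d
  ## pyruvate production: cycling + lactate return + uptake/glycolysis
  rest <- 1 - me1d - v[["ldh_r"]]
  if (rest < -1e-9)
    stop("lactate return plus pyruvate cycling exceed pyruvate consumption")
  rest <- max(rest, 0)
  v["pyr_in"] <- fr$f_pyr_uptake * rest
  v["pk"] <- (1 - fr$f_pyr_uptake) * rest
  ## glycolysis and serine
  v["ser_syn"] <- fr$d_ser; v["ser_out"] <- fr$d_ser
  v["glyc"] <- (v[["pk"]] + v[["ser_syn"]]) / 2
  ## OAA pool: anaplerotic influx rises as needed to cover consumption
  v["asp_syn"] <- fr$d_asp; v["asp_out"] <- fr$d_asp
  oaa_in_fixed <- (if ("pc" %in% rids) v[["pc"]] else 0) + v[["mdh"]]
  oaa_out_need <- v[["cs"]] + v[["asp_syn"]]
  ana <- max(fr$phi_ana, oaa_out_need - oaa_in_fixed)
  if (ana > 1e-12 && !("ana" %in% rids))
    stop("network lacks the anaplerotic influx reaction 'ana' but the flux ",
         "state requires it to balance OAA")
  if ("ana" %in% rids) v["ana"] <- ana
  v["oaa_out"] <- oaa_in_fixed + (if ("ana" %in% rids) v[["ana"]] else 0) -
    oaa_out_need
  v
}
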