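test_that("PC activity ratio follows its definition", {
  r <- pc_activity_ratio(mid(c(0.98, 0.02, 0, 0, 0)),
                         mid(c(0.5, 0.5, 0, 0)))
  expect_equal(r$ratio, 0.04)
  r0 <- pc_activity_ratio(mid(c(1, 0, 0, 0, 0)), mid(c(0.5, 0.5, 0, 0)))
  expect_equal(r0$ratio, 0)
  und <- pc_activity_ratio(mid(c(0.98, 0.02, 0, 0, 0)),
                           mid(c(1, 0, 0, 0)))
  expect_true(und$undefined)
  expect_true(is.na(und$ratio))
  bad <- mid(c(0.9, 0.1, 0, 0))
  attr(bad, "corrected") <- FALSE
  expect_error(pc_activity_ratio(mid(c(1, 0, 0, 0, 0)), bad), "corrected")
})

test_that("PC activity ratio is scale-free in boundary enrichment", {
  ## in the enrichment-linear regime both M+1 signals scale together, so
  ## halving tracer enrichment leaves the ratio unchanged
  ratio_at <- function(e) {
    fr <- flux_fractions(phi_pdh = 0.4, phi_pc = 0.15, phi_me1c = 0.05,
                         f_pyr_uptake = 0.6)
    mids <- simulate_mids(core_net, fractions_to_flux(core_net, fr),
                          list(tracer_1pyr(e)), system = core_sys)
    pc_activity_ratio(mids$asp, mids$pyr)$ratio
  }
  expect_equal(ratio_at(1), ratio_at(0.5), tolerance = 1e-9)
})

test_that("PC activity ratio increases with phi_PC", {
  ratios <- vapply(c(0, 0.1, 0.2, 0.3), function(pc) {
    fr <- flux_fractions(phi_pdh = 0.4, phi_pc = pc, phi_me1c = 0.02,
                         f_pyr_uptake = 0.6)
    mids <- simulate_mids(core_net, fractions_to_flux(core_net, fr),
                          list(tracer_1pyr(1)), system = core_sys)
    pc_activity_ratio(mids$asp, mids$pyr)$ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("M+2/M+3 summary extracts the TCA panel", {
  mids <- list(asp = mid(c(0.6, 0.1, 0.2, 0.1, 0)),
               cit = mid(c(0.5, 0, 0.3, 0.2, 0, 0, 0)),
               accoa = mid(c(0.5, 0.2, 0.3)))
  tab <- summarize_pdh_pc(mids, species = c("asp", "cit", "accoa"))
  expect_equal(tab$m2[tab$metabolite == "asp"], 0.2)
  expect_equal(tab$m3[tab$metabolite == "asp"], 0.1)
  ## two-carbon species: M+3 not applicable
  expect_true(is.na(tab$m3[tab$metabolite == "accoa"]))
  all0 <- summarize_pdh_pc(list(asp = mid(c(1, 0, 0, 0, 0))),
                           species = "asp")
  expect_equal(all0$m2, 0)

  fr <- flux_fractions(phi_pdh = 0.6, phi_pc = 0, phi_me1c = 0, phi_ala = 0,
                       phi_rel = 0, f_pyr_uptake = 1, cit_efflux_frac = 1,
                       d_glu = 0, d_pro = 0, d_ser = 0, rho_ldh = 0)
  m3 <- tracer_spec("pyr.ext", list(list(pattern = c(1, 1, 1), fraction = 1)))
  sim <- simulate_mids(core_net, fractions_to_flux(core_net, fr), list(m3),
                       system = core_sys)
  ptab <- summarize_pdh_pc(sim, species = "cit")
  expect_equal(ptab$m2, 1, tolerance = 1e-9)
  expect_equal(ptab$m3, 0, tolerance = 1e-9)
})

test_that("knockouts zero their fraction and keep the simplex", {
  base <- flux_fractions(phi_pc = 0.25, phi_me1c = 0.10)
  ko <- knockout_scenario(base, "PC")
  expect_equal(ko$phi_pc, 0)
  expect_equal(ko$phi_me1c, 0.10)
  expect_equal(ko$phi_lac, base$phi_lac + 0.25)
  expect_true(is_balanced(core_net, fractions_to_flux(core_net, ko)))
  ## residual aspartate M+1 via malic enzyme under 1-13C-pyruvate
  sim <- simulate_mids(core_net, fractions_to_flux(core_net, ko),
                       list(tracer_1pyr(1)), system = core_sys)
  expect_gt(sim$asp[2L], 0)
  ## double knockout abolishes it
  both <- knockout_scenario(base, "both")
  sim2 <- simulate_mids(core_net, fractions_to_flux(core_net, both),
                        list(tracer_1pyr(1)), system = core_sys)
  expect_lt(sim2$asp[2L], 1e-9)
  ## ME1 knockout with phi_me1c already 0 changes nothing else
  none <- flux_fractions(phi_pc = 0.2, phi_me1c = 0, phi_me1d = 0)
  expect_equal(unclass(knockout_scenario(none, "ME1")), unclass(none))
})

test_that("group comparison reproduces the Welch t-test", {
  same <- c(1, 2, 3)
  res <- compare_groups(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  a <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  b <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7,
         23.2, 17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 24.0, 13.2)
  res2 <- compare_groups(a, b)
  ## hand-computed Welch statistic
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  t_manual <- (mean(a) - mean(b)) / se
  df_manual <- se^4 / ((stats::var(a) / length(a))^2 / (length(a) - 1) +
                         (stats::var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(res2$t, t_manual, tolerance = 1e-12)
  expect_equal(res2$df, df_manual, tolerance = 1e-12)
  expect_equal(res2$p_value,
               2 * stats::pt(-abs(t_manual), df_manual), tolerance = 1e-12)
  ## shift equivariance of the mean difference
  res3 <- compare_groups(a + 5, b)
  expect_equal(res3$difference, res2$difference + 5, tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("null carboxylation is recovered as (near) zero", {
  truth <- flux_fractions(phi_pdh = 0.45, phi_pc = 0, phi_me1c = 0,
                          f_pyr_uptake = 0.5)
  kin <- protein_kinetics(log(2) / 48)
  sim <- simulate_mids(core_net, fractions_to_flux(core_net, truth),
                       list(tracer_1pyr(1)),
                       observables = c("asp", "pyr"))
  cond <- list(tracers = list(tracer_1pyr(1)), knockout = "none",
               protein = list(asp = protein_mid_at(sim$asp, kin, 24)),
               free = list(pyr = sim$pyr), t_label = 24)
  fit <- fit_flux_fractions(list(cond), core_net, kin, base = truth,
                            n_starts = 16, seed = 2)
  expect_lt(fit$estimates[["phi_pc"]] + fit$estimates[["phi_me1c"]], 0.01)
})

test_that("U-13C-glucose alone cannot separate PC from malic enzyme", {
  truth <- flux_fractions(phi_pdh = 0.40, phi_pc = 0.15, phi_me1c = 0.08,
                          f_pyr_uptake = 0.3)
  kin <- protein_kinetics(log(2) / 48)
  sim <- simulate_mids(core_net, fractions_to_flux(core_net, truth),
                       list(tracer_uglc(0.4)),
                       observables = c("asp", "pyr"))
  cond <- list(tracers = list(tracer_uglc(0.4)), knockout = "none",
               protein = list(asp = protein_mid_at(sim$asp, kin, 72)),
               free = list(pyr = sim$pyr), t_label = 72)
  fit <- fit_flux_fractions(list(cond), core_net, kin, base = truth,
                            n_starts = 16, seed = 3)
  expect_false(fit$identifiable)
  ## but the total carboxylation burden is still pinned down
  expect_lt(abs(sum(fit$estimates[c("phi_pc", "phi_me1c")]) - 0.23), 0.04)
})
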