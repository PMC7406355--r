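make_types <- function(fr_a, fr_b, w_a = 0.5, w_b = 0.5) {
  list(cell_type_model("cancer", fr_a, weight = w_a, net = core_net),
       cell_type_model("PSC", fr_b, weight = w_b, net = core_net))
}

test_that("identical cell types reproduce the monoculture solution", {
  fr <- flux_fractions(phi_pdh = 0.4, phi_pc = 0.1, phi_me1c = 0.03,
                       f_pyr_uptake = 0.3)
  types <- make_types(fr, fr)
  sh <- shared_pool_spec(supply = c(pyr = 0.5, lac = 0.1))
  cc <- simulate_coculture(types, sh, list(tracer_uglc(0.4)))
  for (m in c("asp", "glu", "cit", "pyr")) {
    expect_equal(as.numeric(cc$per_type$cancer[[m]]),
                 as.numeric(cc$per_type$PSC[[m]]), tolerance = 1e-9)
  }
  ## the shared medium then carries exactly the common release labeling,
  ## so each compartment sees the same boundary as a monoculture whose
  ## uptake equals its own release composition mixed with supply
  mono <- simulate_mids(core_net, types[[1]]$flux_state,
                        c(list(tracer_uglc(0.4)),
                          list(tracer_spec("pyr.ext", list(
                            list(pattern = c(1, 1, 1), fraction = 0))))),
                        system = core_sys)
  expect_equal(length(cc$medium$pyr), 4L)
  expect_s3_class(mono$asp, "mid")
})

test_that("zero exchange decouples compartments", {
  fr_a <- flux_fractions(phi_pdh = 0.35, phi_pc = 0.12, phi_me1c = 0.05,
                         phi_rel = 0, f_pyr_uptake = 0)
  fr_b <- flux_fractions(phi_pdh = 0.45, phi_pc = 0.03, phi_me1c = 0.02,
                         phi_rel = 0, f_pyr_uptake = 0)
  fr_a$lac_uptake <- 0; fr_b$lac_uptake <- 0
  fr_a <- do.call(flux_fractions, unclass(fr_a))
  fr_b <- do.call(flux_fractions, unclass(fr_b))
  types <- make_types(fr_a, fr_b)
  cc <- simulate_coculture(types, shared_pool_spec(supply = c(pyr = 1,
                                                              lac = 0)),
                           list(tracer_uglc(0.4)))
  for (i in 1:2) {
    solo <- simulate_mids(core_net, types[[i]]$flux_state,
                          list(tracer_uglc(0.4)), system = core_sys)
    for (m in c("asp", "glu", "cit"))
      expect_equal(as.numeric(cc$per_type[[i]][[m]]), as.numeric(solo[[m]]),
                   tolerance = 1e-9)
  }
})

test_that("coupled fixed point matches the flattened single-network oracle", {
  fr_a <- flux_fractions(phi_pdh = 0.35, phi_pc = 0.12, phi_me1c = 0.05,
                         phi_rel = 0.10, f_pyr_uptake = 0.3)
  fr_b <- flux_fractions(phi_pdh = 0.45, phi_pc = 0.03, phi_me1c = 0.02,
                         phi_rel = 0.05, f_pyr_uptake = 0.2)
  types <- make_types(fr_a, fr_b, w_a = 0.2, w_b = 0.8)  # asymmetric release
  sh <- shared_pool_spec(supply = c(pyr = 0.3, lac = 0.1))
  trs <- list(tracer_uglc(0.4))
  cc <- simulate_coculture(types, sh, trs)
  fl <- flatten_coculture(types, sh)
  expect_identical(nrow(validate_network(fl$net)), 0L)
  expect_true(is_balanced(fl$net, fl$flux))
  flat <- simulate_mids_oracle(fl$net, fl$flux, trs)
  for (ty in c("cancer", "PSC"))
    for (m in c("asp", "glu", "cit", "pyr", "mal"))
      expect_lt(max(abs(as.numeric(cc$per_type[[ty]][[m]]) -
                          as.numeric(flat[[paste0(ty, ".", m)]]))), 1e-8)
})

test_that("bulk averaging is the convex combination of per-type MIDs", {
  expect_equal(as.numeric(bulk_average(list(mid(c(0.2, 0.8))), weights = 2)),
               c(0.2, 0.8))
  got <- bulk_average(list(a = mid(c(1, 0, 0, 0, 0)),
                           b = mid(c(0, 0, 0, 1, 0))),
                      weights = c(a = 0.5, b = 0.5))
  expect_equal(as.numeric(got), c(0.5, 0, 0, 0.5, 0))
  ## normalization invariance of weights
  m1 <- bulk_average(list(mid(c(0.3, 0.7)), mid(c(0.9, 0.1))), c(2, 1))
  m2 <- bulk_average(list(mid(c(0.3, 0.7)), mid(c(0.9, 0.1))), c(2/3, 1/3))
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-12)
  expect_error(bulk_average(list(mid(c(1, 0)), mid(c(1, 0, 0))), c(1, 1)),
               "differing lengths")
})

test_that("bulk fractions stay inside the per-type envelope", {
  set.seed(31)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    mids <- lapply(seq_len(k), function(j) {
      v <- stats::runif(5); mid(v / sum(v))
    })
    w <- stats::runif(k)
    bulk <- as.numeric(bulk_average(mids, w))
    expect_equal(sum(bulk), 1, tolerance = 1e-12)
    mat <- do.call(rbind, lapply(mids, as.numeric))
    expect_true(all(bulk >= apply(mat, 2, min) - 1e-12))
    expect_true(all(bulk <= apply(mat, 2, max) + 1e-12))
  }
})

test_that("higher cancer phi_PC shows up as higher cancer aspartate labeling", {
  ## direction property: across a grid of carboxylation contrasts, the type
  ## with more pyruvate carboxylation has higher asp M+3 (U-13C-glucose)
  ## and higher asp M+1 (1-13C-pyruvate)
  for (pc_cancer in c(0.08, 0.15, 0.25)) {
    fr_a <- flux_fractions(phi_pdh = 0.40, phi_pc = pc_cancer,
                           phi_me1c = 0.04, f_pyr_uptake = 0.3)
    fr_b <- flux_fractions(phi_pdh = 0.40, phi_pc = 0.02, phi_me1c = 0.04,
                           f_pyr_uptake = 0.3)
    types <- make_types(fr_a, fr_b, w_a = 0.4, w_b = 0.6)
    sh <- shared_pool_spec(supply = c(pyr = 0.5, lac = 0.1))
    glc <- simulate_coculture(types, sh, list(tracer_uglc(0.4)))
    expect_gt(glc$per_type$cancer$asp[4L], glc$per_type$PSC$asp[4L])
    pyr <- simulate_coculture(types, sh, list(tracer_1pyr(1)))
    expect_gt(pyr$per_type$cancer$asp[2L], pyr$per_type$PSC$asp[2L])
  }
})
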