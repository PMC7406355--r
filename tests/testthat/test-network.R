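test_that("core network is well-formed and carbon-conserving", {
  expect_identical(nrow(validate_network(core_net)), 0L)
  carbons <- setNames(core_net$metabolites$n_carbons, core_net$metabolites$id)
  for (r in core_net$reactions) {
    expect_identical(sum(carbons[r$substrates]), sum(carbons[r$products]))
    ## every substrate carbon has exactly one destination
    expect_identical(sum(vapply(r$carbon_map, nrow, 0L)),
                     as.integer(sum(carbons[r$substrates])))
  }
})

test_that("network options gate the malic-enzyme reactions", {
  net <- build_core_network(me1_reverse = FALSE)
  expect_false("me1c" %in% names(net$reactions))
  ## no malate-producing reaction from pyruvate other than via PC/OAA
  mal_producers <- Filter(function(r) "mal" %in% r$products, net$reactions)
  expect_true(all(vapply(mal_producers, function(r)
    !("pyr" %in% r$substrates), TRUE)))
  expect_identical(nrow(validate_network(net)), 0L)

  net2 <- build_core_network(pyruvate_cycling = FALSE)
  expect_false("me1d" %in% names(net2$reactions))
  expect_error(build_core_network(bogus_flag = TRUE), "unknown network option")
})

test_that("validation reports carbon imbalance and orphans", {
  bad <- core_net
  ## drop one carbon: pretend pdh produces only acetyl-CoA
  bad$reactions$pdh$products <- "accoa"
  bad$reactions$pdh$carbon_map <- NULL
  rep <- validate_network(bad)
  expect_true(any(rep$type == "carbon_imbalance" & rep$where == "pdh"))
  expect_true(any(grepl("imbalance of 1", rep$message)))

  orphan <- atom_network(
    rbind(metabolite("a.in", 2, TRUE), metabolite("b", 2),
          metabolite("c", 2)),
    list(reaction("r1", "a.in -> b", "ab -> ab"),
         reaction("r2", "b -> c", "ab -> ab")))
  rep2 <- validate_network(orphan)
  expect_true(any(rep2$type == "orphan" & rep2$where == "c"))

  dup <- atom_network(rbind(metabolite("x", 2, TRUE), metabolite("x", 2, TRUE)),
                      list())
  expect_true(any(validate_network(dup)$type == "duplicate_id"))
})

test_that("atom-map parser rejects malformed maps", {
  expect_error(reaction("bad", "pyr -> lac", "abc -> abb") |>
                 (\(r) atom_network(core_net$metabolites, list(r)))(),
               "letter reused")
  expect_error(atom_network(core_net$metabolites,
                            list(reaction("bad", "pyr -> lac", "abc -> abd"))),
               "letters differ")
  expect_error(atom_network(core_net$metabolites,
                            list(reaction("bad", "pyr -> lac", "ab -> ab"))),
               "letter counts")
})

test_that("3,4-13C-glucose carbons map exclusively onto pyruvate C1", {
  glyc <- core_net$reactions$glyc
  ## glucose C3 and C4 must land on carbon 1 of (either) triose product
  dests <- glyc$carbon_map[[1]][c(3, 4), ]
  expect_identical(unname(dests[, "carbon"]), c(1L, 1L))
  expect_identical(sort(unname(dests[, "occ"])), c(1L, 2L))
  ## and the triose passes identically to pyruvate
  expect_identical(unname(core_net$reactions$pk$carbon_map[[1]][, "carbon"]),
                   1:3)
})

test_that("flux balance verdicts: loop, imbalance, homogeneity", {
  flux <- setNames(numeric(length(core_net$reactions)),
                   names(core_net$reactions))
  flux[c("pyr_in", "pdh", "cs", "idh", "akgdh", "sdh", "fum_h", "mdh")] <- 1
  expect_true(is_balanced(core_net, flux))

  flux_pc <- flux
  flux_pc["pc"] <- 1          # OAA gains production with no extra consumption
  rep <- validate_flux_balance(core_net, flux_pc)
  oaa <- rep[rep$metabolite == "oaa", ]
  expect_false(oaa$balanced)
  expect_equal(oaa$net, 1)
  ## pyr also unbalanced now (extra consumption)
  expect_false(attr(rep, "balanced"))

  ## homogeneity: scaling all fluxes by 10 keeps the verdict
  expect_true(is_balanced(core_net, flux * 10))
  expect_false(attr(validate_flux_balance(core_net, flux_pc * 10), "balanced"))

  expect_error(validate_flux_balance(core_net, flux[-1]), "flux missing")
})

test_that("fractions map to balanced flux states across the simplex", {
  set.seed(11)
  for (i in 1:25) {
    fr <- random_fractions()
    flux <- fractions_to_flux(core_net, fr)
    expect_true(all(flux >= 0))
    expect_true(is_balanced(core_net, flux))
  }
  ## totality under extreme demands: clamping keeps the state balanced
  fr <- flux_fractions(phi_pdh = 0.01, phi_pc = 0, phi_me1c = 0,
                       d_glu = 0.4, d_pro = 0.3, phi_me1d = 0.5)
  expect_true(is_balanced(core_net, fractions_to_flux(core_net, fr)))
})

test_that("network config YAML round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_config(core_net, path)
  net2 <- read_network_config(path)
  expect_identical(nrow(validate_network(net2)), 0L)
  expect_setequal(names(net2$reactions), names(core_net$reactions))
  expect_identical(net2$symmetric_species, core_net$symmetric_species)
  ## identical simulation behaviour
  flux <- fractions_to_flux(net2, flux_fractions())
  m1 <- simulate_mids(core_net, flux, list(tracer_uglc(0.4)))
  m2 <- simulate_mids(net2, flux, list(tracer_uglc(0.4)))
  expect_equal(as.numeric(m1$asp), as.numeric(m2$asp), tolerance = 1e-12)
})
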