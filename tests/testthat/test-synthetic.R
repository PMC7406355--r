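test_that("identical config and seed give identical datasets", {
  cfg <- preset("pc_ko", seed = 5, n_replicates = 2)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$free, d2$free)
  expect_identical(d1$protein, d2$protein)
  expect_identical(d1$reporter, d2$reporter)
  d3 <- generate_dataset(preset("pc_ko", seed = 6, n_replicates = 2))
  expect_false(identical(d1$protein$fraction, d3$protein$fraction))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(123); before <- stats::runif(3)
  set.seed(123); invisible(generate_dataset(preset("pc_ko", n_replicates = 1)))
  after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("zero-noise data round-trip through natural-abundance correction", {
  cfg <- preset("organoid_coculture", seed = 2, n_replicates = 1)
  cfg$noise_sd <- 0
  ds <- generate_dataset(cfg)
  lib <- fragment_library()
  prot <- ds$protein[ds$protein$cell_type == "cancer" &
                       ds$protein$time_h == 96, ]
  kin <- protein_kinetics(ds$truth$k_new[["cancer"]])
  for (met in c("asp", "glu", "ala")) {
    sub <- prot[prot$metabolite == met, ]
    sub <- sub[order(sub$mass_shift), ]
    corrected <- correct_natural_abundance(sub$fraction, lib[[met]])
    truth_mid <- protein_mid_at(ds$truth$protein_free_mids$cancer[[met]],
                                kin, 96)
    expect_lt(max(abs(as.numeric(corrected) - as.numeric(truth_mid))), 1e-6)
  }
})

test_that("table dimensions follow the experimental design", {
  cfg <- preset("organoid_coculture", seed = 1, n_replicates = 4)
  ds <- generate_dataset(cfg)
  lib <- fragment_library()
  channels <- sum(vapply(cfg$protein_species,
                         function(m) lib[[m]]$n_backbone + 3L + 1L, 0L))
  ## 2 cell types x 4 time points x 4 replicates x sum of fragment channels
  expect_identical(nrow(ds$protein), 2L * 4L * 4L * channels)
  expect_true(all(ds$protein$corrected == FALSE))
  ## every raw spectrum sums to 1
  key <- paste(ds$protein$sample_id, ds$protein$metabolite)
  sums <- as.numeric(tapply(ds$protein$fraction, key, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
})

test_that("noise has the configured per-channel spread", {
  cfg <- preset("pc_ko", seed = 8, n_replicates = 200)
  cfg$noise_sd <- 0.002
  ds <- generate_dataset(cfg)
  sub <- ds$protein[ds$protein$metabolite == "asp" & ds$protein$mass_shift == 2, ]
  ## renormalization slightly reshapes pure additive noise; 10% agreement
  expect_lt(abs(stats::sd(sub$fraction) - 0.002) / 0.002, 0.10)
})

test_that("sort-stability design shows drifting free but stable protein labeling", {
  cfg <- preset("sort_stability", seed = 3, n_replicates = 1)
  cfg$noise_sd <- 0
  ds <- generate_dataset(cfg)
  free_asp <- ds$free[ds$free$cell_type == "cancer" &
                        ds$free$metabolite == "asp" & ds$free$mass_shift == 3, ]
  free_asp <- free_asp[order(free_asp$sort_delay_min), ]
  expect_identical(free_asp$sort_delay_min, c(0, 5, 30, 120, 240))
  expect_true(all(diff(free_asp$fraction) < 0))
  ## protein table carries no sorting drift by construction
  expect_true(all(ds$protein$sort_delay_min == 0))
})

test_that("knockout presets reproduce the expected labeling phenotypes", {
  pc <- generate_dataset(preset("pc_ko", seed = 4))
  expect_true(all(corrected_asp_m1(pc) > 0))
  dko <- generate_dataset(preset("double_ko", seed = 4))
  expect_true(all(corrected_asp_m1(dko) < 0.005))
  ## ground truth documents the knockout and the generating fractions
  expect_identical(dko$truth$config$knockout, "both")
  expect_named(dko$truth$fractions, "cancer")
})

test_that("organoid preset encodes the intended cell-type contrasts", {
  cfg <- preset("organoid_coculture")
  fr <- lapply(cfg$cell_types, `[[`, "fractions")
  names(fr) <- vapply(cfg$cell_types, `[[`, "", "name")
  expect_gt(fr$cancer$phi_pc, fr$PSC$phi_pc)
  k <- vapply(cfg$cell_types, function(ty) ty$kinetics$k_new, numeric(1))
  names(k) <- names(fr)
  expect_gt(k[["PSC"]], k[["cancer"]])
  ## in vivo preset: 40% plasma enrichment, three sorted populations
  iv <- preset("invivo_infusion")
  expect_identical(length(iv$cell_types), 3L)
  expect_equal(iv$tracers[[1]]$components[[1]]$fraction, 0.40)
  expect_error(preset("unknown_preset"), "arg")
})
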