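# Shared fixtures: tiny networks, random balanced flux states, and small
# enumeration oracles used across test files.

core_net <- build_core_network()
core_sys <- emu_system(core_net)

# random flux fractions over the pyruvate-fate simplex (seed-controlled by
# the caller); secondary parameters drawn over sensible culture ranges
random_fractions <- function() {
  u <- -log(stats::runif(6))
  fate <- u / sum(u)
  ## keep a PDH floor so the TCA cycle carries flux in every draw
  fate <- 0.85 * fate + 0.15 * c(1, 0, 0, 0, 0, 0)
  flux_fractions(phi_pdh = fate[1], phi_pc = fate[2], phi_me1c = fate[3],
                 phi_lac = fate[4], phi_ala = fate[5], phi_rel = fate[6],
                 phi_me1d = stats::runif(1, 0, 0.1),
                 phi_ana = stats::runif(1, 0, 0.1),
                 f_pyr_uptake = stats::runif(1, 0, 0.8),
                 rho_ldh = stats::runif(1, 0, 0.5),
                 cit_efflux_frac = stats::runif(1, 0, 0.3))
}

# linear 3-carbon pathway a.in -> b -> c -> c.out (no condensation)
linear_net <- function() {
  atom_network(
    rbind(metabolite("a.in", 3, TRUE), metabolite("b", 3),
          metabolite("c", 3), metabolite("c.out", 3, TRUE)),
    list(reaction("u1", "a.in -> b", "abc -> abc"),
         reaction("u2", "b -> c", "abc -> abc"),
         reaction("u3", "c -> c.out", "abc -> abc")))
}

linear_flux <- c(u1 = 1, u2 = 1, u3 = 1)

# boundary 4-carbon feed into a symmetric pool and out
symmetric_net <- function() {
  atom_network(
    rbind(metabolite("x.in", 4, TRUE), metabolite("sym", 4),
          metabolite("x.out", 4, TRUE)),
    list(reaction("in", "x.in -> sym", "abcd -> abcd"),
         reaction("out", "sym -> x.out", "abcd -> abcd")),
    symmetric_species = "sym")
}

# exhaustive enumeration oracle for the natural-abundance correction
# matrix: every atom is assigned each of its isotopes in turn
enumerate_correction_matrix <- function(f, tab, K) {
  counts <- f$counts
  counts["C"] <- counts["C"] - f$n_backbone
  dist <- c(1)
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    entry <- tab[[el]]
    for (i in seq_len(n)) {
      new <- numeric(length(dist) + max(entry$shift))
      for (d in seq_along(dist))
        for (j in seq_len(nrow(entry)))
          new[d + entry$shift[j]] <- new[d + entry$shift[j]] +
            dist[d] * entry$abundance[j]
      dist <- new
    }
  }
  M <- matrix(0, nrow = K + 1L, ncol = f$n_backbone + 1L)
  for (j in 0:f$n_backbone) {
    col <- numeric(K + 1L)
    for (d in seq_along(dist)) {
      shift <- j + d - 1L
      if (shift <= K) col[shift + 1L] <- dist[d]
    }
    M[, j + 1L] <- col / sum(col)
  }
  M
}

# corrected protein aspartate M+1 per replicate of a generated dataset
corrected_asp_m1 <- function(ds, cell_type = NULL, time_h = NULL) {
  lib <- fragment_library()
  tab <- ds$protein[ds$protein$metabolite == "asp", ]
  if (!is.null(cell_type)) tab <- tab[tab$cell_type == cell_type, ]
  if (!is.null(time_h)) tab <- tab[tab$time_h == time_h, ]
  vapply(split(tab, tab$sample_id), function(sub) {
    sub <- sub[order(sub$mass_shift), ]
    as.numeric(correct_natural_abundance(sub$fraction, lib$asp))[2L]
  }, numeric(1))
}
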