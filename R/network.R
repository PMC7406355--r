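#' Carbon atom-transition networks
#'
#' An atom-transition network records, for every reaction, where each
#' substrate carbon ends up among the product carbons.  This is the level of
#' detail needed to predict mass isotopomer distributions: pyruvate
#' dehydrogenase (PDH) loses the pyruvate carboxyl carbon (C1) as CO2 and
#' passes C2/C3 to acetyl-CoA, while pyruvate carboxylase (PC) retains all
#' three pyruvate carbons and adds a CO2-derived fourth, which is why fully
#' labeled pyruvate marks TCA intermediates M+2 via PDH but M+3 via PC, and
#' why 1-13C-pyruvate labels them only via carboxylation.
#'
#' Carbon indices are 1-based throughout, C1 being the biochemical carboxyl
#' carbon.
#'
#' @name atom_network
NULL

#' Declare a metabolite
#'
#' @param id short unique metabolite id.
#' @param n_carbons number of backbone carbons (>= 1).
#' @param is_boundary `TRUE` for tracer inputs, the CO2 pool and efflux
#'   sinks; boundary pools are not balanced and their labeling is imposed,
#'   not solved.
#' @return a one-row data.frame.
#' @export
metabolite <- function(id, n_carbons, is_boundary = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L)
  n_carbons <- as.integer(n_carbons)
  if (is.na(n_carbons) || n_carbons < 1L)
    stop("metabolite '", id, "': n_carbons must be a positive integer")
  data.frame(id = id, n_carbons = n_carbons, is_boundary = isTRUE(is_boundary),
             stringsAsFactors = FALSE)
}

## Parse "pyr + co2 -> oaa" into sides of metabolite ids.
parse_equation <- function(equation) {
  sides <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("reaction equation must contain exactly one '->': ", equation)
  lapply(sides, function(s) {
    ids <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    ids[nzchar(ids)]
  })
}

## Parse "abc + d -> abcd" against the equation sides; one letter per carbon,
## no letter reused within a side, both sides use the same letter set.
parse_atom_map <- function(map, n_sub, n_prod, id) {
  sides <- strsplit(map, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("reaction '", id, "': atom map must contain exactly one '->'")
  split_side <- function(s) {
    groups <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    lapply(groups[nzchar(groups)], function(g) strsplit(g, "")[[1]])
  }
  sub <- split_side(sides[1]); prod <- split_side(sides[2])
  if (length(sub) != length(n_sub) || length(prod) != length(n_prod))
    stop("reaction '", id, "': atom map groups do not match the equation")
  if (!all(lengths(sub) == n_sub) || !all(lengths(prod) == n_prod))
    stop("reaction '", id, "': atom map letter counts do not match carbon counts")
  sub_letters <- unlist(sub); prod_letters <- unlist(prod)
  if (anyDuplicated(sub_letters))
    stop("reaction '", id, "': letter reused on the substrate side")
  if (anyDuplicated(prod_letters))
    stop("reaction '", id, "': letter reused on the product side")
  if (!setequal(sub_letters, prod_letters))
    stop("reaction '", id, "': substrate and product letters differ ",
         "(carbon not conserved)")
  ## destination of substrate occurrence i, carbon c
  dest <- lapply(seq_along(sub), function(i) {
    m <- matrix(0L, nrow = length(sub[[i]]), ncol = 2L,
                dimnames = list(NULL, c("occ", "carbon")))
    for (c in seq_along(sub[[i]])) {
      letter <- sub[[i]][c]
      for (j in seq_along(prod)) {
        p <- match(letter, prod[[j]])
        if (!is.na(p)) { m[c, ] <- c(j, p); break }
      }
    }
    m
  })
  dest
}

#' Declare an atom-mapped reaction
#'
#' @param id reaction id.
#' @param equation string such as `"pyr + co2 -> oaa"`.
#' @param map letter-per-carbon atom map such as `"abc + d -> abcd"`; each
#'   letter names one carbon and must appear exactly once on each side.
#' @return a reaction object (list) for [atom_network()].
#' @examples
#' reaction("pdh", "pyr -> co2 + accoa", "abc -> a + bc")
#' @export
reaction <- function(id, equation, map) {
  sides <- parse_equation(equation)
  structure(list(id = id, substrates = sides[[1]], products = sides[[2]],
                 map_string = map, equation = equation, carbon_map = NULL),
            class = "atom_reaction")
}

#' Assemble an atom-transition network
#'
#' @param metabolites data.frame of [metabolite()] rows.
#' @param reactions list of [reaction()] objects.
#' @param symmetric_species ids of metabolites with a rotationally symmetric
#'   carbon skeleton (succinate, fumarate): their labeling is scrambled
#'   50/50 between the two carbon orientations.
#' @param co2_id id of the CO2 pool (1 carbon, boundary).
#' @return an object of class `atn`.
#' @seealso [build_core_network()], [validate_network()]
#' @export
atom_network <- function(metabolites, reactions, symmetric_species = character(),
                         co2_id = "co2") {
  mets <- do.call(rbind, lapply(seq_len(nrow(metabolites)), function(i) metabolites[i, ]))
  rownames(mets) <- NULL
  carbons <- stats::setNames(mets$n_carbons, mets$id)
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$carbon_map)) {
      missing <- setdiff(c(r$substrates, r$products), mets$id)
      if (length(missing) == 0L)
        r$carbon_map <- parse_atom_map(r$map_string,
                                       unname(carbons[r$substrates]),
                                       unname(carbons[r$products]), r$id)
    }
    r
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  structure(list(metabolites = mets, reactions = reactions,
                 symmetric_species = symmetric_species, co2_id = co2_id),
            class = "atn")
}

#' @export
print.atn <- function(x, ...) {
  cat("Atom-transition network:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  boundary:", paste(x$metabolites$id[x$metabolites$is_boundary],
                           collapse = ", "), "\n")
  if (length(x$symmetric_species))
    cat("  symmetric:", paste(x$symmetric_species, collapse = ", "), "\n")
  invisible(x)
}

n_carbons_of <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite '", id, "'")
  net$metabolites$n_carbons[i]
}

is_boundary_of <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite '", id, "'")
  net$metabolites$is_boundary[i]
}

#' Build the core PDH/PC/ME1 carbon network
#'
#' Constructs the atom-transition network used throughout the package:
#' lower glycolysis (glucose -> 2 x 3-phosphoglycerate -> pyruvate, with the
#' standard aldolase/triose-phosphate mapping under which pyruvate C1
#' derives from glucose C3/C4), pyruvate exchange with medium pyruvate and
#' lactate, alanine and serine synthesis, PDH (pyruvate C1 lost as CO2), PC
#' (pyruvate + CO2 -> oxaloacetate), carboxylating malic enzyme
#' (pyruvate + CO2 -> malate), optionally decarboxylating malic enzyme, the
#' TCA cycle with standard atom maps (the two CO2 of the first turn derive
#' from the oxaloacetate carboxyl carbons; acetyl carbons are retained;
#' succinate and fumarate are symmetric), amino-acid offshoots
#' (aspartate from OAA, glutamate and proline from alpha-ketoglutarate),
#' an unlabeled anaplerotic OAA influx, and cataplerotic effluxes.
#'
#' @param me1_reverse include the carboxylating (reverse) malic enzyme
#'   reaction `pyr + co2 -> mal`.  Default `TRUE`.
#' @param pyruvate_cycling include the decarboxylating malic enzyme
#'   reaction `mal -> pyr + co2`, which together with PC forms a pyruvate
#'   cycle.  Default `TRUE`.
#' @param unlabeled_anaplerosis include an unlabeled OAA influx
#'   representing anaplerosis from sources outside the model (glutamine
#'   etc.).  Default `TRUE`.
#' @param co2_enrichment fractional 13C enrichment of the CO2 pool consumed
#'   by carboxylation reactions; default 0 (infinite unlabeled pool).
#' @return an `atn` network passing [validate_network()].
#' @examples
#' net <- build_core_network()
#' validate_network(net)
#' @export
build_core_network <- function(me1_reverse = TRUE, pyruvate_cycling = TRUE,
                               unlabeled_anaplerosis = TRUE, co2_enrichment = 0,
                               ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown network option(s): ", paste(names(extra), collapse = ", "))
  if (!is.numeric(co2_enrichment) || co2_enrichment < 0 || co2_enrichment > 1)
    stop("co2_enrichment must lie in [0, 1]")

  mets <- rbind(
    metabolite("glc", 6, TRUE),
    metabolite("pyr.ext", 3, TRUE),
    metabolite("lac.ext", 3, TRUE),
    metabolite("co2", 1, TRUE),
    metabolite("oaa.in", 4, TRUE),
    metabolite("pg3", 3), metabolite("pyr", 3), metabolite("lac", 3),
    metabolite("ala", 3), metabolite("ser", 3), metabolite("accoa", 2),
    metabolite("oaa", 4), metabolite("cit", 6), metabolite("akg", 5),
    metabolite("suc", 4), metabolite("fum", 4), metabolite("mal", 4),
    metabolite("asp", 4), metabolite("glu", 5), metabolite("pro", 5),
    metabolite("pyr.out", 3, TRUE), metabolite("lac.out", 3, TRUE),
    metabolite("ala.out", 3, TRUE), metabolite("ser.out", 3, TRUE),
    metabolite("asp.out", 4, TRUE), metabolite("glu.out", 5, TRUE),
    metabolite("pro.out", 5, TRUE), metabolite("cit.out", 6, TRUE),
    metabolite("oaa.out", 4, TRUE))

  rxns <- list(
    ## glucose C1-C3 -> one triose reversed, C4-C6 -> the other in order,
    ## so pyruvate C1 (carboxyl) derives from glucose C3/C4
    reaction("glyc",    "glc -> pg3 + pg3",      "abcdef -> cba + def"),
    reaction("pk",      "pg3 -> pyr",            "abc -> abc"),
    reaction("ser_syn", "pg3 -> ser",            "abc -> abc"),
    reaction("ser_out", "ser -> ser.out",        "abc -> abc"),
    reaction("ldh_f",   "pyr -> lac",            "abc -> abc"),
    reaction("ldh_r",   "lac -> pyr",            "abc -> abc"),
    reaction("lac_in",  "lac.ext -> lac",        "abc -> abc"),
    reaction("lac_out", "lac -> lac.out",        "abc -> abc"),
    reaction("ala_syn", "pyr -> ala",            "abc -> abc"),
    reaction("ala_out", "ala -> ala.out",        "abc -> abc"),
    reaction("pyr_in",  "pyr.ext -> pyr",        "abc -> abc"),
    reaction("pyr_out", "pyr -> pyr.out",        "abc -> abc"),
    reaction("pdh",     "pyr -> co2 + accoa",    "abc -> a + bc"),
    reaction("pc",      "pyr + co2 -> oaa",      "abc + d -> abcd"),
    ## citrate synthase / TCA maps: IDH releases OAA C1, KGDH releases OAA
    ## C4; acetyl carbons survive the first turn into glutamate C4/C5
    reaction("cs",      "oaa + accoa -> cit",    "abcd + ef -> dcbfea"),
    reaction("idh",     "cit -> akg + co2",      "abcdef -> abcde + f"),
    reaction("akgdh",   "akg -> suc + co2",      "abcde -> bcde + a"),
    reaction("sdh",     "suc -> fum",            "abcd -> abcd"),
    reaction("fum_h",   "fum -> mal",            "abcd -> abcd"),
    reaction("mdh",     "mal -> oaa",            "abcd -> abcd"),
    reaction("asp_syn", "oaa -> asp",            "abcd -> abcd"),
    reaction("asp_out", "asp -> asp.out",        "abcd -> abcd"),
    reaction("glu_syn", "akg -> glu",            "abcde -> abcde"),
    reaction("glu_out", "glu -> glu.out",        "abcde -> abcde"),
    reaction("pro_syn", "glu -> pro",            "abcde -> abcde"),
    reaction("pro_out", "pro -> pro.out",        "abcde -> abcde"),
    reaction("cit_out", "cit -> cit.out",        "abcdef -> abcdef"),
    reaction("oaa_out", "oaa -> oaa.out",        "abcd -> abcd"))

  if (me1_reverse)
    rxns <- c(rxns, list(reaction("me1c", "pyr + co2 -> mal", "abc + d -> abcd")))
  if (pyruvate_cycling)
    rxns <- c(rxns, list(reaction("me1d", "mal -> pyr + co2", "abcd -> abc + d")))
  if (unlabeled_anaplerosis)
    rxns <- c(rxns, list(reaction("ana", "oaa.in -> oaa", "abcd -> abcd")))

  net <- atom_network(mets, rxns, symmetric_species = c("suc", "fum"))
  net$co2_enrichment <- co2_enrichment
  rep <- validate_network(net)
  if (nrow(rep) > 0L)
    stop("core network failed validation: ", paste(rep$message, collapse = "; "))
  net
}

#' Validate an atom-transition network
#'
#' Checks structural well-formedness: unique metabolite ids, reactions
#' referencing declared metabolites, carbon conservation in every reaction
#' (substrate carbon count equals product carbon count and every product
#' carbon receives exactly one source), and that every non-boundary
#' metabolite has at least one producing and one consuming reaction.
#'
#' @param net an `atn` network.
#' @return data.frame with columns `type`, `where`, `message`; zero rows
#'   iff the network is well-formed.
#' @export
validate_network <- function(net) {
  probs <- list()
  note <- function(type, where, message)
    probs[[length(probs) + 1L]] <<- data.frame(type = type, where = where,
                                               message = message,
                                               stringsAsFactors = FALSE)
  ids <- net$metabolites$id
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) note("duplicate_id", d, paste0("duplicate metabolite id '", d, "'"))

  carbons <- stats::setNames(net$metabolites$n_carbons, ids)
  produced <- consumed <- character()
  for (r in net$reactions) {
    missing <- setdiff(c(r$substrates, r$products), ids)
    if (length(missing)) {
      note("unknown_metabolite", r$id,
           paste0("reaction '", r$id, "' references unknown metabolite(s) ",
                  paste(missing, collapse = ", ")))
      next
    }
    ns <- sum(carbons[r$substrates]); np <- sum(carbons[r$products])
    if (ns != np)
      note("carbon_imbalance", r$id,
           paste0("reaction '", r$id, "' carbon imbalance of ", ns - np,
                  " (", ns, " substrate vs ", np, " product carbons)"))
    if (!is.null(r$carbon_map)) {
      ## every product carbon must receive exactly one source
      seen <- matrix(0L, nrow = length(r$products),
                     ncol = max(carbons[r$products]))
      for (i in seq_along(r$carbon_map)) {
        m <- r$carbon_map[[i]]
        for (k in seq_len(nrow(m)))
          seen[m[k, 1L], m[k, 2L]] <- seen[m[k, 1L], m[k, 2L]] + 1L
      }
      for (j in seq_along(r$products))
        for (p in seq_len(carbons[r$products[j]]))
          if (seen[j, p] != 1L)
            note("carbon_map", r$id,
                 paste0("reaction '", r$id, "': product '", r$products[j],
                        "' carbon C", p, " receives ", seen[j, p], " sources"))
    } else if (ns == np) {
      note("carbon_map", r$id, paste0("reaction '", r$id, "' lacks a carbon map"))
    }
    produced <- c(produced, r$products)
    consumed <- c(consumed, r$substrates)
  }
  internal <- ids[!net$metabolites$is_boundary]
  for (m in setdiff(internal, produced))
    note("orphan", m, paste0("metabolite '", m, "' has no producing reaction"))
  for (m in setdiff(internal, consumed))
    note("orphan", m, paste0("metabolite '", m, "' has no consuming reaction"))

  if (length(probs)) do.call(rbind, probs)
  else data.frame(type = character(), where = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Check steady-state flux balance
#'
#' Steady state (production equals consumption for every non-boundary pool)
#' is the premise under which isotopic labeling patterns are interpretable;
#' this verifies it for a candidate flux vector.
#'
#' @param net an `atn` network.
#' @param flux named non-negative numeric vector, one rate per reaction id.
#' @return data.frame with one row per non-boundary metabolite: columns
#'   `metabolite`, `production`, `consumption`, `net`, `balanced`; the whole
#'   state is balanced iff every `|net|` is at most `1e-9` times the pool's
#'   throughput.  Attribute `balanced` carries the overall verdict.
#' @export
validate_flux_balance <- function(net, flux) {
  missing <- setdiff(names(net$reactions), names(flux))
  if (length(missing))
    stop("flux missing for reaction(s): ", paste(missing, collapse = ", "))
  if (any(flux[names(net$reactions)] < -1e-12))
    stop("fluxes must be non-negative")
  internal <- net$metabolites$id[!net$metabolites$is_boundary]
  prod <- cons <- stats::setNames(numeric(length(internal)), internal)
  for (r in net$reactions) {
    v <- flux[[r$id]]
    for (m in r$products) if (m %in% internal) prod[m] <- prod[m] + v
    for (m in r$substrates) if (m %in% internal) cons[m] <- cons[m] + v
  }
  through <- prod + cons
  net_rate <- prod - cons
  ok <- abs(net_rate) <= pmax(1e-9 * through, 1e-12)
  out <- data.frame(metabolite = internal, production = unname(prod),
                    consumption = unname(cons), net = unname(net_rate),
                    balanced = unname(ok), stringsAsFactors = FALSE)
  attr(out, "balanced") <- all(ok)
  out
}

#' @rdname validate_flux_balance
#' @export
is_balanced <- function(net, flux) {
  isTRUE(attr(validate_flux_balance(net, flux), "balanced"))
}
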