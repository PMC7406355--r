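#' Table and configuration I/O
#'
#' Comma-separated tables with a required header row, UTF-8, "." decimal
#' separator.  The MID schema is `sample_id, metabolite, mass_shift,
#' fraction[, corrected]` with one row per mass shift, contiguous from 0
#' within each (sample, metabolite).
#'
#' @name io_cli
NULL

#' Read a MID table
#'
#' @param path CSV file path.
#' @return data.frame of validated rows, ordered by sample, metabolite and
#'   mass shift.
#' @export
read_mid_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "metabolite", "mass_shift", "fraction")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("MID table missing column(s): ", paste(miss, collapse = ", "))
  if (!"corrected" %in% names(df)) df$corrected <- FALSE
  df <- df[order(df$sample_id, df$metabolite, df$mass_shift), ]
  rownames(df) <- NULL
  key <- paste(df$sample_id, df$metabolite, sep = "\r")
  for (k in unique(key)) {
    shifts <- df$mass_shift[key == k]
    if (!identical(as.integer(shifts), seq_along(shifts) - 1L))
      stop("non-contiguous mass shifts for sample/metabolite '",
           sub("\r", " / ", k), "'")
    s <- sum(df$fraction[key == k])
    if (abs(s - 1) > 0.05)
      warning("fractions for '", sub("\r", " / ", k), "' sum to ",
              format(s, digits = 4), call. = FALSE)
  }
  df
}

#' @rdname read_mid_table
#' @param df MID data.frame.
#' @export
write_mid_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a reporter fluorescence table
#'
#' Columns: `sample_id, time_h, fluorescence, is_control` (plus free
#' metadata columns).
#'
#' @param path CSV file path.
#' @export
read_reporter_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "time_h", "fluorescence", "is_control")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("reporter table missing column(s): ", paste(miss, collapse = ", "))
  df$is_control <- as.logical(df$is_control)
  df
}

#' Write / read a network configuration
#'
#' YAML document with blocks `metabolites:` (id, carbons, boundary),
#' `reactions:` (id, equation, map) and `symmetric:`; atom maps use the
#' letter-per-carbon notation of [reaction()].
#'
#' @param net an `atn` network.
#' @param path file path.
#' @export
write_network_config <- function(net, path) {
  doc <- list(
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i)
      list(id = net$metabolites$id[i],
           carbons = net$metabolites$n_carbons[i],
           boundary = net$metabolites$is_boundary[i])),
    reactions = lapply(unname(net$reactions), function(r)
      list(id = r$id, equation = r$equation, map = r$map_string)),
    symmetric = as.list(net$symmetric_species),
    co2 = net$co2_id,
    co2_enrichment = net$co2_enrichment %||% 0)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  for (block in c("metabolites", "reactions"))
    if (is.null(doc[[block]]))
      stop("network config lacks the '", block, "' block")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m)
    metabolite(m$id, m$carbons, isTRUE(m$boundary))))
  rxns <- lapply(doc$reactions, function(r) reaction(r$id, r$equation, r$map))
  net <- atom_network(mets, rxns,
                      symmetric_species = unlist(doc$symmetric) %||% character(),
                      co2_id = doc$co2 %||% "co2")
  net$co2_enrichment <- doc$co2_enrichment %||% 0
  rep <- validate_network(net)
  if (nrow(rep) > 0L)
    stop("network config invalid: ", paste(rep$message, collapse = "; "))
  net
}

tracer_from_name <- function(name, enrichment = 1) {
  switch(name,
         uglc = tracer_uglc(enrichment),
         glc34 = tracer_34glc(enrichment),
         pyr1 = tracer_1pyr(enrichment),
         stop("unknown tracer name '", name, "'"))
}

#' Execute a pipeline command
#'
#' Thin driver over the package's modules, also exposed as a command-line
#' script (`inst/cli/pctrace.R`).  Commands:
#' \describe{
#'   \item{generate}{build a preset scenario and write its synthetic
#'     dataset (free/protein/bulk/reporter CSVs, ground truth and
#'     provenance records).}
#'   \item{simulate}{steady-state MIDs of the core network under a tracer
#'     and flux fractions given in the config.}
#'   \item{correct}{natural-abundance-correct a raw MID table.}
#'   \item{ratio}{PC-activity ratios (asp M+1 / pyr M+1) per sample of a
#'     corrected MID table.}
#'   \item{fit}{fit flux fractions from corrected tables of one or more
#'     conditions described in the config.}
#' }
#'
#' @param config named list (or YAML file path) with command-specific
#'   fields; see the vignette for the layouts.
#' @param command one of `simulate`, `generate`, `correct`, `fit`,
#'   `ratio`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding the config's.
#' @return invisibly, a list of written artifact paths.
#' @export
run_pipeline <- function(config, command = c("simulate", "generate",
                                             "correct", "fit", "ratio"),
                         out_dir = ".", seed = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  artifacts <- character()
  emit <- function(name) {
    p <- file.path(out_dir, name)
    artifacts <<- c(artifacts, p)
    p
  }

  if (command == "generate") {
    cfg <- preset(config$preset %||% "organoid_coculture",
                  tracer = config$tracer, seed = seed,
                  n_replicates = config$n_replicates)
    ds <- generate_dataset(cfg)
    write_mid_table(ds$free, emit("free_mids.csv"))
    write_mid_table(ds$protein, emit("protein_mids.csv"))
    write_mid_table(ds$bulk, emit("bulk_mids.csv"))
    utils::write.csv(ds$reporter, emit("reporter.csv"), row.names = FALSE,
                     quote = FALSE)
    truth <- ds$truth
    yaml::write_yaml(list(
      preset = config$preset %||% "organoid_coculture",
      seed = seed,
      knockout = cfg$knockout,
      weights = as.list(truth$weights),
      k_new = as.list(truth$k_new),
      fractions = lapply(truth$fractions, function(fr)
        lapply(unclass(fr), identity))),
      emit("ground_truth.yaml"))
  } else if (command == "simulate") {
    net <- if (!is.null(config$network)) read_network_config(config$network)
           else build_core_network()
    fr <- do.call(flux_fractions, config$fractions %||% list())
    flux <- fractions_to_flux(net, fr)
    trs <- list(tracer_from_name(config$tracer %||% "uglc",
                                 config$enrichment %||% 1))
    mids <- simulate_mids(net, flux, trs)
    rows <- list()
    for (m in names(mids)) {
      if (anyNA(mids[[m]])) next
      rows[[m]] <- data.frame(sample_id = "steady_state", metabolite = m,
                              mass_shift = seq_along(mids[[m]]) - 1L,
                              fraction = as.numeric(mids[[m]]),
                              corrected = TRUE)
    }
    write_mid_table(do.call(rbind, rows), emit("simulated_mids.csv"))
  } else if (command == "correct") {
    raw <- read_mid_table(config$mid_table)
    lib <- fragment_library()
    key <- paste(raw$sample_id, raw$metabolite, sep = "\r")
    rows <- list()
    for (k in unique(key)) {
      sub <- raw[key == k, ]
      f <- lib[[sub$metabolite[1L]]]
      if (is.null(f)) next
      x <- correct_natural_abundance(sub$fraction, f)
      rows[[k]] <- data.frame(sample_id = sub$sample_id[1L],
                              metabolite = sub$metabolite[1L],
                              mass_shift = seq_along(x) - 1L,
                              fraction = as.numeric(x), corrected = TRUE)
    }
    write_mid_table(do.call(rbind, rows), emit("corrected_mids.csv"))
  } else if (command == "ratio") {
    mids <- read_mid_table(config$mid_table)
    if (!all(mids$corrected))
      stop("ratio requires a corrected MID table")
    samples <- unique(mids$sample_id)
    base_of <- function(s) sub("^[a-z_]+_", "", s)
    rows <- list()
    asp_tab <- mids[mids$metabolite == "asp", ]
    pyr_tab <- mids[mids$metabolite == "pyr", ]
    for (s in unique(asp_tab$sample_id)) {
      asp <- asp_tab[asp_tab$sample_id == s, ]
      cand <- pyr_tab[base_of(pyr_tab$sample_id) == base_of(s) |
                        pyr_tab$sample_id == s, ]
      if (nrow(cand) == 0L) next
      pyr <- cand[cand$sample_id == cand$sample_id[1L], ]
      num <- asp$fraction[asp$mass_shift == 1L]
      den <- pyr$fraction[pyr$mass_shift == 1L]
      rows[[s]] <- data.frame(sample_id = s, asp_m1 = num, pyr_m1 = den,
                              ratio = if (den > 1e-6) num / den else NA_real_,
                              undefined = den <= 1e-6)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    utils::write.csv(out, emit("pc_activity.csv"), row.names = FALSE,
                     quote = FALSE)
  } else if (command == "fit") {
    net <- build_core_network()
    base <- do.call(flux_fractions, config$base %||% list())
    kin <- protein_kinetics(config$k_new %||% log(2) / 48)
    conds <- lapply(config$conditions, function(cd) {
      prot <- read_mid_table(cd$protein_table)
      free <- read_mid_table(cd$free_table)
      grab <- function(tab, met) {
        sub <- tab[tab$metabolite == met, ]
        if (nrow(sub) == 0L) return(NULL)
        s <- sub$sample_id[1L]
        v <- sub$fraction[sub$sample_id == s]
        mid(v / sum(v), met)
      }
      list(tracers = list(tracer_from_name(cd$tracer,
                                           cd$enrichment %||% 1)),
           knockout = cd$knockout %||% "none",
           protein = Filter(Negate(is.null), list(asp = grab(prot, "asp"))),
           free = Filter(Negate(is.null), list(pyr = grab(free, "pyr"))),
           t_label = cd$t_label %||% 24)
    })
    fit <- fit_flux_fractions(conds, net, kin,
                              t_label = config$t_label %||% 24,
                              base = base, seed = seed)
    out <- data.frame(parameter = names(fit$estimates),
                      estimate = unname(fit$estimates),
                      residual = fit$residual,
                      identifiable = fit$identifiable)
    utils::write.csv(out, emit("fit_results.csv"), row.names = FALSE,
                     quote = FALSE)
  }

  ## provenance: enough to reproduce the artifact set exactly
  cfg_file <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config %||% list(), cfg_file)
  yaml::write_yaml(list(command = command, seed = seed,
                        config_md5 = unname(tools::md5sum(cfg_file)),
                        package_version = tryCatch(
                          as.character(utils::packageVersion("pctrace")),
                          error = function(e) "dev"),
                        timestamp = format(Sys.time(), tz = "UTC")),
                   file.path(out_dir, "provenance.yaml"))
  artifacts <- c(artifacts, cfg_file, file.path(out_dir, "provenance.yaml"))
  invisible(artifacts)
}
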