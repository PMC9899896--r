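#' Integrated hazard category from the three assay calls
#'
#' Combines the transcriptomic DDI call, the micronucleus call, and the
#' mode-of-action call (each already collapsed across S9 conditions: positive
#' if positive in either condition) into one hazard category:
#' \tabular{lll}{
#'   TGx \tab MN \tab category \cr
#'   + \tab + \tab genotoxic-clastogen / -aneugen / -pan (per MoA) \cr
#'   - \tab + \tab likely-irrelevant-MN-positive (MoA non-genotoxic) \cr
#'   + \tab + \tab possibly-genotoxic-ambiguous (MoA non-genotoxic) \cr
#'   - \tab - \tab non-genotoxic (MoA non-genotoxic) \cr
#' }
#' Any remaining combination maps to possibly-genotoxic-ambiguous with a note.
#'
#' @param tgx `"positive"`/`"negative"` (or `"DDI"`/`"nonDDI"`).
#' @param mn `"positive"`/`"negative"`.
#' @param moa One of `"clastogen"`, `"aneugen"`, `"pan-genotoxic"` (or
#'   `"pan"`), `"non-genotoxic"` (or `"none"`).
#' @return List with `category` and `note`.
#' @export
integrated_call <- function(tgx, mn, moa) {
  if (missing(tgx) || missing(mn) || missing(moa) ||
      is.na(tgx) || is.na(mn) || is.na(moa)) {
    stop("all three assay calls are required")
  }
  tgx_pos <- tgx %in% c("positive", "DDI", "+")
  mn_pos <- mn %in% c("positive", "+")
  moa <- switch(as.character(moa),
                pan = , "pan-genotoxic" = "pan",
                none = , "non-genotoxic" = "none",
                clastogen = "clastogen", aneugen = "aneugen",
                stop("unknown MoA call: ", moa))
  note <- ""
  category <- if (tgx_pos && mn_pos && moa == "clastogen") "genotoxic-clastogen"
    else if (tgx_pos && mn_pos && moa == "aneugen") "genotoxic-aneugen"
    else if (tgx_pos && mn_pos && moa == "pan") "genotoxic-pan"
    else if (!tgx_pos && mn_pos && moa == "none") "likely-irrelevant-MN-positive"
    else if (tgx_pos && mn_pos && moa == "none") "possibly-genotoxic-ambiguous"
    else if (!tgx_pos && !mn_pos && moa == "none") "non-genotoxic"
    else {
      note <- sprintf("uncommon combination (TGx %s, MN %s, MoA %s)",
                      tgx, mn, moa)
      "possibly-genotoxic-ambiguous"
    }
  list(category = category, note = note)
}

#' Collapse per-S9-condition assay calls and integrate them
#'
#' Takes a table of per-assay, per-S9 calls and produces the integrated
#' category per compound. A compound is assay-positive when positive in
#' either S9 condition; the MoA collapses to pan if any condition is pan,
#' else to clastogen/aneugen if any condition says so, else non-genotoxic.
#'
#' @param calls Data frame with columns `compound`, `tgx_minus`, `tgx_plus`
#'   (`"+"`/`"-"`/`NA` untested), `mn_minus`, `mn_plus`, `moa_minus`,
#'   `moa_plus` (`"C"`, `"A"`, `"C/A"`, `"-"`, `NA`).
#' @return Data frame per compound with collapsed calls and `category`.
#' @export
integrate_call_table <- function(calls) {
  calls <- as.data.frame(calls)
  collapse_pm <- function(a, b) {
    vals <- c(a, b)
    vals <- vals[!is.na(vals) & nzchar(vals)]
    if (!length(vals)) return(NA_character_)
    if (any(vals == "+")) "positive" else "negative"
  }
  collapse_moa <- function(a, b) {
    vals <- c(a, b)
    vals <- vals[!is.na(vals) & nzchar(vals)]
    if (!length(vals)) return(NA_character_)
    if (any(vals == "C/A")) "pan"
    else if (any(vals == "C")) "clastogen"
    else if (any(vals == "A")) "aneugen"
    else "none"
  }
  out <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    tgx <- collapse_pm(r$tgx_minus, r$tgx_plus)
    mn <- collapse_pm(r$mn_minus, r$mn_plus)
    moa <- collapse_moa(r$moa_minus, r$moa_plus)
    ic <- integrated_call(tgx, mn, moa)
    data.frame(compound = r$compound, tgx = tgx, mn = mn, moa = moa,
               category = ic$category, note = ic$note,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run a full synthetic screening study end to end
#'
#' Simulates a study from a configuration (R list, `sim_config`, or a YAML
#' file with a `simulation:` section), runs the three assay callers, BMC
#' modeling, ToxPi integration, and the integrated hazard-call rule, and
#' writes all result tables to `outdir` along with a run log recording every
#' gating and filtering decision and the seeds used.
#'
#' @param config A `sim_config`, a list of [simulation_config()] arguments,
#'   or the path of a YAML file whose `simulation` section holds them.
#' @param outdir Output directory (created if needed).
#' @param n_perm Williams-test permutations for gene BMCs (default 200).
#' @param n_boot_fit Per-gene bootstrap refits (default 50).
#' @return Invisibly, a list with all result tables.
#' @export
run_study <- function(config, outdir, n_perm = 200, n_boot_fit = 50) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    if (!is.null(cfg_list$simulation)) cfg_list <- cfg_list$simulation
    if (!is.null(cfg_list$concentrations) && is.list(cfg_list$concentrations)) {
      cfg_list$concentrations <- unlist(cfg_list$concentrations)
    }
    if (!is.null(cfg_list$test_compounds)) {
      cfg_list$test_compounds <-
        do.call(rbind, lapply(cfg_list$test_compounds, as.data.frame))
    }
    config <- do.call(simulation_config, cfg_list)
  } else if (!inherits(config, "sim_config")) {
    config <- do.call(simulation_config, config)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  result_files <- file.path(outdir, c(
    "tgxddi_conditions.csv", "microflow_endpoints.csv",
    "multiflow_endpoints.csv", "bmc_table.csv", "integrated_calls.csv",
    "toxpi_scores.csv", "run_log.txt"))
  # partial outputs are removed if any stage fails
  on.exit({
    if (!isTRUE(completed)) unlink(result_files)
  }, add = TRUE)
  completed <- FALSE
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("compounds: %s",
                         paste(config$test_compounds$compound, collapse = ", ")))
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))

  expr <- simulate_expression_study(config)
  flow <- simulate_flow_study(config)

  # 1) transcriptomic classification
  tgx <- classify_tgxddi(expr$training$matrix, expr$training$labels,
                         expr$biomarker)
  utils::write.csv(tgx$conditions, file.path(outdir, "tgxddi_conditions.csv"),
                   row.names = FALSE)

  # 2) micronucleus calls
  mf <- compute_microflow_endpoints(flow$microflow)
  for (w in which(mf$wells$gated)) {
    logit("microflow well gated (%s): %s @ %g uM",
          mf$wells$gate_reason[w], mf$wells$compound[w],
          mf$wells$concentration[w])
  }
  mn_calls <- vapply(config$test_compounds$compound, function(cpd) {
    call_mn(mf, compound = cpd)$call
  }, character(1))
  utils::write.csv(mf$by_concentration,
                   file.path(outdir, "microflow_endpoints.csv"),
                   row.names = FALSE)

  # 3) mode-of-action calls
  mflow <- compute_multiflow_endpoints(flow$multiflow)
  gated_conc <- mflow$gated[mflow$gated$gated, , drop = FALSE]
  for (i in seq_len(nrow(gated_conc))) {
    logit("multiflow concentration gated (cytotoxicity %.1f%%): %s @ %g uM",
          gated_conc$cytotoxicity[i], gated_conc$compound[i],
          gated_conc$concentration[i])
  }
  moa_calls <- vapply(config$test_compounds$compound, function(cpd) {
    call_moa(multiflow_fold_table(mflow, cpd))$call
  }, character(1))
  utils::write.csv(mflow$records, file.path(outdir, "multiflow_endpoints.csv"),
                   row.names = FALSE)

  # 4) gene-set BMCs for DDI-positive compounds
  set.seed(sub_seed(config, stream = 9L))
  bmc_rows <- lapply(config$test_compounds$compound, function(cpd) {
    if (tgx$overall[[cpd]] != "DDI") return(NULL)
    gs <- gene_set_bmc(expr$replicates[[cpd]], n_perm = n_perm,
                       n_boot_fit = n_boot_fit)
    logit("gene-set BMC for %s: %d/%d genes surviving", cpd,
          gs$counts[["surviving"]], gs$counts[["total"]])
    data.frame(compound = cpd, endpoint = "tgxddi", bmc = gs$median_bmc,
               bmcl = gs$ci[1L], bmcu = gs$ci[2L], stringsAsFactors = FALSE)
  })
  bmc_table <- do.call(rbind, bmc_rows)
  if (!is.null(bmc_table)) {
    utils::write.csv(bmc_table, file.path(outdir, "bmc_table.csv"),
                     row.names = FALSE)
  }

  # 5) integrated categories
  integrated <- do.call(rbind, lapply(config$test_compounds$compound, function(cpd) {
    ic <- integrated_call(
      tgx = if (tgx$overall[[cpd]] == "DDI") "positive" else "negative",
      mn = if (mn_calls[[cpd]] == "positive") "positive" else "negative",
      moa = moa_calls[[cpd]])
    data.frame(compound = cpd, tgx = tgx$overall[[cpd]], mn = mn_calls[[cpd]],
               moa = moa_calls[[cpd]], category = ic$category, note = ic$note,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(integrated, file.path(outdir, "integrated_calls.csv"),
                   row.names = FALSE)

  # 6) ToxPi over whatever endpoint BMCs are available
  toxpi <- NULL
  if (!is.null(bmc_table) && nrow(bmc_table)) {
    tox_in <- data.frame(compound = bmc_table$compound, slice = "tgxddi",
                         bmcl = bmc_table$bmcl, bmcu = bmc_table$bmcu,
                         stringsAsFactors = FALSE)
    toxpi <- score_profiles(tox_in)
    utils::write.csv(toxpi$scores, file.path(outdir, "toxpi_scores.csv"),
                     row.names = FALSE)
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  completed <- TRUE
  invisible(list(config = config, tgx = tgx, microflow = mf, mn_calls = mn_calls,
                 multiflow = mflow, moa_calls = moa_calls, bmc_table = bmc_table,
                 integrated = integrated, toxpi = toxpi))
}
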