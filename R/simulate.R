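# Synthetic-study generator: expression and flow-cytometry plates with known
# ground truth, shaped like the screening study design (6-point half-log
# transcriptomic series in duplicate, 10-point flow series, solvent controls
# on every plate).

#' Configuration for a synthetic screening study
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' screening design: a 64-gene biomarker panel, a 28-chemical two-class
#' reference (training) set, a 6-point half-log concentration series in
#' duplicate for expression, a 10-point series for the flow assays, Poisson
#' micronucleus counts at a 5,000-nucleated-event stop gate, and
#' multiplicative log-normal noise on fluorescence intensities.
#'
#' @param seed Integer seed fixing all outputs bit-for-bit.
#' @param n_biomarker_genes Biomarker panel size (default 64).
#' @param n_training_chemicals Reference-set size (default 28).
#' @param n_ddi_training Number of DDI-class reference chemicals (default 14;
#'   must be at least 2 and leave at least 2 in the other class).
#' @param concentrations Expression concentration series, top first (default
#'   `build_series(100, 6)`), in micromolar.
#' @param flow_concentrations Flow-assay series (default `build_series(100, 10)`).
#' @param n_replicates Replicate cultures per condition (default 2).
#' @param n_controls Solvent-control wells per plate (default 6, as in the
#'   study design).
#' @param effect_size Mean absolute log2 fold-change at the top concentration
#'   for responsive genes (default 1.5; must be positive — individual test
#'   compounds may still be null via `moa_label`/`class_label`).
#' @param noise_sd Replicate-level log2 SD of expression noise (default 0.25).
#' @param dr_params Dose-response shape parameters: `expr_b`, `expr_d`
#'   (exponential rise of expression effects; `expr_b` defaults to half the
#'   top concentration), optional `true_bmc` (when set, `expr_b` is derived so
#'   the 1-SD benchmark falls exactly there), `mn_fold_max`, `mn_b`, `mn_d`
#'   (micronucleus fold-induction curve), `mcf_noise` (log-SD of fluorescence
#'   noise), biomarker fold maxima `clast_fold`, `aneu_fold`, and survival
#'   decline scales `rs_b` (micronucleus assay) and `rnc_b` (DNA-damage assay)
#'   as fractions of the top concentration.
#' @param background_mn_rate Expected micronuclei per nucleated event in
#'   controls (default 0.007, i.e. 0.7\% MN).
#' @param stop_gate Nucleated events acquired per well (default 5000).
#' @param test_compounds Data frame with `compound`, `class_label`
#'   (`"DDI"`/`"nonDDI"`) and `moa_label` (`"clastogen"`, `"aneugen"`,
#'   `"pan"`, `"none"`); the default holds one clastogen, one aneugen, one
#'   pan-genotoxicant and one inactive compound.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_biomarker_genes = 64L,
                              n_training_chemicals = 28L,
                              n_ddi_training = 14L,
                              concentrations = build_series(100, 6)$concentrations,
                              flow_concentrations = build_series(100, 10)$concentrations,
                              n_replicates = 2L,
                              n_controls = 6L,
                              effect_size = 1.5,
                              noise_sd = 0.25,
                              dr_params = list(),
                              background_mn_rate = 0.007,
                              stop_gate = 5000L,
                              test_compounds = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (any(concentrations <= 0) || is.unsorted(rev(concentrations), strictly = TRUE)) {
    stop("`concentrations` must be strictly positive and strictly decreasing (top first)")
  }
  if (any(flow_concentrations <= 0) ||
      is.unsorted(rev(flow_concentrations), strictly = TRUE)) {
    stop("`flow_concentrations` must be strictly positive and strictly decreasing")
  }
  if (effect_size <= 0) stop("`effect_size` must be positive")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (n_ddi_training >= n_training_chemicals) {
    stop("`n_ddi_training` must be smaller than `n_training_chemicals`")
  }
  if (n_ddi_training < 2L || n_training_chemicals - n_ddi_training < 2L) {
    stop("need at least 2 training chemicals per class")
  }
  if (background_mn_rate < 0) stop("`background_mn_rate` must be non-negative")
  top <- concentrations[1L]
  dp <- utils::modifyList(list(
    expr_b = top / 2, expr_d = 2, true_bmc = NULL,
    mn_fold_max = 4, mn_b = 0.3, mn_d = 2,
    mcf_noise = 0.05, count_noise = TRUE,
    clast_fold = c(gh2ax_4h = 3.0, gh2ax_24h = 3.0, p53_4h = 2.5, p53_24h = 2.2),
    aneu_fold = c(ph3_4h = 3.0, ph3_24h = 2.5, polyploidy_24h = 9, p53_24h = 2.2),
    rs_b = 0.8, rnc_b = 0.7
  ), dr_params)
  if (is.null(test_compounds)) {
    test_compounds <- data.frame(
      compound = c("cpd_clastogen", "cpd_aneugen", "cpd_pan", "cpd_null"),
      class_label = c("DDI", "nonDDI", "DDI", "nonDDI"),
      moa_label = c("clastogen", "aneugen", "pan", "none"),
      stringsAsFactors = FALSE
    )
  }
  test_compounds <- as.data.frame(test_compounds)
  stopifnot(all(c("compound", "class_label", "moa_label") %in% names(test_compounds)),
            all(test_compounds$class_label %in% c("DDI", "nonDDI")),
            all(test_compounds$moa_label %in% c("clastogen", "aneugen", "pan", "none")),
            !anyDuplicated(test_compounds$compound))
  structure(list(seed = as.integer(seed),
                 n_biomarker_genes = as.integer(n_biomarker_genes),
                 n_training_chemicals = as.integer(n_training_chemicals),
                 n_ddi_training = as.integer(n_ddi_training),
                 concentrations = concentrations,
                 flow_concentrations = flow_concentrations,
                 n_replicates = as.integer(n_replicates),
                 n_controls = as.integer(n_controls),
                 effect_size = effect_size, noise_sd = noise_sd,
                 dr_params = dp, background_mn_rate = background_mn_rate,
                 stop_gate = as.integer(stop_gate),
                 test_compounds = test_compounds),
            class = "sim_config")
}

# deterministic per-(stream, index) seed so adding compounds does not perturb
# existing ones; kept below 2^31
sub_seed <- function(config, stream, index = 0L) {
  as.integer((as.numeric(config$seed) * 48271 + stream * 65537 + index * 7919) %%
               2147483647)
}

# expression effect curve: fraction of the asymptotic effect reached at x
expr_curve <- function(x, b, d) 1 - exp(-(x / b)^d)

#' Expected per-gene expression effect for a compound
#'
#' Evaluates the generator's mean log2 fold-change magnitude (for responsive
#' genes, before the per-gene direction sign) at concentration `x`. The
#' asymptotic effect is scaled so the mean absolute log2 fold-change at the
#' top concentration equals `effect_size`.
#'
#' @param config A `sim_config`.
#' @param x Concentration(s) in micromolar.
#' @return Numeric vector of expected absolute log2 fold-changes.
#' @export
expression_effect <- function(config, x) {
  dp <- config$dr_params
  top <- config$concentrations[1L]
  scale <- config$effect_size / expr_curve(top, expr_b(config), dp$expr_d)
  scale * expr_curve(x, expr_b(config), dp$expr_d)
}

expr_b <- function(config) {
  dp <- config$dr_params
  if (is.null(dp$true_bmc)) return(dp$expr_b)
  # choose b so the 1-SD benchmark of the noiseless mean falls at true_bmc:
  # E * (1 - exp(-(bmc/b)^d)) = noise_sd
  top <- config$concentrations[1L]
  f <- function(b) {
    scale <- config$effect_size / expr_curve(top, b, dp$expr_d)
    scale * expr_curve(dp$true_bmc, b, dp$expr_d) - config$noise_sd
  }
  stats::uniroot(f, c(dp$true_bmc * 1e-3, top * 1e3), tol = 1e-10)$root
}

#' Simulate a transcriptomic screening study
#'
#' Generates (a) a labeled two-class reference set whose DDI chemicals carry
#' class-specific mean shifts on the biomarker panel (half the genes
#' up-regulated, half down-regulated), (b) replicate-level log2 expression
#' responses for every test compound over the concentration series, and (c)
#' the replicate-averaged log2 fold-change biomarker matrix used by the
#' classifier ensemble. DDI test compounds follow the exponential
#' dose-response toward the DDI direction; non-DDI compounds have zero
#' expected fold-change; replicate noise is additive Gaussian on the log2
#' scale.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List of class `expression_study`: `training` (matrix + labels),
#'   `biomarker` (genes x conditions averaged log2 fold-changes with a
#'   `conditions` attribute), `replicates` (per-gene list of `x`/`y`
#'   replicate-level data per compound, suitable for BMC modeling), and
#'   `truth` (the ground-truth table).
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("gene%02d", seq_len(config$n_biomarker_genes))
  n_up <- ceiling(config$n_biomarker_genes / 2)
  direction <- rep(c(1, -1), c(n_up, config$n_biomarker_genes - n_up))

  # training set
  set.seed(sub_seed(config, stream = 1L))
  labels <- rep(c("DDI", "nonDDI"),
                c(config$n_ddi_training,
                  config$n_training_chemicals - config$n_ddi_training))
  mu <- outer(as.numeric(labels == "DDI"), direction * config$effect_size)
  training <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                          nrow = nrow(mu))
  dimnames(training) <- list(sprintf("ref%02d", seq_along(labels)), genes)

  conc <- config$concentrations
  reps <- config$n_replicates
  tc <- config$test_compounds
  ddi <- tc$class_label == "DDI"

  biomarker <- NULL
  conds <- NULL
  replicates <- list()
  for (i in seq_len(nrow(tc))) {
    set.seed(sub_seed(config, stream = 2L, index = i))
    eff <- if (ddi[i]) expression_effect(config, conc) else rep(0, length(conc))
    # genes x conc expected means, then replicate noise
    mean_fc <- outer(direction, eff)
    per_rep <- lapply(seq_len(reps), function(r) {
      mean_fc + matrix(stats::rnorm(length(mean_fc), sd = config$noise_sd),
                       nrow = nrow(mean_fc))
    })
    avg <- Reduce(`+`, per_rep) / reps
    colnames(avg) <- paste(tc$compound[i], signif(conc, 6), sep = "@")
    rownames(avg) <- genes
    biomarker <- cbind(biomarker, avg)
    conds <- rbind(conds, data.frame(compound = tc$compound[i],
                                     concentration = conc))
    # replicate-level data with plate solvent controls (x = 0) for
    # dose-response modeling
    n_ctrl <- config$n_controls
    ctrl <- matrix(stats::rnorm(config$n_biomarker_genes * n_ctrl,
                                sd = config$noise_sd),
                   nrow = config$n_biomarker_genes)
    x_vec <- c(rep(0, n_ctrl), rep(rev(conc), each = reps))
    ord <- rev(seq_along(conc))
    replicates[[tc$compound[i]]] <- lapply(seq_along(genes), function(g) {
      y_trt <- unlist(lapply(ord, function(ci) {
        vapply(per_rep, function(m) m[g, ci], numeric(1))
      }), use.names = FALSE)
      list(x = x_vec, y = c(ctrl[g, ], y_trt))
    })
    names(replicates[[tc$compound[i]]]) <- genes
  }
  attr(biomarker, "conditions") <- conds
  class(biomarker) <- c("biomarker_matrix", class(biomarker))

  truth <- data.frame(compound = tc$compound, class_label = tc$class_label,
                      moa_label = tc$moa_label,
                      true_bmc = ifelse(ddi, true_expression_bmc(config), NA_real_),
                      stringsAsFactors = FALSE)
  structure(list(training = list(matrix = training, labels = labels),
                 biomarker = biomarker, replicates = replicates,
                 truth = truth, genes = genes, direction = direction),
            class = "expression_study")
}

#' Analytic 1-SD benchmark of the expression generator
#'
#' Solves `expression_effect(config, x) = noise_sd` for `x` — the
#' concentration at which a responsive gene's noiseless mean departs from
#' control by one replicate SD. This is the generator's ground-truth BMC for
#' responsive genes.
#'
#' @param config A `sim_config`.
#' @return Concentration in micromolar (`NA` if the effect never reaches 1 SD).
#' @export
true_expression_bmc <- function(config) {
  top <- config$concentrations[1L]
  f <- function(x) expression_effect(config, x) - config$noise_sd
  if (f(top * 10) < 0) return(NA_real_)
  stats::uniroot(f, c(top * 1e-8, top * 10), tol = 1e-12)$root
}

# fold-induction curve for flow endpoints: 1 at control, fold_max asymptote
flow_fold <- function(x, fold_max, b_frac, d, top) {
  1 + (fold_max - 1) * (1 - exp(-(x / (b_frac * top))^d))
}

#' Simulate flow-cytometry plates (micronucleus + DNA-damage assays)
#'
#' Builds per-well summary tables for both flow assays over the 10-point
#' series with solvent controls on every plate. Micronucleus counts are
#' Poisson with rate `background_mn_rate` scaled by a fold-induction curve
#' (flat for inactive compounds); nucleated events equal the stop gate.
#' DNA-damage biomarker intensities follow mode-of-action-specific
#' fold-change curves (clastogens: gamma-H2AX and p53; aneugens: p-H3,
#' polyploidy, and 24H p53; pan: both) under multiplicative log-normal noise,
#' with binomial event counts for the frequency endpoints. Nuclei-density
#' decline curves are included so cytotoxicity gating is exercised.
#'
#' @param config A `sim_config`.
#' @param truth Ground-truth table (`compound`, `class_label`, `moa_label`);
#'   defaults to the truth implied by `config$test_compounds`.
#' @return List of class `flow_study` with `microflow` and `multiflow`
#'   well-level data frames.
#' @export
simulate_flow_study <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tc <- config$test_compounds
  if (is.null(truth)) {
    truth <- data.frame(compound = tc$compound, class_label = tc$class_label,
                        moa_label = tc$moa_label, stringsAsFactors = FALSE)
  }
  if (!all(tc$compound %in% truth$compound)) {
    stop("`truth` must cover every simulated compound")
  }
  truth <- truth[match(tc$compound, truth$compound), , drop = FALSE]
  dp <- config$dr_params
  conc <- config$flow_concentrations
  top <- conc[1L]
  reps <- config$n_replicates
  n_ctrl <- config$n_controls
  base_density <- 1e5
  ctrl_mcf <- c(gh2ax = 1000, p53 = 800)
  base_poly <- 0.01   # background 8n fraction
  base_ph3 <- 0.015   # background p-H3-positive fraction
  base_ema <- 2       # background %EMA-positive
  n_events <- 10000L

  micro <- list(); multi <- list()
  for (i in seq_len(nrow(tc))) {
    cpd <- tc$compound[i]
    moa <- truth$moa_label[i]
    active_mn <- moa != "none"
    clast <- moa %in% c("clastogen", "pan")
    aneu <- moa %in% c("aneugen", "pan")

    # --- micronucleus plate -------------------------------------------------
    set.seed(sub_seed(config, stream = 3L, index = i))
    mk_mn_well <- function(x, rep_id, is_control) {
      fold <- if (is_control || !active_mn) 1 else
        flow_fold(x, dp$mn_fold_max, dp$mn_b, dp$mn_d, top)
      surv <- if (is_control) 1 else exp(-(x / (dp$rs_b * top))^2)
      data.frame(compound = cpd, concentration = if (is_control) 0 else x,
                 replicate = rep_id, plate = paste0("mnplate_", cpd),
                 mn_events = stats::rpois(1L, config$stop_gate *
                                            config$background_mn_rate * fold),
                 nucleated_events = config$stop_gate,
                 pct_ema_positive = max(0.1, base_ema *
                                          stats::rlnorm(1L, 0, dp$mcf_noise)),
                 nuclei_per_ml = base_density * surv *
                   stats::rlnorm(1L, 0, dp$mcf_noise),
                 is_control = is_control, stringsAsFactors = FALSE)
    }
    ctrl_rows <- lapply(seq_len(n_ctrl), function(r) mk_mn_well(0, r, TRUE))
    trt_rows <- lapply(conc, function(x)
      do.call(rbind, lapply(seq_len(reps), function(r) mk_mn_well(x, r, FALSE))))
    micro[[cpd]] <- do.call(rbind, c(ctrl_rows, trt_rows))

    # --- DNA-damage plate ---------------------------------------------------
    set.seed(sub_seed(config, stream = 4L, index = i))
    fold_for <- function(x, timepoint) {
      f <- c(gh2ax = 1, p53 = 1, ph3 = 1, poly = 1)
      if (clast) {
        f["gh2ax"] <- flow_fold(x, dp$clast_fold[[paste0("gh2ax_", tolower(timepoint))]],
                                dp$mn_b, dp$mn_d, top)
        f["p53"] <- flow_fold(x, dp$clast_fold[[paste0("p53_", tolower(timepoint))]],
                              dp$mn_b, dp$mn_d, top)
      }
      if (aneu) {
        f["ph3"] <- flow_fold(x, dp$aneu_fold[[paste0("ph3_", tolower(timepoint))]],
                              dp$mn_b, dp$mn_d, top)
        if (timepoint == "24H") {
          f["poly"] <- flow_fold(x, dp$aneu_fold[["polyploidy_24h"]],
                                 dp$mn_b, dp$mn_d, top)
          f["p53"] <- max(f["p53"], flow_fold(x, dp$aneu_fold[["p53_24h"]],
                                              dp$mn_b, dp$mn_d, top))
        }
      }
      f
    }
    mk_mf_well <- function(x, timepoint, rep_id, is_control) {
      f <- if (is_control) c(gh2ax = 1, p53 = 1, ph3 = 1, poly = 1)
           else fold_for(x, timepoint)
      surv <- if (is_control) 1 else exp(-(x / (dp$rnc_b * top))^2)
      p_poly <- min(base_poly * f[["poly"]], 0.5)
      p_ph3 <- min(base_ph3 * f[["ph3"]], 0.5)
      n8 <- stats::rbinom(1L, n_events, p_poly)
      data.frame(compound = cpd, concentration = if (is_control) 0 else x,
                 timepoint = timepoint, replicate = rep_id,
                 plate = paste0("mfplate_", cpd),
                 mcf_gh2ax = ctrl_mcf[["gh2ax"]] * f[["gh2ax"]] *
                   stats::rlnorm(1L, 0, dp$mcf_noise),
                 mcf_p53 = ctrl_mcf[["p53"]] * f[["p53"]] *
                   stats::rlnorm(1L, 0, dp$mcf_noise),
                 events_2n4n = n_events - n8,
                 events_8n = n8,
                 events_ph3_pos = stats::rbinom(1L, n_events, p_ph3),
                 nuclei_per_ml = base_density * surv *
                   stats::rlnorm(1L, 0, dp$mcf_noise),
                 is_control = is_control, stringsAsFactors = FALSE)
    }
    rows <- list()
    for (tp in c("4H", "24H")) {
      rows <- c(rows,
                lapply(seq_len(n_ctrl), function(r) mk_mf_well(0, tp, r, TRUE)),
                lapply(conc, function(x)
                  do.call(rbind, lapply(seq_len(reps), function(r)
                    mk_mf_well(x, tp, r, FALSE)))))
    }
    multi[[cpd]] <- do.call(rbind, rows)
  }
  structure(list(microflow = do.call(rbind, c(micro, make.row.names = FALSE)),
                 multiflow = do.call(rbind, c(multi, make.row.names = FALSE))),
            class = "flow_study")
}

#' Noiseless biomarker fold-changes implied by the generator
#'
#' Returns the expected (noise-free) fold-change table for one compound's
#' DNA-damage biomarkers over the flow series, in the format [call_moa()]
#' consumes. Useful as an oracle: applying the decision table to these means
#' must reproduce the compound's ground-truth mode of action.
#'
#' @param config A `sim_config`.
#' @param moa_label One of `"clastogen"`, `"aneugen"`, `"pan"`, `"none"`.
#' @return Data frame with `biomarker`, `timepoint`, `concentration`, `fold`.
#' @export
expected_fold_table <- function(config, moa_label) {
  dp <- config$dr_params
  conc <- config$flow_concentrations
  top <- conc[1L]
  clast <- moa_label %in% c("clastogen", "pan")
  aneu <- moa_label %in% c("aneugen", "pan")
  rows <- list()
  add <- function(biomarker, timepoint, fold) {
    rows[[length(rows) + 1L]] <<- data.frame(
      biomarker = biomarker, timepoint = timepoint, concentration = conc,
      fold = fold, stringsAsFactors = FALSE)
  }
  for (tp in c("4H", "24H")) {
    g <- if (clast) flow_fold(conc, dp$clast_fold[[paste0("gh2ax_", tolower(tp))]],
                              dp$mn_b, dp$mn_d, top) else rep(1, length(conc))
    p <- if (clast) flow_fold(conc, dp$clast_fold[[paste0("p53_", tolower(tp))]],
                              dp$mn_b, dp$mn_d, top) else rep(1, length(conc))
    if (aneu && tp == "24H") {
      p <- pmax(p, flow_fold(conc, dp$aneu_fold[["p53_24h"]], dp$mn_b, dp$mn_d, top))
    }
    h <- if (aneu) flow_fold(conc, dp$aneu_fold[[paste0("ph3_", tolower(tp))]],
                             dp$mn_b, dp$mn_d, top) else rep(1, length(conc))
    add("gh2ax", tp, g); add("p53", tp, p); add("ph3", tp, h)
    if (tp == "24H") {
      add("polyploidy", tp,
          if (aneu) flow_fold(conc, dp$aneu_fold[["polyploidy_24h"]],
                              dp$mn_b, dp$mn_d, top) else rep(1, length(conc)))
    }
  }
  do.call(rbind, rows)
}
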