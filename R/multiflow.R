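#' Default global evaluation factors (GEFs)
#'
#' Fold-change thresholds over solvent control that define a biologically
#' significant biomarker response. The clastogen set covers gamma-H2AX and
#' nuclear p53 at 4 and 24 hours; the aneugen set covers phospho-histone-H3 at
#' 4 and 24 hours, 24-hour polyploidy, and 24-hour p53. Note that 24H p53
#' belongs to both sets.
#'
#' @return Data frame with columns `biomarker`, `timepoint`, `set`, `gef`.
#' @export
default_gef_table <- function() {
  data.frame(
    biomarker = c("gh2ax", "gh2ax", "p53", "p53", "ph3", "ph3", "polyploidy", "p53"),
    timepoint = c("4H", "24H", "4H", "24H", "4H", "24H", "24H", "24H"),
    set = c(rep("clastogen", 4L), rep("aneugen", 4L)),
    gef = c(1.51, 2.11, 1.40, 1.45, 1.71, 1.52, 5.86, 1.45),
    stringsAsFactors = FALSE
  )
}

#' Compute multiplexed DNA-damage assay endpoints
#'
#' Per (compound, concentration, timepoint), computes:
#' \itemize{
#'   \item gamma-H2AX and p53 shifts = treated median channel fluorescence /
#'     mean solvent-control MCF;
#'   \item \%polyploidy = 100 * 8n events / (2n-4n + 8n events);
#'   \item \%p-H3 = 100 * p-H3-positive events / (2n-4n + 8n events);
#'   \item relative nuclei count RNC = 100 * treated density / mean control
#'     density, and cytotoxicity = 100 - RNC at 24H.
#' }
#' All four biomarkers are also expressed as fold-change versus the mean
#' solvent control (control = 1). Concentrations whose 24-hour cytotoxicity
#' exceeds 80\% are flagged gated and excluded from mode-of-action calling.
#'
#' @param wells Data frame with columns `compound`, `concentration`,
#'   `timepoint` (`"4H"`/`"24H"`), `replicate`, `mcf_gh2ax`, `mcf_p53`,
#'   `events_2n4n`, `events_8n`, `events_ph3_pos`, `nuclei_per_ml`,
#'   `is_control`, optional `plate`.
#' @param cytotox_max Cytotoxicity gate in percent (default 80).
#' @return List of class `multiflow_summary` with `records` (per compound x
#'   concentration x timepoint endpoint values and folds) and `gated`
#'   (per-concentration gate flags).
#' @export
compute_multiflow_endpoints <- function(wells, cytotox_max = 80) {
  wells <- as.data.frame(wells)
  need <- c("compound", "concentration", "timepoint", "mcf_gh2ax", "mcf_p53",
            "events_2n4n", "events_8n", "events_ph3_pos", "nuclei_per_ml",
            "is_control")
  if (!all(need %in% names(wells))) {
    stop("wells table must contain columns: ",
         paste(setdiff(need, names(wells)), collapse = ", "))
  }
  if (is.null(wells$plate)) wells$plate <- "plate1"
  if (any(wells$mcf_gh2ax <= 0) || any(wells$mcf_p53 <= 0)) {
    stop("fluorescence intensities must be positive")
  }
  total <- wells$events_2n4n + wells$events_8n
  if (any(total <= 0)) stop("zero total events in a well")
  wells$pct_polyploidy <- 100 * wells$events_8n / total
  wells$pct_ph3 <- 100 * wells$events_ph3_pos / total

  rec <- do.call(rbind, lapply(
    split(wells, list(wells$plate, wells$timepoint), drop = TRUE),
    function(pw) {
      ctrl <- pw[pw$is_control, , drop = FALSE]
      if (!nrow(ctrl)) stop("no control wells for plate/timepoint ",
                            pw$plate[1L], "/", pw$timepoint[1L])
      cm <- list(gh2ax = mean(ctrl$mcf_gh2ax), p53 = mean(ctrl$mcf_p53),
                 poly = mean(ctrl$pct_polyploidy), ph3 = mean(ctrl$pct_ph3),
                 dens = mean(ctrl$nuclei_per_ml))
      if (cm$gh2ax <= 0 || cm$p53 <= 0 || cm$dens <= 0) {
        stop("zero control MCF or density")
      }
      pw$shift_gh2ax <- pw$mcf_gh2ax / cm$gh2ax
      pw$shift_p53 <- pw$mcf_p53 / cm$p53
      pw$fold_polyploidy <- if (cm$poly > 0) pw$pct_polyploidy / cm$poly else NA_real_
      pw$fold_ph3 <- if (cm$ph3 > 0) pw$pct_ph3 / cm$ph3 else NA_real_
      pw$rnc <- 100 * pw$nuclei_per_ml / cm$dens
      pw
    }))
  rownames(rec) <- NULL

  trt <- rec[!rec$is_control, , drop = FALSE]
  agg <- do.call(rbind, lapply(
    split(trt, list(trt$compound, trt$concentration, trt$timepoint), drop = TRUE),
    function(d) {
      data.frame(compound = d$compound[1L], concentration = d$concentration[1L],
                 timepoint = d$timepoint[1L],
                 fold_gh2ax = mean(d$shift_gh2ax), fold_p53 = mean(d$shift_p53),
                 fold_ph3 = mean(d$fold_ph3), fold_polyploidy = mean(d$fold_polyploidy),
                 pct_polyploidy = mean(d$pct_polyploidy), pct_ph3 = mean(d$pct_ph3),
                 rnc = mean(d$rnc), stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  agg$cytotoxicity <- ifelse(agg$timepoint == "24H", 100 - agg$rnc, NA_real_)

  gate <- agg[agg$timepoint == "24H",
              c("compound", "concentration", "cytotoxicity")]
  gate$gated <- gate$cytotoxicity > cytotox_max
  agg$gated <- gate$gated[match(paste(agg$compound, agg$concentration),
                                paste(gate$compound, gate$concentration))]
  agg$gated[is.na(agg$gated)] <- FALSE
  agg <- agg[order(agg$compound, agg$timepoint, agg$concentration), ]
  rownames(agg) <- NULL
  structure(list(records = agg, gated = gate, cytotox_max = cytotox_max),
            class = "multiflow_summary")
}

# long fold table (biomarker, timepoint, concentration, fold, gated) from a summary
multiflow_fold_table <- function(summary, compound) {
  rec <- summary$records
  rec <- rec[rec$compound == compound, , drop = FALSE]
  if (!nrow(rec)) stop("no records for compound ", compound)
  do.call(rbind, lapply(c("gh2ax", "p53", "ph3", "polyploidy"), function(b) {
    data.frame(biomarker = b, timepoint = rec$timepoint,
               concentration = rec$concentration,
               fold = rec[[paste0("fold_", b)]],
               gated = rec$gated, stringsAsFactors = FALSE)
  }))
}

#' Mode-of-action call from biomarker fold-changes and GEFs
#'
#' A biomarker "hits" at a concentration when its fold-change meets or
#' exceeds its global evaluation factor. For each mode-of-action set
#' (clastogen, aneugen), the set is robustly positive when at least two of its
#' biomarkers hit at the same two consecutive non-gated concentrations
#' (strict reading; a looser any-two-anywhere reading over two consecutive
#' concentrations is available via `strict = FALSE`), and weakly positive when
#' at least two set biomarkers hit at one common concentration. The call is
#' clastogen or aneugen when exactly one set is positive, pan-genotoxic when
#' both are, and non-genotoxic otherwise. Gated concentrations are removed
#' before consecutiveness is assessed.
#'
#' @param fold_table Data frame with columns `biomarker`
#'   (`gh2ax`/`p53`/`ph3`/`polyploidy`), `timepoint` (`"4H"`/`"24H"`),
#'   `concentration`, `fold`, and optional logical `gated`.
#' @param gef GEF table as from [default_gef_table()].
#' @param strict Require the same biomarkers to hit at both consecutive
#'   concentrations (default `TRUE`).
#' @return List of class `moa_call`: `call` (`"clastogen"`, `"aneugen"`,
#'   `"pan-genotoxic"`, `"non-genotoxic"`), `strength` (`"robust"`, `"weak"`,
#'   `"n/a"`), and per-set detail.
#' @export
call_moa <- function(fold_table, gef = default_gef_table(), strict = TRUE) {
  fold_table <- as.data.frame(fold_table)
  if (!nrow(fold_table)) stop("empty fold table")
  if (is.null(fold_table$gated)) fold_table$gated <- FALSE
  ft <- fold_table[!fold_table$gated & !is.na(fold_table$fold), , drop = FALSE]
  concs <- sort(unique(ft$concentration))

  eval_set <- function(set_name) {
    g <- gef[gef$set == set_name, , drop = FALSE]
    # hit matrix: set biomarkers x ordered non-gated concentrations
    hits <- matrix(FALSE, nrow(g), length(concs),
                   dimnames = list(paste(g$timepoint, g$biomarker), NULL))
    for (i in seq_len(nrow(g))) {
      sub <- ft[ft$biomarker == g$biomarker[i] & ft$timepoint == g$timepoint[i], ]
      for (j in seq_along(concs)) {
        f <- sub$fold[sub$concentration == concs[j]]
        hits[i, j] <- length(f) > 0 && any(f >= g$gef[i])
      }
    }
    robust <- FALSE
    if (length(concs) >= 2L) {
      for (j in seq_len(length(concs) - 1L)) {
        if (strict) {
          robust <- robust || sum(hits[, j] & hits[, j + 1L]) >= 2L
        } else {
          robust <- robust || (sum(hits[, j]) >= 2L && sum(hits[, j + 1L]) >= 2L)
        }
      }
    }
    weak <- any(colSums(hits) >= 2L)
    list(robust = robust, weak = weak, hits = hits)
  }

  clast <- eval_set("clastogen")
  aneu <- eval_set("aneugen")
  cl_pos <- clast$robust || clast$weak
  an_pos <- aneu$robust || aneu$weak
  call <- if (cl_pos && an_pos) "pan-genotoxic"
          else if (cl_pos) "clastogen"
          else if (an_pos) "aneugen"
          else "non-genotoxic"
  strength <- if (call == "non-genotoxic") "n/a"
              else if ((cl_pos && clast$robust) || (an_pos && aneu$robust)) "robust"
              else "weak"
  structure(list(call = call, strength = strength,
                 clastogen = clast, aneugen = aneu,
                 concentrations = concs),
            class = "moa_call")
}

#' @export
print.moa_call <- function(x, ...) {
  cat(sprintf("Mode-of-action call: %s (%s)\n", x$call, x$strength))
  invisible(x)
}
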