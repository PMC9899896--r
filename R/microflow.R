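#' Compute micronucleus-assay endpoints from well-level records
#'
#' Computes, per well and per (compound, concentration):
#' \itemize{
#'   \item \%MN = 100 * MN events / nucleated events;
#'   \item fold-\%MN relative to the mean plate solvent control (control = 1);
#'   \item relative survival RS = 100 * treated nuclei density / mean control
#'     density;
#'   \item fold-EMA = treated \%apoptotic-necrotic / mean control \% (a ratio;
#'     no percentage scaling).
#' }
#' Wells are gated out of downstream statistics when RS < 40\% (cytotoxicity)
#' or fold-EMA > 4 (apoptosis/necrosis); the gate boundary retains RS = 40
#' exactly.
#'
#' @param wells Data frame of wells with columns `compound`, `concentration`,
#'   `replicate`, `mn_events`, `nucleated_events`, `pct_ema_positive`,
#'   `nuclei_per_ml`, `is_control`, and optionally `plate` (controls are
#'   matched within plate; a single plate is assumed when absent).
#' @param rs_min RS gate in percent (default 40).
#' @param ema_fold_max Fold-EMA gate (default 4).
#' @return List of class `microflow_summary`: `wells` (per-well endpoints and
#'   gating) and `by_concentration` (replicate-averaged \%MN, fold-\%MN, RS,
#'   fold-EMA and gating per compound x concentration).
#' @export
compute_microflow_endpoints <- function(wells, rs_min = 40, ema_fold_max = 4) {
  wells <- as.data.frame(wells)
  need <- c("compound", "concentration", "mn_events", "nucleated_events",
            "pct_ema_positive", "nuclei_per_ml", "is_control")
  if (!all(need %in% names(wells))) {
    stop("wells table must contain columns: ",
         paste(setdiff(need, names(wells)), collapse = ", "))
  }
  if (is.null(wells$plate)) wells$plate <- "plate1"
  if (any(wells$nucleated_events <= 0)) stop("zero nucleated events in a well")
  if (any(wells$mn_events < 0) || any(wells$mn_events > wells$nucleated_events)) {
    stop("mn_events must lie in [0, nucleated_events]")
  }

  wells$pct_mn <- 100 * wells$mn_events / wells$nucleated_events

  out <- do.call(rbind, lapply(split(wells, wells$plate), function(pw) {
    ctrl <- pw[pw$is_control, , drop = FALSE]
    if (!nrow(ctrl)) stop("no control wells on plate ", pw$plate[1L])
    ctrl_density <- mean(ctrl$nuclei_per_ml)
    if (ctrl_density <= 0) stop("zero control nuclei density on plate ", pw$plate[1L])
    ctrl_mn <- mean(ctrl$pct_mn)
    ctrl_ema <- mean(ctrl$pct_ema_positive)
    pw$rs <- 100 * pw$nuclei_per_ml / ctrl_density
    pw$fold_mn <- if (ctrl_mn > 0) pw$pct_mn / ctrl_mn else NA_real_
    pw$fold_ema <- if (ctrl_ema > 0) pw$pct_ema_positive / ctrl_ema else NA_real_
    pw$gated <- !pw$is_control &
      (pw$rs < rs_min | (!is.na(pw$fold_ema) & pw$fold_ema > ema_fold_max))
    pw$gate_reason <- ifelse(!pw$gated, "",
                             ifelse(pw$rs < rs_min, "cytotoxicity", "apoptosis/necrosis"))
    pw
  }))
  rownames(out) <- NULL

  trt <- out[!out$is_control, , drop = FALSE]
  agg <- do.call(rbind, lapply(
    split(trt, list(trt$compound, trt$concentration), drop = TRUE),
    function(d) {
      data.frame(compound = d$compound[1L], concentration = d$concentration[1L],
                 plate = d$plate[1L],
                 pct_mn = mean(d$pct_mn), fold_mn = mean(d$fold_mn),
                 rs = mean(d$rs), fold_ema = mean(d$fold_ema),
                 gated = all(d$gated),
                 gate_reason = if (all(d$gated)) d$gate_reason[1L] else "",
                 stringsAsFactors = FALSE)
    }))
  agg <- agg[order(agg$compound, agg$concentration), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(wells = out, by_concentration = agg,
                 rs_min = rs_min, ema_fold_max = ema_fold_max),
            class = "microflow_summary")
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Orders raw p-values ascending and sets
#' `adj_i = max_{j <= i} (1 - (1 - p_j)^(m - j + 1))`, capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Poisson log-linear treated-vs-control comparison at one concentration:
# mn_events ~ treated with offset log(nucleated_events); LRT p-value.
poisson_lrt_p <- function(mn, nucleated, treated) {
  fit1 <- stats::glm(mn ~ treated + offset(log(nucleated)), family = stats::poisson())
  fit0 <- stats::glm(mn ~ 1 + offset(log(nucleated)), family = stats::poisson())
  dev <- fit0$deviance - fit1$deviance
  stats::pchisq(max(dev, 0), df = 1L, lower.tail = FALSE)
}

#' Positive/negative micronucleus call for one compound
#'
#' For every non-gated concentration, micronucleus counts are compared with
#' the plate solvent controls in a Poisson log-linear model with the log
#' nucleated-event count as offset (likelihood-ratio test of the treatment
#' indicator); the family of per-concentration p-values is Holm-Sidak
#' adjusted. The compound is positive when at least one non-gated
#' concentration shows both a >= 2.50-fold increase in replicate-averaged
#' \%MN and an adjusted p below 0.05.
#'
#' @param summary A `microflow_summary` from [compute_microflow_endpoints()].
#' @param compound Compound id to call (default: the single compound present).
#' @param fold_min Fold-increase rule (default 2.50).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return List of class `mn_call`: `call` (`"positive"`, `"negative"` or
#'   `"undetermined"` when every concentration is gated) and the
#'   per-concentration evidence table.
#' @export
call_mn <- function(summary, compound = NULL, fold_min = 2.50, alpha = 0.05) {
  stopifnot(inherits(summary, "microflow_summary"))
  wells <- summary$wells
  if (is.null(compound)) {
    compound <- unique(wells$compound[!wells$is_control])
    if (length(compound) != 1L) stop("multiple compounds present; supply `compound`")
  }
  trt <- wells[!wells$is_control & wells$compound == compound, , drop = FALSE]
  if (!nrow(trt)) stop("no treated wells for compound ", compound)
  agg <- summary$by_concentration
  agg <- agg[agg$compound == compound, , drop = FALSE]
  open <- agg[!agg$gated, , drop = FALSE]
  if (!nrow(open)) {
    return(structure(list(call = "undetermined", compound = compound,
                          evidence = agg), class = "mn_call"))
  }
  pvals <- vapply(seq_len(nrow(open)), function(i) {
    conc <- open$concentration[i]
    tw <- trt[trt$concentration == conc & !trt$gated, , drop = FALSE]
    cw <- wells[wells$is_control & wells$plate == open$plate[i], , drop = FALSE]
    poisson_lrt_p(c(cw$mn_events, tw$mn_events),
                  c(cw$nucleated_events, tw$nucleated_events),
                  factor(c(rep("control", nrow(cw)), rep("treated", nrow(tw))),
                         levels = c("control", "treated")))
  }, numeric(1))
  open$p_raw <- pvals
  open$p_adj <- holm_sidak(pvals)
  positive <- any(open$fold_mn >= fold_min & open$p_adj < alpha)
  structure(list(call = if (positive) "positive" else "negative",
                 compound = compound, evidence = open,
                 fold_min = fold_min, alpha = alpha),
            class = "mn_call")
}

#' @export
print.mn_call <- function(x, ...) {
  cat(sprintf("Micronucleus call for %s: %s\n", x$compound, toupper(x$call)))
  if (!is.null(x$evidence$p_adj)) {
    ev <- x$evidence
    cat(sprintf("  top evidence: fold %%MN %.2f, adjusted p %.3g\n",
                max(ev$fold_mn), min(ev$p_adj)))
  }
  invisible(x)
}
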