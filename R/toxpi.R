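#' Default ToxPi slice definitions
#'
#' The transcriptomic (TGx-DDI) and micronucleus BMCs each carry one third of
#' the profile; the four DNA-damage-response flow endpoints (4H/24H p53 and
#' 4H/24H gamma-H2AX) carry one twelfth each, together making the final third.
#'
#' @return Data frame with columns `slice` and `weight` (weights sum to 1).
#' @export
default_slices <- function() {
  data.frame(
    slice = c("tgxddi", "mn", "p53_4h", "p53_24h", "gh2ax_4h", "gh2ax_24h"),
    weight = c(1 / 3, 1 / 3, 1 / 12, 1 / 12, 1 / 12, 1 / 12),
    stringsAsFactors = FALSE
  )
}

#' ToxPi-style weighted potency scores from endpoint BMCs
#'
#' Converts a compound-by-endpoint table of BMC confidence limits into
#' normalized slice scores and an overall weighted score per compound.
#' Missing, infinite, or above-top BMC limits are substituted with
#' `substitution` (10,000 uM by default, i.e. "inactive"); all limits are
#' capped at the substitution value. Each limit is -log10 transformed, the
#' two transformed limits (BMCL and BMCU) are summed, the substitution-only
#' baseline is shifted to zero so inactive slices do not protrude, and each
#' slice is divided by its maximum across compounds to land in [0, 1]. The
#' overall score is the weight-sum of slice scores; its confidence interval
#' comes from rescoring with all-BMCL (upper) and all-BMCU (lower) inputs
#' against the same slice maxima. Ranks descend by overall score with ties
#' sharing a rank.
#'
#' @param bmc_table Data frame with columns `compound`, `slice`, `bmcl`,
#'   `bmcu` (uM). Absent compound/slice combinations are treated as inactive.
#' @param slices Slice definitions (see [default_slices()]); custom weights
#'   are re-normalized to sum to 1.
#' @param substitution Substitution/cap concentration in uM (default 10000).
#' @param transform_each Transform each confidence limit before summing
#'   (default `TRUE`); `FALSE` sums the two limits first and transforms the
#'   sum (offered because slice-score conventions differ on the order, though
#'   -log10 of a concentration sum has no potency interpretation).
#' @param anchor_baseline Shift the substitution-only baseline to zero so
#'   fully inactive slices do not protrude (default `TRUE`).
#' @return Object of class `toxpi_profiles`: `scores` (per-compound slice
#'   scores, `overall`, `ci_lower`, `ci_upper`, `rank`) and `slice_max`.
#' @export
score_profiles <- function(bmc_table, slices = default_slices(),
                           substitution = 10000, transform_each = TRUE,
                           anchor_baseline = TRUE) {
  bmc_table <- as.data.frame(bmc_table)
  if (!nrow(bmc_table)) stop("empty compound set")
  slices$weight <- slices$weight / sum(slices$weight)
  compounds <- unique(bmc_table$compound)

  clean <- function(v) {
    v[!is.finite(v) | is.na(v)] <- substitution
    if (any(v <= 0)) stop("non-positive BMC values are not allowed")
    pmin(v, substitution)
  }
  get_limits <- function(which_col) {
    m <- matrix(substitution, length(compounds), nrow(slices),
                dimnames = list(compounds, slices$slice))
    for (i in seq_len(nrow(bmc_table))) {
      r <- bmc_table[i, ]
      if (!r$slice %in% slices$slice) next
      m[as.character(r$compound), r$slice] <-
        if (is.null(r[[which_col]]) || is.na(r[[which_col]])) NA_real_ else r[[which_col]]
    }
    clean(m)
  }
  L <- get_limits("bmcl")
  U <- get_limits("bmcu")
  trans <- function(lo, up) {
    if (transform_each) (-log10(lo)) + (-log10(up)) else -log10(lo + up)
  }
  baseline <- if (anchor_baseline) {
    trans(substitution, substitution)
  } else 0
  raw <- function(lo, up) trans(lo, up) - baseline
  raw_pt <- raw(L, U)
  slice_max <- apply(raw_pt, 2, max)
  norm <- function(m) {
    out <- sweep(m, 2, ifelse(slice_max > 0, slice_max, 1), "/")
    pmin(pmax(out, 0), 1)
  }
  s_pt <- norm(raw_pt)
  s_hi <- norm(raw(L, L))   # all-BMCL: most potent reading
  s_lo <- norm(raw(U, U))   # all-BMCU: least potent reading

  overall <- as.numeric(s_pt %*% slices$weight)
  ci_hi <- as.numeric(s_hi %*% slices$weight)
  ci_lo <- as.numeric(s_lo %*% slices$weight)
  rk <- rank(-overall, ties.method = "min")
  scores <- data.frame(compound = compounds, s_pt, overall = overall,
                       ci_lower = ci_lo, ci_upper = ci_hi, rank = rk,
                       row.names = NULL, check.names = FALSE,
                       stringsAsFactors = FALSE)
  scores <- scores[order(scores$rank), , drop = FALSE]
  structure(list(scores = scores, slice_max = slice_max, slices = slices,
                 substitution = substitution),
            class = "toxpi_profiles")
}

#' Cluster ToxPi profiles
#'
#' Hierarchically clusters the per-slice score vectors (Euclidean distance,
#' average linkage) and cuts the tree into `k` groups (2 by default).
#'
#' @param profiles A `toxpi_profiles` object from [score_profiles()].
#' @param k Number of clusters (default 2).
#' @return List with the `hclust` tree and a named `cluster` vector; the
#'   cluster ids are also attached to a copy of the scores table.
#' @export
cluster_profiles <- function(profiles, k = 2) {
  stopifnot(inherits(profiles, "toxpi_profiles"))
  sc <- profiles$scores
  if (nrow(sc) < 2L) stop("need at least 2 profiles to cluster")
  m <- as.matrix(sc[, profiles$slices$slice, drop = FALSE])
  rownames(m) <- sc$compound
  # stable leaf order regardless of input order
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = "average")
  cl <- stats::cutree(hc, k = min(k, nrow(m)))
  sc$cluster <- cl[as.character(sc$compound)]
  list(tree = hc, cluster = cl, scores = sc)
}

#' @export
print.toxpi_profiles <- function(x, ...) {
  cat("ToxPi profiles (higher overall score = more potent)\n")
  print(x$scores[, c("compound", "overall", "ci_lower", "ci_upper", "rank")],
        row.names = FALSE)
  invisible(x)
}

#' Plot ToxPi slice scores
#'
#' Simple stacked-bar rendering of the per-slice weighted contributions per
#' compound (base graphics).
#'
#' @param x A `toxpi_profiles` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.toxpi_profiles <- function(x, ...) {
  m <- t(as.matrix(x$scores[, x$slices$slice, drop = FALSE]))
  m <- m * x$slices$weight
  colnames(m) <- x$scores$compound
  graphics::barplot(m, legend.text = x$slices$slice,
                    ylab = "weighted slice score", las = 2, ...)
  invisible(x)
}
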