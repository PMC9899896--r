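#' Construct a half-log (geometric) concentration series
#'
#' Builds the descending geometric concentration series used throughout the
#' screening workflow: `concentrations[i] = top * spacing_factor^(i-1)`. The
#' default spacing factor of 0.70711 (i.e. `1/sqrt(2)`) gives the classic
#' "half-log every two steps" design, so a 6-point series spans roughly one
#' and a half decades.
#'
#' @param top Top (highest) concentration in micromolar; must be positive.
#' @param n_points Number of concentrations in the series (>= 1).
#' @param spacing_factor Ratio between successive concentrations, in (0, 1).
#' @return An object of class `concentration_series`: a list with `top`,
#'   `n_points`, `spacing_factor` and the descending `concentrations` vector.
#' @examples
#' s <- build_series(10000, 6)
#' lowest_concentration(s)   # ~1768 uM
#' @export
build_series <- function(top, n_points, spacing_factor = 0.70711) {
  stopifnot(length(top) == 1L, length(n_points) == 1L, length(spacing_factor) == 1L)
  if (!is.finite(top) || top <= 0) {
    stop("`top` must be a positive concentration (uM)")
  }
  if (!is.finite(n_points) || n_points < 1 || n_points != round(n_points)) {
    stop("`n_points` must be a positive integer")
  }
  if (!is.finite(spacing_factor) || spacing_factor <= 0 || spacing_factor >= 1) {
    stop("`spacing_factor` must lie strictly between 0 and 1")
  }
  conc <- top * spacing_factor^(seq_len(n_points) - 1L)
  structure(
    list(top = top, n_points = as.integer(n_points),
         spacing_factor = spacing_factor, concentrations = conc),
    class = "concentration_series"
  )
}

#' Lowest concentration of a series
#'
#' @param series A `concentration_series` from [build_series()].
#' @return `top * spacing_factor^(n_points - 1)`, in micromolar.
#' @export
lowest_concentration <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  series$concentrations[series$n_points]
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("Concentration series: %d points, spacing %.5f\n",
              x$n_points, x$spacing_factor))
  cat("  ", paste(signif(x$concentrations, 4), collapse = ", "), " uM\n", sep = "")
  invisible(x)
}

#' Select an assay's top concentration from a viability screen
#'
#' Scans tested candidate concentrations (descending) and returns the highest
#' one whose viability meets the assay-specific threshold: 40% viability for
#' the transcriptomic (TGx-DDI) and micronucleus assays, 20% for the
#' multiplexed DNA-damage assay. Non-cytotoxic chemicals are tested up to a
#' solubility-motivated cap (10 mM by default). Selection is restricted to the
#' tested concentrations; viability is never interpolated between them.
#'
#' @param viability Named numeric vector: percent viability (0-100) at each
#'   tested candidate concentration. Names (or `concentrations`) give the
#'   candidate concentrations in micromolar.
#' @param assay One of `"TGxDDI"`, `"MicroFlow"`, `"MultiFlow"`.
#' @param concentrations Optional numeric vector of candidate concentrations;
#'   defaults to `as.numeric(names(viability))`.
#' @param cap_uM Upper cap on the returned concentration (default 10000 uM).
#' @return The selected top concentration in micromolar.
#' @export
select_top_concentration <- function(viability,
                                     assay = c("TGxDDI", "MicroFlow", "MultiFlow"),
                                     concentrations = NULL,
                                     cap_uM = 10000) {
  assay <- match.arg(assay)
  if (length(viability) == 0L) stop("empty viability curve")
  if (is.null(concentrations)) concentrations <- as.numeric(names(viability))
  if (length(concentrations) != length(viability) || anyNA(concentrations)) {
    stop("candidate concentrations missing or mismatched with viability values")
  }
  if (any(viability < 0 | viability > 100, na.rm = TRUE)) {
    stop("viability values must lie in [0, 100]")
  }
  threshold <- if (assay == "MultiFlow") 20 else 40
  ord <- order(concentrations, decreasing = TRUE)
  concentrations <- concentrations[ord]
  viability <- viability[ord]
  if (all(viability >= threshold)) {
    # chemical is not cytotoxic over the tested range: test up to the cap
    return(cap_uM)
  }
  ok <- viability >= threshold
  if (!any(ok)) stop("no tested concentration meets the viability threshold")
  min(concentrations[which(ok)[1L]], cap_uM)
}
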