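# Benchmark-concentration modeling: trend prefilter, continuous model family
# with AIC selection, bootstrap confidence limits, gene-set median BMC, and
# relative-increase (CES) BMCs for flow-cytometry endpoints.

# weighted pool-adjacent-violators: isotonic increasing fit to `means` with
# weights `w`; returns fitted block means
pava <- function(means, w) {
  n <- length(means)
  val <- means; wt <- w; idx <- rep(seq_len(n), 1)
  # block representation
  vals <- means; wts <- w; sizes <- rep(1L, n); nb <- n
  i <- 1L
  while (i < nb) {
    if (vals[i] > vals[i + 1L]) {
      merged <- (vals[i] * wts[i] + vals[i + 1L] * wts[i + 1L]) / (wts[i] + wts[i + 1L])
      vals[i] <- merged
      wts[i] <- wts[i] + wts[i + 1L]
      sizes[i] <- sizes[i] + sizes[i + 1L]
      vals <- vals[-(i + 1L)]; wts <- wts[-(i + 1L)]; sizes <- sizes[-(i + 1L)]
      nb <- nb - 1L
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  rep(vals, sizes)
}

williams_stat <- function(y, group, n_per_group, pooled_var) {
  means <- tapply(y, group, mean)
  k <- length(means)
  iso_up <- pava(as.numeric(means), n_per_group)
  iso_dn <- -pava(-as.numeric(means), n_per_group)
  se <- sqrt(pooled_var * (1 / n_per_group[k] + 1 / n_per_group[1L]))
  t_up <- (iso_up[k] - means[1L]) / se
  t_dn <- (iso_dn[k] - means[1L]) / se
  if (abs(t_up) >= abs(t_dn)) t_up else t_dn
}

#' Williams-type trend test with permutation p-value
#'
#' Tests for a monotone concentration-response trend. The statistic compares
#' the isotonic-regression estimate of the highest-concentration group mean
#' (under a monotone ordering, amalgamated by pool-adjacent-violators with
#' group-size weights) with the control mean, standardized by the pooled
#' within-group variance: `t = (mu_iso_top - mu_0) / sqrt(s^2 (1/n_top + 1/n_0))`.
#' Both monotone orientations are evaluated and the larger magnitude is kept.
#' Significance comes from random permutations of responses across groups:
#' `p = (1 + #{|t*| >= |t|}) / (1 + n_perm)`.
#'
#' @param x Concentration per observation (control = 0, or the lowest value).
#' @param y Response per observation.
#' @param n_perm Number of permutations (default 500).
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
williams_trend_test <- function(x, y, n_perm = 500) {
  stopifnot(length(x) == length(y), n_perm >= 1)
  group <- factor(x, levels = sort(unique(x)))
  if (nlevels(group) < 2L) stop("need at least 2 concentration groups")
  n_per_group <- as.numeric(table(group))
  n <- length(y)
  k <- nlevels(group)
  within_ss <- sum((y - ave(y, group))^2)
  if (n - k <= 0 || within_ss == 0) stop("zero pooled within-group variance")
  s2 <- within_ss / (n - k)
  t_obs <- williams_stat(y, group, n_per_group, s2)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    s2p <- sum((yp - ave(yp, group))^2) / (n - k)
    if (s2p == 0) { exceed <- exceed + 1L; next }
    if (abs(williams_stat(yp, group, n_per_group, s2p)) >= abs(t_obs)) {
      exceed <- exceed + 1L
    }
  }
  list(statistic = unname(t_obs), p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm)
}

# ---- continuous dose-response model family ---------------------------------
# Each fit uses profiled least squares: parameters entering the mean linearly
# are solved exactly; the remaining 1-2 nonlinear parameters are searched
# numerically. Constant-variance Gaussian likelihood, so the ML optimum is
# the least-squares optimum.

lin_profile <- function(X, y) {
  cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, ncol(X)))
  cf[is.na(cf)] <- 0
  r <- y - X %*% cf
  list(coef = cf, sse = sum(r * r))
}

# intercept + single regressor: closed-form least squares, hot path of the
# profiled exponential fits
lin2_profile <- function(e, y) {
  n <- length(y)
  me <- mean(e); my <- mean(y)
  see <- sum(e * e) - n * me * me
  if (see <= 0) {
    b <- 0; a <- my
  } else {
    b <- (sum(e * y) - n * me * my) / see
    a <- my - b * me
  }
  r <- y - a - b * e
  list(coef = c(a, b), sse = sum(r * r))
}

fit_model_linear <- function(x, y) {
  pr <- lin_profile(cbind(1, x), y)
  list(name = "Linear", npar = 2L, sse = pr$sse,
       par = c(a = unname(pr$coef[1L]), b = unname(pr$coef[2L])),
       f = function(z) pr$coef[1L] + pr$coef[2L] * z)
}

# quadratic with same-sign (monotone-on-[0, xmax]) coefficient restriction,
# as in the restricted continuous BMDS forms: both dose coefficients >= 0
# (increasing) or both <= 0 (decreasing)
fit_model_poly2 <- function(x, y) {
  un <- lin_profile(cbind(1, x, x^2), y)
  b <- un$coef[2L]; cc <- un$coef[3L]
  if (sign(b) * sign(cc) >= 0) {
    pr <- un
  } else {
    cand <- list(lin_profile(cbind(1, x), y), lin_profile(cbind(1, x^2), y))
    pick <- which.min(vapply(cand, `[[`, numeric(1), "sse"))
    pr <- cand[[pick]]
    pr$coef <- if (pick == 1L) c(pr$coef, 0) else c(pr$coef[1L], 0, pr$coef[2L])
  }
  list(name = "Poly2", npar = 3L, sse = pr$sse,
       par = c(a = unname(pr$coef[1L]), b = unname(pr$coef[2L]),
               c = unname(pr$coef[3L])),
       f = function(z) pr$coef[1L] + pr$coef[2L] * z + pr$coef[3L] * z^2)
}

fit_model_power <- function(x, y) {
  obj <- function(g) lin2_profile(x^g, y)$sse
  opt <- stats::optimize(obj, c(1, 8))
  g <- if (obj(1) <= opt$objective) 1 else opt$minimum
  pr <- lin2_profile(x^g, y)
  list(name = "Power", npar = 3L, sse = pr$sse,
       par = c(a = unname(pr$coef[1L]), b = unname(pr$coef[2L]), g = g),
       f = function(z) pr$coef[1L] + pr$coef[2L] * z^g)
}

fit_model_exp2 <- function(x, y) {
  xmax <- max(x[x > 0])
  prof <- function(b) {
    e <- exp(pmin(b * x, 500))
    a <- sum(y * e) / sum(e * e)
    list(a = a, sse = sum((y - a * e)^2))
  }
  obj <- function(b) prof(b)$sse
  opt <- stats::optimize(obj, c(-30 / xmax, 30 / xmax))
  b <- opt$minimum
  pr <- prof(b)
  list(name = "Exp2", npar = 2L, sse = pr$sse, par = c(a = pr$a, b = b),
       f = function(z) pr$a * exp(pmin(b * z, 500)))
}

# shared machinery for Exp3 (y = a exp(s (b x)^d)) and Exp5
# (y = alpha + beta exp(-(b x)^d)); d >= 1, b > 0
fit_model_exp3 <- function(x, y) {
  xmax <- max(x[x > 0])
  best <- NULL
  for (s in c(1, -1)) {
    prof <- function(th) {
      b <- exp(th[1L]); d <- 1 + exp(th[2L])
      e <- exp(pmin(s * (b * x)^d, 500))
      a <- sum(y * e) / sum(e * e)
      sum((y - a * e)^2)
    }
    for (start in list(c(log(1 / xmax), log(0.5)), c(log(0.3 / xmax), -2))) {
      opt <- stats::optim(start, prof, method = "Nelder-Mead",
                          control = list(maxit = 300))
      if (is.null(best) || opt$value < best$value) {
        best <- list(value = opt$value, par = opt$par, s = s)
      }
    }
  }
  b <- exp(best$par[1L]); d <- 1 + exp(best$par[2L]); s <- best$s
  e <- exp(pmin(s * (b * x)^d, 500))
  a <- sum(y * e) / sum(e * e)
  list(name = "Exp3", npar = 3L, sse = sum((y - a * e)^2),
       par = c(a = a, b = b, d = d, sign = s),
       f = function(z) a * exp(pmin(s * (b * z)^d, 500)))
}

exp45_profile <- function(x, y, b, d) {
  u <- (b * x)^d
  u[u > 500] <- 500
  pr <- lin2_profile(exp(-u), y)
  list(alpha = unname(pr$coef[1L]), beta = unname(pr$coef[2L]), sse = pr$sse)
}

fit_model_exp4 <- function(x, y) {
  xmax <- max(x[x > 0])
  obj <- function(lb) exp45_profile(x, y, exp(lb), 1)$sse
  opt <- stats::optimize(obj, c(log(0.01 / xmax), log(100 / xmax)))
  b <- exp(opt$minimum)
  pr <- exp45_profile(x, y, b, 1)
  a <- pr$alpha + pr$beta
  list(name = "Exp4", npar = 3L, sse = pr$sse,
       par = c(a = a, b = b, c = if (a != 0) pr$alpha / a else NA_real_),
       f = function(z) pr$alpha + pr$beta * exp(-pmin(b * z, 500)))
}

fit_model_exp5 <- function(x, y) {
  xmax <- max(x[x > 0])
  best <- NULL
  obj <- function(th) exp45_profile(x, y, exp(th[1L]), 1 + exp(th[2L]))$sse
  for (start in list(c(log(1 / xmax), log(0.5)), c(log(0.3 / xmax), -2),
                     c(log(3 / xmax), 0.5))) {
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 400))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  b <- exp(best$par[1L]); d <- 1 + exp(best$par[2L])
  pr <- exp45_profile(x, y, b, d)
  a <- pr$alpha + pr$beta
  list(name = "Exp5", npar = 4L, sse = pr$sse,
       par = c(a = a, b = b, c = if (a != 0) pr$alpha / a else NA_real_, d = d),
       f = function(z) pr$alpha + pr$beta * exp(-pmin((b * z)^d, 500)))
}

model_family <- function() {
  list(Exp2 = fit_model_exp2, Exp3 = fit_model_exp3, Exp4 = fit_model_exp4,
       Exp5 = fit_model_exp5, Linear = fit_model_linear,
       Poly2 = fit_model_poly2, Power = fit_model_power)
}

# solve |f(x) - f(0)| = target over (0, xmax]; extend to 10*xmax if needed.
# returns list(bmc, over_range)
solve_bmc_absolute <- function(f, target, xmax) {
  g <- function(z) abs(f(z) - f(0)) - target
  solve_on <- function(hi) {
    grid <- exp(seq(log(xmax * 1e-6), log(hi), length.out = 200L))
    gv <- vapply(grid, g, numeric(1))
    pos <- which(gv >= 0)
    if (!length(pos)) return(NA_real_)
    i <- pos[1L]
    lo <- if (i == 1L) 0 else grid[i - 1L]
    stats::uniroot(g, c(lo, grid[i]), tol = xmax * 1e-9)$root
  }
  bmc <- solve_on(xmax)
  over <- FALSE
  if (is.na(bmc)) {
    bmc <- solve_on(10 * xmax)
    over <- !is.na(bmc)
    if (is.na(bmc)) return(list(bmc = NA_real_, over_range = FALSE))
  }
  list(bmc = bmc, over_range = over || bmc > xmax)
}

lack_of_fit_p <- function(x, y, sse_model, npar_mean) {
  group <- factor(x)
  g <- nlevels(group)
  n <- length(y)
  sse_sat <- sum((y - ave(y, group))^2)
  df1 <- g - npar_mean
  df2 <- n - g
  if (df1 <= 0 || df2 <= 0 || sse_sat <= 0) return(NA_real_)
  f_stat <- ((sse_model - sse_sat) / df1) / (sse_sat / df2)
  stats::pf(max(f_stat, 0), df1, df2, lower.tail = FALSE)
}

#' Fit the continuous dose-response model family and derive a BMC
#'
#' Fits exponential models 2-5, linear, quadratic polynomial and restricted
#' power (exponent >= 1) models by maximum likelihood under constant-variance
#' Gaussian noise (equivalently least squares; linear parameters are profiled
#' exactly and the remaining nonlinear parameters searched numerically).
#' The best model minimizes AIC = 2k - 2 lnL with k = mean-parameter count
#' plus one for the variance. The benchmark concentration solves
#' `|f(BMC) - f(0)| = bmr_sd * sigma_hat`, with `sigma_hat` the modeled
#' residual standard deviation. Confidence limits come from a nonparametric
#' bootstrap that resamples replicates within concentration and refits the
#' selected model. A lack-of-fit F test against the saturated group-means
#' model yields the fit-adequacy p-value.
#'
#' @param x Concentrations per observation (include control at 0).
#' @param y Responses per observation.
#' @param bmr_sd Benchmark response in residual-SD units (default 1).
#' @param n_boot Bootstrap refits for the confidence limits (default 250).
#' @param models Optional character subset of the family to fit.
#' @param bmr_abs Optional absolute benchmark response on the response scale;
#'   overrides `bmr_sd * sigma_hat` when supplied (useful when the response
#'   change of interest is known a priori).
#' @return Object of class `bmc_fit` with elements `model`, `par`, `aic`
#'   (table over the family), `bmc`, `bmcl`, `bmcu`, `fit_p`, `flags`.
#' @export
fit_dose_response_family <- function(x, y, bmr_sd = 1, n_boot = 250,
                                     models = NULL, bmr_abs = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (!any(x == 0)) stop("a control group (x = 0) is required")
  if (length(unique(x)) < 3L) stop("need >= 2 treated concentrations plus control")
  fam <- model_family()
  if (!is.null(models)) fam <- fam[models]
  n <- length(y)
  fits <- lapply(fam, function(ff) {
    tryCatch(ff(x, y), error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) {
    return(structure(list(model = NA_character_, bmc = NA_real_,
                          flags = "no-fit"), class = "bmc_fit"))
  }
  aic <- vapply(fits, function(ft) {
    sigma2 <- ft$sse / n
    lnl <- -n / 2 * (log(2 * pi * sigma2) + 1)
    2 * (ft$npar + 1) - 2 * lnl
  }, numeric(1))
  best <- fits[[which.min(aic)]]
  # bias-corrected residual SD for the benchmark target (the ML variance
  # SSE/n is noticeably low at the small n of a concentration series)
  sigma_hat <- sqrt(best$sse / max(n - best$npar, 1L))
  flags <- character(0)
  if (sigma_hat == 0) sigma_hat <- .Machine$double.eps
  xmax <- max(x)
  target <- if (is.null(bmr_abs)) bmr_sd * sigma_hat else bmr_abs
  sol <- solve_bmc_absolute(best$f, target, xmax)
  if (is.na(sol$bmc)) flags <- c(flags, "flat-or-undefined")
  if (sol$over_range) flags <- c(flags, "bmc-above-top-concentration")
  fit_p <- lack_of_fit_p(x, y, best$sse, best$npar)

  bmcl <- bmcu <- NA_real_
  if (!is.na(sol$bmc) && n_boot > 0) {
    refit <- fam[[best$name]]
    groups <- split(seq_along(x), x)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(groups, function(g) g[sample.int(length(g), replace = TRUE)]),
                    use.names = FALSE)
      ft <- tryCatch(refit(x[idx], y[idx]), error = function(e) NULL)
      if (is.null(ft)) return(NA_real_)
      sg <- sqrt(ft$sse / max(length(idx) - ft$npar, 1L))
      tb <- if (is.null(bmr_abs)) bmr_sd * max(sg, .Machine$double.eps) else bmr_abs
      solve_bmc_absolute(ft$f, tb, xmax)$bmc
    }, numeric(1))
    ok <- boots[!is.na(boots)]
    if (length(ok) >= n_boot / 2) {
      q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
      bmcl <- q[1L]; bmcu <- q[2L]
    } else {
      flags <- c(flags, "bootstrap-unstable")
    }
  }
  structure(list(model = best$name, par = best$par, sse = best$sse,
                 sigma = sigma_hat, aic = aic, bmc = sol$bmc,
                 bmcl = bmcl, bmcu = bmcu, fit_p = fit_p,
                 flags = if (length(flags)) flags else "",
                 f = best$f, n = n, bmr_sd = bmr_sd),
            class = "bmc_fit")
}

#' @export
print.bmc_fit <- function(x, ...) {
  if (is.na(x$model)) {
    cat("Dose-response fit: no model converged\n")
    return(invisible(x))
  }
  cat(sprintf("Dose-response fit: best model %s (AIC %.2f)\n",
              x$model, min(x$aic)))
  cat(sprintf("  BMC %.4g [%.4g, %.4g] uM%s\n", x$bmc, x$bmcl, x$bmcu,
              if (nzchar(x$flags[1L])) paste0("  flags: ", paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' @export
coef.bmc_fit <- function(object, ...) object$par

#' @export
predict.bmc_fit <- function(object, newdata, ...) {
  if (is.na(object$model)) stop("no fitted model")
  object$f(newdata)
}

#' Apply the gene-level BMC quality filters
#'
#' Removes gene BMCs when the model fit is inadequate (fit p-value < 0.1),
#' or the confidence-limit ratios are extreme: BMC/BMCL >= 20, BMCU/BMC >= 20,
#' or BMCU/BMCL >= 40.
#'
#' @param fits Data frame with columns `bmc`, `bmcl`, `bmcu`, `fit_p`.
#' @param fit_p_min Lack-of-fit p threshold (default 0.1).
#' @param bmc_bmcl_max,bmcu_bmc_max,bmcu_bmcl_max Ratio thresholds
#'   (defaults 20, 20, 40).
#' @return The input with logical columns `removed` and a `removed_by` reason.
#' @export
filter_gene_bmcs <- function(fits, fit_p_min = 0.1, bmc_bmcl_max = 20,
                             bmcu_bmc_max = 20, bmcu_bmcl_max = 40) {
  fits <- as.data.frame(fits)
  reason <- rep("", nrow(fits))
  has_ci <- !is.na(fits$bmcl) & !is.na(fits$bmcu)
  r_ll <- ifelse(has_ci & fits$bmcl > 0, fits$bmc / fits$bmcl, Inf)
  r_ub <- ifelse(has_ci & fits$bmc > 0, fits$bmcu / fits$bmc, Inf)
  r_ul <- ifelse(has_ci & fits$bmcl > 0, fits$bmcu / fits$bmcl, Inf)
  bad_fit <- !is.na(fits$fit_p) & fits$fit_p < fit_p_min
  reason[r_ul >= bmcu_bmcl_max] <- "bmcu/bmcl"
  reason[r_ub >= bmcu_bmc_max] <- "bmcu/bmc"
  reason[r_ll >= bmc_bmcl_max] <- "bmc/bmcl"
  reason[bad_fit] <- "fit-p"
  reason[is.na(fits$bmc)] <- "no-bmc"
  fits$removed <- nzchar(reason)
  fits$removed_by <- reason
  fits
}

#' Gene-set median benchmark concentration with bootstrap interval
#'
#' Runs the full gene-level BMC recipe over a biomarker panel: a Williams
#' trend permutation prefilter (p < `williams_alpha`) combined with a linear
#' fold-change floor (max over concentrations of `2^|mean log2 difference
#' from control|` at least `fold_change_floor`), model-family fitting with
#' AIC selection for every passing gene, the four quality filters of
#' [filter_gene_bmcs()], and finally the median of surviving gene BMCs with a
#' 95\% interval from bootstrap resampling (with replacement) of the surviving
#' BMC set.
#'
#' @param gene_data Named list: per gene, a data frame/list with numeric `x`
#'   (concentrations, control = 0) and `y` (log2-scale response per replicate).
#' @param fold_change_floor Linear fold-change prefilter floor (default 1.5).
#' @param williams_alpha Trend-test permutation p cutoff (default 0.05).
#' @param n_perm Permutations for the trend test (default 500).
#' @param n_boot Bootstrap resamples for the median interval (default 2000).
#' @param n_boot_fit Bootstrap refits per gene for its confidence limits
#'   (default 100).
#' @param bmr_sd Benchmark response in SD units (default 1).
#' @return Object of class `gene_set_bmc`: `median_bmc`, `ci`, per-gene `fits`
#'   table, and `counts` of genes removed at each stage. `median_bmc` is `NA`
#'   when no gene survives.
#' @export
gene_set_bmc <- function(gene_data, fold_change_floor = 1.5,
                         williams_alpha = 0.05, n_perm = 500, n_boot = 2000,
                         n_boot_fit = 100, bmr_sd = 1) {
  stopifnot(length(gene_data) >= 1L)
  genes <- names(gene_data)
  if (is.null(genes)) genes <- paste0("g", seq_along(gene_data))

  pre <- lapply(gene_data, function(d) {
    x <- d$x; y <- d$y
    gm <- tapply(y, factor(x, levels = sort(unique(x))), mean)
    maxfc <- max(2^abs(gm[-1L] - gm[1L]))
    wp <- tryCatch(williams_trend_test(x, y, n_perm = n_perm)$p_value,
                   error = function(e) NA_real_)
    list(maxfc = maxfc, williams_p = wp,
         pass = !is.na(wp) && wp < williams_alpha && maxfc >= fold_change_floor)
  })
  passed <- vapply(pre, `[[`, logical(1), "pass")

  fit_rows <- lapply(seq_along(gene_data), function(i) {
    base <- data.frame(gene = genes[i],
                       williams_p = pre[[i]]$williams_p,
                       max_fold_change = pre[[i]]$maxfc,
                       prefilter_pass = passed[i],
                       model = NA_character_, bmc = NA_real_, bmcl = NA_real_,
                       bmcu = NA_real_, fit_p = NA_real_, flags = "",
                       stringsAsFactors = FALSE)
    if (!passed[i]) return(base)
    ft <- fit_dose_response_family(gene_data[[i]]$x, gene_data[[i]]$y,
                                   bmr_sd = bmr_sd, n_boot = n_boot_fit)
    base$model <- ft$model
    base$bmc <- ft$bmc; base$bmcl <- ft$bmcl; base$bmcu <- ft$bmcu
    base$fit_p <- if (is.null(ft$fit_p)) NA_real_ else ft$fit_p
    base$flags <- paste(ft$flags, collapse = ";")
    base
  })
  fits <- do.call(rbind, fit_rows)

  cand <- fits[fits$prefilter_pass & !is.na(fits$bmc), , drop = FALSE]
  cand <- filter_gene_bmcs(cand)
  surviving <- cand$bmc[!cand$removed]

  counts <- c(total = length(gene_data),
              prefilter_removed = sum(!passed),
              no_bmc = sum(fits$prefilter_pass & is.na(fits$bmc)),
              filter_removed = sum(cand$removed),
              surviving = length(surviving))

  if (!length(surviving)) {
    return(structure(list(median_bmc = NA_real_, ci = c(NA_real_, NA_real_),
                          fits = merge_filter(fits, cand), counts = counts),
                     class = "gene_set_bmc"))
  }
  med <- stats::median(surviving)
  boots <- vapply(seq_len(n_boot), function(b) {
    stats::median(sample(surviving, replace = TRUE))
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  structure(list(median_bmc = med, ci = ci, fits = merge_filter(fits, cand),
                 surviving = surviving, counts = counts),
            class = "gene_set_bmc")
}

merge_filter <- function(fits, cand) {
  fits$removed_by <- cand$removed_by[match(fits$gene, cand$gene)]
  fits$removed_by[is.na(fits$removed_by) & !fits$prefilter_pass] <- "prefilter"
  fits$removed_by[is.na(fits$removed_by)] <- ""
  fits
}

#' @export
print.gene_set_bmc <- function(x, ...) {
  cat("Gene-set benchmark concentration\n")
  if (is.na(x$median_bmc)) {
    cat("  no surviving genes\n")
  } else {
    cat(sprintf("  median BMC %.4g uM, 95%% CI [%.4g, %.4g] (%d genes)\n",
                x$median_bmc, x$ci[1L], x$ci[2L], x$counts[["surviving"]]))
  }
  print(x$counts)
  invisible(x)
}

# ---- relative-increase (CES) BMC for flow endpoints ------------------------

#' Fit the 5-parameter exponential model for a relative-increase BMC
#'
#' Fits `y = a * [c - (c - 1) exp(-(x/b)^d)]` (a > 0, c >= 1, b > 0, d >= 1)
#' to positive fold-change or percent-scale responses and solves
#' `f(BMC)/f(0) - 1 = ces` for the benchmark concentration; the closed form is
#' `BMC = b * (-log((c - 1 - ces)/(c - 1)))^(1/d)` whenever the fitted plateau
#' exceeds the target (`c - 1 > ces`), otherwise the BMC is undefined and
#' flagged. Confidence limits are bootstrap percentiles from refitting
#' resampled replicates within concentration.
#'
#' @param x Concentrations (control at 0).
#' @param y Positive responses (fold-change over control, or percent scale).
#' @param ces Relative increase defining the benchmark response (e.g. 1.0 for
#'   a 100\% increase, 0.5 for 50\%); must be > 0.
#' @param n_boot Bootstrap refits (default 250).
#' @return Object of class `bmc_fit` (model `"Exp5-CES"`).
#' @export
fit_relative_bmc <- function(x, y, ces, n_boot = 250) {
  stopifnot(length(x) == length(y))
  if (!is.finite(ces) || ces <= 0) stop("`ces` must be positive")
  if (any(y <= 0)) stop("responses must be positive on a fold or percent scale")
  if (!any(x == 0)) stop("a control group (x = 0) is required")

  fit_once <- function(x, y) {
    xmax <- max(x[x > 0])
    obj <- function(th) {
      pr <- exp45_profile(x, y, exp(th[1L]), 1 + exp(th[2L]))
      # monotone-increasing constraint: beta <= 0, f(0) = alpha + beta > 0
      pen <- 0
      if (pr$beta > 0) pen <- 1e6 * pr$beta^2
      pr$sse + pen
    }
    best <- NULL
    for (start in list(c(log(1 / xmax), log(0.5)), c(log(0.2 / xmax), -2),
                       c(log(5 / xmax), 0))) {
      opt <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 400))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    brate <- exp(best$par[1L]); d <- 1 + exp(best$par[2L])
    pr <- exp45_profile(x, y, brate, d)
    if (pr$beta > 0) {  # flat fallback
      pr$alpha <- mean(y); pr$beta <- 0
      pr$sse <- sum((y - pr$alpha)^2)
    }
    a <- pr$alpha + pr$beta
    cpar <- if (a > 0) pr$alpha / a else NA_real_
    list(a = a, b = 1 / brate, c = cpar, d = d, sse = pr$sse,
         f = function(z) pr$alpha + pr$beta * exp(-pmin((brate * z)^d, 500)))
  }

  solve_ces <- function(ft) {
    if (is.na(ft$c) || ft$c - 1 <= ces) return(NA_real_)
    ft$b * (-log((ft$c - 1 - ces) / (ft$c - 1)))^(1 / ft$d)
  }

  ft <- fit_once(x, y)
  bmc <- solve_ces(ft)
  flags <- character(0)
  xmax <- max(x)
  if (is.na(bmc)) flags <- c(flags, "plateau-below-ces")
  if (!is.na(bmc) && bmc > xmax) flags <- c(flags, "bmc-above-top-concentration")

  bmcl <- bmcu <- NA_real_
  if (!is.na(bmc) && n_boot > 0) {
    groups <- split(seq_along(x), x)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(groups, function(g) g[sample.int(length(g), replace = TRUE)]),
                    use.names = FALSE)
      solve_ces(tryCatch(fit_once(x[idx], y[idx]), error = function(e)
        list(c = NA_real_)))
    }, numeric(1))
    ok <- boots[!is.na(boots)]
    if (length(ok) >= n_boot / 2) {
      q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
      bmcl <- q[1L]; bmcu <- q[2L]
    } else flags <- c(flags, "bootstrap-unstable")
  }
  n <- length(y)
  structure(list(model = "Exp5-CES", par = c(a = ft$a, b = ft$b, c = ft$c, d = ft$d),
                 sse = ft$sse, sigma = sqrt(ft$sse / n), aic = NA_real_,
                 bmc = bmc, bmcl = bmcl, bmcu = bmcu,
                 fit_p = lack_of_fit_p(x, y, ft$sse, 4L),
                 flags = if (length(flags)) flags else "",
                 f = ft$f, n = n, ces = ces),
            class = "bmc_fit")
}

#' Overall BMC from a set of biomarker fits
#'
#' Reduces a list of biomarker `bmc_fit` objects to the fit with the lowest
#' defined BMC (the most sensitive endpoint). Undefined BMCs are ignored;
#' the result is `NULL` when none is defined.
#'
#' @param fits Named list of `bmc_fit` objects.
#' @return The minimum-BMC fit with an added `endpoint` element, or `NULL`.
#' @export
lowest_bmc <- function(fits) {
  bmcs <- vapply(fits, function(ft) if (is.null(ft$bmc)) NA_real_ else ft$bmc,
                 numeric(1))
  if (all(is.na(bmcs))) return(NULL)
  i <- which.min(bmcs)
  out <- fits[[i]]
  out$endpoint <- names(fits)[i]
  out
}
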