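test_that("Williams statistic detects a maximal trend", {
  set.seed(61)
  x <- rep(c(0, 1, 2, 3), each = 3)
  y <- rep(c(0, 1, 2, 3), each = 3) + rnorm(12, sd = 1e-3)
  res <- williams_trend_test(x, y, n_perm = 200)
  expect_equal(res$p_value, 1 / 201, tolerance = 0.02)
})

test_that("Williams permutation p matches exhaustive enumeration on a tiny case", {
  set.seed(62)
  x <- rep(c(0, 1, 2), each = 2)
  y <- c(0.3, 1.1, 0.8, 1.7, 1.2, 0.1)
  group <- factor(x)
  nper <- as.numeric(table(group))
  stat <- function(yy) {
    s2 <- sum((yy - ave(yy, group))^2) / (length(yy) - nlevels(group))
    gtxscreen:::williams_stat(yy, group, nper, s2)
  }
  t_obs <- abs(stat(y))
  perms <- all_perms(6)
  exhaustive <- mean(apply(perms, 1, function(p) abs(stat(y[p])) >= t_obs - 1e-12))
  res <- williams_trend_test(x, y, n_perm = 1999)
  expect_equal(res$p_value, exhaustive, tolerance = 0.04)
})

test_that("Williams p-values are well calibrated under the null", {
  set.seed(63)
  pvals <- replicate(150, {
    y <- rnorm(12)
    williams_trend_test(rep(c(0, 1, 2, 3), each = 3), y, n_perm = 79)$p_value
  })
  expect_lte(mean(pvals < 0.05), 0.09)   # nominal 5% within sampling error
  expect_gt(mean(pvals), 0.42)
  expect_lt(mean(pvals), 0.60)
  expect_error(williams_trend_test(rep(c(0, 1), each = 2), rep(1, 4)),
               "zero pooled")
})

test_that("noiseless five-parameter exponential data recover the analytic BMC", {
  x <- rep(c(0, 12.5, 25, 50, 100, 200), each = 3)
  a <- 8; cc <- 1.5; b <- 1 / 60; d <- 1.8
  f_true <- function(z) a * (cc - (cc - 1) * exp(-(b * z)^d))
  set.seed(64)
  y <- f_true(x) + rnorm(length(x), sd = 1e-4)
  ft <- fit_dose_response_family(x, y, n_boot = 0)
  # oracle: root of |f_true(z) - f_true(0)| = fitted residual SD
  oracle <- uniroot(function(z) abs(f_true(z) - f_true(0)) - ft$sigma,
                    c(1e-6, 200))$root
  expect_equal(ft$bmc, oracle, tolerance = 0.01)
  expect_match(ft$model, "Exp")
})

test_that("model nesting and degenerate inputs behave correctly", {
  set.seed(65)
  x <- rep(c(0, 5, 10, 20, 40), each = 3)
  y <- 2 + 0.05 * x + rnorm(15, sd = 0.2)
  fits <- lapply(gtxscreen:::model_family(), function(ff) ff(x, y))
  # richer nested models never fit worse in SSE
  expect_lte(fits$Poly2$sse, fits$Linear$sse + 1e-9)
  expect_lte(fits$Power$sse, fits$Linear$sse + 1e-9)
  expect_lte(fits$Exp5$sse, fits$Exp4$sse + 1e-9)

  # flat data: BMC undefined and flagged
  yflat <- rep(3, 15) + rnorm(15, sd = 1e-9)
  ftf <- fit_dose_response_family(x, yflat, n_boot = 0)
  expect_true(is.na(ftf$bmc) || ftf$bmc > max(x))
  expect_error(fit_dose_response_family(c(1, 2, 3), c(1, 2, 3)), "control")
})

test_that("BMC estimates are scale-equivariant in concentration", {
  set.seed(66)
  x <- rep(c(0, 5, 10, 20, 40, 80), each = 2)
  y <- 1 + 2 * (1 - exp(-(x / 30)^1.5)) + rnorm(length(x), sd = 0.1)
  set.seed(1); f1 <- fit_dose_response_family(x, y, n_boot = 50)
  set.seed(1); f2 <- fit_dose_response_family(x * 7, y, n_boot = 50)
  expect_equal(f2$bmc / f1$bmc, 7, tolerance = 1e-4)
  expect_equal(f2$bmcl / f1$bmcl, 7, tolerance = 1e-4)
  expect_equal(f2$bmcu / f1$bmcu, 7, tolerance = 1e-4)
})

test_that("the relative-increase BMC matches its closed form", {
  x <- rep(c(0, 5, 10, 20, 40, 80), each = 2)
  b <- 15
  y <- 3 - 2 * exp(-x / b)          # a = 1, c = 3, d = 1
  ft <- fit_relative_bmc(x, y, ces = 1.0, n_boot = 0)
  expect_equal(ft$bmc, b * log(2), tolerance = 1e-3)

  expect_error(fit_relative_bmc(x, y, ces = 0), "positive")
  expect_error(fit_relative_bmc(x, y - 5, ces = 1), "positive")

  # plateau below the target: 30% max increase cannot reach CES = 1
  y2 <- 1.3 - 0.3 * exp(-x / b)
  ft2 <- fit_relative_bmc(x, y2, ces = 1.0, n_boot = 0)
  expect_true(is.na(ft2$bmc))
  expect_true("plateau-below-ces" %in% ft2$flags)
})

test_that("the overall flow BMC is the lowest defined biomarker BMC", {
  mk <- function(bmc) structure(list(bmc = bmc), class = "bmc_fit")
  fits <- list(gh2ax_4h = mk(80), p53_4h = mk(120), gh2ax_24h = mk(NA_real_))
  low <- lowest_bmc(fits)
  expect_equal(low$bmc, 80)
  expect_identical(low$endpoint, "gh2ax_4h")
  expect_null(lowest_bmc(list(a = mk(NA_real_))))
})

test_that("each quality filter removes exactly its dedicated fixture gene", {
  fx <- data.frame(
    gene = c("clean", "badfit", "ratio_ll", "ratio_ub", "ratio_ul"),
    bmc = c(10, 10, 10, 10, 10),
    bmcl = c(5, 5, 0.4, 7, 0.6),     # ratio_ll: BMC/BMCL = 25
    bmcu = c(20, 20, 15, 250, 24),   # ratio_ub: BMCU/BMC = 25; ratio_ul: BMCU/BMCL = 40
    fit_p = c(0.5, 0.05, 0.5, 0.5, 0.5)
  )
  out <- filter_gene_bmcs(fx)
  expect_identical(out$removed, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(out$removed_by,
                   c("", "fit-p", "bmc/bmcl", "bmcu/bmc", "bmcu/bmcl"))
})

test_that("a flat panel yields an explicit empty gene-set result", {
  set.seed(67)
  flat <- lapply(1:6, function(i) {
    x <- rep(c(0, 10, 20, 40), each = 2)
    list(x = x, y = rnorm(length(x), sd = 0.2))
  })
  names(flat) <- paste0("g", 1:6)
  gs <- gene_set_bmc(flat, n_perm = 99, n_boot_fit = 0, n_boot = 100)
  expect_true(is.na(gs$median_bmc))
  expect_equal(unname(gs$counts[["surviving"]]), 0)
  # every gene is accounted for at some removal stage
  expect_true(all(nzchar(gs$fits$removed_by)))
})

test_that("the gene-set median lands near the generator benchmark", {
  cfg <- simulation_config(seed = 101, dr_params = list(true_bmc = 100),
                           concentrations = build_series(300, 6)$concentrations)
  es <- simulate_expression_study(cfg)
  gs <- gene_set_bmc(es$replicates$cpd_clastogen[1:24], n_perm = 60,
                     n_boot_fit = 20, n_boot = 300)
  expect_false(is.na(gs$median_bmc))
  expect_equal(gs$median_bmc, 100, tolerance = 0.25)
  expect_true(gs$ci[1] < gs$ci[2])
})
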