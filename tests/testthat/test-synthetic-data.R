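test_that("identical configurations reproduce identical studies", {
  cfg <- simulation_config(seed = 21)
  a <- simulate_expression_study(cfg)
  b <- simulate_expression_study(cfg)
  expect_identical(a$training$matrix, b$training$matrix)
  expect_identical(unclass(a$biomarker), unclass(b$biomarker))
  fa <- simulate_flow_study(cfg)
  fb <- simulate_flow_study(cfg)
  expect_identical(fa$microflow, fb$microflow)
  expect_identical(fa$multiflow, fb$multiflow)
})

test_that("adding compounds does not perturb earlier compounds", {
  tc4 <- data.frame(compound = c("a", "b", "c", "d"),
                    class_label = c("DDI", "nonDDI", "DDI", "nonDDI"),
                    moa_label = c("clastogen", "aneugen", "pan", "none"))
  cfg4 <- simulation_config(seed = 5, test_compounds = tc4)
  cfg2 <- simulation_config(seed = 5, test_compounds = tc4[1:2, ])
  e4 <- simulate_expression_study(cfg4)
  e2 <- simulate_expression_study(cfg2)
  cols <- grep("^a@|^b@", colnames(e4$biomarker), value = TRUE)
  expect_identical(e4$biomarker[, cols], e2$biomarker[, cols])
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(effect_size = 0), "effect_size")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(n_ddi_training = 28), "smaller")
  expect_error(simulation_config(n_training_chemicals = 4, n_ddi_training = 1),
               "per class")
  expect_error(simulation_config(concentrations = c(10, 20, 30)), "decreasing")
})

test_that("non-DDI compounds have zero expected expression response", {
  tc <- data.frame(compound = c("act", "null"),
                   class_label = c("DDI", "nonDDI"),
                   moa_label = c("clastogen", "none"))
  cfg <- simulation_config(seed = 3, noise_sd = 1e-6, test_compounds = tc)
  es <- simulate_expression_study(cfg)
  null_cols <- grep("^null@", colnames(es$biomarker))
  expect_lt(max(abs(es$biomarker[, null_cols])), 1e-4)
  # active DDI compound reaches +/- effect_size at the top concentration
  top_col <- grep("^act@", colnames(es$biomarker))[1]
  expect_equal(mean(abs(es$biomarker[, top_col])), cfg$effect_size,
               tolerance = 1e-3)
})

test_that("micronucleus counts follow rate x nucleated events in controls", {
  tc <- data.frame(compound = "null", class_label = "nonDDI", moa_label = "none")
  cfg <- simulation_config(seed = 13, background_mn_rate = 0.01,
                           test_compounds = tc)
  fl <- simulate_flow_study(cfg)
  mn <- fl$microflow
  expect_true(all(mn$nucleated_events == cfg$stop_gate))
  # every well of an inactive compound has expectation 0.01 * 5000 = 50
  expect_equal(mean(mn$mn_events), 50, tolerance = 0.05)
})

test_that("expected response curves are monotone in concentration", {
  cfg <- simulation_config(seed = 1)
  x <- sort(c(cfg$concentrations, cfg$concentrations / 3))
  eff <- expression_effect(cfg, x)
  expect_true(all(diff(eff) > 0))
  for (moa in c("clastogen", "aneugen", "pan")) {
    ft <- expected_fold_table(cfg, moa)
    for (key in split(ft, paste(ft$timepoint, ft$biomarker))) {
      ordered <- key$fold[order(key$concentration)]
      expect_true(all(diff(ordered) >= 0))
    }
  }
  # inactive compounds sit exactly at fold 1 everywhere
  ft0 <- expected_fold_table(cfg, "none")
  expect_true(all(ft0$fold == 1))
})

test_that("the generator's analytic benchmark matches an independent solve", {
  cfg <- simulation_config(seed = 2, dr_params = list(true_bmc = 50),
                           concentrations = build_series(200, 6)$concentrations)
  # independent bisection on the generator mean function
  f <- function(x) expression_effect(cfg, x) - cfg$noise_sd
  lo <- 1e-6; hi <- 200
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(true_expression_bmc(cfg), 50, tolerance = 1e-6)
  expect_equal((lo + hi) / 2, 50, tolerance = 1e-4)
  es <- simulate_expression_study(cfg)
  expect_equal(es$truth$true_bmc[es$truth$class_label == "DDI"][1], 50,
               tolerance = 1e-6)
})

test_that("fitted BMC converges to the generator benchmark as noise vanishes", {
  cfg <- simulation_config(seed = 2, dr_params = list(true_bmc = 50),
                           concentrations = build_series(200, 6)$concentrations)
  # near-noiseless replicates of one responsive gene; the benchmark response
  # is the 1-SD effect the study design targets (0.25 log2 units)
  x <- rep(c(0, rev(cfg$concentrations)), each = 4)
  set.seed(8)
  y <- expression_effect(cfg, x) + rnorm(length(x), sd = 1e-4)
  ft <- fit_dose_response_family(x, y, n_boot = 0, bmr_abs = cfg$noise_sd)
  expect_equal(ft$bmc, 50, tolerance = 0.01)
})

test_that("flow simulation validates the truth table", {
  cfg <- simulation_config(seed = 1)
  bad_truth <- data.frame(compound = "unknown", class_label = "DDI",
                          moa_label = "clastogen")
  expect_error(simulate_flow_study(cfg, bad_truth), "cover every")
})
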