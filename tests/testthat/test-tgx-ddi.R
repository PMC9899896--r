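test_that("preprocessing normalizes depth, collapses probes, and centers on controls", {
  # same composition at different depths: fold-changes must all be zero
  base <- c(p1 = 30, p2 = 120, p3 = 999850)
  counts <- cbind(c1 = base, c2 = base * 3, t1 = base * 2, t2 = base * 5)
  design <- data.frame(sample = colnames(counts),
                       compound = c("ctrl", "ctrl", "cpdA", "cpdA"),
                       concentration = c(0, 0, 10, 10),
                       replicate = c(1, 2, 1, 2),
                       is_control = c(TRUE, TRUE, FALSE, FALSE))
  bm <- preprocess_expression(counts, design)
  expect_true(all(abs(bm) < 1e-12))

  # probe collapsing: log2(CPM+1) of 2 and 4 average to 3
  counts2 <- cbind(s1 = c(pa = 3, pb = 15, pc = 999982))
  design2 <- data.frame(sample = "s1", compound = "ctrl", concentration = 0,
                        replicate = 1, is_control = TRUE)
  pm <- data.frame(probe = c("pa", "pb", "pc"), gene = c("g1", "g1", "g2"))
  # reach the collapsed log values through a fold-change of a duplicate sample
  counts3 <- cbind(counts2, s2 = counts2[, 1])
  design3 <- rbind(design2, data.frame(sample = "s2", compound = "cpd",
                                       concentration = 1, replicate = 1,
                                       is_control = FALSE))
  bm3 <- preprocess_expression(counts3, design3, probe_map = pm)
  expect_identical(rownames(bm3), c("g1", "g2"))
  expect_true(all(abs(bm3) < 1e-12))  # identical samples: zero fold change

  expect_error(preprocess_expression(counts[, 1:2, drop = FALSE],
                                     design[3:4, ]), "absent from")
})

test_that("shrinkage behaves at its extremes and matches hand-computed centroids", {
  tr <- make_tiny_training()
  m0 <- fit_nsc(tr$x, tr$labels, delta = 0)
  for (cl in c("DDI", "nonDDI")) {
    expect_equal(m0$shrunken[cl, ], colMeans(tr$x[tr$labels == cl, ]))
  }
  mBig <- fit_nsc(tr$x, tr$labels, delta = 1e6)
  expect_equal(mBig$shrunken["DDI", ], colMeans(tr$x))
  expect_equal(mBig$shrunken["nonDDI", ], colMeans(tr$x))

  # hand-computed reference on a small set, following the formulas directly
  x <- tr$x; labels <- tr$labels
  n <- nrow(x); K <- 2
  xbar <- colMeans(x)
  cm <- rbind(DDI = colMeans(x[labels == "DDI", ]),
              nonDDI = colMeans(x[labels == "nonDDI", ]))
  resid <- x - cm[labels, ]
  s <- sqrt(colSums(resid^2) / (n - K))
  s0 <- median(s)
  mk <- sqrt(1 / c(5, 5) + 1 / n)
  d <- sweep(cm, 2, xbar) / (mk %o% (s + s0))
  delta <- 0.5
  dsh <- sign(d) * pmax(abs(d) - delta, 0)
  expected <- sweep(mk %o% (s + s0) * dsh, 2, xbar, "+")
  dimnames(expected) <- dimnames(cm)
  m <- fit_nsc(x, labels, delta = 0.5)
  expect_equal(m$shrunken, expected)
  expect_equal(m$s0, s0)
})

test_that("NSC posteriors are calibrated, symmetric, and sum to one", {
  tr <- make_tiny_training()
  m <- fit_nsc(tr$x, tr$labels, delta = 0)
  self <- classify_nsc(m, m$shrunken["DDI", ])
  expect_gt(self$posterior[["DDI"]], 0.90)
  expect_identical(self$call, "DDI")

  mid <- (m$shrunken["DDI", ] + m$shrunken["nonDDI", ]) / 2
  eq <- classify_nsc(m, mid)
  expect_equal(unname(eq$posterior), c(0.5, 0.5))
  expect_identical(eq$call, "unclassifiable")

  # brute-force evaluation of the discriminant formula on random profiles
  set.seed(31)
  for (i in 1:10) {
    prof <- rnorm(ncol(tr$x), sd = 2)
    got <- classify_nsc(m, prof)$posterior
    dk <- sapply(c("DDI", "nonDDI"), function(cl) {
      sum((prof - m$shrunken[cl, ])^2 / (m$s + m$s0)^2) - 2 * log(0.5)
    })
    w <- exp(-(dk - min(dk)) / 2)   # stabilized, same ratio
    want <- w / sum(w)
    expect_equal(sum(got), 1)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
  expect_error(classify_nsc(m, setNames(rnorm(3), c("a", "b", "c"))), "gene set")
})

test_that("PCA projection is oriented, centered, and round-trips the training set", {
  tr <- make_tiny_training()
  samples <- t(tr$x[c(1, 6), , drop = FALSE])  # one DDI, one non-DDI chemical
  res <- classify_pca(tr$x, tr$labels, samples)
  expect_lt(res$pc1[1], 0)          # DDI chemical projects negative
  expect_identical(res$call[1], "DDI")
  expect_gt(res$pc1[2], 0)
  expect_identical(res$call[2], "nonDDI")

  # round-trip: projecting every training chemical reproduces fitted scores
  all_proj <- classify_pca(tr$x, tr$labels, t(tr$x))
  expect_equal(all_proj$pc1, unname(attr(all_proj, "training_scores")))

  # all-zero profile: PC1 = -(center . loading), evaluated not assumed
  zero <- classify_pca(tr$x, tr$labels,
                       matrix(0, ncol(tr$x), 1,
                              dimnames = list(colnames(tr$x), "z")))
  expect_equal(zero$pc1,
               as.numeric(-attr(zero, "center") %*% attr(zero, "loadings")))

  # profile at the training mean sits exactly on the boundary -> nonDDI
  ctr <- classify_pca(tr$x, tr$labels,
                      matrix(colMeans(tr$x), ncol(tr$x), 1,
                             dimnames = list(colnames(tr$x), "m")))
  expect_equal(ctr$pc1, 0, tolerance = 1e-10)
  expect_identical(ctr$call, "nonDDI")
})

test_that("joint clustering agrees with a brute-force average-linkage oracle", {
  tr <- make_tiny_training()
  # a sample identical to a DDI training chemical clusters with it
  res <- classify_hclust(tr$x, tr$labels,
                         matrix(tr$x[1, ], ncol(tr$x), 1,
                                dimnames = list(colnames(tr$x), "dup")))
  expect_identical(res$call, "DDI")

  # random small instances: two-cluster partition must match the naive oracle
  set.seed(17)
  for (i in 1:15) {
    n_items <- sample(6:10, 1)
    m <- matrix(rnorm(n_items * 4), n_items)
    hc <- stats::cutree(stats::hclust(dist(m), method = "average"), k = 2)
    oracle <- brute_average_linkage(m)$partition
    expect_equal(length(unique(paste(hc, oracle))), 2)  # identical partition
  }

  # a far-away orthogonal sample becomes its own branch -> unclassifiable
  far <- matrix(100, ncol(tr$x), 1,
                dimnames = list(colnames(tr$x), "far"))
  res_far <- classify_hclust(tr$x, tr$labels, far)
  expect_identical(res_far$call, "unclassifiable")
})

test_that("the overall call is positive on any single DDI call", {
  expect_identical(overall_ddi_call(c("nonDDI", "nonDDI")), "nonDDI")
  expect_identical(overall_ddi_call(c("nonDDI", "unclassifiable", "DDI")), "DDI")
  expect_identical(overall_ddi_call(rep("unclassifiable", 5)), "nonDDI")
  expect_error(overall_ddi_call(character(0)), "empty")
})

test_that("the full ensemble recovers ground truth on a clear study", {
  cfg <- simulation_config(seed = 99)
  es <- simulate_expression_study(cfg)
  res <- classify_tgxddi(es$training$matrix, es$training$labels, es$biomarker)
  expect_identical(unname(res$overall[es$truth$compound]),
                   ifelse(es$truth$class_label == "DDI", "DDI", "nonDDI"))
  # posteriors in the per-condition table are proper probabilities
  expect_true(all(res$conditions$nsc_posterior >= 0.5 - 1e-9 &
                    res$conditions$nsc_posterior <= 1))
})
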