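mk_bmc_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(compound = r[[1]], slice = r[[2]],
               bmcl = as.numeric(r[[3]]), bmcu = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("default slice weights follow the 1/3 + 1/3 + 4 x 1/12 scheme", {
  s <- default_slices()
  expect_equal(sum(s$weight), 1)
  expect_equal(s$weight[s$slice == "tgxddi"], 1 / 3)
  expect_equal(s$weight[s$slice == "mn"], 1 / 3)
  expect_equal(sum(s$weight[grepl("p53|gh2ax", s$slice)]), 1 / 3)
  expect_true(all(s$weight[grepl("p53|gh2ax", s$slice)] == 1 / 12))
})

test_that("a fully inactive compound scores zero everywhere", {
  tab <- mk_bmc_table(list("active", "tgxddi", 10, 50),
                      list("inactive", "tgxddi", NA, NA))
  res <- score_profiles(tab)
  sc <- res$scores
  inact <- sc[sc$compound == "inactive", ]
  expect_true(all(inact[, default_slices()$slice] == 0))
  expect_equal(inact$overall, 0)
})

test_that("a uniformly more potent compound dominates every slice and rank 1", {
  slices <- default_slices()$slice
  rows <- c(lapply(slices, function(sl) list("potent", sl, 1, 5)),
            lapply(slices, function(sl) list("mild", sl, 100, 500)))
  res <- score_profiles(do.call(mk_bmc_table, rows))
  sc <- res$scores
  expect_true(all(sc[sc$compound == "potent", slices] == 1))
  expect_equal(sc$rank[sc$compound == "potent"], 1L)
  expect_equal(sc$overall[sc$compound == "potent"], 1)
  expect_true(all(sc[sc$compound == "mild", slices] < 1))
})

test_that("scores match an independent arithmetic recomputation", {
  tab <- mk_bmc_table(list("c1", "tgxddi", 10, 100), list("c1", "mn", 50, 200),
                      list("c2", "tgxddi", 5, 20), list("c2", "mn", 1000, 8000),
                      list("c3", "tgxddi", 300, 3000), list("c3", "mn", 2, 9))
  res <- score_profiles(tab)
  # spreadsheet-style recomputation of the transform-sum-normalize chain
  raw <- function(l, u) (-log10(l) - log10(u)) - (-2 * log10(10000))
  raw_tgx <- c(c1 = raw(10, 100), c2 = raw(5, 20), c3 = raw(300, 3000))
  raw_mn <- c(c1 = raw(50, 200), c2 = raw(1000, 8000), c3 = raw(2, 9))
  s_tgx <- raw_tgx / max(raw_tgx)
  s_mn <- raw_mn / max(raw_mn)
  overall <- (s_tgx + s_mn) / 3   # four flow slices are all inactive -> 0
  sc <- res$scores[match(c("c1", "c2", "c3"), res$scores$compound), ]
  expect_equal(sc$tgxddi, unname(s_tgx))
  expect_equal(sc$mn, unname(s_mn))
  expect_equal(sc$overall, unname(overall))
  expect_equal(sc$rank, unname(rank(-overall, ties.method = "min")))
  # confidence bounds bracket the point estimate
  expect_true(all(sc$ci_lower <= sc$overall + 1e-12))
  expect_true(all(sc$ci_upper >= sc$overall - 1e-12))
})

test_that("lowering a BMC never lowers a slice score", {
  set.seed(71)
  slices <- default_slices()$slice
  for (i in 1:8) {
    l1 <- runif(6, 1, 100); u1 <- l1 * runif(6, 1, 10)
    l2 <- runif(6, 1, 100); u2 <- l2 * runif(6, 1, 10)
    mk <- function(l, u) do.call(mk_bmc_table, c(
      lapply(seq_along(slices), function(j) list("a", slices[j], l[j], u[j])),
      lapply(seq_along(slices), function(j) list("b", slices[j], l2[j], u2[j]))))
    base <- score_profiles(mk(l1, u1))$scores
    j <- sample(6, 1)
    l1b <- l1; u1b <- u1
    l1b[j] <- l1[j] * 0.5; u1b[j] <- u1[j] * 0.5
    more <- score_profiles(mk(l1b, u1b))$scores
    a0 <- base[base$compound == "a", slices]
    a1 <- more[more$compound == "a", slices]
    expect_true(all(as.numeric(a1) >= as.numeric(a0) - 1e-12))
  }
})

test_that("joint rescaling of units and substitution leaves scores unchanged", {
  tab <- mk_bmc_table(list("c1", "tgxddi", 10, 100), list("c2", "tgxddi", 5, 20))
  k <- 1000
  tab2 <- tab; tab2$bmcl <- tab2$bmcl * k; tab2$bmcu <- tab2$bmcu * k
  r1 <- score_profiles(tab)
  r2 <- score_profiles(tab2, substitution = 10000 * k)
  expect_equal(r1$scores$overall, r2$scores$overall)
})

test_that("weights of a custom slice set are re-normalized", {
  slices <- data.frame(slice = c("a", "b"), weight = c(2, 6))
  tab <- mk_bmc_table(list("c1", "a", 10, 20), list("c1", "b", 10, 20),
                      list("c2", "a", 100, 200), list("c2", "b", 5, 10))
  res <- score_profiles(tab, slices = slices)
  expect_equal(res$slices$weight, c(0.25, 0.75))
  sc <- res$scores
  expect_equal(sc$overall,
               as.numeric(as.matrix(sc[, c("a", "b")]) %*% c(0.25, 0.75)))
})

test_that("profile clustering merges duplicates at zero and separates groups", {
  slices <- default_slices()$slice
  mk <- function(cpd, l) do.call(mk_bmc_table, lapply(
    seq_along(slices), function(j) list(cpd, slices[j], l[j], l[j] * 2)))
  potent <- c(1, 2, 1, 2, 1, 2); mild <- c(500, 800, 600, 900, 700, 1000)
  tab <- rbind(mk("p1", potent), mk("p2", potent),
               mk("m1", mild), mk("m2", mild * 1.1))
  prof <- score_profiles(tab)
  cl <- cluster_profiles(prof, k = 2)
  expect_equal(min(cl$tree$height), 0)                    # duplicate profiles
  expect_identical(cl$cluster[["p1"]], cl$cluster[["p2"]])
  expect_identical(cl$cluster[["m1"]], cl$cluster[["m2"]])
  expect_false(cl$cluster[["p1"]] == cl$cluster[["m1"]])

  # permuting the input order leaves merge heights unchanged
  perm <- tab[sample(nrow(tab)), ]
  cl2 <- cluster_profiles(score_profiles(perm), k = 2)
  expect_equal(sort(cl2$tree$height), sort(cl$tree$height))
  expect_error(cluster_profiles(score_profiles(mk("only", potent))), "at least 2")
})

test_that("the alternative transform order keeps the score contract", {
  tab <- mk_bmc_table(list("c1", "tgxddi", 10, 100),
                      list("c2", "tgxddi", 5, 20),
                      list("inact", "tgxddi", NA, NA))
  res <- score_profiles(tab, transform_each = FALSE)
  sc <- res$scores
  expect_true(all(sc$tgxddi >= 0 & sc$tgxddi <= 1))
  expect_equal(sc$tgxddi[sc$compound == "inact"], 0)   # anchored baseline
  # the more potent compound still scores higher
  expect_gt(sc$tgxddi[sc$compound == "c2"], sc$tgxddi[sc$compound == "c1"])
  # independent recomputation of the sum-then-transform chain
  raw <- c(-log10(110), -log10(25)) - (-log10(20000))
  expect_equal(sc$tgxddi[match(c("c1", "c2"), sc$compound)], raw / max(raw))
})

test_that("invalid inputs are rejected", {
  expect_error(score_profiles(data.frame()), "empty")
  bad <- mk_bmc_table(list("c1", "tgxddi", -5, 10))
  expect_error(score_profiles(bad), "non-positive")
})
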