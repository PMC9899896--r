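# shared fixtures and independent mini-oracles used across test files

# a tiny, well-separated two-class reference set (chemicals x genes)
make_tiny_training <- function(n_per_class = 5, n_genes = 8, effect = 2,
                               noise = 0.1, seed = 11) {
  set.seed(seed)
  direction <- rep(c(1, -1), length.out = n_genes)
  ddi <- outer(rep(effect, n_per_class), direction) +
    matrix(rnorm(n_per_class * n_genes, sd = noise), n_per_class)
  non <- matrix(rnorm(n_per_class * n_genes, sd = noise), n_per_class)
  x <- rbind(ddi, non)
  dimnames(x) <- list(paste0("chem", seq_len(2 * n_per_class)),
                      paste0("g", seq_len(n_genes)))
  list(x = x, labels = rep(c("DDI", "nonDDI"), each = n_per_class),
       direction = direction)
}

# naive average-linkage agglomeration, independent of stats::hclust:
# returns the two-cluster partition (vector of 1/2) and merge heights
brute_average_linkage <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 2L) {
    k <- length(clusters)
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  part <- integer(n)
  part[clusters[[1L]]] <- 1L
  part[clusters[[2L]]] <- 2L
  list(partition = part, heights = heights)
}

# all permutations of seq_len(n) (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# well-level micronucleus plate with deterministic counts
make_mn_wells <- function(ctrl_mn = rep(35, 6), trt, conc,
                          density = function(x) 1e5, stop_gate = 5000) {
  ctrl <- data.frame(compound = "cpd", concentration = 0,
                     replicate = seq_along(ctrl_mn), plate = "p1",
                     mn_events = ctrl_mn, nucleated_events = stop_gate,
                     pct_ema_positive = 2, nuclei_per_ml = 1e5,
                     is_control = TRUE)
  rows <- lapply(seq_along(conc), function(i) {
    data.frame(compound = "cpd", concentration = conc[i],
               replicate = seq_along(trt[[i]]), plate = "p1",
               mn_events = trt[[i]], nucleated_events = stop_gate,
               pct_ema_positive = 2, nuclei_per_ml = unname(density(conc[i])),
               is_control = FALSE)
  })
  rbind(ctrl, do.call(rbind, rows))
}

# fold table for the MoA caller: named hits like c("4H.gh2ax", "24H.p53")
# get fold `hit_fold` at the chosen concentrations, everything else 1
make_fold_table <- function(hits, at_conc = c(100, 70.7),
                            concs = c(100, 70.7, 50, 35.4),
                            hit_fold = 10) {
  combos <- expand.grid(biomarker = c("gh2ax", "p53", "ph3", "polyploidy"),
                        timepoint = c("4H", "24H"), concentration = concs,
                        stringsAsFactors = FALSE)
  combos$fold <- 1
  key <- paste(combos$timepoint, combos$biomarker, sep = ".")
  combos$fold[key %in% hits & combos$concentration %in% at_conc] <- hit_fold
  combos
}

# independent evaluation of the MoA decision rule from a hit pattern:
# `hits` is the set of biomarkers at/above their GEF at two top concentrations
expected_moa_from_hits <- function(hits) {
  clast_set <- c("4H.gh2ax", "24H.gh2ax", "4H.p53", "24H.p53")
  aneu_set <- c("4H.ph3", "24H.ph3", "24H.polyploidy", "24H.p53")
  cl <- sum(hits %in% clast_set) >= 2
  an <- sum(hits %in% aneu_set) >= 2
  if (cl && an) "pan-genotoxic" else if (cl) "clastogen"
  else if (an) "aneugen" else "non-genotoxic"
}
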