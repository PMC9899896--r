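#' Preprocess a count table into a biomarker fold-change matrix
#'
#' Normalizes a gene/probe-by-sample count table to log2(CPM + 1), collapses
#' multi-probe genes by averaging, averages replicates within each
#' (compound, concentration) condition, and expresses every condition as the
#' log2 fold-change against the mean of the solvent-control samples.
#' Samples failing viability (< 40% by default) or a minimum library depth are
#' dropped before averaging.
#'
#' @param counts Numeric matrix of raw counts, probes/genes in rows, samples
#'   in columns (column names are sample ids).
#' @param design Data frame with one row per sample: columns `sample`,
#'   `compound`, `concentration`, `replicate`, and logical `is_control`.
#' @param probe_map Optional data frame mapping `probe` to `gene`; when
#'   supplied, rows of `counts` are probes and are averaged per gene after the
#'   log transform. Otherwise row names are taken as gene ids.
#' @param viability Optional named numeric vector of percent viability per
#'   sample; samples below `viability_min` are excluded.
#' @param viability_min Viability gate in percent (default 40).
#' @param min_depth Minimum library size (total counts) per sample; samples
#'   below it are excluded (default 0, i.e. no depth gate).
#' @return A genes x conditions matrix of replicate-averaged log2 fold-changes
#'   with a `conditions` attribute (data frame of compound / concentration),
#'   class `biomarker_matrix`.
#' @export
preprocess_expression <- function(counts, design, probe_map = NULL,
                                  viability = NULL, viability_min = 40,
                                  min_depth = 0) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("`counts` must have sample column names")
  design <- as.data.frame(design)
  need <- c("sample", "compound", "concentration", "is_control")
  if (!all(need %in% names(design))) {
    stop("`design` must contain columns: ", paste(need, collapse = ", "))
  }
  missing_design <- setdiff(colnames(counts), design$sample)
  if (length(missing_design)) {
    stop("samples present in `counts` but absent from `design`: ",
         paste(missing_design, collapse = ", "))
  }
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]

  keep <- rep(TRUE, ncol(counts))
  depth <- colSums(counts)
  keep <- keep & depth >= min_depth
  if (!is.null(viability)) {
    v <- viability[colnames(counts)]
    keep <- keep & (is.na(v) | v >= viability_min)
  }
  counts <- counts[, keep, drop = FALSE]
  design <- design[keep, , drop = FALSE]
  if (!any(design$is_control)) stop("no control samples remain after gating")

  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  logx <- log2(cpm + 1)

  if (!is.null(probe_map)) {
    probe_map <- as.data.frame(probe_map)
    gene <- probe_map$gene[match(rownames(logx), probe_map$probe)]
    if (anyNA(gene)) stop("probes without a gene mapping: ",
                          paste(rownames(logx)[is.na(gene)], collapse = ", "))
    logx <- rowsum(logx, gene) / as.vector(table(gene)[sort(unique(gene))])
    logx <- logx[order(rownames(logx)), , drop = FALSE]
  }

  ctrl_mean <- rowMeans(logx[, design$is_control, drop = FALSE])
  trt <- design[!design$is_control, , drop = FALSE]
  key <- interaction(trt$compound, trt$concentration, drop = TRUE)
  conds <- unique(data.frame(compound = trt$compound,
                             concentration = trt$concentration,
                             key = as.character(key),
                             stringsAsFactors = FALSE))
  fc <- vapply(conds$key, function(k) {
    idx <- which(!design$is_control)[key == k]
    rowMeans(logx[, idx, drop = FALSE]) - ctrl_mean
  }, numeric(nrow(logx)))
  fc <- matrix(fc, nrow = nrow(logx),
               dimnames = list(rownames(logx),
                               paste(conds$compound, conds$concentration, sep = "@")))
  attr(fc, "conditions") <- conds[, c("compound", "concentration")]
  class(fc) <- c("biomarker_matrix", class(fc))
  fc
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

#' Fit a nearest-shrunken-centroid (NSC) classifier
#'
#' Summarizes a labeled reference set of chemical expression profiles by
#' per-class standardized centroids, shrinks them toward the overall centroid
#' by soft-thresholding, and stores everything needed for posterior-probability
#' classification of new profiles. The standardized centroid for class k and
#' gene j is `d_kj = (xbar_kj - xbar_j) / (m_k * (s_j + s0))` with
#' `m_k = sqrt(1/n_k + 1/n)`, pooled within-class standard deviation `s_j`,
#' and fudge constant `s0 = median(s_j)`; shrinkage replaces `d_kj` by
#' `sign(d_kj) * max(|d_kj| - delta, 0)`.
#'
#' @param x Chemicals x genes numeric matrix of log2 fold-changes.
#' @param labels Factor/character vector of class labels (two classes, e.g.
#'   `"DDI"` / `"nonDDI"`), one per row of `x`.
#' @param delta Shrinkage threshold; `NULL` (default) selects it by
#'   leave-one-chemical-out cross-validation, taking the smallest value among
#'   those maximizing training accuracy.
#' @param priors Class prior probabilities; default equal (0.5 each),
#'   reflecting that reference-set composition is by design, not prevalence.
#' @return An object of class `nsc_model`.
#' @export
fit_nsc <- function(x, labels, delta = NULL, priors = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes are required")
  nk <- table(factor(labels, levels = classes))
  if (any(nk < 2L)) stop("need at least 2 chemicals per class")
  n <- nrow(x); K <- 2L

  xbar <- colMeans(x)
  class_means <- rbind(colMeans(x[labels == classes[1L], , drop = FALSE]),
                       colMeans(x[labels == classes[2L], , drop = FALSE]))
  rownames(class_means) <- classes
  within_ss <- colSums((x - class_means[labels, , drop = FALSE])^2)
  s <- sqrt(within_ss / (n - K))
  if (all(s == 0)) stop("degenerate training set: zero within-class variance on all genes")
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) + 1 / n)
  d <- sweep(class_means, 2, xbar, "-") / (mk %o% (s + s0))

  if (is.null(delta)) delta <- cv_nsc_delta(x, labels, classes)
  dsh <- soft_threshold(d, delta)
  shrunken <- sweep(mk %o% (s + s0) * dsh, 2, xbar, "+")
  dimnames(shrunken) <- dimnames(class_means)
  if (is.null(priors)) priors <- c(0.5, 0.5)
  priors <- priors / sum(priors)
  structure(list(classes = classes, overall = xbar, class_means = class_means,
                 shrunken = shrunken, s = s, s0 = s0, mk = mk, delta = delta,
                 priors = priors, genes = colnames(x), n = n, nk = as.numeric(nk)),
            class = "nsc_model")
}

# leave-one-chemical-out CV over a delta grid; smallest delta on tied accuracy
cv_nsc_delta <- function(x, labels, classes, n_grid = 20L) {
  dmax <- {
    m <- fit_nsc(x, labels, delta = 0)
    max(abs(sweep(m$class_means, 2, m$overall, "-") / (m$mk %o% (m$s + m$s0))))
  }
  grid <- seq(0, dmax, length.out = n_grid)
  acc <- vapply(grid, function(dl) {
    hits <- vapply(seq_len(nrow(x)), function(i) {
      lab_i <- labels[-i]
      if (min(table(lab_i)) < 2L) return(NA)
      m <- fit_nsc(x[-i, , drop = FALSE], lab_i, delta = dl)
      p <- nsc_posterior(m, x[i, ])
      names(which.max(p)) == labels[i]
    }, logical(1))
    mean(hits, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(acc)]  # which.max returns the first (smallest delta) maximum
}

nsc_posterior <- function(model, profile) {
  denom <- (model$s + model$s0)^2
  delta_k <- colSums(t(sweep(model$shrunken, 2, profile, function(c, p) (p - c)^2)) / denom) -
    2 * log(model$priors)
  w <- exp(-(delta_k - min(delta_k)) / 2)
  p <- w / sum(w)
  names(p) <- model$classes
  p
}

#' Classify a profile with a fitted NSC model
#'
#' Evaluates the shrunken-centroid discriminant
#' `delta_k = sum_j (x_j - xbar'_kj)^2 / (s_j + s0)^2 - 2 log pi_k`,
#' converts it to posterior class probabilities, and assigns the class only
#' when its posterior exceeds the confidence threshold (0.90 by default);
#' otherwise the profile is unclassifiable.
#'
#' @param model An `nsc_model` from [fit_nsc()].
#' @param profile Numeric gene vector (names must cover the model's genes).
#' @param posterior_min Posterior required for a definite call (default 0.90).
#' @return List with `posterior` (named, sums to 1) and `call` (one of the two
#'   class labels or `"unclassifiable"`).
#' @export
classify_nsc <- function(model, profile, posterior_min = 0.90) {
  stopifnot(inherits(model, "nsc_model"))
  if (!is.null(names(profile)) && !is.null(model$genes)) {
    if (!all(model$genes %in% names(profile))) stop("profile gene set does not match model")
    profile <- profile[model$genes]
  } else if (length(profile) != length(model$overall)) {
    stop("profile gene set does not match model")
  }
  p <- nsc_posterior(model, as.numeric(profile))
  call <- if (max(p) > posterior_min) names(which.max(p)) else "unclassifiable"
  list(posterior = p, call = call)
}

#' @export
predict.nsc_model <- function(object, newdata, posterior_min = 0.90, ...) {
  newdata <- as.matrix(newdata)
  res <- apply(newdata, 1L, classify_nsc, model = object,
               posterior_min = posterior_min)
  data.frame(call = vapply(res, `[[`, "", "call"),
             t(vapply(res, `[[`, numeric(2), "posterior")),
             check.names = FALSE)
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("Nearest shrunken centroid model: %d genes, classes %s (n = %s), delta = %.3g\n",
              length(x$overall), paste(x$classes, collapse = "/"),
              paste(x$nk, collapse = "/"), x$delta))
  nz <- sum(colSums(abs(sweep(x$shrunken, 2, x$overall, "-"))) > 0)
  cat(sprintf("  genes surviving shrinkage: %d\n", nz))
  invisible(x)
}

#' Principal-component classification against a reference set
#'
#' Fits principal components on the reference chemicals (observations) by
#' centering each gene at its reference mean (no scaling by default), projects
#' the sample conditions with the reference centering and loadings, and calls
#' a condition DDI when its first principal component is strictly negative.
#' The sign of PC1 is oriented so that the mean PC1 of the DDI reference
#' chemicals is negative, which makes the "negative PC1 means DDI" rule
#' well-defined.
#'
#' @param training Chemicals x genes matrix of the labeled reference set.
#' @param labels Class labels for the reference chemicals (`"DDI"`/`"nonDDI"`).
#' @param samples Genes x conditions matrix (e.g. a `biomarker_matrix`).
#' @param scale. Scale genes to unit variance before PCA (default `FALSE`).
#' @param ddi_label Label identifying the DDI class (default `"DDI"`).
#' @return Data frame per condition with `pc1` and `call`
#'   (`"DDI"` iff `pc1 < 0`, else `"nonDDI"`), plus attributes `loadings`,
#'   `center`, and `training_scores`.
#' @export
classify_pca <- function(training, labels, samples, scale. = FALSE,
                         ddi_label = "DDI") {
  training <- as.matrix(training)
  if (all(apply(training, 2, stats::sd) == 0)) stop("zero-variance training matrix")
  pc <- stats::prcomp(training, center = TRUE, scale. = scale.)
  load1 <- pc$rotation[, 1L]
  train1 <- pc$x[, 1L]
  if (mean(train1[labels == ddi_label]) > 0) {
    load1 <- -load1
    train1 <- -train1
  }
  s <- t(as.matrix(samples))            # conditions x genes
  sc <- sweep(s, 2, pc$center, "-")
  if (!identical(pc$scale, FALSE)) sc <- sweep(sc, 2, pc$scale, "/")
  pc1 <- as.numeric(sc %*% load1)
  out <- data.frame(condition = colnames(as.matrix(samples)), pc1 = pc1,
                    call = ifelse(pc1 < 0, ddi_label, "nonDDI"),
                    stringsAsFactors = FALSE)
  attr(out, "loadings") <- load1
  attr(out, "center") <- pc$center
  attr(out, "training_scores") <- train1
  out
}

#' Two-dimensional hierarchical-clustering classification
#'
#' Jointly clusters reference chemicals and sample conditions on their gene
#' profiles (Euclidean distance, average linkage), cuts the tree at its top
#' split into two main clusters, labels each cluster by the majority class of
#' its reference chemicals, and assigns each sample condition the identity of
#' its cluster. A condition is unclassifiable when its cluster contains no
#' reference chemicals or when the top split fails to separate the two classes
#' by majority.
#'
#' @inheritParams classify_pca
#' @return Data frame per condition with `branch` (cluster id) and `call`.
#' @export
classify_hclust <- function(training, labels, samples, ddi_label = "DDI") {
  training <- as.matrix(training)
  labels <- as.character(labels)
  if (sum(labels == ddi_label) < 2L || sum(labels != ddi_label) < 2L) {
    stop("need at least 2 reference chemicals per class")
  }
  s <- t(as.matrix(samples))
  items <- rbind(training, s)
  if (nrow(items) < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(items), method = "average")
  cl <- stats::cutree(hc, k = 2L)
  n_train <- nrow(training)
  ident <- vapply(1:2, function(g) {
    lab <- labels[cl[seq_len(n_train)] == g]
    if (!length(lab)) return(NA_character_)
    tab <- table(lab)
    if (length(tab) > 1L && tab[1L] == tab[2L]) return(NA_character_)
    names(which.max(tab))
  }, character(1))
  separated <- !anyNA(ident) && length(unique(ident)) == 2L
  sample_cl <- cl[n_train + seq_len(nrow(s))]
  call <- if (separated) ident[sample_cl] else rep("unclassifiable", nrow(s))
  call[is.na(call)] <- "unclassifiable"
  data.frame(condition = rownames(s), branch = unname(sample_cl),
             call = unname(call), stringsAsFactors = FALSE)
}

#' Overall DDI call for one compound
#'
#' A compound is DDI when any of the three analyses (NSC, PCA, clustering)
#' returned a DDI call at any concentration; otherwise it is non-DDI
#' (unclassifiable concentrations are not positive evidence).
#'
#' @param calls Character vector of per-concentration, per-method calls.
#' @param ddi_label Label counting as a positive call (default `"DDI"`).
#' @return `"DDI"` or `"nonDDI"`.
#' @export
overall_ddi_call <- function(calls, ddi_label = "DDI") {
  calls <- as.character(unlist(calls, use.names = FALSE))
  calls <- calls[!is.na(calls)]
  if (!length(calls)) stop("empty call set")
  if (any(calls == ddi_label)) ddi_label else "nonDDI"
}

#' Run the full three-pronged DDI classifier ensemble
#'
#' Applies the NSC posterior classifier, PCA PC1-sign rule, and joint
#' hierarchical clustering to every condition of a biomarker matrix, and
#' combines them into a per-compound overall call (DDI if any method at any
#' concentration is DDI).
#'
#' @param training Chemicals x genes reference matrix.
#' @param labels Reference class labels.
#' @param samples Genes x conditions `biomarker_matrix` (conditions carry a
#'   `conditions` attribute naming compound and concentration; otherwise
#'   column names `compound@concentration` are parsed).
#' @param delta NSC shrinkage; `NULL` for cross-validated choice.
#' @param posterior_min NSC posterior threshold (default 0.90).
#' @return List with `conditions` (per-condition calls from all three
#'   methods) and `overall` (per-compound DDI/nonDDI), class `tgxddi_result`.
#' @export
classify_tgxddi <- function(training, labels, samples, delta = NULL,
                            posterior_min = 0.90) {
  samples <- as.matrix(samples)
  conds <- attr(samples, "conditions")
  if (is.null(conds)) {
    parts <- strsplit(colnames(samples), "@", fixed = TRUE)
    conds <- data.frame(compound = vapply(parts, `[`, "", 1L),
                        concentration = as.numeric(vapply(parts, `[`, "", 2L)))
  }
  model <- fit_nsc(as.matrix(training), labels, delta = delta)
  nsc <- predict(model, t(samples), posterior_min = posterior_min)
  pca <- classify_pca(training, labels, samples)
  hc <- classify_hclust(training, labels, samples)
  tab <- data.frame(compound = conds$compound,
                    concentration = conds$concentration,
                    nsc_call = nsc$call,
                    nsc_posterior = apply(nsc[, -1, drop = FALSE], 1, max),
                    pca_pc1 = pca$pc1, pca_call = pca$call,
                    hc_call = hc$call, row.names = NULL,
                    stringsAsFactors = FALSE)
  overall <- vapply(split(tab, tab$compound), function(d) {
    overall_ddi_call(c(d$nsc_call, d$pca_call, d$hc_call))
  }, character(1))
  structure(list(conditions = tab, overall = overall, model = model),
            class = "tgxddi_result")
}

#' @export
print.tgxddi_result <- function(x, ...) {
  cat("TGx-DDI ensemble classification\n")
  print(x$overall)
  invisible(x)
}
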