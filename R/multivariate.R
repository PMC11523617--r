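#' Principal component analysis of abiotic variables
#'
#' Eigen-decomposition of the covariance (or correlation, when
#' `standardize = TRUE`) matrix of a samples x variables table. Axis signs are
#' fixed so that the variable with the largest absolute loading on each axis
#' has a positive loading, making results reproducible across platforms.
#' Constant variables are dropped with a warning when standardizing; rows with
#' missing values are removed (complete-case handling).
#'
#' @param x Numeric matrix or data frame, samples in rows (>= 3), variables in
#'   columns (>= 2).
#' @param standardize Scale variables to unit variance before decomposition.
#' @return An object of class `habnet_pca`: list with `scores` (samples x
#'   axes, column-centered), `loadings` (orthonormal), `eig` (variances,
#'   nonincreasing), `center`, `scale`.
#' @export
pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  cc <- complete.cases(x)
  if (!all(cc)) {
    message("dropping ", sum(!cc), " row(s) with missing values")
    x <- x[cc, , drop = FALSE]
  }
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("pca() needs >= 3 samples and >= 2 variables", call. = FALSE)
  }
  if (standardize) {
    const <- apply(x, 2, var) == 0
    if (any(const)) {
      warning("dropping constant variable(s): ",
              paste(colnames(x)[const], collapse = ", "))
      x <- x[, !const, drop = FALSE]
      if (ncol(x) < 2L) stop("fewer than 2 variables left after dropping constants",
                             call. = FALSE)
    }
  }
  fit <- prcomp(x, center = TRUE, scale. = standardize)
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  structure(list(scores = fit$x, loadings = fit$rotation,
                 eig = fit$sdev^2, center = fit$center, scale = fit$scale),
            class = "habnet_pca")
}

check_aligned <- function(d, x) {
  n <- attr(d, "Size")
  if (is.null(n)) n <- nrow(as.matrix(d))
  if (NROW(x) != n) {
    stop("covariates (", NROW(x), " rows) do not match distance matrix (",
         n, " samples)", call. = FALSE)
  }
  n
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sum of squares of a dissimilarity matrix by one or more
#' covariates (sequential terms) and tests the pseudo-F statistic against a
#' permutation null, via [vegan::adonis2()]. P-values use the standard
#' `(1 + hits) / (1 + n_perm)` correction. With `exhaustive = TRUE` every
#' relabelling of the samples is enumerated instead of sampling, so the
#' p-value is exact.
#'
#' @param d A `dist` object.
#' @param covariates Numeric vector, factor, or data frame of per-sample
#'   covariates aligned with `d`; data-frame columns are fitted sequentially
#'   in order.
#' @param n_perm Number of random permutations (>= 99).
#' @param seed Integer seed for the permutation RNG.
#' @param exhaustive Enumerate all permutations (only sensible for <= 7
#'   samples).
#' @return Data frame with one row per term (plus Residual/Total): `term`,
#'   `df`, `SumOfSqs`, `R2`, `F`, `p`. Attributes `n_perm` and `seed` record
#'   the permutation design.
#' @export
permanova <- function(d, covariates, n_perm = 999, seed = 1L, exhaustive = FALSE) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (is.null(dim(covariates))) covariates <- data.frame(covariate = covariates)
  covariates <- as.data.frame(covariates)
  n <- check_aligned(d, covariates)
  for (v in names(covariates)) {
    if (length(unique(covariates[[v]])) < 2L) {
      stop("covariate '", v, "' is constant", call. = FALSE)
    }
  }
  if (exhaustive) {
    perm <- permute::allPerms(n, control = permute::how())
  } else {
    if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
    set.seed(seed)
    perm <- n_perm
  }
  fit <- vegan::adonis2(d ~ ., data = covariates, permutations = perm,
                        by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df, SumOfSqs = fit$SumOfSqs,
                    R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`, row.names = NULL)
  attr(out, "n_perm") <- if (exhaustive) nrow(perm) else n_perm
  attr(out, "seed") <- if (exhaustive) NA_integer_ else seed
  out
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' Constrained ordination of a dissimilarity matrix on explanatory axes:
#' principal-coordinate embedding of `d`, regression of the coordinates on the
#' constraints and eigen-analysis of the fitted values, via [vegan::dbrda()].
#' The constrained-inertia fraction equals the PERMANOVA R2 of the same model
#' on the same distances.
#'
#' @param d A `dist` object.
#' @param constraints Data frame or numeric vector of per-sample constraining
#'   variables.
#' @param counts Optional OTU count matrix (OTUs x samples) used to add
#'   species scores (weighted-average projections) to the ordination.
#' @param sqrt_dist Square-root transform the dissimilarities before embedding
#'   (reduces negative-eigenvalue mass for Bray-Curtis input).
#' @param neg_tol Warn when the negative-eigenvalue mass exceeds this fraction
#'   of total inertia.
#' @return List with the fitted `vegan` ordination (`ordination`), `site_scores`,
#'   `species_scores` (or `NULL`), `constrained_eig`, `constrained_fraction`,
#'   and `negative_mass`.
#' @export
dbrda <- function(d, constraints, counts = NULL, sqrt_dist = FALSE,
                  neg_tol = 0.05) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (is.null(dim(constraints))) constraints <- data.frame(constraint = constraints)
  constraints <- as.data.frame(constraints)
  check_aligned(d, constraints)
  if (qr(as.matrix(data.matrix(constraints)))$rank < 1L) {
    stop("constraints have rank 0", call. = FALSE)
  }
  if (sqrt_dist) d <- sqrt(d)
  fit <- vegan::dbrda(d ~ ., data = constraints)
  eig_all <- c(fit$CCA$eig, fit$CA$eig)
  neg_mass <- sum(abs(eig_all[eig_all < 0])) / sum(abs(eig_all))
  if (neg_mass > neg_tol) {
    warning(sprintf("negative-eigenvalue mass %.3f exceeds tolerance %.3f",
                    neg_mass, neg_tol))
  }
  # suppressed: vegan pads the score scaling on degenerate (zero-inertia)
  # constrained axes
  site <- suppressWarnings(vegan::scores(fit, display = "sites",
                                         choices = seq_along(fit$CCA$eig)))
  spp <- NULL
  if (!is.null(counts)) {
    check_otu_counts(counts)
    spp <- vegan::wascores(site, t(counts))
  }
  list(ordination = fit,
       site_scores = site,
       species_scores = spp,
       constrained_eig = fit$CCA$eig,
       constrained_fraction = fit$CCA$tot.chi / fit$tot.chi,
       negative_mass = neg_mass)
}

#' Screen OTUs against an ordination axis with Spearman correlations
#'
#' Rank-correlates each OTU's abundance profile with a per-sample axis (e.g. a
#' principal component) and flags correlations with `p < alpha`. Constant OTU
#' vectors have undefined rank correlation and are reported as `NA`.
#'
#' @param counts OTU count matrix (OTUs x samples).
#' @param axis Numeric per-sample scores aligned with the table columns.
#' @param alpha Significance level for flagging.
#' @return Data frame with `otu_id`, `rho`, `p`, `significant`.
#' @export
spearman_screen <- function(counts, axis, alpha = 0.05) {
  check_otu_counts(counts)
  if (ncol(counts) != length(axis)) {
    stop("axis length does not match number of samples", call. = FALSE)
  }
  if (ncol(counts) < 5L) stop("need >= 5 samples", call. = FALSE)
  res <- apply(counts, 1, function(x) {
    if (length(unique(x)) < 2L) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(x, axis, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  data.frame(otu_id = rownames(counts), rho = res[1, ], p = res[2, ],
             significant = !is.na(res[2, ]) & res[2, ] < alpha,
             row.names = NULL)
}

#' Procrustes concordance Monte Carlo test
#'
#' Measures the concordance of two sample-by-axis score matrices as the sum of
#' the singular values of the cross-product of the column-centered matrices,
#' each scaled to unit sum of squares (so the statistic is 1 when one matrix
#' is a rigid rotation of the other). Significance comes from permuting the
#' rows of `y`.
#'
#' @param x,y Numeric score matrices with the same samples in rows (>= 3).
#' @param n_perm Number of row permutations.
#' @param seed Integer seed for the permutation RNG.
#' @return List of class `procrustes_test` with `statistic`, `p`, `n_perm`,
#'   `seed`.
#' @export
procrustes_test <- function(x, y, n_perm = 999, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same samples", call. = FALSE)
  if (nrow(x) < 3L) stop("need >= 3 samples", call. = FALSE)
  normalize <- function(m) {
    m <- scale(m, center = TRUE, scale = FALSE)
    ss <- sum(m^2)
    if (ss == 0) stop("input matrix has rank 0 after centering", call. = FALSE)
    m / sqrt(ss)
  }
  x <- normalize(x); y <- normalize(y)
  stat <- function(a, b) sum(svd(crossprod(a, b))$d)
  obs <- stat(x, y)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (stat(x, y[sample.int(nrow(y)), , drop = FALSE]) >= obs) hits <- hits + 1L
  }
  structure(list(statistic = obs, p = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "procrustes_test")
}

#' @export
print.procrustes_test <- function(x, ...) {
  cat("Procrustes concordance Monte Carlo test\n")
  cat(sprintf("  statistic (sum of singular values): %.4f\n", x$statistic))
  cat(sprintf("  permutation p-value: %.4g  (%d permutations)\n", x$p, x$n_perm))
  invisible(x)
}

#' Abiotic-gradient analysis chain
#'
#' Runs the full ordination chain for one marker x colonization-status
#' stratum: PCA of the abiotic variables, sequential PERMANOVA of the
#' community dissimilarities on the first two principal components, dbRDA
#' constrained on the same axes, and a Spearman OTU screen against each
#' axis whose PERMANOVA term is significant. Screen tables are present for
#' both axes regardless of significance (empty result sets stay empty, they
#' are never dropped).
#'
#' @param d Community dissimilarity (`dist`), e.g. from [bray_curtis()].
#' @param abiotic Samples x variables numeric table (same sample order as `d`).
#' @param counts OTU count matrix for the same samples.
#' @param n_perm,seed Permutation design passed to [permanova()].
#' @param alpha Significance level for axis terms and the OTU screen.
#' @param sqrt_dist Square-root transform dissimilarities for the dbRDA stage.
#' @return List with `pca`, `permanova`, `dbrda`, `screen` (one data frame per
#'   axis with a `tested` attribute), `alpha`, `seed`.
#' @export
gradient_analysis <- function(d, abiotic, counts, n_perm = 999, seed = 1L,
                              alpha = 0.05, sqrt_dist = TRUE) {
  check_otu_counts(counts)
  ord <- tryCatch(pca(abiotic, standardize = TRUE),
                  error = function(e) stop("pca stage: ", conditionMessage(e), call. = FALSE))
  axes <- as.data.frame(ord$scores[, 1:2, drop = FALSE])
  names(axes) <- c("PC1", "PC2")
  perm <- tryCatch(permanova(d, axes, n_perm = n_perm, seed = seed),
                   error = function(e) stop("permanova stage: ", conditionMessage(e), call. = FALSE))
  dbr <- tryCatch(dbrda(d, axes, counts = counts, sqrt_dist = sqrt_dist),
                  error = function(e) stop("dbrda stage: ", conditionMessage(e), call. = FALSE))
  screen <- lapply(names(axes), function(ax) {
    p_ax <- perm$p[perm$term == ax]
    sig <- isTRUE(p_ax < alpha)
    scr <- spearman_screen(counts, axes[[ax]], alpha = alpha)
    if (!sig) scr <- scr[0, , drop = FALSE]
    attr(scr, "tested") <- sig
    scr
  })
  names(screen) <- names(axes)
  list(pca = ord, permanova = perm, dbrda = dbr, screen = screen,
       alpha = alpha, seed = seed)
}
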