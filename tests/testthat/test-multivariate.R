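test_that("pca recovers collinear structure and conserves variance", {
  x <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  ord <- pca(x, standardize = FALSE)
  expect_equal(ord$eig[1] / sum(ord$eig), 1)
  xs <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  ords <- pca(xs, standardize = TRUE)
  expect_equal(sum(ords$eig), 3)  # trace of the correlation matrix
  expect_true(all(diff(ords$eig) <= 1e-12))
  expect_equal(colMeans(ords$scores), rep(0, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(crossprod(ords$loadings), diag(3), ignore_attr = TRUE)
  # reconstruction oracle at full rank (unstandardized)
  ord2 <- pca(xs, standardize = FALSE)
  rec <- ord2$scores %*% t(ord2$loadings) +
    matrix(ord2$center, 20, 3, byrow = TRUE)
  expect_equal(rec, xs, ignore_attr = TRUE)
  # sign convention: dominant loading positive on every axis
  for (j in 1:3) expect_gt(ord2$loadings[which.max(abs(ord2$loadings[, j])), j], 0)
  xc <- cbind(xs, const = 1)
  expect_warning(ordc <- pca(xc), "constant")
  expect_equal(ncol(ordc$loadings), 3)
})

test_that("permanova partitions perfectly separated clusters with R2 = 1", {
  d <- two_cluster_dist(3)
  res <- permanova(d, factor(rep(c("x", "y"), each = 3)), exhaustive = TRUE)
  expect_equal(res$R2[1], 1)
  expect_equal(sum(res$R2), 1 + res$R2[nrow(res)])  # terms + residual + total
})

test_that("seeded permutation p matches exhaustive enumeration on 6 samples", {
  counts <- otu_fixture(15, 6, seed = 3)
  d <- bray_curtis(counts)
  x <- c(0.3, -1, 2, 0.5, -0.2, 1.1)
  res <- permanova(d, x, exhaustive = TRUE)
  oracle <- permanova_oracle(d, x)
  expect_equal(res$F[1], oracle$F)
  expect_equal(res$p[1], oracle$p)
})

test_that("permanova validates covariates and is reproducible under a seed", {
  counts <- otu_fixture(15, 8, seed = 4)
  d <- bray_curtis(counts)
  expect_error(permanova(d, rep(1, 8)), "constant")
  expect_error(permanova(d, rnorm(5)), "match")
  x <- rnorm(8)
  r1 <- permanova(d, x, n_perm = 199, seed = 11)
  r2 <- permanova(d, x, n_perm = 199, seed = 11)
  expect_identical(r1, r2)
})

test_that("dbrda constrained inertia equals PERMANOVA R2 on shared input", {
  d <- two_cluster_dist(3)
  grp <- c(0, 0, 0, 1, 1, 1)
  expect_equal(dbrda(d, grp)$constrained_fraction,
               permanova(d, grp, n_perm = 99, seed = 1)$R2[1],
               tolerance = 1e-10)
  counts <- otu_fixture(20, 10, seed = 5)
  d2 <- bray_curtis(counts)
  x <- rnorm(10)
  expect_equal(dbrda(d2, x)$constrained_fraction,
               permanova(d2, x, n_perm = 99, seed = 1)$R2[1],
               tolerance = 1e-10)
})

test_that("dbrda yields zero constrained inertia for orthogonal constraints", {
  coords <- matrix(1:8, ncol = 1)  # all community variation on one axis
  d <- stats::dist(coords)
  z <- residuals(lm(rnorm(8) ~ coords))  # exactly orthogonal to the axis
  expect_equal(dbrda(d, as.numeric(z))$constrained_fraction, 0,
               tolerance = 1e-10)
})

test_that("dbrda on Euclidean distances equals redundancy analysis on coordinates", {
  set.seed(8)
  X <- matrix(rnorm(40), 10, 4)
  z <- rnorm(10)
  fit <- dbrda(stats::dist(X), z)
  rda_fit <- vegan::rda(X ~ z)
  expect_equal(fit$constrained_fraction,
               rda_fit$CCA$tot.chi / rda_fit$tot.chi, tolerance = 1e-10)
})

test_that("spearman screen matches the rank-correlation oracle", {
  counts <- otu_fixture(10, 8, seed = 6)
  axis <- rnorm(8)
  counts[1, ] <- as.integer(rank(axis) * 3)          # monotone transform
  counts[2, ] <- as.integer(3 * (9 - rank(axis)))    # reversed ranks
  counts[3, ] <- 5L                                  # constant
  scr <- spearman_screen(counts, axis)
  expect_equal(scr$rho[1], 1)
  expect_equal(scr$rho[2], -1)
  expect_true(is.na(scr$rho[3]))
  # tied-rank oracle: Pearson correlation of the rank vectors
  x <- counts[4, ]
  expect_equal(scr$rho[4], stats::cor(rank(x), rank(axis)))
  expect_error(spearman_screen(counts[, 1:4], axis[1:4]), ">= 5")
})

test_that("procrustes concordance is exact for rotations and matches protest", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  theta <- 0.7
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rot <- procrustes_test(X, X %*% R, n_perm = 99, seed = 1)
  expect_equal(rot$statistic, 1)
  expect_equal(rot$p, 1 / 100)  # smallest attainable
  # statistic invariant to orthogonal rotation of either input
  Y <- matrix(rnorm(30), 10, 3)
  s0 <- procrustes_test(X, Y, n_perm = 99, seed = 1)$statistic
  expect_equal(procrustes_test(X %*% R, Y, n_perm = 99, seed = 1)$statistic, s0)
  # independent route: vegan::protest computes the same statistic
  expect_equal(s0, vegan::protest(X, Y, permutations = 19)$t0)
  expect_error(procrustes_test(matrix(1, 5, 2), Y[1:5, ]), "rank 0")
})

test_that("procrustes p-values are roughly uniform under independence", {
  set.seed(21)
  ps <- replicate(60, {
    procrustes_test(matrix(rnorm(16), 8, 2), matrix(rnorm(16), 8, 2),
                    n_perm = 99, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(min(ps), 0)
})

test_that("gradient analysis reports every stage for both axes", {
  study <- simulate_study(n_gardens = 8, depths = c("16S" = 400),
                          richness = c("16S" = 80), seed = 2)
  counts <- rarefy(study$otu$`16S`$counts[, 1:16], 400, seed = 1)
  abio <- study$water[match(colnames(counts), study$water$sample_id),
                      c("temperature", "ph", "n2o", "ch4", "toc")]
  rep <- gradient_analysis(bray_curtis(counts), abio, counts,
                           n_perm = 99, seed = 1)
  expect_named(rep$screen, c("PC1", "PC2"))
  expect_s3_class(rep$permanova, "data.frame")
  expect_true(all(c("PC1", "PC2") %in% rep$permanova$term))
  for (ax in c("PC1", "PC2")) {
    expect_true(is.data.frame(rep$screen[[ax]]))  # present even when empty
    expect_false(is.null(attr(rep$screen[[ax]], "tested")))
  }
  # stage errors carry the stage name
  expect_error(gradient_analysis(bray_curtis(counts), abio[, 1, drop = FALSE],
                                 counts, n_perm = 99, seed = 1),
               "pca stage")
})

test_that("planted pollution gradients are detected with high power", {
  hits <- vapply(seq_len(100), function(s) {
    g <- simulate_gardens(20, seed = 5000 + s)
    tab <- simulate_otu_table(g, paired_samples(g), depth = 4103,
                              richness = 300, gradient_fraction = 0.3,
                              gradient_slope = 1, n_neg = 0, seed = 6000 + s)
    d <- bray_curtis(tab$counts)
    permanova(d, unname(tab$truth$axis), n_perm = 199, seed = s)$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
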