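test_that("modified z-score follows the median/MAD formula", {
  z <- modified_zscore(c(1, 2, 3, 4, 100))
  expect_equal(as.numeric(z), c(-2, -1, 0, 1, 97))  # med 3, MAD 1
  expect_equal(attr(z, "med"), 3)
  expect_equal(attr(z, "mad"), 1)
  x <- rnorm(30)
  expect_equal(as.numeric(modified_zscore(x + 5)),
               as.numeric(modified_zscore(x)))  # shift invariance
  expect_equal(as.numeric(modified_zscore(x * 3)),
               as.numeric(modified_zscore(x)))  # scale equivariance cancels
  z0 <- modified_zscore(c(2, 2, 2, 9))
  expect_false(attr(z0, "binarizable"))
  expect_true(all(is.na(z0)))
  expect_error(modified_zscore(c(1, 2)), ">= 3")
})

test_that("binarization flags only exceptionally high values, monotonically", {
  z <- c(-2, -1, 0, 1, 97)
  expect_identical(binarize(z, 3.5), c(0L, 0L, 0L, 0L, 1L))
  expect_identical(binarize(c(-5, 0, 2), 3.5), c(0L, 0L, 0L))
  set.seed(1)
  zz <- rnorm(100, 0, 4)
  expect_true(all(binarize(zz, 4) <= binarize(zz, 2)))  # raising never adds 1s
  expect_error(binarize(z, 0), "> 0")
})

test_that("Zhang's score hits its analytic anchor points", {
  a <- c(1, 1, 0, 0, 0)
  expect_equal(zhang_score(a, a), 1)
  expect_equal(zhang_score(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  # exact independence: P(AB) = P(A) P(B)
  expect_equal(zhang_score(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_error(zhang_score(c(1, 1, 1), c(1, 0, 1)), "constant")
  expect_error(zhang_score(a, a[1:3]), "equal length")
})

test_that("Zhang's score is the larger of the two rule directions", {
  a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)  # support 0.5
  b <- c(1, 1, 1, 1, 0, 1, 1, 0, 0, 0)  # support 0.6, co-occurrence 0.4
  directed <- function(p_a, p_b, p_ab) {
    (p_ab - p_a * p_b) / max(p_ab * (1 - p_a), p_a * (p_b - p_ab))
  }
  expect_equal(directed(0.5, 0.6, 0.4), 0.5)  # formula arithmetic
  expect_equal(zhang_score(a, b), max(directed(0.5, 0.6, 0.4),
                                      directed(0.6, 0.5, 0.4)))
  expect_equal(zhang_score(a, b), zhang_score(b, a))
  set.seed(4)
  for (i in 1:50) {
    x <- rbinom(30, 1, 0.4); y <- rbinom(30, 1, 0.4)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_lte(abs(zhang_score(x, y)), 1)
  }
})

test_that("binomial edge test equals the exact tail sum", {
  # disjoint events: zero co-occurrence has tail probability 1
  expect_equal(binomial_edge_test(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 0)), 1)
  # supports 0.5/0.5 on n = 10 with co-occurrence 5: p0 = 0.25
  a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  b <- a
  tail_oracle <- sum(choose(10, 5:10) * 0.25^(5:10) * 0.75^(10 - 5:10))
  expect_equal(binomial_edge_test(a, b), tail_oracle)
  # nonincreasing in the co-occurrence count at fixed margins
  k_p <- vapply(3:5, function(k) {
    x <- integer(10); y <- integer(10)
    x[1:5] <- 1L
    y[seq_len(k)] <- 1L                       # overlap k with x
    if (k < 5) y[6:(10 - k)] <- 1L            # pad to support 5
    binomial_edge_test(x, y)
  }, numeric(1))
  expect_true(all(diff(k_p) < 0))
  expect_warning(p1 <- binomial_edge_test(c(1, 1, 1), c(1, 0, 1)), "degenerate")
  expect_equal(p1, 1)
})

test_that("exceptionality matrix handles mixed types and MAD-zero variables", {
  df <- data.frame(num = c(rnorm(19), 50),
                   flat = rep(2, 20),
                   status = rep(c("NC", "C"), 10),
                   flag = rep(c(TRUE, FALSE), 10),
                   bin = rep(c(1, 0), 10))
  expect_message(exc <- exceptionality_matrix(df), "MAD = 0")
  expect_true(all(exc$matrix %in% c(0L, 1L)))
  expect_true(all(c("num", "status=NC", "status=C", "flag", "bin") %in%
                    colnames(exc$matrix)))
  expect_false("flat" %in% colnames(exc$matrix))
  expect_equal(exc$matrix[, "bin"], as.integer(df$bin), ignore_attr = TRUE)
  expect_false(exc$audit$kept[exc$audit$variable == "flat"])
})

test_that("planted duplicate variables form a certain edge", {
  set.seed(2)
  pat <- as.integer(runif(100) < 0.2)
  bin <- cbind(v1 = pat, v2 = pat,
               noise = as.integer(runif(100) < 0.2))
  net <- build_network(bin)
  e <- net$edges[net$edges$source == "v1" & net$edges$target == "v2", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$zhang, 1)
  expect_lt(e$binom_p, 0.001)
  expect_equal(e$support_ab, mean(pat))
})

test_that("relaxing either threshold never removes an edge", {
  set.seed(6)
  bin <- matrix(rbinom(200 * 8, 1, 0.3), 200, 8,
                dimnames = list(NULL, paste0("v", 1:8)))
  strict <- build_network(bin, zhang_min = 0.4, alpha = 0.01)
  loose <- build_network(bin, zhang_min = 0.1, alpha = 0.1)
  expect_true(all(edge_key(strict$edges) %in% edge_key(loose$edges)))
  # deterministic for fixed inputs
  expect_identical(build_network(bin), build_network(bin))
})

test_that("edge supports are coherent and empty graphs are valid", {
  set.seed(9)
  bin <- matrix(rbinom(50 * 6, 1, 0.4), 50, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
  net <- build_network(bin, zhang_min = 0.99, alpha = 1e-9)
  expect_s3_class(net, "association_graph")
  expect_true(all(c("source", "target", "zhang", "binom_p") %in%
                    names(net$edges)))
  all_pairs <- build_network(bin, zhang_min = -1, alpha = 1)
  with(all_pairs$edges, {
    expect_true(all(support_ab <= pmin(support_a, support_b)))
    expect_true(all(abs(zhang) <= 1))
    expect_true(all(binom_p > 0 & binom_p <= 1))
    expect_true(all(n == 50))
  })
  # pairwise-complete handling records the per-edge n
  bin[1:10, "v1"] <- NA
  net_na <- build_network(bin, zhang_min = -1, alpha = 1)
  e <- net_na$edges
  expect_true(all(e$n[e$source == "v1" | e$target == "v1"] == 40))
})

test_that("the method runs end-to-end at the 13-sample mixed-kingdom scale", {
  # the scale of the study's colonized-water network: 13 samples, mixed kinds;
  # with so few samples the exact binomial is discreteness-limited, so the
  # check is well-formedness plus majority recovery, with no spurious edges
  pl <- plant_associations(13, 25, pairs = cbind(1:3, 4:6), support = 0.25,
                           seed = 3)
  exc <- exceptionality_matrix(as.data.frame(pl$data))
  kinds <- setNames(rep(c("bacteria", "fungi", "physicochemical"),
                        length.out = 25), colnames(pl$data))
  net <- build_network(exc$matrix, kinds = kinds)
  expect_true(all(edge_key(net$edges) %in% edge_key(pl$truth)))
  expect_gte(sum(edge_key(pl$truth) %in% edge_key(net$edges)), 2)
  expect_true(all(net$nodes$kind %in% c("bacteria", "fungi", "physicochemical")))
})
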