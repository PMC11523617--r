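#' Modified z-score (median / MAD standardization)
#'
#' Robust standardization `z_i = (x_i - med(x)) / MAD` with
#' `MAD = median(|x_i - med(x)|)` (no consistency constant), resistant to the
#' outliers it is designed to flag. When the MAD is 0 the variable cannot be
#' binarized and all values are returned as `NA` with attribute
#' `binarizable = FALSE`.
#'
#' @param x Numeric vector with >= 3 finite values.
#' @return Numeric vector of modified z-scores; attribute `med` and `mad`
#'   record the location/scale used.
#' @export
#' @examples
#' modified_zscore(c(1, 2, 3, 4, 100))
modified_zscore <- function(x) {
  if (sum(is.finite(x)) < 3L) stop("need >= 3 finite values", call. = FALSE)
  med <- median(x, na.rm = TRUE)
  mad0 <- median(abs(x - med), na.rm = TRUE)
  if (mad0 == 0) {
    z <- rep(NA_real_, length(x))
    return(structure(z, med = med, mad = 0, binarizable = FALSE))
  }
  structure((x - med) / mad0, med = med, mad = mad0, binarizable = TRUE)
}

#' Binarize modified z-scores at an exceptionality threshold
#'
#' One-sided: only exceptionally HIGH values are flagged, so `z > threshold`
#' maps to 1 and everything else (including `NA`) to 0 or `NA`.
#'
#' The default threshold carries the classical robust-outlier convention
#' (flag beyond 3.5 on the 0.6745-scaled modified z-score) onto the unscaled
#' score used here: `3.5 / 0.6745` (about 5.19) MAD units, i.e. roughly 3.5
#' standard deviations for Gaussian variation. Applying 3.5 directly to the
#' unscaled score would flag about 1% of ordinary Gaussian samples as
#' "exceptional", flooding downstream association screens with chance
#' co-occurrences.
#'
#' @param z Numeric vector of modified z-scores.
#' @param threshold Positive exceptionality threshold (unscaled MAD units).
#' @return Integer vector in `{0, 1}` (NA preserved).
#' @export
binarize <- function(z, threshold = 3.5 / 0.6745) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  as.integer(z > threshold)
}

#' Exceptionality matrix of a mixed-type variable table
#'
#' Converts a samples x variables table into binary exceptionality indicators:
#' numeric variables are modified-z-scored and thresholded (1 = exceptionally
#' high); logical, factor/character (via 0/1 dummy levels) and already-binary
#' 0/1 columns enter directly as indicators. Numeric variables with MAD = 0
#' cannot be binarized and are dropped with a message.
#'
#' @param data Data frame or matrix, samples in rows.
#' @param threshold Exceptionality threshold passed to [binarize()].
#' @return List with `matrix` (samples x variables, values 0/1/NA), `audit`
#'   (per numeric variable: median, MAD, kept) and `threshold`.
#' @export
exceptionality_matrix <- function(data, threshold = 3.5 / 0.6745) {
  data <- as.data.frame(data)
  cols <- list()
  audit <- data.frame(variable = character(), med = numeric(), mad = numeric(),
                      kept = logical())
  for (v in names(data)) {
    x <- data[[v]]
    if (is.logical(x)) {
      cols[[v]] <- as.integer(x)
    } else if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      for (lev in levels(x)) {
        cols[[paste(v, lev, sep = "=")]] <- as.integer(x == lev)
      }
    } else if (is.numeric(x)) {
      if (all(x %in% c(0L, 1L, NA))) {
        cols[[v]] <- as.integer(x)
        next
      }
      z <- modified_zscore(x)
      keep <- isTRUE(attr(z, "binarizable"))
      audit <- rbind(audit, data.frame(variable = v, med = attr(z, "med"),
                                       mad = attr(z, "mad"), kept = keep))
      if (keep) {
        cols[[v]] <- binarize(z, threshold)
      } else {
        message("variable '", v, "' has MAD = 0; dropped from exceptionality matrix")
      }
    } else {
      stop("unsupported column type for '", v, "'", call. = FALSE)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(data)
  list(matrix = m, audit = audit, threshold = threshold)
}

zhang_directed <- function(p_a, p_b, p_ab) {
  den <- max(p_ab * (1 - p_a), p_a * (p_b - p_ab))
  if (den == 0) return(0)
  (p_ab - p_a * p_b) / den
}

#' Zhang's association-rule score for two binary vectors
#'
#' Interestingness metric in `[-1, 1]`: 0 under independence, +1 at perfect
#' association, -1 at perfect disassociation. With supports `P(A)`, `P(B)`
#' and `P(AB)` estimated as sample frequencies the directed score is
#' `(P(AB) - P(A)P(B)) / max(P(AB)(1 - P(A)), P(A)(P(B) - P(AB)))`; the score
#' is computed in both rule directions and the maximum is returned (0 when a
#' denominator vanishes).
#'
#' @param a,b Binary vectors (0/1) of equal length >= 3, both non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' zhang_score(c(1, 1, 0, 0), c(1, 1, 0, 0))
zhang_score <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need n >= 3", call. = FALSE)
  if (!all(a %in% 0:1) || !all(b %in% 0:1)) stop("inputs must be binary 0/1", call. = FALSE)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    stop("Zhang's score is undefined for constant vectors", call. = FALSE)
  }
  p_a <- mean(a); p_b <- mean(b); p_ab <- mean(a & b)
  max(zhang_directed(p_a, p_b, p_ab), zhang_directed(p_b, p_a, p_ab))
}

#' Exact binomial test for excess co-occurrence
#'
#' One-sided exact tail probability `P[K >= k_obs]` for
#' `K ~ Binomial(n, P(A) P(B))`, where `k_obs` is the observed co-occurrence
#' count and the independence null `P(A) P(B)` uses the marginal supports.
#' Degenerate supports (0 or 1) make the null uninformative; `p = 1` is
#' returned with a warning.
#'
#' @param a,b Binary vectors (0/1) of equal length.
#' @return P-value in `(0, 1]`.
#' @export
binomial_edge_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (!all(a %in% 0:1) || !all(b %in% 0:1)) stop("inputs must be binary 0/1", call. = FALSE)
  n <- length(a)
  p_a <- mean(a); p_b <- mean(b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warning("degenerate support; p-value set to 1")
    return(1)
  }
  k <- sum(a & b)
  pbinom(k - 1, n, p_a * p_b, lower.tail = FALSE)
}

#' Build a mixed-type association network
#'
#' For every unordered pair of binary exceptionality variables, computes
#' Zhang's score, the exact binomial co-occurrence test, and (for reference)
#' the Spearman rank correlation of the two indicators, on pairwise-complete
#' samples. An edge is retained iff `zhang > zhang_min` AND
#' `p < alpha`. Constant or degenerate pairs are scored as no-association and
#' never form edges. An empty edge set is a valid result.
#'
#' @param bin Samples x variables binary matrix (0/1, `NA` allowed), e.g. from
#'   [exceptionality_matrix()]; categorical indicator columns may be bound in
#'   directly.
#' @param kinds Optional named character vector mapping variable ids to a kind
#'   label (e.g. bacteria / fungi / eukaryote / organic molecule /
#'   physicochemical).
#' @param zhang_min Minimal Zhang score (exclusive), default 0.25.
#' @param alpha Significance level for the binomial test.
#' @return Object of class `association_graph`: list with `nodes` (id, kind),
#'   `edges` (source, target, zhang, spearman_rho, binom_p, supports, n),
#'   and `thresholds`.
#' @export
build_network <- function(bin, kinds = NULL, zhang_min = 0.25, alpha = 0.05) {
  bin <- as.matrix(bin)
  if (is.null(colnames(bin))) colnames(bin) <- paste0("V", seq_len(ncol(bin)))
  if (ncol(bin) < 2L) stop("need >= 2 variables", call. = FALSE)
  if (!all(bin %in% c(0, 1, NA))) stop("bin must contain only 0/1/NA", call. = FALSE)
  vars <- colnames(bin)
  pairs <- combn(length(vars), 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ok <- !is.na(bin[, i1]) & !is.na(bin[, i2])
    a <- bin[ok, i1]; b <- bin[ok, i2]
    n <- length(a)
    if (n < 3L || length(unique(a)) < 2L || length(unique(b)) < 2L) next
    z <- zhang_score(a, b)
    p <- suppressWarnings(binomial_edge_test(a, b))
    rho <- suppressWarnings(stats::cor(a, b, method = "spearman"))
    rows[[j]] <- data.frame(source = vars[i1], target = vars[i2],
                            zhang = z, spearman_rho = rho, binom_p = p,
                            support_a = mean(a), support_b = mean(b),
                            support_ab = mean(a & b), n = n)
  }
  all_pairs <- do.call(rbind, rows)
  if (is.null(all_pairs)) {
    all_pairs <- data.frame(source = character(), target = character(),
                            zhang = numeric(), spearman_rho = numeric(),
                            binom_p = numeric(), support_a = numeric(),
                            support_b = numeric(), support_ab = numeric(),
                            n = integer())
  }
  edges <- all_pairs[all_pairs$zhang > zhang_min & all_pairs$binom_p < alpha, ,
                     drop = FALSE]
  rownames(edges) <- NULL
  node_kind <- if (is.null(kinds)) rep(NA_character_, length(vars)) else
    unname(kinds[vars])
  structure(list(nodes = data.frame(id = vars, kind = node_kind),
                 edges = edges,
                 thresholds = list(zhang_min = zhang_min, alpha = alpha)),
            class = "association_graph")
}

#' @export
print.association_graph <- function(x, ...) {
  cat("Association graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat(sprintf("  retention: Zhang > %.3g and binomial p < %.3g\n",
              x$thresholds$zhang_min, x$thresholds$alpha))
  invisible(x)
}
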