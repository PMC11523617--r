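# shared fixture builders; everything is generated in code

otu_fixture <- function(n_otu = 15, n_samp = 6, lambda = 20, seed = 1) {
  set.seed(seed)
  matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp,
         dimnames = list(sprintf("OTU%02d", seq_len(n_otu)),
                         sprintf("S%02d", seq_len(n_samp))))
}

paired_samples <- function(gardens) {
  n <- nrow(gardens)
  data.frame(sample_id = paste0(rep(gardens$garden_id, each = 2), c("_NC", "_C")),
             garden_id = rep(gardens$garden_id, each = 2),
             status = rep(c("NC", "C"), n))
}

# unordered edge keys for truth comparison
edge_key <- function(df) paste(pmin(df$source, df$target),
                               pmax(df$source, df$target))

# two-cluster 0/1 distance matrix: all within-cluster distances 0,
# between-cluster distances 1 (Euclidean-embeddable)
two_cluster_dist <- function(n_per = 3) {
  m <- matrix(1, 2 * n_per, 2 * n_per)
  m[seq_len(n_per), seq_len(n_per)] <- 0
  m[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- 0
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", seq_len(2 * n_per))
  stats::as.dist(m)
}

# independent PERMANOVA oracle: direct Gower partition, exhaustive relabelling
permanova_oracle <- function(d, x) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  A <- -dm^2 / 2
  J <- diag(n) - 1 / n
  G <- J %*% A %*% J
  f_of <- function(xx) {
    X <- cbind(1, xx)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    ssm <- sum(diag(H %*% G))
    sst <- sum(diag(G))
    (ssm / 1) / ((sst - ssm) / (n - 2))
  }
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  f_all <- apply(perms, 1, function(p) f_of(x[p]))
  f_obs <- f_of(x)
  list(F = f_obs, p = mean(f_all >= f_obs))
}
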