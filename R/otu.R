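# OTU tables are plain integer matrices: rows = OTUs (rownames = OTU ids),
# columns = samples (colnames = sample ids). Sample metadata travels in a
# separate data.frame keyed by sample_id, as in vegan-style workflows.

check_otu_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (OTUs x samples)", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts needs unique sample ids as colnames", call. = FALSE)
  }
  invisible(counts)
}

#' Remove contaminant OTUs using negative controls
#'
#' An OTU detected in any negative-control sample is treated as a contaminant
#' and removed unless its relative abundance in the study samples is at least
#' `factor` times its relative abundance in the negative controls. Relative
#' abundances are computed per sample (count / sample total); the study-side
#' statistic is the maximum over study samples and the control-side statistic
#' the maximum over negative controls. OTUs absent from all controls are
#' retained. Negative-control columns are dropped from the output.
#'
#' @param counts OTU count matrix (OTUs x samples).
#' @param neg_ids Character vector of negative-control sample ids (columns of
#'   `counts`).
#' @param factor Retention multiplier; the published rule uses 10.
#' @return Filtered count matrix without the negative-control columns.
#' @export
filter_contaminants <- function(counts, neg_ids, factor = 10) {
  check_otu_counts(counts)
  if (length(neg_ids) == 0L) stop("neg_ids must be nonempty", call. = FALSE)
  unknown <- setdiff(neg_ids, colnames(counts))
  if (length(unknown)) {
    stop("unknown negative-control samples: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  study_ids <- setdiff(colnames(counts), neg_ids)
  rel <- sweep(counts, 2, colSums(counts), "/")
  rel[, colSums(counts) == 0] <- 0
  neg_rel <- rel[, neg_ids, drop = FALSE]
  study_rel <- rel[, study_ids, drop = FALSE]
  in_neg <- apply(neg_rel > 0, 1, any)
  max_neg <- apply(neg_rel, 1, max)
  max_study <- apply(study_rel, 1, max)
  keep <- !in_neg | (max_study >= factor * max_neg)
  counts[keep, study_ids, drop = FALSE]
}

#' Remove rare OTUs by overall relative abundance
#'
#' Drops OTUs whose total count across all samples is below
#' `fraction` x (grand total). The boundary is inclusive: an OTU exactly at
#' the threshold is retained.
#'
#' @param counts OTU count matrix.
#' @param fraction Abundance fraction in `[0, 1]`; the published pipeline uses
#'   0.005% (`5e-5`).
#' @return Filtered count matrix.
#' @export
filter_rare <- function(counts, fraction = 5e-5) {
  check_otu_counts(counts)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  grand <- sum(counts)
  if (grand <= 0) stop("table has no reads", call. = FALSE)
  counts[rowSums(counts) >= fraction * grand, , drop = FALSE]
}

#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to exactly `depth` reads. Samples with fewer than
#' `depth` reads are dropped with a warning. A single draw is taken per
#' sample, reproducible for a given `seed`.
#'
#' @param counts OTU count matrix with integer counts.
#' @param depth Target depth (reads), > 0.
#' @param seed Integer seed for the subsampling RNG.
#' @return Rarefied count matrix; every column sums to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  check_otu_counts(counts)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(counts)[!keep], collapse = ", "))
  }
  counts <- counts[, keep, drop = FALSE]
  if (ncol(counts) == 0L) return(counts)
  set.seed(seed)
  out <- apply(counts, 2, function(x) {
    reads <- rep.int(seq_along(x), x)
    tabulate(sample(reads, depth), nbins = length(x))
  })
  rownames(out) <- rownames(counts)
  out
}

#' Shannon diversity index (natural log)
#'
#' `H' = -sum(p_i * log(p_i))` over OTUs with positive counts.
#'
#' @param x Nonnegative count vector for one sample, with positive total.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon(c(1, 1, 2))
shannon <- function(x) {
  if (any(x < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(x) <= 0) stop("sample has no reads", call. = FALSE)
  unname(vegan::diversity(x, index = "shannon"))
}

#' Per-sample alpha diversity of an OTU table
#'
#' @param counts OTU count matrix.
#' @return Data frame with `sample_id`, `shannon` and `depth` (reads used).
#' @export
alpha_diversity <- function(counts) {
  check_otu_counts(counts)
  data.frame(sample_id = colnames(counts),
             shannon = apply(counts, 2, shannon),
             depth = colSums(counts),
             row.names = NULL)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum(|a_i - b_i|) / sum(a_i + b_i)`, computed between the columns
#' of the OTU table.
#'
#' @param counts OTU count matrix with >= 2 samples, all with positive totals.
#' @return A `dist` object with values in `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  check_otu_counts(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(colSums(counts) <= 0)) stop("every sample needs a positive total", call. = FALSE)
  vegan::vegdist(t(counts), method = "bray")
}
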