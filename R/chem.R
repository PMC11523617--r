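#' Group summary (mean and standard error) of a water-chemistry field
#'
#' Arithmetic mean and standard error (sd / sqrt(n)) of one measured field per
#' colonization-status group, matching the "mean +/- SE per container" summary
#' columns of the field-survey tables.
#'
#' @param samples Data frame of water samples with a `status` column (`NC` /
#'   `C`) and one column per measured field.
#' @param field Name of the field to summarize.
#' @param by Grouping column (default `status`).
#' @return Data frame with `group`, `n`, `mean`, `se`.
#' @export
#' @examples
#' w <- read.csv(habnet_example("lyon_water_samples.csv"))
#' water_summary(w, "n2o")
water_summary <- function(samples, field, by = "status") {
  if (!field %in% names(samples)) {
    stop("unknown field '", field, "'", call. = FALSE)
  }
  if (!by %in% names(samples)) stop("unknown grouping column '", by, "'", call. = FALSE)
  groups <- split(samples[[field]], samples[[by]])
  if (any(lengths(groups) < 2L)) stop("need >= 2 samples per group", call. = FALSE)
  out <- data.frame(group = names(groups),
                    n = lengths(groups),
                    mean = vapply(groups, mean, 0, na.rm = TRUE),
                    se = vapply(groups, function(x) {
                      x <- x[!is.na(x)]
                      sd(x) / sqrt(length(x))
                    }, 0),
                    row.names = NULL)
  out
}

#' Container-type tally
#'
#' Percentage of samples per container type, over all samples.
#'
#' @param samples Data frame with a `container_type` column.
#' @return Data frame with `container_type`, `n`, `percent` (sums to 100 up to
#'   rounding).
#' @export
container_tally <- function(samples) {
  if (nrow(samples) == 0L) stop("no samples", call. = FALSE)
  tab <- table(samples$container_type)
  data.frame(container_type = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(samples),
             row.names = NULL)
}

#' Total organic carbon from total and inorganic carbon
#'
#' TOC = TC - IC (mg/l).
#'
#' @param tc Total carbon (mg/l), `tc >= ic`.
#' @param ic Inorganic carbon (mg/l), >= 0.
#' @return TOC in mg/l.
#' @export
toc <- function(tc, ic) {
  if (any(ic < 0)) stop("ic must be >= 0", call. = FALSE)
  if (any(ic > tc)) stop("ic exceeds tc: negative organic carbon", call. = FALSE)
  tc - ic
}

check_feature_matrix <- function(intensities, injections) {
  if (!is.matrix(intensities)) stop("intensities must be a matrix (features x injections)",
                                    call. = FALSE)
  req <- c("injection_id", "sample_id", "role", "replicate", "status")
  miss <- setdiff(req, names(injections))
  if (length(miss)) stop("injections is missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!identical(colnames(intensities), as.character(injections$injection_id))) {
    stop("intensity columns must match injections$injection_id in order", call. = FALSE)
  }
  if (!all(injections$role %in% c("study", "QC", "blank"))) {
    stop("injection roles must be study/QC/blank", call. = FALSE)
  }
  invisible(TRUE)
}

#' Normalize feature intensities to the internal standard
#'
#' Divides every feature intensity by the internal-standard intensity of its
#' injection (e.g. spiked diuron-d6). Injections where the internal standard
#' is missing or nonpositive cannot be normalized; they are excluded with a
#' warning.
#'
#' @param intensities Feature x injection matrix.
#' @param injections Injection metadata aligned with the columns.
#' @param istd_feature Row name of the internal-standard feature.
#' @return List with the normalized `intensities` (internal-standard row kept,
#'   all 1), the matching `injections`, and `excluded` injection ids.
#' @export
normalize_to_istd <- function(intensities, injections, istd_feature) {
  check_feature_matrix(intensities, injections)
  if (!istd_feature %in% rownames(intensities)) {
    stop("internal standard '", istd_feature, "' not in matrix", call. = FALSE)
  }
  istd <- intensities[istd_feature, ]
  ok <- !is.na(istd) & istd > 0
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " injection(s) with missing/zero internal standard: ",
            paste(colnames(intensities)[!ok], collapse = ", "))
  }
  out <- sweep(intensities[, ok, drop = FALSE], 2, istd[ok], "/")
  list(intensities = out, injections = injections[ok, , drop = FALSE],
       excluded = colnames(intensities)[!ok])
}

qc_cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L || mean(x) == 0) return(NA_real_)
  100 * sd(x) / mean(x)
}

#' Untargeted LC-HRMS feature-filter cascade
#'
#' Applies, in order: (1) internal-standard normalization (when
#' `istd_feature` is given); (2) removal of features whose coefficient of
#' variation across QC injections exceeds `cv_max` percent; (3) imputation of
#' a missing study replicate by the mean of its two siblings, or 0 when fewer
#' than two are present; (4) removal of features not detected in 100% of the
#' samples of at least one garden pollution group (or of every group, with
#' `detect_rule = "all_groups"`); (5) removal of features whose mean study
#' intensity is not more than `blank_ratio` times the mean blank intensity;
#' (6) removal of features with no significant difference between
#' noncolonized and colonized samples (two-sided Welch t-test at `alpha`,
#' no multiplicity correction). Replicates are averaged into per-sample
#' intensities after imputation; detection means intensity > 0.
#'
#' Absent QC or blank injections skip stages 2/5 with a loud warning.
#'
#' @param intensities Feature x injection matrix (nonnegative or `NA`).
#' @param injections Injection metadata: `injection_id`, `sample_id`, `role`
#'   (`study`/`QC`/`blank`), `replicate`, `status` (`NC`/`C`/`none`), and
#'   optionally `group` (garden pollution group) for stage 4.
#' @param istd_feature Internal-standard feature name, or `NULL` if the matrix
#'   is already normalized.
#' @param cv_max QC coefficient-of-variation ceiling, percent.
#' @param blank_ratio Minimal study/blank mean-intensity ratio (exclusive).
#' @param alpha Significance level for the status t-test.
#' @param detect_rule Detection-rate rule for stage 4.
#' @return List with `kept` (retained feature ids), `audit` (features
#'   surviving each stage, nonincreasing), `sample_intensities` (retained
#'   features x study samples after imputation and replicate averaging), and
#'   `stages` (per-stage retained-feature sets).
#' @export
filter_cascade <- function(intensities, injections, istd_feature = NULL,
                           cv_max = 30, blank_ratio = 10, alpha = 0.05,
                           detect_rule = c("any_group", "all_groups")) {
  detect_rule <- match.arg(detect_rule)
  check_feature_matrix(intensities, injections)
  if (cv_max <= 0) stop("cv_max must be > 0", call. = FALSE)
  audit <- c(input = nrow(intensities))
  stages <- list()

  if (!is.null(istd_feature)) {
    norm <- normalize_to_istd(intensities, injections, istd_feature)
    intensities <- norm$intensities[setdiff(rownames(norm$intensities), istd_feature), ,
                                    drop = FALSE]
    injections <- norm$injections
  }
  audit["normalized"] <- nrow(intensities)
  stages$normalized <- rownames(intensities)

  qc_cols <- injections$role == "QC"
  if (!any(qc_cols)) {
    warning("no QC injections: QC CV stage skipped")
  } else {
    cv <- apply(intensities[, qc_cols, drop = FALSE], 1, qc_cv)
    intensities <- intensities[is.na(cv) | cv <= cv_max, , drop = FALSE]
  }
  audit["qc_cv"] <- nrow(intensities)
  stages$qc_cv <- rownames(intensities)

  study <- injections$role == "study"
  study_inj <- injections[study, , drop = FALSE]
  study_int <- intensities[, study, drop = FALSE]
  for (sid in unique(study_inj$sample_id)) {
    cols <- which(study_inj$sample_id == sid)
    block <- study_int[, cols, drop = FALSE]
    for (i in seq_len(nrow(block))) {
      v <- block[i, ]
      if (anyNA(v)) {
        present <- v[!is.na(v)]
        v[is.na(v)] <- if (length(present) >= 2L) mean(present) else 0
        block[i, ] <- v
      }
    }
    study_int[, cols] <- block
  }
  audit["imputed"] <- nrow(study_int)
  stages$imputed <- rownames(study_int)

  # replicate averaging -> per-sample intensities
  sample_ids <- unique(study_inj$sample_id)
  samp <- vapply(sample_ids, function(sid) {
    rowMeans(study_int[, study_inj$sample_id == sid, drop = FALSE])
  }, numeric(nrow(study_int)))
  if (is.null(dim(samp))) samp <- matrix(samp, nrow = nrow(study_int),
                                         dimnames = list(rownames(study_int), sample_ids))
  samp_meta <- study_inj[!duplicated(study_inj$sample_id),
                         setdiff(names(study_inj), c("injection_id", "replicate")),
                         drop = FALSE]
  samp_meta <- samp_meta[match(sample_ids, samp_meta$sample_id), , drop = FALSE]

  if (!"group" %in% names(samp_meta) || all(is.na(samp_meta$group))) {
    warning("no pollution-group annotation: detection-rate stage skipped")
  } else {
    det <- vapply(split(seq_len(ncol(samp)), samp_meta$group), function(cols) {
      rowMeans(samp[, cols, drop = FALSE] > 0)
    }, numeric(nrow(samp)))
    det <- matrix(det, nrow = nrow(samp))  # one column per group
    keep <- if (detect_rule == "any_group") {
      apply(det == 1, 1, any)
    } else {
      apply(det == 1, 1, all)
    }
    samp <- samp[keep, , drop = FALSE]
  }
  audit["detection"] <- nrow(samp)
  stages$detection <- rownames(samp)

  blank_cols <- injections$role == "blank"
  if (!any(blank_cols)) {
    warning("no blank injections: blank-ratio stage skipped")
  } else {
    blank_mean <- rowMeans(intensities[rownames(samp), blank_cols, drop = FALSE],
                           na.rm = TRUE)
    blank_mean[is.nan(blank_mean)] <- 0
    study_mean <- rowMeans(samp)
    keep <- ifelse(blank_mean == 0, study_mean > 0,
                   study_mean / blank_mean > blank_ratio)
    samp <- samp[keep, , drop = FALSE]
  }
  audit["blank_ratio"] <- nrow(samp)
  stages$blank_ratio <- rownames(samp)

  st <- samp_meta$status
  if (length(unique(st[st %in% c("NC", "C")])) == 2L && nrow(samp) > 0L) {
    pvals <- apply(samp, 1, function(x) {
      nc <- x[st == "NC"]; co <- x[st == "C"]
      if (var(nc) == 0 && var(co) == 0) return(if (mean(nc) == mean(co)) 1 else 0)
      t.test(nc, co)$p.value
    })
    samp <- samp[pvals < alpha, , drop = FALSE]
  } else if (nrow(samp) > 0L) {
    warning("both NC and C samples required: status t-test stage skipped")
  }
  audit["status_ttest"] <- nrow(samp)
  stages$status_ttest <- rownames(samp)

  list(kept = rownames(samp), audit = audit, sample_intensities = samp,
       sample_meta = samp_meta, stages = stages)
}
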