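# Seeded generators that emulate the statistical structure of the field
# study: paired noncolonized/colonized (NC/C) water samples per garden,
# compositional OTU counts with gradient-correlated taxa, chemistry with a
# planted NC/C status effect on N2O and CH4, LC-HRMS feature matrices with
# replicate/QC/blank structure, and planted variable associations. Every
# generator is a pure function of its arguments and `seed`.

#' Simulate community-garden records
#'
#' Pollution-source distances are log-uniform over a plausible urban range
#' (10 m to 10 km); per-pollutant emissions are lognormal and converted to
#' quartile scores with [quartile_scores()]. Each garden is labelled with the
#' pollution group whose normalized raw variable is largest.
#'
#' @param n_gardens Number of gardens (>= 4).
#' @param seed Integer seed.
#' @param d_range Distance bounds (m).
#' @return Data frame with one row per garden: quartile scores, distances,
#'   agricultural surface and pollution group.
#' @export
simulate_gardens <- function(n_gardens = 23, seed = 1L, d_range = c(10, 1e4)) {
  if (n_gardens < 4) stop("n_gardens must be >= 4", call. = FALSE)
  if (any(d_range <= 0) || d_range[1] >= d_range[2]) {
    stop("invalid config field: d_range", call. = FALSE)
  }
  set.seed(seed)
  logu <- function(n) exp(runif(n, log(d_range[1]), log(d_range[2])))
  g <- data.frame(
    garden_id = sprintf("G%02d", seq_len(n_gardens)),
    q_no2 = quartile_scores(rlnorm(n_gardens, 3, 1)),
    q_pm25 = quartile_scores(rlnorm(n_gardens, 2, 1)),
    q_pm10 = quartile_scores(rlnorm(n_gardens, 2.5, 1)),
    d_highway = logu(n_gardens),
    d_agri = logu(n_gardens),
    d_indus = logu(n_gardens),
    agri_surface = runif(n_gardens, 1, 4)
  )
  pv <- pollution_variables(g)
  g$pollution_group <- c("ATMO", "AGRI", "INDUS")[
    max.col(cbind(pv$var_atmo_norm, pv$var_agri_norm, pv$var_indus_norm))]
  g
}

#' Simulate paired water-sample chemistry
#'
#' One noncolonized (NC) and one colonized (C) sample per garden. All
#' concentrations are lognormal (positive, right-skewed); N2O and CH4 carry a
#' planted status effect: the NC group mean exceeds the C mean by
#' `n2o_ratio` and `ch4_ratio` (defaults 2 and 6). All other fields are
#' status-neutral.
#'
#' @param gardens Garden data frame from [simulate_gardens()].
#' @param n2o_ratio,ch4_ratio NC:C mean ratios (> 0).
#' @param seed Integer seed.
#' @return Water-sample data frame (ids `{GARDEN}_{NC|C}`), with field
#'   physicochemistry, ions, gases and TOC.
#' @export
simulate_chemistry <- function(gardens, n2o_ratio = 2, ch4_ratio = 6, seed = 1L) {
  if (n2o_ratio <= 0 || ch4_ratio <= 0) {
    stop("invalid config field: status ratios must be > 0", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(gardens)
  status <- rep(c("NC", "C"), each = n)
  w <- data.frame(
    sample_id = paste(rep(gardens$garden_id, 2), status, sep = "_"),
    garden_id = rep(gardens$garden_id, 2),
    status = status,
    container_type = sample(c("Rainwater collector", "Bucket", "Watering can"),
                            2 * n, replace = TRUE, prob = c(0.87, 0.09, 0.04)),
    temperature = rnorm(2 * n, 21.5, 3),
    salinity = round(rlnorm(2 * n, log(0.1), 0.8), 2),
    ph = pmin(pmax(rnorm(2 * n, 7.4, 0.7), 4), 10),
    do_mg_l = rlnorm(2 * n, log(6), 0.4),
    redox = rnorm(2 * n, 220, 100)
  )
  for (ion in c("f", "cl", "no2", "br", "no3", "po4", "so4", "na", "nh4",
                "k", "mg", "ca")) {
    w[[ion]] <- rlnorm(2 * n, log(2), 1.2)
  }
  w$gas_o2 <- rlnorm(2 * n, log(2.1), 0.25)
  w$gas_n2 <- rlnorm(2 * n, log(5), 0.2)
  w$co2 <- rlnorm(2 * n, log(2500), 0.9)
  # lognormal with common sdlog: shifting meanlog by log(ratio) scales the mean
  s <- as.integer(w$status == "NC")
  w$ch4 <- rlnorm(2 * n, log(0.3) + s * log(ch4_ratio), 1)
  w$n2o <- rlnorm(2 * n, log(0.5) + s * log(n2o_ratio), 0.8)
  w$toc <- rlnorm(2 * n, log(10), 0.7)
  w
}

#' Simulate a compositional OTU count table with a planted gradient
#'
#' Dirichlet-multinomial counts: per-OTU baseline log-abundances are normal, a
#' planted fraction of OTUs has its log-abundance shifted linearly by the
#' garden's (normalized, centered) industrial pollution variable, per-sample
#' gamma noise induces overdispersion, and counts are multinomial at the
#' sample's depth. Optional negative-control samples carry planted contaminant
#' OTUs that also leak faintly into study samples.
#'
#' @param gardens Garden data frame (used for the pollution axis).
#' @param samples Data frame with `sample_id`, `garden_id` (study samples).
#' @param depth Nominal sequencing depth; per-sample totals are drawn in
#'   `[1.2, 2] * depth` so rarefaction to `depth` always succeeds.
#' @param richness Number of OTUs.
#' @param gradient_fraction Fraction of OTUs correlated with the pollution
#'   axis, in `[0, 1]`.
#' @param gradient_slope Log-abundance shift per unit of the centered axis.
#' @param overdispersion Gamma shape for per-sample noise (smaller = noisier).
#' @param n_neg Number of negative-control samples (ids `NEG{i}`).
#' @param n_contaminants Number of contaminant OTUs planted in the negatives.
#' @param marker Marker label stored in the metadata.
#' @param seed Integer seed.
#' @return List with `counts` (OTUs x samples, negatives included), `meta`
#'   (`sample_id`, `garden_id`, `sample_type`, `marker`) and `truth`
#'   (planted OTU ids, contaminant OTU ids, per-sample axis values).
#' @export
simulate_otu_table <- function(gardens, samples, depth = 4103, richness = 300,
                               gradient_fraction = 0.3, gradient_slope = 1,
                               overdispersion = 2, n_neg = 1,
                               n_contaminants = 5, marker = "16S", seed = 1L) {
  if (gradient_fraction < 0 || gradient_fraction > 1) {
    stop("invalid config field: gradient_fraction", call. = FALSE)
  }
  set.seed(seed)
  pv <- pollution_variables(gardens)
  axis_by_garden <- setNames(pv$var_indus_norm, pv$garden_id)
  axis <- axis_by_garden[samples$garden_id]
  axis_c <- axis - mean(axis)
  otu_ids <- sprintf("OTU%04d", seq_len(richness))
  base <- rnorm(richness, 0, 1.5)
  n_planted <- round(gradient_fraction * richness)
  planted <- sort(sample.int(richness, n_planted))
  sign_j <- sample(c(-1, 1), n_planted, replace = TRUE)
  n_s <- nrow(samples)
  counts <- matrix(0L, richness, n_s, dimnames = list(otu_ids, samples$sample_id))
  for (i in seq_len(n_s)) {
    eta <- base
    eta[planted] <- eta[planted] + gradient_slope * sign_j * axis_c[i]
    w <- exp(eta) * rgamma(richness, shape = overdispersion, rate = overdispersion)
    tot <- round(runif(1, 1.2, 2) * depth)
    counts[, i] <- rmultinom(1, tot, w / sum(w))
  }
  meta <- data.frame(sample_id = samples$sample_id, garden_id = samples$garden_id,
                     sample_type = if ("status" %in% names(samples)) samples$status
                                   else "NC",
                     marker = marker)
  contaminant_ids <- character(0)
  if (n_neg > 0) {
    contam <- sample(setdiff(seq_len(richness), planted), n_contaminants)
    contaminant_ids <- otu_ids[contam]
    neg_ids <- paste0("NEG", seq_len(n_neg))
    neg <- matrix(0L, richness, n_neg, dimnames = list(otu_ids, neg_ids))
    for (j in seq_len(n_neg)) {
      neg[contam, j] <- rmultinom(1, 2000, rep(1 / n_contaminants, n_contaminants))
      dust <- sample.int(richness, 10)  # trace carryover reads
      neg[dust, j] <- neg[dust, j] + 1L
    }
    # faint leakage of the same contaminants into study samples (< 10x rule)
    leak <- matrix(rbinom(n_contaminants * n_s, 3, 0.3), n_contaminants, n_s)
    counts[contam, ] <- counts[contam, ] + leak
    counts <- cbind(counts, neg)
    meta <- rbind(meta, data.frame(sample_id = neg_ids, garden_id = NA,
                                   sample_type = "NEG", marker = marker))
  }
  list(counts = counts, meta = meta,
       truth = list(planted_otus = otu_ids[planted],
                    contaminant_otus = contaminant_ids,
                    axis = setNames(axis, samples$sample_id)))
}

# fixed zero-mean, unit-sd pattern so simulated QC replicates hit an exact
# sample coefficient of variation
cv_pattern <- function(n) {
  v <- seq_len(n) - (n + 1) / 2
  v / sd(v)
}

#' Simulate an LC-HRMS feature matrix with planted ground truth
#'
#' Builds triplicate study injections per water sample, pooled-QC injections
#' with an exact coefficient of variation, blank injections, and an
#' internal-standard feature (`ISTD_diuron_d6`) whose per-injection intensity
#' scales the whole injection. Planted "real" features pass every stage of
#' [filter_cascade()]; each artifact class violates exactly one stage:
#' `cv` (QC CV above the ceiling), `detection` (one zeroed sample per
#' pollution group), `blank` (study/blank ratio below the cutoff), `status`
#' (identical NC and C values, no status effect).
#'
#' @param samples Water-sample data frame with `sample_id`, `status`, and
#'   `garden_id`; pollution group is looked up from `gardens` if given, else
#'   from a `group` column.
#' @param gardens Optional garden data frame with `pollution_group`.
#' @param n_real Number of genuine features.
#' @param n_artifacts Number of artifact features (split evenly across the
#'   four classes).
#' @param status_ratio NC:C mean-intensity ratio for real features.
#' @param qc_cv_real,qc_cv_artifact Exact QC coefficients of variation (%).
#' @param n_qc,n_blank Numbers of QC and blank injections.
#' @param missing_rate Fraction of study replicate values set missing (to
#'   exercise imputation), applied to real features only.
#' @param seed Integer seed.
#' @return List with `intensities` (features x injections, raw scale,
#'   internal-standard row included), `injections` metadata, and `truth`
#'   (feature id, class).
#' @export
simulate_features <- function(samples, gardens = NULL, n_real = 20,
                              n_artifacts = 80, status_ratio = 3,
                              qc_cv_real = 10, qc_cv_artifact = 60,
                              n_qc = 6, n_blank = 3, missing_rate = 0.02,
                              seed = 1L) {
  set.seed(seed)
  if (!is.null(gardens)) {
    samples$group <- gardens$pollution_group[match(samples$garden_id,
                                                   gardens$garden_id)]
  }
  if (!"group" %in% names(samples)) stop("samples needs a pollution group", call. = FALSE)
  n_s <- nrow(samples)
  inj <- rbind(
    data.frame(sample_id = rep(samples$sample_id, each = 3),
               role = "study", replicate = rep(1:3, n_s),
               status = rep(samples$status, each = 3),
               group = rep(samples$group, each = 3)),
    data.frame(sample_id = paste0("QC", seq_len(n_qc)), role = "QC",
               replicate = 1, status = "none", group = NA),
    data.frame(sample_id = paste0("BLANK", seq_len(n_blank)), role = "blank",
               replicate = 1, status = "none", group = NA)
  )
  inj$injection_id <- paste0("inj_", seq_len(nrow(inj)),
                             "_", inj$sample_id)
  n_inj <- nrow(inj)

  per_class <- n_artifacts %/% 4
  classes <- c(rep("real", n_real),
               rep(c("cv", "detection", "blank", "status"),
                   c(per_class, per_class, per_class,
                     n_artifacts - 3 * per_class)))
  n_feat <- length(classes)
  ids <- sprintf("M%03dT%03d", sample(50:999, n_feat, replace = TRUE),
                 sample(40:999, n_feat, replace = TRUE))
  ids <- make.unique(ids, sep = "x")

  m <- matrix(0, n_feat, n_inj, dimnames = list(ids, inj$injection_id))
  is_study <- inj$role == "study"
  is_qc <- inj$role == "QC"
  is_blank <- inj$role == "blank"
  qc_pat <- cv_pattern(n_qc)

  base <- rlnorm(n_feat, log(1e4), 0.5)
  for (f in seq_len(n_feat)) {
    cl <- classes[f]
    # per-sample level; NC raised for classes with a status effect
    lev <- base[f] * rlnorm(n_s, 0, 0.3)
    if (cl != "status") {
      lev[samples$status == "NC"] <- lev[samples$status == "NC"] * status_ratio
    } else {
      # identical NC and C values per garden: Welch t = 0
      nc <- samples$status == "NC"
      lev[!nc] <- lev[nc][match(samples$garden_id[!nc], samples$garden_id[nc])]
    }
    if (cl == "detection") {
      for (gp in unique(samples$group)) {
        idx <- which(samples$group == gp)
        lev[idx[1]] <- 0
      }
    }
    m[f, is_study] <- rep(lev, each = 3) * rlnorm(sum(is_study), 0, 0.05)
    cv <- if (cl == "cv") qc_cv_artifact else qc_cv_real
    m[f, is_qc] <- base[f] * (1 + cv / 100 * qc_pat)
    m[f, is_blank] <- if (cl == "blank") mean(lev) / 5 else 0
  }
  # missing replicates among real features, at most one per sample triplet
  real_rows <- which(classes == "real")
  for (f in real_rows) {
    drop <- which(runif(n_s) < missing_rate * 3)
    for (s in drop) {
      cols <- which(is_study & inj$sample_id == samples$sample_id[s])
      m[f, sample(cols, 1)] <- NA
    }
  }
  # raw scale: multiply each injection by its internal-standard intensity
  istd <- rlnorm(n_inj, log(5e3), 0.2)
  m <- sweep(m, 2, istd, "*")
  m <- rbind(m, ISTD_diuron_d6 = istd)
  list(intensities = m,
       injections = inj[, c("injection_id", "sample_id", "role", "replicate",
                            "status", "group")],
       truth = data.frame(feature = ids, class = classes))
}

#' Plant co-exceptional associations into a variable table
#'
#' Starting from (or generating) a samples x variables table of standard
#' normal noise, gives each member of a planted pair exceptional high values
#' in a `support` fraction of samples, with the two exceedance sets sharing a
#' `joint_prob` fraction of their samples (`joint_prob = 1`: identical
#' patterns, perfect association; `joint_prob = support`: co-occurrence at the
#' independence rate). Every other variable gets independent exceptional
#' spikes at `background_support`. Exceedance sample sets are drawn disjointly
#' across pairs, so the truth list is exactly the set of associations present
#' in the realized data: independently drawn sets would occasionally collide
#' and create genuine cross-pair associations that a recovery score would
#' miscount as false positives.
#'
#' @param n_samples,n_vars Table dimensions (used when `data` is `NULL`).
#' @param pairs Two-column matrix (or list of length-2 vectors) of variable
#'   indices or names to associate; a variable may appear in at most one pair.
#' @param support Marginal exceedance probability of each planted variable.
#' @param joint_prob Probability that an exceptional sample of one pair member
#'   is also exceptional for the other.
#' @param background_support Independent exceptional-spike probability for all
#'   other variables.
#' @param spike Value used for exceptional observations (far above the
#'   modified-z threshold on a standard normal background).
#' @param data Optional existing numeric table to plant into.
#' @param seed Integer seed.
#' @return List with `data` (samples x variables) and `truth` (data frame of
#'   planted pairs, one row each).
#' @export
plant_associations <- function(n_samples = 100, n_vars = 60, pairs,
                               support = 0.1, joint_prob = 1,
                               background_support = 0,
                               spike = 8, data = NULL, seed = 1L) {
  if (joint_prob < 0 || joint_prob > 1 || support <= 0 || support > 1) {
    stop("support must be in (0, 1] and joint_prob in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(data)) {
    data <- matrix(rnorm(n_samples * n_vars), n_samples, n_vars,
                   dimnames = list(NULL, sprintf("VAR%03d", seq_len(n_vars))))
  }
  data <- as.matrix(data)
  n_samples <- nrow(data); vars <- colnames(data)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (is.numeric(pairs)) pairs <- matrix(vars[pairs], ncol = 2)
  if (anyDuplicated(as.vector(pairs))) {
    stop("overlapping pair specifications: a variable may appear in one pair only",
         call. = FALSE)
  }
  planted_vars <- as.vector(pairs)
  k <- max(1L, round(support * n_samples))
  shared <- round(joint_prob * k)
  per_pair <- 2 * k - shared  # samples consumed by one pair
  if (nrow(pairs) * per_pair > n_samples) {
    stop("not enough samples for disjoint exceedance sets: need ",
         nrow(pairs) * per_pair, call. = FALSE)
  }
  pool <- sample.int(n_samples)
  for (r in seq_len(nrow(pairs))) {
    block <- pool[((r - 1) * per_pair + 1):(r * per_pair)]
    set_a <- block[seq_len(k)]
    set_b <- c(set_a[seq_len(shared)], block[k + seq_len(k - shared)])
    data[set_a, pairs[r, 1]] <- spike + rnorm(k, 0, 0.1)
    data[set_b, pairs[r, 2]] <- spike + rnorm(k, 0, 0.1)
  }
  for (v in setdiff(vars, planted_vars)) {
    hit <- runif(n_samples) < background_support
    data[hit, v] <- spike + rnorm(sum(hit), 0, 0.1)
  }
  list(data = data,
       truth = data.frame(source = pairs[, 1], target = pairs[, 2]))
}

#' Simulate a complete paired study dataset
#'
#' Convenience bundle used by [run_pipeline()] and the test-suite: gardens,
#' paired NC/C water chemistry, one OTU table per marker (16S/ITS/18S at the
#' study's rarefaction depths by default), and an LC-HRMS feature matrix.
#'
#' @param n_gardens Number of gardens.
#' @param depths Named vector of per-marker sequencing depths.
#' @param richness Named vector of per-marker OTU richness.
#' @param seed Integer seed (sub-generators use small fixed offsets of it).
#' @param ... Further arguments passed to [simulate_otu_table()].
#' @return List with `gardens`, `water`, `otu` (one list per marker) and
#'   `features`.
#' @export
simulate_study <- function(n_gardens = 23,
                           depths = c("16S" = 4103, "ITS" = 6567, "18S" = 7204),
                           richness = c("16S" = 300, "ITS" = 200, "18S" = 200),
                           seed = 1L, ...) {
  gardens <- simulate_gardens(n_gardens, seed = seed)
  water <- simulate_chemistry(gardens, seed = seed + 1L)
  otu <- lapply(seq_along(depths), function(i) {
    simulate_otu_table(gardens, water[, c("sample_id", "garden_id", "status")],
                       depth = depths[i], richness = richness[names(depths)[i]],
                       marker = names(depths)[i], seed = seed + 10L + i, ...)
  })
  names(otu) <- names(depths)
  features <- simulate_features(water, gardens, seed = seed + 20L)
  list(gardens = gardens, water = water, otu = otu, features = features)
}
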