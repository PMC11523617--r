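test_that("group summaries compute mean and standard error per status", {
  w <- data.frame(status = rep(c("NC", "C"), each = 4),
                  n2o = c(1, 1, 1, 1, 2, 4, 6, 8))
  s <- water_summary(w, "n2o")
  expect_equal(s$mean[s$group == "NC"], 1)
  expect_equal(s$se[s$group == "NC"], 0)
  expect_equal(s$mean[s$group == "C"], 5)
  expect_equal(s$se[s$group == "C"], sd(c(2, 4, 6, 8)) / 2)
  expect_error(water_summary(w, "ph"), "unknown field")
  expect_error(water_summary(w[c(1, 5), ], "n2o"), ">= 2")
})

test_that("container tally percentages count correctly and sum to 100", {
  w <- data.frame(container_type = c(rep("Rainwater collector", 7),
                                     rep("Bucket", 2), "Watering can"))
  tal <- container_tally(w)
  expect_equal(sum(tal$percent), 100)
  expect_equal(tal$percent[tal$container_type == "Rainwater collector"], 70)
  one <- container_tally(data.frame(container_type = rep("Bucket", 5)))
  expect_equal(one$percent, 100)
  expect_error(container_tally(data.frame(container_type = character())),
               "no samples")
})

test_that("TOC is total minus inorganic carbon", {
  expect_equal(toc(5, 5), 0)
  expect_equal(toc(10, 3), 7)
  set.seed(2)
  tc <- runif(20, 5, 50); ic <- tc * runif(20)
  expect_equal(toc(tc, ic), tc - ic)
  expect_error(toc(3, 5), "negative organic carbon")
})

# small already-annotated fixture: 2 NC + 2 C samples x 3 replicates,
# 3 QC injections, 1 blank; intensities on the normalized scale
cascade_fixture <- function(qc = c(100, 120, 140)) {
  samples <- data.frame(sample_id = c("G1_NC", "G2_NC", "G1_C", "G2_C"),
                        status = c("NC", "NC", "C", "C"),
                        group = c("ATMO", "INDUS", "ATMO", "INDUS"))
  inj <- rbind(
    data.frame(injection_id = paste0(rep(samples$sample_id, each = 3), "_r", 1:3),
               sample_id = rep(samples$sample_id, each = 3),
               role = "study", replicate = rep(1:3, 4),
               status = rep(samples$status, each = 3),
               group = rep(samples$group, each = 3)),
    data.frame(injection_id = paste0("QC", 1:3), sample_id = paste0("QC", 1:3),
               role = "QC", replicate = 1, status = "none", group = NA),
    data.frame(injection_id = "BL1", sample_id = "BL1", role = "blank",
               replicate = 1, status = "none", group = NA))
  study_vals <- rep(c(100, 100, 10, 10), each = 3)  # NC 10x C
  m <- rbind(F1 = c(study_vals, qc, 0))
  colnames(m) <- inj$injection_id
  list(m = m, inj = inj)
}

test_that("QC coefficient of variation gates features with boundary kept", {
  fx <- cascade_fixture(qc = c(100, 120, 140))  # CV = 16.7%
  expect_true("F1" %in% filter_cascade(fx$m, fx$inj)$kept)
  fx <- cascade_fixture(qc = c(100, 100, 100))  # CV = 0
  expect_true("F1" %in% filter_cascade(fx$m, fx$inj)$kept)
  fx <- cascade_fixture(qc = c(70, 100, 130))   # CV exactly 30: not "over"
  expect_true("F1" %in% filter_cascade(fx$m, fx$inj)$kept)
  fx <- cascade_fixture(qc = c(50, 100, 150))   # CV = 50%
  res <- filter_cascade(fx$m, fx$inj)
  expect_false("F1" %in% res$kept)
  expect_equal(unname(res$audit["qc_cv"]), 0)
})

test_that("missing replicates are imputed by the sibling mean, others untouched", {
  fx <- cascade_fixture()
  fx$m[1, 1] <- NA  # first replicate of G1_NC
  res <- filter_cascade(fx$m, fx$inj)
  expect_equal(unname(res$sample_intensities["F1", "G1_NC"]), 100)
  expect_equal(unname(res$sample_intensities["F1", "G2_NC"]), 100)
  # all siblings missing -> 0 (placed on a C sample so the NC > C status
  # contrast survives and the imputed zero is observable downstream)
  fx <- cascade_fixture()
  g1c <- which(fx$inj$sample_id == "G1_C")
  fx$m[1, g1c] <- NA
  res0 <- filter_cascade(fx$m, fx$inj)
  expect_equal(unname(res0$sample_intensities["F1", "G1_C"]), 0)
})

test_that("internal-standard normalization is exact and scale invariant", {
  fx <- cascade_fixture()
  istd <- runif(ncol(fx$m), 1000, 2000)
  raw <- rbind(fx$m * rep(istd, each = 1), ISTD = istd)
  rownames(raw) <- c("F1", "ISTD")
  norm <- normalize_to_istd(raw, fx$inj, "ISTD")
  expect_equal(unname(norm$intensities["ISTD", ]), rep(1, ncol(raw)))
  expect_equal(norm$intensities["F1", ], fx$m[1, ])
  # doubling one injection changes nothing after normalization
  raw2 <- raw; raw2[, 3] <- raw2[, 3] * 2
  norm2 <- normalize_to_istd(raw2, fx$inj, "ISTD")
  expect_equal(norm2$intensities, norm$intensities)
  # zero internal standard excludes the injection, loudly
  raw3 <- raw; raw3["ISTD", 2] <- 0
  expect_warning(norm3 <- normalize_to_istd(raw3, fx$inj, "ISTD"), "excluding")
  expect_equal(ncol(norm3$intensities), ncol(raw) - 1)
})

test_that("cascade audit is nonincreasing and skips absent roles loudly", {
  study <- simulate_study(n_gardens = 6, depths = c("16S" = 200),
                          richness = c("16S" = 40), seed = 9)
  f <- study$features
  res <- filter_cascade(f$intensities, f$injections,
                        istd_feature = "ISTD_diuron_d6")
  expect_true(all(diff(res$audit) <= 0))
  no_qc <- f$injections$role != "QC"
  expect_warning(filter_cascade(f$intensities[, no_qc], f$injections[no_qc, ],
                                istd_feature = "ISTD_diuron_d6"),
                 "no QC injections")
  no_bl <- f$injections$role != "blank"
  expect_warning(filter_cascade(f$intensities[, no_bl], f$injections[no_bl, ],
                                istd_feature = "ISTD_diuron_d6"),
                 "no blank injections")
})

test_that("each planted artifact class dies at its designed stage", {
  study <- simulate_study(n_gardens = 10, depths = c("16S" = 200),
                          richness = c("16S" = 40), seed = 13)
  f <- study$features
  res <- filter_cascade(f$intensities, f$injections,
                        istd_feature = "ISTD_diuron_d6")
  expect_setequal(res$kept, f$truth$feature[f$truth$class == "real"])
  stage_of <- c(cv = "qc_cv", detection = "detection", blank = "blank_ratio",
                status = "status_ttest")
  prev_of <- c(qc_cv = "normalized", detection = "imputed",
               blank_ratio = "detection", status_ttest = "blank_ratio")
  for (cl in names(stage_of)) {
    feats <- f$truth$feature[f$truth$class == cl]
    expect_true(all(feats %in% res$stages[[prev_of[[stage_of[cl]]]]]))
    expect_false(any(feats %in% res$stages[[stage_of[cl]]]))
  }
})
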