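#' Pipeline configuration
#'
#' Collects the thresholds of every stage with the published defaults:
#' contaminant retention factor 10, rare-OTU fraction 0.005%, per-marker
#' rarefaction depths 4103/6567/7204, QC CV ceiling 30%, blank ratio 10,
#' test level 0.05, exceptionality threshold 3.5/0.6745 (the classical
#' robust-outlier convention expressed in unscaled MAD units, see
#' [binarize()]) and minimal Zhang score 0.25.
#'
#' @param depths Named per-marker rarefaction depths (reads).
#' @param contaminant_factor Study/control relative-abundance multiplier.
#' @param rare_fraction Overall relative-abundance floor.
#' @param cv_max QC coefficient-of-variation ceiling (percent).
#' @param blank_ratio Minimal study/blank intensity ratio.
#' @param alpha Significance level shared by the tests.
#' @param exceptionality_threshold Modified-z threshold for binarization.
#' @param zhang_min Minimal Zhang score for an edge.
#' @param n_perm Permutations for PERMANOVA.
#' @param seed Mandatory seed for every stochastic stage.
#' @return A `pipeline_config` list (with its own hash).
#' @export
pipeline_config <- function(depths = c("16S" = 4103, "ITS" = 6567, "18S" = 7204),
                            contaminant_factor = 10, rare_fraction = 5e-5,
                            cv_max = 30, blank_ratio = 10, alpha = 0.05,
                            exceptionality_threshold = 3.5 / 0.6745,
                            zhang_min = 0.25,
                            n_perm = 999, seed = 1L) {
  stopifnot(all(depths > 0), contaminant_factor > 0,
            rare_fraction >= 0, rare_fraction <= 1,
            cv_max > 0, blank_ratio > 0, alpha > 0, alpha < 1,
            exceptionality_threshold > 0,
            zhang_min >= -1, zhang_min <= 1, n_perm >= 99,
            is.numeric(seed), length(seed) == 1L)
  cfg <- list(depths = depths, contaminant_factor = contaminant_factor,
              rare_fraction = rare_fraction, cv_max = cv_max,
              blank_ratio = blank_ratio, alpha = alpha,
              exceptionality_threshold = exceptionality_threshold,
              zhang_min = zhang_min, n_perm = n_perm, seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a study dataset
#'
#' Orchestrates the stages in analysis order: pollution variables, OTU
#' preprocessing (contaminant filter, rare filter, rarefaction), diversity and
#' dissimilarity, abiotic-gradient ordination per colonization-status stratum,
#' chemistry summaries, the LC-HRMS feature cascade, harmonized-variable
#' binarization, and the association network. Artifacts are written to
#' `out_dir` with provenance headers (version, seed, config hash); a stage
#' failure halts the run naming the stage, with earlier artifacts preserved.
#'
#' @param study A study bundle as produced by [simulate_study()] (`gardens`,
#'   `water`, `otu` per marker, `features`).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return List with every stage's result: `pollution`, `otu` (per marker:
#'   counts, diversity, dist), `gradient` (per marker x status), `chemistry`,
#'   `cascade`, `network`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  info <- list(seed = config$seed, hash = config$hash)
  emit <- function(df, name, sep = ",") {
    if (!is.null(out_dir)) {
      write_table_prov(df, file.path(out_dir, name), info, sep = sep)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(package = "habnet", version = habnet_version(),
           config = unclass(config)),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  }

  poll <- stage("pollution", pollution_variables(study$gardens))
  emit(poll, "pollution_variables.csv")

  water <- study$water
  abiotic_fields <- intersect(
    c("temperature", "salinity", "ph", "do_mg_l", "redox", "gas_o2", "gas_n2",
      "ch4", "co2", "n2o", "toc"), names(water))
  chem <- stage("chemistry", {
    sums <- lapply(abiotic_fields, function(f) {
      s <- water_summary(water, f)
      cbind(field = f, s)
    })
    list(summaries = do.call(rbind, sums), containers = container_tally(water))
  })
  emit(chem$summaries, "chemistry_summaries.csv")

  otu_res <- list()
  for (marker in names(study$otu)) {
    tab <- study$otu[[marker]]
    otu_res[[marker]] <- stage(paste0("otu_", marker), {
      neg_ids <- tab$meta$sample_id[tab$meta$sample_type == "NEG"]
      counts <- tab$counts
      if (length(neg_ids))

        counts <- filter_contaminants(counts, neg_ids, config$contaminant_factor)
      counts <- filter_rare(counts, config$rare_fraction)
      depth <- config$depths[[marker]]
      if (is.null(depth)) depth <- min(colSums(counts))
      counts <- rarefy(counts, depth, seed = config$seed)
      list(counts = counts, diversity = alpha_diversity(counts),
           dist = bray_curtis(counts))
    })
    emit(otu_res[[marker]]$diversity, paste0("alpha_", marker, ".csv"))
  }

  gradient <- list()
  for (marker in names(otu_res)) {
    counts <- otu_res[[marker]]$counts
    for (st in c("NC", "C")) {
      ids <- intersect(colnames(counts),
                       water$sample_id[water$status == st])
      if (length(ids) < 5L) next
      sub <- counts[, ids, drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      abio <- water[match(ids, water$sample_id), abiotic_fields, drop = FALSE]
      abio <- cbind(abio,
                    poll[match(water$garden_id[match(ids, water$sample_id)],
                               poll$garden_id),
                         grep("_norm$", names(poll)), drop = FALSE])
      gradient[[paste(marker, st, sep = "_")]] <- stage(
        paste0("gradient_", marker, "_", st),
        gradient_analysis(bray_curtis(sub), abio, sub,
                          n_perm = config$n_perm, seed = config$seed,
                          alpha = config$alpha))
    }
  }
  if (!is.null(out_dir)) {
    perm_tables <- lapply(names(gradient), function(k) {
      cbind(stratum = k, gradient[[k]]$permanova)
    })
    if (length(perm_tables)) emit(do.call(rbind, perm_tables), "permanova.csv")
  }

  cascade <- stage("feature_cascade",
                   filter_cascade(study$features$intensities,
                                  study$features$injections,
                                  istd_feature = "ISTD_diuron_d6",
                                  cv_max = config$cv_max,
                                  blank_ratio = config$blank_ratio,
                                  alpha = config$alpha))
  if (!is.null(out_dir)) {
    jsonlite::write_json(as.list(cascade$audit),
                         file.path(out_dir, "cascade_audit.json"),
                         auto_unbox = TRUE)
  }

  network <- stage("association_network", {
    # harmonized variable table on the colonized stratum: chemistry +
    # pollution variables + OTU abundances + retained feature intensities
    ids <- water$sample_id[water$status == "C"]
    vt <- water[match(ids, water$sample_id), abiotic_fields, drop = FALSE]
    kinds <- setNames(rep("physicochemical", ncol(vt)), names(vt))
    gidx <- match(water$garden_id[match(ids, water$sample_id)], poll$garden_id)
    pv <- poll[gidx, grep("_norm$", names(poll)), drop = FALSE]
    kinds <- c(kinds, setNames(rep("physicochemical", ncol(pv)), names(pv)))
    vt <- cbind(vt, pv)
    for (marker in names(otu_res)) {
      counts <- otu_res[[marker]]$counts
      common <- intersect(ids, colnames(counts))
      top <- head(order(rowSums(counts), decreasing = TRUE), 50)
      block <- matrix(NA_real_, length(ids), length(top),
                      dimnames = list(ids, paste(marker,
                                                 rownames(counts)[top],
                                                 sep = "_")))
      block[common, ] <- t(counts[top, common, drop = FALSE])
      kind <- switch(marker, "16S" = "bacteria", "ITS" = "fungi", "eukaryote")
      kinds <- c(kinds, setNames(rep(kind, ncol(block)), colnames(block)))
      vt <- cbind(vt, block)
    }
    if (length(cascade$kept)) {
      fi <- t(cascade$sample_intensities[, intersect(ids, colnames(cascade$sample_intensities)),
                                         drop = FALSE])
      block <- matrix(NA_real_, length(ids), ncol(fi),
                      dimnames = list(ids, colnames(fi)))
      block[rownames(fi), ] <- fi
      kinds <- c(kinds, setNames(rep("organic molecule", ncol(block)),
                                 colnames(block)))
      vt <- cbind(vt, block)
    }
    exc <- exceptionality_matrix(vt, threshold = config$exceptionality_threshold)
    build_network(exc$matrix, kinds = kinds, zhang_min = config$zhang_min,
                  alpha = config$alpha)
  })
  if (!is.null(out_dir)) {
    export_graphml(network, file.path(out_dir, "association_network.graphml"))
    write_edge_list(network, file.path(out_dir, "edges.tsv"), info)
  }

  list(pollution = poll, chemistry = chem, otu = otu_res, gradient = gradient,
       cascade = cascade, network = network, config = config)
}
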