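# Readers/writers for the pipeline's plain-text formats. All writers prepend
# a provenance comment line (package version, seed, config hash); readers
# skip comment lines.

habnet_version <- function() as.character(utils::packageVersion("habnet"))

# small polynomial rolling hash over the serialized object; stable across
# runs for identical configs
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

prov_header <- function(info = NULL) {
  paste0("# habnet ", habnet_version(),
         if (!is.null(info$seed)) paste0("; seed=", info$seed),
         if (!is.null(info$hash)) paste0("; config_hash=", info$hash))
}

write_table_prov <- function(df, path, info = NULL, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov_header(info), con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a garden characterization CSV
#'
#' Expects columns `garden_id`, `pollution_group`, distance columns, and
#' either `atmo_score` or the three quartile scores; comment lines starting
#' with `#` are skipped.
#'
#' @param path CSV file path.
#' @return Data frame of garden records.
#' @export
read_gardens <- function(path) {
  g <- read.csv(path, comment.char = "#")
  req <- c("garden_id", "d_highway", "d_indus")
  miss <- setdiff(req, names(g))
  if (length(miss)) stop("gardens file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  g
}

#' Read/write an OTU table as TSV
#'
#' Rows are OTUs (first column `otu_id`), remaining columns are samples;
#' an optional final `taxonomy` column carries lineage strings.
#'
#' @param path TSV file path.
#' @return For the reader: list with `counts` (integer matrix) and `taxonomy`
#'   (named character vector or `NULL`).
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  if (names(df)[1] != "otu_id") stop("first column must be otu_id", call. = FALSE)
  tax <- NULL
  if ("taxonomy" %in% names(df)) {
    tax <- setNames(df$taxonomy, df$otu_id)
    df$taxonomy <- NULL
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$otu_id
  storage.mode(counts) <- "integer"
  list(counts = counts, taxonomy = tax)
}

#' @rdname read_otu_table
#' @param counts OTU count matrix (OTUs x samples).
#' @param taxonomy Optional per-OTU lineage strings (named by OTU id).
#' @param info Optional provenance info (`seed`, `hash`).
#' @export
write_otu_table <- function(counts, path, taxonomy = NULL, info = NULL) {
  check_otu_counts(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  if (!is.null(taxonomy)) df$taxonomy <- unname(taxonomy[rownames(counts)])
  write_table_prov(df, path, info, sep = "\t")
  invisible(path)
}

#' Read an LC-HRMS feature matrix and its injection metadata
#'
#' @param intensities_path CSV with first column `feature_id`, then one column
#'   per injection.
#' @param injections_path CSV with `injection_id`, `sample_id`, `role`,
#'   `replicate`, `status`, and optionally `group`.
#' @return List with `intensities` (matrix) and `injections` (data frame).
#' @export
read_feature_matrix <- function(intensities_path, injections_path) {
  fm <- read.csv(intensities_path, comment.char = "#", check.names = FALSE)
  if (names(fm)[1] != "feature_id") stop("first column must be feature_id", call. = FALSE)
  m <- as.matrix(fm[, -1, drop = FALSE])
  rownames(m) <- fm$feature_id
  inj <- read.csv(injections_path, comment.char = "#")
  check_feature_matrix(m, inj)
  list(intensities = m, injections = inj)
}

#' Validate pipeline input files
#'
#' Schema-checks each provided file and reconciles sample ids across files.
#' All violations are collected into one report (validation never aborts on
#' the first problem); unreadable paths are an error.
#'
#' @param paths Named list of file paths; recognized names: `gardens`,
#'   `water_samples`, `otu_table`, `features`, `injections`.
#' @return Data frame with columns `file`, `where`, `message`; zero rows for a
#'   clean input set.
#' @export
validate_inputs <- function(paths) {
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("unreadable file: ", p, call. = FALSE)
  }
  v <- list()
  note <- function(file, where, message) {
    v[[length(v) + 1L]] <<- data.frame(file = file, where = where, message = message)
  }
  gardens <- water <- otu <- NULL
  if (!is.null(paths$gardens)) {
    gardens <- tryCatch(read_gardens(paths$gardens), error = function(e) {
      note(paths$gardens, "header", conditionMessage(e)); NULL
    })
    if (!is.null(gardens)) {
      for (dcol in intersect(c("d_highway", "d_indus", "d_agri"), names(gardens))) {
        bad <- which(!is.na(gardens[[dcol]]) & gardens[[dcol]] <= 0)
        for (i in bad) note(paths$gardens, paste0("row ", i, ", ", dcol),
                            "distance must be > 0")
      }
      if (anyDuplicated(gardens$garden_id)) {
        note(paths$gardens, "garden_id", "duplicated garden ids")
      }
    }
  }
  if (!is.null(paths$water_samples)) {
    water <- read.csv(paths$water_samples, comment.char = "#")
    req <- c("sample_id", "garden_id", "status")
    miss <- setdiff(req, names(water))
    if (length(miss)) note(paths$water_samples, "header",
                           paste("missing columns:", paste(miss, collapse = ", ")))
    if ("status" %in% names(water)) {
      bad <- which(!water$status %in% c("NC", "C"))
      for (i in bad) note(paths$water_samples, paste0("row ", i, ", status"),
                          "status must be NC or C")
    }
    if (!is.null(gardens) && all(c("garden_id") %in% names(water))) {
      orphan <- setdiff(water$garden_id, gardens$garden_id)
      if (length(orphan)) note(paths$water_samples, "garden_id",
                               paste("gardens not in garden table:",
                                     paste(orphan, collapse = ", ")))
    }
  }
  if (!is.null(paths$otu_table)) {
    otu <- tryCatch(read_otu_table(paths$otu_table), error = function(e) {
      note(paths$otu_table, "header", conditionMessage(e)); NULL
    })
    if (!is.null(otu)) {
      neg <- which(otu$counts < 0, arr.ind = TRUE)
      for (i in seq_len(nrow(neg))) {
        note(paths$otu_table,
             paste0("otu ", rownames(otu$counts)[neg[i, 1]], ", sample ",
                    colnames(otu$counts)[neg[i, 2]]),
             "negative count")
      }
      if (!is.null(water)) {
        study_cols <- setdiff(colnames(otu$counts),
                              grep("^NEG", colnames(otu$counts), value = TRUE))
        orphan <- setdiff(study_cols, water$sample_id)
        if (length(orphan)) note(paths$otu_table, "samples",
                                 paste("samples not in metadata:",
                                       paste(orphan, collapse = ", ")))
      }
    }
  }
  if (!is.null(paths$features) && !is.null(paths$injections)) {
    fm <- tryCatch(read_feature_matrix(paths$features, paths$injections),
                   error = function(e) {
                     note(paths$features, "header", conditionMessage(e)); NULL
                   })
    if (!is.null(fm)) {
      bad <- which(!is.na(fm$intensities) & fm$intensities < 0, arr.ind = TRUE)
      for (i in seq_len(nrow(bad))) {
        note(paths$features,
             paste0("feature ", rownames(fm$intensities)[bad[i, 1]],
                    ", injection ", colnames(fm$intensities)[bad[i, 2]]),
             "negative intensity")
      }
    }
  }
  if (length(v) == 0L) {
    return(data.frame(file = character(), where = character(),
                      message = character()))
  }
  do.call(rbind, v)
}

#' Export an association graph to GraphML
#'
#' Nodes carry their `kind` label; edges carry Zhang's score, the Spearman
#' correlation, the binomial p-value, supports and the per-edge sample size.
#' The file round-trips losslessly through [import_graphml()].
#'
#' @param graph An `association_graph` from [build_network()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "association_graph"))
  nodes <- graph$nodes
  nodes$kind[is.na(nodes$kind)] <- "unknown"
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                      kind = igraph::vertex_attr(g, "kind"))
  ee <- igraph::as_data_frame(g, what = "edges")
  names(ee)[names(ee) == "from"] <- "source"
  names(ee)[names(ee) == "to"] <- "target"
  list(nodes = nodes, edges = ee)
}

#' Flat TSV edge list of an association graph
#'
#' @param graph An `association_graph`.
#' @param path Output TSV path.
#' @param info Optional provenance info.
#' @export
write_edge_list <- function(graph, path, info = NULL) {
  stopifnot(inherits(graph, "association_graph"))
  write_table_prov(graph$edges, path, info, sep = "\t")
  invisible(path)
}
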