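#' Analysis configuration
#'
#' Bundles the tunable parameters of the effect-estimation pipeline.
#'
#' @param pseudocount positive offset used by [replace_zeros()] (default 1).
#' @param di_space space in which the Dynamic Index is computed:
#'   `"clr_difference"` (default; difference of group-mean clr values,
#'   well-defined for any counts) or `"relative_ratio"` (literal
#'   `ln(N/D)` on group-mean proportions).
#' @param alpha significance level for bootstrap confidence intervals
#'   (default 0.05).
#' @param n_boot number of bootstrap resamples (default 9999, minimum 99).
#' @param Y grazer abundance per replicate (default 1).
#' @param t experiment duration in its own time units (default 1).
#' @param rarefy_depth optional depth for rarefaction before estimation
#'   (default `NULL`, off; the motivating experiment used 6215).
#' @param seed integer seed driving all bootstrap resampling.
#' @param bh_correct apply Benjamini-Hochberg correction across (grazer,
#'   ASV) pairs within a mode when flagging significance (default `FALSE`;
#'   edge significance is then the plain 95% CI rule).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(pseudocount = 1,
                            di_space = c("clr_difference", "relative_ratio"),
                            alpha = 0.05, n_boot = 9999, Y = 1, t = 1,
                            rarefy_depth = NULL, seed = 1,
                            bh_correct = FALSE) {
  di_space <- match.arg(di_space)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (n_boot < 99) stopf("n_boot must be at least 99")
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  if (Y <= 0 || t <= 0) stopf("Y and t must be positive")
  structure(list(pseudocount = pseudocount, di_space = di_space,
                 alpha = alpha, n_boot = as.integer(n_boot), Y = Y, t = t,
                 rarefy_depth = rarefy_depth, seed = as.integer(seed),
                 bh_correct = isTRUE(bh_correct)),
            class = "analysis_config")
}

#' Read a sample-by-ASV count table from TSV
#'
#' The file must be tab-separated with row ids in the first column and
#' column ids in the header. Entries must be non-negative integers.
#'
#' @param path file path.
#' @param orientation `"samples_as_rows"` (default) or `"asvs_as_rows"`
#'   (the matrix is transposed after reading so the result is always
#'   samples x ASVs).
#' @return integer matrix, samples in rows, ASVs in columns.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_as_rows",
                                             "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (orientation == "asvs_as_rows") m <- t(m)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stopf("duplicate sample or ASV ids in %s", path)
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-integer or negative count at sample '%s', ASV '%s' in %s",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table as TSV
#' @param counts samples x ASVs matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Expects a TSV with columns `sample_id`, `treatment_class` (one of
#' `control`, `grazing`, `mucus`), `grazer` (species label; empty/none for
#' controls) and `replicate`. When a count table is supplied the sample id
#' sets are cross-checked.
#'
#' @param path file path.
#' @param counts optional count matrix to validate against.
#' @return data.frame of validated metadata.
#' @export
read_metadata <- function(path, counts = NULL) {
  md <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  needed <- c("sample_id", "treatment_class", "grazer", "replicate")
  missing_cols <- setdiff(needed, names(md))
  if (length(missing_cols) > 0)
    stopf("metadata missing column(s): %s", paste(missing_cols, collapse = ", "))
  md$replicate <- as.integer(md$replicate)
  md$grazer[md$grazer %in% c("", "none", "NA")] <- NA_character_
  validate_metadata(md, counts)
  md
}

validate_metadata <- function(md, counts = NULL) {
  if (anyDuplicated(md$sample_id)) stopf("duplicate sample ids in metadata")
  bad_class <- setdiff(unique(md$treatment_class),
                       c("control", "grazing", "mucus"))
  if (length(bad_class) > 0)
    stopf("unknown treatment_class: %s", paste(bad_class, collapse = ", "))
  need_grazer <- md$treatment_class %in% c("grazing", "mucus")
  if (any(need_grazer & is.na(md$grazer)))
    stopf("grazing/mucus sample(s) without grazer label: %s",
          paste(md$sample_id[need_grazer & is.na(md$grazer)], collapse = ", "))
  if (any(!need_grazer & !is.na(md$grazer)))
    stopf("control sample(s) carry a grazer label: %s",
          paste(md$sample_id[!need_grazer & !is.na(md$grazer)], collapse = ", "))
  if (!is.null(counts)) {
    miss <- setdiff(rownames(counts), md$sample_id)
    extra <- setdiff(md$sample_id, rownames(counts))
    if (length(miss) > 0)
      stopf("metadata missing counted sample(s): %s",
            paste(miss, collapse = ", "))
    if (length(extra) > 0)
      stopf("metadata lists un-counted sample(s): %s",
            paste(extra, collapse = ", "))
  }
  invisible(md)
}

#' Write sample metadata as TSV
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an ASV taxonomy table
#'
#' TSV with an `asv_id` column and ranked lineage columns (e.g. `domain`
#' ... `genus`); a `family` column, when present, is used to annotate
#' network columns.
#'
#' @param path file path.
#' @param counts optional count matrix; taxonomy ids must be a subset of
#'   its ASV ids.
#' @return data.frame keyed by `asv_id`.
#' @export
read_taxonomy <- function(path, counts = NULL) {
  tx <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!"asv_id" %in% names(tx)) stopf("taxonomy missing 'asv_id' column")
  if (anyDuplicated(tx$asv_id)) stopf("duplicate asv ids in taxonomy")
  if (!is.null(counts)) {
    extra <- setdiff(tx$asv_id, colnames(counts))
    if (length(extra) > 0)
      stopf("taxonomy lists unknown ASV(s): %s", paste(extra, collapse = ", "))
  }
  tx
}

#' Write an effect table as TSV
#' @param effects data.frame from [estimate_effects()] or
#'   [decompose_trophic()].
#' @param path output path.
#' @export
write_effects_table <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a bipartite network as an edge list TSV
#'
#' Columns: `source` (grazer), `target` (ASV), `weight` (`|DI|`), `sign`,
#' `mode`, `family` (taxonomic annotation, empty when no taxonomy is
#' supplied). The format is directly loadable by network viewers such as
#' Cytoscape; weights are non-negative with the interaction sign carried
#' in its own column.
#'
#' @param network a `bipartite_network` from [build_networks()].
#' @param path output path.
#' @param taxonomy optional taxonomy data.frame with `asv_id` and `family`.
#' @export
write_edge_list <- function(network, path, taxonomy = NULL) {
  el <- network_edges(network, taxonomy)
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(el) == 0) warnf("network '%s_%s' is empty; wrote header-only file",
                           network$mode, network$sign)
  invisible(path)
}

network_edges <- function(network, taxonomy = NULL) {
  w <- network$weights
  idx <- which(w > 0, arr.ind = TRUE)
  fam <- rep("", nrow(idx))
  if (!is.null(taxonomy) && "family" %in% names(taxonomy) && nrow(idx) > 0) {
    fam <- taxonomy$family[match(colnames(w)[idx[, 2]], taxonomy$asv_id)]
    fam[is.na(fam)] <- ""
  }
  data.frame(source = rownames(w)[idx[, 1]],
             target = colnames(w)[idx[, 2]],
             weight = w[idx], sign = rep(network$sign, nrow(idx)),
             mode = rep(network$mode, nrow(idx)), family = fam)
}

#' Export a bipartite network as GraphML
#'
#' Builds a bipartite igraph graph (grazer nodes vs ASV nodes) with edge
#' attributes `weight`, `sign` and `mode`, and writes GraphML.
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(network, path, taxonomy = NULL) {
  el <- network_edges(network, taxonomy)
  grazers <- rownames(network$weights)
  asvs <- colnames(network$weights)
  g <- igraph::graph_from_data_frame(
    el[, c("source", "target", "weight", "sign", "mode", "family")],
    directed = FALSE,
    vertices = data.frame(name = c(grazers, asvs),
                          type = c(rep(FALSE, length(grazers)),
                                   rep(TRUE, length(asvs)))))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a metric report as JSON
#'
#' Serializes named metric values plus provenance (options, seed, matrix
#' dimensions) losslessly; [read_metrics_report()] restores it.
#'
#' @param report named list of metric values and provenance.
#' @param path output path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
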