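#' Write a simulated experiment to tab-separated files
#'
#' Writes `counts.tsv` (sample x taxon), `metadata.tsv` (design columns),
#' `taxonomy.tsv` (taxon -> kingdom/phylum/family), `biomass.tsv` and
#' `graph_edges.tsv` (planted edges with their precision entries) into a
#' directory.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             biomass = file.path(dir, "biomass.tsv"),
             graph = file.path(dir, "graph_edges.tsv"))
  cnt <- data.frame(sample_id = rownames(sim$counts$counts),
                    sim$counts$counts, check.names = FALSE)
  utils::write.table(cnt, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$design, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$taxonomy, paths["taxonomy"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$biomass, paths["biomass"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ed <- sim$graph$edges
  ge <- data.frame(taxon_a = sim$taxonomy$taxon_id[ed[, 1]],
                   taxon_b = sim$taxonomy$taxon_id[ed[, 2]],
                   precision_value = sim$graph$precision[ed])
  utils::write.table(ge, paths["graph"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a counts table (with optional taxonomy) from tab-separated files
#'
#' Expects the layout written by [write_simulation()]: a `sample_id` first
#' column followed by one column per taxon.
#'
#' @param counts_file path to the counts TSV.
#' @param taxonomy_file optional path to a taxonomy TSV with a `taxon_id`
#'   column.
#' @return An [asv_table].
#' @export
read_counts <- function(counts_file, taxonomy_file = NULL) {
  df <- utils::read.delim(counts_file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  tax <- if (!is.null(taxonomy_file)) utils::read.delim(taxonomy_file)
  asv_table(m, tax)
}

#' Write a network as a tab-separated edge list
#'
#' @param net an [igraph::graph] with vertex names.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_edgelist <- function(net, file) {
  el <- igraph::as_edgelist(net)
  utils::write.table(data.frame(taxon_a = el[, 1], taxon_b = el[, 2]),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
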