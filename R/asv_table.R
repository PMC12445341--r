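#' ASV count table with taxonomy
#'
#' Lightweight container for a sample x taxon table of non-negative integer
#' read counts together with a taxonomy table mapping each taxon (ASV) to a
#' kingdom, phylum and family. This is the unit of data every preprocessing
#' and network-inference step consumes.
#'
#' @param counts numeric matrix of non-negative counts, samples in rows and
#'   taxa in columns; both dimensions must carry unique names.
#' @param taxonomy optional `data.frame` with columns `taxon_id`, `kingdom`,
#'   `phylum`, `family`. Taxa absent from the table (or `NA` entries) are
#'   bucketed as `"unknown"`.
#' @return An object of class `asv_table`: a list with elements `counts`
#'   (the matrix) and `taxonomy` (a complete taxonomy `data.frame`, one row
#'   per taxon, in column order of `counts`).
#' @examples
#' m <- matrix(c(5, 0, 3, 2, 1, 4), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' asv_table(m)
#' @export
asv_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("`counts` must be a numeric matrix")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon identifiers")

  taxa <- colnames(counts)
  full <- data.frame(taxon_id = taxa, kingdom = "unknown",
                     phylum = "unknown", family = "unknown",
                     stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!"taxon_id" %in% names(taxonomy))
      stop("`taxonomy` needs a `taxon_id` column")
    idx <- match(taxa, taxonomy$taxon_id)
    for (col in intersect(c("kingdom", "phylum", "family"), names(taxonomy))) {
      v <- as.character(taxonomy[[col]])[idx]
      v[is.na(v) | v == ""] <- "unknown"
      full[[col]] <- v
    }
  }
  structure(list(counts = counts, taxonomy = full), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d taxa (%s reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  k <- table(x$taxonomy$kingdom)
  cat("kingdoms:", paste(sprintf("%s (%d)", names(k), k), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Subset an ASV table by samples and/or taxa
#'
#' @param x an [asv_table].
#' @param samples,taxa character vectors of identifiers (or logical/integer
#'   index vectors) selecting rows/columns; `NULL` keeps everything.
#' @return A new [asv_table].
#' @export
subset_asv <- function(x, samples = NULL, taxa = NULL) {
  stopifnot(inherits(x, "asv_table"))
  m <- x$counts
  if (!is.null(samples)) {
    if (is.character(samples) && !all(samples %in% rownames(m)))
      stop("unknown sample identifiers: ",
           paste(setdiff(samples, rownames(m)), collapse = ", "))
    m <- m[samples, , drop = FALSE]
  }
  if (!is.null(taxa)) {
    if (is.character(taxa) && !all(taxa %in% colnames(m)))
      stop("unknown taxon identifiers")
    m <- m[, taxa, drop = FALSE]
  }
  asv_table(m, x$taxonomy)
}
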