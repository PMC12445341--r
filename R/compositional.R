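#' Filter ASVs by overall relative abundance and prevalence
#'
#' Removes taxa whose share of the grand total read count falls below
#' `min_rel_abund` or that are present (non-zero) in fewer than
#' `min_prevalence` samples. The defaults mirror common amplicon network
#' practice: overall relative abundance below 0.00025% (fraction `2.5e-6`)
#' and presence in fewer than 5 experimental units. Whether the abundance
#' screen is applied over the whole table or per sample is configurable,
#' since conventions differ.
#'
#' @param x an [asv_table].
#' @param min_rel_abund minimum relative abundance (fraction of reads),
#'   default `2.5e-6`.
#' @param min_prevalence minimum number of samples with a non-zero count,
#'   default 5. Prevalence counts strictly positive entries, not a minimum
#'   count.
#' @param abundance_scope `"dataset"` (default; taxon total over grand
#'   total) or `"sample"` (taxon retained if its within-sample relative
#'   abundance reaches the threshold in at least one sample).
#' @return List with `table` (the filtered [asv_table], taxon order
#'   preserved) and `report` (class `filter_report`): `taxa_in`, `taxa_out`,
#'   `removed_by_abundance`, `removed_by_prevalence`, `removed_total`
#'   (union), and the thresholds used.
#' @examples
#' sim <- simulate_experiment(seed = 1, n_prokaryote = 20, n_fungal = 10)
#' f <- filter_asvs(sim$counts)
#' f$report
#' @export
filter_asvs <- function(x, min_rel_abund = 2.5e-6, min_prevalence = 5,
                        abundance_scope = c("dataset", "sample")) {
  stopifnot(inherits(x, "asv_table"))
  abundance_scope <- match.arg(abundance_scope)
  if (min_rel_abund < 0 || min_prevalence < 0)
    stop("thresholds must be non-negative")
  m <- x$counts
  grand <- sum(m)
  if (grand == 0)
    stop("cannot filter an all-zero count table (grand total = 0)")

  abund_ok <- if (abundance_scope == "dataset") {
    colSums(m) / grand >= min_rel_abund
  } else {
    rel <- m / pmax(rowSums(m), 1)
    apply(rel >= min_rel_abund & m > 0, 2L, any) | min_rel_abund == 0
  }
  prev_ok <- colSums(m > 0) >= min_prevalence
  keep <- abund_ok & prev_ok

  report <- structure(list(
    taxa_in = ncol(m),
    taxa_out = sum(keep),
    removed_by_abundance = sum(!abund_ok),
    removed_by_prevalence = sum(!prev_ok),
    removed_total = sum(!keep),
    min_rel_abund = min_rel_abund,
    min_prevalence = min_prevalence,
    abundance_scope = abundance_scope
  ), class = "filter_report")

  list(table = subset_asv(x, taxa = colnames(m)[keep]), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "filter_report: %d -> %d taxa (removed %d: %d below rel. abundance %g",
    " [%s], %d below prevalence %d)\n"),
    x$taxa_in, x$taxa_out, x$removed_total, x$removed_by_abundance,
    x$min_rel_abund, x$abundance_scope, x$removed_by_prevalence,
    x$min_prevalence))
  invisible(x)
}

#' Centred log-ratio (CLR) transform
#'
#' `clr(x)[s, t] = log(x[s, t]) - mean_t log(x[s, t])`, computed after adding
#' `pseudocount` when the table contains zeros. Every row of the result sums
#' to zero: CLR values live on a hyperplane, and Euclidean distances between
#' CLR rows are Aitchison distances between the compositions.
#'
#' @param x an [asv_table] or a non-negative numeric matrix (samples x taxa).
#' @param pseudocount value added to all counts when any count is zero
#'   (default 1); must be positive in that case. When the table has no
#'   zeros, no pseudocount is added unless one is supplied explicitly.
#' @return Numeric matrix of CLR values with the input dimnames.
#' @examples
#' clr_transform(matrix(c(5, 5, 5, 5), 1), pseudocount = 0)  # all zeros
#' @export
clr_transform <- function(x, pseudocount = 1) {
  m <- if (inherits(x, "asv_table")) x$counts else as.matrix(x)
  if (any(m < 0)) stop("counts must be non-negative")
  has_zero <- any(m == 0)
  if (has_zero && pseudocount <= 0)
    stop("zero counts present: a positive `pseudocount` is required")
  if (has_zero) m <- m + pseudocount
  lv <- log(m)
  lv - rowMeans(lv)
}

#' Aitchison distance between samples
#'
#' Euclidean distance on CLR-transformed rows -- the natural metric for
#' compositional data, invariant to multiplying any sample's counts by a
#' positive scalar.
#'
#' @param clr matrix of CLR values (rows = samples), as from
#'   [clr_transform()], or an [asv_table] (transformed internally with
#'   `pseudocount`).
#' @param pseudocount used only when an [asv_table] is supplied.
#' @return A [stats::dist] object over samples.
#' @export
aitchison_distance <- function(clr, pseudocount = 1) {
  if (inherits(clr, "asv_table")) clr <- clr_transform(clr, pseudocount)
  if (nrow(clr) < 2) stop("need at least 2 samples")
  stats::dist(clr, method = "euclidean")
}

#' Shannon diversity per sample
#'
#' `H = -sum(p * log(p))` over taxa with positive share, natural logarithm.
#'
#' @param x an [asv_table] or counts matrix (samples x taxa).
#' @return Named numeric vector, one value per sample.
#' @export
shannon_index <- function(x) {
  m <- if (inherits(x, "asv_table")) x$counts else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("every sample must have a positive total count")
  p <- m / tot
  lp <- ifelse(p > 0, log(p), 0)
  -rowSums(p * lp)
}

#' Aggregate relative abundance at a taxonomic rank
#'
#' Per-sample relative abundances summed to phylum or family; taxa without a
#' label at the requested rank fall into an `"unknown"` bucket. Shares sum
#' to 1 per sample.
#'
#' @param x an [asv_table] with taxonomy.
#' @param rank `"phylum"` or `"family"`.
#' @return Numeric matrix samples x rank levels of relative abundances.
#' @export
aggregate_rank <- function(x, rank = c("phylum", "family")) {
  stopifnot(inherits(x, "asv_table"))
  rank <- match.arg(rank)
  labels <- x$taxonomy[[rank]]
  labels[is.na(labels) | labels == ""] <- "unknown"
  tot <- rowSums(x$counts)
  if (any(tot <= 0)) stop("every sample must have a positive total count")
  rel <- x$counts / tot
  shares <- t(rowsum(t(rel), group = labels))
  shares[, order(colnames(shares)), drop = FALSE]
}
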