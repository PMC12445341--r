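#' Meinshausen-Buhlmann neighbourhood selection at a fixed penalty
#'
#' Estimates an undirected binary conditional-dependence graph by running,
#' for each taxon, an L1-penalised linear regression of its (standardised)
#' CLR values on all other taxa and taking the non-zero coefficients as its
#' neighbourhood. Neighbourhoods are symmetrised into edges with the
#' `"or"` rule (edge if selected in either direction; default, and a
#' superset of `"and"`) or the `"and"` rule (both directions).
#'
#' The per-node lasso is solved by coordinate descent ([glmnet::glmnet()])
#' on columns standardised to zero mean and unit variance, so the penalty
#' `lambda` is on the usual `(1/2n) RSS + lambda * |beta|_1` scale and the
#' analytic null threshold is `max_j |x_j' y| / n`: at or above it the
#' solution -- and hence the graph -- is empty.
#'
#' @param clr numeric matrix of CLR values (samples x taxa).
#' @param lambda positive penalty.
#' @param symmetrize `"or"` (default) or `"and"`.
#' @return An undirected simple [igraph::graph] over all columns of `clr`
#'   (isolated nodes included), with graph attributes `lambda` and
#'   `symmetrize`.
#' @export
mb_neighborhood <- function(clr, lambda, symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  if (length(lambda) != 1 || lambda <= 0) stop("`lambda` must be positive")
  clr <- as.matrix(clr)
  if (nrow(clr) < 2) stop("need at least 2 samples")
  sel <- mb_selection(clr, lambda_path = mb_warm_path(clr, lambda))
  adj <- sel[, , dim(sel)[3]]
  graph_from_selection(adj, symmetrize, colnames(clr),
                       lambda = lambda)
}

# Selection array over a decreasing lambda path.
# Returns logical array [node i, candidate j, lambda]: j in neighbourhood
# of i. Constant columns select nothing and are never selected.
mb_selection <- function(clr, lambda_path) {
  x <- standardize_cols(clr)
  n <- nrow(x)
  p <- ncol(x)
  sel <- array(FALSE, dim = c(p, p, length(lambda_path)))
  live <- which(apply(x, 2L, function(v) any(v != 0)))
  if (length(live) < 2) return(sel)
  for (i in live) {
    xi <- x[, i]
    others <- setdiff(live, i)
    if (length(others) == 1L) {
      # univariate lasso in closed form: non-zero iff |x'y|/n > lambda
      sel[i, others, ] <-
        as.numeric(abs(crossprod(x[, others], xi))) / n >
          lambda_path * (1 + 1e-9)
      next
    }
    fit <- glmnet::glmnet(x[, others, drop = FALSE], xi,
                          family = "gaussian", lambda = lambda_path,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-6)
    # a coefficient born exactly at the soft-threshold boundary can come
    # back as a floating-point sliver; treat those as not selected
    b <- abs(as.matrix(fit$beta)) > 1e-9
    # glmnet may stop early on a degenerate path; pad with the last column
    if (ncol(b) < length(lambda_path)) {
      pad <- matrix(b[, ncol(b)], nrow(b), length(lambda_path) - ncol(b))
      b <- cbind(b, pad)
    }
    sel[i, others, ] <- b
  }
  sel
}

# Short warm-start path from the null threshold down to the target lambda.
mb_warm_path <- function(clr, lambda, length_out = 10L) {
  lmax <- mb_lambda_max(clr)
  if (lambda >= lmax) return(c(lmax * 1.0001, lambda))
  exp(seq(log(lmax), log(lambda), length.out = length_out))
}

#' Analytic null threshold for the node-wise lasso
#'
#' The smallest penalty at which every node-wise lasso solution is zero:
#' `max_i max_j |x_j' x_i| / n` over standardised columns. At or above this
#' value [mb_neighborhood()] returns the empty graph.
#'
#' @param clr matrix of CLR values (samples x taxa).
#' @return Positive scalar.
#' @export
mb_lambda_max <- function(clr) {
  x <- standardize_cols(as.matrix(clr))
  cc <- abs(crossprod(x)) / nrow(x)
  diag(cc) <- 0
  max(cc)
}

graph_from_selection <- function(adj, symmetrize, node_ids, ...) {
  a <- if (symmetrize == "or") adj | t(adj) else adj & t(adj)
  diag(a) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::V(g)$name <- node_ids %||% paste0("n", seq_len(nrow(a)))
  attrs <- list(...)
  for (nm in names(attrs)) g <- igraph::set_graph_attr(g, nm, attrs[[nm]])
  igraph::set_graph_attr(g, "symmetrize", symmetrize)
}

#' StARS stability selection of the neighbourhood penalty
#'
#' Stability Approach to Regularization Selection: the node-wise lasso is
#' refit on `n_subsamples` random subsamples of size `subsample_size`, each
#' standardised independently; per penalty, the selection frequency `f` of
#' every taxon pair across subsamples gives a total instability
#' `D(lambda) = mean(2 f (1 - f))` over pairs. Instability is monotonised
#' (running maximum) along the path from sparse to dense, and the selected
#' penalty is the smallest (densest) one with monotonised instability at or
#' below `beta`.
#'
#' @param clr matrix of CLR values (samples x taxa).
#' @param lambda_path strictly decreasing positive penalties; by default 30
#'   log-spaced values from the null threshold [mb_lambda_max()] down to
#'   `lambda_min_ratio` times it.
#' @param n_subsamples number of subsamples (default 50).
#' @param subsample_size size of each subsample, strictly less than the
#'   number of samples; default `min(floor(10 sqrt(n)), floor(0.8 n))`.
#' @param beta instability threshold in (0, 0.5), default 0.05.
#' @param seed integer seed for the subsample draws.
#' @param symmetrize edge symmetrisation rule, as in [mb_neighborhood()].
#' @param nlambda,lambda_min_ratio shape of the default path.
#' @return Object of class `stars_result`: `lambda_path`, `instability`,
#'   `monotonized`, `selected_lambda`, `selected_index`, `stability`
#'   (p x p selection-frequency matrix at the selected penalty),
#'   `n_subsamples`, `subsample_size`, `beta`, `seed`.
#' @export
stars_select <- function(clr, lambda_path = NULL, n_subsamples = 50,
                         subsample_size = NULL, beta = 0.05, seed = 1,
                         symmetrize = c("or", "and"),
                         nlambda = 30, lambda_min_ratio = 0.01) {
  symmetrize <- match.arg(symmetrize)
  clr <- as.matrix(clr)
  n <- nrow(clr)
  p <- ncol(clr)
  if (beta <= 0 || beta >= 0.5) stop("`beta` must be in (0, 0.5)")
  if (is.null(subsample_size))
    subsample_size <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  if (subsample_size >= n)
    stop("`subsample_size` must be smaller than the number of samples")
  if (subsample_size < 3)
    stop("too few samples for stability selection")
  if (is.null(lambda_path)) {
    lmax <- mb_lambda_max(clr)
    lambda_path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = nlambda))
  }
  if (any(diff(lambda_path) >= 0) || any(lambda_path <= 0))
    stop("`lambda_path` must be strictly decreasing and positive")
  nl <- length(lambda_path)

  freq <- array(0, dim = c(p, p, nl))
  with_seed(child_seed(seed, 31L), {
    for (s in seq_len(n_subsamples)) {
      idx <- sample.int(n, subsample_size)
      sel <- mb_selection(clr[idx, , drop = FALSE], lambda_path)
      for (l in seq_len(nl)) {
        a <- sel[, , l]
        a <- if (symmetrize == "or") a | t(a) else a & t(a)
        freq[, , l] <- freq[, , l] + a
      }
    }
  })
  freq <- freq / n_subsamples

  ut <- upper.tri(matrix(0, p, p))
  instability <- vapply(seq_len(nl), function(l) {
    f <- freq[, , l][ut]
    mean(2 * f * (1 - f))
  }, numeric(1))
  monotonized <- cummax(instability)
  admissible <- which(monotonized <= beta)
  if (length(admissible)) {
    selected_index <- max(admissible) # densest admissible penalty
  } else {
    warning("no penalty met the instability bound; keeping the sparsest")
    selected_index <- 1L
  }
  structure(list(
    lambda_path = lambda_path,
    instability = instability,
    monotonized = monotonized,
    selected_lambda = lambda_path[selected_index],
    selected_index = selected_index,
    stability = freq[, , selected_index],
    n_subsamples = n_subsamples,
    subsample_size = subsample_size,
    beta = beta,
    seed = seed,
    symmetrize = symmetrize
  ), class = "stars_result")
}

#' @export
print.stars_result <- function(x, ...) {
  cat(sprintf(paste0("stars_result: %d penalties, beta = %g, selected ",
                     "lambda = %.4g (index %d), %d subsamples of %d\n"),
              length(x$lambda_path), x$beta, x$selected_lambda,
              x$selected_index, x$n_subsamples, x$subsample_size))
  invisible(x)
}

#' Infer a co-occurrence network for one experimental group
#'
#' End-to-end inference for a (legacy group x timepoint x kingdom) cell of
#' the design: selects the matching samples and kingdom's taxa, applies the
#' abundance/prevalence filter, CLR-transforms, picks the penalty by StARS
#' and returns the Meinshausen-Buhlmann network at that penalty. Year-2
#' drought and control units are pooled by default (`year2_treatment =
#' NULL`); pass `"drought"` or `"control"` to restrict.
#'
#' @param counts an [asv_table].
#' @param design design `data.frame` with `unit_id`, `swd_2020`,
#'   `timepoint`, `year2_treatment` (rows must match sample ids in
#'   `counts`).
#' @param legacy_group `"control"`, `"mild"` or `"severe"` (see
#'   [assign_legacy_group()]); `NULL` keeps all.
#' @param timepoint `"peak"` or `"recovery"`; `NULL` keeps all.
#' @param kingdom restrict taxa to one kingdom label; `NULL` keeps all.
#' @param year2_treatment optional `"drought"`/`"control"` restriction.
#' @param cutoff,control_swd legacy-group boundaries, defaults 76 and 20.
#' @param min_rel_abund,min_prevalence filter thresholds
#'   (see [filter_asvs()]).
#' @param pseudocount CLR pseudocount.
#' @param seed integer seed (drives the StARS subsamples).
#' @param ... further arguments passed to [stars_select()].
#' @return List with `network` (igraph, provenance in graph attributes),
#'   `stars` (the [stars_select()] result), `filter` (the filter report)
#'   and `samples` (the unit ids used).
#' @export
infer_network <- function(counts, design, legacy_group = NULL,
                          timepoint = NULL, kingdom = NULL,
                          year2_treatment = NULL,
                          cutoff = 76, control_swd = 20,
                          min_rel_abund = 2.5e-6, min_prevalence = 5,
                          pseudocount = 1, seed = 1, ...) {
  stopifnot(inherits(counts, "asv_table"))
  keep <- rep(TRUE, nrow(design))
  if (!is.null(legacy_group)) {
    grp <- assign_legacy_group(design$swd_2020, cutoff = cutoff,
                               control_swd = control_swd)
    keep <- keep & grp == legacy_group
  }
  if (!is.null(timepoint)) keep <- keep & design$timepoint == timepoint
  if (!is.null(year2_treatment))
    keep <- keep & design$year2_treatment == year2_treatment
  units <- design$unit_id[keep]
  if (length(units) == 0)
    stop("the selector matched no samples")
  if (length(units) < 8)
    stop("the selector matched only ", length(units),
         " samples; at least 8 are required for network inference")

  x <- subset_asv(counts, samples = units)
  if (!is.null(kingdom)) {
    taxa <- x$taxonomy$taxon_id[x$taxonomy$kingdom == kingdom]
    if (!length(taxa)) stop("no taxa with kingdom '", kingdom, "'")
    x <- subset_asv(x, taxa = taxa)
  }
  flt <- filter_asvs(x, min_rel_abund = min_rel_abund,
                     min_prevalence = min_prevalence)
  clr <- clr_transform(flt$table, pseudocount = pseudocount)
  stars <- stars_select(clr, seed = seed, ...)
  net <- mb_neighborhood(clr, stars$selected_lambda,
                         symmetrize = stars$symmetrize)
  net <- igraph::set_graph_attr(net, "legacy_group",
                                legacy_group %||% "all")
  net <- igraph::set_graph_attr(net, "timepoint", timepoint %||% "all")
  net <- igraph::set_graph_attr(net, "kingdom", kingdom %||% "all")
  net <- igraph::set_graph_attr(net, "seed", seed)
  list(network = net, stars = stars, filter = flt$report, samples = units)
}
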