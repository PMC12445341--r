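#' Sample a planted sparse interaction graph with a valid precision matrix
#'
#' Draws the ground-truth conditional-dependence structure used by the count
#' simulator: an undirected simple graph plus signed precision-matrix entries
#' on its edges. The implied precision matrix is made symmetric positive
#' definite by diagonal loading (if needed) and rescaled to unit diagonal, so
#' edge weights are interpretable as (negated) partial correlations.
#'
#' Topologies:
#' \describe{
#'   \item{band}{taxon `i` linked to `i + 1, ..., i + w` for a bandwidth `w`
#'     derived from `density` (or given via `band_width`).}
#'   \item{block}{taxa split into `n_blocks` equal groups; edges drawn
#'     uniformly within groups to match `density`.}
#'   \item{scale-free}{Barabasi-Albert preferential attachment with
#'     `m = max(1, round(density * (n_taxa - 1) / 2))` edges per new node;
#'     with one attachment per node this yields exactly `n_taxa - 1` edges.}
#' }
#'
#' @param n_taxa number of taxa (nodes).
#' @param topology one of `"band"`, `"block"`, `"scale-free"`.
#' @param density target edge density in `[0, 1]` (fraction of all
#'   `choose(n_taxa, 2)` pairs); `0` gives the empty graph.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param partial_cor magnitude of the planted partial correlations
#'   (off-diagonal precision entries before loading), default 0.35.
#' @param signs `"random"` (default) or `"positive"` edge signs.
#' @param band_width explicit bandwidth for `topology = "band"`; must be
#'   at least 1 when supplied.
#' @param n_blocks number of blocks for `topology = "block"`, default 4.
#' @param min_eigen lower bound imposed on the smallest eigenvalue via
#'   diagonal loading, default 0.05.
#' @return An object of class `interaction_graph`: list with `n_taxa`,
#'   `edges` (2-column integer matrix, `from < to`), `precision` (dense
#'   matrix with unit diagonal), `topology`, and the loading applied.
#' @examples
#' g <- sample_interaction_graph(30, "band", density = 0.07, seed = 1)
#' nrow(g$edges)
#' min(eigen(g$precision, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
sample_interaction_graph <- function(n_taxa,
                                     topology = c("band", "block", "scale-free"),
                                     density = 0.05,
                                     seed = 1,
                                     partial_cor = 0.35,
                                     signs = c("random", "positive"),
                                     band_width = NULL,
                                     n_blocks = 4,
                                     min_eigen = 0.05) {
  topology <- match.arg(topology)
  signs <- match.arg(signs)
  stopifnot(n_taxa >= 1)
  if (density < 0 || density > 1) stop("`density` must be in [0, 1]")
  if (!is.null(band_width) && band_width < 1)
    stop("band width must be at least 1 (width 0 is incompatible with a band topology)")
  m_target <- round(density * choose(n_taxa, 2))

  edges <- with_seed(child_seed(seed, 11L), {
    if (density == 0 || n_taxa == 1) {
      matrix(integer(), ncol = 2L)
    } else if (topology == "band") {
      w <- band_width %||% band_width_for(n_taxa, m_target)
      pairs <- list()
      for (k in seq_len(w)) {
        i <- seq_len(n_taxa - k)
        pairs[[k]] <- cbind(i, i + k)
      }
      do.call(rbind, pairs)
    } else if (topology == "block") {
      blk <- sort(rep_len(seq_len(n_blocks), n_taxa))
      cand <- which(outer(blk, blk, "==") & upper.tri(diag(n_taxa)),
                    arr.ind = TRUE)
      m <- min(m_target, nrow(cand))
      if (m < 1) stop("`density` too low to place any within-block edge")
      cand[sample.int(nrow(cand), m), , drop = FALSE]
    } else { # scale-free
      m <- max(1L, round(density * (n_taxa - 1) / 2))
      g <- igraph::sample_pa(n_taxa, m = m, directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    }
  })
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])

  omega <- diag(n_taxa)
  if (nrow(edges)) {
    sgn <- with_seed(child_seed(seed, 12L), {
      if (signs == "random") sample(c(-1, 1), nrow(edges), replace = TRUE)
      else rep(1, nrow(edges))
    })
    v <- sgn * partial_cor
    omega[edges] <- v
    omega[edges[, c(2, 1), drop = FALSE]] <- v
  }
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  loading <- if (ev_min < min_eigen) min_eigen - ev_min else 0
  if (loading > 0) diag(omega) <- diag(omega) + loading
  d <- sqrt(diag(omega))
  omega <- omega / outer(d, d)

  structure(list(n_taxa = as.integer(n_taxa), edges = edges,
                 precision = omega, topology = topology,
                 density = density, loading = loading, seed = seed),
            class = "interaction_graph")
}

# smallest bandwidth whose edge count reaches the target
band_width_for <- function(n, m_target) {
  w <- 1L
  while (w < n - 1L && (w * n - w * (w + 1) / 2) < m_target) w <- w + 1L
  w
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d taxa, %d edges (%s topology)\n",
              x$n_taxa, nrow(x$edges), x$topology))
  invisible(x)
}
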