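#' Fit the undirected binary configuration model (UBCM)
#'
#' Maximum-entropy (canonical) null model for an undirected binary network
#' with given degree sequence: each node gets a fitness `x_i >= 0` and edges
#' are independent with probability `p_ij = x_i x_j / (1 + x_i x_j)`, with
#' the fitnesses solved so every node's expected degree matches its observed
#' degree. The ensemble fluctuates around the observed degrees ("soft"
#' constraints) rather than fixing them exactly.
#'
#' Solved by a damped fixed-point iteration
#' `x_i <- k_i / sum_{j != i} x_j / (1 + x_i x_j)`. Boundary nodes are
#' peeled off exactly first: `k_i = 0` forces `x_i = 0` (`p_ij = 0`), and
#' `k_i = n - 1` forces `p_ij -> 1` to every other node in the canonical
#' limit, reducing the remaining problem (this also covers the complete
#' graph, which is flagged).
#'
#' @param degrees non-negative integer degree sequence, each `<= n - 1`.
#' @param tol convergence bound on `max_i |expected degree - k_i|`,
#'   default `1e-8`.
#' @param max_iter iteration cap, default 10000.
#' @return Object of class `ubcm_fit`: `degrees`, `x` (fitnesses; `Inf` for
#'   peeled full-degree nodes), `p` (edge-probability matrix, zero
#'   diagonal), `residual`, `iterations`, `converged`, `complete` (flag for
#'   saturated `p = 1` entries).
#' @examples
#' fit <- fit_ubcm(c(1, 2, 1))
#' round(rowSums(fit$p), 8)
#' @export
fit_ubcm <- function(degrees, tol = 1e-8, max_iter = 10000) {
  k <- as.numeric(degrees)
  n <- length(k)
  if (any(k < 0) || any(k != round(k)))
    stop("degrees must be non-negative integers")
  if (any(k > n - 1))
    stop("degree exceeds n - 1: sequence not realizable")

  p <- matrix(0, n, n)
  x <- numeric(n)
  status <- rep("interior", n)

  # peel structural zeros (k = 0) and structural ones (k = n_active - 1,
  # i.e. connected to every other active node with probability -> 1)
  active <- rep(TRUE, n)
  kk <- k
  repeat {
    idx <- which(active)
    na <- length(idx)
    if (na == 0) break
    zero <- idx[kk[idx] == 0]
    if (length(zero)) {
      # residual degree 0: either a true isolate (x = 0) or a node whose
      # whole degree was absorbed by saturated p = 1 neighbours (x -> 0
      # while the saturated partner's fitness diverges)
      status[zero] <- ifelse(k[zero] > 0, "saturated", "zero")
      active[zero] <- FALSE
      next
    }
    full <- idx[kk[idx] == na - 1 & na > 1]
    if (length(full)) {
      v <- full[1]
      others <- setdiff(idx, v)
      p[v, others] <- 1
      p[others, v] <- 1
      x[v] <- Inf
      status[v] <- "full"
      active[v] <- FALSE
      kk[others] <- kk[others] - 1
      next
    }
    break
  }

  iterations <- 0L
  idx <- which(active)
  if (length(idx) >= 2) {
    ki <- kk[idx]
    m <- length(idx)
    xi <- ki / sqrt(sum(ki))
    for (it in seq_len(max_iter)) {
      iterations <- it
      xo <- outer(xi, xi)
      denom_mat <- matrix(xi, m, m, byrow = TRUE) / (1 + xo)
      diag(denom_mat) <- 0
      xnew <- ki / rowSums(denom_mat)
      xi <- 0.5 * xi + 0.5 * xnew
      pp <- outer(xi, xi)
      pp <- pp / (1 + pp)
      diag(pp) <- 0
      if (max(abs(rowSums(pp) - ki)) <= tol) break
    }
    pp <- outer(xi, xi)
    pp <- pp / (1 + pp)
    diag(pp) <- 0
    p[idx, idx] <- pp
    x[idx] <- xi
  } else if (length(idx) == 1 && kk[idx] != 0) {
    stop("degree sequence not realizable: one active node with k > 0")
  }

  residual <- max(abs(rowSums(p) - k))
  converged <- residual <= tol
  if (!converged)
    warning(sprintf(
      "UBCM solver did not reach tol = %g after %d iterations (residual %g)",
      tol, iterations, residual))
  structure(list(degrees = as.integer(degrees), x = x, p = p,
                 residual = residual, iterations = iterations,
                 converged = converged, complete = any(status == "full")),
            class = "ubcm_fit")
}

#' @export
print.ubcm_fit <- function(x, ...) {
  cat(sprintf(paste0("ubcm_fit: n = %d, residual %.2e after %d iterations",
                     " (%s)%s\n"),
              length(x$degrees), x$residual, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$complete) ", saturated p = 1 entries" else ""))
  invisible(x)
}

#' Sample a null-network ensemble from a fitted UBCM
#'
#' Draws networks with independent Bernoulli edge indicators at the fitted
#' probabilities `p_ij`. Deterministic given the seed.
#'
#' @param fit a converged [fit_ubcm()] result.
#' @param n_networks ensemble size, default 999.
#' @param seed integer seed.
#' @return List of [igraph::graph]s (all on the same node set), with
#'   attributes `seed` and `p` (the probability matrix).
#' @export
sample_ensemble <- function(fit, n_networks = 999, seed = 1) {
  stopifnot(inherits(fit, "ubcm_fit"))
  if (!fit$converged) stop("refusing to sample from a non-converged fit")
  n <- nrow(fit$p)
  ut <- which(upper.tri(fit$p))
  pv <- fit$p[ut]
  nets <- with_seed(child_seed(seed, 41L), {
    lapply(seq_len(n_networks), function(b) {
      on <- ut[stats::runif(length(pv)) < pv]
      a <- matrix(FALSE, n, n)
      a[on] <- TRUE
      igraph::graph_from_adjacency_matrix(a | t(a), mode = "undirected")
    })
  })
  attr(nets, "seed") <- seed
  attr(nets, "p") <- fit$p
  nets
}

#' z-scores of network metrics against a null ensemble
#'
#' Computes each requested metric on the observed network and on every
#' network of the null ensemble with identical settings (the same code
#' path, attack rule and tie-breaks), and reports
#' `z = (observed - null mean) / null sd`. `|z|` at or above `z_threshold`
#' (default 1.96) flags the observed property as significantly different
#' from the degree-sequence-only expectation. Non-finite null values (the
#' within:between ratio can be `Inf`/`NaN` on sparse draws) are dropped
#' and counted; a zero null standard deviation yields `z = NA` rather than
#' a division by zero.
#'
#' @param observed an [igraph::graph] or a [network_metrics()] report.
#' @param ensemble list of null networks from [sample_ensemble()].
#' @param metrics subset of
#'   `c("modularity", "transitivity", "within_between", "robustness")`.
#' @param z_threshold two-sided significance threshold, default 1.96.
#' @param attack,recompute robustness settings applied to observed and
#'   null networks alike (ignored if `observed` is already a report,
#'   whose recorded settings are reused).
#' @return `data.frame` of class `ensemble_summary` with one row per
#'   metric: `observed`, `null_mean`, `null_sd`, `z`, `significant`,
#'   `n_null`, `n_finite`; the threshold, ensemble size and settings are
#'   stored as attributes.
#' @export
zscore_metrics <- function(observed, ensemble,
                           metrics = c("modularity", "transitivity",
                                       "within_between", "robustness"),
                           z_threshold = 1.96,
                           attack = "degree", recompute = TRUE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!length(ensemble)) stop("the null ensemble is empty")
  if (igraph::is_igraph(observed))
    observed <- network_metrics(observed, attack = attack,
                                recompute = recompute)
  stopifnot(inherits(observed, "metrics_report"))
  attack <- observed$attack
  recompute <- observed$recompute

  null_vals <- vapply(ensemble, function(g) {
    r <- network_metrics(g, attack = attack, recompute = recompute)
    c(modularity = r$modularity, transitivity = r$transitivity,
      within_between = r$within_between, robustness = r$robustness)
  }, numeric(4))

  rows <- lapply(metrics, function(mname) {
    obs <- observed[[if (mname == "within_between") "within_between" else mname]]
    nv <- null_vals[mname, ]
    fin <- nv[is.finite(nv)]
    mu <- mean(fin)
    sd_ <- stats::sd(fin)
    z <- if (length(fin) < 2 || is.na(sd_) || sd_ == 0 || !is.finite(obs))
      NA_real_ else (obs - mu) / sd_
    data.frame(metric = mname, observed = obs, null_mean = mu,
               null_sd = sd_, z = z,
               significant = if (is.na(z)) NA else abs(z) >= z_threshold,
               n_null = length(nv), n_finite = length(fin),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "z_threshold") <- z_threshold
  attr(out, "attack") <- attack
  attr(out, "recompute") <- recompute
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary (%d null networks, |z| >= %g flags):\n",
              x$n_null[1], attr(x, "z_threshold")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Microcanonical cross-check: degree-preserving edge swaps
#'
#' Utility sampler that rewires the observed network by double-edge swaps,
#' preserving the degree sequence exactly (hard constraints). Provided as a
#' cross-check on the canonical (soft) UBCM ensemble, not as the main null
#' model.
#'
#' @param net an [igraph::graph].
#' @param n_networks number of rewired draws.
#' @param n_swaps swap attempts per draw (default `10 * ecount`).
#' @param seed integer seed.
#' @return List of rewired [igraph::graph]s.
#' @export
rewire_ensemble <- function(net, n_networks = 99, n_swaps = NULL, seed = 1) {
  n_swaps <- n_swaps %||% (10 * igraph::ecount(net))
  with_seed(child_seed(seed, 42L), {
    lapply(seq_len(n_networks), function(b)
      igraph::rewire(net, igraph::keeping_degseq(niter = n_swaps)))
  })
}
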