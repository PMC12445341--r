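#' Global transitivity (clustering coefficient)
#'
#' `3 * triangles / connected triples`; the probability that two neighbours
#' of a node are themselves connected. Defined as 0 when the graph has no
#' connected triple.
#'
#' @param net an undirected [igraph::graph].
#' @return Fraction in `[0, 1]`.
#' @export
net_transitivity <- function(net) {
  t <- igraph::transitivity(net, type = "global")
  if (is.nan(t) || is.na(t)) 0 else t
}

#' Fast-greedy module detection
#'
#' Agglomerative merging that maximises Newman modularity
#' `Q = sum_m (e_mm - a_m^2)` (Clauset-Newman-Moore), the field-standard
#' community detector for binary co-occurrence networks. Isolated nodes end
#' up as singleton modules; the edgeless graph gets all-singleton modules
#' with `Q = 0`. The greedy merge path is cut at its maximum-modularity
#' point; if a numerically tied cut leaves a worse partition than the
#' connected-component or one-module split, the better of those is
#' returned, so `Q` is never below 0.
#'
#' @param net an undirected simple [igraph::graph].
#' @return Object of class `module_partition`: `membership` (named integer
#'   vector) and `modularity` (the Q of that partition).
#' @export
greedy_modules <- function(net) {
  n <- igraph::vcount(net)
  ids <- igraph::V(net)$name %||% as.character(seq_len(n))
  if (igraph::ecount(net) == 0) {
    membership <- stats::setNames(seq_len(n), ids)
    return(structure(list(membership = membership, modularity = 0),
                     class = "module_partition"))
  }
  cl <- igraph::cluster_fast_greedy(net)
  # the greedy merge path can cut at a numerically tied negative-Q point;
  # never return a partition worse than the component or one-module split
  candidates <- list(as.integer(igraph::membership(cl)),
                     igraph::components(net)$membership,
                     rep(1L, n))
  qs <- vapply(candidates, function(mem) igraph::modularity(net, mem),
               numeric(1))
  best <- candidates[[which.max(qs)]]
  membership <- stats::setNames(as.integer(best), ids)
  structure(list(membership = membership, modularity = max(qs)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.4f\n",
              length(unique(x$membership)), length(x$membership),
              x$modularity))
  invisible(x)
}

#' Within:between module link ratio
#'
#' Number of edges with both endpoints in one module divided by the number
#' of edges crossing modules. `Inf` when there are within-edges but no
#' crossing edges (e.g. disconnected cliques); `NaN` when the graph has no
#' edges at all (0/0).
#'
#' @param net an undirected [igraph::graph].
#' @param partition a `module_partition` from [greedy_modules()] (computed
#'   on the fly when omitted).
#' @return Non-negative real, `Inf`, or `NaN`.
#' @export
within_between_ratio <- function(net, partition = NULL) {
  if (is.null(partition)) partition <- greedy_modules(net)
  mem <- partition$membership
  if (length(mem) != igraph::vcount(net))
    stop("partition does not cover the network's nodes")
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) == 0) return(NaN)
  within <- sum(mem[el[, 1]] == mem[el[, 2]])
  between <- nrow(el) - within
  if (between == 0) {
    if (within == 0) NaN else Inf
  } else {
    within / between
  }
}

#' Targeted-attack robustness (area under the size ~ removal curve)
#'
#' Removes nodes one at a time in decreasing attack-score order (degree or
#' betweenness, recomputed after each removal by default), recording the
#' largest-connected-component fraction `S_k = LCC / n` after `k` removals.
#' Robustness is the trapezoidal area under the curve of `S_k` against the
#' fraction removed `k/n`, including the terminal point `(1, 0)` so values
#' are comparable across network sizes; the complete graph attains the
#' maximum 0.5. Ties in attack score are broken by node order (first
#' vertex wins), making the attack deterministic.
#'
#' @param net an undirected [igraph::graph] with at least one node.
#' @param attack `"degree"` (default) or `"betweenness"`.
#' @param recompute recompute attack scores after each removal
#'   (default `TRUE`).
#' @return List with `auc` and `curve` (a `data.frame` with
#'   `fraction_removed` and `lcc_fraction`, rows `k = 0..n`).
#' @export
robustness_auc <- function(net, attack = c("degree", "betweenness"),
                           recompute = TRUE) {
  attack <- match.arg(attack)
  n <- igraph::vcount(net)
  if (n < 1) stop("the network must have at least one node")
  a <- igraph::as_adjacency_matrix(net, sparse = FALSE) > 0

  order <- attack_order(a, net, attack, recompute)
  s <- lcc_after_removals(a, order)  # S_0 .. S_n
  q <- seq(0, n) / n
  auc <- sum((s[-1] + s[-length(s)]) / 2) / n
  list(auc = auc,
       curve = data.frame(fraction_removed = q, lcc_fraction = s))
}

# Removal order under the attack rule; ties broken by node index.
attack_order <- function(a, net, attack, recompute) {
  n <- nrow(a)
  if (!recompute) {
    score <- if (attack == "degree") rowSums(a) else igraph::betweenness(net)
    return(order(-score, seq_len(n)))
  }
  if (attack == "degree") {
    deg <- rowSums(a)
    active <- rep(TRUE, n)
    ord <- integer(n)
    for (k in seq_len(n)) {
      cand <- which(active)
      v <- cand[which.max(deg[cand])]
      ord[k] <- v
      active[v] <- FALSE
      deg <- deg - a[, v]
    }
    ord
  } else {
    g <- net
    remaining <- seq_len(n)
    ord <- integer(n)
    for (k in seq_len(n)) {
      btw <- igraph::betweenness(g)
      v <- which.max(btw) # first max = lowest index
      ord[k] <- remaining[v]
      remaining <- remaining[-v]
      g <- igraph::delete_vertices(g, v)
    }
    ord
  }
}

# Largest-component fraction after each removal, via reverse union-find:
# replay the removals backwards as additions, merging components.
lcc_after_removals <- function(a, ord) {
  n <- nrow(a)
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  present <- rep(FALSE, n)
  maxsize <- 0L
  s <- numeric(n + 1L)
  s[n + 1L] <- 0 # all nodes removed
  for (j in n:1) {
    v <- ord[j]
    present[v] <- TRUE
    maxsize <- max(maxsize, 1L)
    nb <- which(a[v, ] & present)
    for (u in nb) {
      ru <- find(u); rv <- find(v)
      if (ru != rv) {
        if (size[ru] < size[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
        parent[rv] <- ru
        size[ru] <- size[ru] + size[rv]
        maxsize <- max(maxsize, size[ru])
      }
    }
    s[j] <- maxsize / n # after j - 1 removals
  }
  s
}

#' All four network properties in one report
#'
#' Computes the three complexity properties (transitivity, fast-greedy
#' modularity, within:between link ratio) and the stability property
#' (targeted-attack robustness AUC) with a single set of attack settings,
#' which are recorded in the report so observed and null networks can be
#' measured identically.
#'
#' @param net an undirected simple [igraph::graph].
#' @param attack,recompute robustness settings, see [robustness_auc()].
#' @return Object of class `metrics_report`: `transitivity`, `modularity`,
#'   `within_between`, `robustness`, `curve`, `partition`, and the
#'   settings used.
#' @export
network_metrics <- function(net, attack = "degree", recompute = TRUE) {
  part <- greedy_modules(net)
  rob <- robustness_auc(net, attack = attack, recompute = recompute)
  structure(list(
    transitivity = net_transitivity(net),
    modularity = part$modularity,
    within_between = within_between_ratio(net, part),
    robustness = rob$auc,
    curve = rob$curve,
    partition = part,
    attack = attack,
    recompute = recompute,
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report (%d nodes, %d edges): transitivity ",
                     "%.3f, modularity %.3f, within:between %s, ",
                     "robustness %.3f [%s attack%s]\n"),
              x$n_nodes, x$n_edges, x$transitivity, x$modularity,
              format(x$within_between, digits = 3), x$robustness, x$attack,
              if (x$recompute) ", recomputed" else ""))
  invisible(x)
}

#' Taxonomic composition of network modules
#'
#' Counts the ASVs of each family within each module, sorted by module size
#' (largest first). Used to track guilds -- e.g. whether ammonia-oxidising
#' bacteria and archaea occupy the same or different modules.
#'
#' @param net an undirected [igraph::graph] whose vertex names are taxon ids.
#' @param partition a `module_partition` (computed when omitted).
#' @param taxonomy `data.frame` with `taxon_id` and `family` columns
#'   covering the network's nodes.
#' @return `data.frame` with `module`, `module_size`, `family`, `n_asv`.
#' @export
module_composition <- function(net, partition = NULL, taxonomy) {
  if (is.null(partition)) partition <- greedy_modules(net)
  mem <- partition$membership
  fam <- taxonomy$family[match(names(mem), taxonomy$taxon_id)]
  fam[is.na(fam)] <- "unknown"
  tab <- as.data.frame(table(module = mem, family = fam),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "n_asv"
  sizes <- table(mem)
  tab$module_size <- as.integer(sizes[tab$module])
  tab <- tab[order(-tab$module_size, tab$module, -tab$n_asv), ]
  rownames(tab) <- NULL
  tab[, c("module", "module_size", "family", "n_asv")]
}
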