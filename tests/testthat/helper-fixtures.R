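# Shared fixture builders; everything is generated in code at test time.

# A small complete simulated experiment.
tiny_experiment <- function(seed = 1, n_prok = 30, n_fun = 15, depth = 5000) {
  simulate_experiment(seed = seed, n_prokaryote = n_prok, n_fungal = n_fun,
                      depth = depth)
}

# Replicated design: `n` samples cycling over the standard design rows,
# with optional overrides; used to get many samples at chosen conditions.
replicated_design <- function(n, swd = NULL, treatment = NULL) {
  d <- build_design()
  d <- d[rep(seq_len(nrow(d)), length.out = n), ]
  d$unit_id <- sprintf("s%04d", seq_len(n))
  if (!is.null(swd)) d$swd_2020 <- rep_len(swd, n)
  if (!is.null(treatment)) d$year2_treatment <- rep_len(treatment, n)
  rownames(d) <- NULL
  d
}

# Gaussian data with a planted band(1) dependence, via the count simulator.
band_counts <- function(n_taxa = 30, n_samples = 200, seed = 1,
                        depth = 20000) {
  g <- sample_interaction_graph(n_taxa, "band", band_width = 1,
                                density = 0.05, seed = seed)
  tax <- synth_taxonomy(n_taxa, 0, seed = seed)
  eff <- legacy_effects(tax, prop_responsive = 0, year2_drought_sd = 0,
                        seed = seed)
  d <- replicated_design(n_samples)
  list(graph = g,
       counts = simulate_counts(d, g, eff, depth = depth, seed = seed))
}

# Edge set of an igraph as a canonical character vector "lo-hi".
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(el)) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
}

edge_f1 <- function(estimated, truth_edges) {
  est <- edge_keys(estimated)
  tru <- sort(paste(truth_edges[, 1], truth_edges[, 2], sep = "-"))
  tp <- length(intersect(est, tru))
  precision <- if (length(est)) tp / length(est) else 0
  recall <- if (length(tru)) tp / length(tru) else 1
  if (precision + recall == 0) return(c(f1 = 0, precision = 0, recall = 0))
  c(f1 = 2 * precision * recall / (precision + recall),
    precision = precision, recall = recall)
}

# Brute-force transitivity: 3 * triangles / connected triples.
brute_transitivity <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n <- nrow(a)
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (a[i, j] && a[j, k]) {
      triples <- triples + 1          # ordered path j's two neighbours
      if (a[i, k]) triangles <- triangles + 1
    }
  }
  if (triples == 0) return(0)
  # ordered counts: each triangle counted 6x, each triple 2x -> 3T/P intact
  3 * (triangles / 6) / (triples / 2)
}

# Newman modularity recomputed from scratch for a given membership.
brute_modularity <- function(g, membership) {
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  q <- 0
  for (mod in unique(membership)) {
    nodes <- which(membership == mod)
    e_mm <- sum(membership[el[, 1]] == mod & membership[el[, 2]] == mod) / m
    a_m <- sum(deg[nodes]) / (2 * m)
    q <- q + e_mm - a_m^2
  }
  q
}

# Seeded evaluation that restores the RNG state (keeps tests independent).
with_seed_test <- function(seed, code) withr::with_seed(seed, code)
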