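test_that("UBCM fit matches symmetric and degenerate closed forms", {
  # k-regular: all fitnesses equal, expected degrees exact
  fit <- fit_ubcm(rep(3, 8))
  expect_lt(diff(range(fit$x)), 1e-8)
  expect_lt(max(abs(rowSums(fit$p) - 3)), 1e-8)
  # all-zero degrees
  fit0 <- fit_ubcm(rep(0, 5))
  expect_identical(fit0$x, rep(0, 5))
  expect_true(all(fit0$p == 0))
  # complete graph: saturated p -> 1 limit, flagged
  fitc <- fit_ubcm(rep(4, 5))
  expect_true(fitc$complete)
  expect_true(all(fitc$p[upper.tri(fitc$p)] == 1))
  expect_error(fit_ubcm(c(5, 1, 1)), "realizable")
  expect_error(fit_ubcm(c(-1, 1)), "non-negative")
})

test_that("the path-graph boundary case reproduces its canonical limit", {
  fit <- fit_ubcm(c(1, 2, 1))
  expect_lt(max(abs(rowSums(fit$p) - c(1, 2, 1))), 1e-8)
  # independent oracle: the saturated middle node forces p12 = p23 = 1 and
  # leaves a 2-node system with residual degrees (0, 0), so p13 solves
  # x^2/(1+x^2) = 0 exactly
  expect_equal(fit$p[1, 2], 1)
  expect_equal(fit$p[2, 3], 1)
  expect_equal(fit$p[1, 3], 0)
})

test_that("UBCM expected degrees match observed degrees on random graphs", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.05, 0.4))
    k <- igraph::degree(g)
    fit <- fit_ubcm(k)
    expect_true(fit$converged)
    expect_lte(fit$residual, 1e-8)
    expect_true(all(fit$p >= 0 & fit$p < 1 + 1e-12))
    expect_true(all((fit$x == 0) == (k == 0)))
  }
})

test_that("UBCM fitnesses agree with an independent likelihood maximiser", {
  # the degree-matching fixed point is the stationarity condition of the
  # ensemble log-likelihood L = sum k_i log x_i - sum_{i<j} log(1 + x_i x_j);
  # maximise it directly (in log-fitness space) as the oracle
  set.seed(20)
  g <- igraph::sample_gnp(12, 0.35)
  k <- igraph::degree(g)
  stopifnot(all(k > 0), all(k < 11))
  negll <- function(logx) {
    x <- exp(logx)
    xo <- outer(x, x)
    -(sum(k * logx) - sum(log(1 + xo[upper.tri(xo)])))
  }
  opt <- optim(rep(0, 12), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  fit <- fit_ubcm(k)
  expect_equal(unname(fit$x), unname(exp(opt$par)), tolerance = 1e-4)
  xo <- outer(exp(opt$par), exp(opt$par))
  p_oracle <- xo / (1 + xo)
  diag(p_oracle) <- 0
  expect_equal(fit$p, p_oracle, tolerance = 1e-4)
})

test_that("ensemble sampling respects probabilities, seed and moments", {
  fit0 <- fit_ubcm(rep(0, 6))
  ens0 <- sample_ensemble(fit0, 5, seed = 1)
  expect_true(all(vapply(ens0, igraph::ecount, numeric(1)) == 0))

  set.seed(11)
  g <- igraph::sample_gnp(20, 0.3)
  fit <- fit_ubcm(igraph::degree(g))
  e1 <- sample_ensemble(fit, 30, seed = 4)
  e2 <- sample_ensemble(fit, 30, seed = 4)
  expect_identical(lapply(e1, edge_keys), lapply(e2, edge_keys))

  # per-node mean degree across 999 draws within 4 standard errors of k
  ens <- sample_ensemble(fit, 999, seed = 5)
  degs <- vapply(ens, igraph::degree, numeric(20))
  k <- igraph::degree(g)
  var_deg <- rowSums(fit$p * (1 - fit$p))
  se <- sqrt(var_deg / 999)
  expect_true(all(abs(rowMeans(degs) - k) <= 4 * pmax(se, 1e-12)))

  # mean edge count within 4 SE of sum(p) for near-saturated probabilities
  pfit <- fit
  pfit$p[] <- 1 - 1e-3
  diag(pfit$p) <- 0
  enshi <- sample_ensemble(pfit, 999, seed = 6)
  m <- vapply(enshi, igraph::ecount, numeric(1))
  expected <- sum(pfit$p[upper.tri(pfit$p)])
  se_m <- sqrt(sum(pfit$p[upper.tri(pfit$p)] * 1e-3) / 999)
  expect_lt(abs(mean(m) - expected), 4 * se_m + 1e-9)
})

test_that("z-scores are centred, thresholded and guard degenerate sds", {
  set.seed(12)
  g <- igraph::sample_gnp(25, 0.25)
  fit <- fit_ubcm(igraph::degree(g))
  ens <- sample_ensemble(fit, 99, seed = 7)
  zs <- zscore_metrics(g, ens)
  expect_identical(attr(zs, "z_threshold"), 1.96)
  expect_setequal(zs$metric, c("modularity", "transitivity",
                               "within_between", "robustness"))
  expect_true(all(zs$n_null == 99))
  # observed equal to the null mean gives z = 0 and no flag
  obs <- network_metrics(ens[[1]])
  obs$modularity <- zs$null_mean[zs$metric == "modularity"]
  z0 <- zscore_metrics(obs, ens, metrics = "modularity")
  expect_equal(z0$z, 0)
  expect_false(z0$significant)
  # zero null sd yields the undefined-z sentinel, not a division by zero
  const_ens <- lapply(1:5, function(i) igraph::make_full_graph(6))
  zc <- zscore_metrics(igraph::make_full_graph(6), const_ens,
                       metrics = "transitivity")
  expect_true(is.na(zc$z))
  expect_true(is.na(zc$significant))
  expect_error(zscore_metrics(g, list()), "empty")
})

test_that("z is invariant to affine rescaling applied to both sides", {
  set.seed(13)
  null_vals <- rnorm(50, 3, 0.7)
  obs <- 4.1
  z1 <- (obs - mean(null_vals)) / sd(null_vals)
  a <- 2.5; b <- -1
  z2 <- ((a * obs + b) - mean(a * null_vals + b)) / sd(a * null_vals + b)
  expect_equal(z1, z2)
})

test_that("a planted modular network is flagged against its UBCM ensemble", {
  # two dense blocks, sparse between: modularity should exceed the nulls
  set.seed(14)
  blocks <- igraph::sample_sbm(40, pref.matrix = rbind(c(0.6, 0.02),
                                                       c(0.02, 0.6)),
                               block.sizes = c(20, 20))
  fit <- fit_ubcm(igraph::degree(blocks))
  ens <- sample_ensemble(fit, 99, seed = 8)
  zs <- zscore_metrics(blocks, ens, metrics = "modularity")
  expect_gt(zs$z, 1.96)
  expect_true(zs$significant)
})

test_that("the edge-swap cross-check preserves the degree sequence", {
  set.seed(15)
  g <- igraph::sample_gnp(15, 0.3)
  rw <- rewire_ensemble(g, n_networks = 5, seed = 9)
  for (h in rw)
    expect_identical(igraph::degree(h), igraph::degree(g))
})
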