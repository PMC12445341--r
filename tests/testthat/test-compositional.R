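test_that("CLR transform matches its closed form on small compositions", {
  expect_equal(clr_transform(matrix(c(5, 5, 5, 5), 1), pseudocount = 0),
               matrix(0, 1, 4), ignore_attr = TRUE)
  v <- clr_transform(matrix(c(8, 2), 1), pseudocount = 0)
  expect_equal(as.numeric(v), c(log(2), -log(2)))
  # exponentials of CLR values have geometric mean 1
  w <- clr_transform(matrix(c(1, 2, 4), 1), pseudocount = 0)
  expect_equal(prod(exp(w))^(1 / 3), 1)
  expect_error(clr_transform(matrix(c(0, 2), 1), pseudocount = 0),
               "pseudocount")
})

test_that("CLR rows sum to zero for random count tables", {
  set.seed(1)
  for (i in 1:100) {
    m <- matrix(rpois(6 * 8, lambda = sample(1:50, 1)), 6, 8)
    expect_lt(max(abs(rowSums(clr_transform(m)))), 1e-9)
  }
})

test_that("ASV filtering agrees with a brute-force scan", {
  brute_filter <- function(m, min_ra, min_prev) {
    keep <- logical(ncol(m))
    for (j in seq_len(ncol(m))) {
      ra <- sum(m[, j]) / sum(m)
      prev <- sum(m[, j] > 0)
      keep[j] <- ra >= min_ra && prev >= min_prev
    }
    keep
  }
  set.seed(2)
  for (i in 1:50) {
    m <- matrix(rpois(6 * 10, 2), 6, 10,
                dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
    min_ra <- runif(1, 0, 0.05)
    min_prev <- sample(0:6, 1)
    got <- filter_asvs(asv_table(m), min_ra, min_prev)
    expect_identical(colnames(got$table$counts),
                     colnames(m)[brute_filter(m, min_ra, min_prev)])
    rep <- got$report
    expect_identical(rep$taxa_out + rep$removed_total, rep$taxa_in)
  }
})

test_that("filter report records thresholds and handles edge cases", {
  m <- matrix(c(10, 0, 5, 1, 0, 0, 3, 2, 8, 0, 0, 1,
                2, 2, 2, 2, 2, 2, 0, 0, 0, 0, 0, 1), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:4)))
  f <- filter_asvs(asv_table(m), 0.01, 5)
  expect_identical(f$report$min_rel_abund, 0.01)
  expect_identical(f$report$min_prevalence, 5)
  # identity at zero thresholds
  f0 <- filter_asvs(asv_table(m), 0, 0)
  expect_identical(f0$table$counts, m)
  expect_identical(f0$report$removed_total, 0L)
  # default thresholds mirror the standard convention
  fd <- filter_asvs(asv_table(m))
  expect_identical(fd$report$min_rel_abund, 2.5e-6)
  expect_identical(fd$report$min_prevalence, 5)
  expect_error(filter_asvs(asv_table(matrix(0, 2, 2))), "grand total")
})

test_that("Aitchison distance is a metric and matches hand computation", {
  clr <- clr_transform(rbind(a = c(1, 2, 4), b = c(1, 2, 4), c = c(4, 2, 1)),
                       pseudocount = 0)
  d <- as.matrix(aitchison_distance(clr))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], sqrt(sum((clr[1, ] - clr[3, ])^2)))
  # metric axioms on a random table
  set.seed(3)
  m <- matrix(rpois(5 * 7, 20) + 1, 5, 7)
  dm <- as.matrix(aitchison_distance(clr_transform(m, pseudocount = 0)))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(dm[i, k], dm[i, j] + dm[j, k] + 1e-12)
})

test_that("Aitchison distance is invariant to per-sample scaling", {
  set.seed(4)
  m <- matrix(rpois(4 * 6, 30) + 1, 4, 6)
  m2 <- m
  m2[2, ] <- m2[2, ] * 7
  d1 <- aitchison_distance(clr_transform(m, pseudocount = 0))
  d2 <- aitchison_distance(clr_transform(m2, pseudocount = 0))
  expect_equal(as.matrix(d1), as.matrix(d2))
})

test_that("Shannon diversity matches direct summation and known values", {
  expect_equal(unname(shannon_index(matrix(rep(3, 7), 1))), log(7))
  expect_equal(unname(shannon_index(matrix(c(9, 0, 0), 1))), 0)
  p <- c(1, 1, 2) / 4
  expect_equal(unname(shannon_index(matrix(c(1, 1, 2), 1))),
               -sum(p * log(p)))
  # cross-check against vegan on a random table
  set.seed(5)
  m <- matrix(rpois(6 * 9, 10), 6, 9) + 1
  expect_equal(unname(shannon_index(m)),
               unname(vegan::diversity(m, index = "shannon")))
  expect_error(shannon_index(matrix(c(0, 0), 1)), "positive total")
})

test_that("rank aggregation buckets unknowns and sums to one", {
  m <- matrix(c(30, 60, 70, 140, 0, 100), 2, 3,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  tax <- data.frame(taxon_id = c("t1", "t2"), kingdom = "prokaryote",
                    phylum = "P1", family = c("F1", "F2"))
  shares <- aggregate_rank(asv_table(m, tax), "family")
  expect_equal(rowSums(shares), c(s1 = 1, s2 = 1))
  expect_equal(shares["s1", "F1"], 0.3)
  expect_equal(shares["s1", "F2"], 0.7)
  expect_equal(shares["s2", "unknown"], 100 / 300)
  # single family spans everything
  tax1 <- data.frame(taxon_id = c("t1", "t2", "t3"), family = "F1")
  expect_equal(unname(aggregate_rank(asv_table(m, tax1), "family")[, "F1"]),
               c(1, 1))
  expect_error(aggregate_rank(asv_table(m, tax), "order"), "arg")
})
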