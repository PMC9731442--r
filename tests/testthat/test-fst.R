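test_that("pairwise locus FST matches hand computations and bounds", {
  expect_equal(locus_fst(0.3, 0.3), 0)
  expect_equal(locus_fst(0, 1), 1)
  expect_equal(locus_fst(0.2, 0.8), 0.36)   # H_T=0.5, H_S=0.32
  expect_equal(locus_fst(0, 0), 0)          # monomorphic convention
  expect_error(locus_fst(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("locus FST is symmetric and invariant under allele relabelling", {
  set.seed(11)
  p1 <- runif(200); p2 <- runif(200)
  f <- locus_fst(p1, p2)
  expect_equal(f, locus_fst(p2, p1))
  expect_equal(f, locus_fst(1 - p1, 1 - p2))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("vectorised pairwise FST equals scalar brute-force recomputation", {
  d <- cached_sim("mid", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 2000,
                                       fst_target = 0.1, seed = 21)))
  pf <- pairwise_fst(d$counts)
  snvs <- call_snvs(d$counts, per_pool_window = FALSE)
  set.seed(1)
  for (k in sample(which(!is.na(pf$per_locus[, 1])), 20)) {
    a1 <- snvs$alt_count[k, 1]; r1 <- snvs$ref_count[k, 1]
    a2 <- snvs$alt_count[k, 2]; r2 <- snvs$ref_count[k, 2]
    p1 <- a1 / (a1 + r1); p2 <- a2 / (a2 + r2)
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    expect_equal(unname(pf$per_locus[k, 1]), unname((ht - hs) / ht),
                 tolerance = 1e-12)
  }
})

test_that("identical pools yield near-zero median FST", {
  d <- simulate_metapopulation(sim_config(n_pools = 2, n_loci = 5000,
                                          fst_target = 0, coverage_mean = 100,
                                          seed = 31))
  pf <- pairwise_fst(d$counts)
  expect_lt(abs(pf$median_matrix[1, 2]), 0.01)
})

test_that("median pairwise FST recovers the island-model expectation", {
  # independent oracle: the same estimator applied directly to fresh
  # Balding-Nichols frequency draws with binomial read sampling
  set.seed(99)
  F <- 0.2; L <- 20000
  p <- runif(L, 0.1, 0.9)
  a <- p * (1 - F) / F; b <- (1 - p) * (1 - F) / F
  p1 <- rbeta(L, a, b); p2 <- rbeta(L, a, b)
  c1 <- pmax(rnbinom(L, mu = 100, size = 5), 1)
  c2 <- pmax(rnbinom(L, mu = 100, size = 5), 1)
  h1 <- rbinom(L, c1, p1) / c1; h2 <- rbinom(L, c2, p2) / c2
  pbar <- (h1 + h2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- h1 * (1 - h1) + h2 * (1 - h2)
  oracle <- median(((ht - hs) / ht)[ht > 0])

  d <- simulate_metapopulation(sim_config(n_pools = 2, n_loci = 5000,
                                          fst_target = 0.2, seed = 41))
  pf <- pairwise_fst(d$counts)
  expect_lt(abs(pf$median_matrix[1, 2] - oracle), 0.03)
})

test_that("median FST increases with simulated differentiation", {
  meds <- vapply(c(0.02, 0.1, 0.3), function(F) {
    m <- vapply(1:3, function(s) {
      d <- simulate_metapopulation(sim_config(n_pools = 2, n_loci = 1500,
                                              fst_target = F,
                                              seed = 100 + s))
      pairwise_fst(d$counts)$median_matrix[1, 2]
    }, 0)
    mean(m)
  }, 0)
  expect_true(all(diff(meds) > 0))
})

test_that("multi-population per-locus FST recovers the inbreeding parameter", {
  d <- cached_sim("recov05", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 5000,
                                       fst_target = 0.05, seed = 51)))
  g <- global_fst(d$counts)
  expect_lt(abs(mean(g$fst, na.rm = TRUE) - 0.05), 0.03)
})

test_that("FST distribution check flags locus-set mixtures", {
  d1 <- cached_sim("mid", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 2000,
                                       fst_target = 0.1, seed = 21)))
  pf <- pairwise_fst(d1$counts)
  chk <- fst_distribution_check(pf, pair = 1, seed = 1)
  expect_true(chk$unimodal)

  # 50/50 mixture of weakly and strongly differentiated locus sets, on the
  # population-wide per-locus statistic (the distribution that is inspected
  # for a possible species mixture)
  lo <- simulate_metapopulation(sim_config(n_pools = 4, n_loci = 2000,
                                           fst_target = 0.02, seed = 61))
  hi <- simulate_metapopulation(sim_config(n_pools = 4, n_loci = 2000,
                                           fst_target = 0.6, seed = 62))
  v <- c(multipop_fst(baf_matrix(lo$counts, per_pool_window = FALSE)),
         multipop_fst(baf_matrix(hi$counts, per_pool_window = FALSE)))
  mix <- fst_distribution_check(v[!is.na(v)], seed = 1)
  expect_false(mix$unimodal)

  expect_identical(fst_distribution_check(runif(10))$status, "insufficient")
})

test_that("region aggregation averages cross-region sample-pair medians", {
  m <- matrix(0, 4, 4, dimnames = rep(list(c("a1", "a2", "b1", "b2")), 2))
  regions <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(region_fst(m, regions)["A", "B"], 0)
  m[1, 3] <- m[3, 1] <- 0.2; m[1, 4] <- m[4, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.2; m[2, 4] <- m[4, 2] <- 0.2
  expect_equal(region_fst(m, regions)["A", "B"], 0.2)
  m[1, 3] <- m[3, 1] <- 0.1; m[1, 4] <- m[4, 1] <- 0.1
  m[2, 3] <- m[3, 2] <- 0.3; m[2, 4] <- m[4, 2] <- 0.3
  expect_equal(region_fst(m, regions)["A", "B"], 0.2)
  expect_warning(region_fst(m, c(regions, z9 = "C")), "dropped")
})

test_that("differentiation classes follow the guideline bands", {
  expect_equal(differentiation_class(c(0.14, 0.15, 0, 0.049, 0.05)),
               c("moderate-to-high", "great", "low", "low",
                 "moderate-to-high"))
  expect_error(differentiation_class(1.2), "\\[0, 1\\]")
})
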