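mk_rec <- function(identity, depth = NULL, start = NULL, width = NULL,
                   ref_length = 100, ...) {
  sample_recruitment("s", identity, ref_length, start = start,
                     width = width, depth = depth, ...)
}

test_that("identity filtering composes across the two cascade stages", {
  rec <- mk_rec(c(75, 85, 98, 99), depth = rep(1, 100))
  s80 <- filter_reads_by_identity(rec, 80)
  expect_length(s80$identity, 3)
  s97 <- filter_reads_by_identity(s80, 97)
  expect_length(s97$identity, 2)
  s0 <- filter_reads_by_identity(rec, 0)
  expect_identical(s0$identity, rec$identity)
  expect_warning(filter_reads_by_identity(mk_rec(numeric(0),
                                                 depth = rep(0, 10)), 80),
                 "empty")
})

test_that("identity filtering is idempotent and monotone", {
  set.seed(3)
  rec <- mk_rec(runif(200, 60, 100), depth = rep(2, 100))
  once <- filter_reads_by_identity(rec, 90)
  twice <- filter_reads_by_identity(once, 90)
  expect_identical(once$identity, twice$identity)
  kept <- vapply(c(0, 50, 80, 90, 97, 100),
                 function(t) length(filter_reads_by_identity(rec, t)$identity),
                 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("coverage statistics use all reference positions", {
  cs <- coverage_stats(c(0, 4, 4, 8))
  expect_equal(cs$mean_vertical_coverage, 4)
  expect_equal(cs$coverage_breadth, 75)
  cs0 <- coverage_stats(rep(0, 10))
  expect_equal(cs0$mean_vertical_coverage, 0)
  expect_equal(cs0$coverage_breadth, 0)
  csc <- coverage_stats(rep(4, 1000))
  expect_equal(csc$mean_vertical_coverage, 4)
  expect_equal(csc$coverage_breadth, 100)
  expect_error(coverage_stats(numeric(0)), "empty")
})

test_that("depth is recomputed exactly from read intervals", {
  rec <- mk_rec(c(99, 99, 85), start = c(1L, 5L, 50L), width = c(10L, 10L, 10L),
                ref_length = 60)
  d <- recruitment_depth(rec)
  expect_equal(d[1:4], rep(1, 4))
  expect_equal(d[5:10], rep(2, 6))
  expect_equal(sum(d), 30)
  f <- filter_reads_by_identity(rec, 97)
  expect_equal(sum(recruitment_depth(f)), 20)
})

test_that("unimodality assessment flags mixtures and thin data", {
  set.seed(4)
  uni <- rnbinom(2000, mu = 30, size = 8)
  expect_true(assess_unimodality(uni, seed = 1)$pass)
  bim <- c(rnbinom(1000, mu = 5, size = 8), rnbinom(1000, mu = 60, size = 8))
  r <- assess_unimodality(bim, seed = 1)
  expect_false(r$pass)
  thin <- c(rep(0, 500), rnbinom(50, mu = 30, size = 8))
  expect_identical(assess_unimodality(thin)$status, "insufficient")
})

test_that("the admission verdict lists every failed check", {
  set.seed(5)
  base <- rnbinom(2000, mu = 30, size = 8)
  ids <- c(runif(100, 70, 79), runif(900, 97, 100))
  ok <- admit_sample(mk_rec(ids, depth = base, ref_length = 2000))
  expect_true(ok$admitted)
  expect_length(ok$reasons, 0)

  shallow <- admit_sample(mk_rec(ids, depth = base * 0.12, ref_length = 2000))
  expect_false(shallow$admitted)
  expect_true(any(grepl("coverage<", shallow$reasons)))

  gappy <- base; gappy[1:500] <- 0   # breadth 75%
  g <- admit_sample(mk_rec(ids, depth = gappy, ref_length = 2000))
  expect_false(g$admitted)
  expect_true(any(grepl("breadth<", g$reasons)))
})

test_that("raising thresholds never admits a previously rejected sample", {
  set.seed(6)
  depth <- rnbinom(1500, mu = 6, size = 8)
  ids <- runif(500, 75, 100)
  rec <- mk_rec(ids, depth = depth, ref_length = 1500)
  loose <- admit_sample(rec, qc_thresholds(min_coverage = 2, min_breadth = 50))
  strict <- admit_sample(rec, qc_thresholds(min_coverage = 8, min_breadth = 95))
  expect_true(loose$admitted >= strict$admitted)
})

test_that("relative abundance is a simple normalised percentage", {
  expect_equal(relative_abundance(71, 10000), 0.71)
  expect_equal(relative_abundance(0, 10), 0)
  expect_equal(relative_abundance(10, 10), 100)
  expect_error(relative_abundance(1, 0), "positive")
})

test_that("co-occurrence recovers perfect and inverted rank agreement", {
  set.seed(7)
  ab <- cbind(g1 = 1:6, g2 = (1:6)^2, g3 = rev(1:6) * 2)
  co <- cooccurrence_matrix(ab)
  expect_equal(co$rho["g1", "g1"], 1)
  expect_equal(co$rho["g1", "g2"], 1)    # same ranks
  expect_equal(co$rho["g1", "g3"], -1)   # reversed ranks
  expect_error(cooccurrence_matrix(ab[1:2, ]), "3 samples")
  expect_warning(cooccurrence_matrix(cbind(ab, g4 = rep(2, 6))), "constant")
})

test_that("independent abundances trip the 5% mask at the nominal rate", {
  set.seed(8)
  ab <- matrix(rexp(30 * 40), 30, 40)   # 40 genomes -> 780 pairs
  co <- cooccurrence_matrix(ab)
  rate <- mean(co$p[upper.tri(co$p)] < 0.05)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.10)
})

test_that("the packaged recruitment fixtures drive the cascade deterministically", {
  dir <- system.file("extdata", "toyqc", package = "magpop")
  rec <- read_recruitment_tsv(file.path(dir, "sample_pass.tsv"),
                              ref_length = 2000, total = 300000)
  v <- admit_sample(rec)
  expect_true(v$admitted)
  expect_identical(v$reads_after_pre, 1200L)
  expect_identical(v$reads_after_final, 1000L)
  v2 <- admit_sample(read_recruitment_tsv(file.path(dir, "sample_bimodal.tsv"),
                                          ref_length = 2000, total = 300000))
  expect_false(v2$admitted)
  expect_true("bimodal_coverage" %in% v2$reasons)
})
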