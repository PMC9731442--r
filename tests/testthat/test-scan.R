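test_that("LK statistic matches its chi-squared reference", {
  # a locus at the mean FST scores exactly df
  r <- lk_scan(c(0.2, 0.2, 0.2), n_populations = 4)
  expect_equal(r$statistic, rep(3, 3))
  # worked example: mean 0.2, locus 0.3 -> LK 4.5, chi2_3 upper tail
  r2 <- lk_scan(c(0.1, 0.2, 0.3), n_populations = 4)
  expect_equal(r2$statistic[3], 4.5)
  expect_equal(r2$p[3], pchisq(4.5, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(r2$p[3], 3), 0.212)
  expect_error(lk_scan(rep(0, 10), 4), "no differentiation")
})

test_that("LK is invariant to rescaling the per-locus FST vector", {
  set.seed(31)
  f <- rexp(500, 10)
  a <- lk_scan(f, 5)
  b <- lk_scan(3.7 * f, 5)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
})

test_that("neutral LK p-values are uniform enough for FDR control", {
  d <- cached_sim("recov05", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 5000,
                                       fst_target = 0.05, seed = 51)))
  baf <- baf_matrix(d$counts, per_pool_window = FALSE)
  r <- lk_scan(multipop_fst(baf), 4)
  expect_lt(mean(r$candidate, na.rm = TRUE), 0.02)
  # q monotone in p
  o <- order(r$p)
  expect_true(all(diff(r$q[o]) >= -1e-12))
})

test_that("the PCA scan recovers planted outliers and controls the FDR", {
  d <- cached_sim("planted", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 4000,
                                       fst_target = 0.05, n_selected = 40,
                                       fst_selected = 0.8, seed = 71)))
  baf <- baf_matrix(d$counts, per_pool_window = FALSE)
  sc <- pca_outlier_scan(baf, seed = 1)
  cand <- rownames(sc)[which(sc$candidate)]
  expect_gte(mean(d$truth$selected %in% cand), 0.8)
  neutral <- setdiff(rownames(sc), d$truth$selected)
  expect_lte(mean(sc[neutral, "candidate"], na.rm = TRUE), 0.02)
  # determinism given a fixed input
  sc2 <- pca_outlier_scan(baf, seed = 1)
  expect_identical(sc, sc2)
  # candidate set shrinks as the q threshold tightens
  tight <- pca_outlier_scan(baf, q_threshold = 0.01, seed = 1)
  expect_lte(sum(tight$candidate), sum(sc$candidate))
  expect_true(all(rownames(tight)[which(tight$candidate)] %in% cand))
})

test_that("PCA scan validates its inputs", {
  d <- cached_sim("planted", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 4000,
                                       fst_target = 0.05, n_selected = 40,
                                       fst_selected = 0.8, seed = 71)))
  baf <- baf_matrix(d$counts, per_pool_window = FALSE)
  expect_error(pca_outlier_scan(baf[, 1, drop = FALSE]), "at least 3 pools")
  expect_error(pca_outlier_scan(baf, K = 4), "K must lie")
  expect_error(pca_outlier_scan(baf * 2), "\\[0,1\\]")
})

test_that("aberrant pools are flagged and exclusion re-runs cleanly", {
  d <- cached_sim("planted", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 4000,
                                       fst_target = 0.05, n_selected = 40,
                                       fst_selected = 0.8, seed = 71)))
  baf <- baf_matrix(d$counts, per_pool_window = FALSE)
  d5 <- simulate_metapopulation(sim_config(n_pools = 5, n_loci = 4000,
                                           fst_target = 0.05, seed = 72))
  b5 <- baf_matrix(d5$counts, per_pool_window = FALSE)
  expect_length(detect_outlier_samples(b5), 0)
  # plant a divergent pool: allele frequencies flipped
  b5[, 3] <- 1 - b5[, 3]
  flagged <- detect_outlier_samples(b5)
  expect_identical(as.vector(flagged), "pool3")
  sc <- pca_outlier_scan(b5[, setdiff(colnames(b5), flagged)], seed = 1)
  expect_s3_class(sc, "selection_scan")
})

test_that("the BAF report covers candidates, absences and contig edges", {
  d <- cached_sim("planted", function()
    simulate_metapopulation(sim_config(n_pools = 4, n_loci = 4000,
                                       fst_target = 0.05, n_selected = 40,
                                       fst_selected = 0.8, seed = 71)))
  baf <- baf_matrix(d$counts, per_pool_window = FALSE)
  sc <- pca_outlier_scan(baf, seed = 1)
  rep <- baf_report(baf, sc)
  expect_true(all(rep$baf$baf >= 0 & rep$baf$baf <= 1))
  expect_true(all(rep$neighbourhood$pos >= 1))
  # a locus fixed in one pool reports BAF 1 there; absent pools report 0
  fixed <- which(baf == 1, arr.ind = TRUE)
  if (nrow(fixed)) {
    id <- rownames(baf)[fixed[1, 1]]
    r1 <- baf_report(baf, sc, loci = id)
    expect_equal(r1$baf$baf[r1$baf$pool == colnames(baf)[fixed[1, 2]]], 1)
  }
  # window truncates at the contig edge without error
  first <- rownames(baf)[1]
  edge <- baf_report(baf, sc, loci = first, flank = 1e9)
  expect_true(nrow(edge$neighbourhood) >= 1)
  expect_error(baf_report(baf, sc, loci = "nope:1"), "unknown locus")
})
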