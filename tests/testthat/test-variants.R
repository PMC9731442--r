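test_that("SNV calling honours count and coverage thresholds", {
  snvs <- call_snvs(tiny_counts())
  # locus 1 called with alt G; loci 2 (coverage 3), 3 (minor 1), 4 (monomorphic) not
  expect_equal(nrow(snvs$table), 1)
  expect_equal(snvs$table$pos, 10L)
  expect_equal(snvs$table$alt, "G")
  expect_equal(unname(snvs$alt_count[1, ]), c(2, 2))
})

test_that("alt ties break in fixed A<C<G<T order and bad refs are skipped", {
  counts <- array(0, c(2, 6, 1))
  dimnames(counts) <- list(NULL, c("A", "T", "C", "G", "N", "del"), "p1")
  counts[1, "A", 1] <- 6; counts[1, "C", 1] <- 3; counts[1, "G", 1] <- 3
  counts[2, "A", 1] <- 5; counts[2, "T", 1] <- 5
  ac <- allele_counts(c("c", "c"), c(1L, 2L), c("A", "A"), counts, "p1")
  snvs <- call_snvs(ac, variant_thresholds(min_coverage = 4))
  expect_equal(snvs$table$alt, c("C", "T"))

  expect_error(allele_counts("c", 1L, "N", counts[1, , , drop = FALSE], "p1"),
               "reference base")
})

test_that("raising min_count never increases the SNV count", {
  d <- cached_sim("small", function()
    simulate_metapopulation(sim_config(n_pools = 3, n_loci = 200,
                                       fst_target = 0.1, seed = 5)))
  n <- vapply(c(1, 2, 4, 8, 16), function(mc)
    nrow(call_snvs(d$counts, variant_thresholds(min_count = mc))$table), 0)
  expect_true(all(diff(n) <= 0))
})

test_that("SNV density is percentage per covered position and recovers a planted rate", {
  expect_equal(snv_density(234, 10000), 2.34)
  expect_equal(snv_density(0, 500), 0)
  expect_error(snv_density(3, 0), "positive")
  # planted polymorphism rate: 1% of positions variant at high coverage
  set.seed(10)
  n_pos <- 20000
  n_var <- rbinom(1, n_pos, 0.01)
  expect_lt(abs(snv_density(n_var, n_pos) - 1.0), 0.15)
})

test_that("Ts/Tv counts transitions over transversions", {
  tab <- data.frame(ref = c(rep("A", 6), rep("A", 4)),
                    alt = c(rep("G", 6), rep("C", 4)))
  expect_equal(tstv_ratio(tab), 1.5)
  expect_warning(r <- tstv_ratio(data.frame(ref = "A", alt = "G")),
                 "undefined")
  expect_true(is.na(r))
})

test_that("realized Ts/Tv of simulated alternate alleles converges", {
  d <- cached_sim("tstv", function()
    simulate_metapopulation(sim_config(n_pools = 2, n_loci = 10000,
                                       fst_target = 0.1, tstv_ratio = 2,
                                       seed = 6)))
  snvs <- call_snvs(d$counts)
  expect_lt(abs(tstv_ratio(snvs) - 2), 0.1)
})

test_that("context classification partitions positions with coding precedence", {
  ann <- tiny_annotation()
  expect_equal(classify_context("c1", 8, ann), "coding")
  expect_equal(classify_context("c1", 20, ann), "intergenic")
  expect_equal(classify_context("c1", 5, ann), "UTR")
  expect_equal(classify_context("c1", 49, ann), "intron")
  expect_equal(classify_context("c1", 26, ann), "UTR")   # 3'UTR of '-' gene
  expect_error(classify_context("c1", 1000, ann), "beyond contig")
  expect_error(classify_context("missing", 1, ann), "absent")
  # every position gets exactly one class
  ctx <- classify_context(rep("c1", 60), 1:60, ann)
  expect_equal(sum(table(ctx)), 60)
})

test_that("effect classification follows the genetic code", {
  ann <- tiny_annotation()
  expect_equal(classify_effect("c1", 9, "A", "G", ann), "silent")    # GAA->GAG
  expect_equal(classify_effect("c1", 7, "G", "T", ann), "nonsense")  # GAA->TAA
  expect_equal(classify_effect("c1", 8, "A", "C", ann), "missense")  # GAA->GCA
  expect_equal(classify_effect("c1", 20, "T", "A", ann), "none")     # intergenic
})

test_that("minus-strand effects equal the reverse-complemented plus construction", {
  ann <- tiny_annotation()
  # gene2 ('-') carries the same CDS as gene1 ('+'); genomic position 34 is
  # the third base of its first codon, as position 9 is for gene1
  expect_equal(classify_effect("c1", 34, "T", "C", ann), "silent")
  expect_equal(classify_effect("c1", 36, "C", "A", ann), "nonsense") # GAA->TAA
  expect_equal(classify_effect("c1", 35, "T", "G", ann), "missense") # GAA->GCA
})

test_that("spliced CDS across an intron keeps the reading frame", {
  ann <- tiny_annotation()
  # gene3 CDS = GAA | GCATAA; position 53 is codon 2 base 2 (GCA)
  expect_equal(classify_effect("c1", 53, "G", "C", ann), "missense")
  expect_equal(classify_effect("c1", 46, "A", "G", ann), "silent")   # GAA->GAG
})
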