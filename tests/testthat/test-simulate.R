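test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_pools = 1), "at least 2")
  expect_error(sim_config(fst_target = 1), "\\[0, 1\\)")
  expect_error(sim_config(fst_target = 0.5, n_selected = 5,
                          fst_selected = 0.4), "fst_selected")
  expect_error(sim_config(env_link = c(iron = 0.6, silicate = 0.6)),
               "at most 1")
  expect_error(sim_config(env_link = 0.5), "named")
  expect_error(sim_config(fst_target = 0, env_link = c(iron = 0.5)),
               "fst_target > 0")
})

test_that("identical configuration and seed give bit-identical datasets", {
  cfg <- sim_config(n_pools = 3, n_loci = 300, fst_target = 0.1,
                    n_selected = 5, env_link = c(iron = 0.4), seed = 77)
  d1 <- simulate_metapopulation(cfg)
  d2 <- simulate_metapopulation(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$truth$selected, d2$truth$selected)
})

test_that("nucleotide counts at each locus sum to the drawn coverage", {
  d <- cached_sim("small", function()
    simulate_metapopulation(sim_config(n_pools = 3, n_loci = 200,
                                       fst_target = 0.1, seed = 5)))
  tot <- apply(d$counts$counts, c(1, 3), sum)
  # coverage is ref + alt; N/del never simulated
  expect_equal(tot, pool_coverage(d$counts))
  expect_true(all(d$counts$counts[, c("N", "del"), ] == 0))
})

test_that("planted loci exist in the count table and are differentiated", {
  d <- simulate_metapopulation(sim_config(n_pools = 4, n_loci = 800,
                                          fst_target = 0.05, n_selected = 20,
                                          seed = 13))
  expect_length(d$truth$selected, 20)
  expect_true(all(d$truth$selected %in% locus_ids(d$counts)))
  f <- multipop_fst(d$truth$freq)
  expect_gt(mean(f[d$truth$selected_idx]), mean(f[-d$truth$selected_idx]))
})

test_that("pool metadata aligns 1:1 with count-table pools", {
  d <- cached_sim("small", function()
    simulate_metapopulation(sim_config(n_pools = 3, n_loci = 200,
                                       fst_target = 0.1, seed = 5)))
  expect_identical(d$samples$sample_id, d$counts$pools)
  expect_true(all(c("temperature", "iron", "nitrate", "nitrite", "ammonium",
                    "silicate", "lat", "lon", "region") %in%
                    names(d$samples)))
})

test_that("environmental linkage realizes the requested fraction", {
  d <- simulate_metapopulation(sim_config(n_pools = 8, n_loci = 2000,
                                          fst_target = 0.1,
                                          env_link = c(silicate = 0.5),
                                          seed = 17))
  expect_lt(abs(d$truth$env_fractions_realized[["silicate"]] - 0.5), 0.05)
  # unlinked variable shows no comparable structure by construction
  g <- magpop:::.true_pair_fst(d$truth$freq)
  d2 <- as.vector(dist(d$samples$temperature))^2
  expect_lt(cor(d2, g)^2, 0.5)
})

test_that("dataset serialisation writes the advertised artefacts", {
  d <- simulate_metapopulation(sim_config(n_pools = 3, n_loci = 100,
                                          fst_target = 0.1, seed = 19),
                               annotate = TRUE)
  dir <- withr::local_tempdir()
  write_sim_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir,
    c("counts.sync", "samples.tsv", "truth.json", "annotation.gff3",
      "genome.fasta")))))
  rt <- read_sync(file.path(dir, "counts.sync"))
  expect_equal(unname(rt$counts), unname(d$counts$counts))
})

test_that("toy coverage profiles expose the requested modality", {
  uni <- simulate_coverage_profile(1500, 30, "unimodal", seed = 2)
  expect_true(assess_unimodality(uni$depth, seed = 1)$pass)
  bim <- simulate_coverage_profile(1500, 5, "bimodal", second_mean = 60,
                                   seed = 2)
  expect_false(assess_unimodality(bim$depth, seed = 1)$pass)
  expect_error(simulate_coverage_profile(0, 30), "positive")
  expect_error(simulate_coverage_profile(100, -2), "positive")
  expect_true(all(uni$identity <= 100 & uni$identity >= 0))
})

test_that("simulated annotation honours Ts/Tv and effect mixes", {
  sim <- simulate_annotation(n_genes = 15, tstv_ratio = 1.5,
                             n_mutations = 4000, seed = 23)
  m <- sim$mutations
  expect_lt(abs(sum(m$transition) / sum(!m$transition) - 1.5), 0.1)
  # all-silent degenerate mix
  sil <- simulate_annotation(n_genes = 8, tstv_ratio = 1.5,
                             effect_mix = c(silent = 1, missense = 0,
                                            nonsense = 0),
                             n_mutations = 300, seed = 24)
  cod <- sil$mutations[sil$mutations$context == "coding", ]
  eff <- classify_effect(cod$contig, cod$pos, cod$ref, cod$alt,
                         sil$annotation)
  expect_true(all(eff == "silent"))
  expect_error(simulate_annotation(0), "empty")
  expect_error(simulate_annotation(5, tstv_ratio = 0), "positive")
  expect_error(simulate_annotation(5, effect_mix = c(silent = 0.5,
                                                     missense = 0.2,
                                                     nonsense = 0.2)),
               "sum to 1")
})

test_that("generator truth labels agree with the classifiers on both strands", {
  sim <- cached_sim("ann", function()
    simulate_annotation(n_genes = 15, tstv_ratio = 1.5, n_mutations = 2000,
                        seed = 25))
  m <- sim$mutations
  ctx <- classify_context(m$contig, m$pos, sim$annotation)
  expect_identical(ctx, m$context)
  cod <- m$context == "coding"
  eff <- classify_effect(m$contig[cod], m$pos[cod], m$ref[cod], m$alt[cod],
                         sim$annotation)
  expect_identical(eff, m$effect[cod])
  # both strands are exercised
  cds <- sim$annotation$features[sim$annotation$features$type == "CDS"]
  expect_setequal(unique(as.character(GenomicRanges::strand(cds))),
                  c("+", "-"))
})
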