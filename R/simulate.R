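#' Simulation configuration for a synthetic metapopulation
#'
#' The defaults encode the study conditions the downstream statistics assume:
#' a handful of population pools (3-9 per genome in typical MAG read
#' recruitment; 4 by default), thousands of bi-allelic loci, ~100x pooled
#' depth, low neutral differentiation and strongly differentiated planted
#' outliers.
#'
#' @param n_pools number of population pools (>= 2).
#' @param n_loci number of loci.
#' @param fst_target neutral differentiation (island-model inbreeding
#'   coefficient) in `[0, 1)`.
#' @param ancestral_maf_range interval the ancestral allele frequency is
#'   drawn from, uniformly.
#' @param coverage_mean mean reads per locus per pool.
#' @param coverage_dispersion negative-binomial overdispersion; the Poisson
#'   limit as it approaches 0.
#' @param n_selected number of planted outlier loci.
#' @param fst_selected differentiation of planted loci, in
#'   `(fst_target, 1)`.
#' @param env_link named fractions in `[0, 1]` (summing to at most 1): the
#'   share of pairwise genetic distance each environmental variable's squared
#'   pairwise distance is constructed to explain. Requires `fst_target > 0`.
#' @param tstv_ratio transition:transversion ratio of simulated alternate
#'   alleles.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pools = 4, n_loci = 5000, fst_target = 0.05,
                       ancestral_maf_range = c(0.1, 0.9),
                       coverage_mean = 100, coverage_dispersion = 0.2,
                       n_selected = 0, fst_selected = 0.8,
                       env_link = NULL, tstv_ratio = 1.5, seed = 1L) {
  if (n_pools < 2) stop("n_pools must be at least 2")
  if (fst_target < 0 || fst_target >= 1)
    stop("fst_target must lie in [0, 1)")
  if (n_selected > 0 &&
      (fst_selected <= fst_target || fst_selected >= 1))
    stop("fst_selected must lie in (fst_target, 1)")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] >= 1 ||
      diff(ancestral_maf_range) < 0)
    stop("ancestral_maf_range must be an interval within (0, 1)")
  if (coverage_mean <= 0 || coverage_dispersion < 0)
    stop("invalid coverage parameters")
  if (!is.null(env_link)) {
    if (is.null(names(env_link)) || any(env_link < 0 | env_link > 1) ||
        sum(env_link) > 1)
      stop("env_link must be named fractions in [0,1] summing to at most 1")
    if (any(env_link > 0) && fst_target == 0)
      stop("env_link requires fst_target > 0 (no genetic distance to link to)")
  }
  structure(list(n_pools = n_pools, n_loci = n_loci,
                 fst_target = fst_target,
                 ancestral_maf_range = ancestral_maf_range,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 n_selected = n_selected, fst_selected = fst_selected,
                 env_link = env_link, tstv_ratio = tstv_ratio,
                 seed = as.integer(seed)),
            class = "sim_config")
}

ENV_VARIABLES <- data.frame(
  variable = c("temperature", "salinity", "oxygen", "ammonium", "iron",
               "nitrate", "nitrite", "phosphate", "silicate"),
  mean = c(2, 32, 350, 0.4, 0.6, 4, 0.15, 0.7, 6),
  sd = c(1.5, 1.2, 40, 0.2, 0.3, 2, 0.08, 0.3, 3))

#' Simulate a pooled metapopulation dataset
#'
#' Neutral loci follow the Balding-Nichols island model: an ancestral
#' frequency drawn uniformly from `ancestral_maf_range`, then per-pool
#' frequencies from a Beta with that mean and inbreeding parameter
#' `fst_target` (`fst_selected` for the planted outliers). Per-pool counts
#' are binomial at a negative-binomial depth. When `env_link` is given, pool
#' frequencies are drawn through a Gaussian copula whose inter-pool
#' correlation decays along a latent gradient (Balding-Nichols marginals are
#' preserved), which gives pairwise genetic distance a low-dimensional
#' structure an environmental variable can track; each linked variable is
#' then mixed from the gradient and independent noise with the mixing chosen
#' so the realized squared-environmental-distance vs genetic-distance
#' correlation equals the requested fraction.
#'
#' @param config a [sim_config()].
#' @param annotate if `TRUE`, loci are placed on a simulated annotated genome
#'   (see [simulate_annotation()]) so context/effect classification applies;
#'   otherwise loci sit on a bare contig.
#' @return a `sim_dataset` list: `counts` ([allele_counts()]), `truth`
#'   (list `selected` locus ids, `selected_idx`, `env_fractions`,
#'   `env_fractions_realized`, `freq` true frequencies, `gradient`),
#'   `samples` (data.frame of pool metadata + environment), `annotation`
#'   (or `NULL`), `config`.
#' @export
simulate_metapopulation <- function(config, annotate = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  local_seed(cfg$seed, {
    n <- cfg$n_pools; L <- cfg$n_loci
    acgt <- c("A", "C", "G", "T")
    ## loci on a genome (annotated) or a bare contig
    annotation <- NULL
    if (annotate) {
      n_genes <- max(6L, ceiling(L / 120))
      sim_ann <- simulate_annotation(n_genes, tstv_ratio = cfg$tstv_ratio,
                                     n_mutations = 1,
                                     seed = sample.int(1e6, 1))
      annotation <- sim_ann$annotation
      glen <- stats::setNames(Biostrings::width(annotation$genome),
                              names(annotation$genome))
      if (sum(glen) < 2 * L) stop("toy genome too short for n_loci")
      all_pos <- do.call(rbind, lapply(names(glen), function(chr)
        data.frame(contig = chr, pos = seq_len(glen[[chr]]))))
      pick <- all_pos[sort(sample.int(nrow(all_pos), L)), ]
      contig <- pick$contig; pos <- pick$pos
      ref <- vapply(seq_len(L), function(i)
        substr(as.character(annotation$genome[[contig[i]]]), pos[i], pos[i]),
        "")
      redo <- !ref %in% acgt
      ref[redo] <- sample(acgt, sum(redo), TRUE)
    } else {
      contig <- rep("chr1", L)
      pos <- sort(sample.int(L * 20L, L))
      ref <- sample(acgt, L, TRUE)
    }
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    is_ts <- runif(L) < cfg$tstv_ratio / (1 + cfg$tstv_ratio)
    alt <- ifelse(is_ts, ts_partner[ref],
                  vapply(ref, function(r)
                    sample(setdiff(acgt, c(r, ts_partner[r])), 1), ""))
    ## ancestral and per-pool frequencies
    p_anc <- runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
    gradient <- sort(runif(n))
    use_copula <- !is.null(cfg$env_link) && any(cfg$env_link > 0)
    freq <- .bn_pool_freqs(p_anc, n, cfg$fst_target,
                           gradient = if (use_copula) gradient else NULL)
    sel_idx <- integer(0)
    if (cfg$n_selected > 0) {
      sel_idx <- sort(sample.int(L, cfg$n_selected))
      freq[sel_idx, ] <- .draw_selected_freqs(p_anc[sel_idx], n,
                                              cfg$fst_selected)
    }
    ## depths and counts
    depth <- if (cfg$coverage_dispersion == 0) {
      matrix(stats::rpois(L * n, cfg$coverage_mean), L, n)
    } else {
      matrix(rnbinom(L * n, mu = cfg$coverage_mean,
                     size = 1 / cfg$coverage_dispersion), L, n)
    }
    altc <- matrix(rbinom(L * n, as.vector(depth), as.vector(freq)), L, n)
    refc <- depth - altc
    counts <- array(0, c(L, 6, n))
    dimnames(counts) <- list(NULL, SYNC_BASES, paste0("pool", seq_len(n)))
    ridx <- match(ref, SYNC_BASES); aidx <- match(alt, SYNC_BASES)
    for (j in seq_len(n)) {
      counts[cbind(seq_len(L), ridx, j)] <- refc[, j]
      counts[cbind(seq_len(L), aidx, j)] <-
        counts[cbind(seq_len(L), aidx, j)] + altc[, j]
    }
    ac <- allele_counts(contig, pos, ref, counts)
    ## environmental variables (and their realized linkage)
    env <- .simulate_environment(freq, gradient, cfg)
    samples <- data.frame(
      sample_id = ac$pools,
      station = paste0("ST", 100 + seq_len(n)),
      depth_layer = rep_len(c("SUR", "DCM"), n),
      region = .gradient_regions(gradient),
      lat = round(72 + 12 * gradient + rnorm(n, 0, 0.5), 3),
      lon = round(-40 + 150 * gradient + rnorm(n, 0, 2), 3),
      mapped_reads = round(cfg$coverage_mean * L),
      total_reads = round(cfg$coverage_mean * L * 150),
      stringsAsFactors = FALSE)
    samples <- cbind(samples, env$values)
    structure(list(counts = ac,
                   truth = list(selected = locus_ids(ac)[sel_idx],
                                selected_idx = sel_idx,
                                env_fractions = cfg$env_link,
                                env_fractions_realized = env$realized,
                                freq = freq, gradient = gradient),
                   samples = samples, annotation = annotation,
                   config = cfg),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d loci x %d pools (F=%g, %d planted outliers)\n",
              n_loci(x$counts), n_pools(x$counts), x$config$fst_target,
              x$config$n_selected))
  invisible(x)
}

# Planted outliers: Balding-Nichols draws at the elevated inbreeding
# coefficient, redrawn (up to 50 times per locus) until the realized
# frequency vector is genuinely differentiated and polymorphic - a "selected"
# locus that happened to draw near-identical frequencies in every pool is not
# an outlier and would be an incoherent truth label
.draw_selected_freqs <- function(p_anc, n, F) {
  out <- .bn_pool_freqs(p_anc, n, F)
  for (tries in seq_len(50)) {
    mu <- rowMeans(out)
    bad <- pmin(mu, 1 - mu) < 0.05 | multipop_fst(out) < F / 2
    bad[is.na(bad)] <- TRUE
    if (!any(bad)) break
    out[bad, ] <- .bn_pool_freqs(p_anc[bad], n, F)
  }
  out
}

# Balding-Nichols per-pool frequencies; optional Gaussian-copula correlation
# decaying along a latent gradient (marginals unchanged)
.bn_pool_freqs <- function(p_anc, n, F, gradient = NULL) {
  L <- length(p_anc)
  if (F == 0) return(matrix(rep(p_anc, n), L, n))
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  if (is.null(gradient)) {
    matrix(rbeta(L * n, rep(a, n), rep(b, n)), L, n)
  } else {
    R <- exp(-as.matrix(dist(gradient)) / 0.5)
    Z <- matrix(rnorm(L * n), L, n) %*% chol(R)
    U <- pnorm(Z)
    matrix(qbeta(as.vector(U), rep(a, n), rep(b, n)), L, n)
  }
}

# environmental variables: linked ones mix gradient + noise with the mixing
# weight grid-searched so realized cor^2(pairwise squared env distance,
# pairwise genetic distance) hits the requested fraction
.simulate_environment <- function(freq, gradient, cfg) {
  n <- ncol(freq)
  g <- .true_pair_fst(freq)
  ## base coordinate for linked variables: 1-D classical MDS embedding of the
  ## true genetic distance matrix, so squared env distance can track it
  zs <- as.vector(scale(gradient))
  if (length(g) > 1 && stats::sd(g) > 0) {
    G <- matrix(0, n, n)
    G[lower.tri(G)] <- g
    G <- G + t(G)
    emb <- tryCatch(stats::cmdscale(sqrt(pmax(G, 0)), k = 1),
                    error = function(e) NULL)
    if (!is.null(emb) && stats::sd(emb[, 1]) > 0)
      zs <- as.vector(scale(emb[, 1]))
  }
  link <- cfg$env_link
  realized <- stats::setNames(numeric(0), character(0))
  vals <- list()
  for (i in seq_len(nrow(ENV_VARIABLES))) {
    v <- ENV_VARIABLES$variable[i]
    w <- if (!is.null(link) && v %in% names(link)) link[[v]] else 0
    eta <- as.vector(scale(rnorm(n)))
    if (w > 0 && length(g) > 1 && stats::sd(g) > 0) {
      thetas <- seq(0, pi / 2, length.out = 181)
      c2 <- vapply(thetas, function(th) {
        e <- cos(th) * zs + sin(th) * eta
        d2 <- as.vector(dist(e))^2
        suppressWarnings(cor(d2, g))^2
      }, 0)
      c2[is.na(c2)] <- 0
      th <- thetas[which.min(abs(c2 - w))]
      e <- cos(th) * zs + sin(th) * eta
      realized[v] <- c2[which.min(abs(c2 - w))]
    } else {
      e <- eta
      if (w > 0) realized[v] <- 0
    }
    vals[[v]] <- ENV_VARIABLES$mean[i] + ENV_VARIABLES$sd[i] * e
  }
  list(values = as.data.frame(vals), realized = realized)
}

# median per-pair two-pool FST from true frequencies
.true_pair_fst <- function(freq) {
  n <- ncol(freq)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  apply(pairs, 1, function(pr)
    median(locus_fst(freq[, pr[1]], freq[, pr[2]])))
}

# up to five region labels along the gradient
.gradient_regions <- function(gradient) {
  labels <- c("Pacific-Arctic", "Kara-Laptev", "Atlantic-Arctic",
              "Arctic Archipelago", "Davis-Baffin")
  k <- min(5, length(gradient))
  bins <- cut(gradient, breaks = quantile(gradient, seq(0, 1, length.out = k + 1)),
              include.lowest = TRUE, labels = FALSE)
  labels[bins]
}

#' Write a simulated dataset to disk
#'
#' Emits the sync count table, the sample metadata TSV, a JSON truth file
#' and, when present, the annotation (GFF3 + FASTA).
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sync(dataset$counts, file.path(dir, "counts.sync"))
  write.table(dataset$samples, file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$freq <- NULL                      # bulky; reproducible from config
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(dataset$annotation))
    write_annotation(dataset$annotation, file.path(dir, "annotation.gff3"),
                     file.path(dir, "genome.fasta"))
  invisible(dir)
}
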