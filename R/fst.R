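#' Per-locus pairwise fixation index from two allele frequencies
#'
#' Frequency-based estimator: with \eqn{\bar p = (p_1+p_2)/2},
#' \eqn{H_T = 2\bar p(1-\bar p)}, \eqn{H_S = (2p_1(1-p_1)+2p_2(1-p_2))/2} and
#' \eqn{F_{ST} = (H_T - H_S)/H_T}, defined as 0 when \eqn{H_T = 0}
#' (monomorphic site). Vectorised over loci.
#'
#' @param p1,p2 allele frequencies in `[0, 1]` (recycled to common length).
#' @return numeric vector of fixation indices in `[0, 1]`.
#' @export
#' @examples
#' locus_fst(0.3, 0.3)   # 0: identical frequencies
#' locus_fst(0, 1)       # 1: fixed for alternative alleles
#' locus_fst(0.2, 0.8)   # 0.36
locus_fst <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  ifelse(ht > 0, (ht - hs) / ht, 0)
}

#' Per-locus multi-population fixation index
#'
#' Sample-size-corrected frequency-based estimator across `n` pools:
#' \eqn{\hat F = s^2 / (\bar p(1-\bar p) + s^2/n)} with \eqn{s^2} the unbiased
#' between-pool variance of the allele frequency. Under the island model the
#' ratio of expectations equals the inbreeding coefficient for any `n >= 2`,
#' which makes it the statistic of choice for the Lewontin-Krakauer scan and
#' for differentiation-recovery checks. Monomorphic loci (zero denominator)
#' are returned as `NA`.
#'
#' @param freq numeric matrix `loci x pools` of allele frequencies.
#' @return numeric vector, one value per locus (clamped to `[0, 1]`).
#' @export
multipop_fst <- function(freq) {
  if (!is.matrix(freq) || ncol(freq) < 2)
    stop("'freq' must be a loci x pools matrix with >= 2 pools")
  n <- ncol(freq)
  pbar <- rowMeans(freq)
  s2 <- rowSums((freq - pbar)^2) / (n - 1)
  den <- pbar * (1 - pbar) + s2 / n
  out <- ifelse(den > 0, s2 / den, NA_real_)
  pmin(pmax(out, 0), 1)
}

#' Global per-locus fixation index from pooled counts
#'
#' Convenience wrapper: estimates per-pool alternate-allele frequencies from a
#' called SNV set (alt / (ref + alt)) and applies [multipop_fst()]. Loci
#' failing the coverage window in any pool are dropped (min-covered-fraction 1
#' semantics).
#'
#' @param counts an [allele_counts()] object.
#' @param thresholds a [variant_thresholds()] list.
#' @return data.frame `contig`, `pos`, `fst`.
#' @export
global_fst <- function(counts, thresholds = variant_thresholds()) {
  snvs <- call_snvs(counts, thresholds = thresholds)
  if (nrow(snvs$table) == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      fst = numeric(0)))
  freq <- snv_frequencies(snvs)
  data.frame(contig = snvs$table$contig, pos = snvs$table$pos,
             fst = multipop_fst(freq))
}

#' Pairwise per-locus and median fixation indices between pools
#'
#' For every pool pair, frequencies are estimated per pool as
#' `alt / (ref + alt)`; loci failing the per-pool coverage window or the
#' pooled minor-count threshold for that pair, and loci monomorphic across the
#' pair, are suppressed as non-informative. The per-site (window and step of 1)
#' [locus_fst()] values are aggregated by the median per pool pair.
#'
#' The default estimator works on raw frequencies. `estimator = "corrected"`
#' additionally applies the classical pool-seq finite-sample corrections to the
#' heterozygosities (read depth `c/(c-1)` and pool size `s/(s-1)`).
#'
#' @param counts an [allele_counts()] object.
#' @param thresholds a [variant_thresholds()] list.
#' @param estimator `"frequency"` (default) or `"corrected"`.
#' @param pool_size haploid pool size used by the corrected estimator.
#' @return an object of class `fst_result`: list with `per_locus` (matrix
#'   `loci x pairs`, `NA` where suppressed), `median_matrix`
#'   (`pools x pools`), `n_informative` (`pools x pools`), `pairs`
#'   (data.frame), `contig`, `pos`, `pools`.
#' @export
pairwise_fst <- function(counts, thresholds = variant_thresholds(),
                         estimator = c("frequency", "corrected"),
                         pool_size = 500) {
  estimator <- match.arg(estimator)
  k <- n_pools(counts)
  if (k < 2) stop("need at least 2 pools")
  th <- thresholds
  snvs <- call_snvs(counts, thresholds = th, per_pool_window = FALSE)
  tab <- snvs$table
  L <- nrow(tab)
  cov <- snvs$depth         # loci x pools, total A/C/G/T depth
  alt <- snvs$alt_count
  refc <- snvs$ref_count
  bi <- refc + alt          # bi-allelic depth, frequency denominator
  pair_idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  np <- nrow(pair_idx)
  pools <- counts$pools
  per_locus <- matrix(NA_real_, L, np)
  colnames(per_locus) <- paste(pools[pair_idx[, 1]], pools[pair_idx[, 2]],
                               sep = "|")
  med <- matrix(NA_real_, k, k, dimnames = list(pools, pools))
  ninf <- matrix(0L, k, k, dimnames = list(pools, pools))
  for (q in seq_len(np)) {
    i <- pair_idx[q, 1]; j <- pair_idx[q, 2]
    ok <- cov[, i] >= th$min_coverage & cov[, i] <= th$max_coverage &
          cov[, j] >= th$min_coverage & cov[, j] <= th$max_coverage &
          bi[, i] > 0 & bi[, j] > 0
    minor <- pmin(alt[, i] + alt[, j], refc[, i] + refc[, j])
    ok <- ok & minor >= th$min_count
    p1 <- alt[, i] / pmax(bi[, i], 1)
    p2 <- alt[, j] / pmax(bi[, j], 1)
    f <- if (estimator == "frequency") {
      locus_fst(p1, p2)
    } else {
      .corrected_pair_fst(p1, p2, cov[, i], cov[, j], pool_size)
    }
    # suppress non-informative loci: failed window/count or monomorphic pair
    ht0 <- (p1 + p2) %in% c(0, 2)
    f[!ok | ht0] <- NA_real_
    per_locus[, q] <- f
    vals <- f[!is.na(f)]
    ninf[i, j] <- ninf[j, i] <- length(vals)
    if (length(vals)) {
      med[i, j] <- med[j, i] <- median(vals)
    } else {
      warning("no informative loci for pair ", pools[i], " / ", pools[j])
    }
  }
  structure(list(per_locus = per_locus, median_matrix = med,
                 n_informative = ninf,
                 pairs = data.frame(i = pair_idx[, 1], j = pair_idx[, 2],
                                    pool_i = pools[pair_idx[, 1]],
                                    pool_j = pools[pair_idx[, 2]]),
                 contig = tab$contig, pos = tab$pos, pools = pools,
                 estimator = estimator),
            class = "fst_result")
}

# classical pool-seq corrections: unbiased heterozygosities given read depth
# and haploid pool size
.corrected_pair_fst <- function(p1, p2, c1, c2, pool_size) {
  s <- pool_size
  h1 <- 2 * p1 * (1 - p1) * c1 / pmax(c1 - 1, 1) * s / (s - 1)
  h2 <- 2 * p2 * (1 - p2) * c2 / pmax(c2 - 1, 1) * s / (s - 1)
  hs <- (h1 + h2) / 2
  pbar <- (p1 + p2) / 2
  ct <- c1 + c2
  ht <- 2 * pbar * (1 - pbar) * ct / pmax(ct - 1, 1) * (2 * s) / (2 * s - 1)
  out <- ifelse(ht > 0, (ht - hs) / ht, 0)
  pmin(pmax(out, 0), 1)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %d loci x %d pool pairs (%s estimator)\n",
              nrow(x$per_locus), ncol(x$per_locus), x$estimator))
  cat("median pairwise FST:\n")
  print(round(x$median_matrix, 4))
  invisible(x)
}

#' Unimodality check on a per-locus FST distribution
#'
#' A mixture of two species recruited by the same reference shows up as a
#' multimodal population-wide FST distribution; the bootstrap dip test
#' ([dip_test()]) is applied to the informative per-locus values of one pool
#' pair (or to any numeric vector of per-locus values).
#'
#' @param fst an `fst_result` or a numeric vector of per-locus values.
#' @param pair pair column index or name (when `fst` is an `fst_result`).
#' @param min_loci minimum number of informative loci for a verdict.
#' @param alpha significance level; unimodal when `p >= alpha`.
#' @param n_boot,seed bootstrap controls, see [dip_test()].
#' @return list `statistic`, `p_value`, `unimodal`, `status`, `histogram`
#'   (a [graphics::hist()] object computed without plotting).
#' @export
fst_distribution_check <- function(fst, pair = 1, min_loci = 100,
                                   alpha = 0.05, n_boot = 200, seed = 1L) {
  v <- if (inherits(fst, "fst_result")) fst$per_locus[, pair] else fst
  v <- v[!is.na(v)]
  if (length(v) < min_loci) {
    return(list(statistic = NA_real_, p_value = NA_real_, unimodal = NA,
                status = "insufficient", histogram = NULL))
  }
  t <- dip_test(v, n_boot = n_boot, seed = seed)
  list(statistic = t$statistic, p_value = t$p_value,
       unimodal = t$p_value >= alpha, status = "ok",
       histogram = graphics::hist(v, breaks = 50, plot = FALSE))
}

#' Region-level fixation index matrix
#'
#' For each pair of regions, collects the median pairwise FST of every sample
#' pair spanning the two regions and reports their mean. Regions without
#' admitted samples are dropped with a warning.
#'
#' @param fst an `fst_result` (its `median_matrix` is used) or a symmetric
#'   `pools x pools` median-FST matrix.
#' @param regions named character vector mapping sample (pool) id to region
#'   label.
#' @return symmetric `region x region` matrix with `NA` diagonal.
#' @export
region_fst <- function(fst, regions) {
  m <- if (inherits(fst, "fst_result")) fst$median_matrix else fst
  pools <- rownames(m)
  if (is.null(pools)) stop("median matrix must carry pool names")
  miss <- setdiff(pools, names(regions))
  if (length(miss))
    stop("no region for sample(s): ", paste(miss, collapse = ", "))
  reg <- regions[pools]
  lev <- unique(reg)
  empty <- setdiff(unique(regions), lev)
  if (length(empty))
    warning("region(s) without admitted samples dropped: ",
            paste(empty, collapse = ", "))
  out <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    if (a >= b) next
    ia <- which(reg == lev[a]); ib <- which(reg == lev[b])
    vals <- as.vector(m[ia, ib, drop = FALSE])
    vals <- vals[!is.na(vals)]
    if (length(vals))
      out[a, b] <- out[b, a] <- mean(vals)
  }
  out
}

#' Qualitative differentiation class of an FST value
#'
#' Wright-style guideline bands: `< 0.05` low, `[0.05, 0.15)` moderate to
#' high, `>= 0.15` great genetic differentiation.
#'
#' @param fst numeric vector in `[0, 1]`.
#' @return character vector of labels.
#' @export
differentiation_class <- function(fst) {
  if (any(fst < 0 | fst > 1, na.rm = TRUE)) stop("FST must lie in [0, 1]")
  ifelse(fst >= 0.15, "great",
         ifelse(fst >= 0.05, "moderate-to-high", "low"))
}
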