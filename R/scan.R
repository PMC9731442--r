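#' B-allele-frequency matrix from pooled counts
#'
#' Calls SNVs with the standard thresholds and returns the loci x pools
#' matrix of alternate-allele frequencies. Missing entries (pools without
#' bi-allelic depth at a locus) are imputed with the locus mean, with a
#' warning; loci missing in every pool are dropped.
#'
#' @param counts an [allele_counts()] object.
#' @param thresholds a [variant_thresholds()] list.
#' @param per_pool_window apply the per-pool coverage window during calling
#'   (see [call_snvs()]); the selection scans are usually run without it, as
#'   their own MAF filter governs locus admission.
#' @return numeric matrix `loci x pools`, rownames `contig:pos`.
#' @export
baf_matrix <- function(counts, thresholds = variant_thresholds(),
                       per_pool_window = TRUE) {
  snvs <- call_snvs(counts, thresholds = thresholds,
                    per_pool_window = per_pool_window)
  f <- snv_frequencies(snvs)
  all_na <- rowSums(!is.na(f)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-missing locus/loci dropped")
    f <- f[!all_na, , drop = FALSE]
  }
  if (anyNA(f)) {
    warning(sum(is.na(f)), " missing BAF value(s) imputed with locus means")
    mu <- rowMeans(f, na.rm = TRUE)
    f[is.na(f)] <- mu[row(f)[is.na(f)]]
  }
  f
}

#' Read / write a BAF matrix as TSV (loci in rows, pools in columns)
#' @param path TSV path.
#' @return numeric matrix with `contig:pos` rownames.
#' @export
read_baf_tsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                       check.names = FALSE))
}

#' @rdname read_baf_tsv
#' @param baf numeric matrix `loci x pools`.
#' @export
write_baf_tsv <- function(baf, path) {
  write.table(cbind(locus = rownames(baf), as.data.frame(baf)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lewontin-Krakauer selection scan
#'
#' The per-locus statistic is \eqn{LK_l = (n-1) F_l / \bar F} with \eqn{\bar F}
#' the mean per-locus fixation index across loci; under neutral drift of a
#' single species it follows a chi-squared distribution with `n - 1` degrees
#' of freedom, giving upper-tail p-values and Benjamini-Hochberg q-values.
#'
#' @param fst numeric vector of per-locus multi-population fixation indices
#'   (e.g. from [multipop_fst()] or [global_fst()]); `NA` loci are carried
#'   through.
#' @param n_populations number of populations the indices were computed
#'   from.
#' @param q_threshold candidate threshold on the q-value.
#' @return a data.frame of class `selection_scan`: `statistic`, `p`, `q`,
#'   `candidate`, with attributes `method`, `df`, `n_populations`.
#' @export
lk_scan <- function(fst, n_populations, q_threshold = 0.15) {
  if (n_populations < 2) stop("need at least 2 populations")
  mfst <- mean(fst, na.rm = TRUE)
  if (!is.finite(mfst) || mfst <= 0)
    stop("no differentiation to scan (mean FST is zero)")
  df <- n_populations - 1
  lk <- df * fst / mfst
  p <- pchisq(lk, df = df, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(statistic = lk, p = p, q = q,
                    candidate = !is.na(q) & q < q_threshold)
  if (!is.null(names(fst))) rownames(out) <- names(fst)
  attr(out, "method") <- "LK"
  attr(out, "df") <- df
  attr(out, "n_populations") <- n_populations
  class(out) <- c("selection_scan", class(out))
  out
}

#' PCA / Mahalanobis outlier scan on a BAF matrix
#'
#' The pool-seq analogue of a principal-component selection scan: loci with
#' across-pool minor allele frequency below `maf` are dropped; the remaining
#' loci are centred and scaled by \eqn{\sqrt{\bar p (1-\bar p)}}; the pools x
#' loci matrix is decomposed by SVD; each locus gets a K-vector of scores on
#' the top `K` axes whose robust Mahalanobis distance (minimum covariance
#' determinant) is divided by the genomic inflation factor (observed median
#' over the chi-squared-K median) and referred to chi-squared with `K`
#' degrees of freedom; q-values by Benjamini-Hochberg.
#'
#' @param baf numeric matrix `loci x pools` of B-allele frequencies.
#' @param K number of principal axes (default `pools - 1`).
#' @param maf minor-allele-frequency filter on the mean BAF across pools.
#' @param q_threshold candidate threshold on the q-value.
#' @param seed seed for the (resampling-based) robust covariance estimate.
#' @return a data.frame of class `selection_scan`: `statistic` (Mahalanobis
#'   D^2 after inflation correction), `p`, `q`, `candidate`, `kept` (passed
#'   the MAF filter); loci removed by the MAF filter carry `NA` statistics.
#'   Attributes: `method`, `K`, `gif`.
#' @export
pca_outlier_scan <- function(baf, K = NULL, maf = 0.05, q_threshold = 0.15,
                             seed = 1L) {
  if (!is.matrix(baf)) baf <- as.matrix(baf)
  n <- ncol(baf)
  if (n < 3) stop("need at least 3 pools for the PCA scan")
  if (is.null(K)) K <- n - 1
  if (K < 1 || K >= n) stop("K must lie in [1, pools - 1]")
  if (any(baf < 0 | baf > 1, na.rm = TRUE)) stop("BAF values must lie in [0,1]")
  mu <- rowMeans(baf)
  kept <- pmin(mu, 1 - mu) >= maf
  if (sum(kept) <= n) stop("too few loci pass the MAF filter")
  X <- baf[kept, , drop = FALSE]
  mu <- rowMeans(X)
  Xs <- (X - mu) / sqrt(mu * (1 - mu))
  sv <- svd(t(Xs), nu = K, nv = K)
  if (sv$d[K] < 1e-12)
    stop("degenerate covariance on the top axes; lower K")
  Z <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  rob <- local_seed(seed, tryCatch(
    MASS::cov.rob(Z, method = "mcd"),
    error = function(e) list(center = colMeans(Z), cov = stats::cov(Z))))
  if (min(eigen(rob$cov, symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
    stop("degenerate robust covariance; lower K")
  d2 <- mahalanobis(Z, rob$center, rob$cov)
  gif <- median(d2) / qchisq(0.5, df = K)
  d2c <- d2 / gif
  p <- pchisq(d2c, df = K, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(statistic = NA_real_, p = NA_real_, q = NA_real_,
                    candidate = FALSE, kept = kept)
  out$statistic[kept] <- d2c
  out$p[kept] <- p
  out$q[kept] <- q
  out$candidate[kept] <- q < q_threshold
  if (!is.null(rownames(baf))) rownames(out) <- rownames(baf)
  attr(out, "method") <- "PCA"
  attr(out, "K") <- K
  attr(out, "gif") <- gif
  class(out) <- c("selection_scan", class(out))
  out
}

#' Detect aberrant population pools from the BAF matrix
#'
#' A pool whose variation pattern is very distinct from the others (e.g. a
#' cryptic subpopulation or contaminating lineage) inflates the outlier scan;
#' such pools are flagged by their principal-component scores exceeding a
#' robust threshold (median +/- `k_mad` median absolute deviations on any
#' retained axis) so the caller can exclude them and re-run.
#'
#' @param baf numeric matrix `loci x pools`.
#' @param n_axes number of axes to inspect (default `pools - 1`).
#' @param k_mad MAD multiplier of the flagging threshold.
#' @return character vector of flagged pool names (possibly empty), with the
#'   score matrix as attribute `scores`.
#' @export
detect_outlier_samples <- function(baf, n_axes = NULL, k_mad = 6) {
  n <- ncol(baf)
  if (n < 3) stop("need at least 3 pools")
  if (is.null(n_axes)) n_axes <- n - 1
  mu <- rowMeans(baf)
  ok <- mu > 0 & mu < 1
  Xs <- (baf[ok, , drop = FALSE] - mu[ok]) / sqrt(mu[ok] * (1 - mu[ok]))
  sv <- svd(t(Xs))
  scores <- sv$u[, seq_len(min(n_axes, ncol(sv$u))), drop = FALSE] %*%
    diag(sv$d[seq_len(min(n_axes, ncol(sv$u)))],
         min(n_axes, ncol(sv$u)))
  rownames(scores) <- colnames(baf)
  # only inspect axes carrying at least an average share of the variance;
  # trailing axes of a handful of pools are noise and over-flag
  share <- sv$d[seq_len(ncol(scores))]^2 / sum(sv$d^2)
  retained <- which(share >= 1 / n)
  flagged <- rep(FALSE, n)
  for (a in retained) {
    s <- scores[, a]
    md <- median(s); ma <- stats::mad(s)
    if (ma < 1e-12) next
    flagged <- flagged | abs(s - md) > k_mad * ma
  }
  out <- colnames(baf)[flagged]
  attr(out, "scores") <- scores
  out
}

#' BAF report around candidate loci
#'
#' Long-format per-locus, per-pool BAF table for candidate loci, plus the
#' statistics of neighbouring loci within a window (default +/- 5 kb, i.e. a
#' 10 kb view) for Manhattan-style local plots. Windows are truncated at
#' contig edges.
#'
#' @param baf numeric matrix `loci x pools` with `contig:pos` rownames.
#' @param scan a `selection_scan` over the same loci (row order of `baf`).
#' @param loci character vector of candidate locus ids (`contig:pos`);
#'   defaults to the scan's candidates.
#' @param flank half-window in bases.
#' @return list with `baf` (data.frame `locus`, `contig`, `pos`, `pool`,
#'   `baf`) and `neighbourhood` (data.frame `focal`, `locus`, `contig`,
#'   `pos`, `statistic`, `p`, `q`, `candidate`).
#' @export
baf_report <- function(baf, scan, loci = NULL, flank = 5000) {
  ids <- rownames(baf)
  if (is.null(ids)) stop("'baf' must carry contig:pos rownames")
  if (is.null(loci)) loci <- ids[which(scan$candidate)]
  if (length(loci) == 0) stop("no candidate loci to report")
  unknown <- setdiff(loci, ids)
  if (length(unknown))
    stop("unknown locus id(s): ", paste(head(unknown, 3), collapse = ", "))
  parts <- strsplit(ids, ":", fixed = TRUE)
  contig <- vapply(parts, `[[`, "", 1)
  pos <- as.integer(vapply(parts, `[[`, "", 2))
  li <- match(loci, ids)
  long <- data.frame(
    locus = rep(loci, each = ncol(baf)),
    contig = rep(contig[li], each = ncol(baf)),
    pos = rep(pos[li], each = ncol(baf)),
    pool = rep(colnames(baf), length(loci)),
    baf = as.vector(t(baf[li, , drop = FALSE])),
    stringsAsFactors = FALSE)
  nb <- do.call(rbind, lapply(seq_along(loci), function(k) {
    i <- li[k]
    sel <- which(contig == contig[i] & abs(pos - pos[i]) <= flank)
    data.frame(focal = loci[k], locus = ids[sel], contig = contig[sel],
               pos = pos[sel], statistic = scan$statistic[sel],
               p = scan$p[sel], q = scan$q[sel],
               candidate = scan$candidate[sel], stringsAsFactors = FALSE)
  }))
  list(baf = long, neighbourhood = nb)
}
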