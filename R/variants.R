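#' Variant-calling thresholds
#'
#' Defaults mirror the classical pool-seq settings: minor-allele count of at
#' least 2 (pooled over populations), per-pool depth within `[4, 200]`, and a
#' site must satisfy the window in every admitted pool
#' (min-covered-fraction 1).
#'
#' @param min_count pooled minor-allele count threshold.
#' @param min_coverage,max_coverage per-pool depth window.
#' @return named list.
#' @export
variant_thresholds <- function(min_count = 2, min_coverage = 4,
                               max_coverage = 200) {
  stopifnot(min_count > 0, min_coverage > 0, min_coverage <= max_coverage)
  list(min_count = min_count, min_coverage = min_coverage,
       max_coverage = max_coverage)
}

#' Call SNVs from pooled counts
#'
#' A site is called when, pooling all populations, the minor allele count is
#' at least `min_count` and (when `per_pool_window` is `TRUE`) every pool's
#' depth lies within the coverage window. The alternate allele is the most
#' frequent non-reference base, ties broken in the fixed order `A < C < G < T`;
#' residual third/fourth alleles are ignored (bi-allelic representation).
#' Records with an unknown reference base are skipped with a warning.
#'
#' @param counts an [allele_counts()] object.
#' @param thresholds a [variant_thresholds()] list.
#' @param per_pool_window apply the per-pool coverage window during calling;
#'   set `FALSE` to obtain the candidate set used by pairwise statistics,
#'   which re-apply the window pair by pair.
#' @return an object of class `snv_set`: list with `table` (data.frame
#'   `contig`, `pos`, `ref`, `alt`, `context`, `effect`), matrices
#'   `ref_count`, `alt_count`, `depth` (total A/C/G/T depth) with one column
#'   per pool, and `pools`.
#' @export
call_snvs <- function(counts, thresholds = variant_thresholds(),
                      per_pool_window = TRUE) {
  th <- thresholds
  acgt <- c("A", "C", "G", "T")
  keep_ref <- counts$ref %in% acgt
  if (!all(keep_ref)) {
    warning(sum(!keep_ref), " record(s) with unknown reference base skipped")
    counts <- subset_loci(counts, keep_ref)
  }
  base_counts <- counts$counts[, acgt, , drop = FALSE]   # loci x 4 x pools
  pooled <- apply(base_counts, c(1, 2), sum)             # loci x 4
  if (n_loci(counts) == 1) pooled <- matrix(pooled, nrow = 1,
                                            dimnames = list(NULL, acgt))
  depth <- apply(base_counts, c(1, 3), sum)              # loci x pools
  # minor allele count = pooled count of the 2nd most frequent base
  ord <- t(apply(pooled, 1, sort, decreasing = TRUE))
  minor <- ord[, 2]
  # alt = most frequent non-reference base, ties by fixed base order
  ref_idx <- match(counts$ref, acgt)
  nonref <- pooled
  nonref[cbind(seq_len(nrow(pooled)), ref_idx)] <- -1
  alt_idx <- max.col(nonref, ties.method = "first")
  ok <- minor >= th$min_count
  if (per_pool_window) {
    inwin <- depth >= th$min_coverage & depth <= th$max_coverage
    ok <- ok & apply(inwin, 1, all)
  }
  idx <- which(ok)
  sel <- function(m) m[idx, , drop = FALSE]
  refc <- vapply(seq_len(n_pools(counts)), function(j)
    base_counts[cbind(seq_len(dim(base_counts)[1]), ref_idx,
                      rep(j, dim(base_counts)[1]))],
    numeric(dim(base_counts)[1]))
  altc <- vapply(seq_len(n_pools(counts)), function(j)
    base_counts[cbind(seq_len(dim(base_counts)[1]), alt_idx,
                      rep(j, dim(base_counts)[1]))],
    numeric(dim(base_counts)[1]))
  if (dim(base_counts)[1] == 1) { refc <- matrix(refc, 1); altc <- matrix(altc, 1) }
  colnames(refc) <- colnames(altc) <- counts$pools
  structure(list(
    table = data.frame(contig = counts$contig[idx], pos = counts$pos[idx],
                       ref = counts$ref[idx], alt = acgt[alt_idx][idx],
                       context = rep(NA_character_, length(idx)),
                       effect = rep(NA_character_, length(idx)),
                       stringsAsFactors = FALSE),
    ref_count = sel(refc), alt_count = sel(altc), depth = sel(depth),
    pools = counts$pools), class = "snv_set")
}

#' @export
print.snv_set <- function(x, ...) {
  cat(sprintf("<snv_set> %d SNVs x %d pools\n", nrow(x$table), ncol(x$depth)))
  invisible(x)
}

#' Per-pool alternate-allele (B-allele) frequencies of called SNVs
#'
#' `alt / (ref + alt)` per pool; pools with zero bi-allelic depth at a locus
#' yield `NA`.
#'
#' @param snvs an `snv_set` from [call_snvs()].
#' @return numeric matrix `loci x pools` with rownames `contig:pos`.
#' @export
snv_frequencies <- function(snvs) {
  bi <- snvs$ref_count + snvs$alt_count
  f <- snvs$alt_count / ifelse(bi > 0, bi, NA)
  rownames(f) <- paste0(snvs$table$contig, ":", snvs$table$pos)
  f
}

#' SNV density
#'
#' Percentage of covered positions that are variant, the micro-diversity
#' proxy of a population sample.
#'
#' @param snvs an `snv_set` or an SNV count.
#' @param n_covered number of reference positions passing the same coverage
#'   window (the denominator is *covered* positions, not genome length).
#' @return percentage.
#' @export
snv_density <- function(snvs, n_covered) {
  if (n_covered <= 0) stop("'n_covered' must be positive")
  n <- if (inherits(snvs, "snv_set")) nrow(snvs$table) else snvs
  100 * n / n_covered
}

#' Transition / transversion ratio
#'
#' Transitions are `A<->G` and `C<->T`; all other reference/alternate pairs
#' are transversions. Undefined (with a warning) when no transversion is
#' observed.
#'
#' @param snvs an `snv_set` or a data.frame with `ref` and `alt` columns.
#' @return the ratio, or `NA` when undefined.
#' @export
tstv_ratio <- function(snvs) {
  tab <- if (inherits(snvs, "snv_set")) snvs$table else snvs
  ts <- is_transition(tab$ref, tab$alt)
  ntv <- sum(!ts)
  if (ntv == 0) {
    warning("no transversions: Ts/Tv undefined")
    return(NA_real_)
  }
  sum(ts) / ntv
}

#' Is a substitution a transition?
#' @param ref,alt reference and alternate bases.
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}
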