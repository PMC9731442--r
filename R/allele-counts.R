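#' Pooled allele-count table
#'
#' The pipeline's central matrix: nucleotide counts per locus and population
#' pool, compatible with the PoPoolation2 sync format. Counts are stored as a
#' 3-d array `loci x base x pool` with bases in sync column order
#' `A, T, C, G, N, del`.
#'
#' @param contig character vector of contig names, one per locus.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases (`A`, `C`, `G` or `T`).
#' @param counts numeric array `n_loci x 6 x n_pools`; second dimension in
#'   sync order `A,T,C,G,N,del`.
#' @param pools character vector of pool identifiers (column order of the
#'   sync file).
#'
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(contig, pos, ref, counts, pools = NULL) {
  n <- length(pos)
  stopifnot(length(contig) == n, length(ref) == n)
  if (length(dim(counts)) != 3 || dim(counts)[1] != n || dim(counts)[2] != 6)
    stop("'counts' must be an n_loci x 6 x n_pools array")
  if (any(counts < 0)) stop("negative counts")
  bad <- !ref %in% c("A", "C", "G", "T")
  if (any(bad))
    stop("reference base must be one of A,C,G,T (", sum(bad), " offending loci)")
  n_pools <- dim(counts)[3]
  if (is.null(pools)) pools <- paste0("pool", seq_len(n_pools))
  stopifnot(length(pools) == n_pools)
  dimnames(counts) <- list(NULL, SYNC_BASES, pools)
  structure(
    list(contig = as.character(contig), pos = as.integer(pos),
         ref = as.character(ref), counts = counts, pools = pools),
    class = "allele_counts")
}

SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %d loci x %d pools on %d contig(s)\n",
              n_loci(x), n_pools(x), length(unique(x$contig))))
  invisible(x)
}

#' Number of loci / pools in an allele-count table
#' @param x an `allele_counts` object.
#' @return integer scalar.
#' @export
n_loci <- function(x) length(x$pos)

#' @rdname n_loci
#' @export
n_pools <- function(x) dim(x$counts)[3]

#' Per-pool sequencing depth at each locus
#'
#' Depth is the number of reads carrying a called base (A/C/G/T); `N` and
#' deletion columns do not contribute alleles.
#'
#' @param x an `allele_counts` object.
#' @return numeric matrix `loci x pools`.
#' @export
pool_coverage <- function(x) {
  apply(x$counts[, c("A", "C", "G", "T"), , drop = FALSE], c(1, 3), sum)
}

#' Subset loci of an allele-count table
#' @param x an `allele_counts` object.
#' @param i logical or integer index over loci.
#' @return an `allele_counts` object.
#' @export
subset_loci <- function(x, i) {
  allele_counts(x$contig[i], x$pos[i], x$ref[i],
                x$counts[i, , , drop = FALSE], x$pools)
}

#' Locus identifiers (`contig:pos`)
#' @param x an `allele_counts` object.
#' @return character vector.
#' @export
locus_ids <- function(x) paste0(x$contig, ":", x$pos)
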