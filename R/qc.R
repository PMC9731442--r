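#' Read-recruitment summary for one sample
#'
#' Holds what the QC cascade needs about one metagenomic sample mapped to one
#' reference genome: per-read percent identity (and, when available, the
#' reference interval each read covers), the reference length, and the
#' mapped/total read counts used for relative abundance.
#'
#' @param sample_id sample identifier.
#' @param identity numeric vector of per-read percent identities in `[0,100]`.
#' @param ref_length reference length in bases.
#' @param start,width optional integer vectors (same length as `identity`)
#'   giving each read's 1-based mapped start and width; when present, depth is
#'   recomputed exactly after identity filtering.
#' @param depth optional per-base depth vector of length `ref_length`, used
#'   when read intervals are not available.
#' @param mapped,total mapped and total read counts for the sample.
#' @return an object of class `sample_recruitment`.
#' @export
sample_recruitment <- function(sample_id, identity, ref_length,
                               start = NULL, width = NULL, depth = NULL,
                               mapped = length(identity), total = mapped) {
  if (length(identity) && (min(identity) < 0 || max(identity) > 100))
    stop("identities must lie in [0, 100]")
  if (mapped > total) stop("mapped read count exceeds total")
  if (!is.null(start) && (length(start) != length(identity) ||
                          length(width) != length(identity)))
    stop("'start'/'width' must match 'identity' in length")
  if (is.null(start) && is.null(depth))
    stop("provide either read intervals (start/width) or a depth vector")
  if (!is.null(depth) && any(depth < 0)) stop("negative depth")
  structure(list(sample_id = sample_id, identity = as.numeric(identity),
                 ref_length = as.integer(ref_length),
                 start = start, width = width, depth = depth,
                 mapped = mapped, total = total),
            class = "sample_recruitment")
}

#' @export
print.sample_recruitment <- function(x, ...) {
  cat(sprintf("<sample_recruitment> %s: %d reads over %d bp (mapped %d / total %d)\n",
              x$sample_id, length(x$identity), x$ref_length, x$mapped, x$total))
  invisible(x)
}

#' Per-base depth of a recruitment
#'
#' Computed from read intervals when available, otherwise the stored vector.
#' @param rec a [sample_recruitment()] object.
#' @return integer vector of length `ref_length`.
#' @export
recruitment_depth <- function(rec) {
  if (!is.null(rec$start)) {
    d <- integer(rec$ref_length)
    if (length(rec$start)) {
      from <- pmax(1L, rec$start)
      to <- pmin(rec$ref_length, rec$start + rec$width - 1L)
      keep <- from <= to
      # difference-array coverage accumulation
      diffd <- integer(rec$ref_length + 1L)
      for (i in which(keep)) {
        diffd[from[i]] <- diffd[from[i]] + 1L
        diffd[to[i] + 1L] <- diffd[to[i] + 1L] - 1L
      }
      d <- cumsum(diffd[seq_len(rec$ref_length)])
    }
    d
  } else rec$depth
}

#' Filter recruited reads by percent identity
#'
#' Retains reads with identity at or above the threshold and recomputes the
#' mapped count and (when read intervals are available) the depth. The
#' two-stage use of the cascade (80 then 97) is obtained by composing calls.
#'
#' @param rec a [sample_recruitment()] object.
#' @param min_identity percent identity threshold in `[0, 100]`.
#' @return a filtered [sample_recruitment()] object.
#' @export
filter_reads_by_identity <- function(rec, min_identity) {
  stopifnot(min_identity >= 0, min_identity <= 100)
  if (length(rec$identity) == 0) {
    warning("empty recruitment for sample ", rec$sample_id)
    return(rec)
  }
  keep <- rec$identity >= min_identity
  out <- rec
  out$identity <- rec$identity[keep]
  out$start <- rec$start[keep]
  out$width <- rec$width[keep]
  out$mapped <- sum(keep)
  if (is.null(rec$start) && !is.null(rec$depth)) {
    # no read coordinates: depth is scaled by the retained fraction
    out$depth <- rec$depth * (sum(keep) / length(keep))
  }
  out
}

#' Mean vertical coverage and coverage breadth
#'
#' The mean is taken over *all* reference positions (zeros included); breadth
#' is the percentage of positions with depth of at least 1.
#'
#' @param depth per-base depth vector.
#' @return named list `mean_vertical_coverage`, `coverage_breadth`.
#' @export
coverage_stats <- function(depth) {
  if (length(depth) == 0) stop("empty depth vector")
  list(mean_vertical_coverage = mean(depth),
       coverage_breadth = 100 * mean(depth >= 1))
}

#' Unimodality check on a coverage profile
#'
#' Applies the bootstrap dip test ([dip_test()]) to the depth distribution of
#' covered (nonzero) positions. A bimodal profile is the signature of
#' non-specific read recruitment (e.g. conserved rRNA loci attracting reads
#' from other taxa on top of the genuine population signal).
#'
#' @param depth per-base depth vector.
#' @param min_covered minimum number of covered positions required for a
#'   verdict; below this the sample is reported `insufficient`.
#' @param alpha significance level: the profile passes when `p >= alpha`.
#' @param n_boot,seed passed to [dip_test()].
#' @return list `statistic`, `p_value`, `pass` (logical or `NA` when
#'   insufficient), `status` (`"ok"` or `"insufficient"`).
#' @export
assess_unimodality <- function(depth, min_covered = 100, alpha = 0.05,
                               n_boot = 200, seed = 1L) {
  nz <- depth[depth > 0]
  if (length(nz) < min_covered) {
    return(list(statistic = NA_real_, p_value = NA_real_, pass = NA,
                status = "insufficient"))
  }
  t <- dip_test(nz, n_boot = n_boot, seed = seed)
  list(statistic = t$statistic, p_value = t$p_value,
       pass = t$p_value >= alpha, status = "ok")
}

#' Default QC thresholds
#'
#' Identity 80 then 97, mean vertical coverage at least 4x, coverage breadth at
#' least 80 percent, and a unimodal coverage profile.
#' @param identity_pre,identity_final the two identity stages (percent).
#' @param min_coverage minimum mean vertical coverage (reads/base).
#' @param min_breadth minimum coverage breadth (percent).
#' @param unimodal_alpha dip-test significance level.
#' @param coverage_after_final if `TRUE`, coverage/breadth are evaluated after
#'   the final identity stage instead of after the pre-filter.
#' @param n_boot,seed dip-test bootstrap controls.
#' @return a named list of thresholds.
#' @export
qc_thresholds <- function(identity_pre = 80, identity_final = 97,
                          min_coverage = 4, min_breadth = 80,
                          unimodal_alpha = 0.05, coverage_after_final = FALSE,
                          n_boot = 200, seed = 1L) {
  list(identity_pre = identity_pre, identity_final = identity_final,
       min_coverage = min_coverage, min_breadth = min_breadth,
       unimodal_alpha = unimodal_alpha,
       coverage_after_final = coverage_after_final,
       n_boot = n_boot, seed = seed)
}

#' Admit or reject one sample through the QC cascade
#'
#' Applies, in order: the identity pre-filter, mean-coverage and breadth
#' checks, the final identity filter, and the coverage-profile unimodality
#' check. A sample is admitted only when every check passes; `reasons` lists
#' every failed check.
#'
#' @param rec a [sample_recruitment()] object.
#' @param thresholds a [qc_thresholds()] list.
#' @return a `qc_verdict` list: `sample_id`, `admitted`, `reasons`,
#'   `mean_vertical_coverage`, `coverage_breadth`, `unimodality_statistic`,
#'   `unimodality_p`, `unimodality_pass`, `reads_after_pre`,
#'   `reads_after_final`.
#' @export
admit_sample <- function(rec, thresholds = qc_thresholds()) {
  th <- thresholds
  reasons <- character(0)
  pre <- filter_reads_by_identity(rec, th$identity_pre)
  fin <- filter_reads_by_identity(pre, th$identity_final)
  cov_rec <- if (isTRUE(th$coverage_after_final)) fin else pre
  cs <- coverage_stats(recruitment_depth(cov_rec))
  if (cs$mean_vertical_coverage < th$min_coverage)
    reasons <- c(reasons, sprintf("coverage<%g", th$min_coverage))
  if (cs$coverage_breadth < th$min_breadth)
    reasons <- c(reasons, sprintf("breadth<%g", th$min_breadth))
  uni <- assess_unimodality(recruitment_depth(fin), alpha = th$unimodal_alpha,
                            n_boot = th$n_boot, seed = th$seed)
  if (identical(uni$status, "insufficient")) {
    reasons <- c(reasons, "insufficient_covered_positions")
  } else if (!uni$pass) {
    reasons <- c(reasons, "bimodal_coverage")
  }
  structure(list(sample_id = rec$sample_id,
                 admitted = length(reasons) == 0,
                 reasons = reasons,
                 mean_vertical_coverage = cs$mean_vertical_coverage,
                 coverage_breadth = cs$coverage_breadth,
                 unimodality_statistic = uni$statistic,
                 unimodality_p = uni$p_value,
                 unimodality_pass = uni$pass,
                 reads_after_pre = length(pre$identity),
                 reads_after_final = length(fin$identity)),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict> %s: %s (cov %.2fx, breadth %.1f%%)\n",
              x$sample_id, if (x$admitted) "ADMITTED" else
                paste("rejected:", paste(x$reasons, collapse = ",")),
              x$mean_vertical_coverage, x$coverage_breadth))
  invisible(x)
}

#' Read a recruitment fixture from TSV
#'
#' Two layouts are supported: a read-interval table with columns `read_id`,
#' `identity`, `start`, `width` (depth is then recomputed exactly after
#' filtering), or a pair of files - reads (`read_id`, `identity`) plus a
#' per-base table (`position`, `depth`).
#'
#' @param path reads TSV.
#' @param ref_length reference length in bases.
#' @param sample_id sample identifier (defaults to the file name).
#' @param depth_path optional per-base depth TSV for the two-file layout.
#' @param mapped,total optional read counts (default: rows of `path`, and
#'   `mapped`).
#' @return a [sample_recruitment()].
#' @export
read_recruitment_tsv <- function(path, ref_length, sample_id = NULL,
                                 depth_path = NULL, mapped = NULL,
                                 total = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.tsv$", "", basename(path))
  reads <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  if (is.null(mapped)) mapped <- nrow(reads)
  if (is.null(total)) total <- mapped
  if (!is.null(depth_path)) {
    dep <- read.table(depth_path, header = TRUE, sep = "\t")
    depth <- numeric(ref_length)
    depth[dep$position] <- dep$depth
    sample_recruitment(sample_id, reads$identity, ref_length,
                       depth = depth, mapped = mapped, total = total)
  } else {
    if (!all(c("start", "width") %in% names(reads)))
      stop("reads TSV must carry start/width (or give depth_path)")
    sample_recruitment(sample_id, reads$identity, ref_length,
                       start = reads$start, width = reads$width,
                       mapped = mapped, total = total)
  }
}

#' Write a QC report (TSV + JSON)
#'
#' @param verdicts list of `qc_verdict` objects from [admit_sample()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the TSV path, invisibly.
#' @export
write_qc_report <- function(verdicts, prefix) {
  df <- do.call(rbind, lapply(verdicts, function(v)
    data.frame(sample_id = v$sample_id, admitted = v$admitted,
               reasons = paste(v$reasons, collapse = ";"),
               mean_vertical_coverage = v$mean_vertical_coverage,
               coverage_breadth = v$coverage_breadth,
               unimodality_statistic = v$unimodality_statistic,
               unimodality_p = v$unimodality_p,
               reads_after_pre = v$reads_after_pre,
               reads_after_final = v$reads_after_final)))
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(lapply(verdicts, unclass), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".tsv"))
}

#' Relative abundance of a genome in a sample
#'
#' @param mapped number of reads recruited by the genome.
#' @param total total number of reads in the sample.
#' @return percentage, `100 * mapped / total`.
#' @export
relative_abundance <- function(mapped, total) {
  if (any(total <= 0)) stop("total read count must be positive")
  100 * mapped / total
}

#' Genome co-occurrence from abundance profiles
#'
#' Spearman rank correlation between every pair of genomes across samples,
#' with the correlation test p-value; a display mask at `p < alpha` mirrors
#' the usual correlation-plot convention. Genome columns that are constant
#' across samples have no defined rank correlation and are reported `NA` with
#' a warning.
#'
#' @param abundance numeric matrix `samples x genomes`.
#' @param alpha mask level for the `masked_rho` element.
#' @return list of matrices `rho`, `p`, `masked_rho` (rho with
#'   non-significant entries set `NA`).
#' @export
cooccurrence_matrix <- function(abundance, alpha = 0.05) {
  if (nrow(abundance) < 3) stop("need at least 3 samples")
  g <- ncol(abundance)
  gn <- colnames(abundance)
  if (is.null(gn)) gn <- paste0("genome", seq_len(g))
  rho <- p <- matrix(NA_real_, g, g, dimnames = list(gn, gn))
  diag(rho) <- 1; diag(p) <- 0
  const <- apply(abundance, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    warning("constant abundance column(s): ",
            paste(gn[const], collapse = ", "), " - correlations undefined")
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (const[i] || const[j]) next
    ct <- suppressWarnings(
      cor.test(abundance[, i], abundance[, j], method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  masked <- rho
  masked[!is.na(p) & p >= alpha] <- NA
  diag(masked) <- 1
  list(rho = rho, p = p, masked_rho = masked)
}
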