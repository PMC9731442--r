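#' Pipeline configuration
#'
#' Collects inputs and every stage threshold, with the cascade's standard
#' defaults: identity 80 then 97, mean coverage 4x, breadth 80%, minor count
#' 2, per-pool depth window [4, 200], pool size 500, MAF 0.05, q-value
#' threshold 0.15, 9,999 Mantel permutations.
#'
#' @param counts an [allele_counts()] object or a sync file path.
#' @param samples data.frame of per-pool metadata (must contain
#'   `sample_id`; environmental columns are used by the association stage;
#'   optional `region`, `lat`, `lon`).
#' @param annotation a [gene_annotation()], or `NULL`.
#' @param recruitments optional list of [sample_recruitment()] objects for
#'   the QC stage (one per pool).
#' @param qc a [qc_thresholds()] list.
#' @param variants a [variant_thresholds()] list.
#' @param pool_size haploid pool size for the corrected FST estimator.
#' @param maf,q_threshold selection-scan controls.
#' @param n_perm Mantel permutations.
#' @param min_env_samples environmental association requires at least this
#'   many admitted samples.
#' @param out_dir optional output directory; when given, every artefact is
#'   written there together with a provenance block.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, annotation = NULL,
                            recruitments = NULL,
                            qc = qc_thresholds(),
                            variants = variant_thresholds(),
                            pool_size = 500, maf = 0.05, q_threshold = 0.15,
                            n_perm = 9999, min_env_samples = 3,
                            out_dir = NULL, seed = 1L) {
  structure(list(counts = counts, samples = samples,
                 annotation = annotation, recruitments = recruitments,
                 qc = qc, variants = variants, pool_size = pool_size,
                 maf = maf, q_threshold = q_threshold, n_perm = n_perm,
                 min_env_samples = min_env_samples, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stage order: sample QC (when recruitment summaries are provided), SNV
#' calling and landscape annotation, pairwise and global FST, the LK and PCA
#' selection scans, and - when at least `min_env_samples` samples were
#' admitted - environmental variance partitioning with Mantel verification.
#' Any stage error aborts with the stage name. When `out_dir` is set, every
#' artefact is written (sync/VCF/TSV/JSON) with a provenance block recording
#' the resolved configuration, seed and package version.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with elements `qc`, `snvs`, `landscape`,
#'   `fst`, `lk`, `pca`, `env` (each `NULL` when the stage was skipped, with
#'   the reason in `skipped`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  skipped <- list()
  counts <- stage("input", {
    if (inherits(cfg$counts, "allele_counts")) cfg$counts
    else read_sync(cfg$counts)
  })
  samples <- cfg$samples
  ## QC
  qc_res <- NULL
  if (!is.null(cfg$recruitments)) {
    qc_res <- stage("qc", lapply(cfg$recruitments, admit_sample, thresholds = cfg$qc))
    admitted <- vapply(qc_res, `[[`, TRUE, "admitted")
    keep <- counts$pools %in%
      vapply(qc_res, `[[`, "", "sample_id")[admitted]
    if (!all(keep)) {
      counts$counts <- counts$counts[, , keep, drop = FALSE]
      counts$pools <- counts$pools[keep]
      samples <- samples[samples$sample_id %in% counts$pools, , drop = FALSE]
    }
  }
  if (n_pools(counts) < 2)
    stop("pipeline stage 'qc' failed: fewer than 2 admitted samples")
  ## variants
  snvs <- stage("variants", call_snvs(counts, thresholds = cfg$variants))
  if (!is.null(cfg$annotation)) {
    snvs <- stage("variants", annotate_snvs(snvs, cfg$annotation))
  }
  landscape <- stage("variants", {
    depth_ok <- snvs$depth >= cfg$variants$min_coverage &
      snvs$depth <= cfg$variants$max_coverage
    list(n_snvs = nrow(snvs$table),
         tstv = if (nrow(snvs$table)) suppressWarnings(tstv_ratio(snvs))
                else NA_real_,
         context = if (!is.null(cfg$annotation))
           table(snvs$table$context) else NULL,
         effect = if (!is.null(cfg$annotation))
           table(snvs$table$effect[snvs$table$context == "coding"])
           else NULL)
  })
  ## FST
  fst <- stage("fst", pairwise_fst(counts, thresholds = cfg$variants))
  gfst <- stage("fst", global_fst(counts, thresholds = cfg$variants))
  ## scans
  lk <- stage("scan_lk", {
    f <- stats::setNames(gfst$fst, paste0(gfst$contig, ":", gfst$pos))
    if (all(is.na(f)) || mean(f, na.rm = TRUE) <= 0) NULL
    else lk_scan(f, n_populations = n_pools(counts),
                 q_threshold = cfg$q_threshold)
  })
  if (is.null(lk)) skipped$lk <- "no differentiation to scan"
  pca <- NULL
  if (n_pools(counts) >= 3) {
    pca <- stage("scan_pca", {
      baf <- baf_matrix(counts, thresholds = cfg$variants)
      pca_outlier_scan(baf, maf = cfg$maf, q_threshold = cfg$q_threshold,
                       seed = cfg$seed)
    })
  } else skipped$pca <- "fewer than 3 pools"
  ## environmental association
  env <- NULL
  env_cols <- intersect(ENV_VARIABLES$variable, names(samples))
  if (nrow(samples) < cfg$min_env_samples) {
    skipped$env <- sprintf("fewer than %d admitted samples",
                           cfg$min_env_samples)
  } else if (length(env_cols) == 0) {
    skipped$env <- "no environmental columns in sample table"
  } else {
    env <- stage("env", {
      rownames(samples) <- samples$sample_id
      prep <- preprocess_env(samples[env_cols])
      dists <- lapply(prep$env, euclidean_distance_matrix)
      if (all(c("lat", "lon") %in% names(samples)))
        dists$geography <-
          euclidean_distance_matrix(samples[c("lat", "lon")])
      med <- fst$median_matrix[samples$sample_id, samples$sample_id]
      vp <- variance_partition(med, dists, n_perm = cfg$n_perm,
                               seed = cfg$seed)
      list(preprocess = prep, partition = vp)
    })
  }
  res <- structure(list(qc = qc_res, snvs = snvs, landscape = landscape,
                        fst = fst, global_fst = gfst, lk = lk, pca = pca,
                        env = env, skipped = skipped, config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) .write_pipeline(res, counts)
  res
}

.write_pipeline <- function(res, counts) {
  cfg <- res$config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_sync(counts, p("admitted_counts.sync"))
  write_vcf(res$snvs, p("snvs.vcf"))
  write.table(cbind(locus = paste0(res$fst$contig, ":", res$fst$pos),
                    as.data.frame(res$fst$per_locus)),
              p("fst_per_locus.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$fst$median_matrix, p("fst_median_matrix.tsv"),
              sep = "\t", quote = FALSE)
  if (!is.null(res$lk))
    write.table(cbind(locus = rownames(res$lk), res$lk), p("lk_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$pca))
    write.table(cbind(locus = rownames(res$pca), res$pca), p("pca_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$env)) {
    jsonlite::write_json(
      list(proportions = as.list(res$env$partition$proportions),
           fixed_share = res$env$partition$fixed_share,
           mantel = res$env$partition$mantel),
      p("variance_partition.json"), auto_unbox = TRUE, digits = NA)
  }
  prov <- list(package = "magpop",
               version = as.character(utils::packageVersion("magpop")),
               seed = cfg$seed,
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               thresholds = list(qc = cfg$qc[setdiff(names(cfg$qc), "seed")],
                                 variants = cfg$variants,
                                 pool_size = cfg$pool_size, maf = cfg$maf,
                                 q_threshold = cfg$q_threshold,
                                 n_perm = cfg$n_perm))
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  SNVs: %d  (Ts/Tv %.3g)\n", x$landscape$n_snvs,
              x$landscape$tstv))
  cat(sprintf("  pools: %d;  median pairwise FST range [%.3g, %.3g]\n",
              nrow(x$fst$median_matrix),
              min(x$fst$median_matrix, na.rm = TRUE),
              max(x$fst$median_matrix, na.rm = TRUE)))
  if (length(x$skipped))
    cat("  skipped:", paste(names(x$skipped), unlist(x$skipped),
                            sep = ": ", collapse = "; "), "\n")
  invisible(x)
}
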