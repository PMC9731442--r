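#' Read a sync-format count table
#'
#' Parses the PoPoolation2 sync dialect: tab-separated lines of
#' `contig  position  ref  A:T:C:G:N:del  [...]` with one colon-joined count
#' field per pool. Malformed lines are rejected with their line number rather
#' than silently coerced.
#'
#' @param path path to a sync file.
#' @param pools optional character vector of pool names; defaults to
#'   `pool1..poolK` in column order.
#' @return an [allele_counts()] object.
#' @export
read_sync <- function(path, pools = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty sync file: ", path)
    return(allele_counts(character(0), integer(0), character(0),
                         array(0, c(0, 6, max(1, length(pools)))), pools))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  arity <- lengths(fields)
  if (any(arity < 4)) {
    stop("sync parse error: fewer than 4 tab fields at line ",
         which(arity < 4)[1])
  }
  if (length(unique(arity)) != 1) {
    stop("sync parse error: inconsistent field count at line ",
         which(arity != arity[1])[1])
  }
  k <- arity[1] - 3L
  contig <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos)) stop("sync parse error: non-integer position at line ",
                       which(is.na(pos))[1])
  ref <- toupper(vapply(fields, `[[`, "", 3L))
  counts <- array(0, c(length(lines), 6, k))
  for (j in seq_len(k)) {
    cf <- vapply(fields, `[[`, "", 3L + j)
    parts <- strsplit(cf, ":", fixed = TRUE)
    bad <- lengths(parts) != 6L
    if (any(bad))
      stop("sync parse error: count field '", cf[which(bad)[1]],
           "' is not 6 colon-separated integers at line ", which(bad)[1])
    m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 6,
                                 byrow = TRUE))
    if (anyNA(m)) stop("sync parse error: non-numeric count at line ",
                       which(rowSums(is.na(m)) > 0)[1])
    counts[, , j] <- m
  }
  allele_counts(contig, pos, ref, counts, pools)
}

#' Write an allele-count table in sync format
#'
#' @param x an [allele_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  k <- n_pools(x)
  cols <- vapply(seq_len(k), function(j) {
    m <- x$counts[, , j, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                  collapse = ":"))
  }, character(n_loci(x)))
  if (n_loci(x) == 1) cols <- matrix(cols, nrow = 1)
  lines <- cbind(x$contig, x$pos, x$ref, cols)
  writeLines(apply(lines, 1, paste, collapse = "\t"), path)
  invisible(path)
}
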