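#' Write called SNVs as minimal VCF v4.2
#'
#' One record per SNV, sorted by contig then position (unsorted input is an
#' error). Per-pool depths and allele depths are carried in INFO fields:
#' `DP` (summed depth), `ADP` (per-pool depth), `ADR`/`ADA` (per-pool
#' ref/alt allele depths), `POOLS` in the header records pool order. The
#' file round-trips through [read_vcf()].
#'
#' @param snvs an `snv_set` from [call_snvs()].
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snvs, path, contig_lengths = NULL) {
  tab <- snvs$table
  if (nrow(tab) > 1) {
    o <- order(tab$contig, tab$pos)
    if (!identical(o, seq_len(nrow(tab))))
      stop("records must be sorted by contig, position")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=magpop",
           paste0("##POOLS=", paste(snvs$pools, collapse = ",")),
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
           '##INFO=<ID=ADP,Number=.,Type=Integer,Description="Per-pool depth">',
           '##INFO=<ID=ADR,Number=.,Type=Integer,Description="Per-pool reference allele depth">',
           '##INFO=<ID=ADA,Number=.,Type=Integer,Description="Per-pool alternate allele depth">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                    "QUAL", "FILTER", "INFO"),
                                  collapse = "\t")))
  join <- function(m) apply(m, 1, paste, collapse = ",")
  body <- if (nrow(tab) == 0) character(0) else {
    info <- sprintf("DP=%d;ADP=%s;ADR=%s;ADA=%s",
                    as.integer(rowSums(snvs$depth)),
                    join(snvs$depth), join(snvs$ref_count),
                    join(snvs$alt_count))
    paste(tab$contig, tab$pos, ".", tab$ref, tab$alt, ".", "PASS", info,
          sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return an `snv_set`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!any(startsWith(hdr, "##fileformat=VCF")))
    stop("not a VCF file: ", path)
  pools_line <- hdr[startsWith(hdr, "##POOLS=")]
  pools <- if (length(pools_line))
    strsplit(sub("^##POOLS=", "", pools_line[1]), ",")[[1]] else "pool1"
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  k <- length(pools)
  if (length(body) == 0) {
    empty <- matrix(numeric(0), 0, k, dimnames = list(NULL, pools))
    return(structure(list(
      table = data.frame(contig = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         context = character(0), effect = character(0)),
      ref_count = empty, alt_count = empty, depth = empty, pools = pools),
      class = "snv_set"))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 8)) stop("malformed VCF record at data line ",
                                which(lengths(f) < 8)[1])
  getinfo <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  info <- vapply(f, `[[`, "", 8)
  parsemat <- function(key) {
    v <- strsplit(getinfo(info, key), ",")
    matrix(as.numeric(unlist(v)), ncol = k, byrow = TRUE,
           dimnames = list(NULL, pools))
  }
  structure(list(
    table = data.frame(contig = vapply(f, `[[`, "", 1),
                       pos = as.integer(vapply(f, `[[`, "", 2)),
                       ref = vapply(f, `[[`, "", 4),
                       alt = vapply(f, `[[`, "", 5),
                       context = NA_character_, effect = NA_character_,
                       stringsAsFactors = FALSE),
    ref_count = parsemat("ADR"), alt_count = parsemat("ADA"),
    depth = parsemat("ADP"), pools = pools), class = "snv_set")
}
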