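#' Gene annotation over a toy or real genome
#'
#' Bundles a genome (`Biostrings::DNAStringSet`) with gene features
#' (`GenomicRanges::GRanges` carrying `type`, `gene_id` and, for CDS
#' segments, `exon_rank` in transcription order). A coding map - one row per
#' coding genomic position with its codon, frame position and strand - is
#' precomputed so effect classification is a table lookup.
#'
#' @param genome a named `DNAStringSet`, one sequence per contig.
#' @param features a `GRanges` with metadata columns `type` (one of
#'   `five_prime_UTR`, `CDS`, `intron`, `three_prime_UTR`, `gene`),
#'   `gene_id`, and `exon_rank` (CDS only).
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(genome, features) {
  stopifnot(methods::is(genome, "DNAStringSet"),
            methods::is(features, "GRanges"))
  if (is.null(names(genome))) stop("genome sequences must be named")
  need <- c("type", "gene_id")
  if (!all(need %in% names(S4Vectors::mcols(features))))
    stop("features must carry 'type' and 'gene_id' metadata columns")
  over <- GenomicRanges::end(features) >
    GenomeInfoDb::seqlengths(.with_seqinfo(features, genome))[
      as.character(GenomicRanges::seqnames(features))]
  if (any(over, na.rm = TRUE)) stop("feature interval beyond contig bounds")
  ann <- structure(list(genome = genome, features = features),
                   class = "gene_annotation")
  ann$coding_map <- .build_coding_map(ann)
  ann
}

.with_seqinfo <- function(gr, genome) {
  GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(Biostrings::width(genome), names(genome))[
      GenomeInfoDb::seqlevels(gr)]
  gr
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d contig(s), %d gene(s), %d coding bases\n",
              length(x$genome),
              length(unique(x$features$gene_id[x$features$type != "gene"])),
              nrow(x$coding_map)))
  invisible(x)
}

# one row per coding genomic position: contig, pos, strand, codon (3-char),
# frame position (1..3), amino acid of the reference codon
.build_coding_map <- function(ann) {
  feats <- ann$features
  cds <- feats[feats$type == "CDS"]
  if (length(cds) == 0)
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), codon = character(0),
                      frame = integer(0), aa = character(0)))
  out <- vector("list", length(unique(cds$gene_id)))
  gi <- 0
  for (g in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == g]
    seg <- seg[order(seg$exon_rank)]
    strand <- as.character(GenomicRanges::strand(seg))[1]
    chr <- as.character(GenomicRanges::seqnames(seg))[1]
    segseq <- lapply(seq_along(seg), function(i) {
      s <- Biostrings::subseq(ann$genome[[chr]],
                              GenomicRanges::start(seg)[i],
                              GenomicRanges::end(seg)[i])
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    })
    cdsseq <- paste(unlist(segseq), collapse = "")
    L <- nchar(cdsseq)
    if (L %% 3 != 0)
      stop("annotation error: CDS length of gene ", g,
           " not divisible by 3")
    gpos <- unlist(lapply(seq_along(seg), function(i) {
      p <- GenomicRanges::start(seg)[i]:GenomicRanges::end(seg)[i]
      if (strand == "-") rev(p) else p
    }))
    off <- seq_len(L)
    codon_i <- (off - 1) %/% 3
    codons <- substring(cdsseq, codon_i * 3 + 1, codon_i * 3 + 3)
    gi <- gi + 1
    out[[gi]] <- data.frame(contig = chr, pos = gpos, strand = strand,
                            gene_id = g, codon = codons,
                            frame = (off - 1) %% 3 + 1,
                            stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, out)
  map$aa <- .translate_codons(map$codon)
  map
}

.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Genomic context of a position
#'
#' Assigns each position to exactly one of `coding`, `UTR`, `intron`,
#' `intergenic`, with precedence `coding > UTR > intron` when features
#' overlap.
#'
#' @param contig,pos vectors of contig names and 1-based positions.
#' @param annotation a [gene_annotation()].
#' @return character vector of contexts.
#' @export
classify_context <- function(contig, pos, annotation) {
  feats <- annotation$features
  lens <- stats::setNames(Biostrings::width(annotation$genome),
                          names(annotation$genome))
  if (any(!contig %in% names(lens)))
    stop("contig(s) absent from annotation: ",
         paste(unique(setdiff(contig, names(lens))), collapse = ", "))
  if (any(pos < 1 | pos > lens[contig]))
    stop("position beyond contig length")
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  ctx <- rep("intergenic", length(pos))
  for (cls in list(c("intron", "intron"),
                    c("five_prime_UTR", "UTR"), c("three_prime_UTR", "UTR"),
                    c("CDS", "coding"))) {
    sub <- feats[feats$type == cls[1]]
    if (length(sub) == 0) next
    hit <- IRanges::overlapsAny(q, sub, ignore.strand = TRUE)
    ctx[hit] <- cls[2]
  }
  ctx
}

#' Coding effect of a substitution
#'
#' Substitutes the alternate base in its codon (complementing on the minus
#' strand), translates with the standard genetic code and reports `silent`
#' (same amino acid), `nonsense` (gained stop) or `missense` (any other
#' change; stop-loss is folded into missense as only three effect classes are
#' reported). Positions outside coding sequence return `none`.
#'
#' @param contig,pos,ref,alt vectors describing the substitutions.
#' @param annotation a [gene_annotation()].
#' @return character vector of effects.
#' @export
classify_effect <- function(contig, pos, ref, alt, annotation) {
  map <- annotation$coding_map
  key <- paste0(contig, ":", pos)
  mkey <- paste0(map$contig, ":", map$pos)
  idx <- match(key, mkey)
  eff <- rep("none", length(pos))
  hit <- which(!is.na(idx))
  if (length(hit) == 0) return(eff)
  m <- map[idx[hit], ]
  sub_base <- ifelse(m$strand == "-", COMPLEMENT[alt[hit]], alt[hit])
  ref_check <- ifelse(m$strand == "-", COMPLEMENT[ref[hit]], ref[hit])
  codon_ref <- substring(m$codon, m$frame, m$frame)
  bad <- codon_ref != ref_check
  if (any(bad))
    warning(sum(bad), " substitution(s) whose stated reference base ",
            "disagrees with the genome; classified from the genome codon")
  codon_alt <- m$codon
  substr(codon_alt, m$frame, m$frame) <- sub_base
  aa_ref <- m$aa
  aa_alt <- .translate_codons(codon_alt)
  eff[hit] <- ifelse(aa_alt == aa_ref, "silent",
                     ifelse(aa_alt == "*", "nonsense", "missense"))
  eff
}

#' Annotate an SNV set with context and effect
#'
#' @param snvs an `snv_set` from [call_snvs()].
#' @param annotation a [gene_annotation()].
#' @return the `snv_set` with `context` and `effect` columns filled
#'   (`effect` is `none` outside coding context).
#' @export
annotate_snvs <- function(snvs, annotation) {
  tab <- snvs$table
  tab$context <- classify_context(tab$contig, tab$pos, annotation)
  tab$effect <- classify_effect(tab$contig, tab$pos, tab$ref, tab$alt,
                                annotation)
  snvs$table <- tab
  snvs
}

#' Write annotation as GFF3 (and optionally the genome as FASTA)
#'
#' @param annotation a [gene_annotation()].
#' @param gff_path output GFF3 path.
#' @param fasta_path optional FASTA path for the genome.
#' @return `gff_path`, invisibly.
#' @export
write_annotation <- function(annotation, gff_path, fasta_path = NULL) {
  gr <- .with_seqinfo(annotation$features, annotation$genome)
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(annotation$genome, fasta_path)
  invisible(gff_path)
}

#' Read annotation from GFF3 + FASTA
#'
#' @param gff_path GFF3 file with `type`, `gene_id` (written as `ID`/
#'   attribute `gene_id`) and `exon_rank` attributes as produced by
#'   [write_annotation()].
#' @param fasta_path genome FASTA.
#' @return a [gene_annotation()].
#' @export
read_annotation <- function(gff_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(mc)) stop("GFF3 lacks gene_id attribute")
  if ("exon_rank" %in% names(mc))
    mc$exon_rank <- as.integer(mc$exon_rank)
  mc$type <- as.character(mc$type)
  S4Vectors::mcols(gr) <- mc
  gene_annotation(genome, gr)
}
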