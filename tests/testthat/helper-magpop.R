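# shared fixtures, built in code

# tiny allele-count table: 4 loci x 2 pools
tiny_counts <- function() {
  counts <- array(0, c(4, 6, 2))
  dimnames(counts) <- list(NULL, c("A", "T", "C", "G", "N", "del"),
                           c("p1", "p2"))
  # locus 1: ref A 3, alt G 2 in both pools (called)
  counts[1, "A", ] <- 3; counts[1, "G", ] <- 2
  # locus 2: coverage 3 (below window)
  counts[2, "A", ] <- 2; counts[2, "G", ] <- 1
  # locus 3: minor count 1 at coverage 50
  counts[3, "C", ] <- c(49, 50); counts[3, "T", ] <- c(1, 0)
  # locus 4: monomorphic
  counts[4, "T", ] <- 20
  allele_counts(contig = rep("ctg1", 4), pos = c(10L, 20L, 30L, 40L),
                ref = c("A", "A", "C", "T"), counts = counts,
                pools = c("p1", "p2"))
}

# hand-built annotation: three genes (+, -, + with intron) on one contig
tiny_annotation <- function() {
  seq <- paste0(
    "TTT",        # 1-3   intergenic
    "ACA",        # 4-6   gene1 5'UTR (+)
    "GAAGCATAC",  # 7-15  gene1 CDS: GAA GCA TAC
    "TTT",        # 16-18 gene1 3'UTR
    "ACGTAC",     # 19-24 intergenic
    "CAT",        # 25-27 gene2 3'UTR (-)
    "GTATGCTTC",  # 28-36 gene2 CDS; revcomp = GAAGCATAC
    "TGT",        # 37-39 gene2 5'UTR
    "T",          # 40    intergenic
    "ACA",        # 41-43 gene3 5'UTR (+)
    "GAA",        # 44-46 gene3 CDS exon 1
    "TTTTTT",     # 47-52 gene3 intron
    "GCATAA",     # 53-58 gene3 CDS exon 2
    "GT")         # 59-60 intergenic
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  f <- rbind(
    data.frame(start = 4,  end = 6,  strand = "+", type = "five_prime_UTR",
               gene_id = "g1", exon_rank = NA),
    data.frame(start = 7,  end = 15, strand = "+", type = "CDS",
               gene_id = "g1", exon_rank = 1),
    data.frame(start = 16, end = 18, strand = "+", type = "three_prime_UTR",
               gene_id = "g1", exon_rank = NA),
    data.frame(start = 25, end = 27, strand = "-", type = "three_prime_UTR",
               gene_id = "g2", exon_rank = NA),
    data.frame(start = 28, end = 36, strand = "-", type = "CDS",
               gene_id = "g2", exon_rank = 1),
    data.frame(start = 37, end = 39, strand = "-", type = "five_prime_UTR",
               gene_id = "g2", exon_rank = NA),
    data.frame(start = 41, end = 43, strand = "+", type = "five_prime_UTR",
               gene_id = "g3", exon_rank = NA),
    data.frame(start = 44, end = 46, strand = "+", type = "CDS",
               gene_id = "g3", exon_rank = 1),
    data.frame(start = 47, end = 52, strand = "+", type = "intron",
               gene_id = "g3", exon_rank = NA),
    data.frame(start = 53, end = 58, strand = "+", type = "CDS",
               gene_id = "g3", exon_rank = 2))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(f$start, f$end),
                               strand = f$strand, type = f$type,
                               gene_id = f$gene_id, exon_rank = f$exon_rank)
  gene_annotation(genome, gr)
}

# cache heavier simulated datasets across tests within one run
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}
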