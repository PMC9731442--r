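#' Simulate a toy annotated genome and a mutation list
#'
#' Builds a multi-contig genome whose genes carry 5'/3' UTRs, CDS exons,
#' introns and intergenic gaps on both strands, then draws a mutation list
#' whose genomic-context composition, coding-effect composition and realized
#' transition:transversion ratio converge to the requested values. Effects
#' are planted exactly: for each coding mutation the generator enumerates the
#' three possible alternate bases at candidate positions and picks one whose
#' translated consequence matches the drawn effect class (preferring the
#' substitution type - transition or transversion - drawn from the Ts/Tv
#' target).
#'
#' @param n_genes number of genes (split over `n_contigs` contigs).
#' @param tstv_ratio target transition:transversion ratio (> 0).
#' @param effect_mix named proportions over `silent`, `missense`, `nonsense`
#'   for coding mutations; must sum to 1.
#' @param n_mutations number of mutations to draw.
#' @param context_mix named proportions over `coding`, `intergenic`, `UTR`,
#'   `intron`; must sum to 1.
#' @param n_contigs number of contigs.
#' @param seed RNG seed.
#' @return list with `annotation` (a [gene_annotation()]) and `mutations`
#'   (data.frame `contig`, `pos`, `ref`, `alt`, `context`, `effect`,
#'   `transition`).
#' @export
simulate_annotation <- function(n_genes, tstv_ratio = 1.5,
                                effect_mix = c(silent = 0.46,
                                               missense = 0.53,
                                               nonsense = 0.01),
                                n_mutations = 1000,
                                context_mix = c(coding = 0.50,
                                                intergenic = 0.30,
                                                UTR = 0.15, intron = 0.05),
                                n_contigs = 2, seed = 1L) {
  if (n_genes < 1) stop("empty gene set")
  if (tstv_ratio <= 0) stop("tstv_ratio must be positive")
  if (abs(sum(effect_mix) - 1) > 1e-8) stop("effect_mix must sum to 1")
  if (abs(sum(context_mix) - 1) > 1e-8) stop("context_mix must sum to 1")
  effect_mix <- effect_mix[c("silent", "missense", "nonsense")]
  context_mix <- context_mix[c("coding", "intergenic", "UTR", "intron")]
  if (anyNA(effect_mix) || anyNA(context_mix))
    stop("effect_mix/context_mix must be named with the documented classes")
  local_seed(seed, {
    ann <- .build_toy_genome(n_genes, n_contigs)
    muts <- .draw_mutations(ann, n_mutations, tstv_ratio,
                            effect_mix, context_mix)
    list(annotation = ann, mutations = muts)
  })
}

.build_toy_genome <- function(n_genes, n_contigs) {
  acgt <- c("A", "C", "G", "T")
  per_contig <- diff(round(seq(0, n_genes, length.out = n_contigs + 1)))
  per_contig[per_contig == 0] <- 1
  seqs <- list(); feats <- list(); gid <- 0
  for (ci in seq_len(n_contigs)) {
    chr <- paste0("ctg", ci)
    blocks <- character(0)
    cursor <- 0L
    add_block <- function(n) {
      blocks[[length(blocks) + 1]] <<- paste(sample(acgt, n, TRUE),
                                             collapse = "")
      cursor <<- cursor + n
    }
    for (g in seq_len(per_contig[ci])) {
      add_block(sample(100:300, 1))                       # intergenic gap
      gid <- gid + 1
      gene <- paste0("gene", gid)
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(1:3, 1)
      cds_total <- 3L * sample(60:160, 1)
      cuts <- sort(sample(seq_len(cds_total %/% 3 - 1), n_ex - 1)) * 3L
      ex_len <- diff(c(0L, cuts, cds_total))
      utr5 <- sample(30:90, 1); utr3 <- sample(30:90, 1)
      intr <- if (n_ex > 1) sample(40:120, n_ex - 1, replace = TRUE) else integer(0)
      # blocks in transcription order
      tx <- list(c("five_prime_UTR", utr5))
      for (e in seq_len(n_ex)) {
        tx[[length(tx) + 1]] <- c("CDS", ex_len[e])
        if (e < n_ex) tx[[length(tx) + 1]] <- c("intron", intr[e])
      }
      tx[[length(tx) + 1]] <- c("three_prime_UTR", utr3)
      if (strand == "-") tx <- rev(tx)     # genomic order
      rank_counter <- 0
      gene_start <- cursor + 1L
      for (b in tx) {
        w <- as.integer(b[2])
        st <- cursor + 1L
        add_block(w)
        en <- cursor
        rank <- NA_integer_
        if (b[1] == "CDS") {
          rank_counter <- rank_counter + 1
          # transcription rank: on '-' the genomic-leftmost CDS is the last
          rank <- rank_counter
        }
        feats[[length(feats) + 1]] <-
          data.frame(contig = chr, start = st, end = en, strand = strand,
                     type = b[1], gene_id = gene, exon_rank = rank,
                     stringsAsFactors = FALSE)
      }
      feats[[length(feats) + 1]] <-
        data.frame(contig = chr, start = gene_start, end = cursor,
                   strand = strand, type = "gene", gene_id = gene,
                   exon_rank = NA_integer_, stringsAsFactors = FALSE)
    }
    add_block(sample(100:300, 1))                         # trailing gap
    seqs[[chr]] <- paste(unlist(blocks), collapse = "")
  }
  fd <- do.call(rbind, feats)
  # fix '-' strand CDS ranks: transcription order is descending genomic order
  fd$phase <- NA_integer_
  for (g in unique(fd$gene_id)) {
    sel <- which(fd$gene_id == g & fd$type == "CDS")
    if (!length(sel)) next
    fd$exon_rank[sel] <- if (fd$strand[sel][1] == "-")
      rank(-fd$start[sel]) else rank(fd$start[sel])
    o <- sel[order(fd$exon_rank[sel])]
    before <- cumsum(c(0L, (fd$end[o] - fd$start[o] + 1L)))[seq_along(o)]
    fd$phase[o] <- (3L - before %% 3L) %% 3L
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  gr <- GenomicRanges::GRanges(fd$contig,
                               IRanges::IRanges(fd$start, fd$end),
                               strand = fd$strand, type = fd$type,
                               gene_id = fd$gene_id,
                               exon_rank = fd$exon_rank, phase = fd$phase)
  gene_annotation(genome, gr)
}

# enumerate candidate (position, alt) pairs per effect class and substitution
# type, then draw mutations matching the requested mixes
.draw_mutations <- function(ann, n_mut, tstv_ratio, effect_mix, context_mix) {
  acgt <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  map <- ann$coding_map
  genome_chars <- lapply(seq_along(ann$genome), function(i)
    strsplit(as.character(ann$genome[[i]]), "")[[1]])
  names(genome_chars) <- names(ann$genome)
  # coding candidates: 3 alts per coding position, with effect + ts flag
  refs_tx <- substring(map$codon, map$frame, map$frame)  # transcribed-strand ref
  ref_gen <- ifelse(map$strand == "-", COMPLEMENT[refs_tx], refs_tx)
  cod <- lapply(1:3, function(k) {
    alt_gen <- vapply(ref_gen, function(r) setdiff(acgt, r)[k], "")
    sub_tx <- ifelse(map$strand == "-", COMPLEMENT[alt_gen], alt_gen)
    codon_alt <- map$codon
    substr(codon_alt, map$frame, map$frame) <- sub_tx
    aa_alt <- .translate_codons(codon_alt)
    eff <- ifelse(aa_alt == map$aa, "silent",
                  ifelse(aa_alt == "*", "nonsense", "missense"))
    data.frame(row = seq_len(nrow(map)), ref = ref_gen, alt = alt_gen,
               effect = eff, transition = ts_partner[ref_gen] == alt_gen,
               stringsAsFactors = FALSE)
  })
  cod <- do.call(rbind, cod)
  p_ts <- tstv_ratio / (1 + tstv_ratio)
  n_ctx <- stats::setNames(
    as.vector(stats::rmultinom(1, n_mut, context_mix)), names(context_mix))
  res <- list()
  ## coding mutations
  if (n_ctx[["coding"]] > 0) {
    n_eff <- stats::setNames(
      as.vector(stats::rmultinom(1, n_ctx[["coding"]], effect_mix)),
      names(effect_mix))
    for (e in names(n_eff)) {
      if (n_eff[[e]] == 0) next
      want_ts <- runif(n_eff[[e]]) < p_ts
      for (ts in c(TRUE, FALSE)) {
        k <- sum(want_ts == ts)
        if (k == 0) next
        pool <- cod[cod$effect == e & cod$transition == ts, ]
        if (nrow(pool) == 0) pool <- cod[cod$effect == e, ]
        if (nrow(pool) == 0)
          stop("no attainable substitution for effect class ", e)
        pick <- pool[sample.int(nrow(pool), k, replace = TRUE), ]
        res[[length(res) + 1]] <-
          data.frame(contig = map$contig[pick$row], pos = map$pos[pick$row],
                     ref = pick$ref, alt = pick$alt, context = "coding",
                     effect = e, transition = pick$transition,
                     stringsAsFactors = FALSE)
      }
    }
  }
  ## non-coding mutations
  ctx_pos <- .context_positions(ann)
  for (ctx in c("intergenic", "UTR", "intron")) {
    k <- n_ctx[[ctx]]
    if (k == 0) next
    tab <- ctx_pos[[ctx]]
    if (nrow(tab) == 0) stop("no territory for context ", ctx)
    pick <- tab[sample.int(nrow(tab), k, replace = TRUE), , drop = FALSE]
    ref <- vapply(seq_len(k), function(i)
      genome_chars[[pick$contig[i]]][pick$pos[i]], "")
    ts <- runif(k) < p_ts
    alt <- ifelse(ts, ts_partner[ref],
                  vapply(ref, function(r)
                    sample(setdiff(acgt, c(r, ts_partner[r])), 1), ""))
    res[[length(res) + 1]] <-
      data.frame(contig = pick$contig, pos = pick$pos, ref = ref, alt = alt,
                 context = ctx, effect = "none", transition = ts,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[sample.int(nrow(out)), ]
  rownames(out) <- NULL
  out
}

# per-context position tables honouring the coding > UTR > intron precedence
.context_positions <- function(ann) {
  feats <- ann$features
  expand <- function(types) {
    sub <- feats[feats$type %in% types]
    if (length(sub) == 0)
      return(data.frame(contig = character(0), pos = integer(0)))
    do.call(rbind, lapply(seq_along(sub), function(i)
      data.frame(contig = as.character(GenomicRanges::seqnames(sub))[i],
                 pos = GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i],
                 stringsAsFactors = FALSE)))
  }
  cds <- expand("CDS"); utr <- expand(c("five_prime_UTR", "three_prime_UTR"))
  intr <- expand("intron")
  keyify <- function(d) paste0(d$contig, ":", d$pos)
  utr <- utr[!keyify(utr) %in% keyify(cds), ]
  intr <- intr[!keyify(intr) %in% c(keyify(cds), keyify(utr)), ]
  genic <- unique(c(keyify(cds), keyify(utr), keyify(intr)))
  inter <- do.call(rbind, lapply(names(ann$genome), function(chr)
    data.frame(contig = chr, pos = seq_len(Biostrings::width(ann$genome[chr])),
               stringsAsFactors = FALSE)))
  inter <- inter[!keyify(inter) %in% genic, ]
  list(coding = cds, UTR = utr, intron = intr, intergenic = inter)
}

#' Simulate a per-base coverage profile and read-identity histogram
#'
#' Unimodal profiles draw depths from one negative binomial; bimodal profiles
#' from a two-component mixture with well-separated means (the signature of
#' non-specific recruitment). Identities concentrate above the requested
#' mode.
#'
#' @param genome_length number of reference positions (> 0).
#' @param mean_depth mean depth of the (first) component (> 0).
#' @param mode `"unimodal"` or `"bimodal"`.
#' @param second_mean mean depth of the second mixture component (bimodal).
#' @param mixing proportion of positions from the first component (bimodal).
#' @param dispersion negative-binomial size parameter.
#' @param identity_mode identity percentage around which read identities
#'   concentrate.
#' @param n_reads number of read identities to draw.
#' @param seed RNG seed.
#' @return list with `depth` (integer vector) and `identity` (numeric
#'   vector of per-read percent identities).
#' @export
simulate_coverage_profile <- function(genome_length, mean_depth,
                                      mode = c("unimodal", "bimodal"),
                                      second_mean = 8 * mean_depth,
                                      mixing = 0.5, dispersion = 8,
                                      identity_mode = 98, n_reads = 2000,
                                      seed = 1L) {
  mode <- match.arg(mode)
  if (genome_length <= 0) stop("genome_length must be positive")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  local_seed(seed, {
    depth <- if (mode == "unimodal") {
      rnbinom(genome_length, mu = mean_depth, size = dispersion)
    } else {
      comp1 <- runif(genome_length) < mixing
      ifelse(comp1,
             rnbinom(genome_length, mu = mean_depth, size = dispersion),
             rnbinom(genome_length, mu = second_mean, size = dispersion))
    }
    identity <- pmin(100, identity_mode + rnorm(n_reads, 0, 1.2) -
                       rexp(n_reads, rate = 0.8))
    identity <- pmax(0, identity)
    list(depth = depth, identity = identity)
  })
}
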