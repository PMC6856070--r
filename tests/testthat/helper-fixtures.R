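# Fixtures and independent oracles shared across the suite.
# Everything is built in code at test time; nothing is read from disk.

# Small simulation presets -------------------------------------------------

small_params <- function(seed = 1L, n_sites = 12L, ...) {
  sim_params(n_chrom = 1L, chrom_length = 60000L, n_genes = 8L,
             n_sites = n_sites, mean_count = 50, seed = seed, ...)
}

small_world <- function(seed = 1L, ...) {
  p <- small_params(seed = seed, ...)
  genome <- generate_genome(p)
  genes <- generate_annotation(genome, p)
  truth <- plant_truth_sites(genes, p, genome)
  list(params = p, genome = genome, genes = genes, truth = truth)
}

# The worked single-transcript gene model used in the annotation tests:
# one + strand transcript with exons [1000,1200) and [1500,2000), so
# tss = 1000, tes = 1999 and one intron [1200,1500).
toy_genes <- function(strand = "+") {
  tx <- data.frame(tx_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = strand, start = 1000L, end = 2000L,
                   tss = if (strand == "+") 1000L else 1999L,
                   tes = if (strand == "+") 1999L else 1000L,
                   stringsAsFactors = FALSE)
  ex <- data.frame(tx_id = "t1", exon_rank = 1:2,
                   start = c(1000L, 1500L), end = c(1200L, 2000L),
                   stringsAsFactors = FALSE)
  structure(list(transcripts = tx, exons = ex), class = "gene_models")
}

toy_cluster <- function(rep_, lo = rep_, hi = rep_, strand = "+",
                        chrom = "chr1") {
  data.frame(cluster_id = "c1", chrom = chrom, strand = strand,
             representative = rep_, span_start = lo, span_end = hi,
             stringsAsFactors = FALSE)
}

# Reads --------------------------------------------------------------------

make_reads <- function(sequence, quality = NULL,
                       id = sprintf("r%04d", seq_along(sequence))) {
  if (is.null(quality)) quality <- strrep("I", nchar(sequence))
  data.frame(read_id = id, sequence = sequence, quality = quality,
             stringsAsFactors = FALSE)
}

qual_string <- function(phred) {
  intToUtf8(33L + phred, multiple = FALSE)
}

# Brute-force clustering oracle --------------------------------------------

# Connected components of the graph joining positions <= window apart,
# found by O(n^2) label propagation -- independent of the sorted-gap
# implementation under test.
brute_force_components <- function(positions, window) {
  n <- length(positions)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(positions[i] - positions[j]) <= window &&
            lab[j] < lab[i]) {
          lab[i] <- lab[j]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Mirror transform ----------------------------------------------------------

# Reverse-complement the coordinate system of a gene_models object living
# on chromosomes of length L: positions map to L-1-pos, intervals to
# [L-end, L-start), strands flip.  Class codes must be invariant under
# this transform applied jointly to genes and clusters.
mirror_genes <- function(genes, L) {
  tx <- genes$transcripts
  ex <- genes$exons
  new_tx <- tx
  new_tx$strand <- ifelse(tx$strand == "+", "-", "+")
  new_tx$start <- L - tx$end
  new_tx$end <- L - tx$start
  new_tx$tss <- L - 1L - tx$tss
  new_tx$tes <- L - 1L - tx$tes
  new_ex <- ex
  new_ex$start <- L - ex$end
  new_ex$end <- L - ex$start
  ord <- order(match(new_ex$tx_id, new_tx$tx_id), new_ex$start)
  new_ex <- new_ex[ord, ]
  new_ex$exon_rank <- unlist(lapply(split(seq_len(nrow(new_ex)),
                                          factor(new_ex$tx_id,
                                                 levels = unique(new_ex$tx_id))),
                                    seq_along), use.names = FALSE)
  structure(list(transcripts = new_tx, exons = new_ex),
            class = "gene_models")
}

mirror_clusters <- function(clusters, L) {
  out <- clusters
  out$strand <- ifelse(clusters$strand == "+", "-", "+")
  out$representative <- L - 1L - clusters$representative
  out$span_start <- L - 1L - clusters$span_end
  out$span_end <- L - 1L - clusters$span_start
  out
}

# SAM construction ----------------------------------------------------------

# Minimal single-end SAM for a set of alignments of exact-match reads.
write_toy_sam <- function(path, genome, aln, reads) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  body <- vapply(seq_len(nrow(aln)), function(i) {
    seq <- reads$sequence[match(aln$read_id[i], reads$read_id)]
    flag <- if (aln$strand[i] == "+") 0L else 16L
    if (flag == 16L) {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    }
    paste(aln$read_id[i], flag, aln$chrom[i], aln$start[i] + 1L,
          aln$mapq[i], paste0(nchar(seq), "M"), "*", 0, 0, seq, "*",
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Chi-square survival oracles (closed forms, independent of pchisq) ---------

chisq_sf_df1 <- function(x) 2 * (1 - pnorm(sqrt(x)))
chisq_sf_df2 <- function(x) exp(-x / 2)
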