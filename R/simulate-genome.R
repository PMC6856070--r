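# Synthetic genome and gene annotation.

#' Generate a random toy genome
#'
#' Draws each chromosome as an i.i.d. uniform sequence over A/C/G/T.  Output
#' is deterministic for a given \code{params$seed}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return A named \link[Biostrings]{DNAStringSet} (chromosomes
#'   \code{chr1..chrN}).
#' @examples
#' g <- generate_genome(sim_params(n_chrom = 1, chrom_length = 1000))
#' width(g)
#' @export
generate_genome <- function(params) {
  check(inherits(params, "sim_params"), "params must come from sim_params()")
  with_seed(params$seed, {
    seqs <- vapply(seq_len(params$n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), params$chrom_length,
                   replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(params$n_chrom))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Write a genome to FASTA
#'
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, format = "fasta")
  invisible(path)
}

# Gap kept around every gene so that 2-kb downstream (Edi) regions and
# sense windows of neighbouring genes can never overlap.
GENE_FLANK <- 2500L

#' Generate a toy gene annotation
#'
#' Places \code{params$n_genes} single-transcript genes on the genome with
#' random strands, 2-4 exons (lengths 150-350 nt) separated by introns of
#' 200-500 nt, and an inter-gene gap of at least 2.5 kb so every gene's
#' 2-kb downstream flank is unambiguous.  Internal coordinates are 0-based
#' half-open; \code{tss}/\code{tes} are the first/last transcribed base in
#' genomic coordinates, strand-aware.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} from
#'   \code{\link{generate_genome}}.
#' @param params a \code{\link{sim_params}} object.
#' @return An object of class \code{gene_models}: a list with data frames
#'   \code{$transcripts} (tx_id, gene_id, chrom, strand, start, end, tss,
#'   tes) and \code{$exons} (tx_id, exon_rank, start, end).
#' @export
generate_annotation <- function(genome, params) {
  check(inherits(params, "sim_params"), "params must come from sim_params()")
  check(length(genome) >= 1, "genome must be non-empty")
  lens <- Biostrings::width(genome)
  with_seed(params$seed + 1L, {
    tx <- list(); ex <- list()
    chrom_i <- 1L
    cursor <- GENE_FLANK
    placed <- 0L
    while (placed < params$n_genes) {
      n_ex <- sample(seq(params$exons_per_gene[1], params$exons_per_gene[2]), 1L)
      exon_len <- sample(150:350, n_ex, replace = TRUE)
      intron_len <- if (n_ex > 1L) sample(200:500, n_ex - 1L, replace = TRUE)
                    else integer(0)
      span <- sum(exon_len) + sum(intron_len)
      # advance to next chromosome when this one is full
      while (chrom_i <= length(genome) &&
             cursor + span + GENE_FLANK > lens[chrom_i]) {
        chrom_i <- chrom_i + 1L
        cursor <- GENE_FLANK
      }
      if (chrom_i > length(genome)) {
        stop("genome too small: placed only ", placed, " of ",
             params$n_genes, " genes", call. = FALSE)
      }
      placed <- placed + 1L
      strand <- sample(c("+", "-"), 1L)
      starts <- cursor + c(0L, cumsum(exon_len + c(intron_len, 0L)))[seq_len(n_ex)]
      ends <- starts + exon_len
      gid <- sprintf("g%04d", placed)
      tid <- sprintf("t%04d", placed)
      tx[[placed]] <- data.frame(
        tx_id = tid, gene_id = gid, chrom = names(genome)[chrom_i],
        strand = strand, start = starts[1], end = ends[n_ex],
        tss = if (strand == "+") starts[1] else ends[n_ex] - 1L,
        tes = if (strand == "+") ends[n_ex] - 1L else starts[1],
        stringsAsFactors = FALSE)
      ex[[placed]] <- data.frame(
        tx_id = tid, exon_rank = seq_len(n_ex),
        start = starts, end = ends, stringsAsFactors = FALSE)
      cursor <- ends[n_ex] + GENE_FLANK
    }
    structure(list(transcripts = do.call(rbind, tx),
                   exons = do.call(rbind, ex)),
              class = "gene_models")
  })
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d transcript(s), %d exon(s) on %d chromosome(s)\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon features with ID/Parent links.  Internal
#' 0-based half-open coordinates are converted to the 1-based closed GFF3
#' convention on output.
#'
#' @param genes a \code{gene_models} object.
#' @param path output GFF3 path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  check(inherits(genes, "gene_models"), "genes must be a gene_models object")
  tx <- genes$transcripts
  ex <- genes$exons
  ex_tx <- tx[match(ex$tx_id, tx$tx_id), ]
  gr <- GenomicRanges::GRanges(
    seqnames = c(tx$chrom, tx$chrom, ex_tx$chrom),
    ranges = IRanges::IRanges(
      start = c(tx$start, tx$start, ex$start) + 1L,
      end = c(tx$end, tx$end, ex$end)),
    strand = c(tx$strand, tx$strand, ex_tx$strand))
  n_tx <- nrow(tx)
  S4Vectors::mcols(gr)$type <- c(rep("gene", n_tx), rep("mRNA", n_tx),
                                 rep("exon", nrow(ex)))
  S4Vectors::mcols(gr)$ID <- c(tx$gene_id, tx$tx_id,
                               sprintf("%s.e%d", ex$tx_id, ex$exon_rank))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    c(replicate(n_tx, character(0), simplify = FALSE),
      as.list(tx$gene_id), as.list(ex$tx_id)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon features, groups exons per transcript and converts
#' the 1-based closed GFF3 coordinates to the package's 0-based half-open
#' internal convention.  Transcript features may be typed \code{mRNA} or
#' \code{transcript}.
#'
#' @param path a GFF3 file.
#' @return A \code{gene_models} object (see \code{\link{generate_annotation}}).
#' @export
load_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    warning("empty GFF3: ", path)
    return(structure(list(
      transcripts = data.frame(tx_id = character(0), gene_id = character(0),
                               chrom = character(0), strand = character(0),
                               start = integer(0), end = integer(0),
                               tss = integer(0), tes = integer(0)),
      exons = data.frame(tx_id = character(0), exon_rank = integer(0),
                         start = integer(0), end = integer(0))),
      class = "gene_models"))
  }
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_ex <- type == "exon"
  tx_gr <- gr[is_tx]
  ex_gr <- gr[is_ex]
  parent_of <- function(g) {
    if (is.null(g$Parent)) return(rep(NA_character_, length(g)))
    vapply(g$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  }
  tx_parent <- parent_of(tx_gr)
  ex_parent <- parent_of(ex_gr)
  if (any(is.na(ex_parent))) {
    stop("exon feature(s) without a Parent transcript at index ",
         paste(which(is.na(ex_parent)), collapse = ", "), call. = FALSE)
  }
  tx_id <- as.character(tx_gr$ID)
  bad <- !(ex_parent %in% tx_id)
  if (any(bad)) {
    stop("exon Parent(s) not matching any transcript: ",
         paste(unique(ex_parent[bad]), collapse = ", "), call. = FALSE)
  }
  strand <- as.character(BiocGenerics::strand(tx_gr))
  start0 <- BiocGenerics::start(tx_gr) - 1L
  end0 <- BiocGenerics::end(tx_gr)
  tx <- data.frame(
    tx_id = tx_id,
    gene_id = ifelse(is.na(tx_parent), tx_id, tx_parent),
    chrom = as.character(GenomicRanges::seqnames(tx_gr)),
    strand = strand,
    start = start0, end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    tes = ifelse(strand == "+", end0 - 1L, start0),
    stringsAsFactors = FALSE)
  ex <- data.frame(tx_id = ex_parent,
                   start = BiocGenerics::start(ex_gr) - 1L,
                   end = BiocGenerics::end(ex_gr),
                   stringsAsFactors = FALSE)
  ex <- ex[order(match(ex$tx_id, tx$tx_id), ex$start), ]
  ex$exon_rank <- unlist(lapply(split(ex$tx_id, factor(ex$tx_id,
                                levels = unique(ex$tx_id))), seq_along),
                         use.names = FALSE)
  ex <- ex[, c("tx_id", "exon_rank", "start", "end")]
  rownames(tx) <- rownames(ex) <- NULL
  structure(list(transcripts = tx, exons = ex), class = "gene_models")
}
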