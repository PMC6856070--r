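# Mapping trimmed reads and extracting polyadenylation-adjacent sites.

#' Exact-match mapping of a single read
#'
#' Desk-scale stand-in for a production aligner: searches the read and its
#' reverse complement as exact substrings of every chromosome.  A read is
#' reported only when exactly one location matches (unique, MAPQ fixed at
#' 60 by convention); zero matches return an unmapped record, more than one
#' a multi-mapped record.
#'
#' @param sequence a single read sequence (character, length \eqn{\ge} 16).
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @return one-row data frame with columns read_id (NA here), chrom,
#'   strand (alignment strand), start, end (0-based half-open), mapq,
#'   status (one of \code{mapped}, \code{unmapped}, \code{multi}); chrom
#'   and coordinates are NA unless \code{status == "mapped"}.
#' @examples
#' g <- generate_genome(sim_params(n_chrom = 1, chrom_length = 5000, seed = 3))
#' r <- as.character(Biostrings::subseq(g[[1]], 1001, 1040))
#' naive_map(r, g)
#' @export
naive_map <- function(sequence, genome) {
  check(is.character(sequence) && length(sequence) == 1L,
        "sequence must be a single character string")
  check(nchar(sequence) >= 16, "naive_map expects reads of at least 16 nt")
  pat <- Biostrings::DNAString(sequence)
  rc <- Biostrings::reverseComplement(pat)
  hits <- list()
  for (ci in seq_along(genome)) {
    for (st in c("+", "-")) {
      m <- Biostrings::matchPattern(if (st == "+") pat else rc, genome[[ci]])
      if (length(m) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = names(genome)[ci], strand = st,
          start = BiocGenerics::start(m) - 1L,
          end = BiocGenerics::end(m), stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else NULL
  n <- if (is.null(hits)) 0L else nrow(hits)
  if (n == 1L) {
    data.frame(read_id = NA_character_, chrom = hits$chrom,
               strand = hits$strand, start = hits$start, end = hits$end,
               mapq = 60L, status = "mapped", stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = NA_character_, chrom = NA_character_,
               strand = NA_character_, start = NA_integer_, end = NA_integer_,
               mapq = NA_integer_,
               status = if (n == 0L) "unmapped" else "multi",
               stringsAsFactors = FALSE)
  }
}

#' Exact-match mapping of many reads
#'
#' Vectorized front end to \code{\link{naive_map}}: mapping is computed once
#' per unique sequence and broadcast to all reads sharing it.
#'
#' @param reads data frame with read_id, sequence (qualities ignored).
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @return list with \code{$alignments} (data frame read_id, chrom, strand,
#'   start, end, mapq for uniquely mapped reads) and tallies
#'   \code{$n_unmapped}, \code{$n_multi}.
#' @export
map_reads <- function(reads, genome, .lookup = NULL) {
  check(is.data.frame(reads) && all(c("read_id", "sequence") %in% names(reads)),
        "reads must have read_id and sequence columns")
  if (is.null(.lookup)) {
    useq <- unique(reads$sequence)
    per_seq <- do.call(rbind, lapply(useq, naive_map, genome = genome))
  } else {
    useq <- .lookup$useq
    per_seq <- .lookup$per_seq
    check(all(reads$sequence %in% useq), "lookup table incomplete")
  }
  idx <- match(reads$sequence, useq)
  res <- per_seq[idx, , drop = FALSE]
  res$read_id <- reads$read_id
  rownames(res) <- NULL
  mapped <- res[res$status == "mapped",
                c("read_id", "chrom", "strand", "start", "end", "mapq"),
                drop = FALSE]
  rownames(mapped) <- NULL
  list(alignments = mapped,
       n_unmapped = sum(res$status == "unmapped"),
       n_multi = sum(res$status == "multi"))
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
.cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    toks <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

.cigar_lead_clip <- function(cigar) {
  m <- regmatches(cigar, regexpr("^\\d+S", cigar))
  out <- integer(length(cigar))
  has <- lengths(regmatches(cigar, gregexpr("^\\d+S", cigar))) > 0
  out[has] <- as.integer(sub("S$", "", regmatches(cigar, regexpr("^\\d+S", cigar))))
  out
}

#' Read alignments from a SAM/BAM file
#'
#' Ingestion path for external aligner output.  Keeps primary mapped
#' records only (unmapped, secondary and supplementary alignments are
#' dropped), converts the 1-based SAM POS to the package's 0-based
#' half-open convention, computes the reference end from the CIGAR and
#' carries MAPQ through.  The alignment start is the first \emph{aligned}
#' base: soft-clipped leading bases are ignored (a message is emitted when
#' more than 3 nt are clipped).
#'
#' @param path SAM or BAM file with \code{@SQ} headers.
#' @param sample_id optional sample label attached to every alignment.
#' @return data frame with read_id, chrom, strand, start, end, mapq (and
#'   sample_id when given).
#' @export
read_sam <- function(path, sample_id = NULL) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else tryCatch(
           Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE),
           error = function(e) stop("SAM format error in '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !bitwAnd(rec$flag, 0x4) & !bitwAnd(rec$flag, 0x100) &
    !bitwAnd(rec$flag, 0x800)
  if (!any(keep)) {
    warning("no primary mapped alignments in ", path)
    out <- data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mapq = integer(0))
    if (!is.null(sample_id)) out$sample_id <- character(0)
    return(out)
  }
  cigar <- rec$cigar[keep]
  clip <- .cigar_lead_clip(cigar)
  if (any(clip > 3)) {
    message(sum(clip > 3), " alignment(s) with > 3 nt of leading soft ",
            "clipping; site taken at the first aligned base")
  }
  start0 <- rec$pos[keep] - 1L
  out <- data.frame(
    read_id = rec$qname[keep],
    chrom = as.character(rec$rname[keep]),
    strand = as.character(rec$strand[keep]),
    start = start0,
    end = start0 + .cigar_ref_width(cigar),
    mapq = rec$mapq[keep],
    stringsAsFactors = FALSE)
  if (!is.null(sample_id)) out$sample_id <- sample_id
  rownames(out) <- NULL
  out
}

#' Polyadenylation-adjacent sites from alignments
#'
#' The site is the genomic coordinate of the read's first (5') base:
#' \code{start} for a + alignment, \code{end - 1} for a - alignment.  Under
#' the default \code{antisense} orientation (first-strand cDNA chemistry:
#' the leading poly-T is the complement of the poly(A) tail, so the read is
#' antisense to the mRNA) the site strand is the \emph{opposite} of the
#' alignment strand; \code{sense} keeps the alignment strand.
#'
#' @param alignments data frame from \code{\link{map_reads}} or
#'   \code{\link{read_sam}} (columns chrom, strand, start, end, mapq,
#'   read_id, optionally sample_id).
#' @param orientation \code{"antisense"} (default) or \code{"sense"}.
#' @return data frame of sites: chrom, position (0-based), strand (site
#'   strand), read_id, sample_id (if present), mapq.
#' @export
pas_from_alignments <- function(alignments,
                                orientation = c("antisense", "sense")) {
  orientation <- match.arg(orientation)
  check(all(c("chrom", "strand", "start", "end", "mapq") %in%
              names(alignments)),
        "alignments must have chrom, strand, start, end, mapq")
  pos <- ifelse(alignments$strand == "+", alignments$start,
                alignments$end - 1L)
  st <- if (orientation == "antisense") {
    ifelse(alignments$strand == "+", "-", "+")
  } else {
    alignments$strand
  }
  out <- data.frame(chrom = alignments$chrom, position = as.integer(pos),
                    strand = st, read_id = alignments$read_id,
                    mapq = alignments$mapq, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(alignments)) out$sample_id <- alignments$sample_id
  rownames(out) <- NULL
  out
}

#' Extract sites for every sample of a simulation or FASTQ set
#'
#' Maps each sample's preprocessed reads with \code{\link{map_reads}} and
#' converts unique alignments to polyadenylation-adjacent sites.
#'
#' @param reads_by_sample named list of read data frames (post-trimming).
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @param orientation see \code{\link{pas_from_alignments}}.
#' @return list with \code{$sites} (data frame incl. sample_id) and
#'   \code{$report} (per-sample mapped/unmapped/multi tallies).
#' @export
sites_from_reads <- function(reads_by_sample, genome,
                             orientation = c("antisense", "sense")) {
  orientation <- match.arg(orientation)
  check(!is.null(names(reads_by_sample)),
        "reads_by_sample must be a named list")
  # identical read strings recur across samples (same site, same poly-T
  # length): map each unique sequence once and share the result
  useq <- unique(unlist(lapply(reads_by_sample, `[[`, "sequence"),
                        use.names = FALSE))
  lookup <- list(useq = useq,
                 per_seq = do.call(rbind, lapply(useq, naive_map,
                                                 genome = genome)))
  sites <- list(); rpt <- list()
  for (s in names(reads_by_sample)) {
    m <- map_reads(reads_by_sample[[s]], genome, .lookup = lookup)
    a <- m$alignments
    a$sample_id <- rep(s, nrow(a))
    sites[[s]] <- pas_from_alignments(a, orientation)
    rpt[[s]] <- data.frame(sample_id = s, n_mapped = nrow(a),
                           n_unmapped = m$n_unmapped, n_multi = m$n_multi,
                           stringsAsFactors = FALSE)
  }
  list(sites = do.call(rbind, c(sites, list(make.row.names = FALSE))),
       report = do.call(rbind, c(rpt, list(make.row.names = FALSE))))
}

#' Write sites as 6-column BED
#'
#' BED is 0-based half-open, so each site occupies
#' \code{[position, position + 1)}.  The name field stores
#' \code{sample_id:read_id}; the score field carries MAPQ.
#'
#' @param sites site data frame from \code{\link{pas_from_alignments}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  nm <- if ("sample_id" %in% names(sites)) {
    paste(sites$sample_id, sites$read_id, sep = ":")
  } else {
    sites$read_id
  }
  bed <- data.frame(sites$chrom, sites$position, sites$position + 1L,
                    nm, sites$mapq, sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column site BED written by \code{\link{write_sites_bed}}
#'
#' @param path BED path.
#' @return site data frame (chrom, position, strand, read_id, mapq,
#'   sample_id when encoded in the name field).
#' @export
read_sites_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  check(ncol(bed) >= 6, "expected 6-column BED")
  has_sample <- grepl(":", bed[[4]], fixed = TRUE)
  out <- data.frame(
    chrom = bed[[1]], position = as.integer(bed[[2]]),
    strand = bed[[6]],
    read_id = ifelse(has_sample, sub("^[^:]*:", "", bed[[4]]), bed[[4]]),
    mapq = as.integer(bed[[5]]), stringsAsFactors = FALSE)
  if (any(has_sample)) {
    out$sample_id <- ifelse(has_sample, sub(":.*$", "", bed[[4]]),
                            NA_character_)
  }
  out
}
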