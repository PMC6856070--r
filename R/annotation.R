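# Six-class genomic annotation of predicted APA sites.

#' Annotation parameters
#'
#' @param di_tolerance distance (nt) around the annotated 3' terminus
#'   within which a site is called distal (default 24, matching the
#'   clustering window; the source protocols leave this unstated).
#' @param edi_max maximum downstream distance (nt) for the extended-distal
#'   class (default 2000).
#' @param eex_min_intronic minimum intronic extent (nt) of a cluster span
#'   for the extended-exonic class (default 10).
#' @return An object of class \code{annot_params}.
#' @export
annot_params <- function(di_tolerance = 24L, edi_max = 2000L,
                         eex_min_intronic = 10L) {
  check(is_count(di_tolerance) && di_tolerance >= 0,
        "di_tolerance must be a non-negative integer")
  check(is_count(edi_max) && edi_max >= 0,
        "edi_max must be a non-negative integer")
  check(is_count(eex_min_intronic) && eex_min_intronic >= 0,
        "eex_min_intronic must be a non-negative integer")
  structure(list(di_tolerance = as.integer(di_tolerance),
                 edi_max = as.integer(edi_max),
                 eex_min_intronic = as.integer(eex_min_intronic)),
            class = "annot_params")
}

CONVENTIONAL_CODES <- c("Ex", "Di", "Edi")

# Class priority rank of one cluster against one sense transcript, or NA.
# rep_, span_lo, span_hi are 0-based base coordinates (span closed).
.sense_rank <- function(rep_, span_lo, span_hi, t, te, params) {
  # (1) distal: representative within di_tolerance of the 3' terminus
  if (abs(rep_ - t$tes) <= params$di_tolerance) return(1L)
  # (2) exonic: span entirely inside one exon
  if (any(te$start <= span_lo & span_hi <= te$end - 1L)) return(2L)
  # (3) extended exonic: span overlaps an exon and reaches >= eex_min
  #     nt into an adjacent intron
  ex_ov <- interval_overlap(span_lo, span_hi, te$start, te$end - 1L)
  if (any(ex_ov > 0) && nrow(te) >= 2L) {
    istart <- te$end[-nrow(te)]          # introns between consecutive exons
    iend <- te$start[-1L] - 1L
    in_ov <- interval_overlap(span_lo, span_hi, istart, iend)
    if (any(in_ov >= params$eex_min_intronic)) return(3L)
  }
  # (4) intronic: span entirely inside one intron
  if (nrow(te) >= 2L) {
    istart <- te$end[-nrow(te)]
    iend <- te$start[-1L] - 1L
    if (any(istart <= span_lo & span_hi <= iend)) return(4L)
  }
  # (5) extended distal: representative 1..edi_max nt downstream of the
  #     terminus, strand-aware
  down <- if (t$strand == "+") rep_ - t$tes else t$tes - rep_
  if (down >= 1 && down <= params$edi_max) return(5L)
  NA_integer_
}

#' Classify one predicted APA site
#'
#' Sense candidates are transcripts on the same strand as the site whose
#' strand-aware window (transcript span extended \code{edi_max} nt
#' downstream of the terminus) contains the representative.  Each candidate
#' is scored by priority: distal (Di, representative within
#' \code{di_tolerance} of the 3' terminus), exonic (Ex, cluster span inside
#' one exon), extended exonic (Eex, span overlapping an exon and reaching
#' at least \code{eex_min_intronic} nt into an adjacent intron), intronic
#' (In, span inside one intron), extended distal (Edi, representative
#' 1..\code{edi_max} nt downstream of the terminus).  The highest-priority
#' class achieved by any candidate wins; among candidates achieving it the
#' nearest terminus wins, ties broken lexicographically by transcript id.
#' When no sense assignment exists, the site is antisense (An) if its
#' representative falls inside an exon of an opposite-strand transcript;
#' otherwise it is unassigned (class and gene NA).
#'
#' @param chrom,strand,representative site coordinates (0-based).
#' @param span_start,span_end cluster member span (closed, 0-based);
#'   default to the representative for singleton clusters.
#' @param genes a \code{gene_models} object.
#' @param params an \code{\link{annot_params}} object.
#' @return one-row data frame: gene_id, transcript_id, class_code,
#'   conventional.
#' @export
classify_site <- function(chrom, strand, representative,
                          span_start = representative,
                          span_end = representative,
                          genes, params = annot_params()) {
  cl <- data.frame(cluster_id = "site", chrom = chrom, strand = strand,
                   representative = representative,
                   span_start = span_start, span_end = span_end,
                   stringsAsFactors = FALSE)
  res <- classify_all(cl, genes, params)$sites
  res[, c("gene_id", "transcript_id", "class_code", "conventional")]
}

#' Classify every predicted APA site
#'
#' Applies \code{\link{classify_site}}'s rules to each cluster and tallies
#' the class codes.  Accepts an \code{apa_clusters} object or any data
#' frame with cluster_id, chrom, strand, representative, span_start,
#' span_end.
#'
#' @param clusters clusters to classify.
#' @param genes a \code{gene_models} object.
#' @param params an \code{\link{annot_params}} object.
#' @return list with \code{$sites} (data frame: cluster columns plus
#'   gene_id, transcript_id, class_code, conventional) and \code{$tally}
#'   (named counts over Ex, Di, Edi, Eex, In, An, unassigned).
#' @export
classify_all <- function(clusters, genes, params = annot_params()) {
  if (inherits(clusters, "apa_clusters")) clusters <- clusters$clusters
  check(is.data.frame(clusters) &&
          all(c("cluster_id", "chrom", "strand", "representative",
                "span_start", "span_end") %in% names(clusters)),
        paste("clusters must have cluster_id, chrom, strand,",
              "representative, span_start, span_end"))
  check(inherits(genes, "gene_models"), "genes must be a gene_models object")
  check(inherits(params, "annot_params"), "params must come from annot_params()")
  tx <- genes$transcripts
  ex_by_tx <- split(genes$exons, genes$exons$tx_id)

  n <- nrow(clusters)
  gene_id <- rep(NA_character_, n)
  tx_id <- rep(NA_character_, n)
  code <- rep(NA_character_, n)

  if (n > 0 && nrow(tx) > 0) {
    # strand-aware sense windows: transcript span + edi_max downstream
    win_lo <- ifelse(tx$strand == "+", tx$start, tx$start - params$edi_max)
    win_hi <- ifelse(tx$strand == "+", tx$end - 1L + params$edi_max,
                     tx$end - 1L)
    for (i in seq_len(n)) {
      rep_ <- clusters$representative[i]
      lo <- clusters$span_start[i]; hi <- clusters$span_end[i]
      cand <- which(tx$chrom == clusters$chrom[i] &
                      tx$strand == clusters$strand[i] &
                      win_lo <= rep_ & rep_ <= win_hi)
      if (length(cand) > 0) {
        ranks <- vapply(cand, function(ti)
          .sense_rank(rep_, lo, hi, tx[ti, ], ex_by_tx[[tx$tx_id[ti]]],
                      params), integer(1))
        ok <- !is.na(ranks)
        if (any(ok)) {
          best_rank <- min(ranks[ok])
          at <- cand[ok & ranks == best_rank]
          d <- abs(rep_ - tx$tes[at])
          at <- at[order(d, tx$tx_id[at])][1]
          gene_id[i] <- tx$gene_id[at]
          tx_id[i] <- tx$tx_id[at]
          code[i] <- c("Di", "Ex", "Eex", "In", "Edi")[best_rank]
          next
        }
      }
      # (6) antisense: representative inside an exon of an opposite-strand
      #     transcript
      anti <- which(tx$chrom == clusters$chrom[i] &
                      tx$strand != clusters$strand[i] &
                      tx$start <= rep_ & rep_ < tx$end)
      hit <- integer(0)
      for (ti in anti) {
        te <- ex_by_tx[[tx$tx_id[ti]]]
        if (any(te$start <= rep_ & rep_ < te$end)) hit <- c(hit, ti)
      }
      if (length(hit) > 0) {
        d <- abs(rep_ - tx$tes[hit])
        at <- hit[order(d, tx$tx_id[hit])][1]
        gene_id[i] <- tx$gene_id[at]
        tx_id[i] <- tx$tx_id[at]
        code[i] <- "An"
      }
    }
  }

  sites <- cbind(clusters,
                 data.frame(gene_id = gene_id, transcript_id = tx_id,
                            class_code = code,
                            conventional = ifelse(is.na(code), NA,
                                                  code %in% CONVENTIONAL_CODES),
                            stringsAsFactors = FALSE))
  rownames(sites) <- NULL
  tally <- c(table(factor(code, levels = CLASS_CODES)),
             unassigned = sum(is.na(code)))
  list(sites = sites, tally = tally)
}

#' Write classified sites and the class tally as TSV
#'
#' @param classified result of \code{\link{classify_all}}.
#' @param path output path for the site table; the tally goes to
#'   \code{<path>.tally.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_classified_tsv <- function(classified, path) {
  write.table(classified$sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tal <- data.frame(class_code = names(classified$tally),
                    n = as.integer(classified$tally))
  write.table(tal, paste0(path, ".tally.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
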