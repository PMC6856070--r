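# Single-linkage clustering of polyadenylation-adjacent sites.

#' Clustering parameters
#'
#' @param window maximum gap (nt) between adjacent member positions for two
#'   sites to join the same cluster (default 24, boundary inclusive: a gap
#'   of exactly 24 nt still chains).
#' @param min_total_reads expression cutoff: minimum total read count over
#'   all samples for a cluster to be kept (default 16, inclusive).
#' @return An object of class \code{cluster_params}.
#' @export
cluster_params <- function(window = 24L, min_total_reads = 16L) {
  check(is_count(window) && window >= 0, "window must be a non-negative integer")
  check(is_count(min_total_reads) && min_total_reads >= 1,
        "min_total_reads must be a positive integer")
  structure(list(window = as.integer(window),
                 min_total_reads = as.integer(min_total_reads)),
            class = "cluster_params")
}

#' Cluster polyadenylation-adjacent sites within a fixed window
#'
#' Within each (chromosome, strand), positions are partitioned by
#' single-linkage chaining: two positions share a cluster iff they are
#' connected by a chain of gaps each at most \code{window} nt.  This is
#' order-independent and equals connected components of the graph whose
#' edges join positions at most \code{window} nt apart.  Each cluster's
#' representative is its highest-count member position, ties broken by the
#' 3'-most position relative to the cluster strand (largest coordinate on
#' +, smallest on -).  Clusters are never split however long the chain
#' grows; spans above 200 nt trigger a warning.
#'
#' @param sites data frame with chrom, position, strand, sample_id and
#'   optionally mapq (from \code{\link{pas_from_alignments}}).
#' @param samples sample ordering for the count matrix; defaults to the
#'   sorted unique sample ids present.
#' @param params a \code{\link{cluster_params}} object.
#' @return An object of class \code{apa_clusters}: list with
#'   \code{$clusters} (data frame cluster_id, chrom, strand, representative,
#'   span_start, span_end, n_positions, total, mean_mapq), \code{$counts}
#'   (clusters x samples integer matrix) and \code{$samples}.  Output order
#'   is deterministic: chrom, strand, span start.
#' @examples
#' s <- data.frame(chrom = "chr1", position = c(100, 100, 110, 140),
#'                 strand = "+", sample_id = "s1", mapq = 60)
#' cluster_sites(s)$clusters
#' @export
cluster_sites <- function(sites, samples = NULL,
                          params = cluster_params()) {
  check(is.data.frame(sites) &&
          all(c("chrom", "position", "strand", "sample_id") %in% names(sites)),
        "sites must have chrom, position, strand, sample_id")
  if (!"mapq" %in% names(sites)) sites$mapq <- NA_real_
  if (is.null(samples)) samples <- sort(unique(sites$sample_id))
  check(all(sites$sample_id %in% samples),
        "sites carry sample ids absent from `samples`")

  if (nrow(sites) == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = character(0), chrom = character(0),
                            strand = character(0), representative = integer(0),
                            span_start = integer(0), span_end = integer(0),
                            n_positions = integer(0), total = integer(0),
                            mean_mapq = numeric(0)),
      counts = matrix(0L, 0, length(samples),
                      dimnames = list(NULL, samples)),
      samples = samples), class = "apa_clusters"))
  }

  ord <- order(sites$chrom, sites$strand, sites$position)
  s <- sites[ord, , drop = FALSE]
  grp <- paste(s$chrom, s$strand, sep = "\r")
  out <- list(); cm <- list()
  for (g in unique(grp)) {
    sg <- s[grp == g, , drop = FALSE]
    upos <- unique(sg$position)            # already sorted
    brk <- c(0L, which(diff(upos) > params$window), length(upos))
    cl_of_pos <- rep(seq_len(length(brk) - 1L),
                     times = diff(brk))
    names(cl_of_pos) <- as.character(upos)
    cl <- cl_of_pos[as.character(sg$position)]
    for (ci in unique(cl)) {
      sc <- sg[cl == ci, , drop = FALSE]
      pos_tot <- table(sc$position)
      best <- as.integer(names(pos_tot)[pos_tot == max(pos_tot)])
      repr <- if (sc$strand[1] == "+") max(best) else min(best)
      cnt <- table(factor(sc$sample_id, levels = samples))
      out[[length(out) + 1L]] <- data.frame(
        chrom = sc$chrom[1], strand = sc$strand[1],
        representative = repr,
        span_start = min(sc$position), span_end = max(sc$position),
        n_positions = length(pos_tot), total = nrow(sc),
        mean_mapq = mean(sc$mapq), stringsAsFactors = FALSE)
      cm[[length(cm) + 1L]] <- as.integer(cnt)
    }
  }
  clusters <- do.call(rbind, out)
  counts <- do.call(rbind, cm)
  o <- order(clusters$chrom, clusters$strand, clusters$span_start)
  clusters <- clusters[o, , drop = FALSE]
  counts <- counts[o, , drop = FALSE]
  clusters <- cbind(cluster_id = sprintf("APA%05d", seq_len(nrow(clusters))),
                    clusters, stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  dimnames(counts) <- list(clusters$cluster_id, samples)
  wide <- clusters$span_end - clusters$span_start
  if (any(wide > 200)) {
    warning(sum(wide > 200), " cluster(s) span more than 200 nt")
  }
  structure(list(clusters = clusters, counts = counts, samples = samples),
            class = "apa_clusters")
}

#' @export
print.apa_clusters <- function(x, ...) {
  cat(sprintf("apa_clusters: %d cluster(s) x %d sample(s), %d read(s)\n",
              nrow(x$clusters), length(x$samples), sum(x$counts)))
  invisible(x)
}

#' Expression cutoff on clusters
#'
#' Keeps clusters whose total read count across all samples reaches
#' \code{min_total_reads} (boundary inclusive: a total of exactly 16 reads
#' is kept under the default).
#'
#' @param cl an \code{apa_clusters} object.
#' @param params a \code{\link{cluster_params}} object.
#' @return list with \code{$clusters} (filtered \code{apa_clusters}) and
#'   \code{$report} (n_in, n_kept, n_dropped).
#' @export
expression_filter <- function(cl, params = cluster_params()) {
  check(inherits(cl, "apa_clusters"), "cl must be an apa_clusters object")
  keep <- cl$clusters$total >= params$min_total_reads
  kept <- structure(list(clusters = cl$clusters[keep, , drop = FALSE],
                         counts = cl$counts[keep, , drop = FALSE],
                         samples = cl$samples), class = "apa_clusters")
  rownames(kept$clusters) <- NULL
  list(clusters = kept,
       report = list(n_in = length(keep), n_kept = sum(keep),
                     n_dropped = sum(!keep)))
}

#' Write the cluster table as TSV (counts appended as one column per sample)
#'
#' @param cl an \code{apa_clusters} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clusters_tsv <- function(cl, path) {
  check(inherits(cl, "apa_clusters"), "cl must be an apa_clusters object")
  df <- cbind(cl$clusters, as.data.frame(cl$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
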