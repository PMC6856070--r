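# Read filtration: quality filter, leading poly-T trim, length filter.

#' Preprocessing parameters
#'
#' @param qual_threshold Phred score a base must reach to count as reliable
#'   (default 10, i.e. 90\% base-call accuracy).
#' @param qual_fraction minimum fraction of bases at or above
#'   \code{qual_threshold} for a read to pass (default 0.5; the boundary is
#'   inclusive).
#' @param min_length minimum read length after poly-T trimming (default 16,
#'   inclusive).
#' @return An object of class \code{preprocess_params}.
#' @export
preprocess_params <- function(qual_threshold = 10L, qual_fraction = 0.5,
                              min_length = 16L) {
  check(is.numeric(qual_threshold) && qual_threshold >= 0,
        "qual_threshold must be a non-negative Phred score")
  check(is.numeric(qual_fraction) && qual_fraction > 0 && qual_fraction <= 1,
        "qual_fraction must be in (0, 1]")
  check(is_count(min_length) && min_length >= 1,
        "min_length must be a positive integer")
  structure(list(qual_threshold = qual_threshold,
                 qual_fraction = qual_fraction,
                 min_length = as.integer(min_length)),
            class = "preprocess_params")
}

# Phred scores per read from Phred+33 quality strings, as an IntegerList.
.phred_scores <- function(quality) {
  methods::as(Biostrings::PhredQuality(Biostrings::BStringSet(quality)),
              "IntegerList")
}

#' Quality filter on raw reads
#'
#' A read passes when the fraction of bases with Phred quality at or above
#' \code{qual_threshold} is at least \code{qual_fraction} (exactly the
#' boundary passes).  'N' bases count as failing regardless of their stated
#' quality.
#'
#' @param reads data frame with columns \code{read_id}, \code{sequence},
#'   \code{quality} (Phred+33 strings, same length as the sequence).
#' @param params a \code{\link{preprocess_params}} object.
#' @return logical vector, one element per read.
#' @examples
#' r <- data.frame(read_id = "r1", sequence = strrep("A", 20),
#'                 quality = paste0(strrep("I", 10), strrep("#", 10)))
#' quality_pass(r, preprocess_params())  # exactly 50% good: TRUE
#' @export
quality_pass <- function(reads, params = preprocess_params()) {
  .check_reads(reads)
  check(all(nchar(reads$sequence) > 0), "quality_pass: empty read")
  scores <- .phred_scores(reads$quality)
  good <- sum(scores >= params$qual_threshold)
  len <- lengths(scores)
  hasN <- grepl("N", reads$sequence, fixed = TRUE)
  for (i in which(hasN)) {
    npos <- gregexpr("N", reads$sequence[i], fixed = TRUE)[[1]]
    good[i] <- good[i] - sum(scores[[i]][npos] >= params$qual_threshold)
  }
  good / len >= params$qual_fraction
}

#' Trim the leading thymine run
#'
#' Removes the maximal prefix run of exact 'T' from the sequence and the
#' corresponding bases from the quality string; read ids are unchanged.
#' All-T reads become empty (and are removed later by the length filter).
#'
#' @inheritParams quality_pass
#' @return the reads data frame, trimmed.
#' @examples
#' r <- data.frame(read_id = "r1", sequence = "TTTTTACGTACGTACGTACG",
#'                 quality = strrep("I", 20))
#' trim_leading_t(r)$sequence
#' @export
trim_leading_t <- function(reads) {
  .check_reads(reads)
  ntrim <- attr(regexpr("^T*", reads$sequence), "match.length")
  reads$sequence <- substring(reads$sequence, ntrim + 1L)
  reads$quality <- substring(reads$quality, ntrim + 1L)
  reads
}

#' Post-trim length filter
#'
#' @inheritParams quality_pass
#' @return logical vector: TRUE when the (trimmed) read is at least
#'   \code{min_length} nt (16-nt boundary kept).
#' @export
length_pass <- function(reads, params = preprocess_params()) {
  .check_reads(reads)
  nchar(reads$sequence) >= params$min_length
}

.check_reads <- function(reads) {
  check(is.data.frame(reads) &&
          all(c("read_id", "sequence", "quality") %in% names(reads)),
        "reads must be a data frame with read_id, sequence, quality")
  check(all(nchar(reads$sequence) == nchar(reads$quality)),
        "sequence and quality lengths differ")
}

#' Preprocess reads in memory
#'
#' Applies the three filtration rules in order: quality filter on the raw
#' read, leading poly-T trimming, then the post-trim length filter.
#' Surviving reads keep their input order.
#'
#' @inheritParams quality_pass
#' @return list with \code{$reads} (the kept, trimmed reads) and
#'   \code{$report}, a \code{preprocess_report} with tallies n_input,
#'   n_failed_quality, n_trimmed (reads that lost at least one leading T),
#'   n_failed_length and n_kept; always
#'   \code{n_input == n_failed_quality + n_failed_length + n_kept}.
#' @export
preprocess_reads <- function(reads, params = preprocess_params()) {
  .check_reads(reads)
  n_input <- nrow(reads)
  if (n_input == 0) {
    report <- structure(list(n_input = 0L, n_failed_quality = 0L,
                             n_trimmed = 0L, n_failed_length = 0L,
                             n_kept = 0L), class = "preprocess_report")
    return(list(reads = reads, report = report))
  }
  qok <- quality_pass(reads, params)
  surv <- reads[qok, , drop = FALSE]
  pre_len <- nchar(surv$sequence)
  surv <- trim_leading_t(surv)
  n_trimmed <- sum(nchar(surv$sequence) < pre_len)
  lok <- length_pass(surv, params)
  kept <- surv[lok, , drop = FALSE]
  rownames(kept) <- NULL
  report <- structure(list(
    n_input = n_input,
    n_failed_quality = sum(!qok),
    n_trimmed = n_trimmed,
    n_failed_length = sum(!lok),
    n_kept = nrow(kept)), class = "preprocess_report")
  list(reads = kept, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(paste0("preprocess: %d read(s) in, %d failed quality, ",
                     "%d trimmed, %d failed length, %d kept\n"),
              x$n_input, x$n_failed_quality, x$n_trimmed,
              x$n_failed_length, x$n_kept))
  invisible(x)
}

#' Preprocess a FASTQ file
#'
#' Reads Phred+33 FASTQ (optionally gzipped), applies
#' \code{\link{preprocess_reads}}, writes the surviving trimmed reads to
#' \code{path_out} in input order and returns the tally report.
#'
#' @param path_in input FASTQ path.
#' @param path_out output FASTQ path.
#' @param params a \code{\link{preprocess_params}} object.
#' @return a \code{preprocess_report} (invisibly carries no file handles).
#' @export
preprocess_fastq <- function(path_in, path_out,
                             params = preprocess_params()) {
  reads <- read_fastq(path_in)
  res <- preprocess_reads(reads, params)
  write_fastq(res$reads, path_out)
  res$report
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path (Phred+33; may be gzipped).
#' @return data frame with read_id, sequence, quality.
#' @export
read_fastq <- function(path) {
  out <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    data.frame(read_id = sub(" .*$", "", names(x)),
               sequence = as.character(x),
               quality = as.character(S4Vectors::mcols(x)$qualities),
               stringsAsFactors = FALSE, row.names = NULL)
  }, error = function(e) {
    stop("FASTQ parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  bad <- which(nchar(out$sequence, type = "bytes") !=
                 nchar(out$quality, type = "bytes"))
  if (length(bad)) {
    stop("FASTQ parse error in '", path, "': sequence/quality length ",
         "mismatch at record ", bad[1], call. = FALSE)
  }
  out
}

#' Write a reads data frame to FASTQ
#'
#' @param reads data frame with read_id, sequence, quality.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  .check_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}
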