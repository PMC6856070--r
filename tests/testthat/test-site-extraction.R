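# Mapping and polyadenylation-adjacent site extraction.

test_that("exact-match mapping finds unique hits on both strands", {
  g <- generate_genome(sim_params(n_chrom = 1L, chrom_length = 20000L,
                                  n_sites = 6L, seed = 13L))
  fwd <- as.character(Biostrings::subseq(g[[1]], 1001, 1040))  # 0-based 1000..1039
  a <- naive_map(fwd, g)
  expect_identical(a$status, "mapped")
  expect_identical(a[, c("chrom", "strand", "start", "end", "mapq")],
                   data.frame(chrom = "chr1", strand = "+", start = 1000L,
                              end = 1040L, mapq = 60L))

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(g[[1]], 1001, 1040)))
  b <- naive_map(rc, g)
  expect_identical(b$strand, "-")
  expect_identical(c(b$start, b$end), c(1000L, 1040L))

  expect_identical(naive_map(strrep("AC", 10), g)$status, "unmapped")
})

test_that("ambiguous reads are dropped and tallied as multi-mapped", {
  seg <- strrep("ACGTTGCA", 5)  # 40-mer planted twice
  pad1 <- paste(rep("G", 100), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(pad1, seg, pad1, seg, pad1)))
  expect_identical(naive_map(seg, genome)$status, "multi")
  m <- map_reads(make_reads(c(seg, seg)), genome)
  expect_identical(nrow(m$alignments), 0L)
  expect_identical(m$n_multi, 2L)
})

test_that("site extraction follows the first-base and antisense conventions", {
  aln <- data.frame(read_id = c("a", "b"), chrom = "chr1",
                    strand = c("+", "-"), start = c(1000L, 1000L),
                    end = c(1040L, 1040L), mapq = 60L,
                    stringsAsFactors = FALSE)
  s <- pas_from_alignments(aln)
  expect_identical(s$position, c(1000L, 1039L))
  expect_identical(s$strand, c("-", "+"))
  s2 <- pas_from_alignments(aln, orientation = "sense")
  expect_identical(s2$strand, c("+", "-"))
  expect_identical(s2$position, s$position)
})

test_that("SAM ingestion converts coordinates, strands and flags correctly", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 500)))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:2000",
    paste("r_fwd", 0, "chr1", 1001, 60, "40M", "*", 0, 0,
          strrep("ACGT", 10), "*", sep = "\t"),
    paste("r_rev", 16, "chr1", 1001, 70, "40M", "*", 0, 0,
          strrep("ACGT", 10), "*", sep = "\t"),
    paste("r_sec", 256, "chr1", 1101, 0, "40M", "*", 0, 0,
          strrep("ACGT", 10), "*", sep = "\t"),
    paste("r_clip", 0, "chr1", 1201, 60, "5S35M", "*", 0, 0,
          strrep("ACGT", 10), "*", sep = "\t"),
    paste("r_unmap", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("ACGT", 10), "*", sep = "\t")), sam)
  suppressMessages(aln <- read_sam(sam, sample_id = "s1"))
  expect_identical(aln$read_id, c("r_fwd", "r_rev", "r_clip"))
  expect_identical(aln$start, c(1000L, 1000L, 1200L))
  expect_identical(aln$end, c(1040L, 1040L, 1235L))  # 5S35M: 35 ref nt
  expect_identical(aln$strand, c("+", "-", "+"))
  expect_identical(aln$mapq, c(60L, 70L, 60L))
  expect_identical(unique(aln$sample_id), "s1")

  only_unmapped <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:2000",
               paste("u", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "*",
                     sep = "\t")), only_unmapped)
  expect_warning(out <- read_sam(only_unmapped), "no primary mapped")
  expect_identical(nrow(out), 0L)
})

test_that("SAM ingestion and the built-in mapper yield identical sites", {
  w <- small_world(seed = 21L)
  sim <- simulate_reads(w$genome, w$truth, w$params)
  reads <- preprocess_reads(sim$reads[[1]])$reads
  m <- map_reads(reads, w$genome)
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, w$genome, m$alignments, reads)
  aln2 <- read_sam(sam)
  a <- pas_from_alignments(m$alignments)
  b <- pas_from_alignments(aln2)
  o1 <- order(a$read_id); o2 <- order(b$read_id)
  expect_identical(a[o1, c("chrom", "position", "strand", "mapq")],
                   b[o2, c("chrom", "position", "strand", "mapq")],
                   ignore_attr = TRUE)
})

test_that("simulated error-free reads round-trip to their planted sites", {
  w <- small_world(seed = 17L)
  sim <- simulate_reads(w$genome, w$truth, w$params)
  kept <- lapply(sim$reads, function(r) preprocess_reads(r)$reads)
  ext <- sites_from_reads(kept, w$genome)
  expect_identical(sum(ext$report$n_unmapped), 0L)
  expect_identical(sum(ext$report$n_multi), 0L)

  planted <- unique(rbind(
    w$truth[, c("chrom", "strand", "position")],
    setNames(w$truth[!is.na(w$truth$satellite),
                     c("chrom", "strand", "satellite")],
             c("chrom", "strand", "position"))))
  got <- unique(ext$sites[, c("chrom", "strand", "position")])
  expect_setequal(paste(got$chrom, got$strand, got$position),
                  paste(planted$chrom, planted$strand, planted$position))

  # coordinate sanity: inside the chromosome
  expect_true(all(ext$sites$position >= 0))
  expect_true(all(ext$sites$position <
                    Biostrings::width(w$genome)[
                      match(ext$sites$chrom, names(w$genome))]))

  bed <- tempfile(fileext = ".bed")
  write_sites_bed(ext$sites, bed)
  back <- read_sites_bed(bed)
  expect_identical(back[, c("chrom", "position", "strand", "sample_id")],
                   ext$sites[, c("chrom", "position", "strand", "sample_id")],
                   ignore_attr = TRUE)
})
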