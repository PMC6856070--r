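# Synthetic-data generator: determinism, contracts, truth geometry and
# count moments.

test_that("genome generation is deterministic and respects its contract", {
  p <- sim_params(n_chrom = 2L, chrom_length = 50000L, seed = 7L)
  g1 <- generate_genome(p)
  g2 <- generate_genome(p)
  expect_identical(as.character(g1), as.character(g2))

  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(g1, f1); write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_length(g1, 2L)
  expect_true(all(Biostrings::width(g1) == 50000L))
  freq <- Biostrings::alphabetFrequency(g1)
  expect_true(all(rowSums(freq[, c("A", "C", "G", "T")]) == 50000L))
})

test_that("degenerate simulation parameters are rejected", {
  expect_error(sim_params(n_chrom = 0), "n_chrom")
  expect_error(sim_params(read_length = 20), "read_length")
  expect_error(sim_params(class_fractions = c(Ex = 0.5, Di = 0.2)),
               "sum to 1")
  expect_error(sim_params(polyT_range = c(0, 5)), "polyT_range")
})

test_that("annotation placement round-trips through GFF3 and is exon-consistent", {
  w <- small_world(seed = 3L)
  tx <- w$genes$transcripts
  expect_identical(nrow(tx), w$params$n_genes)
  expect_setequal(unique(tx$strand), c("+", "-"))

  # transcript bounds are the extreme exon boundaries
  for (i in seq_len(nrow(tx))) {
    te <- w$genes$exons[w$genes$exons$tx_id == tx$tx_id[i], ]
    expect_identical(min(te$start), tx$start[i])
    expect_identical(max(te$end), tx$end[i])
    expect_true(all(diff(te$start) > 0))
    expect_true(all(te$start[-1] >= te$end[-nrow(te)]))  # non-overlapping
  }

  gf <- tempfile(fileext = ".gff3")
  write_gff3(w$genes, gf)
  back <- load_gff(gf)
  expect_equal(back$transcripts[order(back$transcripts$tx_id), ],
               tx[order(tx$tx_id), ], ignore_attr = TRUE)
  expect_equal(back$exons[order(back$exons$tx_id, back$exons$start),
                          c("tx_id", "start", "end")],
               w$genes$exons[order(w$genes$exons$tx_id,
                                   w$genes$exons$start),
                             c("tx_id", "start", "end")],
               ignore_attr = TRUE)
})

test_that("an over-full genome triggers a placement error with the count placed", {
  p <- sim_params(n_chrom = 1L, chrom_length = 10000L, n_genes = 1000L,
                  n_sites = 6L)
  g <- generate_genome(p)
  expect_error(generate_annotation(g, p), "placed only \\d+ of 1000")
})

test_that("truth sites honour class quotas, geometry and spacing", {
  p <- sim_params(seed = 2L)   # 60 sites, 6 classes at 1/6
  genome <- generate_genome(p)
  genes <- generate_annotation(genome, p)
  truth <- plant_truth_sites(genes, p, genome)

  codes <- c("Ex", "Di", "Edi", "Eex", "In", "An")
  tally <- table(factor(truth$true_class, levels = codes))
  expect_true(all(tally == 10L))

  # extended-distal sites sit strictly downstream of their terminus,
  # within 2 kb
  tx <- genes$transcripts
  edi <- truth[truth$true_class == "Edi", ]
  for (i in seq_len(nrow(edi))) {
    t <- tx[tx$tx_id == edi$tx_id[i], ]
    down <- if (t$strand == "+") edi$position[i] - t$tes
            else t$tes - edi$position[i]
    expect_gt(down, 0)
    expect_lte(down, 2000)
  }

  # same-strand spacing below which clusters could merge never occurs
  pts <- rbind(truth[, c("chrom", "strand", "position")],
               setNames(truth[!is.na(truth$satellite),
                              c("chrom", "strand", "satellite")],
                        c("chrom", "strand", "position")))
  for (key in split(pts$position, paste(pts$chrom, pts$strand))) {
    d <- diff(sort(key))
    # representative/satellite pairs of one Eex site may be close; any
    # two distinct sites are >= 25 nt apart
    expect_true(all(d >= 10))
  }
  by_site <- split(truth$position, paste(truth$chrom, truth$strand))
  for (v in by_site) {
    if (length(v) > 1) expect_true(all(diff(sort(v)) >= 25))
  }
})

test_that("intronic sites cannot be requested from single-exon genes", {
  p <- sim_params(n_chrom = 1L, chrom_length = 60000L, n_genes = 6L,
                  exons_per_gene = c(1L, 1L), n_sites = 6L,
                  class_fractions = c(In = 1))
  genome <- generate_genome(p)
  genes <- generate_annotation(genome, p)
  expect_error(plant_truth_sites(genes, p, genome), "no introns exist")
})

test_that("simulated reads are deterministic and structurally faithful", {
  w <- small_world(seed = 9L)
  s1 <- simulate_reads(w$genome, w$truth, w$params)
  s2 <- simulate_reads(w$genome, w$truth, w$params)
  expect_identical(s1$reads, s2$reads)

  d1 <- tempfile(); d2 <- tempfile()
  write_sim(s1, d1); write_sim(s2, d2)
  f <- list.files(d1)
  expect_identical(lapply(file.path(d1, f), readLines),
                   lapply(file.path(d2, f), readLines))

  # every read is poly-T + the genome payload implied by its site
  rd <- s1$reads[[1]]
  origin <- sub(":.*$", "", rd$read_id)
  for (i in head(seq_len(nrow(rd)), 50)) {
    tr <- w$truth[w$truth$site_id == origin[i], ]
    seq <- rd$sequence[i]
    ntrim <- attr(regexpr("^T*", seq), "match.length")
    payload <- substring(seq, ntrim + 1L)
    plen <- nchar(payload)
    chrom <- w$genome[[tr$chrom]]
    pos_set <- c(tr$position, tr$satellite)
    ok <- FALSE
    for (pos in pos_set[!is.na(pos_set)]) {
      ref <- if (tr$strand == "+") {
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(chrom, pos - plen + 2L, pos + 1L)))
      } else {
        as.character(Biostrings::subseq(chrom, pos + 1L, pos + plen))
      }
      if (identical(ref, payload)) ok <- TRUE
    }
    expect_true(ok, label = paste("read", rd$read_id[i], "matches genome"))
  }
})

test_that("zero planted sites give empty outputs", {
  w <- small_world(seed = 4L)
  empty <- w$truth[0, ]
  sim <- simulate_reads(w$genome, empty, w$params, outdir = td <- tempfile())
  expect_true(all(vapply(sim$reads, nrow, integer(1)) == 0L))
  expect_identical(nrow(read.delim(file.path(td, "truth_sites.tsv"))), 0L)
  first_fastq <- file.path(td, paste0(sim$design$sample_id[1], ".fastq"))
  expect_identical(length(readLines(first_fastq)), 0L)
})

test_that("per-site read counts follow the negative-binomial moments", {
  w <- small_world(seed = 6L, n_sites = 6L)
  truth <- w$truth[1, , drop = FALSE]
  truth$base_mean <- 100
  mu <- 100; disp <- 0.05
  reps <- 100L
  counts <- numeric(0)
  for (r in seq_len(reps)) {
    p <- small_params(seed = 6L, n_sites = 6L)
    p$seed <- 20000L + r
    sim <- simulate_reads(w$genome, truth, p)
    counts <- c(counts, vapply(sim$reads, nrow, integer(1)))
  }
  n <- length(counts)                       # 16 samples x 100 replicates
  se <- sqrt((mu + disp * mu^2) / n)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # over-dispersion is visible: variance near mu + disp*mu^2 = 600, far
  # from the Poisson value 100
  expect_gt(var(counts), 2 * mu)
  expect_lt(abs(var(counts) - (mu + disp * mu^2)), 0.4 * (mu + disp * mu^2))
})
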