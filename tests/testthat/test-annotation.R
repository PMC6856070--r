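# Six-class annotation: GFF loading, the classification rules, priorities
# and symmetry properties.

test_that("GFF3 coordinates convert to the 0-based half-open convention", {
  gf <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1001\t2000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttoy\texon\t1001\t1200\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\ttoy\texon\t1501\t2000\t.\t+\t.\tID=t1.e2;Parent=t1"), gf)
  g <- load_gff(gf)
  expect_identical(g$exons$start, c(1000L, 1500L))
  expect_identical(g$exons$end, c(1200L, 2000L))
  expect_identical(g$transcripts$tes, 1999L)
  expect_identical(g$transcripts$gene_id, "g1")

  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_warning(e <- load_gff(empty), "empty GFF3")
  expect_identical(nrow(e$transcripts), 0L)

  orphan <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\texon\t1001\t1200\t.\t+\t.\tID=x1"), orphan)
  expect_error(load_gff(orphan), "without a Parent")
})

test_that("each class rule fires on the worked single-transcript geometry", {
  genes <- toy_genes()   # + strand, exons [1000,1200) & [1500,2000), tes 1999
  cls <- function(cl) classify_all(cl, genes)$sites$class_code
  expect_identical(cls(toy_cluster(1100L)), "Ex")
  expect_identical(cls(toy_cluster(1190L, 1190L, 1229L)), "Eex")  # 30 nt intronic
  expect_identical(cls(toy_cluster(1300L)), "In")
  expect_identical(cls(toy_cluster(1999L)), "Di")
  expect_identical(cls(toy_cluster(2500L)), "Edi")                # 501 nt downstream
  expect_identical(cls(toy_cluster(1100L, strand = "-")), "An")

  # below the 10-nt intronic minimum the span is neither Ex nor Eex nor In
  shallow <- classify_all(toy_cluster(1195L, 1195L, 1205L), genes)$sites
  expect_false(identical(shallow$class_code, "Eex"))

  # 2 kb downstream boundary: 2000 nt in, 2001 nt out
  expect_identical(cls(toy_cluster(1999L + 2000L)), "Edi")
  out <- classify_all(toy_cluster(1999L + 2001L), genes)$sites
  expect_true(is.na(out$class_code))
  expect_true(is.na(out$gene_id))
})

test_that("distal priority beats exonic and extended-distal alternatives", {
  genes <- toy_genes()
  # inside the last exon AND within 24 nt of the terminus -> Di, not Ex
  expect_identical(classify_all(toy_cluster(1980L), genes)$sites$class_code,
                   "Di")
  # 24 nt downstream of the terminus -> Di, never Edi
  expect_identical(classify_all(toy_cluster(2023L), genes)$sites$class_code,
                   "Di")
  expect_identical(classify_all(toy_cluster(2024L), genes)$sites$class_code,
                   "Edi")
})

test_that("antisense assignment requires failure of all sense candidates", {
  genes <- toy_genes()
  # a - strand site inside the intron of the + strand gene: no sense
  # transcript, not inside an exon -> unassigned, not An
  res <- classify_all(toy_cluster(1300L, strand = "-"), genes)$sites
  expect_true(is.na(res$class_code))
  # inside an exon -> An with the host gene attached
  res2 <- classify_all(toy_cluster(1100L, strand = "-"), genes)$sites
  expect_identical(res2$class_code, "An")
  expect_identical(res2$gene_id, "g1")
  expect_false(res2$conventional)
})

test_that("every cluster gets exactly one code and the conventional flag", {
  w <- small_world(seed = 8L)
  cls <- classify_all(clusters_from_truth(w$truth), w$genes)
  s <- cls$sites
  expect_identical(nrow(s), nrow(w$truth))
  expect_true(all(!is.na(s$class_code)))
  expect_identical(s$conventional,
                   s$class_code %in% c("Ex", "Di", "Edi"))
  expect_identical(sum(cls$tally), nrow(s))

  none <- classify_all(toy_cluster(100L, chrom = "chrZ"), w$genes)$sites
  expect_true(is.na(none$class_code))
})

test_that("planted truth geometry reproduces its class codes exactly", {
  for (seed in c(2L, 14L)) {
    p <- sim_params(seed = seed)
    genome <- generate_genome(p)
    genes <- generate_annotation(genome, p)
    truth <- plant_truth_sites(genes, p, genome)
    cls <- classify_all(clusters_from_truth(truth), genes)
    expect_identical(cls$sites$class_code, truth$true_class)
    expect_identical(cls$sites$gene_id, truth$gene_id)
  }
})

test_that("class codes are invariant under reverse-complement mirroring", {
  w <- small_world(seed = 19L)
  L <- w$params$chrom_length
  cl <- clusters_from_truth(w$truth)
  fwd <- classify_all(cl, w$genes)$sites$class_code
  rev <- classify_all(mirror_clusters(cl, L),
                      mirror_genes(w$genes, L))$sites$class_code
  expect_identical(rev, fwd)
})
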