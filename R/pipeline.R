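# End-to-end pipeline on simulated (or user-supplied) data.

#' Run the whole APA pipeline on a synthetic dataset
#'
#' Generates genome, annotation, truth sites and reads from \code{params},
#' then runs preprocessing, exact-match mapping, site extraction,
#' clustering with the expression cutoff, six-class annotation and (when
#' both conditions have at least two samples) differential testing.
#' Because the built-in mapper reports MAPQ 60 by convention, the default
#' differential parameters here set \code{mapq_min = 0}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param cl_params a \code{\link{cluster_params}} object.
#' @param an_params an \code{\link{annot_params}} object.
#' @param d_params a \code{\link{de_params}} object.
#' @param outdir optional directory for all intermediate files (FASTA,
#'   GFF3, FASTQ, site BED, cluster/classified/DE TSV).
#' @return list with every stage's output: genome, genes, truth, sim,
#'   preprocess (per-sample reports), sites, clusters (filtered),
#'   cluster_report, classified, de, categories, evaluation (truth
#'   comparison from \code{\link{evaluate_against_truth}}).
#' @export
apa_pipeline <- function(params = sim_params(),
                         cl_params = cluster_params(),
                         an_params = annot_params(),
                         d_params = de_params(mapq_min = 0),
                         outdir = NULL) {
  genome <- generate_genome(params)
  genes <- generate_annotation(genome, params)
  truth <- plant_truth_sites(genes, params, genome)
  sim <- simulate_reads(genome, truth, params, outdir = outdir)

  pp <- lapply(sim$reads, preprocess_reads)
  kept <- lapply(pp, `[[`, "reads")
  reports <- lapply(pp, `[[`, "report")

  ext <- sites_from_reads(kept, genome, orientation = "antisense")
  cl_all <- cluster_sites(ext$sites, samples = sim$design$sample_id,
                          params = cl_params)
  ef <- expression_filter(cl_all, cl_params)
  clusters <- ef$clusters

  classified <- classify_all(clusters, genes, an_params)

  de <- NULL; categories <- NULL
  if (all(table(sim$design$condition) >= 2)) {
    de <- run_de(clusters, sim$design$condition, params = d_params)
    if (de$summary$n_sig_adj > 0) {
      categories <- tryCatch(category_stats(de, classified),
                             error = function(e) NULL)
    }
  }

  evaluation <- evaluate_against_truth(clusters, classified, truth)

  if (!is.null(outdir)) {
    write_genome_fasta(genome, file.path(outdir, "genome.fasta"))
    write_gff3(genes, file.path(outdir, "annotation.gff3"))
    write_sites_bed(ext$sites, file.path(outdir, "sites.bed"))
    write_clusters_tsv(clusters, file.path(outdir, "clusters.tsv"))
    write_classified_tsv(classified, file.path(outdir, "classified.tsv"))
    if (!is.null(de)) write_de_tsv(de, file.path(outdir, "de.tsv"))
  }

  list(genome = genome, genes = genes, truth = truth, sim = sim,
       preprocess = reports, sites = ext$sites, mapping = ext$report,
       clusters = clusters, cluster_report = ef$report,
       classified = classified, de = de, categories = categories,
       evaluation = evaluation)
}

#' Compare recovered clusters and classes against planted truth
#'
#' Matches each truth site to the cluster containing its position (same
#' chromosome and strand, position within the cluster span extended by
#' nothing: exact containment) and scores representative and class
#' recovery.
#'
#' @param clusters an \code{apa_clusters} object.
#' @param classified result of \code{\link{classify_all}} on the same
#'   clusters.
#' @param truth a truth table from \code{\link{plant_truth_sites}}.
#' @return list with \code{$per_site} (truth joined with matched cluster,
#'   recovered representative and class), \code{$n_truth},
#'   \code{$n_clusters}, \code{$n_matched}, \code{$representative_accuracy}
#'   and \code{$class_accuracy} (fractions of truth sites whose cluster
#'   representative / class code equal the planted values).
#' @export
evaluate_against_truth <- function(clusters, classified, truth) {
  cdf <- classified$sites
  n <- nrow(truth)
  cluster_id <- rep(NA_character_, n)
  repr <- rep(NA_integer_, n)
  code <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- which(cdf$chrom == truth$chrom[i] &
                   cdf$strand == truth$strand[i] &
                   cdf$span_start <= truth$position[i] &
                   truth$position[i] <= cdf$span_end)
    if (length(hit) == 1) {
      cluster_id[i] <- cdf$cluster_id[hit]
      repr[i] <- cdf$representative[hit]
      code[i] <- cdf$class_code[hit]
      gene[i] <- cdf$gene_id[hit]
    }
  }
  per_site <- cbind(truth[, c("site_id", "chrom", "strand", "position",
                              "gene_id", "true_class")],
                    data.frame(cluster_id = cluster_id,
                               representative = repr,
                               class_code = code, matched_gene = gene,
                               stringsAsFactors = FALSE))
  matched <- !is.na(cluster_id)
  list(per_site = per_site,
       n_truth = n,
       n_clusters = nrow(cdf),
       n_matched = sum(matched),
       representative_accuracy = if (n) {
         mean(!is.na(repr) & repr == truth$position)
       } else NA_real_,
       class_accuracy = if (n) {
         mean(!is.na(code) & code == truth$true_class)
       } else NA_real_)
}
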