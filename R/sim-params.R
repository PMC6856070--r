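#' Simulation parameters for the synthetic WTTS-seq data generator
#'
#' Bundles and validates every knob of the synthetic-data module.  The
#' defaults define the reference study conditions used throughout the test
#' suite: 8 samples per condition, 60 planted APA sites spread evenly over
#' the six annotation classes, negative-binomial per-sample counts with mean
#' 60 and dispersion 0.05, error-free reads of 50 nt with a uniform 5-15 nt
#' leading poly-T tract.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length (nt) of every chromosome.
#' @param n_genes number of genes to place (one transcript per gene).
#' @param exons_per_gene integer range \code{c(min, max)} of exons per gene.
#'   At least 2 is required whenever intron-dependent classes (In, Eex) are
#'   requested.
#' @param n_sites total number of planted APA truth sites.
#' @param class_fractions named fractions over the six class codes
#'   \code{Ex, Di, Edi, Eex, In, An}; must sum to 1.
#' @param n_per_condition samples per condition (design is
#'   \code{n_per_condition} treated vs the same number of controls).
#' @param mean_count expected read count per site per sample (control
#'   baseline).
#' @param log2_effect log2 condition shift applied to sites selected as
#'   differential (treated mean = \code{mean_count * 2^log2_effect}).
#' @param de_fraction fraction of sites receiving the condition shift.
#' @param polyT_range integer range \code{c(min, max)} of leading poly-T
#'   lengths, each \eqn{\ge} 1.
#' @param read_length total read length (poly-T prefix included).
#' @param error_rate per-base substitution error rate in the genomic payload
#'   (never inside the poly-T prefix).
#' @param nb_dispersion negative-binomial dispersion \eqn{\alpha} of the
#'   per-site per-sample counts (variance \eqn{\mu + \alpha \mu^2}); 0 gives
#'   Poisson counts.
#' @param degrade_fraction fraction of reads emitted with uniformly low
#'   (Q2) base qualities, used to exercise the quality filter.
#' @param min_site_gap minimum distance (nt) enforced between planted sites
#'   on the same chromosome and strand; the default 25 keeps distinct truth
#'   sites from merging under the 24-nt clustering window.
#' @param seed integer seed fixing all randomness of the generator.
#'
#' @return An object of class \code{sim_params} (a validated list).
#' @examples
#' p <- sim_params(n_sites = 12, seed = 7)
#' p$class_fractions
#' @export
sim_params <- function(n_chrom = 2L,
                       chrom_length = 150000L,
                       n_genes = 24L,
                       exons_per_gene = c(2L, 4L),
                       n_sites = 60L,
                       class_fractions = c(Ex = 1/6, Di = 1/6, Edi = 1/6,
                                           Eex = 1/6, In = 1/6, An = 1/6),
                       n_per_condition = 8L,
                       mean_count = 60,
                       log2_effect = 0,
                       de_fraction = 0,
                       polyT_range = c(5L, 15L),
                       read_length = 50L,
                       error_rate = 0,
                       nb_dispersion = 0.05,
                       degrade_fraction = 0,
                       min_site_gap = 25L,
                       seed = 1L) {
  check(is_count(n_chrom) && n_chrom >= 1, "n_chrom must be a positive integer")
  check(is_count(chrom_length) && chrom_length >= 1,
        "chrom_length must be a positive integer")
  check(is_count(n_genes) && n_genes >= 1, "n_genes must be a positive integer")
  check(length(exons_per_gene) == 2L && all(exons_per_gene >= 1) &&
          exons_per_gene[1] <= exons_per_gene[2],
        "exons_per_gene must be an increasing positive integer range")
  check(is_count(n_sites) && n_sites >= 0, "n_sites must be a non-negative integer")
  classes <- c("Ex", "Di", "Edi", "Eex", "In", "An")
  check(!is.null(names(class_fractions)) &&
          all(names(class_fractions) %in% classes),
        "class_fractions must be named with codes among Ex, Di, Edi, Eex, In, An")
  full <- setNames(numeric(6), classes)
  full[names(class_fractions)] <- class_fractions
  check(all(full >= 0) && abs(sum(full) - 1) < 1e-8,
        "class_fractions must be non-negative and sum to 1")
  check(is_count(n_per_condition) && n_per_condition >= 1,
        "n_per_condition must be a positive integer")
  check(is.numeric(mean_count) && mean_count > 0, "mean_count must be positive")
  check(is.numeric(de_fraction) && de_fraction >= 0 && de_fraction <= 1,
        "de_fraction must be in [0, 1]")
  check(length(polyT_range) == 2L && all(polyT_range >= 1) &&
          polyT_range[1] <= polyT_range[2],
        "polyT_range must be an increasing integer range with minimum >= 1")
  check(is_count(read_length), "read_length must be an integer")
  if (read_length < 16 + polyT_range[2]) {
    stop("read_length (", read_length, ") must be at least 16 + the maximum ",
         "poly-T length (", polyT_range[2], "): shorter reads could never ",
         "survive preprocessing", call. = FALSE)
  }
  check(is.numeric(error_rate) && error_rate >= 0 && error_rate < 1,
        "error_rate must be in [0, 1)")
  check(is.numeric(nb_dispersion) && nb_dispersion >= 0,
        "nb_dispersion must be non-negative")
  check(is.numeric(degrade_fraction) && degrade_fraction >= 0 &&
          degrade_fraction <= 1, "degrade_fraction must be in [0, 1]")
  check(is_count(min_site_gap) && min_site_gap >= 1,
        "min_site_gap must be a positive integer")
  check(is_count(seed), "seed must be an integer")

  structure(list(
    n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    n_sites = as.integer(n_sites),
    class_fractions = full,
    n_per_condition = as.integer(n_per_condition),
    mean_count = mean_count,
    log2_effect = log2_effect,
    de_fraction = de_fraction,
    polyT_range = as.integer(polyT_range),
    read_length = as.integer(read_length),
    error_rate = error_rate,
    nb_dispersion = nb_dispersion,
    degrade_fraction = degrade_fraction,
    min_site_gap = as.integer(min_site_gap),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic WTTS-seq simulation parameters\n")
  cat(sprintf("  genome: %d chromosome(s) x %d nt, %d genes\n",
              x$n_chrom, x$chrom_length, x$n_genes))
  cat(sprintf("  sites: %d (%s)\n", x$n_sites,
              paste(sprintf("%s %.2f", names(x$class_fractions),
                            x$class_fractions), collapse = ", ")))
  cat(sprintf("  design: %d + %d samples, mean count %g, dispersion %g\n",
              x$n_per_condition, x$n_per_condition, x$mean_count,
              x$nb_dispersion))
  cat(sprintf("  reads: %d nt, poly-T %d-%d, error rate %g, seed %d\n",
              x$read_length, x$polyT_range[1], x$polyT_range[2],
              x$error_rate, x$seed))
  invisible(x)
}
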