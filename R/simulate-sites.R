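# Planting APA truth sites and simulating WTTS-seq-like reads.

CLASS_CODES <- c("Ex", "Di", "Edi", "Eex", "In", "An")

# Distance kept between an Ex/Di-adjacent placement and the transcript
# terminus so the distal tolerance (24 nt) cannot capture exonic sites.
DI_SAFE_GAP <- 25L

# Is the genomic base at 0-based `pos` compatible with exact site recovery?
# A site read's first payload base must not extend the leading poly-T run:
# on a + strand site the payload starts with the complement of genome[pos]
# (so genome[pos] must not be A); on a - strand site it starts with
# genome[pos] itself (so it must not be T).
.first_base_ok <- function(genome, chrom, pos, strand) {
  b <- as.character(Biostrings::subseq(genome[[chrom]], pos + 1L, pos + 1L))
  if (strand == "+") b != "A" else b != "T"
}

.too_close <- function(new_pos, existing, gap) {
  length(existing) > 0 && any(abs(outer(new_pos, existing, "-")) < gap)
}

# sample() treats a scalar first argument as 1:n; this picks uniformly
# from the elements of x regardless of its length.
.pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Largest-remainder apportionment of n among fractions (keeps exact totals).
.apportion <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Plant APA truth sites with known class geometry
#'
#' Places \code{params$n_sites} polyadenylation sites on the gene models so
#' that each site's geometry satisfies its class under the annotation rules
#' of \code{\link{classify_all}}: \code{Ex} inside an exon (away from the
#' terminus), \code{Di} at the 3' terminus, \code{Edi} 50-2000 nt downstream
#' of it, \code{In} inside an intron, \code{Eex} a representative inside an
#' exon plus a satellite position 10-15 nt into the adjacent intron (a
#' single position cannot "extend" across a boundary, so extended-exonic
#' truth sites are two-position clusters whose representative keeps ~70%
#' of the reads), and \code{An} inside an exon of an opposite-strand gene.
#' Same-strand sites are kept at least \code{params$min_site_gap} nt apart
#' so distinct truth sites can never merge under the clustering window, and
#' positions whose immediate downstream genomic base would extend the
#' poly-T run (making exact site recovery impossible) are resampled.
#'
#' @param genes a \code{gene_models} object.
#' @param params a \code{\link{sim_params}} object.
#' @param genome the \link[Biostrings]{DNAStringSet} the genes live on
#'   (needed for the poly-T boundary check).
#' @return A data frame of truth records: site_id, chrom, strand, position,
#'   satellite (NA except for Eex), gene_id, tx_id, true_class, base_mean,
#'   log2_effect, nb_dispersion.
#' @export
plant_truth_sites <- function(genes, params, genome) {
  check(inherits(genes, "gene_models"), "genes must be a gene_models object")
  check(inherits(params, "sim_params"), "params must come from sim_params()")
  tx <- genes$transcripts
  ex <- genes$exons
  n_per_class <- setNames(.apportion(params$class_fractions, params$n_sites),
                          CLASS_CODES)
  n_exons <- table(ex$tx_id)[tx$tx_id]
  multi <- tx$tx_id[n_exons >= 2]
  if ((n_per_class[["In"]] > 0 || n_per_class[["Eex"]] > 0) &&
      length(multi) == 0) {
    stop("intronic/extended-exonic sites requested but every gene is ",
         "single-exon: no introns exist", call. = FALSE)
  }

  with_seed(params$seed + 2L, {
    used <- new.env(parent = emptyenv())   # positions per chrom|strand
    recs <- list()
    k <- 0L
    gap <- params$min_site_gap

    register <- function(chrom, strand, pos_vec) {
      key <- paste(chrom, strand)
      cur <- if (exists(key, used)) get(key, used) else numeric(0)
      assign(key, c(cur, pos_vec), used)
    }
    free <- function(chrom, strand, pos_vec) {
      key <- paste(chrom, strand)
      cur <- if (exists(key, used)) get(key, used) else numeric(0)
      !.too_close(pos_vec, cur, gap)
    }

    propose <- function(class) {
      # one placement attempt; returns NULL on rejection
      ti <- if (class %in% c("In", "Eex")) sample(multi, 1L)
            else sample(tx$tx_id, 1L)
      t <- tx[tx$tx_id == ti, ]
      te <- ex[ex$tx_id == ti, ]
      strand <- t$strand
      site_strand <- if (class == "An") setdiff(c("+", "-"), strand) else strand
      sat <- NA_integer_
      pos <- switch(class,
        Ex = {
          e <- te[sample(nrow(te), 1L), ]
          p <- sample(e$start:(e$end - 1L), 1L)
          if (abs(p - t$tes) < DI_SAFE_GAP) return(NULL)
          p
        },
        Di = {
          off <- sample(0:8, 1L)
          if (strand == "+") t$tes - off else t$tes + off
        },
        Edi = {
          off <- sample(50:2000, 1L)
          if (strand == "+") t$tes + off else t$tes - off
        },
        In = {
          i <- sample(nrow(te) - 1L, 1L)
          sample((te$end[i] + 1L):(te$start[i + 1L] - 2L), 1L)
        },
        Eex = {
          if (strand == "+") {
            r <- .pick(which(te$exon_rank < nrow(te)))
            p <- te$end[r] - 1L - sample(0:3, 1L)
            sat <- te$end[r] + 9L + sample(0:5, 1L)
          } else {
            r <- .pick(which(te$exon_rank > 1L))
            p <- te$start[r] + sample(0:3, 1L)
            sat <- te$start[r] - 10L - sample(0:5, 1L)
          }
          p
        },
        An = {
          e <- te[sample(nrow(te), 1L), ]
          sample(e$start:(e$end - 1L), 1L)
        })
      pts <- c(pos, if (!is.na(sat)) sat)
      if (!free(t$chrom, site_strand, pts)) return(NULL)
      for (p in pts) {
        if (!.first_base_ok(genome, t$chrom, p, site_strand)) return(NULL)
      }
      register(t$chrom, site_strand, pts)
      data.frame(chrom = t$chrom, strand = site_strand, position = pos,
                 satellite = sat, gene_id = t$gene_id, tx_id = t$tx_id,
                 true_class = class, stringsAsFactors = FALSE)
    }

    for (class in CLASS_CODES) {
      for (i in seq_len(n_per_class[[class]])) {
        rec <- NULL
        for (try in seq_len(500L)) {
          rec <- propose(class)
          if (!is.null(rec)) break
        }
        if (is.null(rec)) {
          stop("could not place a ", class, " site after 500 attempts; ",
               "annotation too crowded for the requested site count",
               call. = FALSE)
        }
        k <- k + 1L
        recs[[k]] <- rec
      }
    }
    truth <- do.call(rbind, recs)
    if (is.null(truth)) {
      truth <- data.frame(chrom = character(0), strand = character(0),
                          position = integer(0), satellite = integer(0),
                          gene_id = character(0), tx_id = character(0),
                          true_class = character(0))
    }
    n <- nrow(truth)
    truth <- cbind(site_id = sprintf("site%04d", seq_len(n)), truth,
                   stringsAsFactors = FALSE)
    truth$base_mean <- rep(params$mean_count, n)
    truth$log2_effect <- 0
    n_de <- round(params$de_fraction * n)
    if (n_de > 0) {
      de <- sample(n, n_de)
      truth$log2_effect[de] <- params$log2_effect *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    truth$nb_dispersion <- params$nb_dispersion
    rownames(truth) <- NULL
    truth
  })
}

#' Per-sample expected counts implied by a truth table
#'
#' @param truth a truth data frame from \code{\link{plant_truth_sites}}.
#' @param params the matching \code{\link{sim_params}}.
#' @return sites x samples matrix of negative-binomial means (treated
#'   samples shifted by \code{2^log2_effect}).
#' @export
expected_counts <- function(truth, params) {
  design <- sim_design(params)
  mu <- outer(truth$base_mean, rep(1, nrow(design)))
  shift <- 2^truth$log2_effect
  mu[, design$condition == "treated"] <-
    mu[, design$condition == "treated", drop = FALSE] * shift
  dimnames(mu) <- list(truth$site_id, design$sample_id)
  mu
}

#' Sample design table for a simulation
#'
#' @param params a \code{\link{sim_params}} object.
#' @return data frame with columns sample_id, condition.
#' @export
sim_design <- function(params) {
  n <- params$n_per_condition
  data.frame(
    sample_id = c(sprintf("treated_%d", seq_len(n)),
                  sprintf("control_%d", seq_len(n))),
    condition = rep(c("treated", "control"), each = n),
    stringsAsFactors = FALSE)
}

# Draw NB counts (Poisson when dispersion == 0).
.rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate WTTS-seq-like reads from planted truth sites
#'
#' For every sample the per-site read count is drawn from
#' NB(mean = expected count, dispersion = \code{nb_dispersion}).  Each read
#' is first-strand cDNA: a poly-T prefix (uniform length in
#' \code{polyT_range}) followed by the reverse complement of the sense-strand
#' sequence reading from the site position into the transcript body,
#' truncated so the whole read is \code{read_length} nt.  A read from a
#' + strand site therefore aligns to the - strand with its 5' end at the
#' site, and vice versa.  Substitution errors (rate \code{error_rate}) hit
#' the genomic payload only, never the poly-T prefix.  Base qualities are
#' constant Q30, except that a \code{degrade_fraction} of reads is emitted
#' at uniform Q2 to exercise the quality filter.  Deterministic under
#' \code{params$seed}.
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param truth a truth table from \code{\link{plant_truth_sites}}.
#' @param params a \code{\link{sim_params}} object.
#' @param outdir if non-NULL, per-sample FASTQ files plus
#'   \code{truth_sites.tsv} and \code{design.tsv} are written there.
#' @return An object of class \code{wtts_sim}: list with \code{$reads}
#'   (per-sample data frames read_id/sequence/quality), \code{$design},
#'   \code{$truth}, \code{$expected} (NB mean matrix) and \code{$params}.
#' @export
simulate_reads <- function(genome, truth, params, outdir = NULL) {
  check(inherits(params, "sim_params"), "params must come from sim_params()")
  design <- sim_design(params)
  mu <- expected_counts(truth, params)
  qual_hi <- strrep(rawToChar(as.raw(33L + 30L)), params$read_length)
  qual_lo <- strrep(rawToChar(as.raw(33L + 2L)), params$read_length)

  # genomic payload for a site position, per poly-T length
  payload <- function(chrom, pos, strand, plen) {
    if (strand == "+") {
      s <- Biostrings::subseq(genome[[chrom]], pos - plen + 2L, pos + 1L)
      as.character(Biostrings::reverseComplement(s))
    } else {
      as.character(Biostrings::subseq(genome[[chrom]], pos + 1L, pos + plen))
    }
  }

  with_seed(params$seed + 3L, {
    tlens <- seq(params$polyT_range[1], params$polyT_range[2])
    # pre-compute payloads for every emitting position x poly-T length
    emit <- list()
    for (i in seq_len(nrow(truth))) {
      r <- truth[i, ]
      pls <- vapply(tlens, function(tl)
        payload(r$chrom, r$position, r$strand, params$read_length - tl),
        character(1))
      emit[[length(emit) + 1L]] <- list(site = i, pos = r$position, pl = pls)
      if (!is.na(r$satellite)) {
        pls <- vapply(tlens, function(tl)
          payload(r$chrom, r$satellite, r$strand, params$read_length - tl),
          character(1))
        emit[[length(emit) + 1L]] <- list(site = i, pos = r$satellite, pl = pls)
      }
    }
    has_sat <- !is.na(truth$satellite)

    reads <- setNames(vector("list", nrow(design)), design$sample_id)
    for (j in seq_len(nrow(design))) {
      n_sites <- nrow(truth)
      counts <- if (n_sites) .rcounts(n_sites, mu[, j], params$nb_dispersion)
                else integer(0)
      site_of <- integer(0); pos_of <- integer(0)
      for (i in seq_len(n_sites)) {
        n_i <- counts[i]
        if (n_i == 0) next
        n_sat <- if (has_sat[i]) floor(0.3 * n_i) else 0L
        site_of <- c(site_of, rep(i, n_i))
        pos_of <- c(pos_of, rep(truth$position[i], n_i - n_sat),
                    rep(truth$satellite[i], n_sat))
      }
      n_reads <- length(site_of)
      if (n_reads == 0) {
        reads[[j]] <- data.frame(read_id = character(0),
                                 sequence = character(0),
                                 quality = character(0))
        next
      }
      tl <- if (length(tlens) == 1L) rep(tlens, n_reads)
            else sample(tlens, n_reads, replace = TRUE)
      key <- paste(pos_of, tl)
      lut <- new.env(parent = emptyenv())
      for (e in emit) {
        for (ti in seq_along(tlens)) {
          assign(paste(e$pos, tlens[ti]), e$pl[ti], lut)
        }
      }
      body <- vapply(key, function(kk) get(kk, lut), character(1),
                     USE.NAMES = FALSE)
      if (params$error_rate > 0) {
        n_err <- rbinom(n_reads, nchar(body), params$error_rate)
        for (ri in which(n_err > 0)) {
          b <- strsplit(body[ri], "")[[1]]
          at <- sample(length(b), min(n_err[ri], length(b)))
          for (p in at) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
          body[ri] <- paste(b, collapse = "")
        }
      }
      seqs <- paste0(strrep("T", tl), body)
      qual <- rep(qual_hi, n_reads)
      if (params$degrade_fraction > 0) {
        n_lo <- round(params$degrade_fraction * n_reads)
        if (n_lo > 0) qual[sample(n_reads, n_lo)] <- qual_lo
      }
      reads[[j]] <- data.frame(
        read_id = sprintf("%s:%s:%d", truth$site_id[site_of],
                          design$sample_id[j], seq_len(n_reads)),
        sequence = seqs, quality = qual, stringsAsFactors = FALSE)
    }

    sim <- structure(list(reads = reads, design = design, truth = truth,
                          expected = mu, params = params),
                     class = "wtts_sim")
    if (!is.null(outdir)) write_sim(sim, outdir)
    sim
  })
}

#' @export
print.wtts_sim <- function(x, ...) {
  cat(sprintf("wtts_sim: %d site(s), %d sample(s), %d read(s)\n",
              nrow(x$truth), length(x$reads),
              sum(vapply(x$reads, nrow, integer(1)))))
  invisible(x)
}

#' Write a simulation to disk (FASTQ per sample, truth and design TSV)
#'
#' @param sim a \code{wtts_sim} object.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$reads)) {
    write_fastq(sim$reads[[s]], file.path(outdir, paste0(s, ".fastq")))
  }
  truth <- sim$truth
  exp_df <- as.data.frame(sim$expected)
  names(exp_df) <- paste0("expected_", colnames(sim$expected))
  write.table(cbind(truth, exp_df),
              file.path(outdir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$design, file.path(outdir, "design.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Simulate a site x sample count matrix directly
#'
#' Count-level companion to \code{\link{simulate_reads}} for calibrating the
#' differential-usage stage at scale: negative-binomial counts for
#' \code{n_sites} sites over an 8 + 8 (by default) two-condition design,
#' with baseline means drawn log-uniformly from \code{mean_range} and an
#' optional planted log2 shift on \code{n_de} randomly chosen sites
#' (random sign).
#'
#' @param n_sites number of sites (rows).
#' @param n_per_condition samples per condition.
#' @param dispersion NB dispersion \eqn{\alpha}; 0 gives Poisson counts.
#' @param mean_range range of baseline means (log-uniform draw).
#' @param n_de number of sites with a planted condition effect.
#' @param log2_effect absolute log2 effect for planted sites.
#' @param seed RNG seed.
#' @return list with \code{$counts} (integer matrix), \code{$condition}
#'   (character vector aligned with columns), \code{$mu} (baseline means),
#'   \code{$log2_effect} (per-site signed truth, 0 for nulls) and
#'   \code{$is_de} (logical).
#' @export
simulate_count_matrix <- function(n_sites = 2000L, n_per_condition = 8L,
                                  dispersion = 0.1,
                                  mean_range = c(20, 2000),
                                  n_de = 0L, log2_effect = 0,
                                  seed = 1L) {
  check(is_count(n_sites) && n_sites >= 1, "n_sites must be positive")
  check(n_de <= n_sites, "n_de cannot exceed n_sites")
  with_seed(seed, {
    condition <- rep(c("treated", "control"), each = n_per_condition)
    sample_id <- paste0(substr(condition, 1, 3), "_",
                        c(seq_len(n_per_condition), seq_len(n_per_condition)))
    mu <- 10^runif(n_sites, log10(mean_range[1]), log10(mean_range[2]))
    lfc <- numeric(n_sites)
    if (n_de > 0) {
      de <- sample(n_sites, n_de)
      lfc[de] <- log2_effect * sample(c(-1, 1), n_de, replace = TRUE)
    }
    counts <- matrix(0L, n_sites, length(condition),
                     dimnames = list(sprintf("site%05d", seq_len(n_sites)),
                                     sample_id))
    for (j in seq_along(condition)) {
      m <- if (condition[j] == "treated") mu * 2^lfc else mu
      counts[, j] <- .rcounts(n_sites, m, dispersion)
    }
    list(counts = counts, condition = condition, mu = mu,
         log2_effect = lfc, is_de = lfc != 0)
  })
}

#' Pseudo-clusters built directly from a truth table
#'
#' Bypasses reads entirely: turns every truth record into the cluster its
#' reads would ideally produce (representative at the planted position;
#' span extended to the satellite for extended-exonic sites).  Used to
#' check that planted geometry reproduces the intended class codes.
#'
#' @param truth a truth table from \code{\link{plant_truth_sites}}.
#' @return data frame with cluster_id, chrom, strand, representative,
#'   span_start, span_end.
#' @export
clusters_from_truth <- function(truth) {
  lo <- pmin(truth$position, truth$satellite, na.rm = TRUE)
  hi <- pmax(truth$position, truth$satellite, na.rm = TRUE)
  data.frame(cluster_id = truth$site_id, chrom = truth$chrom,
             strand = truth$strand, representative = truth$position,
             span_start = lo, span_end = hi, stringsAsFactors = FALSE)
}
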