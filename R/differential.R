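# Differential APA usage: median-of-ratios normalization, moment NB
# dispersion estimation with trend shrinkage, per-site Wald tests, BH
# correction, MAPQ filtering and the signed fold-change convention.

#' Differential-testing parameters
#'
#' @param alpha_raw raw p-value threshold used in summaries (default 0.01).
#' @param alpha_adj BH-adjusted threshold (default 0.1).
#' @param mapq_min minimum cluster mean mapping quality; sites strictly
#'   below are flagged and, when significant, removed (default 70; set to 0
#'   for data mapped with the built-in exact-match mapper, whose MAPQ is
#'   fixed at 60 by convention).
#' @param dispersion_floor lower bound on the NB dispersion (default 1e-8).
#' @param pseudocount added to both normalized means in fold changes so the
#'   ratio is defined at zero (default 0.5).
#' @return An object of class \code{de_params}.
#' @export
de_params <- function(alpha_raw = 0.01, alpha_adj = 0.1, mapq_min = 70,
                      dispersion_floor = 1e-8, pseudocount = 0.5) {
  check(is.numeric(alpha_raw) && alpha_raw > 0 && alpha_raw < 1,
        "alpha_raw must be in (0, 1)")
  check(is.numeric(alpha_adj) && alpha_adj > 0 && alpha_adj < 1,
        "alpha_adj must be in (0, 1)")
  check(is.numeric(mapq_min) && mapq_min >= 0, "mapq_min must be >= 0")
  check(is.numeric(dispersion_floor) && dispersion_floor > 0,
        "dispersion_floor must be positive")
  check(is.numeric(pseudocount) && pseudocount >= 0,
        "pseudocount must be non-negative")
  structure(list(alpha_raw = alpha_raw, alpha_adj = alpha_adj,
                 mapq_min = mapq_min, dispersion_floor = dispersion_floor,
                 pseudocount = pseudocount), class = "de_params")
}

#' Median-of-ratios size factors
#'
#' Classic DESeq-style normalization: the per-site reference is the
#' geometric mean of its counts across samples, computed over sites with
#' strictly positive counts in every sample; each sample's size factor is
#' the median over those sites of count/reference.
#'
#' @param counts sites x samples matrix of non-negative counts.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
#' median_of_ratios(m)  # c(1/sqrt(2), sqrt(2))
#' @export
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  check(is.numeric(counts) && all(counts >= 0),
        "counts must be a non-negative numeric matrix")
  check(ncol(counts) >= 2, "at least two samples required")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no site has nonzero counts in every sample; median-of-ratios is ",
         "undefined (consider a pseudo-reference)", call. = FALSE)
  }
  lg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(col) median(col / exp(lg)))
  check(all(sf > 0), "size factors must be positive")
  sf
}

#' Moment NB dispersion with trend shrinkage
#'
#' Per-site method-of-moments estimate on normalized counts with moments
#' pooled within conditions: \eqn{\hat\alpha = \max(floor, (s^2 - m)/m^2)}
#' where \eqn{s^2} is the pooled within-condition variance and \eqn{m} the
#' overall mean.  The raw estimates are then shrunk 50/50 toward a trend
#' fitted as \eqn{a + b/m} across sites (falling back to the median when
#' the fit is degenerate).  Fully deterministic.
#'
#' @param counts sites x samples count matrix.
#' @param size_factors from \code{\link{median_of_ratios}}.
#' @param condition character vector over samples (two levels).
#' @param dispersion_floor lower bound (default 1e-8).
#' @return numeric vector of per-site dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors, condition,
                                dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  check(length(size_factors) == ncol(counts),
        "one size factor per sample required")
  check(length(condition) == ncol(counts),
        "one condition label per sample required")
  lev <- unique(condition)
  check(length(lev) == 2, "exactly two conditions required")
  check(all(table(condition) >= 2), "at least 2 samples per condition")
  norm <- sweep(counts, 2, size_factors, "/")
  g1 <- condition == lev[1]; g2 <- condition == lev[2]
  n1 <- sum(g1); n2 <- sum(g2)
  v1 <- row_vars(norm[, g1, drop = FALSE])
  v2 <- row_vars(norm[, g2, drop = FALSE])
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m <- rowMeans(norm)
  raw <- (v - m) / m^2
  raw[!is.finite(raw)] <- dispersion_floor
  raw <- pmax(dispersion_floor, raw)
  trend <- .dispersion_trend(raw, m, dispersion_floor)
  pmax(dispersion_floor, 0.5 * raw + 0.5 * trend)
}

# Parametric trend alpha(m) = a + b/m fitted by least squares; median
# fallback when the design is degenerate (too few sites or constant mean).
.dispersion_trend <- function(raw, m, floor) {
  use <- is.finite(raw) & is.finite(m) & m > 0
  if (sum(use) >= 10 && length(unique(round(1 / m[use], 10))) >= 3) {
    fit <- tryCatch(lm(raw[use] ~ I(1 / m[use])), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(coef(fit)))) {
      tr <- coef(fit)[1] + coef(fit)[2] / m
      tr[!is.finite(tr)] <- median(raw[use])
      return(pmax(floor, tr))
    }
  }
  rep(pmax(floor, median(raw[use], na.rm = TRUE)), length(raw))
}

#' Per-site negative-binomial Wald test
#'
#' Fits per-condition means as averages of normalized counts and tests
#' \eqn{\log_2} fold change = 0 with a delta-method standard error from
#' the NB variance \eqn{\mu + \alpha\mu^2}:
#' \eqn{\mathrm{Var}(\bar K_c) = n_c^{-2}\sum_j (\mu_c/s_j + \alpha\mu_c^2)}
#' over the samples of condition c, propagated through the log.  The Wald
#' statistic is referred to the standard normal, two-sided.  All-zero
#' sites return p = 1 and zero fold change.
#'
#' @param counts sites x samples count matrix.
#' @param size_factors from \code{\link{median_of_ratios}}.
#' @param dispersion per-site NB dispersions.
#' @param condition character vector with levels \code{treated} and
#'   \code{control} (any two labels; the first of
#'   \code{treated_level} is the numerator).
#' @param treated_level label treated as the numerator condition
#'   (default \code{"treated"}).
#' @param pseudocount added inside the log ratio (default 0.5).
#' @return data frame: mean_treated, mean_control (normalized), log2_fc,
#'   se, stat, p_value.
#' @export
nb_wald_test <- function(counts, size_factors, dispersion, condition,
                         treated_level = "treated", pseudocount = 0.5) {
  counts <- as.matrix(counts)
  check(treated_level %in% condition,
        "treated_level absent from condition labels")
  lev <- unique(condition)
  check(length(lev) == 2, "exactly two conditions required")
  check(all(table(condition) >= 2), "at least 2 samples per condition")
  trt <- condition == treated_level
  ctl <- !trt
  norm <- sweep(counts, 2, size_factors, "/")
  mt <- rowMeans(norm[, trt, drop = FALSE])
  mc <- rowMeans(norm[, ctl, drop = FALSE])
  nt <- sum(trt); nc <- sum(ctl)
  # delta-method variance of each condition's normalized-count mean
  var_mt <- (mt * sum(1 / size_factors[trt])) / nt^2 + dispersion * mt^2 / nt
  var_mc <- (mc * sum(1 / size_factors[ctl])) / nc^2 + dispersion * mc^2 / nc
  pc <- pseudocount
  lfc <- log2((mt + pc) / (mc + pc))
  l2 <- log(2)^2
  se <- sqrt(var_mt / ((mt + pc)^2 * l2) + var_mc / ((mc + pc)^2 * l2))
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(stat)), 1)
  zero <- mt == 0 & mc == 0
  lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
  data.frame(mean_treated = mt, mean_control = mc, log2_fc = lfc,
             se = se, stat = stat, p_value = p, row.names = rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving by site.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  check(is.numeric(p) && all(p >= 0 & p <= 1, na.rm = TRUE),
        "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Signed fold change
#'
#' Reporting convention for two-condition comparisons: when the treated
#' mean is at least the control mean the fold change is the positive ratio
#' treated/control; otherwise it is minus the ratio control/treated.  A
#' pseudocount keeps the ratio defined at zero means; equal means give
#' +1.
#'
#' @param mean_treated,mean_control non-negative (normalized) means.
#' @param pseudocount added to both means (default 0.5).
#' @return numeric vector of signed fold changes.
#' @examples
#' signed_fold_change(8, 2, pseudocount = 0)   # +4
#' signed_fold_change(2, 8, pseudocount = 0)   # -4
#' @export
signed_fold_change <- function(mean_treated, mean_control,
                               pseudocount = 0.5) {
  check(all(mean_treated >= 0) && all(mean_control >= 0),
        "means must be non-negative")
  t <- mean_treated + pseudocount
  c <- mean_control + pseudocount
  ifelse(mean_treated >= mean_control, t / c, -(c / t))
}

#' MAPQ filter on differential results
#'
#' Flags every site with cluster mean MAPQ below \code{mapq_min}
#' (strictly less fails) and moves significant sites that fail to a
#' removed list.
#'
#' @param results data frame with p_adj and mean_mapq columns (as produced
#'   by \code{\link{run_de}}).
#' @param params a \code{\link{de_params}} object.
#' @return list with \code{$results} (flagged, \code{passed_mapq} column),
#'   \code{$removed} (significant failing sites) and \code{$n_removed}.
#' @export
mapq_filter <- function(results, params = de_params()) {
  check(all(c("p_adj", "mean_mapq") %in% names(results)),
        "results must have p_adj and mean_mapq")
  # sites without MAPQ information (e.g. a bare count matrix) pass only
  # when no MAPQ threshold is in force
  results$passed_mapq <- ifelse(is.na(results$mean_mapq),
                                params$mapq_min <= 0,
                                results$mean_mapq >= params$mapq_min)
  sig <- !is.na(results$p_adj) & results$p_adj < params$alpha_adj
  removed <- results[sig & !results$passed_mapq, , drop = FALSE]
  list(results = results, removed = removed, n_removed = nrow(removed))
}

#' Differential APA usage between two conditions
#'
#' Composition of the whole testing stage: median-of-ratios size factors,
#' moment dispersion estimation with trend shrinkage, per-site NB Wald
#' tests, BH adjustment, signed fold changes and the MAPQ filter.
#'
#' @param x an \code{apa_clusters} object (counts and mean MAPQ are taken
#'   from it) or a sites x samples count matrix.
#' @param condition character vector over samples with levels
#'   \code{treated}/\code{control} (see \code{treated_level}).
#' @param params a \code{\link{de_params}} object.
#' @param treated_level numerator condition label (default
#'   \code{"treated"}).
#' @param mean_mapq per-site mean MAPQ when \code{x} is a bare matrix
#'   (defaults to NA: every site passes only if \code{mapq_min} is 0).
#' @return An object of class \code{apa_de}: list with \code{$results}
#'   (site_id, raw and normalized means, log2_fc, signed_fc, dispersion,
#'   p_value, p_adj, mean_mapq, passed_mapq), \code{$summary} (n_sites,
#'   n_sig_raw at \code{alpha_raw}, n_sig_adj at \code{alpha_adj}, n_up,
#'   n_down among adjusted-significant sites that pass MAPQ,
#'   n_mapq_removed), \code{$size_factors} and \code{$removed}.
#' @export
run_de <- function(x, condition, params = de_params(),
                   treated_level = "treated", mean_mapq = NULL) {
  if (inherits(x, "apa_clusters")) {
    counts <- x$counts
    mean_mapq <- x$clusters$mean_mapq
  } else {
    counts <- as.matrix(x)
    if (is.null(mean_mapq)) mean_mapq <- rep(NA_real_, nrow(counts))
  }
  check(length(condition) == ncol(counts),
        "one condition label per sample required")
  check(length(unique(condition)) == 2 && treated_level %in% condition,
        "condition must have two levels including treated_level")
  check(all(table(condition) >= 1), "both conditions must be non-empty")

  sf <- median_of_ratios(counts)
  disp <- estimate_dispersion(counts, sf, condition,
                              dispersion_floor = params$dispersion_floor)
  wt <- nb_wald_test(counts, sf, disp, condition,
                     treated_level = treated_level,
                     pseudocount = params$pseudocount)
  trt <- condition == treated_level
  res <- data.frame(
    site_id = if (!is.null(rownames(counts))) rownames(counts)
              else sprintf("site%05d", seq_len(nrow(counts))),
    raw_mean_treated = rowMeans(counts[, trt, drop = FALSE]),
    raw_mean_control = rowMeans(counts[, !trt, drop = FALSE]),
    mean_treated = wt$mean_treated,
    mean_control = wt$mean_control,
    log2_fc = wt$log2_fc,
    signed_fc = signed_fold_change(wt$mean_treated, wt$mean_control,
                                   params$pseudocount),
    dispersion = disp,
    stat = wt$stat,
    p_value = wt$p_value,
    p_adj = bh_adjust(wt$p_value),
    mean_mapq = mean_mapq,
    stringsAsFactors = FALSE, row.names = NULL)
  mq <- mapq_filter(res, params)
  res <- mq$results
  sig_adj <- res$p_adj < params$alpha_adj & res$passed_mapq
  summary <- list(
    n_sites = nrow(res),
    n_sig_raw = sum(res$p_value < params$alpha_raw & res$passed_mapq),
    n_sig_adj = sum(sig_adj),
    n_up = sum(sig_adj & res$signed_fc > 0),
    n_down = sum(sig_adj & res$signed_fc < 0),
    n_mapq_removed = mq$n_removed)
  structure(list(results = res, summary = summary, size_factors = sf,
                 removed = mq$removed, params = params),
            class = "apa_de")
}

#' @export
print.apa_de <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("apa_de: %d site(s); %d significant at raw p < %g, ",
                     "%d at BH p < %g (%d up / %d down); %d removed by ",
                     "MAPQ\n"),
              s$n_sites, s$n_sig_raw, x$params$alpha_raw, s$n_sig_adj,
              x$params$alpha_adj, s$n_up, s$n_down, s$n_mapq_removed))
  invisible(x)
}

#' Write the differential table as TSV
#'
#' @param de an \code{apa_de} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  write.table(de$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
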