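# Class-code distribution summaries and chi-square comparison.

#' Tally class codes of up- vs down-regulated sites
#'
#' @param up,down character vectors of class codes (no NA) for the up- and
#'   down-regulated site sets.
#' @return data frame with one row per class code: n_up, prop_up, n_down,
#'   prop_down and prop_diff (down minus up).  Empty groups tally zeros
#'   with a warning.
#' @export
tally_classes <- function(up, down) {
  for (g in list(up, down)) {
    check(!anyNA(g), "class codes must not be NA; drop unassigned sites first")
    check(all(g %in% CLASS_CODES),
          "class codes must be among Ex, Di, Edi, Eex, In, An")
  }
  if (length(up) == 0) warning("empty up-regulated set: proportions are zero")
  if (length(down) == 0) warning("empty down-regulated set: proportions are zero")
  n_up <- as.integer(table(factor(up, levels = CLASS_CODES)))
  n_down <- as.integer(table(factor(down, levels = CLASS_CODES)))
  p_up <- if (length(up)) n_up / length(up) else rep(0, 6)
  p_down <- if (length(down)) n_down / length(down) else rep(0, 6)
  data.frame(class_code = CLASS_CODES, n_up = n_up, prop_up = p_up,
             n_down = n_down, prop_down = p_down,
             prop_diff = p_down - p_up, stringsAsFactors = FALSE)
}

#' Conventional vs non-conventional 2x2 table
#'
#' Conventional APA classes are Ex, Di and Edi; Eex, In and An are
#' non-conventional.  Rows are the up/down groups, columns the two
#' categories.
#'
#' @param tally a data frame from \code{\link{tally_classes}}.
#' @return 2x2 integer matrix with dimnames
#'   \code{list(c("up", "down"), c("conventional", "non_conventional"))}.
#' @export
conventional_table <- function(tally) {
  check(is.data.frame(tally) &&
          all(c("class_code", "n_up", "n_down") %in% names(tally)),
        "tally must come from tally_classes()")
  conv <- tally$class_code %in% CONVENTIONAL_CODES
  m <- matrix(c(sum(tally$n_up[conv]), sum(tally$n_up[!conv]),
                sum(tally$n_down[conv]), sum(tally$n_down[!conv])),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("up", "down"),
                              c("conventional", "non_conventional")))
  storage.mode(m) <- "integer"
  m
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic \eqn{\sum (O - E)^2 / E} with expected counts from the
#' row/column margins and the upper-tail chi-square p-value on
#' \eqn{(r-1)(c-1)} degrees of freedom.  No continuity correction by
#' default (exposed as a flag).  A zero margin makes the test undefined
#' and is an error; expected cells below 5 trigger a warning.
#'
#' @param table matrix of non-negative counts, at least 2x2.
#' @param correct apply the Yates continuity correction (2x2 only;
#'   default FALSE).
#' @return list with statistic, df, p_value, observed, expected.
#' @examples
#' chi_square(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))$statistic  # 20
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  check(is.numeric(table) && all(table >= 0) && all(dim(table) >= 2),
        "table must be a numeric matrix of non-negative counts, >= 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square test undefined: a row or column margin is zero",
         call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  if (any(ct$expected < 5)) {
    warning("expected count(s) below 5: chi-square approximation may be poor")
  }
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), observed = table,
       expected = ct$expected)
}

#' Category statistics for a differential result
#'
#' Convenience wrapper reproducing the class-distribution comparison:
#' splits significant sites into up/down by the sign of the signed fold
#' change, tallies the six class codes, and runs the chi-square test on
#' both the 2x2 conventional split and the full 6-class table (when
#' margins allow).
#'
#' @param de an \code{apa_de} object from \code{\link{run_de}}.
#' @param classified result of \code{\link{classify_all}} on the same
#'   clusters.
#' @param alpha significance threshold on \code{p_adj} (defaults to the
#'   \code{alpha_adj} used in the DE run).
#' @return list with \code{$tally}, \code{$conventional}
#'   (2x2 table), \code{$chisq_conventional}, \code{$chisq_full}
#'   (NULL when a margin is zero).
#' @export
category_stats <- function(de, classified, alpha = de$params$alpha_adj) {
  sites <- classified$sites
  res <- de$results
  m <- match(res$site_id, sites$cluster_id)
  code <- sites$class_code[m]
  sig <- res$p_adj < alpha & res$passed_mapq & !is.na(code)
  up <- code[sig & res$signed_fc > 0]
  down <- code[sig & res$signed_fc < 0]
  tally <- tally_classes(up, down)
  conv <- conventional_table(tally)
  chisq_conv <- if (all(rowSums(conv) > 0) && all(colSums(conv) > 0)) {
    chi_square(conv)
  } else NULL
  full <- rbind(up = tally$n_up, down = tally$n_down)
  colnames(full) <- tally$class_code
  nz <- colSums(full) > 0
  chisq_full <- if (all(rowSums(full) > 0) && sum(nz) >= 2) {
    chi_square(full[, nz, drop = FALSE])
  } else NULL
  list(tally = tally, conventional = conv,
       chisq_conventional = chisq_conv, chisq_full = chisq_full)
}
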