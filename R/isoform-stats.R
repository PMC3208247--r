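#' Isoform-level expression summary of one gene
#'
#' For each TSS group of the gene, averages the log2 values of that group's
#' unique probe sets per sample. When the gene has at least two TSS groups
#' with unique probe sets, the isoform ratio is the long-isoform value minus
#' the short-isoform value (log2 units), where "long" is the most 5' TSS
#' group (rank 1) and "short" the most 3'.
#'
#' @param probe_m transformed `ExpressionMatrix`.
#' @param ann probe-set annotation.
#' @param gene gene symbol.
#' @return An `IsoformSummary`: list with `gene`, `groups` (TSS group x
#'   sample matrix, rows in 5'->3' TSS order), and `ratio` (named per-sample
#'   vector, or NULL with fewer than 2 groups).
#' @export
isoform_expression <- function(probe_m, ann, gene) {
  stopifnot(inherits(probe_m, "ExpressionMatrix"))
  if (!probe_m$transformed) stop("isoform_expression expects log2 values")
  a <- ann[ann$gene == gene & ann$cls == "tss_unique" &
           ann$probeset_id %in% rownames(probe_m$values), , drop = FALSE]
  if (nrow(a) == 0)
    stop("gene ", gene, " has no tss_unique probe sets")
  grp <- factor(a$tss_group)
  v <- probe_m$values[a$probeset_id, , drop = FALSE]
  gm <- rowsum(v, grp) / as.vector(table(grp))
  # 5'->3' order encoded in the group id suffix (_tss<rank>)
  rank <- as.integer(sub(".*_tss(\\d+)$", "\\1", rownames(gm)))
  gm <- gm[order(rank), , drop = FALSE]
  ratio <- if (nrow(gm) >= 2) gm[1, ] - gm[nrow(gm), ] else NULL
  structure(list(gene = gene, groups = gm, ratio = ratio),
            class = "IsoformSummary")
}

.group_values <- function(values, sheet, group) {
  sheet <- validate_sample_sheet(sheet)
  ids <- sheet$sample_id[sheet$group == group]
  if (!all(ids %in% names(values)))
    stop("values must be named by sample id and cover group ", group)
  values[ids]
}

#' Two-group comparison of a per-sample statistic
#'
#' Two-sided Student t-test, equal variances by default (Welch by flag).
#' When both groups are constant the comparison is degenerate: p = 1 for
#' equal means, p = 0 otherwise, with `degenerate = TRUE`.
#'
#' @param values named per-sample numeric vector.
#' @param sheet sample sheet.
#' @param g1,g2 group labels; the estimate is mean(g2) - mean(g1).
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return list with `estimate`, `statistic`, `p`, `n1`, `n2`, `test`,
#'   `degenerate`.
#' @export
compare_groups <- function(values, sheet, g1, g2, var_equal = TRUE) {
  x <- .group_values(values, sheet, g1)
  y <- .group_values(values, sheet, g2)
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 samples")
  est <- mean(y) - mean(x)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(estimate = est, statistic = NA_real_,
                p = if (est == 0) 1 else 0,
                n1 = length(x), n2 = length(y),
                test = "unpaired_t", degenerate = TRUE))
  }
  tt <- stats::t.test(y, x, var.equal = var_equal)
  list(estimate = est, statistic = unname(tt$statistic), p = tt$p.value,
       n1 = length(x), n2 = length(y), test = "unpaired_t",
       degenerate = FALSE)
}

#' Paired within-patient shift
#'
#' Matches patients with one sample in each of `g1` and `g2`, counts how many
#' pairs increase from `g1` to `g2`, and runs a two-sided paired t-test on
#' the within-pair differences. Patients missing either member are excluded.
#'
#' @inheritParams compare_groups
#' @return list with `n_increase`, `n_pairs`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_shift <- function(values, sheet, g1, g2) {
  sheet <- validate_sample_sheet(sheet)
  s1 <- sheet[sheet$group == g1 & !is.na(sheet$patient_id), ]
  s2 <- sheet[sheet$group == g2 & !is.na(sheet$patient_id), ]
  pats <- intersect(s1$patient_id, s2$patient_id)
  dropped <- length(unique(c(s1$patient_id, s2$patient_id))) - length(pats)
  if (dropped > 0)
    message(dropped, " patient(s) without a complete pair were excluded")
  if (length(pats) < 2) stop("need at least 2 complete patient pairs")
  id1 <- stats::setNames(s1$sample_id, s1$patient_id)[pats]
  id2 <- stats::setNames(s2$sample_id, s2$patient_id)[pats]
  stopifnot(all(c(id1, id2) %in% names(values)))
  d <- values[id2] - values[id1]
  degenerate <- stats::sd(d) == 0
  p <- if (degenerate) {
    if (all(d == 0)) 1 else 0
  } else stats::t.test(d)$p.value
  list(n_increase = sum(d > 0), n_pairs = length(d), p = p,
       mean_diff = mean(d), degenerate = degenerate)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, for comparing the
#' array-derived statistic against an orthogonal measurement of the same
#' samples.
#'
#' @param x,y paired numeric vectors (>= 3 observations).
#' @return list with `estimate` (rho), `statistic`, `p`, `n`, `test`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
       p = ct$p.value, n = length(x), test = "spearman")
}
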