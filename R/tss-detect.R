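#' Detection thresholds for the filter cascade
#'
#' @param discovery_q BH-adjusted p-value threshold for the discovery stage
#'   (default 0.05).
#' @param stringent_q stricter BH threshold for the candidate stage
#'   (default 1e-6); must not exceed `discovery_q`.
#' @param si_threshold log2 splicing-index effect gate: a candidate needs at
#'   least one probe set with |delta SI| above this (default 0.5).
#' @param validation_q BH threshold applied within each validation cohort
#'   (default 0.05).
#' @return A `DetectionConfig` list.
#' @export
detection_config <- function(discovery_q = 0.05, stringent_q = 1e-6,
                             si_threshold = 0.5, validation_q = 0.05) {
  stopifnot(stringent_q <= discovery_q, si_threshold > 0,
            discovery_q > 0, discovery_q <= 1, validation_q > 0,
            validation_q <= 1)
  structure(list(discovery_q = discovery_q, stringent_q = stringent_q,
                 si_threshold = si_threshold, validation_q = validation_q),
            class = "DetectionConfig")
}

#' Log2 splicing index
#'
#' SI(probe set, sample) = log2 probe-set value minus the log2 summarized
#' expression of the probe set's gene in that sample. Gene-level shifts
#' cancel, so nonzero SI contrasts reflect isoform-composition changes.
#'
#' @param probe_m transformed `ExpressionMatrix`.
#' @param gene_m `GeneExpressionMatrix` derived from `probe_m` (see
#'   [summarize_gene()]).
#' @param ann probe-set annotation.
#' @return A `SplicingIndexMatrix`: list with `values` (probe set x sample
#'   matrix of SI values) and `gene` (named vector mapping probe set to gene).
#' @export
splicing_index <- function(probe_m, gene_m, ann) {
  stopifnot(inherits(probe_m, "ExpressionMatrix"),
            inherits(gene_m, "GeneExpressionMatrix"))
  if (!probe_m$transformed) stop("splicing_index expects log2 values")
  ann <- ann[ann$cls != "unmapped", , drop = FALSE]
  ann <- ann[ann$probeset_id %in% rownames(probe_m$values), , drop = FALSE]
  has_gene <- ann$gene %in% rownames(gene_m$values)
  if (!all(has_gene))
    warning(sum(!has_gene), " probe set(s) excluded: gene has no summarized value")
  ann <- ann[has_gene, , drop = FALSE]
  stopifnot(identical(colnames(probe_m$values), colnames(gene_m$values)))
  si <- probe_m$values[ann$probeset_id, , drop = FALSE] -
    gene_m$values[ann$gene, , drop = FALSE]
  rownames(si) <- ann$probeset_id
  structure(list(values = si,
                 gene = stats::setNames(ann$gene, ann$probeset_id)),
            class = "SplicingIndexMatrix")
}

#' @export
print.SplicingIndexMatrix <- function(x, ...) {
  cat(sprintf("SplicingIndexMatrix: %d probe sets, %d genes, %d samples\n",
              nrow(x$values), length(unique(x$gene)), ncol(x$values)))
  invisible(x)
}

# Interaction F for one gene: two-way fixed-effects ANOVA of SI on
# group (normal/tumor) and probe set, partial F for group:probeset.
# The design is fully crossed with proportional cell counts (every sample
# measures every probe set), so the orthogonal sums-of-squares decomposition
# with weighted means is exact.
.interaction_F <- function(Y, tumor, eps = 1e-12) {
  P <- nrow(Y); N <- ncol(Y)
  n1 <- sum(!tumor); n2 <- sum(tumor)
  M1 <- rowMeans(Y[, !tumor, drop = FALSE])
  M2 <- rowMeans(Y[, tumor, drop = FALSE])
  rss <- sum((Y[, !tumor, drop = FALSE] - M1)^2) +
         sum((Y[, tumor, drop = FALSE] - M2)^2)
  m_p <- (n1 * M1 + n2 * M2) / N        # probe-set means, sample-weighted
  mg1 <- mean(M1); mg2 <- mean(M2)      # group means
  grand <- (n1 * mg1 + n2 * mg2) / N
  ss_int <- n1 * sum((M1 - mg1 - m_p + grand)^2) +
            n2 * sum((M2 - mg2 - m_p + grand)^2)
  df1 <- P - 1
  df2 <- N * P - 2 * P
  scale <- max(sum(Y^2), 1)
  if (ss_int <= eps * scale) {          # no interaction signal at all
    return(list(F = 0, p = 1, df1 = df1, df2 = df2, degenerate = FALSE))
  }
  if (rss <= eps * scale) {             # interaction without residual noise
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, degenerate = TRUE))
  }
  Fval <- (ss_int / df1) / (rss / df2)
  list(F = Fval, p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

#' Per-gene splicing ANOVA
#'
#' For each gene, tests the group-by-probe-set interaction in the two-way
#' fixed-effects model `SI ~ group + probeset + group:probeset`, contrasting
#' normal against the pooled tumor stratum. With P probe sets and N samples
#' the partial F statistic has (P - 1, N*P - 2*P) degrees of freedom. Genes
#' with interaction signal but zero residual variance (possible in noise-free
#' synthetic data) report p = 0 with `degenerate = TRUE`.
#'
#' @param si a `SplicingIndexMatrix`.
#' @param sheet sample sheet defining the normal/tumor contrast.
#' @return data.frame with columns `gene`, `F`, `p`, `df1`, `df2`,
#'   `degenerate`; one row per gene with >= 2 probe sets.
#' @export
splicing_anova <- function(si, sheet) {
  stopifnot(inherits(si, "SplicingIndexMatrix"))
  sheet <- validate_sample_sheet(sheet)
  stopifnot(all(sheet$sample_id %in% colnames(si$values)))
  v <- si$values[, sheet$sample_id, drop = FALSE]
  tumor <- is_tumor(sheet)
  if (sum(tumor) < 2 || sum(!tumor) < 2)
    stop("each stratum needs at least 2 samples")
  rows_by_gene <- split(seq_len(nrow(v)), si$gene)
  rows_by_gene <- rows_by_gene[lengths(rows_by_gene) >= 2]
  res <- lapply(names(rows_by_gene), function(g) {
    f <- .interaction_F(v[rows_by_gene[[g]], , drop = FALSE], tumor)
    data.frame(gene = g, F = f$F, p = f$p, df1 = f$df1, df2 = f$df2,
               degenerate = f$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (delegated to \code{stats::p.adjust}): monotone,
#' each at least its raw p, capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Per-probe-set tumor-minus-normal SI difference
#'
#' @param si a `SplicingIndexMatrix`.
#' @param sheet sample sheet.
#' @return Named numeric vector (probe set -> mean SI(tumor) - mean SI(normal)).
#' @export
delta_si <- function(si, sheet) {
  stopifnot(inherits(si, "SplicingIndexMatrix"))
  sheet <- validate_sample_sheet(sheet)
  v <- si$values[, sheet$sample_id, drop = FALSE]
  tumor <- is_tumor(sheet)
  rowMeans(v[, tumor, drop = FALSE]) - rowMeans(v[, !tumor, drop = FALSE])
}

#' Full per-gene test results
#'
#' Runs [splicing_anova()], BH-adjusts the p-values, and attaches per-probe-set
#' delta-SI summaries.
#'
#' @inheritParams splicing_anova
#' @return A `GeneTestResults` list: `table` (data.frame gene, F, p, q,
#'   max_abs_delta_si, degenerate) and `delta_si` (named per-probe-set vector).
#' @export
test_splicing <- function(si, sheet) {
  an <- splicing_anova(si, sheet)
  an$q <- bh_adjust(an$p)
  d <- delta_si(si, sheet)
  max_abs <- vapply(split(abs(d), si$gene[names(d)]), max, numeric(1))
  an$max_abs_delta_si <- unname(max_abs[an$gene])
  structure(list(table = an[, c("gene", "F", "p", "q", "max_abs_delta_si",
                                "degenerate")],
                 delta_si = d, gene = si$gene),
            class = "GeneTestResults")
}

#' Two-tier filter cascade
#'
#' Stage `discovery` requires q below `discovery_q`; stage `stringent`
#' additionally requires q below `stringent_q` and at least one probe set
#' with |delta SI| above `si_threshold`. Everything else is `filtered_out`.
#'
#' @param results a `GeneTestResults` (or its `table` data.frame with columns
#'   `gene`, `q`, `max_abs_delta_si`).
#' @param cfg a [detection_config()].
#' @return data.frame of candidate calls: `gene`, `stage`, `cls`
#'   (`"NONE"` until classified), `tumor_preferred_tss`.
#' @export
filter_cascade <- function(results, cfg = detection_config()) {
  tab <- if (inherits(results, "GeneTestResults")) results$table else results
  stopifnot(all(c("gene", "q", "max_abs_delta_si") %in% names(tab)))
  stage <- rep("filtered_out", nrow(tab))
  disc <- tab$q < cfg$discovery_q
  stage[disc] <- "discovery"
  stage[disc & tab$q < cfg$stringent_q &
          tab$max_abs_delta_si > cfg$si_threshold] <- "stringent"
  data.frame(gene = tab$gene, stage = stage, cls = "NONE",
             tumor_preferred_tss = NA_character_,
             supporting_probesets = NA_character_,
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Classify stringent candidates as alternative TSS vs alternative splicing
#'
#' Replaces manual genome-browser curation with a positional rule. A
#' candidate is `ALT_TSS` when every probe set whose |delta SI| exceeds the
#' threshold is TSS-unique, no shared probe set exceeds the threshold, and at
#' least one TSS group's mean delta SI is above `+si_threshold` (that group
#' is recorded as the tumor-preferred TSS). It is `ALT_SPLICING` when the
#' differential probe sets are exclusively internal (cassette-exon-like), and
#' `AMBIGUOUS` otherwise. Calls that pass classification move to stage
#' `classified`.
#'
#' @param calls output of [filter_cascade()].
#' @param results the `GeneTestResults` the calls came from.
#' @param ann probe-set annotation.
#' @param cfg a [detection_config()].
#' @return `calls` with `stage`, `cls`, `tumor_preferred_tss`,
#'   `supporting_probesets` and `reason` filled in for stringent genes.
#' @export
classify_alt_tss <- function(calls, results, ann, cfg = detection_config()) {
  stopifnot(inherits(results, "GeneTestResults"))
  d_all <- results$delta_si
  thr <- cfg$si_threshold
  ann <- ann[ann$cls != "unmapped", , drop = FALSE]
  for (i in which(calls$stage == "stringent")) {
    g <- calls$gene[i]
    a <- ann[ann$gene == g & ann$probeset_id %in% names(d_all), , drop = FALSE]
    d <- d_all[a$probeset_id]
    diff_ps <- abs(d) > thr
    calls$stage[i] <- "classified"
    if (!any(a$cls == "tss_unique")) {
      calls$cls[i] <- "AMBIGUOUS"
      calls$reason[i] <- "no tss_unique probe sets annotated"
      next
    }
    if (!any(diff_ps)) {
      calls$cls[i] <- "AMBIGUOUS"
      calls$reason[i] <- "no probe set exceeds the SI threshold"
      next
    }
    calls$supporting_probesets[i] <- paste(a$probeset_id[diff_ps],
                                           collapse = ",")
    if (all(a$cls[diff_ps] == "internal_unique")) {
      calls$cls[i] <- "ALT_SPLICING"
      next
    }
    tss_uniq <- a$cls == "tss_unique"
    grp_mean <- tapply(d[tss_uniq], a$tss_group[tss_uniq], mean)
    cond_a <- all(a$cls[diff_ps] == "tss_unique")
    cond_c <- all(abs(d[a$cls == "shared"]) <= thr)
    cond_d <- length(grp_mean) > 0 && any(grp_mean > thr)
    if (cond_a && cond_c && cond_d) {
      calls$cls[i] <- "ALT_TSS"
      calls$tumor_preferred_tss[i] <- names(grp_mean)[which.max(grp_mean)]
    } else {
      calls$cls[i] <- "AMBIGUOUS"
      calls$reason[i] <- "differential signal not confined to one TSS group"
    }
  }
  calls
}

#' Confirm candidates in independent validation cohorts
#'
#' A classified `ALT_TSS` candidate is confirmed when, in at least one
#' validation cohort, its splicing-ANOVA q-value (BH across the candidates
#' tested in that cohort) is below `validation_q`, some probe set exceeds the
#' SI threshold, and the tumor-preferred TSS group's mean delta SI is again
#' positive (same direction as in discovery).
#'
#' @param calls classified calls (see [classify_alt_tss()]).
#' @param validation one cohort `list(si = , sheet = )` or a list of such
#'   cohorts; each `si` a `SplicingIndexMatrix` from samples disjoint from
#'   the discovery cohort.
#' @param ann probe-set annotation.
#' @param cfg a [detection_config()].
#' @return `calls` with logical `confirmed` and `reason` columns.
#' @export
validate_candidates <- function(calls, validation, ann,
                                cfg = detection_config()) {
  if (!is.null(validation$si)) validation <- list(validation)
  cand <- which(calls$cls == "ALT_TSS")
  calls$confirmed <- NA
  calls$confirmed[cand] <- FALSE
  if (length(cand) == 0) return(calls)
  ann <- ann[ann$cls != "unmapped", , drop = FALSE]
  reasons <- rep("not significant in any validation set", length(cand))
  for (v in validation) {
    vsi <- v$si; vsheet <- validate_sample_sheet(v$sheet)
    genes <- calls$gene[cand]
    present <- genes %in% vsi$gene
    unmeasured <- !present & !(calls$confirmed[cand] %in% TRUE) &
      reasons == "not significant in any validation set"
    reasons[unmeasured] <- "not measured"
    if (!any(present)) next
    keep <- names(vsi$gene)[vsi$gene %in% genes[present]]
    sub <- structure(list(values = vsi$values[keep, , drop = FALSE],
                          gene = vsi$gene[keep]),
                     class = "SplicingIndexMatrix")
    res <- test_splicing(sub, vsheet)
    tab <- res$table
    for (j in seq_along(cand)) {
      i <- cand[j]
      if (isTRUE(calls$confirmed[i])) next
      if (!present[j]) {
        if (reasons[j] == "not significant in any validation set")
          reasons[j] <- "not measured"
        next
      }
      row <- tab[tab$gene == calls$gene[i], ]
      grp_ps <- ann$probeset_id[ann$gene == calls$gene[i] &
                                !is.na(ann$tss_group) &
                                ann$tss_group == calls$tumor_preferred_tss[i]]
      grp_ps <- intersect(grp_ps, names(res$delta_si))
      same_sign <- length(grp_ps) > 0 && mean(res$delta_si[grp_ps]) > 0
      if (nrow(row) == 1 && row$q < cfg$validation_q &&
          row$max_abs_delta_si > cfg$si_threshold && same_sign) {
        calls$confirmed[i] <- TRUE
        reasons[j] <- NA_character_
      } else if (nrow(row) == 1 && !same_sign &&
                 row$q < cfg$validation_q &&
                 row$max_abs_delta_si > cfg$si_threshold) {
        reasons[j] <- "delta SI direction flipped in validation"
      }
    }
  }
  calls$reason[cand] <- ifelse(is.na(reasons), calls$reason[cand], reasons)
  calls
}
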