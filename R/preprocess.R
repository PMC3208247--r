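#' Probe-set expression matrix
#'
#' Thin container for a probe-set x sample matrix. Values are nonnegative
#' linear intensities until [stabilize_and_log()] sets `transformed = TRUE`,
#' after which they are log2 intensities with a floor of `log2(offset)`.
#'
#' @param values numeric matrix, rows = probe sets (unique rownames),
#'   columns = samples (colnames).
#' @param transformed logical; whether `values` are on the log2 scale.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, transformed = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique rownames (probe-set ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must have unique colnames (sample ids)")
  if (!transformed && any(values < 0))
    stop("negative entries in a linear-intensity matrix")
  structure(list(values = values, transformed = transformed),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probe sets x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "log2" else "linear"))
  invisible(x)
}

#' Read a probe-set expression matrix from TSV
#'
#' Rows are probe sets (first column = probe-set id), remaining columns are
#' samples of linear intensities.
#'
#' @param path file path.
#' @return An untransformed [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, transformed = FALSE)
}

#' Write an expression matrix as TSV
#' @param m an `ExpressionMatrix` or `GeneExpressionMatrix`.
#' @param path output path.
#' @param id_col name of the id column (default `"probeset_id"`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_col = "probeset_id") {
  v <- m$values
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Tab-separated with columns `sample_id`, `group` and optionally
#' `patient_id`. Groups are `normal`, `adenoma`, `cancer_MSS`, `cancer_MSI`;
#' every non-normal group counts as tumor.
#'
#' @param path file path.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) df$patient_id <- NA_character_
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data.frame.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "group")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!"patient_id" %in% names(sheet)) sheet$patient_id <- NA_character_
  groups <- c("normal", "adenoma", "cancer_MSS", "cancer_MSI")
  if (!all(sheet$group %in% groups))
    stop("group must be one of: ", paste(groups, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample_id")
  paired <- sheet[!is.na(sheet$patient_id), ]
  if (nrow(paired) && anyDuplicated(paired[, c("patient_id", "group")]))
    stop("a patient_id may contribute at most one sample per group")
  sheet
}

#' Tumor samples of a sample sheet
#'
#' The tumor stratum pools adenomas and MSS/MSI carcinomas.
#' @param sheet sample sheet.
#' @return logical vector, TRUE for tumor samples.
#' @export
is_tumor <- function(sheet) sheet$group != "normal"

#' Quantile-normalize an expression matrix
#'
#' Makes every sample's intensity distribution identical: the value at each
#' rank becomes the mean of that rank's values across samples (delegated to
#' \code{limma::normalizeQuantiles(ties = FALSE)}). Applied before the log2
#' transform.
#'
#' @param m untransformed `ExpressionMatrix`.
#' @return Normalized `ExpressionMatrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$transformed) stop("quantile_normalize expects linear intensities")
  if (ncol(m$values) < 2) {
    warning("fewer than 2 samples; quantile normalization is a no-op")
    return(m)
  }
  v <- limma::normalizeQuantiles(m$values, ties = FALSE)
  dimnames(v) <- dimnames(m$values)
  expression_matrix(v, transformed = FALSE)
}

#' Variance-stabilizing offset-log2 transform
#'
#' Adds a pseudocount to linear intensities before the log2 transform,
#' `out = log2(in + offset)`. With the default offset of 16 the transformed
#' data have a floor of exactly 4.
#'
#' @param m untransformed `ExpressionMatrix`.
#' @param offset positive intensity offset (default 16).
#' @return Transformed `ExpressionMatrix` (`transformed = TRUE`).
#' @export
stabilize_and_log <- function(m, offset = 16) {
  stopifnot(offset > 0)
  if (is.numeric(m)) {            # convenience for scalar/vector use
    if (any(m < 0)) stop("negative intensity")
    return(log2(m + offset))
  }
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$transformed) stop("matrix is already on the log2 scale")
  if (any(m$values < 0)) stop("negative intensity")
  expression_matrix(log2(m$values + offset), transformed = TRUE)
}

#' Gene-level expression summary
#'
#' Summarizes each gene's log2 probe-set values (after tier filtering) into a
#' gene x sample matrix. With the default mean summarizer over core probe
#' sets, a gene's splicing-index values over those probe sets average to
#' exactly zero in every sample.
#'
#' @param m transformed `ExpressionMatrix`.
#' @param ann probe-set annotation from [annotate_probesets()].
#' @param tier_filter tiers whose probe sets enter the summary
#'   (default `"core"`).
#' @param summarizer `"mean"` or `"median"`.
#' @return A `GeneExpressionMatrix`: list with `values` (gene x sample log2
#'   matrix) and `summarizer`.
#' @export
summarize_gene <- function(m, ann, tier_filter = "core",
                           summarizer = c("mean", "median")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!m$transformed) stop("summarize_gene expects log2 values")
  summarizer <- match.arg(summarizer)
  stopifnot(all(tier_filter %in% c("core", "extended", "full")))

  ann <- ann[ann$cls != "unmapped", , drop = FALSE]
  known <- rownames(m$values) %in% ann$probeset_id
  if (!all(known))
    warning(sum(!known), " probe-set row(s) missing from the annotation were dropped")
  ann_use <- ann[ann$probeset_id %in% rownames(m$values) &
                 ann$tier %in% tier_filter, , drop = FALSE]
  if (nrow(ann_use) == 0) stop("no probe sets pass the tier filter")
  v <- m$values[ann_use$probeset_id, , drop = FALSE]
  g <- factor(ann_use$gene)
  vals <- if (summarizer == "mean") {
    rowsum(v, g) / as.vector(table(g))
  } else {
    out <- t(vapply(split(seq_len(nrow(v)), g),
                    function(i) apply(v[i, , drop = FALSE], 2, stats::median),
                    numeric(ncol(v))))
    dimnames(out) <- list(levels(g), colnames(v))
    out
  }
  dropped <- setdiff(unique(ann$gene), levels(g))
  if (length(dropped))
    message(length(dropped), " gene(s) had no probe set in tiers {",
            paste(tier_filter, collapse = ","), "} and were skipped")
  structure(list(values = vals, summarizer = summarizer),
            class = "GeneExpressionMatrix")
}

#' Above-background gene filter
#'
#' A gene is kept when, in at least `min_sample_frac` of the normal samples
#' and at least `min_sample_frac` of the tumor samples (adenomas and
#' carcinomas pooled), strictly more than `min_probe_frac` of its probe sets
#' exceed `bg_threshold` on the log2 scale.
#'
#' @param m transformed `ExpressionMatrix`.
#' @param sheet sample sheet (needs both normal and tumor samples).
#' @param ann probe-set annotation (gene to probe-set mapping).
#' @param bg_threshold log2 intensity above which a probe set counts as
#'   expressed (default 5.0).
#' @param min_probe_frac fraction of a gene's probe sets that must exceed the
#'   threshold, strictly (default 0.5).
#' @param min_sample_frac fraction of each stratum's samples in which the
#'   probe-set condition must hold (default 0.5).
#' @return Character vector of passing genes.
#' @export
background_filter <- function(m, sheet, ann, bg_threshold = 5,
                              min_probe_frac = 0.5, min_sample_frac = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!m$transformed) stop("background_filter expects log2 values")
  sheet <- validate_sample_sheet(sheet)
  tum <- is_tumor(sheet)
  if (!any(tum) || all(tum))
    stop("need both a normal and a tumor stratum")
  norm_ids <- sheet$sample_id[!tum]
  tum_ids <- sheet$sample_id[tum]
  stopifnot(all(c(norm_ids, tum_ids) %in% colnames(m$values)))

  ann <- ann[ann$cls != "unmapped" & ann$probeset_id %in% rownames(m$values), ]
  passes <- vapply(split(ann$probeset_id, ann$gene), function(ps) {
    above <- m$values[ps, , drop = FALSE] > bg_threshold
    frac_above <- colMeans(above)
    ok <- frac_above > min_probe_frac
    mean(ok[norm_ids]) >= min_sample_frac && mean(ok[tum_ids]) >= min_sample_frac
  }, logical(1))
  sort(names(passes)[passes])
}
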