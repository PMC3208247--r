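#' Run the full alternative-TSS detection screen
#'
#' Orchestrates the pipeline end to end: quantile normalization, offset-log2
#' transform, probe-set annotation, multi-TSS gene selection,
#' above-background filtering, gene summarization (core probe sets),
#' splicing-index computation, per-gene splicing ANOVA with BH correction,
#' the two-tier filter cascade, positional ALT_TSS/ALT_SPLICING
#' classification and, when validation cohorts are supplied, independent
#' confirmation. Inputs may be in-memory objects or file paths in the
#' package's TSV/BED12 formats. All result tables and a reproducibility
#' manifest are written to `out_dir` when given.
#'
#' @param models `GeneModelSet` or path to a BED12/GFF3 file.
#' @param probesets probe-set catalog data.frame or TSV path.
#' @param expr untransformed `ExpressionMatrix` or TSV path.
#' @param sheet sample sheet data.frame or TSV path.
#' @param cfg a [detection_config()].
#' @param validation optional list of `list(expr = , sheet = )` validation
#'   cohorts (untransformed matrices over the same probe sets).
#' @param bg_threshold above-background log2 threshold (default 5).
#' @param tier_filter tiers used for gene summarization (default `"core"`).
#' @param normalize quantile-normalize the intensities before the log2
#'   transform (default TRUE); set FALSE for matrices normalized upstream.
#' @param out_dir optional output directory for TSV reports and
#'   `manifest.json`.
#' @return list with `ann`, `results` (a `GeneTestResults`), `calls`,
#'   `si`, `gene_m`, `funnel` (named stage counts), `passing_genes`.
#' @export
run_detect <- function(models, probesets, expr, sheet,
                       cfg = detection_config(), validation = NULL,
                       bg_threshold = 5, tier_filter = "core",
                       normalize = TRUE, out_dir = NULL) {
  if (is.character(models)) models <- load_gene_models(models)
  if (is.character(probesets)) probesets <- load_probesets(probesets)
  if (is.character(expr)) expr <- read_expression_matrix(expr)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- validate_sample_sheet(sheet)

  prep <- function(e)
    stabilize_and_log(if (normalize) quantile_normalize(e) else e)
  log_m <- prep(expr)
  ann <- annotate_probesets(models, probesets)
  multi <- find_multi_tss_genes(models)
  ann_multi <- ann[ann$gene %in% multi & ann$cls != "unmapped", , drop = FALSE]
  message("multi-TSS genes: ", length(multi))
  with_data <- intersect(multi, unique(
    ann_multi$gene[ann_multi$probeset_id %in% rownames(log_m$values)]))
  message("with expression data: ", length(with_data))
  passing <- background_filter(log_m, sheet,
                               ann_multi[ann_multi$gene %in% with_data, ],
                               bg_threshold = bg_threshold)
  message("above background: ", length(passing))

  ann_use <- ann_multi[ann_multi$gene %in% passing, , drop = FALSE]
  log_use <- expression_matrix(
    log_m$values[rownames(log_m$values) %in% ann_use$probeset_id, ,
                 drop = FALSE], transformed = TRUE)
  gene_m <- summarize_gene(log_use, ann_use, tier_filter = tier_filter)
  si <- splicing_index(log_use, gene_m, ann_use)
  results <- test_splicing(si, sheet)
  calls <- filter_cascade(results, cfg)
  message("discovery (q < ", cfg$discovery_q, "): ",
          sum(calls$stage != "filtered_out"))
  message("stringent candidates: ", sum(calls$stage == "stringent"))
  calls <- classify_alt_tss(calls, results, ann_use, cfg)
  message("classified ALT_TSS: ", sum(calls$cls == "ALT_TSS"))

  if (!is.null(validation)) {
    vsets <- lapply(validation, function(v) {
      ve <- if (is.character(v$expr)) read_expression_matrix(v$expr) else v$expr
      vs <- if (is.character(v$sheet)) read_sample_sheet(v$sheet) else v$sheet
      vlog <- prep(ve)
      vlog <- expression_matrix(
        vlog$values[rownames(vlog$values) %in% ann_use$probeset_id, ,
                    drop = FALSE], transformed = TRUE)
      vgene <- summarize_gene(vlog, ann_use, tier_filter = tier_filter)
      list(si = splicing_index(vlog, vgene, ann_use), sheet = vs)
    })
    calls <- validate_candidates(calls, vsets, ann_use, cfg)
    message("confirmed in validation: ", sum(calls$confirmed %in% TRUE))
  }

  funnel <- c(multi_tss = length(multi), with_data = length(with_data),
              above_background = length(passing),
              discovery = sum(calls$stage != "filtered_out"),
              stringent = sum(calls$stage %in% c("stringent", "classified")),
              alt_tss = sum(calls$cls == "ALT_TSS"))
  out <- list(ann = ann_use, results = results, calls = calls, si = si,
              gene_m = gene_m, funnel = funnel, passing_genes = passing)
  if (!is.null(out_dir)) .write_detect_reports(out, cfg, out_dir)
  out
}

.write_detect_reports <- function(out, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- merge(out$results$table, out$calls, by = "gene", sort = TRUE)
  utils::write.table(tab, file.path(out_dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_annotation(out$ann, file.path(out_dir, "annotation.tsv"))
  dsi <- data.frame(probeset_id = names(out$results$delta_si),
                    gene = unname(out$results$gene[names(out$results$delta_si)]),
                    delta_si = unname(out$results$delta_si),
                    stringsAsFactors = FALSE)
  utils::write.table(dsi, file.path(out_dir, "delta_si.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "alttss",
    version = as.character(utils::packageVersion("alttss")),
    config = unclass(cfg),
    funnel = as.list(out$funnel))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the promoter motif-enrichment stage
#'
#' Foreground promoters belong to the tumor-preferred TSS groups of the
#' classified (and, when validation ran, confirmed) ALT_TSS candidates;
#' background promoters are those genes' other (normal-preferred) TSS
#' groups, optionally extended with a user-supplied background promoter set.
#' Enrichment is Fisher's exact test per motif, and enriched motifs are
#' crossed with the transcription factors' own differential expression.
#'
#' @param detect result of [run_detect()].
#' @param models the `GeneModelSet` used for detection.
#' @param genome `DNAStringSet` or FASTA path.
#' @param pwms list of [pwm()] objects or a JASPAR/MEME file path.
#' @param sheet sample sheet of the discovery cohort.
#' @param tf_map named character vector, motif -> TF gene symbol.
#' @param extra_background optional additional `PromoterSet` appended to the
#'   background.
#' @param alpha significance level (default 0.05).
#' @param out_dir optional output directory.
#' @return list with `fg`, `bg` (PromoterSets), `enrichment`, `tf_hits`.
#' @export
run_motif <- function(detect, models, genome, pwms, sheet, tf_map,
                      extra_background = NULL, alpha = 0.05,
                      out_dir = NULL) {
  if (is.character(pwms)) pwms <- read_pwms(pwms)
  if (length(pwms) == 0) stop("no PWMs supplied")
  sheet <- validate_sample_sheet(sheet)
  calls <- detect$calls
  cand <- calls[calls$cls == "ALT_TSS", , drop = FALSE]
  if ("confirmed" %in% names(calls) && any(cand$confirmed %in% TRUE))
    cand <- cand[cand$confirmed %in% TRUE, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no ALT_TSS candidates; empty enrichment result")
    return(list(fg = NULL, bg = NULL,
                enrichment = data.frame(), tf_hits = data.frame()))
  }
  grp <- tss_group_table(models)
  grp <- grp[grp$gene %in% cand$gene, , drop = FALSE]
  fg_grp <- grp[grp$tss_group %in% cand$tumor_preferred_tss, , drop = FALSE]
  bg_grp <- grp[!grp$tss_group %in% cand$tumor_preferred_tss, , drop = FALSE]
  fg <- extract_promoters(models, genome, fg_grp)
  bg <- extract_promoters(models, genome, bg_grp)
  if (!is.null(extra_background)) bg <- rbind(bg, extra_background)
  if (nrow(bg) == 0) stop("empty background promoter set")
  key <- function(p) paste(p$gene, p$tss_group)
  if (setequal(key(fg), key(bg)))
    stop("foreground and background promoter sets are identical")
  enrichment <- motif_enrichment(fg, bg, pwms)
  tf_hits <- cross_with_expression(enrichment, detect$gene_m, sheet, tf_map,
                                   alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tf_hits, file.path(out_dir, "tf_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fg = fg, bg = bg, enrichment = enrichment, tf_hits = tf_hits)
}

#' Simulate a study and run the detection screen on it
#'
#' Convenience wrapper used by the examples and the evaluation scripts:
#' generates models, catalog and expression with [simulate_gene_models()] /
#' [simulate_expression()], runs [run_detect()], and evaluates the calls
#' against the simulated truth.
#'
#' @param cfg a [simulation_config()].
#' @param det_cfg a [detection_config()].
#' @param out_dir optional output directory passed to [run_detect()].
#' @param ... further arguments passed to [run_detect()].
#' @return list with `sim`, `gm`, `detect`, `metrics`
#'   (from [evaluate_calls()]).
#' @export
simulate_and_detect <- function(cfg = simulation_config(),
                                det_cfg = detection_config(),
                                out_dir = NULL, ...) {
  gm <- simulate_gene_models(cfg)
  sim <- simulate_expression(gm$models, gm$probesets, cfg)
  detect <- suppressMessages(
    run_detect(gm$models, gm$probesets, sim$expr, sim$sheet,
               cfg = det_cfg, out_dir = out_dir, ...))
  list(sim = sim, gm = gm, detect = detect,
       metrics = evaluate_calls(detect$calls, sim$truth))
}
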