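#' Configuration of the synthetic exon-array study
#'
#' Defaults mirror a colorectal discovery cohort: 24 normal mucosa samples,
#' 49 adenomas, 35 carcinomas (30 microsatellite-stable, 5 unstable), with
#' 23 patients contributing both a normal and a tumor sample. Each simulated
#' gene has two isoforms sharing their downstream exons: a long isoform from
#' an upstream TSS and a short isoform from a downstream TSS with its own
#' first exon. The short isoform is the minor species in normal tissue
#' (`minor_offset` log2 units below baseline); in genes carrying a true
#' alternative-TSS event its log-abundance rises by `effect_delta_si` in
#' every tumor sample.
#'
#' @param seed integer seed driving all randomness.
#' @param n_genes number of simulated genes.
#' @param frac_alt_tss fraction of genes with a true alternative-TSS shift.
#' @param frac_alt_splicing fraction with a cassette-like shift on one
#'   internal shared exon instead.
#' @param frac_dark fraction of genes emitted wholly at background level
#'   (exercises the above-background filter).
#' @param n_normal,n_adenoma,n_cancer group sizes; `n_cancer_msi` of the
#'   carcinomas are labelled microsatellite-unstable.
#' @param n_pairs patients with both a normal and a tumor sample.
#' @param probesets_per_exon probe sets tiling each exon.
#' @param exons_shared,exons_unique_long,exons_unique_short exon counts.
#' @param effect_delta_si log2 shift of the tumor-preferred isoform.
#' @param minor_offset log2 units by which the short isoform sits below the
#'   long isoform in normal tissue.
#' @param probe_affinity_sd,sample_effect_sd,noise_sd log2-scale standard
#'   deviations of probe affinities, per-sample effects, and measurement
#'   noise.
#' @param background_mean log2 intensity of below-background probe sets.
#' @param baseline_abundance mean log2 intensity of the major isoform.
#' @param gene_abundance_sd log2 sd of per-gene baseline abundances around
#'   `baseline_abundance`; spreads genes over the broad intensity range real
#'   arrays show, which quantile normalization presupposes.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1, n_genes = 500,
                              frac_alt_tss = 0.1, frac_alt_splicing = 0.1,
                              frac_dark = 0.05,
                              n_normal = 24, n_adenoma = 49, n_cancer = 35,
                              n_cancer_msi = 5, n_pairs = 23,
                              probesets_per_exon = 1,
                              exons_shared = 3, exons_unique_long = 2,
                              exons_unique_short = 1,
                              effect_delta_si = 1.0, minor_offset = 2.5,
                              probe_affinity_sd = 0.25,
                              sample_effect_sd = 0.25, noise_sd = 0.25,
                              background_mean = 3, baseline_abundance = 10,
                              gene_abundance_sd = 1.5) {
  cfg <- as.list(environment())
  stopifnot(frac_alt_tss >= 0, frac_alt_splicing >= 0, frac_dark >= 0,
            frac_alt_tss + frac_alt_splicing + frac_dark <= 1,
            n_genes >= 1, n_normal >= 1, n_adenoma >= 1, n_cancer >= 1,
            n_cancer_msi >= 0, n_cancer_msi <= n_cancer, n_pairs >= 0,
            n_pairs <= n_normal, n_pairs <= n_adenoma + n_cancer,
            probesets_per_exon >= 1, exons_shared >= 1,
            exons_unique_long >= 1, exons_unique_short >= 1,
            effect_delta_si >= 0, minor_offset >= 0,
            probe_affinity_sd >= 0, sample_effect_sd >= 0, noise_sd >= 0,
            gene_abundance_sd >= 0)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate gene models and a probe-set catalog
#'
#' Each gene gets a long transcript (its own upstream first exons plus the
#' shared exons) and a short transcript (a distinct downstream TSS with its
#' own first exon(s) plus the same shared exons). Strands alternate between
#' genes; exons are tiled by `probesets_per_exon` probe sets. Shared exons
#' are tier `core`, TSS-unique first exons tier `extended` (alternative
#' first exons typically carry lower-confidence array annotation), so the
#' gene-level summary rests on the shared (constitutive) exons.
#'
#' @param cfg a [simulation_config()].
#' @return list with `models` (a `GeneModelSet`) and `probesets` (catalog
#'   data.frame).
#' @export
simulate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  exon_len <- 120L; intron_len <- 80L; gene_gap <- 1000L
  el <- cfg$exons_unique_long; es <- cfg$exons_unique_short
  sh <- cfg$exons_shared; ppe <- cfg$probesets_per_exon
  n_ex <- el + es + sh
  span <- n_ex * (exon_len + intron_len)

  tx_rows <- list(); ex_rows <- list(); ps_rows <- list()
  offset <- 1000L
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  for (i in seq_len(cfg$n_genes)) {
    g <- sprintf("gene_%04d", i)
    strand <- strands[i]
    # roles in transcription order: long-unique, short-unique, shared
    roles <- c(rep("uL", el), rep("uS", es), rep("sh", sh))
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    starts <- offset + (seq_len(n_ex) - 1L) * (exon_len + intron_len)
    ex <- data.frame(start = starts, end = starts + exon_len,
                     role = roles[ord], stringsAsFactors = FALSE)
    ex$idx_in_role <- stats::ave(seq_len(n_ex), ex$role, FUN = seq_along)
    long_ex <- ex[ex$role != "uS", ]
    short_ex <- ex[ex$role != "uL", ]
    tx_rows[[length(tx_rows) + 1]] <- data.frame(
      transcript_id = paste0(g, c("_long", "_short")), gene = g,
      chrom = "chrS", strand = strand, coding = TRUE,
      stringsAsFactors = FALSE)
    ex_rows[[length(ex_rows) + 1]] <- data.frame(
      transcript_id = c(rep(paste0(g, "_long"), nrow(long_ex)),
                        rep(paste0(g, "_short"), nrow(short_ex))),
      start = c(long_ex$start, short_ex$start),
      end = c(long_ex$end, short_ex$end), stringsAsFactors = FALSE)
    # probe sets tile every exon
    for (j in seq_len(n_ex)) {
      w <- exon_len %/% ppe
      ps_start <- ex$start[j] + (seq_len(ppe) - 1L) * w
      ps_end <- c(ps_start[-1], ex$end[j])
      ps_rows[[length(ps_rows) + 1]] <- data.frame(
        probeset_id = sprintf("ps_%s_%s%d_%d", g, ex$role[j],
                              ex$idx_in_role[j], seq_len(ppe)),
        chrom = "chrS", start = ps_start, end = ps_end,
        tier = if (ex$role[j] == "sh") "core" else "extended",
        gene = g, role = ex$role[j], exon_index = ex$idx_in_role[j],
        stringsAsFactors = FALSE)
    }
    offset <- offset + span + gene_gap
  }
  models <- gene_model_set(do.call(rbind, tx_rows), do.call(rbind, ex_rows))
  probesets <- do.call(rbind, ps_rows)
  rownames(probesets) <- NULL
  list(models = models, probesets = probesets)
}

#' Simulate probe-set intensities with known truth
#'
#' Linear intensity of probe set p in sample s is
#' `2^(mu(p, s) + a_p + e_s + eps)` with probe affinity
#' `a_p ~ N(0, probe_affinity_sd)`, sample effect `e_s ~ N(0,
#' sample_effect_sd)` and noise `eps ~ N(0, noise_sd)`. TSS-unique probe sets
#' read their isoform's log2 abundance; shared probe sets read
#' `log2(2^long + 2^short)`, so shared-exon responses to an isoform switch
#' are attenuated by the mixing, exactly as on an array. Genes with a true
#' alternative-TSS event raise the short isoform by `effect_delta_si` in
#' every tumor sample; alternative-splicing genes shift one internal shared
#' exon instead; dark genes sit at `background_mean` throughout. Paired
#' patients share half of their sample-effect variance.
#'
#' @param models,catalog output of [simulate_gene_models()].
#' @param cfg the same [simulation_config()].
#' @return list with `expr` (untransformed `ExpressionMatrix`), `sheet`
#'   (sample sheet), `truth` (data.frame gene, truth_cls, true_effect,
#'   tumor_preferred_tss, dark).
#' @export
simulate_expression <- function(models, catalog, cfg, truth = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 10000L)
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))

  # --- sample sheet -------------------------------------------------------
  ids <- c(sprintf("N%02d", seq_len(cfg$n_normal)),
           sprintf("A%02d", seq_len(cfg$n_adenoma)),
           sprintf("C%02d", seq_len(cfg$n_cancer)))
  grp <- c(rep("normal", cfg$n_normal), rep("adenoma", cfg$n_adenoma),
           rep("cancer_MSS", cfg$n_cancer - cfg$n_cancer_msi),
           rep("cancer_MSI", cfg$n_cancer_msi))
  N <- length(ids)
  patient <- sprintf("P%03d", seq_len(N))
  if (cfg$n_pairs > 0) {
    # pair normals with adenomas first, then carcinomas
    tum_idx <- cfg$n_normal + seq_len(cfg$n_pairs)
    patient[tum_idx] <- patient[seq_len(cfg$n_pairs)]
  }
  sheet <- validate_sample_sheet(data.frame(
    sample_id = ids, group = grp, patient_id = patient,
    stringsAsFactors = FALSE))
  tumor <- is_tumor(sheet)

  # --- truth assignment ---------------------------------------------------
  if (!is.null(truth)) {
    stopifnot(identical(truth$gene, genes))
  } else {
  n_tss <- round(cfg$frac_alt_tss * cfg$n_genes)
  n_spl <- round(cfg$frac_alt_splicing * cfg$n_genes)
  n_dark <- round(cfg$frac_dark * cfg$n_genes)
  lab <- sample(c(rep("ALT_TSS", n_tss), rep("ALT_SPLICING", n_spl),
                  rep("DARK", n_dark),
                  rep("NULL", cfg$n_genes - n_tss - n_spl - n_dark)))
  truth <- data.frame(
    gene = genes,
    truth_cls = ifelse(lab == "DARK", "NULL", lab),
    true_effect = ifelse(lab %in% c("ALT_TSS", "ALT_SPLICING"),
                         cfg$effect_delta_si, 0),
    tumor_preferred_tss = ifelse(lab == "ALT_TSS",
                                 paste0(genes, "_tss2"), NA_character_),
    dark = lab == "DARK", stringsAsFactors = FALSE)
  }

  # --- sample effects (paired patients share half the variance) ----------
  u <- stats::rnorm(N, 0, cfg$sample_effect_sd / sqrt(2))
  shared_u <- tapply(seq_len(N), sheet$patient_id, identity)
  for (p in shared_u) if (length(p) > 1) u[p] <- u[p[1]]
  e_s <- u + stats::rnorm(N, 0, cfg$sample_effect_sd / sqrt(2))

  # --- probe signals ------------------------------------------------------
  base_g <- cfg$baseline_abundance +
    stats::rnorm(cfg$n_genes, 0, cfg$gene_abundance_sd)
  cat_by_gene <- split(catalog, catalog$gene)
  mats <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[i]
    ps <- cat_by_gene[[g]]
    P <- nrow(ps)
    a_p <- stats::rnorm(P, 0, cfg$probe_affinity_sd)
    if (truth$dark[i]) {
      mu <- matrix(cfg$background_mean, P, N)
    } else {
      L <- rep(base_g[i], N)
      S <- rep(base_g[i] - cfg$minor_offset, N)
      if (truth$truth_cls[i] == "ALT_TSS") S[tumor] <- S[tumor] + truth$true_effect[i]
      mixed <- log2(2^L + 2^S)
      mu <- matrix(0, P, N)
      mu[ps$role == "uL", ] <- matrix(L, sum(ps$role == "uL"), N, byrow = TRUE)
      mu[ps$role == "uS", ] <- matrix(S, sum(ps$role == "uS"), N, byrow = TRUE)
      mu[ps$role == "sh", ] <- matrix(mixed, sum(ps$role == "sh"), N,
                                      byrow = TRUE)
      if (truth$truth_cls[i] == "ALT_SPLICING") {
        # shift one internal shared exon (the middle one) in tumor samples
        target <- sort(unique(ps$exon_index[ps$role == "sh"]))
        target <- target[ceiling(length(target) / 2)]
        rows <- ps$role == "sh" & ps$exon_index == target
        mu[rows, tumor] <- mu[rows, tumor] + truth$true_effect[i]
      }
    }
    logval <- mu + a_p + matrix(e_s, P, N, byrow = TRUE) +
      matrix(stats::rnorm(P * N, 0, cfg$noise_sd), P, N)
    rownames(logval) <- ps$probeset_id
    mats[[i]] <- logval
  }
  vals <- 2^do.call(rbind, mats)
  colnames(vals) <- ids
  list(expr = expression_matrix(vals, transformed = FALSE),
       sheet = sheet, truth = truth)
}

#' Simulate a genome sequence for simulated gene models
#'
#' Random uniform-base sequence long enough to cover every model, optionally
#' with a motif consensus planted inside selected promoter windows (on the
#' gene's strand, centred in the upstream region), for exercising the
#' promoter-motif stage.
#'
#' @param models a `GeneModelSet` from [simulate_gene_models()].
#' @param cfg the [simulation_config()] (its seed drives the sequence).
#' @param plant optional list with `consensus` (character, ACGT) and
#'   `tss_groups` (character vector of TSS group ids to plant into).
#' @param upstream,downstream promoter window geometry (must match the later
#'   [extract_promoters()] call).
#' @return A `DNAStringSet` with one sequence per chromosome.
#' @export
simulate_genome <- function(models, cfg, plant = NULL,
                            upstream = 300, downstream = 100) {
  set.seed(cfg$seed + 20000L)
  chroms <- unique(models$transcripts$chrom)
  lens <- vapply(chroms, function(ch) {
    tx <- models$transcripts$transcript_id[models$transcripts$chrom == ch]
    max(models$exons$end[models$exons$transcript_id %in% tx]) + upstream + 100
  }, numeric(1))
  seqs <- lapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""))
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms
  if (!is.null(plant)) {
    grp <- tss_group_table(models)
    grp <- grp[grp$tss_group %in% plant$tss_groups, , drop = FALSE]
    cons <- Biostrings::DNAString(plant$consensus)
    for (i in seq_len(nrow(grp))) {
      # place the motif midway through the upstream half of the promoter
      pos_in_promoter <- floor(upstream / 2)
      if (grp$strand[i] == "+") {
        g_start <- grp$tss[i] - upstream + pos_in_promoter     # 0-based
        ins <- cons
      } else {
        g_end <- grp$tss[i] + upstream + 1 - pos_in_promoter   # 0-based excl
        g_start <- g_end - length(cons)
        ins <- Biostrings::reverseComplement(cons)
      }
      genome[[grp$chrom[i]]] <- Biostrings::replaceAt(
        genome[[grp$chrom[i]]],
        IRanges::IRanges(g_start + 1, g_start + length(cons)),
        as.character(ins))
    }
  }
  genome
}

#' Evaluate calls against simulated truth
#'
#' @param calls candidate calls (any stage).
#' @param truth truth table from [simulate_expression()].
#' @return list with `fdr` (false / all stringent-or-later calls; 0 when no
#'   calls, flagged via `n_stringent = 0`), `fdr_discovery` (same at the
#'   discovery stage), `power` (true ALT_TSS genes classified ALT_TSS / all
#'   true ALT_TSS genes), `miscall_alt_splicing` (true ALT_SPLICING genes
#'   called ALT_TSS), `confusion` (truth x call table), `n_discovery`,
#'   `n_stringent`.
#' @export
evaluate_calls <- function(calls, truth) {
  truth_of <- stats::setNames(truth$truth_cls, truth$gene)
  stopifnot(all(calls$gene %in% names(truth_of)))
  tcls <- truth_of[calls$gene]
  disc <- calls$stage %in% c("discovery", "stringent", "classified")
  str <- calls$stage %in% c("stringent", "classified")
  fdr_disc <- if (any(disc)) mean(tcls[disc] == "NULL") else 0
  fdr_str <- if (any(str)) mean(tcls[str] == "NULL") else 0
  is_alt <- truth$truth_cls == "ALT_TSS"
  called_alt <- calls$gene[calls$cls == "ALT_TSS"]
  power <- if (any(is_alt)) mean(truth$gene[is_alt] %in% called_alt) else NA_real_
  is_spl <- truth$truth_cls == "ALT_SPLICING"
  miscall <- if (any(is_spl)) mean(truth$gene[is_spl] %in% called_alt)
             else NA_real_
  call_of <- stats::setNames(calls$cls, calls$gene)
  confusion <- table(truth = truth$truth_cls,
                     call = factor(ifelse(truth$gene %in% names(call_of),
                                          call_of[truth$gene], "NONE"),
                                   levels = c("ALT_TSS", "ALT_SPLICING",
                                              "AMBIGUOUS", "NONE")))
  list(fdr = fdr_str, fdr_discovery = fdr_disc, power = power,
       miscall_alt_splicing = miscall, confusion = confusion,
       n_discovery = sum(disc), n_stringent = sum(str))
}

#' Write simulated data in the formats the pipeline reads
#'
#' @param sim output of [simulate_expression()].
#' @param gm output of [simulate_gene_models()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, gm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(gm$models, file.path(dir, "models.bed"))
  utils::write.table(gm$probesets[, c("probeset_id", "chrom", "start",
                                      "end", "tier", "gene")],
                     file.path(dir, "probesets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_matrix(sim$expr, file.path(dir, "expression.tsv"))
  utils::write.table(sim$sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
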